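test_that("mcc follows the closed form, with zero-marginal convention and
           flip symmetry", {
  expect_equal(mcc(list(tp = 10, tn = 10, fp = 0, fn = 0)), 1)
  expect_equal(mcc(list(tp = 0, tn = 0, fp = 10, fn = 10)), -1)
  # everything predicted active on a mixed truth set: a zero marginal
  expect_equal(mcc(list(tp = 8, fp = 12, tn = 0, fn = 0)), 0)
  expect_equal(round(mcc(list(tp = 6, fp = 2, tn = 5, fn = 3)), 2), 0.38)
  expect_error(mcc(list(tp = 0, fp = 0, tn = 0, fn = 0)), "empty")
  # flipping labels and predictions together leaves MCC unchanged
  withr::with_seed(4, for (i in 1:20) {
    c0 <- as.list(setNames(rmultinom(1, 40, rep(0.25, 4))[, 1],
                           c("tp", "fp", "tn", "fn")))
    flipped <- list(tp = c0$tn, fp = c0$fn, tn = c0$tp, fn = c0$fp)
    expect_equal(mcc(c0), mcc(flipped))
  })
})

test_that("bedroc rewards early enrichment, is monotone-invariant, and
           handles degenerate label sets", {
  # perfect ranking on a large, sparse-active list
  scores <- c(seq(2, 1, length.out = 100), seq(0.9, 0, length.out = 9900))
  labels <- c(rep("active", 100), rep("inactive", 9900))
  expect_equal(bedroc(scores, labels), 1, tolerance = 1e-3)
  # inverse-perfect ranking scores near zero
  expect_lt(bedroc(-scores, labels), 0.01)
  # invariant under strictly monotone transforms of the scores
  s <- withr::with_seed(8, runif(60))
  l <- rep(c("active", "inactive"), 30)
  expect_equal(bedroc(exp(5 * s), l), bedroc(s, l))
  expect_error(bedroc(s, rep("active", 60)), "both classes")
})

test_that("bedroc of random rankings matches the analytic expectation", {
  n_act <- 5L; n_tot <- 50L
  vals <- withr::with_seed(123, replicate(2000, {
    bedroc(runif(n_tot), sample(c(rep("active", n_act),
                                  rep("inactive", n_tot - n_act))))
  }))
  expect_lt(abs(mean(vals) - bedroc_random_expectation(n_act, n_tot, 20)),
            0.02)
})

test_that("bedroc at small alpha approaches rank-sum (AUC-like) behaviour", {
  withr::with_seed(21, for (i in 1:10) {
    sc <- runif(40)
    lb <- sample(c(rep("active", 12), rep("inactive", 28)))
    # brute-force pair-comparison oracle for the AUC
    auc <- mean(outer(sc[lb == "active"], sc[lb == "inactive"], ">"))
    expect_equal(roc_auc(sc, lb), auc)
    expect_equal(bedroc(sc, lb, alpha = 0.1), auc, tolerance = 0.05)
  })
})

test_that("random fill covers exactly the missing pairs, deterministically,
           at a balanced activity rate", {
  pairs <- expand.grid(compound_id = sprintf("C%03d", 1:100),
                       target_id = sprintf("T%02d", 1:100),
                       stringsAsFactors = FALSE)
  have <- make_predictions(pairs[1:500, ], score = rep(7, 500))
  filled <- fill_missing(have, pairs, seed = 7)
  expect_equal(nrow(filled), nrow(pairs))
  expect_identical(fill_missing(have, pairs, seed = 7), filled)
  expect_identical(fill_missing(have, pairs[1:500, ], seed = 7), have)
  added <- filled[filled$provenance == "random_fill", ]
  expect_equal(nrow(added), 9500L)
  expect_true(all(added$score >= 0 & added$score <= 1))
  expect_identical(added$predicted_class,
                   ifelse(added$score > 0.5, "active", "inactive"))
  # binomial 3-sigma bound on the active fraction
  expect_equal(mean(added$predicted_class == "active"), 0.5,
               tolerance = 0.02)
})

test_that("evaluate_predictions pools, averages per target, and reports the
           mean of the two views", {
  # two targets engineered to per-target MCC 1 and 0
  t1 <- data.frame(compound_id = sprintf("A%d", 1:20), target_id = "T1",
                   pchembl = rep(c(7.5, 5.5), 10))
  t2 <- data.frame(compound_id = sprintf("B%d", 1:20), target_id = "T2",
                   pchembl = rep(c(7.5, 5.5), 10))
  truth <- rbind(t1, t2)
  pred <- rbind(
    make_predictions(t1, score = rep(c(7.5, 5.5), 10)),       # perfect
    make_predictions(t2, score = rep(c(7.5, 5.5, 5.5, 7.5), 5)))  # coin-flip
  rep_ <- evaluate_predictions(pred, truth)
  expect_equal(rep_$mcc_per_target_mean, 0.5)
  expect_equal(rep_$reported_mcc, mean(c(rep_$mcc_pooled, 0.5)))
  expect_equal(rep_$sem_mcc,
               sd(c(rep_$mcc_pooled, rep_$mcc_per_target_mean)) / sqrt(2))
  expect_true(rep_$reported_bedroc >= 0 && rep_$reported_bedroc <= 1)
  # single-target set: pooled equals per-target, SEM 0
  rep1 <- evaluate_predictions(make_predictions(t1, rep(c(7.5, 5.5), 10)),
                               t1)
  expect_equal(rep1$mcc_pooled, rep1$mcc_per_target_mean)
  expect_equal(rep1$sem_mcc, 0)
  expect_error(evaluate_predictions(pred, truth[0, ]), "empty")
  expect_error(evaluate_predictions(pred[1:10, ], truth), "fill_missing")
})

test_that("fully random-filled predictions score near zero MCC and the
           random BEDROC expectation", {
  sim <- generate_synthetic(synthetic_config(n_targets = 5L,
                                             n_compounds = 500L,
                                             density = 1, seed = 6L))
  truth <- sim$records
  empty <- data.frame(compound_id = character(0), target_id = character(0),
                      score = numeric(0), predicted_class = character(0),
                      provenance = character(0))
  filled <- fill_missing(empty, truth, seed = 31)
  rep_ <- evaluate_predictions(filled, truth)
  expect_equal(rep_$reported_mcc, 0, tolerance = 0.1)
  n_act <- sum(truth$pchembl >= 6.5)
  expect_equal(rep_$bedroc_pooled,
               bedroc_random_expectation(n_act, nrow(truth)),
               tolerance = 0.1)
})

test_that("z-score ranking reproduces the published row summaries and sums
           to zero per experiment", {
  # four-experiment score vectors of the two reference methods, as printed
  nb10 <- c(-2.41, -2.22, -2.07, -0.67)
  dnn_pcm <- c(0.44, 0.98, 1.09, 1.33)
  expect_equal(round(method_score_vector("nb_10um", nb10)$average, 2), -1.84)
  expect_equal(round(method_score_vector("dnn_pcm", dnn_pcm)$average, 2), 0.96)
  expect_equal(round(method_score_vector("dnn_pcm", dnn_pcm)$sem, 2), 0.19)

  raw <- withr::with_seed(2, matrix(runif(36), 9, 4,
    dimnames = list(paste0("m", 1:9),
                    c("mcc_rand", "bed_rand", "mcc_temp", "bed_temp"))))
  rk <- zscore_rank(raw)
  expect_equal(colSums(rk$z), setNames(rep(0, 4), colnames(raw)),
               tolerance = 1e-9)
  expect_equal(apply(rk$z, 2, sd), setNames(rep(1, 4), colnames(raw)),
               tolerance = 1e-9)
  expect_equal(rk$summary$average, sort(rowMeans(rk$z), decreasing = TRUE),
               ignore_attr = TRUE)
  const <- raw; const[, 2] <- 0.5
  expect_error(zscore_rank(const), "zero across-method")
})

test_that("pairwise tests emit all four tests per method pair and flag
           degenerate cases instead of fabricating p values", {
  z <- rbind(a = c(1, 2, 3, 4), b = c(2, 3, 4, 5), c = c(0, 0, 0, 0),
             d = c(1, -1, 1, -1))
  out <- pairwise_tests(z)
  expect_equal(nrow(out), choose(4, 2) * 4)
  expect_setequal(unique(out$test), c("paired_t", "f_var", "wilcoxon", "ks"))
  # constant differences: paired t is degenerate
  ab_t <- out[out$method_a == "a" & out$method_b == "b" &
                out$test == "paired_t", ]
  expect_true(ab_t$degenerate)
  # zero-variance member: F test degenerate
  cd_f <- out[out$method_a == "c" & out$method_b == "d" &
                out$test == "f_var", ]
  expect_true(cd_f$degenerate)
  ok <- out[!out$degenerate, ]
  expect_true(all(ok$p_value >= 0 & ok$p_value <= 1))
  expect_error(pairwise_tests(z[1, , drop = FALSE]), "two methods")
})
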