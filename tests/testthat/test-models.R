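make_toy_classification <- function(n = 60, d = 8, seed = 2) {
  withr::with_seed(seed, {
    x <- matrix(rbinom(n * d, 1, 0.5), n, d,
                dimnames = list(NULL, paste0("bit_", seq_len(d) - 1L)))
    y <- ifelse(x[, 5] == 1, "active", "inactive")  # bit 5 decides
    list(x = x, y = y)
  })
}

test_that("baseline learners honour their printed hyperparameters and
           separate a linearly separable toy set", {
  toy <- make_toy_classification()
  rf <- train_baseline(model_config("rf", hyper = list(ntree = 100)),
                       toy$x, toy$y)
  pred <- ifelse(baseline_scores(rf, toy$x) > 0.5, "active", "inactive")
  expect_equal(mcc(confusion_counts(toy$y, pred)), 1)
  expect_equal(rf$fit$mtry, floor(0.3 * ncol(toy$x)))

  svm <- train_baseline(model_config("svm"), toy$x, toy$y)
  expect_equal(svm$fit$gamma, 1 / ncol(toy$x))
  expect_equal(svm$fit$cost, 1)

  lr <- train_baseline(model_config("lr"), toy$x, toy$y)
  sc <- baseline_scores(lr, toy$x)
  expect_gt(mean(sc[toy$y == "active"]), mean(sc[toy$y == "inactive"]))

  expect_error(train_baseline(model_config("rf"), toy$x,
                              rep("active", nrow(toy$x))), "single class")
})

test_that("multinomial naive Bayes ranks a decisive bit by its posterior", {
  toy <- make_toy_classification()
  nb <- train_baseline(model_config("nb"), toy$x, toy$y)
  with_bit <- toy$x; with_bit[, 5] <- 1L
  without <- toy$x; without[, 5] <- 0L
  expect_true(all(baseline_scores(nb, with_bit) >
                    baseline_scores(nb, without)))
  expect_true(all(baseline_scores(nb, toy$x) >= 0 &
                    baseline_scores(nb, toy$x) <= 1))
})

test_that("naive Bayes z-score background standardises per target and
           preserves within-target ranking", {
  fx <- small_benchmark_fixture()
  ds <- fx$dataset
  bits <- fx$features$compound
  cfg <- model_config("nb")
  nbz <- train_nb_zscore(cfg, ds$records, bits)
  preds <- nb_zscore_background(nbz, bits)
  for (tid in unique(preds$target_id)) {
    z <- preds$score[preds$target_id == tid]
    expect_equal(mean(z), 0, tolerance = 1e-9)
    expect_equal(sqrt(mean(z^2)), 1, tolerance = 1e-9)
  }
  # affine standardisation: ranking identical to raw scores
  tid <- preds$target_id[1]
  raw <- pcmbench:::.nb_llr(nbz$fits[[tid]], bits)
  expect_equal(order(preds$score[preds$target_id == tid]), order(raw))
  expect_identical(preds$predicted_class,
                   ifelse(preds$score > 0, "active", "inactive"))
})

test_that("z-standardisation arithmetic matches hand computation", {
  # raw scores {1,2,3} under population SD -> {-1.22, 0, 1.22}
  raw <- c(1, 2, 3)
  z <- (raw - mean(raw)) / sqrt(mean((raw - mean(raw))^2))
  expect_equal(z, c(-1.2247, 0, 1.2247), tolerance = 1e-4)
})

test_that("the learning-rate/momentum schedule interpolates linearly and
           monotonically between the printed endpoints", {
  cfg <- dnn_config()
  expect_equal(schedule(1, 2000, cfg),
               list(learning_rate = 0.005, momentum = 0.8))
  expect_equal(schedule(2000, 2000, cfg),
               list(learning_rate = 1e-4, momentum = 0.999))
  expect_equal(schedule(2, 3, cfg),
               list(learning_rate = 0.00255, momentum = 0.8995))
  lrs <- vapply(1:50, function(e) schedule(e, 50, cfg)$learning_rate,
                numeric(1))
  moms <- vapply(1:50, function(e) schedule(e, 50, cfg)$momentum,
                 numeric(1))
  expect_true(all(diff(lrs) < 0))
  expect_true(all(diff(moms) > 0))
  expect_error(schedule(0, 10), "outside")
  expect_error(schedule(11, 10), "outside")
})

test_that("masked loss averages observed cells only and matches an
           explicit-cell oracle on random sparse fixtures", {
  pred <- matrix(c(6.0, 7.0, 5.0), 1, 3)
  obs <- matrix(c(6.5, 7.0, NA), 1, 3)
  expect_equal(masked_multitask_loss(pred, obs), 0.125)
  expect_equal(masked_multitask_loss(pred, matrix(NA_real_, 1, 3)), 0)
  full <- matrix(rnorm(12), 3, 4)
  expect_equal(masked_multitask_loss(full + 0.5, full),
               mean((0.5)^2))
  withr::with_seed(17, for (i in 1:100) {
    p <- matrix(rnorm(30), 5, 6)
    o <- matrix(rnorm(30), 5, 6)
    o[sample(30, sample(0:29, 1))] <- NA
    cells <- which(!is.na(o), arr.ind = TRUE)
    oracle <- if (nrow(cells) == 0) 0 else
      mean(vapply(seq_len(nrow(cells)), function(k)
        (p[cells[k, 1], cells[k, 2]] - o[cells[k, 1], cells[k, 2]])^2,
        numeric(1)))
    expect_equal(masked_multitask_loss(p, o), oracle)
  })
})

test_that("network training is bit-reproducible at dropout 0 and recovers a
           noiseless linear map", {
  withr::with_seed(5, {
    x <- matrix(rnorm(200 * 6), 200, 6)
    w <- rnorm(6)
    y <- 6.5 + x %*% w
  })
  cfg <- dnn_config(hidden_layers = c(8, 4), hidden_dropout = 0,
                    max_epochs = 500, patience = 500, seed = 1)
  m1 <- train_dnn(cfg, x, y)
  m2 <- train_dnn(cfg, x, y)
  expect_identical(m1$layers, m2$layers)
  # evaluation RMSE on the internal split is well under the noise floor
  expect_lt(sqrt(min(m1$eval_curve)), 0.3)
  # held-out prediction agrees with the linear ground truth
  withr::with_seed(6, xt <- matrix(rnorm(50 * 6), 50, 6))
  expect_lt(sqrt(mean((predict(m1, xt) - (6.5 + xt %*% w))^2)), 0.5)
  expect_error(predict(m1, xt[, 1:3]), "features")
})

test_that("dropout training remains deterministic given the seed but
           differs across seeds", {
  withr::with_seed(9, {
    x <- matrix(rnorm(100 * 5), 100, 5)
    y <- rnorm(100, 6.5)
  })
  cfg <- dnn_config(hidden_layers = 8, hidden_dropout = 0.25,
                    max_epochs = 30, patience = 30, seed = 4)
  expect_identical(train_dnn(cfg, x, y)$layers, train_dnn(cfg, x, y)$layers)
  cfg2 <- cfg; cfg2$seed <- 5L
  expect_false(identical(train_dnn(cfg, x, y)$layers,
                         train_dnn(cfg2, x, y)$layers))
})

test_that("early stopping halts after `patience` non-improving epochs and
           keeps the best weights", {
  withr::with_seed(11, {
    x <- matrix(rnorm(60 * 4), 60, 4)
    y <- rnorm(60, 6.5)
  })
  # learning rate below the improvement tolerance: evaluation loss is
  # effectively frozen after epoch 1
  cfg <- dnn_config(hidden_layers = 4, hidden_dropout = 0,
                    lr_start = 1e-30, lr_end = 1e-31,
                    max_epochs = 100, patience = 5, seed = 2)
  m <- train_dnn(cfg, x, y)
  expect_lte(length(m$eval_curve), 6L)  # epoch 1 best + 5 patience
  expect_equal(m$best_epoch, which.min(m$eval_curve))
})

test_that("label permutation drives test MCC of the learners to chance", {
  fx <- default_benchmark_fixture()
  ds <- fx$dataset
  perm <- ds
  perm$records$pchembl <- withr::with_seed(77, sample(ds$records$pchembl))
  sp <- random_split(perm, seed = 5)
  for (alg in c("nb", "rf")) {
    cfg <- model_config(alg, "qsar_single", seed = 3,
                        hyper = list(ntree = 150))
    res <- suppressWarnings(
      benchmark_method(cfg, perm, sp, fx$features))
    expect_lt(abs(res$report$reported_mcc), 0.15)
  }
})
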