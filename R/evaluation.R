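#' Confusion counts from truth and predicted classes
#'
#' @param truth,predicted Character vectors of `"active"` / `"inactive"`.
#' @return List with `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_counts <- function(truth, predicted) {
  stopifnot(length(truth) == length(predicted))
  list(tp = sum(truth == "active" & predicted == "active"),
       fp = sum(truth == "inactive" & predicted == "active"),
       tn = sum(truth == "inactive" & predicted == "inactive"),
       fn = sum(truth == "active" & predicted == "inactive"))
}

#' Matthews correlation coefficient
#'
#' `(tp*tn - fp*fn) / sqrt((tp+fp)(tp+fn)(tn+fp)(tn+fn))`, computed in
#' floating point to avoid integer overflow. When any marginal of the
#' confusion matrix is zero the coefficient is defined as 0, consistent with
#' the convention that uninformative predictions score 0.
#'
#' @param counts A list with `tp`, `fp`, `tn`, `fn` (see
#'   [confusion_counts()]).
#' @return MCC in `[-1, 1]`.
#' @export
mcc <- function(counts) {
  tp <- as.numeric(counts$tp); fp <- as.numeric(counts$fp)
  tn <- as.numeric(counts$tn); fn <- as.numeric(counts$fn)
  if (tp + fp + tn + fn <= 0) stop("empty confusion matrix", call. = FALSE)
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (denom == 0) return(0)
  (tp * tn - fp * fn) / sqrt(denom)
}

#' BEDROC early-enrichment score
#'
#' Boltzmann-enhanced discrimination of ROC: ranks are weighted by a
#' decaying exponential so that early recognition of actives dominates. With
#' the default `alpha = 20` roughly 80% of the score comes from the top 8%
#' of the ranked list. Computed via the robust initial enhancement (RIE)
#' normalisation, giving a score in `[0, 1]`.
#'
#' Ties in `scores` are broken pessimistically (inactives ranked above
#' actives at equal score) to avoid optimistic bias.
#'
#' @param scores Numeric ranking scores, higher = more confidently active.
#' @param labels Truth labels, `"active"` / `"inactive"` (or logical actives).
#' @param alpha Early-recognition parameter (default 20).
#' @return BEDROC score in `[0, 1]`.
#' @export
bedroc <- function(scores, labels, alpha = 20) {
  if (is.logical(labels)) labels <- ifelse(labels, "active", "inactive")
  stopifnot(length(scores) == length(labels), alpha > 0)
  N <- length(scores)
  is_act <- labels == "active"
  n <- sum(is_act)
  if (n == 0L || n == N) {
    stop("BEDROC requires both classes among the labels", call. = FALSE)
  }
  ord <- order(-scores, is_act)  # ties: inactives first (worst case)
  ranks <- which(is_act[ord])
  Ra <- n / N
  s <- sum(exp(-alpha * ranks / N))
  rand_sum <- (n / N) * (1 - exp(-alpha)) / (exp(alpha / N) - 1)
  rie <- s / rand_sum
  rie * Ra * sinh(alpha / 2) /
    (cosh(alpha / 2) - cosh(alpha / 2 - alpha * Ra)) +
    1 / (1 - exp(alpha * (1 - Ra)))
}

#' Expected BEDROC of a random ranking
#'
#' Closed form obtained by setting the robust initial enhancement to its
#' random expectation of 1.
#'
#' @param n_actives,n_total Class sizes.
#' @param alpha Early-recognition parameter.
#' @return Expected BEDROC under random ordering.
#' @export
bedroc_random_expectation <- function(n_actives, n_total, alpha = 20) {
  Ra <- n_actives / n_total
  Ra * sinh(alpha / 2) / (cosh(alpha / 2) - cosh(alpha / 2 - alpha * Ra)) +
    1 / (1 - exp(alpha * (1 - Ra)))
}

#' Cumulative BEDROC weight of the top fraction of a ranked list
#'
#' The share of the total exponential rank weight carried by the top
#' `fraction` of an (infinitely long) ranked list:
#' `(1 - exp(-alpha * fraction)) / (1 - exp(-alpha))`. At `alpha = 20` the
#' top 8% carries about 80% of the weight.
#'
#' @param alpha Early-recognition parameter.
#' @param fraction Top fraction of the list.
#' @return Weight share in `[0, 1]`.
#' @export
bedroc_top_weight <- function(alpha = 20, fraction = 0.08) {
  (1 - exp(-alpha * fraction)) / (1 - exp(-alpha))
}

#' ROC AUC (convenience metric)
#'
#' Probability that a randomly chosen active outscores a randomly chosen
#' inactive, with ties counted half. Provided for cross-study comparison
#' only; the benchmark's primary metrics are MCC and BEDROC.
#'
#' @inheritParams bedroc
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  if (is.logical(labels)) labels <- ifelse(labels, "active", "inactive")
  act <- scores[labels == "active"]
  ina <- scores[labels == "inactive"]
  if (length(act) == 0L || length(ina) == 0L) {
    stop("AUC requires both classes among the labels", call. = FALSE)
  }
  r <- rank(c(act, ina))
  (sum(r[seq_along(act)]) - length(act) * (length(act) + 1) / 2) /
    (length(act) * length(ina))
}

#' Complete a prediction set by random filling
#'
#' Every required compound-target pair without a prediction receives a
#' uniform random score in (0, 1), classified active when the score exceeds
#' 0.5. This simulates honest prospective use: methods are compared on the
#' full pair set, and unpredicted pairs contribute chance-level performance
#' (MCC near 0) rather than being cherry-picked away.
#'
#' @param predictions Prediction-set data frame (`compound_id`, `target_id`,
#'   `score`, `predicted_class`, `provenance`), possibly with zero rows.
#' @param required_pairs Data frame with `compound_id`, `target_id` covering
#'   every pair to evaluate.
#' @param seed Integer seed; filling is deterministic given it.
#' @return Prediction set covering every required pair; filled rows carry
#'   `provenance = "random_fill"`.
#' @export
fill_missing <- function(predictions, required_pairs, seed) {
  req_key <- paste(required_pairs$compound_id, required_pairs$target_id,
                   sep = "\r")
  have_key <- if (nrow(predictions) > 0L)
    paste(predictions$compound_id, predictions$target_id, sep = "\r")
  else character(0)
  missing <- !(req_key %in% have_key)
  if (!any(missing)) return(predictions)
  fill <- with_seed(seed, {
    sc <- runif(sum(missing))
    data.frame(compound_id = required_pairs$compound_id[missing],
               target_id = required_pairs$target_id[missing],
               score = sc,
               predicted_class = ifelse(sc > 0.5, "active", "inactive"),
               provenance = "random_fill",
               stringsAsFactors = FALSE)
  })
  out <- rbind(predictions[, names(fill), drop = FALSE], fill)
  rownames(out) <- NULL
  out
}

#' Score a prediction set against measured truth
#'
#' Computes MCC and BEDROC twice: once pooled over all pairs, and once per
#' target averaged over the targets where the metric is defined (targets
#' whose truth is single-class are skipped and counted). The headline
#' reported value is the mean of the pooled and per-target figures, with the
#' SEM of those two values, mirroring how multi-target benchmarks summarise
#' the two complementary views.
#'
#' @param predictions Prediction set covering every truth pair (run
#'   [fill_missing()] first).
#' @param truth Data frame with `compound_id`, `target_id`, `pchembl`.
#' @param threshold pChEMBL activity threshold; truth classes are recomputed
#'   from `pchembl` here, never taken from stale columns.
#' @param alpha BEDROC early-recognition parameter.
#' @return A `metric_report` list: pooled and per-target MCC/BEDROC, the
#'   reported means and SEMs, and the number of skipped targets.
#' @export
evaluate_predictions <- function(predictions, truth, threshold = 6.5,
                                 alpha = 20) {
  if (nrow(truth) == 0L) stop("empty truth set", call. = FALSE)
  key <- function(d) paste(d$compound_id, d$target_id, sep = "\r")
  m <- match(key(truth), key(predictions))
  if (any(is.na(m))) {
    stop(sprintf("%d truth pair(s) lack predictions; run fill_missing()",
                 sum(is.na(m))), call. = FALSE)
  }
  pred <- predictions[m, , drop = FALSE]
  truth_class <- label_activity(truth$pchembl, threshold)

  mcc_pooled <- mcc(confusion_counts(truth_class, pred$predicted_class))
  bed_pooled <- bedroc(pred$score, truth_class, alpha)

  per <- split(seq_len(nrow(truth)), truth$target_id)
  mcc_t <- bed_t <- rep(NA_real_, length(per))
  for (i in seq_along(per)) {
    idx <- per[[i]]
    tc <- truth_class[idx]
    if (length(unique(tc)) < 2L) next  # metric undefined for one class
    mcc_t[i] <- mcc(confusion_counts(tc, pred$predicted_class[idx]))
    bed_t[i] <- bedroc(pred$score[idx], tc, alpha)
  }
  skipped <- sum(is.na(mcc_t))
  mcc_per <- mean(mcc_t, na.rm = TRUE)
  bed_per <- mean(bed_t, na.rm = TRUE)

  rep_mcc <- mean(c(mcc_pooled, mcc_per))
  rep_bed <- mean(c(bed_pooled, bed_per))
  structure(list(
    mcc_pooled = mcc_pooled, mcc_per_target_mean = mcc_per,
    bedroc_pooled = bed_pooled, bedroc_per_target_mean = bed_per,
    reported_mcc = rep_mcc, reported_bedroc = rep_bed,
    sem_mcc = sd(c(mcc_pooled, mcc_per)) / sqrt(2),
    sem_bedroc = sd(c(bed_pooled, bed_per)) / sqrt(2),
    alpha = alpha, threshold = threshold,
    n_pairs = nrow(truth), n_targets_skipped = skipped),
    class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf(paste0(
    "<metric_report> %d pairs\n",
    "  MCC    %.3f (+/- %.3f)  [pooled %.3f | per-target %.3f]\n",
    "  BEDROC %.3f (+/- %.3f)  [pooled %.3f | per-target %.3f] (alpha=%g)\n"),
    x$n_pairs, x$reported_mcc, x$sem_mcc, x$mcc_pooled, x$mcc_per_target_mean,
    x$reported_bedroc, x$sem_bedroc, x$bedroc_pooled,
    x$bedroc_per_target_mean, x$alpha))
  if (x$n_targets_skipped > 0L) {
    cat(sprintf("  (%d single-class target(s) skipped in per-target means)\n",
                x$n_targets_skipped))
  }
  invisible(x)
}
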