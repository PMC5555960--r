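#' Standardise method metrics to z-scores within each experiment
#'
#' Each experiment (e.g. random-split MCC, random-split BEDROC,
#' temporal-split MCC, temporal-split BEDROC) is a column; each method a
#' row. Within an experiment, a method's z-score is its metric minus the
#' across-method mean, divided by the across-method sample standard
#' deviation (n-1). Rows are then summarised by [method_score_vector()].
#'
#' @param scores Numeric matrix of raw metric values, methods in rows
#'   (rownames = method names), experiments in columns.
#' @return List with `z` (the z-score matrix) and `summary` (data frame of
#'   per-method average and SEM, sorted by average, descending).
#' @export
zscore_rank <- function(scores) {
  stopifnot(is.matrix(scores), nrow(scores) >= 3L)
  sds <- apply(scores, 2L, sd)
  if (any(sds == 0)) {
    stop("zero across-method standard deviation in experiment(s): ",
         paste(colnames(scores)[sds == 0], collapse = ", "), call. = FALSE)
  }
  z <- scale(scores, center = TRUE, scale = TRUE)
  attr(z, "scaled:center") <- NULL
  attr(z, "scaled:scale") <- NULL
  smry <- do.call(rbind, lapply(rownames(z), function(m)
    as.data.frame(method_score_vector(m, z[m, ]))))
  smry <- smry[order(-smry$average), , drop = FALSE]
  rownames(smry) <- NULL
  list(z = z, summary = smry)
}

#' Summarise a method's experiment z-scores
#'
#' The average is the mean of the z-scores; the SEM is their sample
#' standard deviation divided by the square root of the number of
#' experiments.
#'
#' @param method Method name.
#' @param z Numeric vector of z-scores, one per experiment (typically 4).
#' @return List with `method`, `z` and the `average` and `sem`.
#' @export
method_score_vector <- function(method, z) {
  stopifnot(length(z) >= 2L)
  list(method = method, average = mean(z), sem = sd(z) / sqrt(length(z)))
}

#' Pairwise statistical comparison of method score vectors
#'
#' For every unordered pair of methods, four two-sided tests are run on the
#' paired experiment z-scores: a paired Student's t test (do the means
#' differ), an F test (do the variances differ), a Wilcoxon test (do the
#' medians differ; rank-sum by default, signed-rank when
#' `wilcoxon = "signed-rank"`), and a two-sample Kolmogorov-Smirnov test (do
#' the samples come from the same distribution). Degenerate cases (zero
#' variance where a test needs one) are flagged rather than reported with a
#' spurious p value.
#'
#' @param z Z-score matrix, methods in rows, experiments in columns (same
#'   columns for every method).
#' @param wilcoxon `"rank-sum"` (default) or `"signed-rank"`.
#' @return Data frame with `method_a`, `method_b`, `test`, `statistic`,
#'   `p_value`, `degenerate`.
#' @export
pairwise_tests <- function(z, wilcoxon = c("rank-sum", "signed-rank")) {
  stopifnot(is.matrix(z))
  wilcoxon <- match.arg(wilcoxon)
  methods <- rownames(z)
  if (length(methods) < 2L) {
    stop("need at least two methods to compare", call. = FALSE)
  }
  rows <- list()
  for (i in seq_len(length(methods) - 1L)) {
    for (j in seq(i + 1L, length(methods))) {
      a <- z[i, ]; b <- z[j, ]
      rows[[length(rows) + 1L]] <- rbind(
        .test_row(methods[i], methods[j], "paired_t", {
          if (sd(a - b) == 0) NULL else t.test(a, b, paired = TRUE)
        }),
        .test_row(methods[i], methods[j], "f_var", {
          if (sd(a) == 0 || sd(b) == 0) NULL else var.test(a, b)
        }),
        .test_row(methods[i], methods[j], "wilcoxon", {
          if (wilcoxon == "rank-sum") {
            suppressWarnings(wilcox.test(a, b, exact = FALSE))
          } else {
            if (sd(a - b) == 0) NULL
            else suppressWarnings(wilcox.test(a, b, paired = TRUE,
                                              exact = FALSE))
          }
        }),
        .test_row(methods[i], methods[j], "ks", {
          suppressWarnings(ks.test(a, b))
        }))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.test_row <- function(a, b, test, expr) {
  res <- tryCatch(expr, error = function(e) NULL)
  if (is.null(res)) {
    data.frame(method_a = a, method_b = b, test = test,
               statistic = NA_real_, p_value = NA_real_, degenerate = TRUE,
               stringsAsFactors = FALSE)
  } else {
    data.frame(method_a = a, method_b = b, test = test,
               statistic = unname(res$statistic),
               p_value = res$p.value, degenerate = FALSE,
               stringsAsFactors = FALSE)
  }
}
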