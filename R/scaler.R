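#' Fit a zero-mean / unit-variance feature scaler on training rows
#'
#' Learns per-column mean and standard deviation on the supplied (training)
#' rows for the designated columns only; fingerprint bit columns are by
#' convention never scaled. Constant columns get a standard deviation of 1,
#' making scaling a centre-only no-op for them.
#'
#' @param x Numeric training matrix.
#' @param columns Columns to scale: integer/logical index or character names.
#'   Default: every column not named `bit_*`.
#' @return A `feature_scaler`.
#' @export
fit_scaler <- function(x, columns = NULL) {
  stopifnot(is.matrix(x))
  if (is.null(columns)) {
    columns <- if (is.null(colnames(x))) seq_len(ncol(x))
               else which(!grepl("^bit_", colnames(x)))
  }
  if (is.character(columns)) columns <- match(columns, colnames(x))
  if (is.logical(columns)) columns <- which(columns)
  mask <- rep(FALSE, ncol(x)); mask[columns] <- TRUE
  centre <- rep(0, ncol(x)); scale <- rep(1, ncol(x))
  if (any(mask)) {
    mu <- colMeans(x[, mask, drop = FALSE])
    s <- apply(x[, mask, drop = FALSE], 2L, sd)
    constant <- !is.finite(s) | s == 0
    # constant columns: leave untouched (SD guard)
    mu[constant] <- 0
    s[constant] <- 1
    centre[mask] <- mu
    scale[mask] <- s
  }
  structure(list(centre = centre, scale = scale, mask = mask,
                 n_features = ncol(x), fitted = TRUE),
            class = "feature_scaler")
}

#' Apply a fitted scaler to feature rows
#'
#' @param scaler A `feature_scaler` from [fit_scaler()].
#' @param x Numeric matrix with the same number of columns the scaler was
#'   fitted on.
#' @return The matrix with the scaler's designated columns standardised
#'   using the training statistics.
#' @export
apply_scaler <- function(scaler, x) {
  if (!inherits(scaler, "feature_scaler") || !isTRUE(scaler$fitted)) {
    stop("scaler has not been fitted", call. = FALSE)
  }
  stopifnot(is.matrix(x))
  if (ncol(x) != scaler$n_features) {
    stop(sprintf("scaler was fitted on %d features, got %d",
                 scaler$n_features, ncol(x)), call. = FALSE)
  }
  m <- scaler$mask
  x[, m] <- sweep(sweep(x[, m, drop = FALSE], 2L, scaler$centre[m]),
                  2L, scaler$scale[m], "/")
  x
}
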