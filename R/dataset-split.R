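#' Semi-stratified random train/test/holdout partition
#'
#' First sets aside a holdout fraction (default 10%) of the records, then
#' splits the remainder into training and test sets (default 70/30). Both
#' stages stratify on (target, activity class) cells containing at least
#' `min_cell` records, so per-target class balance is preserved where the
#' data permit; smaller cells are pooled and split uniformly. Totals are made
#' exact by largest-remainder allocation across cells. Fully reproducible
#' given the seed.
#'
#' @param dataset A `curated_dataset`.
#' @param seed Integer seed.
#' @param holdout_frac Fraction of all records set aside first (default 0.10).
#' @param test_frac Fraction of the remaining records assigned to the test
#'   set (default 0.30).
#' @param threshold pChEMBL activity threshold used for stratification.
#' @param min_cell Minimum records for a (target, class) cell to be
#'   stratified on its own (default 10).
#' @return A `split_spec`: data frame (`record_id`, `partition`) plus
#'   attributes `kind` and `seed`. Partitions are `train`, `test`, `holdout`.
#' @export
random_split <- function(dataset, seed, holdout_frac = 0.10,
                         test_frac = 0.30, threshold = NULL,
                         min_cell = 10L) {
  stopifnot(inherits(dataset, "curated_dataset"))
  rec <- dataset$records
  if (nrow(rec) == 0L) stop("cannot split an empty dataset", call. = FALSE)
  if (holdout_frac < 0 || holdout_frac >= 1 || test_frac <= 0 ||
      test_frac >= 1 || holdout_frac + test_frac >= 1) {
    stop("fractions must lie in (0,1) and sum to less than 1", call. = FALSE)
  }
  threshold <- threshold %||% dataset$config$activity_threshold %||% 6.5
  cls <- label_activity(rec$pchembl, threshold)
  cell <- paste(rec$target_id, cls, sep = "\r")
  small <- names(which(table(cell) < min_cell))
  cell[cell %in% small] <- ".pooled"

  partition <- rep("train", nrow(rec))
  with_seed(seed, {
    hold_idx <- .stratified_draw(cell, holdout_frac)
    partition[hold_idx] <- "holdout"
    rest <- which(partition != "holdout")
    test_idx <- rest[.stratified_draw(cell[rest], test_frac)]
    partition[test_idx] <- "test"
  })
  .split_spec(rec, partition, kind = "random", seed = seed)
}

# Draw round(frac * n) indices, allocated across strata proportionally with
# largest-remainder correction so the overall count is exact.
.stratified_draw <- function(strata, frac) {
  n <- length(strata)
  want_total <- round(frac * n)
  groups <- split(seq_len(n), strata)
  exact <- vapply(groups, length, integer(1)) * frac
  take <- floor(exact)
  shortfall <- want_total - sum(take)
  if (shortfall > 0) {
    extra <- order(exact - take, decreasing = TRUE)[seq_len(shortfall)]
    take[extra] <- take[extra] + 1L
  } else if (shortfall < 0) {
    victims <- order(exact - take)[seq_len(-shortfall)]
    take[victims] <- pmax(take[victims] - 1L, 0L)
  }
  unlist(lapply(seq_along(groups), function(g) {
    if (take[g] == 0L) return(integer(0))
    sample(groups[[g]], take[g])
  }), use.names = FALSE)
}

#' Temporal train/test partition by publication year
#'
#' Records from publications before the cutoff year form the training set;
#' records from the cutoff year onwards form the test set. This emulates
#' prospective prediction: models are trained on the past and validated on
#' the future. No holdout set is produced.
#'
#' @param dataset A `curated_dataset`; every record must carry a year.
#' @param cutoff_year First year assigned to the test set (default 2013).
#' @return A `split_spec` of kind `"temporal"`.
#' @export
temporal_split <- function(dataset, cutoff_year = 2013L) {
  stopifnot(inherits(dataset, "curated_dataset"))
  rec <- dataset$records
  if (nrow(rec) == 0L) stop("cannot split an empty dataset", call. = FALSE)
  if (any(is.na(rec$year))) {
    stop("temporal_split requires a publication year on every record",
         call. = FALSE)
  }
  partition <- ifelse(rec$year < cutoff_year, "train", "test")
  if (!any(partition == "train")) {
    stop(sprintf("temporal split at %d leaves the training set empty",
                 cutoff_year), call. = FALSE)
  }
  if (!any(partition == "test")) {
    stop(sprintf("temporal split at %d leaves the test set empty",
                 cutoff_year), call. = FALSE)
  }
  .split_spec(rec, partition, kind = "temporal", seed = NA_integer_)
}

.split_spec <- function(rec, partition, kind, seed) {
  id <- paste(rec$compound_id, rec$target_id, sep = "\r")
  structure(data.frame(record_id = id, partition = partition,
                       stringsAsFactors = FALSE),
            kind = kind, seed = seed, class = c("split_spec", "data.frame"))
}

#' Extract the records of one partition of a split
#'
#' @param dataset The `curated_dataset` the split was made on.
#' @param split A `split_spec`.
#' @param partition One of `"train"`, `"test"`, `"holdout"`.
#' @return The matching subset of `dataset$records`.
#' @export
split_records <- function(dataset, split, partition) {
  stopifnot(inherits(split, "split_spec"),
            partition %in% c("train", "test", "holdout"))
  rec <- dataset$records
  id <- paste(rec$compound_id, rec$target_id, sep = "\r")
  want <- split$record_id[split$partition == partition]
  out <- rec[id %in% want, , drop = FALSE]
  rownames(out) <- NULL
  out
}
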