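#' Curation configuration
#'
#' Filter settings for reducing a raw ChEMBL-style activity table to a
#' high-confidence modelling set. Defaults reproduce a strict literature
#' extraction: direct single-protein assays (confidence class 9), at least 30
#' tested compounds per target reported in at least 2 separate publications,
#' no disqualifying activity or validity comments, and a 6.5 pChEMBL
#' (about 300 nM) activity threshold.
#'
#' @param min_compounds_per_target Minimum distinct compounds tested per
#'   target (default 30).
#' @param min_publications_per_target Minimum distinct publications per
#'   target (default 2).
#' @param required_confidence Required assay confidence class (default 9,
#'   direct single-protein target assignment).
#' @param required_target_type Required target type (default
#'   `"single protein"`, matched case-insensitively).
#' @param required_source Required record source (default `"literature"`).
#' @param excluded_comments Activity comments that disqualify a measurement.
#' @param activity_threshold pChEMBL threshold separating active from
#'   inactive (default 6.5).
#' @return An object of class `curation_config`.
#' @export
curation_config <- function(min_compounds_per_target = 30L,
                            min_publications_per_target = 2L,
                            required_confidence = 9L,
                            required_target_type = "single protein",
                            required_source = "literature",
                            excluded_comments = c("not active", "inactive",
                                                  "inconclusive",
                                                  "undetermined"),
                            activity_threshold = 6.5) {
  assert_scalar_number(activity_threshold)
  stopifnot(min_compounds_per_target >= 1L, min_publications_per_target >= 1L)
  structure(list(min_compounds_per_target = as.integer(min_compounds_per_target),
                 min_publications_per_target = as.integer(min_publications_per_target),
                 required_confidence = as.integer(required_confidence),
                 required_target_type = required_target_type,
                 required_source = required_source,
                 excluded_comments = tolower(excluded_comments),
                 activity_threshold = activity_threshold),
            class = "curation_config")
}

#' Collapse repeated measurements of the same compound-target pair
#'
#' When a pair was measured several times, the median pChEMBL value is kept
#' and the duplicates dropped. For an even-sized group the median is the mean
#' of the two central values. Provenance of the surviving record: the year is
#' the earliest in the group and `doc_id` becomes the set of contributing
#' publication ids (separated by `;`), preserving the information needed for
#' the publications-per-target filter. Remaining fields are taken from the
#' group's first record.
#'
#' @param records Activity-record data frame; every row must carry a pChEMBL
#'   value.
#' @return Activity-record data frame with one row per (compound, target).
#' @export
aggregate_duplicates <- function(records) {
  if (any(!is.finite(records$pchembl))) {
    stop("aggregate_duplicates requires a finite pchembl on every record",
         call. = FALSE)
  }
  key <- paste(records$compound_id, records$target_id, sep = "\r")
  if (!anyDuplicated(key)) return(records)
  idx <- split(seq_len(nrow(records)), key)
  rows <- lapply(idx, function(i) {
    r <- records[i[1L], , drop = FALSE]
    r$pchembl <- median(records$pchembl[i])
    yrs <- records$year[i]
    r$year <- if (all(is.na(yrs))) NA_integer_ else min(yrs, na.rm = TRUE)
    docs <- unique(records$doc_id[i])
    docs <- docs[!is.na(docs)]
    r$doc_id <- if (length(docs)) paste(sort(docs), collapse = ";")
                else NA_character_
    r
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$target_id, out$compound_id), , drop = FALSE] -> out
  rownames(out) <- NULL
  out
}

.doc_ids <- function(x) unlist(strsplit(x[!is.na(x)], ";", fixed = TRUE))

#' Curate a raw activity table into a modelling dataset
#'
#' Applies, in order: row-level filters (confidence class, target type,
#' source, presence of a pChEMBL value, duplicate/validity flags, excluded
#' activity comments), median aggregation of repeated measurements, then
#' target-level filters (minimum compounds and minimum distinct publications
#' per target). Target-level filters are evaluated once on the post-row-filter
#' snapshot; `fixpoint = TRUE` re-applies them until no further records drop
#' (the per-target counts are independent across targets, so this converges
#' immediately and is provided for completeness).
#'
#' @param records Activity-record data frame (see [read_activity_table()]).
#' @param config A [curation_config()].
#' @param fixpoint Re-apply target-level filters to a fixed point.
#' @return An object of class `curated_dataset` with elements `records` (one
#'   row per compound-target pair), `compounds` (id -> SMILES), `targets`
#'   (id -> sequence, where known) and `config`.
#' @export
curate <- function(records, config = curation_config(), fixpoint = FALSE) {
  stopifnot(inherits(config, "curation_config"))
  keep <- rep(TRUE, nrow(records))
  keep <- keep & !is.na(records$pchembl) & is.finite(records$pchembl)
  keep <- keep & !is.na(records$confidence) &
    records$confidence == config$required_confidence
  keep <- keep & !is.na(records$target_type) &
    tolower(records$target_type) == tolower(config$required_target_type)
  keep <- keep & !is.na(records$source) &
    tolower(records$source) == tolower(config$required_source)
  keep <- keep & !records$duplicate_flag
  keep <- keep & is.na(records$validity_comment)
  keep <- keep & !(tolower(records$activity_comment) %in%
                     config$excluded_comments & !is.na(records$activity_comment))
  rec <- records[keep, , drop = FALSE]
  if (nrow(rec) > 0L) rec <- aggregate_duplicates(rec)

  repeat {
    if (nrow(rec) == 0L) break
    per_target <- split(seq_len(nrow(rec)), rec$target_id)
    ok_targets <- vapply(per_target, function(i) {
      n_cmp <- length(unique(rec$compound_id[i]))
      n_doc <- length(unique(.doc_ids(rec$doc_id[i])))
      n_cmp >= config$min_compounds_per_target &&
        n_doc >= config$min_publications_per_target
    }, logical(1))
    drop <- !rec$target_id %in% names(per_target)[ok_targets]
    if (!any(drop)) break
    rec <- rec[!drop, , drop = FALSE]
    if (!fixpoint) break
  }
  rownames(rec) <- NULL

  if (nrow(rec) == 0L) {
    warning("curation removed every record; returning an empty dataset",
            call. = FALSE)
  }
  cmp <- rec$smiles[!duplicated(rec$compound_id)]
  names(cmp) <- rec$compound_id[!duplicated(rec$compound_id)]
  structure(list(records = rec,
                 compounds = cmp,
                 targets = character(0),
                 config = config),
            class = "curated_dataset")
}

#' @export
print.curated_dataset <- function(x, ...) {
  cat(sprintf("<curated_dataset> %d records | %d targets | %d compounds\n",
              nrow(x$records), length(unique(x$records$target_id)),
              length(unique(x$records$compound_id))))
  invisible(x)
}

#' Attach target sequences to a curated dataset
#'
#' @param dataset A `curated_dataset`.
#' @param sequences Named character vector (target id -> sequence), e.g. from
#'   [read_fasta_sequences()].
#' @return The dataset with its `targets` map filled in.
#' @export
attach_sequences <- function(dataset, sequences) {
  stopifnot(inherits(dataset, "curated_dataset"))
  ids <- unique(dataset$records$target_id)
  dataset$targets <- sequences[intersect(names(sequences), ids)]
  dataset
}

#' Classify a pChEMBL value as active or inactive
#'
#' A measurement is active when its pChEMBL value is greater than or equal to
#' the threshold (boundary inclusive), inactive below it. The default 6.5
#' threshold corresponds to roughly 300 nM and splits typical ChEMBL
#' literature data about 55/45.
#'
#' @param pchembl Numeric vector of pChEMBL values (finite).
#' @param threshold Activity threshold in pChEMBL units.
#' @return Character vector of `"active"` / `"inactive"`.
#' @export
label_activity <- function(pchembl, threshold = 6.5) {
  assert_scalar_number(threshold)
  if (any(!is.finite(pchembl))) {
    stop("label_activity requires finite pchembl values", call. = FALSE)
  }
  ifelse(pchembl >= threshold, "active", "inactive")
}

#' Convert a pChEMBL threshold to a nanomolar concentration
#'
#' @param pchembl pChEMBL value (negative log10 molar).
#' @param signif_digits Significant digits to round to (default 1, the
#'   convention used when quoting thresholds such as "about 300 nM").
#' @return Concentration in nM.
#' @export
pchembl_to_nM <- function(pchembl, signif_digits = 1L) {
  assert_scalar_number(pchembl)
  signif(10^(9 - pchembl), signif_digits)
}
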