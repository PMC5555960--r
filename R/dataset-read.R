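#' Default ChEMBL-style column mapping
#'
#' Maps the internal activity-record field names to the column names of a
#' typical ChEMBL literature export.
#'
#' @return Named character vector: internal field -> source column.
#' @export
default_column_map <- function() {
  c(compound_id      = "molregno",
    smiles           = "canonical_smiles",
    target_id        = "accession",
    pchembl          = "pchembl_value",
    confidence       = "confidence_score",
    target_type      = "target_type",
    source           = "source",
    year             = "year",
    activity_comment = "activity_comment",
    duplicate_flag   = "potential_duplicate",
    validity_comment = "data_validity_comment",
    doc_id           = "doc_id")
}

.mandatory_fields <- c("compound_id", "target_id")
.record_fields <- names(default_column_map())

#' Read a bioactivity activity table
#'
#' Reads a delimited ChEMBL-style export into the standard activity-record
#' data frame used throughout the package. One row per raw measurement;
#' optional fields missing from the file become `NA`, never zero.
#'
#' @param source Path to a delimited text file with a header row, or a data
#'   frame already in source-column names.
#' @param column_map Named character vector mapping internal field names to
#'   source column names; see [default_column_map()].
#' @param sep Field separator (default `","`; use `"\t"` for TSV).
#' @return A data frame of activity records with columns `compound_id`,
#'   `smiles`, `target_id`, `pchembl`, `confidence`, `target_type`, `source`,
#'   `year`, `activity_comment`, `duplicate_flag`, `validity_comment`,
#'   `doc_id`.
#' @export
read_activity_table <- function(source, column_map = default_column_map(),
                                sep = ",") {
  df <- if (is.data.frame(source)) source
        else read.csv(source, sep = sep, stringsAsFactors = FALSE,
                      check.names = FALSE)
  map <- default_column_map()
  map[names(column_map)] <- column_map
  missing_mand <- .mandatory_fields[!map[.mandatory_fields] %in% names(df)]
  if (length(missing_mand) > 0L) {
    stop(sprintf("activity table is missing mandatory column(s): %s",
                 paste(sprintf("%s (mapped from field '%s')",
                               map[missing_mand], missing_mand),
                       collapse = ", ")), call. = FALSE)
  }
  out <- data.frame(row.names = seq_len(nrow(df)))
  for (field in .record_fields) {
    col <- map[[field]]
    out[[field]] <- if (col %in% names(df)) df[[col]] else NA
  }
  out$compound_id <- as.character(out$compound_id)
  out$target_id   <- as.character(out$target_id)
  out$pchembl     <- suppressWarnings(as.numeric(out$pchembl))
  out$year        <- suppressWarnings(as.integer(out$year))
  out$confidence  <- suppressWarnings(as.integer(out$confidence))
  out$duplicate_flag <- .as_flag(out$duplicate_flag)
  for (ch in c("smiles", "target_type", "source", "activity_comment",
               "validity_comment", "doc_id")) {
    out[[ch]] <- as.character(out[[ch]])
    out[[ch]][!is.na(out[[ch]]) & out[[ch]] == ""] <- NA_character_
  }
  bad <- !nzchar(out$compound_id) | !nzchar(out$target_id) |
    is.na(out$compound_id) | is.na(out$target_id)
  if (any(bad)) {
    stop(sprintf("%d row(s) have empty compound_id or target_id", sum(bad)),
         call. = FALSE)
  }
  if (any(!is.na(out$year) & out$year < 1900L)) {
    stop("publication years before 1900 are not plausible", call. = FALSE)
  }
  rownames(out) <- NULL
  out
}

.as_flag <- function(x) {
  if (is.logical(x)) return(ifelse(is.na(x), FALSE, x))
  x <- tolower(trimws(as.character(x)))
  !is.na(x) & x %in% c("1", "true", "t", "yes", "y")
}

#' Read a FASTA file into a named vector of sequences
#'
#' @param path Path to an uncompressed FASTA file; record ids are taken as the
#'   first whitespace-delimited token of each header.
#' @return Named character vector of upper-case sequences.
#' @export
read_fasta_sequences <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stop("no FASTA headers found in ", path, call. = FALSE)
  idx <- cumsum(hdr)
  ids <- sub("^>(\\S+).*$", "\\1", lines[hdr])
  seqs <- vapply(split(lines[!hdr], idx[!hdr]),
                 function(x) toupper(paste(x, collapse = "")), character(1))
  setNames(unname(seqs), ids)
}

#' Read compound structures from a SMILES or SDF file
#'
#' SMILES files carry one compound per line as `id<TAB>smiles` (or
#' `smiles<TAB>id`; the column that parses as a structure is taken as the
#' structure). SDF files are read through the chemistry toolkit and
#' converted to SMILES, keyed by the molecule title.
#'
#' @param path Path to a `.smi`/`.txt` SMILES file or a `.sdf` file.
#' @return Named character vector (compound id -> SMILES).
#' @export
read_compounds <- function(path) {
  if (grepl("\\.sdf$", path, ignore.case = TRUE)) {
    sdfs <- ChemmineR::read.SDFset(path)
    smi <- as.character(ChemmineR::sdf2smiles(sdfs))
    ids <- ChemmineR::sdfid(sdfs)
    return(setNames(smi, ids))
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "[\t ]+")
  bad <- lengths(parts) < 2L
  if (any(bad)) {
    stop("SMILES file lines must be 'id<TAB>smiles': line ",
         which(bad)[1L], call. = FALSE)
  }
  ids <- vapply(parts, `[[`, character(1), 1L)
  smi <- vapply(parts, `[[`, character(1), 2L)
  setNames(smi, ids)
}

#' Write sequences as FASTA
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta_sequences <- function(seqs, path, width = 60L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(seqs)) {
    writeLines(paste0(">", id), con)
    s <- seqs[[id]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}
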