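# 20x8 physicochemical property table of the standard amino acids, computed
# once from the free amino-acid structures with OpenBabel (logP, H-bond
# acceptors/donors, molecular weight, aromatic bond count, rigidity =
# heavy-atom bonds minus rotatable bonds) plus rule-based values: stereo-atom
# counts from the known stereocentres, side-chain charge at pH 7.4 from
# standard pKa rules (K, R +1; D, E -1; H +0.1), and logD at pH 7.4
# approximated as logP - 3 per unit of charge. Overridable via the `table`
# argument of protein_descriptor().
.AA_PROPERTY_VALUES <- matrix(c(
  # stereo, logd,   charge, hba, hbd, rigidity, aromatic, mw
  1,  0.118,  0.0, 3, 2,  4,  0,  89.093,   # A
  1, -2.447,  1.0, 6, 4,  6,  0, 174.201,   # R
  1, -0.326,  0.0, 5, 3,  5,  0, 132.118,   # N
  1, -3.427, -1.0, 5, 3,  5,  0, 133.103,   # D
  1,  0.028,  0.0, 4, 3,  4,  0, 121.158,   # C
  1, -3.037, -1.0, 5, 3,  5,  0, 147.129,   # E
  1,  0.064,  0.0, 5, 3,  5,  0, 146.144,   # Q
  0, -0.270,  0.0, 3, 2,  3,  0,  75.067,   # G
  1, -0.236,  0.1, 4, 3,  8,  5, 155.155,   # H
  2,  1.145,  0.0, 3, 2,  5,  0, 131.173,   # I
  1,  1.145,  0.0, 3, 2,  5,  0, 131.173,   # L
  1, -2.072,  1.0, 4, 3,  4,  0, 146.188,   # K
  1,  0.852,  0.0, 4, 2,  4,  0, 149.211,   # M
  1,  1.341,  0.0, 3, 2,  9,  6, 165.189,   # F
  1,  0.152,  0.0, 3, 2,  7,  0, 115.130,   # P
  1, -0.909,  0.0, 4, 3,  4,  0, 105.093,   # S
  2, -0.521,  0.0, 4, 3,  5,  0, 119.119,   # T
  1,  1.823,  0.0, 3, 3, 13, 10, 204.225,   # W
  1,  1.047,  0.0, 4, 3, 10,  6, 181.189,   # Y
  1,  0.755,  0.0, 3, 2,  5,  0, 117.146),  # V
  nrow = 20, byrow = TRUE,
  dimnames = list(c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I", "L",
                    "K", "M", "F", "P", "S", "T", "W", "Y", "V"),
                  c("stereo", "logd", "charge", "hba", "hbd", "rigidity",
                    "aromatic", "mw")))

#' Amino-acid physicochemical property table
#'
#' Eight properties for each of the 20 standard residues: stereo-atom count,
#' logD at pH 7.4, formal charge at pH 7.4, hydrogen-bond acceptors and
#' donors, rigidity (count of non-rotatable bonds between heavy atoms),
#' aromatic bond count, and molecular weight (Da, free amino acid). Values
#' were computed once from the free amino-acid structures and are shipped as
#' a versioned constant; supply your own 20x8 matrix with the same column
#' order to override.
#'
#' @return A 20x8 numeric matrix, rows named by one-letter residue codes.
#' @export
aa_property_table <- function() .AA_PROPERTY_VALUES

#' Alignment-free protein sequence descriptor
#'
#' The sequence is split into `n_parts` contiguous, near-equal parts (the
#' first `length %% n_parts` parts take the extra residue). For every part
#' the mean of each of the 8 residue properties is computed, the same is done
#' over the whole sequence, and the sequence length is appended:
#' `n_parts * 8 + 8 + 1` values (169 for the default 20 parts), ordered
#' part 1 properties 1-8, ..., part 20, global mean, length.
#'
#' Non-standard residue letters (X, B, Z, U, ...) are imputed with the
#' unweighted mean property vector of the 20 standard residues; with
#' `strict = TRUE` they raise an error instead.
#'
#' @param sequence Single protein sequence string (upper- or lower-case).
#' @param table Residue property table; see [aa_property_table()].
#' @param n_parts Number of sequence parts (default 20).
#' @param strict Error on non-standard residues instead of imputing.
#' @return Named numeric vector of length `n_parts * 8 + 9`.
#' @export
protein_descriptor <- function(sequence, table = aa_property_table(),
                               n_parts = 20L, strict = FALSE) {
  stopifnot(is.character(sequence), length(sequence) == 1L,
            is.matrix(table), ncol(table) == 8L)
  res <- strsplit(toupper(sequence), "")[[1]]
  n <- length(res)
  if (n < n_parts) {
    stop(sprintf("sequence has %d residues; need at least %d", n, n_parts),
         call. = FALSE)
  }
  known <- res %in% rownames(table)
  if (!all(known)) {
    if (strict) {
      stop("non-standard residue(s): ",
           paste(unique(res[!known]), collapse = ", "), call. = FALSE)
    }
  }
  props <- matrix(NA_real_, n, ncol(table),
                  dimnames = list(NULL, colnames(table)))
  props[known, ] <- table[res[known], , drop = FALSE]
  if (!all(known)) {
    props[!known, ] <- matrix(colMeans(table), sum(!known), ncol(table),
                              byrow = TRUE)
  }
  sizes <- rep(n %/% n_parts, n_parts)
  extra <- n %% n_parts
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  part_of <- rep(seq_len(n_parts), times = sizes)

  blocks <- lapply(seq_len(n_parts), function(p)
    colMeans(props[part_of == p, , drop = FALSE]))
  global <- colMeans(props)
  values <- c(unlist(blocks), global, n)
  names(values) <- c(
    as.vector(t(outer(sprintf("p%02d", seq_len(n_parts)), colnames(table),
                      paste, sep = "_"))),
    paste0("glob_", colnames(table)), "seqlen")
  values
}

#' Featurise a set of protein targets
#'
#' @param sequences Named character vector (target id -> sequence).
#' @param ... Passed to [protein_descriptor()].
#' @return Numeric matrix, one row per target (rownames = target ids).
#' @export
featurize_targets <- function(sequences, ...) {
  stopifnot(!is.null(names(sequences)))
  out <- do.call(rbind, lapply(sequences, protein_descriptor, ...))
  rownames(out) <- names(sequences)
  out
}
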