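# Base length of the hashed circular fingerprint emitted by the chemistry
# backend; requested lengths are modulo-folds of this.
.FP_BASE_BITS <- 4096L

#' Parse SMILES structures into molecule handles
#'
#' Thin wrapper over the OpenBabel parser. Structures that yield no atoms
#' (empty or syntactically invalid SMILES) raise an error carrying the
#' offending input; the parser is otherwise lenient, and whatever it accepts
#' is accepted here.
#'
#' @param smiles Character vector of SMILES strings.
#' @return List of molecule references, named by the input strings.
#' @export
parse_molecules <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) >= 1L)
  if (any(is.na(smiles) | !nzchar(smiles))) {
    stop("empty or missing SMILES string", call. = FALSE)
  }
  mols <- tryCatch(
    ChemmineOB::forEachMol("SMILES", paste(smiles, collapse = "\n"),
                           identity),
    error = function(e) {
      stop("unparseable structure(s) among: ",
           paste(head(smiles, 5L), collapse = ", "), call. = FALSE)
    })
  if (length(mols) != length(smiles)) {
    stop("structure parsing dropped molecules; first input: ", smiles[1L],
         call. = FALSE)
  }
  can <- vapply(smiles, function(s) {
    out <- tryCatch(ChemmineOB::convertFormat("SMILES", "CAN", s),
                    error = function(e) "")
    trimws(out)
  }, character(1))
  bad <- !nzchar(can)
  if (any(bad)) {
    stop("unparseable structure(s): ",
         paste(smiles[bad], collapse = ", "), call. = FALSE)
  }
  names(mols) <- smiles
  mols
}

#' Hashed circular fingerprint of one or more structures
#'
#' Circular substructure environments up to the given bond radius are hashed
#' (extended-connectivity / Morgan family) and folded to `n_bits` by modulo
#' reduction of the backend's 4096-bit output, so a bit set at the shorter
#' length is the OR of its aliases at the longer one.
#'
#' @param smiles Character vector of SMILES.
#' @param radius Environment radius in bonds (1, 2 or 3; default 3).
#' @param n_bits Folded length, at most 4096 (default 256).
#' @return Integer 0/1 matrix, one row per structure, `n_bits` columns named
#'   `bit_0 ... bit_{n_bits-1}`.
#' @export
circular_fingerprint <- function(smiles, radius = 3L, n_bits = 256L) {
  stopifnot(radius %in% c(1L, 2L, 3L), n_bits >= 8L,
            n_bits <= .FP_BASE_BITS)
  mols <- if (is.list(smiles)) smiles else parse_molecules(smiles)
  fpname <- paste0("ECFP", 2L * radius)
  raw <- ChemmineOB::fingerprint_OB(mols, fpname)
  if (is.null(dim(raw))) raw <- matrix(raw, nrow = 1L)
  fold_fingerprint(raw, n_bits)
}

#' Fold a fingerprint matrix to a shorter bit length
#'
#' Bit `i` of the input maps to bit `i mod n_bits` of the output (logical
#' OR). Folding can only merge bits, never clear them, so the population
#' count never increases.
#'
#' @param bits 0/1 matrix.
#' @param n_bits Target length; must divide into the input length.
#' @return 0/1 integer matrix with `n_bits` columns.
#' @export
fold_fingerprint <- function(bits, n_bits) {
  L <- ncol(bits)
  stopifnot(n_bits <= L)
  if (n_bits == L) {
    out <- bits
  } else {
    if (L %% n_bits != 0L) {
      stop("target length must divide the input length", call. = FALSE)
    }
    out <- matrix(0L, nrow(bits), n_bits)
    for (k in seq_len(L / n_bits)) {
      out <- pmax(out, bits[, ((k - 1L) * n_bits + 1L):(k * n_bits),
                            drop = FALSE])
    }
  }
  out <- matrix(as.integer(out), nrow(bits), n_bits)
  colnames(out) <- paste0("bit_", seq_len(n_bits) - 1L)
  rownames(out) <- rownames(bits)
  out
}

# van der Waals radii (Angstrom) for the total-surface approximation
.VDW_RADII <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
                F = 1.47, Cl = 1.75, Br = 1.85, I = 1.98, B = 1.92,
                Si = 2.10)

.ROTATABLE_SMARTS <- "[!$(*#*)&!D1]-!@[!$(*#*)&!D1]"

#' Physicochemical compound descriptors
#'
#' Six properties per structure: calculated octanol/water partition
#' coefficient (AlogP), molecular weight (Da), hydrogen-bond acceptor and
#' donor counts, fractional polar surface area, and rotatable bond count.
#' Fractional PSA is the topological PSA divided by an approximate total
#' molecular surface area summed from atomic van der Waals sphere areas
#' (hydrogens included), clipped to `[0, 1]`.
#'
#' @param smiles Character vector of SMILES.
#' @return Numeric matrix, one row per structure, columns `alogp`, `mw`,
#'   `hba`, `hbd`, `frac_psa`, `rtb`.
#' @export
compound_physchem <- function(smiles) {
  mols <- if (is.list(smiles)) smiles else parse_molecules(smiles)
  props <- suppressWarnings(ChemmineOB::prop_OB(mols))
  rtb <- vapply(mols, function(m)
    ChemmineOB::smartsSearch_OB(list(m), .ROTATABLE_SMARTS), numeric(1))
  tsa <- vapply(props$formula, .approx_total_surface, numeric(1))
  frac_psa <- ifelse(tsa > 0, pmin(pmax(props$TPSA / tsa, 0), 1), 0)
  out <- cbind(alogp = props$logP, mw = props$MW, hba = props$HBA1,
               hbd = props$HBD, frac_psa = frac_psa, rtb = as.numeric(rtb))
  rownames(out) <- names(mols)
  out
}

# Sum of atomic vdW sphere areas from a molecular formula; a crude but
# monotone stand-in for the molecular surface (no overlap correction).
.approx_total_surface <- function(formula) {
  toks <- regmatches(formula, gregexpr("([A-Z][a-z]?)(\\d*)", formula))[[1]]
  area <- 0
  for (tok in toks) {
    el <- sub("^([A-Z][a-z]?).*$", "\\1", tok)
    cnt <- sub("^[A-Z][a-z]?", "", tok)
    cnt <- if (nzchar(cnt)) as.numeric(cnt) else 1
    r <- unname(.VDW_RADII[el])
    if (is.na(r)) r <- 1.7
    area <- area + cnt * 4 * pi * r^2
  }
  area
}

#' Featurise a set of compounds
#'
#' Computes the fingerprint block and, optionally, the physicochemical block
#' for a compound id -> SMILES map, parsing each structure once.
#'
#' @param compounds Named character vector (compound id -> SMILES).
#' @param n_bits Fingerprint length (default 256).
#' @param radius Fingerprint radius in bonds (default 3).
#' @param physchem Also compute the 6 physicochemical descriptors.
#' @return Numeric matrix with one row per compound (rownames = compound
#'   ids); fingerprint bit columns first, physicochemical columns appended
#'   when requested.
#' @export
featurize_compounds <- function(compounds, n_bits = 256L, radius = 3L,
                                physchem = FALSE) {
  stopifnot(!is.null(names(compounds)), all(nzchar(names(compounds))))
  mols <- parse_molecules(unname(compounds))
  bits <- circular_fingerprint(mols, radius = radius, n_bits = n_bits)
  out <- bits
  if (physchem) out <- cbind(bits, compound_physchem(mols))
  rownames(out) <- names(compounds)
  out
}
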