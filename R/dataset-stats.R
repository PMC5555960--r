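#' Sparsity and coverage arithmetic for a compound-target activity matrix
#'
#' Pure count arithmetic, usable directly on published dataset sizes: the
#' matrix size is `n_targets * n_compounds`, completeness the percentage of
#' cells measured, and the mean compounds per target / targets per compound
#' follow from the point count.
#'
#' @param n_targets,n_compounds,n_points Non-negative counts.
#' @return List with `matrix_size`, `completeness_pct`,
#'   `mean_compounds_per_target`, `mean_targets_per_compound`.
#' @export
matrix_stats <- function(n_targets, n_compounds, n_points) {
  stopifnot(n_targets > 0, n_compounds > 0, n_points >= 0)
  size <- as.numeric(n_targets) * as.numeric(n_compounds)
  list(matrix_size = size,
       completeness_pct = 100 * n_points / size,
       mean_compounds_per_target = n_points / n_targets,
       mean_targets_per_compound = n_points / n_compounds)
}

#' Summary statistics of a curated dataset
#'
#' Counts of targets, compounds and measured points, matrix completeness,
#' the distribution of tested compounds per target, the mean number of
#' targets per compound, and optionally the number of distinct Murcko
#' ring-framework scaffolds over all compounds.
#'
#' @param dataset A `curated_dataset`.
#' @param scaffolds Compute the Murcko scaffold count (requires parseable
#'   SMILES for the compounds; default `FALSE` since it is the only part that
#'   needs the chemistry toolkit).
#' @return A list of class `dataset_stats`.
#' @export
dataset_stats <- function(dataset, scaffolds = FALSE) {
  stopifnot(inherits(dataset, "curated_dataset"))
  rec <- dataset$records
  if (nrow(rec) == 0L) stop("dataset is empty", call. = FALSE)
  n_targets <- length(unique(rec$target_id))
  n_compounds <- length(unique(rec$compound_id))
  n_points <- nrow(rec)
  per_target <- table(rec$target_id)
  ms <- matrix_stats(n_targets, n_compounds, n_points)
  out <- list(n_targets = n_targets,
              n_compounds = n_compounds,
              n_points = n_points,
              matrix_size = ms$matrix_size,
              completeness_pct = ms$completeness_pct,
              mean_compounds_per_target = ms$mean_compounds_per_target,
              sd_compounds_per_target = if (n_targets > 1) sd(per_target) else 0,
              median_compounds_per_target = unname(median(per_target)),
              min_compounds_per_target = min(per_target),
              max_compounds_per_target = max(per_target),
              mean_targets_per_compound = ms$mean_targets_per_compound,
              n_scaffolds = NA_integer_)
  if (scaffolds) {
    smiles <- dataset$compounds[!is.na(dataset$compounds)]
    out$n_scaffolds <- count_murcko_scaffolds(smiles)
  }
  structure(out, class = "dataset_stats")
}

#' @export
print.dataset_stats <- function(x, ...) {
  cat(sprintf(paste0(
    "<dataset_stats>\n",
    "  targets: %d | compounds: %d | points: %d\n",
    "  matrix size: %.0f | completeness: %.2f%%\n",
    "  compounds/target: mean %.1f (sd %.1f), median %g, range [%d, %d]\n",
    "  targets/compound: mean %.1f\n"),
    x$n_targets, x$n_compounds, x$n_points, x$matrix_size,
    x$completeness_pct, x$mean_compounds_per_target,
    x$sd_compounds_per_target, x$median_compounds_per_target,
    x$min_compounds_per_target, x$max_compounds_per_target,
    x$mean_targets_per_compound))
  if (!is.na(x$n_scaffolds)) cat(sprintf("  Murcko scaffolds: %d\n", x$n_scaffolds))
  invisible(x)
}

#' Count distinct Murcko scaffolds in a set of structures
#'
#' The Murcko scaffold of a molecule is its ring systems plus the linkers
#' connecting them, with all acyclic substituents pruned away. Pruning is done
#' on the molecular graph by iteratively deleting non-ring atoms of degree
#' one; the remaining framework is canonicalised to SMILES for counting.
#' Acyclic molecules have an empty scaffold and contribute no framework.
#'
#' @param smiles Character vector of SMILES.
#' @return Number of distinct non-empty scaffolds.
#' @export
count_murcko_scaffolds <- function(smiles) {
  scaf <- vapply(smiles, murcko_scaffold, character(1), USE.NAMES = FALSE)
  length(unique(scaf[nzchar(scaf)]))
}

#' Murcko scaffold SMILES of one molecule
#'
#' Pruning non-ring atoms of degree one from the heavy-atom graph until none
#' remain (the graph 2-core) leaves exactly the ring systems and the linkers
#' between them; the framework is then canonicalised by OpenBabel.
#'
#' @param smiles A single SMILES string.
#' @return Canonical SMILES of the ring-and-linker framework, or `""` for an
#'   acyclic molecule.
#' @export
murcko_scaffold <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(smiles))[[1L]]
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elem <- sub("_.*$", "", rownames(ab))
  n <- length(elem)
  if (is.null(bb) || nrow(bb) == 0L || n == 0L) return("")
  from <- as.integer(bb[, 1L]); to <- as.integer(bb[, 2L])
  ord <- as.integer(bb[, 3L])
  keep <- elem != "H"
  repeat {
    live <- keep[from] & keep[to]
    deg <- tabulate(c(from[live], to[live]), n)
    prune <- keep & deg <= 1L
    if (!any(prune)) break
    keep[prune] <- FALSE
  }
  if (!any(keep)) return("")
  idx <- which(keep)
  remap <- integer(n); remap[idx] <- seq_along(idx)
  bk <- keep[from] & keep[to]
  mol <- c("scaffold", "  pcmbench", "",
           sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                   length(idx), sum(bk)),
           sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                   ab[idx, 1L], ab[idx, 2L], 0, elem[idx]),
           sprintf("%3d%3d%3d  0  0  0  0", remap[from[bk]], remap[to[bk]],
                   ord[bk]),
           "M  END", "$$$$")
  out <- ChemmineOB::convertFormat("SDF", "CAN", paste(mol, collapse = "\n"))
  strsplit(trimws(out), "[ \t\n]")[[1L]][1L]
}
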