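#' Grid-search specification for the network configurations
#'
#' The default grid crosses three modelling modes (single-target QSAR,
#' multi-task, PCM), three compound descriptor specifications (256 bits;
#' 4096 bits; 4096 bits plus physicochemical properties) and seven
#' architecture/dropout variants, with the epoch cap lowered to 500:
#' 3 x 3 x 7 = 63 configurations. The seven variants are the four hidden
#' architectures `[1000]`, `[2000, 1000]`, `[4000, 2000, 1000]` and
#' `[8000, 4000, 2000]` under normal dropout (0 input / 25% hidden), plus
#' the three deeper ones under increased dropout (25% input / 50% hidden);
#' the single-layer increased-dropout cell is dropped. Every axis is
#' user-overridable, so alternative factorisations can be enumerated.
#'
#' @param modes Modelling modes to cross.
#' @param descriptors List of descriptor specs, each
#'   `list(n_bits =, physchem =)`.
#' @param architectures List of architecture variants, each
#'   `list(hidden =, input_dropout =, hidden_dropout =)`.
#' @param max_epochs Epoch cap applied to every configuration (default
#'   500).
#' @return A `grid_spec`.
#' @export
grid_spec <- function(modes = c("qsar_single", "multiclass", "pcm"),
                      descriptors = list(
                        list(n_bits = 256L, physchem = FALSE),
                        list(n_bits = 4096L, physchem = FALSE),
                        list(n_bits = 4096L, physchem = TRUE)),
                      architectures = .default_architectures(),
                      max_epochs = 500L) {
  if (length(modes) == 0L || length(descriptors) == 0L ||
      length(architectures) == 0L) {
    stop("every grid axis must be non-empty", call. = FALSE)
  }
  structure(list(modes = modes, descriptors = descriptors,
                 architectures = architectures,
                 max_epochs = as.integer(max_epochs)),
            class = "grid_spec")
}

.default_architectures <- function() {
  widths <- list(c(1000L), c(2000L, 1000L), c(4000L, 2000L, 1000L),
                 c(8000L, 4000L, 2000L))
  normal <- lapply(widths, function(w)
    list(hidden = w, input_dropout = 0, hidden_dropout = 0.25))
  increased <- lapply(widths[-1L], function(w)
    list(hidden = w, input_dropout = 0.25, hidden_dropout = 0.50))
  c(normal, increased)
}

#' Enumerate the configurations of a grid specification
#'
#' Cross product of modes x descriptors x architecture variants, in a
#' deterministic order (mode-major), deduplicated, each entry carrying the
#' paired [model_config()] and [dnn_config()] with the grid's epoch cap.
#'
#' @param spec A [grid_spec()].
#' @param seed Base seed; each configuration derives its own.
#' @param width_scale Passed through to every [dnn_config()].
#' @return List of `list(model, dnn, id)` entries.
#' @export
enumerate_grid <- function(spec = grid_spec(), seed = 1L, width_scale = 1) {
  stopifnot(inherits(spec, "grid_spec"))
  out <- list()
  seen <- character(0)
  for (mode in spec$modes) {
    for (d in spec$descriptors) {
      for (a in spec$architectures) {
        id <- paste(mode, d$n_bits, if (d$physchem) "pc" else "fp",
                    paste(a$hidden, collapse = "-"),
                    a$input_dropout, a$hidden_dropout, sep = "_")
        if (id %in% seen) next
        seen <- c(seen, id)
        out[[length(out) + 1L]] <- list(
          model = model_config(algorithm = "dnn", mode = mode,
                               n_bits = d$n_bits, physchem = d$physchem,
                               seed = derive_seed(seed, id)),
          dnn = dnn_config(hidden_layers = a$hidden,
                           input_dropout = a$input_dropout,
                           hidden_dropout = a$hidden_dropout,
                           max_epochs = spec$max_epochs,
                           width_scale = width_scale,
                           seed = derive_seed(seed, id)),
          id = id)
      }
    }
  }
  out
}

#' Combine member predictions by majority vote
#'
#' The ensemble class for a pair is the modal class over the members. An
#' even split is resolved towards the class whose members carry the higher
#' mean score. The emitted score is the active-vote fraction.
#'
#' @param members List of prediction-set data frames; each must cover every
#'   pair (apply [fill_missing()] first).
#' @param pairs Data frame with `compound_id`, `target_id`.
#' @return Prediction set with `provenance = "majority_vote"`.
#' @export
majority_vote <- function(members, pairs) {
  mats <- .member_matrices(members, pairs)
  votes_active <- rowSums(mats$class == "active")
  n <- length(members)
  cls <- ifelse(votes_active * 2L > n, "active",
                ifelse(votes_active * 2L < n, "inactive", NA))
  if (anyNA(cls)) {
    tie <- is.na(cls)
    mean_act <- rowMeans(ifelse(mats$class == "active", mats$score, NA),
                         na.rm = TRUE)
    mean_ina <- rowMeans(ifelse(mats$class == "inactive", mats$score, NA),
                         na.rm = TRUE)
    cls[tie] <- ifelse(mean_act[tie] >= mean_ina[tie], "active", "inactive")
  }
  data.frame(compound_id = pairs$compound_id, target_id = pairs$target_id,
             score = votes_active / n, predicted_class = cls,
             provenance = "majority_vote", stringsAsFactors = FALSE)
}

#' Combine member predictions by score averaging
#'
#' Member scores must share a scale (all predicted pChEMBL values, or all
#' probabilities); the ensemble score is their arithmetic mean, classified
#' with the rule of that scale (threshold for pChEMBL, > 0.5 for
#' probabilities).
#'
#' @param members List of prediction sets covering every pair.
#' @param pairs Data frame with `compound_id`, `target_id`.
#' @param threshold pChEMBL activity threshold.
#' @param scale `"pchembl"` or `"probability"`; members whose provenance
#'   indicates random fill are allowed on either scale.
#' @return Prediction set with `provenance = "average_vote"`.
#' @export
average_vote <- function(members, pairs, threshold = 6.5,
                         scale = c("pchembl", "probability")) {
  scale <- match.arg(scale)
  mats <- .member_matrices(members, pairs)
  non_fill <- mats$provenance != "random_fill"
  if (scale == "pchembl") {
    looks_prob <- non_fill & mats$score >= 0 & mats$score <= 1
    if (any(colSums(looks_prob) == nrow(mats$score) & nrow(mats$score) > 0)) {
      stop("member scores look like probabilities; mixed scales cannot be ",
           "averaged as pChEMBL values", call. = FALSE)
    }
  } else {
    out_of_range <- non_fill & (mats$score < 0 | mats$score > 1)
    if (any(out_of_range)) {
      stop("member scores outside [0, 1]; mixed scales cannot be averaged ",
           "as probabilities", call. = FALSE)
    }
  }
  sc <- rowMeans(mats$score)
  cls <- if (scale == "pchembl") label_activity(sc, threshold)
         else ifelse(sc > 0.5, "active", "inactive")
  data.frame(compound_id = pairs$compound_id, target_id = pairs$target_id,
             score = sc, predicted_class = cls,
             provenance = "average_vote", stringsAsFactors = FALSE)
}

.member_matrices <- function(members, pairs) {
  if (length(members) == 0L) stop("no ensemble members", call. = FALSE)
  key <- paste(pairs$compound_id, pairs$target_id, sep = "\r")
  score <- cls <- prov <- NULL
  for (m in members) {
    mk <- paste(m$compound_id, m$target_id, sep = "\r")
    idx <- match(key, mk)
    if (anyNA(idx)) {
      stop("an ensemble member does not cover every pair; run ",
           "fill_missing() on each member first", call. = FALSE)
    }
    score <- cbind(score, m$score[idx])
    cls <- cbind(cls, m$predicted_class[idx])
    prov <- cbind(prov, m$provenance[idx])
  }
  list(score = score, class = cls, provenance = prov)
}

#' Percentage improvement over a baseline metric
#'
#' `100 * (value - baseline) / |baseline|`.
#'
#' @param value Metric value.
#' @param baseline Non-zero baseline value.
#' @return Percent change (positive = improvement for higher-is-better
#'   metrics).
#' @export
improvement_percent <- function(value, baseline) {
  assert_scalar_number(value); assert_scalar_number(baseline)
  if (baseline == 0) stop("baseline must be non-zero", call. = FALSE)
  100 * (value - baseline) / abs(baseline)
}
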