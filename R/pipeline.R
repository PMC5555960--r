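#' Featurise every compound and target of a curated dataset
#'
#' @param dataset A `curated_dataset` (with sequences attached when protein
#'   features are requested; see [attach_sequences()]).
#' @param n_bits Fingerprint length.
#' @param physchem Include the physicochemical compound block.
#' @param protein Also compute protein descriptors for the targets.
#' @return List with `compound` (matrix, rownames = compound ids) and
#'   `protein` (matrix or `NULL`).
#' @export
featurize_dataset <- function(dataset, n_bits = 256L, physchem = FALSE,
                              protein = FALSE) {
  stopifnot(inherits(dataset, "curated_dataset"))
  cmp <- featurize_compounds(dataset$compounds, n_bits = n_bits,
                             physchem = physchem)
  prot <- NULL
  if (protein) {
    if (length(dataset$targets) == 0L) {
      stop("protein features requested but no sequences attached",
           call. = FALSE)
    }
    prot <- featurize_targets(dataset$targets)
  }
  list(compound = cmp, protein = prot)
}

#' Fit a benchmark model on the training partition of a split
#'
#' Dispatches on `config$mode` and `config$algorithm`:
#' single-target QSAR trains one model per target on its training compounds
#' (classification for the classical learners, pChEMBL regression for the
#' network); multi-task trains one network whose output layer has one node
#' per training target, on the sparse compound x target value matrix;
#' proteochemometric (PCM) models concatenate compound and protein features
#' per training record. Naive Bayes in QSAR mode scores with the full-matrix
#' z-score background unless `config$hyper$zscore = FALSE`. Protein and
#' physicochemical feature blocks are standardised with statistics learned
#' on the training rows only; fingerprint bits are never scaled.
#'
#' @param config A [model_config()].
#' @param dataset The `curated_dataset`.
#' @param split A `split_spec`.
#' @param features Output of [featurize_dataset()] (with `protein` set for
#'   PCM mode).
#' @param dnn A [dnn_config()] for the network algorithms.
#' @return A `bioactivity_model`.
#' @export
fit_bioactivity_model <- function(config, dataset, split, features,
                                  dnn = dnn_config()) {
  stopifnot(inherits(config, "model_config"))
  train <- split_records(dataset, split, "train")
  if (nrow(train) == 0L) stop("empty training partition", call. = FALSE)
  if (config$mode == "pcm" && is.null(features$protein)) {
    stop("pcm mode requires protein features", call. = FALSE)
  }
  dnn$seed <- config$seed

  model <- list(config = config, dnn = dnn, scaler = NULL, fits = NULL,
                roster = NULL)
  cmpf <- features$compound

  if (config$mode == "pcm") {
    x <- cbind(cmpf[train$compound_id, , drop = FALSE],
               features$protein[train$target_id, , drop = FALSE])
    # PCM input = fingerprint block (+ physchem) + 169 protein features
    stopifnot(ncol(x) == config$n_bits + 6L * config$physchem + 169L)
    model$scaler <- fit_scaler(x)
    x <- apply_scaler(model$scaler, x)
    if (config$algorithm == "dnn") {
      model$fits <- train_dnn(dnn, x, train$pchembl)
    } else if (config$algorithm %in% c("rf", "svm")) {
      labs <- label_activity(train$pchembl, config$threshold)
      model$fits <- train_baseline(config, x, labs)
    } else {
      stop("pcm mode supports rf, svm and dnn", call. = FALSE)
    }
  } else if (config$mode == "multiclass") {
    compounds <- unique(train$compound_id)
    targets <- sort(unique(train$target_id))
    y <- matrix(NA_real_, length(compounds), length(targets),
                dimnames = list(compounds, targets))
    y[cbind(match(train$compound_id, compounds),
            match(train$target_id, targets))] <- train$pchembl
    x <- cmpf[compounds, , drop = FALSE]
    model$scaler <- fit_scaler(x)
    x <- apply_scaler(model$scaler, x)
    model$roster <- targets
    model$fits <- train_dnn(dnn, x, y)
  } else {  # qsar_single
    model$scaler <- fit_scaler(cmpf)
    xs <- apply_scaler(model$scaler, cmpf)
    # naive Bayes works on the raw binary fingerprint block only
    bits <- cmpf[, grepl("^bit_", colnames(cmpf)), drop = FALSE]
    if (config$algorithm == "nb" &&
        !identical(config$hyper$zscore, FALSE)) {
      model$fits <- train_nb_zscore(config, train, bits)
    } else {
      per_target <- split(train, train$target_id)
      fits <- list()
      skipped <- character(0)
      for (tid in names(per_target)) {
        tr <- per_target[[tid]]
        x <- if (config$algorithm == "nb")
          bits[tr$compound_id, , drop = FALSE]
        else xs[tr$compound_id, , drop = FALSE]
        if (config$algorithm == "dnn") {
          cfg_t <- dnn
          cfg_t$seed <- derive_seed(config$seed, tid)
          fits[[tid]] <- train_dnn(cfg_t, x, tr$pchembl)
        } else {
          labs <- label_activity(tr$pchembl, config$threshold)
          if (length(unique(labs)) < 2L) {
            skipped <- c(skipped, tid)
            next
          }
          fits[[tid]] <- train_baseline(config, x, labs)
        }
      }
      if (length(skipped) > 0L) {
        warning(sprintf(
          "skipped %d single-class target(s): %s (pairs fall back to %s)",
          length(skipped), paste(head(skipped, 5L), collapse = ", "),
          "random fill"), call. = FALSE)
      }
      model$fits <- fits
    }
  }
  structure(model, class = "bioactivity_model")
}

#' Predict classes and scores for compound-target pairs
#'
#' Emits one prediction row per pair the model can speak to: single-target
#' and multi-task models only cover targets seen in training (uncovered
#' pairs are left to [fill_missing()]), while PCM models extrapolate to any
#' target with a known sequence. Regression scores are predicted pChEMBL
#' values classified at the activity threshold (boundary inclusive);
#' classifier scores are active-class probabilities classified at
#' strictly > 0.5; naive Bayes z-scores are classified at z > 0.
#'
#' @param model A `bioactivity_model`.
#' @param pairs Data frame with `compound_id` and `target_id`.
#' @param features Output of [featurize_dataset()] covering the pairs'
#'   compounds (and targets, for PCM).
#' @param threshold pChEMBL activity threshold (default: the model's).
#' @return Prediction-set data frame (`compound_id`, `target_id`, `score`,
#'   `predicted_class`, `provenance`).
#' @export
predict_bioactivity <- function(model, pairs, features,
                                threshold = model$config$threshold) {
  stopifnot(inherits(model, "bioactivity_model"))
  cfg <- model$config
  cmpf <- features$compound
  pairs <- pairs[pairs$compound_id %in% rownames(cmpf), , drop = FALSE]
  tag <- paste(cfg$algorithm, cfg$mode, sep = "_")

  if (cfg$mode == "pcm") {
    prot <- features$protein
    pairs <- pairs[pairs$target_id %in% rownames(prot), , drop = FALSE]
    if (nrow(pairs) == 0L) return(.empty_predictions())
    x <- cbind(cmpf[pairs$compound_id, , drop = FALSE],
               prot[pairs$target_id, , drop = FALSE])
    x <- apply_scaler(model$scaler, x)
    if (cfg$algorithm == "dnn") {
      score <- as.numeric(predict(model$fits, x))
      cls <- label_activity(score, threshold)
    } else {
      score <- baseline_scores(model$fits, x)
      cls <- ifelse(score > 0.5, "active", "inactive")
    }
    return(.predictions(pairs, score, cls, tag))
  }

  if (cfg$mode == "multiclass") {
    pairs <- pairs[pairs$target_id %in% model$roster, , drop = FALSE]
    if (nrow(pairs) == 0L) return(.empty_predictions())
    compounds <- unique(pairs$compound_id)
    x <- apply_scaler(model$scaler, cmpf[compounds, , drop = FALSE])
    yhat <- predict(model$fits, x)
    rownames(yhat) <- compounds
    score <- yhat[cbind(match(pairs$compound_id, compounds),
                        match(pairs$target_id, model$roster))]
    cls <- label_activity(score, threshold)
    return(.predictions(pairs, score, cls, tag))
  }

  # qsar_single
  if (inherits(model$fits, "nb_zscore_model")) {
    covered <- names(model$fits$fits)
    pairs <- pairs[pairs$target_id %in% covered, , drop = FALSE]
    if (nrow(pairs) == 0L) return(.empty_predictions())
    compounds <- unique(pairs$compound_id)
    x <- cmpf[compounds, grepl("^bit_", colnames(cmpf)), drop = FALSE]
    all_preds <- nb_zscore_background(model$fits, x)
    key <- function(d) paste(d$compound_id, d$target_id, sep = "\r")
    out <- all_preds[match(key(pairs), key(all_preds)), , drop = FALSE]
    out$provenance <- tag
    rownames(out) <- NULL
    return(out)
  }
  covered <- names(model$fits)
  pairs <- pairs[pairs$target_id %in% covered, , drop = FALSE]
  if (nrow(pairs) == 0L) return(.empty_predictions())
  xs <- if (cfg$algorithm == "nb")
    cmpf[, grepl("^bit_", colnames(cmpf)), drop = FALSE]
  else apply_scaler(model$scaler, cmpf)
  out <- lapply(split(pairs, pairs$target_id), function(p) {
    x <- xs[p$compound_id, , drop = FALSE]
    fit <- model$fits[[p$target_id[1L]]]
    if (cfg$algorithm == "dnn") {
      score <- as.numeric(predict(fit, x))
      cls <- label_activity(score, threshold)
    } else {
      score <- baseline_scores(fit, x)
      cls <- ifelse(score > 0.5, "active", "inactive")
    }
    .predictions(p, score, cls, tag)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

.predictions <- function(pairs, score, cls, provenance) {
  data.frame(compound_id = pairs$compound_id, target_id = pairs$target_id,
             score = as.numeric(score), predicted_class = cls,
             provenance = provenance, stringsAsFactors = FALSE)
}

.empty_predictions <- function() {
  data.frame(compound_id = character(0), target_id = character(0),
             score = numeric(0), predicted_class = character(0),
             provenance = character(0), stringsAsFactors = FALSE)
}

#' Run one method on one split and score it
#'
#' Convenience wrapper: fit on the training partition, predict the test
#' partition, random-fill uncovered pairs, evaluate.
#'
#' @param config A [model_config()].
#' @param dataset The `curated_dataset`.
#' @param split A `split_spec`.
#' @param features Output of [featurize_dataset()].
#' @param dnn A [dnn_config()] for network algorithms.
#' @param fill_seed Seed for the random fill of uncovered pairs.
#' @return List with `model`, `predictions` and the `report`
#'   ([evaluate_predictions()]).
#' @export
benchmark_method <- function(config, dataset, split, features,
                             dnn = dnn_config(),
                             fill_seed = config$seed) {
  model <- fit_bioactivity_model(config, dataset, split, features, dnn)
  test <- split_records(dataset, split, "test")
  preds <- predict_bioactivity(model, test, features)
  preds <- fill_missing(preds, test, seed = fill_seed)
  report <- evaluate_predictions(preds, test,
                                 threshold = config$threshold,
                                 alpha = 20)
  list(model = model, predictions = preds, report = report)
}
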