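#' Model configuration for the benchmarked learners
#'
#' @param algorithm One of `"nb"`, `"rf"`, `"svm"`, `"lr"`, `"dnn"`.
#' @param mode One of `"qsar_single"` (one model per target),
#'   `"multiclass"` (one model, one output per target; networks only) or
#'   `"pcm"` (one model over compound-protein pairs with protein features).
#' @param threshold pChEMBL activity threshold (default 6.5).
#' @param n_bits Fingerprint length (default 256).
#' @param physchem Include the 6 physicochemical compound descriptors.
#' @param hyper Named list of algorithm-specific hyperparameter overrides.
#' @param seed Integer seed.
#' @return A `model_config`.
#' @export
model_config <- function(algorithm = c("nb", "rf", "svm", "lr", "dnn"),
                         mode = c("qsar_single", "multiclass", "pcm"),
                         threshold = 6.5, n_bits = 256L, physchem = FALSE,
                         hyper = list(), seed = 1L) {
  algorithm <- match.arg(algorithm)
  mode <- match.arg(mode)
  if (mode == "multiclass" && algorithm != "dnn") {
    stop("multiclass mode is supported for the network models only",
         call. = FALSE)
  }
  assert_scalar_number(threshold)
  structure(list(algorithm = algorithm, mode = mode, threshold = threshold,
                 n_bits = as.integer(n_bits), physchem = isTRUE(physchem),
                 hyper = hyper, seed = as.integer(seed)),
            class = "model_config")
}

#' Train one classical baseline classifier
#'
#' Fits a single binary classifier with the benchmark's printed settings:
#' \describe{
#'   \item{rf}{random forest, 1000 trees, 30% of the features sampled per
#'     split, unlimited depth}
#'   \item{svm}{RBF-kernel support vector classifier, `gamma = 1/d`,
#'     cost 1}
#'   \item{lr}{L2-regularised logistic regression capped at 100 iterations}
#'   \item{nb}{multinomial-event naive Bayes over binary fingerprint bits
#'     with Laplace smoothing}
#' }
#' Entries of `config$hyper` override the defaults (e.g. `ntree` for desk
#' scale tests).
#'
#' @param config A [model_config()] with algorithm `nb`, `rf`, `svm` or
#'   `lr`.
#' @param features Numeric feature matrix, one row per training example.
#' @param labels Character vector of `"active"` / `"inactive"`.
#' @return A `baseline_model` carrying the fitted state.
#' @export
train_baseline <- function(config, features, labels) {
  stopifnot(inherits(config, "model_config"),
            config$algorithm %in% c("nb", "rf", "svm", "lr"),
            is.matrix(features), nrow(features) == length(labels))
  if (length(unique(labels)) < 2L) {
    stop("training labels contain a single class", call. = FALSE)
  }
  y <- factor(labels, levels = c("inactive", "active"))
  d <- ncol(features)
  h <- config$hyper
  fit <- with_seed(config$seed, switch(
    config$algorithm,
    rf = randomForest::randomForest(
      x = features, y = y,
      ntree = h$ntree %||% 1000L,
      mtry = max(1L, floor((h$mtry_frac %||% 0.30) * d))),
    svm = e1071::svm(
      x = features, y = y, kernel = "radial",
      gamma = h$gamma %||% (1 / d), cost = h$cost %||% 1,
      probability = TRUE, scale = FALSE),  # inputs are pre-scaled
    lr = glmnet::glmnet(
      x = features, y = y, family = "binomial", alpha = 0,
      lambda = h$lambda %||% (1 / nrow(features)),
      maxit = h$maxit %||% 100L),
    nb = .fit_multinomial_nb(features, y, laplace = h$laplace %||% 1)))
  structure(list(config = config, fit = fit, n_features = d),
            class = "baseline_model")
}

#' Active-class scores from a baseline model
#'
#' @param model A `baseline_model`.
#' @param features Feature matrix with the training dimensionality.
#' @return Numeric vector of scores: active-class probability for `rf`,
#'   `svm` and `lr`; log-likelihood ratio for `nb`.
#' @export
baseline_scores <- function(model, features) {
  stopifnot(inherits(model, "baseline_model"), is.matrix(features))
  if (ncol(features) != model$n_features) {
    stop(sprintf("model expects %d features, got %d", model$n_features,
                 ncol(features)), call. = FALSE)
  }
  cfg <- model$config
  switch(cfg$algorithm,
    rf = unname(predict(model$fit, features, type = "prob")[, "active"]),
    svm = {
      p <- predict(model$fit, features, probability = TRUE)
      unname(attr(p, "probabilities")[, "active"])
    },
    lr = as.numeric(predict(model$fit, features, type = "response")),
    nb = stats::plogis(.nb_llr(model$fit, features)))
}

# ---- multinomial naive Bayes -------------------------------------------
# Event model over binary fingerprint bits: feature counts per class with
# Laplace smoothing; score is the log-likelihood ratio active vs inactive.
.fit_multinomial_nb <- function(x, y, laplace = 1) {
  stopifnot(all(x %in% c(0, 1)))
  act <- y == "active"
  count_act <- colSums(x[act, , drop = FALSE]) + laplace
  count_ina <- colSums(x[!act, , drop = FALSE]) + laplace
  list(logp_act = log(count_act / sum(count_act)),
       logp_ina = log(count_ina / sum(count_ina)),
       logprior = log(sum(act) / sum(!act)))
}

.nb_llr <- function(fit, x) {
  as.numeric(x %*% (fit$logp_act - fit$logp_ina) + fit$logprior)
}

#' Naive Bayes target ensemble with full-matrix z-score background
#'
#' Trains one multinomial naive Bayes per target, then scores every
#' compound in the collection against every modelled target and
#' standardises each target's raw scores to zero mean and unit standard
#' deviation (population SD) over all compounds. The emitted score is the
#' z-score; the within-target ranking is unchanged (affine transform), but
#' scores become comparable across targets. Targets whose training data is
#' single-class are skipped with a warning; a target whose raw scores have
#' zero variance gets z = 0 everywhere, with a warning.
#'
#' @param config A [model_config()] with `algorithm = "nb"`.
#' @param train_records Training records (`compound_id`, `target_id`,
#'   `pchembl`).
#' @param compound_features Feature matrix for all compounds (rownames =
#'   compound ids).
#' @param threshold pChEMBL activity threshold for the training labels.
#' @return An `nb_zscore_model`.
#' @export
train_nb_zscore <- function(config, train_records, compound_features,
                            threshold = config$threshold) {
  stopifnot(config$algorithm == "nb")
  per_target <- split(train_records, train_records$target_id)
  fits <- list()
  skipped <- character(0)
  for (tid in names(per_target)) {
    tr <- per_target[[tid]]
    labs <- label_activity(tr$pchembl, threshold)
    if (length(unique(labs)) < 2L) {
      skipped <- c(skipped, tid)
      next
    }
    x <- compound_features[tr$compound_id, , drop = FALSE]
    y <- factor(labs, levels = c("inactive", "active"))
    fits[[tid]] <- .fit_multinomial_nb(x, y)
  }
  if (length(skipped) > 0L) {
    warning(sprintf("naive Bayes skipped %d single-class target(s); %s",
                    length(skipped),
                    "their pairs fall back to random fill"), call. = FALSE)
  }
  structure(list(config = config, fits = fits,
                 n_features = ncol(compound_features)),
            class = "nb_zscore_model")
}

#' Score all compound-target pairs with z-score background correction
#'
#' @param model An `nb_zscore_model`.
#' @param compound_features Feature matrix for the compounds to score
#'   (rownames = compound ids).
#' @return Prediction-set data frame over every (compound, modelled target)
#'   pair; `score` is the per-target z-score, `predicted_class` is active
#'   for z > 0.
#' @export
nb_zscore_background <- function(model, compound_features) {
  stopifnot(inherits(model, "nb_zscore_model"))
  cmp <- rownames(compound_features)
  out <- vector("list", length(model$fits))
  for (k in seq_along(model$fits)) {
    tid <- names(model$fits)[k]
    raw <- .nb_llr(model$fits[[tid]], compound_features)
    s <- sqrt(mean((raw - mean(raw))^2))  # population SD over all compounds
    if (s == 0) {
      warning(sprintf("target %s: zero score variance; z set to 0", tid),
              call. = FALSE)
      z <- rep(0, length(raw))
    } else {
      z <- (raw - mean(raw)) / s
    }
    out[[k]] <- data.frame(compound_id = cmp, target_id = tid, score = z,
                           predicted_class = ifelse(z > 0, "active",
                                                    "inactive"),
                           provenance = "nb_zscore",
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
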