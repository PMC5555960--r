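#' Feed-forward network configuration
#'
#' Defaults mirror the benchmark's production settings: three hidden
#' rectifier layers of 4000/2000/1000 units, linear outputs predicting
#' pChEMBL values, no input dropout, 25% hidden dropout, batches of 128,
#' at most 2000 epochs with early stopping at 200 epochs patience on an
#' internal evaluation split (20% of the training rows), learning rate
#' annealed linearly from 0.005 to 0.0001 and Nesterov momentum grown
#' linearly from 0.8 to 0.999 over the run. `width_scale` shrinks every
#' hidden layer proportionally for desk-scale work without changing the
#' documented architecture.
#'
#' @param hidden_layers Integer vector of hidden-layer widths.
#' @param input_dropout Dropout fraction on the input layer (default 0).
#' @param hidden_dropout Dropout fraction on the hidden layers (default
#'   0.25).
#' @param batch_size Mini-batch size (default 128; 256 is the documented
#'   fallback for unstable runs).
#' @param max_epochs Maximum training epochs (default 2000; 500 in grid
#'   search).
#' @param patience Early-stopping patience in epochs (default 200).
#' @param lr_start,lr_end Learning-rate schedule endpoints.
#' @param momentum_start,momentum_end Nesterov momentum schedule endpoints.
#' @param eval_fraction Fraction of training rows held out for early
#'   stopping (default 0.20).
#' @param width_scale Multiplier applied to every hidden width (default 1).
#' @param seed Integer seed controlling initialisation, shuffling and
#'   dropout.
#' @return A `dnn_config`.
#' @export
dnn_config <- function(hidden_layers = c(4000L, 2000L, 1000L),
                       input_dropout = 0, hidden_dropout = 0.25,
                       batch_size = 128L, max_epochs = 2000L,
                       patience = 200L, lr_start = 0.005, lr_end = 1e-4,
                       momentum_start = 0.8, momentum_end = 0.999,
                       eval_fraction = 0.20, width_scale = 1, seed = 1L) {
  stopifnot(all(hidden_layers >= 1L),
            input_dropout >= 0, input_dropout < 1,
            hidden_dropout >= 0, hidden_dropout < 1,
            lr_start > lr_end, momentum_end > momentum_start,
            eval_fraction > 0, eval_fraction < 1, width_scale > 0)
  structure(list(hidden_layers = as.integer(hidden_layers),
                 input_dropout = input_dropout,
                 hidden_dropout = hidden_dropout,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 lr_start = lr_start, lr_end = lr_end,
                 momentum_start = momentum_start,
                 momentum_end = momentum_end,
                 eval_fraction = eval_fraction,
                 width_scale = width_scale,
                 seed = as.integer(seed)),
            class = "dnn_config")
}

#' Per-epoch learning-rate and momentum schedule
#'
#' Both quantities are interpolated linearly in the epoch number: the
#' learning rate from `lr_start` at epoch 1 down to `lr_end` at the last
#' epoch, the Nesterov momentum from `momentum_start` up to
#' `momentum_end`. Decaying the step size reduces the chance of jumping
#' over a minimum late in training, while growing momentum helps escape
#' local minima early on.
#'
#' @param epoch 1-based epoch index.
#' @param total_epochs Total number of epochs (at least 2).
#' @param config A [dnn_config()] supplying the endpoints.
#' @return List with `learning_rate` and `momentum`.
#' @export
schedule <- function(epoch, total_epochs, config = dnn_config()) {
  stopifnot(total_epochs >= 2L)
  if (epoch < 1L || epoch > total_epochs) {
    stop(sprintf("epoch %d outside [1, %d]", epoch, total_epochs),
         call. = FALSE)
  }
  f <- (epoch - 1) / (total_epochs - 1)
  list(learning_rate = config$lr_start + f * (config$lr_end - config$lr_start),
       momentum = config$momentum_start +
         f * (config$momentum_end - config$momentum_start))
}

#' Masked mean-squared-error over a sparse observation grid
#'
#' The squared error is averaged over the observed entries only: every
#' observed compound-target value carries equal weight, and unobserved
#' cells of the prediction grid contribute nothing. A batch with no
#' observed entry contributes a loss of 0.
#'
#' @param predicted Numeric matrix (rows x targets) of predictions.
#' @param observed Numeric matrix of the same shape with `NA` for
#'   unobserved cells.
#' @return Scalar masked MSE.
#' @export
masked_multitask_loss <- function(predicted, observed) {
  stopifnot(identical(dim(predicted), dim(observed)))
  mask <- !is.na(observed)
  n <- sum(mask)
  if (n == 0L) return(0)
  sum((predicted[mask] - observed[mask])^2) / n
}

# Glorot-style fan-scaled uniform initialisation
.init_layers <- function(sizes) {
  lapply(seq_len(length(sizes) - 1L), function(i) {
    fan_in <- sizes[i]; fan_out <- sizes[i + 1L]
    s <- sqrt(6 / (fan_in + fan_out))
    list(W = matrix(runif(fan_in * fan_out, -s, s), fan_in, fan_out),
         b = rep(0, fan_out))
  })
}

.forward <- function(layers, x, input_dropout = 0, hidden_dropout = 0,
                     training = FALSE) {
  acts <- vector("list", length(layers) + 1L)
  h <- x
  if (training && input_dropout > 0) {
    keep <- matrix(runif(length(h)) >= input_dropout, nrow(h), ncol(h))
    h <- h * keep / (1 - input_dropout)
  }
  acts[[1L]] <- h
  for (i in seq_along(layers)) {
    zi <- sweep(h %*% layers[[i]]$W, 2L, layers[[i]]$b, "+")
    if (i < length(layers)) {
      h <- pmax(zi, 0)  # rectified linear hidden units
      if (training && hidden_dropout > 0) {
        keep <- matrix(runif(length(h)) >= hidden_dropout, nrow(h), ncol(h))
        h <- h * keep / (1 - hidden_dropout)
      }
    } else {
      h <- zi  # linear output
    }
    acts[[i + 1L]] <- h
  }
  acts
}

#' Train a feed-forward bioactivity regression network
#'
#' Trains a rectifier network with linear outputs on pChEMBL values by
#' stochastic gradient descent with Nesterov momentum, the linear
#' learning-rate/momentum schedules of [schedule()], inverted dropout, and
#' the masked loss of [masked_multitask_loss()], so rows may carry values
#' for any subset of the output targets. Early stopping monitors the masked
#' loss on a seeded 20% evaluation split of the training rows and restores
#' the best-epoch weights after `patience` epochs without improvement.
#' Training is deterministic given `config$seed`.
#'
#' @param config A [dnn_config()].
#' @param x Numeric feature matrix (already scaled; see [fit_scaler()]).
#' @param y Numeric matrix of observed pChEMBL values, `NA` where a row has
#'   no measurement for a target; a plain vector is treated as a one-column
#'   matrix (single-task and proteochemometric modes).
#' @param verbose Print the evaluation loss every 50 epochs.
#' @return A `dnn_model` with the fitted weights, the training curve and
#'   the best epoch.
#' @export
train_dnn <- function(config, x, y, verbose = FALSE) {
  stopifnot(inherits(config, "dnn_config"), is.matrix(x))
  if (!is.matrix(y)) y <- matrix(y, ncol = 1L)
  stopifnot(nrow(x) == nrow(y))
  widths <- pmax(1L, as.integer(round(config$hidden_layers *
                                        config$width_scale)))
  sizes <- c(ncol(x), widths, ncol(y))

  with_seed(config$seed, {
    layers <- .init_layers(sizes)
    vel <- lapply(layers, function(l)
      list(W = matrix(0, nrow(l$W), ncol(l$W)), b = rep(0, length(l$b))))

    n <- nrow(x)
    eval_idx <- sample(n, max(1L, round(config$eval_fraction * n)))
    train_idx <- setdiff(seq_len(n), eval_idx)
    xe <- x[eval_idx, , drop = FALSE]; ye <- y[eval_idx, , drop = FALSE]
    xt <- x[train_idx, , drop = FALSE]; yt <- y[train_idx, , drop = FALSE]

    best <- list(loss = Inf, layers = layers, epoch = 0L)
    curve <- numeric(0)
    total <- config$max_epochs
    for (epoch in seq_len(total)) {
      sch <- schedule(epoch, max(total, 2L), config)
      lr <- sch$learning_rate; mom <- sch$momentum
      ord <- sample(nrow(xt))
      starts <- seq(1L, nrow(xt), by = config$batch_size)
      for (s in starts) {
        idx <- ord[s:min(s + config$batch_size - 1L, nrow(xt))]
        xb <- xt[idx, , drop = FALSE]; yb <- yt[idx, , drop = FALSE]
        mask <- !is.na(yb)
        nobs <- sum(mask)
        if (nobs == 0L) next
        acts <- .forward(layers, xb, config$input_dropout,
                         config$hidden_dropout, training = TRUE)
        pred <- acts[[length(acts)]]
        delta <- matrix(0, nrow(pred), ncol(pred))
        delta[mask] <- 2 * (pred[mask] - yb[mask]) / nobs
        if (any(!is.finite(delta))) {
          stop("divergent loss (non-finite gradient); consider batch_size ",
               "= 256 or a smaller learning rate", call. = FALSE)
        }
        for (i in rev(seq_along(layers))) {
          a_in <- acts[[i]]
          gW <- crossprod(a_in, delta)
          gb <- colSums(delta)
          if (i > 1L) {
            # stored activations are post-dropout: zeroed units kill the
            # gradient, kept units carry the inverted-dropout 1/(1-p) scale
            delta <- (delta %*% t(layers[[i]]$W)) * (acts[[i]] > 0)
            if (config$hidden_dropout > 0) {
              delta <- delta / (1 - config$hidden_dropout)
            }
          }
          # Nesterov momentum update (velocity form)
          vel[[i]]$W <- mom * vel[[i]]$W - lr * gW
          vel[[i]]$b <- mom * vel[[i]]$b - lr * gb
          layers[[i]]$W <- layers[[i]]$W + mom * vel[[i]]$W - lr * gW
          layers[[i]]$b <- layers[[i]]$b + mom * vel[[i]]$b - lr * gb
        }
      }
      acts_e <- .forward(layers, xe, training = FALSE)
      eloss <- masked_multitask_loss(acts_e[[length(acts_e)]], ye)
      if (!is.finite(eloss)) {
        stop("divergent loss (non-finite evaluation loss); consider ",
             "batch_size = 256 or a smaller learning rate", call. = FALSE)
      }
      curve <- c(curve, eloss)
      if (eloss < best$loss - 1e-12) {
        best <- list(loss = eloss, layers = layers, epoch = epoch)
      }
      if (verbose && epoch %% 50L == 0L) {
        message(sprintf("epoch %d: eval loss %.4f (best %.4f @ %d)",
                        epoch, eloss, best$loss, best$epoch))
      }
      if (epoch - best$epoch >= config$patience) break
    }
  })

  structure(list(config = config, layers = best$layers,
                 best_epoch = best$epoch, eval_curve = curve,
                 n_features = ncol(x), n_outputs = ncol(y),
                 output_names = colnames(y)),
            class = "dnn_model")
}

#' Predict pChEMBL values with a trained network
#'
#' @param object A `dnn_model`.
#' @param x Feature matrix with the training dimensionality (scaled with the
#'   same scaler as the training rows).
#' @param ... Unused.
#' @return Numeric matrix of predicted pChEMBL values (rows x outputs).
#' @export
predict.dnn_model <- function(object, x, ...) {
  stopifnot(is.matrix(x))
  if (ncol(x) != object$n_features) {
    stop(sprintf("network expects %d features, got %d", object$n_features,
                 ncol(x)), call. = FALSE)
  }
  acts <- .forward(object$layers, x, training = FALSE)
  out <- acts[[length(acts)]]
  colnames(out) <- object$output_names
  out
}
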