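#' Initialise a one-hidden-layer feed-forward network
#'
#' Architecture n_i - n_h - 1: logistic-sigmoid hidden layer, linear output.
#' The forward map is `y = sum_J W_J * sigmoid(sum_I W_JI x_I + b_J) + b_out`.
#' Weights and biases are drawn uniformly from [-0.3, 0.3] under the given
#' seed (small symmetric initialisation keeps the sigmoids un-saturated);
#' momentum buffers start at zero.
#'
#' @param n_inputs,n_hidden Layer sizes, >= 1.
#' @param seed Integer seed; identical seeds give identical states.
#' @return An object of class `bpnn`: `W1` (n_hidden x n_inputs), `b1`,
#'   `w2` (length n_hidden), `b2`, plus zeroed `prev` update buffers.
#' @export
#' @examples
#' net <- init_network(6, 5, seed = 1)  # the 6-5-1 architecture: 41 parameters
init_network <- function(n_inputs, n_hidden, seed = 1L) {
  stopifnot(n_inputs >= 1, n_hidden >= 1)
  with_seed(seed, {
    structure(
      list(
        n_inputs = as.integer(n_inputs), n_hidden = as.integer(n_hidden),
        W1 = matrix(stats::runif(n_hidden * n_inputs, -0.3, 0.3),
                    nrow = n_hidden),
        b1 = stats::runif(n_hidden, -0.3, 0.3),
        w2 = stats::runif(n_hidden, -0.3, 0.3),
        b2 = stats::runif(1, -0.3, 0.3),
        prev = list(W1 = matrix(0, n_hidden, n_inputs),
                    b1 = numeric(n_hidden),
                    w2 = numeric(n_hidden),
                    b2 = 0)
      ),
      class = "bpnn"
    )
  })
}

#' @export
print.bpnn <- function(x, ...) {
  cat(sprintf("<bpnn> %d-%d-1 (sigmoid hidden, linear output), %d parameters\n",
              x$n_inputs, x$n_hidden,
              x$n_hidden * x$n_inputs + 2 * x$n_hidden + 1))
  invisible(x)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

#' Forward pass of a network
#'
#' @param state A `bpnn`.
#' @param x Input: a length-`n_inputs` vector or a rows-as-samples matrix.
#' @return Numeric vector of network outputs, one per input row.
#' @export
nn_forward <- function(state, x) {
  X <- if (is.null(dim(x))) matrix(x, nrow = 1) else as.matrix(x)
  if (ncol(X) != state$n_inputs) {
    stop(sprintf("shape mismatch: network expects %d inputs, got %d",
                 state$n_inputs, ncol(X)), call. = FALSE)
  }
  H <- sigmoid(X %*% t(state$W1) + matrix(state$b1, nrow(X), state$n_hidden,
                                          byrow = TRUE))
  as.numeric(H %*% state$w2 + state$b2)
}

#' Training configuration for backpropagation with momentum
#'
#' @param learning_rate Step size mu in (0, 1]; 0 is accepted and means the
#'   network does not learn (a fixed point of training).
#' @param momentum Momentum alpha in [0, 1): fraction of the previous weight
#'   update added to the current one.
#' @param max_epochs Maximum number of full-batch epochs.
#' @param patience Early-stopping patience: training stops once the
#'   validation MSE has not improved for this many consecutive epochs
#'   (`Inf` disables early stopping).
#' @param seed Integer seed (used by callers that also initialise weights).
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.7, momentum = 0.2,
                         max_epochs = 300, patience = 50, seed = 1L) {
  stopifnot(learning_rate >= 0, learning_rate <= 1,
            momentum >= 0, momentum < 1, max_epochs >= 1, patience >= 1)
  structure(
    list(learning_rate = learning_rate, momentum = momentum,
         max_epochs = as.integer(max_epochs), patience = patience,
         seed = as.integer(seed)),
    class = "train_config"
  )
}

#' One full-batch backpropagation step with momentum
#'
#' Computes the gradient of the half-mean-squared error
#' `E = 1/(2n) sum (yhat_i - y_i)^2` over the whole batch and applies the
#' momentum update `delta_w = -mu * dE/dw + alpha * delta_w_prev`; the
#' applied update replaces the momentum buffers.
#'
#' @param state A `bpnn`.
#' @param X Batch inputs (n x n_inputs matrix), scaled.
#' @param y Batch targets (length n), scaled.
#' @param config A [train_config()].
#' @return List with the updated `state` and the pre-update batch `mse`
#'   (mean of squared residuals).
#' @export
train_step <- function(state, X, y, config) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n == 0) stop("empty batch", call. = FALSE)
  if (!all(is.finite(X)) || !all(is.finite(y))) {
    stop("non-finite training inputs", call. = FALSE)
  }
  H <- sigmoid(X %*% t(state$W1) + matrix(state$b1, n, state$n_hidden,
                                          byrow = TRUE))
  yhat <- as.numeric(H %*% state$w2 + state$b2)
  res <- yhat - y
  # gradients of E = mean(res^2)/2
  g_out <- res / n                                   # dE/dyhat
  g_w2 <- as.numeric(crossprod(H, g_out))            # dE/dw2
  g_b2 <- sum(g_out)
  g_hidden <- (g_out %*% t(state$w2)) * H * (1 - H)  # n x n_hidden
  g_W1 <- crossprod(g_hidden, X)                     # n_hidden x n_inputs
  g_b1 <- colSums(g_hidden)

  mu <- config$learning_rate
  al <- config$momentum
  upd <- list(
    W1 = -mu * g_W1 + al * state$prev$W1,
    b1 = -mu * g_b1 + al * state$prev$b1,
    w2 = -mu * g_w2 + al * state$prev$w2,
    b2 = -mu * g_b2 + al * state$prev$b2
  )
  state$W1 <- state$W1 + upd$W1
  state$b1 <- state$b1 + upd$b1
  state$w2 <- state$w2 + upd$w2
  state$b2 <- state$b2 + upd$b2
  state$prev <- upd
  list(state = state, mse = mean(res^2))
}

#' Train a network with validation-based early stopping
#'
#' Runs full-batch epochs up to `max_epochs`, evaluating validation MSE
#' after every epoch. Training stops once the validation MSE has not
#' improved for `patience` consecutive epochs, and the returned state is the
#' one from the epoch with minimum validation MSE (best-state restoration).
#'
#' @param state A `bpnn` initial state.
#' @param X,y Training inputs/targets (scaled).
#' @param X_val,y_val Validation inputs/targets (scaled), disjoint from the
#'   training set.
#' @param config A [train_config()].
#' @return An object of class `train_result`: `state` (best), `train_mse`
#'   and `val_mse` epoch curves, `best_epoch`, `stop_epoch`.
#' @export
train_network <- function(state, X, y, X_val, y_val, config) {
  X <- as.matrix(X); X_val <- as.matrix(X_val)
  if (nrow(X) == 0 || nrow(X_val) == 0) {
    stop("training and validation sets must be non-empty", call. = FALSE)
  }
  train_mse <- numeric(config$max_epochs)
  val_mse <- numeric(config$max_epochs)
  best_val <- Inf
  best_state <- state
  best_epoch <- 0L
  since_best <- 0L
  stop_epoch <- config$max_epochs
  for (epoch in seq_len(config$max_epochs)) {
    step <- train_step(state, X, y, config)
    state <- step$state
    train_mse[epoch] <- mean((nn_forward(state, X) - y)^2)
    val_mse[epoch] <- mean((nn_forward(state, X_val) - y_val)^2)
    if (val_mse[epoch] < best_val) {
      best_val <- val_mse[epoch]
      best_state <- state
      best_epoch <- epoch
      since_best <- 0L
    } else {
      since_best <- since_best + 1L
      if (since_best >= config$patience) {
        stop_epoch <- epoch
        break
      }
    }
  }
  structure(
    list(state = best_state,
         train_mse = train_mse[seq_len(stop_epoch)],
         val_mse = val_mse[seq_len(stop_epoch)],
         best_epoch = best_epoch, stop_epoch = stop_epoch),
    class = "train_result"
  )
}

#' @export
print.train_result <- function(x, ...) {
  cat(sprintf(
    "<train_result> stopped at epoch %d (best validation MSE %.3g at epoch %d)\n",
    x$stop_epoch, min(x$val_mse), x$best_epoch))
  invisible(x)
}

#' Fit input/target scaling on calibration data
#'
#' Inputs (PC scores) are standardised to zero mean / unit variance;
#' targets (concentrations) are min-max scaled to [0.1, 0.9], the classic
#' convention that keeps sigmoid-era networks away from saturation. Scaling
#' parameters are frozen on the calibration set only.
#'
#' @param X Calibration inputs (n x d matrix).
#' @param y Calibration targets (molar).
#' @return An object of class `nn_scaling`.
#' @export
fit_nn_scaling <- function(X, y) {
  X <- as.matrix(X)
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  y_min <- min(y); y_max <- max(y)
  if (y_max == y_min) stop("constant targets: scaling undefined", call. = FALSE)
  structure(
    list(x_center = ctr, x_scale = scl, y_min = y_min, y_max = y_max,
         y_lo = 0.1, y_hi = 0.9),
    class = "nn_scaling"
  )
}

#' Apply input scaling
#' @param scaling An `nn_scaling`.
#' @param X Inputs with the calibration number of columns.
#' @return Scaled matrix.
#' @export
scale_inputs <- function(scaling, X) {
  X <- if (is.null(dim(X))) matrix(X, nrow = 1) else as.matrix(X)
  sweep(sweep(X, 2, scaling$x_center), 2, scaling$x_scale, "/")
}

#' Apply / invert target scaling
#' @param scaling An `nn_scaling`.
#' @param y Targets in molar units (`scale_targets`) or network units
#'   (`unscale_targets`).
#' @return Numeric vector.
#' @export
scale_targets <- function(scaling, y) {
  scaling$y_lo + (scaling$y_hi - scaling$y_lo) *
    (y - scaling$y_min) / (scaling$y_max - scaling$y_min)
}

#' @rdname scale_targets
#' @export
unscale_targets <- function(scaling, y) {
  scaling$y_min + (y - scaling$y_lo) / (scaling$y_hi - scaling$y_lo) *
    (scaling$y_max - scaling$y_min)
}

#' Predict concentrations with a trained network
#'
#' Scales the inputs, runs the forward pass, and inverts the target scaling
#' back to molar units.
#'
#' @param state A trained `bpnn`.
#' @param scaling The `nn_scaling` fitted on the calibration set.
#' @param X Raw (unscaled) inputs, rows = samples.
#' @return Predicted concentrations (molar).
#' @export
nn_predict <- function(state, scaling, X) {
  unscale_targets(scaling, nn_forward(state, scale_inputs(scaling, X)))
}

#' Serialise a trained network (with scaling) to a text file
#'
#' Plain-text format carrying shapes, weights at full precision, and the
#' scaling parameters, so a model reloads exactly.
#'
#' @param state A `bpnn`.
#' @param scaling An `nn_scaling` (or `NULL`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_network <- function(state, scaling, path) {
  num <- function(x) paste(fmt_num(as.numeric(x)), collapse = " ")
  lines <- c(
    "# eemcalib bpnn v1",
    paste("n_inputs", state$n_inputs),
    paste("n_hidden", state$n_hidden),
    paste("W1", num(state$W1)),
    paste("b1", num(state$b1)),
    paste("w2", num(state$w2)),
    paste("b2", num(state$b2))
  )
  if (!is.null(scaling)) {
    lines <- c(lines,
               paste("x_center", num(scaling$x_center)),
               paste("x_scale", num(scaling$x_scale)),
               paste("y_range", num(c(scaling$y_min, scaling$y_max,
                                      scaling$y_lo, scaling$y_hi))))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Reload a serialised network
#'
#' @param path File written by [write_network()].
#' @return List with `state` (`bpnn`) and `scaling` (`nn_scaling` or `NULL`).
#' @export
read_network <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  fields <- list()
  for (ln in lines) {
    parts <- strsplit(ln, " ")[[1]]
    fields[[parts[1]]] <- as.numeric(parts[-1])
  }
  n_i <- as.integer(fields$n_inputs)
  n_h <- as.integer(fields$n_hidden)
  state <- structure(
    list(n_inputs = n_i, n_hidden = n_h,
         W1 = matrix(fields$W1, n_h, n_i),
         b1 = fields$b1, w2 = fields$w2, b2 = fields$b2,
         prev = list(W1 = matrix(0, n_h, n_i), b1 = numeric(n_h),
                     w2 = numeric(n_h), b2 = 0)),
    class = "bpnn"
  )
  scaling <- NULL
  if (!is.null(fields$x_center)) {
    scaling <- structure(
      list(x_center = fields$x_center, x_scale = fields$x_scale,
           y_min = fields$y_range[1], y_max = fields$y_range[2],
           y_lo = fields$y_range[3], y_hi = fields$y_range[4]),
      class = "nn_scaling"
    )
  }
  list(state = state, scaling = scaling)
}
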