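# The surrogate ("mapper"): a fully connected multilayer perceptron that
# predicts a candidate's cost from its normalized parameters, so that
# candidates predicted to be clearly poor can skip the expensive property
# evaluation. Architecture: four ReLU hidden layers of 40 nodes each, a
# dropout layer (rate 0.10) after every hidden layer, a max-norm constraint
# of 5.0 on each unit's incoming weights, and a linear output. Trained with
# Adam on the mean squared error with early stopping on a validation split.

#' Surrogate network configuration
#'
#' Architecture defaults (4 hidden layers of 40 ReLU nodes, dropout 0.10,
#' max-norm 5.0, linear output, early stopping) are fixed by the design of
#' the screening loop; the remaining training hyperparameters are surfaced
#' here with conventional defaults.
#'
#' @param hidden_layers Number of hidden layers.
#' @param nodes Nodes per hidden layer.
#' @param dropout Dropout rate applied after each hidden layer in training.
#' @param max_norm Maximum L2 norm of each unit's incoming weight vector.
#' @param patience Early-stopping patience (epochs without validation
#'   improvement).
#' @param val_fraction Fraction of rows held out for validation.
#' @param learning_rate Adam step size.
#' @param batch_size Minibatch size.
#' @param max_epochs Epoch cap.
#' @param min_rows Below this many training rows the mapper refuses to train
#'   and the skip gate becomes pass-through.
#' @param transform Target transform: `"log1p"` (default) trains the network
#'   on `log(1 + cost)` and back-transforms predictions, concentrating
#'   resolution at the low-cost end where gate decisions are made;
#'   `"identity"` trains on the raw cost.
#' @param seed Optional integer; when given, training is run under this seed
#'   (the caller's RNG state is restored afterwards).
#' @return An object of class `mapper_config`.
#' @export
mapper_config <- function(hidden_layers = 4L, nodes = 40L, dropout = 0.10,
                          max_norm = 5.0, patience = 50L, val_fraction = 0.2,
                          learning_rate = 1e-3, batch_size = 128L,
                          max_epochs = 500L, min_rows = 20L,
                          transform = c("log1p", "identity"), seed = NULL) {
  transform <- match.arg(transform)
  stopifnot(hidden_layers >= 1, nodes >= 1, dropout >= 0, dropout < 1,
            max_norm > 0, patience >= 1, val_fraction > 0, val_fraction < 1,
            learning_rate > 0, batch_size >= 1, max_epochs >= 1, min_rows >= 2)
  structure(list(hidden_layers = as.integer(hidden_layers),
                 nodes = as.integer(nodes), dropout = dropout,
                 max_norm = max_norm, patience = as.integer(patience),
                 val_fraction = val_fraction, learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 min_rows = as.integer(min_rows), transform = transform,
                 seed = seed),
            class = "mapper_config")
}

# Run expr under a local seed, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

mlp_init <- function(n_in, config) {
  sizes <- c(n_in, rep(config$nodes, config$hidden_layers), 1L)
  lapply(seq_len(length(sizes) - 1L), function(l) {
    # He-normal initialization for the ReLU stack
    list(W = matrix(rnorm(sizes[l] * sizes[l + 1L], sd = sqrt(2 / sizes[l])),
                    sizes[l], sizes[l + 1L]),
         b = rep(0, sizes[l + 1L]))
  })
}

# Forward pass; X is (batch x n_in). Returns activations when training.
mlp_forward <- function(layers, X, dropout = 0, keep_cache = FALSE) {
  nl <- length(layers)
  A <- X
  cache <- if (keep_cache) vector("list", nl) else NULL
  for (l in seq_len(nl)) {
    # column-major bias add, cheaper than sweep() in this hot loop
    Z <- A %*% layers[[l]]$W + rep(layers[[l]]$b, each = nrow(A))
    if (l < nl) {
      H <- pmax(Z, 0)
      mask <- NULL
      if (dropout > 0) {
        mask <- matrix(runif(length(H)) >= dropout, nrow(H), ncol(H)) /
          (1 - dropout)
        H <- H * mask
      }
      if (keep_cache) cache[[l]] <- list(A_in = A, Z = Z, mask = mask)
      A <- H
    } else {
      if (keep_cache) cache[[l]] <- list(A_in = A)
      A <- Z
    }
  }
  if (keep_cache) list(out = A, cache = cache) else A
}

# One Adam minibatch update on squared-error loss; returns layers + moments.
mlp_update <- function(layers, mom, X, y, config, t, lr) {
  fw <- mlp_forward(layers, X, dropout = config$dropout, keep_cache = TRUE)
  n <- nrow(X)
  delta <- 2 * (fw$out - y) / n # d(mse)/d(out), y column vector
  nl <- length(layers)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  for (l in rev(seq_len(nl))) {
    A_in <- fw$cache[[l]]$A_in
    gW <- crossprod(A_in, delta)
    gb <- colSums(delta)
    if (l > 1L) {
      delta <- delta %*% t(layers[[l]]$W)
      mask <- fw$cache[[l - 1L]]$mask
      if (!is.null(mask)) delta <- delta * mask
      delta <- delta * (fw$cache[[l - 1L]]$Z > 0)
    }
    m <- mom[[l]]
    m$mW <- b1 * m$mW + (1 - b1) * gW
    m$vW <- b2 * m$vW + (1 - b2) * gW^2
    m$mb <- b1 * m$mb + (1 - b1) * gb
    m$vb <- b2 * m$vb + (1 - b2) * gb^2
    corr1 <- 1 - b1^t; corr2 <- 1 - b2^t
    layers[[l]]$W <- layers[[l]]$W -
      lr * (m$mW / corr1) / (sqrt(m$vW / corr2) + eps)
    layers[[l]]$b <- layers[[l]]$b -
      lr * (m$mb / corr1) / (sqrt(m$vb / corr2) + eps)
    if (l < nl) {
      # max-norm constraint on each unit's incoming weight vector
      cn <- sqrt(colSums(layers[[l]]$W^2))
      over <- cn > config$max_norm
      if (any(over))
        layers[[l]]$W[, over] <- sweep(layers[[l]]$W[, over, drop = FALSE],
                                       2, config$max_norm / cn[over], "*")
    }
    mom[[l]] <- m
  }
  list(layers = layers, mom = mom)
}

#' Train the cost-predicting surrogate
#'
#' Fits the multilayer perceptron to observed (normalized parameters, cost)
#' pairs. Training holds out a validation fraction, stops when the
#' validation loss has not improved for `patience` epochs, and restores the
#' best-validation weights. With fewer than `min_rows` rows the mapper
#' refuses to train and returns a pass-through surrogate whose skip gate
#' never rejects a candidate.
#'
#' @param x Numeric matrix (rows = observations) of normalized parameters in
#'   `[0, 1]`.
#' @param y Observed costs, finite and `>= 0`.
#' @param config A [mapper_config()].
#' @return An object of class `water_mapper`; check `$trained`.
#' @export
train_mapper <- function(x, y, config = mapper_config()) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  if (nrow(x) != length(y)) stop("nrow(x) must equal length(y)", call. = FALSE)
  if (any(!is.finite(y)) || any(y < 0))
    stop("training costs must be finite and >= 0", call. = FALSE)
  if (any(!is.finite(x)) || any(x < -1e-9) || any(x > 1 + 1e-9))
    stop("training inputs must lie in [0, 1]", call. = FALSE)
  if (nrow(x) < config$min_rows) {
    return(structure(list(trained = FALSE, config = config,
                          n_train = nrow(x)),
                     class = "water_mapper"))
  }
  with_local_seed(config$seed, train_mapper_impl(x, y, config))
}

train_mapper_impl <- function(x, y, config) {
  n <- nrow(x)
  if (config$transform == "log1p") y <- log1p(y)
  y_center <- mean(y)
  y_scale <- sd(y)
  if (!is.finite(y_scale) || y_scale < 1e-12) y_scale <- 1
  ys <- (y - y_center) / y_scale

  idx <- sample.int(n)
  n_val <- max(1L, floor(config$val_fraction * n))
  val_idx <- idx[seq_len(n_val)]
  tr_idx <- idx[-seq_len(n_val)]
  Xtr <- x[tr_idx, , drop = FALSE]; ytr <- ys[tr_idx]
  Xval <- x[val_idx, , drop = FALSE]; yval <- ys[val_idx]

  layers <- mlp_init(ncol(x), config)
  mom <- lapply(layers, function(l)
    list(mW = l$W * 0, vW = l$W * 0, mb = l$b * 0, vb = l$b * 0))

  best_layers <- layers
  best_val <- Inf
  wait <- 0L
  t <- 0L
  lr <- config$learning_rate
  lr_wait <- 0L
  log_epoch <- integer(0); log_train <- numeric(0); log_val <- numeric(0)
  ntr <- nrow(Xtr)
  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample.int(ntr)
    starts <- seq(1L, ntr, by = config$batch_size)
    for (s in starts) {
      rows <- ord[s:min(s + config$batch_size - 1L, ntr)]
      t <- t + 1L
      up <- mlp_update(layers, mom,
                       Xtr[rows, , drop = FALSE],
                       matrix(ytr[rows], ncol = 1), config, t, lr)
      layers <- up$layers; mom <- up$mom
    }
    tr_mse <- mean((mlp_forward(layers, Xtr) - ytr)^2)
    val_mse <- mean((mlp_forward(layers, Xval) - yval)^2)
    log_epoch <- c(log_epoch, epoch)
    log_train <- c(log_train, tr_mse)
    log_val <- c(log_val, val_mse)
    if (val_mse < best_val - 1e-12) {
      best_val <- val_mse
      best_layers <- layers
      wait <- 0L
      lr_wait <- 0L
    } else {
      wait <- wait + 1L
      lr_wait <- lr_wait + 1L
      if (wait >= config$patience) break
      # dropout makes the gradient noisy; anneal the step size on plateaus
      # so the fit can settle below the constant-rate noise floor
      if (lr_wait >= max(5L, config$patience %/% 4L) && lr > 1e-5) {
        lr <- lr / 2
        lr_wait <- 0L
      }
    }
  }
  structure(list(trained = TRUE, config = config, layers = best_layers,
                 y_center = y_center, y_scale = y_scale, n_train = n,
                 val_mse = best_val,
                 val_r2 = 1 - best_val / max(mean((yval - mean(yval))^2),
                                             .Machine$double.eps),
                 log = data.frame(epoch = log_epoch, train_mse = log_train,
                                  val_mse = log_val)),
            class = "water_mapper")
}

#' @export
print.water_mapper <- function(x, ...) {
  if (!x$trained) {
    cat("Untrained (pass-through) cost surrogate;", x$n_train,
        "rows available\n")
  } else {
    cat(sprintf(
      "Cost surrogate: MLP %d x %d ReLU, trained on %d rows, %d epochs, val MSE %.4g\n",
      x$config$hidden_layers, x$config$nodes, x$n_train, nrow(x$log),
      x$val_mse * x$y_scale^2))
  }
  invisible(x)
}

# Internal: wrap an arbitrary function of the normalized 6-vector as a
# surrogate (used to test search machinery against analytic landscapes).
function_surrogate <- function(fn) {
  structure(list(trained = TRUE, fn = fn, n_train = NA_integer_),
            class = "water_mapper")
}

#' Predict the cost of normalized candidates
#'
#' Deterministic forward pass (dropout disabled). Inputs must lie in the
#' unit hypercube. For an untrained (pass-through) surrogate the prediction
#' is `NA`.
#'
#' @param surrogate A `water_mapper` from [train_mapper()].
#' @param x Normalized 6-vector, or a matrix of row vectors.
#' @return Numeric vector of predicted costs.
#' @export
predict_cost <- function(surrogate, x) {
  stopifnot(inherits(surrogate, "water_mapper"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  x <- as.matrix(x)
  if (any(!is.finite(x)) || any(x < -1e-9) || any(x > 1 + 1e-9))
    stop("normalized inputs must lie in [0, 1]", call. = FALSE)
  if (!surrogate$trained) return(rep(NA_real_, nrow(x)))
  if (!is.null(surrogate$fn))
    return(vapply(seq_len(nrow(x)), function(i) surrogate$fn(x[i, ]),
                  numeric(1)))
  out <- mlp_forward(surrogate$layers, x)
  z <- as.numeric(out) * surrogate$y_scale + surrogate$y_center
  if (surrogate$config$transform == "log1p") expm1(z) else z
}

#' Surrogate gate: should a candidate skip true evaluation?
#'
#' A candidate whose predicted cost exceeds the threshold is skipped (its
#' expensive property evaluation is not run, and a new candidate is drawn).
#' Wrongly rejected good candidates are not lost permanently: the stochastic
#' proposal process can re-propose that region later, once the surrogate has
#' improved. An untrained surrogate never skips.
#'
#' @param surrogate A `water_mapper`.
#' @param x Normalized 6-vector.
#' @param threshold Cost threshold; `Inf` disables the gate.
#' @return List (class `skip_decision`) with `predicted`, `threshold`,
#'   `skipped`.
#' @export
should_skip <- function(surrogate, x, threshold) {
  stopifnot(is.numeric(threshold), length(threshold) == 1L)
  pred <- predict_cost(surrogate, x)[1]
  skipped <- surrogate$trained && is.finite(pred) && pred > threshold
  structure(list(predicted = pred, threshold = threshold, skipped = skipped),
            class = "skip_decision")
}
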