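#' Rectified linear unit
#'
#' @param x numeric vector/matrix.
#' @return `x` where `x >= 0`, else 0.
#' @export
relu <- function(x) pmax(x, 0)

# run `code` under a private RNG stream, restoring the caller's state
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Training configuration for the autoencoder
#'
#' Defaults fix the hyperparameters the reference procedure leaves open:
#' ridge penalty `lambda = 1e-4`, SGD with `learning_rate = 0.01` and
#' `momentum = 0.9`, `batch_size = 32`, `epochs = 500`, uniform
#' plus/minus `1/sqrt(fan_in)` initialization.
#'
#' @param lambda ridge penalty on all weight matrices (biases excluded).
#' @param learning_rate SGD step size.
#' @param momentum classical momentum coefficient.
#' @param epochs number of passes over the data.
#' @param batch_size mini-batch size.
#' @param clip_norm per-batch gradient global-norm clip; SGD with this
#'   momentum overshoots into dead-ReLU collapse on z-scored panels
#'   without it. `Inf` disables clipping.
#' @param seed integer seed controlling initialization and shuffling.
#' @param hidden encoder hidden layer sizes before the bottleneck.
#' @param bottleneck bottleneck width (number of nodes), default 20.
#' @param linear_bottleneck if `TRUE` the bottleneck layer is linear
#'   instead of ReLU.
#' @return list of class `training_config`.
#' @export
training_config <- function(lambda = 1e-4, learning_rate = 0.01,
                            momentum = 0.9, epochs = 500L,
                            batch_size = 32L, clip_norm = 5,
                            seed = 1L,
                            hidden = c(400L, 100L), bottleneck = 20L,
                            linear_bottleneck = FALSE) {
  stopifnot(lambda >= 0, learning_rate > 0, momentum >= 0, epochs >= 1,
            batch_size >= 1, clip_norm > 0, bottleneck >= 1)
  structure(list(lambda = lambda, learning_rate = learning_rate,
                 momentum = momentum, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 clip_norm = clip_norm,
                 seed = as.integer(seed), hidden = as.integer(hidden),
                 bottleneck = as.integer(bottleneck),
                 linear_bottleneck = isTRUE(linear_bottleneck)),
            class = "training_config")
}

#' Initialize a symmetric autoencoder
#'
#' Encoder compresses `d_in -> hidden... -> bottleneck`; the decoder
#' mirrors the sizes back up to `d_in`. Every hidden layer (bottleneck
#' included, unless `linear_bottleneck`) is followed by a ReLU; the
#' reconstruction output layer is linear because the targets are
#' z-scores that can be negative. Weights are drawn uniformly from
#' plus/minus `1/sqrt(fan_in)` under `seed`; biases start at 0. Encoder
#' and decoder weights are not tied.
#'
#' @param d_in input width (panel size; 1000 in the reference setup).
#' @param hidden encoder hidden sizes, default `c(400, 100)`.
#' @param bottleneck bottleneck width, default 20.
#' @param seed integer seed.
#' @param linear_bottleneck logical, see [training_config()].
#' @return list of class `autoencoder`.
#' @export
init_autoencoder <- function(d_in, hidden = c(400L, 100L), bottleneck = 20L,
                             seed = 1L, linear_bottleneck = FALSE) {
  sizes <- c(d_in, hidden, bottleneck)
  if (any(sizes <= 0)) stop("layer sizes must be positive")
  if (any(diff(sizes) >= 0))
    stop("layer sizes must be strictly decreasing to the bottleneck: ",
         paste(sizes, collapse = " -> "))
  dec_sizes <- rev(sizes)
  rand_w <- function(nin, nout)
    matrix(stats::runif(nin * nout, -1 / sqrt(nin), 1 / sqrt(nin)), nin, nout)
  model <- with_seed(seed, {
    W <- b <- Wd <- bd <- list()
    for (l in seq_len(length(sizes) - 1L)) {
      W[[l]] <- rand_w(sizes[[l]], sizes[[l + 1L]])
      b[[l]] <- numeric(sizes[[l + 1L]])
      Wd[[l]] <- rand_w(dec_sizes[[l]], dec_sizes[[l + 1L]])
      bd[[l]] <- numeric(dec_sizes[[l + 1L]])
    }
    list(W = W, b = b, Wd = Wd, bd = bd)
  })
  structure(c(model,
              list(layer_sizes = as.integer(sizes),
                   linear_bottleneck = isTRUE(linear_bottleneck),
                   trained = FALSE, seed = as.integer(seed))),
            class = "autoencoder")
}

#' @export
print.autoencoder <- function(x, ...) {
  cat(sprintf("<autoencoder> %s -> %s (%s), %s\n",
              paste(x$layer_sizes, collapse = "-"),
              paste(rev(x$layer_sizes)[-1L], collapse = "-"),
              if (x$linear_bottleneck) "linear bottleneck" else "ReLU bottleneck",
              if (x$trained) "trained" else "untrained"))
  invisible(x)
}

# add a bias row-vector to every row (faster than sweep)
add_bias <- function(z, b) z + rep(b, rep.int(nrow(z), length(b)))

# forward pass keeping pre-/post-activation caches for backprop
ae_forward_cache <- function(model, X) {
  L <- length(model$W)
  ez <- ea <- dz <- da <- vector("list", L)
  a <- X
  for (l in seq_len(L)) {
    z <- add_bias(a %*% model$W[[l]], model$b[[l]])
    a <- if (l == L && model$linear_bottleneck) z else pmax(z, 0)
    ez[[l]] <- z; ea[[l]] <- a
  }
  for (l in seq_len(L)) {
    z <- add_bias(a %*% model$Wd[[l]], model$bd[[l]])
    a <- if (l == L) z else pmax(z, 0)
    dz[[l]] <- z; da[[l]] <- a
  }
  list(enc_z = ez, enc_a = ea, dec_z = dz, dec_a = da)
}

#' Forward pass of the autoencoder
#'
#' @param model [init_autoencoder()] model.
#' @param X samples x d_in matrix (z-scored expression, samples in rows).
#' @return list with `scores` (samples x bottleneck post-activation
#'   features) and `reconstruction` (samples x d_in linear output).
#' @export
ae_forward <- function(model, X) {
  stopifnot(inherits(model, "autoencoder"))
  X <- as.matrix(X)
  if (ncol(X) != model$layer_sizes[[1L]])
    stop(sprintf("input has %d columns; model expects %d",
                 ncol(X), model$layer_sizes[[1L]]))
  cache <- ae_forward_cache(model, X)
  L <- length(model$W)
  list(scores = cache$enc_a[[L]], reconstruction = cache$dec_a[[L]])
}

#' Regularized square reconstruction loss
#'
#' `L = sum_i 0.5 * ||x_i - D(E(x_i))||^2 + lambda * ||w||^2`, where
#' `||w||^2` sums the squared entries of all encoder and decoder weight
#' matrices; biases are excluded from the penalty.
#'
#' @inheritParams ae_forward
#' @param lambda ridge penalty.
#' @return scalar loss.
#' @export
ae_loss <- function(model, X, lambda = 0) {
  fw <- ae_forward(model, X)
  0.5 * sum((X - fw$reconstruction)^2) +
    lambda * (sum(vapply(model$W, function(w) sum(w^2), 0)) +
              sum(vapply(model$Wd, function(w) sum(w^2), 0)))
}

#' Analytic gradients of the regularized square loss
#'
#' Full-batch backpropagation of [ae_loss()] with respect to every
#' weight matrix and bias vector. Exposed mainly so the gradients can be
#' verified against finite differences.
#'
#' @inheritParams ae_loss
#' @return list with gradient lists `W`, `b`, `Wd`, `bd` matching the
#'   model's parameter shapes.
#' @export
ae_gradients <- function(model, X, lambda = 0) {
  stopifnot(inherits(model, "autoencoder"))
  X <- as.matrix(X)
  L <- length(model$W)
  cache <- ae_forward_cache(model, X)
  gW <- gb <- gWd <- gbd <- vector("list", L)
  # decoder, last layer linear
  delta <- cache$dec_a[[L]] - X
  for (l in rev(seq_len(L))) {
    a_prev <- if (l == 1L) cache$enc_a[[L]] else cache$dec_a[[l - 1L]]
    gWd[[l]] <- crossprod(a_prev, delta) + 2 * lambda * model$Wd[[l]]
    gbd[[l]] <- colSums(delta)
    delta <- tcrossprod(delta, model$Wd[[l]])
    if (l > 1L) delta <- delta * (cache$dec_z[[l - 1L]] > 0)
  }
  # through the bottleneck activation into the encoder
  if (!model$linear_bottleneck) delta <- delta * (cache$enc_z[[L]] > 0)
  for (l in rev(seq_len(L))) {
    a_prev <- if (l == 1L) X else cache$enc_a[[l - 1L]]
    gW[[l]] <- crossprod(a_prev, delta) + 2 * lambda * model$W[[l]]
    gb[[l]] <- colSums(delta)
    if (l > 1L) {
      delta <- tcrossprod(delta, model$W[[l]])
      delta <- delta * (cache$enc_z[[l - 1L]] > 0)
    }
  }
  list(W = gW, b = gb, Wd = gWd, bd = gbd)
}

#' Train the autoencoder by mini-batch SGD with momentum
#'
#' Minimizes [ae_loss()] by stochastic gradient descent. Per-batch
#' updates use the mean data gradient plus the ridge gradient rescaled
#' by `1/n`, a monotone rescaling of the full objective that keeps the
#' step size independent of cohort size, and are clipped to a global
#' gradient norm of `config$clip_norm` (momentum SGD otherwise
#' overshoots into a dead-ReLU collapse on z-scored expression
#' panels). Shuffling and every other
#' source of randomness derive from `config$seed`, so a run is fully
#' reproducible. There is no early stopping: `epochs` is the only stop
#' criterion.
#'
#' @param model [init_autoencoder()] model (shapes must match `config`).
#' @param X samples x d_in z-scored matrix.
#' @param config [training_config()].
#' @return the trained model, with attributes stored in
#'   `model$loss_history` (full-data loss before training and after each
#'   epoch, length `epochs + 1`) and `model$trained = TRUE`.
#' @export
train_autoencoder <- function(model, X, config = training_config()) {
  stopifnot(inherits(model, "autoencoder"),
            inherits(config, "training_config"))
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < config$batch_size)
    stop("fewer samples than batch_size")
  L <- length(model$W)
  lam <- config$lambda
  vel <- list(W = lapply(model$W, function(w) w * 0),
              b = lapply(model$b, function(b) b * 0),
              Wd = lapply(model$Wd, function(w) w * 0),
              bd = lapply(model$bd, function(b) b * 0))
  history <- numeric(config$epochs + 1L)
  history[[1L]] <- ae_loss(model, X, lam)
  model <- with_seed(config$seed, {
    for (ep in seq_len(config$epochs)) {
      idx <- sample.int(n)
      for (start in seq(1L, n, by = config$batch_size)) {
        rows <- idx[start:min(start + config$batch_size - 1L, n)]
        m <- length(rows)
        # raw data-term gradients (sums over the batch); the ridge term
        # and the 1/m batch-mean scaling are folded into the update
        g <- ae_gradients(model, X[rows, , drop = FALSE], 0)
        sc <- 1 / m
        if (is.finite(config$clip_norm)) {
          gn <- 0
          for (part in c("W", "b", "Wd", "bd"))
            for (l in seq_len(L)) gn <- gn + sum(g[[part]][[l]]^2)
          gn <- sqrt(gn) / m
          if (gn > config$clip_norm) sc <- sc * config$clip_norm / gn
        }
        lr <- config$learning_rate
        decay <- lr * 2 * lam / n
        for (l in seq_len(L)) {
          vel$W[[l]] <- config$momentum * vel$W[[l]] -
            (lr * sc) * g$W[[l]] - decay * model$W[[l]]
          model$W[[l]] <- model$W[[l]] + vel$W[[l]]
          vel$Wd[[l]] <- config$momentum * vel$Wd[[l]] -
            (lr * sc) * g$Wd[[l]] - decay * model$Wd[[l]]
          model$Wd[[l]] <- model$Wd[[l]] + vel$Wd[[l]]
          vel$b[[l]] <- config$momentum * vel$b[[l]] - (lr * sc) * g$b[[l]]
          model$b[[l]] <- model$b[[l]] + vel$b[[l]]
          vel$bd[[l]] <- config$momentum * vel$bd[[l]] - (lr * sc) * g$bd[[l]]
          model$bd[[l]] <- model$bd[[l]] + vel$bd[[l]]
        }
      }
      history[[ep + 1L]] <- ae_loss(model, X, lam)
      if (!is.finite(history[[ep + 1L]]))
        stop("training diverged (loss not finite); try a smaller learning_rate")
    }
    model
  })
  model$trained <- TRUE
  model$loss_history <- history
  model$config <- config
  model
}

#' Encode samples to bottleneck node scores
#'
#' @param model trained autoencoder.
#' @param X samples x d_in matrix.
#' @return samples x bottleneck matrix of node scores (column j = node
#'   j's score per sample).
#' @export
ae_encode <- function(model, X) {
  stopifnot(inherits(model, "autoencoder"))
  if (!isTRUE(model$trained))
    stop("model is untrained; call train_autoencoder() first")
  ae_forward(model, X)$scores
}

#' Reconstruction R-squared
#'
#' `1 - SS_res / SS_tot` over all matrix entries, with `SS_tot` taken
#' about the grand mean of `X`.
#'
#' @inheritParams ae_forward
#' @return scalar, at most 1.
#' @export
reconstruction_r2 <- function(model, X) {
  X <- as.matrix(X)
  ss_tot <- sum((X - mean(X))^2)
  if (ss_tot == 0) stop("X is constant; R-squared undefined")
  fw <- ae_forward(model, X)
  1 - sum((X - fw$reconstruction)^2) / ss_tot
}
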