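# shared fixtures, all generated in code

# tiny expression matrix with known values
toy_expr <- function(space = "raw") {
  v <- matrix(c(1, 3, 5,
                2, 4, 6,
                0, 1, 3), nrow = 3, byrow = TRUE,
              dimnames = list(c("GA", "GB", "GC"), c("S1", "S2", "S3")))
  expression_matrix(v, space = space)
}

# small synthetic cohort, cheap enough for unit tests
small_cohort <- function(seed = 1, n = 120, genes = 300, block = 60, ...) {
  generate_cohort(simulation_config(
    n_samples = n, n_genes = genes, n_immune_genes = block,
    n_intrinsic_genes = block, seed = seed, ...))
}

# reduced-size training config for tests
small_config <- function(seed = 1, epochs = 40, ...) {
  training_config(epochs = epochs, seed = seed,
                  hidden = c(40L, 30L), bottleneck = 20L, ...)
}

# train a small TE-side pipeline on a small cohort; returns list with
# everything downstream tests need
small_pipeline <- function(seed = 1, epochs = 40, k = 60, n = 120,
                           genes = 300, block = 60, ...) {
  co <- small_cohort(seed = seed, n = n, genes = genes, block = block, ...)
  z <- log_zscore(co$expression)
  rho <- correlate_with_lymphocyte(z, co$lymph_scores)
  sel <- select_signature_genes(rho, k)
  X <- t(z$values[sel$gh_genes, , drop = FALSE])
  model <- init_autoencoder(k, hidden = c(40L, 30L), bottleneck = 20L,
                            seed = seed)
  model <- train_autoencoder(model, X, small_config(seed = seed,
                                                    epochs = epochs))
  F <- ae_encode(model, X)
  rownames(F) <- z$sample_ids
  list(cohort = co, z = z, selection = sel, X = X, model = model, F = F)
}

# independent brute-force path-sum oracle for gene attribution
path_sum_oracle <- function(model, node) {
  W <- model$W
  d_in <- nrow(W[[1]])
  gw <- numeric(d_in)
  for (i in seq_len(d_in)) {
    tot <- 0
    for (j in seq_len(ncol(W[[1]]))) {
      for (k in seq_len(ncol(W[[2]]))) {
        tot <- tot + W[[1]][i, j] * W[[2]][j, k] * W[[3]][k, node]
      }
    }
    gw[i] <- tot
  }
  gw
}

# independent layer-by-layer scalar-loop forward oracle
forward_oracle <- function(model, X) {
  n <- nrow(X)
  L <- length(model$W)
  out_scores <- matrix(NA_real_, n, model$layer_sizes[length(model$layer_sizes)])
  out_rec <- matrix(NA_real_, n, model$layer_sizes[1])
  for (s in seq_len(n)) {
    a <- X[s, ]
    for (l in seq_len(L)) {
      z <- as.numeric(t(model$W[[l]]) %*% a) + model$b[[l]]
      a <- if (l == L && model$linear_bottleneck) z else pmax(z, 0)
    }
    out_scores[s, ] <- a
    for (l in seq_len(L)) {
      z <- as.numeric(t(model$Wd[[l]]) %*% a) + model$bd[[l]]
      a <- if (l == L) z else pmax(z, 0)
    }
    out_rec[s, ] <- a
  }
  list(scores = out_scores, reconstruction = out_rec)
}

# hand-stepped running-sum oracle for the enrichment score
es_oracle <- function(genes, weights, set, p = 1) {
  N <- length(genes)
  hit <- genes %in% set
  wp <- abs(weights)^p
  run <- numeric(N)
  cur <- 0
  for (i in seq_len(N)) {
    if (hit[i]) cur <- cur + wp[i] / sum(wp[hit])
    else cur <- cur - 1 / (N - sum(hit))
    run[i] <- cur
  }
  run[which.max(abs(run))]
}
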