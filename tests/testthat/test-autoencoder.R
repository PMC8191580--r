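test_that("relu and initialization contracts hold", {
  expect_identical(relu(5), 5)
  expect_identical(relu(-2), 0)
  expect_identical(relu(0), 0)
  m1 <- init_autoencoder(10, hidden = c(6, 4), bottleneck = 2, seed = 9)
  m2 <- init_autoencoder(10, hidden = c(6, 4), bottleneck = 2, seed = 9)
  expect_identical(m1$W, m2$W)  # same seed -> bitwise identical
  expect_identical(m1$Wd, m2$Wd)
  md <- init_autoencoder(1000)
  expect_identical(lapply(md$W, dim),
                   list(c(1000L, 400L), c(400L, 100L), c(100L, 20L)))
  expect_identical(lapply(md$Wd, dim),
                   list(c(20L, 100L), c(100L, 400L), c(400L, 1000L)))
  m10 <- init_autoencoder(100, hidden = 50, bottleneck = 10, seed = 1)
  expect_identical(ncol(ae_forward(m10, matrix(0, 3, 100))$scores), 10L)
  expect_error(init_autoencoder(10, hidden = c(4, 6), bottleneck = 2),
               "decreasing")
})

test_that("forward pass matches a scalar layer-by-layer oracle", {
  m <- init_autoencoder(8, hidden = c(5, 3), bottleneck = 2, seed = 4)
  set.seed(21)
  X <- matrix(rnorm(5 * 8), 5, 8)
  fw <- ae_forward(m, X)
  oracle <- forward_oracle(m, X)
  expect_equal(fw$scores, oracle$scores, tolerance = 1e-12)
  expect_equal(fw$reconstruction, oracle$reconstruction, tolerance = 1e-12)
  # zero model -> zero outputs
  mz <- m
  for (p in c("W", "b", "Wd", "bd"))
    mz[[p]] <- lapply(mz[[p]], function(x) x * 0)
  fz <- ae_forward(mz, X)
  expect_true(all(fz$scores == 0) && all(fz$reconstruction == 0))
  expect_error(ae_forward(m, matrix(0, 2, 7)), "expects 8")
})

test_that("encode is row-separable and non-negative under ReLU", {
  m <- init_autoencoder(8, hidden = c(5, 3), bottleneck = 2, seed = 4)
  m$trained <- TRUE
  set.seed(22)
  X <- matrix(rnorm(6 * 8), 6, 8)
  batch <- ae_encode(m, X)
  onebyone <- do.call(rbind, lapply(seq_len(6), function(i)
    ae_encode(m, X[i, , drop = FALSE])))
  expect_equal(batch, onebyone, tolerance = 1e-12)
  expect_true(all(batch >= 0))
  m$trained <- FALSE
  expect_error(ae_encode(m, X), "untrained")
})

test_that("loss matches a term-by-term oracle and the lambda identity", {
  m <- init_autoencoder(6, hidden = 4, bottleneck = 2, seed = 8)
  set.seed(31)
  X <- matrix(rnorm(4 * 6), 4, 6)
  # independent evaluation: per-sample squared error + ridge
  rec <- ae_forward(m, X)$reconstruction
  eps <- vapply(seq_len(nrow(X)), function(i)
    0.5 * sum((X[i, ] - rec[i, ])^2), 0)
  wsq <- sum(unlist(lapply(c(m$W, m$Wd), function(w) w^2)))
  lam <- 0.37
  expect_equal(ae_loss(m, X, lam), sum(eps) + lam * wsq, tolerance = 1e-12)
  # loss(lambda) == loss(0) + lambda * ||w||^2 exactly
  expect_equal(ae_loss(m, X, lam) - ae_loss(m, X, 0), lam * wsq,
               tolerance = 1e-12)
  # zero model on a single sample [1, 1] -> L = 1
  mz <- init_autoencoder(2, hidden = NULL, bottleneck = 1, seed = 1)
  mz$W[[1]][] <- 0; mz$Wd[[1]][] <- 0
  expect_equal(ae_loss(mz, matrix(c(1, 1), 1, 2), 0), 1)
})

test_that("analytic gradients match central finite differences", {
  m <- init_autoencoder(4, hidden = 2, bottleneck = 1, seed = 3)
  set.seed(9)
  X <- matrix(rnorm(12), 3, 4)
  lam <- 1e-3
  g <- ae_gradients(m, X, lam)
  eps <- 1e-6
  for (part in c("W", "b", "Wd", "bd")) {
    for (l in seq_along(m[[part]])) {
      for (i in seq_along(m[[part]][[l]])) {
        mp <- m; mp[[part]][[l]][i] <- mp[[part]][[l]][i] + eps
        mm <- m; mm[[part]][[l]][i] <- mm[[part]][[l]][i] - eps
        num <- (ae_loss(mp, X, lam) - ae_loss(mm, X, lam)) / (2 * eps)
        ana <- g[[part]][[l]][i]
        expect_lt(abs(ana - num) / max(1e-8, abs(ana) + abs(num)), 1e-5)
      }
    }
  }
})

test_that("training reduces loss, is seed-reproducible, and responds to lambda", {
  co <- small_cohort(seed = 2)
  z <- log_zscore(co$expression)
  sel <- select_signature_genes(
    correlate_with_lymphocyte(z, co$lymph_scores), 60)
  X <- t(z$values[sel$gh_genes, ])
  m0 <- init_autoencoder(60, hidden = c(40, 30), bottleneck = 20, seed = 1)
  cfg <- small_config(seed = 1, epochs = 30)
  m1 <- train_autoencoder(m0, X, cfg)
  h <- m1$loss_history
  expect_length(h, 31L)
  expect_lt(h[length(h)], h[1])
  expect_true(m1$trained)
  # determinism: identical loss history on rerun
  m2 <- train_autoencoder(m0, X, cfg)
  expect_identical(m1$loss_history, m2$loss_history)
  expect_identical(m1$W, m2$W)
  # heavier ridge shrinks weights
  wsq <- function(m) sum(unlist(lapply(c(m$W, m$Wd), function(w) w^2)))
  mh <- train_autoencoder(m0, X, small_config(seed = 1, epochs = 30,
                                              lambda = 10))
  ml <- train_autoencoder(m0, X, small_config(seed = 1, epochs = 30,
                                              lambda = 1e-4))
  expect_lt(wsq(mh), wsq(ml))
  expect_error(train_autoencoder(m0, X[1:10, ],
                                 small_config(batch_size = 32)),
               "batch_size")
})

test_that("trained model beats its untrained twin across 5 seeds", {
  co <- small_cohort(seed = 4)
  z <- log_zscore(co$expression)
  sel <- select_signature_genes(
    correlate_with_lymphocyte(z, co$lymph_scores), 60)
  X <- t(z$values[sel$gh_genes, ])
  for (seed in 1:5) {
    m0 <- init_autoencoder(60, hidden = c(40, 30), bottleneck = 20,
                           seed = seed)
    mu <- m0; mu$trained <- TRUE
    mt <- train_autoencoder(m0, X, small_config(seed = seed, epochs = 25))
    expect_gt(reconstruction_r2(mt, X), reconstruction_r2(mu, X))
  }
})

test_that("reconstruction_r2 matches the direct formula", {
  m <- init_autoencoder(6, hidden = 4, bottleneck = 2, seed = 2)
  m$trained <- TRUE
  set.seed(5)
  X <- matrix(rnorm(30), 5, 6)
  rec <- ae_forward(m, X)$reconstruction
  expect_equal(reconstruction_r2(m, X),
               1 - sum((X - rec)^2) / sum((X - mean(X))^2),
               tolerance = 1e-12)
  expect_error(reconstruction_r2(m, matrix(1, 5, 6)), "constant")
})
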