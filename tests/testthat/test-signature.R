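test_that("gene_weights equals brute-force path sums and matrix product", {
  m <- init_autoencoder(10, hidden = c(4, 3), bottleneck = 2, seed = 13)
  for (node in 1:2) {
    gw <- gene_weights(m, node)
    expect_equal(gw, path_sum_oracle(m, node), tolerance = 1e-10)
    expect_equal(gw, (m$W[[1]] %*% m$W[[2]] %*% m$W[[3]])[, node],
                 tolerance = 1e-12)
  }
  expect_error(gene_weights(m, 3), "out of range")
})

test_that("gene_weights path-counting toy and scaling property", {
  # 2 -> 2 -> 2 -> 1 net with all weights 1: 4 unit paths per gene
  m <- init_autoencoder(4, hidden = c(3, 2), bottleneck = 1, seed = 1)
  m$W <- list(matrix(1, 2, 2), matrix(1, 2, 2), matrix(1, 2, 1))
  m$layer_sizes <- c(2L, 2L, 2L, 1L)
  expect_equal(gene_weights(m, 1), c(4, 4))
  m$W <- lapply(m$W, function(w) w * 0)
  expect_equal(gene_weights(m, 1), c(0, 0))
  # scaling w3[, node] by c scales GW by exactly c
  m2 <- init_autoencoder(10, hidden = c(5, 3), bottleneck = 2, seed = 2)
  base <- gene_weights(m2, 1)
  m2$W[[3]][, 1] <- 3.5 * m2$W[[3]][, 1]
  expect_equal(gene_weights(m2, 1), 3.5 * base, tolerance = 1e-12)
})

test_that("rank_genes_for_gsea sorts stably with lexicographic ties", {
  expect_identical(
    rank_genes_for_gsea(c(A = 0.2, B = -0.1, C = 0.9))$gene,
    c("C", "A", "B"))
  expect_identical(
    rank_genes_for_gsea(c(B = 1, A = 1, C = 1))$gene, c("A", "B", "C"))
  set.seed(3)
  w <- setNames(rnorm(1000), sprintf("G%04d", sample(1000)))
  r <- rank_genes_for_gsea(w)
  expect_setequal(r$gene, names(w))
  expect_true(all(diff(r$weight) <= 0))
})

test_that("select_prognostic_node picks the planted node and breaks ties low", {
  set.seed(77)
  n <- 200
  K <- 8L
  F <- matrix(rnorm(n * K), n, K,
              dimnames = list(sprintf("S%03d", 1:n), NULL))
  # plant node 5 as the survival driver
  lp <- 1.2 * F[, 5]
  time <- rexp(n, 0.05 * exp(lp))
  clinical <- data.frame(sample_id = rownames(F), time = time,
                         event = rep(1L, n))
  def <- select_prognostic_node(F, clinical, "TE")
  expect_identical(def$node_index, 5L)
  expect_identical(nrow(def$selection_stats), K)
  expect_lt(def$selection_stats$p[5], min(def$selection_stats$p[-5]))
  # K = 1 trivially selected
  def1 <- select_prognostic_node(F[, 5, drop = FALSE], clinical, "TE")
  expect_identical(def1$node_index, 1L)
  expect_error(select_prognostic_node(F * 0, clinical, "TE"), "constant")
  cl0 <- clinical; cl0$event <- 0L
  expect_error(select_prognostic_node(F, cl0, "TE"), "event")
})

test_that("node selection is invariant to monotone score transforms", {
  set.seed(42)
  n <- 100
  F <- matrix(rnorm(n * 5), n, 5,
              dimnames = list(sprintf("S%03d", 1:n), NULL))
  time <- rexp(n, 0.05 * exp(F[, 2]))
  clinical <- data.frame(sample_id = rownames(F), time = time,
                         event = rep(1L, n))
  d1 <- select_prognostic_node(F, clinical, "TE")
  Fm <- exp(F)          # strictly monotone transform
  d2 <- select_prognostic_node(Fm, clinical, "TE")
  expect_identical(d1$node_index, d2$node_index)
  expect_equal(d1$selection_stats$p, d2$selection_stats$p,
               tolerance = 1e-10)
})

test_that("orientation flips the score so TE is protective, TI harmful", {
  set.seed(8)
  n <- 150
  F <- matrix(rnorm(n), n, 1, dimnames = list(sprintf("S%03d", 1:n), NULL))
  # high score -> high hazard
  time <- rexp(n, 0.05 * exp(1.5 * F[, 1]))
  clinical <- data.frame(sample_id = rownames(F), time = time,
                         event = rep(1L, n))
  te <- orient_signature(select_prognostic_node(F, clinical, "TE"))
  ti <- orient_signature(select_prognostic_node(F, clinical, "TI"))
  expect_identical(te$sign, -1)  # must flip: higher TE = lower hazard
  expect_identical(ti$sign, 1)
})

test_that("score_cohort is self-consistent and permutation-invariant", {
  co <- small_cohort(seed = 9)
  bundle <- decompose_cohort(co$expression, co$lymph_scores, co$clinical,
                             k = 60, config = small_config(seed = 9,
                                                           epochs = 10))
  sc <- score_cohort(bundle, co$expression)
  # scoring the training cohort reproduces training-time scores
  expect_equal(sc$te_score, bundle$scores$te_score, tolerance = 1e-10)
  expect_equal(sc$ti_score, bundle$scores$ti_score, tolerance = 1e-10)
  # permuting gene rows changes nothing (alignment is by name)
  perm <- sample(nrow(co$expression$values))
  ep <- expression_matrix(co$expression$values[perm, ], "raw")
  sp <- score_cohort(bundle, ep)
  expect_equal(sp$te_score, sc$te_score, tolerance = 1e-12)
  # duplicating the full sample set leaves per-cohort z-scores intact up
  # to the sample-sd denominator (n-1 vs 2n-1), an O(1/n) rescaling
  v2 <- cbind(co$expression$values,
              `colnames<-`(co$expression$values,
                           paste0(co$expression$sample_ids, "_dup")))
  sd2 <- score_cohort(bundle, expression_matrix(v2, "raw"))
  expect_equal(sd2$te_score[seq_len(nrow(sc))], sc$te_score,
               tolerance = 0.01)
})
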