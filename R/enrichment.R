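#' Weighted Kolmogorov-Smirnov-like enrichment score
#'
#' Walks the ranked gene list from top to bottom, incrementing the
#' running sum by `|w|^p` (normalized over in-set genes) at every set
#' member and decrementing by `1 / (N - N_set)` otherwise; the
#' enrichment score is the running-sum value of largest magnitude.
#' `p = 0` reduces to the classic unweighted KS statistic, `p = 1`
#' (the default used downstream) weights hits by their attribution.
#'
#' @param ranked data.frame with columns `gene` and `weight`, ordered
#'   by descending weight (see [rank_genes_for_gsea()]), or a named
#'   numeric vector already in rank order.
#' @param gene_set character vector of gene symbols.
#' @param p weight exponent, default 1.
#' @return list with `es` (scalar in `[-1, 1]`) and `running` (the full
#'   running-sum vector over list positions).
#' @export
enrichment_score <- function(ranked, gene_set, p = 1) {
  if (is.data.frame(ranked)) {
    genes <- ranked$gene
    w <- ranked$weight
  } else {
    genes <- names(ranked)
    w <- unname(ranked)
  }
  N <- length(genes)
  hit <- genes %in% gene_set
  Nh <- sum(hit)
  if (Nh == 0L) {
    warning("gene set has no overlap with the ranked list; skipped")
    return(list(es = NA_real_, running = rep(NA_real_, N)))
  }
  wp <- abs(w)^p
  denom_hit <- sum(wp[hit])
  if (denom_hit == 0) {  # all in-set weights zero: fall back to unweighted
    step_hit <- ifelse(hit, 1 / Nh, 0)
  } else {
    step_hit <- ifelse(hit, wp / denom_hit, 0)
  }
  step_miss <- if (N == Nh) 0 else ifelse(hit, 0, 1 / (N - Nh))
  running <- cumsum(step_hit - step_miss)
  es <- running[[which.max(abs(running))]]
  list(es = es, running = running)
}

#' Pre-ranked gene-set enrichment analysis
#'
#' Computes the enrichment score of every gene set against the ranked
#' attribution list and a gene-label permutation null: each permutation
#' draws a random set of the same size from the ranked list. The
#' normalized score divides ES by the mean |null ES| of the same sign;
#' the nominal p is `(1 + #{same-sign null with |ES_null| >= |ES|}) /
#' (1 + #same-sign null)`. Benjamini-Hochberg FDR across sets is
#' appended.
#'
#' @param ranked ranked data.frame (gene, weight) or named vector, see
#'   [enrichment_score()].
#' @param sets named list of gene sets ([read_gmt()]).
#' @param n_perm number of permutations, minimum 100.
#' @param seed integer seed; results are reproducible.
#' @param min_size,max_size gene-set size bounds (after intersection
#'   with the ranked list).
#' @param p weight exponent.
#' @return data.frame: set, size, es, nes, pval, padj, n_perm,
#'   leading_edge (comma-separated gene symbols).
#' @export
preranked_gsea <- function(ranked, sets, n_perm = 1000L, seed = 1L,
                           min_size = 1L, max_size = Inf, p = 1) {
  if (n_perm < 100L) stop("n_perm must be >= 100")
  if (is.data.frame(ranked)) {
    genes <- ranked$gene
  } else {
    genes <- names(ranked)
  }
  N <- length(genes)
  sizes <- vapply(sets, function(s) sum(genes %in% s), 0L)
  keep <- sizes >= min_size & sizes <= max_size
  if (!any(keep)) {
    warning("all gene sets outside size bounds")
    return(data.frame(set = character(0), size = integer(0),
                      es = numeric(0), nes = numeric(0),
                      pval = numeric(0), padj = numeric(0),
                      n_perm = integer(0), leading_edge = character(0)))
  }
  sets <- sets[keep]
  sizes <- sizes[keep]
  # one permutation null per distinct set size
  null_es <- with_seed(seed, {
    out <- list()
    for (sz in unique(sizes)) {
      out[[as.character(sz)]] <- vapply(seq_len(n_perm), function(i) {
        enrichment_score(ranked, sample(genes, sz), p = p)$es
      }, 0)
    }
    out
  })
  rows <- lapply(seq_along(sets), function(i) {
    sc <- enrichment_score(ranked, sets[[i]], p = p)
    es <- sc$es
    null <- null_es[[as.character(sizes[[i]])]]
    same <- null[sign(null) == sign(es)]
    nes <- if (length(same)) es / mean(abs(same)) else NA_real_
    pval <- (1 + sum(abs(same) >= abs(es))) / (1 + length(same))
    peak <- which.max(abs(sc$running))
    hit <- if (is.data.frame(ranked)) ranked$gene else names(ranked)
    inset <- hit %in% sets[[i]]
    le <- if (es >= 0) hit[seq_len(peak)][inset[seq_len(peak)]]
          else hit[peak:N][inset[peak:N]]
    data.frame(set = names(sets)[[i]], size = sizes[[i]], es = es,
               nes = nes, pval = pval, n_perm = as.integer(n_perm),
               leading_edge = paste(le, collapse = ","))
  })
  out <- do.call(rbind, rows)
  out$padj <- stats::p.adjust(out$pval, method = "BH")
  out[order(out$pval, -abs(out$nes)),
      c("set", "size", "es", "nes", "pval", "padj", "n_perm",
        "leading_edge")]
}

#' Mean z-score pathway activity (exploratory substitute)
#'
#' A deliberately simple per-sample pathway activity: the mean z-scored
#' expression of the set's genes. This is not a GSVA reimplementation
#' and is provided for exploratory use only.
#'
#' @param expr z-scored [expression_matrix()].
#' @param sets named list of gene sets.
#' @return sets x samples matrix of mean z-scores.
#' @export
pathway_activity <- function(expr, sets) {
  stopifnot(inherits(expr, "expression_matrix"))
  if (expr$space != "zscore") stop("expects a z-scored matrix")
  t(vapply(sets, function(s) {
    g <- intersect(s, expr$gene_ids)
    if (!length(g)) return(rep(NA_real_, ncol(expr$values)))
    colMeans(expr$values[g, , drop = FALSE])
  }, numeric(ncol(expr$values))))
}
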