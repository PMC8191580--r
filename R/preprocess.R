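#' Log-transform and z-score an expression matrix
#'
#' RNA-seq style input (`space = "raw"`) is first transformed to
#' `log2(value + pseudo)`; matrices already on a log scale
#' (`space = "log"`, e.g. microarray intensities) skip the log step.
#' Every gene row is then standardized to mean 0 / sd 1 across samples.
#' Genes with zero variance carry no relative signal and are removed;
#' their symbols are kept in the `dropped_genes` attribute.
#'
#' @param expr [expression_matrix()] with space `"raw"` or `"log"`.
#' @param pseudo positive pseudo-count added before the log, default 1.
#' @return [expression_matrix()] with `space = "zscore"` and attribute
#'   `dropped_genes`.
#' @export
log_zscore <- function(expr, pseudo = 1) {
  stopifnot(inherits(expr, "expression_matrix"))
  if (ncol(expr$values) < 2L) stop("need at least 2 samples to z-score")
  if (expr$space == "zscore") {
    v <- expr$values
  } else if (expr$space == "log") {
    v <- expr$values
  } else {
    if (pseudo <= 0) stop("`pseudo` must be positive")
    if (any(expr$values < 0)) stop("raw expression must be non-negative")
    v <- log2(expr$values + pseudo)
  }
  mu <- rowMeans(v)
  sdev <- apply(v, 1L, stats::sd)
  keep <- sdev > 0
  dropped <- rownames(v)[!keep]
  v <- (v[keep, , drop = FALSE] - mu[keep]) / sdev[keep]
  out <- expression_matrix(v, space = "zscore")
  attr(out, "dropped_genes") <- dropped
  out
}

#' Correlate every gene with lymphocyte infiltration scores
#'
#' @param expr z-scored [expression_matrix()].
#' @param scores named numeric vector, sample id -> ordinal/real
#'   lymphocyte infiltration score.
#' @param method `"spearman"` (default; the score is ordinal IHC) or
#'   `"pearson"`.
#' @return named numeric vector, gene -> rho.
#' @export
correlate_with_lymphocyte <- function(expr, scores,
                                      method = c("spearman", "pearson")) {
  method <- match.arg(method)
  stopifnot(inherits(expr, "expression_matrix"))
  if (is.null(names(scores))) stop("`scores` must be named by sample id")
  scores <- scores[is.finite(scores)]
  shared <- intersect(expr$sample_ids, names(scores))
  if (length(shared) < 3L)
    stop("need >= 3 samples shared between expression and lymphocyte scores")
  s <- scores[shared]
  if (length(unique(s)) < 3L)
    stop("lymphocyte scores need at least 3 distinct values")
  v <- expr$values[, shared, drop = FALSE]
  if (method == "spearman") {
    sr <- rank(s)
    rho <- apply(v, 1L, function(g) stats::cor(rank(g), sr))
  } else {
    rho <- apply(v, 1L, function(g) stats::cor(g, s))
  }
  rho
}

#' Select the lymphocyte-correlated gene panels GH' and GL'
#'
#' GH' holds the k genes with the largest (most positive) correlations
#' with the lymphocyte score, GL' the k with the smallest (most
#' negative). Ties at a panel boundary break by gene-symbol lexicographic
#' order so panels are reproducible across platforms. Within each panel
#' genes are ordered by descending absolute correlation.
#'
#' @param correlations named numeric vector, gene -> rho.
#' @param k panel size (the reference analysis uses 1000).
#' @return list of class `gene_selection` with `gh_genes`, `gl_genes`,
#'   `correlations`, `k`.
#' @export
select_signature_genes <- function(correlations, k) {
  if (k < 1) stop("`k` must be a positive integer")
  rho <- correlations[is.finite(correlations)]
  if (length(rho) < 2L * k)
    stop(sprintf("only %d genes with finite rho; need >= 2k = %d (use smaller k)",
                 length(rho), 2L * k))
  # deterministic order: rho descending, then symbol ascending
  ord <- order(-rho, names(rho), method = "radix")
  gh <- names(rho)[ord[seq_len(k)]]
  gl <- names(rho)[rev(ord)[seq_len(k)]]
  # within-panel ordering: descending |rho|, symbol tiebreak
  gh <- gh[order(-abs(rho[gh]), gh, method = "radix")]
  gl <- gl[order(-abs(rho[gl]), gl, method = "radix")]
  structure(list(gh_genes = gh, gl_genes = gl,
                 correlations = rho, k = as.integer(k)),
            class = "gene_selection")
}

#' Align a z-scored cohort to a trained gene panel
#'
#' Rows are returned exactly in panel order. Panel genes absent from the
#' cohort are filled with 0 — the cohort mean in z-score space. An
#' overlap below `min_overlap` is a hard error; overlap in
#' `[min_overlap, 0.8)` raises a warning.
#'
#' @param expr z-scored [expression_matrix()].
#' @param panel ordered character vector of panel genes.
#' @param min_overlap minimum tolerated fraction of panel genes present,
#'   default 0.5.
#' @return genes x samples matrix in panel order, with attribute
#'   `overlap` (fraction of panel genes found).
#' @export
align_genes <- function(expr, panel, min_overlap = 0.5) {
  stopifnot(inherits(expr, "expression_matrix"))
  if (expr$space != "zscore")
    stop("align_genes expects a z-scored matrix; run log_zscore() first")
  hit <- panel %in% expr$gene_ids
  overlap <- mean(hit)
  if (overlap < min_overlap)
    stop(sprintf("panel overlap %.1f%% below minimum %.1f%%",
                 100 * overlap, 100 * min_overlap))
  if (overlap < 0.8)
    warning(sprintf("panel overlap only %.1f%%; scores may be degraded",
                    100 * overlap))
  out <- matrix(0, nrow = length(panel), ncol = ncol(expr$values),
                dimnames = list(panel, expr$sample_ids))
  out[panel[hit], ] <- expr$values[panel[hit], , drop = FALSE]
  attr(out, "overlap") <- overlap
  out
}
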