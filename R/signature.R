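#' Select the most prognostic bottleneck node
#'
#' For every bottleneck node, the per-sample score is dichotomized at
#' the cohort median (ties to the low group), a univariate
#' proportional-hazards model is fitted on the binary group and the
#' hazard ratio (high vs low) and Wald p-value recorded; the node with
#' the smallest p is selected (ties break toward the smaller node
#' index). Nodes with constant scores cannot be dichotomized and are
#' skipped. No multiple-testing correction is applied across nodes —
#' the scan is exploratory, mirroring a raw per-node -log10(p) profile.
#'
#' @param node_scores samples x K matrix of node scores, rownames =
#'   sample ids.
#' @param clinical data.frame with `sample_id`, `time`, `event`.
#' @param compartment `"TE"` or `"TI"` (metadata only).
#' @param method `"wald"` (default) or `"logrank"` (score test p).
#' @return list of class `signature_definition`: `compartment`,
#'   `node_index`, `selection_stats` (data.frame node, hr, p, n,
#'   events), `sign` (+1; see [orient_signature()]).
#' @export
select_prognostic_node <- function(node_scores, clinical,
                                   compartment = c("TE", "TI"),
                                   method = c("wald", "logrank")) {
  compartment <- match.arg(compartment)
  method <- match.arg(method)
  node_scores <- as.matrix(node_scores)
  if (is.null(rownames(node_scores)))
    stop("node_scores must have sample ids as rownames")
  shared <- intersect(rownames(node_scores), clinical$sample_id)
  cl <- clinical[match(shared, clinical$sample_id), ]
  ok <- is.finite(cl$time) & cl$event %in% c(0, 1)
  cl <- cl[ok, ]
  F <- node_scores[cl$sample_id, , drop = FALSE]
  if (nrow(F) < 20L) stop("need >= 20 samples with survival data")
  if (sum(cl$event) < 1L) stop("need at least one event")
  K <- ncol(F)
  hr <- p <- rep(NA_real_, K)
  surv <- survival::Surv(cl$time, cl$event)
  for (k in seq_len(K)) {
    s <- F[, k]
    if (length(unique(s)) < 2L) next  # constant node (e.g. dead ReLU unit)
    grp <- dichotomize(s)
    if (length(unique(grp)) < 2L) next
    fit <- tryCatch(survival::coxph(surv ~ I(grp == "high")),
                    error = function(e) NULL, warning = function(w) {
                      suppressWarnings(survival::coxph(surv ~ I(grp == "high")))
                    })
    if (is.null(fit)) next
    sm <- summary(fit)
    hr[[k]] <- unname(sm$coefficients[1L, "exp(coef)"])
    p[[k]] <- if (method == "wald")
      unname(sm$coefficients[1L, "Pr(>|z|)"])
    else unname(sm$sctest[["pvalue"]])
  }
  if (all(is.na(p))) stop("all nodes constant; cannot select a prognostic node")
  best <- which(p == min(p, na.rm = TRUE))[[1L]]  # ties -> smaller index
  structure(list(compartment = compartment, node_index = best,
                 selection_stats = data.frame(node = seq_len(K), hr = hr,
                                              p = p),
                 n = nrow(F), events = sum(cl$event), sign = 1,
                 method = method),
            class = "signature_definition")
}

#' Orient a signature score's sign convention
#'
#' After node selection the score direction is arbitrary. By convention
#' the TE score is oriented so that higher = lower hazard (protective,
#' HR < 1 for the high group) and the TI score so that higher = higher
#' hazard. If the selected node's dichotomized HR contradicts the
#' convention, the score sign is flipped and `sign = -1` recorded in the
#' definition, which [score_cohort()] then applies everywhere.
#'
#' @param def [select_prognostic_node()] result.
#' @return the definition with `sign` set to +1 or -1.
#' @export
orient_signature <- function(def) {
  stopifnot(inherits(def, "signature_definition"))
  hr <- def$selection_stats$hr[[def$node_index]]
  def$sign <- if (def$compartment == "TE") {
    if (hr > 1) -1 else 1
  } else {
    if (hr < 1) -1 else 1
  }
  def
}

#' Attribute a bottleneck node to genes by weighted path sums
#'
#' The contribution of gene i to bottleneck node `node_index` is the sum
#' over all encoder paths of the products of the traversed weights:
#' `GW(i) = sum_{j,k} w1[i,j] * w2[j,k] * w3[k,node]`, i.e. column
#' `node_index` of the product of the encoder weight matrices. Biases
#' and ReLU nonlinearities are deliberately excluded — the attribution
#' is the exact linearized path weight, not a saliency method.
#'
#' @param model trained (or initialized) autoencoder.
#' @param node_index bottleneck node, 1-based.
#' @param genes optional character vector naming the input rows (panel
#'   order); names the result.
#' @return numeric vector of per-gene weights (length d_in).
#' @export
gene_weights <- function(model, node_index, genes = NULL) {
  stopifnot(inherits(model, "autoencoder"))
  K <- model$layer_sizes[[length(model$layer_sizes)]]
  if (node_index < 1 || node_index > K)
    stop(sprintf("node_index %d out of range [1, %d]", node_index, K))
  gw <- Reduce(`%*%`, model$W)[, node_index]
  if (!is.null(genes)) {
    if (length(genes) != length(gw))
      stop("`genes` length does not match model input width")
    names(gw) <- genes
  }
  gw
}

#' Rank genes by attribution weight for pre-ranked GSEA
#'
#' @param gw named numeric vector of gene weights.
#' @return data.frame (gene, weight, rank) in stable descending weight
#'   order; ties break by gene symbol.
#' @export
rank_genes_for_gsea <- function(gw) {
  if (is.null(names(gw))) stop("`gw` must be named by gene")
  if (!all(is.finite(gw))) stop("gene weights must be finite")
  ord <- order(-gw, names(gw), method = "radix")
  data.frame(gene = names(gw)[ord], weight = unname(gw[ord]),
             rank = seq_along(gw))
}

#' Train the full two-compartment decomposition on a cohort
#'
#' Runs the complete training pipeline: log/z-score normalization,
#' lymphocyte correlation screening into the GH' (top positive) and GL'
#' (top negative) panels, one autoencoder per panel, prognostic node
#' selection per compartment, sign orientation, and gene attribution
#' for the selected nodes.
#'
#' @param expr [expression_matrix()], raw or log space.
#' @param lymph_scores named numeric vector of lymphocyte infiltration
#'   scores.
#' @param clinical clinical data.frame (`sample_id`, `time`, `event`).
#' @param k panel size (reference setup: 1000).
#' @param config [training_config()].
#' @param cor_method `"spearman"` or `"pearson"`.
#' @param pseudo pseudo-count for [log_zscore()].
#' @return list of class `decomp_bundle` with elements `te` and `ti`
#'   (each: `model`, `panel`, `def`, `gene_weights`), `selection`
#'   ([select_signature_genes()] result), `config`, plus per-sample
#'   training scores in `scores` (data.frame sample_id, te_score,
#'   ti_score).
#' @export
decompose_cohort <- function(expr, lymph_scores, clinical, k = 1000L,
                             config = training_config(),
                             cor_method = "spearman", pseudo = 1) {
  z <- log_zscore(expr, pseudo = pseudo)
  rho <- correlate_with_lymphocyte(z, lymph_scores, method = cor_method)
  sel <- select_signature_genes(rho, k)
  fit_side <- function(panel, compartment, seed_offset) {
    X <- t(z$values[panel, , drop = FALSE])
    cfg <- config
    cfg$seed <- config$seed + seed_offset
    model <- init_autoencoder(length(panel), hidden = cfg$hidden,
                              bottleneck = cfg$bottleneck, seed = cfg$seed,
                              linear_bottleneck = cfg$linear_bottleneck)
    model <- train_autoencoder(model, X, cfg)
    F <- ae_encode(model, X)
    rownames(F) <- z$sample_ids
    def <- select_prognostic_node(F, clinical, compartment = compartment)
    def <- orient_signature(def)
    gw <- gene_weights(model, def$node_index, genes = panel)
    list(model = model, panel = panel, def = def,
         gene_weights = def$sign * gw,
         scores = def$sign * F[, def$node_index])
  }
  te <- fit_side(sel$gh_genes, "TE", 0L)
  ti <- fit_side(sel$gl_genes, "TI", 1L)
  structure(list(
    te = te[c("model", "panel", "def", "gene_weights")],
    ti = ti[c("model", "panel", "def", "gene_weights")],
    selection = sel, config = config,
    scores = data.frame(sample_id = z$sample_ids,
                        te_score = unname(te$scores),
                        ti_score = unname(ti$scores))),
    class = "decomp_bundle")
}

#' Score a cohort with a trained decomposition bundle
#'
#' Applies the frozen encoders to a new cohort: the cohort is z-scored
#' within itself, aligned to the bundle's gene panels (missing panel
#' genes filled with the z-score mean 0), encoded, and the selected
#' node's column extracted with the bundle's sign convention. No
#' re-training occurs.
#'
#' @param bundle [decompose_cohort()] result (possibly reloaded via
#'   [load_model_bundle()]).
#' @param expr [expression_matrix()] in raw or log space.
#' @param min_overlap minimum panel overlap fraction, see
#'   [align_genes()].
#' @param pseudo pseudo-count for [log_zscore()].
#' @return data.frame with `sample_id`, `te_score`, `ti_score`.
#' @export
score_cohort <- function(bundle, expr, min_overlap = 0.5, pseudo = 1) {
  stopifnot(inherits(bundle, "decomp_bundle"))
  z <- log_zscore(expr, pseudo = pseudo)
  one <- function(side) {
    X <- t(align_genes(z, side$panel, min_overlap = min_overlap))
    F <- ae_encode(side$model, X)
    side$def$sign * F[, side$def$node_index]
  }
  data.frame(sample_id = z$sample_ids,
             te_score = unname(one(bundle$te)),
             ti_score = unname(one(bundle$ti)))
}
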