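#' Simulation configuration for a synthetic melanoma-like cohort
#'
#' The defaults state the world the pipeline is built for: a cohort of
#' 358 samples (the size of the metastatic training cohort the method
#' targets), 2000 genes of which 250 form a planted "immune" block
#' driven positively by a latent immune factor and 250 a
#' "tumor-intrinsic" block driven by a second latent factor, unit
#' loadings with gene-level noise sd 0.5, a 4-level ordinal lymphocyte
#' score, exponential survival with protective immune log-hazard -0.7
#' and harmful intrinsic log-hazard +0.7 per factor SD, ~30% independent
#' censoring, and a responder probability whose logit is the immune
#' factor.
#'
#' @param n_samples cohort size.
#' @param n_genes total genes.
#' @param n_immune_genes,n_intrinsic_genes planted block sizes
#'   (disjoint, leading genes of the matrix).
#' @param immune_loading,intrinsic_loading effect of the latent factor
#'   on its block, in log2-expression units per factor SD.
#' @param noise_sd gene-level log2 noise sd.
#' @param lymph_levels ordinal levels of the lymphocyte score.
#' @param surv_beta_te true log-hazard per SD of the immune factor
#'   (negative = protective).
#' @param surv_beta_ti true log-hazard per SD of the intrinsic factor.
#' @param censor_rate target fraction censored, in `[0, 1)`.
#' @param baseline_hazard exponential baseline hazard (per month).
#' @param beta_age,beta_sex,beta_stage clinical log-hazard effects
#'   (age per year, sex male vs female, stage per ordinal step).
#' @param response_beta logit effect of the immune factor on response.
#' @param factor_corr correlation planted between the two latent
#'   factors (default 0 = independent).
#' @param weibull_shape survival time shape; 1 (default) = exponential.
#' @param seed integer seed.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(n_samples = 358L, n_genes = 2000L,
                              n_immune_genes = 250L,
                              n_intrinsic_genes = 250L,
                              immune_loading = 1, intrinsic_loading = 1,
                              noise_sd = 0.5, lymph_levels = 4L,
                              surv_beta_te = -0.7, surv_beta_ti = 0.7,
                              censor_rate = 0.3, baseline_hazard = 0.02,
                              beta_age = 0.02, beta_sex = 0.1,
                              beta_stage = 0.3, response_beta = 1,
                              factor_corr = 0, weibull_shape = 1,
                              seed = 1L) {
  if (n_immune_genes + n_intrinsic_genes > n_genes)
    stop("gene blocks exceed n_genes")
  if (censor_rate < 0 || censor_rate >= 1)
    stop("censor_rate must be in [0, 1)")
  structure(as.list(environment()), class = "simulation_config")
}

#' Generate a synthetic cohort with planted immune and intrinsic factors
#'
#' Per sample, latent factors `z_imm` and `z_int` are standard normal
#' (optionally correlated). Log2 expression of gene g is
#' `base + loading * z_block + N(0, noise_sd)` for block members and
#' pure noise otherwise, exponentiated to a non-negative raw scale.
#' The lymphocyte score is `z_imm` quantile-binned into ordinal levels.
#' Survival times follow a Weibull (default exponential) model whose
#' log-hazard is `surv_beta_te * z_imm + surv_beta_ti * z_int` plus
#' linear age/sex/stage terms, with independent exponential censoring
#' calibrated to the target censor rate. Mutation counts are Poisson
#' with log-mean linear in `z_int`; per-sample CNV segment counts grow
#' as `z_imm` falls, so CNV burden correlates negatively with the
#' immune factor; response is Bernoulli with logit `response_beta *
#' z_imm`. Everything is reproducible from `config$seed`.
#'
#' @param config [simulation_config()].
#' @return list of class `synthetic_cohort` with `expression`
#'   ([expression_matrix()], raw space), `lymph_scores`, `clinical`
#'   (data.frame sample_id, time, event, age, sex, stage, breslow,
#'   response), `mutation_counts`, `segments` (CNV table), `truth`
#'   (data.frame sample_id, z_imm, z_int), `immune_genes`,
#'   `intrinsic_genes`, `config`.
#' @export
generate_cohort <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  cf <- config
  with_seed(cf$seed, {
    n <- cf$n_samples
    ids <- sprintf("S%04d", seq_len(n))
    genes <- sprintf("G%05d", seq_len(cf$n_genes))
    imm_genes <- genes[seq_len(cf$n_immune_genes)]
    int_genes <- genes[cf$n_immune_genes + seq_len(cf$n_intrinsic_genes)]

    z_imm <- stats::rnorm(n)
    z_int <- cf$factor_corr * z_imm +
      sqrt(1 - cf$factor_corr^2) * stats::rnorm(n)

    base <- 6
    logex <- matrix(stats::rnorm(cf$n_genes * n, 0, cf$noise_sd),
                    cf$n_genes, n, dimnames = list(genes, ids)) + base
    logex[imm_genes, ] <- logex[imm_genes, ] +
      cf$immune_loading * matrix(z_imm, cf$n_immune_genes, n, byrow = TRUE)
    logex[int_genes, ] <- logex[int_genes, ] +
      cf$intrinsic_loading * matrix(z_int, cf$n_intrinsic_genes, n,
                                    byrow = TRUE)
    expr <- expression_matrix(2^logex, space = "raw")

    lymph <- as.integer(cut(z_imm,
                            breaks = stats::quantile(
                              z_imm, probs = seq(0, 1,
                                                 length.out = cf$lymph_levels + 1L)),
                            include.lowest = TRUE, labels = FALSE))
    names(lymph) <- ids

    age <- round(stats::rnorm(n, 60, 10))
    sex <- sample(c("female", "male"), n, replace = TRUE)
    stage <- sample(1:4, n, replace = TRUE, prob = c(0.15, 0.3, 0.35, 0.2))
    breslow <- round(stats::rlnorm(n, log(2), 0.6), 2)
    lp <- cf$surv_beta_te * z_imm + cf$surv_beta_ti * z_int +
      cf$beta_age * (age - 60) + cf$beta_sex * (sex == "male") +
      cf$beta_stage * (stage - mean(stage))
    # Weibull with shape a: S(t) = exp(-h0 * t^a * exp(lp))
    u <- stats::runif(n)
    t_event <- (-log(u) / (cf$baseline_hazard * exp(lp)))^(1 / cf$weibull_shape)
    if (cf$censor_rate > 0) {
      cens_rate <- cf$baseline_hazard * cf$censor_rate / (1 - cf$censor_rate)
      t_cens <- stats::rexp(n, cens_rate)^(1 / cf$weibull_shape)
    } else {
      t_cens <- rep(Inf, n)
    }
    time <- pmin(t_event, t_cens)
    event <- as.integer(t_event <= t_cens)
    clinical <- data.frame(
      sample_id = ids, time = time, event = event, age = age, sex = sex,
      stage = stage, breslow = breslow,
      response = ifelse(
        stats::rbinom(n, 1, stats::plogis(cf$response_beta * z_imm)) == 1,
        "responder", "non-responder"))

    mut <- stats::rpois(n, exp(log(100) + 0.3 * z_int))
    names(mut) <- ids

    n_seg <- stats::rpois(n, exp(log(15) - 0.5 * z_imm))
    segments <- do.call(rbind, lapply(seq_len(n), function(i) {
      if (n_seg[[i]] == 0L) return(NULL)
      size <- round(stats::runif(n_seg[[i]], 1e6, 2e7))
      start <- cumsum(c(1, utils::head(size, -1L) + 1e5))
      data.frame(sample_id = ids[[i]], chrom = "chr1",
                 start = start, end = start + size,
                 copy_number = sample(c(0, 1, 3, 4, 5), n_seg[[i]],
                                      replace = TRUE,
                                      prob = c(0.05, 0.4, 0.35, 0.15, 0.05)))
    }))

    structure(list(expression = expr, lymph_scores = lymph,
                   clinical = clinical, mutation_counts = mut,
                   segments = segments,
                   truth = data.frame(sample_id = ids, z_imm = z_imm,
                                      z_int = z_int),
                   immune_genes = imm_genes, intrinsic_genes = int_genes,
                   config = cf),
              class = "synthetic_cohort")
  })
}

#' Gene sets carrying the cohort's ground truth
#'
#' Emits `TRUE_IMMUNE` and `TRUE_INTRINSIC` sets equal to the planted
#' gene blocks plus `n_decoys` size-matched random decoy sets, for
#' end-to-end enrichment recovery tests.
#'
#' @param cohort [generate_cohort()] result.
#' @param n_decoys number of decoy sets, default 10.
#' @param seed seed for decoy sampling.
#' @return named list of gene sets (class `gene_set_collection`).
#' @export
generate_gene_sets <- function(cohort, n_decoys = 10L, seed = 1L) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  genes <- cohort$expression$gene_ids
  sets <- list(TRUE_IMMUNE = cohort$immune_genes,
               TRUE_INTRINSIC = cohort$intrinsic_genes)
  decoys <- with_seed(seed, {
    lapply(seq_len(n_decoys), function(i)
      sample(genes, length(cohort$immune_genes)))
  })
  names(decoys) <- sprintf("DECOY_%02d", seq_len(n_decoys))
  structure(c(sets, decoys), class = "gene_set_collection")
}

#' Write a synthetic cohort to a directory in pipeline formats
#'
#' @param cohort [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_expression(cohort$expression, file.path(dir, "expression.tsv"))
  utils::write.table(
    data.frame(sample_id = names(cohort$lymph_scores),
               lymph_score = unname(cohort$lymph_scores)),
    file.path(dir, "lymph_scores.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  utils::write.table(cohort$clinical, file.path(dir, "clinical.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(sample_id = names(cohort$mutation_counts),
               mutation_count = unname(cohort$mutation_counts)),
    file.path(dir, "mutation_counts.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  utils::write.table(cohort$segments, file.path(dir, "segments.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$truth, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_gmt(generate_gene_sets(cohort, seed = cohort$config$seed),
            file.path(dir, "gene_sets.gmt"))
  invisible(dir)
}
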