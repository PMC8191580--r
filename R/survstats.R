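#' Median dichotomization
#'
#' Scores strictly above the cohort median go to `"high"`; scores at or
#' below the median (ties included) go to `"low"`.
#'
#' @param scores numeric vector, length >= 2.
#' @return factor with levels `low`, `high`, same names as `scores`.
#' @export
dichotomize <- function(scores) {
  if (length(scores) < 2L) stop("need >= 2 samples to dichotomize")
  if (length(unique(scores)) < 2L)
    stop("all scores equal; cannot dichotomize at the median")
  med <- stats::median(scores)
  factor(ifelse(scores > med, "high", "low"), levels = c("low", "high"))
}

# assemble a matched (time, event, ...) frame from clinical + extras
match_clinical <- function(clinical, ids) {
  idx <- match(ids, clinical$sample_id)
  if (anyNA(idx))
    stop("samples missing from clinical table: ",
         paste(utils::head(ids[is.na(idx)], 3L), collapse = ", "), " ...")
  clinical[idx, , drop = FALSE]
}

#' Kaplan-Meier curves and log-rank test between groups
#'
#' @param groups factor (or vector) of group labels, named by sample id
#'   or aligned with `clinical` rows.
#' @param clinical data.frame with `sample_id`, `time`, `event`.
#' @return list with `fit` (a [survival::survfit] object carrying the
#'   product-limit curves and censoring marks), `p` (log-rank p-value),
#'   `median` (named vector of per-group KM median survival).
#' @export
km_logrank <- function(groups, clinical) {
  if (!is.null(names(groups))) clinical <- match_clinical(clinical, names(groups))
  if (length(groups) != nrow(clinical))
    stop("groups and clinical rows do not align")
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) < 2L)
    stop("need at least two non-empty groups for a log-rank test")
  if (any(table(groups) == 0L)) stop("a group has zero subjects")
  d <- data.frame(time = clinical$time, event = clinical$event, group = groups)
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = d)
  sdf <- survival::survdiff(survival::Surv(time, event) ~ group, data = d)
  p <- stats::pchisq(sdf$chisq, df = nlevels(groups) - 1L, lower.tail = FALSE)
  med <- summary(fit)$table[, "median"]
  names(med) <- sub("^group=", "", rownames(summary(fit)$table))
  list(fit = fit, p = p, median = med)
}

#' Cox proportional-hazards fit
#'
#' Fits a partial-likelihood proportional-hazards model of survival on
#' the given covariates (univariate when one covariate is passed).
#' Rows with missing covariate values are dropped listwise and the
#' count reported via a message.
#'
#' @param data data.frame of covariates, one row per sample, with a
#'   `sample_id` column.
#' @param clinical data.frame with `sample_id`, `time`, `event`.
#' @param covariates character vector of column names in `data` (or in
#'   `clinical`) to include.
#' @return list of class `survival_result`: `table` (data.frame
#'   covariate, hr, lo95, hi95, p), `concordance`, `n`, `events`,
#'   `fit` (the underlying [survival::coxph] object).
#' @export
cox_fit <- function(data, clinical, covariates) {
  if (!length(covariates)) stop("need at least one covariate")
  merged <- merge(clinical[c("sample_id", "time", "event")],
                  data, by = "sample_id")
  miss <- setdiff(covariates, colnames(merged))
  take <- intersect(miss, colnames(clinical))
  if (length(take))
    merged <- merge(merged, clinical[c("sample_id", take)], by = "sample_id")
  miss <- setdiff(covariates, colnames(merged))
  if (length(miss)) stop("covariate(s) not found: ", paste(miss, collapse = ", "))
  d <- merged[c("time", "event", covariates)]
  keep <- stats::complete.cases(d)
  if (any(!keep))
    message(sum(!keep), " sample(s) dropped for missing covariate values")
  d <- d[keep, , drop = FALSE]
  for (cv in covariates) {
    if (length(unique(d[[cv]])) < 2L)
      stop("covariate has a single level: ", cv)
  }
  if (sum(d$event) < length(covariates))
    stop("fewer events than covariates")
  form <- stats::as.formula(paste(
    "survival::Surv(time, event) ~",
    paste(sprintf("`%s`", covariates), collapse = " + ")))
  fit <- withCallingHandlers(
    survival::coxph(form, data = d),
    warning = function(w) {
      if (grepl("converge|infinite|singular", conditionMessage(w)))
        warning("possible separation or non-convergence: ",
                conditionMessage(w), call. = FALSE)
      invokeRestart("muffleWarning")
    })
  sm <- summary(fit)
  tab <- data.frame(
    covariate = rownames(sm$coefficients),
    hr = sm$coefficients[, "exp(coef)"],
    lo95 = sm$conf.int[, "lower .95"],
    hi95 = sm$conf.int[, "upper .95"],
    p = sm$coefficients[, "Pr(>|z|)"],
    row.names = NULL)
  structure(list(table = tab,
                 concordance = unname(sm$concordance[["C"]]),
                 n = nrow(d), events = sum(d$event), fit = fit),
            class = "survival_result")
}

#' @export
print.survival_result <- function(x, ...) {
  cat(sprintf("Cox PH fit: n = %d, events = %d, C = %.3f\n",
              x$n, x$events, x$concordance))
  print(x$table, digits = 3)
  invisible(x)
}

#' Cross the TE and TI median dichotomizations into four groups
#'
#' @param te_scores,ti_scores numeric vectors over the same samples
#'   (matched by name when named).
#' @return factor with levels `TEhi/TIlo`, `TEhi/TIhi`, `TElo/TIlo`,
#'   `TElo/TIhi`.
#' @export
four_group_stratify <- function(te_scores, ti_scores) {
  if (!is.null(names(te_scores)) && !is.null(names(ti_scores))) {
    if (!setequal(names(te_scores), names(ti_scores)))
      stop("TE and TI scores cover different sample sets")
    ti_scores <- ti_scores[names(te_scores)]
  } else if (length(te_scores) != length(ti_scores)) {
    stop("TE and TI score vectors differ in length")
  }
  te <- dichotomize(te_scores)
  ti <- dichotomize(ti_scores)
  lab <- paste0(ifelse(te == "high", "TEhi", "TElo"), "/",
                ifelse(ti == "high", "TIhi", "TIlo"))
  out <- factor(lab, levels = c("TEhi/TIlo", "TEhi/TIhi",
                                "TElo/TIlo", "TElo/TIhi"))
  names(out) <- names(te_scores)
  out
}

#' Compare prognostic feature sets by concordance index
#'
#' Fits one proportional-hazards model per feature set and reports
#' Harrell's C of its linear predictor. In-sample by default, mirroring
#' per-cohort reporting; `cv_folds > 1` switches to k-fold
#' cross-validated concordance (C of the out-of-fold linear predictor).
#'
#' @param data covariate data.frame with `sample_id`.
#' @param clinical clinical data.frame.
#' @param feature_sets named list, label -> character vector of
#'   covariate names.
#' @param cv_folds 1 (in-sample, default) or a fold count.
#' @param seed seed for fold assignment.
#' @return data.frame (label, c_index, n, events), class
#'   `model_comparison`.
#' @export
compare_models <- function(data, clinical, feature_sets, cv_folds = 1L,
                           seed = 1L) {
  stopifnot(is.list(feature_sets), length(names(feature_sets)) > 0)
  res <- lapply(names(feature_sets), function(lab) {
    covs <- feature_sets[[lab]]
    if (cv_folds <= 1L) {
      fit <- cox_fit(data, clinical, covs)
      data.frame(label = lab, c_index = fit$concordance,
                 n = fit$n, events = fit$events)
    } else {
      merged <- merge(clinical[c("sample_id", "time", "event")], data,
                      by = "sample_id")
      merged <- merged[stats::complete.cases(merged[c("time", "event", covs)]), ]
      n <- nrow(merged)
      folds <- with_seed(seed, sample(rep_len(seq_len(cv_folds), n)))
      lp <- numeric(n)
      for (f in seq_len(cv_folds)) {
        tr <- merged[folds != f, , drop = FALSE]
        fit <- cox_fit(tr[c("sample_id", covs)], tr, covs)
        te <- merged[folds == f, , drop = FALSE]
        lp[folds == f] <- as.numeric(as.matrix(te[covs]) %*%
                                       stats::coef(fit$fit))
      }
      cc <- survival::concordance(
        survival::Surv(merged$time, merged$event) ~ lp, reverse = TRUE)
      data.frame(label = lab, c_index = unname(cc$concordance),
                 n = n, events = sum(merged$event))
    }
  })
  out <- do.call(rbind, res)
  class(out) <- c("model_comparison", class(out))
  out
}

#' Responder statistics: rank-sum tests, ROC curve and AUC
#'
#' For binary labels, reports the two-sided Mann-Whitney (Wilcoxon
#' rank-sum) p for responder vs non-responder and the rank-statistic
#' AUC (`U / (n1 * n2)`, the probability a responder outscores a
#' non-responder). For three-level labels NR/LS/CR the contrasts are
#' CR vs NR and LS vs NR, with the AUC computed for responder
#' (CR or LS) vs NR.
#'
#' @param scores numeric vector.
#' @param labels vector of class labels. Binary inputs use the factor's
#'   second level (or `"responder"`) as the positive class; 3-level
#'   inputs must use labels `NR`, `LS`, `CR`.
#' @param positive optional name of the positive (responder) class for
#'   binary labels.
#' @return list with `tests` (data.frame contrast, p), `auc`, `roc`
#'   (data.frame fpr, tpr at every threshold).
#' @export
response_stats <- function(scores, labels, positive = NULL) {
  labels <- as.character(labels)
  ok <- is.finite(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  lv <- unique(labels)
  if (length(lv) < 2L) stop("need at least two classes")
  if (any(table(labels) < 2L)) stop("need >= 2 samples per class")
  wtest <- function(a, b)
    suppressWarnings(stats::wilcox.test(a, b, exact = FALSE)$p.value)
  if (setequal(lv, c("NR", "LS", "CR"))) {
    tests <- data.frame(
      contrast = c("CR vs NR", "LS vs NR"),
      p = c(wtest(scores[labels == "CR"], scores[labels == "NR"]),
            wtest(scores[labels == "LS"], scores[labels == "NR"])))
    pos <- labels %in% c("CR", "LS")
  } else if (length(lv) == 2L) {
    if (is.null(positive))
      positive <- if ("responder" %in% lv) "responder" else sort(lv)[[2L]]
    tests <- data.frame(
      contrast = sprintf("%s vs %s", positive, setdiff(lv, positive)),
      p = wtest(scores[labels == positive], scores[labels != positive]))
    pos <- labels == positive
  } else {
    stop("labels must be binary or the NR/LS/CR triplet")
  }
  n1 <- sum(pos); n0 <- sum(!pos)
  r <- rank(scores)
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  roc <- data.frame(
    fpr = vapply(thr, function(t) mean(scores[!pos] >= t), 0),
    tpr = vapply(thr, function(t) mean(scores[pos] >= t), 0))
  list(tests = tests, auc = auc, roc = roc)
}
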