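test_that("dichotomize median split with ties going low", {
  expect_identical(as.character(dichotomize(c(1, 2, 3, 4))),
                   c("low", "low", "high", "high"))
  expect_identical(as.character(dichotomize(c(1, 2, 2, 3))),
                   c("low", "low", "low", "high"))
  g <- dichotomize(rnorm(101))
  expect_lte(sum(g == "high"), sum(g == "low"))
  expect_error(dichotomize(rep(2, 5)), "equal")
  expect_error(dichotomize(1), "2 samples")
})

test_that("km_logrank null, power and invariances", {
  set.seed(5)
  n <- 200
  clinical <- data.frame(sample_id = sprintf("S%03d", 1:n),
                         time = rexp(n, 0.1), event = rep(1L, n))
  same <- factor(rep(c("a", "b"), each = n / 2))
  # identical survival distribution in both groups -> p not small
  res <- km_logrank(same, clinical)
  expect_gt(res$p, 0.05)
  # relabeling group names leaves p unchanged
  relab <- factor(rep(c("x", "y"), each = n / 2))
  expect_equal(km_logrank(relab, clinical)$p, res$p, tolerance = 1e-12)
  expect_error(km_logrank(factor(rep("a", n)), clinical), "two")
  # planted HR = 3: power over 20 quick simulations
  hits <- 0L
  for (i in 1:20) {
    grp <- rep(c(0, 1), each = n / 2)
    cl <- data.frame(sample_id = clinical$sample_id,
                     time = rexp(n, 0.05 * 3^grp), event = 1L)
    if (km_logrank(factor(grp), cl)$p < 0.01) hits <- hits + 1L
  }
  expect_gte(hits, 19L)
})

test_that("cox_fit recovers a planted log-hazard ratio", {
  set.seed(23)
  ok <- 0L
  for (i in 1:25) {
    n <- 500
    x <- rnorm(n)
    time <- rexp(n, 0.05 * exp(log(2) * x))
    cens <- rexp(n, 0.012)
    cl <- data.frame(sample_id = sprintf("S%03d", 1:n),
                     time = pmin(time, cens),
                     event = as.integer(time <= cens))
    fit <- cox_fit(data.frame(sample_id = cl$sample_id, score = x),
                   cl, "score")
    hr <- fit$table$hr[1]
    if (hr >= 1.6 && hr <= 2.5) ok <- ok + 1L
  }
  expect_gte(ok, 23L)  # >= 90% of simulations inside [1.6, 2.5]
})

test_that("cox_fit handles missing data, single-level and multivariate", {
  set.seed(31)
  n <- 120L
  x <- rnorm(n)
  cl <- data.frame(sample_id = sprintf("S%03d", 1:n),
                   time = rexp(n, 0.1 * exp(0.8 * x)), event = 1L,
                   age = c(NA, round(rnorm(n - 1, 60, 8))),
                   sex = sample(c("m", "f"), n, TRUE))
  d <- data.frame(sample_id = cl$sample_id, score = x)
  expect_message(fit <- cox_fit(d, cl, c("score", "age", "sex")),
                 "dropped")
  expect_identical(fit$n, n - 1L)
  expect_identical(nrow(fit$table), 3L)
  expect_true(all(fit$table$hr > 0))
  expect_true(all(fit$table$lo95 <= fit$table$hr &
                  fit$table$hr <= fit$table$hi95))
  d$flat <- 1
  expect_error(cox_fit(d, cl, "flat"), "single level")
})

test_that("univariate Cox p is calibrated under the null", {
  set.seed(99)
  n <- 80
  reps <- 200
  p <- replicate(reps, {
    cl <- data.frame(sample_id = sprintf("S%02d", 1:n),
                     time = rexp(n, 0.1), event = 1L)
    cox_fit(data.frame(sample_id = cl$sample_id, score = rnorm(n)),
            cl, "score")$table$p[1]
  })
  expect_gt(ks.test(p, "punif")$p.value, 0.01)
})

test_that("four_group_stratify crosses the two median splits", {
  te <- c(a = 1, b = 2, c = 3, d = 4)
  ti <- c(a = 4, b = 3, c = 2, d = 1)
  g <- four_group_stratify(te, ti)
  expect_identical(as.character(g), c("TElo/TIhi", "TElo/TIhi",
                                      "TEhi/TIlo", "TEhi/TIlo"))
  g2 <- four_group_stratify(te, te)
  expect_setequal(as.character(g2), c("TElo/TIlo", "TEhi/TIhi"))
  expect_identical(sum(table(g)), 4L)
  expect_error(four_group_stratify(te, ti[1:3]), "different sample sets")
})

test_that("compare_models: perfect predictor C=1, random C~0.5", {
  set.seed(12)
  n <- 200
  cl <- data.frame(sample_id = sprintf("S%03d", 1:n),
                   time = rexp(n, 0.1), event = 1L)
  d <- data.frame(sample_id = cl$sample_id,
                  perfect = -cl$time,   # higher score = shorter survival
                  noise = rnorm(n))
  # the perfect predictor separates by construction -> documented warning
  expect_warning(
    cmp <- compare_models(d, cl, list(perfect = "perfect", noise = "noise")),
    "separation|converge")
  expect_equal(cmp$c_index[cmp$label == "perfect"], 1)
  expect_lt(abs(cmp$c_index[cmp$label == "noise"] - 0.5), 0.08)
  expect_true(all(cmp$c_index >= 0 & cmp$c_index <= 1))
})

test_that("C-index of a predictor mirrors to 1 - C for its negation", {
  set.seed(4)
  n <- 150
  x <- rnorm(n)
  cl <- data.frame(sample_id = sprintf("S%03d", 1:n),
                   time = rexp(n, 0.1 * exp(x)), event = 1L)
  cc <- function(v) unname(survival::concordance(
    survival::Surv(cl$time, cl$event) ~ v, reverse = TRUE)$concordance)
  expect_equal(cc(x), 1 - cc(-x), tolerance = 1e-12)
})

test_that("response_stats AUC equals the exact rank-sum construction", {
  # 6 vs 6 with exactly one overlapping pair -> AUC = 35/36
  resp <- c(2, 3, 4, 5, 6, 6.5)
  nonr <- c(0, 0.5, 1, 1.2, 1.5, 2.5)
  scores <- c(resp, nonr)
  labels <- rep(c("responder", "non-responder"), each = 6)
  rs <- response_stats(scores, labels)
  expect_equal(rs$auc, 35 / 36, tolerance = 1e-12)
  # p agrees with the exact Wilcoxon distribution
  exact_p <- wilcox.test(resp, nonr, exact = TRUE)$p.value
  expect_lt(abs(rs$tests$p[1] - exact_p), 0.02)  # normal approx vs exact
  # U / (n1 n2) identity on random data
  set.seed(2)
  sc <- rnorm(40)
  lb <- rep(c("responder", "non-responder"), 20)
  rs2 <- response_stats(sc, lb)
  U <- unname(wilcox.test(sc[lb == "responder"],
                          sc[lb == "non-responder"],
                          exact = FALSE)$statistic)
  expect_equal(rs2$auc, U / 400, tolerance = 1e-12)
})

test_that("response_stats separations, ROC and three-level labels", {
  rs <- response_stats(c(1, 2, 3, 10, 11, 12),
                       rep(c("non-responder", "responder"), each = 3))
  expect_equal(rs$auc, 1)
  expect_equal(max(rs$roc$tpr), 1)
  expect_equal(min(rs$roc$fpr), 0)
  # NR/LS/CR: two contrasts, responder = CR or LS
  set.seed(6)
  sc <- c(rnorm(10, 2), rnorm(10, 2), rnorm(10, 0))
  lb <- rep(c("CR", "LS", "NR"), each = 10)
  rs3 <- response_stats(sc, lb)
  expect_setequal(rs3$tests$contrast, c("CR vs NR", "LS vs NR"))
  expect_gt(rs3$auc, 0.7)
  expect_error(response_stats(1:5, rep("x", 5)), "two classes")
})
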