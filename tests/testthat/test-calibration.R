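# ROC/AUROC/Youden calibration, logistic screening, cohort comparisons.

test_that("AUROC handles separation, ties, and degenerate label sets", {
  expect_equal(auroc(c(1, 2, 3, 4), c("neg", "neg", "pos", "pos")), 1)
  expect_equal(auroc(rep(5, 10), rep(c("pos", "neg"), 5)), 0.5)
  expect_error(auroc(1:4, rep("pos", 4)), class = "qus_calibration_error")
})

test_that("AUROC is antisymmetric in score direction and rank-invariant", {
  set.seed(101)
  for (rep in 1:50) {
    inst <- random_instance()
    a <- auroc(inst$scores, inst$labels)
    expect_equal(a + auroc(-inst$scores, inst$labels), 1)
    # any strictly increasing transform leaves the AUROC unchanged
    expect_equal(auroc(exp(inst$scores / 2), inst$labels), a)
    expect_equal(auroc(rank(inst$scores, ties.method = "average"), inst$labels), a)
  }
})

test_that("AUROC equals the trapezoidal area under the empirical ROC", {
  set.seed(102)
  for (rep in 1:20) {
    inst <- random_instance()
    roc <- roc_curve(inst$scores, inst$labels)
    p <- roc$points
    trap <- sum(diff(p$fpr) * (head(p$tpr, -1) + tail(p$tpr, -1)) / 2)
    expect_equal(roc$auc, trap, tolerance = 1e-12)
  }
})

test_that("AUROC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(103)
  for (rep in 1:10) {
    inst <- random_instance()
    ref <- suppressMessages(pROC::auc(pROC::roc(
      response = inst$labels, predictor = inst$scores,
      levels = c("neg", "pos"), direction = "<")))
    expect_equal(auroc(inst$scores, inst$labels), as.numeric(ref))
  }
})

test_that("the ROC best Youden point matches the brute-force threshold scan", {
  set.seed(104)
  for (rep in 1:200) {
    inst <- random_instance(50)
    roc <- roc_curve(inst$scores, inst$labels)
    expect_equal(roc$youden_j, oracle_best_j(inst$scores, inst$labels),
                 tolerance = 1e-12)
    # internal consistency of the reported operating point
    ss <- sens_spec_at(inst$scores, inst$labels, roc$best_cutoff)
    expect_equal(ss$sens, roc$sens_at_best)
    expect_equal(ss$spec, roc$spec_at_best)
    expect_equal(roc$youden_j, roc$sens_at_best + roc$spec_at_best - 1)
    # thresholds never coincide with observed scores
    expect_false(roc$best_cutoff %in% inst$scores)
  }
})

test_that("perfectly separated toy data yield the expected operating point", {
  roc <- roc_curve(c(1, 2, 3, 4), c("neg", "neg", "pos", "pos"))
  expect_equal(roc$best_cutoff, 2.5)
  expect_equal(roc$youden_j, 1)
  expect_equal(roc$sens_at_best, 1)
  expect_equal(roc$spec_at_best, 1)
  expect_equal(roc$auc, 1)
  expect_true(all(diff(roc$points$fpr) >= 0))
  expect_true(all(diff(roc$points$tpr) >= 0))
})

test_that("Hanley-McNeil SE shrinks with sample size at fixed AUC", {
  ses <- vapply(c(50, 500, 5000), function(n) auroc_se_hanley(0.85, n, n),
                numeric(1))
  expect_true(all(diff(ses) < 0))
  expect_lt(ses[3] / ses[1], 0.15)
})

test_that("ci95 is the clipped normal interval around the AUROC", {
  set.seed(105)
  inst <- random_instance()
  roc <- roc_curve(inst$scores, inst$labels)
  expect_equal(roc$ci95[1], max(0, roc$auc - 1.96 * roc$auc_se))
  expect_equal(roc$ci95[2], min(1, roc$auc + 1.96 * roc$auc_se))
  perfect <- roc_curve(c(1, 2, 10, 11), c("neg", "neg", "pos", "pos"))
  expect_lte(perfect$ci95[2], 1)
})

test_that("Youden index arithmetic and domain checks", {
  expect_equal(youden_from_rates(0.68, 0.90), 0.58)
  expect_equal(youden_from_rates(1, 1), 1)
  expect_equal(youden_from_rates(0.5, 0.5), 0)
  expect_error(youden_from_rates(1.2, 0.5), class = "qus_domain_error")
  expect_error(youden_from_rates(0.5, -0.1), class = "qus_domain_error")
})

test_that("sensitivity/specificity at fixed cut-offs match the binormal closed form", {
  set.seed(106)
  n <- 60000
  pos <- rnorm(n, 30.1, 6.8)
  neg <- rnorm(n, 21.9, 4.1)
  ss <- sens_spec_at(c(pos, neg), rep(c("pos", "neg"), each = n), 26.85)
  se <- sqrt(0.68 * 0.32 / n)
  expect_lt(abs(ss$sens - pnorm((30.1 - 26.85) / 6.8)), 4 * se)
  expect_lt(abs(ss$spec - pnorm((26.85 - 21.9) / 4.1)), 4 * se)
  posl <- rnorm(n, 26.5, 6.0)
  sl <- sens_spec_at(c(posl, neg), rep(c("pos", "neg"), each = n), 21.25)
  expect_lt(abs(sl$sens - pnorm((26.5 - 21.25) / 6.0)), 4 * se)
  # and the large-sample AUROC approaches its binormal closed form
  a <- auroc(c(pos, neg), rep(c("pos", "neg"), each = n))
  expect_lt(abs(a - binormal_auc(30.1, 6.8, 21.9, 4.1)), 0.005)
})

test_that("IRLS logistic fit maximizes the likelihood and matches glm", {
  x <- c(1, 2, 3, 4, 5, 6, 7, 8)
  y <- c(0, 0, 1, 0, 1, 1, 1, 1)
  fit <- logistic_fit_univariate(x, y)
  expect_true(fit$converged)

  loglik <- function(b0, b1) {
    eta <- b0 + b1 * x
    sum(y * eta - log(1 + exp(eta)))
  }
  # the IRLS optimum beats an exhaustive 200 x 200 coefficient grid
  grid_ll <- outer(seq(-10, 5, length.out = 200),
                   seq(-2, 3, length.out = 200), Vectorize(loglik))
  expect_gte(loglik(fit$intercept, fit$beta), max(grid_ll))

  ref <- glm(y ~ x, family = binomial())
  expect_equal(fit$beta, unname(coef(ref)[2]), tolerance = 1e-6)
  expect_equal(fit$intercept, unname(coef(ref)[1]), tolerance = 1e-6)
  expect_equal(fit$se, unname(sqrt(diag(vcov(ref)))[2]), tolerance = 1e-4)
  expect_equal(fit$odds_ratio, exp(fit$beta))
  expect_gte(fit$wald, 0)
})

test_that("fitted probabilities average to the empirical positive rate", {
  set.seed(107)
  for (rep in 1:10) {
    n <- 80
    x <- rnorm(n)
    y <- rbinom(n, 1, plogis(-0.3 + 0.8 * x))
    if (length(unique(y)) < 2) next
    fit <- logistic_fit_univariate(x, y)
    p_hat <- plogis(fit$intercept + fit$beta * x)
    expect_lt(abs(mean(p_hat) - mean(y)), 1e-8)
  }
})

test_that("degenerate logistic inputs are flagged or rejected", {
  # complete separation: flagged, not silently reported
  xs <- c(1, 2, 3, 10, 11, 12)
  ys <- c(0, 0, 0, 1, 1, 1)
  fit <- logistic_fit_univariate(xs, ys)
  expect_false(fit$converged)
  expect_error(logistic_fit_univariate(rep(2, 6), ys), class = "qus_fit_error")
  expect_error(logistic_fit_univariate(1:6, rep(1, 6)),
               class = "qus_calibration_error")
})

test_that("odds ratios are exp(beta) at the printed precision", {
  expect_equal(round(or_from_beta(0.342), 3), 1.408)
  expect_equal(round(or_from_beta(-0.044), 3), 0.957)
  expect_equal(or_from_beta(0), 1)
  expect_error(or_from_beta(Inf), class = "qus_domain_error")
})

test_that("pooled t-test matches the hand-computed formula", {
  same <- ttest_independent(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t_stat, 0)
  expect_equal(same$t_p, 1)

  a <- c(1, 2, 3)
  b <- c(11, 12, 13)
  res <- ttest_independent(a, b)
  sp2 <- (2 * var(a) + 2 * var(b)) / 4
  expect_equal(res$t_stat, (mean(a) - mean(b)) / sqrt(sp2 * (1 / 3 + 1 / 3)))
  expect_equal(res$df, 4)
  expect_error(ttest_independent(1, c(1, 2)), class = "qus_stats_error")
})

test_that("group StdDev difference is detected on a simulated cohort", {
  scores <- simulate_scores(cohort_params(seed = 2024))
  res <- ttest_independent(scores$t_sd[scores$reference_label == "pos"],
                           scores$t_sd[scores$reference_label == "neg"])
  expect_lt(res$t_p, 0.001)
})

test_that("chi-square for proportions matches the direct formula", {
  same <- chi_square_proportions(20, 100, 20, 100)
  expect_equal(same$chi2_stat, 0)
  expect_equal(same$chi2_p, 1)

  # sex split similar to the cohort's: not significant
  sexes <- chi_square_proportions(54, 136, 82, 200)
  expect_gt(sexes$chi2_p, 0.05)

  set.seed(108)
  for (rep in 1:20) {
    n1 <- sample(10:200, 1); n2 <- sample(10:200, 1)
    k1 <- sample(1:(n1 - 1), 1); k2 <- sample(1:(n2 - 1), 1)
    res <- suppressWarnings(chi_square_proportions(k1, n1, k2, n2))
    obs <- rbind(c(k1, n1 - k1), c(k2, n2 - k2))
    expected <- outer(rowSums(obs), colSums(obs)) / sum(obs)
    expect_equal(res$chi2_stat, sum((obs - expected)^2 / expected))
  }
  expect_error(chi_square_proportions(0, 10, 0, 10), class = "qus_stats_error")
})
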