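# Cut-off calibration and diagnostic performance: empirical ROC, rank-based
# AUROC with Hanley-McNeil standard error, Youden-optimal operating point,
# univariate logistic screening, and the two-group cohort comparisons.

check_two_classes <- function(labels) {
  labels <- as.character(labels)
  if (!all(labels %in% c("pos", "neg"))) {
    qus_stop("labels must be \"pos\"/\"neg\"", "qus_calibration_error")
  }
  pos <- labels == "pos"
  if (!any(pos) || all(pos)) {
    qus_stop("both classes must be present to calibrate", "qus_calibration_error")
  }
  pos
}

#' Rank-based AUROC (Mann-Whitney estimator)
#'
#' Probability that a randomly chosen positive scores above a randomly chosen
#' negative, ties counted one half; identical to the trapezoidal area under
#' the empirical ROC curve.
#'
#' @param scores numeric scores (higher = more disease-like).
#' @param labels `"pos"`/`"neg"` per score.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  pos <- check_two_classes(labels)
  if (anyNA(scores)) qus_stop("scores contain NA", "qus_calibration_error")
  r <- rank(scores)
  n_pos <- as.numeric(sum(pos))  # numeric: n_pos * n_neg overflows int32
  n_neg <- as.numeric(sum(!pos))
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Hanley-McNeil standard error of an AUROC
#'
#' Uses the exponential approximation `Q1 = A/(2-A)`, `Q2 = 2A^2/(1+A)`.
#'
#' @param auc AUROC estimate.
#' @param n_pos,n_neg class sizes.
#' @return Standard error.
#' @export
auroc_se_hanley <- function(auc, n_pos, n_neg) {
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  sqrt((auc * (1 - auc) + (n_pos - 1) * (q1 - auc^2) +
          (n_neg - 1) * (q2 - auc^2)) / (n_pos * n_neg))
}

#' Youden index from an operating point
#'
#' @param sens,spec sensitivity and specificity in `[0, 1]`.
#' @return `sens + spec - 1`.
#' @export
youden_from_rates <- function(sens, spec) {
  if (!is.numeric(sens) || !is.numeric(spec) ||
      any(!is.finite(sens)) || any(!is.finite(spec)) ||
      any(sens < 0 | sens > 1) || any(spec < 0 | spec > 1)) {
    qus_stop("sens and spec must lie in [0, 1]", "qus_domain_error")
  }
  sens + spec - 1
}

#' Sensitivity and specificity at a fixed cut-off
#'
#' Positivity is strict: a score must surpass the cut-off.
#'
#' @inheritParams auroc
#' @param cutoff decision threshold.
#' @return Named list `sens` (fraction of positives with score > cutoff) and
#'   `spec` (fraction of negatives with score <= cutoff).
#' @export
sens_spec_at <- function(scores, labels, cutoff) {
  pos <- check_two_classes(labels)
  list(sens = mean(scores[pos] > cutoff),
       spec = mean(scores[!pos] <= cutoff))
}

#' Empirical ROC curve with Youden-optimal cut-off
#'
#' Candidate thresholds are the midpoints between consecutive distinct sorted
#' scores, plus one sentinel below the minimum and one above the maximum, so
#' the selected cut-off never coincides with an observed score. The AUROC is
#' the rank-based estimator of [auroc()]; its standard error is Hanley-McNeil
#' and the 95% CI is the normal approximation clipped to `[0, 1]`. The best
#' cut-off maximizes the Youden index J = sens + spec - 1; ties are broken
#' toward higher specificity, then toward the lower threshold.
#'
#' @inheritParams auroc
#' @return An object of class `qus_roc`: `points` (data frame `threshold`,
#'   `fpr`, `tpr` ordered by increasing fpr), `auc`, `auc_se`, `ci95`,
#'   `best_cutoff`, `youden_j`, `sens_at_best`, `spec_at_best`, `n_pos`,
#'   `n_neg`.
#' @export
roc_curve <- function(scores, labels) {
  pos <- check_two_classes(labels)
  if (anyNA(scores)) qus_stop("scores contain NA", "qus_calibration_error")
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  u <- sort(unique(scores))
  thr <- c(u[1] - 1, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2,
           u[length(u)] + 1)
  pos_sorted <- sort(scores[pos])
  neg_sorted <- sort(scores[!pos])
  sens <- 1 - findInterval(thr, pos_sorted) / n_pos  # P(pos score > thr)
  spec <- findInterval(thr, neg_sorted) / n_neg      # P(neg score <= thr)
  j <- sens + spec - 1

  best <- which(j == max(j))
  if (length(best) > 1L) best <- best[order(-spec[best], thr[best])][1L]

  auc <- auroc(scores, c("neg", "pos")[pos + 1L])
  se <- auroc_se_hanley(auc, n_pos, n_neg)
  ord <- order(1 - spec, sens)
  structure(
    list(
      points = data.frame(threshold = thr[ord], fpr = (1 - spec)[ord],
                          tpr = sens[ord]),
      auc = auc,
      auc_se = se,
      ci95 = c(max(0, auc - 1.96 * se), min(1, auc + 1.96 * se)),
      best_cutoff = thr[best],
      youden_j = j[best],
      sens_at_best = sens[best],
      spec_at_best = spec[best],
      n_pos = n_pos,
      n_neg = n_neg
    ),
    class = "qus_roc"
  )
}

#' @export
print.qus_roc <- function(x, ...) {
  cat(sprintf(
    paste0("<qus_roc> n = %d pos / %d neg\n",
           "  AUROC %.3f +/- %.3f (95%% CI %.3f-%.3f)\n",
           "  best cut-off %.4g: J = %.2f, sens %.0f%%, spec %.0f%%\n"),
    x$n_pos, x$n_neg, x$auc, x$auc_se, x$ci95[1], x$ci95[2],
    x$best_cutoff, x$youden_j, 100 * x$sens_at_best, 100 * x$spec_at_best))
  invisible(x)
}

#' Odds ratio from a logistic coefficient
#'
#' @param beta finite logistic slope.
#' @return `exp(beta)`.
#' @export
or_from_beta <- function(beta) {
  if (!all(is.finite(beta))) qus_stop("`beta` must be finite", "qus_domain_error")
  exp(beta)
}

#' Univariate logistic screen (intercept + one predictor)
#'
#' Maximum-likelihood fit by iteratively reweighted least squares;
#' convergence when the largest coefficient change drops below `1e-8`, up to
#' 25 iterations. Standard errors come from the inverse observed information;
#' the Wald statistic is `(beta/se)^2` with a chi-square(1) upper-tail
#' p-value. Complete separation is flagged (`converged = FALSE`, huge
#' drifting coefficients) rather than silently reported.
#'
#' @param x numeric predictor (non-constant).
#' @param y outcomes: 0/1 or `"neg"`/`"pos"`.
#' @return An object of class `qus_logit`: `beta`, `se`, `wald`, `p`,
#'   `odds_ratio` (slope quantities), `intercept`, `intercept_se`,
#'   `converged`, `n_iter`.
#' @export
logistic_fit_univariate <- function(x, y) {
  if (is.character(y)) y <- as.integer(y == "pos")
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) {
    qus_stop("`y` must be 0/1 or \"neg\"/\"pos\"", "qus_usage_error")
  }
  if (length(unique(y)) < 2L) {
    qus_stop("both outcome classes must be present", "qus_calibration_error")
  }
  if (length(unique(x)) < 2L) {
    qus_stop("predictor is constant; no slope is identifiable", "qus_fit_error")
  }
  X <- cbind(1, x)
  beta <- c(0, 0)
  converged <- FALSE
  n_iter <- 0L
  for (it in seq_len(25L)) {
    n_iter <- it
    eta <- drop(X %*% beta)
    p <- 1 / (1 + exp(-eta))
    w <- pmax(p * (1 - p), 1e-10)
    z <- eta + (y - p) / w
    xtw <- t(X * w)
    beta_new <- tryCatch(unname(drop(solve(xtw %*% X, xtw %*% z))),
                         error = function(e) {
                           qus_stop("IRLS normal equations are singular",
                                    "qus_fit_error")
                         })
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    if (delta < 1e-8) {
      converged <- TRUE
      break
    }
  }
  eta <- drop(X %*% beta)
  p <- 1 / (1 + exp(-eta))
  w <- pmax(p * (1 - p), 1e-10)
  info <- t(X * w) %*% X
  cov <- tryCatch(solve(info), error = function(e) matrix(NA_real_, 2, 2))
  se <- unname(sqrt(diag(cov)))
  if (max(abs(beta)) > 1e3) converged <- FALSE  # separation drift
  wald <- (beta[2] / se[2])^2
  structure(
    list(
      beta = beta[2],
      se = se[2],
      wald = wald,
      p = stats::pchisq(wald, df = 1, lower.tail = FALSE),
      odds_ratio = exp(beta[2]),
      intercept = beta[1],
      intercept_se = se[1],
      converged = converged,
      n_iter = n_iter
    ),
    class = "qus_logit"
  )
}

#' @export
print.qus_logit <- function(x, ...) {
  cat(sprintf(
    "<qus_logit> beta %.4g (SE %.4g), Wald %.3f, p %.4g, OR %.4g%s\n",
    x$beta, x$se, x$wald, x$p, x$odds_ratio,
    if (x$converged) "" else "  [NOT CONVERGED]"))
  invisible(x)
}

#' Pooled-variance independent two-sample t-test
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @return Named list `t_stat`, `t_p` (two-sided), `df`.
#' @export
ttest_independent <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) {
    qus_stop("each group needs at least 2 observations", "qus_stats_error")
  }
  fit <- stats::t.test(a, b, var.equal = TRUE)
  list(t_stat = unname(fit$statistic), t_p = fit$p.value,
       df = unname(fit$parameter))
}

#' Pearson chi-square test for two proportions
#'
#' 2x2 Pearson chi-square on 1 degree of freedom, no continuity correction.
#'
#' @param k1,n1 successes and total in group 1.
#' @param k2,n2 successes and total in group 2.
#' @return Named list `chi2_stat`, `chi2_p`.
#' @export
chi_square_proportions <- function(k1, n1, k2, n2) {
  if (n1 <= 0 || n2 <= 0 || k1 < 0 || k2 < 0 || k1 > n1 || k2 > n2) {
    qus_stop("counts must satisfy 0 <= k <= n, n > 0", "qus_stats_error")
  }
  tab <- rbind(c(k1, n1 - k1), c(k2, n2 - k2))
  if (any(colSums(tab) == 0) || any(rowSums(tab) == 0)) {
    qus_stop("degenerate 2x2 table: a margin is zero", "qus_stats_error")
  }
  fit <- stats::chisq.test(tab, correct = FALSE)
  list(chi2_stat = unname(fit$statistic), chi2_p = fit$p.value)
}
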