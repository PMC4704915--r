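# Design-stage power and sample-size calculations for the evaluation
# protocol: a one-sided paired t design on log cost, the incremental-R^2
# F test, and a comparison of two correlated AUCs.

#' Sample size for a one-sided paired t test
#'
#' Computes the number of pairs needed to detect a standardized mean paired
#' difference (`effect`, in units of the standard deviation of the paired
#' differences) with a one-sided paired test, using the normal-approximation
#' design formula `n = ceiling((z[1-alpha] + z[power])^2 / effect^2)`.
#'
#' At `alpha = 0.05`, `power = 0.90` and an effect of 0.1 SD this returns 857
#' pairs, the design size used for comparing per-patient log costs between
#' two management policies.
#'
#' @param effect Standardized effect size (mean paired difference divided by
#'   the SD of the paired differences). Must be positive.
#' @param alpha One-sided significance level.
#' @param power Target power.
#' @return Required number of pairs (integer).
#' @examples
#' paired_t_sample_size(effect = 0.1, alpha = 0.05, power = 0.90)  # 857
#' @export
paired_t_sample_size <- function(effect, alpha = 0.05, power = 0.90) {
  if (!is.numeric(effect) || length(effect) != 1L || is.na(effect) || effect <= 0) {
    stopf("`effect` must be a single positive number")
  }
  check_prob(alpha, "alpha")
  check_prob(power, "power")
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1) {
    stopf("`alpha` and `power` must lie strictly inside (0, 1)")
  }
  z <- qnorm(1 - alpha) + qnorm(power)
  as.integer(ceiling(z^2 / effect^2))
}

#' Power of the incremental-R^2 F test
#'
#' Power of the F test that adding `k_added` predictors to a linear model with
#' `k_base` predictors increases the population R^2 by `delta_R2`, at sample
#' size `n`. Uses the noncentral-F formulation with Cohen's effect size
#' `f2 = delta_R2 / (1 - base_R2 - delta_R2)` and noncentrality
#' `lambda = f2 * (u + v + 1)` where `u = k_added` and
#' `v = n - k_base - k_added - 1`.
#'
#' @param n Sample size.
#' @param base_R2 Population R^2 of the base model.
#' @param delta_R2 Increment in population R^2 attributable to the added
#'   predictors.
#' @param k_base Number of predictors in the base model.
#' @param k_added Number of added predictors under test.
#' @param alpha Significance level.
#' @return Power in (0, 1).
#' @examples
#' f_test_r2_power(n = 245, base_R2 = 0.15, delta_R2 = 0.10,
#'                 k_base = 70, k_added = 30)
#' @export
f_test_r2_power <- function(n, base_R2, delta_R2, k_base, k_added, alpha = 0.05) {
  n <- check_count(n, "n")
  k_base <- check_count(k_base, "k_base")
  k_added <- check_count(k_added, "k_added")
  check_prob(base_R2, "base_R2")
  if (!is.numeric(delta_R2) || delta_R2 < 0) stopf("`delta_R2` must be non-negative")
  check_prob(alpha, "alpha")
  if (base_R2 + delta_R2 >= 1) {
    stopf("`base_R2` + `delta_R2` must be < 1")
  }
  if (n <= k_base + k_added + 1L) {
    stopf("`n` must exceed k_base + k_added + 1")
  }
  u <- k_added
  v <- n - k_base - k_added - 1L
  if (delta_R2 == 0) return(alpha)
  f2 <- delta_R2 / (1 - base_R2 - delta_R2)
  lambda <- f2 * (u + v + 1)
  crit <- qf(1 - alpha, u, v)
  1 - pf(crit, u, v, ncp = lambda)
}

# Hanley-McNeil variance of a single AUC under the exponential-score
# approximation, for n_pos positive and n_neg negative instances.
auc_variance_hm <- function(auc, n_pos, n_neg) {
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  (auc * (1 - auc) + (n_pos - 1) * (q1 - auc^2) + (n_neg - 1) * (q2 - auc^2)) /
    (n_pos * n_neg)
}

#' Sample size to compare two correlated AUCs
#'
#' Per-class sample size needed to detect the difference between two AUCs
#' measured on the same instances (two models scored on one test set) with a
#' two-sided z test. Uses the Hanley-McNeil exponential-distribution variance
#' approximation for each AUC and a correlation `r` between the two models'
#' prediction results, assumed common to both classes, so that
#' `Var(A1 - A2) = V1 + V2 - 2 r sqrt(V1 V2)`.
#'
#' Balanced classes are assumed: the returned `n` is the number of instances
#' in each class. The smallest `n` whose analytic power reaches the target is
#' found by bisection.
#'
#' @param auc1,auc2 The two AUCs, each in `[0.5, 1)` and not equal.
#' @param r Correlation between the two models' predictions.
#' @param alpha Two-sided significance level.
#' @param power Target power.
#' @return Required instances per class (integer).
#' @examples
#' correlated_auc_sample_size(auc1 = 0.70, auc2 = 0.80, r = 0.6)
#' @export
correlated_auc_sample_size <- function(auc1, auc2, r, alpha = 0.05, power = 0.90) {
  for (a in c(auc1, auc2)) {
    if (!is.numeric(a) || a < 0.5 || a >= 1) stopf("AUCs must lie in [0.5, 1)")
  }
  if (auc1 == auc2) stopf("`auc1` and `auc2` are equal: zero effect, no finite n")
  if (!is.numeric(r) || r < -1 || r > 1) stopf("`r` must be a correlation in [-1, 1]")
  check_prob(alpha, "alpha")
  check_prob(power, "power")

  pow_at <- function(n) correlated_auc_power(auc1, auc2, r, n, alpha)
  lo <- 2L
  hi <- 2L
  while (pow_at(hi) < power) {
    hi <- hi * 2L
    if (hi > 1e7) stopf("required n exceeds 1e7; effect too small")
  }
  while (hi - lo > 1L) {
    mid <- (lo + hi) %/% 2L
    if (pow_at(mid) >= power) hi <- mid else lo <- mid
  }
  hi
}

#' Power of the two-correlated-AUC z test at a given per-class n
#'
#' @inheritParams correlated_auc_sample_size
#' @param n Instances per class.
#' @return Analytic power of the two-sided z test.
#' @export
correlated_auc_power <- function(auc1, auc2, r, n, alpha = 0.05) {
  n <- check_count(n, "n")
  v1 <- auc_variance_hm(auc1, n, n)
  v2 <- auc_variance_hm(auc2, n, n)
  vd <- v1 + v2 - 2 * r * sqrt(v1 * v2)
  if (vd <= 0) return(1)
  z_alpha <- qnorm(1 - alpha / 2)
  delta <- abs(auc1 - auc2) / sqrt(vd)
  pnorm(delta - z_alpha) + pnorm(-delta - z_alpha)
}
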