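# Policy outcome simulation: per-patient enrolled cost h + c_i - n_e*p*c_e,
# aggregate costs / admissions / ED visits under a stratification policy,
# sensitivity grids, attribute-combination tables, the minimum-accuracy
# search, and the paired comparison tests.

#' Build per-patient trajectories for a simulation year
#'
#' Extracts, for each patient-year row of the chosen index year, the
#' baseline future cost `h`, future undesirable-event count `n_e`, its
#' admission / ED breakdown, and the model's predicted risk used for
#' ranking.
#'
#' @param fm A `feature_matrix`.
#' @param model A fitted `risk_model` (trained on earlier years), or `NULL`
#'   to use the column named in `pred_col`.
#' @param year Index year to simulate (default: last present).
#' @param pred_col Column holding predictions when `model` is `NULL`.
#' @return Data frame `patient_id`, `pred`, `h`, `n_e`, `admissions`, `ed`.
#' @export
holdout_trajectories <- function(fm, model = NULL, year = NULL,
                                 pred_col = NULL) {
  if (is.null(year)) year <- max(fm$index_year)
  rows <- fm$index_year == year
  if (!any(rows)) stopf("no rows for year %d", year)
  dat <- fm[rows, , drop = FALSE]
  pred <- if (!is.null(model)) predict(model, dat) else dat[[pred_col]]
  if (is.null(pred)) stopf("no predictions: supply `model` or `pred_col`")
  data.frame(
    patient_id = dat$patient_id, pred = as.numeric(pred),
    h = dat$cost_next, n_e = dat$n_events_next,
    admissions = dat$admissions_next, ed = dat$ed_next,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Simulate one patient under a management level
#'
#' If the patient is enrolled, the future cost becomes
#' `h + c_i - n_e * p * c_e` and the expected event count `n_e * (1 - p)`
#' (realized by binomial thinning in stochastic mode). Costs that would go
#' negative are floored at zero and counted.
#'
#' @param h Baseline future cost.
#' @param n_e Baseline future event count.
#' @param level A [management_level()].
#' @param c_e Average cost of one event.
#' @param enrolled Whether the uptake draw succeeded (default TRUE).
#' @param mode `"expectation"` (deterministic formulas) or `"stochastic"`
#'   (binomial thinning of events).
#' @return List `cost`, `events`, `floored`.
#' @examples
#' cm <- management_level("case management", c_i = 5000, p = 0.4)
#' simulate_patient(h = 20000, n_e = 2, level = cm, c_e = 10000)  # cost 17000
#' @export
simulate_patient <- function(h, n_e, level, c_e, enrolled = TRUE,
                             mode = c("expectation", "stochastic")) {
  mode <- match.arg(mode)
  if (!enrolled) {
    return(list(cost = h, events = n_e, floored = FALSE))
  }
  cost <- h + level$c_i - n_e * level$p * c_e
  floored <- cost < 0
  if (floored) cost <- 0
  events <- if (mode == "expectation") {
    n_e * (1 - level$p)
  } else {
    rbinom(1L, n_e, 1 - level$p)
  }
  list(cost = cost, events = events, floored = floored)
}

#' Simulate a stratification policy over a patient population
#'
#' Ranks patients by predicted risk, maps them onto the policy's
#' percentile-bin assignment, and simulates every patient. In expectation
#' mode an uptake fraction `u < 1` scales the per-patient enrollment effect
#' (`cost = h + u * (c_i - n_e p c_e)`, `events = n_e (1 - u p)`); in
#' stochastic mode each assigned patient enrolls with probability `u` and
#' events are thinned binomially. Fixed seed gives identical output.
#'
#' @param traj Trajectories from [holdout_trajectories()].
#' @param policy A `strat_policy` from [optimize_thresholds()] or
#'   [heuristic_policy()].
#' @param c_e Average cost per event (default: the policy's).
#' @param uptake Fraction of assignments acted on, in `[0, 1]`.
#' @param mode `"expectation"` or `"stochastic"`.
#' @param seed Seed for stochastic mode.
#' @return A `policy_outcome`: totals, per-level enrollment, per-patient
#'   table, count of floored costs, parameters used.
#' @export
simulate_policy <- function(traj, policy, c_e = NULL, uptake = 1,
                            mode = c("expectation", "stochastic"),
                            seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(inherits(policy, "strat_policy"))
  check_prob(uptake, "uptake")
  if (is.null(c_e)) c_e <- policy$c_e
  lv_names <- vapply(policy$levels, `[[`, "", "name")
  asg <- policy$assignment
  if (!all(asg$level %in% lv_names)) {
    stopf("policy references unknown level(s): %s",
          paste(setdiff(asg$level, lv_names), collapse = ", "))
  }

  n <- nrow(traj)
  n_bins <- nrow(asg)
  ord <- order(traj$pred, decreasing = TRUE)
  base <- n %/% n_bins
  extra <- n %% n_bins
  sizes <- rep(base, n_bins) + c(rep(1L, extra), rep(0L, n_bins - extra))
  bin_of <- integer(n)
  bin_of[ord] <- rep(seq_len(n_bins), times = sizes)
  level_of <- asg$level[bin_of]

  c_i <- vapply(policy$levels, `[[`, 0, "c_i")[match(level_of, lv_names)]
  p <- vapply(policy$levels, `[[`, 0, "p")[match(level_of, lv_names)]

  with_seed(seed, {
    if (mode == "expectation") {
      eff <- uptake * (c_i - traj$n_e * p * c_e)
      cost <- traj$h + eff
      events <- traj$n_e * (1 - uptake * p)
      admissions <- traj$admissions * (1 - uptake * p)
      ed <- traj$ed * (1 - uptake * p)
    } else {
      enrolled <- runif(n) < uptake
      cost <- ifelse(enrolled, traj$h + c_i - traj$n_e * p * c_e, traj$h)
      events <- ifelse(enrolled, rbinom(n, traj$n_e, 1 - p), traj$n_e)
      admissions <- ifelse(enrolled, rbinom(n, traj$admissions, 1 - p),
                           traj$admissions)
      ed <- ifelse(enrolled, rbinom(n, traj$ed, 1 - p), traj$ed)
    }
    floored <- cost < 0
    cost[floored] <- 0

    per_patient <- data.frame(
      patient_id = traj$patient_id, level = level_of,
      baseline_cost = traj$h, cost = cost,
      baseline_events = traj$n_e, events = events,
      admissions = admissions, ed = ed,
      stringsAsFactors = FALSE, row.names = NULL
    )
    structure(list(
      total_cost = sum(cost),
      total_events = sum(events),
      total_admissions = sum(admissions),
      total_ed = sum(ed),
      baseline_cost = sum(traj$h),
      baseline_admissions = sum(traj$admissions),
      baseline_ed = sum(traj$ed),
      enrollment = table(level_of),
      n_floored = sum(floored),
      params = list(c_e = c_e, uptake = uptake, mode = mode, seed = seed),
      per_patient = per_patient
    ), class = "policy_outcome")
  })
}

#' @export
print.policy_outcome <- function(x, ...) {
  cat("<policy_outcome>\n")
  cat(sprintf("  total cost: %.0f (baseline %.0f, change %+.0f)\n",
              x$total_cost, x$baseline_cost, x$total_cost - x$baseline_cost))
  cat(sprintf("  admissions: %.1f (baseline %d), ED visits: %.1f (baseline %d)\n",
              x$total_admissions, x$baseline_admissions,
              x$total_ed, x$baseline_ed))
  if (x$n_floored > 0) cat(sprintf("  %d costs floored at 0\n", x$n_floored))
  invisible(x)
}

#' All-null baseline policy outcome
#'
#' Convenience wrapper: simulates the "no program for anyone" policy, whose
#' totals equal the baseline exactly.
#'
#' @inheritParams simulate_policy
#' @param n_bins Number of percentile bins (cosmetic; totals are invariant).
#' @return A `policy_outcome`.
#' @export
baseline_policy_outcome <- function(traj, c_e, n_bins = 100L) {
  n_bins <- min(n_bins, nrow(traj))
  stats <- data.frame(bin = seq_len(n_bins),
                      n_patients = rep(1L, n_bins), avg_n_e = 0)
  pol <- optimize_thresholds(list(), stats, c_e = c_e)
  simulate_policy(traj, pol, c_e = c_e, uptake = 1, mode = "expectation")
}

#' Full-factorial sensitivity grid over program cost, benefit and uptake
#'
#' Varies one program's `c_i` and `p` together with the clinician uptake
#' fraction over `n_grid` levels each (default 5, minimum to maximum),
#' re-optimizes the thresholds for every cell, simulates the policy, and
#' returns one outcome row per cell.
#'
#' @param traj Trajectories ([holdout_trajectories()]).
#' @param levels List of [management_level()]s.
#' @param c_e Average cost per event.
#' @param c_i_range,p_range,uptake_range Length-2 `c(min, max)` ranges.
#' @param n_grid Grid levels per axis.
#' @param level_name Program to vary (default: first level).
#' @param n_bins Percentile bins for threshold optimization.
#' @param mode,seed Passed to [simulate_policy()].
#' @return Data frame with `c_i`, `p`, `uptake`, `total_cost`,
#'   `total_admissions`, `total_ed`, `n_enrolled`.
#' @export
sensitivity_grid <- function(traj, levels, c_e, c_i_range, p_range,
                             uptake_range = c(1, 1), n_grid = 5L,
                             level_name = NULL, n_bins = 100L,
                             mode = "expectation", seed = 1L) {
  n_grid <- check_count(n_grid, "n_grid")
  for (r in list(c_i_range, p_range, uptake_range)) {
    if (length(r) != 2L || r[1] > r[2]) stopf("ranges must be c(min, max)")
  }
  levels <- normalize_levels(levels)
  lv_names <- vapply(levels, `[[`, "", "name")
  if (is.null(level_name)) level_name <- lv_names[1L]
  idx <- match(level_name, lv_names)
  if (is.na(idx)) stopf("unknown level `%s`", level_name)

  n_bins <- min(n_bins, nrow(traj))
  event_costs <- ifelse(traj$n_e > 0, traj$n_e * c_e, 0)
  stats <- compute_percentile_stats(traj$pred, traj$n_e, event_costs,
                                    n_bins = n_bins)
  attr(stats, "c_e") <- c_e  # c_e supplied, not re-estimated

  grid <- expand.grid(
    c_i = seq(c_i_range[1], c_i_range[2], length.out = n_grid),
    p = seq(p_range[1], p_range[2], length.out = n_grid),
    uptake = seq(uptake_range[1], uptake_range[2], length.out = n_grid)
  )
  grid <- unique(grid)
  res <- lapply(seq_len(nrow(grid)), function(g) {
    lv2 <- levels
    lv2[[idx]]$c_i <- grid$c_i[g]
    lv2[[idx]]$p <- grid$p[g]
    pol <- optimize_thresholds(lv2, stats, c_e = c_e)
    out <- simulate_policy(traj, pol, c_e = c_e, uptake = grid$uptake[g],
                           mode = mode, seed = seed)
    enr <- out$enrollment
    data.frame(
      c_i = grid$c_i[g], p = grid$p[g], uptake = grid$uptake[g],
      total_cost = out$total_cost,
      total_admissions = out$total_admissions,
      total_ed = out$total_ed,
      n_enrolled = if (level_name %in% names(enr))
        as.integer(enr[[level_name]]) else 0L
    )
  })
  do.call(rbind, res)
}

#' Attribute-combination table
#'
#' For each requested subset of attribute groups, retrains the model
#' restricted to the features in those groups, evaluates it on the holdout
#' year, optimizes thresholds with its predictions and simulates the
#' policy. Rows are sorted by simulated total cost, so the table shows
#' which attribute groups a site needs to collect for the model to remain
#' clinically useful.
#'
#' @param fm A `feature_matrix` with `groups` attribute.
#' @param spec Base [model_spec()].
#' @param levels Management levels for the simulation.
#' @param c_e Average cost per event.
#' @param subsets List of character vectors of group names, or `"all"` for
#'   every non-empty subset.
#' @param holdout_year Holdout index year.
#' @param n_bins,uptake,seed Simulation controls.
#' @return Data frame: `groups`, `n_features`, `metric`, `total_cost`,
#'   `total_admissions`, sorted by `total_cost`.
#' @export
attribute_combination_table <- function(fm, spec, levels, c_e,
                                        subsets = "all", holdout_year = NULL,
                                        n_bins = 100L, uptake = 1, seed = 1L) {
  groups <- attr(fm, "groups")
  if (is.null(groups)) stopf("feature matrix lacks the `groups` attribute")
  gnames <- sort(unique(groups))
  if (identical(subsets, "all")) {
    subsets <- unlist(lapply(seq_along(gnames), function(k) {
      combn(gnames, k, simplify = FALSE)
    }), recursive = FALSE)
  }
  if (is.null(holdout_year)) holdout_year <- max(fm$index_year)
  train_years <- setdiff(sort(unique(fm$index_year)), holdout_year)

  rows <- lapply(subsets, function(gs) {
    feats <- names(groups)[groups %in% gs]
    if (length(feats) == 0L) {
      warning(sprintf("subset {%s} selects no features; skipped",
                      paste(gs, collapse = ",")), call. = FALSE)
      return(NULL)
    }
    sp <- spec
    sp$features <- feats
    mod <- train_and_cv(fm, sp, train_years = train_years, seed = seed)
    rep_h <- evaluate_holdout(mod, fm, holdout_year)
    traj <- holdout_trajectories(fm, mod, holdout_year)
    n_b <- min(n_bins, nrow(traj))
    stats <- compute_percentile_stats(traj$pred, traj$n_e,
                                      ifelse(traj$n_e > 0, traj$n_e * c_e, 0),
                                      n_bins = n_b)
    attr(stats, "c_e") <- c_e
    pol <- optimize_thresholds(levels, stats, c_e = c_e)
    out <- simulate_policy(traj, pol, c_e = c_e, uptake = uptake,
                           mode = "expectation", seed = seed)
    data.frame(
      groups = paste(gs, collapse = "+"), n_features = length(feats),
      metric = rep_h$value, total_cost = out$total_cost,
      total_admissions = out$total_admissions,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out[order(out$total_cost), , drop = FALSE]
}

#' Minimum model accuracy at which the policy beats baseline
#'
#' Degrades a calibrated predictor (the true event probabilities) by
#' blending with uniform noise, `pred(w) = w * truth + (1 - w) * noise`,
#' and searches the blend weight at which the simulated policy's total cost
#' crosses the baseline total. Reports the AUC at the crossing — the least
#' accurate a model can be while the stratified policy still pays for
#' itself.
#'
#' @param traj Trajectories with a `true_p` column (calibrated risk) and
#'   the usual [holdout_trajectories()] columns.
#' @param levels Management levels.
#' @param c_e Average cost per event.
#' @param uptake Uptake fraction.
#' @param n_bins Percentile bins.
#' @param seed Seed for the single noise draw.
#' @param tol Bisection tolerance on the blend weight.
#' @return List: `achievable`, `min_auc` (NA when not achievable),
#'   `auc_perfect`, `cost_gain_perfect` (baseline minus policy cost at
#'   `w = 1`), `w_cross`.
#' @export
min_accuracy_requirement <- function(traj, levels, c_e, uptake = 1,
                                     n_bins = 100L, seed = 1L, tol = 1e-3) {
  n <- nrow(traj)
  noise <- with_seed(seed, runif(n))
  truth <- traj$true_p
  if (is.null(truth)) stopf("`traj` must carry a `true_p` column")
  label <- as.integer(traj$n_e > 0)
  n_bins <- min(n_bins, n)

  cost_diff <- function(w) {
    pred <- w * truth + (1 - w) * noise
    stats <- compute_percentile_stats(pred, traj$n_e,
                                      ifelse(traj$n_e > 0, traj$n_e * c_e, 0),
                                      n_bins = n_bins)
    attr(stats, "c_e") <- c_e
    pol <- optimize_thresholds(levels, stats, c_e = c_e)
    tr2 <- traj
    tr2$pred <- pred
    out <- simulate_policy(tr2, pol, c_e = c_e, uptake = uptake,
                           mode = "expectation")
    out$total_cost - out$baseline_cost
  }
  auc_at <- function(w) auc_binary(label, w * truth + (1 - w) * noise)

  d1 <- cost_diff(1)
  if (d1 >= 0) {
    return(list(achievable = FALSE, min_auc = NA_real_,
                auc_perfect = auc_at(1), cost_gain_perfect = -d1,
                w_cross = NA_real_))
  }
  d0 <- cost_diff(0)
  if (d0 < 0) {
    # even a pure-noise predictor pays off: the requirement is vacuous
    return(list(achievable = TRUE, min_auc = auc_at(0),
                auc_perfect = auc_at(1), cost_gain_perfect = -d1,
                w_cross = 0))
  }
  lo <- 0; hi <- 1
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (cost_diff(mid) >= 0) lo <- mid else hi <- mid
  }
  w_cross <- (lo + hi) / 2
  list(achievable = TRUE, min_auc = auc_at(w_cross),
       auc_perfect = auc_at(1), cost_gain_perfect = -d1, w_cross = w_cross)
}

#' Paired comparison of two policy outcomes
#'
#' One-sided paired t test on log-transformed per-patient costs
#' (`log(cost + 1)` to admit zero-cost patients; alternative: policy A's
#' costs exceed policy B's), and McNemar tests on the paired any-admission
#' and any-ED-visit indicators. Patients are paired by id.
#'
#' @param outcome_a,outcome_b `policy_outcome` objects over the same
#'   patients, or data frames with `patient_id`, `cost`, `admissions`, `ed`.
#' @param alpha Significance level for the reported decisions.
#' @param log_offset Offset inside the log transform (`log(cost +
#'   log_offset)`); the default 1 admits zero-cost patients, 0 gives the
#'   plain log for strictly positive costs.
#' @return A `policy_comparison`: `t` (statistic, p, mean log difference,
#'   n), `mcnemar_admissions`, `mcnemar_ed` (each statistic, p, discordant
#'   counts, informative flag), `alpha`, and per-test `reject` decisions.
#' @export
compare_policies <- function(outcome_a, outcome_b, alpha = 0.05,
                             log_offset = 1) {
  pa <- if (inherits(outcome_a, "policy_outcome")) outcome_a$per_patient else outcome_a
  pb <- if (inherits(outcome_b, "policy_outcome")) outcome_b$per_patient else outcome_b
  m <- merge(pa[, c("patient_id", "cost", "admissions", "ed")],
             pb[, c("patient_id", "cost", "admissions", "ed")],
             by = "patient_id", suffixes = c("_a", "_b"))
  if (nrow(m) != nrow(pa) || nrow(m) != nrow(pb)) {
    stopf("outcomes cover different patients; cannot pair")
  }
  la <- log(m$cost_a + log_offset)
  lb <- log(m$cost_b + log_offset)
  d <- la - lb
  if (sd(d) < 1e-10 * max(1, abs(mean(d)))) {
    # constant paired difference: the t statistic degenerates
    md <- mean(d)
    tt <- if (abs(md) < 1e-12) {
      list(statistic = 0, p.value = 1)
    } else {
      list(statistic = sign(md) * Inf, p.value = if (md > 0) 0 else 1)
    }
  } else {
    tt <- t.test(la, lb, paired = TRUE, alternative = "greater")
  }

  mcn <- function(xa, xb) {
    a01 <- sum(xa == 0 & xb > 0)
    a10 <- sum(xa > 0 & xb == 0)
    if (a01 + a10 == 0L) {
      return(list(statistic = NA_real_, p = NA_real_, discordant = 0L,
                  informative = FALSE, reject = FALSE))
    }
    tb <- table(factor(xa > 0, c(FALSE, TRUE)), factor(xb > 0, c(FALSE, TRUE)))
    mt <- mcnemar.test(tb)
    list(statistic = unname(mt$statistic), p = mt$p.value,
         discordant = a01 + a10, informative = TRUE,
         reject = mt$p.value < alpha)
  }

  structure(list(
    t = list(statistic = unname(tt$statistic), p = tt$p.value,
             mean_log_diff = mean(d), n = nrow(m),
             reject = tt$p.value < alpha),
    mcnemar_admissions = mcn(m$admissions_a, m$admissions_b),
    mcnemar_ed = mcn(m$ed_a, m$ed_b),
    alpha = alpha
  ), class = "policy_comparison")
}

#' @export
print.policy_comparison <- function(x, ...) {
  cat("<policy_comparison>\n")
  cat(sprintf("  paired one-sided t on log cost: t = %.3f, p = %.4g (n = %d)%s\n",
              x$t$statistic, x$t$p, x$t$n,
              if (x$t$reject) " *" else ""))
  for (nm in c("mcnemar_admissions", "mcnemar_ed")) {
    mc <- x[[nm]]
    if (mc$informative) {
      cat(sprintf("  %s: chi2 = %.3f, p = %.4g (%d discordant)%s\n",
                  nm, mc$statistic, mc$p, mc$discordant,
                  if (mc$reject) " *" else ""))
    } else {
      cat(sprintf("  %s: no discordant pairs (non-informative)\n", nm))
    }
  }
  invisible(x)
}
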