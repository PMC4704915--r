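# Optimal thresholds for risk strata: assign each risk percentile to the
# management level minimizing the expected change in future cost
# delta = c_i - avg_n_e * p * c_e, subject to program capacities.

#' Define a management level
#'
#' A management program in the risk-stratification hierarchy (for example
#' case management, disease management, supported self-care, wellness
#' promotion).
#'
#' @param name Program name.
#' @param c_i Average program cost per patient per period (currency).
#' @param p Fraction of undesirable events the program avoids, in `[0, 1]`.
#' @param capacity Maximum number of enrollable patients (`Inf` for
#'   unconstrained programs).
#' @return A `management_level` object.
#' @examples
#' management_level("case management", c_i = 5000, p = 0.4, capacity = 100)
#' @export
management_level <- function(name, c_i, p, capacity = Inf) {
  if (!is.character(name) || length(name) != 1L) stopf("`name` must be a string")
  if (!is.numeric(c_i) || length(c_i) != 1L || is.na(c_i) || c_i < 0) {
    stopf("`c_i` must be a non-negative cost")
  }
  check_prob(p, "p")
  if (!is.numeric(capacity) || length(capacity) != 1L || is.na(capacity) || capacity < 0) {
    stopf("`capacity` must be non-negative (possibly Inf)")
  }
  structure(list(name = name, c_i = c_i, p = p, capacity = capacity),
            class = "management_level")
}

#' @export
print.management_level <- function(x, ...) {
  cat(sprintf("<management_level> %s: c_i = %.2f, p = %.3f, capacity = %s\n",
              x$name, x$c_i, x$p,
              if (is.infinite(x$capacity)) "unlimited" else format(x$capacity)))
  invisible(x)
}

# The implicit "no program" comparator: zero cost, zero benefit, unlimited
# capacity, so delta = 0 and the optimizer is always feasible.
null_level <- function() management_level("none", c_i = 0, p = 0, capacity = Inf)

#' Expected per-patient cost change of enrolling a percentile in a program
#'
#' `delta = c_i - avg_n_e * p * c_e`: the program's per-patient cost minus
#' the benefit gained by avoiding a fraction `p` of the `avg_n_e` expected
#' undesirable events, each costing `c_e` on average. Negative delta means
#' enrollment is expected to save money.
#'
#' @param level A [management_level()].
#' @param avg_n_e Average number of undesirable events per patient in the
#'   risk percentile.
#' @param c_e Average cost of one undesirable event.
#' @return The expected cost change per enrolled patient (vectorized over
#'   `avg_n_e`).
#' @examples
#' cm <- management_level("case management", c_i = 5000, p = 0.4)
#' level_delta(cm, avg_n_e = 2, c_e = 10000)  # -3000
#' @export
level_delta <- function(level, avg_n_e, c_e) {
  stopifnot(inherits(level, "management_level"))
  if (any(avg_n_e < 0) || c_e < 0) stopf("`avg_n_e` and `c_e` must be non-negative")
  level$c_i - avg_n_e * level$p * c_e
}

#' Per-percentile event statistics from predictions and observations
#'
#' Ranks patients by predicted risk (highest first), splits them into
#' `n_bins` equal-count bins, and computes the average observed event count
#' per bin together with the cohort-wide average cost of one event
#' (`c_e` = total event cost / total events).
#'
#' @param predictions Numeric predicted risk (or predicted cost when
#'   stratifying by cost), one per patient.
#' @param events Observed undesirable-event counts, aligned with
#'   `predictions`.
#' @param event_costs Observed total event cost per patient, aligned.
#' @param n_bins Number of equal-count risk bins (default 100 percentiles).
#' @return A `percentile_stats` data frame with columns `bin`, `n_patients`,
#'   `avg_n_e`, and attribute `c_e`. Bin 1 is the highest-risk bin.
#' @export
compute_percentile_stats <- function(predictions, events, event_costs,
                                     n_bins = 100L) {
  n <- length(predictions)
  if (length(events) != n || length(event_costs) != n) {
    stopf("`predictions`, `events` and `event_costs` must be aligned by patient")
  }
  n_bins <- check_count(n_bins, "n_bins")
  if (n_bins > n) stopf("more bins (%d) than patients (%d)", n_bins, n)
  if (sum(events) == 0) stopf("no events observed: c_e is undefined")

  ord <- order(predictions, decreasing = TRUE)
  # Equal-count bins; remainders spread one patient at a time over the
  # highest-risk bins.
  base <- n %/% n_bins
  extra <- n %% n_bins
  sizes <- rep(base, n_bins) + c(rep(1L, extra), rep(0L, n_bins - extra))
  bin <- rep(seq_len(n_bins), times = sizes)
  ev <- events[ord]
  avg_n_e <- as.numeric(tapply(ev, bin, mean))
  out <- data.frame(bin = seq_len(n_bins), n_patients = sizes, avg_n_e = avg_n_e)
  attr(out, "c_e") <- sum(event_costs) / sum(events)
  class(out) <- c("percentile_stats", "data.frame")
  out
}

#' Optimal assignment of risk percentiles to management levels
#'
#' Walks the risk percentiles from highest to lowest risk; for each bin,
#' among the levels whose program still has capacity for the whole bin, picks
#' the one with the smallest expected per-patient cost change
#' ([level_delta()]). A zero-cost, zero-benefit "no program" level is always
#' available, so every bin gets an assignment. Ties are broken toward the
#' less intensive (cheaper, then lower-benefit) program to conserve scarce
#' capacity.
#'
#' @param levels List of [management_level()] objects (the "no program"
#'   level is appended automatically).
#' @param stats A `percentile_stats` object from
#'   [compute_percentile_stats()], or a data frame with columns `bin`,
#'   `n_patients`, `avg_n_e` plus a `c_e` attribute or argument.
#' @param c_e Average cost per event; defaults to `attr(stats, "c_e")`.
#' @param prune With the expectation that `avg_n_e` decreases down the risk
#'   ranking, stop the per-bin search early: once every program has shown a
#'   positive delta for a full bin while its capacity is untouched, assign
#'   all remaining bins to "no program" without further evaluation.
#' @return A `strat_policy` object: data frame `assignment` (bin, level,
#'   delta, n_patients), `thresholds` (bins where the level changes),
#'   `total_delta`, and `enrollment` per level.
#' @export
optimize_thresholds <- function(levels, stats, c_e = NULL, prune = FALSE) {
  levels <- normalize_levels(levels)
  if (is.null(c_e)) c_e <- attr(stats, "c_e")
  if (is.null(c_e)) stopf("`c_e` not supplied and absent from `stats`")
  stopifnot(all(c("bin", "n_patients", "avg_n_e") %in% names(stats)))

  lv_names <- vapply(levels, `[[`, "", "name")
  if (anyDuplicated(lv_names)) stopf("level names must be unique")
  remaining <- vapply(levels, `[[`, 0, "capacity")
  names(remaining) <- lv_names
  null_name <- lv_names[length(lv_names)]

  # Tie-break order: cheaper program first, then smaller p (less intensive).
  c_is <- vapply(levels, `[[`, 0, "c_i")
  ps <- vapply(levels, `[[`, 0, "p")
  tie_ord <- order(c_is, ps)

  n_bins <- nrow(stats)
  assigned <- character(n_bins)
  deltas <- numeric(n_bins)
  # Pruning state: a level is "retired" once it has had delta > 0 on a bin
  # while never having enrolled anyone.
  positive_seen <- setNames(rep(FALSE, length(levels)), lv_names)

  for (b in seq_len(n_bins)) {
    if (prune && all(positive_seen[lv_names != null_name])) {
      assigned[b:n_bins] <- null_name
      deltas[b:n_bins] <- 0
      break
    }
    avg_n_e <- stats$avg_n_e[b]
    n_b <- stats$n_patients[b]
    best <- NULL
    best_delta <- Inf
    for (i in tie_ord) {
      lv <- levels[[i]]
      if (remaining[[lv$name]] < n_b) next
      d <- level_delta(lv, avg_n_e, c_e)
      if (d > 0 && remaining[[lv$name]] == lv$capacity) {
        positive_seen[[lv$name]] <- TRUE
      }
      if (d < best_delta) {  # strict: earlier (less intensive) wins ties
        best_delta <- d
        best <- lv
      }
    }
    assigned[b] <- best$name
    deltas[b] <- best_delta
    remaining[[best$name]] <- remaining[[best$name]] - n_b
  }

  assignment <- data.frame(
    bin = stats$bin, level = assigned, delta = deltas,
    n_patients = stats$n_patients, stringsAsFactors = FALSE
  )
  thresholds <- which(assigned[-1L] != assigned[-n_bins])
  enrollment <- tapply(assignment$n_patients, assignment$level, sum)
  structure(list(
    assignment = assignment,
    thresholds = thresholds,
    total_delta = sum(deltas * stats$n_patients),
    enrollment = enrollment,
    c_e = c_e,
    levels = levels
  ), class = "strat_policy")
}

normalize_levels <- function(levels) {
  if (inherits(levels, "management_level")) levels <- list(levels)
  stopifnot(is.list(levels), all(vapply(levels, inherits, TRUE, "management_level")))
  if (!any(vapply(levels, function(l) l$c_i == 0 && l$p == 0 && is.infinite(l$capacity), TRUE))) {
    levels <- c(levels, list(null_level()))
  }
  levels
}

#' @export
print.strat_policy <- function(x, ...) {
  cat("<strat_policy>\n")
  cat(sprintf("  bins: %d, total expected cost change: %.2f\n",
              nrow(x$assignment), x$total_delta))
  if (length(x$thresholds)) {
    cat("  level changes after bins:", paste(x$thresholds, collapse = ", "), "\n")
  }
  enr <- x$enrollment
  for (nm in names(enr)) cat(sprintf("  %s: %d patients\n", nm, as.integer(enr[[nm]])))
  invisible(x)
}

#' Exhaustive-search oracle for small stratification instances
#'
#' Enumerates every capacity-feasible assignment of bins to levels and
#' returns the minimum-total-delta assignment. Intended as a test oracle for
#' the greedy optimizer; refuses instances larger than `max_bins` bins or
#' `max_levels` levels.
#'
#' @inheritParams optimize_thresholds
#' @param max_bins,max_levels Size guard for the enumeration.
#' @return List with `assignment` (level name per bin) and `total_delta`.
#' @export
exact_assignment_oracle <- function(levels, stats, c_e = NULL,
                                    max_bins = 6L, max_levels = 4L) {
  levels <- normalize_levels(levels)
  if (is.null(c_e)) c_e <- attr(stats, "c_e")
  n_bins <- nrow(stats)
  n_lev <- length(levels)
  if (n_bins > max_bins || n_lev > max_levels + 1L) {
    stopf("instance too large for exhaustive enumeration (%d bins, %d levels)",
          n_bins, n_lev)
  }
  lv_names <- vapply(levels, `[[`, "", "name")
  caps <- vapply(levels, `[[`, 0, "capacity")

  # Per-bin delta matrix.
  dmat <- vapply(levels, function(lv) level_delta(lv, stats$avg_n_e, c_e),
                 numeric(n_bins))
  dmat <- matrix(dmat, nrow = n_bins)

  grid <- as.matrix(expand.grid(rep(list(seq_len(n_lev)), n_bins)))
  cost <- numeric(nrow(grid))
  feasible <- rep(TRUE, nrow(grid))
  for (b in seq_len(n_bins)) {
    cost <- cost + dmat[b, grid[, b]] * stats$n_patients[b]
  }
  for (l in which(is.finite(caps))) {
    used <- numeric(nrow(grid))
    for (b in seq_len(n_bins)) {
      used <- used + stats$n_patients[b] * (grid[, b] == l)
    }
    feasible <- feasible & used <= caps[l]
  }
  cost[!feasible] <- Inf
  best <- grid[which.min(cost), ]
  list(assignment = lv_names[best], total_delta = min(cost))
}

#' Sensitivity of thresholds to program cost and benefit estimates
#'
#' Re-optimizes the stratification over an `n_grid` x `n_grid` grid of
#' (`c_i`, `p`) values for one target program, holding the other programs
#' fixed, and reports the thresholds and expected totals for every cell.
#'
#' @inheritParams optimize_thresholds
#' @param level_name Name of the program whose `c_i` and `p` are varied;
#'   defaults to the first level.
#' @param c_i_range,p_range Length-2 numeric `c(min, max)` ranges.
#' @param n_grid Number of grid points per axis (default 5 levels from
#'   minimum to maximum).
#' @return Data frame with one row per grid cell: `c_i`, `p`,
#'   `total_delta`, `n_enrolled` (in the varied program) and `thresholds`
#'   (comma-separated bin boundaries).
#' @export
sensitivity_thresholds <- function(levels, stats, c_i_range, p_range,
                                   n_grid = 5L, level_name = NULL, c_e = NULL) {
  levels <- normalize_levels(levels)
  n_grid <- check_count(n_grid, "n_grid")
  if (length(c_i_range) != 2L || length(p_range) != 2L) {
    stopf("ranges must be length-2 c(min, max) vectors")
  }
  if (c_i_range[1] > c_i_range[2] || p_range[1] > p_range[2]) {
    stopf("range minimum exceeds maximum")
  }
  lv_names <- vapply(levels, `[[`, "", "name")
  if (is.null(level_name)) level_name <- lv_names[1L]
  idx <- match(level_name, lv_names)
  if (is.na(idx)) stopf("unknown level `%s`", level_name)

  c_i_grid <- seq(c_i_range[1], c_i_range[2], length.out = n_grid)
  p_grid <- seq(p_range[1], p_range[2], length.out = n_grid)
  cells <- expand.grid(c_i = c_i_grid, p = p_grid)
  res <- lapply(seq_len(nrow(cells)), function(k) {
    lv2 <- levels
    lv2[[idx]]$c_i <- cells$c_i[k]
    lv2[[idx]]$p <- cells$p[k]
    pol <- optimize_thresholds(lv2, stats, c_e = c_e)
    enr <- pol$enrollment
    data.frame(
      c_i = cells$c_i[k], p = cells$p[k],
      total_delta = pol$total_delta,
      n_enrolled = if (level_name %in% names(enr)) as.integer(enr[[level_name]]) else 0L,
      thresholds = paste(pol$thresholds, collapse = ","),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, res)
}

#' Heuristic pyramid policy
#'
#' The conventional literature thresholds: the top share of patients by
#' predicted risk to the most intensive program and so on down the pyramid.
#' Expressed as cumulative population fractions per level, mapped onto the
#' percentile bins of `stats`.
#'
#' @param levels List of [management_level()]s ordered most- to
#'   least-intensive (excluding "no program").
#' @param stats `percentile_stats` object.
#' @param shares Population fraction per level, in the same order; patients
#'   below the summed shares get no program. Default: 1% case management,
#'   4% disease management, 15% supported self-care.
#' @inheritParams optimize_thresholds
#' @return A `strat_policy` object with the fixed assignment.
#' @export
heuristic_policy <- function(levels, stats, shares = c(0.01, 0.04, 0.15),
                             c_e = NULL) {
  levels <- normalize_levels(levels)
  if (is.null(c_e)) c_e <- attr(stats, "c_e")
  lv_names <- vapply(levels, `[[`, "", "name")
  null_name <- lv_names[length(lv_names)]
  k <- length(shares)
  if (k > length(levels) - 1L) stopf("more shares than programs")

  n_bins <- nrow(stats)
  cum <- cumsum(shares)
  frac <- (seq_len(n_bins) - 0.5) / n_bins  # bin midpoints as population fraction
  assigned <- rep(null_name, n_bins)
  for (i in rev(seq_len(k))) assigned[frac <= cum[i]] <- lv_names[i]

  deltas <- numeric(n_bins)
  for (b in seq_len(n_bins)) {
    lv <- levels[[match(assigned[b], lv_names)]]
    deltas[b] <- level_delta(lv, stats$avg_n_e[b], c_e)
  }
  assignment <- data.frame(bin = stats$bin, level = assigned, delta = deltas,
                           n_patients = stats$n_patients, stringsAsFactors = FALSE)
  thresholds <- which(assigned[-1L] != assigned[-n_bins])
  structure(list(
    assignment = assignment, thresholds = thresholds,
    total_delta = sum(deltas * stats$n_patients),
    enrollment = tapply(assignment$n_patients, assignment$level, sum),
    c_e = c_e, levels = levels
  ), class = "strat_policy")
}
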