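# Seeded synthetic EHR-like cohort with known ground truth.
#
# The generator emulates the statistical structure the downstream stages
# assume: a linked patient / physician / encounter / dispensing /
# environmental schema, rare acute-care events driven by a planted risk
# model (base rate + planted feature patterns + per-physician effects on
# the log-odds scale), and a pyramid-shaped cost distribution (heavy-tailed
# lognormal body plus per-event costs).

ICD_ASTHMA <- c("493.00", "493.02", "493.90", "493.92")
ICD_OTHER <- c("460", "786.2", "401.9", "V20.2", "780.6")
MED_CONTROLLER <- c("inhaled steroid", "leukotriene modifier",
                    "other inhaled anti-inflammatory")
MED_RELIEVER <- "beta-agonist"
MED_CLASSES <- c(MED_CONTROLLER, MED_RELIEVER, "oral steroid", "other")
ACUTE_TYPES <- c("inpatient", "urgent care", "emergency")

#' Declare a planted risk pattern
#'
#' A planted pattern is a conjunction of conditions on the generator's
#' per-patient-year state that either sets the absolute event probability
#' (`prob`) or multiplies the event odds (`odds_mult`) for patient-years
#' satisfying it. Patterns are applied in list order; a later pattern
#' overrides an earlier absolute probability.
#'
#' Conditions are a named list over the state vocabulary: `age`,
#' `gender`, `race`, `insurance`, `prior_inpatient` (inpatient encounters in
#' the previous year), `prior_events` (acute events in the previous year),
#' `controller_ratio_prior`, `phys_asthma_panel` (the primary physician's
#' number of asthma patients). A condition is a character vector of allowed
#' values (categorical) or `list(min =, max =)` for the half-open numeric
#' interval `[min, max)`.
#'
#' @param conditions Named list of conditions (see Details).
#' @param prob Absolute event probability for satisfying patient-years.
#' @param odds_mult Multiplier on the event odds (alternative to `prob`).
#' @param name Label used in the truth table.
#' @return A `planted_pattern`.
#' @examples
#' planted_pattern(list(prior_inpatient = list(min = 1, max = Inf)),
#'                 prob = 0.8, name = "prior inpatient stay")
#' @export
planted_pattern <- function(conditions, prob = NULL, odds_mult = NULL,
                            name = "pattern") {
  if (is.null(prob) == is.null(odds_mult)) {
    stopf("supply exactly one of `prob` or `odds_mult`")
  }
  if (!is.null(prob)) check_prob(prob, "prob")
  if (!is.null(odds_mult) && odds_mult <= 0) stopf("`odds_mult` must be positive")
  stopifnot(is.list(conditions), length(conditions) >= 1L,
            !is.null(names(conditions)))
  structure(list(conditions = conditions, prob = prob,
                 odds_mult = odds_mult, name = name),
            class = "planted_pattern")
}

pattern_satisfied <- function(pattern, state) {
  sat <- rep(TRUE, nrow(state))
  for (f in names(pattern$conditions)) {
    x <- state[[f]]
    if (is.null(x)) stopf("pattern condition on unknown state feature `%s`", f)
    cond <- pattern$conditions[[f]]
    if (is.list(cond)) {
      s <- !is.na(x) & x >= cond$min & x < cond$max
    } else {
      s <- !is.na(x) & as.character(x) %in% as.character(cond)
    }
    sat <- sat & s
  }
  sat
}

#' Default environmental variable profile
#'
#' Monthly mean, seasonal amplitude, noise SD and peak month for the 21
#' environmental series the generator produces (air quality, weather,
#' pollen/mold and respiratory-virus activity).
#'
#' @return Data frame with columns `variable`, `mean`, `amplitude`,
#'   `noise_sd`, `peak_month`.
#' @export
default_env_profile <- function() {
  data.frame(
    variable = c("pm25", "pm10", "ozone", "no2", "so2", "co",
                 "temperature_mean", "temperature_max", "temperature_min",
                 "humidity", "wind_speed", "precipitation", "pressure",
                 "pollen_tree", "pollen_grass", "pollen_weed", "mold_spores",
                 "influenza_activity", "rsv_activity", "rhinovirus_activity",
                 "smoke_days"),
    mean = c(9, 20, 40, 18, 3, 0.5,
             11, 17, 5,
             55, 10, 40, 1015,
             50, 30, 25, 800,
             10, 6, 15,
             1),
    amplitude = c(4, 8, 15, 5, 1, 0.2,
                  12, 13, 11,
                  15, 3, 20, 5,
                  50, 30, 25, 600,
                  10, 6, 8,
                  1.5),
    noise_sd = c(2, 4, 5, 2, 0.5, 0.1,
                 2, 2, 2,
                 5, 2, 10, 2,
                 15, 10, 8, 150,
                 3, 2, 4,
                 0.8),
    peak_month = c(12, 7, 7, 1, 1, 1,
                   7, 7, 7,
                   12, 4, 4, 1,
                   5, 6, 9, 8,
                   1, 12, 10,
                   8),
    stringsAsFactors = FALSE
  )
}

#' Generative parameters for the synthetic cohort
#'
#' Validates and fills defaults for the parameters of
#' [generate_cohort()]. The defaults describe the study conditions the
#' toolkit is exercised under: an 11-year horizon, a rare acute-care event
#' (5% per patient-year base rate), one planted pattern (a prior-year
#' inpatient stay raises next-year event probability to 0.8), moderate
#' physician effects on the event log-odds, and a heavy-tailed lognormal
#' cost body yielding a pyramid-shaped cost distribution.
#'
#' @param n_patients,n_physicians,n_years,n_stations Counts.
#' @param asthma_prevalence Fraction of generated patients who truly have
#'   asthma.
#' @param base_event_rate Probability per patient-year of an acute-care
#'   event for asthma patients absent patterns and physician effects.
#' @param planted_patterns List of [planted_pattern()]s.
#' @param physician_effect_sd SD of the per-physician additive effect on
#'   the event log-odds.
#' @param cost_body Named vector `c(meanlog =, sdlog =)` of the lognormal
#'   non-event cost body.
#' @param event_unit_cost_mean Mean cost of one acute event.
#' @param env_profile Environmental profile data frame
#'   ([default_env_profile()]).
#' @param station_offsets Optional matrix (`n_stations` x variables) of
#'   per-station additive offsets; drawn from
#'   `N(0, station_offset_sd)` when `NULL`.
#' @param station_offset_sd SD of random station offsets.
#' @param missing_rate Fraction of patient attribute cells blanked
#'   completely at random.
#' @param seed Integer RNG seed; identical parameters and seed give a
#'   byte-identical bundle.
#' @return A validated `cohort_params` list.
#' @export
cohort_params <- function(n_patients = 2000L, n_physicians = 40L,
                          n_years = 11L, n_stations = 4L,
                          asthma_prevalence = 0.7,
                          base_event_rate = 0.05,
                          planted_patterns = list(
                            planted_pattern(
                              list(prior_inpatient = list(min = 1, max = Inf)),
                              prob = 0.8, name = "prior inpatient stay")
                          ),
                          physician_effect_sd = 0.8,
                          cost_body = c(meanlog = 7.0, sdlog = 1.5),
                          event_unit_cost_mean = 6000,
                          env_profile = default_env_profile(),
                          station_offsets = NULL,
                          station_offset_sd = 0.2,
                          missing_rate = 0.02,
                          seed = 1L) {
  p <- list(
    n_patients = check_count(n_patients, "n_patients"),
    n_physicians = check_count(n_physicians, "n_physicians"),
    n_years = check_count(n_years, "n_years"),
    n_stations = check_count(n_stations, "n_stations"),
    asthma_prevalence = check_prob(asthma_prevalence, "asthma_prevalence"),
    base_event_rate = check_prob(base_event_rate, "base_event_rate"),
    planted_patterns = planted_patterns,
    physician_effect_sd = physician_effect_sd,
    cost_body = cost_body,
    event_unit_cost_mean = event_unit_cost_mean,
    env_profile = env_profile,
    station_offsets = station_offsets,
    station_offset_sd = station_offset_sd,
    missing_rate = check_prob(missing_rate, "missing_rate"),
    seed = as.integer(seed)
  )
  if (!is.list(planted_patterns) ||
      !all(vapply(planted_patterns, inherits, TRUE, "planted_pattern"))) {
    stopf("`planted_patterns` must be a list of planted_pattern objects")
  }
  if (physician_effect_sd < 0) stopf("`physician_effect_sd` must be non-negative")
  if (!all(c("meanlog", "sdlog") %in% names(cost_body)) || cost_body["sdlog"] < 0) {
    stopf("`cost_body` must be c(meanlog =, sdlog =) with sdlog >= 0")
  }
  if (event_unit_cost_mean < 0) stopf("`event_unit_cost_mean` must be non-negative")
  need <- c("variable", "mean", "amplitude", "noise_sd", "peak_month")
  if (!all(need %in% names(env_profile))) {
    stopf("`env_profile` must have columns: %s", paste(need, collapse = ", "))
  }
  class(p) <- "cohort_params"
  p
}

#' Generate the environmental monitoring table
#'
#' Monthly values per station and variable over the simulated years:
#' `value = mean + station offset + amplitude * cos(2 pi (month - peak)/12)
#' + noise`. Stations differ through their configured (or randomly drawn)
#' offsets, emulating monitoring stations whose readings differ across a
#' region.
#'
#' @param params A [cohort_params()] object.
#' @param variables Which variables to generate (default: all in the
#'   profile). Unknown names are an error.
#' @return Data frame `station_id`, `year`, `month`, `variable`, `value`.
#' @export
generate_env_series <- function(params, variables = NULL) {
  stopifnot(inherits(params, "cohort_params"))
  prof <- params$env_profile
  if (is.null(variables)) variables <- prof$variable
  unknown <- setdiff(variables, prof$variable)
  if (length(unknown)) {
    stopf("unknown environmental variable(s): %s", paste(unknown, collapse = ", "))
  }
  prof <- prof[match(variables, prof$variable), , drop = FALSE]
  n_st <- params$n_stations
  n_var <- nrow(prof)

  with_seed(params$seed + 1000L, {
    offs <- params$station_offsets
    if (is.null(offs)) {
      offs <- matrix(rnorm(n_st * n_var, 0, params$station_offset_sd),
                     nrow = n_st, ncol = n_var)
      colnames(offs) <- prof$variable
    } else {
      offs <- offs[, variables, drop = FALSE]
    }
    years <- cohort_years(params)
    grid <- expand.grid(month = 1:12, year = years,
                        station_id = seq_len(n_st), vi = seq_len(n_var))
    seasonal <- prof$mean[grid$vi] +
      prof$amplitude[grid$vi] *
        cos(2 * pi * (grid$month - prof$peak_month[grid$vi]) / 12)
    value <- seasonal + offs[cbind(grid$station_id, grid$vi)] +
      rnorm(nrow(grid), 0, prof$noise_sd[grid$vi])
    data.frame(
      station_id = paste0("S", grid$station_id),
      year = grid$year, month = grid$month,
      variable = prof$variable[grid$vi],
      value = value, stringsAsFactors = FALSE
    )
  })
}

cohort_years <- function(params) 2005L + seq_len(params$n_years) - 1L

#' Generate a synthetic cohort bundle
#'
#' Simulates the full linked schema year by year. Each asthma patient-year
#' draws an acute-care event from the planted risk model: the event
#' log-odds are the base rate plus the primary physician's effect, then any
#' satisfied planted pattern either multiplies the odds or overrides the
#' probability outright. Events produce acute encounters (inpatient /
#' emergency / urgent care, primary asthma diagnosis) with per-event costs;
#' all patients accrue routine outpatient encounters carrying a heavy-tailed
#' lognormal cost body. Dispensing records give asthma patients controller
#' and reliever medications (oral steroids correlated with events). The
#' truth table records each patient-year's true event probability, event
#' count and total cost.
#'
#' @param params A [cohort_params()] object.
#' @return A `cohort_bundle`: list of data frames `patients`, `physicians`,
#'   `encounters`, `dispensings`, `env`, `truth`, plus `params` and
#'   `station_xy`.
#' @export
generate_cohort <- function(params) {
  stopifnot(inherits(params, "cohort_params"))
  years <- cohort_years(params)
  env <- generate_env_series(params)

  with_seed(params$seed, {
    n_ph <- params$n_physicians
    n_pt <- params$n_patients

    physicians <- data.frame(
      physician_id = paste0("MD", seq_len(n_ph)),
      age = sample(32:66, n_ph, replace = TRUE),
      gender = sample(c("F", "M"), n_ph, replace = TRUE),
      languages = vapply(seq_len(n_ph), function(i) {
        l <- "english"
        if (runif(1) < 0.3) l <- c(l, sample(c("spanish", "other"), 1L))
        paste(l, collapse = ";")
      }, ""),
      insurances = vapply(seq_len(n_ph), function(i) {
        paste(sample(c("commercial", "medicaid", "medicare", "selfpay"),
                     sample(2:4, 1L)), collapse = ";")
      }, ""),
      office_x = runif(n_ph), office_y = runif(n_ph),
      office_hours = sample(20:60, n_ph, replace = TRUE),
      specialty = sample(c("family medicine", "pediatrics",
                           "internal medicine", "pulmonology"),
                         n_ph, replace = TRUE, prob = c(0.4, 0.3, 0.2, 0.1)),
      stringsAsFactors = FALSE
    )
    physicians$years_practice <- pmax(1L, physicians$age - 30L +
                                        sample(-3:3, n_ph, replace = TRUE))
    phys_effect <- rnorm(n_ph, 0, params$physician_effect_sd)

    age0 <- sample(0:75, n_pt, replace = TRUE,
                   prob = c(rep(2, 18), rep(1, 58)))  # pediatric-weighted mix
    patients <- data.frame(
      patient_id = paste0("PT", seq_len(n_pt)),
      birth_year = years[1L] - age0,
      gender = sample(c("F", "M"), n_pt, replace = TRUE),
      race = sample(c("white", "black", "asian", "hispanic", "other"),
                    n_pt, replace = TRUE, prob = c(0.6, 0.1, 0.05, 0.2, 0.05)),
      language = sample(c("english", "spanish", "other"),
                        n_pt, replace = TRUE, prob = c(0.8, 0.15, 0.05)),
      insurance = sample(c("commercial", "medicaid", "medicare", "selfpay"),
                         n_pt, replace = TRUE, prob = c(0.55, 0.25, 0.12, 0.08)),
      home_x = runif(n_pt), home_y = runif(n_pt),
      physician_id = physicians$physician_id[
        sample.int(n_ph, n_pt, replace = TRUE)],
      stringsAsFactors = FALSE
    )
    asthma <- runif(n_pt) < params$asthma_prevalence
    phys_idx <- match(patients$physician_id, physicians$physician_id)
    phys_asthma_panel <- as.integer(tapply(asthma, phys_idx, sum)[
      as.character(phys_idx)])
    phys_asthma_panel[is.na(phys_asthma_panel)] <- 0L

    enc_list <- list()
    disp_list <- list()
    truth_list <- list()
    prior_inpatient <- integer(n_pt)
    prior_events <- integer(n_pt)
    controller_ratio_prior <- rep(NA_real_, n_pt)

    base_logit <- qlogis(params$base_event_rate)
    meanlog_ev <- log(params$event_unit_cost_mean) - 0.5 * 0.6^2

    for (t in seq_along(years)) {
      yr <- years[t]
      state <- data.frame(
        age = yr - patients$birth_year,
        gender = patients$gender, race = patients$race,
        insurance = patients$insurance,
        prior_inpatient = prior_inpatient,
        prior_events = prior_events,
        controller_ratio_prior = controller_ratio_prior,
        phys_asthma_panel = phys_asthma_panel,
        stringsAsFactors = FALSE
      )

      logit_p <- base_logit + phys_effect[phys_idx]
      p <- plogis(logit_p)
      for (pat in params$planted_patterns) {
        sat <- pattern_satisfied(pat, state)
        if (!is.null(pat$prob)) {
          p[sat] <- pat$prob
        } else {
          p[sat] <- plogis(qlogis(p[sat]) + log(pat$odds_mult))
        }
      }
      p[!asthma] <- 0  # acute asthma events only for true asthma patients
      event_any <- rbinom(n_pt, 1L, p)
      n_events <- event_any * (1L + rpois(n_pt, 0.4))

      # acute encounters (one row per event)
      ev_pat <- rep(seq_len(n_pt), n_events)
      n_ev_rows <- length(ev_pat)
      acute_df <- NULL
      if (n_ev_rows > 0L) {
        ev_cost <- rlnorm(n_ev_rows, meanlog_ev, 0.6)
        acute_df <- data.frame(
          patient_id = patients$patient_id[ev_pat],
          year = yr, month = sample(1:12, n_ev_rows, replace = TRUE),
          visit_type = sample(ACUTE_TYPES, n_ev_rows, replace = TRUE,
                              prob = c(0.25, 0.25, 0.5)),
          primary_dx = sample(c("493.92", "493.02"), n_ev_rows,
                              replace = TRUE, prob = c(0.7, 0.3)),
          cost = ev_cost, stringsAsFactors = FALSE
        )
        enc_list[[length(enc_list) + 1L]] <- acute_df
      } else {
        ev_cost <- numeric(0)
      }

      # routine outpatient encounters carrying the lognormal cost body
      n_routine <- 1L + rpois(n_pt, 1.5)
      body_total <- rlnorm(n_pt, params$cost_body["meanlog"],
                           params$cost_body["sdlog"])
      rt_pat <- rep(seq_len(n_pt), n_routine)
      w <- runif(length(rt_pat))
      w <- w / ave(w, rt_pat, FUN = sum)
      rt_dx <- ifelse(
        asthma[rt_pat] & runif(length(rt_pat)) < 0.4,
        sample(c("493.00", "493.90"), length(rt_pat), replace = TRUE),
        sample(ICD_OTHER, length(rt_pat), replace = TRUE)
      )
      enc_list[[length(enc_list) + 1L]] <- data.frame(
        patient_id = patients$patient_id[rt_pat],
        year = yr, month = sample(1:12, length(rt_pat), replace = TRUE),
        visit_type = "outpatient", primary_dx = rt_dx,
        cost = body_total[rt_pat] * w, stringsAsFactors = FALSE
      )

      # dispensings
      n_ctrl <- ifelse(asthma, rpois(n_pt, 2), 0L)
      n_rel <- ifelse(asthma, rpois(n_pt, 2), 0L)
      n_ltm <- ifelse(asthma, rpois(n_pt, 0.3), 0L)
      n_os <- ifelse(asthma, rpois(n_pt, 0.15 + 0.6 * n_events), 0L)
      n_oth <- rpois(n_pt, 0.3)
      counts <- cbind(n_ctrl, n_ltm, n_rel, n_os, n_oth)
      classes <- c("inhaled steroid", "leukotriene modifier", "beta-agonist",
                   "oral steroid", "other")
      dsp_pat <- rep(rep(seq_len(n_pt), ncol(counts)), as.vector(counts))
      dsp_cls <- rep(rep(classes, each = n_pt), as.vector(counts))
      if (length(dsp_pat)) {
        disp_list[[length(disp_list) + 1L]] <- data.frame(
          patient_id = patients$patient_id[dsp_pat],
          year = yr, month = sample(1:12, length(dsp_pat), replace = TRUE),
          med_class = dsp_cls,
          amount = 30 * sample(1:2, length(dsp_pat), replace = TRUE,
                               prob = c(0.7, 0.3)),
          stringsAsFactors = FALSE
        )
      }

      ev_cost_by_pat <- numeric(n_pt)
      if (n_ev_rows > 0L) {
        agg <- tapply(ev_cost, ev_pat, sum)
        ev_cost_by_pat[as.integer(names(agg))] <- as.numeric(agg)
      }
      truth_list[[length(truth_list) + 1L]] <- data.frame(
        patient_id = patients$patient_id, year = yr,
        asthma = asthma, true_p = p, n_events = n_events,
        total_cost = body_total + ev_cost_by_pat,
        stringsAsFactors = FALSE
      )

      # roll state forward
      prior_inpatient <- integer(n_pt)
      if (!is.null(acute_df)) {
        inpt <- tapply(acute_df$visit_type == "inpatient",
                       acute_df$patient_id, sum)
        m <- match(names(inpt), patients$patient_id)
        prior_inpatient[m] <- as.integer(inpt)
      }
      prior_events <- n_events
      tot_asthma_med <- n_ctrl + n_ltm + n_rel
      controller_ratio_prior <- ifelse(tot_asthma_med > 0,
                                       (n_ctrl + n_ltm) / tot_asthma_med, NA)
    }

    # missingness, completely at random, on soft patient attributes
    if (params$missing_rate > 0) {
      for (col in c("race", "language", "insurance")) {
        blank <- runif(n_pt) < params$missing_rate
        patients[[col]][blank] <- NA
      }
    }

    structure(list(
      patients = patients,
      physicians = physicians,
      encounters = do.call(rbind, enc_list),
      dispensings = if (length(disp_list)) do.call(rbind, disp_list) else
        data.frame(patient_id = character(0), year = integer(0),
                   month = integer(0), med_class = character(0),
                   amount = numeric(0)),
      env = env,
      truth = do.call(rbind, truth_list),
      station_xy = with_seed(params$seed + 2000L, data.frame(
        station_id = paste0("S", seq_len(params$n_stations)),
        x = runif(params$n_stations), y = runif(params$n_stations),
        stringsAsFactors = FALSE
      )),
      phys_effect = data.frame(physician_id = physicians$physician_id,
                               effect = phys_effect,
                               stringsAsFactors = FALSE),
      params = params,
      years = years
    ), class = "cohort_bundle")
  })
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat("<cohort_bundle>\n")
  cat(sprintf("  %d patients, %d physicians, years %d-%d\n",
              nrow(x$patients), nrow(x$physicians),
              min(x$years), max(x$years)))
  cat(sprintf("  %d encounters, %d dispensings, %d env rows\n",
              nrow(x$encounters), nrow(x$dispensings), nrow(x$env)))
  cat(sprintf("  events: %d across %d patient-years (rate %.3f)\n",
              sum(x$truth$n_events), nrow(x$truth),
              mean(x$truth$n_events > 0)))
  invisible(x)
}

#' Write a cohort bundle as delimited text files
#'
#' One CSV per table (header row, UTF-8); the truth table is written
#' separately (`truth.csv`) so pipelines can run blind to the ground truth.
#'
#' @param bundle A `cohort_bundle`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(bundle, dir) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (tb in c("patients", "physicians", "encounters", "dispensings",
               "env", "station_xy", "truth")) {
    utils::write.csv(bundle[[tb]], file.path(dir, paste0(tb, ".csv")),
                     row.names = FALSE, fileEncoding = "UTF-8")
  }
  invisible(dir)
}

#' Read a cohort bundle written by [write_cohort()]
#'
#' @param dir Directory containing the CSVs.
#' @param truth Read the truth table too (default TRUE; set FALSE to run
#'   blind).
#' @return A `cohort_bundle` (without generative parameters).
#' @export
read_cohort <- function(dir, truth = TRUE) {
  rd <- function(f) utils::read.csv(file.path(dir, paste0(f, ".csv")),
                                    stringsAsFactors = FALSE)
  tabs <- c("patients", "physicians", "encounters", "dispensings",
            "env", "station_xy")
  out <- lapply(tabs, rd)
  names(out) <- tabs
  if (truth && file.exists(file.path(dir, "truth.csv"))) out$truth <- rd("truth")
  out$years <- sort(unique(out$encounters$year))
  structure(out, class = "cohort_bundle")
}
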