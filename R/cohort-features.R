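# Cohort identification, outcome labelling and the three feature families
# (patient, physician practice profile, environmental).
#
# Rows are patient-years: features use data up to and including the index
# year, outcomes come from the following year.

# (year, month) pairs are compared on an approximate day scale.
date_num <- function(year, month) year * 360 + (month - 1) * 30 + 15

is_asthma_dx <- function(dx) startsWith(as.character(dx), "493")

QUALIFYING_MEDS <- c("inhaled steroid", "beta-agonist", "leukotriene modifier",
                     "other inhaled anti-inflammatory")

#' Identify the asthma cohort
#'
#' A patient belongs to the cohort iff they have (a) at least one encounter
#' with a diagnosis code in the 493.xx family, or (b) at least two
#' asthma-related medication dispensings — inhaled steroids, beta-agonists,
#' leukotriene modifiers or other inhaled anti-inflammatories, oral steroids
#' excluded — within any 365-day span.
#'
#' @param encounters Encounter table (`patient_id`, `year`, `month`,
#'   `primary_dx`, ...).
#' @param dispensings Dispensing table (`patient_id`, `year`, `month`,
#'   `med_class`, ...).
#' @return Character vector of patient ids.
#' @export
identify_asthma <- function(encounters, dispensings) {
  by_dx <- unique(encounters$patient_id[is_asthma_dx(encounters$primary_dx)])

  q <- dispensings[dispensings$med_class %in% QUALIFYING_MEDS, , drop = FALSE]
  by_med <- character(0)
  if (nrow(q) > 0L) {
    q$d <- date_num(q$year, q$month)
    spl <- split(q$d, q$patient_id)
    ok <- vapply(spl, function(d) {
      if (length(d) < 2L) return(FALSE)
      d <- sort(d)
      any(diff(d) <= 365)
    }, TRUE)
    by_med <- names(spl)[ok]
  }
  sort(unique(c(by_dx, by_med)))
}

#' Label next-year outcomes for a cohort
#'
#' For each cohort patient and index year, the primary outcome is whether
#' any acute-care encounter (inpatient stay, urgent care, or emergency
#' department visit) with a primary asthma diagnosis occurred in the
#' following year; the secondary outcome is the summed reliever and
#' oral-steroid refill amount in that year; the cost outcome is the total
#' encounter cost in that year. Patients with no records in the outcome
#' year are labelled 0 / 0 / 0 — absence of care is an observable absence
#' of events.
#'
#' @param bundle A `cohort_bundle`.
#' @param cohort Character vector of cohort patient ids.
#' @param index_year Index year; `index_year + 1` must exist in the bundle.
#' @return Data frame keyed by `patient_id` with columns `high_risk`,
#'   `reliever_next`, `cost_next`, `n_events_next`, `admissions_next`,
#'   `ed_next`.
#' @export
label_outcomes <- function(bundle, cohort, index_year) {
  out_year <- index_year + 1L
  if (!out_year %in% bundle$years) {
    stopf("outcome year %d not present in the bundle", out_year)
  }
  enc <- bundle$encounters[bundle$encounters$year == out_year, , drop = FALSE]
  dsp <- bundle$dispensings[bundle$dispensings$year == out_year, , drop = FALSE]

  acute <- enc[enc$visit_type %in% ACUTE_TYPES & is_asthma_dx(enc$primary_dx),
               , drop = FALSE]
  n_events <- table(factor(acute$patient_id, levels = cohort))
  adm <- table(factor(acute$patient_id[acute$visit_type == "inpatient"],
                      levels = cohort))
  ed <- table(factor(acute$patient_id[acute$visit_type == "emergency"],
                     levels = cohort))

  rel <- dsp[dsp$med_class %in% c("beta-agonist", "oral steroid"), , drop = FALSE]
  rel_amt <- tapply(rel$amount, factor(rel$patient_id, levels = cohort), sum)
  rel_amt[is.na(rel_amt)] <- 0

  cost <- tapply(enc$cost, factor(enc$patient_id, levels = cohort), sum)
  cost[is.na(cost)] <- 0

  data.frame(
    patient_id = cohort,
    high_risk = as.integer(as.integer(n_events) > 0L),
    reliever_next = as.numeric(rel_amt),
    cost_next = as.numeric(cost),
    n_events_next = as.integer(n_events),
    admissions_next = as.integer(adm),
    ed_next = as.integer(ed),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Patient features at an index year
#'
#' Demographics plus prior-year utilization: age at the index year, gender,
#' race, language, insurance, index-year encounter counts by visit type,
#' index-year acute asthma event count, index-year total cost, and the
#' controller-to-total asthma medication ratio.
#'
#' @inheritParams label_outcomes
#' @return Data frame keyed by `patient_id`.
#' @export
build_patient_features <- function(bundle, cohort, index_year) {
  pts <- bundle$patients
  m <- match(cohort, pts$patient_id)
  if (anyNA(m)) stopf("unknown patient id(s): %s",
                      paste(head(cohort[is.na(m)], 3L), collapse = ", "))
  enc <- bundle$encounters[bundle$encounters$year == index_year, , drop = FALSE]
  dsp <- bundle$dispensings[bundle$dispensings$year == index_year, , drop = FALSE]

  fp <- function(ids) factor(ids, levels = cohort)
  cnt <- function(sub) as.integer(table(fp(sub$patient_id)))

  acute <- enc[enc$visit_type %in% ACUTE_TYPES & is_asthma_dx(enc$primary_dx),
               , drop = FALSE]
  cost <- tapply(enc$cost, fp(enc$patient_id), sum)
  cost[is.na(cost)] <- 0

  ctrl <- cnt(dsp[dsp$med_class %in% MED_CONTROLLER, , drop = FALSE])
  rel <- cnt(dsp[dsp$med_class == MED_RELIEVER, , drop = FALSE])
  tot <- ctrl + rel
  ratio <- ifelse(tot > 0, ctrl / tot, NA_real_)

  data.frame(
    patient_id = cohort,
    age = index_year - pts$birth_year[m],
    gender = pts$gender[m], race = pts$race[m],
    language = pts$language[m], insurance = pts$insurance[m],
    prior_outpatient = cnt(enc[enc$visit_type == "outpatient", , drop = FALSE]),
    prior_inpatient = cnt(enc[enc$visit_type == "inpatient", , drop = FALSE]),
    prior_urgent = cnt(enc[enc$visit_type == "urgent care", , drop = FALSE]),
    prior_ed = cnt(enc[enc$visit_type == "emergency", , drop = FALSE]),
    prior_events = cnt(acute),
    prior_cost = as.numeric(cost),
    controller_ratio = ratio,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Physician practice-profile features at an index year
#'
#' For each cohort patient's primary physician: log-scale panel counts
#' (`log(1 + count / normalizer)`), the log count of acute-care encounters
#' in the panel, leave-one-out panel means of the index-year event
#' indicator and cost over the physician's asthma patients (excluding the
#' index patient, falling back to the population mean when fewer than
#' `min_panel` such patients remain), the panel mean controller ratio, the
#' physician's own attributes, and patient-physician match features
#' (distance, same gender, same language, insurance accepted).
#'
#' @inheritParams label_outcomes
#' @param asthma_ids Patient ids forming the asthma panel universe
#'   (default: [identify_asthma()] on the bundle's tables).
#' @param min_panel Minimum number of (other) asthma patients a physician
#'   needs before their own panel mean is used instead of the population
#'   mean.
#' @param normalizer Divisor inside the log panel-count features.
#' @return Data frame keyed by `patient_id`.
#' @export
build_physician_profile_features <- function(bundle, cohort, index_year,
                                             asthma_ids = NULL,
                                             min_panel = 5L, normalizer = 1) {
  pts <- bundle$patients
  phys <- bundle$physicians
  m <- match(cohort, pts$patient_id)
  if (anyNA(m)) stopf("unknown patient id(s)")
  pid <- pts$physician_id[m]
  pm <- match(pid, phys$physician_id)
  if (anyNA(pm)) stopf("unresolvable physician id(s): %s",
                       paste(unique(pid[is.na(pm)]), collapse = ", "))

  if (is.null(asthma_ids)) {
    asthma_ids <- identify_asthma(bundle$encounters, bundle$dispensings)
  }

  # per-patient index-year event indicator, cost and controller ratio over
  # the full asthma panel universe
  au <- data.frame(patient_id = asthma_ids, stringsAsFactors = FALSE)
  au$physician_id <- pts$physician_id[match(asthma_ids, pts$patient_id)]
  au <- au[!is.na(au$physician_id), , drop = FALSE]
  enc <- bundle$encounters[bundle$encounters$year == index_year, , drop = FALSE]
  dsp <- bundle$dispensings[bundle$dispensings$year == index_year, , drop = FALSE]
  fa <- function(ids) factor(ids, levels = au$patient_id)
  acute <- enc[enc$visit_type %in% ACUTE_TYPES & is_asthma_dx(enc$primary_dx),
               , drop = FALSE]
  au$event <- as.integer(as.integer(table(fa(acute$patient_id))) > 0L)
  cost <- tapply(enc$cost, fa(enc$patient_id), sum)
  cost[is.na(cost)] <- 0
  au$cost <- as.numeric(cost)
  ctrl <- as.integer(table(fa(dsp$patient_id[dsp$med_class %in% MED_CONTROLLER])))
  rel <- as.integer(table(fa(dsp$patient_id[dsp$med_class == MED_RELIEVER])))
  tot <- ctrl + rel
  au$ratio <- ifelse(tot > 0, ctrl / tot, NA_real_)

  # panel aggregates per physician
  g <- factor(au$physician_id, levels = phys$physician_id)
  panel_asthma_n <- as.integer(table(g))
  sum_event <- tapply(au$event, g, sum)
  sum_cost <- tapply(au$cost, g, sum)
  mean_ratio <- tapply(au$ratio, g, mean, na.rm = TRUE)
  sum_event[is.na(sum_event)] <- 0
  sum_cost[is.na(sum_cost)] <- 0
  pop_event <- mean(au$event)
  pop_cost <- mean(au$cost)
  pop_ratio <- mean(au$ratio, na.rm = TRUE)
  mean_ratio[is.nan(mean_ratio)] <- pop_ratio
  mean_ratio[is.na(mean_ratio)] <- pop_ratio

  panel_total_n <- as.integer(table(factor(pts$physician_id,
                                           levels = phys$physician_id)))
  acute_by_phys <- as.integer(table(factor(
    pts$physician_id[match(acute$patient_id, pts$patient_id)],
    levels = phys$physician_id)))

  # leave-one-out means for the index patient
  in_panel <- cohort %in% au$patient_id
  own_event <- au$event[match(cohort, au$patient_id)]
  own_cost <- au$cost[match(cohort, au$patient_id)]
  n_g <- panel_asthma_n[pm]
  se_g <- as.numeric(sum_event[pm])
  sc_g <- as.numeric(sum_cost[pm])
  n_loo <- ifelse(in_panel, n_g - 1L, n_g)
  se_loo <- ifelse(in_panel, se_g - own_event, se_g)
  sc_loo <- ifelse(in_panel, sc_g - own_cost, sc_g)
  mean_event_loo <- ifelse(n_loo >= min_panel, se_loo / n_loo, pop_event)
  mean_cost_loo <- ifelse(n_loo >= min_panel, sc_loo / n_loo, pop_cost)

  dist <- sqrt((pts$home_x[m] - phys$office_x[pm])^2 +
                 (pts$home_y[m] - phys$office_y[pm])^2)
  pt_lang <- pts$language[m]
  same_lang <- mapply(function(l, ls) {
    if (is.na(l)) return(NA_integer_)
    as.integer(l %in% strsplit(ls, ";", fixed = TRUE)[[1L]])
  }, pt_lang, phys$languages[pm], USE.NAMES = FALSE)
  pt_ins <- pts$insurance[m]
  ins_ok <- mapply(function(i, is) {
    if (is.na(i)) return(NA_integer_)
    as.integer(i %in% strsplit(is, ";", fixed = TRUE)[[1L]])
  }, pt_ins, phys$insurances[pm], USE.NAMES = FALSE)

  data.frame(
    patient_id = cohort,
    phys_log_panel = log1p(panel_total_n[pm] / normalizer),
    phys_log_asthma = log1p(panel_asthma_n[pm] / normalizer),
    phys_log_acute = log1p(acute_by_phys[pm] / normalizer),
    phys_mean_outcome = mean_event_loo,
    phys_mean_cost = mean_cost_loo,
    phys_mean_ctrl_ratio = as.numeric(mean_ratio[pm]),
    phys_age = phys$age[pm],
    phys_office_hours = phys$office_hours[pm],
    phys_years_practice = phys$years_practice[pm],
    phys_specialty = phys$specialty[pm],
    phys_distance = dist,
    same_gender = as.integer(pts$gender[m] == phys$gender[pm]),
    same_language = same_lang,
    insurance_accepted = ins_ok,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Environmental features at an index year
#'
#' Yearly mean and maximum of the monthly values of each environmental
#' variable, taken at the monitoring station nearest the patient's home.
#'
#' @inheritParams label_outcomes
#' @return Data frame keyed by `patient_id` with columns
#'   `env_<variable>_mean` and `env_<variable>_max`.
#' @export
build_env_features <- function(bundle, cohort, index_year) {
  st <- bundle$station_xy
  if (is.null(st) || nrow(st) == 0L) stopf("bundle has no monitoring stations")
  pts <- bundle$patients
  m <- match(cohort, pts$patient_id)
  d2 <- outer(pts$home_x[m], st$x, `-`)^2 + outer(pts$home_y[m], st$y, `-`)^2
  nearest <- st$station_id[max.col(-d2, ties.method = "first")]

  ev <- bundle$env[bundle$env$year == index_year, , drop = FALSE]
  if (nrow(ev) == 0L) stopf("no environmental data for year %d", index_year)
  key <- interaction(ev$station_id, ev$variable, drop = FALSE)
  mu <- tapply(ev$value, key, mean)
  mx <- tapply(ev$value, key, max)

  vars <- sort(unique(ev$variable))
  out <- data.frame(patient_id = cohort, stringsAsFactors = FALSE)
  for (v in vars) {
    out[[paste0("env_", v, "_mean")]] <-
      as.numeric(mu[paste(nearest, v, sep = ".")])
    out[[paste0("env_", v, "_max")]] <-
      as.numeric(mx[paste(nearest, v, sep = ".")])
  }
  out
}

#' Assemble the patient-year feature matrix
#'
#' One row per cohort patient per index year, combining the three feature
#' families with the next-year outcome columns. The feature family and
#' attribute group of every column are recorded in attributes
#' (`families`, `groups`) and in the JSON sidecar written by
#' [write_feature_matrix()].
#'
#' @param bundle A `cohort_bundle`.
#' @param index_years Index years to include (default: all years with a
#'   following year in the bundle).
#' @param cohort Cohort patient ids (default: [identify_asthma()] on the
#'   bundle).
#' @param min_panel,normalizer Passed to
#'   [build_physician_profile_features()].
#' @return A `feature_matrix` data frame with attributes `families`,
#'   `groups`, `outcome_cols`.
#' @export
build_feature_matrix <- function(bundle, index_years = NULL, cohort = NULL,
                                 min_panel = 5L, normalizer = 1) {
  if (is.null(index_years)) index_years <- head(bundle$years, -1L)
  if (is.null(cohort)) {
    cohort <- identify_asthma(bundle$encounters, bundle$dispensings)
  }
  if (length(cohort) == 0L) stopf("empty cohort")
  asthma_ids <- cohort

  rows <- lapply(index_years, function(iy) {
    pf <- build_patient_features(bundle, cohort, iy)
    phf <- build_physician_profile_features(bundle, cohort, iy,
                                            asthma_ids = asthma_ids,
                                            min_panel = min_panel,
                                            normalizer = normalizer)
    ef <- build_env_features(bundle, cohort, iy)
    lab <- label_outcomes(bundle, cohort, iy)
    stopifnot(identical(pf$patient_id, phf$patient_id),
              identical(pf$patient_id, ef$patient_id),
              identical(pf$patient_id, lab$patient_id))
    cbind(data.frame(patient_id = pf$patient_id, index_year = iy,
                     stringsAsFactors = FALSE),
          pf[-1L], phf[-1L], ef[-1L], lab[-1L])
  })
  fm <- do.call(rbind, rows)

  outcome_cols <- c("high_risk", "reliever_next", "cost_next",
                    "n_events_next", "admissions_next", "ed_next")
  feat_cols <- setdiff(names(fm), c("patient_id", "index_year", outcome_cols))
  families <- setNames(rep("patient", length(feat_cols)), feat_cols)
  families[startsWith(feat_cols, "phys_") |
             feat_cols %in% c("same_gender", "same_language",
                              "insurance_accepted")] <- "physician_profile"
  families[startsWith(feat_cols, "env_")] <- "environmental"

  groups <- setNames(rep("demographics", length(feat_cols)), feat_cols)
  groups[feat_cols %in% c("prior_outpatient", "prior_inpatient", "prior_urgent",
                          "prior_ed", "prior_events", "prior_cost")] <- "utilization"
  groups[feat_cols == "controller_ratio"] <- "medications"
  groups[families == "physician_profile"] <- "phys_profile"
  groups[feat_cols %in% c("phys_distance", "same_gender", "same_language",
                          "insurance_accepted")] <- "phys_match"
  groups[families == "environmental"] <- "environmental"

  attr(fm, "families") <- families
  attr(fm, "groups") <- groups
  attr(fm, "outcome_cols") <- outcome_cols
  class(fm) <- c("feature_matrix", "data.frame")
  fm
}

#' Feature columns of a feature matrix
#' @param fm A `feature_matrix`.
#' @param families Optional subset of families to keep
#'   (`"patient"`, `"physician_profile"`, `"environmental"`).
#' @return Character vector of column names.
#' @export
feature_cols <- function(fm, families = NULL) {
  fams <- attr(fm, "families")
  out <- names(fams)
  if (!is.null(families)) out <- out[fams %in% families]
  out
}

#' Write a feature matrix with its JSON sidecar
#'
#' The matrix goes to `<path>.csv`; the per-feature family and attribute
#' group map goes to `<path>.json`.
#'
#' @param fm A `feature_matrix`.
#' @param path Output path stem (without extension).
#' @export
write_feature_matrix <- function(fm, path) {
  utils::write.csv(as.data.frame(fm), paste0(path, ".csv"), row.names = FALSE)
  jsonlite::write_json(
    list(families = as.list(attr(fm, "families")),
         groups = as.list(attr(fm, "groups")),
         outcome_cols = attr(fm, "outcome_cols")),
    paste0(path, ".json"), auto_unbox = TRUE
  )
  invisible(path)
}

#' Read a feature matrix written by [write_feature_matrix()]
#' @param path Path stem used when writing.
#' @return A `feature_matrix`.
#' @export
read_feature_matrix <- function(path) {
  fm <- utils::read.csv(paste0(path, ".csv"), stringsAsFactors = FALSE)
  side <- jsonlite::read_json(paste0(path, ".json"))
  attr(fm, "families") <- unlist(side$families)
  attr(fm, "groups") <- unlist(side$groups)
  attr(fm, "outcome_cols") <- unlist(side$outcome_cols)
  class(fm) <- c("feature_matrix", "data.frame")
  fm
}
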