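test_that("asthma cohort membership follows the diagnosis and dispensing rules", {
  enc <- data.frame(patient_id = "X", year = 2005L, month = 3L,
                    visit_type = "outpatient", primary_dx = "493.02",
                    cost = 100, stringsAsFactors = FALSE)
  dsp0 <- data.frame(patient_id = character(0), year = integer(0),
                     month = integer(0), med_class = character(0),
                     amount = numeric(0))
  # a single 493.xx code suffices
  expect_equal(identify_asthma(enc, dsp0), "X")

  # two inhaled-steroid dispensings ~400 days apart do not qualify
  far <- data.frame(patient_id = c("Y", "Y"), year = c(2005L, 2006L),
                    month = c(1L, 2L), med_class = "inhaled steroid",
                    amount = 30, stringsAsFactors = FALSE)
  expect_equal(length(identify_asthma(enc[0, ], far)), 0L)
  # the same two within a year qualify
  near <- far
  near$year <- c(2005L, 2005L)
  near$month <- c(1L, 12L)
  expect_equal(identify_asthma(enc[0, ], near), "Y")

  # oral steroids alone never qualify
  oral <- data.frame(patient_id = c("Z", "Z", "Z"), year = 2005L,
                     month = c(1L, 2L, 3L), med_class = "oral steroid",
                     amount = 10, stringsAsFactors = FALSE)
  expect_equal(length(identify_asthma(enc[0, ], oral)), 0L)
  expect_equal(length(identify_asthma(enc[0, ], dsp0)), 0L)
})

test_that("adding records never removes a patient from the cohort", {
  set.seed(11)
  for (rep in 1:5) {
    n <- 30L
    enc <- data.frame(
      patient_id = sample(paste0("P", 1:10), n, replace = TRUE),
      year = sample(2005:2007, n, replace = TRUE),
      month = sample(1:12, n, replace = TRUE),
      visit_type = "outpatient",
      primary_dx = sample(c("493.00", "460", "401.9"), n, replace = TRUE),
      cost = 10, stringsAsFactors = FALSE
    )
    dsp <- data.frame(
      patient_id = sample(paste0("P", 1:10), n, replace = TRUE),
      year = sample(2005:2007, n, replace = TRUE),
      month = sample(1:12, n, replace = TRUE),
      med_class = sample(c("inhaled steroid", "beta-agonist", "oral steroid"),
                         n, replace = TRUE),
      amount = 30, stringsAsFactors = FALSE
    )
    base <- identify_asthma(enc[1:15, ], dsp[1:15, ])
    grown <- identify_asthma(enc, dsp)
    expect_true(all(base %in% grown))
  }
})

test_that("next-year outcomes are labelled from acute asthma care only", {
  b <- make_toy_bundle()
  lab <- label_outcomes(b, c("A", "B", "C", "D"), 2005L)
  # A: ED encounter coded 493.92 in 2006
  expect_equal(lab$high_risk[lab$patient_id == "A"], 1L)
  # B: outpatient-only 2006
  expect_equal(lab$high_risk[lab$patient_id == "B"], 0L)
  # D: absent from 2006 entirely -> zeros
  expect_equal(unlist(lab[lab$patient_id == "D",
                          c("high_risk", "reliever_next", "cost_next")],
                      use.names = FALSE), c(0, 0, 0))
  # A's reliever+oral-steroid refills in 2006: 30 + 60
  expect_equal(lab$reliever_next[lab$patient_id == "A"], 90)
  expect_equal(lab$cost_next[lab$patient_id == "A"], 1000)
  expect_error(label_outcomes(b, "A", 2006L), "not present")
})

test_that("patient features compute age, utilization counts and medication ratio", {
  b <- make_toy_bundle()
  pf <- build_patient_features(b, c("A", "B", "C", "D"), 2005L)
  a <- pf[pf$patient_id == "A", ]
  expect_equal(a$age, 5)
  expect_equal(a$prior_ed, 3L)       # three 2005 emergency encounters
  expect_equal(a$prior_events, 3L)   # all carried a 493.xx primary dx
  expect_equal(a$prior_cost, 800 + 700 + 900 + 100)
  expect_equal(a$controller_ratio, 0.5)  # 2 controllers, 2 relievers
  expect_equal(pf$age[pf$patient_id == "C"], 15)
  expect_true(is.na(pf$controller_ratio[pf$patient_id == "C"]))
  expect_error(build_patient_features(b, "nobody", 2005L), "unknown")
})

test_that("physician profile features cover panel, fallback and match logic", {
  b <- make_toy_bundle()
  cohort <- c("A", "B", "C", "D")
  ph <- build_physician_profile_features(b, cohort, 2005L, min_panel = 5L)
  # log panel counts with normalizer 1: MD1 has 3 patients
  expect_equal(ph$phys_log_panel[ph$patient_id == "A"], log(1 + 3))
  # every physician has < 5 asthma patients here: mean outcome falls back to
  # the population mean for everyone
  expect_equal(length(unique(ph$phys_mean_outcome)), 1L)
  # patient A and MD1 both female; B is male
  expect_equal(ph$same_gender[ph$patient_id == "A"], 1L)
  expect_equal(ph$same_gender[ph$patient_id == "B"], 0L)
  # B speaks spanish, MD1 lists it; C's MD2 does not accept medicaid
  expect_equal(ph$same_language[ph$patient_id == "B"], 1L)
  expect_equal(ph$insurance_accepted[ph$patient_id == "C"], 1L)
  bad <- b
  bad$patients$physician_id[1] <- "MD9"
  expect_error(build_physician_profile_features(bad, cohort, 2005L),
               "unresolvable")
})

test_that("leave-one-out panel means are invariant to deleting the index patient", {
  p <- cohort_params(n_patients = 400L, n_physicians = 5L, n_years = 3L,
                     seed = 41L, missing_rate = 0)
  b <- generate_cohort(p)
  cohort <- identify_asthma(b$encounters, b$dispensings)
  ph <- build_physician_profile_features(b, cohort, b$years[2], min_panel = 5L,
                                         asthma_ids = cohort)
  # pick an asthma patient whose physician has a large panel (no fallback)
  i <- which.max(ph$phys_log_asthma)
  pid <- ph$patient_id[i]
  ph2 <- build_physician_profile_features(b, pid, b$years[2], min_panel = 5L,
                                          asthma_ids = setdiff(cohort, pid))
  expect_equal(ph2$phys_mean_outcome, ph$phys_mean_outcome[i])
  expect_equal(ph2$phys_mean_cost, ph$phys_mean_cost[i])
})

test_that("environmental features use the nearest station's yearly summary", {
  b <- make_toy_bundle()
  ef <- build_env_features(b, c("A", "C"), 2005L)
  # A lives at (0.1, 0.1): nearest S1 (constant 7); C at (0.8, 0.8): S2 (12)
  expect_equal(ef$env_pm25_mean[ef$patient_id == "A"], 7)
  expect_equal(ef$env_pm25_max[ef$patient_id == "A"], 7)
  expect_equal(ef$env_pm25_mean[ef$patient_id == "C"], 12)
  # monthly values 1..12 summarize to mean 6.5, max 12
  b2 <- make_toy_bundle()
  b2$env <- data.frame(station_id = "S1", year = 2005L, month = 1:12,
                       variable = "pm25", value = 1:12,
                       stringsAsFactors = FALSE)
  b2$station_xy <- b2$station_xy[1, ]
  ef2 <- build_env_features(b2, "A", 2005L)
  expect_equal(ef2$env_pm25_mean, 6.5)
  expect_equal(ef2$env_pm25_max, 12)
  b3 <- b2
  b3$station_xy <- b3$station_xy[0, ]
  expect_error(build_env_features(b3, "A", 2005L), "station")
})

test_that("the assembled matrix has no temporal leakage from the outcome year", {
  p <- cohort_params(n_patients = 200L, n_physicians = 5L, n_years = 3L,
                     seed = 51L)
  b <- generate_cohort(p)
  cohort <- identify_asthma(b$encounters, b$dispensings)
  fm <- build_feature_matrix(b, index_years = b$years[1], cohort = cohort)
  # permute all outcome-year encounter costs and visit types
  b2 <- b
  out_rows <- b2$encounters$year == b$years[2]
  set.seed(1)
  perm <- sample(sum(out_rows))
  b2$encounters$cost[out_rows] <- b2$encounters$cost[out_rows][perm]
  b2$encounters$primary_dx[out_rows] <- b2$encounters$primary_dx[out_rows][perm]
  fm2 <- build_feature_matrix(b2, index_years = b$years[1], cohort = cohort)
  feats <- feature_cols(fm)
  expect_identical(as.data.frame(fm)[feats], as.data.frame(fm2)[feats])
})

test_that("feature families and groups partition the feature columns", {
  p <- cohort_params(n_patients = 150L, n_physicians = 5L, n_years = 3L,
                     seed = 61L)
  fm <- build_feature_matrix(generate_cohort(p))
  fams <- attr(fm, "families")
  expect_setequal(unique(fams), c("patient", "physician_profile", "environmental"))
  expect_setequal(names(fams), feature_cols(fm))
  expect_equal(length(feature_cols(fm, "environmental")), 42L)  # 21 vars x 2
  groups <- attr(fm, "groups")
  expect_setequal(names(groups), feature_cols(fm))
  # one row per patient-year and outcome columns present
  expect_false(anyDuplicated(paste(fm$patient_id, fm$index_year)) > 0)
  expect_true(all(c("high_risk", "cost_next") %in% names(fm)))
  # round-trip with the JSON sidecar
  path <- tempfile()
  write_feature_matrix(fm, path)
  back <- read_feature_matrix(path)
  expect_identical(attr(back, "families"), fams)
  expect_equal(nrow(back), nrow(fm))
})
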