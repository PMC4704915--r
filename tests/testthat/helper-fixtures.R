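# Shared fixtures: all built in code at test time.

# Wrap a plain data frame as a feature_matrix with family/group metadata.
as_feature_matrix <- function(df, families = NULL, groups = NULL,
                              outcome_cols = intersect(
                                c("high_risk", "cost_next", "n_events_next",
                                  "admissions_next", "ed_next", "reliever_next"),
                                names(df))) {
  feat <- setdiff(names(df), c("patient_id", "index_year", outcome_cols))
  if (is.null(families)) families <- setNames(rep("patient", length(feat)), feat)
  if (is.null(groups)) groups <- setNames(rep("g1", length(feat)), feat)
  attr(df, "families") <- families
  attr(df, "groups") <- groups
  attr(df, "outcome_cols") <- outcome_cols
  class(df) <- c("feature_matrix", "data.frame")
  df
}

# Minimal hand-built cohort bundle for feature-construction tests.
# Two physicians, four patients, two years of data (2005 index, 2006 outcome).
make_toy_bundle <- function() {
  patients <- data.frame(
    patient_id = c("A", "B", "C", "D"),
    birth_year = c(2000L, 1995L, 1990L, 2001L),
    gender = c("F", "M", "F", "F"),
    race = c("white", "black", "white", "hispanic"),
    language = c("english", "spanish", "english", "english"),
    insurance = c("commercial", "medicaid", "commercial", "medicaid"),
    home_x = c(0.1, 0.2, 0.8, 0.15),
    home_y = c(0.1, 0.2, 0.8, 0.12),
    physician_id = c("MD1", "MD1", "MD2", "MD1"),
    stringsAsFactors = FALSE
  )
  physicians <- data.frame(
    physician_id = c("MD1", "MD2"),
    age = c(45L, 55L), gender = c("F", "M"),
    languages = c("english;spanish", "english"),
    insurances = c("commercial;medicaid", "commercial"),
    office_x = c(0.1, 0.9), office_y = c(0.1, 0.9),
    office_hours = c(40L, 30L),
    specialty = c("pediatrics", "family medicine"),
    years_practice = c(15L, 25L),
    stringsAsFactors = FALSE
  )
  encounters <- data.frame(
    patient_id = c("A", "A", "A", "A", "B", "C", "A", "B", "C"),
    year = c(2005L, 2005L, 2005L, 2005L, 2005L, 2005L, 2006L, 2006L, 2006L),
    month = c(1L, 3L, 5L, 7L, 2L, 6L, 4L, 5L, 8L),
    visit_type = c("emergency", "emergency", "emergency", "outpatient",
                   "outpatient", "inpatient", "emergency", "outpatient",
                   "outpatient"),
    primary_dx = c("493.92", "493.92", "493.02", "493.00", "460", "493.92",
                   "493.92", "401.9", "786.2"),
    cost = c(800, 700, 900, 100, 120, 5000, 1000, 90, 60),
    stringsAsFactors = FALSE
  )
  dispensings <- data.frame(
    patient_id = c("A", "A", "A", "A", "B", "B", "D", "D", "A", "A"),
    year = c(2005L, 2005L, 2005L, 2005L, 2005L, 2005L, 2005L, 2005L,
             2006L, 2006L),
    month = c(1L, 4L, 6L, 9L, 2L, 5L, 3L, 4L, 2L, 6L),
    med_class = c("inhaled steroid", "inhaled steroid", "beta-agonist",
                  "beta-agonist", "oral steroid", "oral steroid",
                  "beta-agonist", "inhaled steroid",
                  "beta-agonist", "oral steroid"),
    amount = c(30, 30, 30, 30, 10, 10, 30, 30, 30, 60),
    stringsAsFactors = FALSE
  )
  env <- expand.grid(station_id = c("S1", "S2"), year = c(2005L, 2006L),
                     month = 1:12, stringsAsFactors = FALSE)
  env$variable <- "pm25"
  env$value <- ifelse(env$station_id == "S1", 7, 12)
  station_xy <- data.frame(station_id = c("S1", "S2"),
                           x = c(0, 1), y = c(0, 1),
                           stringsAsFactors = FALSE)
  structure(list(
    patients = patients, physicians = physicians, encounters = encounters,
    dispensings = dispensings, env = env, station_xy = station_xy,
    years = c(2005L, 2006L)
  ), class = "cohort_bundle")
}

# Brute-force class-association-rule enumeration: every conjunction of up
# to max_len items (one item per feature) passing both thresholds.
# Independent of the miner's level-wise search.
brute_force_rules <- function(data, items, label_col = "high_risk",
                              min_support = 0.01, min_confidence = 0.70,
                              max_len = 4L) {
  n <- nrow(data)
  lab <- as.integer(data[[label_col]])
  M <- vapply(items, stratikit:::item_satisfied, logical(n), data = data)
  M <- matrix(M, nrow = n)
  feat <- vapply(items, `[[`, "", "feature")
  out <- list()
  for (k in seq_len(min(max_len, length(items)))) {
    combos <- utils::combn(seq_along(items), k, simplify = FALSE)
    combos <- Filter(function(ix) !anyDuplicated(feat[ix]), combos)
    if (length(combos) == 0L) next
    C <- vapply(combos, function(ix) {
      v <- integer(length(items)); v[ix] <- 1L; v
    }, integer(length(items)))
    sat <- (M %*% C) == k
    n_lhs <- colSums(sat)
    n_match <- colSums(sat & lab == 1L)
    supp <- n_match / n
    conf <- ifelse(n_lhs > 0, n_match / n_lhs, 0)
    pass <- which(supp >= min_support - 1e-9 & conf >= min_confidence - 1e-12 &
                    n_lhs > 0)
    for (j in pass) {
      out[[length(out) + 1L]] <- stratikit:::make_rule(
        items[combos[[j]]], support = supp[j], confidence = conf[j],
        n_lhs = n_lhs[j], n_match = n_match[j]
      )
    }
  }
  stratikit:::as_rule_set(out)
}

rule_signature <- function(rules) {
  sig <- vapply(rules, function(r) {
    sprintf("%s|%.10f|%.10f", r$id, r$support, r$confidence)
  }, "")
  sort(sig)
}

# Random binary feature matrix with a couple of planted label drivers.
random_rule_matrix <- function(seed, n_feat = NULL, n_rows = NULL) {
  set.seed(seed)
  if (is.null(n_feat)) n_feat <- sample(4:12, 1L)
  if (is.null(n_rows)) n_rows <- sample(60:500, 1L)
  X <- matrix(rbinom(n_rows * n_feat, 1L, runif(n_feat, 0.1, 0.6)),
              nrow = n_rows, byrow = TRUE)
  colnames(X) <- paste0("f", seq_len(n_feat))
  eta <- -2.2 + 2.5 * X[, 1L] + 1.5 * X[, min(2L, n_feat)]
  d <- as.data.frame(X)
  d$high_risk <- rbinom(n_rows, 1L, plogis(eta))
  d
}

# Random small stratification instances for the optimizer oracle.
random_strata_instance <- function(seed, force_unbounded = FALSE) {
  set.seed(seed)
  n_bins <- sample(2:6, 1L)
  n_lev <- sample(1:3, 1L)
  stats <- data.frame(
    bin = seq_len(n_bins),
    n_patients = sample(5:20, n_bins, replace = TRUE),
    avg_n_e = sort(runif(n_bins, 0, 3), decreasing = TRUE)
  )
  levels <- lapply(seq_len(n_lev), function(i) {
    cap <- if (force_unbounded || runif(1) < 0.4) Inf else
      sample(5:40, 1L)
    management_level(paste0("L", i), c_i = runif(1, 500, 8000),
                     p = runif(1, 0.1, 0.6), capacity = cap)
  })
  list(stats = stats, levels = levels, c_e = runif(1, 2000, 15000))
}
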