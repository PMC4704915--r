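synth_fm <- function(n = 360L, seed = 1L, noise = 1, years = 1:3) {
  set.seed(seed)
  x1 <- rnorm(n)
  x2 <- rnorm(n)
  x3 <- rnorm(n)
  eta <- 1.5 * x1 + x2
  y <- rbinom(n, 1L, plogis(eta / noise))
  df <- data.frame(
    patient_id = paste0("P", seq_len(n)),
    index_year = rep_len(years, n),
    x1 = x1, x2 = x2, x3 = x3,
    high_risk = y,
    cost_next = 100 + 40 * x1 + 10 * x2 + rnorm(n, 0, 5),
    n_events_next = y, admissions_next = y, ed_next = 0L
  )
  as_feature_matrix(df)
}

test_that("cross-validation is stratified, per fold, and perfect when separable", {
  fm <- synth_fm(seed = 2)
  fm$high_risk <- as.integer(fm$x1 > 0)  # perfectly separable
  m <- train_and_cv(fm, model_spec("logistic", features = "x1"),
                    n_folds = 5, seed = 3)
  expect_equal(m$report$value, 1.0)
  expect_equal(length(m$report$per_fold), 5L)
  # single-class data refuse to train
  fm1 <- fm
  fm1$high_risk <- 1L
  expect_error(train_and_cv(fm1, model_spec("logistic"), n_folds = 5),
               "single class")
})

test_that("randomly permuted labels give chance-level CV AUC", {
  fm <- synth_fm(n = 400, seed = 4)
  set.seed(9)
  fm$high_risk <- sample(fm$high_risk)
  m <- train_and_cv(fm, model_spec("logistic"), n_folds = 5, seed = 5)
  n1 <- sum(fm$high_risk[fm$index_year %in% 1:2] == 1)
  n0 <- sum(fm$high_risk[fm$index_year %in% 1:2] == 0)
  band <- 3 * sqrt(stratikit:::auc_variance_hm(0.5, n1, n0))
  expect_lt(abs(m$report$value - 0.5), band + 0.05)  # CV adds refit noise
})

test_that("a noiseless linear target is recovered exactly by the linear learner", {
  fm <- synth_fm(seed = 6)
  fm$cost_next <- 5 + 2 * fm$x1 - 3 * fm$x2
  m <- train_and_cv(fm, model_spec("linear", outcome = "cost_next"),
                    n_folds = 5, seed = 7)
  expect_gt(m$report$value, 0.999)        # R2
  expect_lt(m$report$mae, 1e-6)           # Cumming's measure
})

test_that("holdout evaluation touches only the unseen year and guards misuse", {
  fm <- synth_fm(seed = 8)
  m <- train_and_cv(fm, model_spec("logistic"), n_folds = 5,
                    train_years = 1:2, seed = 9)
  h <- evaluate_holdout(m, fm, year = 3)
  expect_true(h$value > 0.5)
  expect_equal(h$n, sum(fm$index_year == 3))
  expect_error(evaluate_holdout(m, fm, year = 2), "training")
  expect_error(evaluate_holdout(m, fm[fm$index_year != 3, ], year = 3),
               "no rows")
  # constant predictions score exactly at chance
  fm0 <- fm
  fm0$x0 <- 0
  m0 <- train_and_cv(fm0, model_spec("logistic", features = "x0"),
                     n_folds = 5, train_years = 1:2, seed = 9)
  expect_equal(evaluate_holdout(m0, fm0, year = 3)$value, 0.5)
})

test_that("predictions predating the mean are definitionally R2 <= 0 on holdout", {
  fm <- synth_fm(seed = 10)
  # a constant-feature regression predicts the training mean
  fm$x0 <- 0
  m <- train_and_cv(fm, model_spec("linear", outcome = "cost_next",
                                   features = "x0"),
                    n_folds = 5, train_years = 1:2, seed = 2)
  h <- evaluate_holdout(m, fm, year = 3)
  expect_lte(h$value, 0.01)
})

test_that("synthetic oversampling balances classes by interpolation", {
  set.seed(12)
  n <- 200L
  X <- cbind(a = rnorm(n), b = rnorm(n))
  y <- c(rep(1L, 20), rep(0L, 180))
  rb <- rebalance(X, y, ratio = 1, seed = 13)
  tab <- table(rb$y)
  expect_equal(unname(tab[["1"]]), unname(tab[["0"]]))
  # balanced input returned unchanged
  yb <- rep(c(0L, 1L), each = n / 2)
  rb2 <- rebalance(X, yb, ratio = 1, seed = 13)
  expect_identical(rb2$X, X)
  # synthetic minority points lie on segments between minority neighbors
  Xm <- X[y == 1L, ]
  Xnew <- rb$X[(n + 1):nrow(rb$X), , drop = FALSE]
  on_segment <- apply(Xnew, 1L, function(s) {
    for (i in seq_len(nrow(Xm) - 1L)) {
      for (j in seq((i + 1L), nrow(Xm))) {
        v <- Xm[j, ] - Xm[i, ]
        w <- s - Xm[i, ]
        cross <- v[1] * w[2] - v[2] * w[1]
        t_par <- sum(w * v) / sum(v * v)
        if (abs(cross) < 1e-8 && t_par >= -1e-8 && t_par <= 1 + 1e-8) return(TRUE)
      }
    }
    FALSE
  })
  expect_true(all(on_segment))
  expect_error(rebalance(X, c(1L, rep(0L, n - 1L))), "fewer than 2")
})

test_that("rebalancing inside CV leaves held-out rows untouched", {
  fm <- synth_fm(n = 300, seed = 14)
  m <- train_and_cv(fm, model_spec("logistic", rebalance = TRUE),
                    n_folds = 5, seed = 15)
  # the report is computed on exactly the original training rows
  expect_equal(m$report$n, sum(fm$index_year %in% 1:2))
})

test_that("backward elimination drops noise and keeps signal within tolerance", {
  set.seed(16)
  n <- 500L
  x_sig <- rnorm(n)
  df <- data.frame(
    patient_id = paste0("P", 1:n), index_year = rep_len(1:3, n),
    signal = x_sig, noise1 = rnorm(n), noise2 = rnorm(n),
    high_risk = rbinom(n, 1L, plogis(2.5 * x_sig)),
    cost_next = 0, n_events_next = 0L, admissions_next = 0L, ed_next = 0L
  )
  fm <- as_feature_matrix(df)
  be <- backward_eliminate(fm, model_spec("logistic"), tolerance = 0.02,
                           n_folds = 5, seed = 17)
  expect_true("signal" %in% be$retained)
  expect_true(length(be$dropped) >= 1L)
  expect_true(all(c("noise1", "noise2") %in% c(be$dropped, be$retained)))
  # the invariant the rule promises: final metric within tolerance of full
  expect_gte(be$metric_final, be$metric_full - 0.02 - 1e-9)
})

test_that("feature merging keeps the top-associated features and clusters the rest", {
  set.seed(18)
  n <- 300L
  sig <- rnorm(n)
  dup <- rnorm(n)
  df <- data.frame(
    patient_id = paste0("P", 1:n), index_year = 1L,
    sig = sig,
    dup_a = dup, dup_b = dup,           # perfectly correlated pair
    other = rnorm(n), flat = 1,
    cost_next = 3 * sig + rnorm(n, 0, 0.5),
    high_risk = 0L, n_events_next = 0L, admissions_next = 0L, ed_next = 0L
  )
  fm <- as_feature_matrix(df)
  expect_warning(
    red <- reduce_features(fm, "cost_next", n_keep = 1, n_groups = 2),
    "constant"
  )
  expect_equal(red$kept, "sig")
  # duplicated features must share a cluster
  expect_equal(red$grouping[["dup_a"]], red$grouping[["dup_b"]])
  # output column count: n_keep + n_groups feature columns exactly
  fcols <- setdiff(names(red$matrix), c("patient_id", "index_year", "cost_next"))
  expect_equal(length(fcols), 1L + 2L)
  # degenerate clustering: plain top-k selection
  red0 <- suppressWarnings(reduce_features(fm, "cost_next", n_keep = 2,
                                           n_groups = 0))
  fcols0 <- setdiff(names(red0$matrix), c("patient_id", "index_year", "cost_next"))
  expect_equal(sort(fcols0), sort(red0$kept))
  expect_error(suppressWarnings(reduce_features(fm, "cost_next", 4, 3)),
               "exceeds")
})

test_that("identical specifications give a difference of exactly zero", {
  fm <- synth_fm(seed = 20)
  sp <- model_spec("logistic")
  cmp <- compare_feature_families(fm, sp, sp, holdout_year = 3,
                                  n_folds = 5, seed = 21)
  expect_equal(cmp$difference, 0)
  expect_equal(cmp$decision, "reject")
})

test_that("every registry learner trains and predicts on both task types", {
  fm <- synth_fm(n = 240, seed = 22)
  for (lrn in c("logistic", "tree", "random_forest", "gradient_boosting",
                "ridge", "knn")) {
    m <- train_and_cv(fm, model_spec(lrn, params = list(k = 7)),
                      n_folds = 3, train_years = 1:2, seed = 23)
    pr <- predict(m, fm[fm$index_year == 3, ])
    expect_true(all(pr >= 0 & pr <= 1), info = lrn)
  }
  for (lrn in c("linear", "tree", "random_forest", "gradient_boosting",
                "ridge")) {
    m <- train_and_cv(fm, model_spec(lrn, outcome = "cost_next"),
                      n_folds = 3, train_years = 1:2, seed = 23)
    expect_true(is.finite(evaluate_holdout(m, fm, 3)$value), info = lrn)
  }
  expect_error(model_spec("deep_net"), "unknown learner")
})
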