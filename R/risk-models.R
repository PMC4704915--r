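# Outcome and cost models under the accuracy protocol: stratified 10-fold
# cross-validation on the training years, a held-out final year, minority
# rebalancing inside training folds only, backward elimination at a 0.02
# tolerance, and the feature-merging reduction for cost models.

# ---- encoding -------------------------------------------------------------

# One-hot encoding fitted on training data and re-applied to new data.
# Numeric columns are median-imputed; categorical columns get one indicator
# per non-reference level plus a "(missing)" level when NAs occur; unseen
# levels map to all-zero indicators.
encode_fit <- function(df, cols) {
  enc <- list()
  for (col in cols) {
    x <- df[[col]]
    if (is.numeric(x)) {
      med <- median(x, na.rm = TRUE)
      if (is.na(med)) med <- 0
      enc[[col]] <- list(type = "num", median = med)
    } else {
      x <- as.character(x)
      lv <- sort(unique(x[!is.na(x)]))
      if (anyNA(x)) lv <- c(lv, "(missing)")
      enc[[col]] <- list(type = "cat", levels = lv)
    }
  }
  structure(list(cols = cols, enc = enc), class = "feature_encoder")
}

encode_apply <- function(encoder, df) {
  out <- list()
  for (col in encoder$cols) {
    e <- encoder$enc[[col]]
    x <- df[[col]]
    if (is.null(x)) stopf("column `%s` missing from data", col)
    if (e$type == "num") {
      x <- as.numeric(x)
      x[is.na(x)] <- e$median
      out[[col]] <- x
    } else {
      x <- as.character(x)
      x[is.na(x)] <- "(missing)"
      lv <- e$levels
      ref <- if (length(lv) > 1L) lv[-1L] else lv
      for (v in ref) out[[paste(col, v, sep = "=")]] <- as.numeric(x == v)
    }
  }
  m <- do.call(cbind, out)
  rownames(m) <- NULL
  m
}

# ---- learner registry -----------------------------------------------------

# Each learner is a fit/predict pair over a numeric design matrix. `task`
# is "binary" (predicts P(high risk)) or "continuous".
learner_registry <- function() {
  list(
    logistic = list(
      fit = function(X, y, task, params) {
        fit <- suppressWarnings(glm.fit(cbind(`(Intercept)` = 1, X), y,
                                        family = binomial()))
        beta <- coef(fit)
        beta[is.na(beta)] <- 0
        list(beta = beta)
      },
      predict = function(fit, X, task) {
        as.numeric(plogis(cbind(1, X) %*% fit$beta))
      }
    ),
    linear = list(
      fit = function(X, y, task, params) {
        fit <- lm.fit(cbind(`(Intercept)` = 1, X), y)
        beta <- coef(fit)
        beta[is.na(beta)] <- 0
        list(beta = beta)
      },
      predict = function(fit, X, task) as.numeric(cbind(1, X) %*% fit$beta)
    ),
    ridge = list(
      fit = function(X, y, task, params) {
        fam <- if (task == "binary") "binomial" else "gaussian"
        glmnet::cv.glmnet(X, y, alpha = 0, family = fam, nfolds = 5)
      },
      predict = function(fit, X, task) {
        as.numeric(predict(fit, newx = X, s = "lambda.min",
                           type = "response"))
      }
    ),
    tree = list(
      fit = function(X, y, task, params) {
        d <- as.data.frame(X)
        names(d) <- paste0("x", seq_len(ncol(X)))
        d$.y <- if (task == "binary") factor(y, levels = c(0, 1)) else y
        rpart::rpart(.y ~ ., data = d,
                     method = if (task == "binary") "class" else "anova",
                     cp = params$cp %||% 0.01)
      },
      predict = function(fit, X, task) {
        d <- as.data.frame(X)
        names(d) <- paste0("x", seq_len(ncol(X)))
        if (task == "binary") predict(fit, d, type = "prob")[, "1"]
        else as.numeric(predict(fit, d))
      }
    ),
    random_forest = list(
      fit = function(X, y, task, params) {
        d <- as.data.frame(X)
        names(d) <- paste0("x", seq_len(ncol(X)))
        d$.y <- if (task == "binary") factor(y, levels = c(0, 1)) else y
        ranger::ranger(.y ~ ., data = d,
                       num.trees = params$num_trees %||% 300,
                       probability = task == "binary",
                       num.threads = 1, seed = params$seed %||% 1)
      },
      predict = function(fit, X, task) {
        d <- as.data.frame(X)
        names(d) <- paste0("x", seq_len(ncol(X)))
        pr <- predict(fit, d, num.threads = 1)$predictions
        if (task == "binary") pr[, "1"] else as.numeric(pr)
      }
    ),
    gradient_boosting = list(
      fit = function(X, y, task, params) {
        obj <- if (task == "binary") "binary:logistic" else "reg:squarederror"
        xgboost::xgb.train(
          params = list(objective = obj, max_depth = params$max_depth %||% 3,
                        eta = params$eta %||% 0.3, nthread = 1),
          data = xgboost::xgb.DMatrix(X, label = y, nthread = 1),
          nrounds = params$nrounds %||% 50, verbose = 0
        )
      },
      predict = function(fit, X, task) {
        as.numeric(predict(fit, xgboost::xgb.DMatrix(X, nthread = 1)))
      }
    ),
    knn = list(
      fit = function(X, y, task, params) {
        if (task != "binary") stopf("knn learner supports binary outcomes only")
        list(X = X, y = y, k = params$k %||% 15L)
      },
      predict = function(fit, X, task) {
        pr <- class::knn(fit$X, X, factor(fit$y, levels = c(0, 1)),
                         k = fit$k, prob = TRUE)
        p <- attr(pr, "prob")
        ifelse(pr == "1", p, 1 - p)
      }
    )
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Model specification
#'
#' @param learner Learner name: one of `"logistic"`, `"linear"`, `"ridge"`,
#'   `"tree"`, `"random_forest"`, `"gradient_boosting"`, `"knn"`.
#' @param outcome Outcome column: `"high_risk"` (binary) or a continuous
#'   column such as `"cost_next"`.
#' @param families Feature families to include (default all three:
#'   patient, physician_profile, environmental).
#' @param features Explicit feature columns (overrides `families`).
#' @param rebalance Apply synthetic minority oversampling to binary
#'   training data (inside CV folds, training portion only).
#' @param params Learner hyperparameters.
#' @return A `model_spec`.
#' @export
model_spec <- function(learner = "logistic", outcome = "high_risk",
                       families = NULL, features = NULL,
                       rebalance = FALSE, params = list()) {
  if (!learner %in% names(learner_registry())) {
    stopf("unknown learner `%s`; registry has: %s", learner,
          paste(names(learner_registry()), collapse = ", "))
  }
  if (!is.null(families) && length(families) == 0L) {
    stopf("feature-family mask must be nonempty")
  }
  structure(list(learner = learner, outcome = outcome, families = families,
                 features = features, rebalance = rebalance, params = params),
            class = "model_spec")
}

spec_features <- function(spec, fm) {
  if (!is.null(spec$features)) return(spec$features)
  feature_cols(fm, families = spec$families)
}

spec_task <- function(spec) if (spec$outcome == "high_risk") "binary" else "continuous"

# Stratified fold assignment; binary labels are split within class.
make_folds <- function(y, n_folds, stratify, seed) {
  with_seed(seed, {
    fold <- integer(length(y))
    if (stratify) {
      for (cls in unique(y)) {
        idx <- which(y == cls)
        fold[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
      }
    } else {
      fold[] <- sample(rep_len(seq_len(n_folds), length(y)))
    }
    fold
  })
}

# ---- rebalancing ----------------------------------------------------------

#' Synthetic minority oversampling
#'
#' Upsamples the minority class of a binary training set to `ratio` times
#' the majority count by interpolating between each sampled minority point
#' and one of its `k` nearest minority neighbors (new point
#' `x + u * (neighbor - x)`, `u ~ U(0,1)`), so synthetic points lie on
#' segments between minority neighbors. Intended for training rows only;
#' never applied to held-out data.
#'
#' @param X Numeric design matrix.
#' @param y Binary 0/1 labels.
#' @param ratio Target minority/majority ratio (default 1, balanced).
#' @param k Number of nearest neighbors to interpolate toward.
#' @param seed RNG seed.
#' @return List with upsampled `X` and `y`.
#' @export
rebalance <- function(X, y, ratio = 1, k = 5L, seed = 1L) {
  y <- as.integer(y)
  tab <- table(factor(y, levels = c(0L, 1L)))
  minority <- if (tab[["1"]] <= tab[["0"]]) 1L else 0L
  n_min <- min(tab)
  n_maj <- max(tab)
  if (n_min < 2L) stopf("minority class has fewer than 2 instances")
  target <- floor(ratio * n_maj)
  n_new <- target - n_min
  if (n_new <= 0L) return(list(X = X, y = y))

  min_idx <- which(y == minority)
  Xm <- X[min_idx, , drop = FALSE]
  k <- min(k, n_min - 1L)
  d <- as.matrix(dist(Xm))
  diag(d) <- Inf
  nn <- t(apply(d, 1L, function(r) order(r)[seq_len(k)]))

  with_seed(seed, {
    base <- sample.int(n_min, n_new, replace = TRUE)
    pick <- nn[cbind(base, sample.int(k, n_new, replace = TRUE))]
    u <- runif(n_new)
    Xnew <- Xm[base, , drop = FALSE] +
      u * (Xm[pick, , drop = FALSE] - Xm[base, , drop = FALSE])
    list(X = rbind(X, Xnew), y = c(y, rep(minority, n_new)))
  })
}

# ---- training and evaluation ----------------------------------------------

eval_metrics <- function(task, y, pred) {
  if (task == "binary") {
    list(metric = "auc", value = auc_binary(y, pred))
  } else {
    list(metric = "r2", value = r_squared(y, pred),
         mae = mean_abs_error(y, pred))
  }
}

#' Train a model with stratified 10-fold cross-validation
#'
#' Rows from `train_years` are cross-validated: folds are stratified by the
#' binary label, the metric (AUC for binary outcomes, R-squared plus the
#' mean absolute prediction error for continuous outcomes) is reported per
#' fold and pooled over all held-out predictions, and any rebalancing is
#' applied only to the training portion of each fold. The final model is
#' then fitted on all training rows. The held-out final year is never
#' touched here.
#'
#' @param fm A `feature_matrix`.
#' @param spec A [model_spec()].
#' @param n_folds Number of CV folds (default 10).
#' @param train_years Index years to train on (default: all but the last
#'   year present).
#' @param seed Seed controlling fold assignment and any learner/rebalance
#'   randomness.
#' @return A `risk_model` with elements `fit`, `encoder`, `spec`, `report`
#'   (class `eval_report`), `train_years`.
#' @export
train_and_cv <- function(fm, spec, n_folds = 10L, train_years = NULL,
                         seed = 1L) {
  stopifnot(inherits(spec, "model_spec"))
  n_folds <- check_count(n_folds, "n_folds")
  if (is.null(train_years)) train_years <- head(sort(unique(fm$index_year)), -1L)
  rows <- fm$index_year %in% train_years
  dat <- fm[rows, , drop = FALSE]
  if (nrow(dat) == 0L) stopf("no rows in the training years")

  task <- spec_task(spec)
  y <- dat[[spec$outcome]]
  if (is.null(y)) stopf("outcome column `%s` not found", spec$outcome)
  if (task == "binary") {
    y <- as.integer(y)
    if (length(unique(y)) < 2L) stopf("training data contain a single class")
    if (min(table(y)) < n_folds) {
      stopf("need at least %d rows per class for %d stratified folds",
            n_folds, n_folds)
    }
  }

  feats <- spec_features(spec, fm)
  encoder <- encode_fit(dat, feats)
  X <- encode_apply(encoder, dat)
  lrn <- learner_registry()[[spec$learner]]

  fold <- make_folds(y, n_folds, stratify = task == "binary", seed = seed)
  cv_pred <- numeric(nrow(dat))
  per_fold <- numeric(n_folds)
  for (f in seq_len(n_folds)) {
    tr <- fold != f
    Xtr <- X[tr, , drop = FALSE]
    ytr <- y[tr]
    if (spec$rebalance && task == "binary") {
      rb <- rebalance(Xtr, ytr, seed = seed + f)
      Xtr <- rb$X
      ytr <- rb$y
    }
    fit_f <- with_seed(seed + 100L + f,
                       lrn$fit(Xtr, ytr, task, spec$params))
    cv_pred[!tr] <- lrn$predict(fit_f, X[!tr, , drop = FALSE], task)
    per_fold[f] <- eval_metrics(task, y[!tr], cv_pred[!tr])$value
  }
  pooled <- eval_metrics(task, y, cv_pred)

  Xfin <- X
  yfin <- y
  if (spec$rebalance && task == "binary") {
    rb <- rebalance(Xfin, yfin, seed = seed)
    Xfin <- rb$X
    yfin <- rb$y
  }
  fit <- with_seed(seed + 999L, lrn$fit(Xfin, yfin, task, spec$params))

  report <- structure(list(
    metric = pooled$metric, value = pooled$value,
    mae = pooled$mae, per_fold = per_fold, n_folds = n_folds,
    n = nrow(dat), seed = seed
  ), class = "eval_report")

  structure(list(
    spec = spec, task = task, fit = fit, encoder = encoder,
    features = feats, report = report, train_years = train_years
  ), class = "risk_model")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %s = %.4f (%d-fold CV, n = %d)\n",
              toupper(x$metric), x$value, x$n_folds, x$n))
  if (!is.null(x$mae)) cat(sprintf("  mean absolute prediction error: %.2f\n", x$mae))
  cat(sprintf("  per fold: %s\n", paste(sprintf("%.3f", x$per_fold), collapse = " ")))
  invisible(x)
}

#' @export
print.risk_model <- function(x, ...) {
  cat(sprintf("<risk_model> learner %s, outcome %s (%s)\n",
              x$spec$learner, x$spec$outcome, x$task))
  cat(sprintf("  %d features, trained on years %s\n", length(x$features),
              paste(range(x$train_years), collapse = "-")))
  print(x$report)
  invisible(x)
}

#' @export
summary.risk_model <- function(object, ...) print(object)

#' Predict from a fitted risk model
#'
#' @param object A `risk_model`.
#' @param newdata A `feature_matrix` (or data frame with the model's
#'   feature columns).
#' @param ... Unused.
#' @return Numeric vector: P(high risk) for binary models, predicted
#'   outcome for continuous models.
#' @export
predict.risk_model <- function(object, newdata, ...) {
  X <- encode_apply(object$encoder, newdata)
  lrn <- learner_registry()[[object$spec$learner]]
  lrn$predict(object$fit, X, object$task)
}

#' Evaluate a fitted model on the held-out year
#'
#' @param model A `risk_model` whose training years exclude `year`.
#' @param fm The `feature_matrix`.
#' @param year Holdout index year (default: the last year present).
#' @return An `eval_report` computed once on the holdout rows.
#' @export
evaluate_holdout <- function(model, fm, year = NULL) {
  if (is.null(year)) year <- max(fm$index_year)
  if (year %in% model$train_years) {
    stopf("year %d was used in training; holdout must be unseen", year)
  }
  rows <- fm$index_year == year
  if (!any(rows)) stopf("no rows for holdout year %d", year)
  dat <- fm[rows, , drop = FALSE]
  pred <- predict(model, dat)
  y <- dat[[model$spec$outcome]]
  if (model$task == "binary") y <- as.integer(y)
  met <- eval_metrics(model$task, y, pred)
  structure(list(metric = met$metric, value = met$value, mae = met$mae,
                 per_fold = numeric(0), n_folds = 0L, n = nrow(dat),
                 holdout_year = year),
            class = "eval_report")
}

# ---- backward elimination -------------------------------------------------

#' Backward elimination at a fixed accuracy tolerance
#'
#' Greedily removes the feature whose removal degrades the CV metric least,
#' as long as the degradation from the full model's metric stays within
#' `tolerance` (default 0.02). Fold seeds are re-used across candidate
#' models so metrics are comparable. Ties are broken by feature name order.
#'
#' @param fm A `feature_matrix`.
#' @param spec A [model_spec()].
#' @param tolerance Maximum allowed drop from the full-model metric.
#' @param n_folds,train_years,seed Passed to [train_and_cv()].
#' @return List: `retained` (feature names), `metric_full`,
#'   `metric_final`, `dropped` (in removal order).
#' @export
backward_eliminate <- function(fm, spec, tolerance = 0.02, n_folds = 10L,
                               train_years = NULL, seed = 1L) {
  feats <- sort(spec_features(spec, fm))
  if (length(feats) < 2L) stopf("need at least 2 features")
  cv_metric <- function(fs) {
    sp <- spec
    sp$features <- fs
    train_and_cv(fm, sp, n_folds = n_folds, train_years = train_years,
                 seed = seed)$report$value
  }
  m_full <- cv_metric(feats)
  current <- feats
  dropped <- character(0)
  m_cur <- m_full
  while (length(current) > 1L) {
    cand <- vapply(current, function(f) cv_metric(setdiff(current, f)),
                   numeric(1))
    best <- names(cand)[which.max(cand)]  # ties: first in name order
    if (m_full - max(cand) <= tolerance + 1e-12) {
      current <- setdiff(current, best)
      dropped <- c(dropped, best)
      m_cur <- max(cand)
    } else {
      break
    }
  }
  list(retained = current, metric_full = m_full, metric_final = m_cur,
       dropped = dropped)
}

# ---- feature-merging reduction --------------------------------------------

# Association of one feature with the target: absolute Pearson correlation
# for numeric features, the correlation ratio (eta) for categorical ones.
feature_association <- function(x, y) {
  if (is.numeric(x)) {
    ok <- complete.cases(x, y)
    if (sd(x[ok]) == 0) return(NA_real_)
    abs(cor(x[ok], y[ok]))
  } else {
    x <- as.character(x)
    x[is.na(x)] <- "(missing)"
    mu <- tapply(y, x, mean)
    n_g <- tapply(y, x, length)
    ss_between <- sum(n_g * (mu - mean(y))^2)
    ss_total <- sum((y - mean(y))^2)
    if (ss_total == 0) return(NA_real_)
    sqrt(ss_between / ss_total)
  }
}

#' Reduce features by keeping the strongest and merging the rest
#'
#' The `n_keep` features with the largest absolute association with the
#' target stay as separate columns; the remaining features are clustered
#' into `n_groups` groups by average-linkage agglomerative clustering on
#' `1 - |correlation|`, and each cluster is replaced by one merged feature:
#' the mean of its standardized members. Categorical features enter the
#' correlation through target-mean encoding. Constant features are excluded
#' from the association ranking with a warning.
#'
#' @param fm A `feature_matrix` (or data frame).
#' @param target Target column name (e.g. `"cost_next"`).
#' @param n_keep Number of top-associated features kept unmerged.
#' @param n_groups Number of merged clusters (0 = plain top-`n_keep`
#'   selection).
#' @param features Candidate features (default: all feature columns).
#' @return List: `matrix` (data frame of kept + merged columns plus the
#'   target), `kept`, `grouping` (named vector feature -> cluster id),
#'   `association` (named vector).
#' @export
reduce_features <- function(fm, target, n_keep, n_groups, features = NULL) {
  if (is.null(features)) features <- feature_cols(fm)
  y <- fm[[target]]
  if (is.null(y)) stopf("target column `%s` not found", target)
  n_keep <- check_count(n_keep, "n_keep", positive = FALSE)
  n_groups <- check_count(n_groups, "n_groups", positive = FALSE)
  if (n_keep + n_groups > length(features)) {
    stopf("n_keep + n_groups exceeds the number of candidate features")
  }

  assoc <- vapply(features, function(f) feature_association(fm[[f]], y),
                  numeric(1))
  if (anyNA(assoc)) {
    warning(sprintf("excluding constant feature(s): %s",
                    paste(names(assoc)[is.na(assoc)], collapse = ", ")),
            call. = FALSE)
    features <- features[!is.na(assoc)]
    assoc <- assoc[!is.na(assoc)]
    if (n_keep + n_groups > length(features)) {
      stopf("n_keep + n_groups exceeds the number of usable features")
    }
  }

  ord <- order(-assoc, names(assoc))
  kept <- names(assoc)[ord][seq_len(n_keep)]
  rest <- setdiff(names(assoc), kept)

  # numeric representation for correlations and merging
  num_rep <- function(f) {
    x <- fm[[f]]
    if (is.numeric(x)) {
      x[is.na(x)] <- median(x, na.rm = TRUE)
      x
    } else {
      x <- as.character(x)
      x[is.na(x)] <- "(missing)"
      as.numeric(tapply(y, x, mean)[x])  # target-mean encoding
    }
  }

  out <- fm[, intersect(c("patient_id", "index_year"), names(fm)), drop = FALSE]
  for (f in kept) out[[f]] <- fm[[f]]
  grouping <- setNames(integer(0), character(0))

  if (n_groups > 0L && length(rest) > 0L) {
    R <- vapply(rest, num_rep, numeric(nrow(fm)))
    R <- matrix(R, nrow = nrow(fm), dimnames = list(NULL, rest))
    if (length(rest) == 1L) {
      cl <- setNames(1L, rest)
    } else {
      cm <- suppressWarnings(abs(cor(R)))
      cm[is.na(cm)] <- 0
      hc <- hclust(as.dist(1 - cm), method = "average")
      cl <- cutree(hc, k = min(n_groups, length(rest)))
    }
    grouping <- cl
    for (g in sort(unique(cl))) {
      members <- names(cl)[cl == g]
      Z <- scale(R[, members, drop = FALSE])
      Z[is.nan(Z)] <- 0
      out[[paste0("merged_", g)]] <- rowMeans(Z)
    }
  }
  out[[target]] <- y
  list(matrix = out, kept = kept, grouping = grouping, association = assoc)
}

# ---- feature-family comparison --------------------------------------------

#' Compare models with and without a feature family
#'
#' Trains two specifications identically (same folds, seed and protocol),
#' evaluates both on the holdout year, and decides whether the first
#' (typically the model including physician-profile features) beats the
#' second by at least `threshold` — read as an absolute difference of 0.10
#' in AUC or R-squared by default, with a relative mode behind a flag.
#'
#' @param fm A `feature_matrix`.
#' @param spec_full,spec_reduced The two [model_spec()]s.
#' @param holdout_year Holdout index year (default: last present).
#' @param threshold Decision threshold on the metric difference.
#' @param relative If TRUE, compare `diff / metric_reduced` to `threshold`.
#' @param n_folds,seed CV protocol controls.
#' @return List: `report_full`, `report_reduced` (holdout reports),
#'   `cv_full`, `cv_reduced`, `difference`, `decision` (`"accept"` /
#'   `"reject"`).
#' @export
compare_feature_families <- function(fm, spec_full, spec_reduced,
                                     holdout_year = NULL, threshold = 0.10,
                                     relative = FALSE, n_folds = 10L,
                                     seed = 1L) {
  if (is.null(holdout_year)) holdout_year <- max(fm$index_year)
  train_years <- setdiff(sort(unique(fm$index_year)), holdout_year)
  m_full <- train_and_cv(fm, spec_full, n_folds = n_folds,
                         train_years = train_years, seed = seed)
  m_red <- train_and_cv(fm, spec_reduced, n_folds = n_folds,
                        train_years = train_years, seed = seed)
  h_full <- evaluate_holdout(m_full, fm, holdout_year)
  h_red <- evaluate_holdout(m_red, fm, holdout_year)
  diff <- h_full$value - h_red$value
  rel_diff <- if (h_red$value != 0) diff / abs(h_red$value) else Inf
  accept <- if (relative) rel_diff >= threshold else diff >= threshold
  list(report_full = h_full, report_reduced = h_red,
       cv_full = m_full$report, cv_reduced = m_red$report,
       difference = diff, relative_difference = rel_diff,
       decision = if (accept) "accept" else "reject")
}
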