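# Internal helpers shared across modules.

#' @importFrom stats predict coef qnorm pnorm qf pf rnorm rlnorm rbinom rpois
#'   runif sd cor var aggregate quantile median complete.cases t.test
#'   mcnemar.test hclust cutree as.dist binomial glm lm plogis qlogis
#'   setNames ave dist
#' @importFrom utils combn head
NULL

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards so library code never clobbers it.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv(), inherits = FALSE)
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stopf("`%s` must be a single probability in [0, 1]", name)
  }
  invisible(x)
}

check_count <- function(x, name, positive = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != as.integer(x) ||
      (positive && x <= 0) || (!positive && x < 0)) {
    stopf("`%s` must be a %s integer", name, if (positive) "positive" else "non-negative")
  }
  invisible(as.integer(x))
}

# Area under the ROC curve for a binary label and a numeric score.
# Thin wrapper around pROC with fixed direction so that higher score =
# higher predicted risk.
auc_binary <- function(label, score) {
  label <- as.integer(label)
  if (length(unique(label)) < 2L) {
    stopf("AUC undefined: labels contain a single class")
  }
  as.numeric(pROC::auc(
    response = label, predictor = as.numeric(score),
    levels = c(0L, 1L), direction = "<", quiet = TRUE
  ))
}

# R-squared of predictions against observations (1 - SSE/SST).
r_squared <- function(observed, predicted) {
  sst <- sum((observed - mean(observed))^2)
  if (sst == 0) stopf("R-squared undefined: constant outcome")
  1 - sum((observed - predicted)^2) / sst
}

# Mean absolute prediction error (Cumming's prediction measure).
mean_abs_error <- function(observed, predicted) {
  mean(abs(observed - predicted))
}
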