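# Class association rules explaining high-risk predictions.
#
# A rule is a conjunction of feature-value items ("items") implying the
# high-risk class. Support = fraction of ALL rows that satisfy the left side
# AND are high-risk; confidence = among rows satisfying the left side, the
# fraction that are high-risk. Rules with attached interventions are
# "actionable".

# ---- items ----------------------------------------------------------------

#' Create a rule item (feature-value pair)
#'
#' An item is either an equality condition on a categorical feature or a
#' half-open numeric interval `[lower, upper)`.
#'
#' @param feature Feature name.
#' @param value Category value (for equality items).
#' @param lower,upper Interval bounds (for range items); `-Inf`/`Inf`
#'   allowed, `lower < upper` required.
#' @return A `rule_item`.
#' @export
rule_item <- function(feature, value = NULL, lower = NULL, upper = NULL) {
  stopifnot(is.character(feature), length(feature) == 1L)
  if (!is.null(value)) {
    it <- list(feature = feature, kind = "eq", value = as.character(value))
    it$label <- sprintf("%s=%s", feature, it$value)
  } else {
    if (is.null(lower) || is.null(upper) || lower >= upper) {
      stopf("range item needs lower < upper")
    }
    it <- list(feature = feature, kind = "range", lower = lower, upper = upper)
    it$label <- sprintf("%s in [%g,%g)", feature, lower, upper)
  }
  structure(it, class = "rule_item")
}

# Logical vector: which rows of `data` satisfy the item. NA never satisfies.
item_satisfied <- function(item, data) {
  x <- data[[item$feature]]
  if (is.null(x)) stopf("feature `%s` not present in data", item$feature)
  if (item$kind == "eq") {
    out <- as.character(x) == item$value
  } else {
    x <- as.numeric(x)
    out <- x >= item$lower & x < item$upper
  }
  out & !is.na(out)
}

rule_lhs_satisfied <- function(items, data) {
  out <- rep(TRUE, nrow(data))
  for (it in items) out <- out & item_satisfied(it, data)
  out
}

rule_id_of <- function(items) {
  paste(sort(vapply(items, `[[`, "", "label")), collapse = " & ")
}

# ---- discretization -------------------------------------------------------

#' Discretize a feature matrix into candidate rule items
#'
#' Categorical (or low-cardinality) features yield one equality item per
#' observed level; numeric features are cut at quartiles into half-open
#' intervals `[low, high)` (outer bounds open to `-Inf`/`Inf`). Users can
#' restrict which values of a feature may appear in rules via `constraints`:
#' a named list whose entries are either a character vector of allowed
#' levels, or `"high"`/`"low"` to keep only the top/bottom interval of a
#' numeric feature.
#'
#' @param data Data frame of features (label columns excluded by the caller).
#' @param features Character vector of feature columns to discretize;
#'   defaults to all columns.
#' @param n_bins Number of quantile bins for numeric features (default 4,
#'   quartiles).
#' @param constraints Optional named list of per-feature value constraints.
#' @param max_levels A numeric column with at most this many distinct values
#'   is treated as categorical.
#' @return List of `rule_item` objects.
#' @export
discretize_features <- function(data, features = NULL, n_bins = 4L,
                                constraints = NULL, max_levels = 6L) {
  if (is.null(features)) features <- names(data)
  items <- list()
  for (f in features) {
    x <- data[[f]]
    if (is.null(x)) stopf("feature `%s` not present in data", f)
    cons <- constraints[[f]]
    if (is.numeric(x) && length(unique(x[!is.na(x)])) > max_levels) {
      qs <- unique(quantile(x, probs = seq(0, 1, length.out = n_bins + 1L),
                            na.rm = TRUE, names = FALSE))
      if (length(qs) < 2L) next  # constant feature: no informative item
      brk <- qs
      brk[1L] <- -Inf
      brk[length(brk)] <- Inf
      f_items <- lapply(seq_len(length(brk) - 1L), function(i) {
        rule_item(f, lower = brk[i], upper = brk[i + 1L])
      })
      if (!is.null(cons)) {
        if (identical(cons, "high")) f_items <- f_items[length(f_items)]
        else if (identical(cons, "low")) f_items <- f_items[1L]
        else stopf("numeric constraint for `%s` must be \"high\" or \"low\"", f)
      }
    } else {
      lv <- sort(unique(as.character(x[!is.na(x)])))
      if (!is.null(cons)) lv <- intersect(lv, as.character(cons))
      f_items <- lapply(lv, function(v) rule_item(f, value = v))
    }
    items <- c(items, f_items)
  }
  items
}

# ---- support / confidence -------------------------------------------------

#' Support and confidence of a rule's left side
#'
#' Support is the fraction of all rows that satisfy the left side and are
#' high-risk; confidence is, among rows satisfying the left side, the
#' fraction that are high-risk. Confidence is undefined (an error) when no
#' row satisfies the left side.
#'
#' @param items List of [rule_item()]s (the conjunction).
#' @param data Feature data frame containing `label_col`.
#' @param label_col Name of the binary high-risk column (0/1).
#' @return Named list `support`, `confidence`, `n_lhs`, `n_match`.
#' @examples
#' d <- data.frame(a = c(1,1,1,1,1,0,0,0,0,0),
#'                 high_risk = c(1,1,1,1,0,0,0,0,0,0))
#' compute_support_confidence(list(rule_item("a", value = "1")), d)
#' @export
compute_support_confidence <- function(items, data, label_col = "high_risk") {
  lab <- data[[label_col]]
  if (is.null(lab)) stopf("label column `%s` not found", label_col)
  lab <- as.integer(lab)
  sat <- rule_lhs_satisfied(items, data)
  n_lhs <- sum(sat)
  if (n_lhs == 0L) stopf("no row satisfies the rule's left side: confidence undefined")
  n_match <- sum(sat & lab == 1L)
  list(support = n_match / nrow(data), confidence = n_match / n_lhs,
       n_lhs = n_lhs, n_match = n_match)
}

make_rule <- function(items, support, confidence, n_lhs, n_match) {
  structure(list(
    items = items, id = rule_id_of(items), length = length(items),
    support = support, confidence = confidence,
    n_lhs = n_lhs, n_match = n_match,
    actionable = FALSE, interventions = character(0)
  ), class = "risk_rule")
}

#' @export
print.risk_rule <- function(x, ...) {
  cat(sprintf("<rule> %s => high risk  (supp %.3f, conf %.3f%s)\n",
              x$id, x$support, x$confidence,
              if (x$actionable) ", actionable" else ""))
  invisible(x)
}

#' @export
print.rule_set <- function(x, ...) {
  cat(sprintf("<rule_set> %d rules\n", length(x)))
  for (r in head(x, 10L)) print(r)
  if (length(x) > 10L) cat(sprintf("  ... and %d more\n", length(x) - 10L))
  invisible(x)
}

as_rule_set <- function(rules) structure(rules, class = c("rule_set", "list"))

# ---- mining ---------------------------------------------------------------

#' Mine class association rules for the high-risk class
#'
#' Level-wise (Apriori-style) enumeration of conjunctions of up to `max_len`
#' items whose support and confidence pass the thresholds. Because support
#' counts rows that satisfy the left side *and* are high-risk, the support
#' numerator is anti-monotone in the item set, so candidate itemsets are
#' grown only over items present in high-risk rows — a pure efficiency
#' device that cannot change the output (support and confidence are always
#' computed against the full matrix).
#'
#' @param data Feature data frame containing `label_col`.
#' @param label_col Binary high-risk column name.
#' @param min_support Minimum support (fraction of all rows), in `(0, 1]`.
#' @param min_confidence Minimum confidence, in `(0, 1]`.
#' @param max_len Maximum number of items per rule.
#' @param items Candidate items; defaults to
#'   `discretize_features(data[features], constraints = constraints)`.
#' @param features Feature columns to mine over (default: all except
#'   `label_col`).
#' @param constraints Per-feature value constraints, see
#'   [discretize_features()].
#' @param prune Drop redundant rules via [prune_redundant()] (default TRUE).
#' @return A `rule_set` (list of rules).
#' @export
mine_rules <- function(data, label_col = "high_risk",
                       min_support = 0.01, min_confidence = 0.70,
                       max_len = 4L, items = NULL, features = NULL,
                       constraints = NULL, prune = TRUE) {
  if (min_support <= 0 || min_support > 1) stopf("`min_support` must be in (0, 1]")
  if (min_confidence <= 0 || min_confidence > 1) stopf("`min_confidence` must be in (0, 1]")
  max_len <- check_count(max_len, "max_len")
  lab <- data[[label_col]]
  if (is.null(lab)) stopf("label column `%s` not found", label_col)
  lab <- as.integer(lab)
  n <- nrow(data)
  if (is.null(features)) features <- setdiff(names(data), label_col)
  if (is.null(items)) {
    items <- discretize_features(data[, features, drop = FALSE],
                                 constraints = constraints)
  }
  if (length(items) == 0L || sum(lab) == 0L) return(as_rule_set(list()))

  # Item indicator matrix over all rows.
  M <- vapply(items, item_satisfied, logical(n), data = data)
  M <- matrix(M, nrow = n)
  hr <- lab == 1L
  min_count <- ceiling(min_support * n - 1e-9)

  # Level 1: restrict to items meeting the support numerator on high-risk rows.
  feat_of <- vapply(items, `[[`, "", "feature")
  supp_num <- colSums(M & hr)
  keep <- which(supp_num >= min_count)
  if (length(keep) == 0L) return(as_rule_set(list()))

  rules <- list()
  emit <- function(idx_sets, ind_cols) {
    # idx_sets: list of item-index vectors; ind_cols: matrix of LHS indicators
    for (j in seq_along(idx_sets)) {
      sat <- ind_cols[, j]
      n_lhs <- sum(sat)
      n_match <- sum(sat & hr)
      conf <- n_match / n_lhs
      if (conf >= min_confidence - 1e-12) {
        rules[[length(rules) + 1L]] <<- make_rule(
          items[idx_sets[[j]]], support = n_match / n,
          confidence = conf, n_lhs = n_lhs, n_match = n_match
        )
      }
    }
  }

  cur_sets <- as.list(keep)
  cur_ind <- M[, keep, drop = FALSE]
  emit(cur_sets, cur_ind)

  len <- 1L
  while (len < max_len && length(cur_sets) > 1L) {
    # Apriori join: combine itemsets sharing their first len-1 items.
    prefixes <- vapply(cur_sets, function(s) paste(s[-length(s)], collapse = ","), "")
    lasts <- vapply(cur_sets, function(s) s[length(s)], 0L)
    freq_keys <- new.env(parent = emptyenv())
    for (s in cur_sets) assign(paste(s, collapse = ","), TRUE, envir = freq_keys)

    new_sets <- list()
    new_ind <- list()
    for (pref in unique(prefixes)) {
      grp <- which(prefixes == pref)
      if (length(grp) < 2L) next
      grp <- grp[order(lasts[grp])]
      for (a in seq_len(length(grp) - 1L)) {
        for (b in seq((a + 1L), length(grp))) {
          i1 <- grp[a]; i2 <- grp[b]
          cand <- c(cur_sets[[i1]], lasts[i2])
          # items on the same feature are mutually exclusive
          if (anyDuplicated(feat_of[cand])) next
          # all len-subsets must be frequent
          ok <- TRUE
          if (len >= 2L) {
            for (drop_i in seq_len(len + 1L)) {
              sub <- sort(cand[-drop_i])
              if (!exists(paste(sub, collapse = ","), envir = freq_keys)) {
                ok <- FALSE; break
              }
            }
          }
          if (!ok) next
          ind <- cur_ind[, i1] & M[, lasts[i2]]
          if (sum(ind & hr) >= min_count) {
            new_sets[[length(new_sets) + 1L]] <- cand
            new_ind[[length(new_ind) + 1L]] <- ind
          }
        }
      }
    }
    if (length(new_sets) == 0L) break
    cur_sets <- new_sets
    cur_ind <- matrix(unlist(new_ind), nrow = n)
    emit(cur_sets, cur_ind)
    len <- len + 1L
  }

  rules <- as_rule_set(rules)
  if (prune) rules <- prune_redundant(rules)
  rules
}

#' Drop rules dominated by a sub-rule
#'
#' A rule is removed iff a strict sub-rule (a rule whose items are a proper
#' subset of its items) exists in the set with confidence at least as high:
#' the longer rule then adds conditions without adding accuracy.
#'
#' @param rules A `rule_set`.
#' @return The pruned `rule_set`.
#' @export
prune_redundant <- function(rules) {
  if (length(rules) == 0L) return(as_rule_set(list()))
  labels <- lapply(rules, function(r) vapply(r$items, `[[`, "", "label"))
  lens <- vapply(rules, `[[`, 0L, "length")
  confs <- vapply(rules, `[[`, 0, "confidence")
  keep <- rep(TRUE, length(rules))
  for (i in seq_along(rules)) {
    for (j in seq_along(rules)) {
      if (i == j || lens[j] >= lens[i]) next
      if (all(labels[[j]] %in% labels[[i]]) && confs[j] >= confs[i]) {
        keep[i] <- FALSE
        break
      }
    }
  }
  as_rule_set(rules[keep])
}

# ---- interventions --------------------------------------------------------

#' Build an intervention registry
#'
#' @param interventions Data frame with columns `id`, `description`,
#'   `level` (`"patient"` or `"system"`), `cost_per_patient`, `p_benefit`
#'   (fraction of events the intervention avoids; used by the outcome
#'   simulator).
#' @param rule_map Named list: rule id (canonical sorted item string) ->
#'   character vector of intervention ids.
#' @return An `intervention_registry`.
#' @export
intervention_registry <- function(interventions, rule_map = list()) {
  need <- c("id", "description", "level", "cost_per_patient", "p_benefit")
  if (!all(need %in% names(interventions))) {
    stopf("`interventions` must have columns: %s", paste(need, collapse = ", "))
  }
  if (anyDuplicated(interventions$id)) stopf("intervention ids must be unique")
  if (!all(interventions$level %in% c("patient", "system"))) {
    stopf("intervention `level` must be \"patient\" or \"system\"")
  }
  unknown <- setdiff(unlist(rule_map), interventions$id)
  if (length(unknown)) stopf("rule_map references unknown interventions: %s",
                             paste(unknown, collapse = ", "))
  structure(list(interventions = interventions, rule_map = rule_map),
            class = "intervention_registry")
}

#' Attach interventions to mined rules
#'
#' Marks a rule actionable iff the registry maps its canonical id to at
#' least one intervention. Rules on a deny list (the modeled clinician
#' review) are dropped.
#'
#' @param rules A `rule_set`.
#' @param registry An [intervention_registry()].
#' @param deny Character vector of rule ids to drop.
#' @return The annotated `rule_set`.
#' @export
attach_interventions <- function(rules, registry, deny = character(0)) {
  stopifnot(inherits(registry, "intervention_registry"))
  out <- list()
  for (r in rules) {
    if (r$id %in% deny) next
    ivs <- registry$rule_map[[r$id]]
    if (!is.null(ivs) && length(ivs)) {
      r$actionable <- TRUE
      r$interventions <- ivs
    }
    out[[length(out) + 1L]] <- r
  }
  as_rule_set(out)
}

# ---- ranking and explanation ----------------------------------------------

#' Rank rules for display
#'
#' Actionable rules come before nonactionable ones; within each block rules
#' are ordered by descending confidence, then descending support, then
#' ascending length, with the canonical item string as a final
#' lexicographic tie-break so the order is a deterministic total order.
#'
#' @param rules A `rule_set`.
#' @return The sorted `rule_set`.
#' @export
rank_rules <- function(rules) {
  if (length(rules) == 0L) return(as_rule_set(list()))
  act <- vapply(rules, `[[`, TRUE, "actionable")
  conf <- vapply(rules, `[[`, 0, "confidence")
  supp <- vapply(rules, `[[`, 0, "support")
  len <- vapply(rules, `[[`, 0L, "length")
  id <- vapply(rules, `[[`, "", "id")
  ord <- order(-act, -conf, -supp, len, id, method = "radix")
  as_rule_set(rules[ord])
}

#' Build an inverted item index over a rule set
#'
#' Maps each item label to the rules containing it, so matching a patient
#' intersects posting lists instead of scanning every rule.
#'
#' @param rules A `rule_set`.
#' @return A `rule_index`.
#' @export
build_rule_index <- function(rules) {
  postings <- list()
  for (j in seq_along(rules)) {
    for (it in rules[[j]]$items) {
      postings[[it$label]] <- c(postings[[it$label]], j)
    }
  }
  structure(list(postings = postings, rules = rules,
                 lengths = vapply(rules, `[[`, 0L, "length")),
            class = "rule_index")
}

# Indices (into the index's rule set) of rules fully satisfied by the patient.
match_rules_index <- function(index, patient, data_items = NULL) {
  if (length(index$rules) == 0L) return(integer(0))
  hits <- integer(length(index$rules))
  for (lbl in names(index$postings)) {
    it <- NULL
    # locate one instance of the item to evaluate it on the patient row
    for (j in index$postings[[lbl]]) {
      for (cand in index$rules[[j]]$items) {
        if (cand$label == lbl) { it <- cand; break }
      }
      if (!is.null(it)) break
    }
    if (item_satisfied(it, patient)) {
      hits[index$postings[[lbl]]] <- hits[index$postings[[lbl]]] + 1L
    }
  }
  which(hits == index$lengths)
}

#' Explain a high-risk patient with matching rules
#'
#' Returns the top-`k` ranked rules whose every item the patient satisfies,
#' each carrying its confidence and attached interventions. A patient may
#' match no rule, in which case the explanation is empty.
#'
#' @param patient One-row data frame with the patient's feature values.
#' @param rules A ranked `rule_set` (see [rank_rules()]); ranking is applied
#'   if the set is not already sorted.
#' @param k Maximum number of rules to show (default 3).
#' @param show_all Return all matching rules regardless of `k`.
#' @param index Optional [build_rule_index()] over `rules` for fast matching.
#' @return A `rule_set` of matched rules in rank order.
#' @export
explain_patient <- function(patient, rules, k = 3L, show_all = FALSE,
                            index = NULL) {
  stopifnot(nrow(patient) == 1L)
  rules <- rank_rules(rules)
  if (!is.null(index)) {
    # index was built over some ordering; re-rank its matches
    m <- match_rules_index(index, patient)
    matched <- rank_rules(as_rule_set(index$rules[m]))
  } else {
    sat <- vapply(rules, function(r) all(rule_lhs_satisfied(r$items, patient)),
                  TRUE)
    matched <- as_rule_set(rules[sat])
  }
  if (!show_all && length(matched) > k) matched <- as_rule_set(matched[seq_len(k)])
  matched
}

#' Coverage of high-risk patients by actionable rules
#'
#' @param rules A `rule_set`.
#' @param data Feature data frame with the high-risk label.
#' @param label_col Binary label column name.
#' @return List: `coverage` (fraction of high-risk rows matched by at least
#'   one actionable rule) and `rule_matches` (per-rule count of matched
#'   high-risk rows).
#' @export
coverage_report <- function(rules, data, label_col = "high_risk") {
  hr <- as.integer(data[[label_col]]) == 1L
  n_hr <- sum(hr)
  covered <- rep(FALSE, nrow(data))
  matches <- integer(length(rules))
  for (j in seq_along(rules)) {
    sat <- rule_lhs_satisfied(rules[[j]]$items, data)
    matches[j] <- sum(sat & hr)
    if (rules[[j]]$actionable) covered <- covered | sat
  }
  list(
    coverage = if (n_hr == 0L) 0 else sum(covered & hr) / n_hr,
    rule_matches = setNames(matches, vapply(rules, `[[`, "", "id"))
  )
}

# ---- serialization --------------------------------------------------------

#' Write rules to JSON
#' @param rules A `rule_set`.
#' @param path Output file.
#' @export
write_rules <- function(rules, path) {
  ser <- lapply(rules, function(r) {
    list(
      id = r$id,
      items = lapply(r$items, function(it) {
        it_list <- unclass(it)
        # JSON has no Inf: open outer bounds are omitted and restored on read
        if (identical(it_list$kind, "range")) {
          if (is.infinite(it_list$lower)) it_list$lower <- NULL
          if (is.infinite(it_list$upper)) it_list$upper <- NULL
        }
        it_list[!vapply(it_list, is.null, TRUE)]
      }),
      support = r$support, confidence = r$confidence,
      n_lhs = r$n_lhs, n_match = r$n_match,
      actionable = r$actionable, interventions = r$interventions
    )
  })
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read rules from JSON written by [write_rules()]
#' @param path JSON file.
#' @return A `rule_set`.
#' @export
read_rules <- function(path) {
  ser <- jsonlite::read_json(path)
  as_rule_set(lapply(ser, function(s) {
    items <- lapply(s$items, function(it) {
      if (it$kind == "eq") {
        rule_item(it$feature, value = it$value)
      } else {
        # JSON has no Inf; open outer bounds round-trip as null
        lo <- if (is.null(it$lower)) -Inf else it$lower
        hi <- if (is.null(it$upper)) Inf else it$upper
        rule_item(it$feature, lower = lo, upper = hi)
      }
    })
    r <- make_rule(items, s$support, s$confidence, s$n_lhs, s$n_match)
    r$actionable <- isTRUE(s$actionable)
    r$interventions <- as.character(unlist(s$interventions))
    r
  }))
}
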