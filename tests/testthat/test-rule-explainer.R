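ten_row <- function() {
  # 5 rows satisfy a=1; 4 of those are high-risk
  data.frame(
    a = c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0),
    b = c(1, 0, 1, 0, 1, 1, 0, 1, 0, 0),
    high_risk = c(1, 1, 1, 1, 0, 0, 0, 0, 1, 0)
  )
}

test_that("support and confidence match direct counts on hand-built tables", {
  d <- ten_row()
  sc <- compute_support_confidence(list(rule_item("a", value = "1")), d)
  expect_equal(sc$support, 0.40)
  expect_equal(sc$confidence, 0.80)
  # LHS satisfied by all rows: both collapse to the prevalence
  d$all1 <- 1
  sc2 <- compute_support_confidence(list(rule_item("all1", value = "1")), d)
  expect_equal(sc2$support, 0.5)
  expect_equal(sc2$confidence, 0.5)
  # LHS satisfied only by high-risk rows
  d$only_hr <- as.integer(d$high_risk == 1)
  sc3 <- compute_support_confidence(list(rule_item("only_hr", value = "1")), d)
  expect_equal(sc3$confidence, 1.0)
  # empty LHS coverage is an explicit error, not NaN
  d$never <- 0
  expect_error(compute_support_confidence(list(rule_item("never", value = "1")), d),
               "undefined")
})

test_that("sub-rule dominance pruning drops exactly the dominated rules", {
  ia <- rule_item("A", value = "1")
  ib <- rule_item("B", value = "1")
  r1 <- stratikit:::make_rule(list(ia), 0.2, 0.9, 20, 18)
  r2 <- stratikit:::make_rule(list(ia, ib), 0.1, 0.85, 10, 8)
  pruned <- prune_redundant(stratikit:::as_rule_set(list(r1, r2)))
  expect_equal(vapply(pruned, `[[`, "", "id"), r1$id)
  # a longer rule that adds confidence is kept
  r3 <- stratikit:::make_rule(list(ia), 0.2, 0.7, 20, 14)
  r4 <- stratikit:::make_rule(list(ia, ib), 0.1, 0.95, 10, 9)
  kept <- prune_redundant(stratikit:::as_rule_set(list(r3, r4)))
  expect_equal(length(kept), 2L)
  expect_equal(length(prune_redundant(stratikit:::as_rule_set(list()))), 0L)
})

random_rule_set <- function(seed, n = 30L) {
  set.seed(seed)
  feats <- paste0("f", 1:6)
  rules <- lapply(seq_len(n), function(i) {
    k <- sample(1:3, 1L)
    its <- lapply(sample(feats, k), function(f)
      rule_item(f, value = as.character(sample(0:1, 1L))))
    r <- stratikit:::make_rule(its,
                               support = sample(c(0.02, 0.05, 0.1), 1L),
                               confidence = sample(c(0.7, 0.8, 0.9), 1L),
                               n_lhs = 10L, n_match = 8L)
    r$actionable <- runif(1) < 0.4
    r
  })
  stratikit:::as_rule_set(rules)
}

test_that("rule ranking is the documented deterministic total order", {
  for (s in 1:5) {
    rs <- rank_rules(random_rule_set(s))
    for (i in seq_len(length(rs) - 1L)) {
      a <- rs[[i]]; b <- rs[[i + 1L]]
      ka <- c(-as.numeric(a$actionable), -a$confidence, -a$support, a$length)
      kb <- c(-as.numeric(b$actionable), -b$confidence, -b$support, b$length)
      cmp <- sign(ka - kb)
      first <- cmp[cmp != 0][1]
      if (is.na(first)) {
        expect_true(a$id <= b$id)  # full tie: lexicographic item order
      } else {
        expect_equal(first, -1)
      }
    }
    # sorting twice and sorting a permuted input give identical sequences
    expect_identical(rule_signature(rank_rules(rs)), rule_signature(rs))
    set.seed(s)
    perm <- sample(seq_along(rs))
    rs2 <- rank_rules(stratikit:::as_rule_set(unclass(rs)[perm]))
    expect_identical(vapply(rs2, `[[`, "", "id"), vapply(rs, `[[`, "", "id"))
  }
})

test_that("actionable rules outrank nonactionable ones regardless of confidence", {
  ia <- rule_item("A", value = "1")
  act <- stratikit:::make_rule(list(ia), 0.05, 0.75, 10, 8)
  act$actionable <- TRUE
  non <- stratikit:::make_rule(list(rule_item("B", value = "1")), 0.2, 0.95, 20, 19)
  rs <- rank_rules(stratikit:::as_rule_set(list(non, act)))
  expect_true(rs[[1]]$actionable)
  # equal confidence: higher support first; then shorter rule first
  r_hi <- stratikit:::make_rule(list(ia), 0.05, 0.8, 10, 8)
  r_lo <- stratikit:::make_rule(list(rule_item("B", value = "1")), 0.02, 0.8, 5, 4)
  rs2 <- rank_rules(stratikit:::as_rule_set(list(r_lo, r_hi)))
  expect_equal(rs2[[1]]$support, 0.05)
  r_short <- stratikit:::make_rule(list(ia), 0.05, 0.8, 10, 8)
  r_long <- stratikit:::make_rule(list(rule_item("B", value = "1"),
                                       rule_item("C", value = "1")),
                                  0.05, 0.8, 10, 8)
  rs3 <- rank_rules(stratikit:::as_rule_set(list(r_long, r_short)))
  expect_equal(rs3[[1]]$length, 1L)
})

test_that("miner equals brute-force enumeration on a small binary matrix", {
  d <- random_rule_matrix(99, n_feat = 8, n_rows = 300)
  items <- discretize_features(d[setdiff(names(d), "high_risk")])
  mined <- mine_rules(d, items = items, min_support = 0.01,
                      min_confidence = 0.70, max_len = 4, prune = FALSE)
  brute <- brute_force_rules(d, items, min_support = 0.01,
                             min_confidence = 0.70, max_len = 4)
  expect_identical(rule_signature(mined), rule_signature(brute))
  # and after identical pruning
  expect_identical(rule_signature(prune_redundant(mined)),
                   rule_signature(prune_redundant(brute)))
})

test_that("the miner respects value constraints and degenerate inputs", {
  d <- random_rule_matrix(7, n_feat = 5, n_rows = 200)
  rs <- mine_rules(d, min_support = 0.01, min_confidence = 0.5, max_len = 2,
                   constraints = list(f1 = "1"))
  for (r in rs) {
    for (it in r$items) {
      if (it$feature == "f1") expect_equal(it$value, "1")
    }
  }
  d0 <- d
  d0$high_risk <- 0L
  expect_equal(length(mine_rules(d0)), 0L)
  expect_error(mine_rules(d, min_support = 0), "min_support")
  expect_error(mine_rules(d, min_confidence = 1.2), "min_confidence")
})

test_that("explanations return the top-k matched rules, index and scan agree", {
  d <- random_rule_matrix(13, n_feat = 8, n_rows = 400)
  rules <- mine_rules(d, min_support = 0.01, min_confidence = 0.4,
                      max_len = 3, prune = FALSE)
  expect_gt(length(rules), 5)
  rules <- rank_rules(rules)
  idx <- build_rule_index(rules)
  for (i in c(1, 5, 10, 50)) {
    pt <- d[i, , drop = FALSE]
    via_scan <- explain_patient(pt, rules, show_all = TRUE)
    via_index <- explain_patient(pt, rules, show_all = TRUE, index = idx)
    expect_identical(rule_signature(via_scan), rule_signature(via_index))
    top3 <- explain_patient(pt, rules, k = 3)
    expect_lte(length(top3), 3L)
    if (length(via_scan) >= 3L) {
      expect_identical(vapply(top3, `[[`, "", "id"),
                       vapply(via_scan[1:3], `[[`, "", "id"))
    }
  }
  # a patient matching nothing gets an empty explanation
  pt_none <- d[1, , drop = FALSE]
  pt_none[1, ] <- -99
  expect_equal(length(explain_patient(pt_none, rules, show_all = TRUE)), 0L)
})

test_that("interventions flag actionability and drive coverage", {
  d <- ten_row()
  rules <- mine_rules(d, min_support = 0.05, min_confidence = 0.6,
                      max_len = 2, prune = TRUE)
  expect_gt(length(rules), 0)
  # before any registry mapping: no actionable rules, coverage 0
  cov0 <- coverage_report(rules, d)
  expect_equal(cov0$coverage, 0)
  reg <- intervention_registry(
    data.frame(id = "iv1", description = "action plan review",
               level = "patient", cost_per_patient = 100, p_benefit = 0.2,
               stringsAsFactors = FALSE),
    rule_map = setNames(list("iv1"), rules[[1]]$id)
  )
  rules2 <- attach_interventions(rules, reg)
  act <- vapply(rules2, `[[`, TRUE, "actionable")
  expect_equal(sum(act), 1L)
  cov <- coverage_report(rules2, d)
  # manual count: high-risk rows matched by the actionable rule
  sat <- stratikit:::rule_lhs_satisfied(rules2[[which(act)]]$items, d)
  expect_equal(cov$coverage, sum(sat & d$high_risk == 1) / sum(d$high_risk == 1))
  # deny list models the clinician review
  rules3 <- attach_interventions(rules, reg, deny = rules[[1]]$id)
  expect_equal(length(rules3), length(rules) - 1L)
})

test_that("rules round-trip through JSON", {
  d <- random_rule_matrix(21, n_feat = 6, n_rows = 150)
  d$num <- rnorm(150)  # force one quartile-binned numeric feature
  rules <- mine_rules(d, min_support = 0.01, min_confidence = 0.4, max_len = 2)
  path <- tempfile(fileext = ".json")
  write_rules(rules, path)
  back <- read_rules(path)
  expect_identical(rule_signature(rules), rule_signature(back))
})

test_that("every stored rule satisfies its thresholds when recomputed from scratch", {
  d <- random_rule_matrix(31, n_feat = 10, n_rows = 400)
  rules <- mine_rules(d, min_support = 0.02, min_confidence = 0.6, max_len = 3)
  for (r in rules) {
    sc <- compute_support_confidence(r$items, d)
    expect_equal(sc$support, r$support)
    expect_equal(sc$confidence, r$confidence)
    expect_gte(sc$support, 0.02)
    expect_gte(sc$confidence, 0.6)
    # support can never exceed the high-risk prevalence
    expect_lte(sc$support, mean(d$high_risk))
  }
})
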