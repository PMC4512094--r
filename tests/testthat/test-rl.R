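# Statistics ----------------------------------------------------------------

test_that("certainty factor estimators match their formulas", {
  expect_equal(certainty_factor(0, 0, "laplace", 2L), 0.5)
  expect_equal(certainty_factor(0, 0, "precision"), 0)
  expect_equal(certainty_factor(56, 4, "precision"), 56 / 60)
  expect_equal(certainty_factor(56, 4, "laplace", 2L), 57 / 62)
  expect_error(certainty_factor(-1, 0), "negative")
})

test_that("Fisher enrichment tail matches table enumeration", {
  expect_equal(fisher_exact_p(0, 0, 3, 5), 1)
  expect_equal(fisher_exact_p(2, 0, 0, 2), 1 / 6)
  set.seed(8)
  for (rep in 1:60) {
    cells <- as.integer(stats::rmultinom(1, size = sample(4:12, 1),
                                         prob = rep(1 / 4, 4)))
    got <- fisher_exact_p(cells[1], cells[2], cells[3], cells[4])
    want <- oracle_fisher(cells[1], cells[2], cells[3], cells[4])
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("rule statistics count matches and non-matches correctly", {
  ds <- worked_example_dataset()
  rule <- trlfm:::new_rule(c("gene1", "gene2"), c(2L, 1L), "Case")
  r <- rule_statistics(rule, ds)
  expect_equal(r$tp, 56L)
  expect_equal(r$fp, 4L)
  expect_equal(r$coverage, 60L)
  expect_equal(r$cf, 57 / 62)

  none <- rule_statistics(trlfm:::new_rule(c("gene1", "gene2"), c(2L, 2L),
                                           "Case"), ds)
  expect_equal(c(none$tp, none$fp, none$coverage), c(0L, 0L, 0L))
  expect_equal(none$p, 1)

  expect_error(rule_statistics(trlfm:::new_rule("nope", 1L, "Case"), ds),
               "unknown variable")
})

test_that("single-conjunct statistics equal exhaustive per-instance checks", {
  set.seed(3)
  ds <- random_toy_dataset(n_vars = 2L, n_samples = 8L)
  for (v in ds$variable_names) {
    for (iv in 1:2) {
      for (cl in ds$class_domain) {
        r <- rule_statistics(trlfm:::new_rule(v, iv, cl), ds)
        match <- ds$values[, v] == iv
        expect_equal(r$tp, sum(match & ds$class_labels == cl))
        expect_equal(r$fp, sum(match & ds$class_labels != cl))
        expect_equal(r$coverage, r$tp + r$fp)
      }
    }
  }
})

# Seeding and specialization -------------------------------------------------

test_that("each discretized marker value spawns one rule per class", {
  ds1 <- random_toy_dataset(n_vars = 1L, n_samples = 6L)
  expect_length(initial_rules(ds1), 1L * 2L * 2L)
  ds3 <- random_toy_dataset(n_vars = 3L, n_samples = 6L)
  rules <- initial_rules(ds3)
  expect_length(rules, 3L * 2L * 2L)
  # two rules per variable-interval pair, one per class
  keys <- table(vapply(rules, function(r) {
    paste(r$vars, r$intervals, sep = "=")
  }, character(1)))
  expect_true(all(keys == 2L))
  ds0 <- trlfm_dataset(matrix(integer(0), nrow = 4, ncol = 0),
                       class_labels = c("Case", "Case", "Control", "Control"),
                       discrete = TRUE, intervals = integer(0))
  expect_length(initial_rules(ds0), 0L)
})

test_that("specialization extends by one fresh conjunct, coverage shrinks", {
  set.seed(5)
  ds <- random_toy_dataset(n_vars = 3L, n_samples = 8L)
  base <- rule_statistics(trlfm:::new_rule("v1", 1L, "Case"), ds)
  kids <- specialize(base, ds, max_conjuncts = 3L)
  expect_length(kids, 2L * 2L)  # 2 other binary variables
  for (k in kids) {
    expect_length(k$vars, 2L)
    expect_false(anyDuplicated(k$vars) > 0)
    expect_lte(k$coverage, base$coverage)
  }
  maxed <- rule_statistics(trlfm:::new_rule(c("v1", "v2", "v3"),
                                            c(1L, 1L, 1L), "Case"), ds)
  expect_length(specialize(maxed, ds, max_conjuncts = 3L), 0L)
})

test_that("good-rule criteria apply their boundary conventions", {
  ds <- worked_example_dataset()
  r <- rule_statistics(trlfm:::new_rule(c("gene1", "gene2"), c(2L, 1L),
                                        "Case"), ds)
  crit_eq <- rule_criteria(min_cf = 57 / 62, min_coverage = 60L,
                           max_fp_rate = 4 / 34)
  expect_true(is_good(r, crit_eq, ds))  # cf and coverage exactly at bound
  expect_false(is_good(r, rule_criteria(min_cf = 0.95), ds))
  expect_false(is_good(r, rule_criteria(min_cf = 0, min_coverage = 61L,
                                        max_fp_rate = 1), ds))
  zero <- rule_statistics(trlfm:::new_rule(c("gene1", "gene2"), c(2L, 2L),
                                           "Case"), ds)
  expect_false(is_good(zero, rule_criteria(min_cf = 0, min_coverage = 1L,
                                           max_fp_rate = 1), ds))
})

# Beam search ----------------------------------------------------------------

test_that("unbounded beam equals exhaustive search under monotone criteria", {
  set.seed(17)
  crit <- rule_criteria(min_cf = 0, min_coverage = 1L, max_fp_rate = 1,
                        max_conjuncts = 3L, inductive_strengthening = 0L,
                        beam_width = 100000L)
  for (rep in 1:15) {
    ds <- random_toy_dataset(n_vars = sample(2:3, 1L),
                             n_samples = sample(5:8, 1L))
    model <- learn_rules(ds, crit)
    got <- sort(vapply(model$rules, trlfm:::rule_key, character(1)))
    expect_equal(got, oracle_rule_search(ds, crit))
  }
})

test_that("the best learned rule matches exhaustive search's best rule", {
  set.seed(23)
  ds <- random_toy_dataset(n_vars = 2L, n_samples = 6L)
  crit <- rule_criteria(min_cf = 0, min_coverage = 1L, max_fp_rate = 1,
                        max_conjuncts = 2L, inductive_strengthening = 0L,
                        beam_width = 100000L)
  model <- learn_rules(ds, crit)
  expect_true(trlfm:::rule_key(model$rules[[1L]]) %in%
                oracle_rule_search(ds, crit))
  # model rules arrive in beam order: non-increasing (cf, coverage)
  cfs <- vapply(model$rules, `[[`, numeric(1), "cf")
  covs <- vapply(model$rules, function(r) as.numeric(r$coverage), numeric(1))
  expect_true(all(diff(cfs) < 1e-12))
  same_cf <- abs(diff(cfs)) < 1e-12
  expect_true(all(diff(covs)[same_cf] <= 0))
})

test_that("degenerate criteria give empty models; perfect markers are found", {
  ds <- random_toy_dataset(n_vars = 2L, n_samples = 6L)
  strict <- rule_criteria(min_cf = 0, min_coverage = 100L, max_fp_rate = 1)
  expect_length(learn_rules(ds, strict)$rules, 0L)

  vals <- cbind(marker = c(1L, 1L, 1L, 2L, 2L, 2L, 2L, 1L))
  labels <- c(rep("Case", 3), rep("Control", 4), "Case")
  vals[8L, 1L] <- 1L
  perfect <- trlfm_dataset(vals, labels, discrete = TRUE,
                           intervals = c(marker = 2L))
  model <- learn_rules(perfect, rule_criteria(min_cf = 0.8,
                                              min_coverage = 3L,
                                              max_fp_rate = 0))
  keys <- vapply(model$rules, trlfm:::rule_key, character(1))
  expect_true("marker=1=>Case" %in% keys)
  expect_true(all(vapply(model$rules, function(r) r$fp == 0L, logical(1))))
})

test_that("beam search is deterministic and respects its invariants", {
  set.seed(29)
  ds <- random_toy_dataset(n_vars = 3L, n_samples = 8L)
  crit <- rule_criteria(min_cf = 0.5, min_coverage = 2L, max_fp_rate = 0.5,
                        beam_width = 10L, inductive_strengthening = 0L)
  m1 <- learn_rules(ds, crit)
  m2 <- learn_rules(ds, crit)
  expect_identical(m1$rules, m2$rules)
  expect_lte(length(m1$rules), crit$beam_width)
  for (r in m1$rules) {
    expect_true(is_good(r, crit, ds))
    expect_equal(r$coverage, r$tp + r$fp)
  }
})

test_that("inductive strengthening drops rules adding no new true positives", {
  # v1 and v2 are identical predictors; with strengthening 1 only one of the
  # equally-ranked duplicated rules enters the model
  vals <- cbind(v1 = rep(c(1L, 2L), each = 4), v2 = rep(c(1L, 2L), each = 4))
  ds <- trlfm_dataset(vals, rep(c("Case", "Control"), each = 4),
                      discrete = TRUE, intervals = c(v1 = 2L, v2 = 2L))
  crit <- function(is) rule_criteria(min_cf = 0.8, min_coverage = 4L,
                                     max_fp_rate = 0, max_conjuncts = 1L,
                                     inductive_strengthening = is)
  with_is <- learn_rules(ds, crit(1L))
  without_is <- learn_rules(ds, crit(0L))
  expect_equal(length(without_is$rules), 4L)
  expect_equal(length(with_is$rules), 2L)
  expect_setequal(vapply(with_is$rules, `[[`, character(1), "class"),
                  c("Case", "Control"))
})

# Prediction -----------------------------------------------------------------

test_that("prediction votes by CF and abstains without a match", {
  ds <- trlfm_dataset(cbind(v1 = c(1L, 2L, 3L)),
                      c("Case", "Control", "Case"),
                      class_domain = c("Case", "Control"),
                      discrete = TRUE, intervals = c(v1 = 3L))
  mk <- function(iv, cl, cf) {
    r <- trlfm:::new_rule("v1", iv, cl, tp = 1L, fp = 0L)
    r$cf <- cf
    r
  }
  model <- trlfm:::new_rule_model(
    list(mk(1L, "Case", 0.8), mk(1L, "Case", 0.7), mk(1L, "Control", 0.9),
         mk(2L, "Case", 0.9)),
    rule_criteria(), list(class_domain = c("Case", "Control")))
  pred <- predict(model, ds)
  expect_equal(pred$prediction, c("Case", "Case", "ABSTAIN"))
  expect_equal(pred$score, c(0.8 + 0.7 - 0.9, 0.9, 0))
})
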