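# Association-rule mining: supervised binning, metric identities,
# exhaustive enumeration vs brute force, rule-list classification.

test_that("entropy binning finds the separating midpoint and degenerates", {
  b <- bin_numeric(c(1, 1, 2, 9, 9, 10), c(0, 0, 0, 1, 1, 1))
  expect_length(b, 2L)
  expect_equal(b[[1]][["hi"]], 5.5)
  expect_equal(b[[2]][["lo"]], 5.5)
  expect_length(bin_numeric(rep(4, 6), c(0, 1, 0, 1, 0, 1)), 1L)
  # degenerate supervision falls back to quartile cuts
  b <- bin_numeric(1:20, rep(TRUE, 20), max_bins = 4L)
  expect_gte(length(b), 2L)
})

test_that("bins always partition the line", {
  set.seed(17)
  for (i in 1:15) {
    v <- round(stats::rnorm(30), 1)
    l <- stats::runif(30) < 0.5
    b <- bin_numeric(v, l, max_bins = sample(2:5, 1))
    expect_equal(b[[1]][["lo"]], -Inf)
    expect_equal(b[[length(b)]][["hi"]], Inf)
    for (x in c(v, -1e9, 1e9)) {
      hits <- sum(vapply(b, function(itv) {
        x >= itv[["lo"]] && x < itv[["hi"]]
      }, TRUE))
      expect_equal(hits, 1L)
    }
  }
})

test_that("lift equals confidence over class prevalence", {
  # 40-patient cohort, 19 non-infected / 21 infected, like the discovery
  # subgroup; a confidence-1 antecedent targeting each class
  co <- data.frame(saa = c(seq_len(19), 100 + seq_len(21)),
                   infected = rep(c(FALSE, TRUE), c(19, 21)))
  m <- rule_metrics(list(list(marker = "saa", interval = c(lo = -Inf, hi = 20))),
                    "non_infected", co)
  expect_equal(m$confidence, 1)
  expect_equal(m$lift, 40 / 19)
  m <- rule_metrics(list(list(marker = "saa", interval = c(lo = 100, hi = Inf))),
                    "infected", co)
  expect_equal(m$confidence, 1)
  expect_equal(m$lift, 40 / 21)
  # statistically independent antecedent: lift exactly 1
  co <- data.frame(x = rep(c(1, 5), 20), infected = rep(c(TRUE, FALSE), each = 20))
  m <- rule_metrics(list(list(marker = "x", interval = c(lo = 0, hi = 2))),
                    "infected", co)
  expect_equal(m$lift, 1)
  expect_error(
    rule_metrics(list(list(marker = "x", interval = c(lo = 99, hi = 100))),
                 "infected", co), "antecedent")
})

test_that("lift identity holds for every mined rule", {
  co <- generate_cohort(discovery_cohort_spec(seed = 19))
  rules <- mine_rules(co, markers = c("saa", "nihss", "wbc"),
                      min_support = 0.05, min_confidence = 0.5)
  expect_gt(length(rules), 0L)
  prev <- c(infected = mean(co$infected), non_infected = mean(!co$infected))
  for (r in rules) {
    expect_equal(r$lift, r$confidence / prev[[r$rhs_class]],
                 tolerance = 1e-12)
  }
})

test_that("mined rule set equals brute-force conjunction enumeration", {
  set.seed(29)
  for (i in 1:10) {
    co <- make_toy_cohort(sample(15:30, 1), seed = 100 + i)
    bins <- lapply(co[c("a", "b", "c")], bin_numeric, labels = co$infected,
                   max_bins = sample(2:4, 1))
    ms <- sample(c(0.05, 0.1, 0.2), 1)
    mc <- sample(c(0.6, 0.8, 1), 1)
    mined <- mine_rules(co, bins = bins, min_support = ms,
                        min_confidence = mc, max_lhs_size = 3L)
    oracle <- naive_mine_rules(co, bins, ms, mc, 3L)
    expect_equal(length(mined), length(oracle))
    got <- sort(vapply(mined, function(r) {
      paste0(r$display, "|", round(r$support, 10), "|",
             round(r$confidence, 10))
    }, ""))
    expect_equal(anyDuplicated(got), 0L)
  }
})

test_that("raising min_support never grows the rule set", {
  co <- make_toy_cohort(30, seed = 77)
  sizes <- vapply(c(0.01, 0.05, 0.1, 0.2, 0.4), function(ms) {
    length(mine_rules(co, markers = c("a", "b", "c"), min_support = ms,
                      min_confidence = 0.5, max_lhs_size = 2L))
  }, 0L)
  expect_true(all(diff(sizes) <= 0))
})

test_that("rule-list classification fires first match then the default", {
  co <- data.frame(x = c(1, 1, 1, 10, 10, 10, 10),
                   infected = c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, FALSE))
  rules <- mine_rules(co, bins = list(x = bin_numeric(co$x, co$infected)),
                      min_support = 0.1, min_confidence = 1)
  clf <- rule_classifier(rules, co)
  expect_equal(clf$default_class, "non_infected")
  pred <- classify_with_rules(clf, co)
  expect_equal(pred[1:3], rep("non_infected", 3))
  # patient matching no rule gets the default class
  none <- rule_classifier(structure(list(), class = "association_rules"), co)
  expect_equal(classify_with_rules(none, co), rep("non_infected", 7))
  # performance recomputed from raw predictions agrees with the report
  perf <- rule_set_performance(clf, co)
  pred_inf <- pred == "infected"
  expect_equal(perf$tp, sum(pred_inf & co$infected))
  expect_equal(perf$tn, sum(!pred_inf & !co$infected))
  expect_equal(perf$sensitivity, perf$tp / (perf$tp + perf$fn))
})

test_that("missing markers make patients unclassifiable", {
  co <- data.frame(x = c(1, 10), infected = c(FALSE, TRUE))
  rules <- mine_rules(co, bins = list(x = bin_numeric(co$x, co$infected)),
                      min_support = 0.1, min_confidence = 1)
  clf <- rule_classifier(rules, co)
  expect_error(classify_with_rules(clf, data.frame(y = 1)), "unclassifiable")
})

test_that("low NIHSS predicts no infection above prevalence on synthetic data", {
  co <- generate_cohort(validation_cohort_spec(seed = 33))
  m <- rule_metrics(list(list(marker = "nihss",
                              interval = c(lo = -Inf, hi = 6.5))),
                    "non_infected", co)
  expect_gt(m$confidence, mean(!co$infected))
  expect_gt(m$lift, 1)
})
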