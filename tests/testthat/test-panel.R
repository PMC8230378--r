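# k-of-n panels: voting semantics on the published threshold rules,
# grid construction, exhaustive search vs naive enumeration, refitting.

published_high_se_val <- panel_rule(list(
  threshold_condition("wbc", ">", 10),
  threshold_condition("saa", ">", 10.6),
  threshold_condition("nihss", ">", 6.5)), min_votes = 1L)

published_high_sp_val <- panel_rule(list(
  threshold_condition("wbc", ">", 13.33),
  threshold_condition("saa", ">", 41),
  threshold_condition("nihss", ">", 17.5)), min_votes = 2L)

test_that("panel voting follows the published threshold rules", {
  p1 <- data.frame(wbc = 8, saa = 5, nihss = 4)
  r <- apply_panel(published_high_se_val, p1)
  expect_equal(r$votes, 0L)
  expect_equal(r$predicted, "non_infected")
  p2 <- data.frame(wbc = 13, saa = 5, nihss = 4)
  r <- apply_panel(published_high_se_val, p2)
  expect_equal(r$votes, 1L)
  expect_equal(r$predicted, "infected")
  p3 <- data.frame(wbc = 14, saa = 50, nihss = 10)
  r <- apply_panel(published_high_sp_val, p3)
  expect_equal(r$votes, 2L)
  expect_equal(r$predicted, "infected")
  expect_error(apply_panel(published_high_se_val, data.frame(wbc = 1)),
               "unclassifiable")
  expect_error(panel_rule(list(threshold_condition("wbc", ">", 1)),
                          min_votes = 2L), "min_votes")
})

test_that("panel performance covers the trivial corners and recounts", {
  co <- generate_cohort(discovery_cohort_spec(seed = 61))
  always <- panel_rule(list(threshold_condition("saa", ">", -1)), 1L)
  p <- panel_performance(always, co)
  expect_equal(p$sensitivity, 1)
  expect_equal(p$specificity, 0)
  never <- panel_rule(list(threshold_condition("saa", ">", 1e9),
                           threshold_condition("wbc", ">", 1e9)), 2L)
  p <- panel_performance(never, co)
  expect_equal(p$sensitivity, 0)
  expect_equal(p$specificity, 1)
  # independent per-patient recount
  res <- apply_panel(published_high_se_val, co)
  p <- panel_performance(published_high_se_val, co)
  expect_equal(p$tp, sum(res$predicted == "infected" & co$infected))
  expect_equal(p$tn, sum(res$predicted == "non_infected" & !co$infected))
  expect_equal(p$tp + p$fp + p$tn + p$fn, nrow(co))
  # missing markers are excluded and counted
  co$saa[1:3] <- NA
  p <- panel_performance(published_high_se_val, co)
  expect_equal(p$n_unclassified, 3L)
  expect_equal(p$tp + p$fp + p$tn + p$fn, nrow(co) - 3L)
})

test_that("candidate threshold grids are midpoints, thinned under a cap", {
  expect_equal(candidate_thresholds(c(1, 2, 3)), c(1.5, 2.5))
  expect_equal(candidate_thresholds(c(3, 1, 2, 2)), c(1.5, 2.5))
  expect_length(candidate_thresholds(rep(5, 4)), 0L)
  full <- candidate_thresholds(1:101, cap = 200L)
  thin <- candidate_thresholds(1:101, cap = 10L)
  expect_length(thin, 10L)
  expect_true(all(thin %in% full))
  expect_true(all(diff(thin) > 0))
  expect_equal(thin[1], full[1])
  expect_equal(thin[10], full[length(full)])
})

test_that("single-marker search agrees with the ROC cutoff module", {
  set.seed(91)
  for (i in 1:8) {
    co <- make_toy_cohort(30, seed = 700 + i, shift = 2)
    r <- roc_curve(co$a, co$infected)
    ch <- cutoff_at_min_sensitivity(r, 0.9)
    res <- exhaustive_search(co, "a", mode = "high-se", s = 0.9,
                             grid_cap = 100L)
    if (res$feasible && !ch$low_information) {
      expect_equal(res$performance$sensitivity, ch$sensitivity)
      expect_equal(res$performance$specificity, ch$specificity)
    }
  }
})

test_that("a separating marker yields a perfect panel", {
  co <- data.frame(a = c(1, 2, 3, 10, 11, 12), b = stats::rnorm(6),
                   infected = rep(c(FALSE, TRUE), each = 3))
  res <- exhaustive_search(co, c("a", "b"), mode = "high-se", s = 0.95)
  expect_true(res$feasible)
  expect_equal(res$performance$sensitivity, 1)
  expect_equal(res$performance$specificity, 1)
  expect_length(res$panel$conditions, 1L)  # fewer markers preferred on ties
  expect_equal(res$panel$conditions[[1]]$marker, "a")
})

test_that("search equals naive enumeration across random instances", {
  for (i in 1:30) {
    co <- make_toy_cohort(sample(10:24, 1), seed = 800 + i)
    s <- stats::runif(1, 0.5, 1)
    cap <- sample(3:10, 1)
    mode <- sample(c("high-se", "high-sp"), 1)
    want <- naive_panel_search(co, c("a", "b", "c"), mode, s, cap)
    got <- exhaustive_search(co, c("a", "b", "c"), mode = mode, s = s,
                             grid_cap = cap)
    if (is.null(want)) {
      expect_false(got$feasible)
    } else {
      expect_true(got$feasible)
      gobj <- if (mode == "high-se") got$performance$specificity else
        got$performance$sensitivity
      gsec <- if (mode == "high-se") got$performance$sensitivity else
        got$performance$specificity
      expect_equal(gobj, want$obj, tolerance = 1e-12)
      expect_equal(gsec, want$sec, tolerance = 1e-12)
    }
  }
})

test_that("raising the constraint never improves the optimum", {
  co <- make_toy_cohort(40, seed = 888, shift = 1.5)
  sps <- c()
  for (s in c(0.6, 0.8, 0.9, 0.95, 1)) {
    res <- exhaustive_search(co, c("a", "b"), mode = "high-se", s = s,
                             grid_cap = 10L)
    sps <- c(sps, if (res$feasible) res$performance$specificity else NA)
  }
  sps <- sps[!is.na(sps)]
  expect_true(all(diff(sps) <= 1e-12))
})

test_that("search is deterministic and reports infeasibility honestly", {
  co <- make_toy_cohort(20, seed = 999)
  a <- exhaustive_search(co, c("a", "b"), mode = "high-se", s = 0.9,
                         grid_cap = 8L)
  b <- exhaustive_search(co, c("a", "b"), mode = "high-se", s = 0.9,
                         grid_cap = 8L)
  expect_identical(a$panel, b$panel)
  # an unattainable constraint: SP = 1 with overlapping classes
  co2 <- data.frame(a = c(1, 2, 1, 2), infected = c(TRUE, FALSE, FALSE, TRUE))
  res <- exhaustive_search(co2, "a", mode = "high-sp", s = 1)
  expect_false(res$feasible)
  expect_s3_class(res$panel, "panel_rule")
  expect_error(exhaustive_search(data.frame(a = rep(1, 4),
                                            infected = c(TRUE, FALSE, TRUE,
                                                         FALSE)), "a"),
               "empty grid")
})

test_that("refit on a fixed marker set matches the unrestricted search", {
  co <- make_toy_cohort(30, seed = 123, shift = 1)
  full <- exhaustive_search(co, c("a", "b"), mode = "high-se", s = 0.9,
                            grid_cap = 8L, max_panel_size = 2L)
  # restricting to the full candidate set can only do at least as well as
  # any panel limited to exactly that set
  ref <- refit_thresholds(c("a", "b"), co, mode = "high-se", s = 0.9,
                          grid_cap = 8L)
  if (full$feasible && ref$feasible) {
    expect_gte(full$performance$specificity,
               ref$performance$specificity - 1e-12)
  }
  # refit with the search's own marker set reproduces its operating point
  pm <- sort(vapply(full$panel$conditions, `[[`, "", "marker"))
  ref2 <- refit_thresholds(pm, co, mode = "high-se", s = 0.9, grid_cap = 8L)
  expect_equal(ref2$performance$specificity, full$performance$specificity)
  expect_equal(ref2$performance$sensitivity, full$performance$sensitivity)
})

test_that("refit panels honor the sensitivity constraint when feasible", {
  for (seed in c(5, 6, 7)) {
    co <- generate_cohort(validation_cohort_spec(seed = seed))
    res <- refit_thresholds(c("saa", "wbc", "nihss"), co, mode = "high-se",
                            s = 0.95, grid_cap = 25L)
    if (res$feasible) {
      expect_gte(res$performance$sensitivity, 0.95 - 1e-12)
    }
  }
})

test_that("lower-is-infected directions are supported", {
  co <- data.frame(a = c(10, 9, 8, 1, 2, 3),
                   infected = rep(c(FALSE, TRUE), each = 3))
  res <- exhaustive_search(co, "a", mode = "high-se", s = 0.95,
                           directions = c(a = "<"))
  expect_true(res$feasible)
  expect_equal(res$performance$sensitivity, 1)
  expect_equal(res$performance$specificity, 1)
  expect_equal(res$panel$conditions[[1]]$op, "<")
})
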