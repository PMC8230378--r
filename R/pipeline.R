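# End-to-end study pipeline: generate (or load) discovery and validation
# cohorts, let each white-box method select its markers on discovery,
# re-estimate rules/trees/thresholds on validation restricted to the
# selected markers, and report per-method performance on both subgroups.

#' Study configuration
#'
#' @param discovery,validation Either a [cohort_spec()] or a path to a
#'   cohort CSV.
#' @param seed Master seed; cohort seeds derive from it when specs are
#'   given.
#' @param candidate_markers Markers offered to every method.
#' @param panel_modes Panel-search objectives to run.
#' @param panel_s Constraint level for the panel search.
#' @param grid_cap Cutoff-grid cap per marker.
#' @param max_panel_size Maximum panel size.
#' @param rules_min_confidence,rules_min_support,rules_max_lhs Rule-mining
#'   constraints on the discovery subgroup.
#' @param rules_val_min_confidence,rules_val_min_support Relaxed constraints
#'   when re-mining on the (larger, lower-prevalence) validation subgroup,
#'   where perfectly confident rules and high supports are unattainable.
#' @param rules_n_markers Number of markers the rules method carries into
#'   validation (the highest-lift markers among the discovery rules).
#' @param tree_min_leaf_discovery,tree_min_leaf_validation Terminal-node
#'   size regularization per subgroup.
#' @return A list of class `study_config`.
#' @export
study_config <- function(discovery = discovery_cohort_spec(),
                         validation = validation_cohort_spec(),
                         seed = 1L,
                         candidate_markers = c("saa", "crp", "pct", "wbc",
                                               "monocytes", "nihss",
                                               "temperature"),
                         panel_modes = c("high-se", "high-sp"),
                         panel_s = 0.95, grid_cap = 25L, max_panel_size = 3L,
                         rules_min_confidence = 1, rules_min_support = 0.1,
                         rules_max_lhs = 2L, rules_val_min_confidence = 0.5,
                         rules_val_min_support = 0.02, rules_n_markers = 3L,
                         tree_min_leaf_discovery = 4L,
                         tree_min_leaf_validation = 9L) {
  structure(list(discovery = discovery, validation = validation,
                 seed = as.integer(seed),
                 candidate_markers = candidate_markers,
                 panel_modes = panel_modes, panel_s = panel_s,
                 grid_cap = grid_cap, max_panel_size = max_panel_size,
                 rules_min_confidence = rules_min_confidence,
                 rules_min_support = rules_min_support,
                 rules_max_lhs = rules_max_lhs,
                 rules_val_min_confidence = rules_val_min_confidence,
                 rules_val_min_support = rules_val_min_support,
                 rules_n_markers = as.integer(rules_n_markers),
                 tree_min_leaf_discovery = tree_min_leaf_discovery,
                 tree_min_leaf_validation = tree_min_leaf_validation),
            class = "study_config")
}

resolve_cohort <- function(x, seed_offset, master_seed) {
  if (inherits(x, "cohort_spec")) {
    generate_cohort(x, seed = (master_seed * 1000L + seed_offset) %% .Machine$integer.max)
  } else if (is.character(x)) {
    read_cohort_csv(x)
  } else if (is.data.frame(x)) {
    x
  } else {
    stop("cohort input must be a cohort_spec, a CSV path, or a data.frame")
  }
}

check_both_classes <- function(cohort, name) {
  inf <- as.logical(cohort$infected)
  if (!any(inf) || all(inf)) {
    stop("subgroup '", name, "' does not contain both classes")
  }
}

perf_to_list <- function(p) {
  list(tp = p$tp, fp = p$fp, tn = p$tn, fn = p$fn,
       sensitivity = p$sensitivity, specificity = p$specificity,
       n_unclassified = p$n_unclassified)
}

# markers of the discovery rules ranked by the best (lift, support,
# confidence) of any rule containing them, top n retained
select_rule_markers <- function(rules, n) {
  if (!length(rules)) return(character())
  rows <- do.call(rbind, lapply(rules, function(r) {
    data.frame(marker = vapply(r$lhs, `[[`, "", "marker"),
               lift = r$lift, support = r$support,
               confidence = r$confidence)
  }))
  rows <- rows[order(-rows$lift, -rows$support, -rows$confidence,
                     rows$marker), ]
  best <- rows[!duplicated(rows$marker), ]
  sort(best$marker[seq_len(min(n, nrow(best)))])
}

stage_log <- function(stage, t0, extra = list()) {
  c(list(stage = stage,
         runtime_s = round(as.numeric(Sys.time()) - t0, 3)), extra)
}

#' Run the discovery-to-validation study
#'
#' Reproduces the two-stage protocol: each method (association rules,
#' decision tree, panel search) is trained once on the discovery subgroup
#' to select a restrained marker set; rules, tree and panel thresholds are
#' then re-estimated on the validation subgroup restricted to those
#' markers, and sensitivity/specificity are reported for both subgroups.
#' Fully deterministic given the config (and its seed).
#'
#' @param config A [study_config()].
#' @return A list of class `study_report` with elements `roc`
#'   (per-subgroup marker tables), `methods` (per-method markers and
#'   per-subgroup performance), `panels` (threshold rules per mode and
#'   subgroup), and `provenance`.
#' @export
run_study <- function(config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  t0 <- as.numeric(Sys.time())
  disc <- resolve_cohort(config$discovery, 1L, config$seed)
  vali <- resolve_cohort(config$validation, 2L, config$seed)
  check_both_classes(disc, "discovery")
  check_both_classes(vali, "validation")
  markers <- intersect(config$candidate_markers, names(disc))
  logs <- list(stage_log("cohorts", t0, list(
    n_discovery = nrow(disc), n_validation = nrow(vali),
    seed = config$seed)))

  t1 <- as.numeric(Sys.time())
  roc_tabs <- list(
    discovery = roc_table(disc, markers, se_min = 0.9),
    validation = roc_table(vali, markers, se_min = 0.9)
  )
  logs <- c(logs, list(stage_log("roc", t1)))

  # --- association rules -------------------------------------------------
  t1 <- as.numeric(Sys.time())
  disc_rules <- mine_rules(disc, markers = markers,
                           min_support = config$rules_min_support,
                           min_confidence = config$rules_min_confidence,
                           max_lhs_size = config$rules_max_lhs)
  rule_markers <- select_rule_markers(disc_rules, config$rules_n_markers)
  if (!length(rule_markers)) rule_markers <- markers
  disc_clf <- rule_classifier(disc_rules, disc)
  val_rules <- mine_rules(vali, markers = rule_markers,
                          min_support = config$rules_val_min_support,
                          min_confidence = config$rules_val_min_confidence,
                          max_lhs_size = config$rules_max_lhs)
  val_clf <- rule_classifier(val_rules, vali)
  rules_method <- list(
    method = "association_rules",
    markers = rule_markers,
    discovery = perf_to_list(rule_set_performance(disc_clf, disc)),
    validation = perf_to_list(rule_set_performance(val_clf, vali)),
    rules = list(discovery = lapply(disc_rules, `[`,
                                    c("display", "rhs_class", "support",
                                      "confidence", "lift")),
                 validation = lapply(val_rules, `[`,
                                     c("display", "rhs_class", "support",
                                       "confidence", "lift")))
  )
  logs <- c(logs, list(stage_log("rules", t1,
                                 list(n_rules_discovery = length(disc_rules)))))

  # --- decision tree -----------------------------------------------------
  t1 <- as.numeric(Sys.time())
  disc_tree <- grow_tree(disc, markers,
                         min_leaf = config$tree_min_leaf_discovery)
  tmarkers <- tree_markers(disc_tree)
  if (!length(tmarkers)) tmarkers <- markers
  val_tree <- grow_tree(vali, tmarkers,
                        min_leaf = config$tree_min_leaf_validation)
  tree_method <- list(
    method = "decision_tree",
    markers = tmarkers,
    discovery = perf_to_list(tree_performance(disc_tree, disc)),
    validation = perf_to_list(tree_performance(val_tree, vali)),
    trees = list(discovery = tree_to_list(disc_tree),
                 validation = tree_to_list(val_tree))
  )
  logs <- c(logs, list(stage_log("tree", t1)))

  # --- panel search ------------------------------------------------------
  panels <- list()
  panel_methods <- list()
  for (mode in config$panel_modes) {
    t1 <- as.numeric(Sys.time())
    sel <- exhaustive_search(disc, markers, mode = mode, s = config$panel_s,
                             max_panel_size = config$max_panel_size,
                             grid_cap = config$grid_cap)
    pm <- sort(vapply(sel$panel$conditions, `[[`, "", "marker"))
    ref <- refit_thresholds(pm, vali, mode = mode, s = config$panel_s,
                            grid_cap = config$grid_cap)
    disc_perf <- panel_performance(sel$panel, disc)
    val_perf <- panel_performance(ref$panel, vali)
    key <- paste0("panel_", mode)
    panel_methods[[key]] <- list(
      method = key, markers = pm,
      discovery = perf_to_list(disc_perf),
      validation = perf_to_list(val_perf)
    )
    panels[[mode]] <- list(
      mode = mode, s = config$panel_s, markers = pm,
      discovery = list(rule = format(sel$panel),
                       conditions = lapply(sel$panel$conditions, unclass),
                       min_votes = sel$panel$min_votes,
                       feasible = sel$feasible,
                       performance = perf_to_list(disc_perf)),
      validation = list(rule = format(ref$panel),
                        conditions = lapply(ref$panel$conditions, unclass),
                        min_votes = ref$panel$min_votes,
                        feasible = ref$feasible,
                        performance = perf_to_list(val_perf))
    )
    logs <- c(logs, list(stage_log(key, t1)))
  }

  methods <- c(list(rules_method, tree_method), unname(panel_methods))
  names(methods) <- vapply(methods, `[[`, "", "method")
  structure(list(
    roc = roc_tabs,
    methods = methods,
    panels = panels,
    provenance = list(
      seed = config$seed,
      candidate_markers = markers,
      config = list(panel_s = config$panel_s, grid_cap = config$grid_cap,
                    max_panel_size = config$max_panel_size,
                    rules_min_confidence = config$rules_min_confidence,
                    rules_min_support = config$rules_min_support,
                    rules_val_min_confidence = config$rules_val_min_confidence,
                    tree_min_leaf_discovery = config$tree_min_leaf_discovery,
                    tree_min_leaf_validation = config$tree_min_leaf_validation),
      log = logs)
  ), class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>\n")
  for (m in x$methods) {
    cat(sprintf("  %-18s [%s]  discovery SE %.1f%% SP %.1f%% | validation SE %.1f%% SP %.1f%%\n",
                m$method, paste(m$markers, collapse = ","),
                100 * m$discovery$sensitivity, 100 * m$discovery$specificity,
                100 * m$validation$sensitivity,
                100 * m$validation$specificity))
  }
  invisible(x)
}

#' Rank methods by discovery-to-validation stability
#'
#' Stability of a method is the total drift of its operating point between
#' subgroups, `|SE_d - SE_v| + |SP_d - SP_v|`; smaller is stabler. The
#' ranking echoes the argument that a method whose discovery performance
#' transfers is preferable for triage even when another method has higher
#' single-subgroup accuracy.
#'
#' @param report A [run_study()] report.
#' @return data.frame with one row per method sorted by stability
#'   (ascending, ties by method name).
#' @export
compare_methods <- function(report) {
  stopifnot(inherits(report, "study_report"))
  rows <- lapply(report$methods, function(m) {
    data.frame(method = m$method,
               markers = paste(m$markers, collapse = ","),
               discovery_se = m$discovery$sensitivity,
               discovery_sp = m$discovery$specificity,
               validation_se = m$validation$sensitivity,
               validation_sp = m$validation$specificity,
               stability = abs(m$discovery$sensitivity -
                                 m$validation$sensitivity) +
                 abs(m$discovery$specificity - m$validation$specificity))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$stability, out$method), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write / read a study report as JSON
#'
#' @param report A `study_report`.
#' @param path File path.
#' @return `write_study_report()` returns `path` invisibly;
#'   `read_study_report()` the parsed report.
#' @export
write_study_report <- function(report, path) {
  stopifnot(inherits(report, "study_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "rows")
  invisible(path)
}

#' @rdname write_study_report
#' @export
read_study_report <- function(path) {
  structure(jsonlite::read_json(path, simplifyVector = TRUE),
            class = "study_report")
}
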