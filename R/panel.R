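# k-of-n threshold-panel classifiers and the exhaustive panel search:
# enumerate marker subsets x per-marker threshold grids x vote counts k,
# and pick the panel maximizing specificity at a fixed minimum sensitivity
# (or the reverse).
#
# The search does not loop panel-by-panel: for a fixed marker subset every
# patient is reduced to a per-marker threshold rank, and the confusion
# counts of ALL grid cells at once are obtained from reverse-cumulative
# rank histograms combined by inclusion-exclusion over condition subsets
# (counts of "votes >= k" are a signed sum of elementary symmetric subset
# counts). The test suite checks this against a naive quadruple loop.

#' Confusion-count performance report
#'
#' @param predicted,truth Logical vectors (`TRUE` = infected).
#' @param n_unclassified Patients excluded from the counts.
#' @return Object of class `perf_report`: `tp`, `fp`, `tn`, `fn`,
#'   `sensitivity`, `specificity`, `n_unclassified`.
#' @export
perf_report <- function(predicted, truth, n_unclassified = 0L) {
  stopifnot(length(predicted) == length(truth))
  tp <- sum(predicted & truth); fn <- sum(!predicted & truth)
  fp <- sum(predicted & !truth); tn <- sum(!predicted & !truth)
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
                 specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
                 n_unclassified = as.integer(n_unclassified)),
            class = "perf_report")
}

#' @export
print.perf_report <- function(x, ...) {
  cat(sprintf(
    "<perf_report> SE %.1f%% SP %.1f%% (TP %d FP %d TN %d FN %d%s)\n",
    100 * x$sensitivity, 100 * x$specificity, x$tp, x$fp, x$tn, x$fn,
    if (x$n_unclassified) paste0(", ", x$n_unclassified, " unclassified")
    else ""))
  invisible(x)
}

#' Single threshold condition of a panel
#'
#' @param marker Marker name.
#' @param op `">"` (marker above cutoff votes for infection) or `"<"`.
#' @param cutoff Finite cutoff in marker units.
#' @return Object of class `threshold_condition`.
#' @export
threshold_condition <- function(marker, op = c(">", "<"), cutoff) {
  op <- match.arg(op)
  stopifnot(is.finite(cutoff))
  structure(list(marker = marker, op = op, cutoff = cutoff),
            class = "threshold_condition")
}

#' k-of-n threshold panel
#'
#' A panel declares infection when at least `min_votes` of its threshold
#' conditions hold.
#'
#' @param conditions List of [threshold_condition()] objects.
#' @param min_votes Vote count `k`, `1 <= k <= length(conditions)`.
#' @return Object of class `panel_rule`.
#' @export
panel_rule <- function(conditions, min_votes = 1L) {
  stopifnot(length(conditions) >= 1L,
            all(vapply(conditions, inherits, TRUE, "threshold_condition")))
  min_votes <- as.integer(min_votes)
  if (min_votes < 1L || min_votes > length(conditions)) {
    stop("panel_rule: need 1 <= min_votes <= number of conditions")
  }
  structure(list(conditions = conditions, min_votes = min_votes),
            class = "panel_rule")
}

#' @export
format.panel_rule <- function(x, ...) {
  conds <- vapply(x$conditions, function(cn) {
    sprintf("%s %s %g", toupper(cn$marker), cn$op, cn$cutoff)
  }, "")
  sprintf("%s (infection when >= %d)", paste(conds, collapse = " and "),
          x$min_votes)
}

#' @export
print.panel_rule <- function(x, ...) {
  cat("<panel_rule>", format(x), "\n")
  cat(panel_rule_ifelse(x))
  invisible(x)
}

#' Render a panel as if-else pseudocode
#'
#' The human-readable decision-rule rendering of a panel.
#'
#' @param panel A [panel_rule()].
#' @return A single string.
#' @export
panel_rule_ifelse <- function(panel) {
  conds <- vapply(panel$conditions, function(cn) {
    sprintf("(%s %s %g)", cn$marker, cn$op, cn$cutoff)
  }, "")
  paste0("if ", paste(conds, collapse = " + "), " >= ", panel$min_votes,
         " then infected else non-infected\n")
}

#' Apply a panel to patients
#'
#' @param panel A [panel_rule()].
#' @param patients Cohort data.frame rows.
#' @return data.frame with columns `votes` and `predicted`
#'   (`"infected"`/`"non_infected"`), one row per patient.
#' @export
apply_panel <- function(panel, patients) {
  stopifnot(inherits(panel, "panel_rule"))
  for (cn in panel$conditions) {
    if (!cn$marker %in% names(patients)) {
      stop("unclassifiable: patients lack marker '", cn$marker, "'")
    }
  }
  votes <- rep(0L, nrow(patients))
  na <- rep(FALSE, nrow(patients))
  for (cn in panel$conditions) {
    v <- patients[[cn$marker]]
    na <- na | is.na(v)
    hit <- if (cn$op == ">") v > cn$cutoff else v < cn$cutoff
    votes <- votes + ifelse(is.na(hit), 0L, hit)
  }
  votes[na] <- NA_integer_
  data.frame(votes = votes,
             predicted = ifelse(is.na(votes), NA_character_,
                                ifelse(votes >= panel$min_votes, "infected",
                                       "non_infected")))
}

#' Confusion performance of a panel on a cohort
#'
#' Patients missing any panel marker are unclassifiable: they are counted
#' in `n_unclassified` and excluded from the confusion counts.
#'
#' @param panel A [panel_rule()].
#' @param cohort Cohort with an `infected` column.
#' @return A [perf_report()].
#' @export
panel_performance <- function(panel, cohort) {
  res <- apply_panel(panel, cohort)
  ok <- !is.na(res$votes)
  perf_report(res$predicted[ok] == "infected",
              as.logical(cohort$infected)[ok],
              n_unclassified = sum(!ok))
}

#' Candidate threshold grid for one marker
#'
#' Midpoints between consecutive distinct sorted values; when there are
#' more than `cap`, the grid is thinned to `cap` cutoffs by even spacing
#' through the ordered midpoint list, always retaining the two extreme
#' midpoints. A constant marker yields an empty grid.
#'
#' @param values Numeric marker values.
#' @param cap Maximum number of cutoffs (>= 1).
#' @return Sorted numeric vector of cutoffs (possibly empty).
#' @export
candidate_thresholds <- function(values, cap = 25L) {
  stopifnot(cap >= 1L)
  values <- values[!is.na(values)]
  if (!length(values)) stop("candidate_thresholds: empty input")
  u <- sort(unique(values))
  if (length(u) < 2L) return(numeric())
  mids <- (u[-1] + u[-length(u)]) / 2
  if (length(mids) <= cap) return(mids)
  idx <- unique(round(seq(1L, length(mids), length.out = cap)))
  mids[idx]
}

rev_cumsum_dim <- function(a, d) {
  dims <- dim(a)
  perm <- c(d, setdiff(seq_along(dims), d))
  ap <- aperm(a, perm)
  m <- matrix(ap, nrow = dims[d])
  m <- apply(m[rev(seq_len(nrow(m))), , drop = FALSE], 2L, cumsum)
  m <- matrix(m, nrow = dims[d])[rev(seq_len(dims[d])), , drop = FALSE]
  aperm(array(m, dim = dims[perm]), order(perm))
}

# Reverse-cumulative rank histogram for condition subset T:
# A[i_1..i_|T|] = #patients with rank_m >= i_m for all m in T.
subset_count_array <- function(rank_mat, Tidx, gdims) {
  gT <- gdims[Tidx]
  dims0 <- gT + 1L
  lin <- rep(1L, nrow(rank_mat))
  stride <- 1L
  for (j in seq_along(Tidx)) {
    lin <- lin + rank_mat[, Tidx[j]] * stride
    stride <- stride * dims0[j]
  }
  H <- array(tabulate(lin, nbins = prod(dims0)), dim = dims0)
  for (d in seq_along(dims0)) H <- rev_cumsum_dim(H, d)
  # drop rank-0 slice in every dimension: cell i means rank >= i, i = 1..g
  do.call(`[`, c(list(H), lapply(dims0, function(k) 2:k), list(drop = FALSE)))
}

broadcast_to_grid <- function(A, Tidx, gdims) {
  p <- length(gdims)
  rest <- setdiff(seq_len(p), Tidx)
  full <- array(A, dim = c(gdims[Tidx], gdims[rest]))
  ord <- c(Tidx, rest)
  aperm(full, match(seq_len(p), ord))
}

# counts of patients with >= t satisfied conditions, for every grid cell
votes_ge_counts <- function(rank_mat, gdims, t) {
  p <- length(gdims)
  total <- array(0, dim = gdims)
  for (j in t:p) {
    coef <- (-1)^(j - t) * choose(j - 1L, t - 1L)
    for (Tidx in utils::combn(p, j, simplify = FALSE)) {
      total <- total +
        coef * broadcast_to_grid(subset_count_array(rank_mat, Tidx, gdims),
                                 Tidx, gdims)
    }
  }
  total
}

compare_candidates <- function(a, b) {
  # TRUE when candidate a beats b: higher objective, then higher secondary;
  # subset size and marker-name ties are resolved by enumeration order
  # (sizes ascending, names lexicographic, keep-first); within a subset,
  # smaller cutoff combination wins before smaller k.
  if (is.null(b)) return(TRUE)
  if (a$objective != b$objective) return(a$objective > b$objective)
  if (a$secondary != b$secondary) return(a$secondary > b$secondary)
  if (identical(a$S, b$S)) {
    for (j in seq_along(a$cell)) {
      if (a$cell[j] != b$cell[j]) return(a$cell[j] < b$cell[j])
    }
    return(a$t < b$t)
  }
  FALSE
}

best_cell <- function(objective, secondary, mask, gdims) {
  obj <- objective
  obj[!mask] <- -Inf
  m <- max(obj)
  if (!is.finite(m)) return(NULL)
  cells <- which(obj == m)
  sec <- secondary[cells]
  cells <- cells[sec == max(sec)]
  rows <- arrayInd(cells, gdims)
  ord <- do.call(order, as.data.frame(rows))
  list(cell = rows[ord[1L], , drop = TRUE], objective = m,
       secondary = max(sec))
}

#' Exhaustive k-of-n threshold-panel search
#'
#' Enumerates every marker subset up to `max_panel_size`, every combination
#' of per-marker cutoffs from [candidate_thresholds()], and every vote
#' count `k`, and returns the panel optimizing the configured objective:
#' maximal specificity subject to sensitivity `>= s` (`mode = "high-se"`),
#' or maximal sensitivity subject to specificity `>= s` (`"high-sp"`).
#'
#' Ties break deterministically: higher secondary metric, then fewer
#' markers, then lexicographic marker names, then lexicographically
#' smallest cutoff combination, then smallest `k`. When no enumerated panel
#' satisfies the constraint, the best-effort panel maximizing the
#' constrained metric is returned with `feasible = FALSE` (small discovery
#' subgroups make infeasibility common; an error would be unhelpful).
#'
#' @param cohort Cohort with both classes present.
#' @param markers Candidate marker names.
#' @param mode `"high-se"` or `"high-sp"`.
#' @param s Constraint level in `(0, 1]` (default 0.95).
#' @param max_panel_size Maximum number of markers in a panel.
#' @param grid_cap Per-marker cutoff cap for [candidate_thresholds()].
#' @param directions Optional named vector of `">"`/`"<"` per marker;
#'   default all `">"` (marker above threshold votes for infection).
#' @param fixed_set Search exactly the given marker set instead of all
#'   subsets (used when re-estimating cutoffs on a validation cohort for a
#'   marker set selected elsewhere).
#' @return List of class `panel_search_result`: `panel` ([panel_rule()]),
#'   `performance` ([perf_report()] on `cohort`), `feasible`, `mode`, `s`,
#'   and a `log` of per-subset enumeration counts.
#' @export
exhaustive_search <- function(cohort, markers,
                              mode = c("high-se", "high-sp"), s = 0.95,
                              max_panel_size = 3L, grid_cap = 25L,
                              directions = NULL, fixed_set = FALSE) {
  mode <- match.arg(mode)
  stopifnot(s > 0, s <= 1, max_panel_size >= 1L)
  truth <- as.logical(cohort$infected)
  if (!any(truth) || all(truth)) {
    stop("exhaustive_search: both classes must be present")
  }
  markers <- sort(unique(markers))
  stopifnot(all(markers %in% names(cohort)))
  keep <- rowSums(is.na(as.matrix(cohort[, markers, drop = FALSE]))) == 0
  truth <- truth[keep]
  npos <- sum(truth); nneg <- sum(!truth)
  dir_of <- function(m) {
    if (!is.null(directions) && m %in% names(directions)) directions[[m]]
    else ">"
  }
  # normalize "<" conditions to ">" by sign flip
  vals <- lapply(markers, function(m) {
    v <- cohort[[m]][keep]
    if (dir_of(m) == "<") -v else v
  })
  names(vals) <- markers
  grids <- lapply(vals, candidate_thresholds, cap = grid_cap)
  usable <- markers[vapply(grids, length, 0L) > 0L]
  if (!length(usable)) stop("exhaustive_search: empty grid for every marker")
  subsets <- if (fixed_set) {
    if (!all(markers %in% usable)) {
      stop("exhaustive_search: fixed marker set contains a constant marker")
    }
    list(markers)
  } else {
    unlist(lapply(seq_len(min(max_panel_size, length(usable))), function(sz) {
      utils::combn(usable, sz, simplify = FALSE)
    }), recursive = FALSE)
  }
  best <- NULL; best_effort <- NULL
  log <- list()
  for (S in subsets) {
    p <- length(S)
    gdims <- vapply(grids[S], length, 0L)
    ranks <- vapply(seq_along(S), function(j) {
      g <- grids[[S[j]]]
      findInterval(vals[[S[j]]], g, left.open = TRUE)
    }, integer(sum(keep)))
    ranks <- matrix(ranks, ncol = p)
    rk_pos <- ranks[truth, , drop = FALSE]
    rk_neg <- ranks[!truth, , drop = FALSE]
    n_feas <- 0L
    for (t in seq_len(p)) {
      tp <- votes_ge_counts(rk_pos, gdims, t)
      fp <- votes_ge_counts(rk_neg, gdims, t)
      se <- tp / npos
      sp <- (nneg - fp) / nneg
      if (mode == "high-se") {
        mask <- se >= s - 1e-12
        obj <- sp; sec <- se
        eff_obj <- se; eff_sec <- sp
      } else {
        mask <- sp >= s - 1e-12
        obj <- se; sec <- sp
        eff_obj <- sp; eff_sec <- se
      }
      n_feas <- n_feas + sum(mask)
      wrap <- function(cell_res) {
        if (is.null(cell_res)) return(NULL)
        c(cell_res, list(S = S, t = t, gdims = gdims))
      }
      cand <- wrap(best_cell(obj, sec, mask, gdims))
      if (!is.null(cand) && compare_candidates(cand, best)) best <- cand
      eff <- wrap(best_cell(eff_obj, eff_sec, array(TRUE, dim = gdims),
                            gdims))
      if (!is.null(eff) && compare_candidates(eff, best_effort)) {
        best_effort <- eff
      }
    }
    log[[length(log) + 1L]] <- list(markers = S,
                                    n_combos = prod(gdims) * p,
                                    n_feasible = n_feas)
  }
  feasible <- !is.null(best)
  chosen <- if (feasible) best else best_effort
  conds <- lapply(seq_along(chosen$S), function(j) {
    m <- chosen$S[j]
    cut <- grids[[m]][chosen$cell[j]]
    if (dir_of(m) == "<") {
      threshold_condition(m, "<", -cut)
    } else {
      threshold_condition(m, ">", cut)
    }
  })
  panel <- panel_rule(conds, min_votes = chosen$t)
  structure(list(panel = panel,
                 performance = panel_performance(panel, cohort),
                 feasible = feasible, mode = mode, s = s, log = log),
            class = "panel_search_result")
}

#' @export
print.panel_search_result <- function(x, ...) {
  cat(sprintf("<panel_search_result> %s, constraint %.2f%s\n", x$mode, x$s,
              if (x$feasible) "" else " [constraint infeasible: best effort]"))
  cat(" ", format(x$panel), "\n")
  print(x$performance)
  invisible(x)
}

#' Re-estimate panel cutoffs on a new cohort for a fixed marker set
#'
#' The discovery-to-validation protocol keeps only the marker identities
#' from the selection step and re-runs the threshold search on the (larger)
#' validation cohort restricted to exactly that marker set; the vote count
#' `k` stays free, since the best `k` can change with the cohort.
#'
#' @param markers The fixed marker set.
#' @param cohort Cohort to re-estimate on.
#' @param ... Passed to [exhaustive_search()] (`mode`, `s`, `grid_cap`,
#'   `directions`).
#' @return A `panel_search_result`.
#' @export
refit_thresholds <- function(markers, cohort, ...) {
  exhaustive_search(cohort, markers, fixed_set = TRUE,
                    max_panel_size = length(markers), ...)
}
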