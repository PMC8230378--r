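# Class-association-rule mining: supervised discretization, the
# support/confidence/lift metrics, exhaustive enumeration of interval
# conjunction rules, and a first-match rule-list classifier.
#
# Intervals are closed-open [lo, hi) and every marker's bins partition the
# whole real line, so each patient falls in exactly one bin per marker.

interval <- function(lo, hi) {
  stopifnot(lo < hi)
  c(lo = lo, hi = hi)
}

in_interval <- function(x, itv) !is.na(x) & x >= itv[["lo"]] & x < itv[["hi"]]

format_interval <- function(itv) {
  lo <- if (is.infinite(itv[["lo"]])) "-Inf" else format(itv[["lo"]])
  hi <- if (is.infinite(itv[["hi"]])) "Inf" else format(itv[["hi"]])
  paste0("[", lo, ",", hi, ")")
}

cuts_to_intervals <- function(cuts) {
  b <- c(-Inf, sort(cuts), Inf)
  lapply(seq_len(length(b) - 1L), function(i) interval(b[i], b[i + 1L]))
}

class_entropy <- function(labels) {
  if (!length(labels)) return(0)
  p <- mean(labels)
  h <- function(q) if (q <= 0 || q >= 1) 0 else -q * log2(q) - (1 - q) * log2(1 - q)
  h(p)
}

#' Supervised discretization of a numeric marker
#'
#' Bins a marker into contiguous closed-open intervals covering the whole
#' line. Cut points are midpoints between adjacent distinct values chosen
#' by recursive entropy-minimizing binary splits against the class label;
#' splitting stops at `max_bins` bins or when no split reduces the weighted
#' class entropy. When supervision is degenerate (a single class, or a
#' constant column) the fallback is equal-frequency quartile cuts.
#'
#' @param values Numeric vector.
#' @param labels Logical class labels.
#' @param max_bins Maximum number of bins (>= 2).
#' @return List of intervals (`c(lo, hi)` pairs) partitioning the line.
#' @export
bin_numeric <- function(values, labels, max_bins = 4L) {
  stopifnot(max_bins >= 2L, length(values) == length(labels))
  keep <- !is.na(values) & !is.na(labels)
  values <- values[keep]; labels <- as.logical(labels[keep])
  if (!length(values) || length(unique(values)) == 1L) {
    return(cuts_to_intervals(numeric()))
  }
  if (length(unique(labels)) < 2L) {
    qs <- unique(unname(stats::quantile(values, c(0.25, 0.5, 0.75), type = 7)))
    qs <- qs[qs > min(values) & qs < max(values)]
    return(cuts_to_intervals(qs[seq_len(min(length(qs), max_bins - 1L))]))
  }
  candidate_cuts <- function(v) {
    u <- sort(unique(v))
    if (length(u) < 2L) numeric() else (u[-1] + u[-length(u)]) / 2
  }
  # segments of (values, labels); repeatedly apply the globally best split
  segs <- list(list(v = values, l = labels))
  cuts <- numeric()
  while (length(segs) < max_bins) {
    best <- NULL
    for (si in seq_along(segs)) {
      v <- segs[[si]]$v; l <- segs[[si]]$l
      h0 <- class_entropy(l) * length(l)
      for (c in candidate_cuts(v)) {
        left <- v < c
        h <- class_entropy(l[left]) * sum(left) +
          class_entropy(l[!left]) * sum(!left)
        gain <- h0 - h
        if (gain > 1e-12 && (is.null(best) || gain > best$gain + 1e-12)) {
          best <- list(si = si, cut = c, gain = gain)
        }
      }
    }
    if (is.null(best)) break
    seg <- segs[[best$si]]
    left <- seg$v < best$cut
    segs[[best$si]] <- list(v = seg$v[left], l = seg$l[left])
    segs <- append(segs, list(list(v = seg$v[!left], l = seg$l[!left])),
                   after = best$si)
    cuts <- c(cuts, best$cut)
  }
  cuts_to_intervals(cuts)
}

lhs_matches <- function(lhs, cohort) {
  m <- rep(TRUE, nrow(cohort))
  for (cond in lhs) {
    m <- m & in_interval(cohort[[cond$marker]], cond$interval)
  }
  m
}

format_lhs <- function(lhs) {
  paste0("{", paste(vapply(lhs, function(cond) {
    paste0(toupper(cond$marker), " = ", format_interval(cond$interval))
  }, ""), collapse = ", "), "}")
}

#' Association-rule metrics: support, confidence, lift
#'
#' For a rule `A -> B` on a cohort: support is the fraction of patients
#' satisfying both the antecedent A and the class B; confidence the
#' fraction of A-patients that are B; lift the ratio of the joint support
#' to the product of the marginal supports, which reduces to
#' `confidence / prevalence(B)`. Lift 1 means A and B are independent.
#'
#' @param lhs List of conditions, each `list(marker=, interval=c(lo, hi))`.
#' @param rhs_class `"infected"` or `"non_infected"`.
#' @param cohort Cohort data.frame.
#' @return List with `support`, `confidence`, `lift`, `n_lhs`, `n_joint`.
#' @export
rule_metrics <- function(lhs, rhs_class, cohort) {
  rhs_class <- match.arg(rhs_class, c("infected", "non_infected"))
  if (!nrow(cohort)) stop("rule_metrics: empty cohort")
  A <- lhs_matches(lhs, cohort)
  B <- if (rhs_class == "infected") as.logical(cohort$infected) else
    !as.logical(cohort$infected)
  nA <- sum(A)
  if (nA == 0) stop("rule_metrics: no patient satisfies the antecedent")
  N <- nrow(cohort)
  n_joint <- sum(A & B)
  support <- n_joint / N
  confidence <- n_joint / nA
  lift <- support / ((nA / N) * (sum(B) / N))
  list(support = support, confidence = confidence, lift = lift,
       n_lhs = nA, n_joint = n_joint)
}

#' Mine class-association rules
#'
#' Exhaustively enumerates antecedents that are conjunctions of up to
#' `max_lhs_size` per-marker interval conditions (one bin per marker, over
#' the supervised bins from [bin_numeric()]) against both classes, and
#' keeps every rule meeting the support and confidence constraints. Output
#' is sorted by confidence, then support, then lift (all descending), then
#' the antecedent's display string.
#'
#' @param cohort Cohort data.frame with an `infected` column.
#' @param bins Named list: per marker, a list of intervals (as returned by
#'   [bin_numeric()]). Built automatically from `markers` when `NULL`.
#' @param markers Markers to bin when `bins` is `NULL`.
#' @param min_support,min_confidence Constraints in `[0, 1]`.
#' @param max_lhs_size Maximum number of conjuncts.
#' @param max_bins Passed to [bin_numeric()] when binning here.
#' @return List of rules (class `association_rules`); each rule carries
#'   `lhs`, `rhs_class`, `support`, `confidence`, `lift`, `display`.
#' @export
mine_rules <- function(cohort, bins = NULL,
                       markers = c("saa", "nihss", "wbc"),
                       min_support = 0.1, min_confidence = 1,
                       max_lhs_size = 2L, max_bins = 4L) {
  stopifnot(nrow(cohort) > 0)
  if (is.null(bins)) {
    bins <- lapply(stats::setNames(markers, markers), function(m) {
      bin_numeric(cohort[[m]], cohort$infected, max_bins = max_bins)
    })
  }
  marker_names <- names(bins)
  rules <- list()
  for (size in seq_len(min(max_lhs_size, length(marker_names)))) {
    for (sel in utils::combn(marker_names, size, simplify = FALSE)) {
      grids <- lapply(sel, function(m) seq_along(bins[[m]]))
      combos <- expand.grid(grids, KEEP.OUT.ATTRS = FALSE)
      for (ri in seq_len(nrow(combos))) {
        lhs <- lapply(seq_along(sel), function(j) {
          list(marker = sel[j],
               interval = bins[[sel[j]]][[combos[ri, j][[1]]]])
        })
        A <- lhs_matches(lhs, cohort)
        if (!sum(A)) next
        for (rhs in c("infected", "non_infected")) {
          met <- rule_metrics(lhs, rhs, cohort)
          if (met$support >= min_support - 1e-12 &&
              met$confidence >= min_confidence - 1e-12) {
            rules[[length(rules) + 1L]] <-
              list(lhs = lhs, rhs_class = rhs, support = met$support,
                   confidence = met$confidence, lift = met$lift,
                   display = paste0(format_lhs(lhs), " => {infection = ",
                                    if (rhs == "infected") "yes" else "no",
                                    "}"))
          }
        }
      }
    }
  }
  if (length(rules)) {
    key <- order(-vapply(rules, `[[`, 0, "confidence"),
                 -vapply(rules, `[[`, 0, "support"),
                 -vapply(rules, `[[`, 0, "lift"),
                 vapply(rules, `[[`, "", "display"))
    rules <- rules[key]
  }
  structure(rules, class = "association_rules", bins = bins)
}

#' @export
print.association_rules <- function(x, ...) {
  cat(sprintf("<association_rules> %d rule(s)\n", length(x)))
  for (r in x) {
    cat(sprintf("  %-55s supp %.3f conf %.2f lift %.2f\n",
                r$display, r$support, r$confidence, r$lift))
  }
  invisible(x)
}

#' Build a rule-list classifier
#'
#' Orders mined rules deterministically (the [mine_rules()] sort order) and
#' attaches a default class — the majority class of the training cohort —
#' for patients no rule covers.
#'
#' @param rules An `association_rules` list.
#' @param cohort Training cohort (fixes the default class).
#' @return Object of class `rule_classifier`.
#' @export
rule_classifier <- function(rules, cohort) {
  default <- if (sum(cohort$infected) > sum(!cohort$infected)) {
    "infected"
  } else "non_infected"
  structure(list(rules = rules, default_class = default),
            class = "rule_classifier")
}

#' Classify patients with a rule list
#'
#' The first rule (in classifier order) whose antecedent a patient
#' satisfies fires; uncovered patients get the default class.
#'
#' @param classifier A [rule_classifier()].
#' @param patients Cohort data.frame (one or more rows).
#' @return Character vector of `"infected"` / `"non_infected"`.
#' @export
classify_with_rules <- function(classifier, patients) {
  stopifnot(inherits(classifier, "rule_classifier"))
  needed <- unique(unlist(lapply(classifier$rules, function(r) {
    vapply(r$lhs, `[[`, "", "marker")
  })))
  absent <- setdiff(needed, names(patients))
  if (length(absent) && length(classifier$rules)) {
    stop("unclassifiable: patients lack marker(s) ",
         paste(absent, collapse = ", "))
  }
  out <- rep(classifier$default_class, nrow(patients))
  assigned <- rep(FALSE, nrow(patients))
  for (r in classifier$rules) {
    hit <- !assigned & lhs_matches(r$lhs, patients)
    out[hit] <- r$rhs_class
    assigned <- assigned | hit
  }
  out
}

#' Confusion performance of a rule classifier on a cohort
#'
#' @param classifier A [rule_classifier()].
#' @param cohort Cohort with an `infected` column.
#' @return A `perf_report` (see [perf_report()]).
#' @export
rule_set_performance <- function(classifier, cohort) {
  pred <- classify_with_rules(classifier, cohort) == "infected"
  perf_report(pred, as.logical(cohort$infected))
}
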