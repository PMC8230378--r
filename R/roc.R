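# Single-marker ROC curves, AUC, and sensitivity-constrained cutoff choice.
#
# Classification convention: with direction "higher" a patient is called
# infected when score > cutoff (strict). Cutoffs are placed at midpoints
# between adjacent distinct scores, plus the two trivial endpoints -Inf
# (everyone positive) and +Inf (no one positive).

#' Empirical ROC curve
#'
#' @param scores Numeric marker values.
#' @param labels Logical (or 0/1) infection labels, `TRUE` = infected.
#' @param direction `"higher"` when larger scores indicate infection,
#'   `"lower"` for the reverse.
#' @param marker Optional marker name carried in the result.
#' @return A data.frame of class `roc_curve` with columns `cutoff`,
#'   `sensitivity`, `specificity`, and attributes `auc`, `direction`,
#'   `marker`, `n_pos`, `n_neg`.
#' @export
roc_curve <- function(scores, labels, direction = c("higher", "lower"),
                      marker = NULL) {
  direction <- match.arg(direction)
  labels <- as.logical(labels)
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  stopifnot(length(scores) == length(labels))
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) {
    stop("roc_curve: both classes must be present")
  }
  s <- if (direction == "higher") scores else -scores
  u <- sort(unique(s))
  cutoffs <- c(-Inf, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, Inf)
  # predicted positive when s > cutoff
  se <- vapply(cutoffs, function(c) sum(labels & s > c) / n_pos, 0)
  sp <- vapply(cutoffs, function(c) sum(!labels & s <= c) / n_neg, 0)
  out_cut <- if (direction == "higher") cutoffs else -cutoffs
  curve <- data.frame(cutoff = out_cut, sensitivity = se, specificity = sp)
  a <- sum(vapply(which(labels), function(i) {
    sum(s[i] > s[!labels]) + 0.5 * sum(s[i] == s[!labels])
  }, 0)) / (n_pos * n_neg)
  structure(curve, auc = a, direction = direction,
            marker = if (is.null(marker)) NA_character_ else marker,
            n_pos = n_pos, n_neg = n_neg,
            class = c("roc_curve", "data.frame"))
}

#' Area under the ROC curve
#'
#' Trapezoidal area, equal to the concordance probability (probability that
#' a random infected patient's score lies on the infected side of a random
#' non-infected patient's, tied scores counted 1/2).
#'
#' @param roc A [roc_curve()].
#' @return AUC as a fraction in `[0, 1]`.
#' @export
roc_auc <- function(roc) {
  stopifnot(inherits(roc, "roc_curve"))
  fpr <- 1 - roc$specificity
  tpr <- roc$sensitivity
  o <- order(fpr, tpr)
  fpr <- fpr[o]; tpr <- tpr[o]
  sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
}

#' Best specificity subject to a minimum sensitivity
#'
#' Among attainable ROC points with sensitivity at least `se_min`, returns
#' the one with maximal specificity; ties are broken toward higher
#' sensitivity, then toward the cutoff excluding more non-infected patients.
#' When the constraint is only attainable at specificity 0 (the degenerate
#' call-everyone-positive corner), that point is returned with
#' `low_information = TRUE`.
#'
#' @param roc A [roc_curve()].
#' @param se_min Minimum sensitivity, in `(0, 1]`.
#' @return List of class `cutoff_choice`: `cutoff`, `sensitivity`,
#'   `specificity`, `low_information`.
#' @export
cutoff_at_min_sensitivity <- function(roc, se_min) {
  stopifnot(inherits(roc, "roc_curve"), se_min > 0, se_min <= 1)
  eps <- 1e-12
  ok <- which(roc$sensitivity >= se_min - eps)
  if (!length(ok)) stop("no ROC point attains sensitivity >= ", se_min)
  sp <- roc$specificity[ok]
  best_sp <- max(sp)
  cand <- ok[sp >= best_sp - eps]
  se <- roc$sensitivity[cand]
  cand <- cand[se >= max(se) - eps]
  # exclude more non-infected = larger cutoff on the infected side
  dirhi <- attr(roc, "direction") == "higher"
  cut <- roc$cutoff[cand]
  pick <- cand[if (dirhi) which.max(cut) else which.min(cut)]
  structure(list(cutoff = roc$cutoff[pick],
                 sensitivity = roc$sensitivity[pick],
                 specificity = roc$specificity[pick],
                 low_information = roc$specificity[pick] == 0),
            class = "cutoff_choice")
}

#' @export
print.cutoff_choice <- function(x, ...) {
  cat(sprintf("<cutoff_choice> cutoff %s: SE %.1f%%, SP %.1f%%%s\n",
              format(x$cutoff), 100 * x$sensitivity, 100 * x$specificity,
              if (x$low_information) " [low information]" else ""))
  invisible(x)
}

#' Per-marker ROC table for a cohort
#'
#' One row per marker: AUC, and the sensitivity/specificity/cutoff chosen
#' by [cutoff_at_min_sensitivity()] — the table-of-markers report of a
#' triage analysis ("best specificity at >= 90% sensitivity").
#'
#' @param cohort Cohort data.frame with an `infected` column.
#' @param markers Marker column names.
#' @param se_min Minimum sensitivity for cutoff selection.
#' @param directions Optional named character vector (`"higher"`/`"lower"`)
#'   per marker; default all `"higher"`.
#' @return A data.frame with columns `marker`, `auc`, `sensitivity`,
#'   `specificity`, `cutoff`, `low_information`.
#' @export
roc_table <- function(cohort, markers = c("saa", "nihss", "temperature",
                                          "wbc", "crp", "pct", "monocytes"),
                      se_min = 0.9, directions = NULL) {
  rows <- lapply(markers, function(m) {
    dir <- if (!is.null(directions) && m %in% names(directions)) {
      directions[[m]]
    } else "higher"
    r <- roc_curve(cohort[[m]], cohort$infected, direction = dir, marker = m)
    ch <- cutoff_at_min_sensitivity(r, se_min)
    data.frame(marker = m, auc = attr(r, "auc"),
               sensitivity = ch$sensitivity, specificity = ch$specificity,
               cutoff = if (ch$low_information) NA_real_ else ch$cutoff,
               low_information = ch$low_information)
  })
  do.call(rbind, rows)
}
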