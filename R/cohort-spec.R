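# Marker distribution specs and cohort specs: the summary-statistic
# parameterization (per-class median and quartiles) from which synthetic
# cohorts are generated.

Z75 <- stats::qnorm(0.75)  # 0.6744898: standard-normal upper quartile

#' Fit a lognormal distribution from a median and interquartile range
#'
#' Calibrates a two-parameter lognormal to a printed `median (q1-q3)`
#' summary. The meanlog is `log(median)` (the lognormal median is exact by
#' construction) and the sdlog reproduces the interquartile range on the log
#' scale: `sigma = (log(q3) - log(q1)) / (2 * qnorm(0.75))`.
#'
#' Note that a two-parameter lognormal can match the median and the log-width
#' of the IQR exactly, but can only reproduce `q1` and `q3` individually when
#' the triple is log-symmetric (`median^2 == q1 * q3`). Skewed printed
#' summaries (the usual case for acute-phase proteins) are matched in median
#' and IQR spread, not endpoint by endpoint.
#'
#' @param median,q1,q3 Positive numbers with `q1 <= median <= q3`.
#' @return A list with elements `mu`, `sigma` and logical `degenerate`
#'   (`TRUE` when `sigma == 0`, i.e. a point mass at `median`).
#' @examples
#' fit_lognormal_from_quantiles(16.7, 4.7, 89.2)
#' @export
fit_lognormal_from_quantiles <- function(median, q1, q3) {
  stopifnot(is.numeric(median), is.numeric(q1), is.numeric(q3),
            length(median) == 1L, length(q1) == 1L, length(q3) == 1L)
  if (!is.finite(median) || !is.finite(q1) || !is.finite(q3) ||
      median <= 0 || q1 <= 0 || q3 <= 0) {
    stop("lognormal calibration requires strictly positive median, q1, q3")
  }
  if (q1 > median || median > q3) {
    stop("inconsistent quantiles: need q1 <= median <= q3 (got ",
         q1, ", ", median, ", ", q3, ")")
  }
  if (q1 == q3 && q1 != median) {
    stop("inconsistent quantiles: q1 == q3 but != median")
  }
  sigma <- (log(q3) - log(q1)) / (2 * Z75)
  list(mu = log(median), sigma = sigma, degenerate = sigma == 0)
}

#' Per-marker class-conditional distribution specification
#'
#' Describes how one marker is distributed in infected and non-infected
#' patients, parameterized by the (median, q1, q3) triple printed in a
#' demographics table.
#'
#' @param marker Marker name (column name in the cohort table).
#' @param family One of `"lognormal"`, `"normal"`,
#'   `"discretized-lognormal"` (lognormal rounded to integer and clamped
#'   to `range`, used for ordinal scores such as the NIHSS).
#' @param infected,non_infected Numeric triples `c(median, q1, q3)`.
#' @param floor Optional detection-limit floor: draws below it are clamped
#'   up to it (e.g. CRP assays reporting "< 3" as 3).
#' @param range Integer clamp range for `discretized-lognormal`.
#' @return An object of class `marker_dist_spec`.
#' @export
marker_dist_spec <- function(marker, family, infected, non_infected,
                             floor = NULL, range = c(0L, 42L)) {
  family <- match.arg(family, c("lognormal", "normal", "discretized-lognormal"))
  chk <- function(x, who) {
    if (length(x) != 3L || anyNA(x)) {
      stop("marker ", marker, ": ", who, " must be c(median, q1, q3)")
    }
    x <- as.numeric(x)
    if (x[2] > x[1] || x[1] > x[3]) {
      stop("marker ", marker, " (", who, "): need q1 <= median <= q3")
    }
    if (family != "normal" && any(x <= 0)) {
      stop("marker ", marker, " (", who,
           "): lognormal families need strictly positive quantiles")
    }
    x
  }
  structure(list(marker = marker, family = family,
                 infected = chk(infected, "infected"),
                 non_infected = chk(non_infected, "non_infected"),
                 floor = if (!is.null(floor)) as.numeric(floor),
                 range = as.integer(range)),
            class = "marker_dist_spec")
}

#' @export
print.marker_dist_spec <- function(x, ...) {
  fmt <- function(q) sprintf("%g (%g-%g)", q[1], q[2], q[3])
  cat(sprintf("<marker_dist_spec> %s [%s]\n  infected:     %s\n  non-infected: %s\n",
              x$marker, x$family, fmt(x$infected), fmt(x$non_infected)))
  invisible(x)
}

#' Cohort specification
#'
#' Everything needed to generate one synthetic subgroup: exact class counts,
#' per-marker distribution specs and per-class categorical proportions.
#'
#' @param subgroup `"discovery"` or `"validation"`.
#' @param n_total,n_infected Class counts; `n_infected` infected records and
#'   `n_total - n_infected` non-infected records are generated exactly.
#' @param markers List of [marker_dist_spec()] objects.
#' @param sex_female Named numeric `c(non_infected=, infected=)` proportion
#'   of female patients per class.
#' @param cvrf Named list of per-class probability pairs for cardiovascular
#'   risk-factor flags, each `c(non_infected=, infected=)`.
#' @param toast Optional list with per-class probability vectors over TOAST
#'   stroke-etiology categories: `list(levels=, non_infected=, infected=)`.
#' @param seed Integer seed making the cohort a pure function of the spec.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(subgroup, n_total, n_infected, markers,
                        sex_female = NULL, cvrf = NULL, toast = NULL,
                        seed = 1L) {
  subgroup <- match.arg(subgroup, c("discovery", "validation"))
  n_total <- as.integer(n_total); n_infected <- as.integer(n_infected)
  if (is.na(n_total) || is.na(n_infected) || n_total < 0 ||
      n_infected < 0 || n_infected > n_total) {
    stop("invalid class counts: need 0 <= n_infected <= n_total")
  }
  stopifnot(all(vapply(markers, inherits, TRUE, "marker_dist_spec")))
  names(markers) <- vapply(markers, `[[`, "", "marker")
  prop_ok <- function(p) all(p >= 0 & p <= 1)
  if (!is.null(sex_female) && !prop_ok(sex_female)) {
    stop("sex_female proportions must lie in [0, 1]")
  }
  if (!is.null(cvrf) && !all(vapply(cvrf, prop_ok, TRUE))) {
    stop("cvrf proportions must lie in [0, 1]")
  }
  structure(list(subgroup = subgroup, n_total = n_total,
                 n_infected = n_infected, markers = markers,
                 sex_female = sex_female, cvrf = cvrf, toast = toast,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("<cohort_spec> %s: n = %d (%d infected, %d non-infected), seed %d\n",
              x$subgroup, x$n_total, x$n_infected,
              x$n_total - x$n_infected, x$seed))
  cat("  markers:", paste(names(x$markers), collapse = ", "), "\n")
  invisible(x)
}

# Published summary statistics of the 40-patient discovery subgroup
# (19 non-infected / 21 infected): per-class median (q1-q3) for each marker
# and per-class categorical proportions.
#' Built-in discovery-subgroup specification
#'
#' The 40-patient discovery subgroup (19 non-infected, 21 infected) with
#' class-conditional marker summaries taken from the published demographic
#' table: age and admission temperature are modelled normal, the NIHSS
#' discretized-lognormal, and the right-skewed labs (SAA, CRP, PCT, WBC,
#' monocytes) lognormal with a CRP detection floor at 3.
#'
#' @param seed Integer seed.
#' @return A [cohort_spec()].
#' @export
discovery_cohort_spec <- function(seed = 1L) {
  m <- list(
    marker_dist_spec("age", "normal",
                     infected = c(80.4, 69.5, 83), non_infected = c(78.26, 74.5, 80.5)),
    marker_dist_spec("nihss", "discretized-lognormal",
                     infected = c(12, 4, 14), non_infected = c(3, 2, 7)),
    marker_dist_spec("temperature", "normal",
                     infected = c(36.8, 36.2, 37.2), non_infected = c(37.1, 36.9, 37.3)),
    marker_dist_spec("saa", "lognormal",
                     infected = c(16.8, 7.1, 81.4), non_infected = c(4.27, 2.32, 8.39)),
    marker_dist_spec("crp", "lognormal",
                     infected = c(4.8, 3, 17.4), non_infected = c(3.6, 3, 6.65),
                     floor = 3),
    marker_dist_spec("pct", "lognormal",
                     infected = c(0.017, 0.012, 0.028), non_infected = c(0.013, 0.012, 0.02)),
    marker_dist_spec("wbc", "lognormal",
                     infected = c(9.3, 7.4, 11.2), non_infected = c(7.66, 6.3, 9.2)),
    marker_dist_spec("monocytes", "lognormal",
                     infected = c(0.44, 0.32, 0.52), non_infected = c(0.38, 0.32, 0.51))
  )
  cohort_spec(
    "discovery", n_total = 40L, n_infected = 21L, markers = m,
    sex_female = c(non_infected = 9 / 19, infected = 9 / 21),
    cvrf = list(
      hypertension      = c(non_infected = 12 / 19, infected = 19 / 21),
      atrial_fibrillation = c(non_infected = 3 / 19, infected = 6 / 21),
      smoking           = c(non_infected = 5 / 19, infected = 6 / 21),
      diabetes          = c(non_infected = 4 / 19, infected = 3 / 21),
      coronary_heart_disease = c(non_infected = 4 / 19, infected = 6 / 21)
    ),
    toast = list(
      levels = c("large_vessel", "cardioembolic", "microangiopathic",
                 "other", "unknown"),
      non_infected = c(3, 4, 5, 0, 7) / 19,
      infected = c(5, 4, 9, 0, 3) / 21
    ),
    seed = seed
  )
}

#' Built-in validation-subgroup specification
#'
#' The 243-patient validation subgroup (204 non-infected, 39 infected),
#' parameterized like [discovery_cohort_spec()].
#'
#' @param seed Integer seed.
#' @return A [cohort_spec()].
#' @export
validation_cohort_spec <- function(seed = 1L) {
  m <- list(
    marker_dist_spec("age", "normal",
                     infected = c(76.07, 68.7, 81.9), non_infected = c(74, 60.3, 81.6)),
    marker_dist_spec("nihss", "discretized-lognormal",
                     infected = c(9, 5.5, 18.5), non_infected = c(4, 2, 8)),
    marker_dist_spec("temperature", "normal",
                     infected = c(37.1, 36.8, 37.3), non_infected = c(37, 36.6, 37.5)),
    marker_dist_spec("saa", "lognormal",
                     infected = c(16.7, 4.7, 89.2), non_infected = c(4.97, 2.52, 12.7)),
    marker_dist_spec("crp", "lognormal",
                     infected = c(5.6, 3, 15.8), non_infected = c(3, 3, 5.7),
                     floor = 3),
    marker_dist_spec("pct", "lognormal",
                     infected = c(0.02, 0.01, 0.03), non_infected = c(0.02, 0.012, 0.02)),
    marker_dist_spec("wbc", "lognormal",
                     infected = c(9.77, 7.75, 11.7), non_infected = c(7.8, 6.4, 9.4)),
    marker_dist_spec("monocytes", "lognormal",
                     infected = c(0.38, 0.31, 0.51), non_infected = c(0.38, 0.29, 0.48))
  )
  cohort_spec(
    "validation", n_total = 243L, n_infected = 39L, markers = m,
    sex_female = c(non_infected = 72 / 204, infected = 25 / 39),
    cvrf = list(
      hypertension      = c(non_infected = 147 / 204, infected = 35 / 39),
      atrial_fibrillation = c(non_infected = 35 / 204, infected = 13 / 39),
      smoking           = c(non_infected = 75 / 204, infected = 18 / 39),
      diabetes          = c(non_infected = 39 / 204, infected = 9 / 39),
      coronary_heart_disease = c(non_infected = 46 / 204, infected = 5 / 39)
    ),
    toast = list(
      levels = c("large_vessel", "cardioembolic", "microangiopathic",
                 "other", "unknown"),
      non_infected = c(40, 39, 63, 12, 49) / 203,
      infected = c(6, 2, 20, 2, 9) / 39
    ),
    seed = seed
  )
}

#' Read / write a cohort specification as JSON
#'
#' Serializes a [cohort_spec()] (counts, per-marker per-class quantile
#' triples, categorical proportions, seed) so that a study is fully
#' reproducible from a plain-text config file.
#'
#' @param spec A `cohort_spec`.
#' @param path File path.
#' @return `write_cohort_spec_json()` returns `path` invisibly;
#'   `read_cohort_spec_json()` returns a `cohort_spec`.
#' @export
write_cohort_spec_json <- function(spec, path) {
  stopifnot(inherits(spec, "cohort_spec"))
  x <- list(
    subgroup = spec$subgroup, n_total = spec$n_total,
    n_infected = spec$n_infected, seed = spec$seed,
    markers = lapply(unname(spec$markers), function(m) {
      out <- list(marker = m$marker, family = m$family,
                  infected = m$infected, non_infected = m$non_infected)
      if (!is.null(m$floor)) out$floor <- m$floor
      if (m$family == "discretized-lognormal") out$range <- m$range
      out
    }),
    sex_female = as.list(spec$sex_female),
    cvrf = lapply(spec$cvrf, as.list),
    toast = spec$toast
  )
  # I(17) significant digits: decimal round-trip of doubles is exact
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_cohort_spec_json
#' @export
read_cohort_spec_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE)
  mk <- function(m) {
    floor <- m$floor
    if (!is.null(floor) && is.na(floor)) floor <- NULL
    marker_dist_spec(m$marker, m$family,
                     infected = unlist(m$infected),
                     non_infected = unlist(m$non_infected),
                     floor = floor,
                     range = if (!is.null(m$range)) {
                       as.integer(unlist(m$range))
                     } else c(0L, 42L))
  }
  markers <- lapply(x$markers, mk)
  toast <- x$toast
  if (!is.null(toast)) {
    toast <- list(levels = unlist(toast$levels),
                  non_infected = unlist(toast$non_infected),
                  infected = unlist(toast$infected))
  }
  cohort_spec(x$subgroup, x$n_total, x$n_infected, markers,
              sex_female = unlist(x$sex_female),
              cvrf = lapply(x$cvrf, unlist),
              toast = toast, seed = x$seed)
}
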