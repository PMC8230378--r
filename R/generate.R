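# Synthetic cohort generation and CSV round-trip.

COHORT_CORE_COLS <- c("id", "subgroup", "infected", "age", "sex", "nihss",
                      "temperature", "saa", "crp", "pct", "wbc", "monocytes")

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  code
}

draw_marker <- function(m, class, n) {
  q <- m[[class]]
  fit_norm <- function() {
    list(mean = q[1], sd = (q[3] - q[2]) / (2 * Z75))
  }
  x <- switch(
    m$family,
    "normal" = {
      p <- fit_norm()
      stats::rnorm(n, p$mean, p$sd)
    },
    "lognormal" = {
      p <- fit_lognormal_from_quantiles(q[1], q[2], q[3])
      stats::rlnorm(n, p$mu, p$sigma)
    },
    "discretized-lognormal" = {
      p <- fit_lognormal_from_quantiles(q[1], q[2], q[3])
      v <- round(stats::rlnorm(n, p$mu, p$sigma))
      pmin(pmax(v, m$range[1]), m$range[2])
    }
  )
  if (!is.null(m$floor)) x <- pmax(x, m$floor)
  x
}

#' Generate a synthetic patient cohort
#'
#' Draws a patient-level table whose class-conditional marker distributions
#' are calibrated to the spec's median/IQR triples. Class counts are exact
#' (not in expectation): exactly `n_infected` infected rows are produced.
#' Markers are drawn independently within class; see the methods vignette
#' for why and for what that leaves out.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed; defaults to `spec$seed`. The cohort is a pure
#'   function of `(spec, seed)`.
#' @return A `data.frame` of class `cohort` with columns
#'   `id, subgroup, infected, age, sex, nihss, temperature, saa, crp, pct,
#'   wbc, monocytes`, plus CVRF flags and `toast` when the spec carries
#'   them. Attributes `spec` and `seed` record provenance.
#' @export
generate_cohort <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  required <- c("age", "nihss", "temperature", "saa", "crp", "pct", "wbc",
                "monocytes")
  missing_m <- setdiff(required, names(spec$markers))
  if (length(missing_m)) {
    stop("cohort_spec lacks marker specs for: ",
         paste(missing_m, collapse = ", "))
  }
  n1 <- spec$n_infected
  n0 <- spec$n_total - spec$n_infected
  with_seed(seed, {
    infected <- c(rep(FALSE, n0), rep(TRUE, n1))
    n <- length(infected)
    prefix <- toupper(substr(spec$subgroup, 1L, 1L))
    df <- data.frame(
      id = if (n) sprintf("%s%03d", prefix, seq_len(n)) else character(),
      subgroup = rep(spec$subgroup, n),
      infected = infected,
      stringsAsFactors = FALSE
    )
    per_class <- function(fun0, fun1) c(fun0(n0), fun1(n1))
    for (nm in required) {
      m <- spec$markers[[nm]]
      df[[nm]] <- per_class(function(k) draw_marker(m, "non_infected", k),
                            function(k) draw_marker(m, "infected", k))
    }
    df$sex <- if (!is.null(spec$sex_female)) {
      p <- spec$sex_female
      fem <- per_class(function(k) stats::runif(k) < p[["non_infected"]],
                       function(k) stats::runif(k) < p[["infected"]])
      ifelse(fem, "female", "male")
    } else {
      rep("female", n)
    }
    df <- df[, intersect(COHORT_CORE_COLS, names(df))]
    for (flag in names(spec$cvrf)) {
      p <- spec$cvrf[[flag]]
      df[[flag]] <- per_class(function(k) stats::runif(k) < p[["non_infected"]],
                              function(k) stats::runif(k) < p[["infected"]])
    }
    if (!is.null(spec$toast)) {
      t <- spec$toast
      samp <- function(k, p) {
        if (k == 0) character() else sample(t$levels, k, TRUE, prob = p)
      }
      df$toast <- per_class(function(k) samp(k, t$non_infected),
                            function(k) samp(k, t$infected))
    }
    structure(df, spec = spec, seed = as.integer(seed),
              class = c("cohort", "data.frame"))
  })
}

#' Write a cohort to CSV
#'
#' Plain UTF-8 comma-separated file whose header starts with the canonical
#' columns `id,subgroup,infected,age,sex,nihss,temperature,saa,crp,pct,wbc,
#' monocytes` (extra columns appended). `infected` and logical flags are
#' encoded 0/1; missing cells as empty strings. Doubles are written with 17
#' significant digits so that write/read round-trips exactly.
#'
#' @param cohort A `cohort` (or compatible data.frame).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  stopifnot(is.data.frame(cohort))
  miss <- setdiff(COHORT_CORE_COLS, names(cohort))
  if (length(miss)) {
    stop("cohort lacks required columns: ", paste(miss, collapse = ", "))
  }
  df <- cohort[, c(COHORT_CORE_COLS,
                   setdiff(names(cohort), COHORT_CORE_COLS)), drop = FALSE]
  out <- lapply(df, function(col) {
    if (is.logical(col)) {
      ifelse(is.na(col), "", as.character(as.integer(col)))
    } else if (is.double(col)) {
      ifelse(is.na(col), "", sprintf("%.17g", col))
    } else {
      ifelse(is.na(col), "", as.character(col))
    }
  })
  m <- do.call(cbind, out)
  lines <- c(paste(names(df), collapse = ","),
             if (nrow(df)) apply(m, 1L, paste, collapse = ","))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a cohort from CSV
#'
#' Inverse of [write_cohort_csv()]. Validates the header, coerces marker
#' columns to numeric with an error naming the offending row and column,
#' and enforces that `nihss` is an integer in `[0, 42]`. Unknown columns
#' are kept with a warning; empty cells become `NA`.
#'
#' @param path CSV file path.
#' @return A `cohort` data.frame.
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = FALSE)
  miss <- setdiff(COHORT_CORE_COLS, names(df))
  if (length(miss)) {
    stop("cohort CSV lacks required columns: ", paste(miss, collapse = ", "))
  }
  known_logical <- c("infected", "hypertension", "atrial_fibrillation",
                     "smoking", "diabetes", "coronary_heart_disease")
  known <- c(COHORT_CORE_COLS, known_logical, "toast")
  unknown <- setdiff(names(df), known)
  # extra numeric-looking columns are tolerated (markers beyond the core set)
  if (length(unknown)) {
    warning("unknown column(s) in cohort CSV kept as-is: ",
            paste(unknown, collapse = ", "))
  }
  num_cols <- c("age", "temperature", "saa", "crp", "pct", "wbc", "monocytes")
  parse_num <- function(col) {
    raw <- df[[col]]
    raw[raw == ""] <- NA_character_
    x <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & is.na(x))
    if (length(bad)) {
      stop("non-numeric value ", dQuote(raw[bad[1]]), " in column '", col,
           "', row ", bad[1])
    }
    x
  }
  for (col in num_cols) df[[col]] <- parse_num(col)
  nihss <- parse_num("nihss")
  frac <- which(!is.na(nihss) & nihss %% 1 != 0)
  if (length(frac)) {
    stop("non-integer value ", nihss[frac[1]], " in column 'nihss', row ",
         frac[1], " (NIHSS must be an integer in [0, 42])")
  }
  if (any(nihss < 0 | nihss > 42, na.rm = TRUE)) {
    stop("NIHSS outside [0, 42] in column 'nihss'")
  }
  df$nihss <- as.integer(nihss)
  for (col in intersect(known_logical, names(df))) {
    raw <- df[[col]]
    raw[raw == ""] <- NA_character_
    val <- suppressWarnings(as.integer(raw))
    bad <- which(!is.na(raw) & (is.na(val) | !val %in% c(0L, 1L)))
    if (length(bad)) {
      stop("column '", col, "' must be 0/1; row ", bad[1], " has ",
           dQuote(raw[bad[1]]))
    }
    df[[col]] <- as.logical(val)
  }
  for (col in unknown) {
    x <- suppressWarnings(as.numeric(ifelse(df[[col]] == "", NA, df[[col]])))
    if (!all(is.na(x) == (df[[col]] == ""))) next
    df[[col]] <- x
  }
  structure(df, class = c("cohort", "data.frame"))
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %s: %d patients (%d infected, %d non-infected)\n",
              if (nrow(x)) x$subgroup[1] else "(empty)", nrow(x),
              sum(x$infected), sum(!x$infected)))
  NextMethod()
}
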