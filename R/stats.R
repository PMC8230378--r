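# Demographic-table statistics: median/IQR summaries, Mann-Whitney U,
# Fisher exact, chi-squared, and n (%) crosstab rows.
#
# The tests are implemented from first principles (with exact enumeration
# where small counts allow) rather than wrapping stats::wilcox.test etc.,
# so that the test suite can use the base-R routines as independent oracles.

#' Median and interquartile range
#'
#' Quantiles by the linear-interpolation convention (type 7).
#'
#' @param values Non-empty numeric vector; `NA`s are dropped.
#' @return Named numeric `c(median, q1, q3)`.
#' @export
median_iqr <- function(values) {
  values <- values[!is.na(values)]
  if (!length(values)) stop("median_iqr: empty input")
  q <- unname(stats::quantile(values, c(0.5, 0.25, 0.75), type = 7))
  c(median = q[1], q1 = q[2], q3 = q[3])
}

mw_u_statistic <- function(x, y) {
  # number of (x_i, y_j) pairs with x_i > y_j, ties counted 1/2
  sum(vapply(x, function(xi) sum(xi > y) + 0.5 * sum(xi == y), 0))
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum comparison of two unpaired groups. `U` counts pairs
#' `(x_i, y_j)` with `x_i > y_j` plus half the tied pairs. The p-value is
#' computed by exact enumeration over all group assignments when
#' `length(x) + length(y) <= exact_limit`, otherwise by the normal
#' approximation with tie correction and a 0.5 continuity correction. The
#' two-sided p doubles the smaller one-sided tail, capped at 1.
#'
#' @param x,y Non-empty numeric vectors.
#' @param exact_limit Total-size threshold for exact enumeration.
#' @return List with `U`, `p_value`, and `method` (`"exact"` or
#'   `"normal-approximation"`).
#' @export
mann_whitney_u <- function(x, y, exact_limit = 12L) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) || !length(y)) stop("mann_whitney_u: empty group")
  nx <- length(x); ny <- length(y); n <- nx + ny
  U <- mw_u_statistic(x, y)
  if (n <= exact_limit) {
    pool <- c(x, y)
    idx <- utils::combn(n, nx)
    us <- apply(idx, 2L, function(i) mw_u_statistic(pool[i], pool[-i]))
    eps <- 1e-9
    p_lo <- mean(us <= U + eps)
    p_hi <- mean(us >= U - eps)
    p <- min(1, 2 * min(p_lo, p_hi))
    return(list(U = U, p_value = p, method = "exact"))
  }
  mu <- nx * ny / 2
  ties <- table(c(x, y))
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- nx * ny / 12 * ((n + 1) - tie_term)
  if (sigma2 <= 0) {
    return(list(U = U, p_value = 1, method = "normal-approximation"))
  }
  z <- (abs(U - mu) - 0.5) / sqrt(sigma2)
  z <- max(z, 0)
  p <- min(1, 2 * stats::pnorm(z, lower.tail = FALSE))
  list(U = U, p_value = p, method = "normal-approximation")
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value: the sum of hypergeometric probabilities, with both
#' margins fixed, of every table whose probability does not exceed the
#' observed table's (up to a small relative tolerance).
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return The two-sided p-value.
#' @export
fisher_exact_2x2 <- function(table) {
  tab <- as.matrix(table)
  if (!all(dim(tab) == c(2L, 2L))) stop("fisher_exact_2x2: need a 2x2 table")
  if (any(tab < 0) || any(tab %% 1 != 0)) {
    stop("fisher_exact_2x2: counts must be non-negative integers")
  }
  a <- tab[1, 1]
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); N <- sum(tab)
  if (N == 0) return(1)
  lo <- max(0, r1 + c1 - N); hi <- min(r1, c1)
  support <- lo:hi
  logp <- lchoose(c1, support) + lchoose(N - c1, r1 - support) -
    lchoose(N, r1)
  p_obs <- logp[support == a]
  sum(exp(logp[logp <= p_obs + 1e-7]))
}

#' Pearson chi-squared test for a 2 x k table
#'
#' Statistic `sum((O - E)^2 / E)` with `df = k - 1`; no continuity
#' correction by default (Yates available via `correct = TRUE` for the
#' 2x2 case).
#'
#' @param table 2 x k matrix of counts (k >= 2).
#' @param correct Apply the Yates continuity correction (2x2 only).
#' @return List with `statistic`, `df`, `p_value`.
#' @export
chi_squared_2xk <- function(table, correct = FALSE) {
  tab <- as.matrix(table)
  if (nrow(tab) != 2L || ncol(tab) < 2L) {
    stop("chi_squared_2xk: need a 2 x k table with k >= 2")
  }
  if (any(tab < 0)) stop("chi_squared_2xk: negative counts")
  rs <- rowSums(tab); cs <- colSums(tab); N <- sum(tab)
  if (any(rs == 0) || any(cs == 0)) {
    stop("chi_squared_2xk: zero row or column margin")
  }
  E <- outer(rs, cs) / N
  d <- abs(tab - E)
  if (correct && ncol(tab) == 2L) d <- pmax(d - 0.5, 0)
  stat <- sum(d^2 / E)
  df <- ncol(tab) - 1L
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Crosstab row for a binary flag against infection status
#'
#' Reproduces the demographic tables' `n (%)` rows: among flagged patients,
#' the count and percentage (one decimal) infected and non-infected.
#'
#' @param flag,infected Logical vectors of equal length.
#' @return List with `n_flagged`, `n_infected`, `n_non_infected`,
#'   `pct_infected`, `pct_non_infected` (percentages are `NA` when no
#'   patient carries the flag).
#' @export
crosstab_percentages <- function(flag, infected) {
  stopifnot(length(flag) == length(infected))
  keep <- !is.na(flag) & !is.na(infected)
  flag <- flag[keep]; infected <- infected[keep]
  n <- sum(flag)
  n1 <- sum(flag & infected)
  n0 <- n - n1
  pct <- function(k) if (n == 0) NA_real_ else round(100 * k / n, 1)
  list(n_flagged = n, n_infected = n1, n_non_infected = n0,
       pct_infected = pct(n1), pct_non_infected = pct(n0))
}

#' Demographics comparison table for a cohort
#'
#' Summarizes each numeric variable as per-class median (IQR) with a
#' Mann-Whitney p-value, and each categorical/flag variable as counts with
#' a Fisher (when any expected cell count is below `fisher_threshold`) or
#' chi-squared p-value; the chosen test is recorded per row.
#'
#' @param cohort A cohort data.frame with an `infected` column.
#' @param numeric_vars,flag_vars Column names to summarize.
#' @param fisher_threshold Expected-count threshold switching to Fisher.
#' @return A list of per-variable comparison rows (class
#'   `group_comparison_table`).
#' @export
cohort_summary_table <- function(cohort,
                                 numeric_vars = c("age", "nihss",
                                                  "temperature", "wbc", "crp",
                                                  "monocytes", "pct", "saa"),
                                 flag_vars = intersect(
                                   c("hypertension", "atrial_fibrillation",
                                     "smoking", "diabetes",
                                     "coronary_heart_disease"),
                                   names(cohort)),
                                 fisher_threshold = 5) {
  stopifnot(is.data.frame(cohort), "infected" %in% names(cohort))
  inf <- as.logical(cohort$infected)
  rows <- list()
  for (v in intersect(numeric_vars, names(cohort))) {
    x <- cohort[[v]][inf]; y <- cohort[[v]][!inf]
    test <- mann_whitney_u(x, y)
    rows[[v]] <- list(variable = v, type = "numeric",
                      infected = median_iqr(x),
                      non_infected = median_iqr(y),
                      test = paste0("mann-whitney-", test$method),
                      statistic = test$U, p_value = test$p_value)
  }
  if ("sex" %in% names(cohort)) flag_vars <- c("sex", flag_vars)
  for (v in flag_vars) {
    flag <- if (v == "sex") cohort$sex == "female" else as.logical(cohort[[v]])
    tab <- rbind(c(sum(flag & inf), sum(flag & !inf)),
                 c(sum(!flag & inf), sum(!flag & !inf)))
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(E < fisher_threshold)) {
      rows[[v]] <- list(variable = v, type = "flag",
                        cross = crosstab_percentages(flag, inf),
                        test = "fisher-exact", statistic = NA_real_,
                        p_value = fisher_exact_2x2(tab))
    } else {
      ch <- chi_squared_2xk(tab)
      rows[[v]] <- list(variable = v, type = "flag",
                        cross = crosstab_percentages(flag, inf),
                        test = "chi-squared", statistic = ch$statistic,
                        p_value = ch$p_value)
    }
  }
  structure(rows, class = "group_comparison_table")
}

#' @export
print.group_comparison_table <- function(x, ...) {
  cat("<group_comparison_table>\n")
  for (r in x) {
    if (r$type == "numeric") {
      fmt <- function(q) sprintf("%.3g (%.3g-%.3g)", q[1], q[2], q[3])
      cat(sprintf("  %-24s inf %s  non-inf %s  p=%.3g [%s]\n", r$variable,
                  fmt(r$infected), fmt(r$non_infected), r$p_value, r$test))
    } else {
      cat(sprintf("  %-24s n=%d (%.1f%% infected)  p=%.3g [%s]\n", r$variable,
                  r$cross$n_flagged,
                  if (is.na(r$cross$pct_infected)) NA else r$cross$pct_infected,
                  r$p_value, r$test))
    }
  }
  invisible(x)
}
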