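# Independent oracles and fixture builders shared across the suite.
# Each oracle is a deliberately naive reimplementation (or a base-R
# routine) kept separate from the package's code paths.

# small random cohort with numeric markers a, b, c
make_toy_cohort <- function(n, seed, p_inf = 0.4, shift = 1) {
  set.seed(seed)
  repeat {
    infected <- stats::runif(n) < p_inf
    if (any(infected) && !all(infected)) break
  }
  data.frame(
    a = stats::rnorm(n) + shift * infected,
    b = stats::rnorm(n) + 0.5 * shift * infected,
    c = stats::rnorm(n),
    infected = infected
  )
}

# quadruple-loop panel search: subsets x cutoffs x k, same objective and
# primary/secondary tie handling as the package (deeper ties unchecked)
naive_panel_search <- function(cohort, markers, mode = "high-se", s = 0.95,
                               cap = 10) {
  truth <- cohort$infected
  best <- NULL
  update <- function(best, obj, sec) {
    if (is.null(best) || obj > best$obj + 1e-12 ||
        (abs(obj - best$obj) < 1e-12 && sec > best$sec + 1e-12)) {
      list(obj = obj, sec = sec)
    } else best
  }
  for (sz in seq_along(markers)) {
    for (S in utils::combn(sort(markers), sz, simplify = FALSE)) {
      grids <- lapply(S, function(m) candidate_thresholds(cohort[[m]], cap))
      if (any(vapply(grids, length, 0L) == 0L)) next
      combos <- expand.grid(lapply(grids, seq_along))
      for (ri in seq_len(nrow(combos))) {
        votes <- rep(0, nrow(cohort))
        for (j in seq_len(sz)) {
          votes <- votes + (cohort[[S[j]]] > grids[[j]][combos[ri, j]])
        }
        for (k in seq_len(sz)) {
          pred <- votes >= k
          se <- sum(pred & truth) / sum(truth)
          sp <- sum(!pred & !truth) / sum(!truth)
          feas <- if (mode == "high-se") se >= s - 1e-12 else sp >= s - 1e-12
          if (!feas) next
          if (mode == "high-se") best <- update(best, sp, se)
          else best <- update(best, se, sp)
        }
      }
    }
  }
  best
}

# brute-force class-association miner: double loop over all conjunctions
naive_mine_rules <- function(cohort, bins, min_support, min_confidence,
                             max_lhs_size) {
  markers <- names(bins)
  N <- nrow(cohort)
  out <- list()
  for (sz in seq_len(min(max_lhs_size, length(markers)))) {
    for (S in utils::combn(markers, sz, simplify = FALSE)) {
      combos <- expand.grid(lapply(S, function(m) seq_along(bins[[m]])))
      for (ri in seq_len(nrow(combos))) {
        match_vec <- rep(TRUE, N)
        for (j in seq_len(sz)) {
          itv <- bins[[S[j]]][[combos[ri, j]]]
          v <- cohort[[S[j]]]
          match_vec <- match_vec & v >= itv[["lo"]] & v < itv[["hi"]]
        }
        nA <- sum(match_vec)
        if (nA == 0) next
        for (rhs in c("infected", "non_infected")) {
          B <- if (rhs == "infected") cohort$infected else !cohort$infected
          supp <- sum(match_vec & B) / N
          conf <- sum(match_vec & B) / nA
          if (supp >= min_support - 1e-12 && conf >= min_confidence - 1e-12) {
            key <- paste(S, vapply(seq_len(sz), function(j) {
              paste(bins[[S[j]]][[combos[ri, j]]], collapse = "_")
            }, ""), rhs, collapse = "|")
            out[[key]] <- c(support = supp, confidence = conf)
          }
        }
      }
    }
  }
  out
}

# hypergeometric enumeration: two-sided Fisher p for fixed margins
fisher_enum_p <- function(a, r1, c1, N) {
  lo <- max(0, r1 + c1 - N)
  hi <- min(r1, c1)
  probs <- stats::dhyper(lo:hi, c1, N - c1, r1)
  sum(probs[probs <= probs[a - lo + 1] * (1 + 1e-7)])
}

# exhaustive best split by direct enumeration
naive_best_split <- function(data, markers, min_leaf) {
  labels <- data$infected
  n <- nrow(data)
  gini <- function(l) {
    if (!length(l)) return(0)
    p <- mean(l)
    1 - p^2 - (1 - p)^2
  }
  parent <- gini(labels) * n
  best <- NULL
  for (m in sort(markers)) {
    u <- sort(unique(data[[m]]))
    if (length(u) < 2) next
    for (cut in (u[-1] + u[-length(u)]) / 2) {
      left <- data[[m]] <= cut
      if (sum(left) < min_leaf || sum(!left) < min_leaf) next
      dec <- (parent - gini(labels[left]) * sum(left) -
                gini(labels[!left]) * sum(!left)) / n
      if (dec > 1e-12 && (is.null(best) || dec > best$decrease + 1e-12)) {
        best <- list(marker = m, cutoff = cut, decrease = dec)
      }
    }
  }
  best
}
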