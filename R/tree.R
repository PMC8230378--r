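# CART-style classification tree: binary splits on marker thresholds,
# impurity-driven, regularized only by a minimum terminal-node size.

#' Gini impurity of a two-class node
#'
#' `1 - p0^2 - p1^2`; 0 for a pure node, 0.5 at a 50/50 split.
#'
#' @param class_counts Numeric pair `c(n_non_infected, n_infected)` (order
#'   irrelevant).
#' @return Impurity in `[0, 0.5]`.
#' @export
gini_impurity <- function(class_counts) {
  n <- sum(class_counts)
  if (n <= 0) stop("gini_impurity: empty node")
  p <- class_counts / n
  1 - sum(p^2)
}

entropy_impurity <- function(class_counts) {
  n <- sum(class_counts)
  if (n <= 0) stop("entropy_impurity: empty node")
  p <- class_counts / n
  p <- p[p > 0]
  -sum(p * log2(p))
}

node_impurity <- function(labels, criterion) {
  counts <- c(sum(!labels), sum(labels))
  if (criterion == "gini") gini_impurity(counts) else entropy_impurity(counts)
}

#' Best single split of a node
#'
#' Searches all markers and all midpoint cutoffs between adjacent distinct
#' values for the split maximizing the decrease in size-weighted impurity
#' (patients with value `<= cutoff` go left, `> cutoff` right). Returns
#' `NULL` when no split decreases impurity or every candidate would leave a
#' child smaller than `min_leaf`. Ties break by larger decrease, then
#' marker name order, then lower cutoff.
#'
#' @param data Cohort rows at the node (needs `infected`).
#' @param markers Candidate marker columns.
#' @param min_leaf Minimum child size.
#' @param criterion `"gini"` (default) or `"entropy"`.
#' @return `NULL`, or a list `marker`, `cutoff`, `decrease`.
#' @export
best_split <- function(data, markers, min_leaf = 1L,
                       criterion = c("gini", "entropy")) {
  criterion <- match.arg(criterion)
  stopifnot(nrow(data) > 0)
  labels <- as.logical(data$infected)
  n <- length(labels)
  parent <- node_impurity(labels, criterion) * n
  best <- NULL
  for (m in sort(markers)) {
    v <- data[[m]]
    u <- sort(unique(v))
    if (length(u) < 2L) next
    for (cut in (u[-1] + u[-length(u)]) / 2) {
      left <- v <= cut
      nl <- sum(left)
      if (nl < min_leaf || n - nl < min_leaf) next
      child <- node_impurity(labels[left], criterion) * nl +
        node_impurity(labels[!left], criterion) * (n - nl)
      dec <- (parent - child) / n
      if (dec > 1e-12 && (is.null(best) || dec > best$decrease + 1e-12)) {
        best <- list(marker = m, cutoff = cut, decrease = dec)
      }
    }
  }
  best
}

#' Grow a classification tree
#'
#' Recursive application of [best_split()]; growth at a node stops when the
#' node is pure, no split decreases impurity, or any split would violate
#' `min_leaf`. Leaves predict their majority class; exact ties predict
#' non-infected, the triage-safe default (a tie must not favor the
#' intervention class).
#'
#' @param cohort Training cohort.
#' @param markers Candidate marker columns.
#' @param min_leaf Minimum number of patients in each terminal node.
#' @param criterion Impurity criterion.
#' @return A nested list of class `tree_node`: internal nodes carry
#'   `marker`, `cutoff`, `left` (`<= cutoff`), `right` (`> cutoff`);
#'   leaves carry `class` and `counts`.
#' @export
grow_tree <- function(cohort, markers = c("saa", "crp", "pct", "wbc",
                                          "monocytes", "nihss",
                                          "temperature"),
                      min_leaf = 4L, criterion = c("gini", "entropy")) {
  criterion <- match.arg(criterion)
  stopifnot(min_leaf >= 1L, nrow(cohort) > 0)
  markers <- intersect(markers, names(cohort))
  build <- function(data) {
    labels <- as.logical(data$infected)
    counts <- c(non_infected = sum(!labels), infected = sum(labels))
    leaf <- structure(list(
      class = if (counts[["infected"]] > counts[["non_infected"]]) {
        "infected"
      } else "non_infected",
      counts = counts), class = "tree_node")
    sp <- best_split(data, markers, min_leaf = min_leaf,
                     criterion = criterion)
    if (is.null(sp)) return(leaf)
    left <- data[[sp$marker]] <= sp$cutoff
    structure(list(marker = sp$marker, cutoff = sp$cutoff,
                   counts = counts,
                   left = build(data[left, , drop = FALSE]),
                   right = build(data[!left, , drop = FALSE])),
              class = "tree_node")
  }
  build(cohort)
}

is_leaf <- function(node) is.null(node$marker)

#' Predict with a classification tree
#'
#' Deterministic root-to-leaf descent: value `> cutoff` goes right.
#'
#' @param tree A [grow_tree()] result.
#' @param patients Cohort data.frame.
#' @return Character vector `"infected"` / `"non_infected"`.
#' @export
predict_tree <- function(tree, patients) {
  one <- function(node, row) {
    while (!is_leaf(node)) {
      v <- if (node$marker %in% names(row)) row[[node$marker]] else NULL
      if (is.null(v) || is.na(v)) {
        stop("unclassifiable: patient lacks marker '", node$marker, "'")
      }
      node <- if (v > node$cutoff) node$right else node$left
    }
    node$class
  }
  vapply(seq_len(nrow(patients)), function(i) one(tree, patients[i, ]), "")
}

#' Confusion performance of a tree on a cohort
#'
#' @param tree A `tree_node`.
#' @param cohort Cohort with an `infected` column.
#' @return A [perf_report()].
#' @export
tree_performance <- function(tree, cohort) {
  pred <- predict_tree(tree, cohort) == "infected"
  perf_report(pred, as.logical(cohort$infected))
}

tree_markers <- function(tree) {
  if (is_leaf(tree)) return(character())
  sort(unique(c(tree$marker, tree_markers(tree$left),
                tree_markers(tree$right))))
}

tree_to_list <- function(tree) {
  if (is_leaf(tree)) {
    list(class = tree$class, counts = as.list(tree$counts))
  } else {
    list(marker = tree$marker, cutoff = tree$cutoff,
         counts = as.list(tree$counts),
         left = tree_to_list(tree$left), right = tree_to_list(tree$right))
  }
}

#' @export
print.tree_node <- function(x, ..., indent = "") {
  if (is_leaf(x)) {
    cat(sprintf("%sleaf: %s (non-inf %d / inf %d)\n", indent, x$class,
                x$counts[["non_infected"]], x$counts[["infected"]]))
  } else {
    cat(sprintf("%s%s <= %g ?\n", indent, x$marker, x$cutoff))
    print(x$left, indent = paste0(indent, "  "))
    print(x$right, indent = paste0(indent, "  "))
  }
  invisible(x)
}
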