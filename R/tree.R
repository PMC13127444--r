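# From-scratch CART: regression trees split on sum-of-squared-deviation
# reduction, classification trees on Gini impurity. The exhaustive split
# scan lives in compiled code (src/cart.cpp); recursion, prediction, and
# rule accounting live here.

#' Gini impurity of a class-count vector
#'
#' `1 - sum((n_k / n)^2)`; at most 0.5 for two classes, 0 for a pure node.
#'
#' @param class_counts nonnegative counts per class, total > 0.
#' @return impurity in `[0, 1)`.
#' @export
gini_impurity <- function(class_counts) {
  if (any(class_counts < 0)) stop("class counts must be >= 0")
  n <- sum(class_counts)
  if (n == 0) stop("total class count must be > 0")
  1 - sum((class_counts / n)^2)
}

#' Best CART split of a node
#'
#' Exhaustive scan over all features and all midpoints between consecutive
#' distinct sorted values. The gain is parent impurity minus the combined
#' child impurity (absolute SSE sums for regression; size-weighted mean
#' Gini for classification). Ties — gains within a small tolerance
#' proportional to the parent impurity — resolve to the lower feature
#' index, then the lower threshold.
#'
#' @param X numeric matrix, samples in rows.
#' @param y response: numeric (`"sse"`) or 0/1 (`"gini"`).
#' @param criterion `"sse"` or `"gini"`.
#' @param min_samples_leaf minimum rows per child.
#' @param idx optional row subset (default all rows).
#' @return list with `feature` (column name or index), `feature_index`,
#'   `threshold`, `gain`, and the parent `impurity`; or `NULL` when no
#'   admissible split exists or no split improves impurity.
#' @export
best_split <- function(X, y, criterion = c("sse", "gini"),
                       min_samples_leaf = 5, idx = seq_len(nrow(X))) {
  criterion <- match.arg(criterion)
  res <- cpp_best_split(X, as.integer(idx), as.numeric(y),
                        if (criterion == "sse") 0L else 1L,
                        as.integer(min_samples_leaf))
  if (!res$found || res$gain <= 0) return(NULL)
  feat <- if (!is.null(colnames(X))) colnames(X)[res$feature] else res$feature
  list(feature = feat, feature_index = res$feature,
       threshold = res$threshold, gain = res$gain, impurity = res$impurity)
}

node_prediction <- function(y, task, levels) {
  if (task == "regression") return(mean(y))
  counts <- c(sum(y == 0), sum(y == 1))
  # majority class; deterministic tie-break to the first class
  if (counts[1] >= counts[2]) levels[1] else levels[2]
}

#' Fit a CART decision tree
#'
#' Recursive partitioning by [best_split()] until a stop rule fires
#' (maximum depth, minimum leaf size, or no split with gain above
#' `min_gain`). Regression leaves predict the mean response;
#' classification leaves the majority class with a deterministic tie-break
#' to the first class level.
#'
#' @param X numeric matrix, samples in rows, features in columns.
#' @param y numeric response (regression) or two-level response
#'   (classification; logical, factor, or 0/1).
#' @param task `"regression"` or `"classification"`.
#' @param max_depth maximum split depth (`Inf` = unlimited; 0 gives a
#'   single leaf).
#' @param min_samples_leaf minimum samples per leaf.
#' @param min_gain minimum impurity gain to accept a split.
#' @return a `cart_tree` object.
#' @export
fit_tree <- function(X, y, task = c("regression", "classification"),
                     max_depth = Inf, min_samples_leaf = 5, min_gain = 0) {
  task <- match.arg(task)
  X <- as.matrix(X)
  if (nrow(X) == 0) stop("empty input")
  if (length(y) != nrow(X)) stop("y must match rows of X")
  if (any(!is.finite(X))) stop("X must be finite")
  levels_ <- NULL
  if (task == "classification") {
    yf <- if (is.factor(y)) y else factor(y)
    if (nlevels(yf) > 2) stop("classification supports two classes")
    levels_ <- levels(yf)
    y <- as.numeric(yf) - 1
  } else {
    y <- as.numeric(y)
  }
  criterion <- if (task == "regression") "sse" else "gini"
  n_root <- nrow(X)

  grow <- function(idx, depth) {
    yv <- y[idx]
    node <- list(n = length(idx), depth = depth,
                 prediction = node_prediction(yv, task, levels_))
    if (task == "classification")
      node$class_counts <- setNames(c(sum(yv == 0), sum(yv == 1)), levels_)
    split <- NULL
    if (depth < max_depth && length(idx) >= 2 * min_samples_leaf)
      split <- best_split(X, y, criterion, min_samples_leaf, idx)
    if (is.null(split) || split$gain <= min_gain) {
      node$is_leaf <- TRUE
      return(node)
    }
    node$is_leaf <- FALSE
    node$feature <- split$feature
    node$feature_index <- split$feature_index
    node$threshold <- split$threshold
    node$gain <- split$gain
    node$impurity <- split$impurity
    left_idx <- idx[X[idx, split$feature_index] <= split$threshold]
    right_idx <- idx[X[idx, split$feature_index] > split$threshold]
    node$left <- grow(left_idx, depth + 1)
    node$right <- grow(right_idx, depth + 1)
    node
  }

  structure(list(root = grow(seq_len(n_root), 0), task = task,
                 levels = levels_, n = n_root,
                 features = colnames(X) %||% seq_len(ncol(X))),
            class = "cart_tree")
}

#' @export
predict.cart_tree <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  apply(newdata, 1, function(row) {
    node <- object$root
    while (!node$is_leaf) {
      node <- if (row[node$feature_index] <= node$threshold) node$left
              else node$right
    }
    node$prediction
  })
}

#' @export
print.cart_tree <- function(x, ...) {
  count_nodes <- function(node) {
    if (node$is_leaf) return(c(1L, 0L))
    c(0L, 1L) + count_nodes(node$left) + count_nodes(node$right)
  }
  cn <- count_nodes(x$root)
  cat(sprintf("cart_tree (%s): %d samples, %d internal nodes, %d leaves\n",
              x$task, x$n, cn[2], cn[1]))
  invisible(x)
}

#' Per-feature usage score of a fitted tree
#'
#' How prominently each feature participates in the tree's decision rules,
#' weighting splits high in the tree more. The default `"peak_coverage"`
#' credits a feature once per tree with the sample fraction governed by
#' its shallowest split (`n_node / n_root`; 1 for the root), so importance
#' reflects how high the feature sits rather than how often an overfit
#' tree re-uses it in small subtrees. `"coverage"` sums `n_node / n_root`
#' over every node using the feature; `"count"` credits 1 per node;
#' `"depth_decay"` sums `2^-depth`.
#'
#' @param tree a [fit_tree()] result.
#' @param variant scoring variant.
#' @return list with `score` (named per feature; zero when unused) and
#'   `first_depth` (depth of shallowest use, `NA` when unused).
#' @export
taxon_usage <- function(tree, variant = c("peak_coverage", "coverage",
                                          "count", "depth_decay")) {
  variant <- match.arg(variant)
  feats <- as.character(tree$features)
  score <- setNames(numeric(length(feats)), feats)
  first_depth <- setNames(rep(NA_real_, length(feats)), feats)
  walk <- function(node) {
    if (node$is_leaf) return(invisible())
    f <- as.character(node$feature)
    w <- switch(variant,
                peak_coverage = , coverage = node$n / tree$n,
                count = 1, depth_decay = 2^(-node$depth))
    score[f] <<- if (variant == "peak_coverage") max(score[f], w)
                 else score[f] + w
    if (is.na(first_depth[f]) || node$depth < first_depth[f])
      first_depth[f] <<- node$depth
    walk(node$left)
    walk(node$right)
  }
  walk(tree$root)
  list(score = score, first_depth = first_depth)
}
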