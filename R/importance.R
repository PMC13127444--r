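# Monte-Carlo cross-validated rule mining: repeated 70/30 splits, tree
# refits, and accumulation of per-taxon usage into stability importance.

split_indices <- function(y, task, train_frac) {
  n <- length(y)
  if (task == "classification") {
    # stratified by class so both splits keep both classes
    train <- unlist(lapply(unique(y), function(k) {
      rows <- which(y == k)
      n_tr <- min(max(round(train_frac * length(rows)), 1L), length(rows) - 1L)
      sample(rows, n_tr)
    }))
    sort(train)
  } else {
    sort(sample(n, round(train_frac * n)))
  }
}

test_accuracy <- function(y_test, y_hat, task) {
  if (task == "regression") {
    ss_tot <- sum((y_test - mean(y_test))^2)
    if (ss_tot == 0) return(NA_real_)
    1 - sum((y_test - y_hat)^2) / ss_tot
  } else {
    recall <- vapply(unique(y_test), function(k) {
      mean(y_hat[y_test == k] == k)
    }, numeric(1))
    mean(recall)
  }
}

#' Monte-Carlo cross-validated taxon importance
#'
#' Repeats `n_iter` times: draw a seeded `train_frac`/(1 - `train_frac`)
#' split without replacement (stratified by class for classification), fit
#' a CART tree on the training part, record accuracy on the held-out part
#' (R-squared for regression, balanced accuracy for classification), and
#' accumulate each taxon's [taxon_usage()] score. Importance is the mean
#' usage score over iterations; the selection frequency is the fraction of
#' iterations in which the taxon is used in any split. Fully reproducible
#' given `seed` (sub-seeds from [derive_seed()]).
#'
#' @param X CLR matrix, samples in rows, taxa in columns.
#' @param y response (continuous concentration or presence labels).
#' @param task `"regression"` or `"classification"`.
#' @param n_iter number of Monte-Carlo iterations.
#' @param train_frac training fraction per split.
#' @param seed integer seed.
#' @param max_depth,min_samples_leaf,min_gain tree hyperparameters.
#' @param variant usage-score variant, see [taxon_usage()].
#' @return a `mining_result`: `importance` table (taxon, mean_score,
#'   selection_frequency, mean_first_depth, rank), per-iteration
#'   `accuracy`, and settings.
#' @export
monte_carlo_importance <- function(X, y, task = c("regression", "classification"),
                                   n_iter = 1000, train_frac = 0.70, seed = 1,
                                   max_depth = Inf, min_samples_leaf = 5,
                                   min_gain = 0,
                                   variant = c("peak_coverage", "coverage",
                                               "count", "depth_decay")) {
  task <- match.arg(task)
  variant <- match.arg(variant)
  X <- as.matrix(X)
  if (nrow(X) < 10) stop("need at least 10 samples")
  if (n_iter < 1) stop("n_iter must be >= 1")
  if (!(train_frac > 0 && train_frac < 1)) stop("train_frac must be in (0, 1)")
  taxa <- as.character(colnames(X) %||% seq_len(ncol(X)))
  if (task == "classification") {
    yf <- if (is.factor(y)) y else factor(y)
    y_int <- as.numeric(yf) - 1
    if (min(table(y_int)) < 2)
      stop("each class needs at least 2 samples")
  } else {
    y_int <- as.numeric(y)
  }

  score_sum <- setNames(numeric(length(taxa)), taxa)
  sel_count <- setNames(numeric(length(taxa)), taxa)
  depth_sum <- setNames(numeric(length(taxa)), taxa)
  accuracy <- numeric(n_iter)
  n_resampled <- 0L

  for (iter in seq_len(n_iter)) {
    set.seed(derive_seed(seed, iter))
    repeat {
      train <- split_indices(y_int, task, train_frac)
      if (task != "classification" ||
          length(unique(y_int[train])) == 2) break
      n_resampled <- n_resampled + 1L
    }
    test <- setdiff(seq_len(nrow(X)), train)
    tree <- fit_tree(X[train, , drop = FALSE], y_int[train], task = task,
                     max_depth = max_depth,
                     min_samples_leaf = min_samples_leaf, min_gain = min_gain)
    y_hat <- predict(tree, X[test, , drop = FALSE])
    if (task == "classification")
      y_hat <- as.numeric(factor(y_hat, levels = tree$levels)) - 1
    accuracy[iter] <- test_accuracy(y_int[test], y_hat, task)
    usage <- taxon_usage(tree, variant)
    score_sum <- score_sum + usage$score
    used <- usage$score > 0
    sel_count[used] <- sel_count[used] + 1
    depth_sum[used] <- depth_sum[used] + usage$first_depth[used]
  }

  imp <- data.frame(taxon = taxa,
                    mean_score = unname(score_sum / n_iter),
                    selection_frequency = unname(sel_count / n_iter),
                    mean_first_depth = unname(ifelse(sel_count > 0,
                                                     depth_sum / sel_count, NA)),
                    stringsAsFactors = FALSE)
  imp <- imp[order(-imp$mean_score, imp$taxon), ]
  imp$rank <- seq_len(nrow(imp))
  rownames(imp) <- NULL
  structure(list(importance = imp, accuracy = accuracy, task = task,
                 n_iter = n_iter, train_frac = train_frac, seed = seed,
                 n_resampled = n_resampled,
                 settings = list(max_depth = max_depth,
                                 min_samples_leaf = min_samples_leaf,
                                 min_gain = min_gain, variant = variant)),
            class = "mining_result")
}

#' @export
print.mining_result <- function(x, ...) {
  cat(sprintf("mining_result (%s): %d iterations, mean accuracy %.3f\n",
              x$task, x$n_iter, mean(x$accuracy, na.rm = TRUE)))
  print(head(x$importance, 5))
  invisible(x)
}

#' Permutation p-value for the mined association
#'
#' Observed statistic: mean test accuracy of [monte_carlo_importance()]
#' over a reduced iteration budget. Null distribution: the same statistic
#' with the response permuted across samples, `B` times.
#' `p = (1 + #\{null >= observed\}) / (1 + B)`.
#'
#' @inheritParams monte_carlo_importance
#' @param B number of permutations (>= 1).
#' @param n_iter Monte-Carlo iterations per (re)fit.
#' @return list with `p`, `observed`, and the `null` statistics.
#' @export
permutation_pvalue <- function(X, y, task = c("regression", "classification"),
                               B = 99, n_iter = 50, seed = 1,
                               train_frac = 0.70, max_depth = Inf,
                               min_samples_leaf = 5, min_gain = 0) {
  task <- match.arg(task)
  if (B < 1) stop("B must be >= 1")
  stat <- function(yy, s) {
    r <- monte_carlo_importance(X, yy, task = task, n_iter = n_iter,
                                train_frac = train_frac, seed = s,
                                max_depth = max_depth,
                                min_samples_leaf = min_samples_leaf,
                                min_gain = min_gain)
    mean(r$accuracy, na.rm = TRUE)
  }
  observed <- stat(y, derive_seed(seed, 0))
  null <- vapply(seq_len(B), function(b) {
    set.seed(derive_seed(seed, 500000 + b))
    stat(y[sample(length(y))], derive_seed(seed, 900000 + b))
  }, numeric(1))
  list(p = (1 + sum(null >= observed)) / (1 + B),
       observed = observed, null = null)
}
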