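test_that("gini impurity evaluates the class-count formula", {
  expect_equal(gini_impurity(c(5, 5)), 0.5)
  expect_equal(gini_impurity(c(10, 0)), 0)
  expect_equal(gini_impurity(c(3, 1)), 0.375)
  expect_error(gini_impurity(c(0, 0)), "> 0")
  expect_error(gini_impurity(c(-1, 2)), ">= 0")
})

test_that("best_split finds the toy split and refuses constant targets", {
  X <- matrix(c(1, 2, 3, 4), 4, 1, dimnames = list(NULL, "t1"))
  s <- best_split(X, c(0, 0, 10, 10), "sse", min_samples_leaf = 1)
  expect_equal(s$feature, "t1")
  expect_equal(s$threshold, 2.5)
  expect_equal(s$gain, 100) # parent SSE 100, pure children
  expect_null(best_split(X, rep(3, 4), "sse", min_samples_leaf = 1))
})

test_that("best_split equals the brute-force oracle on random instances", {
  for (seed in 1:60) {
    inst <- random_split_instance(seed)
    for (crit in c("sse", "gini")) {
      y <- if (crit == "sse") inst$y else inst$y_cls
      mine <- best_split(inst$X, y, crit, min_samples_leaf = 1)
      oracle <- brute_best_split(inst$X, y, crit, min_leaf = 1)
      if (is.null(oracle)) {
        expect_null(mine)
      } else {
        expect_equal(mine$feature_index, oracle$feature)
        expect_equal(mine$threshold, oracle$threshold)
        expect_equal(mine$gain, oracle$gain, tolerance = 1e-9)
      }
    }
  }
})

test_that("trees respect stop rules and the toy data give a depth-1 perfect fit", {
  X <- matrix(c(1, 2, 3, 4), 4, 1, dimnames = list(NULL, "t1"))
  y <- c(0, 0, 10, 10)
  stump <- fit_tree(X, y, max_depth = 0)
  expect_true(stump$root$is_leaf)
  expect_equal(stump$root$prediction, mean(y))
  tr <- fit_tree(X, y, min_samples_leaf = 1)
  expect_false(tr$root$is_leaf)
  expect_true(tr$root$left$is_leaf && tr$root$right$is_leaf)
  expect_equal(unname(predict(tr, X)), y) # training R^2 = 1
  expect_error(fit_tree(X[0, , drop = FALSE], numeric(0)), "empty")
})

test_that("every split strictly reduces impurity and children partition the parent", {
  set.seed(31)
  X <- matrix(rnorm(200 * 5), 200, 5, dimnames = list(NULL, paste0("t", 1:5)))
  y <- X[, 2] * 2 + rnorm(200)
  tr <- fit_tree(X, y, min_samples_leaf = 5)
  check <- function(node) {
    if (node$is_leaf) return(invisible())
    expect_gt(node$gain, 0)
    expect_equal(node$left$n + node$right$n, node$n)
    check(node$left); check(node$right)
  }
  check(tr$root)
})

test_that("classification trees agree with a reference CART implementation", {
  skip_if_not_installed("rpart")
  for (seed in 1:10) {
    set.seed(seed)
    n <- 40
    X <- matrix(runif(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
    y <- as.integer(X[, 1] + 0.3 * runif(n) > 0.6)
    if (length(unique(y)) < 2) next
    mine <- fit_tree(X, y, task = "classification", max_depth = 3,
                     min_samples_leaf = 5)
    ref <- rpart::rpart(y ~ ., data = data.frame(y = factor(y), X),
                        method = "class",
                        control = rpart::rpart.control(
                          minsplit = 10, minbucket = 5, cp = 0,
                          maxdepth = 3, xval = 0, maxsurrogate = 0,
                          maxcompete = 0))
    p_ref <- as.character(predict(ref, data.frame(X), type = "class"))
    expect_equal(unname(predict(mine, X)), p_ref)
  }
})

test_that("usage scores weight nodes by coverage with variants available", {
  # hand-built tree: root splits on A over 100 samples, its left child
  # (60 samples) splits on B, right child is a leaf
  leaf <- function(n, depth) list(is_leaf = TRUE, n = n, depth = depth,
                                  prediction = 0)
  tree <- structure(list(
    root = list(is_leaf = FALSE, n = 100, depth = 0, feature = "A",
                feature_index = 1, threshold = 0,
                left = list(is_leaf = FALSE, n = 60, depth = 1,
                            feature = "B", feature_index = 2, threshold = 0,
                            left = leaf(30, 2), right = leaf(30, 2)),
                right = leaf(40, 1)),
    task = "regression", n = 100, features = c("A", "B", "C")),
    class = "cart_tree")
  u <- taxon_usage(tree, "coverage")
  expect_equal(u$score, c(A = 1.0, B = 0.6, C = 0))
  expect_equal(u$first_depth[["B"]], 1)
  expect_true(is.na(u$first_depth[["C"]]))
  expect_equal(taxon_usage(tree, "peak_coverage")$score,
               c(A = 1.0, B = 0.6, C = 0))
  expect_equal(taxon_usage(tree, "count")$score, c(A = 1, B = 1, C = 0))
  expect_equal(taxon_usage(tree, "depth_decay")$score,
               c(A = 1, B = 0.5, C = 0))
  # a feature used at two nodes accumulates coverage, but its peak score
  # is the coverage of its shallowest use
  tree$root$left$feature <- "A"; tree$root$left$feature_index <- 1
  expect_equal(taxon_usage(tree, "coverage")$score[["A"]], 1.6)
  expect_equal(taxon_usage(tree, "peak_coverage")$score[["A"]], 1.0)
  # a stump scores zero everywhere
  stump <- structure(list(root = leaf(10, 0), task = "regression", n = 10,
                          features = c("A", "B", "C")),
                     class = "cart_tree")
  expect_equal(sum(taxon_usage(stump)$score), 0)
})

test_that("Monte-Carlo importance is reproducible and finds a planted feature", {
  set.seed(77)
  n <- 60
  X <- matrix(rnorm(n * 21), n, 21,
              dimnames = list(NULL, sprintf("f%02d", 1:21)))
  y <- X[, 1] + rnorm(n, 0, 0.2)
  r1 <- monte_carlo_importance(X, y, "regression", n_iter = 100, seed = 5)
  r2 <- monte_carlo_importance(X, y, "regression", n_iter = 100, seed = 5)
  expect_identical(r1$importance, r2$importance)
  expect_identical(r1$accuracy, r2$accuracy)
  expect_equal(r1$importance$taxon[1], "f01")
  expect_gt(mean(r1$accuracy), 0.3)
})

test_that("classification mining stays stratified with imbalanced classes", {
  set.seed(13)
  n <- 40
  X <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("f", 1:5)))
  y <- c(rep(1, 6), rep(0, n - 6))
  r <- monte_carlo_importance(X, y, "classification", n_iter = 50, seed = 2)
  expect_equal(r$n_resampled, 0L)
  expect_length(r$accuracy, 50)
  expect_true(all(is.finite(r$accuracy)))
})

test_that("permutation p-values hit their combinatorial bounds", {
  set.seed(9)
  n <- 40
  X <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("f", 1:4)))
  y <- X[, 1] * 3 + rnorm(n, 0, 0.1) # unmistakable signal
  pv <- permutation_pvalue(X, y, "regression", B = 19, n_iter = 5, seed = 3)
  expect_equal(pv$p, 0.05) # observed beats all 19 nulls: 1/(B+1)
  expect_error(permutation_pvalue(X, y, "regression", B = 0), "B must be")
})
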