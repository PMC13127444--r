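random_clr <- function(n, p, seed) {
  set.seed(seed)
  clr(matrix(rexp(n * p) + 0.05, n, p,
             dimnames = list(sprintf("s%d", 1:n), sprintf("t%d", 1:p))))
}

test_that("compositional PCA captures rank and normalizes proportions", {
  # rank-1 gradient
  grad <- seq(-1, 1, length.out = 6)
  X <- outer(grad, c(1, -2, 0.5, 0.5))
  r1 <- coda_pca(X)
  expect_equal(r1$proportions[1], 1)
  cm <- random_clr(10, 6, 2)
  r <- coda_pca(cm)
  expect_equal(sum(r$proportions), 1)
  expect_true(all(diff(r$eigenvalues) <= 1e-12))
  expect_error(coda_pca(matrix(1, 4, 4)), "constant")
})

test_that("PCA eigenvalues match an independent covariance eigensolve", {
  cm <- random_clr(6, 4, 7)
  r <- coda_pca(cm)
  ev <- eigen(stats::cov(cm), symmetric = TRUE)$values
  ev <- ev[ev > max(ev) * 1e-10]
  expect_equal(r$eigenvalues, ev, tolerance = 1e-10)
})

test_that("db-RDA on Aitchison distances equals RDA on the CLR table", {
  for (seed in 1:5) {
    cm <- random_clr(12, 7, seed)
    set.seed(seed + 100)
    Z <- matrix(rnorm(12 * 3), 12, 3, dimnames = list(NULL, c("a", "b", "c")))
    via_dist <- db_rda(aitchison_dist(cm), Z)
    via_clr <- db_rda(cm, Z)
    expect_equal(via_dist$eigenvalues, via_clr$eigenvalues, tolerance = 1e-8)
    expect_equal(via_dist$constrained_fraction, via_clr$constrained_fraction,
                 tolerance = 1e-8)
  }
})

test_that("db-RDA matches the vegan reference implementation", {
  skip_if_not_installed("vegan")
  cm <- random_clr(15, 8, 3)
  set.seed(103)
  Z <- data.frame(a = rnorm(15), b = rnorm(15))
  mine <- db_rda(cm, as.matrix(Z))
  ref <- vegan::rda(cm ~ a + b, data = Z)
  expect_equal(unname(mine$eigenvalues),
               unname(ref$CCA$eig[seq_along(mine$eigenvalues)]),
               tolerance = 1e-8)
  expect_equal(mine$total_inertia, unname(ref$tot.chi), tolerance = 1e-8)
})

test_that("constrained and residual inertia partition the total", {
  cm <- random_clr(10, 5, 9)
  set.seed(9)
  Z <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("a", "b")))
  r <- db_rda(cm, Z)
  expect_equal(sum(r$eigenvalues) + sum(r$unconstrained_eigenvalues),
               r$total_inertia, tolerance = 1e-9)
  expect_true(all(r$proportions >= 0 & r$proportions <= 1 + 1e-9))
})

test_that("degenerate constraint sets behave as documented", {
  cm <- random_clr(10, 5, 4)
  # a constraint equal to the first principal coordinate explains PC1 exactly
  pca <- coda_pca(cm)
  r1 <- db_rda(cm, matrix(pca$scores[, 1], ncol = 1,
                          dimnames = list(NULL, "pc1")))
  expect_equal(r1$proportions[1], pca$proportions[1], tolerance = 1e-8)
  # an orthogonal constraint explains nothing
  set.seed(5)
  v <- rnorm(10)
  ortho <- v - qr.fitted(qr(cbind(1, scale(cm, scale = FALSE))), v)
  r0 <- db_rda(cm, matrix(ortho, ncol = 1, dimnames = list(NULL, "o")))
  expect_lte(r0$constrained_fraction, 1e-10)
  # intercept-only constraints explain fraction zero
  rint <- db_rda(cm, matrix(numeric(0), nrow = 10, ncol = 0))
  expect_equal(rint$constrained_fraction, 0)
  # collinear constraints are rejected by name
  Z <- cbind(a = rnorm(10))
  expect_error(db_rda(cm, cbind(Z, dup = 2 * Z[, 1])), "dup")
  # non-Euclidean distances are rejected
  D <- as.matrix(dist(matrix(rnorm(30), 10, 3)))
  D[1, 2] <- D[2, 1] <- max(D) * 3 # break the triangle inequality
  expect_error(db_rda(stats::as.dist(D), Z), "non-Euclidean")
})
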