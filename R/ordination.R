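# Ordination of the widespread-taxa CLR subtable: compositional PCA and
# distance-based redundancy analysis constrained on pore-fluid chemistry.

#' Compositional principal component analysis (CoDa-PCA)
#'
#' PCA of the column-centered CLR matrix via singular value decomposition.
#' Eigenvalues use the (n - 1) variance divisor; loadings are the right
#' singular vectors scaled by the singular values, with the sign of each
#' component fixed so its largest-magnitude loading is positive.
#'
#' @param clr_sub CLR matrix, samples in rows, features in columns
#'   (>= 2 of each).
#' @return an `ordination_result` with eigenvalues, variance proportions,
#'   sample scores, and feature loadings.
#' @export
coda_pca <- function(clr_sub) {
  clr_sub <- as.matrix(clr_sub)
  if (nrow(clr_sub) < 2 || ncol(clr_sub) < 2)
    stop("need at least 2 samples and 2 features")
  Xc <- scale(clr_sub, center = TRUE, scale = FALSE)
  if (all(abs(Xc) < 1e-12))
    stop("constant matrix: variance proportions are undefined")
  sv <- svd(Xc)
  keep <- sv$d > max(sv$d) * 1e-10
  d <- sv$d[keep]
  eig <- d^2 / (nrow(Xc) - 1)
  scores <- sv$u[, keep, drop = FALSE] %*% diag(d, length(d))
  loadings <- sv$v[, keep, drop = FALSE] %*% diag(d, length(d))
  for (i in seq_along(d)) { # sign convention
    j <- which.max(abs(loadings[, i]))
    if (loadings[j, i] < 0) {
      loadings[, i] <- -loadings[, i]
      scores[, i] <- -scores[, i]
    }
  }
  ax <- paste0("PC", seq_along(d))
  dimnames(scores) <- list(rownames(clr_sub), ax)
  dimnames(loadings) <- list(colnames(clr_sub), ax)
  structure(list(type = "coda_pca", eigenvalues = eig,
                 proportions = eig / sum(eig), scores = scores,
                 loadings = loadings, total_inertia = sum(eig)),
            class = "ordination_result")
}

standardize_constraints <- function(constraints) {
  Z <- as.matrix(constraints)
  sds <- apply(Z, 2, sd)
  if (any(sds == 0))
    stop("constant constraint column(s): ",
         paste(colnames(Z)[sds == 0], collapse = ", "))
  Zs <- scale(Z)
  qz <- qr(Zs)
  if (qz$rank < ncol(Zs)) {
    bad <- colnames(Zs)[qz$pivot[(qz$rank + 1):ncol(Zs)]]
    stop("collinear constraint column(s): ", paste(bad, collapse = ", "))
  }
  Zs
}

#' Distance-based redundancy analysis
#'
#' Constrained ordination of a response by explanatory (chemistry)
#' variables. With a distance-matrix response: Gower double-centering of
#' the squared distances, principal-coordinate extraction, then regression
#' of the coordinates on the standardized constraints and eigen-
#' decomposition of the fitted (constrained) and residual (unconstrained)
#' variance. With a matrix response (e.g. a CLR table) the regression acts
#' on the centered columns directly — classical RDA, which coincides with
#' the distance path when the distance is Euclidean in that space (as the
#' Aitchison distance is in CLR space). Non-Euclidean distance input
#' (negative principal-coordinate eigenvalues) is rejected.
#'
#' @param response a `dist` object or a numeric matrix (samples in rows).
#' @param constraints numeric matrix of explanatory variables, rows
#'   matching the response samples; standardized internally, must be full
#'   column rank. Zero columns give a purely unconstrained analysis.
#' @return an `ordination_result` with constrained eigenvalues and
#'   proportions (relative to total inertia), the constrained-inertia
#'   fraction, sample scores on constrained axes, unconstrained
#'   eigenvalues, and constraint biplot scores.
#' @export
db_rda <- function(response, constraints) {
  if (inherits(response, "dist")) {
    D <- as.matrix(response)
    n <- nrow(D)
    A <- -0.5 * D^2
    # double-centering: G = (I - 11'/n) A (I - 11'/n)
    G <- A - outer(rowMeans(A), rep(1, n)) -
      outer(rep(1, n), colMeans(A)) + mean(A)
    ev <- eigen(G, symmetric = TRUE)
    tol <- max(abs(ev$values)) * 1e-8
    if (any(ev$values < -tol))
      stop("non-Euclidean distance matrix: negative principal-coordinate eigenvalues")
    keep <- ev$values > tol
    Y <- ev$vectors[, keep, drop = FALSE] %*%
      diag(sqrt(ev$values[keep]), sum(keep))
    rownames(Y) <- rownames(D)
  } else {
    Y <- scale(as.matrix(response), center = TRUE, scale = FALSE)
    n <- nrow(Y)
  }
  if (n < 3) stop("need at least 3 samples")
  total <- sum(Y^2) / (n - 1)

  if (is.null(constraints) || NCOL(constraints) == 0) {
    fitted <- matrix(0, n, ncol(Y)); resid <- Y; Zs <- NULL
  } else {
    Zs <- standardize_constraints(constraints)
    if (nrow(Zs) != n) stop("constraint rows must match response rows")
    qz <- qr(cbind(1, Zs))
    fitted <- qr.fitted(qz, Y)
    resid <- Y - fitted
  }

  decomp <- function(M) {
    sv <- svd(M)
    keep <- sv$d > max(sv$d, 1e-300) * 1e-9
    list(eig = sv$d[keep]^2 / (n - 1),
         scores = sv$u[, keep, drop = FALSE] %*% diag(sv$d[keep], sum(keep)))
  }
  con <- decomp(fitted)
  unc <- decomp(resid)
  constrained <- sum(con$eig)
  scores <- con$scores
  if (length(con$eig) > 0) {
    colnames(scores) <- paste0("RDA", seq_along(con$eig))
    rownames(scores) <- rownames(Y)
  }
  biplot <- NULL
  if (!is.null(Zs) && length(con$eig) > 0)
    biplot <- cor(Zs, scores)
  structure(list(type = "db_rda", eigenvalues = con$eig,
                 proportions = if (total > 0) con$eig / total else con$eig,
                 constrained_fraction = if (total > 0) constrained / total else 0,
                 unconstrained_eigenvalues = unc$eig,
                 total_inertia = total, scores = scores, biplot = biplot),
            class = "ordination_result")
}

#' @export
print.ordination_result <- function(x, ...) {
  cat(sprintf("ordination_result (%s): %d axes", x$type, length(x$eigenvalues)))
  if (!is.null(x$constrained_fraction))
    cat(sprintf(", constrained fraction %.3f", x$constrained_fraction))
  cat("\n  proportions:",
      paste(sprintf("%.3f", head(x$proportions, 5)), collapse = " "), "\n")
  invisible(x)
}
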