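# Compositional data analysis primitives: pseudo-value zero imputation,
# centered log-ratio transform, Aitchison distance.

#' Zero-impute a count matrix with a pseudo-count
#'
#' Adds the pseudo-value (default 1 count) to every cell so the CLR
#' transform is defined.
#'
#' @param counts nonnegative integer matrix or vector.
#' @param pseudo pseudo-count added to every cell.
#' @return positive numeric matrix/vector.
#' @export
zero_impute_counts <- function(counts, pseudo = 1) {
  if (any(counts < 0)) stop("counts must be nonnegative")
  counts + pseudo
}

#' Zero-impute concentrations with a pseudo-concentration
#'
#' Adds the pseudo-value (default 0.001 uM) to every concentration.
#'
#' @param conc nonnegative concentrations, uM.
#' @param pseudo pseudo-concentration, uM.
#' @return positive values.
#' @export
zero_impute_conc <- function(conc, pseudo = 0.001) {
  if (any(conc < 0, na.rm = TRUE)) stop("concentrations must be >= 0")
  conc + pseudo
}

#' Centered log-ratio transform
#'
#' Rows are compositions (samples), columns parts (features):
#' `clr(x)_ij = ln(x_ij) - mean_j ln(x_ij)`. Every row of the result sums
#' to zero; the transform is invariant to rescaling a row.
#'
#' @param mat strictly positive matrix, samples in rows.
#' @return the CLR matrix (same dimnames).
#' @export
clr <- function(mat) {
  mat <- as.matrix(mat)
  if (any(mat <= 0))
    stop("clr requires strictly positive values; apply zero_impute_counts()/zero_impute_conc() first")
  lx <- log(mat)
  lx - rowMeans(lx)
}

#' Aitchison distance between two compositions
#'
#' Euclidean distance between the CLR representations of two compositions:
#' zero iff the compositions are proportional.
#'
#' @param clr_a,clr_b CLR-transformed rows over the same features.
#' @return nonnegative scalar.
#' @export
aitchison_distance <- function(clr_a, clr_b) {
  if (length(clr_a) != length(clr_b))
    stop("feature sets differ in length")
  if (!is.null(names(clr_a)) && !is.null(names(clr_b)) &&
      !identical(names(clr_a), names(clr_b)))
    stop("feature sets differ")
  sqrt(sum((clr_a - clr_b)^2))
}

#' Pairwise Aitchison distance matrix of a CLR matrix
#'
#' @param clr_mat CLR matrix, samples in rows.
#' @return a `dist` object.
#' @export
aitchison_dist <- function(clr_mat) {
  stats::dist(clr_mat, method = "euclidean")
}

#' Transform chemistry concentrations for regression and ordination
#'
#' Two modes for placing the four constituents on a log-ratio-like scale.
#' `"log_center"` (default) treats each constituent's concentration vector
#' across samples separately: `ln(c + pseudo)` centered across samples.
#' `"composition"` treats the four constituents of one sample as a single
#' composition and applies the CLR across constituents within each sample.
#'
#' @param conc numeric matrix, samples in rows, constituents in columns;
#'   or a vector for a single constituent (log_center mode only).
#' @param mode `"log_center"` or `"composition"`.
#' @param pseudo pseudo-concentration, uM.
#' @return transformed matrix/vector.
#' @export
chem_transform <- function(conc, mode = c("log_center", "composition"),
                           pseudo = 0.001) {
  mode <- match.arg(mode)
  if (mode == "composition") {
    if (is.null(dim(conc))) stop("composition mode needs a matrix of constituents")
    return(clr(zero_impute_conc(as.matrix(conc), pseudo)))
  }
  lx <- log(zero_impute_conc(conc, pseudo))
  if (is.null(dim(lx))) lx - mean(lx) else scale(lx, center = TRUE, scale = FALSE)
}
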