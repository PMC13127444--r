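# Candidate-taxon screening: presence/absence labels per constituent,
# rank-sum differential abundance tests, Storey q-value FDR control.

#' Presence/absence labels for one constituent
#'
#' Presence is decided on the raw (pre-pseudo-value) concentration:
#' present iff value > `detection_limit`. Samples without a usable value
#' are dropped (anoxia-imputed oxygen zeros count as absent).
#'
#' @param chem a `sample_chemistry` data frame.
#' @param constituent one of `"O2"`, `"NO3"`, `"NH4"`, `"Mn"`.
#' @param detection_limit presence threshold, uM.
#' @return logical vector named by sample id (`TRUE` = present).
#' @export
presence_labels <- function(chem, constituent, detection_limit = 0) {
  stopifnot(constituent %in% CONSTITUENTS)
  ok <- chem_available(chem, constituent)
  labels <- setNames(chem[[constituent]][ok] > detection_limit,
                     chem$sample_id[ok])
  if (length(unique(labels)) < 2)
    stop(sprintf("degenerate grouping: all available %s samples fall in one presence class",
                 constituent))
  labels
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact enumeration when the combined sample size is at most 12 and there
#' are no ties; otherwise the normal approximation with tie and continuity
#' correction. Degenerate input with no variation returns p = 1.
#'
#' @param values numeric vector.
#' @param labels logical/two-level vector splitting `values` into groups.
#' @return two-sided p-value.
#' @export
rank_sum_test <- function(values, labels) {
  labels <- as.logical(labels)
  x <- values[labels]; y <- values[!labels]
  if (length(x) == 0 || length(y) == 0)
    stop("both groups must be non-empty")
  if (length(unique(values)) == 1) return(1)
  exact <- (length(values) <= 12) && !anyDuplicated(values)
  suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided", exact = exact,
                correct = TRUE)$p.value
  )
}

#' Storey q-values
#'
#' Estimates the null proportion as
#' `pi0 = #\{p > lambda\} / (m (1 - lambda))`, clipped to (0, 1], then
#' applies the step-down rule on sorted p-values:
#' `q(m) = pi0 p(m)`, `q(i) = min(q(i+1), pi0 m p(i) / i)`.
#'
#' @param p_values p-values in `[0, 1]`.
#' @param lambda tuning parameter of the pi0 estimator.
#' @return q-values in the input order.
#' @export
storey_qvalues <- function(p_values, lambda = 0.5) {
  m <- length(p_values)
  if (m < 1) stop("need at least one p-value")
  if (any(p_values < 0 | p_values > 1, na.rm = FALSE))
    stop("p-values must lie in [0, 1]")
  pi0 <- sum(p_values > lambda) / (m * (1 - lambda))
  pi0 <- min(1, max(pi0, 1 / m))
  ord <- order(p_values)
  ps <- p_values[ord]
  q <- numeric(m)
  q[m] <- pi0 * ps[m]
  if (m > 1)
    for (i in (m - 1):1) q[i] <- min(q[i + 1], pi0 * m * ps[i] / i)
  q[order(ord)]
}

#' Estimate of the null proportion used by [storey_qvalues()]
#' @inheritParams storey_qvalues
#' @return the clipped pi0 estimate.
#' @export
storey_pi0 <- function(p_values, lambda = 0.5) {
  m <- length(p_values)
  min(1, max(sum(p_values > lambda) / (m * (1 - lambda)), 1 / m))
}

#' Screen taxa for differential CLR abundance across presence classes
#'
#' For every constituent, each taxon's CLR abundances are compared between
#' presence and absence of that constituent with a two-sided rank-sum
#' test; q-values are computed within constituent, and the candidate set
#' is the union over constituents of taxa with `q < q_threshold`.
#' Constituents whose labels are degenerate (one class only) are skipped
#' with a warning.
#'
#' @param clr_table CLR matrix, samples in rows, taxa in columns.
#' @param chem a `sample_chemistry` data frame covering those samples.
#' @param q_threshold q-value cutoff for candidacy.
#' @param lambda Storey pi0 tuning parameter.
#' @param detection_limit presence threshold, uM (scalar or named per
#'   constituent).
#' @return list with `table` (per taxon x constituent: group sizes, p, q,
#'   selected flag) and `candidates` (union candidate taxa, sorted).
#' @export
screen_taxa <- function(clr_table, chem, q_threshold = 0.05, lambda = 0.5,
                        detection_limit = 0) {
  taxa <- colnames(clr_table)
  if (length(detection_limit) == 1)
    detection_limit <- setNames(rep(detection_limit, 4), CONSTITUENTS)
  rows <- list()
  for (con in CONSTITUENTS) {
    labels <- tryCatch(presence_labels(chem, con, detection_limit[[con]]),
                       error = function(e) {
                         warning(sprintf("skipping %s: %s", con, conditionMessage(e)))
                         NULL
                       })
    if (is.null(labels)) next
    ids <- intersect(names(labels), rownames(clr_table))
    lab <- labels[ids]
    sub <- clr_table[ids, , drop = FALSE]
    if (sum(lab) < 2 || sum(!lab) < 2)
      stop(sprintf("%s: need >= 2 samples per presence class", con))
    p <- vapply(taxa, function(t) rank_sum_test(sub[, t], lab), numeric(1))
    q <- storey_qvalues(p, lambda)
    rows[[con]] <- data.frame(taxon = taxa, constituent = con,
                              n_present = sum(lab), n_absent = sum(!lab),
                              p = p, q = q, selected = q < q_threshold,
                              stringsAsFactors = FALSE, row.names = NULL)
  }
  if (length(rows) == 0) stop("no constituent could be screened")
  table <- do.call(rbind, rows)
  rownames(table) <- NULL
  list(table = table,
       candidates = sort(unique(table$taxon[table$selected])))
}
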