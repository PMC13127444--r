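# Widespread-taxa selection: high mining importance combined with
# detection in every geographic area.

#' Per-area presence of each taxon
#'
#' A taxon is present in an area when it has a positive count in at least
#' `min_samples` samples of that area.
#'
#' @param table a [community_table()].
#' @param min_samples minimum positive-count samples per area.
#' @return logical matrix, taxa in rows, areas in columns.
#' @export
area_presence <- function(table, min_samples = 1) {
  areas <- sort(unique(table$metadata$area_id))
  if (length(areas) == 0) stop("no areas in metadata")
  pres <- vapply(areas, function(a) {
    cols <- table$metadata$sample_id[table$metadata$area_id == a]
    if (length(cols) == 0) stop("area with zero samples: ", a)
    rowSums(table$counts[, cols, drop = FALSE] > 0) >= min_samples
  }, logical(nrow(table$counts)))
  rownames(pres) <- rownames(table$counts)
  pres
}

#' Select the widespread taxa
#'
#' Dual criteria: (1) high Monte-Carlo mining importance — each taxon's
#' candidate score is its mean usage score aggregated across constituents
#' (`"max"` by default) — and (2) presence in every geographic area. Taxa
#' failing all-areas presence are removed before ranking; the top `k` by
#' score are kept, ties broken lexicographically by taxon id.
#'
#' @param importances named list (per constituent) of importance tables
#'   from [monte_carlo_importance()] (`$importance`, or the data frame
#'   itself).
#' @param presence logical taxon-by-area matrix from [area_presence()].
#' @param k number of taxa to select.
#' @param aggregate cross-constituent score aggregation, `"max"` or
#'   `"mean"`.
#' @return a `widespread_set` data frame: rank, taxon, score,
#'   per-constituent score and rank columns, per-area presence columns.
#'   The full pre-truncation ranking is kept in attribute `"ranking"`.
#' @export
select_widespread <- function(importances, presence, k = 20,
                              aggregate = c("max", "mean")) {
  aggregate <- match.arg(aggregate)
  if (length(importances) < 1) stop("need at least one importance table")
  imp_tabs <- lapply(importances, function(x) {
    if (inherits(x, "mining_result")) x$importance else x
  })
  taxa <- sort(unique(unlist(lapply(imp_tabs, `[[`, "taxon"))))
  score_mat <- vapply(imp_tabs, function(tab) {
    s <- setNames(tab$mean_score, tab$taxon)[taxa]
    ifelse(is.na(s), 0, s)
  }, numeric(length(taxa)))
  rank_mat <- vapply(imp_tabs, function(tab) {
    setNames(tab$rank, tab$taxon)[taxa]
  }, numeric(length(taxa)))
  score <- apply(score_mat, 1, if (aggregate == "max") max else mean)

  ranking <- data.frame(taxon = taxa, score = unname(score),
                        stringsAsFactors = FALSE)
  colnames(score_mat) <- paste0("score_", names(imp_tabs))
  colnames(rank_mat) <- paste0("rank_", names(imp_tabs))
  ranking <- cbind(ranking, score_mat, rank_mat)

  pres_taxa <- intersect(taxa, rownames(presence))
  all_areas <- rownames(presence)[rowSums(!presence) == 0]
  eligible <- ranking[ranking$taxon %in% all_areas, , drop = FALSE]
  eligible <- eligible[order(-eligible$score, eligible$taxon), , drop = FALSE]
  if (nrow(eligible) < k)
    warning(sprintf("only %d eligible taxa for k = %d", nrow(eligible), k))
  sel <- head(eligible, k)
  pm <- presence[sel$taxon, , drop = FALSE]
  colnames(pm) <- paste0("present_", colnames(pm))
  out <- cbind(data.frame(rank = seq_len(nrow(sel))), sel, pm)
  rownames(out) <- NULL
  structure(out, ranking = ranking, class = c("widespread_set", "data.frame"))
}
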