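# Reading, validation, family-level binning, chemistry interpolation, and
# the anoxia assignment rule.

#' Construct and validate a community table
#'
#' The central container: a nonnegative integer taxon-by-sample count
#' matrix, a taxonomy table of rank-prefixed semicolon-separated lineages,
#' and sample metadata (core, geographic area, depth below seafloor).
#'
#' @param counts integer matrix, taxa in rows, samples in columns (both
#'   dimnames required).
#' @param taxonomy data frame with columns `taxon_id`, `lineage`; taxa in
#'   `counts` but absent here are retained with lineage `"Unclassified"`.
#' @param metadata data frame with columns `sample_id`, `core_id`,
#'   `area_id`, `depth_cm`.
#' @return a `community_table` object.
#' @export
community_table <- function(counts, taxonomy, metadata) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have taxon rownames and sample colnames")
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]),
               collapse = ", "))
  bad <- which(counts < 0 | counts != round(counts), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("counts must be nonnegative integers; first offending cell: taxon '%s', sample '%s'",
                 rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]]))
  need <- c("sample_id", "core_id", "area_id", "depth_cm")
  if (!all(need %in% names(metadata)))
    stop("metadata must have columns ", paste(need, collapse = ", "))
  missing_meta <- setdiff(colnames(counts), metadata$sample_id)
  if (length(missing_meta) > 0)
    stop("samples missing from metadata: ", paste(missing_meta, collapse = ", "))
  if (any(metadata$depth_cm < 0)) stop("depth_cm must be >= 0")
  metadata <- metadata[match(colnames(counts), metadata$sample_id), , drop = FALSE]
  rownames(metadata) <- NULL
  taxonomy <- taxonomy[, c("taxon_id", "lineage"), drop = FALSE]
  unknown <- setdiff(rownames(counts), taxonomy$taxon_id)
  if (length(unknown) > 0)
    taxonomy <- rbind(taxonomy, data.frame(taxon_id = unknown,
                                           lineage = "Unclassified"))
  taxonomy <- taxonomy[match(rownames(counts), taxonomy$taxon_id), , drop = FALSE]
  rownames(taxonomy) <- NULL
  structure(list(counts = counts, taxonomy = taxonomy, metadata = metadata),
            class = "community_table")
}

#' @export
print.community_table <- function(x, ...) {
  cat(sprintf("community_table: %d taxa x %d samples, %d cores, %d areas\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$metadata$core_id)),
              length(unique(x$metadata$area_id))))
  invisible(x)
}

#' Read a community table from count, taxonomy, and metadata TSV files
#'
#' Dialects: counts TSV with first column `taxon_id` and one column per
#' sample; taxonomy TSV with `taxon_id` and `lineage` (rank-prefixed,
#' semicolon-separated fields); metadata TSV with `sample_id`, `core_id`,
#' `area_id`, `depth_cm`.
#'
#' @param count_path,taxonomy_path,metadata_path file paths.
#' @return a [community_table()].
#' @export
read_community <- function(count_path, taxonomy_path, metadata_path) {
  raw <- read.delim(count_path, check.names = FALSE,
                    colClasses = NA, stringsAsFactors = FALSE)
  if (names(raw)[1] != "taxon_id") stop("counts file must start with a 'taxon_id' column")
  counts_num <- as.matrix(raw[, -1, drop = FALSE])
  if (!is.numeric(counts_num)) {
    bad <- which(is.na(suppressWarnings(apply(raw[, -1, drop = FALSE], 2, as.numeric))),
                 arr.ind = TRUE)
    stop(sprintf("non-numeric count at row %d, column '%s'",
                 bad[1, 1], colnames(raw[, -1, drop = FALSE])[bad[1, 2]]))
  }
  rownames(counts_num) <- raw$taxon_id
  taxonomy <- read.delim(taxonomy_path, stringsAsFactors = FALSE)
  metadata <- read.delim(metadata_path, stringsAsFactors = FALSE)
  community_table(counts_num, taxonomy, metadata)
}

#' Write a community table as the three TSV files [read_community()] reads
#'
#' @param table a [community_table()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_community <- function(table, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  counts <- data.frame(taxon_id = rownames(table$counts), table$counts,
                       check.names = FALSE)
  write.table(counts, file.path(dir, "counts.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(table$taxonomy, file.path(dir, "taxonomy.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(table$metadata, file.path(dir, "metadata.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}

RANK_NAMES <- c(d = "domain", k = "domain", p = "phylum", c = "class",
                o = "order", f = "family", g = "genus", s = "species")

# Parse one lineage string into a named vector of rank -> name.
parse_lineage <- function(lineage) {
  fields <- trimws(strsplit(lineage, ";", fixed = TRUE)[[1]])
  fields <- fields[nzchar(fields)]
  has_prefix <- grepl("^[a-z]__", fields)
  ranks <- ifelse(has_prefix, substr(fields, 1, 1), "")
  names_ <- ifelse(has_prefix, substring(fields, 4), fields)
  keep <- nzchar(names_)
  setNames(names_[keep], ranks[keep])
}

# Family-level bin label for one lineage: the family name if classified at
# family rank, otherwise "Unclassified_<rank>_<name>" at the lowest
# classified rank.
family_bin <- function(lineage) {
  lv <- parse_lineage(lineage)
  if ("f" %in% names(lv)) return(unname(lv[["f"]]))
  if (length(lv) == 0) return("Unclassified")
  last <- length(lv)
  rank <- RANK_NAMES[names(lv)[last]]
  if (is.na(rank)) rank <- "rank"
  sprintf("Unclassified_%s_%s", rank, unname(lv[last]))
}

#' Bin a community table to family level
#'
#' Taxa sharing a family are summed; taxa with no family rank are kept as
#' pseudo-families under their lowest classified rank
#' (`Unclassified_<rank>_<name>`). Per-sample totals are conserved exactly.
#'
#' @param table a [community_table()].
#' @return a family-level [community_table()].
#' @export
bin_to_family <- function(table) {
  fams <- vapply(table$taxonomy$lineage, family_bin, character(1),
                 USE.NAMES = FALSE)
  binned <- rowsum(table$counts, group = fams, reorder = TRUE)
  first <- !duplicated(fams)
  taxonomy <- data.frame(taxon_id = fams[first],
                         lineage = table$taxonomy$lineage[first],
                         stringsAsFactors = FALSE)
  community_table(binned, taxonomy, table$metadata)
}

#' Read a pore-fluid profile CSV
#'
#' Columns `core_id`, `depth_cm`, `O2_uM`, `NO3_uM`, `NH4_uM`, `Mn_uM`;
#' empty cells mark missing measurements.
#'
#' @param path file path.
#' @return a `pore_fluid` data frame.
#' @export
read_pore_fluid <- function(path) {
  prof <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("core_id", "depth_cm", "O2_uM", "NO3_uM", "NH4_uM", "Mn_uM")
  if (!all(need %in% names(prof)))
    stop("pore-fluid file must have columns ", paste(need, collapse = ", "))
  conc <- as.matrix(prof[, need[-(1:2)]])
  if (any(conc < 0, na.rm = TRUE)) stop("concentrations must be >= 0")
  class(prof) <- c("pore_fluid", "data.frame")
  prof
}

#' Interpolate pore-fluid chemistry onto microbial sampling depths
#'
#' Linear interpolation per core and constituent. Sample depths inside the
#' measured range get the interpolant (a depth equal to a measurement knot
#' returns the measured value, provenance `measured`); depths outside the
#' range are flagged `out_of_range` with no value — no extrapolation.
#' A core with fewer than two non-missing measurements for a constituent
#' has all its samples flagged `unavailable` for it, with a warning.
#'
#' @param profile a `pore_fluid` data frame (may hold several cores).
#' @param samples sample metadata with `sample_id`, `core_id`, `depth_cm`.
#' @return a `sample_chemistry` data frame: per sample, one value column
#'   and one provenance column per constituent (`O2`, `NO3`, `NH4`, `Mn`).
#' @export
interpolate_chemistry <- function(profile, samples) {
  out <- data.frame(sample_id = samples$sample_id,
                    core_id = samples$core_id,
                    depth_cm = samples$depth_cm,
                    stringsAsFactors = FALSE)
  for (con in CONSTITUENTS) {
    out[[con]] <- NA_real_
    out[[paste0(con, "_flag")]] <- "unavailable"
  }
  for (core in unique(samples$core_id)) {
    srows <- which(samples$core_id == core)
    prows <- profile[profile$core_id == core, , drop = FALSE]
    for (con in CONSTITUENTS) {
      col <- paste0(con, "_uM")
      meas <- prows[!is.na(prows[[col]]), c("depth_cm", col)]
      meas <- meas[order(meas$depth_cm), , drop = FALSE]
      if (nrow(meas) < 2) {
        warning(sprintf("core %s: fewer than 2 %s measurements; samples flagged unavailable",
                        core, con))
        next
      }
      z <- samples$depth_cm[srows]
      inside <- z >= min(meas$depth_cm) & z <= max(meas$depth_cm)
      vals <- rep(NA_real_, length(z))
      if (any(inside))
        vals[inside] <- approx(meas$depth_cm, meas[[col]], xout = z[inside],
                               ties = "ordered")$y
      at_knot <- z %in% meas$depth_cm
      flag <- ifelse(!inside, "out_of_range",
                     ifelse(at_knot, "measured", "interpolated"))
      out[[con]][srows] <- vals
      out[[paste0(con, "_flag")]][srows] <- flag
    }
  }
  class(out) <- c("sample_chemistry", "data.frame")
  out
}

#' Assign anoxia: impute zero oxygen from ammonium and manganese
#'
#' Samples without an oxygen value whose ammonium is at or above
#' `nh4_threshold` and (when `require_mn`) whose manganese is present get
#' oxygen set to 0 uM with provenance `imputed_anoxic`. Measured or
#' interpolated oxygen is never overwritten; the rule is idempotent.
#'
#' @param chem a `sample_chemistry` data frame.
#' @param nh4_threshold ammonium threshold, uM (default 10).
#' @param require_mn require manganese presence (default `TRUE`).
#' @param mn_detection_limit manganese presence limit, uM (default 0:
#'   any positive value counts as present).
#' @return the updated `sample_chemistry`.
#' @export
impute_anoxia <- function(chem, nh4_threshold = 10, require_mn = TRUE,
                          mn_detection_limit = 0) {
  no_o2 <- chem$O2_flag %in% c("unavailable", "out_of_range")
  nh4_hi <- !is.na(chem$NH4) & chem$NH4 >= nh4_threshold
  mn_ok <- if (require_mn) !is.na(chem$Mn) & chem$Mn > mn_detection_limit
           else rep(TRUE, nrow(chem))
  hit <- no_o2 & nh4_hi & mn_ok
  chem$O2[hit] <- 0
  chem$O2_flag[hit] <- "imputed_anoxic"
  chem
}

# Samples with a usable value for a constituent (measured, interpolated,
# or anoxia-imputed for oxygen).
chem_available <- function(chem, constituent) {
  chem[[paste0(constituent, "_flag")]] %in%
    c("measured", "interpolated", "imputed_anoxic")
}
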