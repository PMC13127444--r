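# Sample bookkeeping of the six-area deep-sea sediment survey whose
# design the synthetic generator emulates, shipped as plain-text
# inventories under extdata.

#' Site and sample inventory of the emulated survey
#'
#' Per geographic area (Arctic Mid-Ocean Ridge, Western North Atlantic
#' Gyre, Mid-Atlantic Ridge, North-West Pacific Ocean, South Pacific
#' Ocean, South China Sea): number of sites and 16S samples per source
#' dataset.
#'
#' @return data frame with columns `area`, `dataset`, `n_sites`,
#'   `n_samples`.
#' @export
study_sample_inventory <- function() {
  read.delim(system.file("extdata", "survey_site_inventory.tsv",
                         package = "redoxtaxa"),
             stringsAsFactors = FALSE)
}

#' Per-area sample counts available per chemical constituent
#'
#' Number of survey samples with a usable pore-fluid value (measured,
#' interpolated, or anoxia-assigned) for each redox constituent.
#'
#' @return data frame with columns `area`, `O2`, `NO3`, `NH4`, `Mn`.
#' @export
constituent_sample_counts <- function() {
  read.delim(system.file("extdata", "survey_constituent_counts.tsv",
                         package = "redoxtaxa"),
             stringsAsFactors = FALSE)
}
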