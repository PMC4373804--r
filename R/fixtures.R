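## Packaged example data sets.

#' Galapagos carpenter bee haplotype incidence matrix (reconstructed)
#'
#' Haplotype-by-island sample counts for the 12 mitochondrial *COII*
#' haplotypes of *Xylocopa darwini* across the nine occupied Galapagos
#' islands (118 bees). The island occupancy sets, the per-island haplotype
#' richness, and the totals for the widespread haplotypes (h3: 53 samples
#' on six islands; h4: 25 on three; h11 on two) follow the published
#' summary of the data set; the split of the remaining counts across
#' islands is a plausible reconstruction, since per-cell counts were
#' never published. Sequence-free: only the incidence structure is known.
#'
#' @return A `hap_table` with 12 haplotypes and 9 islands.
#' @seealso [inferred_events()], [galapagos_species_summary()]
#' @export
xylocopa_incidence <- function() {
  read_incidence(system.file("extdata",
                             "xylocopa_coii_incidence_reconstructed.tsv",
                             package = "islehaps", mustWork = TRUE))
}

#' Cross-species colonization summary (published inputs)
#'
#' Published per-species inputs for the cross-archipelago comparison:
#' islands occupied, archipelago islands considered, haplotype count and
#' the inferred number of colonization events reported by each source
#' study (Galapagos, Azores, Canary Islands; three animals, four plants).
#'
#' @return List of species records for [species_report()].
#' @export
galapagos_species_summary <- function() {
  read_species_summary(system.file("extdata",
                                   "galapagos_species_summary.tsv",
                                   package = "islehaps", mustWork = TRUE))
}

#' Qualitative colonization patterns of Galapagos animal groups
#'
#' Static reference table: occupancy and a one-line colonization pattern
#' for ten animal groups studied across the Galapagos archipelago.
#' Shipped for context only; nothing in the package computes from it.
#'
#' @return Data.frame with columns `species_group`, `n_islands_occupied`,
#'   `pattern`.
#' @export
colonization_patterns <- function() {
  utils::read.delim(system.file("extdata", "colonization_patterns.tsv",
                                package = "islehaps", mustWork = TRUE),
                    sep = "\t", stringsAsFactors = FALSE)
}
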