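#' Default insect species roster
#'
#' Metadata for the 13-species, four-order study panel: one hemipteran
#' (pea aphid), one coleopteran (red flour beetle), two lepidopterans
#' (silkworm, monarch) and nine dipterans (mosquitoes and drosophilids).
#' `sex_system` records the sex-determination system used to stratify the
#' chromosome cross-tabulation.
#'
#' @return A data.frame with columns `species_id`, `order_name`,
#'   `sex_system`, `display_name`.
#' @export
default_species_meta <- function() {
  data.frame(
    species_id = c("Apis", "Tcas", "Bmor", "Dple", "Aaeg", "Aalb", "Agam",
                   "Aste", "Dmel", "Dpse", "Dsim", "Dvir", "Dyak"),
    order_name = c("Hemiptera", "Coleoptera", "Lepidoptera", "Lepidoptera",
                   rep("Diptera", 9L)),
    sex_system = c("XO", "XY", "ZW", "ZW", rep("XY", 9L)),
    display_name = c("Acyrthosiphon pisum", "Tribolium castaneum",
                     "Bombyx mori", "Danaus plexippus", "Aedes aegypti",
                     "Anopheles albimanus", "Anopheles gambiae",
                     "Anopheles stephensi", "Drosophila melanogaster",
                     "Drosophila pseudoobscura", "Drosophila simulans",
                     "Drosophila virilis", "Drosophila yakuba"),
    stringsAsFactors = FALSE
  )
}

#' Default 13-taxon species tree
#'
#' A fixed ultrametric-ish species tree mirroring the order-level structure
#' of the study panel: the hemipteran outermost, then the coleopteran and
#' the lepidopteran pair, then the dipteran clade (mosquitoes vs
#' drosophilids). Branch lengths are in expected substitutions per site.
#' The coleopteran terminal is deliberately long: it is the lineage on
#' which expression reversals concentrate under the default simulation
#' settings.
#'
#' @return An object of class `phylo`.
#' @export
default_species_tree <- function() {
  txt <- paste0(
    "(Apis:0.45,((Tcas:0.42,(Bmor:0.21,Dple:0.19):0.16):0.08,",
    "((Aaeg:0.18,((Agam:0.06,Aalb:0.07):0.03,Aste:0.08):0.07):0.09,",
    "((Dmel:0.05,(Dsim:0.03,Dyak:0.04):0.02):0.06,",
    "(Dpse:0.07,Dvir:0.10):0.04):0.07):0.10):0.05);"
  )
  read_newick(text = txt)
}

valid_sex_systems <- c("XY", "ZW", "XO", "unknown")
valid_chromosome_classes <- c("X", "Z", "autosome", "unknown")
bias_directions <- c("male", "female", "unbiased")
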