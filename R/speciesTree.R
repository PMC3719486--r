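#' Default eight-species plant tree with named ancestors
#'
#' A species tree covering the classic FBA study panel: the green alga
#' Coccomyxa as outgroup, two lower land plants (Physcomitrella patens,
#' Selaginella moellendorffii), two monocots (Oryza sativa, Sorghum
#' bicolor) and three eudicots (Vitis vinifera, Populus trichocarpa,
#' Arabidopsis thaliana). Ancestor nodes are labeled N0 (Chloroplastida
#' ancestor), N1 (land plants), N2 (angiosperms), N3 (monocots), N4
#' (eudicots); the two remaining internal nodes (N1a: vascular plants,
#' N4a: rosids) are named for uniqueness. Branch lengths are arbitrary
#' time units of order one.
#'
#' @return a rooted `phylo` with unique tip and node names.
#' @export
defaultSpeciesTree <- function() {
  ape::read.tree(text = paste0(
    "((Physcomitrella_patens:0.50,(Selaginella_moellendorffii:0.47,",
    "((Oryza_sativa:0.12,Sorghum_bicolor:0.12)N3:0.18,",
    "(Vitis_vinifera:0.22,(Populus_trichocarpa:0.20,",
    "Arabidopsis_thaliana:0.20)N4a:0.02)N4:0.08)N2:0.17)N1a:0.03)N1:0.60,",
    "Coccomyxa_sp:1.10)N0;"))
}
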