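#' Benchmark scenario: recoverable clade structure
#'
#' A fixed study design used by the recovery analyses: the eight-species
#' panel with a long pre-land-plant stem carrying an early duplication
#' wave (a burst confined to the first 4% of the stem) that founds on
#' the order of a dozen subfamily lineages, followed by a compressed
#' ingroup radiation, losses on the ingroup branches that confine some
#' founders to single species, and recent duplication waves on every
#' terminal ingroup branch (strongest in Arabidopsis thaliana).
#'
#' The design makes within-founder divergence small against the
#' saturating divergence separating founders — the regime in which
#' supported clades in a bootstrap NJ tree correspond to founder
#' lineages, so the stable/unstable/singleton truth is recoverable.
#' The outgroup branch carries no events and always contributes the
#' single rooting gene.
#'
#' @param seed master seed stored in the returned parameters.
#' @return list with `speciesTree` (a `phylo`) and `params`
#'   (a [SimParams-class]).
#' @export
recoveryScenario <- function(seed = 1L) {
  tree <- ape::read.tree(text = paste0(
    "((Physcomitrella_patens:0.30,(Selaginella_moellendorffii:0.28,",
    "((Oryza_sativa:0.10,Sorghum_bicolor:0.10)N3:0.10,",
    "(Vitis_vinifera:0.16,(Populus_trichocarpa:0.12,",
    "Arabidopsis_thaliana:0.12)N4a:0.04)N4:0.04)N2:0.08)N1a:0.02)N1:2.50,",
    "Coccomyxa_sp:2.80)N0;"))
  terminals <- c("Physcomitrella_patens", "Selaginella_moellendorffii",
                 "Oryza_sativa", "Sorghum_bicolor", "Vitis_vinifera",
                 "Populus_trichocarpa", "Arabidopsis_thaliana")
  waves <- rbind(
    data.frame(branch = "N1", mult = 1400, from = 0, to = 0.04),
    data.frame(branch = terminals,
               mult = ifelse(terminals == "Arabidopsis_thaliana",
                             600, 100),
               from = 0, to = 1))
  lambda <- c(0.02, Coccomyxa_sp = 0)    # global baseline; quiet outgroup
  mu <- c(0, setNames(rep(5.0, 13L),
                      c(terminals, "N1a", "N2", "N3", "N4", "N4a",
                        "Coccomyxa_sp")))
  mu[["Coccomyxa_sp"]] <- 0              # the rooting gene never dies
  params <- simParams(
    lambda = lambda, mu = mu, waves = waves,
    kappa = 2, omegaBackground = 0.3,
    regions = data.frame(name = c("F-box", "FBA-D"),
                         start = c(11L, 101L), end = c(60L, 190L),
                         omega = c(0.05, 1.2)),
    rootLength = 200L, seed = seed)
  list(speciesTree = tree, params = params)
}
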