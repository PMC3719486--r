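# famwave

Birth–death evolution of large plant gene families: simulation,
phylogeny-based classification, ancestral gain/loss reconstruction,
selection profiling and expression divergence.

## The problem

Plant F-box proteins — the substrate-recognition subunits of SCF
ubiquitin ligases — form one of the fastest-evolving gene families in
plants. Subfamilies such as the FBA proteins (F-box plus a C-terminal
FBA interaction domain) expanded from a single ancestral gene to
hundreds of copies in individual genomes, in lineage-specific bursts
("expansion waves"). Analysing such a family means answering, from
sequences, trees, coordinates and expression data:

* which genes sit in conserved multi-species clades (**stable**), which
  in single-species expansions (**unstable**), and which cluster with
  nothing (**singletons**);
* how many genes the ancestors had, and how many were gained and lost
  on each branch of the species tree;
* whether duplicates sit in tandem arrays (< 10 kb apart) on the
  chromosomes;
* how selection (Ka/Ks) differs between domains and between stable and
  unstable genes;
* whether sequence clades still share expression programs.

famwave implements that pipeline as reusable R functions, plus a seeded
simulator that generates families with known ground truth so every step
can be validated by recovery rather than by eyeball.

## Methods at a glance

* **Simulator** — Gillespie birth–death along a species tree with named
  ancestors (N0…N4 style); per-branch rates λ, μ and duplication waves;
  MG94-style codon evolution with transition bias κ and per-domain ω
  (stop codons rejected, so alignments stay gap- and stop-free); tandem
  vs dispersed locus placement; log2 expression with a stable-gene
  offset δ. Ground truth records every event.
* **Phylogenetics** — JTT maximum-likelihood distances (pairwise
  deletion, 1-D likelihood optimization, saturation cap at 10
  subst/site); Saitou–Nei neighbor joining with deterministic tie-breaks
  and non-negative branches; bootstrap majority-rule consensus
  (frequency ≥ 0.5) with supports = round(100·frequency); outgroup
  rooting at the midpoint of the subtending edge; reciprocal best hits
  by global BLOSUM62 alignment.
* **Classification** — maximal clades with bootstrap support strictly
  > 40 and ≥ 2 leaves; stable / unstable / singleton by species span;
  per-species tallies with integer percentages.
* **Gain/loss** — Dollo parsimony: each clade gained once at the MRCA of
  its species, one ancestral copy along retention paths, losses where a
  clade disappears; `count(child) = count(parent) + gains − losses` is
  enforced on every branch.
* **Selection** — NG86 counting (synonymous fraction of non-stop
  changes per position; pathway-averaged differences excluding
  stop-traversing paths) with Jukes–Cantor correction
  d = −(3/4)·ln(1 − 4p/3); sliding windows (150 bp / 9 bp); per-domain
  estimates; Kruskal–Wallis group contrast.
* **Tandem** — per chromosome, link neighbours with intergenic gap
  strictly < 10 kb; single-linkage chains of ≥ 2 genes are clusters.
* **Expression** — log2 preprocessing; UPGMA (average linkage) on
  euclidean or 1 − Pearson distances, heights on the ultrametric d/2
  convention; pooled two-sample t test of per-gene means; adjusted Rand
  index between sequence clades and expression clusters.

See `vignettes/famwave-methods.Rmd` for the models, parameter defaults
and numerical conventions in detail.

## Worked example

Simulate a family on the bundled eight-species tree, rebuild its
phylogeny, classify genes, and reconstruct gains and losses:

```r
library(famwave)

scn <- recoveryScenario(seed = 1)      # species tree + wave parameters
sim <- simulateFamily(scn$speciesTree, scn$params)
sim$truth
#> SimTruth: 32 extant genes in 8 species; 29 duplications, 32 losses
#>   true categories: singleton=2, stable=26, unstable=4

cds  <- evolveSequences(sim$geneTree, scn$params)
prot <- translateCds(cds)
cons <- bootstrapConsensus(prot, nReps = 1000, seed = 101)
og   <- names(speciesMap(sim$truth))[
          speciesMap(sim$truth) == "Coccomyxa_sp"]
tree <- rootWithOutgroup(cons, og)

ca <- classifyGenes(extractSupportedClades(tree, minSupport = 40,
                                           outgroup = og),
                    speciesMap(sim$truth))
ca
#> CladeAssignment: 7 supported clades (> 40 support), 1 singletons
#>   categories: singleton=2, stable=26, unstable=4
mean(categories(ca)[names(trueCategories(sim$truth))] ==
     trueCategories(sim$truth))
#> [1] 1

h <- reconstructHistory(ca, scn$speciesTree)
h
#> FamilyHistory on 15 species-tree nodes; 9 clades
#>   total gains 20 ; total losses 8
head(historyTables(h)$branches)
#>                       branch gains losses
#> 1                         N1     1      0
#> 2      Physcomitrella_patens     2      0
#> 3                        N1a     2      0
#> 4 Selaginella_moellendorffii     3      1
#> 5                         N2     1      0
#> 6                         N3     0      2
```

Every gene was put back in its true category, and the branch table gives
the per-branch gains/losses that draw the usual "+n/−m" annotations on
the species tree. The same functions run on real data read with
`readLociBed()`, `readExpressionTsv()`, `readSpeciesMap()`,
`Biostrings::readAAStringSet()` and `ape::read.tree()`.

Ka/Ks on a simulated ortholog pair, with the classic window profile:

```r
p   <- simParams(kappa = 1, seed = 3)
gt  <- ape::read.tree(text = "(A_g1:0.3,B_g1:0.3);")
cds <- evolveSequences(gt, p)
r   <- kaksPair(as.character(cds[[1]]), as.character(cds[[2]]))
r
#> KaKsResult: 200 codons; Ka=0.3763 Ks=0.598 ratio=0.6293 [ok]
prof <- slidingWindowKaKs(as.character(cds[[1]]), as.character(cds[[2]]))
prof
#> KaKsProfile: 51 windows of 150 bp, step 9 bp over 600 bp
```

The whole-sequence ratio below one reflects the purifying background and
F-box region of the default domain map; the window table localizes the
diversifying C-terminal region.

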