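---
title: "Models and methods behind famwave"
author: "famwave maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind famwave}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famwave)
```

# Scope

famwave studies how a large plant gene family — the motivating case is the
F-box/FBA subfamily, whose members pair an N-terminal F-box domain with a
C-terminal FBA protein–protein interaction domain — expands and contracts
across a species phylogeny, and what that history does to selection
pressure and expression. The package provides two things:

1. a **generator** that simulates gene families with the statistical
   structure this kind of analysis assumes (birth–death histories with
   lineage-specific duplication waves, codon sequences with per-domain
   selection, tandem versus dispersed chromosomal placement,
   category-linked expression), together with full ground truth; and
2. the **analysis pipeline** itself: JTT protein distances, bootstrap NJ
   consensus trees, supported-clade extraction and
   stable/unstable/singleton classification, Dollo reconstruction of
   per-branch gene gains and losses, NG86 sliding-window Ka/Ks, tandem
   cluster detection, and expression clustering with clade-concordance
   measures.

Every analysis step accepts user data in standard formats (FASTA, Newick,
BED, TSV), so the generator is a testbed, not a dependency.

# The family simulator

## Birth–death process with waves

`simulateFamily()` evolves gene lineages along a species tree with named
ancestor nodes. Each lineage on a branch waits an exponential time for the
next event (Gillespie simulation); a duplication (rate $\lambda$) splits
the lineage in two, a loss (rate $\mu$) ends it, and at a speciation every
surviving lineage enters both descendant branches. Rates are per gene
lineage per unit branch length and may be overridden per branch. A
**wave** multiplies $\lambda$ on a declared fraction of one branch — the
minimal mechanism for the lineage-specific expansion bursts that shape
families like FBA, where a single founder gene in the land-plant ancestor
grew to hundreds of copies in individual angiosperm genomes.

Bookkeeping is exact: for every branch, lineages out = lineages in +
duplications − losses, asserted by the `SimTruth` validity. A family in
which every lineage dies is returned as an explicit empty result.

## Ground-truth categories

The classification the pipeline aims to recover is defined on the true
history via **founder lineages**: the gene lineages alive at a reference
node of the species tree (by default the ingroup ancestor when the root
subtends a single-species outgroup). A founder retained in two or more
species is *stable*; one confined to a single species with two or more
surviving copies is *unstable* (a lineage-specific expansion); a lone
survivor is a *singleton*. This mirrors the clade-level definitions used
on reconstructed trees — multi-species clade, single-species clade,
unplaced gene — while being derivable from the simulation record alone.
A second, finer decomposition (`trueCladeAssignment(truth, "event")`)
makes one group per retained duplication copy and is the right yardstick
for gain/loss recovery, where each duplication should surface as exactly
one Dollo gain.

## Codon sequences

`evolveSequences()` draws a stop-free random CDS at the root (default 200
codons) and evolves it by single-base events: transition bias $\kappa$
(default 2), nonsynonymous changes scaled by a per-region $\omega$, and
stop-creating mutations rejected outright, so frames stay open by
construction. Rates are normalized by $\kappa + 2$ so one unit of branch
length is one expected neutral mutation per site. There are no indels:
rows come out pre-aligned, which is what the downstream pairwise Ka/Ks
machinery consumes. The default domain map places a purifying F-box-like
region (codons 11–60, $\omega = 0.1$) and a diversifying FBA-like region
(codons 101–190, $\omega = 1.5$) over a background of 0.4 — the
qualitative pattern reported for real FBA genes, where the F-box stays
under purifying selection while the target-recognition domain
diversifies.

Because the mutation process has $\kappa$ bias, the NG86 estimator (which
assumes unbiased substitution) is only asked to be *calibrated* under
$\kappa = 1$; the neutrality and region-ordering checks therefore run the
generator with $\kappa = 1$.

## Loci and expression

`placeLoci()` lays each species' genes on long synthetic chromosomes.
Within a within-species paralog group (same founder), each copy after the
first is placed in tandem — downstream of the previous copy at a gap
drawn from 200–9000 bp — with probability `tandemProb` (default 0.35, the
order of the tandem fraction reported for unstable FBA genes), otherwise
at a dispersed position at least 200 kb from everything placed so far, so
that no dispersed pair can fall under the 10 kb rule by accident. Tandem
runs are recorded as truth.

`simulateExpression()` makes log2-scale values
$x_{gs} = \mathrm{baseline} + \delta\,[g\ \mathrm{stable}] +
\varepsilon_{gs}$ with iid Gaussian noise $\sigma$ (defaults: baseline 6,
$\delta = 2$, $\sigma = 1$), emulating the observation that stable genes
are expressed above unstable ones. An optional clade-linked random effect
(per clade and sample) induces within-clade co-expression for the
concordance analyses.

## Seeding discipline

All randomness flows from one integer seed in `SimParams`: the family
uses `seed`, sequences `seed + 1`, loci `seed + 2`, expression
`seed + 3`. Each stage restores the caller's RNG state, and identical
parameters give byte-identical outputs.

# The analysis pipeline

## JTT distances

`jttMlDistance()` computes the time $t \ge 0$ maximizing the likelihood
of the aligned residue pairs under the JTT replacement model (Jones,
Taylor & Thornton 1992; the published exchangeability counts and
frequencies are embedded as constants), with the generator normalized to
one expected substitution per site. Columns with a gap or non-standard
residue in either row are dropped first (pairwise deletion); zero shared
columns is an error. The optimization is Brent's method on $[10^{-8},
10]$ with tolerance $10^{-6}$; estimates at the cap of 10
substitutions/site are flagged saturated. A Poisson-corrected distance
($-\ln(1 - p)$) is available as a fallback method.

One subtlety worth recording: the folk rule "corrected distance ≥
p-distance" is *not* a theorem for ML distances under an empirical
matrix. A single D↔E difference — one of the most frequent exchanges
under JTT — in a short alignment is explained by less than one expected
substitution per differing site, so the estimate can undercut the
p-distance. At one mismatch in 100 sites the correction does exceed
1/100, and the test suite asserts exactly that regime plus positivity.

## Neighbor joining, bootstrap, rooting

`neighborJoining()` is the standard Saitou–Nei agglomeration with two
contracts pinned down: ties in the Q criterion are broken by the
lexicographically smallest pair of cluster labels (so results are
invariant to input order), and a negative pendant branch is clamped to
zero with the deficit shifted to its sister, preserving the pair's total.
On additive matrices it reproduces the generating tree's path distances
exactly (tested to $10^{-9}$ against 200 random trees, with ape's NJ as
an independent topological cross-check).

`bootstrapConsensus()` resamples columns with replacement, rebuilds an NJ
tree per replicate, and returns the majority-rule consensus keeping
bipartitions with frequency ≥ 0.5 (the boundary is inclusive), node
labels carrying round(100·frequency). Within replicates, pairwise JTT
likelihoods are maximized on a fixed 64-point log-spaced time grid with
parabolic refinement — a deliberate approximation (~1–2% on a distance)
far inside bootstrap resampling noise that makes thousand-replicate runs
on dozens of sequences routine; the exact optimizer remains the
single-pair estimator.

`rootWithOutgroup()` places the root at the midpoint of the edge
subtending the outgroup leaf, preserving supports (they are carried as
edge-associated labels through the re-rooting) and total branch length.

`reciprocalBestHits()` replaces a BLAST screen at desk scale: exact
global Needleman–Wunsch scores under BLOSUM62 with affine gaps (open 11,
extend 1); a pair is kept exactly when each sequence is the other's
best hit, with lexicographic tie-breaking and a flag on tied pairs.

## Clades and categories

`extractSupportedClades()` walks a rooted tree from the root; on each
root-to-leaf path the first internal node with support strictly greater
than the threshold (default 40, matching the clustering rule used for
FBA proteins) and at least two leaves defines a maximal clade. Nested
supported nodes are absorbed; leaves covered by no supported node are
singletons. Three conservative conventions: missing or unparseable
supports count as zero, the root is never clade-defining, and a declared
outgroup is removed before extraction and reported as its own singleton.
Classification then follows the species span: ≥ 2 species → stable, one
species with ≥ 2 genes → unstable, otherwise singleton.
`tallyBySpecies()` reproduces the per-species count/percentage table
shape, with percentages rounded to the nearest integer.

Where curated information groups genes differently than raw support
(e.g. clades merged with an external gene-family resource),
`applyCladeOverride()` accepts a gene → clade table and re-partitions
accordingly; the default remains the single reproducible support rule.

## Dollo gains and losses

`reconstructHistory()` treats each clade (singletons included as one-gene
clades) as a Dollo character: gained exactly once at its origin — the
species-tree MRCA of the species retaining it — present as a *single*
ancestral copy along every path from the origin to a retaining species,
absent elsewhere. Ancestral node counts are the number of clades present;
internal-branch gains are the clades originating at the child and losses
the clades present at the parent but absent at the child; terminal
branches additionally absorb within-species copy-number expansion, so a
species' observed count is always reached on its own branch. The
conservation identity count(child) = count(parent) + gains − losses is
enforced on every branch by the class validity.

Two modelling choices deserve a note. Ancestral copy number per clade is
fixed at one — the minimal reading consistent with narratives like a
single-copy land-plant ancestor; the reconstruction is a parsimony lower
bound, and no attempt is made to time duplications within branches. And
when losses strand a founding clade's survivors below the root, Dollo
re-infers the family origin as a gain on a lower branch; totals can
therefore exceed the true duplication count by exactly one, while with
$\mu = 0$ reconstructed gains equal true duplication counts exactly.

## NG86 Ka/Ks

`ng86CodonSites()` counts synonymous sites per codon position as the
fraction of non-stop single-base changes that are synonymous;
`kaksPair()` counts differences by averaging over all orderings of the
minimal mutation path between each codon pair, excluding orderings that
pass through a stop codon and falling back to all orderings when every
one is blocked. Proportions per site are corrected with the Jukes–Cantor
transform $d = -\tfrac34 \ln(1 - \tfrac43 p)$; $p \ge 3/4$ raises a
saturation flag instead of producing arithmetic. $K_s = 0$ yields an
undefined ratio with a machine-readable flag ("undefined" when $K_a = 0$
too, "infinite" otherwise) rather than an infinity. Codons containing a
gap or ambiguity in either row are deleted pairwise; an aligned terminal
stop is trimmed.

`slidingWindowKaKs()` applies the estimator to windows of 150 bp moved in
9 bp steps (both configurable, multiples of 3), reporting 1-based
alignment coordinates and midpoints — the resolution at which the F-box
versus C-terminal-domain contrast becomes visible in single gene pairs.
`regionKaKs()` restricts to a codon interval, and `kaksGroupTest()` wraps
the Kruskal–Wallis rank test (tie-corrected, $\chi^2$ approximation) for
contrasts such as stable versus unstable ratio sets, excluding undefined
ratios with a logged count and returning $H = 0, p = 1$ for completely
tied inputs.

The estimator is deliberately the approximate counting method: it is
consistent across the sliding windows, fast enough for genome-scale
screens, and validated here against a brute-force pathway enumerator on
every ordered pair of sense codons. Likelihood-based $\omega$ estimators
are out of scope.

## Tandem clusters

`findTandemClusters()` sorts each chromosome's loci by start and links
adjacent genes whose intergenic gap (next start − previous end, 0-based
half-open coordinates) is strictly below 10 kb; chains of two or more
linked genes form single-linkage clusters, so a run is one cluster even
when its extremes are farther apart. Overlapping genes count as gap zero
and strand is ignored. The gap convention is the conservative reading of
"distance between genes"; both the measuring points and the threshold are
arguments. `tandemStats()` crosses cluster membership with categories
(counts and rounded percentages per category) and reports the fraction of
clustered genes whose cluster spans several phylogenetic clades.

## Expression

`preprocessLog2()` log2-transforms positive intensities exactly once
(double transformation and nonpositive cells are errors naming the
offender). `upgmaCluster()` is average-linkage clustering on euclidean or
correlation (1 − Pearson r) distances with merge heights reported on the
ultrametric convention — two genes at distance $d$ join at height $d/2$ —
and rows sorted by label first so ties resolve deterministically; a
zero-variance gene under the correlation metric is an error naming the
gene. `groupMeanTest()` averages each gene over samples and applies the
two-sample pooled-variance t test (groups in sorted label order; Welch by
flag). `cladeCoherence()` cuts the dendrogram into $k$ flat clusters
($k$ defaults to the number of sequence clades, since no principled cut
rule exists for a visual comparison) and reports the adjusted Rand index
against the clade partition plus each clade's co-clustered pair fraction;
a single-class partition returns NA flagged degenerate rather than a
number.

# Study designs used by the checks

The recovery benchmark (`recoveryScenario()`) is the regime in which
clade classification is identifiable: an early duplication wave confined
to the first 4% of a long (2.5 substitutions/site) pre-land-plant stem
founds on the order of a dozen lineages whose mutual divergence is
saturating while the splits *between* them are nearly simultaneous — so
deep bipartitions attract little bootstrap support — followed by a
compressed ingroup radiation (≤ 0.3 substitutions/site) in which each
founder's orthologs stay tight. Loss at rate 5 on ingroup branches gives
each founder about a 22% chance of retention per species path, producing
a mixture of multi-species founders (stable), single-species expansions
(unstable, amplified by recent terminal waves, strongest on the
*A. thaliana* branch) and lone survivors (singletons). The outgroup
branch carries no events, so a single alga gene always roots the tree.
With 1000 bootstrap replicates the pipeline recovers ≥ 90% of true
categories in this regime; small families (a handful of founders) are
the known weak spot, because a random deep bipartition among few groups
can exceed the 40-support threshold and absorb a lineage-specific clade.

Problem sizes in the test suite and acceptance script were chosen to make
Monte-Carlo error small relative to the effects under test: 2000
replicates for the pure-birth mean, 500 two-leaf replicates (150 codons)
for region ordering, 300 replicates of 1500 codons for the neutral
$K_a/K_s$ confidence interval (long sequences keep the ratio's Jensen
bias below the interval half-width), 1000 simulated datasets for t-test
calibration, and 200 random additive matrices for NJ. The recovery
benchmark itself runs at its design size of roughly 10–90 genes with
1000 bootstrap replicates.

# Known limitations

* No indels, no among-site rate variation, and no explicit
  pseudogenization state in the sequence model; neutral regions stand in
  for decaying genes.
* NG86 counting is biased under transition-biased mutation
  ($\kappa \ne 1$) — by design, as in the original method; calibration
  claims are made at $\kappa = 1$ only.
* Dollo reconstruction gives parsimony bounds, not probabilistic
  reconciliation; within-species expansions are attributed wholly to
  terminal branches.
* Bootstrap-replicate distances use the grid-accelerated JTT likelihood;
  supports inherit its ~1–2% distance accuracy, which is negligible
  against resampling noise but means replicate trees are not guaranteed
  bit-identical to ones built with the exact optimizer.
* The generator's expression model is Gaussian on the log2 scale with a
  single global offset for stable genes; real tissue atlases have
  heavier tails, correlated tissues and missing probes, so passing the
  calibration and power checks here says nothing about normalization
  issues in real microarray data.
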