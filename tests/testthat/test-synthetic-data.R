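## The birth-death family simulator, codon evolution, locus placement
## and expression generator.

twoLeafTree <- function(len = 2) ape::read.tree(
  text = sprintf("(A:%g,B:%g)R;", len, len))

test_that("without events every species keeps exactly one congruent gene", {
  tr <- defaultSpeciesTree()
  sim <- simulateFamily(tr, simParams(lambda = 0, mu = 0, seed = 1))
  sp <- speciesMap(sim$truth)
  expect_setequal(unname(sp), tr$tip.label)
  expect_equal(length(sp), length(tr$tip.label))
  ## topology congruent with the species tree
  gt <- sim$geneTree
  gt$tip.label <- unname(sp[gt$tip.label])
  expect_equal(ape::dist.topo(ape::unroot(gt), ape::unroot(tr)), 0,
               ignore_attr = TRUE)
  expect_true(all(sim$truth@branchCounts$dups == 0))
  expect_true(all(sim$truth@branchCounts$losses == 0))
})

test_that("pure-birth growth matches the e^(lambda T) expectation", {
  tr <- twoLeafTree(2)
  lam <- 0.5
  counts <- vapply(1:2000, function(s) {
    sim <- simulateFamily(tr, simParams(lambda = lam, mu = 0, seed = s))
    sum(speciesMap(sim$truth) == "A")
  }, numeric(1))
  expected <- exp(lam * 2)
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - expected), 3 * se + 1e-9)
})

test_that("the simulator is deterministic in its seed", {
  tr <- defaultSpeciesTree()
  p <- simParams(seed = 7)
  s1 <- simulateFamily(tr, p)
  s2 <- simulateFamily(tr, p)
  expect_identical(ape::write.tree(s1$geneTree),
                   ape::write.tree(s2$geneTree))
  expect_identical(s1$truth@events, s2$truth@events)
  s3 <- simulateFamily(tr, simParams(seed = 8))
  expect_false(identical(ape::write.tree(s1$geneTree),
                         ape::write.tree(s3$geneTree)))
})

test_that("total extinction yields an explicit empty family", {
  tr <- twoLeafTree(2)
  sim <- simulateFamily(tr, simParams(lambda = 0, mu = 30, seed = 3))
  expect_null(sim$geneTree)
  expect_length(speciesMap(sim$truth), 0)
})

test_that("branch bookkeeping balances for random parameter draws", {
  tr <- defaultSpeciesTree()
  for (s in 1:15) {
    p <- simParams(lambda = runif(1, 0, 0.8), mu = runif(1, 0, 0.6),
                   seed = s)
    sim <- simulateFamily(tr, p)
    bc <- sim$truth@branchCounts
    expect_equal(bc$nOut, bc$nIn + bc$dups - bc$losses)
  }
})

test_that("the pure-death limit leaves at most one gene per species", {
  tr <- defaultSpeciesTree()
  for (s in 1:15) {
    sim <- simulateFamily(tr, simParams(lambda = 0, mu = 0.5, seed = s))
    if (length(speciesMap(sim$truth)))
      expect_true(all(table(speciesMap(sim$truth)) == 1))
  }
})

test_that("duplication waves multiply the rate only inside their window", {
  tr <- twoLeafTree(1)
  waves <- data.frame(branch = "A", mult = 60, from = 0, to = 0.5)
  hits <- vapply(1:300, function(s) {
    sim <- simulateFamily(tr, simParams(lambda = 0.01, mu = 0,
                                        waves = waves, seed = s))
    ev <- sim$truth@events
    c(sum(ev$branch == "A" & ev$time < 0.5),
      sum(ev$branch == "A" & ev$time >= 0.5))
  }, numeric(2))
  expect_gt(sum(hits[1, ]), 10 * max(sum(hits[2, ]), 1))
})

test_that("zero branch lengths copy the root sequence to every tip", {
  gt <- ape::read.tree(text = "(A_g1:0,B_g1:0);")
  cds <- evolveSequences(gt, simParams(seed = 5))
  expect_equal(length(unique(as.character(cds))), 1L)
})

test_that("evolved sequences are aligned, stop-free and seed-reproducible", {
  scn <- recoveryScenario(seed = 2)
  sim <- simulateFamily(scn$speciesTree, scn$params)
  cds <- evolveSequences(sim$geneTree, scn$params)
  expect_true(all(Biostrings::width(cds) == 3 * scn$params@rootLength))
  prot <- translateCds(cds)
  expect_false(any(grepl("\\*", prot)))
  cds2 <- evolveSequences(sim$geneTree, scn$params)
  expect_identical(as.character(cds), as.character(cds2))
})

test_that("per-region omega shapes the NG86 estimates in the right order", {
  p <- simParams(kappa = 1, omegaBackground = 1,
                 regions = data.frame(name = c("conserved", "adaptive"),
                                      start = c(1L, 101L),
                                      end = c(50L, 150L),
                                      omega = c(0.2, 2.0)),
                 rootLength = 150L)
  gt <- twoLeafTree(0.3)
  gt$tip.label <- c("A_g1", "B_g1")
  ratios <- vapply(1:60, function(s) {
    cds <- evolveSequences(gt, p, seed = s)
    a <- as.character(cds[[1]]); b <- as.character(cds[[2]])
    c(regionKaKs(a, b, 1, 50)@ratio, regionKaKs(a, b, 101, 150)@ratio)
  }, numeric(2))
  expect_lt(mean(ratios[1, ], na.rm = TRUE), 1)
  expect_gt(mean(ratios[2, ], na.rm = TRUE), 1)
})

test_that("tandem placement round-trips through the detector", {
  scn <- recoveryScenario(seed = 6)
  p <- scn$params
  sim <- simulateFamily(scn$speciesTree, p)

  pTandem <- p; pTandem@tandemProb <- 1
  pl <- placeLoci(sim$truth, pTandem)
  found <- findTandemClusters(pl$loci, maxGap = 10000)
  expect_equal(sort(vapply(found$clusters, paste, "", collapse = "+")),
               sort(vapply(pl$clusters, paste, "", collapse = "+")))
  expect_gt(length(pl$clusters), 0)

  pNone <- p; pNone@tandemProb <- 0
  pl0 <- placeLoci(sim$truth, pNone)
  expect_length(findTandemClusters(pl0$loci, 10000)$clusters, 0)
  expect_length(pl0$clusters, 0)
})

test_that("a single-gene family yields one locus and no clusters", {
  tr <- twoLeafTree(1)
  sim <- simulateFamily(tr, simParams(lambda = 0, mu = 1.2, seed = 2))
  expect_length(speciesMap(sim$truth), 1)
  pl <- placeLoci(sim$truth, simParams(seed = 2))
  expect_length(pl$loci, 1)
  expect_length(pl$clusters, 0)
})

test_that("expression simulation is seeded and powered as designed", {
  cats <- setNames(rep(c("stable", "unstable"), each = 10),
                   paste0("g", 1:20))
  p <- simParams(exprDelta = 3, exprSigma = 1, seed = 2)
  m1 <- simulateExpression(cats, p, nSamples = 20)
  m2 <- simulateExpression(cats, p, nSamples = 20)
  expect_identical(m1, m2)
  expect_true(isTRUE(attr(m1, "log2")))

  ## delta = 3 sigma with 10 genes per group: essentially always detected
  rej <- vapply(1:200, function(s) {
    m <- simulateExpression(cats, p, nSamples = 20, seed = s)
    groupMeanTest(m, cats)$p < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.95)
})

test_that("the fixture bundle round-trips through the plain-text readers", {
  dir <- tempfile("bundle")
  fb <- writeFixtureBundle(dir, params = simParams(seed = 4),
                           nSamples = 8)
  expect_true(all(file.exists(unlist(fb$paths))))
  prot <- Biostrings::readAAStringSet(fb$paths$proteins)
  expect_setequal(names(prot), names(speciesMap(fb$truth)))
  gr <- readLociBed(fb$paths$loci)
  expect_setequal(names(gr), names(speciesMap(fb$truth)))
  expect_equal(GenomicRanges::start(gr), GenomicRanges::start(fb$loci))
  m <- readExpressionTsv(fb$paths$expression)
  expect_equal(unname(m), unname(fb$expression), tolerance = 1e-6,
               ignore_attr = TRUE)
  sp <- readSpeciesMap(fb$paths$speciesMap)
  expect_identical(sp, speciesMap(fb$truth))
  unlink(dir, recursive = TRUE)
})
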