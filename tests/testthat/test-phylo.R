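## JTT distances, neighbor joining, bootstrap consensus, rooting, RBH.

test_that("JTT ML distance behaves at the boundaries", {
  a <- randomProtein(80)
  expect_identical(as.numeric(jttMlDistance(a, a)), 0)
  expect_false(attr(jttMlDistance(a, a), "saturated"))

  ## one mismatch in 100 comparable sites: the multiple-hit correction
  ## pushes the estimate above the p-distance
  base <- strsplit(strrep("ALKE", 25), "")[[1]]
  mut <- base; mut[50] <- "W"
  d <- jttMlDistance(paste(base, collapse = ""), paste(mut, collapse = ""))
  expect_gt(as.numeric(d), 0.01)

  ## gap columns are deleted pairwise; all-gap overlap is an error
  expect_error(jttMlDistance("AR--", "--AR"), "no shared sites")
  g1 <- "ARND-LKE"; g2 <- "ARNE-LKE"
  expect_equal(as.numeric(jttMlDistance(g1, g2)),
               as.numeric(jttMlDistance("ARNDLKE", "ARNELKE")),
               tolerance = 1e-9)
})

test_that("JTT ML distance is symmetric and matches an independent ML fit", {
  set.seed(42)
  for (i in 1:5) {
    a <- randomProtein(120)
    b <- strsplit(a, "")[[1]]
    k <- sample(120, 25)
    b[k] <- vapply(k, function(.) randomProtein(1), "")
    b <- paste(b, collapse = "")
    d1 <- as.numeric(jttMlDistance(a, b))
    expect_equal(d1, as.numeric(jttMlDistance(b, a)), tolerance = 1e-9)
    ## independent oracle: phangorn's ML pairwise distance under JTT
    x <- phangorn::phyDat(rbind(s1 = strsplit(a, "")[[1]],
                                s2 = strsplit(b, "")[[1]]), type = "AA")
    d2 <- as.matrix(phangorn::dist.ml(x, model = "JTT"))[1, 2]
    expect_equal(d1, d2, tolerance = 1e-3)
  }
})

test_that("JTT distance is positive iff sequences differ, and saturates", {
  ## equality with the p-distance only at zero; positive whenever any
  ## comparable column differs
  set.seed(7)
  for (i in 1:10) {
    a <- randomProtein(200)
    b <- strsplit(a, "")[[1]]
    k <- sample(200, 15)
    b[k] <- vapply(k, function(.) randomProtein(1), "")
    p <- mean(strsplit(a, "")[[1]] != b)
    d <- as.numeric(jttMlDistance(a, paste(b, collapse = "")))
    if (p > 0) expect_gt(d, 0) else expect_identical(d, 0)
  }
  ## a rare exchange at every site pushes the estimate past the cap
  d <- jttMlDistance(strrep("A", 50), strrep("W", 50))
  expect_true(attr(d, "saturated"))
  expect_equal(as.numeric(d), 10)
  ## poisson fallback exceeds the p-distance by construction
  dp <- jttMlDistance("AAAA", "AAAR", method = "poisson")
  expect_equal(as.numeric(dp), -log(1 - 0.25), tolerance = 1e-12)
  expect_gt(as.numeric(dp), 0.25)
})

test_that("neighbor joining recovers an additive four-leaf tree exactly", {
  ## leaf edges 1,2,3,4 around an internal edge of length 1
  d <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4, 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tr <- neighborJoining(d)
  expect_equal(cophenetic(tr)[LETTERS[1:4], LETTERS[1:4]], d,
               tolerance = 1e-12)
  ## the split AB|CD is present
  parts <- ape::prop.part(ape::root(tr, "A", resolve.root = TRUE))
  tipsets <- lapply(parts, function(p) sort(attr(parts, "labels")[p]))
  expect_true(list(c("C", "D")) %in% tipsets ||
              list(c("A", "B")) %in% tipsets)
})

test_that("three labels resolve by the three-point formulas", {
  d <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- neighborJoining(d)
  expect_equal(sort(tr$tip.label), c("a", "b", "c"))
  expect_equal(cophenetic(tr)[c("a", "b", "c"), c("a", "b", "c")], d,
               tolerance = 1e-12)
})

test_that("NJ reproduces path distances on random additive matrices", {
  set.seed(99)
  for (i in 1:40) {
    n <- sample(4:8, 1)
    ad <- randomAdditiveMatrix(n)
    tr <- neighborJoining(ad$d)
    expect_lt(max(abs(cophenetic(tr)[rownames(ad$d), colnames(ad$d)] -
                      ad$d)), 1e-9)
    ## cross-check the topology against ape's reference NJ
    expect_equal(ape::dist.topo(ape::unroot(tr),
                                ape::unroot(ape::nj(ad$d))), 0,
                 ignore_attr = TRUE)
  }
})

test_that("NJ is invariant under permutation of the input labels", {
  set.seed(5)
  ad <- randomAdditiveMatrix(7)
  tr1 <- neighborJoining(ad$d)
  perm <- sample(7)
  tr2 <- neighborJoining(ad$d[perm, perm])
  expect_equal(ape::dist.topo(tr1, tr2), 0, ignore_attr = TRUE)
  expect_equal(cophenetic(tr2)[rownames(ad$d), rownames(ad$d)],
               cophenetic(tr1)[rownames(ad$d), rownames(ad$d)],
               tolerance = 1e-9)
})

test_that("NJ rejects malformed input", {
  d <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_error(neighborJoining(d), "at least 3")
  d3 <- matrix(c(0, 1, 2, 3, 0, 1, 2, 1, 0), 3, 3)
  expect_error(neighborJoining(d3), "not symmetric")
})

test_that("bootstrap consensus gives full support to a clean bipartition", {
  ## two tight cherries and a distant fifth sequence: every column
  ## supports the same splits
  set.seed(19)
  base <- strsplit(randomProtein(120), "")[[1]]
  mut <- function(x, k) {
    i <- sample(length(x), k)
    x[i] <- vapply(i, function(.) randomProtein(1), "")
    x
  }
  grp2 <- mut(base, 40)
  grp3 <- mut(grp2, 40)
  cdAnc <- mut(grp2, 15)   # private stem so {C,D} has its own edge
  aln <- vapply(list(A = mut(base, 3), B = mut(base, 3),
                     C = mut(cdAnc, 3), D = mut(cdAnc, 3),
                     E = mut(grp3, 3), F = mut(grp3, 3)),
                paste, "", collapse = "")
  cons <- bootstrapConsensus(aln, nReps = 100, seed = 1)
  sup <- suppressWarnings(as.numeric(cons$node.label))
  expect_true(all(sup[!is.na(sup)] >= 95))
  parts <- ape::prop.part(cons)
  tipsets <- lapply(parts, function(p) sort(attr(parts, "labels")[p]))
  expect_true(any(vapply(tipsets, identical, TRUE, y = c("A", "B"))))
  expect_true(any(vapply(tipsets, identical, TRUE, y = c("C", "D"))))
  ## identical runs from the same seed
  cons2 <- bootstrapConsensus(aln, nReps = 100, seed = 1)
  expect_identical(ape::write.tree(cons), ape::write.tree(cons2))
})

test_that("consensus keeps only bipartitions at or above the threshold", {
  set.seed(3)
  aln <- vapply(1:6, function(.) randomProtein(60), "")
  names(aln) <- paste0("g", 1:6)
  cons <- bootstrapConsensus(aln, nReps = 150, seed = 2, threshold = 0.5)
  sup <- suppressWarnings(as.numeric(cons$node.label))
  expect_true(all(sup[!is.na(sup)] >= 50))
  expect_error(bootstrapConsensus(aln[1:2], nReps = 10, seed = 1),
               "at least 3")
})

test_that("bootstrap supports survive duplicating the alignment columns", {
  set.seed(29)
  base <- strsplit(randomProtein(150), "")[[1]]
  mut <- function(x, k) {
    i <- sample(length(x), k)
    x[i] <- vapply(i, function(.) randomProtein(1), "")
    x
  }
  grp2 <- mut(base, 50)
  grp3 <- mut(grp2, 50)
  cdAnc <- mut(grp2, 30)
  aln <- vapply(list(A = mut(base, 3), B = mut(base, 3),
                     C = mut(cdAnc, 3), D = mut(cdAnc, 3),
                     E = mut(grp3, 3), F = mut(grp3, 3)),
                paste, "", collapse = "")
  s1 <- bootstrapConsensus(aln, nReps = 80, seed = 4)
  s2 <- bootstrapConsensus(setNames(paste0(aln, aln), names(aln)),
                           nReps = 80, seed = 4)
  ## supports of the clean bipartitions are unchanged by doubling the
  ## column block; resampling noise cannot move a 100% split
  expect_identical(sort(s1$node.label), sort(s2$node.label))
  expect_true(all(suppressWarnings(
    as.numeric(s1$node.label[-1])) == 100))
})

test_that("outgroup rooting places the root mid-edge and conserves length", {
  tr <- ape::read.tree(text = "((A:1,B:2):0.5,(C:1.5,X:3):0.5);")
  r <- rootWithOutgroup(tr, "X")
  expect_true(ape::is.rooted(r))
  kids <- r$edge[r$edge[, 1] == length(r$tip.label) + 1, 2]
  expect_true(match("X", r$tip.label) %in% kids)
  expect_equal(sum(r$edge.length), sum(tr$edge.length), tolerance = 1e-12)
  ## rooting twice is idempotent on topology
  r2 <- rootWithOutgroup(r, "X")
  expect_equal(ape::dist.topo(ape::unroot(r), ape::unroot(r2)), 0,
               ignore_attr = TRUE)
  expect_true(match("X", r2$tip.label) %in%
                r2$edge[r2$edge[, 1] == length(r2$tip.label) + 1, 2])
  expect_error(rootWithOutgroup(tr, "nope"), "not found")
})

test_that("reciprocal best hits form a matching with correct tie handling", {
  set.seed(11)
  seqs <- setNames(vapply(1:4, function(.) randomProtein(50), ""),
                   paste0("p", 1:4))
  rbh <- reciprocalBestHits(seqs, setNames(seqs, paste0("q", 1:4)))
  expect_equal(nrow(rbh), 4L)
  expect_equal(sub("q", "p", rbh$geneB), rbh$geneA)
  expect_false(any(duplicated(rbh$geneA)) || any(duplicated(rbh$geneB)))

  one <- reciprocalBestHits(c(a = "MKLVW"), c(b = "MKLVW"))
  expect_equal(nrow(one), 1L)

  ## A1's best hit is B1, but B1 prefers A2: no pair for A1
  A <- c(A1 = "MKLVWAAA", A2 = "MKLVWPPF")
  B <- c(B1 = "MKLVWPPF")
  rb <- reciprocalBestHits(A, B)
  expect_equal(rb$geneA, "A2")
  expect_error(reciprocalBestHits(character(), B), "empty")
})
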