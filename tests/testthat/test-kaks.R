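## NG86 counting, Jukes-Cantor correction, windows and group contrast.

test_that("codon site counts match hand enumeration", {
  expect_equal(ng86CodonSites("TTT"), c(s = 1 / 3, n = 8 / 3))
  expect_equal(ng86CodonSites("CTT"), c(s = 1, n = 2))
  ## TGG: stop-creating changes leave positions 2 and 3 with smaller
  ## denominators but no synonymous option
  expect_equal(ng86CodonSites("TGG"), c(s = 0, n = 3))
  expect_error(ng86CodonSites("TAA"), "stop")
  expect_error(ng86CodonSites("TTN"), "unambiguous")
})

test_that("site counts equal the enumeration oracle on all sense codons", {
  for (cd in allSenseCodons())
    expect_equal(unname(ng86CodonSites(cd)),
                 unname(oracleCodonSites(cd)), tolerance = 1e-12,
                 label = cd)
})

test_that("pairwise differences match the pathway oracle on random codon pairs", {
  set.seed(31)
  sense <- allSenseCodons()
  for (i in 1:150) {
    c1 <- sample(sense, 1); c2 <- sample(sense, 1)
    r <- kaksPair(c1, c2)
    o <- oracleDiffs(c1, c2)
    expect_equal(r@sDiff, o[["sd"]], tolerance = 1e-12,
                 label = paste(c1, c2))
    expect_equal(r@nDiff, o[["nd"]], tolerance = 1e-12)
  }
})

test_that("the single-codon worked example is exact", {
  r <- kaksPair("TTT", "TTA")
  expect_equal(r@sDiff, 0)
  expect_equal(r@nDiff, 1)
  expect_equal(r@sSites, 0.5)
  expect_equal(r@nSites, 2.5)
  expect_equal(r@ks, 0)
  expect_equal(r@ka, -0.75 * log(1 - 4 / 3 * 0.4), tolerance = 1e-12)
  expect_equal(r@flag, "infinite")
  expect_true(is.na(kaksRatio(r)))
})

test_that("kaksPair is symmetric and flags identity as undefined", {
  set.seed(17)
  sense <- allSenseCodons()
  a <- paste(sample(sense, 40, replace = TRUE), collapse = "")
  b <- paste(sample(sense, 40, replace = TRUE), collapse = "")
  r1 <- kaksPair(a, b); r2 <- kaksPair(b, a)
  expect_equal(r1@sDiff, r2@sDiff, tolerance = 1e-12)
  expect_equal(r1@nDiff, r2@nDiff, tolerance = 1e-12)
  expect_equal(r1@sSites, r2@sSites, tolerance = 1e-12)
  same <- kaksPair(a, a)
  expect_equal(same@ka, 0)
  expect_equal(same@flag, "undefined")
  ## counting identities: sites sum to sequence length, differences to
  ## the literal mismatch count
  expect_equal(r1@sSites + r1@nSites, nchar(a))
  expect_equal(r1@sDiff + r1@nDiff,
               sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]]))
})

test_that("input validation and gap handling work", {
  expect_error(kaksPair("TTTA", "TTTA"), "divisible by 3")
  expect_error(kaksPair("TTTTAATTT", "TTTTAATTT"), "stop codon")
  ## terminal aligned stop is trimmed silently
  r <- kaksPair("TTTTAA", "TTCTAA")
  expect_equal(r@nCodons, 1L)
  ## gap codons are deleted pairwise
  g <- kaksPair("TTT---AAA", "TTCGGGAAA")
  expect_equal(g@nCodons, 2L)
  expect_equal(g@sDiff + g@nDiff, 1)
})

test_that("sliding windows tile the alignment as specified", {
  a <- strrep("CTT", 100); b <- a
  pr <- slidingWindowKaKs(a, b, window = 150, step = 9)
  expect_equal(nrow(profileWindows(pr)), 17L)
  expect_true(all(profileWindows(pr)$ka == 0))
  expect_true(all(profileWindows(pr)$ks == 0))
  expect_error(slidingWindowKaKs(a, b, window = 100, step = 9),
               "multiples of 3")

  ## a single nonsynonymous change at bp 199-201 (codon 67, middle base
  ## at bp 200) appears exactly in the windows covering that codon
  bb <- paste0(substr(a, 1, 198), "CAT", substr(a, 202, 300))
  pw <- profileWindows(slidingWindowKaKs(a, bb, window = 150, step = 9))
  hit <- pw$ka > 0
  overlap <- pw$start <= 199 & pw$end >= 201
  expect_equal(hit, overlap)
})

test_that("region estimates restrict and add up", {
  set.seed(23)
  sense <- allSenseCodons()
  a <- paste(sample(sense, 60, replace = TRUE), collapse = "")
  b <- paste(sample(sense, 60, replace = TRUE), collapse = "")
  whole <- kaksPair(a, b)
  reg <- regionKaKs(a, b, 1, 60)
  expect_equal(reg@sDiff, whole@sDiff, tolerance = 1e-12)
  expect_equal(reg@sSites, whole@sSites, tolerance = 1e-12)
  r1 <- regionKaKs(a, b, 1, 25)
  r2 <- regionKaKs(a, b, 26, 60)
  expect_equal(r1@sDiff + r2@sDiff, whole@sDiff, tolerance = 1e-12)
  expect_equal(r1@nDiff + r2@nDiff, whole@nDiff, tolerance = 1e-12)
  expect_error(regionKaKs(a, b, 10, 5), "empty or invalid")
  expect_error(regionKaKs(a, b, 1, 61), "exceeds")
})

test_that("the Kruskal-Wallis contrast matches the hand computation", {
  kt <- kaksGroupTest(list(stable = c(1, 2, 3), unstable = c(4, 5, 6)))
  expect_equal(kt$H, 12 / 42 * 87 - 21, tolerance = 1e-9)  # 3.857
  same <- kaksGroupTest(list(a = c(2, 2), b = c(2, 2)))
  expect_equal(same$H, 0)
  expect_equal(same$p, 1)
  ## rank-based: invariant under a monotone transform
  k1 <- kaksGroupTest(list(a = c(0.1, 0.5, 0.9), b = c(1.2, 2, 3.3)))
  k2 <- kaksGroupTest(list(a = exp(c(0.1, 0.5, 0.9)),
                           b = exp(c(1.2, 2, 3.3))))
  expect_equal(k1$H, k2$H, tolerance = 1e-12)
  ## undefined ratios are dropped with a message
  expect_message(kaksGroupTest(list(a = c(1, 2, NA), b = c(3, 4))),
                 "excluded")
})
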