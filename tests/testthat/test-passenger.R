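refVec <- function(values) {
  v <- setNames(rep(NA_real_, 59), degenerateCodons())
  v[names(values)] <- values
  new("LogOddsVector", values = v, context = "reference")
}

test_that("focal-exclusion profile: hand-computed example", {
  lib <- ConstructLibrary(c(c1 = "ATGAAAGGGACC"), window = c(2, 4))
  ref <- refVec(c(GGG = 0.4, ACC = -0.2, AAA = 9))
  prof <- focalExclusionProfile(lib, ref)
  row <- prof[prof$codon == "AAA", ]
  expect_equal(row$meanOfMeans, mean(c(0.4, -0.2)))  # AAA's own 9 excluded
  expect_equal(row$n, 1)
  expect_true(is.na(row$sd))                          # single construct
})

test_that("N counts constructs, not focal occurrences", {
  lib <- ConstructLibrary(c(c1 = "ATGAAAAAAGGG", c2 = "ATGAAAGGGACC"),
                          window = c(2, 4))
  ref <- refVec(c(GGG = 0.4, ACC = -0.2, AAA = 9))
  prof <- focalExclusionProfile(lib, ref)
  row <- prof[prof$codon == "AAA", ]
  expect_equal(row$n, 2)                              # c1 has AAA twice
  expect_equal(row$meanOfMeans, mean(c(0.4, mean(c(0.4, -0.2)))))
  expect_equal(row$sem, row$sd / sqrt(2))
})

test_that("profile equals the brute-force oracle on a small library", {
  lib <- randomLibrary(30, seed = 201)
  ref <- withr::with_seed(202,
    refVec(setNames(rnorm(59, 0, 0.5), degenerateCodons())))
  got <- focalExclusionProfile(lib, ref)
  ref61 <- setNames(rep(NA_real_, 61), senseCodons())
  ref61[degenerateCodons()] <- logOddsValues(ref)
  want <- oracleProfile(lib, ref61)
  expect_equal(got, want, tolerance = 1e-10)
})

test_that("co-occurrence counts: structure, homogeneity, row sums, oracle", {
  # identical codon multiset in every construct: observed == expected
  same <- ConstructLibrary(
    setNames(rep("ATGAAAAAGCCGGGTACC", 5), paste0("c", 1:5)),
    window = c(2, 6))
  st <- cooccurrenceCounts(same)
  o <- observedCounts(st); e <- expectedCounts(st)
  expect_equal(sum(!is.na(o)), 3660)
  ok <- !is.na(e) & e > 0
  expect_equal(o[ok], e[ok], tolerance = 1e-10)
  expect_equal(chi2Sum(st), 0, tolerance = 1e-10)
  expect_true(all(perCodonDev(st)[rowSums(ok) > 0] < 1e-12))

  lib <- randomLibrary(25, seed = 211)
  st2 <- cooccurrenceCounts(lib)
  o2 <- observedCounts(st2); e2 <- expectedCounts(st2)
  expect_equal(rowSums(o2, na.rm = TRUE), rowSums(e2, na.rm = TRUE),
               tolerance = 1e-9)
  want <- oracleCooccurrence(lib)
  expect_equal(o2, want$observed, tolerance = 1e-10)
  expect_equal(e2, want$expected, tolerance = 1e-10)
  expect_equal(chi2Sum(st2), want$chi2, tolerance = 1e-9)
  expect_equal(perCodonDev(st2), want$dev, tolerance = 1e-10)
})

test_that("chi2 contribution formula on a planted single-cell deviation", {
  st <- cooccurrenceCounts(randomLibrary(20, seed = 221))
  o <- observedCounts(st); e <- expectedCounts(st)
  cell <- which(!is.na(e) & e > 0, arr.ind = TRUE)[1, ]
  base <- chi2Sum(st)
  o2 <- o; o2[cell[1], cell[2]] <- e[cell[1], cell[2]] + 4
  st2 <- new("CooccurrenceStats", observed = o2, expected = e,
             nConstructs = st@nConstructs)
  oldCell <- (o[cell[1], cell[2]] - e[cell[1], cell[2]])^2 /
    e[cell[1], cell[2]]
  expect_equal(chi2Sum(st2), base - oldCell + 16 / e[cell[1], cell[2]],
               tolerance = 1e-9)
})

test_that("subsampled null: determinism and trivial statistic", {
  lib <- randomLibrary(300, seed = 231)
  n1 <- subsampleNull(lib, function(l) length(l), subsampleSize = 100,
                      reps = 10, seed = 3)
  expect_true(all(nullValues(n1) == 100))
  n2 <- subsampleNull(lib, function(l) chi2Sum(cooccurrenceCounts(l)),
                      subsampleSize = 100, reps = 5, seed = 9)
  n3 <- subsampleNull(lib, function(l) chi2Sum(cooccurrenceCounts(l)),
                      subsampleSize = 100, reps = 5, seed = 9)
  expect_identical(nullValues(n2), nullValues(n3))
  expect_error(subsampleNull(lib, length, subsampleSize = 301, reps = 2),
               "smaller")
})

test_that("z-score against a null distribution", {
  null <- new("NullDistribution", values = c(1, 2, 3),
              subsampleSize = 3L, seed = 1L)
  expect_equal(zScore(4, null), 2)
  expect_equal(zScore(2, null), 0)
  flat <- new("NullDistribution", values = c(2, 2, 2),
              subsampleSize = 3L, seed = 1L)
  expect_error(zScore(1, flat), "zero-variance")
})

test_that("profile SD summary", {
  prof <- data.frame(codon = degenerateCodons(),
                     meanOfMeans = rep(0.3, 59))
  expect_equal(sdOfProfile(prof), 0)
  prof$meanOfMeans <- c(0.1, -0.1, rep(NA, 57))
  expect_equal(sdOfProfile(prof), sd(c(0.1, -0.1)))
  prof$meanOfMeans <- c(0.1, rep(NA, 58))
  expect_error(sdOfProfile(prof), "fewer than 2")
})

test_that("window deduplication keeps first occurrences", {
  seqs <- c(a = "ATGAAACCCGGG", b = "ATGAAACCCGGG", c = "ATGAAGCCCGGG",
            d = "ATGAAACCCGGG", e = "ATGAAGCCAGGG")
  lib <- ConstructLibrary(seqs, window = c(2, 4))
  dd <- dedupeWindows(lib)
  expect_equal(constructIds(dd), c("a", "c", "e"))
  distinct <- ConstructLibrary(seqs[c(1, 3, 5)], window = c(2, 4))
  expect_equal(length(dedupeWindows(distinct)), 3)
})

test_that("residual attribution: null case and degenerate input", {
  vA <- withr::with_seed(241,
    refVec(setNames(rnorm(59), degenerateCodons())))
  expect_error(residualAttribution(vA, vA, NULL, NULL), "identical")
  # profile orthogonal to residuals by construction -> rho near 0
  vB <- withr::with_seed(242,
    refVec(setNames(rnorm(59), degenerateCodons())))
  prof <- data.frame(codon = degenerateCodons(),
                     meanOfMeans = withr::with_seed(243, rnorm(59)))
  res <- residualAttribution(vA, vB, prof, prof)
  expect_lt(abs(res$rhoTest), 0.35)   # independent noise, n = 59
  expect_equal(res$fractionExplainedTest, res$rhoTest^2)
})
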