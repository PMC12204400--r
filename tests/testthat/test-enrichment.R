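test_that("quartile partition takes inclusive tails on distinct values", {
  lib <- randomLibrary(100, seed = 11)
  m <- constructMetrics(lib)
  m$expr <- as.numeric(1:100)
  constructMetrics(lib) <- m
  q <- partitionQuartiles(lib, "expr")
  expect_equal(length(q$high), 25)
  expect_equal(length(q$low), 25)
  expect_setequal(metricValues(q$high, "expr"), 76:100)
  expect_setequal(metricValues(q$low, "expr"), 1:25)

  m$expr <- rep(1, 100)
  constructMetrics(lib) <- m
  expect_error(partitionQuartiles(lib, "expr"), "identical")
  expect_error(partitionQuartiles(lib, "absent"), "not present")
})

test_that("log-odds formula and Haldane-Anscombe correction", {
  # counts 10/30 vs 5/30 -> ln 2, via a synthetic two-codon setup
  mk <- function(codons) paste0("ATG", paste(codons, collapse = ""))
  hi <- ConstructLibrary(c(h = mk(c(rep("AAA", 10), rep("AAG", 30)))),
                         window = c(2, 41))
  lo <- ConstructLibrary(c(l = mk(c(rep("AAA", 5), rep("AAG", 30)))),
                         window = c(2, 41))
  v <- logOddsValues(logOdds(hi, lo, span = c(2, 41)))
  expect_equal(v[["AAA"]], log(2), tolerance = 1e-12)
  expect_equal(v[["AAG"]], -log(2), tolerance = 1e-12)

  # zero cell: c1f=0, c1s=10, c2f=4, c2s=10 -> ln(1/9)
  hi0 <- ConstructLibrary(c(h = mk(rep("AAG", 10))), window = c(2, 11))
  lo0 <- ConstructLibrary(c(l = mk(c(rep("AAA", 4), rep("AAG", 10)))),
                          window = c(2, 15))
  v0 <- logOddsValues(logOdds(hi0, lo0, span = c(2, 15)))
  k <- c(0, 10, 4, 10) + 0.5
  expect_equal(v0[["AAA"]], log((k[1] / k[2]) / (k[3] / k[4])),
               tolerance = 1e-12)
  expect_equal(v0[["AAA"]], log(1 / 9), tolerance = 1e-12)

  # absent amino acid: NA for the whole block
  expect_true(all(is.na(v[synonymousBlocks()[["P"]]])))
})

test_that("log-odds invariants: antisymmetry, swap, duplication", {
  lib <- applyExpression(randomLibrary(400, seed = 21), seed = 22)
  q <- partitionQuartiles(lib, "protein_per_rna")
  v <- logOddsValues(logOdds(q$high, q$low))
  # 2-fold blocks are exact negatives
  for (block in synonymousBlocks()) {
    if (length(block) != 2) next
    if (anyNA(v[block])) next
    expect_equal(v[[block[1]]], -v[[block[2]]], tolerance = 1e-12)
  }
  # swapping conditions negates every entry
  vs <- logOddsValues(logOdds(q$low, q$high))
  expect_equal(vs, -v, tolerance = 1e-12)
  # duplicating every construct in both sets changes nothing
  dup <- function(l) {
    l2 <- l
    ids <- c(constructIds(l), paste0(constructIds(l), "_b"))
    ConstructLibrary(rep(as.character(constructSeqs(l)), 2), ids = ids,
                     window = libraryWindow(l))
  }
  vd <- logOddsValues(logOdds(dup(q$high), dup(q$low)))
  expect_equal(vd, v, tolerance = 1e-12)
})

test_that("log-odds equals the brute-force recount oracle", {
  lib <- applyExpression(randomLibrary(48, seed = 31), seed = 32)
  q <- partitionQuartiles(lib, "protein_per_rna")
  v <- logOddsValues(logOdds(q$high, q$low))
  o <- oracleLogOdds(oracleWindows(q$high), oracleWindows(q$low))
  expect_equal(v, o, tolerance = 1e-10)
})

test_that("positional log-odds: per-position independence and symmetry", {
  lib <- toyLibrary()
  hi <- lib[1:3]; lo <- lib[4:6]
  P <- positionalLogOdds(hi, lo)
  expect_equal(dim(logOddsValues(P)), c(59, 10))
  # identical high and low sets: all non-NA entries are 0
  P0 <- logOddsValues(positionalLogOdds(hi, hi))
  expect_true(all(abs(P0[!is.na(P0)]) < 1e-12))
  # column +2 equals the single-position recount oracle
  o <- oracleLogOdds(oracleWindows(hi, c(2, 2)), oracleWindows(lo, c(2, 2)))
  expect_equal(logOddsValues(P)[, "+2"], o, tolerance = 1e-10)
})

test_that("5'-vs-core vector matches an oracle recount on a toy genome", {
  genes <- genomeSet(20, lengthRange = c(40, 60), gc3Target = 0.5,
                     fivePrimeAtBoost = 0.3, seed = 41)
  v <- logOddsValues(fivePrimeVsCore(genes))
  # oracle: recount five-prime and core codon sets directly
  s <- as.character(genes)
  five <- unlist(lapply(s, function(x)
    sapply(2:11, function(p) substr(x, 3 * p - 2, 3 * p))))
  core <- unlist(lapply(s, function(x) {
    nc <- nchar(x) / 3
    sapply(12:(nc - 1), function(p) substr(x, 3 * p - 2, 3 * p))
  }))
  o <- oracleLogOdds(list(five), list(core))
  expect_equal(v, o, tolerance = 1e-10)
  # A/T-ending codons are 5'-enriched by construction
  atEnding <- substr(degenerateCodons(), 3, 3) %in% c("A", "T")
  expect_gt(mean(v[atEnding], na.rm = TRUE), 0)
  expect_lt(mean(v[!atEnding], na.rm = TRUE), 0)
})

test_that("ordinal TEF groups fill to 25% and are seed-deterministic", {
  lib <- randomLibrary(1000, seed = 51)
  m <- constructMetrics(lib)
  m$tef <- rep(1:5, each = 200)
  constructMetrics(lib) <- m
  g <- ordinalGroups(lib, mode = "M9", seed = 7)
  expect_equal(length(g$low), 250)
  expect_equal(length(g$high), 250)
  tl <- metricValues(g$low, "tef"); th <- metricValues(g$high, "tef")
  expect_equal(sum(tl == 1), 200); expect_equal(sum(tl == 2), 50)
  expect_equal(sum(th == 5), 200); expect_equal(sum(th == 4), 50)
  g2 <- ordinalGroups(lib, mode = "M9", seed = 7)
  expect_identical(constructIds(g$high), constructIds(g2$high))
  expect_identical(constructIds(g$low), constructIds(g2$low))

  # greedy fill across whole fractions: sizes {400,50,50,50,450};
  # the high group needs only a subsample of fraction 5
  m$tef <- rep(1:5, times = c(400, 50, 50, 50, 450))
  constructMetrics(lib) <- m
  g3 <- ordinalGroups(lib, mode = "M9", seed = 1)
  expect_equal(length(g3$high), 250)
  expect_true(all(metricValues(g3$high, "tef") == 5))
  expect_true(all(metricValues(g3$low, "tef") == 1))
  # a fraction holding more than half the constructs is rejected
  m$tef <- rep(1:5, times = c(100, 100, 100, 100, 600))
  constructMetrics(lib) <- m
  expect_error(ordinalGroups(lib, mode = "M9", seed = 1), "exceeds 50%")
})

test_that("bootstrap log-odds: determinism and degenerate library", {
  lib <- applyExpression(randomLibrary(200, seed = 61), seed = 62)
  q <- partitionQuartiles(lib, "protein_per_rna")
  b1 <- bootstrapLogOdds(q$high, q$low, reps = 20, seed = 5)
  b2 <- bootstrapLogOdds(q$high, q$low, reps = 20, seed = 5)
  expect_identical(b1$vectors, b2$vectors)
  expect_equal(nrow(b1$vectors), 20)
  expect_error(bootstrapLogOdds(q$high, q$low, reps = 1), "reps")
  # all-identical constructs: every bootstrap vector identical
  same <- ConstructLibrary(setNames(rep("ATGAAAAAGCCGCCAGGTGGCTTATTGCGTCGATAA", 6),
                                    paste0("c", 1:6)), window = c(2, 11))
  b0 <- bootstrapLogOdds(same[1:3], same[4:6], reps = 5, seed = 1)
  expect_true(all(apply(b0$vectors, 2, function(col)
    length(unique(col[!is.na(col)])) <= 1)))
})

test_that("expression aggregation modes", {
  m <- rbind(c(2, NA, 4), c(NA, NA, NA))
  expect_equal(aggregateExpression(m, "mean_zero"), c(2, 0))
  expect_equal(aggregateExpression(m, "mean_na"), c(3, NA))
  expect_equal(aggregateExpression(m, "median_na"), c(3, NA))
  expect_equal(aggregateExpression(m, "median_zero"), c(2, 0))
  expect_error(aggregateExpression(m, "mode_x"))
})
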