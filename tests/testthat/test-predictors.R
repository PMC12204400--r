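test_that("adaptation scores reuse the enrichment machinery", {
  heg <- rep("AAAAAGAAA", 5)   # Lys-rich, AAA-dominant
  leg <- rep("AAGAAGAAA", 5)
  v <- logOddsValues(adaptationScores(heg, leg))
  o <- oracleLogOdds(list(unlist(strsplit(gsub("(...)", "\\1 ", heg), " "))),
                     list(unlist(strsplit(gsub("(...)", "\\1 ", leg), " "))))
  expect_equal(v, o, tolerance = 1e-10)
  expect_gt(v[["AAA"]], 0)
  expect_equal(v[["AAA"]], -v[["AAG"]], tolerance = 1e-12)
  # identical sets: all represented blocks 0
  v0 <- logOddsValues(adaptationScores(heg, heg))
  expect_true(all(abs(v0[!is.na(v0)]) < 1e-12))
})

test_that("feature table: densities, CAI spans, GC of first 30 nt", {
  # 10 codons: NGG x2 in first 6 (+2..+7), Pro x3, Lys x2, His, Arg
  codons <- c("AGG", "GGG", "CCG", "CCA", "CCT", "AAA",
              "AAG", "CAT", "CGT", "TTT")
  downstream <- rep("GAA", 20)
  seqs <- paste0("ATG", paste(codons, collapse = ""),
                 paste(downstream, collapse = ""))
  lib <- ConstructLibrary(c(c1 = seqs), window = c(2, 11))
  scores <- setNames(rep(0, 59), degenerateCodons())
  scores[c("AGG", "GGG")] <- c(0.2, -0.2)
  sv <- new("LogOddsVector", values = scores, context = "t")
  ft <- suppressWarnings(codonFeatures(lib, sv))
  expect_equal(ft$ngg, 2 / 6)
  expect_equal(ft$pro, 3 / 10)
  expect_equal(ft$pos, 5 / 10)   # AGG(R), AAA, AAG, CAT, CGT
  expect_equal(ft$gc, gcFraction(substr(seqs, 4, 33)))
  # CAI: mean over degenerate codons of span; +0.2 and -0.2 cancel
  expect_equal(ft$cai, 0)
  expect_equal(ft$delta_cai, 0 - 0)  # downstream GAA all score 0
  # short construct: delta_cai NA
  short <- ConstructLibrary(c(s = paste0("ATG",
    paste(codons, collapse = ""))), window = c(2, 11))
  fts <- suppressWarnings(suppressMessages(codonFeatures(short, sv)))
  expect_true(is.na(fts$delta_cai))
  expect_false(is.na(fts$cai))
})

test_that("features invariant to synonymous changes outside their window", {
  base <- paste0("ATG", strrep("AAA", 10), strrep("GAA", 21))
  # change downstream codons synonymously: 5' features unchanged
  alt <- paste0("ATG", strrep("AAA", 10), strrep("GAG", 21))
  sv <- new("LogOddsVector",
            values = setNames(rep(0.1, 59), degenerateCodons()),
            context = "t")
  f1 <- suppressWarnings(codonFeatures(
    ConstructLibrary(c(a = base), window = c(2, 11)), sv))
  f2 <- suppressWarnings(codonFeatures(
    ConstructLibrary(c(a = alt), window = c(2, 11)), sv))
  for (col in c("cai", "ngg", "pro", "pos", "gc"))
    expect_equal(f1[[col]], f2[[col]])
})

test_that("partial Spearman: limiting cases and matrix-inversion oracle", {
  d <- withr::with_seed(301, data.frame(
    x = rnorm(200), y = rnorm(200), z1 = rnorm(200), z2 = rnorm(200)))
  d$y <- d$y + 0.5 * d$x
  # no covariates: equals plain Spearman
  expect_equal(partialSpearman(d, "x", "y")$rho,
               cor(d$x, d$y, method = "spearman"), tolerance = 1e-12)
  # y fully explained by a covariate: partial rho collapses to 0
  d$ycopy <- d$y
  expect_equal(partialSpearman(d, "x", "y", "ycopy")$rho, 0)
  # matches the rank-correlation-matrix inversion oracle
  got <- partialSpearman(d, "x", "y", c("z1", "z2"))$rho
  want <- oraclePartialSpearman(d, "x", "y", c("z1", "z2"))
  expect_equal(got, want, tolerance = 1e-10)
  # 8-variable table
  d8 <- withr::with_seed(302, as.data.frame(
    matrix(rnorm(150 * 8), 150, dimnames = list(NULL, paste0("v", 1:8)))))
  d8$v2 <- d8$v2 + 0.4 * d8$v1 + 0.2 * d8$v3
  got8 <- partialSpearman(d8, "v1", "v2", paste0("v", 3:8))$rho
  want8 <- oraclePartialSpearman(d8, "v1", "v2", paste0("v", 3:8))
  expect_equal(got8, want8, tolerance = 1e-10)
  expect_error(partialSpearman(d, "x", "y", c("z1", "z1")), "collinear")
})

test_that("LMG decomposition: identities and enumeration oracle", {
  set.seed(311)
  n <- 500
  # near-orthogonal predictors: shares approach marginal R2
  x1 <- rnorm(n); x2 <- rnorm(n); x3 <- rnorm(n)
  y <- 1 * x1 + 0.5 * x2 + rnorm(n, 0, 0.5)
  d <- data.frame(y = y, x1 = x1, x2 = x2, x3 = x3)
  res <- lmgImportance(d, "y", c("x1", "x2", "x3"))
  expect_equal(sum(res$shares), res$r2, tolerance = 1e-12)
  expect_equal(res$shares, oracleLmg(d, "y", c("x1", "x2", "x3")),
               tolerance = 1e-10)
  # k = 2 closed form: share(x1) = (R2(x1) + R2(both) - R2(x2)) / 2
  r2of <- function(f) summary(lm(f, d))$r.squared
  cf <- (r2of(y ~ x1) + r2of(y ~ x1 + x2) - r2of(y ~ x2)) / 2
  res2 <- lmgImportance(d, "y", c("x1", "x2"))
  expect_equal(unname(res2$shares["x1"]), cf, tolerance = 1e-10)
  # duplicated predictor pair splits its contribution equally
  d$x1b <- d$x1 + rnorm(n, 0, 1e-8)
  resDup <- lmgImportance(d, "y", c("x1", "x1b", "x2"))
  expect_equal(unname(resDup$shares["x1"]), unname(resDup$shares["x1b"]),
               tolerance = 1e-3)
})

test_that("quadratic GC3 fit: exact parabola, linear data, recovery", {
  gc3v <- seq(0.25, 0.75, length.out = 30)
  y <- 0.2 + 1.5 * gc3v - 2 * gc3v^2
  f <- suppressWarnings(quadraticGc3Fit(gc3v, y))  # perfect-fit warning
  expect_equal(unname(f$coefficients), c(0.2, 1.5, -2), tolerance = 1e-9)
  expect_equal(f$adjR2, 1, tolerance = 1e-9)
  # linear data: curvature term near zero
  fl <- suppressWarnings(quadraticGc3Fit(gc3v, 0.1 + 0.5 * gc3v))
  expect_lt(abs(fl$coefficients[["quadratic"]]), 1e-9)
  # noisy parabola, n = 200: coefficients within 3 SE of truth
  set.seed(321)
  x <- runif(200, 0.2, 0.8)
  yn <- 0.1 + 2 * x - 3 * x^2 + rnorm(200, 0, 0.05)
  fn <- quadraticGc3Fit(x, yn)
  truth <- c(0.1, 2, -3)
  expect_true(all(abs(fn$coefficients - truth) <= 3 * fn$se))
  expect_error(quadraticGc3Fit(gc3v[1:3], y[1:3]), "4 points")
})
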