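#' Focal-codon-exclusion passenger profile
#'
#' The central passenger-effect diagnostic. For each degenerate focal codon
#' F: identify the constructs whose counting window contains at least one
#' F; within each such construct take the mean reference log odds of all
#' window codons that are not F (every copy of F excluded; codons with `NA`
#' reference excluded); then report the mean of these per-construct means,
#' their SD, SEM = SD/sqrt(N), and N = the number of constructs containing
#' F (constructs, not F occurrences -- counting occurrences would reuse
#' data from multi-F constructs, i.e. pseudoreplicate).
#'
#' For a perfectly randomized library scored with a zero-centred reference
#' the null mean of means is zero; a codon disproportionately placed in
#' high-scoring (low-scoring) construct contexts has a positive (negative)
#' mean of means. The reference vector should come from a dataset believed
#' free of passenger effects -- using a biased dataset's own log odds would
#' re-import the distortion being diagnosed.
#'
#' @param x a [ConstructLibrary-class].
#' @param reference a [LogOddsVector-class] (or named numeric over the 59
#'   degenerate codons) of per-codon scores.
#' @return data.frame with columns `codon`, `meanOfMeans`, `sd`, `sem`,
#'   `n`; codons absent from every construct get an `NA` row.
#' @export
focalExclusionProfile <- function(x, reference) {
  ref61 <- setNames(rep(NA_real_, 61L), senseCodons())
  ref61[degenerateCodons()] <- .asLogOddsValues(reference)
  if (all(is.na(ref61))) stop("reference vector is entirely NA")
  idm <- .codonIdMatrix(x)
  refm <- matrix(ref61[idm], nrow = nrow(idm))   # per-cell reference value
  rowSum <- rowSums(refm, na.rm = TRUE)
  rowCnt <- rowSums(!is.na(refm))
  counts <- .constructCodonCounts(idm)
  out <- data.frame(codon = degenerateCodons(),
                    meanOfMeans = NA_real_, sd = NA_real_, sem = NA_real_,
                    n = 0L)
  for (i in seq_len(59L)) {
    f <- out$codon[i]
    nF <- counts[, f]
    has <- nF > 0L
    if (!any(has)) next
    vF <- ref61[f]
    exSum <- rowSum[has] - if (is.na(vF)) 0 else nF[has] * vF
    exCnt <- rowCnt[has] - if (is.na(vF)) 0L else nF[has]
    means <- ifelse(exCnt > 0L, exSum / exCnt, NA_real_)
    means <- means[!is.na(means)]
    out$n[i] <- length(means)
    if (length(means)) {
      out$meanOfMeans[i] <- mean(means)
      if (length(means) >= 2L) {
        out$sd[i] <- sd(means)
        out$sem[i] <- out$sd[i] / sqrt(length(means))
      }
    }
  }
  out
}

#' Between-codon spread of a passenger profile
#'
#' The SD across the 59 mean-of-means values: a library-level summary of
#' how unevenly codons are placed in favourable or unfavourable construct
#' contexts. A randomized library has a low but non-zero value; design
#' bias inflates it.
#'
#' @param profile a data.frame from [focalExclusionProfile()].
#' @return numeric SD.
#' @export
sdOfProfile <- function(profile) {
  v <- profile$meanOfMeans[!is.na(profile$meanOfMeans)]
  if (length(v) < 2L) stop("fewer than 2 non-NA codons in profile")
  sd(v)
}

#' Codon co-occurrence observed and expected counts
#'
#' For each of the 61 sense focal codons F, counts every other sense codon
#' X over the windows of constructs containing at least one F
#' (occurrence-based: multiple copies count multiply). The expected count
#' is the focal-conditioned total of non-F codons times the frequency of X
#' among non-F codons in the whole dataset, so row sums of observed and
#' expected agree by construction. The 61 x 60 off-diagonal cells give
#' 3660 observed/expected comparisons.
#'
#' @param x a [ConstructLibrary-class].
#' @return a [CooccurrenceStats-class].
#' @export
cooccurrenceCounts <- function(x) {
  idm <- .codonIdMatrix(x)
  counts <- .constructCodonCounts(idm)
  .cooccurrenceFromCounts(counts, length(x))
}

.cooccurrenceFromCounts <- function(counts, n) {
  present <- counts > 0L
  observed <- crossprod(present, counts)       # obs[F, X]: X counts where F present
  total <- colSums(counts)                      # dataset-wide codon counts
  grand <- sum(total)
  diag(observed) <- NA_real_
  rowTot <- rowSums(observed, na.rm = TRUE)
  freq <- outer(seq_len(61L), seq_len(61L), function(f, xx)
    total[xx] / (grand - total[f]))             # freq(X | not F), dataset-wide
  expected <- rowTot * freq
  diag(expected) <- NA_real_
  sc <- senseCodons()
  dimnames(observed) <- dimnames(expected) <- list(sc, sc)
  new("CooccurrenceStats", observed = observed, expected = expected,
      nConstructs = as.integer(n))
}

setMethod("show", "CooccurrenceStats", function(object) {
  cat(sprintf(
    "CooccurrenceStats: 61 x 60 cells over %d constructs; chi2 sum = %.1f\n",
    object@nConstructs, chi2Sum(object)))
})

#' @describeIn cooccurrenceCounts accessors for the 61 x 61 matrices
#'   (diagonal `NA`).
#' @param stats a [CooccurrenceStats-class].
#' @export
observedCounts <- function(stats) stats@observed

#' @rdname cooccurrenceCounts
#' @export
expectedCounts <- function(stats) stats@expected

#' Summary statistics of codon co-occurrence deviation
#'
#' `chi2Sum()` is the sum of (O-E)^2/E over all 3660 focal/other cells, a
#' library-level measure of non-random codon allocation (sensitive to total
#' counts, so libraries are compared through size-matched subsampled
#' nulls). `perCodonDev()` is, per focal codon, the mean of |O-E|/E over
#' its 60 cells -- a per-codon non-randomness measure largely insensitive
#' to codon abundance. Cells with zero expected count (codon absent from
#' the dataset) are excluded with a message.
#'
#' @param stats a [CooccurrenceStats-class].
#' @return `chi2Sum()`: a single number; `perCodonDev()`: named numeric of
#'   length 61.
#' @export
chi2Sum <- function(stats) {
  o <- stats@observed; e <- stats@expected
  use <- !is.na(e) & e > 0
  skipped <- sum(!is.na(e) & e == 0)
  if (skipped) message(skipped, " zero-expected cell(s) excluded from chi2")
  sum((o[use] - e[use])^2 / e[use])
}

#' @rdname chi2Sum
#' @export
perCodonDev <- function(stats) {
  o <- stats@observed; e <- stats@expected
  dev <- abs(o - e) / e
  dev[!is.na(e) & e == 0] <- NA
  rowMeans(dev, na.rm = TRUE)
}

#' Subsampled null distribution of a library statistic
#'
#' Recomputes `statistic` on `reps` without-replacement subsamples of
#' `subsampleSize` constructs, giving a size-matched null against which the
#' statistic of another (equal-sized) library can be compared as a
#' z-score. Deterministic under `seed`.
#'
#' @param x a [ConstructLibrary-class] with at least `subsampleSize`
#'   constructs.
#' @param statistic function taking a ConstructLibrary and returning a
#'   single number (e.g. `function(l) chi2Sum(cooccurrenceCounts(l))`).
#' @param subsampleSize constructs per subsample (the published analysis
#'   matches the smaller dataset's 14234).
#' @param reps number of subsamples.
#' @param seed integer seed.
#' @return a [NullDistribution-class].
#' @export
subsampleNull <- function(x, statistic, subsampleSize = 14234L,
                          reps = 1000L, seed = 1L) {
  subsampleSize <- as.integer(subsampleSize)
  if (length(x) < subsampleSize)
    stop("library smaller than subsampleSize")
  vals <- withSeed(seed, {
    vapply(seq_len(reps), function(r) {
      statistic(x[sample.int(length(x), subsampleSize)])
    }, numeric(1))
  })
  new("NullDistribution", values = vals, subsampleSize = subsampleSize,
      seed = as.integer(seed))
}

setMethod("show", "NullDistribution", function(object) {
  cat(sprintf(
    "NullDistribution: %d reps of %d constructs (seed %d); mean %.3g, SD %.3g\n",
    length(object@values), object@subsampleSize, object@seed,
    mean(object@values), sd(object@values)))
})

#' @describeIn subsampleNull the replicate values.
#' @param null a [NullDistribution-class].
#' @export
nullValues <- function(null) null@values

#' Z-score of a value against a subsampled null
#'
#' `(value - mean(null)) / SD(null)`: the deviation of an observed
#' statistic from its size-matched null in units of the null's SD.
#'
#' @param value observed statistic.
#' @param null a [NullDistribution-class].
#' @return numeric z.
#' @export
zScore <- function(value, null) {
  s <- sd(null@values)
  if (s == 0) stop("zero-variance null distribution")
  (value - mean(null@values)) / s
}

#' Attribute between-dataset disagreement to passenger effects
#'
#' Regresses `vTest` on `vRef` (ordinary least squares over shared non-NA
#' codons) and takes each codon's residual as its disagreement between the
#' two datasets. The residuals are then correlated (Spearman and Pearson)
#' against each library's focal-codon-exclusion mean of means: if the test
#' library's passenger scores predict the residuals while the reference
#' library's do not, the disagreement is attributable to non-random
#' construct design in the test library. The squared correlation is the
#' fraction of disagreement explained.
#'
#' @param vTest,vRef [LogOddsVector-class] objects (test and reference
#'   datasets).
#' @param profileTest,profileRef passenger profiles from
#'   [focalExclusionProfile()] for the corresponding libraries.
#' @return list with `residuals` (named numeric), `rhoTest`, `pTest`,
#'   `rhoRef`, `pRef`, `pearsonTest`, `pearsonRef`, and
#'   `fractionExplainedTest` (= rhoTest^2).
#' @export
residualAttribution <- function(vTest, vRef, profileTest, profileRef) {
  a <- .asLogOddsValues(vTest); b <- .asLogOddsValues(vRef)
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 10L) stop("fewer than 10 shared non-NA codons")
  if (max(abs(a[ok] - b[ok])) < .Machine$double.eps^0.5)
    stop("vectors identical: residuals all zero, correlation undefined")
  fit <- lm(a[ok] ~ b[ok])
  res <- setNames(resid(fit), names(a)[ok])
  corTo <- function(profile) {
    mm <- setNames(profile$meanOfMeans, profile$codon)[names(res)]
    use <- !is.na(mm)
    sp <- suppressWarnings(cor.test(res[use], mm[use], method = "spearman"))
    pe <- suppressWarnings(cor.test(res[use], mm[use], method = "pearson"))
    list(rho = unname(sp$estimate), p = sp$p.value,
         pearson = unname(pe$estimate))
  }
  ct <- corTo(profileTest); cr <- corTo(profileRef)
  list(residuals = res,
       rhoTest = ct$rho, pTest = ct$p, pearsonTest = ct$pearson,
       rhoRef = cr$rho, pRef = cr$p, pearsonRef = cr$pearson,
       fractionExplainedTest = ct$rho^2)
}

#' Drop constructs with duplicate window sequences
#'
#' Keeps one representative construct (the first occurrence) per distinct
#' window sequence, guarding co-occurrence statistics against libraries
#' that reuse the same 5' CDS in many constructs.
#'
#' @param x a [ConstructLibrary-class].
#' @return the deduplicated ConstructLibrary.
#' @export
dedupeWindows <- function(x) {
  w <- libraryWindow(x)
  key <- substr(as.character(constructSeqs(x)),
                3L * (w[1L] - 1L) + 1L, 3L * w[2L])
  x[!duplicated(key)]
}
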