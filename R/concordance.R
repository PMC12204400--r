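#' Rank correlation between two log-odds vectors
#'
#' Spearman correlation over the pairwise-complete (both non-NA) codons.
#'
#' @param vA,vB [LogOddsVector-class] objects (or named numeric vectors
#'   over the 59 degenerate codons).
#' @return list with `rho`, `p` and `n` (codons used).
#' @export
compareVectors <- function(vA, vB) {
  a <- .asLogOddsValues(vA); b <- .asLogOddsValues(vB)
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 4L) stop("fewer than 4 shared non-NA codons")
  ct <- suppressWarnings(cor.test(a[ok], b[ok], method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}

.asLogOddsValues <- function(v) {
  if (is(v, "LogOddsVector")) return(v@values)
  stopifnot(is.numeric(v), !is.null(names(v)))
  v[degenerateCodons()]
}

#' Orthogonal (principal-axis) regression of one vector on another
#'
#' Fits the line along the first principal axis of the centered 2-D cloud
#' `(vA, vB)` over shared non-NA codons, the intercept chosen so the line
#' passes through the means. Unlike ordinary least squares this treats the
#' two datasets symmetrically: swapping the axes maps the slope s to 1/s.
#'
#' @inheritParams compareVectors
#' @return list with `slope`, `intercept` and `n`.
#' @export
orthogonalFit <- function(vA, vB) {
  a <- .asLogOddsValues(vA); b <- .asLogOddsValues(vB)
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 3L) stop("fewer than 3 shared non-NA points")
  x <- a[ok]; y <- b[ok]
  if (sd(x) == 0 && sd(y) == 0) stop("degenerate point cloud")
  pc <- prcomp(cbind(x, y), center = TRUE, scale. = FALSE)
  dir <- pc$rotation[, 1L]
  if (abs(dir[1L]) < .Machine$double.eps^0.5)
    stop("first principal axis is vertical; slope undefined")
  slope <- dir[2L] / dir[1L]
  list(slope = unname(slope),
       intercept = unname(mean(y) - slope * mean(x)), n = sum(ok))
}

#' Oriented within-block pairwise comparison of two vectors
#'
#' Controls for the non-independence inside synonymous blocks (in a 2-fold
#' block the two log odds are exact negatives) by comparing all unordered
#' codon pairs within each block: for each pair, x is the difference
#' hi - lo >= 0 where hi/lo are ranked by `vA`, and y is the `vB` difference
#' taken with the same orientation (sign free). On complete vectors there
#' are exactly 87 pairs.
#'
#' @inheritParams compareVectors
#' @return list with `pairs` (data.frame: hi, lo, x, y), `rho`, `p`, `n`.
#' @export
withinBlockPairs <- function(vA, vB) {
  a <- .asLogOddsValues(vA); b <- .asLogOddsValues(vB)
  rows <- list()
  for (block in synonymousBlocks()) {
    for (pr in asplit(combn(block, 2L), 2L)) {
      c1 <- pr[1L]; c2 <- pr[2L]
      if (is.na(a[c1]) || is.na(a[c2])) next
      if (a[c1] >= a[c2]) { hi <- c1; lo <- c2 } else { hi <- c2; lo <- c1 }
      rows[[length(rows) + 1L]] <- data.frame(
        hi = hi, lo = lo, x = a[hi] - a[lo],
        y = if (is.na(b[hi]) || is.na(b[lo])) NA_real_ else b[hi] - b[lo])
    }
  }
  pairs <- do.call(rbind, rows)
  rownames(pairs) <- NULL
  ok <- !is.na(pairs$y)
  if (sum(ok) < 4L) stop("fewer than 4 usable within-block pairs")
  ct <- suppressWarnings(
    cor.test(pairs$x[ok], pairs$y[ok], method = "spearman"))
  list(pairs = pairs, rho = unname(ct$estimate), p = ct$p.value,
       n = sum(ok))
}

#' Best-codon matrix from a positional log-odds matrix
#'
#' For each of the 18 degenerate amino acids at each window position, the
#' codon with the highest (non-NA) log odds; `NA` where the amino acid is
#' unrepresented at that position. Exact ties are broken towards the
#' lexicographically smallest codon and flagged in the `"ties"` attribute.
#'
#' @param P a [PositionalLogOdds-class].
#' @return character matrix, 18 amino acids x positions, with a logical
#'   `"ties"` attribute of the same shape.
#' @export
bestCodonMatrix <- function(P) {
  m <- P@values
  aas <- names(synonymousBlocks())
  best <- matrix(NA_character_, length(aas), ncol(m),
                 dimnames = list(aas, colnames(m)))
  ties <- matrix(FALSE, length(aas), ncol(m),
                 dimnames = dimnames(best))
  for (aa in aas) {
    block <- synonymousBlocks()[[aa]]
    for (j in seq_len(ncol(m))) {
      v <- m[block, j]
      if (all(is.na(v))) next
      mx <- max(v, na.rm = TRUE)
      winners <- sort(block[!is.na(v) & v == mx])
      best[aa, j] <- winners[1L]
      ties[aa, j] <- length(winners) > 1L
    }
  }
  attr(best, "ties") <- ties
  best
}

#' Concordance of two best-codon matrices
#'
#' Scores +1 where the two matrices nominate the same codon and 0
#' otherwise. Per amino acid, an exact binomial test of the agreement count
#' against a null success probability of 1/degeneracy; overall, successes
#' and trials are pooled across amino acids and tested against the
#' trial-weighted mean of 1/degeneracy. Two-tailed p-values use the exact
#' minimum-likelihood convention of [stats::binom.test()] (all outcomes no
#' more likely than the observed one).
#'
#' @param mA,mB best-codon matrices from [bestCodonMatrix()] with
#'   identical shape.
#' @param perRowAlternative tail for the per-amino-acid tests (the overall
#'   test is always two-sided).
#' @return list with `perAminoAcid` (data.frame: aminoAcid, successes,
#'   trials, nullP, p) and `overall` (successes, trials, nullP, p,
#'   expectedSuccesses).
#' @export
agreementTest <- function(mA, mB, perRowAlternative = "two.sided") {
  stopifnot(identical(dim(mA), dim(mB)),
            identical(rownames(mA), rownames(mB)))
  blocks <- synonymousBlocks()
  rows <- lapply(rownames(mA), function(aa) {
    ok <- !is.na(mA[aa, ]) & !is.na(mB[aa, ])
    trials <- sum(ok)
    successes <- sum(mA[aa, ok] == mB[aa, ok])
    p0 <- 1 / length(blocks[[aa]])
    p <- if (trials > 0L)
      binom.test(successes, trials, p0,
                 alternative = perRowAlternative)$p.value else NA_real_
    data.frame(aminoAcid = aa, successes = successes, trials = trials,
               nullP = p0, p = p)
  })
  per <- do.call(rbind, rows)
  totTrials <- sum(per$trials)
  if (totTrials == 0L) stop("zero trials: no cell non-NA in both matrices")
  totSucc <- sum(per$successes)
  nullP <- sum(per$trials * per$nullP) / totTrials
  overallP <- binom.test(totSucc, totTrials, nullP,
                         alternative = "two.sided")$p.value
  list(perAminoAcid = per,
       overall = list(successes = totSucc, trials = totTrials,
                      nullP = nullP, p = overallP,
                      expectedSuccesses = round(totTrials * nullP)))
}

#' Exact two-tailed sign binomial test
#'
#' Exact binomial test of `successes` out of `trials` against p = 0.5; the
#' two-tailed p doubles the smaller tail, capped at 1.
#'
#' @param successes,trials non-negative counts, `successes <= trials`.
#' @return the two-tailed p-value.
#' @examples
#' signBinomial(55, 61)  # about 5e-11
#' @export
signBinomial <- function(successes, trials) {
  stopifnot(trials >= 1L, successes >= 0L, successes <= trials)
  binom.test(successes, trials, p = 0.5,
             alternative = "two.sided")$p.value
}
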