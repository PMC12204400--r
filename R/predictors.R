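#' Codon adaptation scores from native gene cores
#'
#' A log-odds analogue of the codon adaptation index: per-codon enrichment
#' in the cores of highly expressed native genes (condition 1) relative to
#' lowly expressed ones (condition 2), computed with the same formula and
#' zero-cell corrections as [logOdds()]. Span-level CAI values are then
#' means of these per-codon scores.
#'
#' @param hegCores,legCores [Biostrings::DNAStringSet] or character vectors
#'   of in-frame core sequences (already windowed to the designated core
#'   span) from highly / lowly expressed native genes.
#' @return a [LogOddsVector-class] of adaptation scores.
#' @export
adaptationScores <- function(hegCores, legCores) {
  count <- function(set) {
    codons <- unlist(lapply(as.character(set), splitCodons))
    id <- match(codons, senseCodons())
    tabulate(id[!is.na(id)], nbins = 61L) |> setNames(senseCodons())
  }
  if (length(hegCores) == 0L || length(legCores) == 0L)
    stop("both core sets must be non-empty")
  v <- .logOddsFromCounts(count(hegCores), count(legCores))
  new("LogOddsVector", values = v, context = "HEG cores vs LEG cores")
}

#' Per-construct 5' feature table
#'
#' Computes, for every construct, the 5' sequence features used as
#' expression predictors: span-level CAI (mean per-codon adaptation score
#' over degenerate codons at +2..+11, non-degenerate codons skipped),
#' deltaCAI (CAI at +2..+11 minus CAI at +12..+31, `NA` for constructs
#' shorter than 31 codons), NGG density in the first 6 codons (+2..+7),
#' proline density and positively charged (K/R/H) density in the first 10
#' codons, and G+C fraction of the first 30 nt after the start codon.
#' Stability columns and the response are copied from the library metrics.
#'
#' @param x a [ConstructLibrary-class].
#' @param scores a [LogOddsVector-class] of adaptation scores (from
#'   [adaptationScores()]).
#' @param response name of the response metric column (e.g. protein per
#'   RNA); copied into the table as `response`.
#' @param stabilityCols names of precomputed stability metric columns to
#'   carry over (missing ones become `NA` with a warning).
#' @param nggSpan,fiveSpan,downstreamSpan codon spans for the NGG density,
#'   5' features, and the deltaCAI downstream window.
#' @return data.frame with columns `construct_id`, `response`, any
#'   stability columns, `cai`, `delta_cai`, `ngg`, `pro`, `pos`, `gc`.
#' @export
codonFeatures <- function(x, scores, response = NULL,
                          stabilityCols = c("stab30", "stab60"),
                          nggSpan = c(2L, 7L), fiveSpan = c(2L, 11L),
                          downstreamSpan = c(12L, 31L)) {
  sc <- setNames(rep(NA_real_, 61L), senseCodons())
  sc[degenerateCodons()] <- .asLogOddsValues(scores)
  seqs <- as.character(constructSeqs(x))
  nCod <- nchar(seqs) %/% 3L

  spanMeanScore <- function(span) {
    idm <- .codonIdMatrix(x, span)
    sm <- matrix(sc[idm], nrow = nrow(idm))
    ok <- nCod >= span[2L]
    out <- rowMeans(sm, na.rm = TRUE)
    out[!ok | !rowSums(!is.na(sm))] <- NA_real_
    out
  }
  cai <- spanMeanScore(fiveSpan)
  caiDown <- spanMeanScore(downstreamSpan)

  idmNgg <- .codonIdMatrix(x, nggSpan)
  nggDens <- rowMeans(matrix(isNGG(senseCodons())[idmNgg],
                             nrow = nrow(idmNgg)), na.rm = TRUE)
  idm10 <- .codonIdMatrix(x, fiveSpan)
  aa <- codonAminoAcid(senseCodons())
  aam <- matrix(aa[idm10], nrow = nrow(idm10))
  proDens <- rowMeans(aam == "P", na.rm = TRUE)
  posm <- matrix(aam %in% c("K", "R", "H"), nrow = nrow(aam))
  posm[is.na(aam)] <- NA
  posDens <- rowMeans(posm, na.rm = TRUE)
  first30 <- substr(seqs, 4L, 33L)
  gcc <- ifelse(nchar(first30) > 0, gcFraction(first30), NA_real_)

  out <- data.frame(construct_id = constructIds(x),
                    response = NA_real_)
  if (!is.null(response)) out$response <- metricValues(x, response)
  for (col in stabilityCols) {
    if (col %in% colnames(constructMetrics(x)))
      out[[col]] <- metricValues(x, col)
    else {
      warning("stability column '", col, "' missing; feature set to NA")
      out[[col]] <- NA_real_
    }
  }
  out$cai <- cai
  out$delta_cai <- cai - caiDown
  out$ngg <- nggDens
  out$pro <- proDens
  out$pos <- posDens
  out$gc <- gcc
  out
}

#' Partial Spearman correlation
#'
#' Rank-transforms all variables, residualizes x and y on the covariates
#' by least squares, and correlates the residuals (Pearson on ranks); with
#' no covariates this equals the ordinary Spearman correlation. The
#' p-value uses the t approximation with `df = n - 2 - #covariates`.
#'
#' @param data data.frame of variables.
#' @param x,y column names of the two variables of interest.
#' @param covariates character vector of covariate column names (may be
#'   empty).
#' @return list with `rho`, `p` and `n` (complete rows used).
#' @export
partialSpearman <- function(data, x, y, covariates = character()) {
  cols <- c(x, y, covariates)
  d <- data[, cols, drop = FALSE]
  d <- d[complete.cases(d), , drop = FALSE]
  n <- nrow(d)
  if (n < length(covariates) + 3L) stop("too few complete rows")
  r <- as.data.frame(lapply(d, rank))
  if (length(covariates)) {
    Z <- as.matrix(r[, covariates, drop = FALSE])
    qr_ <- qr(cbind(1, Z))
    if (qr_$rank < ncol(Z) + 1L) stop("collinear covariates")
    rx <- qr.resid(qr_, r[[x]])
    ry <- qr.resid(qr_, r[[y]])
  } else {
    rx <- r[[x]]; ry <- r[[y]]
  }
  # a variable fully explained by the covariates has nothing left to
  # correlate: partial rho is 0 by convention
  if (sd(rx) < 1e-10 || sd(ry) < 1e-10)
    return(list(rho = 0, p = 1, n = n))
  rho <- cor(rx, ry)
  df <- n - 2L - length(covariates)
  tstat <- rho * sqrt(df / (1 - rho^2))
  list(rho = rho, p = 2 * pt(-abs(tstat), df), n = n)
}

#' LMG relative-importance decomposition of a linear model
#'
#' Attributes the R-squared of a linear regression to its predictors by
#' averaging, over all k! predictor orderings, each predictor's
#' incremental R-squared when added -- computed exactly by enumerating all
#' 2^k subsets S and weighting the increment `R2(S + j) - R2(S)` by
#' `|S|! (k - |S| - 1)! / k!`. Shares always sum to the full-model
#' R-squared. Predictors are z-score normalised before fitting so that the
#' reported coefficient signs are comparable.
#'
#' @param data data.frame; rows with any `NA` among the used columns are
#'   dropped.
#' @param response response column name.
#' @param predictors character vector of predictor columns (k <= 15).
#' @return list with `shares` (named, summing to `r2`), `percent`
#'   (shares as % of R2), `r2`, `adjR2`, `coefficients` (z-normalised
#'   full-model slopes), and `n`.
#' @export
lmgImportance <- function(data, response, predictors) {
  k <- length(predictors)
  if (k < 1L || k > 15L) stop("need 1..15 predictors")
  d <- data[, c(response, predictors), drop = FALSE]
  d <- d[complete.cases(d), , drop = FALSE]
  n <- nrow(d)
  if (n < k + 2L) stop("too few complete rows")
  y <- d[[response]]
  X <- scale(as.matrix(d[, predictors, drop = FALSE]))
  tss <- sum((y - mean(y))^2)
  r2sub <- numeric(2^k)                       # R2 per subset bitmask
  for (mask in seq_len(2^k - 1L)) {
    j <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(k) - 1L)) != 0L)
    fit <- lm.fit(cbind(1, X[, j, drop = FALSE]), y)
    r2sub[mask + 1L] <- 1 - sum(fit$residuals^2) / tss
  }
  lf <- lfactorial(0:k)
  shares <- setNames(numeric(k), predictors)
  for (j in seq_len(k)) {
    bitJ <- bitwShiftL(1L, j - 1L)
    for (mask in 0:(2^k - 1L)) {
      if (bitwAnd(mask, bitJ) != 0L) next
      s <- sum(bitwAnd(mask, bitwShiftL(1L, seq_len(k) - 1L)) != 0L)
      w <- exp(lf[s + 1L] + lf[k - s] - lf[k + 1L])
      shares[j] <- shares[j] +
        w * (r2sub[bitwOr(mask, bitJ) + 1L] - r2sub[mask + 1L])
    }
  }
  r2 <- r2sub[2^k]
  full <- lm.fit(cbind(1, X), y)
  list(shares = shares, percent = 100 * shares / r2, r2 = r2,
       adjR2 = 1 - (1 - r2) * (n - 1) / (n - k - 1),
       coefficients = setNames(full$coefficients[-1L], predictors), n = n)
}

#' Quadratic fit of correlation against genomic GC3
#'
#' Least-squares fit of `correlation ~ a + b GC3 + c GC3^2`, the model
#' describing how well a transgene-derived enrichment vector predicts
#' 5'-versus-core codon usage across genomes of varying GC3.
#'
#' @param gc3 numeric vector of genome mean GC3 values.
#' @param correlation numeric vector of the per-genome correlations.
#' @return list with `coefficients` (intercept, linear, quadratic),
#'   `se` (their standard errors), `adjR2`, `p` (overall F-test), `n`.
#' @export
quadraticGc3Fit <- function(gc3, correlation) {
  ok <- !is.na(gc3) & !is.na(correlation)
  if (sum(ok) < 4L) stop("need at least 4 points")
  fit <- lm(correlation[ok] ~ gc3[ok] + I(gc3[ok]^2))
  sm <- summary(fit)
  f <- sm$fstatistic
  list(coefficients = setNames(coef(fit),
                               c("intercept", "linear", "quadratic")),
       se = setNames(sm$coefficients[, "Std. Error"],
                     c("intercept", "linear", "quadratic")),
       adjR2 = sm$adj.r.squared,
       p = unname(pf(f[1L], f[2L], f[3L], lower.tail = FALSE)),
       n = sum(ok))
}
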