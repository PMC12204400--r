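#' Partition a library into upper and lower quartiles of a metric
#'
#' Condition 1 of every enrichment comparison is the upper quartile of the
#' chosen expression metric and condition 2 the lower quartile. Thresholds
#' are linear-interpolation percentiles; constructs exactly at a threshold
#' are included in the respective tail. Constructs with `NA` metric values
#' are excluded before percentiles are computed.
#'
#' @param x a [ConstructLibrary-class].
#' @param metric name of the metric column to rank by.
#' @param probs the two percentile cut points, default `c(0.25, 0.75)`.
#' @return list with elements `high` and `low`, each a ConstructLibrary.
#' @export
partitionQuartiles <- function(x, metric, probs = c(0.25, 0.75)) {
  v <- metricValues(x, metric)
  keep <- which(!is.na(v))
  if (length(keep) < 8L)
    stop("need >= 8 constructs with non-NA '", metric, "'")
  v <- v[keep]
  if (diff(range(v)) == 0)
    stop("all '", metric, "' values identical: degenerate partition")
  q <- quantile(v, probs = probs, names = FALSE, type = 7)
  list(high = x[keep[v >= q[2L]]], low = x[keep[v <= q[1L]]])
}

## Log odds for all 59 degenerate focal codons from two 61-count vectors.
## Per focal codon F with synonyms S: value = ln((c1F/c1S)/(c2F/c2S)).
## Modified Haldane-Anscombe rule: if some but not all of the four counts
## are zero, add 0.5 to all four; if all four are zero the whole amino-acid
## block is NA (absence of data).
.logOddsFromCounts <- function(c1, c2) {
  out <- setNames(rep(NA_real_, 59L), degenerateCodons())
  for (block in synonymousBlocks()) {
    b1 <- c1[block]; b2 <- c2[block]
    t1 <- sum(b1); t2 <- sum(b2)
    for (f in block) {
      k <- c(b1[f], t1 - b1[f], b2[f], t2 - b2[f])
      if (all(k == 0)) next                      # block absent: stays NA
      if (any(k == 0)) k <- k + 0.5
      out[f] <- log((k[1L] / k[2L]) / (k[3L] / k[4L]))
    }
  }
  out
}

#' Synonymous-block log-odds enrichment vector
#'
#' For each of the 59 degenerate focal codons, the log odds ratio
#' `ln((c1f/c1s)/(c2f/c2s))` where `c1f` is the focal-codon count over the
#' counting window in the `high` set, `c1s` the count of its synonyms
#' (focal excluded) there, and `c2f`, `c2s` likewise in the `low` set. Zero
#' cells are handled by the modified Haldane-Anscombe correction: if some
#' but not all of the four counts are zero, 0.5 is added to all four before
#' forming the ratio; if all four are zero the amino acid's whole block is
#' set to `NA` (absence of data).
#'
#' @param high,low [ConstructLibrary-class] objects for condition 1
#'   (e.g. upper expression quartile) and condition 2 (lower quartile).
#' @param span codon-position window; defaults to the `high` library's
#'   window (+2..+11 normally).
#' @param context optional description stored on the result.
#' @return a [LogOddsVector-class].
#' @examples
#' lib <- ConstructLibrary(c(a = "ATGAAAAAACCG", b = "ATGAAGAAGCCG"),
#'                         window = c(2, 4))
#' logOdds(lib[1], lib[2])
#' @export
logOdds <- function(high, low, span = libraryWindow(high),
                    context = "high vs low") {
  if (length(high) == 0L || length(low) == 0L)
    stop("both construct sets must be non-empty")
  v <- .logOddsFromCounts(.codonCounts(high, span), .codonCounts(low, span))
  new("LogOddsVector", values = v, context = context)
}

#' @describeIn logOdds the 59 log-odds values as a named numeric vector.
#' @param x a LogOddsVector (or PositionalLogOdds for the matrix variant).
#' @export
logOddsValues <- function(x) {
  stopifnot(is(x, "LogOddsVector") || is(x, "PositionalLogOdds"))
  x@values
}

setMethod("show", "LogOddsVector", function(object) {
  v <- object@values
  cat("LogOddsVector (", object@context, "): ",
      sum(!is.na(v)), "/59 non-NA\n", sep = "")
  print(head(round(v[!is.na(v)], 4), 6))
})

setMethod("show", "PositionalLogOdds", function(object) {
  cat("PositionalLogOdds (", object@context, "): 59 x ",
      ncol(object@values), " positions\n", sep = "")
})

#' Positional log-odds matrix
#'
#' The log-odds vector computed independently at each codon position of the
#' window, giving a 59 x positions matrix (+2..+11 by default).
#'
#' @inheritParams logOdds
#' @return a [PositionalLogOdds-class].
#' @export
positionalLogOdds <- function(high, low, span = libraryWindow(high),
                              context = "high vs low") {
  if (length(high) == 0L || length(low) == 0L)
    stop("both construct sets must be non-empty")
  pos <- seq.int(span[1L], span[2L])
  m <- vapply(pos, function(p) {
    sp <- c(p, p)
    .logOddsFromCounts(.codonCounts(high, sp), .codonCounts(low, sp))
  }, numeric(59L))
  dimnames(m) <- list(degenerateCodons(), paste0("+", pos))
  new("PositionalLogOdds", values = m, context = context)
}

#' 5'-versus-core enrichment vector for a CDS collection
#'
#' Condition 1 counts codons in the 5' window (+2..+11) of every CDS;
#' condition 2 counts the gene cores (codons +12 through the penultimate
#' codon, terminal stop excluded, configurable via `coreStart`). Same
#' formula and zero-cell corrections as [logOdds()].
#'
#' @param cds a [Biostrings::DNAStringSet] (or character vector) of in-frame
#'   CDSs; each must have at least `coreStart + 1` codons plus the stop.
#' @param fivePrimeSpan 5' window, default `c(2, 11)`.
#' @param coreStart first codon position of the core, default 12.
#' @return a [LogOddsVector-class] (positive = 5'-enriched).
#' @export
fivePrimeVsCore <- function(cds, fivePrimeSpan = c(2L, 11L),
                            coreStart = 12L) {
  if (length(cds) == 0L) stop("empty CDS collection")
  s <- as.character(cds)
  s <- toupper(chartr("U", "T", s))
  nc <- nchar(s) %/% 3L
  usable <- nc >= coreStart + 2L   # core of >= 1 codon before the stop
  if (!any(usable)) stop("no CDS long enough for a core region")
  if (any(!usable))
    message(sum(!usable), " CDS(s) too short for a core; skipped")
  s <- s[usable]; nc <- nc[usable]
  count <- function(codons) {
    id <- match(codons, senseCodons())
    tabulate(id[!is.na(id)], nbins = 61L) |> setNames(senseCodons())
  }
  five <- unlist(lapply(s, function(x)
    splitCodons(substr(x, 3L * (fivePrimeSpan[1L] - 1L) + 1L,
                       3L * fivePrimeSpan[2L]))))
  core <- unlist(lapply(seq_along(s), function(i)
    splitCodons(substr(s[i], 3L * (coreStart - 1L) + 1L,
                       3L * (nc[i] - 1L)))))
  v <- .logOddsFromCounts(count(five), count(core))
  new("LogOddsVector", values = v, context = "5' window vs gene core")
}

#' High/low groups from an ordinal translation-efficiency scale
#'
#' For libraries scored on a coarse ordinal scale (translation-efficiency
#' fractions, TEF 1..5) rather than a continuous metric, the low group is
#' the lowest fraction topped up with a random subsample of the adjacent
#' fraction, and the high group the highest fraction(s) likewise, so that
#' each group comprises a fixed fraction (default 25%) of all constructs.
#' Two compositions mirror the published media recipes: `"LB"` uses
#' fractions {1 + part of 2} vs {5, 4 + part of 3}; `"M9"` uses
#' {1 + part of 2} vs {5 + part of 4}.
#'
#' @param x a [ConstructLibrary-class].
#' @param tef name of the ordinal column (integers 1..nBins).
#' @param targetFraction group size as a fraction of all constructs.
#' @param mode `"LB"` or `"M9"` group composition (see above), or a list
#'   `list(low = c(1, 2), high = c(5, 4, 3))` giving the fractions to fill
#'   from, outermost first; the last listed fraction is subsampled.
#' @param seed integer seed for the subsampling.
#' @return list with `high` and `low` ConstructLibrary objects.
#' @export
ordinalGroups <- function(x, tef = "tef", targetFraction = 0.25,
                          mode = c("LB", "M9"), seed = 1L) {
  if (is.character(mode)) {
    mode <- match.arg(mode)
    mode <- switch(mode,
      LB = list(low = c(1L, 2L), high = c(5L, 4L, 3L)),
      M9 = list(low = c(1L, 2L), high = c(5L, 4L)))
  }
  v <- as.integer(metricValues(x, tef))
  target <- floor(targetFraction * length(x))
  fill <- function(order) {
    picked <- integer()
    for (f in order) {
      idx <- which(v == f)
      need <- target - length(picked)
      if (need <= 0L) break
      if (length(idx) <= need) picked <- c(picked, idx)
      else picked <- c(picked, sample(idx, need))
    }
    if (length(picked) < target)
      stop("cannot fill a ", targetFraction, " group from fractions ",
           paste(order, collapse = ","))
    picked
  }
  counts <- table(factor(v, levels = sort(unique(v))))
  if (any(counts > 0.5 * length(x)))
    stop("a single fraction exceeds 50% of constructs; ",
         "cannot form symmetric groups")
  rng <- withSeed(seed, {
    low <- fill(mode$low)
    high <- fill(mode$high)
    list(low = low, high = high)
  })
  list(high = x[rng$high], low = x[rng$low])
}

#' Bootstrap distribution of the log-odds vector
#'
#' Repeats the log-odds calculation `reps` times, each time resampling both
#' the high and the low construct groups with replacement at their original
#' sizes. Returns the per-codon bootstrap quantiles (2.5%, 50%, 97.5%
#' by default), the point estimate on the unresampled groups, and the
#' distribution of pairwise Spearman correlations between bootstrap
#' vectors (a measure of within-experiment reproducibility).
#'
#' @inheritParams logOdds
#' @param reps number of bootstrap replicates (>= 2), default 100.
#' @param seed integer seed.
#' @param quantiles probabilities for the per-codon envelope.
#' @return list with `vectors` (reps x 59 matrix), `quantiles` (59 x 3),
#'   `pointEstimate` ([LogOddsVector-class]), and `pairwiseCor` (numeric).
#' @export
bootstrapLogOdds <- function(high, low, span = libraryWindow(high),
                             reps = 100L, seed = 1L,
                             quantiles = c(0.025, 0.5, 0.975)) {
  if (reps < 2L) stop("reps must be >= 2")
  idH <- .codonIdMatrix(high, span)
  idL <- .codonIdMatrix(low, span)
  count <- function(idm, rows) {
    v <- idm[rows, , drop = FALSE]
    tabulate(v[!is.na(v)], nbins = 61L) |> setNames(senseCodons())
  }
  vectors <- withSeed(seed, {
    t(vapply(seq_len(reps), function(r) {
      hi <- sample.int(nrow(idH), nrow(idH), replace = TRUE)
      lo <- sample.int(nrow(idL), nrow(idL), replace = TRUE)
      .logOddsFromCounts(count(idH, hi), count(idL, lo))
    }, numeric(59L)))
  })
  colnames(vectors) <- degenerateCodons()
  qs <- t(apply(vectors, 2L, quantile, probs = quantiles, na.rm = TRUE,
                names = FALSE))
  colnames(qs) <- paste0("q", quantiles)
  pc <- if (reps <= 200L) {
    cm <- suppressWarnings(cor(t(vectors), method = "spearman",
                               use = "pairwise.complete.obs"))
    cm[upper.tri(cm)]
  } else numeric(0)
  list(vectors = vectors, quantiles = qs,
       pointEstimate = logOdds(high, low, span, "bootstrap point estimate"),
       pairwiseCor = pc)
}

#' Aggregate repeated expression measures per entity
#'
#' Collapses multiple measure columns to one value per entity under the
#' four conventions used for native-expression compendia: mean or median,
#' with missing entries either treated as zero or dropped.
#'
#' @param measures numeric matrix or data.frame, one row per entity, one
#'   column per measure; `NA` marks "no data".
#' @param mode one of `"mean_zero"`, `"mean_na"`, `"median_zero"`,
#'   `"median_na"`.
#' @return numeric vector, one value per entity. An entity with no values
#'   at all is 0 in the zero modes and `NA` in the NA modes.
#' @export
aggregateExpression <- function(measures,
    mode = c("mean_zero", "mean_na", "median_zero", "median_na")) {
  mode <- match.arg(mode)
  m <- as.matrix(measures)
  fun <- if (startsWith(mode, "mean")) mean else median
  zero <- endsWith(mode, "zero")
  apply(m, 1L, function(r) {
    if (zero) r[is.na(r)] <- 0
    else r <- r[!is.na(r)]
    if (!length(r)) return(NA_real_)
    fun(r)
  })
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with `set.seed(seed)` in effect and restores the caller's
#' RNG state afterwards, so seeded package operations do not perturb user
#' randomness.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
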