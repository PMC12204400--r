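#' @importClassesFrom Biostrings DNAStringSet
#' @importClassesFrom S4Vectors DataFrame
NULL

#' ConstructLibrary: a set of in-frame transgene constructs
#'
#' The central container: an ordered collection of constructs, each an
#' in-frame coding sequence with the start codon at position +1, together
#' with per-construct expression metrics (protein, RNA, protein per RNA,
#' precomputed stabilities, an optional ordinal translation-efficiency
#' fraction, ...). The `window` slot records the codon-position span used by
#' all 5' counting statistics, by default +2..+11 (the first ten codons
#' after the start codon).
#'
#' @slot seqs a [Biostrings::DNAStringSet] of the construct coding
#'   sequences; names are the construct identifiers (unique, non-empty).
#' @slot metrics a [S4Vectors::DataFrame] with one row per construct.
#' @slot window integer of length 2: first and last codon position of the
#'   counting window (1-based, start codon = +1), first >= 2.
#' @aliases ConstructLibrary
#' @exportClass ConstructLibrary
setClass("ConstructLibrary",
  representation(seqs = "DNAStringSet", metrics = "DataFrame",
                 window = "integer"))

setValidity("ConstructLibrary", function(object) {
  msg <- character()
  ids <- names(object@seqs)
  if (is.null(ids) || any(!nzchar(ids)))
    msg <- c(msg, "constructs must have non-empty ids (names on seqs)")
  else if (anyDuplicated(ids))
    msg <- c(msg, "construct ids must be unique")
  if (any(Biostrings::width(object@seqs) %% 3L != 0L))
    msg <- c(msg, "all sequence lengths must be divisible by 3")
  if (nrow(object@metrics) != length(object@seqs))
    msg <- c(msg, "metrics must have one row per construct")
  w <- object@window
  if (length(w) != 2L || anyNA(w) || w[1L] < 2L || w[1L] > w[2L])
    msg <- c(msg, "window must be c(first, last) with 2 <= first <= last")
  if (length(msg)) msg else TRUE
})

#' LogOddsVector: 59-element synonymous-block enrichment vector
#'
#' Per-codon log odds of enrichment in condition 1 relative to condition 2,
#' computed within synonymous blocks over the 59 degenerate codons. Entries
#' are `NA` block-wise when an amino acid is absent from both conditions.
#'
#' @slot values named numeric of length 59; names are `degenerateCodons()`
#'   in their canonical (alphabetical) order.
#' @slot context free-text description of the two conditions compared.
#' @aliases LogOddsVector
#' @exportClass LogOddsVector
setClass("LogOddsVector",
  representation(values = "numeric", context = "character"))

setValidity("LogOddsVector", function(object) {
  if (!identical(names(object@values), degenerateCodons()))
    return("values must be named by the 59 degenerate codons, in order")
  TRUE
})

#' PositionalLogOdds: per-position 59 x positions enrichment matrix
#'
#' One [LogOddsVector] per codon position of the counting window, stored as
#' a 59 x n matrix (rows = degenerate codons, columns = positions +2..+11
#' by default). Each column independently satisfies the LogOddsVector
#' invariants.
#'
#' @slot values numeric matrix, 59 rows named by `degenerateCodons()`,
#'   columns named by codon position (e.g. `"+2"`).
#' @slot context description of the comparison.
#' @aliases PositionalLogOdds
#' @exportClass PositionalLogOdds
setClass("PositionalLogOdds",
  representation(values = "matrix", context = "character"))

setValidity("PositionalLogOdds", function(object) {
  if (!identical(rownames(object@values), degenerateCodons()))
    return("rows must be the 59 degenerate codons, in order")
  TRUE
})

#' CooccurrenceStats: codon co-occurrence observed/expected counts
#'
#' For each of the 61 sense focal codons, the observed count of every other
#' sense codon within the counting windows of constructs containing the
#' focal codon, and the expected count under random codon allocation
#' (focal-conditioned total times the dataset-wide frequency of each
#' non-focal codon among non-focal codons). The 61 x 61 matrices carry `NA`
#' on the diagonal; the 3660 off-diagonal cells are the comparisons.
#'
#' @slot observed,expected 61 x 61 numeric matrices, dimnames =
#'   `senseCodons()`, diagonal `NA`.
#' @slot nConstructs number of constructs counted.
#' @aliases CooccurrenceStats
#' @exportClass CooccurrenceStats
setClass("CooccurrenceStats",
  representation(observed = "matrix", expected = "matrix",
                 nConstructs = "integer"))

setValidity("CooccurrenceStats", function(object) {
  sc <- senseCodons()
  for (m in list(object@observed, object@expected))
    if (!identical(dimnames(m), list(sc, sc)))
      return("observed/expected must be 61 x 61 with sense-codon dimnames")
  ok <- is.na(diag(object@observed)) & is.na(diag(object@expected))
  if (!all(ok)) return("diagonal cells must be NA (focal = other excluded)")
  TRUE
})

#' NullDistribution: a subsampled null for a library-level statistic
#'
#' Values of a statistic recomputed on repeated without-replacement
#' subsamples of a construct library, used to standardise an observed value
#' as a z-score.
#'
#' @slot values numeric vector of the statistic, one per subsample.
#' @slot subsampleSize constructs drawn per replicate.
#' @slot seed the seed the subsampling was run under.
#' @aliases NullDistribution
#' @exportClass NullDistribution
setClass("NullDistribution",
  representation(values = "numeric", subsampleSize = "integer",
                 seed = "integer"))

setValidity("NullDistribution", function(object) {
  if (length(object@values) < 2L) return("need at least 2 replicates")
  TRUE
})
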