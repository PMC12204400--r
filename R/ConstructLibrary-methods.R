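#' Build a ConstructLibrary
#'
#' @param seqs construct coding sequences: a character vector or
#'   [Biostrings::DNAStringSet], in frame, start codon at position +1. `U`
#'   is accepted and mapped to `T`.
#' @param ids construct identifiers; defaults to names of `seqs` or
#'   `construct_1..n`.
#' @param metrics a data.frame/DataFrame of per-construct metric columns
#'   (may be empty).
#' @param window codon-position span used by all 5' counting statistics;
#'   default `c(2, 11)`, the first ten codons after the start.
#' @return a [ConstructLibrary-class] object.
#' @examples
#' lib <- ConstructLibrary(c(a = "ATGAAACCC", b = "ATGAAGCCA"),
#'                         window = c(2, 3))
#' length(lib)
#' @export
ConstructLibrary <- function(seqs, ids = NULL, metrics = NULL,
                             window = c(2L, 11L)) {
  if (is.character(seqs)) {
    seqs <- toupper(chartr("Uu", "Tt", seqs))
    if (is.null(ids)) ids <- names(seqs)
    seqs <- Biostrings::DNAStringSet(seqs)
  } else {
    seqs <- Biostrings::DNAStringSet(seqs)
    if (is.null(ids)) ids <- names(seqs)
  }
  if (is.null(ids)) ids <- paste0("construct_", seq_along(seqs))
  names(seqs) <- as.character(ids)
  if (is.null(metrics))
    metrics <- S4Vectors::DataFrame(matrix(nrow = length(seqs), ncol = 0L))
  else
    metrics <- S4Vectors::DataFrame(metrics)
  rownames(metrics) <- NULL
  new("ConstructLibrary", seqs = seqs, metrics = metrics,
      window = .checkSpan(window))
}

#' @describeIn ConstructLibrary number of constructs.
#' @param x,object a ConstructLibrary.
#' @export
setMethod("length", "ConstructLibrary", function(x) length(x@seqs))

#' @describeIn ConstructLibrary subset by index, logical mask or id.
#' @param i index vector.
#' @param j,drop,... ignored.
#' @export
setMethod("[", "ConstructLibrary", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, names(x@seqs))
  initialize(x, seqs = x@seqs[i], metrics = x@metrics[i, , drop = FALSE])
})

setMethod("show", "ConstructLibrary", function(object) {
  cat(sprintf(
    "ConstructLibrary: %d constructs, window +%d..+%d, %d metric column(s)\n",
    length(object), object@window[1L], object@window[2L],
    ncol(object@metrics)))
  if (ncol(object@metrics))
    cat("  metrics:", paste(colnames(object@metrics), collapse = ", "), "\n")
})

#' Accessors for ConstructLibrary
#'
#' `constructIds()` returns the identifiers, `constructSeqs()` the
#' [Biostrings::DNAStringSet], `constructMetrics()` the per-construct metric
#' DataFrame, `libraryWindow()` the codon-position counting window, and
#' `metricValues()` one metric column as a plain numeric vector.
#'
#' @param x a [ConstructLibrary-class].
#' @param metric metric column name.
#' @param value replacement value.
#' @name library-accessors
NULL

#' @rdname library-accessors
#' @export
constructIds <- function(x) names(x@seqs)

#' @rdname library-accessors
#' @export
constructSeqs <- function(x) x@seqs

#' @rdname library-accessors
#' @export
constructMetrics <- function(x) x@metrics

#' @rdname library-accessors
#' @export
libraryWindow <- function(x) x@window

#' @rdname library-accessors
#' @export
`libraryWindow<-` <- function(x, value) {
  initialize(x, window = .checkSpan(value))
}

#' @rdname library-accessors
#' @export
metricValues <- function(x, metric) {
  if (!metric %in% colnames(x@metrics))
    stop("metric '", metric, "' not present in library")
  as.numeric(x@metrics[[metric]])
}

#' @rdname library-accessors
#' @export
`constructMetrics<-` <- function(x, value) {
  initialize(x, metrics = S4Vectors::DataFrame(value))
}

#' Codon matrix over the counting window
#'
#' Returns the n x p character matrix of window codons (one row per
#' construct, one column per codon position of `span`). Constructs shorter
#' than the window yield `NA` cells with a message; codons containing
#' non-ACGT characters (ambiguity codes) are set to `NA` so that counting
#' operations skip them.
#'
#' @param x a [ConstructLibrary-class].
#' @param span codon-position span; defaults to the library window.
#' @return character matrix with construct ids as rownames and positions
#'   `+first..+last` as colnames.
#' @export
windowCodons <- function(x, span = libraryWindow(x)) {
  span <- .checkSpan(span)
  s <- as.character(x@seqs)
  pos <- seq.int(span[1L], span[2L])
  m <- vapply(pos, function(p)
    substring(s, 3L * (p - 1L) + 1L, 3L * p), character(length(s)))
  m <- matrix(m, nrow = length(s),
              dimnames = list(names(x@seqs), paste0("+", pos)))
  short <- nchar(s) < 3L * span[2L]
  bad <- nchar(m) != 3L | grepl("[^ACGT]", m)
  if (any(bad)) m[bad] <- NA_character_
  if (any(short)) {
    message(sum(short), " construct(s) shorter than the window; ",
            "missing codons treated as NA")
  }
  m
}

## Integer codon ids (1..61 over senseCodons(), NA for stops/ambiguous),
## the workhorse for all counting statistics.
.codonIdMatrix <- function(x, span = libraryWindow(x)) {
  m <- windowCodons(x, span)
  structure(match(m, senseCodons()), dim = dim(m), dimnames = dimnames(m))
}

## n x 61 per-construct codon count matrix over the window.
.constructCodonCounts <- function(idm) {
  n <- nrow(idm)
  counts <- matrix(0L, n, 61L, dimnames = list(rownames(idm), senseCodons()))
  ok <- which(!is.na(idm))
  if (length(ok)) {
    rows <- ((ok - 1L) %% n) + 1L
    tab <- table(factor(rows, levels = seq_len(n)),
                 factor(idm[ok], levels = seq_len(61L)))
    counts[] <- as.integer(tab)
  }
  counts
}

## 61-vector of codon counts over the whole library window.
.codonCounts <- function(x, span = libraryWindow(x)) {
  idm <- .codonIdMatrix(x, span)
  tabulate(idm[!is.na(idm)], nbins = 61L) |>
    setNames(senseCodons())
}
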