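#' Read a construct table into a ConstructLibrary
#'
#' Reads a delimited text file (tab or comma, sniffed from the header
#' line) with one row per construct. The column map names the id and
#' sequence columns and any metric columns to carry over; the three large
#' published libraries all use different column names, so there is no
#' hard-coded schema. Rows whose sequence fails validation (length not
#' divisible by 3, shorter than the window, characters outside ACGTU) are
#' dropped with a message giving per-reason counts. `U` is accepted and
#' mapped to `T`.
#'
#' @param path file path.
#' @param columns list with elements `id`, `sequence`, and optionally
#'   `metrics` (named character vector: target metric name -> source
#'   column) and `tef` (ordinal column).
#' @param window codon-position counting window, default `c(2, 11)`.
#' @return a [ConstructLibrary-class].
#' @export
readConstructLibrary <- function(path,
    columns = list(id = "id", sequence = "sequence"),
    window = c(2L, 11L)) {
  sep <- .sniffSep(path)
  df <- read.delim(path, sep = sep, stringsAsFactors = FALSE,
                   check.names = FALSE)
  if (nrow(df) == 0L) stop("empty file: ", path)
  if (!columns$sequence %in% colnames(df))
    stop("sequence column '", columns$sequence, "' not found")
  seqs <- toupper(chartr("Uu", "Tt", df[[columns$sequence]]))
  ids <- if (!is.null(columns$id) && columns$id %in% colnames(df))
    as.character(df[[columns$id]]) else paste0("construct_", seq_len(nrow(df)))
  window <- .checkSpan(window)
  badFrame <- nchar(seqs) %% 3L != 0L
  badChar <- grepl("[^ACGT]", seqs)
  tooShort <- nchar(seqs) < 3L * window[2L]
  drop <- badFrame | badChar | tooShort
  if (any(drop))
    message("dropped ", sum(drop), " row(s): ", sum(badFrame),
            " out of frame, ", sum(badChar), " non-ACGT, ",
            sum(tooShort), " shorter than window")
  keep <- which(!drop)
  metrics <- list()
  for (name in names(columns$metrics)) {
    src <- columns$metrics[[name]]
    if (!src %in% colnames(df)) stop("metric column '", src, "' not found")
    metrics[[name]] <- as.numeric(df[[src]][keep])
  }
  if (!is.null(columns$tef)) {
    if (!columns$tef %in% colnames(df))
      stop("tef column '", columns$tef, "' not found")
    metrics$tef <- as.integer(df[[columns$tef]][keep])
  }
  ConstructLibrary(seqs[keep], ids = ids[keep],
                   metrics = if (length(metrics))
                     S4Vectors::DataFrame(metrics) else NULL,
                   window = window)
}

.sniffSep <- function(path) {
  header <- readLines(path, n = 1L)
  if (!length(header)) stop("empty file: ", path)
  if (lengths(regmatches(header, gregexpr("\t", header))) > 0) "\t" else ","
}

#' Write a ConstructLibrary as TSV
#'
#' Columns: `id`, `sequence`, then every metric column. `NA` is written as
#' the literal string `NA`.
#'
#' @param x a [ConstructLibrary-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeConstructLibrary <- function(x, path) {
  df <- data.frame(id = constructIds(x),
                   sequence = as.character(constructSeqs(x)))
  m <- as.data.frame(constructMetrics(x))
  if (ncol(m)) df <- cbind(df, m)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a CDS collection from FASTA
#'
#' Reads CDS records with [Biostrings::readDNAStringSet()] and filters
#' records failing validation: length not divisible by 3, missing start
#' codon (ATG/GTG/TTG), missing terminal stop, or (under `strict`) an
#' internal stop codon. Per-reason counts are reported in a message.
#'
#' @param path FASTA file path.
#' @param strict drop records with internal stop codons (default TRUE).
#' @return a [Biostrings::DNAStringSet] of the retained CDSs.
#' @export
readCdsFasta <- function(path, strict = TRUE) {
  set <- Biostrings::readDNAStringSet(path)
  s <- toupper(chartr("U", "T", as.character(set)))
  stops <- c("TAA", "TAG", "TGA")
  badFrame <- nchar(s) %% 3L != 0L
  noStart <- !substr(s, 1L, 3L) %in% c("ATG", "GTG", "TTG")
  noStop <- rep(TRUE, length(s))
  internalStop <- rep(FALSE, length(s))
  for (i in which(!badFrame)) {
    cod <- splitCodons(s[i])
    noStop[i] <- !cod[length(cod)] %in% stops
    internalStop[i] <- any(cod[-length(cod)] %in% stops)
  }
  drop <- badFrame | noStart | (!badFrame & noStop) |
    (strict & internalStop)
  if (any(drop))
    message("filtered ", sum(drop), " record(s): ", sum(badFrame),
            " out of frame, ", sum(noStart), " bad start, ",
            sum(noStop & !badFrame), " no terminal stop, ",
            sum(internalStop & strict), " internal stop")
  set[!drop]
}

#' Serialize log-odds results as TSV
#'
#' `writeLogOdds()` writes a [LogOddsVector-class] as a two-column TSV
#' (`codon`, `log_odds`; `NA` literal) and a [PositionalLogOdds-class] as
#' a 59-row matrix TSV with a header row of positions. `readLogOdds()`
#' reads the two-column form back into a LogOddsVector.
#'
#' @param x the object to write.
#' @param path file path.
#' @param context context string for the read-back object.
#' @return the path / a [LogOddsVector-class].
#' @export
writeLogOdds <- function(x, path) {
  if (is(x, "LogOddsVector")) {
    df <- data.frame(codon = names(x@values),
                     log_odds = sprintf("%.12g", x@values))
    df$log_odds[is.na(x@values)] <- "NA"
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else if (is(x, "PositionalLogOdds")) {
    df <- data.frame(codon = rownames(x@values), x@values,
                     check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else stop("unsupported object")
  invisible(path)
}

#' @rdname writeLogOdds
#' @export
readLogOdds <- function(path, context = basename(path)) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  v <- setNames(as.numeric(df$log_odds), df$codon)[degenerateCodons()]
  names(v) <- degenerateCodons()
  new("LogOddsVector", values = v, context = context)
}

#' Serialize best-codon matrices and their agreement as TSV
#'
#' `writeBestCodonMatrix()` writes an 18 x 10 matrix of top-scoring
#' codons (from [bestCodonMatrix()]); `writeAgreementTable()` writes the
#' cell-by-cell agreement of two such matrices coded `agree` /
#' `disagree` / `NA` (the tile-plot semantics: white, black, missing).
#'
#' @param x,mA,mB best-codon matrices.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeBestCodonMatrix <- function(x, path) {
  df <- data.frame(amino_acid = rownames(x), x, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeBestCodonMatrix
#' @export
writeAgreementTable <- function(mA, mB, path) {
  stopifnot(identical(dim(mA), dim(mB)))
  code <- matrix(NA_character_, nrow(mA), ncol(mA), dimnames = dimnames(mA))
  ok <- !is.na(mA) & !is.na(mB)
  code[ok] <- ifelse(mA[ok] == mB[ok], "agree", "disagree")
  df <- data.frame(amino_acid = rownames(code), code, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialize passenger diagnostics as TSV
#'
#' `writePassengerProfile()` writes the profile data.frame (codon,
#' meanOfMeans, sd, sem, n). `writeCooccurrence()` writes the observed and
#' expected counts in long format (focal, other, observed, expected; 3660
#' rows). `writeNullDistribution()` writes the replicate values as a
#' single-column TSV plus a JSON sidecar (`<path>.json`) recording reps,
#' subsample size and seed so the run is reproducible.
#'
#' @param x the object to write.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writePassengerProfile <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writePassengerProfile
#' @export
writeCooccurrence <- function(x, path) {
  stopifnot(is(x, "CooccurrenceStats"))
  sc <- senseCodons()
  long <- expand.grid(other = sc, focal = sc, stringsAsFactors = FALSE)
  long <- long[long$focal != long$other, c("focal", "other")]
  long$observed <- x@observed[cbind(long$focal, long$other)]
  long$expected <- x@expected[cbind(long$focal, long$other)]
  write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writePassengerProfile
#' @export
writeNullDistribution <- function(x, path) {
  stopifnot(is(x, "NullDistribution"))
  write.table(data.frame(value = x@values), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(reps = length(x@values), subsample_size = x@subsampleSize,
         seed = x@seed),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
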