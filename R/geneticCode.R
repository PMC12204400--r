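#' @import methods
#' @importFrom stats quantile cor cor.test lm lm.fit coef resid median sd
#'   setNames binom.test pt pf rnorm runif rlnorm prcomp complete.cases
#' @importFrom utils read.delim write.table head combn
NULL

## Standard-code facts used throughout: 61 sense codons, 18 degenerate amino
## acids, 59 degenerate codons (61 minus ATG and TGG), 87 within-block pairs.

.BASES <- c("A", "C", "G", "T")

.codonTable <- function() {
  codons <- as.vector(outer(outer(.BASES, .BASES, paste0), .BASES, paste0))
  codons <- sort(codons)
  aa <- as.character(Biostrings::GENETIC_CODE[codons])
  names(aa) <- codons
  aa
}

.CODON_TO_AA <- .codonTable()
.SENSE_CODONS <- names(.CODON_TO_AA)[.CODON_TO_AA != "*"]
.SENSE_AA <- .CODON_TO_AA[.SENSE_CODONS]
.BLOCKS <- split(.SENSE_CODONS, .SENSE_AA)
.DEGENERATE_AA <- names(.BLOCKS)[lengths(.BLOCKS) >= 2L]
.DEGENERATE_CODONS <- unlist(.BLOCKS[.DEGENERATE_AA], use.names = FALSE)
.DEGENERATE_CODONS <- .SENSE_CODONS[.SENSE_CODONS %in% .DEGENERATE_CODONS]

#' Genetic-code facts for the standard code
#'
#' Helpers exposing the codon sets the package's statistics are defined over:
#' the 61 sense codons, the synonymous blocks of the 18 degenerate amino
#' acids, and the 59 degenerate codons (sense codons minus the single-codon
#' amino acids ATG/Met and TGG/Trp). All codon vectors are alphabetically
#' ordered, which fixes the row order of every vector and matrix the package
#' produces.
#'
#' @return `senseCodons()` and `degenerateCodons()` return character vectors
#'   of length 61 and 59. `synonymousBlocks()` returns a named list mapping
#'   each amino acid (one-letter symbol) to its ordered codon block;
#'   `degenerate = TRUE` restricts it to the 18 blocks of size >= 2.
#'   `codonAminoAcid()` translates a codon vector to amino-acid symbols
#'   (`"*"` for stops).
#' @examples
#' length(degenerateCodons())  # 59
#' synonymousBlocks()[["K"]]   # AAA, AAG
#' @export
senseCodons <- function() .SENSE_CODONS

#' @rdname senseCodons
#' @export
degenerateCodons <- function() .DEGENERATE_CODONS

#' @rdname senseCodons
#' @param degenerate logical; keep only blocks with two or more codons.
#' @export
synonymousBlocks <- function(degenerate = TRUE) {
  if (degenerate) .BLOCKS[.DEGENERATE_AA] else .BLOCKS
}

#' @rdname senseCodons
#' @param codon character vector of trinucleotides.
#' @export
codonAminoAcid <- function(codon) {
  aa <- .CODON_TO_AA[codon]
  if (anyNA(aa)) stop("invalid codon(s): ",
                      paste(unique(codon[is.na(aa)]), collapse = ", "))
  unname(aa)
}

#' Translate a codon vector to an amino-acid string
#'
#' Standard-code translation; stop codons are rendered as `*`.
#'
#' @param codons character vector of trinucleotides.
#' @return single amino-acid string.
#' @examples
#' translateCodons(c("ATG", "AGG"))  # "MR"
#' @export
translateCodons <- function(codons) {
  paste(codonAminoAcid(codons), collapse = "")
}

#' Codon-level sequence predicates and composition
#'
#' `isNGG()` is TRUE for codons with G at positions 2 and 3 (AGG, CGG, GGG,
#' TGG); these are the codons reported suppressive at early 5' positions via
#' peptidyl-tRNA drop-off. `gcFraction()` is the G+C fraction of a nucleotide
#' string. `gc3()` is the fraction of codon third positions that are G or C,
#' computed over sense codons only: the start codon is included, a terminal
#' stop codon is excluded, and codons containing ambiguity characters are
#' skipped.
#'
#' @param codon,nt,cds character; a codon vector, nucleotide string(s), or
#'   in-frame coding sequence(s).
#' @return logical vector / numeric fraction(s) in `[0, 1]`.
#' @examples
#' isNGG(c("AGG", "AGA", "GGA"))  # TRUE FALSE FALSE
#' gc3("ATGGCC")                  # 1.0 (thirds are G and C)
#' @export
isNGG <- function(codon) {
  if (any(nchar(codon) != 3L)) stop("codons must be trinucleotides")
  substr(codon, 2L, 3L) == "GG"
}

#' @rdname isNGG
#' @export
gcFraction <- function(nt) {
  if (any(!nzchar(nt))) stop("empty sequence")
  ch <- strsplit(toupper(nt), "", fixed = TRUE)
  vapply(ch, function(x) mean(x %in% c("G", "C")), numeric(1))
}

#' @rdname isNGG
#' @export
gc3 <- function(cds) {
  vapply(cds, function(s) {
    cod <- splitCodons(s)
    aa <- .CODON_TO_AA[cod]
    # drop terminal stop; skip ambiguous codons (NA lookup) and internal stops
    if (length(cod) && !is.na(aa[length(cod)]) && aa[length(cod)] == "*")
      cod <- cod[-length(cod)]
    keep <- !is.na(.CODON_TO_AA[cod]) & .CODON_TO_AA[cod] != "*"
    cod <- cod[keep]
    if (!length(cod)) return(NA_real_)
    mean(substr(cod, 3L, 3L) %in% c("G", "C"))
  }, numeric(1), USE.NAMES = FALSE)
}

#' Split an in-frame sequence into codons
#'
#' @param cds nucleotide string, length divisible by 3, position +1 = start.
#' @return character vector of codons.
#' @keywords internal
splitCodons <- function(cds) {
  cds <- toupper(chartr("U", "T", cds))
  n <- nchar(cds)
  if (n %% 3L != 0L) stop("sequence length not divisible by 3")
  substring(cds, seq(1L, n - 2L, by = 3L), seq(3L, n, by = 3L))
}

#' Extract the codons at given codon positions
#'
#' Codon positions are 1-based with the start codon at +1, so the ten codons
#' after the start span +2..+11.
#'
#' @param cds in-frame nucleotide string.
#' @param span integer vector of length 2, first and last codon position
#'   (inclusive), e.g. `c(2, 11)`.
#' @return character vector of codons at the requested positions.
#' @examples
#' codonsOf("ATGAAACCC", c(2, 3))  # "AAA" "CCC"
#' @export
codonsOf <- function(cds, span) {
  span <- .checkSpan(span)
  cds <- toupper(chartr("U", "T", cds))
  if (grepl("[^ACGT]", cds)) stop("non-ACGT character in sequence")
  n <- nchar(cds)
  if (n %% 3L != 0L) stop("sequence length not divisible by 3")
  if (3L * span[2L] > n)
    stop("sequence too short for span +", span[1L], "..+", span[2L])
  pos <- seq.int(span[1L], span[2L])
  substring(cds, 3L * (pos - 1L) + 1L, 3L * pos)
}

.checkSpan <- function(span) {
  span <- as.integer(span)
  if (length(span) != 2L || anyNA(span) || span[1L] > span[2L] ||
      span[1L] < 1L)
    stop("span must be c(first, last) with 1 <= first <= last")
  span
}
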