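## Synthetic construct libraries with controlled randomization, planted
## design bias, and a stated 5'-composition expression model. These
## emulate the structure of the large published transgene libraries
## (thousands of constructs varying only in the first ten codons after the
## start) without requiring any downloads.

.aaAlphabet <- function() names(synonymousBlocks(degenerate = FALSE))

.sampleBackbones <- function(n, backbone, length = 10L) {
  if (is.null(backbone) || identical(backbone, "random")) {
    aas <- .aaAlphabet()
    matrix(sample(aas, n * length, replace = TRUE), nrow = n)
  } else if (identical(backbone, "distinct")) {
    # each backbone uses `length` distinct amino acids, so no window can
    # hold two codons of the same synonymous block; this makes flanking
    # composition independent of the focal codon (exact null for the
    # focal-exclusion diagnostic)
    aas <- .aaAlphabet()
    if (length > base::length(aas)) stop("backboneLength > 20 for 'distinct'")
    t(vapply(seq_len(n), function(i) sample(aas, length),
             character(length)))
  } else {
    bb <- strsplit(backbone, "", fixed = TRUE)
    if (any(lengths(bb) < 10L))
      stop("backbone(s) must be >= 10 residues")
    if (length(unique(lengths(bb))) != 1L)
      stop("all backbones must have equal length")
    bad <- setdiff(unique(unlist(bb)), .aaAlphabet())
    if (length(bad))
      stop("backbone contains untranslatable symbols: ",
           paste(bad, collapse = ", "))
    idx <- sample(length(bb), n, replace = TRUE)
    do.call(rbind, bb[idx])
  }
}

## Uniform synonymous codon choice per residue, optionally with per-codon
## weights (a named multiplier over the block members).
.sampleCodons <- function(aaMat, weights = NULL) {
  blocks <- synonymousBlocks(degenerate = FALSE)
  out <- matrix(NA_character_, nrow(aaMat), ncol(aaMat))
  for (aa in unique(as.vector(aaMat))) {
    cells <- which(aaMat == aa)
    block <- blocks[[aa]]
    w <- rep(1, length(block))
    if (!is.null(weights)) {
      hit <- match(block, names(weights))
      w[!is.na(hit)] <- weights[hit[!is.na(hit)]]
    }
    out[cells] <- sample(block, length(cells), replace = TRUE,
                         prob = w / sum(w))
  }
  out
}

#' Fully randomized synthetic construct library
#'
#' Each construct is `ATG` followed by one codon per backbone residue,
#' chosen independently and uniformly within the residue's synonymous
#' block -- the idealised fully randomized design. Backbones are either a
#' supplied amino-acid sequence (>= 10 residues, reused across constructs)
#' or, by default, random 10-residue peptides drawn uniformly from the 20
#' amino acids so that all 61 sense codons occur.
#'
#' @param n number of constructs.
#' @param backbone amino-acid string(s) for the variable region;
#'   `"random"`/`NULL` for random 10-residue backbones (residues drawn
#'   with replacement); or `"distinct"` for random backbones of distinct
#'   residues, under which no window holds two codons of the same
#'   synonymous block -- the design for which the focal-codon-exclusion
#'   null is exactly zero (see the methods vignette).
#' @param backboneLength residues per random backbone.
#' @param seed integer seed; generation is bit-reproducible under it.
#' @return a [ConstructLibrary-class] with window +2..+(backbone length+1).
#' @export
randomLibrary <- function(n, backbone = "random", backboneLength = 10L,
                          seed = 1L) {
  withSeed(seed, {
    aaMat <- .sampleBackbones(n, backbone, backboneLength)
    codons <- .sampleCodons(aaMat)
    seqs <- paste0("ATG", apply(codons, 1L, paste, collapse = ""))
    ConstructLibrary(seqs, ids = sprintf("sim_%06d", seq_len(n)),
                     window = c(2L, ncol(aaMat) + 1L))
  })
}

#' Synthetic library with planted design bias (passenger coupling)
#'
#' Emulates non-random construct design: constructs are generated as in
#' [randomLibrary()], so the focal codon is placed with its natural
#' uniform probability, but a construct that happens to contain the focal
#' codon has, with probability `couplingProb`, its remaining positions
#' redrawn from a skewed background pool (synonymous choice weighted by
#' `poolWeight` for A-ending codons). The focal codon is thereby coupled
#' to a high-expression-promoting (A-rich) context while remaining
#' causally neutral itself -- the in-silico analogue of a designed library
#' in which one codon rides as a passenger of its neighbours.
#'
#' @inheritParams randomLibrary
#' @param focalCodon the codon to couple (must be degenerate).
#' @param couplingProb probability q that a focal-containing construct is
#'   redrawn from the skewed pool.
#' @param poolWeight sampling weight multiplier for A-ending codons in the
#'   skewed pool (> 1 = A-enriched background).
#' @return a [ConstructLibrary-class]; the logical metric column
#'   `biased` records which constructs were redrawn.
#' @export
biasedLibrary <- function(n, focalCodon = "AGG", couplingProb = 0.9,
                          poolWeight = 8, backbone = "random",
                          backboneLength = 10L, seed = 1L) {
  if (!focalCodon %in% degenerateCodons())
    stop("focalCodon must be one of the 59 degenerate codons")
  withSeed(seed, {
    aaMat <- .sampleBackbones(n, backbone, backboneLength)
    codons <- .sampleCodons(aaMat)
    aending <- senseCodons()[substr(senseCodons(), 3L, 3L) == "A"]
    skew <- setNames(rep(poolWeight, length(aending)), aending)
    hasFocal <- rowSums(codons == focalCodon) > 0L
    redraw <- hasFocal & runif(n) < couplingProb
    if (any(redraw)) {
      sub <- codons[redraw, , drop = FALSE]
      keep <- sub == focalCodon       # focal copies stay where they landed
      newdraw <- .sampleCodons(aaMat[redraw, , drop = FALSE], weights = skew)
      sub[!keep] <- newdraw[!keep]
      codons[redraw, ] <- sub
    }
    seqs <- paste0("ATG", apply(codons, 1L, paste, collapse = ""))
    lib <- ConstructLibrary(seqs, ids = sprintf("sim_%06d", seq_len(n)),
                            window = c(2L, ncol(aaMat) + 1L))
    constructMetrics(lib) <- S4Vectors::DataFrame(biased = redraw)
    lib
  })
}

#' Apply the 5'-composition expression model
#'
#' Generates expression metrics from the stated log-additive model:
#' `log(protein/RNA) = betaAt * Afrac - nggPenalty * nNGG + codon effects
#' + Normal(0, noiseSd)`, where `Afrac` is the A fraction of the first 30
#' nt after the start codon (the package's composition proxy for low 5'
#' mRNA stability: A-rich = unstable = efficiently initiated) and `nNGG`
#' counts NGG codons in the first six codons (+2..+7, the span where NGG
#' suppression via peptidyl-tRNA drop-off acts). An independent lognormal
#' `rna` column is also drawn so that `protein` (= protein_per_rna * rna)
#' and `protein_per_rna` order constructs differently.
#'
#' @param x a [ConstructLibrary-class].
#' @param betaAt effect of 5' A fraction on log(protein/RNA).
#' @param nggPenalty per-NGG-codon penalty on log(protein/RNA).
#' @param codonEffects optional named per-codon additive effects applied
#'   once per occurrence in the window.
#' @param noiseSd Gaussian noise SD on the log scale (> 0).
#' @param seed integer seed.
#' @return the library with metric columns `protein_per_rna`, `rna`,
#'   `protein` added (existing columns kept).
#' @export
applyExpression <- function(x, betaAt = 6, nggPenalty = 0.8,
                            codonEffects = NULL, noiseSd = 0.5,
                            seed = 1L) {
  if (noiseSd <= 0) stop("noiseSd must be > 0")
  seqs <- as.character(constructSeqs(x))
  first30 <- substr(seqs, 4L, 33L)
  afrac <- vapply(strsplit(first30, "", fixed = TRUE),
                  function(ch) mean(ch == "A"), numeric(1))
  nggSpan <- c(2L, min(7L, libraryWindow(x)[2L]))
  idm <- .codonIdMatrix(x, nggSpan)
  nNgg <- rowSums(matrix(isNGG(senseCodons())[idm], nrow = nrow(idm)),
                  na.rm = TRUE)
  eff <- 0
  if (!is.null(codonEffects)) {
    e61 <- setNames(rep(0, 61L), senseCodons())
    e61[names(codonEffects)] <- codonEffects
    idw <- .codonIdMatrix(x)
    eff <- rowSums(matrix(e61[idw], nrow = nrow(idw)), na.rm = TRUE)
  }
  withSeed(seed, {
    logPpr <- betaAt * afrac - nggPenalty * nNgg + eff +
      rnorm(length(x), 0, noiseSd)
    rna <- rlnorm(length(x), meanlog = 0, sdlog = 1)
    m <- constructMetrics(x)
    m$protein_per_rna <- exp(logPpr)
    m$rna <- rna
    m$protein <- exp(logPpr) * rna
    constructMetrics(x) <- m
  })
  x
}

#' Synthetic genome-like CDS collection with controlled GC3
#'
#' Random CDS sets whose third-position G+C composition matches a target
#' in the gene core and is reduced by `fivePrimeAtBoost` in codons
#' +2..+11, emulating the A/T-enriched 5' ends of bacterial genes. Each
#' CDS starts with ATG, contains only sense codons, and ends with TAA.
#'
#' @param nGenes number of CDSs.
#' @param lengthRange range (codons, excluding start and stop) to sample
#'   lengths from uniformly.
#' @param gc3Target core third-position G+C probability, in (0, 1).
#' @param fivePrimeAtBoost reduction of the GC3 probability at +2..+11
#'   (clipped into [0.01, 0.99] with a message if infeasible).
#' @param seed integer seed.
#' @return a named [Biostrings::DNAStringSet].
#' @export
genomeSet <- function(nGenes, lengthRange = c(100L, 300L),
                      gc3Target = 0.5, fivePrimeAtBoost = 0,
                      seed = 1L) {
  stopifnot(gc3Target > 0, gc3Target < 1)
  sc <- senseCodons()
  third <- substr(sc, 3L, 3L)
  gcPool <- sc[third %in% c("G", "C")]
  atPool <- sc[third %in% c("A", "T")]
  p5 <- gc3Target - fivePrimeAtBoost
  if (p5 < 0.01 || p5 > 0.99) {
    p5 <- min(max(p5, 0.01), 0.99)
    message("5' GC3 probability clipped to ", p5)
  }
  drawCodons <- function(k, p) {
    gc <- runif(k) < p
    out <- character(k)
    out[gc] <- sample(gcPool, sum(gc), replace = TRUE)
    out[!gc] <- sample(atPool, sum(!gc), replace = TRUE)
    out
  }
  withSeed(seed, {
    lens <- sample(seq.int(lengthRange[1L], lengthRange[2L]), nGenes,
                   replace = TRUE)
    seqs <- vapply(lens, function(L) {
      five <- drawCodons(min(10L, L), p5)
      core <- if (L > 10L) drawCodons(L - 10L, gc3Target) else character()
      paste0("ATG", paste(c(five, core), collapse = ""), "TAA")
    }, character(1))
    Biostrings::DNAStringSet(setNames(seqs,
                                      sprintf("gene_%05d", seq_len(nGenes))))
  })
}

#' Bin a continuous metric into ordinal translation-efficiency fractions
#'
#' Equal-frequency quantile bins labelled 1..nBins (1 = lowest), emulating
#' fluorescence-sorted library fractions.
#'
#' @param x a [ConstructLibrary-class].
#' @param metric metric column to bin.
#' @param nBins number of fractions.
#' @return the library with an integer `tef` metric column added.
#' @export
tefBinning <- function(x, metric, nBins = 5L) {
  v <- metricValues(x, metric)
  if (length(unique(v[!is.na(v)])) < nBins)
    stop("too few distinct values for ", nBins, " bins")
  br <- quantile(v, probs = seq(0, 1, length.out = nBins + 1L),
                 na.rm = TRUE, names = FALSE, type = 7)
  br[1L] <- -Inf; br[nBins + 1L] <- Inf
  if (anyDuplicated(br))
    stop("metric too tied for ", nBins, " equal-frequency bins")
  tef <- as.integer(cut(v, breaks = br, labels = FALSE))
  m <- constructMetrics(x)
  m$tef <- tef
  constructMetrics(x) <- m
  x
}
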