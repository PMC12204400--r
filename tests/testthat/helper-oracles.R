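# Independent brute-force oracles. These deliberately share no code with
# the package internals: plain loops over codon lists, written directly
# from the definitions of the statistics.

# Codon list of one construct's window, +2..+11 by default.
oracleWindow <- function(seq, span = c(2, 11)) {
  sapply(span[1]:span[2], function(p) substr(seq, 3 * p - 2, 3 * p))
}

oracleWindows <- function(lib, span = libraryWindow(lib)) {
  lapply(as.character(constructSeqs(lib)), oracleWindow, span = span)
}

# Brute-force log odds: count focal and synonyms in each condition by
# looping over codon lists; apply the 0.5 rule per focal codon.
oracleLogOdds <- function(windowsHigh, windowsLow) {
  all1 <- unlist(windowsHigh)
  all2 <- unlist(windowsLow)
  out <- setNames(rep(NA_real_, 59), degenerateCodons())
  blocks <- synonymousBlocks()
  for (aa in names(blocks)) {
    block <- blocks[[aa]]
    for (f in block) {
      syn <- setdiff(block, f)
      k <- c(sum(all1 == f), sum(all1 %in% syn),
             sum(all2 == f), sum(all2 %in% syn))
      if (all(k == 0)) next
      if (any(k == 0)) k <- k + 0.5
      out[f] <- log((k[1] / k[2]) / (k[3] / k[4]))
    }
  }
  out
}

# Brute-force focal-codon-exclusion profile.
oracleProfile <- function(lib, refValues) {
  wins <- oracleWindows(lib)
  res <- data.frame(codon = degenerateCodons(), meanOfMeans = NA_real_,
                    sd = NA_real_, sem = NA_real_, n = 0L)
  for (i in seq_len(59)) {
    f <- res$codon[i]
    means <- c()
    for (w in wins) {
      if (!any(w == f)) next
      others <- w[w != f]
      vals <- refValues[others]
      vals <- vals[!is.na(vals)]
      if (length(vals)) means <- c(means, mean(vals))
    }
    res$n[i] <- length(means)
    if (length(means) >= 1) res$meanOfMeans[i] <- mean(means)
    if (length(means) >= 2) {
      res$sd[i] <- sd(means)
      res$sem[i] <- sd(means) / sqrt(length(means))
    }
  }
  res
}

# Brute-force co-occurrence observed/expected, chi2 sum and per-codon dev.
oracleCooccurrence <- function(lib) {
  wins <- oracleWindows(lib)
  sc <- senseCodons()
  allCodons <- unlist(wins)
  obs <- exp_ <- matrix(NA_real_, 61, 61, dimnames = list(sc, sc))
  for (f in sc) {
    with_f <- Filter(function(w) any(w == f), wins)
    pooled <- unlist(with_f)
    pooled <- pooled[pooled != f]
    totNonF <- sum(allCodons != f)
    for (x in sc) {
      if (x == f) next
      obs[f, x] <- sum(pooled == x)
      exp_[f, x] <- length(pooled) * sum(allCodons == x) / totNonF
    }
  }
  chi2 <- 0; dev <- setNames(rep(NA_real_, 61), sc)
  for (f in sc) {
    ds <- c()
    for (x in sc) {
      if (x == f || is.na(exp_[f, x]) || exp_[f, x] == 0) next
      chi2 <- chi2 + (obs[f, x] - exp_[f, x])^2 / exp_[f, x]
      ds <- c(ds, abs(obs[f, x] - exp_[f, x]) / exp_[f, x])
    }
    if (length(ds)) dev[f] <- mean(ds)
  }
  list(observed = obs, expected = exp_, chi2 = chi2, dev = dev)
}

# Partial Spearman via inversion of the rank correlation matrix.
oraclePartialSpearman <- function(data, x, y, covariates) {
  d <- data[complete.cases(data[, c(x, y, covariates)]),
            c(x, y, covariates)]
  R <- cor(apply(d, 2, rank))
  P <- solve(R)
  -P[1, 2] / sqrt(P[1, 1] * P[2, 2])
}

# LMG by direct enumeration of all k! orderings.
oracleLmg <- function(data, response, predictors) {
  d <- data[complete.cases(data[, c(response, predictors)]),
            c(response, predictors)]
  y <- d[[response]]
  X <- scale(as.matrix(d[, predictors]))
  r2 <- function(cols) {
    if (!length(cols)) return(0)
    fit <- lm.fit(cbind(1, X[, cols, drop = FALSE]), y)
    1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
  }
  k <- length(predictors)
  perms <- gtoolsPerms(k)
  shares <- setNames(numeric(k), predictors)
  for (p in seq_len(nrow(perms))) {
    ord <- perms[p, ]
    for (pos in seq_len(k)) {
      before <- ord[seq_len(pos - 1)]
      j <- ord[pos]
      shares[j] <- shares[j] + r2(c(before, j)) - r2(before)
    }
  }
  shares / nrow(perms)
}

# All permutations of 1..k (small k only).
gtoolsPerms <- function(k) {
  if (k == 1) return(matrix(1))
  sub <- gtoolsPerms(k - 1)
  out <- NULL
  for (i in seq_len(k)) {
    rest <- setdiff(seq_len(k), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}

# Exact two-tailed binomial p by the minimum-likelihood convention: sum of
# probabilities of all outcomes no more likely than the observed one.
oracleBinomTwoTailed <- function(x, n, p0) {
  probs <- dbinom(0:n, n, p0)
  sum(probs[probs <= probs[x + 1] * (1 + 1e-7)])
}

# A small deterministic hand-built library with known metric values.
toyLibrary <- function() {
  seqs <- c(
    t1 = "ATGAAAGGGACCTTTCCGAAAGAGGATCTGCTGTAA",
    t2 = "ATGAAGGGAACGTTCCCGAAGGAGGACCTGCTGTAA",
    t3 = "ATGAAAGGGACCTTTCCAAAAGAAGATTTACTATAA",
    t4 = "ATGAAGGGCACATTTCCGAAAGAGGATCTGTTGTAA",
    t5 = "ATGAAAGGAACCTTCCCGAAGGAAGACCTCCTTTAA",
    t6 = "ATGAAGGGGACCTTTCCGAAAGAGGATCTGCTATAA")
  ConstructLibrary(seqs,
                   metrics = data.frame(expr = c(10, 8, 6, 4, 2, 1)),
                   window = c(2, 11))
}
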