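# codonPassenger

Synonymous codon enrichment and passenger-effect diagnostics for
transgene construct libraries.

## The problem

Large *E. coli* transgene libraries vary only the synonymous codons of
the first ten positions after the start codon (+2..+11, with the start at
+1) and measure protein output per transcript. The per-codon summary is a
synonymous-block log-odds enrichment: for each of the 59 degenerate sense
codons, with focal count c<sub>1f</sub> and synonym count c<sub>1s</sub>
in the upper expression quartile and c<sub>2f</sub>, c<sub>2s</sub> in the
lower quartile,

```
log odds = ln( (c1f / c1s) / (c2f / c2s) )
```

with the modified Haldane–Anscombe zero-cell correction (add 0.5 to all
four counts when some but not all are zero; a block whose amino acid is
absent from both conditions is NA).

This statistic is causally interpretable only for randomized construct
designs. When design couples a codon to high-performing neighbours, the
codon inherits their signal — a **passenger effect**. The package
implements the enrichment statistics, concordance tests between analyses
(orthogonal fits, within-block oriented pairs, best-codon matrices with
exact weighted binomial tests), and a passenger diagnostic suite:
focal-codon-exclusion mean-of-means profiles, 61 x 60 codon co-occurrence
observed/expected statistics with subsampled chi-squared nulls, and
residual attribution of between-dataset disagreement. A seeded synthetic
library generator (randomized or with planted design bias, plus a stated
5'-composition expression model) makes every stage verifiable without
external data. See the methods vignette
(`vignettes/passenger-diagnostics.Rmd`) for the full account.

Audience: anyone analysing 5' codon-randomization libraries, designing
transgene construct sets, or auditing published per-codon enrichment
claims for design artefacts.

## Worked example

The package's core demonstration: a causally neutral codon (AGG, given an
expression effect of exactly zero) planted into A-rich construct contexts
acquires a strongly positive enrichment signal, and the diagnostic suite
attributes it to design bias.

```r
library(codonPassenger)
rec <- artefactRecovery(n = 10000, seed = 1)

cat("AGG log odds (biased library):", round(rec$focalLogOdds, 2), "\n")
cat("bootstrap 95% CI:", round(rec$focalCI[["q0.025"]], 2), "-",
    round(rec$focalCI[["q0.975"]], 2), "\n")
cat("AGG log odds (randomized reference):", round(rec$focalLogOddsRef, 2), "\n")
cat("focal-exclusion mean of means:", round(rec$profileRow$meanOfMeans, 3),
    "+/-", round(rec$profileRow$sem, 4), "(SEM), N =", rec$profileRow$n, "\n")
cat("per-codon deviation rank of AGG:", rec$devRank, "of 61\n")
cat("residuals ~ passenger scores, Spearman rho:", round(rec$rhoTest, 2), "\n")
```

```
AGG log odds (biased library): 3.01
bootstrap 95% CI: 2.7 - 3.52
AGG log odds (randomized reference): -0.66
focal-exclusion mean of means: 0.944 +/- 0.0157 (SEM), N = 764
per-codon deviation rank of AGG: 1 of 61
residuals ~ passenger scores, Spearman rho: 0.66
```

Reading the output: in the biased library AGG looks like the strongest
expression-promoting codon (log odds 3.0, CI well above 0), yet in the
randomized reference library built under the *same* expression model it
scores negative — the apparent effect is an artefact. The diagnostics
localise it: constructs carrying AGG have flanking codons whose mean
reference score is 0.94 (60 SEMs above the null of zero), AGG ranks first
among all 61 codons in co-occurrence deviation difference against a
matched random library, and the disagreement between the two vectors is
predicted by the biased library's passenger scores (rho = 0.66, i.e.
roughly 40% of the disagreement explained).

Typical building blocks for real data:

```r
lib <- readConstructLibrary("constructs.tsv",
         columns = list(id = "id", sequence = "seq",
                        metrics = c(protein_per_rna = "PNI_over_RNA")))
q   <- partitionQuartiles(lib, "protein_per_rna")
v   <- logOdds(q$high, q$low)          # 59-element enrichment vector
P   <- positionalLogOdds(q$high, q$low)
prof <- focalExclusionProfile(lib, referenceVector)
```

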