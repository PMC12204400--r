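---
title: "Synonymous codon enrichment and passenger-effect diagnostics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synonymous codon enrichment and passenger-effect diagnostics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codonPassenger)
```

## The problem

Large transgene libraries in *E. coli* vary only the synonymous codons of
the first ten positions after the start codon and measure the resulting
protein output. Because synonymous 5' composition controls mRNA folding
around the initiation region, such libraries are the main source of
evidence on which codons to use at 5' ends. The per-codon summary
statistic is a *synonymous-block log-odds enrichment*: how over-represented
a codon is, relative to its synonyms, among the most productive constructs
compared with the least productive ones.

The statistic is only causally interpretable if codons are allocated to
constructs at random. When construct design couples a codon to
high-performing neighbours, the codon inherits their signal — a
*passenger effect*, analogous to hitchhiking in population genetics or
passenger mutations in tumours. This package implements both the
enrichment statistics and a diagnostic suite that detects and quantifies
passenger effects, together with a synthetic library generator that makes
every stage testable end to end.

## The enrichment statistic

For each of the 59 degenerate sense codons (61 sense codons minus ATG and
TGG, which have no synonyms), with focal-codon count $c_{1f}$ and synonym
count $c_{1s}$ in condition 1 (upper quartile of the chosen metric) and
$c_{2f}$, $c_{2s}$ in condition 2 (lower quartile):

$$\log\text{odds} = \ln\frac{c_{1f}/c_{1s}}{c_{2f}/c_{2s}}$$

Counting uses the window +2..+11 (start codon = +1) unless configured
otherwise. Zero cells are handled by the modified Haldane–Anscombe
correction: if some but not all of the four counts are zero, 0.5 is added
to all four before forming the ratio; if all four are zero the amino
acid's entire block is set to `NA` (absence of data). The correction is
applied per focal codon; because a 2-fold block's two focal codons share
the same four counts (in swapped roles), the two log odds are exact
negatives, an invariant the tests assert.

Numerical conventions, chosen where the procedure is genuinely open:

* **Quartile cuts** use linear-interpolation (type 7) percentiles with
  *inclusive* tails: values exactly at a threshold join the respective
  tail. Whether published analyses used strict or inclusive inequalities
  is not documented; inclusive tails keep the two groups symmetric for
  continuous metrics, and the cut points are exposed through `probs` so
  either convention can be run.
* **Ties in best-codon matrices** (`bestCodonMatrix()`) break towards the
  lexicographically smallest codon and are flagged in a `"ties"`
  attribute. Ties have probability zero on continuous data but occur on
  small synthetic inputs.
* **Short or ambiguous codons**: constructs shorter than the window are
  kept, with their missing codons treated as `NA` and a logged count;
  codons containing ambiguity characters are skipped in all counting.
  `U` is mapped to `T` on input.
* **GC3** includes the start codon and excludes the terminal stop; the
  convention is documented rather than universal, and is applied
  consistently to both synthetic and read data.
* **Core region** for 5'-versus-core vectors is codon +12 through the
  penultimate codon (stop excluded), configurable via `coreStart`.

For ordinal translation-efficiency fractions (TEF 1–5 from sorted
libraries), `ordinalGroups()` forms 25% groups by taking the extreme
fraction(s) whole and topping up with a seeded random subsample of the
adjacent fraction; the two published media compositions are available as
`mode = "LB"` and `mode = "M9"`, and arbitrary compositions as a list.
`bootstrapLogOdds()` resamples both groups with replacement at their
original sizes to give per-codon bootstrap envelopes; subsampled nulls
(`subsampleNull()`) draw *without* replacement, since they model a smaller
library, not measurement resampling.

## Concordance between analyses

Two enrichment analyses are compared at three levels:

1. **Vector level** — Spearman correlation over pairwise-complete codons
   (`compareVectors()`), and a principal-axis (orthogonal) regression
   (`orthogonalFit()`) that treats the two datasets symmetrically, so
   swapping axes maps slope $s$ to $1/s$.
2. **Within-block level** — all 87 unordered codon pairs within
   synonymous blocks, oriented so the pair difference in the first vector
   is non-negative (`withinBlockPairs()`). This controls for the exact
   anti-symmetry of 2-fold blocks, which makes codon-level points
   non-independent.
3. **Best-codon level** — 18 amino acids x 10 positions matrices of the
   top-scoring codon (`bestCodonMatrix()`), scored cell-by-cell for
   agreement. `agreementTest()` tests each amino acid's agreement count
   against 1/degeneracy, and pools all cells into an overall exact
   binomial test whose null success probability is the trial-weighted
   mean of 1/degeneracy, with expected agreements rounded to the nearest
   integer. Two-tailed p-values use the exact minimum-likelihood
   convention of `binom.test()` (sum over outcomes no more likely than
   the observed one); this convention is what makes the published
   concordance p-values reproducible to their printed precision. The
   per-amino-acid tests default to two-sided and expose the tail as an
   argument, since the tail used for the per-row tests is not documented.

## The passenger diagnostic suite

**Focal-codon exclusion** (`focalExclusionProfile()`): for each focal
codon, over the constructs containing it, the per-construct mean of an
externally supplied reference log-odds over all *other* window codons
(every copy of the focal codon excluded), then the mean, SD and
SEM = SD/sqrt(N) of these per-construct means. N counts constructs, not
focal occurrences, to avoid pseudoreplication. The reference should come
from a library believed free of passenger effects: scoring a suspect
library with its own vector re-imports the distortion under test.

**When is the null exactly zero?** For a randomized library and a
zero-mean reference the mean of means should be zero. This holds exactly
only when flanking composition is independent of the focal codon. If
backbones draw residues *with replacement*, a construct containing focal
codon F is enriched for F's amino acid and hence for F's synonyms among
its flanks — a small passenger effect created by the randomization design
itself, which can shift the null by a few SEM at large N. The generator
therefore offers `backbone = "distinct"` (ten distinct residues per
construct, so no window holds two codons of one block), and
`nullReference()` supplies a reference centred within every synonymous
block; under that pairing the null is exact, and `nullCalibration()`
verifies it. This sensitivity of the null to backbone design is worth
bearing in mind when applying the diagnostic to real libraries whose
amino-acid composition varies between constructs.

**Co-occurrence statistics** (`cooccurrenceCounts()`): for each of the 61
sense focal codons, the observed count of every other sense codon in the
windows of focal-containing constructs, against an expected count equal
to the focal-conditioned total times the dataset-wide frequency of the
other codon among non-focal codons — 3660 observed/expected cells.
`chi2Sum()` sums $(O-E)^2/E$ (zero-expected cells are excluded with a
logged count); because the statistic is sensitive to totals, libraries
are compared through size-matched subsampled nulls (`subsampleNull()`,
`zScore()`). `perCodonDev()` gives the per-focal-codon mean of
$|O-E|/E$, largely insensitive to codon abundance. Multiple copies of a
codon in one window count multiply (occurrence-based counting; the
construct-level alternative would discard within-window dosage).

**Residual attribution** (`residualAttribution()`): ordinary least
squares of the test vector on the reference vector (asymmetric by intent:
the reference dataset predicts the test dataset), each codon's residual
read as its between-dataset disagreement, then correlated against each
library's focal-exclusion means. A positive correlation with the test
library's passenger scores, absent for the reference library's, attributes
the disagreement to the test library's construct design; the squared
correlation is reported as the fraction of disagreement explained. On
synthetic data the *reference* correlation tends to come out slightly
negative rather than zero, a mechanical coupling between the reference
profile and the reference vector through the exclusion construction; the
test-library correlation is the diagnostic quantity.

## Predictor analysis

`codonFeatures()` computes per-construct 5' features: span-level CAI (the
arithmetic mean of per-codon adaptation log odds — themselves a log-odds
analogue of the codon adaptation index, from `adaptationScores()` on
highly versus lowly expressed native gene cores — over degenerate codons
at +2..+11; non-degenerate codons are skipped rather than zero-scored, so
Met/Trp content does not dilute the average), deltaCAI (+2..+11 minus
+12..+31, `NA` below 31 codons), NGG density over the first six codons
(+2..+7), proline and positive-charge (K/R/H) densities over the first
ten, and G+C of the first 30 nt after the start.

`partialSpearman()` rank-transforms all variables, residualizes the two
variables of interest on the covariates by least squares and correlates
the residuals, with a t-approximation p-value at $n - 2 - k$ degrees of
freedom; the matrix-inversion route through the rank correlation matrix
is implemented independently in the test suite as the oracle. Each cell
of a correlation table partials out *all* remaining variables — the
all-covariate convention is an assumption, stated here because published
tables rarely document it.

`lmgImportance()` decomposes a linear model's $R^2$ into per-predictor
shares by exact enumeration of all $2^k$ predictor subsets with the
standard ordering weights $|S|!(k-|S|-1)!/k!$ (k = 8 in the motivating
model, i.e. 256 subsets; no sampling approximation). Shares sum to the
full-model $R^2$ by construction, an identity the tests assert, and
coefficients are reported for z-score-normalised predictors so signs are
comparable across predictors.

## What the generator emulates — and what it does not

`randomLibrary()` emulates a fully randomized synonymous library: ATG
plus one uniformly chosen synonymous codon per backbone residue, with
random 10-residue backbones by default. `biasedLibrary()` plants design
bias: a construct containing the focal codon has, with probability `q`,
its remaining positions redrawn from an A-ending-weighted pool, coupling
the focal codon to an A-rich context while leaving its own placement at
natural frequency. `applyExpression()` generates
$\log(\text{protein}/\text{RNA}) = \beta_A \cdot f_A - \gamma_{NGG} \cdot
n_{NGG} + \sum \text{codon effects} + \mathcal{N}(0, \sigma)$, where
$f_A$ is the A fraction of the first 30 nt after the start — the
package's composition proxy for low 5' mRNA stability (A pairs weakly, G
strongly, so A-rich 5' ends fold weakly and initiate efficiently) — and
$n_{NGG}$ counts NGG codons in the first six codons, where peptidyl-tRNA
drop-off acts. An independent lognormal RNA column makes protein,
RNA and protein-per-RNA genuinely different metrics.

Defaults, chosen once as a realistic regime: $\beta_A = 6$ (the
full observed range of $f_A$, roughly 0.1–0.5, then spans ~2.4 natural
log units, matching libraries whose output varies by orders of magnitude
with composition dominant), $\gamma_{NGG} = 0.8$ per codon (a strong,
clearly suppressive effect), $\sigma = 0.5$ (composition explains most
but not all variance). `genomeSet()` produces CDS sets with a target core
GC3 and an A/T-enriched 5' window for the cross-species analysis;
`tefBinning()` converts a continuous metric into ordinal fractions.

The generator does **not** emulate: actual RNA folding energetics
(stability enters as composition or as user-supplied precomputed
columns), FACS sorting and sequencing noise, amino-acid-level effects on
expression (the expression model sees only nucleotide and codon
composition, never the encoded peptide), plasmid copy
number, or growth-rate feedback. Passing the recovery tests therefore
shows that the *statistics* behave as designed under their stated model,
not that any particular biological claim holds in real libraries.

## The packaged experiments

`nullCalibration()` (n = 5000 constructs, 100 null replicates subsampled
from a 100,000-construct pool of the same generator) checks that on a
randomized library with sequence-independent expression, at least 95% of
codons sit within 3 SEM of zero mean-of-means and the library's
chi-squared sum falls inside the central 99% of its size-matched null.
The pool is deliberately 20x the subsample so subsamples are nearly
independent draws; subsampling a library from itself would understate
between-library variance.

`artefactRecovery()` (test library n = 10,000 at q = 0.9 with a strongly
skewed pool, A-ending weight 50; randomized reference library n = 30,000,
mirroring the asymmetry between reference and test datasets in practice;
expression +0.5 per A-ending codon, the focal codon's effect exactly
zero) reproduces the full artefact storyline in silico: the causally
neutral focal codon acquires a positive enrichment log odds whose
bootstrap 95% CI excludes zero, a focal-exclusion mean of means far
beyond 3 SEM, the top rank in per-codon co-occurrence deviation
difference against a size-matched random library, and regression
residuals predicted by the test library's passenger scores (Spearman rho
above 0.5). These problem sizes are the package's validation scale; all
statistics accept libraries of any size.

## Limitations

* The diagnostic *detects* passenger effects; it does not produce
  corrected per-codon estimates. Deconfounding would require a joint
  model of codon effects and construct composition.
* RNA secondary-structure energies are consumed, never computed; where no
  stability columns exist the A-fraction proxy stands in, which ignores
  position- and pairing-specific structure.
* The focal-exclusion null is exactly zero only under composition-
  independent randomization (see above); for real libraries the
  subsampled-null comparisons, which carry the same composition
  structure on both sides, are the safer instrument.
* Exact LMG enumeration is limited to 15 predictors ($2^{15}$ subsets);
  larger models would need the sampling approximations found in
  dedicated relative-importance packages.
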