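---
title: "Assessing genotype imputation accuracy with chance-corrected agreement"
author: "ImputeAccuracy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing genotype imputation accuracy with chance-corrected agreement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ImputeAccuracy)
```

## The problem

Genotype imputation infers untyped variants from typed markers and a
haplotype reference panel, and every downstream use of imputed data depends
on knowing how accurate that inference was.  When true genotypes are
available for comparison — typically because typed genotypes were *masked*
before imputation and held back as truth — several per-SNP statistics
compete for the job, and they do not agree.  The best known failure mode is
the concordance rate at rare variants: a caller that blindly assigns the
major homozygote to everyone is concordant with the truth for roughly
$(1-q)^2$ of individuals at minor allele frequency $q$, so at $q = 0.01$ it
scores about 0.98 while carrying no information at all.  This package
implements the chance-corrected alternative alongside the commonly used
statistics so that such divergences can be measured rather than argued
about.

## Statistics computed

All statistics operate on, per SNP, an $N \times 3$ matrix of imputed
posterior probabilities $p_{nk}$ over the genotype classes (AA, AB, BB,
with B the coded allele) and, where truth is required, a length-$N$ vector
of true calls $g_n \in \{0, 1, 2\}$.

**Probability contingency table.**  Cell $(i, j)$ of a $3 \times 3$ table
accumulates $\sum_n p_{ni}$ over individuals whose actual class is $j$.
Column totals are the actual class counts $N_1, N_2, N_3$; the grand total
is $N$.  Individuals with missing truth are excluded entirely (pairwise
deletion); nothing is ever imputed for them.

**Concordance rate** $P_o = \mathrm{tr}(T)/N$ — probability-weighted
agreement.

**Chance agreement** $P_c = \sum_i N_i R_i / N^2$ where $R_i$ is the $i$-th
row total — the agreement expected from the margins alone.

**Imputation Quality Score (IQS)** $= (P_o - P_c)/(1 - P_c)$, the Cohen's
kappa of the probability table.  1 means perfect, 0 means chance-level,
negative means worse than chance.  Because $P_o P_c \le P_c$ implies
$P_o - P_c \le P_o(1 - P_c)$, IQS can never exceed $P_o$: the package
treats this inequality as an invariant and the test suite checks it over
10,000 random tables.  When $1 - P_c$ falls below tolerance (single-class
truth) the score is undefined and reported as `NA` with a `MONOMORPHIC`
flag — made explicit rather than silently dropped, so that callers can
count what was excluded.

**Squared dosage correlation** $R^2 = 1 - SSE/SS_{yy}$ from the
least-squares regression of true dosage on expected imputed dosage
$e_n = p_{n1} + 2p_{n2}$; identical to the squared Pearson coefficient and
verified against an independent implementation at $10^{-10}$.

**Allelic R² (BEAGLE style)**, computable without truth: the squared
covariance between the best-guess genotype $z_n$ and $e_n$, divided by the
product of the variance of $z$ and the term
$\sum_n f_n - (\sum_n e_n)^2/N$, where $f_n = p_{n1} + 4p_{n2}$ is the
dosage second moment.  One published rendering of this formula prints
$\sum z_n$ where the variance form requires $\sum z_n^2$; we implement the
variance form, which is the only reading consistent with the statistic
being a squared correlation (bounded by 1, equal to 1 when every row is
degenerate).  Tiny negative numerators are clipped to 0 and the result to
$[0, 1]$.

**IMPUTE2 INFO** $= 1 - \sum_n (f_n - e_n^2) / (2N\hat\theta(1 -
\hat\theta))$ with $\hat\theta = \bar e / 2$: dosage uncertainty relative
to binomial variance at the sample allele frequency.  At most 1, possibly
negative (a uniform probability row over 3 classes gives exactly $-1/3$ at
$\hat\theta = 1/2$), undefined when $\hat\theta$ is at a boundary.

**Best-guess tie rule.**  $z_n$ is the class with the highest posterior;
on exact ties the lowest genotype index wins.  Any fixed rule works — the
choice only matters for reproducibility, and this one is deterministic and
order-free.

## MAF, LD and binning

MAF is computed from the genotyped (truth) calls, never from imputed
dosages.  Frequency classes follow the usual convention: rare means MAF
$\le$ 1%, low-frequency 1–5% (both boundaries inclusive on the left
class), common above.

LD between an imputed target and each typed SNP is the haplotype
$r^2 = D^2/(p_A p_a p_B p_b)$ with two-locus haplotype frequencies
estimated by EM from unphased genotype pairs — the convention of standard
LD software.  Only the double heterozygote has ambiguous phase; the EM
splits it between coupling and repulsion in proportion to current
estimates, starting from linkage equilibrium, stopping at
$\Delta\log L < 10^{-10}$ or 1,000 iterations.  A two-SNP EM from a
linkage-equilibrium start is deterministic, so no restarts are used.
Whether externally produced LD values were computed from phased reference
haplotypes or unphased genotypes is generally unknowable from the numbers
alone; EM-on-genotypes is our documented convention, testable against
closed-form haplotype counting on configurations free of double
heterozygotes.  `maxR2Ld` takes the maximum over a typed panel, optionally
within a base-pair window; an empty panel yields `NA` with an
`EMPTY_LD_PANEL` flag.

Bin summaries use 0.01-increment bins on either axis, half-open
$[k/100, (k+1)/100)$ with the final bin closed at the axis maximum (0.5
for MAF, 1.0 for $r^2$).  Published bin notations are often internally
inconsistent at the boundaries; we fix one convention and state it.  Bin
dispersion is the sample SD ($n - 1$ denominator); singleton bins report
SD 0 rather than `NA` so error bars degrade gracefully.

## Masking

`maskToArray` partitions a truth panel by (chromosome, position) membership
in an array manifest — matching is positional only, since rsIDs drift
across builds; allele checking happens separately at load time.
`maskRandomFraction` masks exactly `round(fraction * M)` sites uniformly at
random under a seed, the other common masking design.  Both preserve masked
truth byte-for-byte for later comparison.  Multi-allelic records and indels
are excluded at VCF load with a logged count because every formula above
assumes three genotype classes.

Allele orientation between the imputed file and the truth VCF is verified
per site: matching (REF, ALT) pairs pass; swapped pairs are column-flipped
(AA↔BB) unless the pair is strand-ambiguous (A/T or C/G), in which case the
SNP is excluded — silent strand guessing corrupts dosage orientation, and
an excluded SNP is recoverable while a mis-oriented one poisons the
results.

## The synthetic-data generator

The generator emulates the masking experiment at desk scale so that every
pipeline stage is testable without external data.  It is a model of the
*statistical character* of imputed probabilities, not of any imputation
algorithm:

* **Truth**: i.i.d. Hardy–Weinberg draws at a per-SNP MAF.  The default
  spectrum is log-uniform on $[0.001, 0.5]$, skewed toward rare variants
  the way real site-frequency spectra are, so rare bins are populated.
* **Imputer**: each individual's probability row is
  $\lambda \cdot \mathbf{1}[g_n] + (1 - \lambda) \cdot
  \mathrm{Dirichlet}(c \cdot \pi_{HWE})$ — a blend of a point mass on the
  truth (weight $\lambda$, the *fidelity*) and a chance draw centred on the
  HWE genotype frequencies with concentration $c$ (default 20, moderately
  sharp).  $\lambda = 1$ is perfect imputation; $\lambda = 0$ ("CHANCE") is
  truth-independent; "MAJOR_HOMOZYGOTE" puts all mass on AA, the caller
  that makes concordance misleading at rare SNPs.
* **Typed proxy**: each target gets one typed SNP obtained by flipping each
  of its $2n$ allele copies with probability $\varepsilon$; $\varepsilon =
  0$ gives a perfect tag, and expected $r^2$ decreases monotonically in
  $\varepsilon$.

What this emulates well: the dependence of every statistic on fidelity,
MAF and tag quality, and the rare-variant divergence between concordance
and chance-corrected agreement.  What it does not emulate: haplotype-block
structure, reference-panel size effects, and imputation error that is
correlated across individuals through shared haplotypes.  Passing tests on
synthetic data therefore validate the *statistics and the pipeline*, not
any claim about how accurately a particular program imputes real genomes.

All randomness flows from one mandatory seed; the global RNG state is
never disturbed, and two runs of any seeded entry point are byte-identical.

## Numerical choices

* Probability rows summing to 1 within $10^{-4}$ are renormalized (common
  formats round to few decimals); rows further out reject the SNP with a
  logged reason rather than being silently repaired.
* Denominators ($1 - P_c$, variance terms, $\hat\theta(1-\hat\theta)$) are
  compared against $10^{-12}$ before dividing; below that the statistic is
  `NA` with a flag, avoiding floating-point sign flips near degeneracy.
* Undefined values propagate as `NA` (rendered `NA` in TSV output), never
  as fabricated numbers, and each carries a flag naming the cause:
  `MONOMORPHIC`, `DEGENERATE_VARIANCE`, `THETA_BOUNDARY`,
  `EMPTY_LD_PANEL`.

## Pipeline semantics

`runAccuracyComparison` restricts reporting to masked, polymorphic SNPs —
monomorphic filtering happens *after* masking, on the truth calls of masked
sites, and the excluded SNPs go to a sidecar table rather than vanishing.
Samples are intersected (truth-file order); per-stage counts (read, skipped
multiallelic, orientation-flipped, monomorphic, reported) are written to a
JSON metadata file, because filter provenance is the main debugging surface
of this kind of pipeline.  When a reporting region with flanking buffers is
configured, buffer variants are excluded from reporting but remain eligible
as LD partners by default (flag-controlled): a typed SNP just outside the
reporting window is still a real tag.

## Problem sizes

The test suite and the acceptance script run entirely on synthetic data at
sizes chosen to make Monte-Carlo checks sharp while keeping a full run in
well under a minute of compute: 10,000 random tables for the kappa
inequality, 200 chance-mode SNPs at $N = 500$ for the null, 40 rare SNPs
at $N = 10{,}000$ for the rare-variant contrast, and 60 replicate SNPs per
fidelity level for the monotonicity check.  These sizes give standard
errors small enough that the qualitative claims (mean IQS at 0 under
chance, concordance minus IQS above 0.5 at rare SNPs) are resolved with
wide margins.

## Worked example

```{r example}
cfg <- SimulationConfig(nIndividuals = 300, nSnps = 8, seed = 7,
                        imputerMode = "MAJOR_HOMOZYGOTE",
                        mafRange = c(0.002, 0.01))
ds <- simulateComparisonDataset(cfg)
res <- assessPanel(ds$truth, ds$imputed)
res$records[1:4, c("snp_id", "maf", "concordance", "iqs")]
```

Concordance near 1, IQS at 0: the headline divergence, reproduced in four
lines.

## Known limitations

* Two-SNP unphased EM only; no multi-locus phasing, no $D'$.
* Biallelic SNPs only; multi-allelic sites and indels are excluded, not
  decomposed.
* The allelic-R² and INFO recomputations assume the probability matrix is
  exactly what the program emitted; heavily rounded input (2-decimal GP
  fields) shifts these statistics slightly, which is why the row-sum
  tolerance exists.
* No BCF or indexed access; files are read whole, which is appropriate for
  region-scale analyses, not genome-wide ones.
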