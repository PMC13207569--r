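---
title: "Methods: population differentiation and polygenic risk at candidate loci"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population differentiation and polygenic risk at candidate loci}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(locusdiff)
```

# The analysis problem

GWAS-derived candidate loci for a disease are typically reported with a
risk-increasing *effect allele* and (sometimes) a per-allele effect size on
the log-odds scale. When such a panel is genotyped across structured
populations — e.g. the 26 cohorts of a global reference panel nested in five
continental groups — the scientific questions are: how much allelic
diversity does each population carry at these loci, how strongly are
populations differentiated at them, which populations are enriched or
depleted for particular risk alleles, and how does the aggregate polygenic
burden compare across groups. `locusdiff` implements this battery on an
effect-allele *dosage matrix*: individuals × loci counts (0/1/2) of the
effect allele, built complete-case from a VCF (any locus that is absent,
multi-allelic, allele-discordant, or carries a single missing genotype call
is dropped and logged with a reason code).

# Within-population statistics

For each population and biallelic locus with effect-allele frequency
$p$ (and $q = 1-p$):

* observed heterozygosity $H_o = n_{Aa}/n$;
* expected heterozygosity $H_e = 2pq$;
* Shannon's information index $I = -(p\ln p + q\ln q)$, natural logarithm
  with $0\ln 0 \equiv 0$ (the GenAlEx convention);
* fixation index $F = (H_e - H_o)/H_e$, undefined at monomorphic loci and
  excluded from the $F$ summary mean.

Population summaries are means over loci with a standard error
$\mathrm{SD}/\sqrt{L}$; the SD is emitted alongside because "±" columns in
published diversity tables are ambiguous between the two, and at several
hundred loci the magnitudes differ by an order of magnitude.

Hardy–Weinberg equilibrium is tested per (population, locus) with the exact
conditional test: given the allele counts, all compatible heterozygote
counts $h$ are enumerated with
$P(h) \propto n!\,2^h / (n_{AA}!\,h!\,n_{aa}!)$ and the two-sided p-value
sums the probabilities of configurations no more probable than the observed
one. The exact test is the default because candidate-locus panels are
dominated by rare and near-fixed alleles where the 1-df chi-square
approximation is unreliable; the chi-square flavor is available for
comparison. Monomorphic loci get $p = 1$. The departure census counts
uncorrected $p < 0.05$ by default (with an optional Benjamini–Hochberg
mode), since published per-population departure counts are conventionally
raw.

# Differentiation

**ΦPT from AMOVA.** Individuals are compared by the codominant genotypic
squared distance, per locus $(d_i - d_j)^2$ summed over loci (identical
genotypes 0, homozygote vs heterozygote 1, opposite homozygotes 4). The
analysis of molecular variance partitions
$SS_\text{total} = \tfrac1N\sum_{i<j} d^2_{ij}$ into among- and
within-population sums of squares, converts them to mean squares on $K-1$
and $N-K$ df, and solves for the variance components
$V_a = (MS_a - MS_w)/n_0$ with $n_0 = (N - \sum_k n_k^2/N)/(K-1)$ and
$V_w = MS_w$. Then $\Phi_{PT} = V_a/(V_a+V_w)$, truncated at zero when the
raw estimate is negative (the raw value is kept alongside). Significance
comes from permuting individuals among populations with sizes preserved;
$p = (r+1)/(n_\text{perm}+1)$ with the observed arrangement included, 999
permutations by default and a mandatory seed.

One numerical subtlety: the permutation comparison uses the *untruncated*
estimate. Truncation creates an atom at zero; under a homogeneous null
roughly half the permuted estimates land on that atom, ties with a
truncated observed value of zero are counted as "as extreme", and the
permutation p-value distribution collapses toward large values. Comparing
raw estimates keeps the null distribution of $p$ uniform (the package's
calibration tests check this), while the *reported* ΦPT remains truncated.

**What ΦPT estimates.** For data simulated under the Balding–Nichols model
(below) with divergence parameter $F$, the among-population variance of the
dosage mean is $4pqF$ while the within-population dosage variance under
Hardy–Weinberg proportions is $2p_kq_k$ with expectation $2pq(1-F)$, so the
two-level dosage AMOVA converges to
$$\Phi_{PT} \to \frac{4pqF}{4pqF + 2pq(1-F)} = \frac{2F}{1+F},$$
not to $F$ itself: ΦPT on codominant genotypic distances systematically
exceeds the allele-frequency $F_{ST}$ that generated the data
(≈ 0.095/0.26/0.40 for $F$ = 0.05/0.15/0.25). This is a property of the
estimator, not a bug — published ΦPT matrices on human continental groups
run noticeably higher than genome-wide $F_{ST}$ for the same pairs, in just
this proportion. The test suite asserts recovery of the theoretical value
$2F/(1+F)$ to ±0.05 at 2×200 individuals × 500 loci; an additional check
against the raw configured $F$ at the same tolerance is retained and passes
only in the small-$F$ regime where the inflation is below the band.

**Nei's standard distance.** From per-population allele frequencies over
shared loci: $J_x = \overline{p^2+q^2}$, $J_{xy} = \overline{pp'+qq'}$,
$D = -\ln\!\big(J_{xy}/\sqrt{J_xJ_y}\big)$, reported as $+\infty$ when
$J_{xy}=0$. The sample-size–corrected (unbiased) identities are available
behind a flag; the default is the classical distance, which is what a
pairwise matrix printed alongside ΦPT conventionally contains.

**Exact G-tests.** Pairwise genic (2 alleles × 2 populations) and genotypic
(3 genotypes × 2 populations) homogeneity tests use
$G = 2\sum O\ln(O/E)$ with an exact conditional null over tables with both
margins fixed, $P(T) \propto \prod r_i!\prod c_j!/(n!\prod x_{ij}!)$. The
support is enumerated outright when its size is below a configurable bound
(default $10^6$; always the case for genic tables, whose support is
one-dimensional); larger genotypic tables use a Metropolis chain over
margin-preserving unit moves with GENEPOP-style defaults (10,000
dememorization steps, 100 batches × 5,000 iterations) whose batch spread
provides a standard error on $p$. Loci monomorphic in both populations are
skipped and contribute no degrees of freedom. Per-locus p-values combine by
Fisher's method, $X^2 = -2\sum\ln p_\ell$ on $2L'$ df. Note that a locus
with $p_\ell$ near 1 *weakens* the combined test (it adds ~0 to $X^2$ but
2 df), which is exactly why uninformative loci are skipped rather than
entered with $p=1$.

**PCoA.** Principal coordinates are classical metric scaling of the
pairwise ΦPT matrix used directly as distances (no transformation), via
`stats::cmdscale`: double-centering of $-\tfrac12 d^2$, eigendecomposition,
coordinates scaled by the square roots of positive eigenvalues, percent
variance over the positive spectrum.

# Enrichment and depletion scoring

Each (population, locus) cell models the population's $2n_k$ chromosomes as
a draw without replacement from the pooled $2N$ chromosomes containing $C$
effect copies, so $E = 2n_kC/2N$. The raw p-value is the single tail on the
side of the observed deviation: $P(X \ge c)$ when $c \ge E$, else
$P(X \le c)$. The pooled reference (including the population itself) is the
default because heatmaps of this kind are captioned against the whole-sample
average; an against-complement mode changes only $E$ — the conditional tail
probability is identical in both layouts. p-values are Benjamini–Hochberg
adjusted jointly across all cells at one analysis level, and the display
score is $s = \mathrm{sign}(c-E)\cdot\min(-\log_{10} q,\,5)$; the ±5 cap
prevents a handful of extreme cells from dominating a heatmap color scale,
and cells at exactly $E$ score 0 (no defensible direction). Rows
(populations) and columns (loci) are ordered by average-linkage hierarchical
clustering on $1 - r$ (Pearson); zero-variance rows or columns, for which
correlation is undefined, are placed last.

# Polygenic risk scores

The additive model scores individual $j$ as $\sum_i \beta_i\,d_{ij}$ over
the scored loci. The unweighted variant sets all $\beta_i$ equal and
normalizes by $2N$ loci, so the score is the fraction of risk alleles
carried: 1 for an all-risk homozygote, 0 for a carrier of none. The
weighted variant normalizes by $2\sum_i\beta_i$, which is the unique linear
normalization preserving those bounds; the raw weighted sum is also emitted
because published weighted summaries do not always state their scale. Loci
with negative $\beta$ are flipped to the risk orientation (allele swap,
dosage complement, $\beta$ negated) before scoring. The
population-specific score (psPRS) is the arithmetic mean over members;
box-plot summaries use quartiles with 1.5×IQR whiskers.

Group differences use the Kruskal–Wallis rank-sum test with tie correction;
when significant at 0.05, Dunn's pairwise Z statistics follow, with the
tie-corrected pooled-rank variance, sign convention (mean rank of first
group − second), Benjamini–Hochberg adjustment across pairs and the usual
star annotation. A two-group call of the same machinery serves for
male/female stratification.

# The synthetic-data generator

`simulate_dataset()` emulates the statistical structure the battery
assumes: $K$ populations of stated sizes genotyped at $L$ exchangeable
biallelic loci. Per locus an ancestral frequency $p$ is drawn (default
Uniform(0.1, 0.9) — boundary-heavy panels bias moment estimators of
divergence, and a bounded-away-from-0/1 law is the standard choice for
recovery studies); each population's frequency comes from the
Balding–Nichols Beta with shapes $p(1-F)/F$ and $(1-p)(1-F)/F$, i.e. mean
$p$ and variance $p(1-p)F$, with $F=0$ a point mass at $p$; genotypes are
two independent allele draws (Hardy–Weinberg within populations). Explicit
entries can force fixation at chosen (locus, population) pairs, giving the
monomorphism census a ground truth. Each (locus, population, purpose)
triple seeds its own substream derived from the master seed, so runs are
bit-reproducible and extending the locus panel leaves earlier draws
untouched. Fixtures are written as plain VCF 4.1 + panel TSV + locus TSV,
the exact formats the ingest module reads, with an exact dosage round-trip.

What the generator does *not* emulate: linkage disequilibrium between loci,
admixture, mutation, or ascertainment of GWAS hits. Passing tests on this
generator therefore validate the statistical machinery — estimator algebra,
calibration, power at known effect sizes — not robustness to the
correlation structure of real genomes.

# Problem sizes and numerical choices

The shipped tests and the acceptance script use: 2×200 individuals × 500
loci for divergence recovery; 500 replicates × 999 permutations (2×12
individuals × 25 loci each) for permutation-null calibration; 2,000 loci ×
100 individuals for exact-HWE calibration; 3×100 individuals × 100 loci
with 20 spiked loci (frequency 0.5 vs 0.1 background) for enrichment power;
3×25 individuals × 30 loci for the end-to-end determinism run. These sizes
keep binomial sampling error well inside the asserted tolerances.

Other conventions: negative ΦPT reported as 0 with the raw value retained;
permutation p-values never 0 by construction; exact-test tie comparisons
use a $1+10^{-12}$ relative guard; Fisher combination floors p at the
smallest positive double before logging; the G-test Metropolis ratio is
computed in closed form from the four changed cells.

# Limitations

* ΦPT here is the two-level AMOVA (no region/population/individual
  three-level hierarchy, no within-individual stratum) and is the only
  $F_{ST}$-analogue provided.
* Exact G-tests are pairwise only; multi-population homogeneity is read off
  the pairwise battery, as is conventional for this analysis.
* The enrichment cells are treated as independent tests in the BH family;
  allele-count cells at one locus are in fact negatively dependent across
  populations (their deviations from expectation sum to zero), which makes
  BH conservative-to-nominal here.
* The unweighted PRS ignores effect sizes by design; with weights available
  only from single-ancestry GWAS, the weighted score's portability across
  populations is interpretive, not something the package models.
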