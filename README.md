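# locusdiff

Population-genetic analysis of a panel of candidate disease loci genotyped
across structured populations — the kind of question raised when GWAS hits
for a disease are examined in a global reference panel such as the 1000
Genomes cohorts (26 subpopulations nested in 5 continental
superpopulations): how diverse is each population at the risk loci, how
strongly are populations differentiated there, which populations are
enriched or depleted for particular effect alleles, and how does the
aggregate polygenic burden compare across groups.

The package takes three inputs — a locus table (rsid, position, effect and
other allele, optional effect size β), diploid genotypes in VCF, and a
sample panel mapping sample → subpopulation → superpopulation → sex — and
builds a complete-case effect-allele **dosage matrix** (0/1/2 per
individual and locus; loci that are absent, multi-allelic, allele-discordant
or contain any missing call are dropped with logged reasons). On it, the
battery computes:

* **Within-population statistics** — allele frequencies, a monomorphism
  census, exact (and chi-square) Hardy–Weinberg tests, and the diversity
  summary *H*ₒ, *H*ₑ = 2pq, Shannon's *I* = −(p ln p + q ln q), and the
  fixation index *F* = (*H*ₑ − *H*ₒ)/*H*ₑ, with mean ± SE over loci.
* **Differentiation** — Φ_PT = V_a/(V_a+V_w) from an AMOVA on codominant
  genotypic distances, with label-permutation significance; Nei's standard
  genetic distance D = −ln(J_xy/√(J_x J_y)); exact G-tests of genic and
  genotypic differentiation (full enumeration or a Markov chain over tables
  with fixed margins) combined across loci by Fisher's method; and PCoA of
  the pairwise Φ_PT matrix.
* **Enrichment scoring** — per population × locus, a hypergeometric tail
  against the pooled-sample expectation, BH-FDR adjusted, reported as
  signed scores sign(c−E)·min(−log₁₀ q, 5) with correlation-based
  average-linkage row/column orders for heatmap export.
* **Polygenic risk** — PRS = Σᵢ βᵢ·SNPᵢ under the additive dosage model,
  in an unweighted form bounded on [0,1] (score 1 = risk-homozygous
  everywhere) and a weighted form normalized by 2Σβ; population-specific
  psPRS summaries and Kruskal–Wallis → Dunn → Benjamini–Hochberg group
  comparison.
* **Synthetic data** — a Balding–Nichols simulator (population frequencies
  Beta-distributed around an ancestral draw with variance p(1−p)·F_ST,
  Hardy–Weinberg genotypes, optional forced fixation, per-locus seeded
  substreams) that writes VCF/panel/locus fixtures with an exact
  round-trip, so the entire pipeline is testable without any download.

See the methods vignette (`vignettes/locusdiff-methods.Rmd`) for the
statistical details, including what Φ_PT on dosage distances converges to
under the Balding–Nichols model.

## Worked example

Three simulated populations of 60 individuals at 120 loci, one population
(POP1) strongly diverged (F_ST 0.25 vs 0.05):

```r
library(locusdiff)
cfg <- sim_config(n_pops = 3, pop_sizes = 60, n_loci = 120,
                  fst = c(0.25, 0.05, 0.05), seed = 7)
ds  <- simulate_dataset(cfg)

diversity(ds$dosage, "subpop")$summary
#>   Ho_mean  Ho_se He_mean  He_se I_mean   I_se  F_mean   F_se  pop
#> 1  0.2931 0.0151  0.2944 0.0148 0.4487 0.0194  0.0000 0.0115 POP1
#> 2  0.3811 0.0130  0.3703 0.0118 0.5474 0.0141 -0.0293 0.0113 POP2
#> 3  0.3833 0.0121  0.3815 0.0110 0.5613 0.0130 -0.0053 0.0115 POP3
```

The diverged population is the least diverse, and inbreeding coefficients
hover around zero, as they must for Hardy–Weinberg genotypes. The combined
differentiation matrix (Φ_PT below the diagonal, Nei's D above):

```r
dmx <- differentiation_matrix(ds$dosage, "subpop", n_perm = 999, seed = 99)
round(dmx$combined, 4)
#>        POP1   POP2   POP3
#> POP1 0.0000 0.0930 0.0927
#> POP2 0.2566 0.0000 0.0323
#> POP3 0.2494 0.0818 0.0000
```

All pairwise Φ_PT permutation p-values are 0.001 at 999 permutations. PCoA
of the Φ_PT matrix puts 92.6% of the variance on axis 1, with POP1 alone at
one end (0.167 vs −0.087/−0.079) — the diverged group dominates the primary
axis. The unweighted risk scores:

```r
prs <- compute_prs(ds$dosage, ds$loci)
compare_groups(prs, "subpop")
#> KW H = 7.258, df = 2, p = 0.0265
#>  group1 group2      Z p_unadj  p_adj stars
#>    POP1   POP2 -1.750 0.08080 0.1210    ns
#>    POP1   POP3 -2.650 0.00805 0.0242     *
#>    POP2   POP3 -0.904 0.36600 0.3660    ns
```

psPRS means are 0.477/0.484/0.489: the Kruskal–Wallis test detects the
shift, and Dunn's test (BH-adjusted) localizes it to the POP1–POP3 pair.

A full run from one config — ingest or simulate, population statistics,
differentiation, enrichment, risk scores, every table as TSV plus a
`manifest.json` of md5-hashed outputs — is:

```r
run_pipeline(run_config(simulation = cfg, levels = "subpop",
                        n_perm = 999, seed = 7), "out/")
```

Reruns with the same seeds reproduce every output byte for byte. Real data
go through the same entry point with
`run_config(input = list(vcf = ..., panel = ..., loci = ...))`; the panel
uses the 1000 Genomes `.panel` dialect (`sample`, `pop`, `super_pop`,
`gender`).

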