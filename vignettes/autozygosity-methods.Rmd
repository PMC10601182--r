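---
title: "Assessing autozygosity in small, shallow-pedigree populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing autozygosity in small, shallow-pedigree populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(autozyg)
```

## The problem

In very small livestock populations under conservation management — a
handful of founders, a few discrete generations, large full-sib families,
and a breeding policy that forbids matings between close relatives —
pedigree-based inbreeding ($F$) and SNP-based homozygosity diverge for
well-understood reasons: Mendelian sampling, identity-by-state (IBS)
homozygosity that is not identity-by-descent (IBD), between-chromosome
variance in IBD sharing, and the arbitrariness of the base population (BP)
against which "zero inbreeding" is defined. `autozyg` implements a
complete, testable pipeline for confronting genealogical and genomic
measures of autozygosity in exactly this setting.

## Genealogical layer

Inbreeding coefficients are computed with the Meuwissen–Luo
within-individual accumulation algorithm; coancestries come from the
tabular relationship matrix ($C_{ij} = A_{ij}/2$; self-coancestry
$(1+F_i)/2$). Pedigree depth is summarised by the fully traced generations
$G$ and the equivalent discrete generations
$t = \sum_{\text{known ancestors}} (1/2)^n$. Rates of loss are

* individual increase in inbreeding
  $\Delta F_i = 1 - \sqrt[t_i - 1]{1 - F_i}$, undefined at $t \le 1$
  (the exponent is singular; such individuals are excluded from cohort
  means rather than zero-filled, which would bias $N_e$ upward),
* increase in pairwise coancestry
  $\Delta C_{ij} = 1 - \sqrt[(t_i + t_j)/2]{1 - C_{ij}}$,

with realized effective sizes $N_{e,F_i} = 1/(2\overline{\Delta F_i})$ and
$N_{e,C_{ij}} = 1/(2\overline{\Delta C})$. For $N_{e,C_{ij}}$ all unordered
within-cohort pairs are used (self-pairs excluded); the averaging set was
an open choice and all-pairs is the natural reading of a pairwise mean.
A cohort whose members are all non-inbred has $\overline{\Delta F_i} = 0$;
its $N_e$ is reported as infinite (no measurable loss), never negative.

Founders are individuals with both parents unknown; an individual with one
known parent contributes that side only to $t$ (standard
Maignel–Boichard accounting, `G = 0` in that case since the ancestry is
not fully traced).

## Run detection (ROH and HRR)

Runs are detected per chromosome by a consecutive-runs criterion. A
conforming window starts and ends on a SNP supporting the run state
(homozygous for ROH, heterozygous for heterozygosity-rich regions),
contains at most `max_opposite` opposite-state and `max_missing` missing
calls, and never spans a gap larger than `max_gap_bp` between consecutive
SNPs (the gap closes the run; treating the gap rule as merely splitting
candidates would silently join stretches across SNP deserts, so the
closing interpretation is used). `detect_runs` emits **all maximal**
conforming windows and then filters on `min_snps` and `min_length_bp`.
Defaults (ROH 20/5/5/1 kb/1 Mb; HRR 10/5/5/1 kb/1 Mb) are the standard
consecutive-runs settings for a high-density porcine array.

Two design points deserve emphasis:

* *Maximality rather than greedy scanning.* A left-to-right greedy scan
  closes a run when a budget is exceeded and restarts after it; the
  restarted run can often be extended leftwards, so greedy output is not a
  set of maximal windows and depends on scan direction. Enumerating
  maximal windows is direction-free and matches an exhaustive-window
  definition that can be checked by brute force. When the opposite-state
  budget binds on both sides two maximal runs may overlap; coverage-based
  quantities therefore always measure the **union** of an individual's
  segments, so no base pair is counted twice.
* *Coordinates.* A run spans the bp positions of its first and last SNP,
  1-based inclusive, and `length = end - start + 1`; BED export converts
  to 0-based half-open. Monomorphic SNPs participate in run detection
  (arrays carry a large monomorphic fraction and those sites are still
  informative about homozygous stretches) but are excluded from the
  frequency-based estimators below.

Population-level ROH/HRR regions are the sweep-line union of segments
across individuals, scored by the number of distinct contributing
individuals.

## The four homozygosity estimators

For individual $i$, with $L_{AUTO}$ the autosomal genome length:

* $F_{ROH} = \sum L_{ROH}/L_{AUTO}$ and
  $F_{HRR} = 1 - \sum L_{HRR}/L_{AUTO}$. $L_{AUTO}$ defaults to the
  marker-map span per autosome (last SNP − first SNP + 1, summed), which
  makes the estimators self-contained in the data and lets full coverage
  reach exactly 1; an assembly-length override is available.
* $F_{LH} = \dfrac{S\,F_{NEJ} - \sum_k [1 - 2p_{k(0)}(1 - p_{k(0)})]}
  {S - \sum_k [1 - 2p_{k(0)}(1 - p_{k(0)})]}$, the Li–Horvitz deviation of
  observed homozygosity from the BP Hardy–Weinberg expectation, with
  $F_{NEJ}$ the homozygous fraction of the $S$ usable loci.
* $F_{YAN} = \dfrac{1}{S}\sum_k
  \dfrac{x_k^2 - (1 + 2p_{k(0)})x_k + 2p_{k(0)}^2}
  {2p_{k(0)}(1 - p_{k(0)})}$, the Yang correlation between uniting
  gametes, which up-weights homozygosity for rare alleles.

$p_{k(0)}$ is the reference-allele frequency counted over the BP members
(missing genotypes excluded per SNP). SNPs monomorphic in the BP are
excluded from $F_{LH}$ and $F_{YAN}$ (the Yang denominator is singular
there); loci missing in the individual are removed from both $S$ and
$F_{NEJ}$. A polymorphic-only $F_{NEJ}$ is the default; an
`include_monomorphic_bp` switch restores the all-SNP convention, since
either reading is defensible.

## Adjustment: BP centring and jackknifing over autosomes

Raw estimators live on different scales, so two consecutive adjustments
are applied. First the Powell-style BP adjustment
$F_{ia} = (F_i - F_{BP})/(1 - F_{BP})$, genome-wide with the genome-wide
BP mean. Second, the same adjustment per autosome with *that autosome's
own* BP mean, followed by a delete-one jackknife over autosomes: with
$\hat\theta$ the mean of the $n$ per-autosome adjusted values and
$\hat\theta_{(-c)}$ the mean leaving autosome $c$ out, pseudo-values
$n\hat\theta - (n-1)\hat\theta_{(-c)}$ give the estimate (their mean) and
a standard error (from their variance). The pseudo-value (Quenouille/
Tukey) form was chosen because the underlying reference procedure is not
spelled out anywhere reproducible; it reduces to the plain mean in the
unweighted case and degrades gracefully when chromosomes drop out. A
weighted variant (SNP counts or lengths) is available behind a flag.
Negative adjusted values are retained — their frequency is itself a
result, not an artefact to truncate.

## Increases in homozygosity and genomic $N_e$

Two per-individual rates are derived from adjusted values:

* $\Delta t F_i = 1 - \sqrt[t]{1 - F_i}$ — note the exponent $1/t$, not
  $1/(t-1)$: a genomic estimate already deviates from the BP in the first
  generation, so the full depth is the time scale. Consequently
  $\Delta t F < \Delta F_i$ for equal $F$, and genomic $N_e$ runs higher
  than its genealogical counterpart.
* $\Delta p F_{ijk} = \dfrac{F_i - \frac12(F_j + F_k)}
  {1 - \frac12(F_j + F_k)}$ — the offspring's excess over its parents'
  mean, rescaled by the parents' remaining heterozygosity. Individuals
  with a non-genotyped parent are excluded from cohort means (imputation
  would manufacture information).

Cohort-level $N_e = 1/(2 \cdot \text{mean rate})$ for every estimator ×
basis (BP-adjusted / jackknifed) × approach (individual / pairwise), and
each genomic series is compared with each genealogical reference via
$\mathrm{RMSE} = \sqrt{\sum (N_e - \bar N_e)^2 / n}$ across the cohorts.

## The synthetic-data generator

`sim_config()` defaults emulate the population the pipeline is designed
for: 6 founders, 4 discrete generations, an initial phase of full-sib
matings followed by strict avoidance of pairs with coancestry
$\ge 0.125$, litter counts `c(12, 20, 30, 33)` with litter sizes
$1 + \mathrm{NegBin}(\mu = 4.6, k = 2)$ (≈ 95 litters and ≈ 530
genotyped offspring, family sizes reaching the mid-thirties), 18 autosomes
of 1 Morgan / 100 Mb carrying 400 SNPs each (7,200 markers — an
array-like density scaled to a size that keeps a full pipeline run in
seconds), founder reference-allele frequencies from Beta(0.8, 0.8) with
30% of sites forced monomorphic (an array-like site-frequency spectrum),
and 1% missing genotypes. Gene dropping uses Haldane recombination
(Poisson crossover count in map length, uniform placement, no
interference; the map function is pluggable) and labels every founder
haplotype, so each individual's realized IBD fraction is recorded
*exactly*, genome-wide and per autosome. That truth table is the recovery
target for the whole downstream pipeline.

What the generator does **not** emulate: genotyping error and null
alleles (so the Mendelian filter is exercised by construction rather than
by realistic error rates), linkage-disequilibrium structure inherited
from an ancestral population (founder haplotypes are in linkage
equilibrium), selection, mutation, and the X chromosome. Passing tests
therefore demonstrate internal consistency and parameter recovery under
the stated model, not robustness to array artefacts.

## Parameter-recovery design

The recovery experiment mates 30 independent founder pairs, crosses one
full-sib pair per family, and genotypes ≈ 510 offspring with pedigree
$F = 0.25$, using all 60 founders as the BP over ≥ 5,000 polymorphic
SNPs. Two quantitative cautions informed this design:

* With a BP of $N$ founders, the finite-sample heterozygosity excess
  biases $E[F_{LH}]$ to approximately $0.25 - 0.75/(2N - 1)$; at $N = 60$
  the bias (≈ 0.006) is well inside the Monte-Carlo band. A very small
  BP (e.g. a single founder pair) would drive $F_{LH}$ toward 0 — worth
  remembering when interpreting BP-referenced estimators in real data.
* Coverage estimators have a density-limited resolution: an ROH needs 20
  SNPs, so IBD tracts shorter than the implied physical span are
  invisible, while IBS background inflates coverage. BP adjustment
  removes the background to first order and the residual error shrinks
  with marker density; the tests assert exactly that (error at 800
  SNPs/autosome below the error at 300, and within 0.1 of the realized
  IBD mean), rather than pretending segment-based estimators are exact.

Standard errors for clustered quantities (full-sib families share
grandparents) are computed over family means.

## Numerical choices and degenerate inputs

* Unknown parents enter the Meuwissen–Luo recursion with $F = -1$, giving
  founders the correct Mendelian-sampling variance of 1.
* `delta_F_individual`, `delta_t_homozygosity`, `delta_C_pairwise` and
  `delta_p_homozygosity` return `NA` (never an error) outside their
  domains; cohort means skip `NA`s and report the count used.
* A non-positive mean rate yields `Inf` $N_e$; RMSE rows are only formed
  from cohorts where every term is finite.
* The jackknife drops undefined chromosome values with a warning and
  requires at least two; with all values equal its SE is exactly 0.
* PED import recodes to counts of the lexicographically smaller allele
  label, making the coding reproducible across imports; `F_LH` is
  invariant under label flips and the run detectors are invariant under
  0↔2 swaps, which the tests assert.
* Pedigree tables are topologically sorted at construction; cycles are
  fatal with an explicit offending chain.

## Known limitations

* The pedigree-kinship matrix is dense ($O(n^2)$ memory): comfortable to
  a few thousand individuals, not for national herdbooks.
* Run detection reports maximal windows; tools using greedy consecutive
  scans can split or trim runs differently near budget boundaries, so
  segment counts are not expected to match such tools SNP-for-SNP even at
  identical parameter values (coverage fractions agree closely).
* $L_{AUTO}$ from map span slightly shortens chromosomes relative to
  assembly lengths; both conventions are supported, and comparisons
  across datasets should fix one.
* The replay path trusts deposited per-individual values; it validates
  column presence, not their provenance.
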