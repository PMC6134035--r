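---
title: "Models and methods behind fragdiv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind fragdiv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fragdiv)
```

`fragdiv` implements the population-genetic toolchain used to ask whether a
fragmented tree population still holds the genetic diversity of its
continuous counterpart: mining microsatellites from RAD reads, standard
diversity and differentiation statistics, a likelihood-based per-population
F, linkage-disequilibrium effective sizes, and coalescent ABC over competing
demographic histories. This vignette describes the models, the defaults, and
the choices made where the design was genuinely open.

## The data model

All statistics consume a `genotype_matrix`: unordered diploid integer allele
calls per individual and locus, with individuals mapped to populations and
populations to regions. Allele codes are dense positive integers; original
file labels are kept alongside so that fragment lengths remain recoverable
for length-coded microsatellites. The `marker_kind` tag distinguishes three
marker semantics:

* `ssr_length` — classical microsatellites; the allele code maps to a
  fragment length or repeat count, so allele-size statistics are meaningful;
* `ssr_id` — RAD-mined microsatellites whose alleles are full read
  sequences coded as arbitrary integers. Two alleles of equal length but
  different sequence get different codes, which is the whole point of the
  marker type; conversely, length- or size-based statistics are forbidden
  and `allele_sizes()` refuses these loci;
* `snp` — biallelic markers, split in this study design into transition and
  transversion panels that differ in mutation rate and locus count.

## RAD-SSR calling

`find_dinucleotide_loci()` scans catalog consensus sequences for perfect
tandem di-nucleotide repeats (two distinct bases, at least 5 repeats by
default — interrupted repeats are deliberately not detected, since any
mismatch tolerance would need a threshold the marker definition does not
provide) and keeps loci present in strictly more than 50 individuals.
`call_genotype()` applies the depth rules in a fixed order: sequences with
fewer than 3 identical reads are discarded first; if fewer than 10 reads
survive, the call is missing; one surviving sequence is a homozygote; a
second becomes the other allele of a heterozygote only when its count
exceeds 10% of the bundle's total (pre-filter) read count. The order of
those two rules, and the denominator of the fraction test, are genuine
free choices; the implementation fixes both (support filter first,
pre-filter denominator) so that a 2-read contaminant can never rescue
itself through the fraction rule. When more than two sequences qualify, the
two highest-count sequences are taken with lexicographic tie-breaks and
the call is flagged — deterministic behaviour was preferred over erroring
on real (messy) data. Loci with more than 40 distinct diploid genotypes
are dropped as likely error accumulations; an option counts distinct
alleles instead, since either reading of "unique genotypes" is defensible.

## Diversity and differentiation

Rarefied allelic richness is the exact hypergeometric expectation
$\sum_i [1 - \binom{N-N_i}{g}/\binom{N}{g}]$, evaluated with log-binomials.
The rarefaction standard is 40 gene copies (20 diploid individuals) to
match the reporting convention of the study design; populations with fewer
copies at a locus contribute no value rather than a biased one. Expected
heterozygosity is Nei's unbiased $\frac{n}{n-1}(1-\sum p_i^2)$ in gene
copies; per-population values average over loci without weighting (the
conventional choice; locus weighting only matters under heavy
missingness). $F_{IS} = 1 - H_{obs}/\hat H_e$ per locus, averaged with
weights equal to the number of genotyped individuals. Region summaries
exclude populations with fewer than five individuals, because one or two
exhaustively sampled remnant plants say nothing stable about
within-population diversity.

$F_{ST}$ is Weir & Cockerham's $\theta$ with variance components summed
over alleles and loci (ratio of sums). Loci are screened before
estimation: at most 25% missing data, pooled minor-allele frequency above
0.05 (pooled over the scope being analysed — the common convention — with
per-population MAF available by subsetting first), and optionally data in
every population. Negative estimates are retained everywhere except when
linearized: $M = (1-F_{ST})/F_{ST}$ maps non-positive values to $+\infty$
with a warning, and isolation-by-distance tests drop such pairs. The
permutation test shuffles individuals across populations; it defaults to
off because a 10,000-iteration test per pair makes a 29-population matrix
needlessly slow in exploratory use — pass `n_perm = 10000` to reproduce
the survey convention. Mantel tests correlate the upper triangles, log
distance by default, with one-sided p-values
$(1 + \#\{r_{perm} \ge r_{obs}\})/(1+n_{perm})$; an exhaustive mode
enumerates all $n!$ relabellings for small population sets. Great-circle
distances use the haversine formula on a 6371-km sphere.

## Maximum-likelihood local F

The per-population divergence estimate models the focal population's
allele frequencies as Dirichlet around the regional mean $\pi$ with
parameters $\pi_i(1-F)/F$, so that $E[p_i] = \pi_i$ and
$\mathrm{Var}[p_i] = F\,\pi_i(1-\pi_i)$. Integrating the frequencies out,
a focal sample of $n$ gene copies with counts $n_i$ contributes
$$\ln\Gamma(A) - \ln\Gamma(A+n) + \sum_i [\ln\Gamma(\alpha_i + n_i) -
\ln\Gamma(\alpha_i)], \qquad A = \tfrac{1-F}{F},\; \alpha_i = \pi_i A,$$
summed over loci and maximized over $F$ by a 200-point log-spaced grid
followed by golden-section refinement to $10^{-6}$. The grid stage guards
against plateaus; in every case examined the likelihood was unimodal in
$F$. Two open choices are fixed as defaults and exposed as options: the
regional mean pools gene copies (rather than averaging population
frequency vectors), and the focal population is included in its own
regional mean — the literal reading of "relative to the regional mean" —
with exclusion available for sensitivity analysis. Loci monomorphic in
the region carry no information and are skipped; a focal allele absent
from the regional mean would make the likelihood undefined, so its
frequency is floored at $1/(2N_{region}+k)$, the smallest defensible
pseudo-count. The synthetic generator `simulate_balding_nichols()` is the
exact forward direction of this model, which makes parameter-recovery
tests self-consistent: with known $\pi$, 500 biallelic loci and 30
individuals, the estimator recovers $F = 0.10$ within $\pm 0.02$ in well
over 90% of replicates. The single-individual variant re-estimates each
population from one individual's two gene copies to show that small-sample
artifacts do not drive the pattern.

## LD-based effective size

Burrows' composite disequilibrium needs no phase:
$\hat\Delta = \frac{1}{n}\sum_i X_iY_i/2 - 2\hat p_A\hat p_B$ on allele
dosages, squared and normalized by allele variances including the
homozygote-excess terms $D_A = P_{AA} - p_A^2$. The plain moment form of
$\hat\Delta$ is used (no small-sample multiplier), which is the form the
published sampling-expectation weights were fitted against; on
independent loci the mean $\hat r^2$ matches $1/S + 3.19/S^2$ (for
harmonic-mean sample size $S \ge 30$; $0.0018 + 0.907/S + 4.44/S^2$
below, with the boundary $S = 30$ on the large-sample branch) to within
the few-percent accuracy of that empirical fit. The drift signal
$r^2{}' = \bar r^2 - E(r^2_S)$ inverts to
$\hat N_e = (1/3 + \sqrt{1/9 - 2.76\,r^2{}'})/(2 r^2{}')$ (0.308 and 2.08
for $S < 30$); non-positive $r^2{}'$ returns $+\infty$, honestly reporting
"no drift signal" rather than a huge number. Multi-allelic loci are
decomposed into allele-vs-rest dosages with a within-population MAF
screen of 0.02 (the cited tool's common setting; the survey's own cutoff
is not recorded); the allele-vs-rest comparisons retained after the
screen enter a pair's $r^2$ with equal weight. The forward Wright-Fisher
simulator provides ground truth: unlinked loci in a closed
random-mating population of known size develop exactly the drift LD the
estimator reads, and at $N_e = 50$, $S = 50$, 200 loci the median
estimate over 20 replicates falls well inside [33, 75]. On
Balding-Nichols output, which contains no drift LD by construction, the
estimator correctly returns predominantly infinite sizes.

## Coalescent scenarios and ABC

The simulator runs a Kingman coalescent per unlinked locus over
piecewise-constant diploid sizes with pure divergence (no migration, as
in the scenario trees being compared): lineages coalesce within demes at
rate $\binom{k}{2}/2N(t)$ per generation; at $t_1$ all focal populations
merge into an ancestral focal population; at $t_2$ the focal and
out-group lineages merge, and the ancestral population persists at the
out-group size — the scenario parameterization has no separate ancestral
size, so some choice is forced and this one is overridable. Scenario 1
puts the bottleneck after divergence (focal populations at historic size
`ne_br` until a shared recent drop at `tb1`), scenario 1b gives each
population its own current size (optionally with census-centered priors),
and scenario 2 puts the bottleneck at colonization with no later event.
Microsatellites mutate under the symmetric single-step model; each
mutation also mints a fresh sequence identity, so the same locus yields
length-coded and identity-coded alleles whose homoplasy differs exactly
as it should. SNPs carry one mutation placed uniformly on the genealogy
and are conditioned on sample polymorphism, emulating RAD SNP
ascertainment; the transition and transversion panels differ only in
locus count under this fixed-polymorphism scheme. Two analytic checks
pin the simulator down: mean pairwise coalescence times of $2N$
generations, and stepwise-mutation equilibrium heterozygosity
$1 - 1/\sqrt{1+8N\mu}$ (0.667 at $8N\mu = 8$).

ABC follows the rejection-plus-regression recipe: statistics are
standardized by median absolute deviation, the nearest 1% retained,
scenario posteriors come from multinomial logistic regression evaluated
at the observed vector (falling back to retained proportions when the
regression degenerates), and parameter posteriors from local-linear
adjustment with Epanechnikov weights, clipped to the prior support, with
the peak and 0.05–0.95 interval reported and prior-boundary peaks
flagged. Posteriors from independent marker sets are combined by
multiplying kernel densities on a shared grid and renormalizing. The
default summary set — mean alleles per locus, mean expected
heterozygosity, global $\theta$, between-region $\theta$, and (for
length-coded SSRs only) mean allele-size variance — is a standard
DIYABC-style selection compatible with the constraint that identity-coded
markers admit no length statistics; the exact per-marker statistic lists
and priors of the original analysis live in supplementary material that
is not reproduced here, so the defaults are documented as defaults, not
as reproductions. Default priors bracket the reported posterior
intervals: historic sizes uniform on [1000, 10000], $t_2$ on [100, 2000],
$t_1$ and $t_{b1}$ on [10, 1000] drawn conditionally so
$t_{b1} \le t_1 \le t_2$, current sizes log-uniform on [50, 2000], SSR
mutation rate log-uniform on $[10^{-4}, 10^{-3}]$.

## Problem sizes and what the tests show

The validation experiments run at desk scale, chosen so the whole suite
completes in minutes while leaving each check statistically sharp: 5,000
simulations per scenario and 20 pseudo-observed datasets for scenario
recovery (the original analysis used $10^6$ and 1,000), four focal
populations of five diploids with an eight-diploid out-group, 15
microsatellite loci per simulated dataset, 2,000 loci for the
mutation-equilibrium check, and 10,000 replicate genealogies for the
coalescence-time check. At this scale scenario 1 wins against scenario 2
in well over 70% of pseudo-observed replicates and the NeBr 0.05–0.95
interval covers the generating value in over 80% — with ~50 retained
simulations the regression-adjusted intervals are diffuse, which is the
honest behaviour at this reference-table size.

The synthetic study fixture mirrors the sampling design the statistics
assume: 29 fragmented-region and 10 continuous-region populations,
including exhaustively sampled remnants of one or two plants that
exercise the five-individual exclusion rule; census categories spanning
1–10 to 1000–10,000; divergence F tied to census size
($F = \min(0.4,\, F_0 (1000/\mathrm{census})^{1/4})$ with $F_0$ = 0.08
fragmented, 0.02 continuous, so that small fragments drift harder, as
the study found); and RAD marker sets restricted to a six-individual
subset per population. Read bundles default to 25 of the identity-coded
loci — bundles dominate fixture bulk and more add nothing to coverage.
What the fixture does *not* emulate: null alleles, genotyping error in
the PCR markers, linked loci, migration after divergence, and selection;
passing tests therefore validate the estimators under their own model
assumptions, not robustness to those violations.

## Numerical notes and limitations

Exact rational arithmetic is avoided in favour of log-space binomials and
log-gamma throughout; rarefaction agrees with exhaustive enumeration to
$10^{-10}$ on every configuration up to 12 gene copies. Dirichlet draws
at very small $\alpha$ can underflow to an all-zero gamma vector; the
generator falls back to the mean frequencies in that measure-zero case.
The $F$ search returns a boundary flag instead of silently clamping.
Monomorphic loci return $H_e = 0$, undefined $F_{IS}$, and are skipped by
the likelihood and LD machinery with explicit reason codes. Repeat
counts reflect at two units to keep stepwise mutation away from
non-physical lengths; the root state (100 repeats) is arbitrary and
cancels from all identity-by-state comparisons. Known limitations: no
migration or recombination in the coalescent, no null-allele
co-estimation, no HWE tests or selection scans, and the ABC machinery
implements rejection/regression only — sequential and random-forest
variants are out of scope.
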