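---
title: "Methods: SNP panel density, genomic relationships and Gibbs GBLUP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SNP panel density, genomic relationships and Gibbs GBLUP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`snpladder` studies a practical question in genomic evaluation: when a
breed's effective population size (Ne) is small and linkage disequilibrium
(LD) is correspondingly long-ranged, how few equally-spaced SNPs suffice to
reconstruct the genomic relationship matrix, the genetic variance, and
genomic breeding values (GEBVs) that a full chip would give? This vignette
records the models, the default parameters and the design decisions, so
that results produced by the package can be interpreted — and so the limits
of what its synthetic data can show are explicit.

## The synthetic population

Real small-Ne cattle cohorts are rarely shareable, so every analysis stage
runs on data from the package's own generator.

**Forward Wright–Fisher simulation.** `simulate_haplotypes()` evolves
`2 * Ne` haplotypes per generation by random-mating resampling. Crossovers
follow a Haldane (Poisson) process at 1 cM/Mb; mutation flips an allele
with probability `mutation_rate` per locus and gamete. Founder allele
frequencies are drawn uniformly on (0.1, 0.9). Marker positions are uniform
along each chromosome, apportioned to chromosomes by physical length.

Defaults: 29 autosomes of 86 Mb (a 2.5 Gb genome), 40,000 markers,
`Ne = 30`, 100 generations, mutation rate `1e-3`. `Ne = 30` matches the
effective size reported for closed beef breeds such as Japanese Black and
is what produces the elevated long-range LD the package is about. The
generation count and mutation rate were chosen together: around 100
generations of drift at Ne = 30 are needed before mean adjacent-pair r²
decays monotonically across the 0–0.1 / 0.1–0.2 / 0.2–0.5 / 0.5–1 Mb
distance bins (shorter histories give strong but distance-flat LD), while
the allele-flip mutation keeps a steady supply of segregating markers
against drift. Under these defaults roughly half to two thirds of markers
remain polymorphic at MAF > 0.01; the rest are removed by the QC stage,
exactly as fixed markers on a real chip would be, and `n_markers_total` can
simply be raised when a target post-QC count is needed. A higher
polymorphism rate is not attainable under a constant-Ne = 30 design at
realistic mutation rates — drift at that size fixes alleles faster than any
plausible flip rate restores them — and we prefer honouring Ne = 30 over
inflating mutation to unrealistic levels.

**Cohort sampling and polarization.** `sample_genotypes()` builds each
diploid individual from two haplotypes drawn without replacement from the
final generation; different individuals reuse haplotypes, as in a truly
small population. Dosages are polarized once, on the sampled cohort, so
every column counts the minor allele (frequency at most 0.5); marker
subsets taken later inherit that polarization.

**Traits.** `simulate_phenotypes()` is the data-generating twin of the
analysis model `y = Xb + g + e`. True breeding values are
`g_i = sum_j a_j (dosage_ij - 2 p_j)` over a QTL set from
`assign_qtl_effects()`. Two preset architectures bracket the cases of
interest: a carcass-weight-like trait with 3 large-effect QTLs on a
polygenic background (about half the genetic variance from the 3 QTLs at
the default effect SDs), and a marbling-like trait with only small-effect
QTLs. The residual variance is set so that the realized sample
heritability equals `target_h2` exactly; defaults for the two traits are
0.54 and 0.68. Fixed effects: 2 markets, 10 years (the market-year class
count is configurable; records pooled across two wholesale markets over a
decade motivate the default), and linear plus quadratic age at slaughter
drawn uniformly on 15.3–43.0 months. Effect magnitudes default to fractions
of the phenotypic SD (market 0.5, year 0.3) so they are visible but do not
dominate.

**Ordinal scores.** A 12-category marbling-like score is produced by
cutting the liability at 11 thresholds (`marbling_thresholds()`), with
category probabilities chosen to give the right-heavy, mildly bimodal
distribution typical of graded carcass data; the probabilities are
configuration, not dogma. A liability exactly equal to a threshold goes to
the upper category — one convention had to be picked and this one keeps
`score = 1 + findInterval(liability, tau)`.

## Quality control

`apply_filters()` retains markers with a defined map position, call rate
strictly above 0.95, MAF strictly above 0.01, and an exact Hardy–Weinberg
test p-value strictly above 0.001. "Larger than" is read as strict
inequality and documented as such. A marker failing several criteria is
counted once, under the fixed precedence no-position, call-rate, MAF, HWE —
the criteria themselves define the retained set; the precedence only
disambiguates the report.

The HWE test is the Levene–Haldane exact test (two-sided,
probability-mass ordering of heterozygote counts), the SNP-QC community
convention; a 1-df chi-square version is kept as an option and the two
agree closely once expected genotype counts are in the hundreds.

`fill_missing()` deliberately does **not** reimplement haplotype-cluster
imputation software. At the few-percent missingness left after the
call-rate filter, the G matrix is insensitive to the filling rule (the test
suite verifies element correlations above 0.999 between `hwe_draw` and
`locus_mode` fills at 2% missingness on a chip-density panel), so three
transparent rules are offered: Hardy–Weinberg draws, the locus mode, and
the mode conditional on the nearest non-missing flanking marker.

## Panels, G matrices and LD

**Equally-spaced selection.** "Equally spaced" has no unique reading;
`select_equally_spaced()` uses per-chromosome allocation proportional to
physical span (largest remainder, at least one marker per chromosome when
possible), an endpoint-inclusive grid within each chromosome, nearest
marker by bp per grid point with ties to the lower position, and stepping
to the nearest unused marker on collisions. An every-m-th-marker
alternative is available for sensitivity checks. The default ladder is
100, 200, 500, 1,000, 2,000, 4,000, 6,000, 8,000, 10,000, 20,000, 30,000
and all markers.

**G matrix.** `build_grm()` implements the VanRaden centered cross-product
with allele frequencies recomputed on the analysed cohort for the panel's
markers (self-consistency; the alternative of freezing full-panel
frequencies changes third-decimal details only) and `1e-4` added to the
diagonal for positive definiteness. Monomorphic markers are an error by
design — they contribute nothing to the denominator and should have been
filtered. `grm_correlation()` reports Pearson correlations over the
diagonal (`r_D`), the strict upper triangle (`r_N`), and the full flattened
matrix (`r_A`, diagonal once, off-diagonals twice — "all elements" also
needed a convention).

**LD.** `adjacent_r2()` computes r² only for within-chromosome adjacent
pairs (all-pairs LD matrices are deliberately out of scope) using
maximum-likelihood haplotype frequencies from the two-locus EM on unphased
genotypes; only the double heterozygote is phase-ambiguous and the EM
splits it by the current coupling/repulsion odds. When no double
heterozygotes occur the EM reproduces direct haplotype counting exactly,
and its r² equals the squared correlation of the phased allele indicators.
Note that it does *not* generally equal the squared correlation of the
dosages: that composite estimator absorbs within-locus departures from
Hardy–Weinberg proportions and cross-haplotype associations, which is why
it is offered only as an approximate cross-check (`method = "dosage"`).
Binned summaries use half-open intervals with the default edges 0, 0.1,
0.2, 0.5, 1 Mb plus an overflow bin; nested 0–x ranges are available via
`cumulative = TRUE`.

## Gibbs samplers

`gibbs_model1()` samples the linear animal model with a flat prior on the
fixed effects and independent scaled-inverse-chi-square priors on both
variances; the default degree of belief -2 with scale 0 is flat on the
variance scale, giving posterior degrees of freedom `n - 2` (hence the
requirement of at least `ncol(X) + 3` records). Full conditionals are
standard; the one structural choice is sampling `g` in the eigenbasis of
`G`, computed once per matrix: the rotated coordinates are conditionally
independent univariate normals, so an iteration costs O(n·p) instead of a
dense solve, with no approximation — the fixed-variance sampler is checked
against the closed-form GLS/BLUP oracle (explicit V-inversion, itself
cross-checked against Henderson's mixed-model equations) to within 3
batch-means Monte Carlo standard errors elementwise and correlation > 0.99.

Identifiability under the flat prior comes from reference-level dropping in
`build_design()` (treatment coding; raw age and age², not orthogonalized).
Market and year enter as separate factors; a combined market-year coding
can be emulated by pre-crossing the factors in the phenotype table.

`gibbs_model2()` fits the liability threshold model by data augmentation
with the residual variance fixed at 1. Binary mode fixes the single
threshold at 0 (the intercept remains free); ordinal mode fixes the first
threshold at 0 and draws the others uniformly between the flanking
liability order statistics. That threshold update is known to mix very
slowly; the sampler surfaces a Geweke-style convergence flag and a warning,
and the chain length is configuration — diagnostic chains of millions of
samples are supported but not default. Posterior summaries (mean ± SD) are
computed per retained sample, including derived quantities: the phenotypic
variance and the variance ratio are summarized from per-sample sums and
ratios, never as ratios of means. The default protocol — 110,000
iterations, 10,000 burn-in, thinning 10, a single chain — retains 10,000
samples.

## Imputation stand-in

`naive_impute()` predicts each untyped marker from the flanking typed
marker with the highest absolute dosage correlation in a disjoint reference
cohort (default 494 reference animals in the pipeline), imputing the modal
reference genotype conditional on the individual's flank genotype. It is
deliberately simple — exactly testable against enumerated conditional
modes — and exists to exercise the evaluation logic (concordance
percentages, G matrices and GEBVs from imputed data); the interface accepts
externally imputed matrices so a real phasing/imputation tool can be
swapped in.

## The evaluation ladder

`run_pipeline()` chains the stages deterministically from one master seed
(per-stage seeds are derived, so any stage can be reproduced in isolation)
and emits one table row per panel × trait × model: LD aggregates, GRM
element correlations against the full panel, posterior variance components
with percentages of the full-panel estimates, and GEBV
correlation/regression against the full-panel GEBVs (reduced-panel GEBVs
as the dependent variable, so slopes below 1 read as shrinkage).
GEBV comparisons use posterior-mean GEBVs; posterior SDs are carried along
but not part of the comparison statistics. Figures are qualitative
scatter/ladder plots, optional.

## What the synthetic data can and cannot show

The generator reproduces the features that drive panel-density behaviour:
long-range LD from small Ne, monotone LD decay with distance, dense
within-cohort relatedness, contrasting genetic architectures, fixed-effect
structure, ordinal scoring, and few-percent missingness. It does not
emulate sequence-level variation, selection, pedigree structure beyond the
final generations, array-specific genotyping error, or — most importantly —
the haplotype diversity of a real national population. A constant-size
Wright–Fisher population of Ne = 30 ends with at most 60 distinct
haplotypes, so a sampled cohort of hundreds of animals is far more densely
related than a real cohort of the same nominal Ne, whose census size is
orders of magnitude larger.

That compression has a visible consequence which users should expect in
results from this package: genomic-relationship and variance-capture
statistics **saturate at very low panel densities**. A few dozen markers
often suffice to recover genome-wide kinship among 60-haplotype mixtures,
so the estimated genetic variance reaches its full-panel level (and can
overshoot it, within posterior uncertainty) at the sparse end of the
ladder, and the advantage that a few-large-QTL trait should enjoy at low
density — better tagging of its large QTLs — is masked: variance capture is
kinship-mediated rather than QTL-LD-mediated. GRM correlations, mean
adjacent r², GEBV correlations and regression slopes remain cleanly
monotone in density; the estimated-variance curve and the
large-QTL-versus-polygenic contrast are the two statistics where desk-scale
synthetic cohorts genuinely differ from a real small-Ne population, and the
package's test suite reflects that honestly rather than masking it.

## Problem sizes and numerical choices

The test suite and the acceptance script run scaled-down configurations
chosen to keep the full run in the tens of minutes on one CPU while leaving
every qualitative pattern measurable: simulations of 500–5,000 markers on
2–12 chromosomes, cohorts of 50–500 animals, chains of 4,000–22,000
iterations with proportional burn-in and thinning (the oracle-equivalence
and recovery checks use 11,000/1,000/10). Other fixed numerical choices:
GRM jitter `1e-4`; EM tolerance `1e-10` with a 1,000-iteration cap
(non-converged pairs are flagged and excluded from aggregates);
truncated-normal draws by inverse CDF with tail guards at `1e-12`;
grid-selection ties broken toward the lower bp position; monotone-curve
checks allow one Monte Carlo violation. The PED/MAP writer codes major and
minor alleles as `A`/`B` with `0 0` for missing, 1-based positions.
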