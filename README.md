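# snpladder

How many equally-spaced SNPs does genomic evaluation actually need? For
breeds with a small effective population size — closed beef cattle
populations such as Japanese Black, where Ne is around 30 and
linkage disequilibrium (LD) extends over megabases — a low-density panel may
capture almost all of the genetic variance a 50K chip would. `snpladder` is
an R toolkit for quantifying that trade-off: it simulates a small-Ne
genotyped cohort, builds a ladder of equally-spaced SNP subsets, and
measures how LD summaries, the genomic relationship matrix, Gibbs-estimated
variance components and genomic breeding values (GEBVs) change with panel
density. It is aimed at animal-breeding researchers designing low-density
panels and at method developers who need a fully reproducible, tested
GBLUP stack in plain R.

## The models

**Linear animal model (GBLUP).** Records are analysed as

```
y = X b + g + e,   g ~ N(0, G sigma_g^2),   e ~ N(0, I sigma_e^2)
```

where `b` holds fixed market and year effects plus linear and quadratic
age-at-slaughter covariates, and `G` is VanRaden's genomic relationship
matrix

```
G = (M - 2P)(M - 2P)' / (2 * sum_i p_i (1 - p_i)) + 1e-4 * I
```

with `M` the minor-allele dosage matrix, `p_i` the allele frequencies of
the markers in the panel, and a small diagonal jitter for positive
definiteness. All parameters are estimated by Gibbs sampling with a flat
prior on `b` and scaled-inverse-chi-square priors (degree of belief -2,
scale 0, i.e. flat on the variances); the genetic effects are sampled in
the eigenbasis of `G`, which is exact and needs one decomposition per
matrix. The default chain protocol is 110,000 samples, 10,000 burn-in,
thinning rate 10.

**Liability threshold model.** Ordinal scores (e.g. 12-category marbling
grades) are modelled through an underlying Gaussian liability
`eta = X b + g + e` with `sigma_e^2 = 1`, sampled by data augmentation
(truncated-normal liabilities, Albert–Chib threshold updates); the quantity
of interest is `sigma_g^2 / (sigma_g^2 + 1)`, the heritability on the
liability scale. Scores can be collapsed to a binary trait (default split:
scores up to 6 versus 7 and above) or analysed with all observed categories.

**Supporting machinery.** Forward Wright–Fisher simulation (Haldane
recombination, allele-flip mutation) generating the elevated LD of a
small-Ne population; SNP QC with the Levene–Haldane exact Hardy–Weinberg
test (MAF > 0.01, call rate > 0.95, HWE p > 0.001 by default);
adjacent-pair r² via two-locus EM haplotype-frequency estimation from
unphased genotypes; equally-spaced panel selection on a per-chromosome
grid; a transparent conditional-mode genotype imputation stand-in with
concordance scoring; and a closed-form GLS/BLUP oracle used to validate the
samplers.

## Worked example

```r
library(snpladder)

cfg <- pipeline_config(
  sim = sim_config(n_chromosomes = 2, chrom_length_bp = 40e6,
                   n_markers_total = 800, seed = 1),
  n_animals = 150, n_reference = 0, missing_rate = 0.02,
  ladder = c(50, 150, 1e6),
  chain = chain_config(4000, 1000, 5, seed = 1),
  traits = list(cw = trait_spec("cw", "continuous", n_large = 3,
                                n_small = 100, large_sd = 2,
                                small_sd = 0.25, target_h2 = 0.54)),
  impute_sizes = NULL, seed = 2025)
res <- run_pipeline(cfg)
print(res)
#> Cross-density ladder result: 3 panels x 1 traits
#>   panel panel_size trait  model mean_r2   r_N sigma_g2_mean h2_mean
#> 1    50         50    cw linear   0.128 0.882          7.33   0.656
#> 2   150        150    cw linear   0.192 0.964          8.27   0.751
#> 3   all        359    cw linear   0.229 1.000          8.01   0.778
#>   pct_sigma_g2 gebv_cor gebv_slope
#> 1         91.6    0.916       0.77
#> 2        103.3    0.985       0.93
#> 3        100.0    1.000       1.00
```

Reading the table: thinning the panel from all 359 post-QC markers to 50
lowers the mean adjacent-pair r² from 0.23 to 0.13 (wider spacing), the
upper-triangle GRM correlation with the full panel (`r_N`) falls to 0.88,
GEBVs still correlate 0.92 with the full-panel GEBVs but are shrunken
(regression slope 0.77 — the characteristic downward bias of sparse
panels), while the estimated genetic variance is already near its
full-panel level because a small-Ne cohort is densely related. Each row
also carries posterior SDs, residual/phenotypic variances and percentages
of the full-panel estimates (not shown above).

Lower-level entry points do one thing each: `simulate_haplotypes()`,
`sample_genotypes()`, `apply_filters()`, `fill_missing()`,
`select_equally_spaced()`, `build_grm()`, `adjacent_r2()`/`bin_summary()`,
`gibbs_model1()`/`gibbs_model2()`, `naive_impute()`, `gebv_compare()`.
PLINK PED/MAP and TSV readers/writers round-trip all the data types.

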