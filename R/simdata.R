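#' Simulation configuration for a small-Ne cattle-like population
#'
#' Defines the forward Wright-Fisher simulation that generates haplotypes
#' carrying elevated long-range linkage disequilibrium, as expected in a
#' breed with a small effective population size (Japanese Black-like,
#' Ne of about 30). Defaults emulate a 50K-chip-like marker panel:
#' about 40,000 SNPs spread over 29 autosomes of a 2.5 Gbp genome.
#'
#' @param n_chromosomes Number of autosomes.
#' @param chrom_length_bp Chromosome length in base pairs (recycled to
#'   `n_chromosomes`).
#' @param n_markers_total Total number of markers genome-wide.
#' @param effective_size Effective population size Ne (diploid individuals
#'   per generation); must be at least 2.
#' @param n_generations Number of Wright-Fisher generations to evolve.
#' @param mutation_rate Per-locus, per-gamete allele-flip probability.
#' @param recomb_cM_per_Mb Recombination rate; crossovers follow a Haldane
#'   (Poisson) process at this map density. Default 1 cM/Mb.
#' @param seed Integer seed controlling the whole simulation.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_chromosomes = 29L,
                       chrom_length_bp = 86e6,
                       n_markers_total = 40000L,
                       effective_size = 30L,
                       n_generations = 100L,
                       mutation_rate = 1e-3,
                       recomb_cM_per_Mb = 1,
                       seed = 1L) {
  stop_if_not_scalar_number(n_chromosomes, "n_chromosomes", 1)
  stop_if_not_scalar_number(n_markers_total, "n_markers_total", 1)
  if (n_markers_total < n_chromosomes)
    stop("n_markers_total must be >= n_chromosomes", call. = FALSE)
  if (!is.numeric(effective_size) || effective_size < 2)
    stop("effective_size (Ne) must be >= 2", call. = FALSE)
  stop_if_not_scalar_number(n_generations, "n_generations", 0)
  stop_if_not_scalar_number(mutation_rate, "mutation_rate", 0, 1)
  stop_if_not_scalar_number(recomb_cM_per_Mb, "recomb_cM_per_Mb", 0)
  chrom_length_bp <- rep_len(as.numeric(chrom_length_bp), n_chromosomes)
  if (any(chrom_length_bp < 1))
    stop("chromosome lengths must be positive", call. = FALSE)
  structure(list(
    n_chromosomes = as.integer(n_chromosomes),
    chrom_length_bp = chrom_length_bp,
    n_markers_total = as.integer(n_markers_total),
    effective_size = as.integer(effective_size),
    n_generations = as.integer(n_generations),
    mutation_rate = mutation_rate,
    recomb_cM_per_Mb = recomb_cM_per_Mb,
    seed = as.integer(seed)
  ), class = "sim_config")
}

# Largest-remainder apportionment of k items across weights, each bucket
# receiving at least min_each when k allows it.
largest_remainder <- function(weights, k, min_each = 0L) {
  quota <- k * weights / sum(weights)
  base <- floor(quota)
  rem <- k - sum(base)
  if (rem > 0) {
    extra <- order(quota - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  base <- as.integer(base)
  if (min_each > 0 && k >= length(weights) * min_each) {
    while (any(base < min_each)) {
      i <- which.min(base)
      j <- which.max(base)
      base[i] <- base[i] + 1L
      base[j] <- base[j] - 1L
    }
  }
  base
}

# One meiosis for one chromosome: recombine the parent's two haplotype
# vectors at Poisson (Haldane) crossover points.
meiosis_chrom <- function(hap1, hap2, morgan_pos, len_morgan) {
  n_x <- stats::rpois(1L, len_morgan)
  start <- sample.int(2L, 1L)
  if (n_x == 0L) {
    return(if (start == 1L) hap1 else hap2)
  }
  xo <- sort(stats::runif(n_x, 0, len_morgan))
  seg <- findInterval(morgan_pos, xo)
  use1 <- (seg + start) %% 2L == 1L
  out <- hap2
  out[use1] <- hap1[use1]
  out
}

#' Simulate a haplotype panel by forward Wright-Fisher evolution
#'
#' Founder haplotypes are drawn at intermediate allele frequencies and
#' evolved for `n_generations` of random-mating Wright-Fisher resampling at
#' constant size Ne, with Haldane-model recombination and allele-flip
#' mutation. Small Ne builds the strong short- and long-range LD typical of
#' closed beef cattle populations; the allele-flip mutation keeps a steady
#' supply of polymorphic markers against drift (markers that still fix are
#' meant to be removed by the MAF filter in the QC stage).
#'
#' Marker positions are drawn uniformly along each chromosome; the number of
#' markers per chromosome is apportioned to chromosome length by largest
#' remainder. A chromosome that would receive no markers is dropped with a
#' warning.
#'
#' @param cfg A [sim_config()].
#' @return A list of class `haplotype_panel` with elements
#'   `haplotypes` (2*Ne x m matrix of 0/1 alleles, final generation),
#'   `founders` (the founder haplotype matrix), and `map` (a data.frame
#'   with columns `marker_id`, `chromosome`, `position_bp`, sorted).
#' @export
simulate_haplotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    n_mark <- largest_remainder(cfg$chrom_length_bp, cfg$n_markers_total,
                                min_each = 1L)
    if (any(n_mark == 0L)) {
      warning("dropping ", sum(n_mark == 0L),
              " chromosome(s) that received no markers")
      keep <- n_mark > 0L
      cfg$chrom_length_bp <- cfg$chrom_length_bp[keep]
      cfg$n_chromosomes <- sum(keep)
      n_mark <- n_mark[keep]
    }
    pos_list <- lapply(seq_len(cfg$n_chromosomes), function(c) {
      p <- sort(sample.int(cfg$chrom_length_bp[c], n_mark[c]))
      p
    })
    map <- data.frame(
      marker_id = sprintf("snp%06d", seq_len(sum(n_mark))),
      chromosome = rep(seq_len(cfg$n_chromosomes), n_mark),
      position_bp = unlist(pos_list),
      stringsAsFactors = FALSE
    )
    m <- nrow(map)
    n_hap <- 2L * cfg$effective_size

    # founders: per-marker base frequency away from the boundaries so drift,
    # not initialisation, decides which loci drop out
    p0 <- stats::runif(m, 0.1, 0.9)
    hap <- matrix(stats::rbinom(n_hap * m, 1L, rep(p0, each = n_hap)),
                  nrow = n_hap, ncol = m)
    founders <- hap

    # per-chromosome marker index blocks and genetic lengths
    blocks <- split(seq_len(m), map$chromosome)
    morgan_per_bp <- cfg$recomb_cM_per_Mb / 100 / 1e6
    len_morgan <- cfg$chrom_length_bp * morgan_per_bp
    morgan_pos <- lapply(seq_along(blocks), function(c)
      map$position_bp[blocks[[c]]] * morgan_per_bp)

    ne <- cfg$effective_size
    for (gen in seq_len(cfg$n_generations)) {
      nxt <- matrix(0L, n_hap, m)
      for (ind in seq_len(ne)) {
        parents <- sample.int(ne, 2L, replace = TRUE)
        for (gam in 1:2) {
          p <- parents[gam]
          row <- integer(m)
          for (c in seq_along(blocks)) {
            idx <- blocks[[c]]
            row[idx] <- meiosis_chrom(hap[2L * p - 1L, idx],
                                      hap[2L * p, idx],
                                      morgan_pos[[c]], len_morgan[c])
          }
          nxt[2L * ind - 2L + gam, ] <- row
        }
      }
      if (cfg$mutation_rate > 0) {
        n_mut <- stats::rbinom(1L, n_hap * m, cfg$mutation_rate)
        if (n_mut > 0L) {
          at <- sample.int(n_hap * m, n_mut)
          nxt[at] <- 1L - nxt[at]
        }
      }
      hap <- nxt
    }
    structure(list(haplotypes = hap, founders = founders, map = map),
              class = "haplotype_panel")
  })
}

#' Sample diploid genotypes from a haplotype panel
#'
#' Each individual receives two haplotypes drawn without replacement from
#' the final-generation pool (different individuals may reuse haplotypes,
#' mimicking the high relatedness of a small-Ne cohort). Dosages are then
#' polarized once so that every column counts the minor allele: columns with
#' sample allele frequency above 0.5 are flipped (`dosage <- 2 - dosage`).
#' Marker subsets taken later inherit this polarization.
#'
#' @param panel A `haplotype_panel` from [simulate_haplotypes()].
#' @param n_individuals Number of diploid individuals to form.
#' @param seed Integer seed.
#' @param id_prefix Prefix for generated individual ids.
#' @return Integer matrix (individuals x markers) of minor-allele dosages in
#'   \{0,1,2\} with individual ids as rownames, marker ids as colnames, and a
#'   logical attribute `flipped` marking columns that were re-polarized.
#' @export
sample_genotypes <- function(panel, n_individuals, seed = 1L,
                             id_prefix = "ind") {
  stopifnot(inherits(panel, "haplotype_panel"))
  if (n_individuals < 1) stop("n_individuals must be >= 1", call. = FALSE)
  n_hap <- nrow(panel$haplotypes)
  if (n_hap < 2L) stop("panel must contain at least 2 haplotypes", call. = FALSE)
  with_seed(seed, {
    G <- matrix(0L, n_individuals, ncol(panel$haplotypes))
    for (i in seq_len(n_individuals)) {
      h <- sample.int(n_hap, 2L, replace = FALSE)
      G[i, ] <- panel$haplotypes[h[1L], ] + panel$haplotypes[h[2L], ]
    }
    freq <- colMeans(G) / 2
    flipped <- freq > 0.5
    if (any(flipped)) G[, flipped] <- 2L - G[, flipped]
    rownames(G) <- sprintf("%s%05d", id_prefix, seq_len(n_individuals))
    colnames(G) <- panel$map$marker_id
    attr(G, "flipped") <- flipped
    G
  })
}

#' Assign additive QTL effects to a marker map
#'
#' Draws QTL positions uniformly without replacement and allele-substitution
#' effects from zero-mean normals. Two presets mirror contrasting genetic
#' architectures: a carcass-weight-like trait with a few large QTLs on a
#' polygenic background (`n_large > 0`) and a marbling-like trait controlled
#' only by many small QTLs (`n_large = 0`).
#'
#' @param map Marker map data.frame (`marker_id`, `chromosome`,
#'   `position_bp`).
#' @param n_large,n_small Numbers of large- and small-effect QTLs.
#' @param large_sd,small_sd Standard deviations (trait units) of the two
#'   effect classes.
#' @param seed Integer seed.
#' @return A list of class `qtl_model` with `qtl_marker_indices`, `effects`
#'   and `architecture_label`.
#' @export
assign_qtl_effects <- function(map, n_large, n_small,
                               large_sd = 1, small_sd = 0.1, seed = 1L) {
  if (large_sd < 0 || small_sd < 0) stop("effect SDs must be >= 0", call. = FALSE)
  n_qtl <- n_large + n_small
  if (n_qtl > nrow(map))
    stop("n_large + n_small exceeds the number of markers", call. = FALSE)
  with_seed(seed, {
    idx <- if (n_qtl > 0L) sort(sample.int(nrow(map), n_qtl)) else integer(0)
    eff <- numeric(n_qtl)
    if (n_qtl > 0L) {
      large_pick <- if (n_large > 0L) sample(seq_len(n_qtl), n_large) else integer(0)
      eff[large_pick] <- stats::rnorm(n_large, 0, large_sd)
      small_pick <- setdiff(seq_len(n_qtl), large_pick)
      eff[small_pick] <- stats::rnorm(length(small_pick), 0, small_sd)
      is_large <- seq_len(n_qtl) %in% large_pick
    } else is_large <- logical(0)
    structure(list(
      qtl_marker_indices = idx,
      effects = eff,
      is_large = is_large,
      architecture_label = if (n_large > 0) "mixed_large_plus_polygenic"
                           else "polygenic_only"
    ), class = "qtl_model")
  })
}

#' Fixed-effect design settings for phenotype simulation
#'
#' Controls the slaughter market/year structure and the age covariate of the
#' simulated records. Effect sizes default to `NULL`, in which case they are
#' drawn once (seeded) at magnitudes proportional to the trait's phenotypic
#' standard deviation.
#'
#' @param n_markets,n_years Numbers of market and year levels.
#' @param age_range_months Age-at-slaughter range sampled uniformly;
#'   defaults to 15.3-43.0 months.
#' @param market_effects,year_effects Optional explicit effect vectors.
#' @param beta_age,beta_age2 Optional linear/quadratic age coefficients.
#' @param mean Overall trait mean.
#' @return A list of class `pheno_design`.
#' @export
pheno_design <- function(n_markets = 2L, n_years = 10L,
                         age_range_months = c(15.3, 43.0),
                         market_effects = NULL, year_effects = NULL,
                         beta_age = NULL, beta_age2 = NULL, mean = 0) {
  stopifnot(n_markets >= 1, n_years >= 1,
            length(age_range_months) == 2L,
            age_range_months[1] < age_range_months[2])
  structure(list(n_markets = as.integer(n_markets),
                 n_years = as.integer(n_years),
                 age_range_months = age_range_months,
                 market_effects = market_effects,
                 year_effects = year_effects,
                 beta_age = beta_age, beta_age2 = beta_age2,
                 mean = mean),
            class = "pheno_design")
}

#' Simulate phenotypes with fixed effects and a genomic true breeding value
#'
#' The data-generating twin of the linear analysis model y = Xb + g + e.
#' True breeding values are g_i = sum_j a_j (dosage_ij - 2 p_j) over the QTL
#' set; the residual variance is chosen so that the realized (sample)
#' heritability var(g) / (var(g) + sigma_e^2) equals `target_h2`. Fixed
#' effects comprise market and year class effects plus linear and quadratic
#' age-at-slaughter covariates.
#'
#' @param G Complete dosage matrix (individuals x markers).
#' @param qtl A `qtl_model` from [assign_qtl_effects()].
#' @param design A [pheno_design()].
#' @param target_h2 Target narrow-sense heritability in `[0, 1)`; 0 is
#'   permitted only together with an empty/zero-variance QTL model.
#' @param seed Integer seed.
#' @return A list with `phenotypes` (data.frame: `individual_id`, `value`,
#'   `market`, `year`, `age_months`), `tbv` (true breeding values),
#'   `sigma_e2`, `fixed_part`, and the realized effect values in `design`.
#' @export
simulate_phenotypes <- function(G, qtl, design = pheno_design(),
                                target_h2 = 0.5, seed = 1L) {
  stopifnot(inherits(qtl, "qtl_model"), inherits(design, "pheno_design"))
  if (target_h2 < 0 || target_h2 >= 1)
    stop("target_h2 must be in [0, 1)", call. = FALSE)
  n <- nrow(G)
  idx <- qtl$qtl_marker_indices
  if (length(idx) > 0L) {
    Q <- G[, idx, drop = FALSE]
    p <- colMeans(Q) / 2
    g <- as.vector((Q - matrix(2 * p, n, length(idx), byrow = TRUE)) %*%
                     qtl$effects)
  } else g <- numeric(n)
  var_g <- stats::var(g)
  if (target_h2 > 0 && (length(g) < 2 || var_g <= 0))
    stop("QTL model yields zero genetic variance but target_h2 > 0",
         call. = FALSE)
  sigma_e2 <- if (target_h2 > 0) var_g * (1 - target_h2) / target_h2 else 1
  sigma_p <- sqrt(var_g + sigma_e2)

  with_seed(seed, {
    mk_eff <- design$market_effects %||%
      stats::rnorm(design$n_markets, 0, 0.5 * sigma_p)
    yr_eff <- design$year_effects %||%
      stats::rnorm(design$n_years, 0, 0.3 * sigma_p)
    b_age <- design$beta_age %||% (0.05 * sigma_p)
    b_age2 <- design$beta_age2 %||% (-0.002 * sigma_p)
    market <- sample.int(design$n_markets, n, replace = TRUE)
    year <- sample.int(design$n_years, n, replace = TRUE)
    age <- stats::runif(n, design$age_range_months[1],
                        design$age_range_months[2])
    fixed <- design$mean + mk_eff[market] + yr_eff[year] +
      b_age * age + b_age2 * age^2
    e <- stats::rnorm(n, 0, sqrt(sigma_e2))
    ids <- rownames(G) %||% sprintf("ind%05d", seq_len(n))
    design$market_effects <- mk_eff
    design$year_effects <- yr_eff
    design$beta_age <- b_age
    design$beta_age2 <- b_age2
    list(
      phenotypes = data.frame(
        individual_id = ids,
        value = fixed + g + e,
        market = factor(paste0("m", market)),
        year = factor(paste0("y", year)),
        age_months = age,
        stringsAsFactors = FALSE
      ),
      tbv = g,
      sigma_e2 = sigma_e2,
      fixed_part = fixed,
      design = design
    )
  })
}

#' Map liabilities to ordinal scores through ascending thresholds
#'
#' A liability equal to a threshold is assigned to the upper category, so
#' `score = 1 + #(thresholds <= liability)` at ties and
#' `1 + #(thresholds < liability)` otherwise.
#'
#' @param liability Numeric vector on the underlying (liability) scale.
#' @param thresholds Strictly increasing cut points; K-1 values give K
#'   categories.
#' @return Integer scores in `1..(length(thresholds) + 1)`.
#' @export
discretize_liability <- function(liability, thresholds) {
  if (length(thresholds) < 1L || is.unsorted(thresholds, strictly = TRUE))
    stop("thresholds must be strictly increasing", call. = FALSE)
  findInterval(liability, thresholds) + 1L
}

#' Default 12-category marbling-like thresholds
#'
#' Cut points on the liability scale chosen so a normal liability with the
#' given mean and SD produces a right-heavy, mildly bimodal score
#' distribution over categories 1..12, qualitatively matching carcass
#' marbling-score data. Category probabilities are configurable.
#'
#' @param mu,sigma Mean and SD of the liability distribution the thresholds
#'   will be applied to.
#' @param probs Length-12 vector of target category probabilities
#'   (summing to 1).
#' @return Numeric vector of 11 ascending thresholds.
#' @export
marbling_thresholds <- function(mu = 0, sigma = 1,
                                probs = c(0.04, 0.07, 0.09, 0.10, 0.08,
                                          0.07, 0.07, 0.08, 0.10, 0.11,
                                          0.10, 0.09)) {
  if (length(probs) != 12L || any(probs <= 0) ||
      abs(sum(probs) - 1) > 1e-8)
    stop("probs must be 12 positive values summing to 1", call. = FALSE)
  stats::qnorm(cumsum(probs)[-12L], mean = mu, sd = sigma)
}

#' Mask genotype entries at random
#'
#' Independently sets each dosage to missing with probability
#' `missing_rate`, emulating the few-percent missingness of chip genotype
#' data before imputation.
#'
#' @param G Dosage matrix.
#' @param missing_rate Probability in `[0, 1)` of masking each entry.
#' @param seed Integer seed.
#' @return The matrix with masked entries set to `NA`.
#' @export
mask_genotypes <- function(G, missing_rate, seed = 1L) {
  stop_if_not_scalar_number(missing_rate, "missing_rate", 0, 1 - 1e-12)
  if (missing_rate == 0) return(G)
  with_seed(seed, {
    mask <- stats::runif(length(G)) < missing_rate
    G[mask] <- NA
    G
  })
}
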