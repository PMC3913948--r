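test_that("no recombination and no mutation reproduces founder haplotypes", {
  cfg <- sim_config(n_chromosomes = 1, chrom_length_bp = 10e6,
                    n_markers_total = 50, effective_size = 10,
                    n_generations = 15, mutation_rate = 0,
                    recomb_cM_per_Mb = 0, seed = 3)
  panel <- simulate_haplotypes(cfg)
  founder_keys <- apply(panel$founders, 1, paste, collapse = "")
  final_keys <- apply(panel$haplotypes, 1, paste, collapse = "")
  expect_true(all(final_keys %in% founder_keys))
})

test_that("simulation is deterministic given the seed", {
  cfg <- sim_config(n_chromosomes = 2, chrom_length_bp = 10e6,
                    n_markers_total = 80, effective_size = 8,
                    n_generations = 5, seed = 11)
  p1 <- simulate_haplotypes(cfg)
  p2 <- simulate_haplotypes(cfg)
  expect_identical(p1$haplotypes, p2$haplotypes)
  expect_identical(p1$map, p2$map)
  expect_identical(sample_genotypes(p1, 20, seed = 4),
                   sample_genotypes(p2, 20, seed = 4))
})

test_that("marker map is sorted with strictly increasing positions", {
  fx <- get_fixture()
  map <- fx$panel$map
  expect_false(is.unsorted(map$chromosome))
  for (c in unique(map$chromosome)) {
    pos <- map$position_bp[map$chromosome == c]
    expect_false(is.unsorted(pos, strictly = TRUE))
  }
  expect_false(any(duplicated(map$marker_id)))
})

test_that("adjacent-pair LD exceeds a permuted-marker control and decays with distance", {
  fx <- get_fixture()
  ld <- adjacent_r2(fx$Gq, fx$map, method = "dosage")
  perm <- withr::with_seed(5, sample(ncol(fx$Gq)))
  ld_perm <- adjacent_r2(fx$Gq[, perm, drop = FALSE], fx$map,
                         method = "dosage")
  expect_gt(ld$mean_r2, ld_perm$mean_r2)
})

test_that("mean r2 in the 0-0.1 Mb bin exceeds the 0.5-1 Mb bin over seeds", {
  bins <- sapply(1:10, function(s) {
    cfg <- sim_config(n_chromosomes = 1, chrom_length_bp = 40e6,
                      n_markers_total = 250, effective_size = 30,
                      n_generations = 80, seed = s)
    panel <- simulate_haplotypes(cfg)
    G <- sample_genotypes(panel, 120, seed = s + 500)
    keep <- compute_maf(G) > 0.05
    ld <- adjacent_r2(G[, keep, drop = FALSE],
                      panel$map[keep, , drop = FALSE], method = "dosage")
    b <- bin_summary(ld)
    c(near = b$mean_r2[1], far = b$mean_r2[4])
  })
  expect_gt(mean(bins["near", ], na.rm = TRUE),
            mean(bins["far", ], na.rm = TRUE))
})

test_that("smaller Ne yields higher mean adjacent r2", {
  mean_r2_for_ne <- function(ne) {
    mean(sapply(1:10, function(s) {
      cfg <- sim_config(n_chromosomes = 1, chrom_length_bp = 30e6,
                        n_markers_total = 150, effective_size = ne,
                        n_generations = 40, seed = 7000 + s)
      panel <- simulate_haplotypes(cfg)
      G <- sample_genotypes(panel, 100, seed = 8000 + s)
      keep <- compute_maf(G) > 0.05
      adjacent_r2(G[, keep, drop = FALSE],
                  panel$map[keep, , drop = FALSE],
                  method = "dosage")$mean_r2
    }))
  }
  r2_by_ne <- c(mean_r2_for_ne(30), mean_r2_for_ne(100), mean_r2_for_ne(500))
  expect_true(all(diff(r2_by_ne) < 0))
})

test_that("genotype sampling polarizes to the minor allele and tracks pool frequencies", {
  fx <- get_fixture()
  G <- sample_genotypes(fx$panel, 500, seed = 9)
  n <- nrow(G)
  freq <- colMeans(G) / 2
  expect_true(all(freq <= 0.5 + 1 / (2 * n)))
  # column frequencies track the haplotype-pool frequencies (after matching
  # polarization) within binomial error
  pool <- colMeans(fx$panel$haplotypes)
  pool <- pmin(pool, 1 - pool)
  se <- sqrt(pool * (1 - pool) / (2 * n))
  poly <- pool > 0.05
  expect_lt(mean(abs(freq[poly] - pool[poly]) > 4 * se[poly] + 1 / (2 * n)),
            0.02)
})

test_that("two complementary haplotypes give an all-heterozygous individual", {
  hap <- rbind(rep(0L, 10), rep(1L, 10))
  panel <- structure(list(haplotypes = hap,
                          map = data.frame(marker_id = paste0("m", 1:10),
                                           chromosome = 1L,
                                           position_bp = 1:10 * 1000)),
                     class = "haplotype_panel")
  G <- sample_genotypes(panel, 1, seed = 1)
  expect_true(all(G == 1L))
})

test_that("QTL effect assignment separates large and small effect classes", {
  fx <- get_fixture()
  expect_error(assign_qtl_effects(fx$map, 1, 1, large_sd = -1),
               "SDs")
  empty <- assign_qtl_effects(fx$map, 0, 0, seed = 1)
  expect_length(empty$qtl_marker_indices, 0)
  expect_identical(empty$architecture_label, "polygenic_only")
  expect_identical(assign_qtl_effects(fx$map, 3, 20, seed = 5),
                   assign_qtl_effects(fx$map, 3, 20, seed = 5))
  # with a 10x SD ratio the 3 large effects usually dominate
  hits <- sapply(1:100, function(s) {
    q <- assign_qtl_effects(fx$map, 3, 20, large_sd = 1, small_sd = 0.1,
                            seed = s)
    top3 <- order(abs(q$effects), decreasing = TRUE)[1:3]
    all(q$is_large[top3])
  })
  expect_gt(mean(hits), 0.5)
})

test_that("phenotype simulation realizes the target heritability", {
  fx <- get_fixture()
  G <- sample_genotypes(fx$panel, 2000, seed = 21)
  keep <- compute_maf(G) > 0.01
  qtl <- assign_qtl_effects(fx$map[seq_len(sum(keep)), ], 0, 100,
                            small_sd = 0.2, seed = 22)
  sim <- simulate_phenotypes(G[, keep][, seq_len(sum(keep))], qtl,
                             target_h2 = 0.5, seed = 23)
  resid <- sim$phenotypes$value - sim$fixed_part
  h2_real <- var(sim$tbv) / var(resid)
  expect_lt(abs(h2_real - 0.5), 0.05)
  expect_true(all(sim$phenotypes$age_months >= 15.3))
  expect_true(all(sim$phenotypes$age_months <= 43.0))
})

test_that("an empty QTL model yields zero breeding values and errors for h2 > 0", {
  fx <- get_fixture()
  empty <- assign_qtl_effects(fx$map, 0, 0)
  sim <- simulate_phenotypes(fx$Gq, empty, target_h2 = 0, seed = 2)
  expect_true(all(sim$tbv == 0))
  expect_error(simulate_phenotypes(fx$Gq, empty, target_h2 = 0.5),
               "zero genetic variance")
})

test_that("liability discretization follows the upper-category tie rule", {
  expect_identical(discretize_liability(c(-1, 1), 0), c(1L, 2L))
  expect_identical(discretize_liability(0, 0), 2L)  # tie goes up
  tau <- marbling_thresholds()
  expect_length(tau, 11)
  expect_false(is.unsorted(tau, strictly = TRUE))
  scores <- discretize_liability(rnorm(5000), tau)
  expect_true(all(scores >= 1L & scores <= 12L))
  expect_error(discretize_liability(1, c(1, 0)), "increasing")
})

test_that("genotype masking hits the target rate and is seeded", {
  fx <- get_fixture()
  expect_identical(mask_genotypes(fx$Gq, 0), fx$Gq)
  big <- matrix(1L, 1000, 1000)
  masked <- mask_genotypes(big, 0.02, seed = 4)
  rate <- mean(is.na(masked))
  se <- sqrt(0.02 * 0.98 / length(big))
  expect_lt(abs(rate - 0.02), 3 * se)
  expect_identical(masked, mask_genotypes(big, 0.02, seed = 4))
})

test_that("PLINK and TSV writers round-trip", {
  fx <- get_fixture()
  G <- mask_genotypes(fx$Gq[1:20, 1:50], 0.05, seed = 6)
  map <- fx$map[1:50, ]
  prefix <- file.path(withr::local_tempdir(), "geno")
  write_plink(G, map, prefix)
  rt <- read_plink(prefix)
  expect_equal(unname(rt$genotypes), unname(as.matrix(G)))
  expect_equal(rt$map$position_bp, map$position_bp)
  expect_equal(rt$map$marker_id, map$marker_id)

  tsv <- file.path(withr::local_tempdir(), "dose.tsv")
  write_dosage_tsv(G, tsv)
  expect_equal(unname(read_dosage_tsv(tsv)), unname(as.matrix(G)))

  qtl <- assign_qtl_effects(map, 1, 5, seed = 8)
  sim <- simulate_phenotypes(fill_missing(G, qc_config(seed = 2)), qtl,
                             target_h2 = 0.4, seed = 9)
  ppath <- file.path(withr::local_tempdir(), "phenos.tsv")
  write_phenotypes_tsv(sim$phenotypes, ppath)
  back <- read_phenotypes_tsv(ppath)
  expect_equal(back$value, sim$phenotypes$value)
  expect_equal(as.character(back$market), as.character(sim$phenotypes$market))

  tprefix <- file.path(withr::local_tempdir(), "truth")
  write_truth_tsv(sim$tbv, qtl, sim$phenotypes$individual_id, tprefix)
  tr <- read_truth_tsv(tprefix)
  expect_equal(unname(tr$tbv), sim$tbv)
  expect_equal(tr$qtl$qtl_marker_indices, qtl$qtl_marker_indices)
  expect_equal(tr$qtl$effects, qtl$effects)
})
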