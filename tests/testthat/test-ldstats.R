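test_that("EM recovers the trivial phase configurations", {
  em <- em_haplotype_freqs(c(0, 0, 2, 2), c(0, 0, 2, 2))
  expect_equal(unname(em$freqs["f_AB"]), 0.5, tolerance = 1e-8)
  expect_equal(unname(em$freqs["f_ab"]), 0.5, tolerance = 1e-8)
  expect_equal(em$r2, 1, tolerance = 1e-8)

  d1 <- rep(0:2, each = 9)
  d2 <- rep(rep(0:2, each = 3), 3)  # all combinations equally often
  em0 <- em_haplotype_freqs(d1, d2)
  expect_equal(em0$D, 0, tolerance = 1e-8)
  expect_equal(em0$r2, 0, tolerance = 1e-8)
})

test_that("EM equals the 1-D likelihood grid oracle with double heterozygotes", {
  set.seed(12)
  for (i in 1:10) {
    x <- rbinom(80, 2, runif(1, 0.2, 0.5))
    y <- rbinom(80, 2, runif(1, 0.2, 0.5))
    if (var(x) == 0 || var(y) == 0 || !any(x == 1 & y == 1)) next
    em <- em_haplotype_freqs(x, y)
    oracle <- em_grid_oracle(x, y)
    expect_lt(abs(unname(em$freqs["f_AB"]) - oracle$f_AB), 1e-4)
    expect_lt(abs(em$r2 - oracle$r2), 1e-4)
  }
})

test_that("EM equals phased haplotype correlation when phase is unambiguous", {
  # with no double heterozygotes every genotype resolves into its two
  # haplotypes, so the EM must reproduce direct haplotype counting and its
  # r2 the squared correlation of the phased allele indicators
  set.seed(3)
  for (rep in 1:20) {
    n <- 60
    # force one locus homozygous per individual so no double heterozygote
    # can arise, while both loci stay polymorphic overall
    hom1 <- rbinom(n, 1, 0.5) == 1
    a1 <- rbinom(n, 1, 0.45); a2 <- ifelse(hom1, a1, rbinom(n, 1, 0.45))
    draw_b <- function(a) ifelse(rbinom(n, 1, 0.7) == 1, a, rbinom(n, 1, 0.4))
    b1 <- draw_b(a1); b2 <- ifelse(hom1, draw_b(a2), b1)
    hapA <- c(a1, a2); hapB <- c(b1, b2)
    x <- a1 + a2; y <- b1 + b2
    if (any(x == 1 & y == 1) || var(hapA) == 0 || var(hapB) == 0) next
    em <- em_haplotype_freqs(x, y)
    expect_equal(unname(em$freqs["f_AB"]), mean(hapA == 1 & hapB == 1),
                 tolerance = 1e-10)
    expect_equal(em$r2, cor(hapA, hapB)^2, tolerance = 1e-9)
  }
})

test_that("r2 is bounded and invariant to allele relabeling", {
  set.seed(9)
  for (i in 1:20) {
    x <- rbinom(50, 2, runif(1, 0.1, 0.9))
    y <- rbinom(50, 2, runif(1, 0.1, 0.9))
    if (var(x) == 0 || var(y) == 0) next
    r2 <- em_haplotype_freqs(x, y)$r2
    expect_gte(r2, 0)
    expect_lte(r2, 1)
    expect_equal(em_haplotype_freqs(2L - x, y)$r2, r2, tolerance = 1e-8)
    expect_equal(em_haplotype_freqs(x, 2L - y)$r2, r2, tolerance = 1e-8)
  }
})

test_that("adjacent pairs count m - c and stay within chromosomes", {
  fx <- get_fixture()
  ld <- adjacent_r2(fx$Gq, fx$map)
  n_chrom <- length(unique(fx$map$chromosome))
  expect_equal(nrow(ld$pairs), nrow(fx$map) - n_chrom)
  expect_true(all(ld$pairs$d_mb > 0))
  expect_true(all(ld$pairs$r2 >= 0 & ld$pairs$r2 <= 1, na.rm = TRUE))
})

test_that("a perfect-LD adjacent pair attains r2 = 1", {
  set.seed(4)
  g <- rbinom(100, 2, 0.3)
  G <- cbind(a = g, b = g, c = rbinom(100, 2, 0.5))
  map <- data.frame(marker_id = c("a", "b", "c"), chromosome = 1L,
                    position_bp = c(1e5, 2e5, 3e5))
  ld <- adjacent_r2(G, map)
  expect_equal(ld$pairs$r2[1], 1, tolerance = 1e-6)
})

test_that("thinning a panel lowers mean adjacent r2", {
  fx <- get_fixture()
  full <- adjacent_r2(fx$Gq, fx$map, method = "dosage")
  ps <- select_equally_spaced(fx$map, 60)
  thin <- adjacent_r2(fx$Gq[, ps$indices, drop = FALSE],
                      fx$map[ps$indices, , drop = FALSE], method = "dosage")
  expect_gt(full$mean_r2, thin$mean_r2)
  expect_gt(thin$mean_d_mb, full$mean_d_mb)
})

test_that("bin summary aggregates half-open bins with an overflow bin", {
  pairs <- data.frame(chromosome = 1L, pos1_bp = 0, pos2_bp = 0,
                      d_mb = c(0.05, 0.05, 0.15), r2 = c(0.1, 0.5, 0.2))
  ld <- structure(list(pairs = pairs, mean_r2 = mean(pairs$r2),
                       sd_r2 = sd(pairs$r2), mean_d_mb = mean(pairs$d_mb),
                       sd_d_mb = sd(pairs$d_mb), n_pairs = 3L, n_na = 0L),
                  class = "ld_summary")
  b <- bin_summary(ld, bin_edges_mb = c(0, 0.1, 0.2))
  expect_equal(b$mean_r2[1], 0.3)
  expect_equal(b$frac_gt_threshold[1], 0.5)
  expect_equal(b$mean_r2[2], 0.2)
  expect_equal(b$frac_gt_threshold[2], 0)
  expect_equal(b$n_pairs[3], 0)      # overflow bin empty
  expect_true(is.na(b$mean_r2[3]))

  # constant r2 above the threshold gives 100% in every non-empty bin
  pairs$r2 <- 0.4
  ld$pairs <- pairs
  b2 <- bin_summary(ld, bin_edges_mb = c(0, 0.1, 0.2))
  expect_true(all(b2$frac_gt_threshold[b2$n_pairs > 0] == 1))

  # cumulative mode reproduces nested 0-x ranges
  ld$pairs <- data.frame(chromosome = 1L, pos1_bp = 0, pos2_bp = 0,
                         d_mb = c(0.05, 0.15), r2 = c(0.4, 0.2))
  bc <- bin_summary(ld, bin_edges_mb = c(0, 0.1, 0.2), cumulative = TRUE)
  expect_equal(bc$mean_r2, c(0.4, 0.3))
})
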