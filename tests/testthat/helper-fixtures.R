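# Shared fixtures and independent oracles, built once per test run.

.fixture_env <- new.env(parent = emptyenv())

# A small simulated cohort reused across module tests: 2 chromosomes,
# 700 markers before QC, Ne = 30, 200 individuals.
get_fixture <- function() {
  if (!exists("fx", envir = .fixture_env)) {
    cfg <- sim_config(n_chromosomes = 2, chrom_length_bp = 40e6,
                      n_markers_total = 700, effective_size = 30,
                      seed = 101)
    panel <- simulate_haplotypes(cfg)
    G <- sample_genotypes(panel, 200, seed = 102)
    qc <- apply_filters(G, panel$map, qc_config())
    .fixture_env$fx <- list(cfg = cfg, panel = panel, G = G,
                            Gq = qc$genotypes, map = qc$map,
                            report = qc$report)
  }
  .fixture_env$fx
}

# Independent HWE oracle: Levene-Haldane pmf built by the upward recurrence
# P(h) / P(h-2) = 4 * homR(h-2) * homC(h-2) / (h (h-1)), a different route
# from the package's direct log-factorial evaluation.
hwe_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nr <- min(2 * n_aa + n_Aa, 2 * n_AA + n_Aa)
  if (nr == 0) return(1)
  hets <- seq(nr %% 2, min(nr, 2 * n - nr), by = 2)
  pr <- numeric(length(hets))
  pr[1] <- 1
  for (k in seq_along(hets)[-1]) {
    h <- hets[k]
    homr <- (nr - (h - 2)) / 2
    homc <- ((2 * n - nr) - (h - 2)) / 2
    pr[k] <- pr[k - 1] * 4 * homr * homc / (h * (h - 1))
  }
  pr <- pr / sum(pr)
  obs <- pr[match(n_Aa, hets)]
  min(1, sum(pr[pr <= obs * (1 + 1e-7)]))
}

# Brute-force 1-D likelihood grid oracle for the two-locus EM: profiles the
# multinomial genotype likelihood over f_AB with the allele frequencies held
# at their marginal MLEs.
em_grid_oracle <- function(x, y, grid_n = 200001L) {
  pA <- mean(x) / 2
  pB <- mean(y) / 2
  loglik <- function(fAB) {
    f <- c(fAB, pA - fAB, pB - fAB, 1 - pA - pB + fAB)
    if (any(f < 0)) return(-Inf)
    gp <- matrix(0, 3, 3)
    gp[3, 3] <- f[1]^2;          gp[3, 2] <- 2 * f[1] * f[2]
    gp[3, 1] <- f[2]^2;          gp[2, 3] <- 2 * f[1] * f[3]
    gp[2, 2] <- 2 * f[1] * f[4] + 2 * f[2] * f[3]
    gp[2, 1] <- 2 * f[2] * f[4]; gp[1, 3] <- f[3]^2
    gp[1, 2] <- 2 * f[3] * f[4]; gp[1, 1] <- f[4]^2
    sum(log(gp[cbind(x + 1, y + 1)]))
  }
  grid <- seq(max(0, pA + pB - 1), min(pA, pB), length.out = grid_n)
  ll <- vapply(grid, loglik, numeric(1))
  fAB <- grid[which.max(ll)]
  D <- fAB - pA * pB
  list(f_AB = fAB, r2 = D^2 / (pA * (1 - pA) * pB * (1 - pB)))
}

# Mixed-model-equation route for (b, g), algebraically distinct from the
# explicit V-inversion in gls_oracle: solves Henderson's equations.
mme_solve <- function(y, X, K, sg2, se2) {
  n <- length(y)
  p <- ncol(X)
  lambda <- se2 / sg2
  Kinv <- solve(K)
  lhs <- rbind(cbind(crossprod(X), t(X)),
               cbind(X, diag(n) + lambda * Kinv))
  rhs <- c(crossprod(X, y), y)
  sol <- solve(lhs, rhs)
  list(b = sol[seq_len(p)], g = sol[-seq_len(p)])
}

# Count strict decreases along a curve (monotonicity up to MC noise).
n_violations <- function(x) sum(diff(x) < 0, na.rm = TRUE)

# A wider marker panel (chip-like density over 4 chromosomes) for tests
# whose claims concern many-marker averages.
get_fixture_wide <- function() {
  if (!exists("fxw", envir = .fixture_env)) {
    cfg <- sim_config(n_chromosomes = 4, chrom_length_bp = 50e6,
                      n_markers_total = 2200, effective_size = 30,
                      seed = 301)
    panel <- simulate_haplotypes(cfg)
    G <- sample_genotypes(panel, 180, seed = 302)
    qc <- apply_filters(G, panel$map, qc_config())
    .fixture_env$fxw <- list(panel = panel, Gq = qc$genotypes, map = qc$map)
  }
  .fixture_env$fxw
}
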