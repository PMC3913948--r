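# A small fitted problem shared across the sampler tests.
.bayes_env <- new.env(parent = emptyenv())
get_bayes_problem <- function() {
  if (!exists("bp", envir = .bayes_env)) {
    fx <- get_fixture()
    G <- fx$Gq[1:80, ]
    poly <- compute_maf(G) > 0
    G <- G[, poly]
    map <- fx$map[poly, ]
    K <- build_grm(G)
    qtl <- assign_qtl_effects(map, 2, 60, large_sd = 1, small_sd = 0.2,
                              seed = 201)
    sim <- simulate_phenotypes(G, qtl, target_h2 = 0.5, seed = 202)
    des <- build_design(sim$phenotypes)
    .bayes_env$bp <- list(G = G, map = map, K = K, qtl = qtl, sim = sim,
                          X = des$X, y = des$y)
  }
  .bayes_env$bp
}

test_that("design matrix uses treatment coding with quadratic age", {
  fx <- get_fixture()
  set.seed(14)
  ph <- data.frame(value = rnorm(60),
                   market = factor(sample(c("m1", "m2"), 60, replace = TRUE)),
                   year = factor(c(paste0("y", 1:10),
                                   sample(paste0("y", 1:10), 50,
                                          replace = TRUE))),
                   age_months = runif(60, 15.3, 43))
  des <- build_design(ph)
  expect_equal(ncol(des$X), 1 + 1 + 9 + 2)
  expect_equal(qr(des$X)$rank, ncol(des$X))
  # degenerate factors are dropped with a warning
  ph1 <- ph
  ph1$market <- factor("m1")
  ph1$year <- factor("y1")
  expect_warning(expect_warning(des1 <- build_design(ph1), "market"), "year")
  expect_equal(colnames(des1$X),
               c("(Intercept)", "age_months", "age_months_sq"))
  # constructed collinearity raises an informative error
  ph2 <- ph
  ph2$age_months <- rep(2, 60)  # age and age^2 collinear with intercept
  expect_error(build_design(ph2), "rank deficient")
})

test_that("GLS oracle agrees with Henderson's mixed-model equations", {
  set.seed(5)
  n <- 12
  K <- crossprod(matrix(rnorm(n * n), n)) / n + diag(0.01, n)
  X <- cbind(1, rnorm(n))
  y <- rnorm(n)
  o1 <- gls_oracle(y, X, K, 1.3, 0.7)
  o2 <- mme_solve(y, X, K, 1.3, 0.7)
  expect_equal(o1$b, o2$b, tolerance = 1e-8)
  expect_equal(unname(o1$g), unname(o2$g), tolerance = 1e-8)
})

test_that("GLS oracle limits: no genetics gives OLS, noiseless recovers truth", {
  set.seed(6)
  n <- 30
  K <- crossprod(matrix(rnorm(n * n), n)) / n + diag(0.01, n)
  X <- cbind(1, rnorm(n), rnorm(n))
  b_true <- c(2, -1, 0.5)
  y <- drop(X %*% b_true + rnorm(n))
  low <- gls_oracle(y, X, K, 1e-10, 1)
  expect_equal(unname(low$b),
               unname(drop(solve(crossprod(X), crossprod(X, y)))),
               tolerance = 1e-6)
  expect_lt(max(abs(low$g)), 1e-6)
  y0 <- drop(X %*% b_true)
  exact <- gls_oracle(y0, X, K, 1, 1e-8)
  expect_equal(unname(exact$b), b_true, tolerance = 1e-3)
})

test_that("chain protocol defaults retain 10,000 samples", {
  ch <- chain_config()
  expect_equal(ch$n_iter, 110000L)
  expect_equal(ch$burn_in, 10000L)
  expect_equal(ch$thin, 10L)
  expect_length(snpladder:::retained_iterations(ch), 10000L)
})

test_that("Gibbs sampler with fixed variances matches the GLS oracle", {
  bp <- get_bayes_problem()
  vg <- var(bp$sim$tbv)
  ve <- bp$sim$sigma_e2
  oracle <- gls_oracle(bp$y, bp$X, bp$K, vg, ve)
  fit <- gibbs_model1(bp$y, bp$X, bp$K,
                      chain_config(6000, 1000, 5, seed = 303,
                                   fixed_variances = c(vg, ve)))
  expect_gt(cor(fit$gebv, oracle$g), 0.99)
  expect_true(all(abs(fit$gebv - oracle$g) < 3 * fit$gebv_mcse))
  expect_gt(cor(fit$b, oracle$b), 0.99)
  expect_true(all(abs(fit$b - oracle$b) < 3 * fit$b_mcse))
})

test_that("Gibbs sampler is reproducible and decomposes variance per sample", {
  bp <- get_bayes_problem()
  ch <- chain_config(3000, 500, 5, seed = 7)
  f1 <- gibbs_model1(bp$y, bp$X, bp$K, ch, keep_samples = TRUE)
  f2 <- gibbs_model1(bp$y, bp$X, bp$K, ch, keep_samples = TRUE)
  expect_identical(f1$sigma_g2, f2$sigma_g2)
  expect_identical(f1$gebv, f2$gebv)
  # per-sample additivity of the variance decomposition
  expect_equal(f1$sigma_p2["mean"],
               c(mean = mean(f1$samples$sigma_g2 + f1$samples$sigma_e2)),
               tolerance = 1e-12)
  expect_equal(f1$h2["mean"],
               c(mean = mean(f1$samples$sigma_g2 /
                               (f1$samples$sigma_g2 + f1$samples$sigma_e2))),
               tolerance = 1e-12)
})

test_that("sampler rejects undersized or indefinite problems", {
  bp <- get_bayes_problem()
  expect_error(gibbs_model1(bp$y[1:5], bp$X[1:5, ], bp$K[1:5, 1:5],
                            chain_config(100, 10, 1)),
               "records")
  Kbad <- bp$K
  Kbad[1, 1] <- -5
  expect_error(gibbs_model1(bp$y, bp$X, Kbad, chain_config(100, 10, 1)),
               "positive definite")
})

test_that("threshold model defaults split scores at 6 vs 7 and is seeded", {
  bp <- get_bayes_problem()
  liab <- scale(bp$y)[, 1]
  scores <- discretize_liability(liab, marbling_thresholds())
  ch <- chain_config(1500, 300, 3, seed = 11)
  f1 <- suppressWarnings(gibbs_model2(scores, bp$X, bp$K, ch, mode = "binary"))
  f2 <- suppressWarnings(gibbs_model2(scores, bp$X, bp$K, ch, mode = "binary"))
  expect_identical(f1$sigma_g2, f2$sigma_g2)
  expect_identical(f1$model, "threshold-binary")
  expect_equal(unname(f1$sigma_e2["mean"]), 1)
  expect_true(all(f1$h2 >= 0 & f1$h2 <= 1))
  # the binary split groups <= 6 against >= 7: refitting with an explicit
  # split at 6 gives the identical chain
  f3 <- suppressWarnings(gibbs_model2(scores, bp$X, bp$K, ch, mode = "binary",
                                      binary_split = 6L))
  expect_identical(f1$sigma_g2, f3$sigma_g2)
  # while a different split changes the data and the chain
  f4 <- suppressWarnings(gibbs_model2(scores, bp$X, bp$K, ch, mode = "binary",
                                      binary_split = 3L))
  expect_false(identical(f1$sigma_g2, f4$sigma_g2))
})

test_that("ordinal threshold model fixes the first threshold at zero", {
  bp <- get_bayes_problem()
  liab <- scale(bp$y)[, 1]
  scores <- discretize_liability(liab, c(-0.8, 0, 0.9))
  fit <- suppressWarnings(gibbs_model2(scores, bp$X, bp$K,
                                       chain_config(2000, 400, 4, seed = 13),
                                       mode = "ordinal"))
  expect_equal(fit$thresholds[1], 0)
  expect_true(all(diff(fit$thresholds) > 0))
})

test_that("chain summaries follow the retention protocol", {
  x <- c(1:20)
  s <- summarize_chain(x, burn_in = 0, thin = 1)
  expect_equal(s$mean, mean(x))
  expect_equal(s$sd, sd(x))
  expect_equal(s$n_retained, 20L)
  s2 <- summarize_chain(rep(4, 50), burn_in = 10, thin = 2)
  expect_equal(s2$mean, 4)
  expect_equal(s2$sd, 0)
  expect_equal(s2$n_retained, 20L)
  expect_error(summarize_chain(1:3, burn_in = 2, thin = 2), "few")
})
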