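#' Build the fixed-effect design matrix
#'
#' Constructs X for the model y = Xb + g + e: intercept, treatment-coded
#' market and year factors (first level dropped), and raw linear plus
#' quadratic age-at-slaughter covariates. A factor with a single level is
#' omitted with a warning; a rank-deficient design raises an error naming
#' the collinear columns.
#'
#' @param phenos Phenotype data.frame with columns `value`, `market`,
#'   `year`, `age_months`.
#' @return A list with `X` (full column rank) and the response `y`.
#' @export
build_design <- function(phenos) {
  need <- c("value", "market", "year", "age_months")
  if (!all(need %in% names(phenos)))
    stop("phenotype table must contain ", paste(need, collapse = ", "),
         call. = FALSE)
  if (anyNA(phenos[need])) stop("missing covariates are not allowed",
                                call. = FALSE)
  n <- nrow(phenos)
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  for (fac in c("market", "year")) {
    f <- factor(phenos[[fac]])
    if (nlevels(f) < 2L) {
      warning("factor '", fac, "' has a single level; column omitted")
      next
    }
    C <- stats::model.matrix(~f)[, -1, drop = FALSE]
    colnames(C) <- paste0(fac, levels(f)[-1])
    X <- cbind(X, C)
  }
  age <- phenos$age_months
  X <- cbind(X, age_months = age, age_months_sq = age^2)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  list(X = X, y = phenos$value)
}

#' Closed-form GLS/BLUP solution of the animal model
#'
#' Solves, for known variances, the mixed model y = Xb + g + e with
#' g ~ N(0, K sigma_g2), e ~ N(0, I sigma_e2) by direct inversion of
#' V = K sigma_g2 + I sigma_e2:
#' `b = (X'V^-1 X)^-1 X'V^-1 y` and `g = sigma_g2 K V^-1 (y - Xb)`.
#' Used as the independent oracle against which the Gibbs sampler is
#' validated.
#'
#' @param y Response vector.
#' @param X Full-rank design matrix.
#' @param K Genomic relationship matrix.
#' @param sigma_g2,sigma_e2 Known variance components (> 0).
#' @return A list with `b` and `g`.
#' @export
gls_oracle <- function(y, X, K, sigma_g2, sigma_e2) {
  if (sigma_g2 <= 0 || sigma_e2 <= 0)
    stop("variances must be positive", call. = FALSE)
  n <- length(y)
  V <- sigma_g2 * K + diag(sigma_e2, n)
  Vi <- solve(V)
  XtVi <- crossprod(X, Vi)
  A <- XtVi %*% X
  if (rcond(A) < 1e-12) stop("X'V^-1X is singular", call. = FALSE)
  b <- solve(A, XtVi %*% y)
  g <- sigma_g2 * K %*% Vi %*% (y - X %*% b)
  list(b = drop(b), g = drop(g))
}

#' Gibbs chain settings
#'
#' Defaults follow the standard single-chain protocol for these models:
#' 110,000 samples, 10,000 burn-in, thinning rate 10 (10,000 retained).
#'
#' @param n_iter Total iterations.
#' @param burn_in Iterations discarded before retention.
#' @param thin Keep every `thin`-th post-burn-in sample.
#' @param seed Integer seed.
#' @param fixed_variances Optional `c(sigma_g2, sigma_e2)`; when set, the
#'   variance updates are skipped (oracle-testing mode).
#' @return An object of class `chain_config`.
#' @export
chain_config <- function(n_iter = 110000L, burn_in = 10000L, thin = 10L,
                         seed = 1L, fixed_variances = NULL) {
  if (burn_in >= n_iter) stop("burn_in must be < n_iter", call. = FALSE)
  if (thin < 1) stop("thin must be >= 1", call. = FALSE)
  if (burn_in + thin > n_iter)
    stop("chain retains no samples: burn_in + thin exceeds n_iter",
         call. = FALSE)
  if (!is.null(fixed_variances)) {
    stopifnot(length(fixed_variances) == 2L, all(fixed_variances > 0))
  }
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), seed = as.integer(seed),
                 fixed_variances = fixed_variances),
            class = "chain_config")
}

#' Scaled-inverse-chi-square priors for the variance components
#'
#' The default degree of belief -2 with scale 0 is flat on the variance
#' (no prior information); the posterior degrees of freedom are then
#' `n - 2`, which requires at least 3 records/animals.
#'
#' @param nu_g,S_g Degree of belief and scale for sigma_g2.
#' @param nu_e,S_e Degree of belief and scale for sigma_e2.
#' @return An object of class `prior_config`.
#' @export
prior_config <- function(nu_g = -2, S_g = 0, nu_e = -2, S_e = 0) {
  structure(list(nu_g = nu_g, S_g = S_g, nu_e = nu_e, S_e = S_e),
            class = "prior_config")
}

retained_iterations <- function(chain) {
  seq.int(chain$burn_in + chain$thin, chain$n_iter, by = chain$thin)
}

#' Batch-means Monte Carlo standard error
#'
#' @param x Numeric chain (retained samples).
#' @return Estimated MC standard error of the chain mean.
#' @export
mcse_batch <- function(x) {
  len <- length(x)
  bs <- max(1L, floor(sqrt(len)))
  nb <- len %/% bs
  bm <- colMeans(matrix(x[seq_len(nb * bs)], nrow = bs))
  stats::sd(bm) / sqrt(nb)
}

geweke_ok <- function(x, z_max = 3) {
  n <- length(x)
  if (n < 40L) return(TRUE)
  a <- x[seq_len(floor(0.1 * n))]
  b <- x[seq.int(floor(0.5 * n) + 1L, n)]
  se <- sqrt(mcse_batch(a)^2 + mcse_batch(b)^2)
  if (!is.finite(se) || se == 0) return(stats::sd(x) == 0)
  abs(mean(a) - mean(b)) / se < z_max
}

col_sds <- function(M) {
  n <- nrow(M)
  mu <- colMeans(M)
  sqrt(pmax(0, (colSums(M^2) - n * mu^2) / (n - 1)))
}

make_posterior_summary <- function(sg2s, se2s, Gmat, Bmat, bnames, model,
                                   converged, extra = list()) {
  sp2s <- sg2s + se2s
  h2s <- sg2s / sp2s
  s <- function(v) c(mean = mean(v), sd = stats::sd(v))
  out <- c(list(
    model = model,
    sigma_g2 = s(sg2s),
    sigma_e2 = s(se2s),
    sigma_p2 = s(sp2s),
    h2 = s(h2s),
    gebv = colMeans(Gmat),
    gebv_sd = col_sds(Gmat),
    gebv_mcse = apply(Gmat, 2, mcse_batch),
    b = stats::setNames(colMeans(Bmat), bnames),
    b_sd = stats::setNames(col_sds(Bmat), bnames),
    b_mcse = stats::setNames(apply(Bmat, 2, mcse_batch), bnames),
    sigma_g2_mcse = mcse_batch(sg2s),
    n_retained = length(sg2s),
    converged = converged
  ), extra)
  class(out) <- "posterior_summary"
  out
}

#' @export
print.posterior_summary <- function(x, ...) {
  cat(sprintf("Posterior summary (%s model, %d retained samples)\n",
              x$model, x$n_retained))
  fmt <- function(nm, v) cat(sprintf("  %-10s %10.4f +/- %.4f\n", nm,
                                     v["mean"], v["sd"]))
  fmt("sigma_g2", x$sigma_g2)
  fmt("sigma_e2", x$sigma_e2)
  fmt("sigma_p2", x$sigma_p2)
  fmt(if (x$model == "linear") "h2" else "h2 (liab.)", x$h2)
  if (!x$converged) cat("  WARNING: convergence diagnostic failed\n")
  invisible(x)
}

# Shared eigen-space setup: sampling g in the eigenbasis of K turns the
# joint multivariate-normal update into independent univariate normals,
# which is exact in distribution and needs one decomposition per K.
grm_eigen <- function(K) {
  e <- eigen(K, symmetric = TRUE)
  if (min(e$values) <= 0)
    stop("G matrix is not positive definite; add diagonal jitter ",
         "(see build_grm)", call. = FALSE)
  e
}

#' Gibbs sampler for the linear animal model (model 1)
#'
#' Samples from the posterior of y = Xb + g + e with g ~ N(0, K sigma_g2),
#' e ~ N(0, I sigma_e2), a flat prior on b and independent scaled-inverse-
#' chi-square priors on the variances. Full conditionals: b is multivariate
#' normal around the least-squares solution of y - g; g is sampled in the
#' eigenbasis of K (independent univariate normals); each variance is
#' scaled-inverse-chi-square with degrees of freedom n + nu and scale
#' (SS + nu S) / (n + nu).
#'
#' @param y Response vector.
#' @param X Full-rank design matrix.
#' @param K Positive-definite genomic relationship matrix.
#' @param chain A [chain_config()].
#' @param prior A [prior_config()].
#' @param keep_samples Retain the variance-component chains in the output.
#' @return An object of class `posterior_summary` with posterior mean/SD of
#'   sigma_g2, sigma_e2, sigma_p2 and their ratio (computed per-sample),
#'   per-animal GEBVs (posterior means, SDs, MC standard errors), fixed
#'   effects, and a convergence flag.
#' @export
gibbs_model1 <- function(y, X, K, chain = chain_config(),
                         prior = prior_config(), keep_samples = FALSE) {
  stopifnot(inherits(chain, "chain_config"), inherits(prior, "prior_config"))
  n <- length(y)
  p <- ncol(X)
  if (n < p + 3L)
    stop("need at least ncol(X) + 3 records for a proper posterior",
         call. = FALSE)
  eg <- grm_eigen(K)
  U <- eg$vectors
  d <- eg$values
  W <- crossprod(U, X)
  z <- crossprod(U, y)[, 1]
  XtX <- crossprod(X)
  R <- chol(XtX)
  fixed <- !is.null(chain$fixed_variances)

  with_seed(chain$seed, {
    b <- backsolve(R, backsolve(R, crossprod(X, y), transpose = TRUE))[, 1]
    tvec <- numeric(n)
    if (fixed) {
      sg2 <- chain$fixed_variances[1]
      se2 <- chain$fixed_variances[2]
    } else {
      sg2 <- se2 <- stats::var(y) / 2
    }
    keep <- retained_iterations(chain)
    n_ret <- length(keep)
    sg2s <- se2s <- numeric(n_ret)
    Tmat <- matrix(0, n_ret, n)
    Bmat <- matrix(0, n_ret, p)
    ki <- 1L
    for (it in seq_len(chain$n_iter)) {
      # b | rest
      rb <- crossprod(W, z - tvec)
      b_mean <- backsolve(R, backsolve(R, rb, transpose = TRUE))[, 1]
      b <- b_mean + sqrt(se2) * backsolve(R, stats::rnorm(p))
      # g | rest, in the eigenbasis
      rt <- z - (W %*% b)[, 1]
      v <- 1 / (1 / (d * sg2) + 1 / se2)
      tvec <- stats::rnorm(n, v * rt / se2, sqrt(v))
      if (!fixed) {
        ssg <- sum(tvec^2 / d)
        sg2 <- (ssg + prior$nu_g * prior$S_g) /
          stats::rchisq(1L, n + prior$nu_g)
        e <- rt - tvec
        sse <- sum(e^2)
        se2 <- (sse + prior$nu_e * prior$S_e) /
          stats::rchisq(1L, n + prior$nu_e)
      }
      if (ki <= n_ret && it == keep[ki]) {
        sg2s[ki] <- sg2
        se2s[ki] <- se2
        Tmat[ki, ] <- tvec
        Bmat[ki, ] <- b
        ki <- ki + 1L
      }
    }
    Gmat <- Tmat %*% t(U)
    colnames(Gmat) <- rownames(K)
    conv <- if (fixed) TRUE else geweke_ok(sg2s)
    extra <- if (keep_samples)
      list(samples = list(sigma_g2 = sg2s, sigma_e2 = se2s)) else list()
    make_posterior_summary(sg2s, se2s, Gmat, Bmat, colnames(X), "linear",
                           conv, extra)
  })
}

# vectorized truncated-normal draw via inverse CDF, guarded against
# underflow far in the tails
rtruncnorm_vec <- function(mu, lower, upper) {
  plo <- stats::pnorm(lower - mu)
  pup <- stats::pnorm(upper - mu)
  u <- stats::runif(length(mu), plo, pup)
  u <- pmin(pmax(u, 1e-12), 1 - 1e-12)
  out <- mu + stats::qnorm(u)
  pmin(pmax(out, ifelse(is.finite(lower), lower, -Inf)),
       ifelse(is.finite(upper), upper, Inf))
}

#' Gibbs sampler for the liability threshold model (model 2)
#'
#' Data-augmentation sampler for ordinal scores: each record's liability is
#' drawn from a normal (residual variance fixed at 1) truncated to its
#' category's interval; b, g and sigma_g2 are then updated as in the linear
#' model with the liabilities as response. In binary mode the observed
#' scores are split at `binary_split` (scores <= split vs above) and the
#' single threshold is fixed at 0. In ordinal mode the observed score values
#' define the categories (gaps are merged with a warning), the first
#' threshold is fixed at 0, and the remaining thresholds are drawn uniformly
#' between the flanking liability order statistics (Albert-Chib update) —
#' an update known to mix slowly, which the convergence flag monitors.
#'
#' @param scores Integer ordinal scores.
#' @param X Full-rank design matrix.
#' @param K Positive-definite genomic relationship matrix.
#' @param chain A [chain_config()]; `fixed_variances[1]` fixes sigma_g2.
#' @param mode `"binary"` or `"ordinal"`.
#' @param binary_split Largest score assigned to the lower binary class
#'   (default 6, i.e. scores up to 6 vs 7 and above).
#' @param prior A [prior_config()]; only the genetic-variance prior is used.
#' @return A `posterior_summary`; `h2` holds the posterior of
#'   sigma_g2 / (sigma_g2 + 1), the proportion of variance on the liability
#'   scale. `thresholds` gives posterior means of the free thresholds.
#' @export
gibbs_model2 <- function(scores, X, K, chain = chain_config(),
                         mode = c("binary", "ordinal"), binary_split = 6L,
                         prior = prior_config()) {
  mode <- match.arg(mode)
  stopifnot(inherits(chain, "chain_config"))
  n <- length(scores)
  p <- ncol(X)
  if (n < p + 3L)
    stop("need at least ncol(X) + 3 records for a proper posterior",
         call. = FALSE)
  if (mode == "binary") {
    cat_idx <- ifelse(scores <= binary_split, 1L, 2L)
    K_cat <- 2L
  } else {
    lev <- sort(unique(scores))
    if (length(lev) < 2L) stop("need at least 2 observed categories",
                               call. = FALSE)
    if (any(diff(lev) > 1L))
      warning("empty interior categories merged with their neighbours")
    cat_idx <- match(scores, lev)
    K_cat <- length(lev)
  }
  if (length(unique(cat_idx)) < 2L)
    stop("need at least 2 observed categories", call. = FALSE)

  eg <- grm_eigen(K)
  U <- eg$vectors
  d <- eg$values
  XtX <- crossprod(X)
  R <- chol(XtX)
  fixed <- !is.null(chain$fixed_variances)

  with_seed(chain$seed, {
    props <- tabulate(cat_idx, K_cat) / n
    tau <- stats::qnorm(cumsum(props)[-K_cat])
    tau <- tau - tau[1]                      # first threshold fixed at 0
    eta <- stats::qnorm(pmin(pmax(cumsum(props)[cat_idx] - props[cat_idx] / 2,
                                  0.01), 0.99))
    b <- backsolve(R, backsolve(R, crossprod(X, eta), transpose = TRUE))[, 1]
    tvec <- numeric(n)
    sg2 <- if (fixed) chain$fixed_variances[1] else 1
    keep <- retained_iterations(chain)
    n_ret <- length(keep)
    sg2s <- numeric(n_ret)
    Tmat <- matrix(0, n_ret, n)
    Bmat <- matrix(0, n_ret, p)
    TauMat <- matrix(0, n_ret, K_cat - 1L)
    slow_mixing <- FALSE
    ki <- 1L
    for (it in seq_len(chain$n_iter)) {
      # liabilities | rest
      g <- (U %*% tvec)[, 1]
      mu <- (X %*% b)[, 1] + g
      tau_ext <- c(-Inf, tau, Inf)
      eta <- rtruncnorm_vec(mu, tau_ext[cat_idx], tau_ext[cat_idx + 1L])
      z <- crossprod(U, eta)[, 1]
      # b | rest (residual variance 1)
      rb <- crossprod(X, eta - g)
      b_mean <- backsolve(R, backsolve(R, rb, transpose = TRUE))[, 1]
      b <- b_mean + backsolve(R, stats::rnorm(p))
      # g | rest in the eigenbasis
      rt <- z - crossprod(U, (X %*% b)[, 1])[, 1]
      v <- 1 / (1 / (d * sg2) + 1)
      tvec <- stats::rnorm(n, v * rt, sqrt(v))
      if (!fixed) {
        ssg <- sum(tvec^2 / d)
        sg2 <- (ssg + prior$nu_g * prior$S_g) /
          stats::rchisq(1L, n + prior$nu_g)
      }
      # thresholds | rest (ordinal only; tau_1 stays 0)
      if (K_cat > 2L) {
        for (j in 2:(K_cat - 1L)) {
          lo <- max(eta[cat_idx == j], if (j > 2) tau[j - 1] else 0)
          hi <- min(eta[cat_idx == j + 1L], if (j < K_cat - 1L) tau[j + 1]
                    else Inf)
          if (!is.finite(lo) || lo >= hi) {
            slow_mixing <- TRUE
            next
          }
          if (hi - lo < 1e-12) slow_mixing <- TRUE
          tau[j] <- stats::runif(1L, lo, hi)
        }
      }
      if (ki <= n_ret && it == keep[ki]) {
        sg2s[ki] <- sg2
        Tmat[ki, ] <- tvec
        Bmat[ki, ] <- b
        TauMat[ki, ] <- tau
        ki <- ki + 1L
      }
    }
    Gmat <- Tmat %*% t(U)
    colnames(Gmat) <- rownames(K)
    conv <- if (fixed) TRUE else geweke_ok(sg2s)
    if (slow_mixing)
      warning("threshold updates hit zero-width intervals; ",
              "chain may be mixing extremely slowly")
    if (!conv)
      warning("convergence diagnostic failed; threshold-model chains are ",
              "prone to extremely slow mixing - consider a much longer chain")
    out <- make_posterior_summary(
      sg2s, rep(1, n_ret), Gmat, Bmat, colnames(X),
      paste0("threshold-", mode), conv,
      extra = list(thresholds = colMeans(TauMat)))
    out
  })
}

#' Summarize an MCMC chain by the retention protocol
#'
#' Applies burn-in and thinning, then reports the mean and SD of the
#' retained samples (column-wise for a matrix chain).
#'
#' @param samples Numeric vector, or matrix with one row per iteration.
#' @param burn_in Samples discarded from the front.
#' @param thin Keep every `thin`-th remaining sample.
#' @return A list with `mean`, `sd`, `n_retained`.
#' @export
summarize_chain <- function(samples, burn_in = 0L, thin = 1L) {
  vec <- is.null(dim(samples))
  n <- if (vec) length(samples) else nrow(samples)
  if (burn_in + thin > n) stop("too few retained samples", call. = FALSE)
  idx <- seq.int(burn_in + thin, n, by = thin)
  if (length(idx) < 2L) stop("too few retained samples", call. = FALSE)
  if (vec) {
    x <- samples[idx]
    list(mean = mean(x), sd = stats::sd(x), n_retained = length(idx))
  } else {
    M <- samples[idx, , drop = FALSE]
    list(mean = colMeans(M), sd = col_sds(M), n_retained = length(idx))
  }
}
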