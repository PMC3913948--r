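#' Quality-control configuration
#'
#' Thresholds follow common chip-genotype practice: markers are retained
#' when MAF and call rate are strictly larger than their minima and the
#' exact Hardy-Weinberg test p-value is strictly larger than `hwe_p_min`.
#'
#' @param maf_min Minimum minor allele frequency (exclusive). Default 0.01.
#' @param call_rate_min Minimum genotype call rate (exclusive). Default 0.95.
#' @param hwe_p_min Minimum Hardy-Weinberg exact-test p-value (exclusive).
#'   Default 0.001.
#' @param fill_method One of `"hwe_draw"`, `"locus_mode"`,
#'   `"neighbor_conditional"` (see [fill_missing()]).
#' @param seed Integer seed used by stochastic filling.
#' @return An object of class `qc_config`.
#' @export
qc_config <- function(maf_min = 0.01, call_rate_min = 0.95,
                      hwe_p_min = 0.001, fill_method = "hwe_draw",
                      seed = 1L) {
  stop_if_not_scalar_number(maf_min, "maf_min", 0, 1)
  stop_if_not_scalar_number(call_rate_min, "call_rate_min", 0, 1)
  stop_if_not_scalar_number(hwe_p_min, "hwe_p_min", 0, 1)
  fill_method <- match.arg(fill_method,
                           c("hwe_draw", "locus_mode", "neighbor_conditional"))
  structure(list(maf_min = maf_min, call_rate_min = call_rate_min,
                 hwe_p_min = hwe_p_min, fill_method = fill_method,
                 seed = as.integer(seed)),
            class = "qc_config")
}

#' Per-marker minor allele frequency
#'
#' Frequency of the minor allele among non-missing calls. Because dosages
#' are already polarized to count an allele at frequency <= 0.5, the MAF is
#' `min(f, 1 - f)` of the counted-allele frequency, guaranteeing a value in
#' `[0, 0.5]`. Markers with no non-missing call return `NA`.
#'
#' @param G Dosage matrix with possible `NA`s.
#' @return Numeric vector of MAFs in `[0, 0.5]` (or `NA`).
#' @export
compute_maf <- function(G) {
  f <- colMeans(G, na.rm = TRUE) / 2
  f[is.nan(f)] <- NA
  pmin(f, 1 - f)
}

# log pmf of the heterozygote count under the Levene-Haldane conditional
# distribution given n individuals and nA copies of the rarer allele
hwe_log_pmf <- function(n_het, n, n_a) {
  n_b <- 2L * n - n_a
  n_hom_a <- (n_a - n_het) / 2
  n_hom_b <- (n_b - n_het) / 2
  lgamma(n + 1) - lgamma(n_hom_a + 1) - lgamma(n_het + 1) -
    lgamma(n_hom_b + 1) + n_het * log(2) +
    lgamma(n_a + 1) + lgamma(n_b + 1) - lgamma(2 * n + 1)
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Two-sided exact test conditioning on the observed allele counts
#' (Levene-Haldane distribution of the heterozygote count). The p-value is
#' the total probability of all heterozygote counts no more probable than
#' the observed one. Monomorphic markers return `p = 1` by convention.
#'
#' @param n_AA,n_Aa,n_aa Genotype counts.
#' @return Two-sided exact p-value.
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  if (any(c(n_AA, n_Aa, n_aa) < 0)) stop("counts must be >= 0", call. = FALSE)
  n <- n_AA + n_Aa + n_aa
  if (n < 1) stop("total genotype count must be >= 1", call. = FALSE)
  n_a <- 2L * n_aa + n_Aa
  n_A <- 2L * n_AA + n_Aa
  if (n_a == 0 || n_A == 0) return(1)
  n_rare <- min(n_a, n_A)
  hets <- seq.int(n_rare %% 2L, min(n_rare, 2L * n - n_rare), by = 2L)
  logp <- hwe_log_pmf(hets, n, n_rare)
  prob <- exp(logp - max(logp))
  prob <- prob / sum(prob)
  obs <- prob[match(n_Aa, hets)]
  min(1, sum(prob[prob <= obs * (1 + 1e-7)]))
}

#' Chi-square Hardy-Weinberg test (1 df, no continuity correction)
#'
#' Provided as a large-sample cross-check for [hwe_exact_test()].
#'
#' @inheritParams hwe_exact_test
#' @return Chi-square p-value.
#' @export
hwe_chisq_test <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  p <- (2 * n_AA + n_Aa) / (2 * n)
  if (p == 0 || p == 1) return(1)
  expd <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  x2 <- sum((c(n_AA, n_Aa, n_aa) - expd)^2 / expd)
  stats::pchisq(x2, df = 1, lower.tail = FALSE)
}

# genotype counts (dosage 0/1/2) per marker, ignoring NAs
genotype_counts <- function(G) {
  t(apply(G, 2, function(x) c(sum(x == 0, na.rm = TRUE),
                              sum(x == 1, na.rm = TRUE),
                              sum(x == 2, na.rm = TRUE))))
}

#' Apply SNP quality-control filters
#'
#' Retains markers with defined position, call rate > `call_rate_min`,
#' MAF > `maf_min`, and exact Hardy-Weinberg p > `hwe_p_min`. A marker
#' failing several criteria is counted once, in the fixed precedence
#' no-position, call-rate, MAF, HWE.
#'
#' @param G Dosage matrix (may contain `NA`).
#' @param map Marker map aligned to `G`'s columns.
#' @param cfg A [qc_config()].
#' @return A list with filtered `genotypes` and `map`, plus `report`, a list
#'   of class `qc_report` with the counts `n_input`, `n_removed_no_position`,
#'   `n_removed_callrate`, `n_removed_maf`, `n_removed_hwe`, `n_retained`.
#' @export
apply_filters <- function(G, map, cfg = qc_config()) {
  stopifnot(ncol(G) == nrow(map), inherits(cfg, "qc_config"))
  m <- ncol(G)
  no_pos <- is.na(map$position_bp)
  call_rate <- colMeans(!is.na(G))
  maf <- compute_maf(G)
  fail_call <- !no_pos & !(call_rate > cfg$call_rate_min)
  fail_maf <- !no_pos & !fail_call &
    (is.na(maf) | !(maf > cfg$maf_min))
  counts <- genotype_counts(G)
  hwe_p <- rep(1, m)
  todo <- which(!no_pos & !fail_call & !fail_maf)
  hwe_p[todo] <- vapply(todo, function(j)
    hwe_exact_test(counts[j, 1], counts[j, 2], counts[j, 3]), numeric(1))
  fail_hwe <- !no_pos & !fail_call & !fail_maf & !(hwe_p > cfg$hwe_p_min)
  keep <- !(no_pos | fail_call | fail_maf | fail_hwe)
  if (!any(keep)) stop("no markers pass the QC filters", call. = FALSE)
  report <- structure(list(
    n_input = m,
    n_removed_no_position = sum(no_pos),
    n_removed_callrate = sum(fail_call),
    n_removed_maf = sum(fail_maf),
    n_removed_hwe = sum(fail_hwe),
    n_retained = sum(keep)
  ), class = "qc_report")
  G_keep <- G[, keep, drop = FALSE]
  attr(G_keep, "flipped") <- attr(G, "flipped")[keep]
  list(genotypes = G_keep, map = map[keep, , drop = FALSE], report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("SNP QC report\n")
  cat("  input markers:      ", x$n_input, "\n")
  cat("  removed no-position:", x$n_removed_no_position, "\n")
  cat("  removed call-rate:  ", x$n_removed_callrate, "\n")
  cat("  removed MAF:        ", x$n_removed_maf, "\n")
  cat("  removed HWE:        ", x$n_removed_hwe, "\n")
  cat("  retained:           ", x$n_retained, "\n")
  invisible(x)
}

#' Fill missing genotypes
#'
#' A deliberately simple stand-in for haplotype-based imputation software,
#' adequate at the few-percent missingness left after the call-rate filter.
#' Methods: `"hwe_draw"` samples the genotype from the locus'
#' Hardy-Weinberg proportions; `"locus_mode"` fills with the locus' most
#' frequent genotype (ties toward the lower dosage); and
#' `"neighbor_conditional"` fills with the modal genotype conditional on the
#' individual's genotype at the nearest non-missing flanking marker on the
#' same chromosome (table estimated from complete cases, falling back to the
#' locus mode when the conditional cell is empty or no flank exists).
#'
#' @param G Dosage matrix with `NA`s.
#' @param cfg A [qc_config()]; `fill_method` and `seed` are used.
#' @param map Marker map; required for `neighbor_conditional`.
#' @return A complete dosage matrix; attribute `n_filled` counts the filled
#'   entries. Non-missing entries are never altered.
#' @export
fill_missing <- function(G, cfg = qc_config(), map = NULL) {
  stopifnot(inherits(cfg, "qc_config"))
  miss <- is.na(G)
  n_filled <- sum(miss)
  if (n_filled == 0L) {
    attr(G, "n_filled") <- 0L
    return(G)
  }
  locus_mode <- apply(G, 2, function(x) {
    tab <- tabulate(x + 1L, 3L)
    which.max(tab) - 1L
  })
  out <- G
  if (cfg$fill_method == "hwe_draw") {
    out <- with_seed(cfg$seed, {
      for (j in which(colSums(miss) > 0L)) {
        x <- G[, j]
        q <- mean(x, na.rm = TRUE) / 2
        if (is.nan(q)) stop("all-missing marker cannot be filled; run QC first",
                            call. = FALSE)
        probs <- c((1 - q)^2, 2 * q * (1 - q), q^2)
        out[miss[, j], j] <- sample(0:2, sum(miss[, j]), replace = TRUE,
                                    prob = probs)
      }
      out
    })
  } else if (cfg$fill_method == "locus_mode") {
    for (j in which(colSums(miss) > 0L)) out[miss[, j], j] <- locus_mode[j]
  } else {
    if (is.null(map)) stop("neighbor_conditional filling requires 'map'",
                           call. = FALSE)
    stopifnot(nrow(map) == ncol(G))
    for (j in which(colSums(miss) > 0L)) {
      same_chr <- which(map$chromosome == map$chromosome[j] &
                          seq_len(ncol(G)) != j)
      for (i in which(miss[, j])) {
        cand <- same_chr[!is.na(G[i, same_chr])]
        if (length(cand) == 0L) {
          out[i, j] <- locus_mode[j]
          next
        }
        flank <- cand[which.min(abs(map$position_bp[cand] -
                                      map$position_bp[j]))]
        cc <- !is.na(G[, j]) & !is.na(G[, flank])
        sub <- G[cc & G[, flank] == G[i, flank], j]
        out[i, j] <- if (length(sub) > 0L) {
          tab <- tabulate(sub + 1L, 3L)
          which.max(tab) - 1L
        } else locus_mode[j]
      }
    }
  }
  attr(out, "n_filled") <- n_filled
  attr(out, "flipped") <- attr(G, "flipped")
  out
}
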