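#' EM estimation of two-locus haplotype frequencies from unphased genotypes
#'
#' Maximum-likelihood haplotype frequencies under random mating, computed by
#' expectation-maximisation over the nine two-locus genotype classes. Only
#' the double heterozygote is phase-ambiguous; each E-step splits it between
#' coupling and repulsion phase by the current frequency odds. Allele labels
#' follow the dosage coding: `A`/`B` denote the counted allele at locus 1
#' and 2 respectively.
#'
#' @param d1,d2 Dosage vectors (0/1/2; `NA` allowed) at the two loci.
#' @param max_iter Maximum EM iterations.
#' @param tol Convergence tolerance on the largest frequency change.
#' @return A list with `freqs` (named `f_AB`, `f_Ab`, `f_aB`, `f_ab`),
#'   `D` (`f_AB - p_A p_B`), `r2`, `converged`, `n_iter`, and the marginal
#'   allele frequencies `p_A`, `p_B`.
#' @export
em_haplotype_freqs <- function(d1, d2, max_iter = 1000L, tol = 1e-10) {
  cc <- !is.na(d1) & !is.na(d2)
  x <- d1[cc]; y <- d2[cc]
  n <- length(x)
  if (n < 1L) stop("no complete cases", call. = FALSE)
  pA <- mean(x) / 2
  pB <- mean(y) / 2
  if (pA <= 0 || pA >= 1 || pB <= 0 || pB >= 1)
    stop("both loci must be polymorphic among complete cases", call. = FALSE)
  # genotype table: counts of (x, y) in 0..2 x 0..2
  tab <- matrix(0L, 3L, 3L)
  for (k in seq_len(n)) tab[x[k] + 1L, y[k] + 1L] <- tab[x[k] + 1L, y[k] + 1L] + 1L
  n_dh <- tab[2L, 2L]

  # unambiguous haplotype counts contributed by the eight resolved classes;
  # haplotype order: AB, Ab, aB, ab with "A"/"B" = counted allele present
  base <- numeric(4)
  add <- function(cnt, hap, times) base[hap] <<- base[hap] + cnt * times
  # genotype (x,y): x copies of A spread over two haplotypes
  add(tab[3, 3], 1, 2)                       # (2,2): AB,AB
  add(tab[3, 2], 1, 1); add(tab[3, 2], 2, 1) # (2,1): AB,Ab
  add(tab[3, 1], 2, 2)                       # (2,0): Ab,Ab
  add(tab[2, 3], 1, 1); add(tab[2, 3], 3, 1) # (1,2): AB,aB
  add(tab[2, 1], 2, 1); add(tab[2, 1], 4, 1) # (1,0): Ab,ab
  add(tab[1, 3], 3, 2)                       # (0,2): aB,aB
  add(tab[1, 2], 3, 1); add(tab[1, 2], 4, 1) # (0,1): aB,ab
  add(tab[1, 1], 4, 2)                       # (0,0): ab,ab

  f <- c(pA * pB, pA * (1 - pB), (1 - pA) * pB, (1 - pA) * (1 - pB))
  converged <- FALSE
  it <- 0L
  repeat {
    it <- it + 1L
    coup <- f[1] * f[4]
    rep_ <- f[2] * f[3]
    w <- if (coup + rep_ > 0) coup / (coup + rep_) else 0.5
    cnt <- base
    cnt[c(1, 4)] <- cnt[c(1, 4)] + n_dh * w
    cnt[c(2, 3)] <- cnt[c(2, 3)] + n_dh * (1 - w)
    f_new <- cnt / (2 * n)
    delta <- max(abs(f_new - f))
    f <- f_new
    if (delta < tol) { converged <- TRUE; break }
    if (it >= max_iter) break
  }
  D <- f[1] - pA * pB
  r2 <- D^2 / (pA * (1 - pA) * pB * (1 - pB))
  list(freqs = stats::setNames(f, c("f_AB", "f_Ab", "f_aB", "f_ab")),
       D = D, r2 = min(1, r2), converged = converged, n_iter = it,
       p_A = pA, p_B = pB)
}

#' Squared dosage-correlation LD estimator
#'
#' Composite estimator `cor(d1, d2)^2`, equal to the EM r-squared whenever
#' phase is unambiguous; kept as a fast cross-check.
#'
#' @inheritParams em_haplotype_freqs
#' @return Squared Pearson correlation of the dosages.
#' @export
dosage_r2 <- function(d1, d2) {
  cc <- !is.na(d1) & !is.na(d2)
  stats::cor(d1[cc], d2[cc])^2
}

#' Adjacent-pair linkage disequilibrium summary
#'
#' Computes r-squared and physical distance for every pair of adjacent SNPs
#' within each chromosome. r-squared is `D^2 / (p_A(1-p_A) p_B(1-p_B))` with
#' `D` from the two-locus EM (or the squared dosage correlation when
#' `method = "dosage"`). Pairs involving a monomorphic locus, or whose EM
#' does not converge, carry `NA` and are excluded from the aggregates.
#'
#' @param G Complete dosage matrix.
#' @param map Marker map aligned to `G`'s columns, sorted by
#'   (chromosome, position).
#' @param method `"em"` (default) or `"dosage"`.
#' @return A list of class `ld_summary`: `pairs` (data.frame `chromosome`,
#'   `pos1_bp`, `pos2_bp`, `d_mb`, `r2` — one row per adjacent pair),
#'   `mean_r2`, `sd_r2`, `mean_d_mb`, `sd_d_mb`, `n_pairs`, `n_na`.
#' @export
adjacent_r2 <- function(G, map, method = c("em", "dosage")) {
  method <- match.arg(method)
  stopifnot(ncol(G) == nrow(map))
  ord <- order(map$chromosome, map$position_bp)
  if (any(ord != seq_len(nrow(map))))
    stop("map must be sorted by (chromosome, position_bp)", call. = FALSE)
  first <- which(!duplicated(map$chromosome))
  j1 <- setdiff(seq_len(nrow(map) - 1L), first[-1] - 1L)
  # j1 indexes the left member of each within-chromosome adjacent pair
  j1 <- j1[map$chromosome[j1] == map$chromosome[j1 + 1L]]
  r2 <- rep(NA_real_, length(j1))
  for (k in seq_along(j1)) {
    a <- G[, j1[k]]; b <- G[, j1[k] + 1L]
    va <- stats::var(a); vb <- stats::var(b)
    if (is.na(va) || is.na(vb) || va == 0 || vb == 0) next
    if (method == "dosage") {
      r2[k] <- dosage_r2(a, b)
    } else {
      em <- em_haplotype_freqs(a, b)
      if (em$converged) r2[k] <- em$r2
    }
  }
  d_mb <- (map$position_bp[j1 + 1L] - map$position_bp[j1]) / 1e6
  pairs <- data.frame(chromosome = map$chromosome[j1],
                      pos1_bp = map$position_bp[j1],
                      pos2_bp = map$position_bp[j1 + 1L],
                      d_mb = d_mb, r2 = r2)
  structure(list(
    pairs = pairs,
    mean_r2 = mean(r2, na.rm = TRUE),
    sd_r2 = stats::sd(r2, na.rm = TRUE),
    mean_d_mb = mean(d_mb),
    sd_d_mb = stats::sd(d_mb),
    n_pairs = nrow(pairs),
    n_na = sum(is.na(r2))
  ), class = "ld_summary")
}

#' @export
print.ld_summary <- function(x, ...) {
  cat(sprintf("LD summary: %d adjacent pairs (%d unusable)\n",
              x$n_pairs, x$n_na))
  cat(sprintf("  mean r2 = %.4f (SD %.4f); mean d = %.3f Mb (SD %.3f)\n",
              x$mean_r2, x$sd_r2, x$mean_d_mb, x$sd_d_mb))
  invisible(x)
}

#' Distance-binned LD aggregates
#'
#' Aggregates adjacent-pair r-squared into half-open distance bins
#' `[lo, hi)`; pairs at or beyond the last edge fall into an overflow bin.
#' With `cumulative = TRUE` the bins are instead the nested ranges
#' `[first_edge, edge_k)`, matching the overlapping 0-x Mb ranges often
#' quoted in LD surveys.
#'
#' @param ld An `ld_summary` from [adjacent_r2()].
#' @param bin_edges_mb Ascending bin edges in Mb (default
#'   `c(0, 0.1, 0.2, 0.5, 1)`).
#' @param r2_threshold Threshold for the exceedance fraction (default 0.3).
#' @param cumulative Use nested `[e1, e_k)` ranges instead of disjoint bins.
#' @return data.frame with columns `bin_lo_mb`, `bin_hi_mb`, `n_pairs`,
#'   `mean_r2`, `frac_gt_threshold`.
#' @export
bin_summary <- function(ld, bin_edges_mb = c(0, 0.1, 0.2, 0.5, 1),
                        r2_threshold = 0.3, cumulative = FALSE) {
  stopifnot(inherits(ld, "ld_summary"))
  if (length(bin_edges_mb) < 2L || is.unsorted(bin_edges_mb, strictly = TRUE))
    stop("bin_edges_mb must be >= 2 ascending values", call. = FALSE)
  p <- ld$pairs[!is.na(ld$pairs$r2), , drop = FALSE]
  if (cumulative) {
    lo <- rep(bin_edges_mb[1], length(bin_edges_mb) - 1L)
    hi <- bin_edges_mb[-1]
  } else {
    lo <- c(bin_edges_mb[-length(bin_edges_mb)],
            bin_edges_mb[length(bin_edges_mb)])
    hi <- c(bin_edges_mb[-1], Inf)
  }
  res <- lapply(seq_along(lo), function(k) {
    inb <- p$d_mb >= lo[k] & p$d_mb < hi[k]
    n <- sum(inb)
    data.frame(bin_lo_mb = lo[k], bin_hi_mb = hi[k], n_pairs = n,
               mean_r2 = if (n > 0) mean(p$r2[inb]) else NA_real_,
               frac_gt_threshold = if (n > 0)
                 mean(p$r2[inb] > r2_threshold) else NA_real_)
  })
  do.call(rbind, res)
}
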