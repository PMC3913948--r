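#' The study ladder of panel sizes
#'
#' The standard sequence of equally-spaced panel sizes evaluated across the
#' package: 100, 200, 500, 1,000, 2,000, 4,000, 6,000, 8,000, 10,000,
#' 20,000, 30,000, truncated to the available marker count and completed by
#' the full panel.
#'
#' @param n_markers Total markers available.
#' @return Integer vector of panel sizes ending with `n_markers`.
#' @export
panel_ladder <- function(n_markers) {
  sizes <- c(100L, 200L, 500L, 1000L, 2000L, 4000L, 6000L, 8000L,
             10000L, 20000L, 30000L)
  c(sizes[sizes < n_markers], n_markers)
}

#' Select an equally-spaced SNP panel
#'
#' Markers are apportioned to chromosomes proportionally to physical span
#' (largest-remainder rounding, at least one marker per chromosome whenever
#' `k` allows). Within a chromosome, `k_c` grid points are placed
#' endpoint-inclusive across the marker span (midpoint when `k_c = 1`), and
#' each grid point takes the nearest marker by bp position, ties broken
#' toward the lower position; an already-used marker is replaced by the
#' nearest unused one. `method = "every_mth"` instead takes every m-th
#' marker in map order, as a sensitivity alternative.
#'
#' @param map Sorted marker map.
#' @param k Number of markers to select (`1 <= k <=` marker count).
#' @param method `"grid"` (default) or `"every_mth"`.
#' @return A list of class `panel_spec` with `target_count` and sorted
#'   unique `indices` into `map`.
#' @export
select_equally_spaced <- function(map, k, method = c("grid", "every_mth")) {
  method <- match.arg(method)
  m <- nrow(map)
  if (k < 1 || k > m) stop("k must be between 1 and the marker count",
                           call. = FALSE)
  if (k == m) {
    return(structure(list(target_count = as.integer(k),
                          indices = seq_len(m)), class = "panel_spec"))
  }
  if (method == "every_mth") {
    idx <- unique(round(seq(1, m, length.out = k)))
    return(structure(list(target_count = as.integer(k), indices = idx),
                     class = "panel_spec"))
  }
  chroms <- unique(map$chromosome)
  span <- vapply(chroms, function(c) {
    p <- map$position_bp[map$chromosome == c]
    max(max(p) - min(p), 1)
  }, numeric(1))
  avail <- vapply(chroms, function(c) sum(map$chromosome == c), integer(1))
  k_c <- largest_remainder(span, k,
                           min_each = if (k >= length(chroms)) 1L else 0L)
  # cap at available markers, pushing surplus to chromosomes with room
  repeat {
    over <- k_c > avail
    if (!any(over)) break
    surplus <- sum(k_c[over] - avail[over])
    k_c[over] <- avail[over]
    room <- which(k_c < avail)
    if (length(room) == 0L || surplus == 0L) break
    addto <- room[order(span[room] / pmax(k_c[room], 1),
                        decreasing = TRUE)]
    for (i in rep_len(addto, surplus)) k_c[i] <- k_c[i] + 1L
  }
  idx <- integer(0)
  for (ci in seq_along(chroms)) {
    if (k_c[ci] == 0L) next
    rows <- which(map$chromosome == chroms[ci])
    pos <- map$position_bp[rows]
    grid <- if (k_c[ci] == 1L) (min(pos) + max(pos)) / 2
            else seq(min(pos), max(pos), length.out = k_c[ci])
    used <- logical(length(rows))
    pick <- integer(k_c[ci])
    for (g in seq_along(grid)) {
      dist <- abs(pos - grid[g])
      dist[used] <- Inf
      best <- which(dist == min(dist))
      best <- best[which.min(pos[best])]
      used[best] <- TRUE
      pick[g] <- rows[best]
    }
    idx <- c(idx, pick)
  }
  structure(list(target_count = as.integer(k), indices = sort(unique(idx))),
            class = "panel_spec")
}

#' Build the VanRaden genomic relationship matrix
#'
#' `G = (M - 2P)(M - 2P)' / (2 sum_i p_i (1 - p_i)) + jitter * I`, where `M`
#' holds minor-allele dosages for the panel's markers and `p_i` is the
#' counted-allele frequency recomputed on the analyzed individuals. The
#' small diagonal jitter keeps the matrix positive definite.
#'
#' @param G Complete dosage matrix (individuals x markers).
#' @param panel Optional `panel_spec` (or integer index vector); default
#'   uses all markers.
#' @param jitter Scalar added to the diagonal (default `1e-4`).
#' @return Symmetric positive-definite matrix with attributes `panel`,
#'   `jitter` and `allele_freqs`.
#' @export
build_grm <- function(G, panel = NULL, jitter = 1e-4) {
  idx <- if (is.null(panel)) seq_len(ncol(G))
         else if (inherits(panel, "panel_spec")) panel$indices
         else as.integer(panel)
  if (length(idx) == 0L) stop("panel is empty", call. = FALSE)
  M <- G[, idx, drop = FALSE]
  if (anyNA(M)) stop("genotypes must be complete; fill missing first",
                     call. = FALSE)
  p <- colMeans(M) / 2
  if (any(p <= 0 | p >= 1))
    stop("panel contains monomorphic markers; apply QC filters first",
         call. = FALSE)
  Z <- M - matrix(2 * p, nrow(M), length(idx), byrow = TRUE)
  K <- tcrossprod(Z) / (2 * sum(p * (1 - p)))
  diag(K) <- diag(K) + jitter
  dimnames(K) <- list(rownames(G), rownames(G))
  attr(K, "panel") <- idx
  attr(K, "jitter") <- jitter
  attr(K, "allele_freqs") <- p
  K
}

#' Correlations between the elements of two genomic relationship matrices
#'
#' Pearson correlations of the diagonal elements (`r_D`), the strictly
#' upper-triangular elements (`r_N`), and all elements of the flattened
#' matrices (`r_A`, diagonal once and each off-diagonal twice), comparing a
#' reduced-panel matrix with the full-panel baseline.
#'
#' @param sub,full Genomic relationship matrices over the same individuals
#'   in the same order.
#' @return A list of class `grm_comparison` with `r_D`, `r_N`, `r_A`.
#' @export
grm_correlation <- function(sub, full) {
  if (!all(dim(sub) == dim(full)))
    stop("matrices must have identical dimensions", call. = FALSE)
  up <- upper.tri(sub)
  structure(list(
    r_D = stats::cor(diag(sub), diag(full)),
    r_N = stats::cor(sub[up], full[up]),
    r_A = stats::cor(as.vector(sub), as.vector(full))
  ), class = "grm_comparison")
}

#' Write/read a genomic relationship matrix as sparse-style text triples
#'
#' Plain-text persistence: one `(i, j, value)` row per element of the lower
#' triangle including the diagonal, with an id header line.
#'
#' @param K Relationship matrix with rownames.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_grm_tsv <- function(K, path) {
  ids <- rownames(K) %||% sprintf("ind%05d", seq_len(nrow(K)))
  lt <- which(lower.tri(K, diag = TRUE), arr.ind = TRUE)
  df <- data.frame(i = ids[lt[, 1]], j = ids[lt[, 2]],
                   value = K[lt])
  utils::write.table(df, path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}

#' @rdname write_grm_tsv
#' @export
read_grm_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  ids <- unique(c(df$i, df$j))
  n <- length(ids)
  K <- matrix(0, n, n, dimnames = list(ids, ids))
  K[cbind(match(df$i, ids), match(df$j, ids))] <- df$value
  K[cbind(match(df$j, ids), match(df$i, ids))] <- df$value
  K
}
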