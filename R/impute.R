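#' Naive reference-based genotype imputation
#'
#' A transparent stand-in for haplotype-based imputation software: for each
#' untyped marker, the typed flanking marker with the highest absolute
#' dosage correlation in the reference cohort is chosen as predictor, and
#' each study individual receives the modal reference genotype conditional
#' on its genotype at that predictor (falling back to the marker's modal
#' reference genotype when the conditional cell is empty, or when no typed
#' marker exists on the chromosome). Typed markers pass through unchanged.
#' The interface accepts any externally imputed matrix in its place, so the
#' stand-in is swappable for a real phasing/imputation tool.
#'
#' @param low Dosage matrix of the study cohort at the low-density panel.
#' @param low_map Marker map of `low` (subset of `ref_map` by `marker_id`).
#' @param ref Complete dosage matrix of the reference cohort at full
#'   density; individuals must be disjoint from the study cohort.
#' @param ref_map Full-density marker map.
#' @return A list of class `imputation_result` with `genotypes` (study
#'   cohort at full density), `imputed_markers` (indices into `ref_map` of
#'   the untyped markers) and `predictor` (chosen flank per untyped marker,
#'   `NA` when the mode fallback was used).
#' @export
naive_impute <- function(low, low_map, ref, ref_map) {
  if (anyNA(ref)) stop("reference panel must be complete", call. = FALSE)
  typed <- match(low_map$marker_id, ref_map$marker_id)
  if (anyNA(typed))
    stop("low-density markers must be a subset of the reference markers",
         call. = FALSE)
  if (length(intersect(rownames(low), rownames(ref))) > 0L)
    stop("reference individuals must be disjoint from the study cohort",
         call. = FALSE)
  m <- nrow(ref_map)
  n <- nrow(low)
  out <- matrix(NA_integer_, n, m,
                dimnames = list(rownames(low), ref_map$marker_id))
  out[, typed] <- as.matrix(low)
  untyped <- setdiff(seq_len(m), typed)
  predictor <- rep(NA_integer_, length(untyped))
  is_typed <- seq_len(m) %in% typed
  ref_mode <- apply(ref, 2, function(x) which.max(tabulate(x + 1L, 3L)) - 1L)
  for (k in seq_along(untyped)) {
    j <- untyped[k]
    same <- which(is_typed & ref_map$chromosome == ref_map$chromosome[j])
    if (length(same) == 0L) {
      warning("no typed marker on chromosome ", ref_map$chromosome[j],
              "; falling back to the reference mode for ",
              ref_map$marker_id[j])
      out[, j] <- ref_mode[j]
      next
    }
    # flanking typed markers: nearest on each side
    pos <- ref_map$position_bp
    left <- same[pos[same] < pos[j]]
    right <- same[pos[same] > pos[j]]
    cand <- c(if (length(left)) left[which.max(pos[left])],
              if (length(right)) right[which.min(pos[right])])
    if (length(cand) == 0L) cand <- same[which.min(abs(pos[same] - pos[j]))]
    cors <- vapply(cand, function(f) {
      r <- suppressWarnings(stats::cor(ref[, j], ref[, f]))
      if (is.na(r)) 0 else abs(r)
    }, numeric(1))
    flank <- cand[which.max(cors)]
    predictor[k] <- flank
    # conditional modal genotype table from the reference
    cond_mode <- vapply(0:2, function(gflank) {
      sub <- ref[ref[, flank] == gflank, j]
      if (length(sub) == 0L) return(ref_mode[j])
      which.max(tabulate(sub + 1L, 3L)) - 1L
    }, numeric(1))
    gf <- out[, flank]
    filled <- ifelse(is.na(gf), ref_mode[j], cond_mode[gf + 1L])
    out[, j] <- as.integer(filled)
  }
  structure(list(genotypes = out, imputed_markers = untyped,
                 predictor = predictor),
            class = "imputation_result")
}

#' Imputation concordance
#'
#' Percentage of scored genotype calls exactly equal to the truth, overall
#' and per individual (mean and SD across individuals), plus a per-marker
#' breakdown.
#'
#' @param truth Complete true dosage matrix at full density.
#' @param imputed Imputed dosage matrix (same dimensions/order).
#' @param scored_markers Column indices to score (the untyped set).
#' @return A list with `overall_pct`, `per_individual_pct` (vector),
#'   `mean_pct`, `sd_pct`, and `per_marker_pct`.
#' @export
imputation_accuracy <- function(truth, imputed, scored_markers) {
  if (!all(dim(truth) == dim(imputed)))
    stop("matrices must be aligned", call. = FALSE)
  if (length(scored_markers) == 0L)
    stop("scored marker set is empty", call. = FALSE)
  tt <- truth[, scored_markers, drop = FALSE]
  ii <- imputed[, scored_markers, drop = FALSE]
  hit <- tt == ii
  per_ind <- rowMeans(hit) * 100
  list(overall_pct = mean(hit) * 100,
       per_individual_pct = per_ind,
       mean_pct = mean(per_ind),
       sd_pct = stats::sd(per_ind),
       per_marker_pct = colMeans(hit) * 100)
}
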