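#' Compare GEBVs from a reduced panel with the full-panel baseline
#'
#' Pearson correlation plus the ordinary least-squares regression slope with
#' the reduced-panel GEBVs as dependent variable and the full-panel GEBVs as
#' independent variable; a slope below 1 indicates downward-biased
#' (shrunken) GEBVs at the lower density.
#'
#' @param sub_gebv,full_gebv Aligned GEBV vectors (length >= 3).
#' @return A list of class `gebv_comparison` with `correlation` and
#'   `regression_slope`.
#' @export
gebv_compare <- function(sub_gebv, full_gebv) {
  if (length(sub_gebv) != length(full_gebv) || length(sub_gebv) < 3L)
    stop("need aligned vectors of length >= 3", call. = FALSE)
  if (stats::var(sub_gebv) == 0 || stats::var(full_gebv) == 0)
    stop("zero-variance GEBV vector", call. = FALSE)
  structure(list(
    correlation = stats::cor(sub_gebv, full_gebv),
    regression_slope = stats::cov(sub_gebv, full_gebv) /
      stats::var(full_gebv)
  ), class = "gebv_comparison")
}

#' Variance components as percentages of the full-panel estimates
#'
#' 100 x (reduced-panel posterior mean / full-panel posterior mean) for the
#' residual, genetic and phenotypic variances, as tabulated next to
#' absolute estimates in cross-density comparisons.
#'
#' @param sub,full `posterior_summary` objects fitted on identical records.
#' @return A list with `sigma_e2_pct`, `sigma_g2_pct`, `sigma_p2_pct`
#'   (`NA` where the full-panel component is zero).
#' @export
variance_explained_percent <- function(sub, full) {
  stopifnot(inherits(sub, "posterior_summary"),
            inherits(full, "posterior_summary"))
  pct <- function(a, b) if (b["mean"] == 0) NA_real_
                        else 100 * unname(a["mean"] / b["mean"])
  list(sigma_e2_pct = pct(sub$sigma_e2, full$sigma_e2),
       sigma_g2_pct = pct(sub$sigma_g2, full$sigma_g2),
       sigma_p2_pct = pct(sub$sigma_p2, full$sigma_p2))
}

#' Cross-panel correlations along a density ladder
#'
#' Correlates, across panel sizes, the GRM upper-triangle agreement `r_N`
#' with the mean adjacent-pair r-squared, and the mean r-squared with the
#' estimated variance components (genetic variance rises and residual
#' variance falls as denser panels capture more LD with the QTLs).
#'
#' @param ladder A `ladder_result` from [run_pipeline()], or its `table`.
#' @param trait Trait name to use for the variance-component correlations
#'   (default: first trait in the table).
#' @return A list with `cor_rN_mean_r2`, `cor_mean_r2_sigma_g2`,
#'   `cor_mean_r2_sigma_e2`, and `n_panels`.
#' @export
cross_panel_statistics <- function(ladder, trait = NULL) {
  tab <- if (inherits(ladder, "ladder_result")) ladder$table else ladder
  tab <- tab[tab$model == "linear", , drop = FALSE]
  trait <- trait %||% tab$trait[1]
  tab <- tab[tab$trait == trait, , drop = FALSE]
  if (nrow(tab) < 3L) stop("need at least 3 ladder rows", call. = FALSE)
  ok_rn <- !is.na(tab$r_N)
  list(
    cor_rN_mean_r2 = stats::cor(tab$r_N[ok_rn], tab$mean_r2[ok_rn]),
    cor_mean_r2_sigma_g2 = stats::cor(tab$mean_r2, tab$sigma_g2_mean),
    cor_mean_r2_sigma_e2 = stats::cor(tab$mean_r2, tab$sigma_e2_mean),
    n_panels = nrow(tab)
  )
}

#' Trait specification for the pipeline
#'
#' Two presets bracket the genetic architectures of interest: a continuous
#' carcass-weight-like trait with a few large QTLs on a polygenic background
#' and an ordinal marbling-like trait controlled only by small QTLs, scored
#' into 12 right-heavy categories on the liability scale.
#'
#' @param name Trait label.
#' @param type `"continuous"` or `"ordinal"`.
#' @param n_large,n_small QTL counts per effect class.
#' @param large_sd,small_sd Effect standard deviations.
#' @param target_h2 Heritability of the (liability) trait.
#' @param fit_threshold Also fit the threshold models (ordinal traits only).
#' @param binary_split Binary-classification cut for the threshold model.
#' @return An object of class `trait_spec`.
#' @export
trait_spec <- function(name, type = c("continuous", "ordinal"),
                       n_large = 0L, n_small = 300L,
                       large_sd = 2, small_sd = 0.25,
                       target_h2 = 0.5, fit_threshold = FALSE,
                       binary_split = 6L) {
  type <- match.arg(type)
  structure(list(name = name, type = type, n_large = n_large,
                 n_small = n_small, large_sd = large_sd,
                 small_sd = small_sd, target_h2 = target_h2,
                 fit_threshold = fit_threshold,
                 binary_split = as.integer(binary_split)),
            class = "trait_spec")
}

#' Default trait pair: carcass-weight-like and marbling-like
#' @return Named list of two [trait_spec()] objects.
#' @export
default_traits <- function() {
  list(
    carcass_weight = trait_spec("carcass_weight", "continuous",
                                n_large = 3L, n_small = 300L,
                                large_sd = 2, small_sd = 0.25,
                                target_h2 = 0.54),
    marbling = trait_spec("marbling", "ordinal",
                          n_large = 0L, n_small = 300L,
                          large_sd = 0, small_sd = 0.25,
                          target_h2 = 0.68, fit_threshold = FALSE)
  )
}

#' Pipeline configuration
#'
#' Bundles every stage's settings. Defaults emulate the motivating study
#' design: an 872-animal cohort genotyped on a 50K-like chip, a disjoint
#' 494-animal reference cohort for imputation, about 2% missing genotypes,
#' the standard QC thresholds, the 100-to-30,000 panel ladder, and the full
#' single-chain Gibbs protocol.
#'
#' @param sim A [sim_config()].
#' @param n_animals Study-cohort size.
#' @param n_reference Reference-cohort size (0 disables the imputation arm).
#' @param missing_rate Genotype missingness before filling.
#' @param qc A [qc_config()].
#' @param ladder Panel sizes; `NULL` uses [panel_ladder()] on the post-QC
#'   marker count.
#' @param chain A [chain_config()].
#' @param traits List of [trait_spec()]s.
#' @param impute_sizes Panel sizes receiving an imputation arm (must be in
#'   the ladder), or `NULL`.
#' @param seed Master seed; all stage seeds derive from it.
#' @param outdir Output directory for TSV reports and figures, or `NULL`.
#' @param make_plots Write diagnostic figures when `outdir` is set.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), n_animals = 872L,
                            n_reference = 494L, missing_rate = 0.02,
                            qc = qc_config(), ladder = NULL,
                            chain = chain_config(), traits = default_traits(),
                            impute_sizes = c(4000L, 10000L), seed = 1L,
                            outdir = NULL, make_plots = FALSE) {
  structure(list(sim = sim, n_animals = as.integer(n_animals),
                 n_reference = as.integer(n_reference),
                 missing_rate = missing_rate, qc = qc, ladder = ladder,
                 chain = chain, traits = traits,
                 impute_sizes = impute_sizes, seed = as.integer(seed),
                 outdir = outdir, make_plots = make_plots),
            class = "pipeline_config")
}

fit_one <- function(y, X, K, chain, seed, model, binary_split = 6L) {
  ch <- chain_config(n_iter = chain$n_iter, burn_in = chain$burn_in,
                     thin = chain$thin, seed = seed,
                     fixed_variances = chain$fixed_variances)
  switch(model,
    linear = gibbs_model1(y, X, K, ch),
    `threshold-binary` = gibbs_model2(y, X, K, ch, mode = "binary",
                                      binary_split = binary_split),
    `threshold-ordinal` = gibbs_model2(y, X, K, ch, mode = "ordinal"),
    stop("unknown model ", model))
}

#' Run the end-to-end cross-density evaluation pipeline
#'
#' Simulates (haplotypes, genotypes, phenotypes), applies QC and missing-
#' genotype filling, then for every panel in the ladder: selects an
#' equally-spaced subset, summarizes adjacent-pair LD, builds the VanRaden
#' G matrix, compares it with the full-panel matrix, fits the Gibbs
#' sampler(s) per trait, and compares GEBVs and variance components with the
#' full-panel fit. Optional imputation arms impute selected low panels back
#' to full density through the reference cohort and repeat the fits.
#' Fully deterministic given the master seed.
#'
#' @param config A [pipeline_config()].
#' @return An object of class `ladder_result`: `table` (one row per
#'   panel x trait x model), `fits`, `ld`, `grm_comparisons`, `truth`,
#'   `imputation`, `seeds` and `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  seeds <- derive_seeds(config$seed, 6L)

  message("stage simdata: simulating haplotype panel")
  sim <- config$sim
  sim$seed <- seeds[1]
  panel <- tryCatch(simulate_haplotypes(sim),
                    error = function(e) stop("stage simdata: ",
                                             conditionMessage(e),
                                             call. = FALSE))
  n_tot <- config$n_animals + config$n_reference
  G_all <- sample_genotypes(panel, n_tot, seed = seeds[2])
  study_rows <- seq_len(config$n_animals)
  G_study <- G_all[study_rows, , drop = FALSE]
  G_ref <- if (config$n_reference > 0)
    G_all[-study_rows, , drop = FALSE] else NULL

  message("stage qc: masking, filtering, filling")
  G_masked <- mask_genotypes(G_study, config$missing_rate, seed = seeds[3])
  qc_out <- tryCatch(apply_filters(G_masked, panel$map, config$qc),
                     error = function(e) stop("stage qc: ",
                                              conditionMessage(e),
                                              call. = FALSE))
  keep_idx <- match(qc_out$map$marker_id, panel$map$marker_id)
  G_true <- G_study[, keep_idx, drop = FALSE]
  G <- fill_missing(qc_out$genotypes, config$qc, qc_out$map)
  map <- qc_out$map
  if (!is.null(G_ref)) G_ref <- G_ref[, keep_idx, drop = FALSE]
  m <- ncol(G)

  ladder <- config$ladder %||% panel_ladder(m)
  ladder <- sort(unique(pmin(ladder, m)))

  message("stage simdata: trait simulation")
  trait_data <- list()
  tseeds <- derive_seeds(seeds[4], 2L * length(config$traits))
  for (i in seq_along(config$traits)) {
    tr <- config$traits[[i]]
    qtl <- assign_qtl_effects(map, tr$n_large, tr$n_small,
                              tr$large_sd, tr$small_sd,
                              seed = tseeds[2 * i - 1])
    sim_ph <- simulate_phenotypes(G, qtl, pheno_design(),
                                  target_h2 = tr$target_h2,
                                  seed = tseeds[2 * i])
    ph <- sim_ph$phenotypes
    if (tr$type == "ordinal") {
      tau <- marbling_thresholds(mu = mean(ph$value), sigma = stats::sd(ph$value))
      ph$value <- discretize_liability(ph$value, tau)
    }
    des <- build_design(ph)
    trait_data[[tr$name]] <- list(spec = tr, qtl = qtl, truth = sim_ph,
                                  phenotypes = ph, X = des$X, y = des$y)
  }

  message("stage panels/ld/fit: full-panel baseline")
  K_full <- build_grm(G)
  fseeds <- derive_seeds(seeds[5],
                         (length(ladder) + length(config$impute_sizes) + 1L) *
                           3L * length(config$traits))
  si <- 0L
  next_seed <- function() { si <<- si + 1L; fseeds[si] }
  fit_models <- function(td) {
    models <- "linear"
    if (td$spec$type == "ordinal" && td$spec$fit_threshold)
      models <- c(models, "threshold-binary", "threshold-ordinal")
    models
  }
  run_fits <- function(K, label) {
    fits <- list()
    for (nm in names(trait_data)) {
      td <- trait_data[[nm]]
      for (mod in fit_models(td)) {
        fit <- tryCatch(
          fit_one(td$y, td$X, K, config$chain, next_seed(), mod,
                  td$spec$binary_split),
          error = function(e) stop("stage fit (", label, ", ", nm, ", ",
                                   mod, "): ", conditionMessage(e),
                                   call. = FALSE))
        fits[[paste(nm, mod, sep = ".")]] <- fit
      }
    }
    fits
  }
  full_fits <- run_fits(K_full, "all")
  ld_full <- adjacent_r2(G, map)

  rows <- list()
  fits_store <- list(all = full_fits)
  ld_store <- list(all = ld_full)
  grm_store <- list()
  add_rows <- function(label, size, ld, cmp, fits) {
    for (key in names(fits)) {
      parts <- strsplit(key, ".", fixed = TRUE)[[1]]
      fit <- fits[[key]]
      base <- fits_store$all[[key]]
      is_base <- identical(fit, base)
      gc <- if (is_base) list(correlation = 1, regression_slope = 1)
            else gebv_compare(fit$gebv, base$gebv)
      vp <- variance_explained_percent(fit, base)
      rows[[length(rows) + 1L]] <<- data.frame(
        panel = label, panel_size = size,
        trait = parts[1], model = parts[2],
        mean_r2 = ld$mean_r2, sd_r2 = ld$sd_r2,
        mean_d_mb = ld$mean_d_mb, sd_d_mb = ld$sd_d_mb,
        r_D = cmp$r_D %||% NA_real_, r_N = cmp$r_N %||% NA_real_,
        r_A = cmp$r_A %||% NA_real_,
        sigma_g2_mean = unname(fit$sigma_g2["mean"]),
        sigma_g2_sd = unname(fit$sigma_g2["sd"]),
        sigma_e2_mean = unname(fit$sigma_e2["mean"]),
        sigma_e2_sd = unname(fit$sigma_e2["sd"]),
        sigma_p2_mean = unname(fit$sigma_p2["mean"]),
        sigma_p2_sd = unname(fit$sigma_p2["sd"]),
        h2_mean = unname(fit$h2["mean"]), h2_sd = unname(fit$h2["sd"]),
        pct_sigma_g2 = vp$sigma_g2_pct, pct_sigma_e2 = vp$sigma_e2_pct,
        pct_sigma_p2 = vp$sigma_p2_pct,
        gebv_cor = gc$correlation, gebv_slope = gc$regression_slope,
        converged = fit$converged,
        stringsAsFactors = FALSE)
    }
  }

  for (k in ladder) {
    label <- if (k == m) "all" else format(k, scientific = FALSE)
    message("stage panels/ld/fit: panel ", label)
    if (k == m) {
      add_rows("all", m, ld_full, list(r_D = 1, r_N = 1, r_A = 1), full_fits)
      grm_store[["all"]] <- list(r_D = 1, r_N = 1, r_A = 1)
      next
    }
    ps <- select_equally_spaced(map, k)
    Ksub <- build_grm(G, ps)
    cmp <- grm_correlation(Ksub, K_full)
    ld <- adjacent_r2(G[, ps$indices, drop = FALSE],
                      map[ps$indices, , drop = FALSE])
    fits <- run_fits(Ksub, label)
    add_rows(label, k, ld, cmp, fits)
    fits_store[[label]] <- fits
    ld_store[[label]] <- ld
    grm_store[[label]] <- cmp
  }

  imputation <- list()
  if (!is.null(config$impute_sizes) && !is.null(G_ref) &&
      config$n_reference > 0) {
    for (k in config$impute_sizes) {
      k <- min(k, m)
      if (k == m) next
      label <- paste0("imp", format(k, scientific = FALSE))
      message("stage impute: ", label)
      ps <- select_equally_spaced(map, k)
      low <- G[, ps$indices, drop = FALSE]
      res <- naive_impute(low, map[ps$indices, , drop = FALSE], G_ref, map)
      acc <- imputation_accuracy(G_true, res$genotypes, res$imputed_markers)
      poly <- compute_maf(res$genotypes) > 0
      Kimp <- build_grm(res$genotypes[, poly, drop = FALSE])
      cmp <- grm_correlation(Kimp, K_full)
      fits <- run_fits(Kimp, label)
      add_rows(label, k, ld_full, cmp, fits)  # analysed at full density
      imputation[[label]] <- list(panel_size = k, accuracy = acc,
                                  grm_comparison = cmp)
      fits_store[[label]] <- fits
    }
  }

  table <- do.call(rbind, rows)
  result <- structure(list(table = table, fits = fits_store,
                           ld = ld_store, grm_comparisons = grm_store,
                           truth = lapply(trait_data, function(td)
                             list(qtl = td$qtl, tbv = td$truth$tbv)),
                           imputation = imputation,
                           qc_report = qc_out$report,
                           seeds = seeds, config = config),
                      class = "ladder_result")
  if (!is.null(config$outdir)) write_ladder_outputs(result, config)
  result
}

write_ladder_outputs <- function(result, config) {
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  path <- function(f) file.path(config$outdir, f)
  utils::write.table(format(result$table, digits = 10), path("ladder.tsv"),
                     quote = FALSE, sep = "\t", row.names = FALSE)
  utils::write.table(result$ld$all$pairs, path("ld_pairs_all.tsv"),
                     quote = FALSE, sep = "\t", row.names = FALSE)
  for (nm in names(result$fits$all)) {
    f <- result$fits$all[[nm]]
    utils::write.table(
      data.frame(individual_id = names(f$gebv) %||% seq_along(f$gebv),
                 gebv = f$gebv, gebv_sd = f$gebv_sd),
      path(paste0("gebv_all_", nm, ".tsv")),
      quote = FALSE, sep = "\t", row.names = FALSE)
  }
  manifest <- list(
    package = "snpladder",
    seed = config$seed,
    stage_seeds = result$seeds,
    n_animals = config$n_animals,
    n_reference = config$n_reference,
    ladder = sort(unique(result$table$panel_size)),
    chain = unclass(config$chain)[c("n_iter", "burn_in", "thin")],
    qc = unclass(result$qc_report)
  )
  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  if (isTRUE(config$make_plots)) plot_ladder(result, config$outdir)
  invisible(result)
}

#' Diagnostic figures for a ladder result
#'
#' Writes qualitative analogues of the standard cross-density figures:
#' mean r-squared against mean distance, GRM element correlations against
#' panel size, the percentage of full-panel genetic variance against panel
#' size, and reduced-versus-full GEBV scatter plots.
#'
#' @param result A `ladder_result`.
#' @param outdir Directory for the PDF files.
#' @return Invisibly, the output paths.
#' @export
plot_ladder <- function(result, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  tab <- result$table[result$table$model == "linear", ]
  tr1 <- tab[tab$trait == tab$trait[1], ]
  tr1 <- tr1[order(tr1$panel_size), ]
  paths <- character(0)
  pp <- function(f) { p <- file.path(outdir, f); paths <<- c(paths, p); p }
  grDevices::pdf(pp("ld_decay.pdf"), width = 5, height = 4)
  plot(tr1$mean_d_mb, tr1$mean_r2, pch = 19, xlab = "mean d (Mb)",
       ylab = expression(mean ~ r^2), main = "LD vs marker spacing")
  grDevices::dev.off()
  grDevices::pdf(pp("grm_correlations.pdf"), width = 5, height = 4)
  sub <- tr1[!is.na(tr1$r_N) & tr1$panel != "all", ]
  sub <- sub[!startsWith(sub$panel, "imp"), ]
  plot(sub$panel_size, sub$r_D, type = "b", pch = 1, log = "x",
       ylim = range(c(sub$r_D, sub$r_N, sub$r_A)),
       xlab = "panel size", ylab = "correlation with full-panel G")
  graphics::lines(sub$panel_size, sub$r_N, type = "b", pch = 2)
  graphics::lines(sub$panel_size, sub$r_A, type = "b", pch = 0)
  graphics::legend("bottomright", c("r_D", "r_N", "r_A"), pch = c(1, 2, 0))
  grDevices::dev.off()
  grDevices::pdf(pp("variance_explained.pdf"), width = 5, height = 4)
  plot(tr1$panel_size, tr1$pct_sigma_g2, type = "b", pch = 19, log = "x",
       xlab = "panel size", ylab = "% of full-panel genetic variance")
  grDevices::dev.off()
  invisible(paths)
}

#' @export
print.ladder_result <- function(x, ...) {
  cat("Cross-density ladder result:",
      length(unique(x$table$panel)), "panels x",
      length(unique(x$table$trait)), "traits\n")
  print(x$table[, c("panel", "panel_size", "trait", "model", "mean_r2",
                    "r_N", "sigma_g2_mean", "h2_mean", "pct_sigma_g2",
                    "gebv_cor", "gebv_slope")], digits = 3)
  invisible(x)
}
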