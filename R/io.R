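#' Write genotypes to PLINK PED/MAP text files
#'
#' Dosages are expanded to two allele columns per marker with `A` for the
#' major and `B` for the minor allele (`0 -> A A`, `1 -> A B`, `2 -> B B`,
#' missing -> `0 0`). The MAP file carries chromosome, marker id, a zero
#' genetic distance column, and the 1-based bp position.
#'
#' @param G Dosage matrix (individuals x markers), `NA` for missing.
#' @param map Marker map data.frame (`marker_id`, `chromosome`,
#'   `position_bp`).
#' @param prefix Output path prefix; writes `<prefix>.ped` and
#'   `<prefix>.map`.
#' @return Invisibly, the two file paths.
#' @export
write_plink <- function(G, map, prefix) {
  stopifnot(ncol(G) == nrow(map))
  ids <- rownames(G) %||% sprintf("ind%05d", seq_len(nrow(G)))
  code <- c(`0` = "A A", `1` = "A B", `2` = "B B")
  geno <- matrix("0 0", nrow(G), ncol(G))
  ok <- !is.na(G)
  geno[ok] <- code[as.character(G[ok])]
  ped <- cbind(ids, ids, "0", "0", "0", "-9", geno)
  ped_path <- paste0(prefix, ".ped")
  map_path <- paste0(prefix, ".map")
  utils::write.table(ped, ped_path, quote = FALSE, sep = " ",
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(
    data.frame(map$chromosome, map$marker_id, 0, map$position_bp),
    map_path, quote = FALSE, sep = " ",
    row.names = FALSE, col.names = FALSE)
  invisible(c(ped = ped_path, map = map_path))
}

#' Read genotypes from PLINK PED/MAP text files
#'
#' Inverse of [write_plink()]: dosage counts the `B` allele; `0` alleles are
#' read as missing.
#'
#' @param prefix Path prefix of the `.ped`/`.map` pair.
#' @return A list with `genotypes` (dosage matrix) and `map` (data.frame).
#' @export
read_plink <- function(prefix) {
  map_raw <- utils::read.table(paste0(prefix, ".map"),
                               stringsAsFactors = FALSE)
  map <- data.frame(marker_id = as.character(map_raw[[2]]),
                    chromosome = as.integer(map_raw[[1]]),
                    position_bp = as.numeric(map_raw[[4]]),
                    stringsAsFactors = FALSE)
  ped <- utils::read.table(paste0(prefix, ".ped"),
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  m <- nrow(map)
  stopifnot(ncol(ped) == 6 + 2 * m)
  a1 <- as.matrix(ped[, 6 + 2 * seq_len(m) - 1])
  a2 <- as.matrix(ped[, 6 + 2 * seq_len(m)])
  G <- (a1 == "B") + (a2 == "B")
  G[a1 == "0" | a2 == "0"] <- NA
  storage.mode(G) <- "integer"
  rownames(G) <- ped[[2]]
  colnames(G) <- map$marker_id
  list(genotypes = G, map = map)
}

#' Write/read a dosage matrix as TSV
#'
#' The first column holds individual ids; remaining columns are marker
#' dosages named by marker id. Missing entries are written as `NA`.
#'
#' @param G Dosage matrix.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_dosage_tsv <- function(G, path) {
  df <- data.frame(individual_id = rownames(G) %||%
                     sprintf("ind%05d", seq_len(nrow(G))),
                   G, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}

#' @rdname write_dosage_tsv
#' @export
read_dosage_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  G <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(G) <- "integer"
  rownames(G) <- df[[1]]
  G
}

#' Write/read a phenotype table as TSV
#'
#' Columns: `individual_id`, `value`, `market`, `year`, `age_months`.
#'
#' @param phenos Phenotype data.frame.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_phenotypes_tsv <- function(phenos, path) {
  utils::write.table(phenos, path, quote = FALSE, sep = "\t",
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes_tsv
#' @export
read_phenotypes_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  df$market <- factor(df$market)
  df$year <- factor(df$year)
  df
}

#' Write/read the simulation truth sidecar
#'
#' Persists true breeding values and the QTL table so downstream accuracy
#' checks can be reproduced from disk.
#'
#' @param tbv Named or unnamed numeric vector of true breeding values.
#' @param qtl A `qtl_model`.
#' @param ids Individual ids matching `tbv`.
#' @param prefix Path prefix; writes `<prefix>_tbv.tsv` and
#'   `<prefix>_qtl.tsv`.
#' @return Invisibly, the two paths.
#' @export
write_truth_tsv <- function(tbv, qtl, ids, prefix) {
  tbv_path <- paste0(prefix, "_tbv.tsv")
  qtl_path <- paste0(prefix, "_qtl.tsv")
  utils::write.table(data.frame(individual_id = ids, tbv = tbv),
                     tbv_path, quote = FALSE, sep = "\t", row.names = FALSE)
  utils::write.table(
    data.frame(marker_index = qtl$qtl_marker_indices,
               effect = qtl$effects,
               is_large = qtl$is_large,
               architecture = qtl$architecture_label),
    qtl_path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(c(tbv = tbv_path, qtl = qtl_path))
}

#' @rdname write_truth_tsv
#' @export
read_truth_tsv <- function(prefix) {
  tbv <- utils::read.table(paste0(prefix, "_tbv.tsv"), header = TRUE,
                           sep = "\t", stringsAsFactors = FALSE)
  qtl_df <- utils::read.table(paste0(prefix, "_qtl.tsv"), header = TRUE,
                              sep = "\t", stringsAsFactors = FALSE)
  qtl <- structure(list(
    qtl_marker_indices = qtl_df$marker_index,
    effects = qtl_df$effect,
    is_large = qtl_df$is_large,
    architecture_label = if (nrow(qtl_df)) qtl_df$architecture[1]
                         else "polygenic_only"
  ), class = "qtl_model")
  list(tbv = stats::setNames(tbv$tbv, tbv$individual_id), qtl = qtl)
}
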