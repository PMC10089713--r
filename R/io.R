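# Tab-delimited and JSON serialization for the package's data types.
# Dialects:
#   diallel TSV : female_line, male_line, replicate, n_female, n_male
#                 (+ total_adjusted for adjusted datasets)
#   panel TSV   : line_id, infected, expression (empty cell = missing)
#   genotype TSV: line_id, then one column per variant, cells 0/1/NA
#   truth JSON  : all diallel_truth fields

read_tsv_checked <- function(path, required, what) {
  if (!file.exists(path)) stop_invalid(what, " file not found: ", path)
  if (file.size(path) == 0) stop_invalid(what, " file is empty: ", path)
  x <- read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                  check.names = FALSE)
  miss <- setdiff(required, names(x))
  if (length(miss)) {
    stop_invalid(what, " file ", path, ": malformed header, missing column(s) ",
                 paste(miss, collapse = ", "))
  }
  x
}

#' Write / read a diallel dataset as TSV
#'
#' @param dataset A `diallel_dataset` (possibly adjusted, see
#'   [adjust_productivity()]).
#' @param path File path.
#' @return `read_diallel()` returns a validated `diallel_dataset`;
#'   `write_diallel()` returns `path` invisibly.
#' @export
write_diallel <- function(dataset, path) {
  cols <- c("female_line", "male_line", "replicate", "n_female", "n_male")
  if ("total_adjusted" %in% names(dataset)) cols <- c(cols, "total_adjusted")
  write.table(as.data.frame(dataset)[cols], path, sep = "\t",
              quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_diallel
#' @export
read_diallel <- function(path) {
  x <- read_tsv_checked(
    path, c("female_line", "male_line", "replicate", "n_female", "n_male"),
    "diallel")
  for (col in c("replicate", "n_female", "n_male")) {
    v <- suppressWarnings(as.numeric(x[[col]]))
    bad <- which(is.na(v) & !is.na(x[[col]]))
    if (length(bad)) {
      stop_invalid("diallel file ", path, ": non-numeric `", col,
                   "` at line ", bad[1] + 1L)  # +1 for header
    }
    x[[col]] <- v
  }
  neg <- which(x$n_female < 0 | x$n_male < 0)
  if (length(neg)) {
    stop_invalid("diallel file ", path, ": negative count at line ",
                 neg[1] + 1L)
  }
  x$female_line <- as.character(x$female_line)
  x$male_line <- as.character(x$male_line)
  as_diallel_dataset(x)
}

#' Write / read a line panel as TSV
#'
#' @param panel A `diallel_panel`.
#' @param path File path.
#' @return `read_panel()` returns a `diallel_panel`.
#' @export
write_panel <- function(panel, path) {
  write.table(as.data.frame(panel)[c("line_id", "infected", "expression")],
              path, sep = "\t", quote = FALSE, row.names = FALSE, na = "",
              fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  x <- read_tsv_checked(path, c("line_id", "infected"), "panel")
  x$line_id <- as.character(x$line_id)
  x$infected <- as.integer(x$infected)
  bad <- which(!(x$infected %in% c(0L, 1L)))
  if (length(bad)) {
    stop_invalid("panel file ", path, ": infected must be 0/1 at line ",
                 bad[1] + 1L)
  }
  if (is.null(x$expression)) {
    x$expression <- NA_real_
  } else {
    x$expression <- suppressWarnings(as.numeric(x$expression))
  }
  class(x) <- c("diallel_panel", "data.frame")
  validate_panel(x)
  x
}

#' Write / read a genotype matrix as TSV
#'
#' The TSV layout is one row per line: a `line_id` column followed by one
#' column per variant with cells 0/1/NA.
#'
#' @param genotypes 0/1/`NA` genotype matrix.
#' @param path File path.
#' @return `read_genotypes()` returns the genotype matrix with recomputed
#'   `maf` attribute.
#' @export
write_genotypes <- function(genotypes, path) {
  df <- data.frame(line_id = rownames(genotypes),
                   as.data.frame(genotypes, check.names = FALSE),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_genotypes
#' @export
read_genotypes <- function(path) {
  x <- read_tsv_checked(path, "line_id", "genotype")
  if (ncol(x) < 2) stop_invalid("genotype file ", path, ": no variant columns")
  ids <- as.character(x$line_id)
  G <- as.matrix(x[, -1, drop = FALSE])
  vals <- suppressWarnings(as.integer(G))
  bad <- which(!(vals %in% c(0L, 1L)) & !is.na(G))
  if (length(bad)) {
    row <- (bad[1] - 1L) %% nrow(G) + 1L
    stop_invalid("genotype file ", path, ": unknown genotype code `",
                 G[bad[1]], "` at line ", row + 1L)
  }
  G <- matrix(vals, nrow(G), ncol(G),
              dimnames = list(ids, colnames(G)))
  attr(G, "maf") <- genotype_maf(G)
  G
}

#' Read a genotype matrix from a VCF file
#'
#' One VCF sample per inbred line, `GT` field only. Homozygous reference
#' (`0/0`, `0|0`) maps to 0, homozygous alternate (`1/1`, `1|1`) to 1; any
#' other call — heterozygous, multiallelic or missing — is treated as missing,
#' matching the convention that residual segregating genotypes within an
#' inbred line are removed.
#'
#' @param path Path to a VCF 4.x file (plain text or gzipped).
#' @return Lines x variants 0/1/`NA` matrix with `maf` attribute; variant ids
#'   from the VCF `ID` column (or `CHROM_POS` when missing).
#' @export
read_genotypes_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop_invalid("reading VCF requires the `vcfR` package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  ids <- v@fix[, "ID"]
  fallback <- paste(v@fix[, "CHROM"], v@fix[, "POS"], sep = "_")
  ids <- ifelse(is.na(ids) | ids == ".", fallback, ids)
  code <- function(x) {
    x <- gsub("\\|", "/", x)
    out <- rep(NA_integer_, length(x))
    out[x == "0/0"] <- 0L
    out[x == "1/1"] <- 1L
    out
  }
  G <- apply(gt, 2, code)
  if (is.null(dim(G))) G <- matrix(G, nrow = 1)
  G <- t(G)  # vcfR gives variants x samples
  dimnames(G) <- list(colnames(gt), ids)
  attr(G, "maf") <- genotype_maf(G)
  G
}

#' Write / read ground-truth parameters as JSON
#'
#' @param truth A [diallel_truth()].
#' @param path File path.
#' @return `read_truth()` returns a `diallel_truth`.
#' @export
write_truth <- function(truth, path) {
  x <- unclass(truth)
  x$infection_effects <- as.list(x$infection_effects)  # keep cell names
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  diallel_truth(
    mu = x$mu,
    sigma2_f = x$sigma2_f, sigma2_m = x$sigma2_m, sigma2_fm = x$sigma2_fm,
    sigma2_n = x$sigma2_n, sigma2_nn = x$sigma2_nn, sigma2_e = x$sigma2_e,
    infection_effects = unlist(x$infection_effects),
    self_cross_effect = x$self_cross_effect,
    causal = x$causal,
    mediation = x$mediation
  )
}
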