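#' Simulate a homozygous line x variant genotype matrix
#'
#' Genotypes for fully inbred lines are coded 0/1 (major/minor homozygote);
#' heterozygous calls do not occur and residual segregating sites are treated
#' as missing. Each variant's minor-allele count is fixed exactly at
#' `round(f * n_lines)` with `f` drawn uniformly from `maf_range`, and the
#' minor-allele lines are a uniform random subset, so realized frequencies are
#' controlled by construction. An optional causal variant is embedded the same
#' way at its own target MAF; the causal column is kept free of injected
#' missingness so that downstream effect-recovery and mediation analyses are
#' defined for every line.
#'
#' @param panel A [make_panel()] line panel.
#' @param n_variants Number of variants (>= 1).
#' @param maf_range Length-2 numeric interval within (0, 0.5] from which
#'   per-variant target minor-allele frequencies are drawn.
#' @param causal Optional causal-variant request: a list with elements `id`
#'   (variant name) and `maf` (target minor-allele frequency).
#' @param missing_rate Probability that a non-causal genotype call is missing
#'   (must be < 0.5).
#' @param seed Integer seed.
#'
#' @return An integer matrix (lines x variants, 0/1/`NA`) with `rownames` =
#'   line ids, `colnames` = variant ids, and attribute `maf` giving each
#'   variant's minor-allele frequency among non-missing lines. The causal
#'   variant id, if any, is stored in attribute `causal_id`.
#' @export
#' @examples
#' panel <- make_panel(20, seed = 1)
#' g <- make_genotypes(panel, 50, causal = list(id = "snp_X", maf = 0.3),
#'                     seed = 2)
#' range(attr(g, "maf"))
make_genotypes <- function(panel, n_variants, maf_range = c(0.1, 0.5),
                           causal = NULL, missing_rate = 0, seed = 1L) {
  validate_panel(panel)
  if (!is.numeric(n_variants) || n_variants < 1 ||
      n_variants != round(n_variants)) {
    stop_invalid("`n_variants` must be a positive integer")
  }
  if (length(maf_range) != 2L || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2]) {
    stop_invalid("`maf_range` must lie within (0, 0.5]")
  }
  if (missing_rate < 0 || missing_rate >= 0.5) {
    stop_invalid("`missing_rate` must be in [0, 0.5)")
  }
  n_variants <- as.integer(n_variants)
  n <- nrow(panel)
  ids <- sprintf("V%0*d", max(4L, nchar(as.character(n_variants))),
                 seq_len(n_variants))
  if (!is.null(causal)) {
    if (is.null(causal$id) || is.null(causal$maf)) {
      stop_invalid("`causal` must be a list with elements `id` and `maf`")
    }
    ids[1L] <- as.character(causal$id)
  }

  G <- with_seed(seed, {
    G <- matrix(0L, n, n_variants, dimnames = list(panel$line_id, ids))
    for (v in seq_len(n_variants)) {
      f <- if (v == 1L && !is.null(causal)) causal$maf else
        runif(1, maf_range[1], maf_range[2])
      k <- as.integer(round_half_up(f * n))
      G[sample.int(n, k), v] <- 1L
    }
    if (missing_rate > 0) {
      miss <- matrix(runif(n * n_variants) < missing_rate, n, n_variants)
      if (!is.null(causal)) miss[, 1L] <- FALSE
      G[miss] <- NA_integer_
    }
    G
  })
  attr(G, "maf") <- genotype_maf(G)
  if (!is.null(causal)) attr(G, "causal_id") <- ids[1L]
  G
}

#' Minor-allele frequency per variant
#'
#' Computed among non-missing lines and folded to the minor allele, so
#' `0 <= maf <= 0.5` always; all-missing variants get `NA`.
#'
#' @param genotypes A 0/1/`NA` lines x variants matrix.
#' @return Named numeric vector of per-variant MAFs.
#' @export
genotype_maf <- function(genotypes) {
  bad <- !(genotypes %in% c(0L, 1L) | is.na(genotypes))
  if (any(bad)) stop_invalid("genotype entries must be 0, 1 or NA")
  f <- colMeans(genotypes == 1L, na.rm = TRUE)
  f[is.nan(f)] <- NA_real_
  pmin(f, 1 - f)
}

#' Filter variants by minor-allele frequency
#'
#' Removes variants whose MAF among non-missing lines falls below `maf_min`
#' (the boundary is inclusive: MAF exactly equal to `maf_min` is retained)
#' and variants with no non-missing calls. MAF metadata is recomputed on the
#' retained set.
#'
#' @param genotypes A 0/1/`NA` genotype matrix.
#' @param maf_min Minimum minor-allele frequency, default 0.10.
#' @return The filtered genotype matrix with updated `maf` attribute.
#' @export
filter_variants <- function(genotypes, maf_min = 0.10) {
  maf <- genotype_maf(genotypes)
  keep <- !is.na(maf) & maf >= maf_min
  if (!any(keep)) {
    warning("no variants pass the MAF filter", call. = FALSE)
  }
  out <- genotypes[, keep, drop = FALSE]
  attr(out, "maf") <- maf[keep]
  cid <- attr(genotypes, "causal_id")
  if (!is.null(cid) && cid %in% colnames(out)) attr(out, "causal_id") <- cid
  out
}
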