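#' Female line means of productivity
#'
#' The mapped trait for association analysis: for each line, the mean of the
#' (adjusted) totals over every vial in which it served as the female parent
#' — all crosses, self-crosses included. Lines never used as a female are
#' excluded with a warning.
#'
#' @inheritParams fit_biomodel
#' @return A `line_means` data frame: `line_id`, `mean` (flies), `n_vials`.
#' @export
female_line_means <- function(dataset, response = NULL) {
  response <- response %||%
    (if ("total_adjusted" %in% names(dataset)) "total_adjusted" else "total")
  y <- as.numeric(dataset[[response]])
  fem <- as.character(dataset$female_line)
  mn <- tapply(y, fem, mean)
  nv <- tapply(y, fem, length)
  all_lines <- sort(unique(c(fem, as.character(dataset$male_line))))
  never <- setdiff(all_lines, names(mn))
  if (length(never)) {
    warning("line(s) never used as female, excluded: ",
            paste(never, collapse = ", "), call. = FALSE)
  }
  out <- data.frame(line_id = names(mn), mean = as.numeric(mn),
                    n_vials = as.integer(nv), row.names = NULL,
                    stringsAsFactors = FALSE)
  out <- out[order(out$line_id), ]
  rownames(out) <- NULL
  class(out) <- c("line_means", "data.frame")
  out
}

as_line_values <- function(phenotype) {
  if (inherits(phenotype, "line_means") ||
      (is.data.frame(phenotype) && all(c("line_id", "mean") %in%
                                       names(phenotype)))) {
    return(setNames(phenotype$mean, phenotype$line_id))
  }
  if (is.numeric(phenotype) && !is.null(names(phenotype))) return(phenotype)
  stop_invalid("phenotype must be a line_means data frame or a named vector")
}

# closed-form simple OLS of y on a 0/1 genotype; covariate model via lm()
ols_variant <- function(y, g, covariate = NULL) {
  n <- length(y)
  if (is.null(covariate)) {
    xb <- mean(g); yb <- mean(y)
    sxx <- sum((g - xb)^2)
    slope <- sum((g - xb) * (y - yb)) / sxx
    resid <- y - yb - slope * (g - xb)
    df <- n - 2
    se <- sqrt(sum(resid^2) / df / sxx)
    tt <- slope / se
    # perfect fits give se = 0; report the smallest positive double rather
    # than 0 so p-values stay in (0, 1]
    p <- max(2 * pt(-abs(tt), df), .Machine$double.xmin)
    list(effect = slope, se = se, p = p, p_conditional = NA_real_)
  } else {
    fit0 <- lm(y ~ g)
    fit1 <- lm(y ~ g + covariate)
    s0 <- summary(fit0)$coefficients
    s1 <- summary(fit1)$coefficients
    list(effect = s0["g", 1], se = s0["g", 2], p = s0["g", 4],
         p_conditional = s1["g", 4])
  }
}

#' Single-variant regression on line means
#'
#' Ordinary least squares of the line phenotype on the 0/1 homozygous
#' genotype (lines with a missing call are dropped pairwise). The effect is
#' signed per minor allele among the lines actually used: if allele 1 is the
#' major allele there, the sign is flipped and the minor-allele label swapped.
#' When a per-line covariate is supplied, the covariate-conditional p-value
#' is reported alongside the simple-regression estimate.
#'
#' @param phenotype [female_line_means()] output or a named per-line vector.
#' @param genotype Named 0/1/`NA` vector: one genotype per line.
#' @param covariate Optional named per-line numeric covariate (e.g. thorax
#'   length).
#' @param variant Variant id used in the output row.
#' @return One-row data frame: `variant`, `minor_allele` (`"1"` or `"0"`,
#'   i.e. which genotype code is minor among used lines), `maf`, `n`,
#'   `effect` (flies per minor allele), `se`, `p`, `p_conditional`,
#'   `var_explained` (`NA` until filled via [variance_explained()]).
#' @export
variant_regression <- function(phenotype, genotype, covariate = NULL,
                               variant = "variant") {
  y <- as_line_values(phenotype)
  if (is.null(names(genotype))) stop_invalid("`genotype` must be named by line")
  lines <- intersect(names(y), names(genotype))
  g <- genotype[lines]
  yy <- y[lines]
  cv <- NULL
  if (!is.null(covariate)) {
    cv <- covariate[lines]
    keep <- !is.na(g) & !is.na(yy) & !is.na(cv)
  } else {
    keep <- !is.na(g) & !is.na(yy)
  }
  g <- as.numeric(g[keep]); yy <- yy[keep]
  if (!is.null(cv)) cv <- as.numeric(cv[keep])
  n <- length(yy)
  if (n < 3) stop_invalid("fewer than 3 lines with complete data")
  if (length(unique(g)) < 2) {
    stop_invalid("monomorphic genotype after dropping missing lines")
  }
  freq1 <- mean(g)
  minor <- if (freq1 <= 0.5) "1" else "0"
  res <- ols_variant(yy, g, cv)
  flip <- if (minor == "1") 1 else -1
  data.frame(
    variant = variant, minor_allele = minor, maf = min(freq1, 1 - freq1),
    n = n, effect = flip * res$effect, se = res$se, p = res$p,
    p_conditional = res$p_conditional, var_explained = NA_real_,
    stringsAsFactors = FALSE
  )
}

#' Genome-wide association on line means
#'
#' Runs [variant_regression()] for every variant in the (MAF-filtered)
#' genotype matrix, ranks by p-value (ties broken by variant id) and flags
#' the subset below `p_threshold`. Variants that cannot be tested
#' (monomorphic after missing-data removal, or too few lines) are skipped and
#' recorded in the `skipped` attribute.
#'
#' @param phenotype [female_line_means()] output or named per-line vector.
#' @param genotypes Lines x variants 0/1/`NA` matrix (see
#'   [filter_variants()]).
#' @param covariate Optional named per-line covariate.
#' @param p_threshold Significance threshold (default `1e-5`).
#' @param sigma2_g Optional genetic variance of line means (flies^2) used to
#'   fill `var_explained` (see [linemean_genetic_variance()]).
#' @return A `gwas_result` data frame (one row per tested variant, sorted by
#'   p) with a logical `significant` column; attribute `skipped` names
#'   untestable variants.
#' @export
run_gwas <- function(phenotype, genotypes, covariate = NULL,
                     p_threshold = 1e-5, sigma2_g = NULL) {
  y <- as_line_values(phenotype)
  rows <- vector("list", ncol(genotypes))
  skipped <- character(0)
  for (v in seq_len(ncol(genotypes))) {
    id <- colnames(genotypes)[v]
    row <- tryCatch(
      variant_regression(y, genotypes[, v], covariate = covariate,
                         variant = id),
      error = function(e) {
        skipped <<- c(skipped, setNames(conditionMessage(e), id))
        NULL
      })
    rows[[v]] <- row
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- variant_regression(y, genotypes[, 1])[0, ]
  out <- out[order(out$p, out$variant), ]
  rownames(out) <- NULL
  if (!is.null(sigma2_g)) {
    out$var_explained <- vapply(seq_len(nrow(out)), function(i) {
      variance_explained(out$effect[i], out$maf[i], sigma2_g, warn = FALSE)
    }, numeric(1))
  }
  out$significant <- out$p < p_threshold
  attr(out, "skipped") <- skipped
  attr(out, "p_threshold") <- p_threshold
  class(out) <- c("gwas_result", "data.frame")
  out
}

#' Proportion of line-mean genetic variance explained by a variant
#'
#' For a biallelic variant with minor-allele frequency `p` and per-allele
#' effect `a` among homozygous lines, the between-class variance it generates
#' in line means is `p (1 - p) a^2`; the returned proportion divides this by
#' the genetic variance of the line means. Values above 1 are capped with a
#' warning.
#'
#' @param effect Per-allele effect in flies, or a one-row [run_gwas()] /
#'   [variant_regression()] data frame (its `effect` and `maf` are used).
#' @param maf Minor-allele frequency (ignored when `effect` is a row).
#' @param sigma2_g Genetic variance of line means (flies^2), > 0.
#' @param warn Warn when capping at 1.
#' @return Proportion in `[0, 1]`.
#' @export
variance_explained <- function(effect, maf = NULL, sigma2_g, warn = TRUE) {
  if (is.data.frame(effect)) {
    maf <- effect$maf[1]
    effect <- effect$effect[1]
  }
  if (is.null(sigma2_g) || !is.finite(sigma2_g) || sigma2_g <= 0) {
    stop_invalid("`sigma2_g` must be a positive number")
  }
  ve <- maf * (1 - maf) * effect^2 / sigma2_g
  if (ve >= 1) {
    if (warn) warning("variance explained exceeds 1; capped", call. = FALSE)
    ve <- 1
  }
  ve
}

#' Genetic variance of female line means implied by a bio-model fit
#'
#' A female line mean averages `n_lines * n_reps` vials over all mates, so
#' the male and mate-average terms wash out and its genetic variance is
#' `sigma2_f + sigma2_n + (sigma2_fm + sigma2_nn) / n_lines`: the female
#' extranuclear and nuclear line effects survive averaging intact (the
#' self-cross nuclear bonus folds exactly into `sigma2_n`'s coefficient),
#' while the per-mate interaction terms are attenuated by the number of
#' mates. This is the denominator used for [variance_explained()].
#'
#' @param vc A `biomodel_fit` or named `sigma2_*` vector.
#' @param n_lines Number of lines each female was mated to.
#' @return Genetic variance of line means (flies^2).
#' @export
linemean_genetic_variance <- function(vc, n_lines) {
  v <- extract_vc(vc)
  v[["sigma2_f"]] + v[["sigma2_n"]] +
    (v[["sigma2_fm"]] + v[["sigma2_nn"]]) / n_lines
}

#' Re-test top variants in an independent phenotype
#'
#' Re-runs [variant_regression()] for each top variant against a new per-line
#' phenotype (e.g. self-cross productivity measured in an independent
#' experiment). Variants absent from the new genotype panel are skipped with
#' a note.
#'
#' @param top A [run_gwas()] result (or subset) whose `variant` column names
#'   the variants to re-test.
#' @param phenotype New per-line phenotype ([female_line_means()] format or
#'   named vector).
#' @param genotypes Genotype matrix for the new panel.
#' @param alpha Replication significance level (default 0.05).
#' @return Data frame: `variant`, `effect`, `se`, `p`, `replicated` (p <
#'   `alpha`); attribute `skipped` for absent variants.
#' @export
replicate_variants <- function(top, phenotype, genotypes, alpha = 0.05) {
  if (!nrow(top)) {
    out <- data.frame(variant = character(), effect = numeric(),
                      se = numeric(), p = numeric(), replicated = logical())
    attr(out, "skipped") <- character(0)
    return(out)
  }
  y <- as_line_values(phenotype)
  skipped <- character(0)
  rows <- lapply(top$variant, function(id) {
    if (!id %in% colnames(genotypes)) {
      skipped <<- c(skipped, id)
      return(NULL)
    }
    row <- tryCatch(
      variant_regression(y, genotypes[, id], variant = id),
      error = function(e) {
        skipped <<- c(skipped, setNames(conditionMessage(e), id))
        NULL
      })
    row
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(variant = character(), effect = numeric(),
                      se = numeric(), p = numeric())
  } else {
    out <- out[, c("variant", "effect", "se", "p")]
  }
  out$replicated <- out$p < alpha
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Pearson correlation with pairwise-complete handling
#'
#' @param x,y Per-line numeric vectors (aligned by names when both are
#'   named, else positionally).
#' @return List: `r`, `p_value` (two-sided, t distribution), `n`.
#' @export
pearson_correlation <- function(x, y) {
  if (!is.null(names(x)) && !is.null(names(y))) {
    common <- intersect(names(x), names(y))
    x <- x[common]; y <- y[common]
  }
  if (length(x) != length(y)) stop_invalid("x and y lengths differ")
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop_invalid("fewer than 3 complete pairs")
  if (var(x) == 0 || var(y) == 0) {
    stop_invalid("zero variance in x or y; correlation undefined")
  }
  ct <- stats::cor.test(x, y)
  list(r = unname(ct$estimate), p_value = ct$p.value, n = n)
}
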