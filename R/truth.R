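#' Ground-truth parameters for a simulated diallel experiment
#'
#' Bundles everything the generator needs to run the bio-model forward:
#' the grand mean, the six variance components (flies^2), fixed deviations
#' for the four female x male infection-status cells (anchored at the
#' uninfected x uninfected cell), a self-cross fixed deviation, and optional
#' causal-variant and expression-mediation parameters.
#'
#' @param mu Baseline latent mean (adult flies per vial) for an uninfected x
#'   uninfected cross carrying zero minor alleles (and, when a mediator is
#'   present, before the mediator's contribution `beta2 * expression`).
#' @param sigma2_f,sigma2_m,sigma2_fm,sigma2_n,sigma2_nn,sigma2_e Variance
#'   components (flies^2): female extranuclear, male extranuclear,
#'   extranuclear interaction, nuclear, nuclear interaction, residual. All
#'   must be non-negative.
#' @param infection_effects Named numeric deviations (flies) for cells
#'   `F0M0, F0M1, F1M0, F1M1` (female status first); `F0M0` must be 0.
#' @param self_cross_effect Fixed deviation (flies) added when a line is
#'   crossed to itself.
#' @param causal Optional list: `id`, `maf`, `effect_direct` (flies added per
#'   minor allele carried by the female parent line, not routed through the
#'   mediator).
#' @param mediation Optional list: `alpha0`, `alpha1` (expression intercept
#'   and slope on the female line's causal genotype), `beta2` (flies per
#'   expression unit), `sd_expression` (residual SD of expression).
#'
#' @return An object of class `diallel_truth` (a list of the above).
#' @seealso [fertility_preset_truth()] for the calibrated default preset.
#' @export
diallel_truth <- function(mu,
                          sigma2_f, sigma2_m, sigma2_fm,
                          sigma2_n, sigma2_nn, sigma2_e,
                          infection_effects = c(F0M0 = 0, F0M1 = 0,
                                                F1M0 = 0, F1M1 = 0),
                          self_cross_effect = 0,
                          causal = NULL,
                          mediation = NULL) {
  vc <- c(sigma2_f, sigma2_m, sigma2_fm, sigma2_n, sigma2_nn, sigma2_e)
  if (any(!is.finite(vc)) || any(vc < 0)) {
    stop_invalid("all variance components must be finite and non-negative")
  }
  infection_effects <- infection_effects[INFECTION_CELLS]
  if (anyNA(infection_effects)) {
    stop_invalid("`infection_effects` must name all four cells ",
                 paste(INFECTION_CELLS, collapse = ", "))
  }
  if (infection_effects[["F0M0"]] != 0) {
    stop_invalid("infection effects are anchored: F0M0 must be 0")
  }
  if (!is.null(mediation) && is.null(causal)) {
    stop_invalid("a mediation pathway requires a causal variant")
  }
  out <- list(
    mu = mu,
    sigma2_f = sigma2_f, sigma2_m = sigma2_m, sigma2_fm = sigma2_fm,
    sigma2_n = sigma2_n, sigma2_nn = sigma2_nn, sigma2_e = sigma2_e,
    infection_effects = infection_effects,
    self_cross_effect = self_cross_effect,
    causal = causal,
    mediation = mediation
  )
  class(out) <- "diallel_truth"
  out
}

#' Calibrated generator preset for a 50-line fertility diallel
#'
#' Reconstructs the statistical conditions of a 50-line, 3-replicate full
#' diallel productivity experiment from its study-level summaries:
#'
#' * observed grand mean 737868 flies / 7500 vials = 98.3824 flies per vial,
#'   coefficient of variation 37% of raw vial totals;
#' * 39% of phenotypic variance genetic (among crosses), of which 85% is the
#'   female extranuclear component (33% of phenotypic variance);
#' * infection-cell deviations of -6 flies when the female parent is infected
#'   (either male status) and -3 flies for uninfected females mated to
#'   infected males;
#' * one causal variant whose minor allele raises female line-mean
#'   productivity by 13.92 flies in total, 19% of it mediated through
#'   expression of the candidate gene.
#'
#' The remaining 15% of genetic variance, which the study reports only as
#' small and (for the nuclear terms) non-significant, is split as
#' `sigma2_m = 30`, `sigma2_fm = 30`, `sigma2_n = 5` (counted twice in the
#' genetic total), with `sigma2_nn` absorbing the remainder. The causal
#' variant's contribution `maf(1-maf) * 13.92^2` and the mediator noise
#' contribution `beta2^2 * sd_expression^2` are carved out of the female
#' extranuclear total, so the REML female share stays at its target. The
#' baseline `mu` is set so the expected raw vial mean equals 98.3824 after
#' infection, causal and mediator contributions (infection statuses at
#' probability 0.5).
#'
#' @param causal_maf Target minor-allele frequency of the embedded causal
#'   variant (default 0.30, i.e. 15 of 50 lines).
#' @param infection_prob Infection probability used for mean calibration
#'   (must match the panel the truth will be used with; default 0.5).
#' @return A [diallel_truth()] object with additional attribute
#'   `expected_mean` (the calibrated raw grand mean).
#' @export
#' @examples
#' truth <- fertility_preset_truth()
#' unlist(truth[c("sigma2_f", "sigma2_e")])
fertility_preset_truth <- function(causal_maf = 0.30, infection_prob = 0.5) {
  mean_target <- 737868 / 7500            # 98.3824 flies/vial
  cv_target <- 0.37
  sigma2_P <- (cv_target * mean_target)^2 # 1325.07 flies^2
  sigma2_G <- 0.39 * sigma2_P             # genetic (among-cross) variance
  sigma2_e <- sigma2_P - sigma2_G

  sigma2_f_total <- 0.85 * sigma2_G       # female extranuclear, all sources
  sigma2_m <- 30
  sigma2_fm <- 30
  sigma2_n <- 5                           # enters sigma2_G as 2 * sigma2_n
  sigma2_nn <- 0.15 * sigma2_G - sigma2_m - sigma2_fm - 2 * sigma2_n

  effect_total <- 13.92                   # flies per minor allele, females
  prop_mediated <- 0.19
  acme <- prop_mediated * effect_total
  effect_direct <- effect_total - acme
  alpha1 <- 0.3                           # log2-expression units per allele
  beta2 <- acme / alpha1                  # flies per log2-expression unit
  sd_expression <- 0.8
  alpha0 <- 5

  var_snp <- causal_maf * (1 - causal_maf) * effect_total^2
  var_expr_noise <- beta2^2 * sd_expression^2
  sigma2_f_base <- sigma2_f_total - var_snp - var_expr_noise
  if (sigma2_f_base <= 0) {
    stop_invalid("causal/mediator variance exceeds the female component; ",
                 "lower `causal_maf` or the mediator parameters")
  }

  infection_effects <- c(F0M0 = 0, F0M1 = -3, F1M0 = -6, F1M1 = -6)
  p <- infection_prob
  e_infection <- (1 - p) * p * infection_effects[["F0M1"]] +
    p * (1 - p) * infection_effects[["F1M0"]] +
    p * p * infection_effects[["F1M1"]]
  mu <- mean_target - e_infection - causal_maf * effect_total -
    beta2 * alpha0

  out <- diallel_truth(
    mu = mu,
    sigma2_f = sigma2_f_base, sigma2_m = sigma2_m, sigma2_fm = sigma2_fm,
    sigma2_n = sigma2_n, sigma2_nn = sigma2_nn, sigma2_e = sigma2_e,
    infection_effects = infection_effects,
    self_cross_effect = 0,
    causal = list(id = "causal_snp", maf = causal_maf,
                  effect_direct = effect_direct),
    mediation = list(alpha0 = alpha0, alpha1 = alpha1, beta2 = beta2,
                     sd_expression = sd_expression)
  )
  attr(out, "expected_mean") <- mean_target
  out
}

# Total per-allele effect of the causal variant on a female line's mean:
# direct part plus the mediated part alpha1 * beta2.
causal_total_effect <- function(truth) {
  if (is.null(truth$causal)) return(0)
  eff <- truth$causal$effect_direct
  if (!is.null(truth$mediation)) {
    eff <- eff + truth$mediation$alpha1 * truth$mediation$beta2
  }
  eff
}

#' @export
print.diallel_truth <- function(x, ...) {
  cat("Diallel ground truth\n")
  cat(sprintf("  mu (baseline latent mean): %.3f flies\n", x$mu))
  vc <- unlist(x[c("sigma2_f", "sigma2_m", "sigma2_fm", "sigma2_n",
                   "sigma2_nn", "sigma2_e")])
  cat("  variance components (flies^2):\n")
  print(round(vc, 3))
  cat("  infection cell effects:",
      paste(names(x$infection_effects), x$infection_effects, sep = "=",
            collapse = " "), "\n")
  if (!is.null(x$causal)) {
    cat(sprintf("  causal variant %s: maf %.2f, direct effect %.3f flies\n",
                x$causal$id, x$causal$maf, x$causal$effect_direct))
  }
  if (!is.null(x$mediation)) {
    cat(sprintf("  mediation: alpha1 %.3f, beta2 %.3f, ACME %.3f flies\n",
                x$mediation$alpha1, x$mediation$beta2,
                x$mediation$alpha1 * x$mediation$beta2))
  }
  invisible(x)
}
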