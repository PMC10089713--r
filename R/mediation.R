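#' Linear causal mediation analysis of a variant effect through expression
#'
#' Partitions the effect of a 0/1 genotype on a line-level phenotype into the
#' part transmitted through an expression mediator and the direct remainder.
#' Two least-squares models are fitted:
#'
#' * mediator model `M = alpha0 + alpha1 G + error`
#' * outcome model `Y = beta0 + beta1 G + beta2 M + error`
#'
#' In this linear, no-interaction case the average causal mediation effect
#' (ACME) is the coefficient product `alpha1 * beta2`, the average direct
#' effect (ADE) is `beta1`, and the total effect is their sum exactly.
#' Uncertainty comes from resampling: quasi-Bayesian draws of the two
#' coefficient vectors from their estimated sampling distributions (default),
#' or a nonparametric bootstrap over lines. Intervals are percentile
#' intervals; p-values are two-sided resample tail probabilities.
#'
#' @param genotype Named 0/1 per-line vector (polymorphic).
#' @param mediator Named per-line expression values.
#' @param outcome Named per-line phenotype ([female_line_means()] output also
#'   accepted).
#' @param n_resamples Number of resamples (default 1000).
#' @param seed Integer seed (required: resampling must be reproducible).
#' @param method `"quasi-bayesian"` (default) or `"bootstrap"`.
#' @param conf_level Interval coverage (default 0.95).
#' @param prop_from_resamples Report `prop_mediated` as the resample median of
#'   ACME/total instead of the point-estimate ratio (default FALSE).
#' @return A `mediation_result`: point estimates `acme`, `ade`,
#'   `total_effect`, `prop_mediated`; `ci` (matrix of interval bounds);
#'   `p_values` (for ACME, ADE, total and proportion); `n`, `n_resamples`,
#'   `seed`, `method`.
#' @export
#' @examples
#' g <- setNames(rep(0:1, each = 10), paste0("L", 1:20))
#' m <- 2 * g + 0.1 * seq_along(g)            # mediator depends on genotype
#' y <- 4 * g + 3 * m + 0.05 * rev(seq_along(g))
#' names(m) <- names(y) <- names(g)
#' fit <- fit_mediation(g, m, y, n_resamples = 200, seed = 1)
#' fit$acme + fit$ade - fit$total_effect  # exactly zero
fit_mediation <- function(genotype, mediator, outcome, n_resamples = 1000,
                          seed, method = c("quasi-bayesian", "bootstrap"),
                          conf_level = 0.95, prop_from_resamples = FALSE) {
  method <- match.arg(method)
  if (missing(seed)) stop_invalid("`seed` is required")
  outcome <- as_line_values(outcome)
  if (!is.null(names(genotype)) && !is.null(names(outcome))) {
    common <- Reduce(intersect, list(names(genotype), names(mediator),
                                     names(outcome)))
    genotype <- genotype[common]
    mediator <- mediator[common]
    outcome <- outcome[common]
  }
  keep <- !is.na(genotype) & !is.na(mediator) & !is.na(outcome)
  g <- as.numeric(genotype[keep])
  m <- as.numeric(mediator[keep])
  y <- as.numeric(outcome[keep])
  n <- length(g)
  if (n < 10) stop_invalid("need >= 10 complete (genotype, mediator, ",
                           "outcome) triples")
  if (length(unique(g)) < 2) stop_invalid("monomorphic genotype")

  fit_m <- lm(m ~ g)
  fit_y <- lm(y ~ g + m)
  alpha1 <- coef(fit_m)[["g"]]
  beta1 <- coef(fit_y)[["g"]]
  beta2 <- coef(fit_y)[["m"]]
  acme <- alpha1 * beta2
  ade <- beta1
  total <- acme + ade

  draws <- with_seed(seed, {
    if (method == "quasi-bayesian") {
      am <- rmvn_chol(n_resamples, coef(fit_m), vcov(fit_m))
      ay <- rmvn_chol(n_resamples, coef(fit_y), vcov(fit_y))
      cbind(acme = am[, "g"] * ay[, "m"], ade = ay[, "g"])
    } else {
      t(vapply(seq_len(n_resamples), function(i) {
        idx <- sample.int(n, n, replace = TRUE)
        fm <- lm(m[idx] ~ g[idx])
        fy <- lm(y[idx] ~ g[idx] + m[idx])
        c(acme = unname(coef(fm)[2] * coef(fy)[3]),
          ade = unname(coef(fy)[2]))
      }, numeric(2)))
    }
  })
  tot_s <- draws[, "acme"] + draws[, "ade"]
  prop_s <- ifelse(abs(tot_s) > 0, draws[, "acme"] / tot_s, NA_real_)

  qs <- c((1 - conf_level) / 2, 1 - (1 - conf_level) / 2)
  ci <- rbind(
    acme = stats::quantile(draws[, "acme"], qs, names = FALSE),
    ade = stats::quantile(draws[, "ade"], qs, names = FALSE),
    total_effect = stats::quantile(tot_s, qs, names = FALSE),
    prop_mediated = stats::quantile(prop_s, qs, names = FALSE, na.rm = TRUE)
  )
  colnames(ci) <- c("lower", "upper")
  p2 <- function(s) {
    s <- s[!is.na(s)]
    min(1, 2 * min(mean(s <= 0), mean(s >= 0)))
  }
  prop_point <- if (abs(total) > 0) acme / total else NA_real_
  if (is.na(prop_point)) {
    warning("total effect is zero; proportion mediated is undefined",
            call. = FALSE)
  }
  out <- list(
    acme = acme, ade = ade, total_effect = total,
    prop_mediated = if (prop_from_resamples) {
      stats::median(prop_s, na.rm = TRUE)
    } else prop_point,
    ci = ci,
    p_values = c(acme = p2(draws[, "acme"]), ade = p2(draws[, "ade"]),
                 total_effect = p2(tot_s),
                 prop_mediated = p2(prop_s)),
    n = n, n_resamples = n_resamples, seed = seed, method = method
  )
  class(out) <- "mediation_result"
  out
}

# multivariate normal draws via Cholesky of the (possibly semi-definite)
# covariance
rmvn_chol <- function(n, mu, Sigma) {
  p <- length(mu)
  R <- tryCatch(chol(Sigma),
                error = function(e) chol(Sigma + diag(1e-12, p)))
  z <- matrix(rnorm(n * p), n, p)
  out <- sweep(z %*% R, 2, mu, `+`)
  colnames(out) <- names(mu)
  out
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("Mediation analysis (%s, %d resamples, n = %d lines)\n",
              x$method, x$n_resamples, x$n))
  tab <- data.frame(
    estimate = c(x$acme, x$ade, x$total_effect, x$prop_mediated),
    lower = x$ci[, "lower"], upper = x$ci[, "upper"],
    p_value = unname(x$p_values),
    row.names = c("ACME", "ADE", "total effect", "prop. mediated")
  )
  print(round(tab, 4))
  invisible(x)
}
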