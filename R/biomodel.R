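#' Fit the Cockerham-Weir bio-model by REML
#'
#' Estimates the six-component partition of diallel phenotypic variance
#' (female extranuclear `f`, male extranuclear `m`, extranuclear interaction
#' `fm`, nuclear `n`, nuclear interaction `nn`, residual `e`) by restricted
#' maximum likelihood under the Gaussian model whose covariance is assembled
#' from the relative-class rules (see [cross_covariance()]).
#'
#' For complete balanced designs (every cross observed with the same number
#' of replicates `r >= 2`) the fit uses an exact reduction: the restricted
#' likelihood factorizes into a cross-means model — in which `fm`, having one
#' level per cross, is absorbed into the means-level residual
#' `tau = sigma2_fm + sigma2_e / r` — and an independent within-cross
#' chi-square part that yields `sigma2_e = SSW / (C (r - 1))`. The factorized
#' optimum equals the full-data REML optimum whenever the recovered
#' `sigma2_fm = tau - sigma2_e / r` is non-negative; if it is not, the fit
#' falls back to a full-data fit with `sigma2_fm` pinned at zero. Reported
#' log-likelihoods are always on the full-data scale, so fits from either
#' path are comparable in likelihood-ratio tests.
#'
#' @param dataset A `diallel_dataset`.
#' @param response Column to analyse; defaults to `total_adjusted` when
#'   present (see [adjust_productivity()]), else `total`.
#' @param self_effect Add a fixed indicator for self-crosses (used by
#'   [inbreeding_contrast()]).
#' @param drop Character vector of components (`"f"`, `"m"`, `"fm"`, `"n"`,
#'   `"nn"`) to constrain to zero (used by [lrt_component()]).
#' @param reduce `"auto"` (use the balanced reduction when valid) or
#'   `"never"` (always fit the full data).
#' @param control A [reml_control()].
#'
#' @return A `biomodel_fit`: list with `sigma2` (named `sigma2_f`, ...,
#'   `sigma2_e`), `loglik` (full-data restricted log-likelihood), `beta`,
#'   `beta_vcov`, `method` (`"reduced"` or `"full"`), `convergence`,
#'   `boundary_fm` (TRUE when `sigma2_fm` was pinned at zero by the
#'   non-negativity constraint), `n`, `n_lines`, `response`.
#' @export
#' @examples
#' panel <- make_panel(6, seed = 1)
#' truth <- diallel_truth(100, 80, 10, 10, 4, 4, 50)
#' d <- simulate_diallel(panel, truth = truth, n_reps = 3, seed = 2)
#' fit <- fit_biomodel(d)
#' partition_summary(fit)
fit_biomodel <- function(dataset, response = NULL,
                         self_effect = FALSE, drop = character(),
                         reduce = c("auto", "never"),
                         control = reml_control()) {
  reduce <- match.arg(reduce)
  response <- response %||%
    (if ("total_adjusted" %in% names(dataset)) "total_adjusted" else "total")
  if (!response %in% names(dataset)) {
    stop_invalid("response column `", response, "` not found")
  }
  bad <- setdiff(drop, c("f", "m", "fm", "n", "nn"))
  if (length(bad)) stop_invalid("unknown component(s): ",
                                paste(bad, collapse = ", "))
  y <- as.numeric(dataset[[response]])
  if (anyNA(y)) stop_invalid("response contains missing values")
  fem <- as.character(dataset$female_line)
  mal <- as.character(dataset$male_line)

  cross <- paste(fem, mal, sep = ":")
  reps <- table(cross)
  balanced <- length(unique(reps)) == 1L && reps[1] >= 2L
  use_reduced <- reduce == "auto" && balanced && !("fm" %in% drop)

  if (use_reduced) {
    r <- as.integer(reps[1])
    ord <- order(fem, mal)
    key <- cross[ord]
    ybar <- tapply(y[ord], key, mean)
    cells <- names(ybar)
    C <- length(cells)
    ssw <- sum((y[ord] - ybar[key])^2)
    sigma2_e <- ssw / (C * (r - 1))

    split_key <- strsplit(cells, ":", fixed = TRUE)
    mean_df <- data.frame(
      female_line = vapply(split_key, `[`, "", 1L),
      male_line = vapply(split_key, `[`, "", 2L),
      replicate = 1L, stringsAsFactors = FALSE
    )
    fixed <- if (self_effect) {
      cbind(self = as.numeric(mean_df$female_line == mean_df$male_line))
    } else NULL
    des <- build_design(mean_df, fixed = fixed)
    Zm <- des$Z[setdiff(c("f", "m", "n", "nn"), drop)]
    fit <- reml_fit(as.numeric(ybar), des$X, Zm, control = control)

    tau <- fit$sigma2[["resid"]]
    sigma2_fm <- tau - sigma2_e / r
    boundary_fm <- sigma2_fm < 0
    if (!boundary_fm) {
      sig <- c(f = 0, m = 0, fm = sigma2_fm, n = 0, nn = 0)
      for (cc in setdiff(c("f", "m", "n", "nn"), drop)) {
        sig[[cc]] <- fit$sigma2[[cc]]
      }
      loglik <- fit$loglik - 0.5 * C * log(r) -
        0.5 * (C * (r - 1)) * (log(2 * pi * sigma2_e) + 1)
      out <- list(
        sigma2 = c(sigma2_f = sig[["f"]], sigma2_m = sig[["m"]],
                   sigma2_fm = sig[["fm"]], sigma2_n = sig[["n"]],
                   sigma2_nn = sig[["nn"]], sigma2_e = sigma2_e),
        loglik = loglik, beta = fit$beta, beta_vcov = fit$beta_vcov,
        method = "reduced", boundary_fm = FALSE,
        convergence = fit$convergence,
        n = length(y), n_lines = length(des$levels$lines),
        response = response
      )
      class(out) <- "biomodel_fit"
      return(out)
    }
    drop <- union(drop, "fm")  # constrained fit below
  }

  fixed <- if (self_effect) cbind(self = as.numeric(fem == mal)) else NULL
  des <- build_design(dataset, fixed = fixed)
  Zf <- des$Z[setdiff(c("f", "m", "fm", "n", "nn"), drop)]
  fit <- reml_fit(y, des$X, Zf, control = control)
  sig <- c(f = 0, m = 0, fm = 0, n = 0, nn = 0)
  for (cc in names(Zf)) sig[[cc]] <- fit$sigma2[[cc]]
  out <- list(
    sigma2 = c(sigma2_f = sig[["f"]], sigma2_m = sig[["m"]],
               sigma2_fm = sig[["fm"]], sigma2_n = sig[["n"]],
               sigma2_nn = sig[["nn"]], sigma2_e = fit$sigma2[["resid"]]),
    loglik = fit$loglik, beta = fit$beta, beta_vcov = fit$beta_vcov,
    method = "full", boundary_fm = "fm" %in% drop && use_reduced,
    convergence = fit$convergence,
    n = length(y), n_lines = length(des$levels$lines),
    response = response
  )
  class(out) <- "biomodel_fit"
  out
}

#' @export
print.biomodel_fit <- function(x, ...) {
  cat(sprintf("Bio-model REML fit (%s path, %d vials, %d lines)\n",
              x$method, x$n, x$n_lines))
  print(round(x$sigma2, 3))
  cat(sprintf("restricted log-likelihood: %.3f\n", x$loglik))
  invisible(x)
}

#' Total genetic variance from the cross-as-random-effect model
#'
#' Fits the one-way random-effects model `y = mu + cross + e` by REML; the
#' among-cross component is the total genetic variance, since crosses differ
#' only by parental genotype. For balanced complete designs the REML solution
#' is closed-form (the ANOVA estimator truncated at zero, with the residual
#' re-estimated under the boundary constraint).
#'
#' @inheritParams fit_biomodel
#' @return A `genetic_share` list: `sigma2_cross`, `sigma2_e`, `share`
#'   (= sigma2_cross / (sigma2_cross + sigma2_e)), `n_crosses`, `method`.
#' @export
total_genetic_model <- function(dataset, response = NULL,
                                control = reml_control()) {
  response <- response %||%
    (if ("total_adjusted" %in% names(dataset)) "total_adjusted" else "total")
  y <- as.numeric(dataset[[response]])
  cross <- paste(dataset$female_line, dataset$male_line, sep = ":")
  reps <- table(cross)
  if (length(reps) < 2) stop_invalid("need >= 2 crosses")
  if (max(reps) < 2) {
    stop_invalid("single replicate everywhere: residual variance is not ",
                 "identifiable")
  }
  if (length(unique(reps)) == 1L) {
    r <- as.integer(reps[1])
    C <- length(reps)
    ybar <- tapply(y, cross, mean)
    ssw <- sum((y - ybar[cross])^2)
    s2e <- ssw / (C * (r - 1))
    tau <- var(as.numeric(ybar))
    s2g <- tau - s2e / r
    if (s2g < 0) {
      s2g <- 0
      s2e <- sum((y - mean(y))^2) / (length(y) - 1)
    }
    method <- "closed-form"
  } else {
    lev <- sort(unique(cross))
    Zc <- Matrix::sparseMatrix(i = seq_along(y), j = match(cross, lev),
                               x = 1, dims = c(length(y), length(lev)))
    fit <- reml_fit(y, matrix(1, length(y), 1), list(cross = Zc),
                    control = control)
    s2g <- fit$sigma2[["cross"]]
    s2e <- fit$sigma2[["resid"]]
    method <- "reml"
  }
  out <- list(sigma2_cross = s2g, sigma2_e = s2e,
              share = s2g / (s2g + s2e), n_crosses = length(reps),
              method = method)
  class(out) <- "genetic_share"
  out
}

#' @export
print.genetic_share <- function(x, ...) {
  cat(sprintf(
    "Among-cross (genetic) variance: %.2f; residual: %.2f; share %.1f%%\n",
    x$sigma2_cross, x$sigma2_e, 100 * x$share))
  invisible(x)
}

#' Variance-partition table
#'
#' Expresses each bio-model component as an absolute contribution to the
#' phenotypic variance and as percentages of the total genetic and total
#' phenotypic variance. The nuclear component enters the genetic total as
#' `2 * sigma2_n` (its weight in the covariance among non-self full sibs), so
#' `sigma2_G = sigma2_f + sigma2_m + sigma2_fm + 2 sigma2_n + sigma2_nn` and
#' `sigma2_P = sigma2_G + sigma2_e`.
#'
#' @param vc A `biomodel_fit` or a named vector/list of the six `sigma2_*`
#'   components.
#' @return A data frame with one row per component (plus the residual):
#'   `component`, `sigma2` (the raw component), `contribution` (its weight in
#'   `sigma2_P`, i.e. `2 * sigma2_n` for the nuclear row), `pct_genetic`,
#'   `pct_phenotypic`. Percentage columns each sum to 100. Attributes
#'   `sigma2_G` and `sigma2_P` carry the totals.
#' @export
partition_summary <- function(vc) {
  v <- extract_vc(vc)
  contrib <- c(f = v[["sigma2_f"]], m = v[["sigma2_m"]],
               fm = v[["sigma2_fm"]], n = 2 * v[["sigma2_n"]],
               nn = v[["sigma2_nn"]])
  sigma2_G <- sum(contrib)
  sigma2_P <- sigma2_G + v[["sigma2_e"]]
  if (sigma2_P <= 0) stop_invalid("total phenotypic variance is zero; ",
                                  "shares are undefined")
  if (sigma2_G <= 0) stop_invalid("all genetic components are zero; ",
                                  "genetic shares are undefined")
  out <- data.frame(
    component = c(names(contrib), "residual"),
    sigma2 = c(v[["sigma2_f"]], v[["sigma2_m"]], v[["sigma2_fm"]],
               v[["sigma2_n"]], v[["sigma2_nn"]], v[["sigma2_e"]]),
    contribution = c(contrib, v[["sigma2_e"]]),
    pct_genetic = c(100 * contrib / sigma2_G, NA),
    pct_phenotypic = 100 * c(contrib, v[["sigma2_e"]]) / sigma2_P,
    row.names = NULL
  )
  attr(out, "sigma2_G") <- sigma2_G
  attr(out, "sigma2_P") <- sigma2_P
  out
}

#' Likelihood-ratio test of a single variance component
#'
#' Refits the bio-model with one component constrained to zero and compares
#' restricted log-likelihoods. Because the null value lies on the boundary of
#' the parameter space, the p-value uses the 50:50 mixture of a point mass at
#' zero and a 1-df chi-square.
#'
#' @inheritParams fit_biomodel
#' @param component One of `"f"`, `"m"`, `"fm"`, `"n"`, `"nn"`.
#' @param fit Optional full [fit_biomodel()] fit to reuse.
#' @return A `component_test` list: `component`, `loglik_full`,
#'   `loglik_reduced`, `statistic` (non-negative), `p_value`.
#' @export
lrt_component <- function(dataset, component, response = NULL,
                          self_effect = FALSE, fit = NULL,
                          control = reml_control()) {
  component <- match.arg(component, c("f", "m", "fm", "n", "nn"))
  if (is.null(fit)) {
    fit <- fit_biomodel(dataset, response = response,
                        self_effect = self_effect, control = control)
  }
  reduced <- fit_biomodel(dataset, response = response,
                          self_effect = self_effect, drop = component,
                          control = control)
  stat <- 2 * (fit$loglik - reduced$loglik)
  if (stat < -1e-4) {
    warning("reduced model has higher restricted likelihood (stat = ",
            format(stat, digits = 3), "); reporting 0", call. = FALSE)
  }
  stat <- max(0, stat)
  p <- if (stat <= 0) 1 else 0.5 * pchisq(stat, df = 1, lower.tail = FALSE)
  out <- list(component = component, loglik_full = fit$loglik,
              loglik_reduced = reduced$loglik, statistic = stat, p_value = p)
  class(out) <- "component_test"
  out
}

#' @export
print.component_test <- function(x, ...) {
  cat(sprintf(
    "LRT for component `%s`: stat = %.3f, p = %.4g (boundary mixture)\n",
    x$component, x$statistic, x$p_value))
  invisible(x)
}
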