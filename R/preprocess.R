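#' Estimate Wolbachia infection effects on productivity
#'
#' Fits a mixed model with female infection status, male infection status and
#' their interaction as fixed effects, and female line and male line (each
#' nested within its infection status, which is automatic since every line
#' has a single status) as random effects, using the package REML engine.
#' Effects are reported as deviations of the four female-status x male-status
#' cells from the uninfected x uninfected baseline. Raw cell-mean differences
#' are reported alongside the model-based (default) estimates.
#'
#' @param dataset A `diallel_dataset`.
#' @param panel Line panel carrying each line's `infected` status.
#' @param response Response column; defaults to `total_adjusted` when present,
#'   else `total`.
#' @param control A [reml_control()].
#' @return An `infection_effects` object: `cell_effects` (named `F0M0` = 0,
#'   `F0M1`, `F1M0`, `F1M1`, in flies), `cell_se`, `tests` (Wald z and p for
#'   female status, male status, interaction), `raw_cell_effects`,
#'   `line_status`, `sigma2` (line and residual variances), `loglik`.
#' @export
fit_infection_model <- function(dataset, panel, response = NULL,
                                control = reml_control()) {
  validate_panel(panel)
  response <- response %||%
    (if ("total_adjusted" %in% names(dataset)) "total_adjusted" else "total")
  y <- as.numeric(dataset[[response]])
  fem <- as.character(dataset$female_line)
  mal <- as.character(dataset$male_line)
  status <- setNames(as.integer(panel$infected), panel$line_id)
  if (anyNA(status[unique(c(fem, mal))])) {
    stop_invalid("every line in the dataset needs a known infection status")
  }
  if (length(unique(status[unique(c(fem, mal))])) < 2) {
    stop_invalid("degenerate design: all lines share one infection status")
  }
  sf <- status[fem]
  sm <- status[mal]
  X <- cbind(`(Intercept)` = 1, F = sf, M = sm, FM = sf * sm)

  lines <- sort(unique(c(fem, mal)))
  inc <- function(j) Matrix::sparseMatrix(i = seq_along(y), j = j, x = 1,
                                          dims = c(length(y), length(lines)))
  fit <- reml_fit(y, X, list(female = inc(match(fem, lines)),
                             male = inc(match(mal, lines))),
                  control = control)

  b <- fit$beta
  V <- fit$beta_vcov
  cells <- rbind(F0M0 = c(0, 0, 0, 0), F0M1 = c(0, 0, 1, 0),
                 F1M0 = c(0, 1, 0, 0), F1M1 = c(0, 1, 1, 1))
  cell_effects <- drop(cells %*% b)
  cell_se <- sqrt(pmax(0, diag(cells %*% V %*% t(cells))))
  z <- b[-1] / sqrt(diag(V)[-1])
  tests <- data.frame(
    term = c("female_status", "male_status", "interaction"),
    estimate = unname(b[-1]), se = unname(sqrt(diag(V)[-1])),
    z = unname(z), p_value = unname(2 * pnorm(-abs(z)))
  )
  cell <- infection_cell(sf, sm)
  raw_means <- tapply(y, cell, mean)
  raw <- setNames(as.numeric(raw_means - raw_means[["F0M0"]]),
                  names(raw_means))

  out <- list(
    cell_effects = cell_effects, cell_se = cell_se, tests = tests,
    raw_cell_effects = raw[INFECTION_CELLS],
    line_status = status, sigma2 = fit$sigma2, loglik = fit$loglik,
    response = response
  )
  class(out) <- "infection_effects"
  out
}

#' @export
print.infection_effects <- function(x, ...) {
  cat("Wolbachia infection-cell effects (flies, baseline F0M0 = 0)\n")
  print(round(rbind(estimate = x$cell_effects, se = x$cell_se), 3))
  print(x$tests, digits = 3)
  invisible(x)
}

#' Adjust productivity for parental infection status
#'
#' Subtracts each record's estimated infection-cell effect from its total,
#' storing the result in `total_adjusted` (baseline-cell records are
#' unchanged). Adjusted values are kept as reals; only the fixed cell effects
#' are removed — line-level predictions stay in the data, since they carry the
#' genetic signal that downstream variance partitioning estimates.
#'
#' @param dataset A `diallel_dataset`.
#' @param effects A [fit_infection_model()] result.
#' @return The dataset with a `total_adjusted` column.
#' @export
adjust_productivity <- function(dataset, effects) {
  if (!inherits(effects, "infection_effects")) {
    stop_invalid("`effects` must come from fit_infection_model()")
  }
  fem <- as.character(dataset$female_line)
  mal <- as.character(dataset$male_line)
  sf <- effects$line_status[fem]
  sm <- effects$line_status[mal]
  if (anyNA(sf) || anyNA(sm)) {
    unknown <- unique(c(fem[is.na(sf)], mal[is.na(sm)]))
    stop_invalid("record(s) with line(s) of unknown infection status: ",
                 paste(unknown, collapse = ", "))
  }
  cell <- infection_cell(sf, sm)
  dataset$total_adjusted <- dataset$total - unname(effects$cell_effects[cell])
  as_diallel_dataset(dataset)
}

#' Test for sex-ratio bias in offspring counts
#'
#' Pools all vials and tests the overall female proportion against 1/2 with
#' an exact two-sided binomial test; a per-cross proportion table is returned
#' for inspection (descriptive, no multiplicity correction).
#'
#' @param dataset A `diallel_dataset`.
#' @return A `sex_ratio_result`: `proportion_female`, `p_value`,
#'   `n_offspring`, `per_cross` (data frame with per-cross counts and female
#'   proportions).
#' @export
sex_ratio_test <- function(dataset) {
  if (!nrow(dataset)) stop_invalid("empty dataset")
  nf <- sum(dataset$n_female)
  nt <- sum(dataset$total)
  if (nt <= 0) stop_invalid("no offspring counted")
  ht <- binom.test(nf, nt, p = 0.5)
  cross <- paste(dataset$female_line, dataset$male_line, sep = ":")
  agg_f <- tapply(dataset$n_female, cross, sum)
  agg_t <- tapply(dataset$total, cross, sum)
  per_cross <- data.frame(
    cross = names(agg_f),
    n_female = as.numeric(agg_f),
    total = as.numeric(agg_t),
    prop_female = ifelse(agg_t > 0, agg_f / agg_t, NA_real_),
    row.names = NULL
  )
  out <- list(proportion_female = nf / nt, p_value = ht$p.value,
              n_offspring = nt, per_cross = per_cross)
  class(out) <- "sex_ratio_result"
  out
}

#' @export
print.sex_ratio_result <- function(x, ...) {
  cat(sprintf(
    "Sex ratio: %.4f female of %d offspring; binomial p = %.3g\n",
    x$proportion_female, x$n_offspring, x$p_value))
  invisible(x)
}

#' Test the self-cross (progeny inbreeding) contrast
#'
#' Adds a fixed self-cross indicator to the bio-model and reports its Wald
#' test: self-crosses produce fully inbred progeny, so this contrast measures
#' the effect of progeny inbreeding on productivity.
#'
#' @inheritParams fit_biomodel
#' @return List with `estimate` (flies), `se`, `z`, `p_value` and the
#'   underlying `fit`.
#' @export
inbreeding_contrast <- function(dataset, response = NULL,
                                control = reml_control()) {
  if (!any(dataset$female_line == dataset$male_line)) {
    stop_invalid("dataset contains no self-crosses")
  }
  fit <- fit_biomodel(dataset, response = response, self_effect = TRUE,
                      control = control)
  est <- fit$beta[["self"]]
  se <- sqrt(diag(fit$beta_vcov)[[which(names(fit$beta) == "self")]])
  z <- est / se
  list(estimate = est, se = se, z = z, p_value = 2 * pnorm(-abs(z)),
       fit = fit)
}
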