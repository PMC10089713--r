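#' Simulate per-line expression of the candidate gene
#'
#' Runs the mediator model forward: for each line,
#' `expression = alpha0 + alpha1 * g + noise`, where `g` is the line's 0/1
#' genotype at the causal variant and the noise is normal with SD
#' `sd_expression`. Lines with a missing causal genotype get missing
#' expression.
#'
#' @param panel A [make_panel()] panel.
#' @param genotypes Genotype matrix containing the causal variant.
#' @param truth A [diallel_truth()] with a `mediation` block.
#' @param seed Integer seed.
#' @return The panel with its `expression` column filled in.
#' @export
simulate_expression <- function(panel, genotypes, truth, seed = 1L) {
  validate_panel(panel)
  if (is.null(truth$mediation)) {
    stop_invalid("`truth$mediation` is not set; nothing to simulate")
  }
  cid <- truth$causal$id
  if (is.null(cid) || !cid %in% colnames(genotypes)) {
    stop_invalid("causal variant `", cid %||% "<none>",
                 "` not present in `genotypes`")
  }
  g <- genotypes[panel$line_id, cid]
  med <- truth$mediation
  noise <- with_seed(seed, rnorm(nrow(panel), 0, med$sd_expression))
  panel$expression <- med$alpha0 + med$alpha1 * g + noise
  panel$expression[is.na(g)] <- NA_real_
  panel
}

#' Simulate a complete full diallel cross
#'
#' Generates one replicate experiment of the bio-model run forward. For each
#' line the generator draws a female extranuclear effect `f_i`, a male
#' extranuclear effect `m_i` and a nuclear effect `n_i`; one extranuclear
#' interaction `fm_ij` per ordered pair of parents; and one nuclear
#' interaction `nn_ij` per unordered pair. The latent value of replicate
#' vial `k` of cross female `i` x male `j` is
#'
#' `mu + f_i + m_j + fm_ij + n_i + n_j + nn_ij + infection(cell_ij)
#'  + self_effect * 1[i == j] + a * g_i + beta2 * expression_i + eps_ijk`
#'
#' where the nuclear term is `2 * n_i` for a self-cross (the model equation
#' evaluated at `i = j`), `g_i` is the female line's causal genotype (term
#' present only with a causal variant), and the mediator term is present only
#' when expression has been simulated. Latent values are rounded half-up and
#' floored at zero to give counts, then split into female and male offspring
#' as Binomial(total, 1/2); `integer_counts = FALSE` keeps the latent reals
#' (and splits them evenly) for moment checks.
#'
#' @param panel A line panel (with expression filled in if `truth$mediation`
#'   is set).
#' @param genotypes Genotype matrix; required when `truth$causal` is set.
#' @param truth A [diallel_truth()].
#' @param n_reps Replicate vials per cross (>= 1).
#' @param seed Integer seed.
#' @param integer_counts Round/floor latent values into counts (default TRUE).
#'
#' @return A `diallel_dataset`: data frame with columns `female_line`,
#'   `male_line`, `replicate`, `n_female`, `n_male`, `total`, ordered by
#'   (female, male, replicate), with `n_lines^2 * n_reps` rows.
#' @export
#' @examples
#' panel <- make_panel(5, seed = 1)
#' truth <- diallel_truth(mu = 100, sigma2_f = 50, sigma2_m = 10,
#'                        sigma2_fm = 10, sigma2_n = 2, sigma2_nn = 2,
#'                        sigma2_e = 100)
#' d <- simulate_diallel(panel, truth = truth, n_reps = 3, seed = 2)
#' nrow(d)  # 5^2 * 3
simulate_diallel <- function(panel, genotypes = NULL, truth, n_reps,
                             seed = 1L, integer_counts = TRUE) {
  validate_panel(panel)
  if (!inherits(truth, "diallel_truth")) {
    stop_invalid("`truth` must be a diallel_truth object")
  }
  if (!is.numeric(n_reps) || n_reps < 1 || n_reps != round(n_reps)) {
    stop_invalid("`n_reps` must be a positive integer")
  }
  n_reps <- as.integer(n_reps)
  n <- nrow(panel)
  ids <- panel$line_id

  g <- NULL
  if (!is.null(truth$causal)) {
    cid <- truth$causal$id
    if (is.null(genotypes) || !cid %in% colnames(genotypes)) {
      stop_invalid("truth has a causal variant but `genotypes` lacks `",
                   cid, "`")
    }
    g <- genotypes[ids, cid]
    if (anyNA(g)) {
      stop_invalid("causal genotype is missing for lines ",
                   paste(ids[is.na(g)], collapse = ", "),
                   "; the generator needs complete causal genotypes")
    }
  }
  expr <- NULL
  if (!is.null(truth$mediation)) {
    expr <- panel$expression
    if (anyNA(expr)) {
      stop_invalid("mediation is enabled but expression is missing for ",
                   "lines ", paste(ids[is.na(expr)], collapse = ", "),
                   "; run simulate_expression() first")
    }
  }

  with_seed(seed, {
    f_eff <- rnorm(n, 0, sqrt(truth$sigma2_f))
    m_eff <- rnorm(n, 0, sqrt(truth$sigma2_m))
    n_eff <- rnorm(n, 0, sqrt(truth$sigma2_n))
    fm_eff <- matrix(rnorm(n * n, 0, sqrt(truth$sigma2_fm)), n, n)
    nn_eff <- matrix(0, n, n)
    upper <- upper.tri(nn_eff, diag = TRUE)
    nn_eff[upper] <- rnorm(sum(upper), 0, sqrt(truth$sigma2_nn))
    nn_eff <- nn_eff + t(nn_eff * upper.tri(nn_eff))  # symmetrize, diag once

    fem <- rep(seq_len(n), each = n * n_reps)
    mal <- rep(rep(seq_len(n), each = n_reps), times = n)
    rep_k <- rep(seq_len(n_reps), times = n * n)

    nuclear <- n_eff[fem] + n_eff[mal]           # = 2*n_i when fem == mal
    cell <- infection_cell(panel$infected[fem], panel$infected[mal])
    latent <- truth$mu + f_eff[fem] + m_eff[mal] +
      fm_eff[cbind(fem, mal)] + nuclear + nn_eff[cbind(fem, mal)] +
      truth$infection_effects[cell] +
      truth$self_cross_effect * (fem == mal)
    if (!is.null(g)) latent <- latent + truth$causal$effect_direct * g[fem]
    if (!is.null(expr)) latent <- latent + truth$mediation$beta2 * expr[fem]
    latent <- latent + rnorm(length(latent), 0, sqrt(truth$sigma2_e))

    if (integer_counts) {
      total <- pmax(0, round_half_up(latent))
      n_female <- rbinom(length(total), size = as.integer(total), prob = 0.5)
      n_male <- total - n_female
    } else {
      total <- latent
      n_female <- total / 2
      n_male <- total / 2
    }

    dataset <- data.frame(
      female_line = ids[fem],
      male_line = ids[mal],
      replicate = rep_k,
      n_female = n_female,
      n_male = n_male,
      total = total,
      stringsAsFactors = FALSE
    )
    as_diallel_dataset(dataset)
  })
}

#' Coerce and validate a diallel dataset
#'
#' @param x Data frame with columns `female_line`, `male_line`, `replicate`,
#'   `n_female`, `n_male` and optionally `total` (recomputed if absent).
#' @return A validated `diallel_dataset`.
#' @export
as_diallel_dataset <- function(x) {
  need <- c("female_line", "male_line", "replicate", "n_female", "n_male")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    stop_invalid("dataset lacks columns: ", paste(miss, collapse = ", "))
  }
  if (is.null(x[["total"]])) x$total <- x$n_female + x$n_male
  if (any(x$n_female < 0 | x$n_male < 0, na.rm = TRUE)) {
    stop_invalid("offspring counts must be non-negative")
  }
  if (max(abs(x[["total"]] - (x$n_female + x$n_male))) > 1e-8) {
    stop_invalid("total must equal n_female + n_male")
  }
  key <- paste(x$female_line, x$male_line, x$replicate)
  if (anyDuplicated(key)) {
    stop_invalid("duplicated (female, male, replicate) combinations")
  }
  lines <- sort(unique(c(x$female_line, x$male_line)))
  n <- length(lines)
  reps <- table(paste(x$female_line, x$male_line))
  complete <- length(reps) == n^2 && length(unique(reps)) == 1L
  structure(x,
            n_lines = n,
            n_reps = if (complete) unname(reps[1]) else NA_integer_,
            complete = complete,
            class = c("diallel_dataset", "data.frame"))
}

#' @export
print.diallel_dataset <- function(x, ...) {
  cat(sprintf(
    "Diallel dataset: %d vials, %d lines%s\n", nrow(x), attr(x, "n_lines"),
    if (isTRUE(attr(x, "complete"))) {
      sprintf(", complete with %d replicates/cross", attr(x, "n_reps"))
    } else ", incomplete design"))
  print.data.frame(head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("...", nrow(x) - 6, "more vials\n")
  invisible(x)
}

#' Simulate the full calibrated preset experiment
#'
#' Convenience wrapper: builds a panel, genotypes (with the embedded causal
#' variant), expression and a complete diallel under [fertility_preset_truth()],
#' deriving one sub-seed per stage from `seed`.
#'
#' @param seed Integer seed for the whole experiment.
#' @param n_lines,n_reps Design size (defaults 50 lines, 3 replicates).
#' @param n_variants Number of simulated variants (default 1000).
#' @param missing_rate Missingness for non-causal genotypes (default 0.02).
#' @param infection_prob Per-line infection probability (default 0.5).
#' @param truth Optional [diallel_truth()] overriding the preset.
#' @return List with elements `panel`, `genotypes`, `dataset`, `truth`.
#' @export
simulate_fertility_preset <- function(seed, n_lines = 50, n_reps = 3,
                                n_variants = 1000, missing_rate = 0.02,
                                infection_prob = 0.5, truth = NULL) {
  truth <- truth %||% fertility_preset_truth(infection_prob = infection_prob)
  seed <- as.integer(seed)
  panel <- make_panel(n_lines, infection_prob, seed = seed)
  genotypes <- make_genotypes(panel, n_variants,
                              causal = truth$causal,
                              missing_rate = missing_rate,
                              seed = seed + 1L)
  if (!is.null(truth$mediation)) {
    panel <- simulate_expression(panel, genotypes, truth, seed = seed + 2L)
  }
  dataset <- simulate_diallel(panel, genotypes, truth, n_reps,
                              seed = seed + 3L)
  list(panel = panel, genotypes = genotypes, dataset = dataset, truth = truth)
}
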