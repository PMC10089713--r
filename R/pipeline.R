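#' Run the full diallel analysis pipeline from one configuration
#'
#' Executes, in fixed order, the enabled stages `simulate` (or load inputs),
#' `adjust` (infection-effect estimation + phenotype adjustment), `fit`
#' (total genetic variance + bio-model partition), `gwas` (female line-mean
#' association) and `mediate` (expression mediation at the causal/top
#' variant), writing artifacts and a consolidated JSON report to `out_dir`.
#' The run is fully reproducible: all randomness derives from `seed`.
#'
#' Configuration fields (a named list, or a path to a YAML file with the same
#' structure):
#' \describe{
#'   \item{seed}{integer, required when any stochastic stage is enabled.}
#'   \item{out_dir}{output directory, required.}
#'   \item{stages}{character vector from `simulate`, `adjust`, `fit`, `gwas`,
#'     `mediate`, or `"all"` (default).}
#'   \item{preset}{`"fertility50"` (default) to simulate; alternatively supply
#'     `inputs` with paths `diallel`, `panel`, `genotypes` (TSV; genotypes
#'     may be a `.vcf`).}
#'   \item{params}{optional overrides: `n_lines`, `n_reps`, `n_variants`,
#'     `missing_rate`, `infection_prob`, `maf_min`, `p_threshold`,
#'     `resamples`.}
#' }
#'
#' @param config Named list or path to a YAML config file.
#' @return A `pipeline_report` (invisibly): per-stage summary blocks plus the
#'   echoed config; also written to `out_dir/report.json`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop_invalid("config error: file not found: ",
                                           config)
    config <- yaml::read_yaml(config)
  }
  config <- validate_config(config)
  stages <- config$stages
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- config$params
  art <- function(name) file.path(config$out_dir, name)
  report <- list(
    package = "diallelQG",
    version = as.character(utils::packageVersion("diallelQG")),
    config = config, stages = list(), warnings = character(0)
  )
  run_stage <- function(name, expr) {
    message(sprintf("[%s] started", name))
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e) {
      stop("stage `", name, "` failed: ", conditionMessage(e), call. = FALSE)
    })
    message(sprintf("[%s] done in %.1fs", name,
                    as.numeric(Sys.time() - t0, units = "secs")))
    out
  }

  truth <- NULL
  if ("simulate" %in% stages) {
    sim <- run_stage("simulate", {
      sim <- simulate_fertility_preset(
        seed = config$seed, n_lines = p$n_lines, n_reps = p$n_reps,
        n_variants = p$n_variants, missing_rate = p$missing_rate,
        infection_prob = p$infection_prob)
      write_diallel(sim$dataset, art("dataset.tsv"))
      write_panel(sim$panel, art("panel.tsv"))
      write_genotypes(sim$genotypes, art("genotypes.tsv"))
      write_truth(sim$truth, art("truth.json"))
      sim
    })
    dataset <- sim$dataset
    panel <- sim$panel
    genotypes <- sim$genotypes
    truth <- sim$truth
    report$stages$simulate <- list(
      n_lines = attr(dataset, "n_lines"), n_reps = attr(dataset, "n_reps"),
      n_vials = nrow(dataset), n_variants = ncol(genotypes),
      mean_total = mean(dataset$total),
      cv_total = sd(dataset$total) / mean(dataset$total)
    )
  } else {
    inp <- config$inputs
    dataset <- read_diallel(inp$diallel)
    panel <- read_panel(inp$panel)
    genotypes <- if (grepl("\\.vcf(\\.gz)?$", inp$genotypes)) {
      read_genotypes_vcf(inp$genotypes)
    } else {
      read_genotypes(inp$genotypes)
    }
  }

  if ("adjust" %in% stages) {
    adj <- run_stage("adjust", {
      eff <- fit_infection_model(dataset, panel, response = "total")
      dataset <- adjust_productivity(dataset, eff)
      write_diallel(dataset, art("dataset_adjusted.tsv"))
      jsonlite::write_json(
        list(cell_effects = as.list(eff$cell_effects),
             cell_se = as.list(eff$cell_se), tests = eff$tests),
        art("infection_effects.json"), auto_unbox = TRUE, digits = NA)
      list(eff = eff, dataset = dataset)
    })
    dataset <- adj$dataset
    report$stages$adjust <- list(
      cell_effects = as.list(adj$eff$cell_effects),
      interaction_p = adj$eff$tests$p_value[3]
    )
  }

  bio_fit <- NULL
  if ("fit" %in% stages) {
    fits <- run_stage("fit", {
      tg <- total_genetic_model(dataset)
      bio <- fit_biomodel(dataset)
      part <- partition_summary(bio)
      write.table(part, art("variance_partition.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      jsonlite::write_json(
        list(sigma2 = as.list(bio$sigma2), loglik = bio$loglik,
             genetic_share = tg$share,
             convergence = bio$convergence),
        art("biomodel_fit.json"), auto_unbox = TRUE, digits = NA)
      list(tg = tg, bio = bio, part = part)
    })
    bio_fit <- fits$bio
    report$stages$fit <- list(
      genetic_share = fits$tg$share,
      sigma2 = as.list(fits$bio$sigma2),
      pct_genetic = setNames(as.list(fits$part$pct_genetic),
                             fits$part$component),
      pct_phenotypic = setNames(as.list(fits$part$pct_phenotypic),
                                fits$part$component)
    )
  }

  lm_phe <- NULL
  gwas <- NULL
  if ("gwas" %in% stages) {
    gw <- run_stage("gwas", {
      lm_phe <- female_line_means(dataset)
      geno <- filter_variants(genotypes, p$maf_min)
      s2g <- if (!is.null(bio_fit)) {
        linemean_genetic_variance(bio_fit, attr(dataset, "n_lines"))
      } else NULL
      gwas <- run_gwas(lm_phe, geno, p_threshold = p$p_threshold,
                       sigma2_g = s2g)
      write.table(as.data.frame(gwas), art("gwas.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      list(lm_phe = lm_phe, gwas = gwas)
    })
    lm_phe <- gw$lm_phe
    gwas <- gw$gwas
    report$stages$gwas <- list(
      n_tested = nrow(gwas), n_significant = sum(gwas$significant),
      top = as.list(gwas[1, c("variant", "maf", "effect", "se", "p",
                              "var_explained")])
    )
  }

  if ("mediate" %in% stages) {
    med <- run_stage("mediate", {
      target <- attr(genotypes, "causal_id") %||%
        (if (!is.null(gwas) && nrow(gwas)) gwas$variant[1] else
           stop("no causal/top variant available for mediation"))
      if (is.null(lm_phe)) lm_phe <- female_line_means(dataset)
      expr <- setNames(panel$expression, panel$line_id)
      if (all(is.na(expr))) stop("panel has no expression values")
      m <- fit_mediation(
        genotype = setNames(genotypes[, target], rownames(genotypes)),
        mediator = expr, outcome = lm_phe,
        n_resamples = p$resamples, seed = config$seed + 7L)
      jsonlite::write_json(
        list(variant = target, acme = m$acme, ade = m$ade,
             total_effect = m$total_effect, prop_mediated = m$prop_mediated,
             ci = as.data.frame(m$ci), p_values = as.list(m$p_values),
             n_resamples = m$n_resamples),
        art("mediation.json"), auto_unbox = TRUE, digits = NA)
      m
    })
    report$stages$mediate <- list(
      acme = med$acme, ade = med$ade, total_effect = med$total_effect,
      prop_mediated = med$prop_mediated,
      p_acme = unname(med$p_values["acme"])
    )
  }

  jsonlite::write_json(report, art("report.json"), auto_unbox = TRUE,
                       digits = NA, null = "null", force = TRUE)
  class(report) <- "pipeline_report"
  invisible(report)
}

default_params <- function() {
  list(n_lines = 50L, n_reps = 3L, n_variants = 1000L, missing_rate = 0.02,
       infection_prob = 0.5, maf_min = 0.10, p_threshold = 1e-5,
       resamples = 1000L)
}

validate_config <- function(config) {
  if (!is.list(config)) stop_invalid("config error: config must be a list")
  known <- c("seed", "out_dir", "stages", "preset", "inputs", "params")
  unknown <- setdiff(names(config), known)
  if (length(unknown)) {
    stop_invalid("config error: unknown field(s): ",
                 paste(unknown, collapse = ", "))
  }
  if (is.null(config$out_dir)) stop_invalid("config error: `out_dir` missing")
  stages_all <- c("simulate", "adjust", "fit", "gwas", "mediate")
  stages <- config$stages %||% "all"
  if (identical(stages, "all")) stages <- stages_all
  bad <- setdiff(stages, stages_all)
  if (length(bad)) stop_invalid("config error: unknown stage(s): ",
                                paste(bad, collapse = ", "))
  config$stages <- stages_all[stages_all %in% stages]
  stochastic <- any(c("simulate", "mediate") %in% config$stages)
  if (stochastic && is.null(config$seed)) {
    stop_invalid("config error: `seed` is required for stochastic stages")
  }
  config$seed <- if (is.null(config$seed)) 0L else as.integer(config$seed)
  config$preset <- config$preset %||% "fertility50"
  if (!identical(config$preset, "fertility50")) {
    stop_invalid("config error: unknown preset `", config$preset, "`")
  }
  if (!"simulate" %in% config$stages) {
    need <- c("diallel", "panel", "genotypes")
    have <- names(config$inputs %||% list())
    miss <- setdiff(need, have)
    if (length(miss)) {
      stop_invalid("config error: generator disabled but `inputs` lacks: ",
                   paste(miss, collapse = ", "))
    }
    for (f in unlist(config$inputs[need])) {
      if (!file.exists(f)) stop_invalid("config error: input not found: ", f)
    }
  }
  params <- default_params()
  over <- config$params %||% list()
  bad <- setdiff(names(over), names(params))
  if (length(bad)) stop_invalid("config error: unknown param(s): ",
                                paste(bad, collapse = ", "))
  params[names(over)] <- over
  config$params <- params
  config
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Diallel pipeline report (diallelQG", x$version, ")\n")
  cat("stages run:", paste(names(x$stages), collapse = ", "), "\n")
  for (s in names(x$stages)) {
    cat("--", s, "--\n")
    blk <- x$stages[[s]]
    flat <- unlist(blk)
    print(utils::head(flat, 12))
  }
  invisible(x)
}
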