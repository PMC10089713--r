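test_that("complete designs have the right cardinality and conserve counts", {
  for (case in list(c(2, 1), c(3, 2), c(5, 3))) {
    d <- toy_diallel(n_lines = case[1], n_reps = case[2], seed = case[1])
    expect_identical(nrow(d), as.integer(case[1]^2 * case[2]))
    expect_true(attr(d, "complete"))
    expect_identical(
      nrow(unique(as.data.frame(d)[c("female_line", "male_line")])),
      as.integer(case[1]^2))
    expect_true(all(d$total == d$n_female + d$n_male))
    expect_true(all(d$total >= 0))
  }
})

test_that("simulation is deterministic under a fixed seed", {
  a <- toy_diallel(4, 2, seed = 11)
  b <- toy_diallel(4, 2, seed = 11)
  expect_identical(a, b)
  expect_false(identical(a, toy_diallel(4, 2, seed = 12)))
})

test_that("a noise-free generator returns the grand mean everywhere", {
  truth <- diallel_truth(100, 0, 0, 0, 0, 0, 0)
  d <- simulate_diallel(make_panel(4, 0, seed = 1), truth = truth,
                        n_reps = 2, seed = 1)
  expect_true(all(d$total == 100))
})

test_that("latent moments match the bio-model covariance rules", {
  # Monte-Carlo: covariance of vial totals across seeds, for one pair of
  # vials per relative class, against cross_covariance. Rounding disabled.
  truth <- toy_truth(sigma2_e = 20)
  panel <- make_panel(4, 0, seed = 1)
  nsim <- 900
  sims <- vapply(seq_len(nsim), function(s) {
    simulate_diallel(panel, truth = truth, n_reps = 1, seed = 1000 + s,
                     integer_counts = FALSE)$total
  }, numeric(16))
  d0 <- simulate_diallel(panel, truth = truth, n_reps = 1, seed = 1,
                         integer_counts = FALSE)
  rec <- function(i) as.list(d0[i, c("female_line", "male_line", "replicate")])
  pick <- function(f, m) which(d0$female_line == f & d0$male_line == m)

  pairs <- list(
    same_vial = c(pick("L1", "L2"), pick("L1", "L2")),
    reciprocal = c(pick("L1", "L2"), pick("L2", "L1")),
    maternal_hs = c(pick("L1", "L2"), pick("L1", "L3")),
    paternal_hs = c(pick("L1", "L2"), pick("L3", "L2")),
    reciprocal_hs = c(pick("L1", "L2"), pick("L3", "L1")),
    unrelated = c(pick("L1", "L2"), pick("L3", "L4")),
    self_vial = c(pick("L1", "L1"), pick("L1", "L1"))
  )
  for (nm in names(pairs)) {
    i <- pairs[[nm]][1]; j <- pairs[[nm]][2]
    expected <- cross_covariance(rec(i), rec(j), truth)
    observed <- if (i == j) var(sims[i, ]) else cov(sims[i, ], sims[j, ])
    # MC tolerance: SE of a covariance estimate at n = 900 draws
    tol <- 4 * (expected + 200) / sqrt(nsim)
    expect_lt(abs(observed - expected), tol)
  }

  # total variance of a non-self vial = full-sib covariance + residual
  i <- pick("L1", "L2")
  expect_lt(abs(var(sims[i, ]) -
                (truth$sigma2_f + truth$sigma2_m + truth$sigma2_fm +
                 2 * truth$sigma2_n + truth$sigma2_nn + truth$sigma2_e)),
            40)
})

test_that("expression simulation follows the mediator model", {
  truth <- toy_truth()
  truth$causal <- list(id = "snp", maf = 0.5, effect_direct = 2)
  truth$mediation <- list(alpha0 = 0, alpha1 = 1, beta2 = 3,
                          sd_expression = 0)
  panel <- make_panel(20, 0, seed = 2)
  g <- make_genotypes(panel, 3, causal = truth$causal, missing_rate = 0,
                      seed = 2)
  p2 <- simulate_expression(panel, g, truth, seed = 3)
  # alpha1 = 1, intercept 0, zero noise: expression equals genotype
  expect_equal(p2$expression, unname(as.numeric(g[, "snp"])))

  # missing causal genotype -> missing expression
  g2 <- g
  g2[3, "snp"] <- NA_integer_
  p3 <- simulate_expression(panel, g2, truth, seed = 3)
  expect_true(is.na(p3$expression[3]))
  expect_error(simulate_diallel(p3, g2, truth, 2, seed = 1), "missing")
})

test_that("total causal effect decomposes as direct + mediated exactly", {
  # noise-free limit: all variances zero, expression noise zero
  truth <- diallel_truth(100, 0, 0, 0, 0, 0, 0,
                         causal = list(id = "snp", maf = 0.5,
                                       effect_direct = 4),
                         mediation = list(alpha0 = 0, alpha1 = 2, beta2 = 3,
                                          sd_expression = 0))
  panel <- make_panel(10, 0, seed = 4)
  g <- make_genotypes(panel, 2, causal = truth$causal, missing_rate = 0,
                      seed = 4)
  panel <- simulate_expression(panel, g, truth, seed = 5)
  d <- simulate_diallel(panel, g, truth, 1, seed = 6, integer_counts = FALSE)
  lm_phe <- female_line_means(d, response = "total")
  vals <- setNames(lm_phe$mean, lm_phe$line_id)
  gap <- mean(vals[g[, "snp"] == 1]) - mean(vals[g[, "snp"] == 0])
  expect_equal(gap, 4 + 2 * 3, tolerance = 1e-12)
})

test_that("invalid truth parameters are rejected", {
  expect_error(diallel_truth(100, -1, 0, 0, 0, 0, 0), "non-negative")
  expect_error(
    diallel_truth(100, 1, 1, 1, 1, 1, 1,
                  infection_effects = c(F0M0 = 1, F0M1 = 0, F1M0 = 0,
                                        F1M1 = 0)),
    "anchored")
  expect_error(
    diallel_truth(100, 1, 1, 1, 1, 1, 1,
                  mediation = list(alpha0 = 0, alpha1 = 1, beta2 = 1,
                                   sd_expression = 1)),
    "causal")
})
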