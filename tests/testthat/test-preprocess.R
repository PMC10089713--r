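test_that("noise-free infection effects equal the exact cell-mean contrasts", {
  panel <- make_panel(2, 0, seed = 1)
  panel$infected <- c(1L, 0L)  # L1 infected, L2 not
  truth <- diallel_truth(100, 0, 0, 0, 0, 0, 0,
                         infection_effects = c(F0M0 = 0, F0M1 = -3,
                                               F1M0 = -6, F1M1 = -6))
  d <- simulate_diallel(panel, truth = truth, n_reps = 2, seed = 1)
  eff <- fit_infection_model(d, panel)
  expect_equal(unname(eff$cell_effects),
               c(0, -3, -6, -6), tolerance = 1e-8)
  expect_equal(unname(eff$raw_cell_effects), c(0, -3, -6, -6),
               tolerance = 1e-8)
})

test_that("degenerate infection designs are refused", {
  panel <- make_panel(4, 0, seed = 1)
  d <- toy_diallel(4, 2, seed = 1)
  expect_error(fit_infection_model(d, panel), "degenerate")
})

test_that("adjustment subtracts cell effects and is idempotent", {
  truth <- toy_truth(sigma2_e = 30)
  truth$infection_effects <- c(F0M0 = 0, F0M1 = -3, F1M0 = -6, F1M1 = -6)
  panel <- make_panel(10, 0.5, seed = 40)
  d <- simulate_diallel(panel, truth = truth, n_reps = 3, seed = 41)
  eff <- fit_infection_model(d, panel)
  adj <- adjust_productivity(d, eff)

  # arithmetic contract: adjusted = observed - estimated cell effect
  sf <- eff$line_status[adj$female_line]
  sm <- eff$line_status[adj$male_line]
  cell <- paste0("F", sf, "M", sm)
  expect_equal(adj$total_adjusted,
               adj$total - unname(eff$cell_effects[cell]))
  base <- cell == "F0M0"
  expect_equal(adj$total_adjusted[base], as.numeric(adj$total[base]))

  # refit on adjusted data: all cell effects vanish
  eff2 <- fit_infection_model(adj, panel)
  expect_lt(max(abs(eff2$cell_effects)), 1e-6 * sd(d$total))

  # zero effects leave the dataset unchanged
  eff0 <- eff
  eff0$cell_effects[] <- 0
  adj0 <- adjust_productivity(d, eff0)
  expect_equal(adj0$total_adjusted, as.numeric(d$total))

  # unknown line
  d2 <- d
  d2$female_line[1] <- "ghost"
  expect_error(adjust_productivity(as_diallel_dataset(d2), eff), "ghost")
})

test_that("infection effect estimates are unbiased over repeated draws", {
  truth <- toy_truth(sigma2_f = 40, sigma2_e = 30)
  truth$infection_effects <- c(F0M0 = 0, F0M1 = -3, F1M0 = -6, F1M1 = -6)
  est <- t(vapply(1:12, function(s) {
    panel <- make_panel(16, 0.5, seed = 100 + s)
    d <- simulate_diallel(panel, truth = truth, n_reps = 2, seed = 200 + s)
    fit_infection_model(d, panel)$cell_effects[c("F0M1", "F1M0", "F1M1")]
  }, numeric(3)))
  avg <- colMeans(est)
  # Monte-Carlo tolerance ~ 3 SE with 16 lines x 12 seeds
  expect_lt(abs(avg[["F0M1"]] + 3), 2.0)
  expect_lt(abs(avg[["F1M0"]] + 6), 2.5)
  expect_lt(abs(avg[["F1M1"]] + 6), 2.5)
})

test_that("sex-ratio test behaves at its extremes and holds its size", {
  d <- as_diallel_dataset(data.frame(
    female_line = c("A", "A"), male_line = c("B", "B"), replicate = 1:2,
    n_female = c(25, 30), n_male = c(25, 30)))
  res <- sex_ratio_test(d)
  expect_equal(res$proportion_female, 0.5)
  expect_equal(res$p_value, 1)
  expect_identical(nrow(res$per_cross), 1L)

  all_f <- as_diallel_dataset(data.frame(
    female_line = "A", male_line = "B", replicate = 1,
    n_female = 100, n_male = 0))
  expect_lt(sex_ratio_test(all_f)$p_value, 1e-20)

  expect_error(sex_ratio_test(d[0, ]), "empty")

  # type-I error under the generator's binomial split
  rejections <- sum(vapply(1:150, function(s) {
    dd <- toy_diallel(3, 2, seed = 300 + s)
    sex_ratio_test(dd)$p_value < 0.05
  }, logical(1)))
  # binomial(150, 0.05) 99.9% upper bound
  expect_lte(rejections, 17)
})

test_that("the self-cross contrast recovers a strong inbreeding effect", {
  truth <- toy_truth(sigma2_f = 10, sigma2_m = 5, sigma2_fm = 2,
                     sigma2_n = 1, sigma2_nn = 1, sigma2_e = 4)
  truth$self_cross_effect <- -20
  d <- toy_diallel(8, 3, seed = 50, truth = truth)
  res <- inbreeding_contrast(d, response = "total")
  expect_lt(abs(res$estimate + 20), 4)
  expect_lt(res$p_value, 0.01)

  no_self <- as.data.frame(d)
  no_self <- no_self[no_self$female_line != no_self$male_line, ]
  expect_error(inbreeding_contrast(as_diallel_dataset(no_self)),
               "no self-crosses")
})
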