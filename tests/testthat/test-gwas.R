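test_that("female line means average the right vials", {
  d <- toy_diallel(4, 2, seed = 60)
  lm_phe <- female_line_means(d, response = "total")
  expect_identical(lm_phe$n_vials, rep(8L, 4))  # n_lines * n_reps
  manual <- tapply(d$total, d$female_line, mean)
  expect_equal(lm_phe$mean, as.numeric(manual[lm_phe$line_id]))

  d2 <- as_diallel_dataset(data.frame(
    female_line = "A", male_line = c("A", "B"), replicate = 1,
    n_female = c(80, 80), n_male = 0))
  expect_warning(out <- female_line_means(d2, response = "total"),
                 "never used as female")
  expect_equal(out$mean, 80)
})

test_that("line means track the drawn female effects as noise vanishes", {
  truth <- toy_truth(sigma2_f = 100, sigma2_m = 1, sigma2_fm = 1,
                     sigma2_n = 0.5, sigma2_nn = 0.5, sigma2_e = 1)
  panel <- make_panel(15, 0, seed = 61)
  d <- simulate_diallel(panel, truth = truth, n_reps = 3, seed = 62)
  # reconstruct the f draws with the generator's own RNG layout
  f_draws <- with(list(), {
    set.seed(62L)
    rnorm(15, 0, 10)
  })
  lm_phe <- female_line_means(d, response = "total")
  expect_gt(cor(lm_phe$mean, f_draws), 0.98)
})

test_that("single-variant OLS matches the closed form and textbook lm", {
  set.seed(70)
  for (i in 1:20) {
    n <- sample(6:20, 1)
    g <- rbinom(n, 1, 0.4)
    if (length(unique(g)) < 2) g[1:2] <- c(0L, 1L)
    y <- 5 + 3 * g + rnorm(n)
    names(g) <- names(y) <- paste0("L", seq_len(n))
    row <- variant_regression(y, g)
    ref <- summary(lm(y ~ g))$coefficients
    flip <- if (mean(g) <= 0.5) 1 else -1
    expect_equal(row$effect, flip * ref["g", 1], tolerance = 1e-10)
    expect_equal(row$se, ref["g", 2], tolerance = 1e-10)
    expect_equal(row$p, ref["g", 4], tolerance = 1e-10)
    expect_identical(row$n, n)
  }
})

test_that("effects are reported per minor allele", {
  y <- setNames(c(10, 10, 10, 20, 20, 20, 20, 20, 20, 20),
                paste0("L", 1:10))
  g_major1 <- setNames(c(0L, 0L, 0L, rep(1L, 7)), names(y))  # allele 1 major
  row <- variant_regression(y, g_major1)
  expect_identical(row$minor_allele, "0")
  expect_equal(row$maf, 0.3)
  expect_equal(row$effect, -10)  # minor (0) allele lowers the mean

  # exact fit documents the smallest-positive-p behaviour
  expect_gt(row$p, 0)
  expect_lte(row$p, 1)
})

test_that("missing genotypes are dropped pairwise and small n rejected", {
  y <- setNames(rnorm(12, 100), paste0("L", 1:12))
  g <- setNames(rep(c(0L, 1L), 6), names(y))
  g[1:3] <- NA
  row <- variant_regression(y, g)
  expect_identical(row$n, 9L)
  g2 <- g
  g2[] <- NA
  g2[1:2] <- c(0L, 1L)
  expect_error(variant_regression(y, g2), "fewer than 3")
  expect_error(variant_regression(y, setNames(rep(0L, 12), names(y))),
               "monomorphic")
})

test_that("a conditioning covariate independent of the variant leaves the effect", {
  set.seed(71)
  g <- setNames(rep(0:1, each = 15), paste0("L", 1:30))
  cv <- setNames(rnorm(30), names(g))       # independent covariate
  y <- setNames(100 + 8 * g + rnorm(30, 0, 2), names(g))
  plain <- variant_regression(y, g)
  cond <- variant_regression(y, g, covariate = cv)
  expect_equal(cond$effect, plain$effect, tolerance = 1e-10)
  expect_false(is.na(cond$p_conditional))
  expect_lt(cond$p_conditional, 1e-6)
})

test_that("run_gwas ranks the causal variant first and orders ties by id", {
  truth <- toy_truth(sigma2_f = 4, sigma2_m = 1, sigma2_fm = 1,
                     sigma2_n = 0.5, sigma2_nn = 0.5, sigma2_e = 2)
  truth$causal <- list(id = "snp_causal", maf = 0.4, effect_direct = 30)
  panel <- make_panel(20, 0, seed = 72)
  G <- make_genotypes(panel, 60, causal = truth$causal, missing_rate = 0,
                      seed = 73)
  d <- simulate_diallel(panel, G, truth, n_reps = 2, seed = 74)
  res <- run_gwas(female_line_means(d, response = "total"), G)
  expect_identical(res$variant[1], "snp_causal")
  expect_true(res$significant[1])
  expect_true(all(diff(res$p) >= 0))
  expect_lt(abs(res$effect[1] - 30), 6)

  # monomorphic variants are recorded as skipped, not fatal
  G2 <- cbind(G, mono = rep(0L, 20))
  res2 <- run_gwas(female_line_means(d, response = "total"), G2)
  expect_true("mono" %in% names(attr(res2, "skipped")))
  expect_identical(nrow(res2), 61L - 1L)
})

test_that("variance explained follows p(1-p)a^2 / sigma2_g with capping", {
  expect_warning(ve <- variance_explained(2, 0.5, 1), "capped")
  expect_equal(ve, 1)
  expect_equal(variance_explained(0, 0.3, 10), 0)
  expect_equal(variance_explained(2, 0.25, 3), 0.25)
  expect_error(variance_explained(1, 0.2, 0), "positive")

  vc <- c(sigma2_f = 100, sigma2_m = 10, sigma2_fm = 20, sigma2_n = 5,
          sigma2_nn = 10, sigma2_e = 50)
  expect_equal(linemean_genetic_variance(vc, 50), 100 + 5 + 30 / 50)
})

test_that("top variants replicate in a same-truth independent dataset", {
  truth <- toy_truth(sigma2_f = 4, sigma2_m = 1, sigma2_fm = 1,
                     sigma2_n = 0.5, sigma2_nn = 0.5, sigma2_e = 2)
  truth$causal <- list(id = "snp_causal", maf = 0.4, effect_direct = 30)
  panel <- make_panel(20, 0, seed = 75)
  G <- make_genotypes(panel, 40, causal = truth$causal, missing_rate = 0,
                      seed = 76)
  d1 <- simulate_diallel(panel, G, truth, n_reps = 2, seed = 77)
  d2 <- simulate_diallel(panel, G, truth, n_reps = 2, seed = 78)
  res <- run_gwas(female_line_means(d1, response = "total"), G)
  top <- res[res$significant, ]
  rep_res <- replicate_variants(top, female_line_means(d2, response = "total"),
                                G)
  expect_true(rep_res$replicated[rep_res$variant == "snp_causal"])

  # absent variants are skipped with a note; empty top list is fine
  rep2 <- replicate_variants(top, female_line_means(d2, response = "total"),
                             G[, setdiff(colnames(G), "snp_causal")])
  expect_true("snp_causal" %in% attr(rep2, "skipped"))
  rep0 <- replicate_variants(res[0, ],
                             female_line_means(d2, response = "total"), G)
  expect_identical(nrow(rep0), 0L)
})

test_that("pearson correlation matches the textbook formula", {
  x <- c(1, 3, 4, 6, 8)
  y <- c(2, 3, 7, 6, 12)
  res <- pearson_correlation(x, y)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t_hand <- r_hand * sqrt(3 / (1 - r_hand^2))
  expect_equal(res$r, r_hand)
  expect_equal(res$p_value, 2 * pt(-abs(t_hand), 3))
  expect_identical(res$n, 5L)

  expect_equal(pearson_correlation(x, x)$r, 1)
  expect_error(pearson_correlation(rep(1, 5), y), "zero variance")
  xn <- setNames(c(x, 99), paste0("L", 1:6))
  yn <- setNames(y, paste0("L", 1:5))
  expect_identical(pearson_correlation(xn, yn)$n, 5L)  # name alignment
})
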