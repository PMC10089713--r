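test_that("the REML optimum matches a brute-force dense-covariance search", {
  d <- toy_diallel(3, 2, seed = 6, truth = toy_truth(sigma2_e = 20))
  obj <- function(th) {
    v <- exp(th)
    -dense_reml_loglik(d, c(sigma2_f = v[1], sigma2_m = v[2],
                            sigma2_fm = v[3], sigma2_n = v[4],
                            sigma2_nn = v[5], sigma2_e = v[6]))
  }
  opt <- stats::nlminb(log(rep(20, 6)), obj, lower = log(1e-6),
                       upper = log(1e5))
  fit <- fit_biomodel(d, response = "total")
  expect_equal(fit$loglik, -opt$objective, tolerance = 1e-5)
  expect_equal(unname(fit$sigma2), unname(exp(opt$par)), tolerance = 1e-2)
})

test_that("a constant phenotype gives zero variances and the constant mean", {
  d <- toy_diallel(3, 2, seed = 1)
  d$total <- 42
  fit <- fit_biomodel(d, response = "total")
  expect_true(all(fit$sigma2 == 0))
  expect_equal(unname(fit$beta[1]), 42)
})

test_that("balanced reduction and full-data fits agree", {
  d <- toy_diallel(5, 3, seed = 8)
  red <- fit_biomodel(d, response = "total")
  full <- fit_biomodel(d, response = "total", reduce = "never")
  expect_identical(red$method, "reduced")
  expect_identical(full$method, "full")
  expect_equal(red$sigma2, full$sigma2, tolerance = 1e-3)
  expect_equal(red$loglik, full$loglik, tolerance = 1e-6)
})

test_that("estimates are invariant to relabelling lines", {
  d <- toy_diallel(4, 2, seed = 9)
  fit1 <- fit_biomodel(d, response = "total")
  relabel <- c(L1 = "Zebra", L2 = "Alpha", L3 = "Mango", L4 = "Kiwi")
  d2 <- d
  d2$female_line <- unname(relabel[d$female_line])
  d2$male_line <- unname(relabel[d$male_line])
  fit2 <- fit_biomodel(as_diallel_dataset(d2), response = "total")
  expect_equal(fit1$sigma2, fit2$sigma2, tolerance = 1e-6)
  expect_equal(fit1$loglik, fit2$loglik, tolerance = 1e-8)
})

test_that("a female-only generator is recovered and matches method of moments", {
  truth <- toy_truth(sigma2_f = 100, sigma2_m = 0, sigma2_fm = 0,
                     sigma2_n = 0, sigma2_nn = 0, sigma2_e = 25)
  d <- toy_diallel(12, 3, seed = 10, truth = truth)
  fit <- fit_biomodel(d, response = "total")
  # method-of-moments one-way ANOVA on female groups as an independent check
  y <- d$total
  fem <- d$female_line
  gm <- tapply(y, fem, mean)
  k <- as.integer(table(fem)[1])
  msb <- k * var(as.numeric(gm))
  msw <- sum((y - gm[fem])^2) / (length(y) - length(gm))
  mom_f <- (msb - msw) / k
  expect_equal(fit$sigma2[["sigma2_f"]], mom_f, tolerance = 0.25 * mom_f)
  others <- fit$sigma2[c("sigma2_m", "sigma2_fm", "sigma2_n", "sigma2_nn")]
  expect_true(all(others < 0.2 * mom_f))
})

test_that("sub-models the reference mixed-model fitter can express agree", {
  d <- toy_diallel(6, 2, seed = 12,
                   truth = toy_truth(sigma2_n = 0, sigma2_nn = 0))
  y <- d$total
  lines <- sort(unique(d$female_line))
  inc <- function(idx) {
    Matrix::sparseMatrix(i = seq_along(y), j = idx, x = 1,
                         dims = c(length(y), length(lines)))
  }
  ours <- reml_fit(y, matrix(1, length(y), 1),
                   list(female = inc(match(d$female_line, lines)),
                        male = inc(match(d$male_line, lines))))
  lmer_fit <- lme4::lmer(total ~ 1 + (1 | female_line) + (1 | male_line),
                         data = as.data.frame(d), REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(lmer_fit))
  ref <- setNames(vc$vcov, vc$grp)
  expect_equal(ours$sigma2[["female"]], ref[["female_line"]],
               tolerance = 1e-3)
  expect_equal(ours$sigma2[["male"]], ref[["male_line"]], tolerance = 1e-3)
  expect_equal(ours$sigma2[["resid"]], ref[["Residual"]], tolerance = 1e-3)
  expect_equal(unname(ours$beta[1]), unname(lme4::fixef(lmer_fit)[1]),
               tolerance = 1e-5)
})

test_that("optimization never ends below its starting likelihood", {
  for (s in 1:5) {
    d <- toy_diallel(4, 2, seed = 100 + s)
    des <- build_design(d)
    start <- c(f = 10, m = 10, fm = 10, n = 10, nn = 10, resid = 10)
    ll0 <- reml_loglik(d$total, des$X, des$Z, start)
    fit <- reml_fit(d$total, des$X, des$Z,
                    control = reml_control(start = start))
    expect_gte(fit$loglik, ll0 - 1e-8)
  }
})

test_that("degenerate designs are rejected with clear errors", {
  d <- toy_diallel(3, 2, seed = 2)
  des <- build_design(d)
  expect_error(reml_fit(d$total, matrix(1, nrow(d), 2), des$Z["f"]),
               "singular")
  expect_error(reml_fit(d$total, matrix(1, 3, 1), des$Z["f"]),
               "not conformable")
})
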