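# Independent oracles and shared fixtures for the test suite.

# Dense brute-force restricted log-likelihood: V is assembled record-by-record
# from the relative-class covariance rules, never from incidence matrices.
dense_reml_loglik <- function(dataset, vc, response = "total") {
  y <- as.numeric(dataset[[response]])
  n <- length(y)
  X <- matrix(1, n, 1)
  V <- covariance_matrix(dataset, vc)
  R <- chol(V)
  Vi <- chol2inv(R)
  XtViX <- crossprod(X, Vi %*% X)
  beta <- solve(XtViX, crossprod(X, Vi %*% y))
  r <- y - X %*% beta
  as.numeric(-0.5 * ((n - 1) * log(2 * pi) + 2 * sum(log(diag(R))) +
                       log(det(XtViX)) + crossprod(r, Vi %*% r)))
}

# a tiny quick truth for structural tests
toy_truth <- function(...) {
  args <- list(mu = 100, sigma2_f = 80, sigma2_m = 10, sigma2_fm = 10,
               sigma2_n = 4, sigma2_nn = 4, sigma2_e = 50)
  over <- list(...)
  args[names(over)] <- over
  do.call(diallel_truth, args)
}

toy_diallel <- function(n_lines = 5, n_reps = 3, seed = 1, truth = toy_truth(),
                        infection_prob = 0) {
  panel <- make_panel(n_lines, infection_prob, seed = seed)
  simulate_diallel(panel, truth = truth, n_reps = n_reps, seed = seed + 1)
}

# incidence-matrix representation of Cov(y): sum_c sigma2_c Z_c Z_c' + s2e I
incidence_covariance <- function(dataset, vc) {
  des <- build_design(dataset)
  V <- matrix(0, nrow(dataset), nrow(dataset))
  comp <- c(f = "sigma2_f", m = "sigma2_m", fm = "sigma2_fm", n = "sigma2_n",
            nn = "sigma2_nn")
  for (c in names(comp)) {
    Zc <- as.matrix(des$Z[[c]])
    V <- V + vc[[comp[[c]]]] * tcrossprod(Zc)
  }
  V + vc[["sigma2_e"]] * diag(nrow(dataset))
}
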