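# Restricted maximum likelihood for Gaussian variance-component models
#
#   y ~ N(X beta, V),  V = sum_c sigma2_c Z_c Z_c' + tau I
#
# The engine never forms V. All solves go through the q x q system
# M = tau G^{-1} + Z'Z (Woodbury identity), with q the total number of
# random-effect levels, so cost scales with q rather than with n. Components
# are optimized on the log scale (hence constrained positive; a component
# converging to the lower bound is reported at that floor, effectively zero)
# with the analytic REML gradient, using nlminb.

#' Control parameters for the REML optimizer
#'
#' @param max_iter Maximum optimizer iterations.
#' @param rel_tol Relative convergence tolerance passed to [stats::nlminb()].
#' @param grad_tol Gradient-norm threshold used to flag doubtful convergence.
#' @param lower_frac Lower bound for each variance component, as a fraction
#'   of `var(y)` (log-scale parameterization cannot reach exactly zero).
#' @param start Optional named numeric vector of starting variances.
#' @return A list of class `reml_control`.
#' @export
reml_control <- function(max_iter = 300, rel_tol = 1e-10, grad_tol = 0.05,
                         lower_frac = 1e-9, start = NULL) {
  structure(list(max_iter = max_iter, rel_tol = rel_tol, grad_tol = grad_tol,
                 lower_frac = lower_frac, start = start),
            class = "reml_control")
}

#' Restricted log-likelihood at fixed variance components
#'
#' Evaluates the REML criterion (including all constants) for given component
#' values, without optimizing. Useful for profiling and for cross-checking
#' the incidence-matrix representation against a covariance matrix assembled
#' by other means.
#'
#' @inheritParams reml_fit
#' @param sigma2 Named vector: one positive entry per element of `Z` plus
#'   `resid`.
#' @return The restricted log-likelihood (scalar).
#' @export
reml_loglik <- function(y, X, Z, sigma2) {
  n <- length(y)
  X <- as.matrix(X)
  p <- ncol(X)
  qs <- vapply(Z, ncol, integer(1))
  sig <- unlist(sigma2)[c(names(Z), "resid")]
  if (anyNA(sig) || any(sig <= 0)) {
    stop_invalid("`sigma2` must give a positive value for every term and ",
                 "`resid`")
  }
  tau <- sig[["resid"]]
  Zall <- do.call(cbind, lapply(Z, function(z) as(z, "CsparseMatrix")))
  qtot <- sum(qs)
  M <- as.matrix(Matrix::crossprod(Zall))
  diag(M) <- diag(M) + rep(tau / sig[seq_along(Z)], qs)
  R <- chol(M)
  L <- t(R)
  Zty <- as.numeric(Matrix::crossprod(Zall, y))
  ZtX <- as.matrix(Matrix::crossprod(Zall, X))
  a1 <- forwardsolve(L, Zty)
  AX <- forwardsolve(L, ZtX)
  ldetV <- (n - qtot) * log(tau) + 2 * sum(log(diag(R))) +
    sum(qs * log(sig[seq_along(Z)]))
  XtVinvX <- (crossprod(X) - crossprod(AX)) / tau
  XtVinvy <- (drop(crossprod(X, y)) - drop(crossprod(AX, a1))) / tau
  RX <- chol(XtVinvX)
  beta <- backsolve(RX, forwardsolve(t(RX), XtVinvy))
  yPy <- (sum(y^2) - sum(a1^2)) / tau - sum(XtVinvy * beta)
  -0.5 * ((n - p) * log(2 * pi) + ldetV + 2 * sum(log(diag(RX))) + yPy)
}

#' REML fit of a Gaussian variance-component model
#'
#' @param y Numeric response vector.
#' @param X Fixed-effect design matrix (must have full column rank).
#' @param Z Named list of (sparse) incidence matrices, one per random term.
#' @param control A [reml_control()].
#' @return List with `sigma2` (named vector: one entry per random term plus
#'   `resid`), `loglik` (restricted log-likelihood including constants),
#'   `beta`, `beta_vcov`, `fitted_fixed` and `convergence` (iterations,
#'   gradient norm, optimizer message).
#' @export
reml_fit <- function(y, X, Z, control = reml_control()) {
  n <- length(y)
  X <- as.matrix(X)
  p <- ncol(X)
  if (nrow(X) != n) stop_invalid("X and y are not conformable")
  if (qr(X)$rank < p) stop_invalid("singular fixed-effect design")
  K <- length(Z)
  if (K < 1) stop_invalid("at least one random term is required")
  if (is.null(names(Z)) || any(names(Z) == "")) {
    stop_invalid("`Z` must be a named list")
  }
  qs <- vapply(Z, ncol, integer(1))
  if (any(qs < 2)) stop_invalid("each random term needs >= 2 levels")

  Zall <- do.call(cbind, lapply(Z, function(z) as(z, "CsparseMatrix")))
  qtot <- sum(qs)
  idx <- split(seq_len(qtot), rep(seq_len(K), qs))
  ZtZ <- as.matrix(Matrix::crossprod(Zall))
  ZtX <- as.matrix(Matrix::crossprod(Zall, X))
  Zty <- as.numeric(Matrix::crossprod(Zall, y))
  XtX <- crossprod(X)
  Xty <- drop(crossprod(X, y))
  yty <- sum(y^2)
  vy <- var(y)

  # Degenerate data: (near-)constant response, or a fixed design that fits
  # exactly. All variances are zero; report the OLS solution.
  ols <- stats::lm.fit(X, y)
  mse <- mean(ols$residuals^2)
  if (!is.finite(vy) || vy < 1e-12 * max(1, mean(y)^2) ||
      mse < 1e-12 * max(1, mean(y^2))) {
    sig <- setNames(numeric(K + 1), c(names(Z), "resid"))
    bv <- tryCatch(chol2inv(chol(XtX)) * mse, error = function(e) NULL)
    return(list(
      sigma2 = sig, loglik = NA_real_, beta = coef(ols),
      beta_vcov = bv, fitted_fixed = drop(X %*% coef(ols)),
      convergence = list(code = 0L, iterations = 0L, grad_norm = 0,
                         message = "degenerate: response fitted exactly")
    ))
  }

  lb <- vy * control$lower_frac
  ub <- vy * 1e4
  diag_ZtZ <- diag(ZtZ)
  comp <- seq_len(K)

  # restricted log-likelihood and its gradient at sig = exp(theta)
  eval_point <- function(theta, want_grad) {
    sig <- exp(theta)
    tau <- sig[K + 1L]
    dG <- rep(tau / sig[comp], qs)
    M <- ZtZ
    diag(M) <- diag(M) + dG
    R <- tryCatch(chol(M), error = function(e) NULL)
    if (is.null(R)) return(NULL)
    L <- t(R)
    a1 <- forwardsolve(L, Zty)
    AX <- forwardsolve(L, ZtX)
    ldetM <- 2 * sum(log(diag(R)))
    ldetV <- (n - qtot) * log(tau) + ldetM + sum(qs * log(sig[comp]))
    XtVinvX <- (XtX - crossprod(AX)) / tau
    XtVinvy <- (Xty - drop(crossprod(AX, a1))) / tau
    RX <- tryCatch(chol(XtVinvX), error = function(e) NULL)
    if (is.null(RX)) return(NULL)
    beta <- backsolve(RX, forwardsolve(t(RX), XtVinvy))
    ldetXVX <- 2 * sum(log(diag(RX)))
    yVinvy <- (yty - sum(a1^2)) / tau
    yPy <- yVinvy - sum(XtVinvy * beta)
    loglik <- -0.5 * ((n - p) * log(2 * pi) + ldetV + ldetXVX + yPy)
    out <- list(loglik = loglik, beta = beta, XtVinvX = XtVinvX, RX = RX)
    if (!want_grad) return(out)

    # traces through the q-space: T = L^{-1} Z'Z, Rinv = R^{-1}
    Tm <- forwardsolve(L, ZtZ)
    colsq <- colSums(Tm^2)
    Rinv <- backsolve(R, diag(qtot))
    diagMinv <- rowSums(Rinv^2)
    XtVinvX_inv <- chol2inv(RX)

    MinvZtX <- backsolve(R, AX)
    VinvX <- (X - as.matrix(Zall %*% MinvZtX)) / tau
    Minv_Zty <- backsolve(R, a1)
    Vinvy <- (y - as.numeric(Zall %*% Minv_Zty)) / tau
    Py <- Vinvy - VinvX %*% beta
    ZtPy <- as.numeric(Matrix::crossprod(Zall, Py))
    ZtVinvX <- as.matrix(Matrix::crossprod(Zall, VinvX))

    g <- numeric(K + 1L)
    for (c in comp) {
      ic <- idx[[c]]
      trVinvA <- (sum(diag_ZtZ[ic]) - sum(colsq[ic])) / tau
      XAX <- crossprod(ZtVinvX[ic, , drop = FALSE])
      trPA <- trVinvA - sum(XtVinvX_inv * XAX)
      quad <- sum(ZtPy[ic]^2)
      g[c] <- -0.5 * (trPA - quad) * sig[c]
    }
    trMinvZtZ <- qtot - sum(dG * diagMinv)
    trVinv <- (n - trMinvZtZ) / tau
    trP <- trVinv - sum(XtVinvX_inv * crossprod(VinvX))
    g[K + 1L] <- -0.5 * (trP - sum(Py^2)) * tau
    out$grad <- g
    out
  }

  cache <- new.env(parent = emptyenv())
  get_point <- function(theta, want_grad) {
    key <- paste(format(theta, digits = 17), collapse = ",")
    hit <- cache$pt
    if (!is.null(hit) && identical(cache$key, key) &&
        (!want_grad || !is.null(hit$grad))) {
      return(hit)
    }
    pt <- eval_point(theta, want_grad)
    if (!is.null(pt)) {
      cache$key <- key
      cache$pt <- pt
    }
    pt
  }

  objective <- function(theta) {
    pt <- get_point(theta, want_grad = FALSE)
    if (is.null(pt) || !is.finite(pt$loglik)) return(1e10)
    -pt$loglik
  }
  gradient <- function(theta) {
    pt <- get_point(theta, want_grad = TRUE)
    if (is.null(pt)) return(rep(0, K + 1L))
    -pt$grad
  }

  start <- control$start
  if (is.null(start)) {
    start <- c(rep(vy / (2 * K), K), vy / 2)
  } else {
    start <- unlist(start)[c(names(Z), "resid")]
    if (anyNA(start)) stop_invalid("`start` must name every term and `resid`")
  }
  start <- pmin(pmax(start, lb * 10), ub / 10)

  opt <- stats::nlminb(
    log(start), objective, gradient,
    lower = log(lb), upper = log(ub),
    control = list(iter.max = control$max_iter,
                   eval.max = 4 * control$max_iter,
                   rel.tol = control$rel_tol)
  )
  final <- get_point(opt$par, want_grad = TRUE)
  if (is.null(final)) stop_invalid("REML failed: covariance not positive definite at optimum")
  sig <- exp(opt$par)
  # interior gradient check (bound-active parameters are allowed nonzero grad)
  at_bound <- opt$par <= log(lb) + 1e-6 | opt$par >= log(ub) - 1e-6
  gnorm <- sqrt(sum(final$grad[!at_bound]^2))
  if (opt$convergence != 0 && gnorm > control$grad_tol) {
    stop(structure(class = c("reml_nonconvergence", "error", "condition"),
                   list(message = paste0(
                     "REML did not converge: ", opt$message,
                     " (iterations = ", opt$iterations,
                     ", |grad| = ", format(gnorm, digits = 3), ")"),
                     call = NULL, sigma2 = setNames(sig, c(names(Z), "resid")),
                     loglik = final$loglik)))
  }
  sig[sig <= lb * 1.01] <- 0  # components pinned at the floor are zeros
  list(
    sigma2 = setNames(sig, c(names(Z), "resid")),
    loglik = final$loglik,
    beta = setNames(drop(final$beta), colnames(X)),
    beta_vcov = chol2inv(final$RX),
    fitted_fixed = drop(X %*% final$beta),
    convergence = list(code = opt$convergence, iterations = opt$iterations,
                       grad_norm = gnorm, message = opt$message)
  )
}
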