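#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm rbinom runif var sd lm coef vcov pnorm pchisq pt
#'   binom.test setNames
#' @importFrom utils read.delim write.table head
#' @importFrom methods as
NULL

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG state. All user-facing stochastic operations funnel through this so
# identical arguments give byte-identical results.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

stop_invalid <- function(...) {
  stop(..., call. = FALSE)
}

# round half away from zero (base round() is round-half-even)
round_half_up <- function(x) floor(x + 0.5)

`%||%` <- function(a, b) if (is.null(a)) b else a

infection_cell <- function(female_infected, male_infected) {
  paste0("F", as.integer(female_infected), "M", as.integer(male_infected))
}

INFECTION_CELLS <- c("F0M0", "F0M1", "F1M0", "F1M1")
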