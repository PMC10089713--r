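#' Create a panel of inbred lines with symbiont infection status
#'
#' A line panel is the unit of replication for a diallel cross: a set of
#' fully inbred (homozygous) lines, each carrying a binary *Wolbachia*
#' infection status. Infection statuses are drawn independently as
#' Bernoulli(`infection_prob`), emulating a reference panel in which roughly
#' half the lines are infected.
#'
#' @param n_lines Number of lines (>= 2).
#' @param infection_prob Probability that a line is infected, in `[0, 1]`.
#' @param seed Integer seed; the same arguments and seed reproduce the panel
#'   exactly.
#' @param line_ids Optional character vector of unique line identifiers;
#'   defaults to `L01 ... Lnn`.
#'
#' @return A `diallel_panel`: a data frame with columns `line_id` (character),
#'   `infected` (0/1 integer) and `expression` (numeric, `NA` until an
#'   expression mediator is simulated; see [simulate_expression()]).
#' @seealso [make_genotypes()], [simulate_diallel()]
#' @export
#' @examples
#' panel <- make_panel(10, infection_prob = 0.5, seed = 1)
#' table(panel$infected)
make_panel <- function(n_lines, infection_prob = 0.5, seed = 1L,
                       line_ids = NULL) {
  if (!is.numeric(n_lines) || length(n_lines) != 1L || n_lines < 2 ||
      n_lines != round(n_lines)) {
    stop_invalid("`n_lines` must be a single integer >= 2")
  }
  if (!is.numeric(infection_prob) || infection_prob < 0 || infection_prob > 1) {
    stop_invalid("`infection_prob` must be in [0, 1]")
  }
  n_lines <- as.integer(n_lines)
  if (is.null(line_ids)) {
    line_ids <- sprintf("L%0*d", nchar(as.character(n_lines)), seq_len(n_lines))
  }
  line_ids <- as.character(line_ids)
  if (anyDuplicated(line_ids) || length(line_ids) != n_lines) {
    stop_invalid("`line_ids` must be ", n_lines, " unique identifiers")
  }
  infected <- with_seed(seed, rbinom(n_lines, 1L, infection_prob))
  panel <- data.frame(
    line_id = line_ids,
    infected = as.integer(infected),
    expression = NA_real_,
    stringsAsFactors = FALSE
  )
  class(panel) <- c("diallel_panel", "data.frame")
  panel
}

validate_panel <- function(panel) {
  if (!is.data.frame(panel) ||
      !all(c("line_id", "infected") %in% names(panel))) {
    stop_invalid("panel must be a data frame with columns line_id, infected")
  }
  if (anyDuplicated(panel$line_id)) {
    stop_invalid("panel line_ids must be unique")
  }
  bad <- !(panel$infected %in% c(0L, 1L) | is.na(panel$infected))
  if (any(bad)) stop_invalid("panel$infected must be 0/1")
  invisible(panel)
}

#' @export
print.diallel_panel <- function(x, ...) {
  cat(sprintf("Line panel: %d lines, %d infected", nrow(x),
              sum(x$infected, na.rm = TRUE)))
  if (!all(is.na(x$expression))) {
    cat(sprintf(", expression simulated for %d lines",
                sum(!is.na(x$expression))))
  }
  cat("\n")
  print.data.frame(head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("...", nrow(x) - 6, "more lines\n")
  invisible(x)
}
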