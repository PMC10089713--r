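#' Build bio-model design matrices for a diallel dataset
#'
#' Constructs the fixed design and the sparse incidence structure of each
#' random term of the bio-model
#' `y_ijk = mu + f_i + m_j + fm_ij + n_i + n_j + nn_ij + e_ijk`:
#'
#' * `f` — female parent line (one column per line, row entry 1);
#' * `m` — male parent line;
#' * `fm` — ordered parent pair `(i, j)` (reciprocal crosses get distinct
#'   columns);
#' * `n` — nuclear line effect: entry 1 for each of the two parental lines,
#'   accumulating to 2 for a self-cross (the model equation at `i = j`);
#' * `nn` — unordered parent pair `{i, j}` (reciprocals share a column).
#'
#' Level indexing is deterministic: line levels are sorted line ids, ordered
#' pairs sort by (female, male), unordered pairs by (min, max).
#'
#' @param dataset A `diallel_dataset` (or any data frame with `female_line`
#'   and `male_line`).
#' @param fixed Optional numeric matrix/data frame of extra fixed covariates
#'   (one row per record); an intercept is always included.
#' @return List with elements `X` (dense fixed design), `Z` (named list of
#'   sparse incidence matrices `f`, `m`, `fm`, `n`, `nn`), and `levels`
#'   (the line and pair level labels).
#' @export
#' @examples
#' panel <- make_panel(2, seed = 1)
#' truth <- diallel_truth(100, 1, 1, 1, 1, 1, 1)
#' d <- simulate_diallel(panel, truth = truth, n_reps = 1, seed = 1)
#' as.matrix(build_design(d)$Z$n)  # rows (2,0), (1,1), (1,1), (0,2)
build_design <- function(dataset, fixed = NULL) {
  fem <- as.character(dataset$female_line)
  mal <- as.character(dataset$male_line)
  if (!length(fem)) stop_invalid("dataset is empty")
  lines <- sort(unique(c(fem, mal)))
  fi <- match(fem, lines)
  mi <- match(mal, lines)
  if (anyNA(fi) || anyNA(mi)) stop_invalid("unresolvable line label")
  nrec <- length(fi)
  nl <- length(lines)

  inc <- function(j, nlev, labels) {
    Matrix::sparseMatrix(i = seq_len(nrec), j = j, x = 1,
                         dims = c(nrec, nlev),
                         dimnames = list(NULL, labels))
  }
  Z_f <- inc(fi, nl, lines)
  Z_m <- inc(mi, nl, lines)

  op <- paste(fem, mal, sep = ":")
  op_lev <- sort(unique(op))
  Z_fm <- inc(match(op, op_lev), length(op_lev), op_lev)

  # nuclear incidence: duplicated (row, line) entries sum, so self-crosses
  # get coefficient 2
  Z_n <- Matrix::sparseMatrix(i = rep(seq_len(nrec), 2L), j = c(fi, mi),
                              x = 1, dims = c(nrec, nl),
                              dimnames = list(NULL, lines))

  up <- paste(pmin(fem, mal), pmax(fem, mal), sep = ":")
  up_lev <- sort(unique(up))
  Z_nn <- inc(match(up, up_lev), length(up_lev), up_lev)

  X <- matrix(1, nrec, 1, dimnames = list(NULL, "(Intercept)"))
  if (!is.null(fixed)) {
    fixed <- as.matrix(fixed)
    if (nrow(fixed) != nrec) stop_invalid("`fixed` must have one row per record")
    X <- cbind(X, fixed)
  }
  list(
    X = X,
    Z = list(f = Z_f, m = Z_m, fm = Z_fm, n = Z_n, nn = Z_nn),
    levels = list(lines = lines, ordered_pairs = op_lev,
                  unordered_pairs = up_lev)
  )
}
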