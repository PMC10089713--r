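#' Covariance between two diallel records under the bio-model
#'
#' Implements the relative-class covariance rules that identify the bio-model
#' components. With `a` the vial of cross female `i1` x male `j1` and `b` of
#' `i2` x `j2`, the covariance of their totals is
#'
#' `sigma2_f [i1=i2] + sigma2_m [j1=j2] + sigma2_fm [i1=i2][j1=j2]
#'  + sigma2_n ([i1=i2] + [i1=j2] + [j1=i2] + [j1=j2])
#'  + sigma2_nn [{i1,j1} = {i2,j2}] + sigma2_e [same vial]`
#'
#' which reproduces the named classes: full sibs (same cross, different
#' vials) `sf2 + sm2 + sfm2 + 2 sn2 + snn2`; reciprocal full sibs
#' `2 sn2 + snn2`; maternal half sibs `sf2 + sn2`; paternal half sibs
#' `sm2 + sn2`; reciprocal half sibs `sn2`; unrelated crosses 0. Replicates
#' of a self-cross pick up `4 sigma2_n` through the nuclear bracket, and the
#' same-vial case adds the residual to give the phenotypic variance.
#'
#' @param record_a,record_b Single records: lists or one-row data frames with
#'   `female_line`, `male_line`, `replicate`.
#' @param vc Variance components: named list/vector with `sigma2_f`,
#'   `sigma2_m`, `sigma2_fm`, `sigma2_n`, `sigma2_nn`, `sigma2_e` (a
#'   [diallel_truth()] or a [fit_biomodel()] `$sigma2` both work).
#' @return Covariance in flies^2.
#' @export
#' @examples
#' vc <- c(sigma2_f = 1, sigma2_m = 2, sigma2_fm = 4, sigma2_n = 8,
#'         sigma2_nn = 16, sigma2_e = 32)
#' rec <- function(f, m, k = 1) list(female_line = f, male_line = m,
#'                                   replicate = k)
#' cross_covariance(rec("A", "B", 1), rec("A", "B", 2))  # full sibs
#' cross_covariance(rec("A", "B"), rec("B", "A"))        # reciprocal
cross_covariance <- function(record_a, record_b, vc) {
  vc <- extract_vc(vc)
  f1 <- as.character(record_a$female_line); m1 <- as.character(record_a$male_line)
  f2 <- as.character(record_b$female_line); m2 <- as.character(record_b$male_line)
  same_vial <- f1 == f2 && m1 == m2 &&
    as.character(record_a$replicate) == as.character(record_b$replicate)
  nuc <- (f1 == f2) + (f1 == m2) + (m1 == f2) + (m1 == m2)
  same_pair <- identical(sort(c(f1, m1)), sort(c(f2, m2)))
  unname(
    vc["sigma2_f"] * (f1 == f2) +
    vc["sigma2_m"] * (m1 == m2) +
    vc["sigma2_fm"] * (f1 == f2 && m1 == m2) +
    vc["sigma2_n"] * nuc +
    vc["sigma2_nn"] * same_pair +
    vc["sigma2_e"] * same_vial
  )
}

#' Assemble the full phenotypic covariance matrix record-by-record
#'
#' Brute-force construction of `Cov(y)` by applying [cross_covariance()] to
#' every pair of records. Quadratic in the number of vials; intended for
#' small designs and as an independent oracle for the incidence-matrix
#' representation used by the REML fitter.
#'
#' @param dataset A `diallel_dataset`.
#' @param vc Variance components (see [cross_covariance()]).
#' @return A dense `nrow(dataset)` square covariance matrix.
#' @export
covariance_matrix <- function(dataset, vc) {
  vc <- extract_vc(vc)
  n <- nrow(dataset)
  f <- as.character(dataset$female_line)
  m <- as.character(dataset$male_line)
  r <- as.character(dataset$replicate)
  Feq <- outer(f, f, "==")
  Meq <- outer(m, m, "==")
  nuc <- Feq + Meq + outer(f, m, "==") + outer(m, f, "==")
  pair <- outer(pmin(f, m), pmin(f, m), "==") &
    outer(pmax(f, m), pmax(f, m), "==")
  vial <- Feq & Meq & outer(r, r, "==")
  vc[["sigma2_f"]] * Feq + vc[["sigma2_m"]] * Meq +
    vc[["sigma2_fm"]] * (Feq & Meq) + vc[["sigma2_n"]] * nuc +
    vc[["sigma2_nn"]] * pair + vc[["sigma2_e"]] * vial
}

extract_vc <- function(vc) {
  need <- c("sigma2_f", "sigma2_m", "sigma2_fm", "sigma2_n", "sigma2_nn",
            "sigma2_e")
  if (inherits(vc, "biomodel_fit")) vc <- vc$sigma2
  v <- unlist(vc)[need]
  if (anyNA(v)) {
    stop_invalid("variance components must name all of ",
                 paste(need, collapse = ", "))
  }
  v
}
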