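# Vectorised statistic kernels. `cc` and `nc` are B x m matrices of case and
# control minor-allele counts (one row per phenotype relabelling); the same
# code serves the observed data as a 1 x m matrix.
.row_max <- function(x) do.call(pmax, as.data.frame(x))

.length_stat <- function(cc, nc, n_cases, n_controls, p) {
  fp <- cc / (2 * n_cases)
  fm <- nc / (2 * n_controls)
  if (is.infinite(p)) {
    return(.row_max(fp) - .row_max(fm))
  }
  rowSums(fp^p)^(1 / p) - rowSums(fm^p)^(1 / p)
}

.joint_stat <- function(cc, nc, n_cases, n_controls, p, absolute = FALSE) {
  d <- cc / (2 * n_cases) - nc / (2 * n_controls)
  if (is.infinite(p)) {
    if (absolute) d <- abs(d)
    return(.row_max(d))
  }
  rowSums(abs(d)^p)^(1 / p)
}

.check_norm <- function(p) {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 1) {
    abort("`norm` must be a single number >= 1 (Inf allowed).")
  }
}

#' Length (burden-style) test statistic
#'
#' Compares the L^p norms of the case and control minor-allele frequency
#' vectors: `(sum_i (c+_i / 2N+)^p)^(1/p) - (sum_i (c-_i / 2N-)^p)^(1/p)`.
#' For `norm = Inf` the statistic is the difference of the per-group maxima.
#' Larger positive values indicate a higher aggregate minor-allele frequency
#' in cases; the statistic can be negative.
#'
#' @param counts A [cohort_counts()] object.
#' @param norm The L^p norm order; any value `>= 1`, including `Inf`.
#'   Published burden tests mostly use `1`.
#' @return A single numeric statistic value.
#' @examples
#' x <- cohort_counts(c(4, 2), c(1, 1), 100, 100)
#' length_statistic(x, 1)   # 0.02
#' length_statistic(x, Inf) # 0.015
#' @seealso [joint_statistic()], [rv_statistics()]
#' @export
length_statistic <- function(counts, norm = 1) {
  stopifnot(inherits(counts, "cohort_counts"))
  .check_norm(norm)
  .length_stat(
    matrix(counts$case_counts, nrow = 1), matrix(counts$control_counts, nrow = 1),
    counts$n_cases, counts$n_controls, norm
  )[1]
}

#' Joint (variance-component-style) test statistic
#'
#' Aggregates per-site case-control frequency differences
#' `D_i = c+_i / 2N+ - c-_i / 2N-` as `(sum_i |D_i|^p)^(1/p)`. With
#' `norm = Inf` the statistic is the maximum signed difference `max_i D_i`,
#' matching the one-sided use of the infinity-norm test; set
#' `absolute = TRUE` to take `max_i |D_i|` instead (useful when protective
#' variants are expected to drive the signal).
#'
#' @inheritParams length_statistic
#' @param absolute For `norm = Inf` only: use the maximum absolute difference
#'   rather than the maximum signed difference. Default `FALSE`.
#' @return A single numeric statistic value (non-negative for finite norms).
#' @examples
#' x <- cohort_counts(c(4, 2), c(1, 1), 100, 100)
#' joint_statistic(x, 2)   # sqrt(10)/200
#' joint_statistic(x, Inf) # 0.015
#' @export
joint_statistic <- function(counts, norm = 2, absolute = FALSE) {
  stopifnot(inherits(counts, "cohort_counts"))
  .check_norm(norm)
  .joint_stat(
    matrix(counts$case_counts, nrow = 1), matrix(counts$control_counts, nrow = 1),
    counts$n_cases, counts$n_controls, norm, absolute = absolute
  )[1]
}

#' Compute a panel of length and joint statistics
#'
#' @inheritParams length_statistic
#' @param families Character vector from `c("length", "joint")`.
#' @param norms Numeric vector of norm orders (default the panel
#'   `1, 2, 4, 8, Inf`).
#' @param absolute Passed to [joint_statistic()] for the infinity norm.
#' @return A tibble with columns `family`, `norm`, `value`.
#' @examples
#' rv_statistics(cohort_counts(c(4, 2), c(1, 1), 100, 100))
#' @export
rv_statistics <- function(counts, families = c("length", "joint"),
                          norms = c(1, 2, 4, 8, Inf), absolute = FALSE) {
  stopifnot(inherits(counts, "cohort_counts"))
  families <- match.arg(families, several.ok = TRUE)
  tidyr::expand_grid(family = families, norm = norms) |>
    dplyr::mutate(value = purrr::map2_dbl(.data$family, .data$norm, function(fam, p) {
      if (fam == "length") length_statistic(counts, p)
      else joint_statistic(counts, p, absolute = absolute)
    }))
}

#' Moments of the scaled case-control count difference
#'
#' For `D_i = c+_i / 2N+ - c-_i / 2N-` with binomial allele counts, the mean
#' is `f+ - f-` and the variance `f+(1-f+)/(2N+) + f-(1-f-)/(2N-)`. These
#' moments drive all asymptotic calculations in the package.
#'
#' @param f_case,f_control Per-allele minor-allele frequencies in cases and
#'   controls (vectorised).
#' @param n_cases,n_controls Case and control sample sizes (individuals).
#' @return A tibble with columns `mean` and `variance`, one row per site.
#' @examples
#' diff_moments(0.011, 0.001, 1000, 1000) # mean 0.01, variance 5.939e-6
#' @export
diff_moments <- function(f_case, f_control, n_cases, n_controls) {
  if (any(f_case < 0 | f_case > 1 | f_control < 0 | f_control > 1)) {
    abort("Frequencies must lie in [0, 1].")
  }
  if (n_cases < 1 || n_controls < 1) abort("Sample sizes must be positive.")
  tibble::tibble(
    mean = f_case - f_control,
    variance = f_case * (1 - f_case) / (2 * n_cases) +
      f_control * (1 - f_control) / (2 * n_controls)
  )
}

#' Variance-scaled J2 statistic
#'
#' `sum_i (D_i / sigma_Di)^2`, where each `sigma_Di` is evaluated under the
#' null hypothesis `f+_i = f-_i = f_i` at the supplied frequencies. The
#' statistic is asymptotically chi-square with `m` degrees of freedom under
#' the null, and acts as a frequency-weighted version of the joint test.
#' Sites whose null variance is zero (monomorphic under the supplied
#' frequencies) are rejected; drop or merge them before calling.
#'
#' @inheritParams length_statistic
#' @param null_freq Vector of per-site null minor-allele frequencies `f_i`
#'   (typically the population or pooled MAF), length `m`.
#' @return A single non-negative statistic value.
#' @examples
#' scaled_joint2(cohort_counts(6, 2, 1000, 1000), 0.002) # ~2.004
#' @export
scaled_joint2 <- function(counts, null_freq) {
  stopifnot(inherits(counts, "cohort_counts"))
  if (length(null_freq) != counts$m) {
    abort("`null_freq` must supply one frequency per variant site.")
  }
  mom <- diff_moments(null_freq, null_freq, counts$n_cases, counts$n_controls)
  if (any(mom$variance <= 0)) {
    abort(paste0(
      "Degenerate site(s) ", paste(which(mom$variance <= 0), collapse = ", "),
      ": null variance is zero; drop or merge these sites."
    ))
  }
  d <- counts$case_counts / (2 * counts$n_cases) -
    counts$control_counts / (2 * counts$n_controls)
  sum(d^2 / mom$variance)
}
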