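#' Per-site allele misclassification rates
#'
#' One row per variant site, holding the four per-allele error probabilities:
#' `eps01` is the chance a major allele is read as minor, `eps10` the chance a
#' minor allele is read as major, each possibly different between cases and
#' controls (differential errors). Rates are non-differential when the case
#' and control columns agree at every site.
#'
#' @param eps01_case,eps10_case Per-allele error rates in cases (recycled to
#'   `m` sites).
#' @param eps01_control,eps10_control Per-allele error rates in controls;
#'   default equal to the case rates (non-differential).
#' @param m Number of variant sites; defaults to the longest rate vector.
#' @return A tibble of class `error_rates` with columns `eps01_case`,
#'   `eps10_case`, `eps01_control`, `eps10_control`.
#' @examples
#' error_rates(0.01, 0.1, m = 8)                    # non-differential
#' error_rates(0.012, 0, 0.010, 0, m = 8)           # differential eps01
#' @export
error_rates <- function(eps01_case = 0, eps10_case = 0,
                        eps01_control = eps01_case,
                        eps10_control = eps10_case,
                        m = NULL) {
  if (is.null(m)) {
    m <- max(length(eps01_case), length(eps10_case),
             length(eps01_control), length(eps10_control))
  }
  out <- tibble::tibble(
    eps01_case = rep_len(eps01_case, m),
    eps10_case = rep_len(eps10_case, m),
    eps01_control = rep_len(eps01_control, m),
    eps10_control = rep_len(eps10_control, m)
  )
  rates <- as.matrix(out)
  if (any(rates < 0 | rates >= 1)) abort("Error rates must lie in [0, 1).")
  if (any(out$eps01_case + out$eps10_case >= 1) ||
      any(out$eps01_control + out$eps10_control >= 1)) {
    abort("eps01 + eps10 must be < 1 within each phenotype group.")
  }
  class(out) <- c("error_rates", class(out))
  out
}

is_nondifferential <- function(rates) {
  all(rates$eps01_case == rates$eps01_control) &&
    all(rates$eps10_case == rates$eps10_control)
}

#' Minor-allele frequency after misclassification
#'
#' The observed (error-perturbed) MAF when each allele is independently
#' misread: `f* = f (1 - eps10) + (1 - f) eps01`.
#'
#' @param f True per-allele minor-allele frequency (vectorised).
#' @param eps01 Probability a major allele is called minor.
#' @param eps10 Probability a minor allele is called major.
#' @return The perturbed frequency, in `[0, 1]`.
#' @examples
#' perturbed_maf(0.001, 0.01, 0.1) # 0.01089
#' @export
perturbed_maf <- function(f, eps01, eps10) {
  if (any(f < 0 | f > 1 | eps01 < 0 | eps01 > 1 | eps10 < 0 | eps10 > 1)) {
    abort("`f`, `eps01` and `eps10` must lie in [0, 1].")
  }
  f * (1 - eps10) + (1 - f) * eps01
}

#' Shrinkage of the case-control mean difference under non-differential errors
#'
#' With equal error rates in cases and controls, the expected per-site
#' difference shrinks by the factor `1 - eps10 - eps01`: misclassification
#' pulls the alternative-hypothesis mean toward the null. Both error channels
#' contribute equally to this mean shrinkage (their asymmetric impact on
#' power enters through the variance, not the mean).
#'
#' @inheritParams perturbed_maf
#' @return The multiplicative factor in `(0, 1]`.
#' @examples
#' mean_shrinkage(0.05, 0.5) # 0.45
#' @export
mean_shrinkage <- function(eps01, eps10) {
  if (any(eps01 < 0) || any(eps10 < 0) || any(eps01 + eps10 >= 1)) {
    abort("Requires eps01, eps10 >= 0 and eps01 + eps10 < 1.")
  }
  1 - eps10 - eps01
}

#' Expected number of misclassification events
#'
#' Back-of-the-envelope error burden: the expected count of allele (or
#' genotype) misreads among `carrier_count` opportunities at a given per-event
#' rate. Useful for appreciating why the major-to-minor channel dominates at
#' rare sites: almost everyone is a common homozygote, so even a 1% rate
#' yields on the order of a hundred errors per 10,000 individuals, while a
#' 10% rate on a handful of true minor alleles yields about one.
#'
#' @param carrier_count Non-negative number of individuals (or alleles)
#'   exposed to the error channel.
#' @param rate Per-event misclassification probability.
#' @return The expected event count `rate * carrier_count`.
#' @examples
#' expected_misclassifications(9990, 0.01) # 99.9
#' expected_misclassifications(10, 0.10)   # 1
#' @export
expected_misclassifications <- function(carrier_count, rate) {
  if (any(carrier_count < 0)) abort("`carrier_count` must be non-negative.")
  if (any(rate < 0 | rate > 1)) abort("`rate` must lie in [0, 1].")
  rate * carrier_count
}

#' Apply allele-level genotype errors to a cohort
#'
#' Each of an individual's two alleles is independently misread: a minor
#' allele reverts to major with its group's `eps10`, a major allele flips to
#' minor with `eps01`. Dosages therefore move by at most 2, and a
#' homozygous-major genotype becomes a heterozygote at rate
#' `2 eps01 (1 - eps01)`. Rare-homozygote errors arise only as the
#' composition of two single-allele flips; there is no separate genotype-level
#' channel.
#'
#' @param genotypes A [genotype_data()] object.
#' @param rates An [error_rates()] tibble with one row per variant site (a
#'   single row is recycled).
#' @param seed Optional integer. When supplied, draws use deterministic
#'   per-site, per-group substreams, so adding a variant site does not perturb
#'   the errors applied at earlier sites. The global RNG state is advanced.
#' @return A new [genotype_data()] object with perturbed dosages.
#' @examples
#' g <- genotype_data(matrix(0L, 4, 2), c(1, 1, 0, 0))
#' identical(apply_errors(g, error_rates(0, 0, m = 2))$dosages, g$dosages)
#' @export
apply_errors <- function(genotypes, rates, seed = NULL) {
  stopifnot(inherits(genotypes, "genotype_data"))
  if (!inherits(rates, "error_rates")) {
    abort("`rates` must be built with error_rates().")
  }
  m <- ncol(genotypes$dosages)
  if (nrow(rates) == 1L) rates <- rates[rep(1L, m), ]
  if (nrow(rates) != m) {
    abort("`rates` must have one row per variant site (or a single row).")
  }
  out <- genotypes$dosages
  case <- genotypes$phenotype == 1L
  groups <- list(case = case, control = !case)
  for (j in seq_len(m)) {
    for (g in seq_along(groups)) {
      idx <- groups[[g]]
      if (!any(idx)) next
      e01 <- if (g == 1L) rates$eps01_case[j] else rates$eps01_control[j]
      e10 <- if (g == 1L) rates$eps10_case[j] else rates$eps10_control[j]
      if (e01 == 0 && e10 == 0) next
      if (!is.null(seed)) set.seed(derive_seed(seed, "err", j, g))
      d <- out[idx, j]
      lost <- rbinom(length(d), d, e10)
      gained <- rbinom(length(d), 2L - d, e01)
      out[idx, j] <- d - lost + gained
    }
  }
  genotype_data(out, genotypes$phenotype)
}
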