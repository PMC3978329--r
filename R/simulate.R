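#' Case minor-allele frequency implied by a per-allele relative risk
#'
#' Maps the population (control) MAF `f` and a multiplicative per-allele
#' relative risk to the case-group MAF under the rare-disease approximation:
#' `f+ = f RR / (1 + f (RR - 1))`. The map is the identity at `RR = 1`,
#' strictly increasing in `RR`, keeps frequencies inside `(0, 1)`, and is
#' self-inverse for protective risks `RR = 1/r`.
#'
#' @param f Population MAF in `(0, 1)` (vectorised).
#' @param relative_risk Per-allele relative risk, `> 0`.
#' @return The case MAF.
#' @examples
#' case_maf(0.001, 3)      # ~0.0029940
#' case_maf(0.01, 1 / 1.5) # ~0.0066890
#' @export
case_maf <- function(f, relative_risk) {
  if (any(f <= 0 | f >= 1)) abort("`f` must lie in (0, 1).")
  if (any(relative_risk <= 0)) abort("`relative_risk` must be positive.")
  f * relative_risk / (1 + f * (relative_risk - 1))
}

#' Define one gene-level simulation scenario
#'
#' A `gene_setting` fixes everything needed to simulate a case-control cohort
#' at one gene: per-variant population MAF, per-allele relative risk and
#' causal status, the two sample sizes, and per-variant misclassification
#' rates.
#'
#' @param maf Vector of population (control) MAFs, one per variant site.
#' @param relative_risk Vector of per-allele relative risks (1 for
#'   non-causal sites). Defaults to all 1.
#' @param causal Character vector from
#'   `c("non_causal", "risk_increasing", "risk_reducing")`; defaults inferred
#'   from `relative_risk`.
#' @param n_cases,n_controls Sample sizes (individuals).
#' @param errors An [error_rates()] tibble (one row per site, or one row
#'   recycled). Defaults to no errors.
#' @param label Identifier used in grid manifests and result tables.
#' @return An object of class `gene_setting`.
#' @examples
#' gene_setting(maf = rep(0.01, 8), relative_risk = rep(1.5, 8),
#'              n_cases = 1000, n_controls = 1000)
#' @export
gene_setting <- function(maf, relative_risk = rep(1, length(maf)),
                         causal = NULL, n_cases = 1000, n_controls = 1000,
                         errors = error_rates(m = length(maf)),
                         label = "setting") {
  m <- length(maf)
  if (m < 1L) abort("At least one variant site is required.")
  relative_risk <- rep_len(relative_risk, m)
  if (is.null(causal)) {
    causal <- dplyr::case_when(
      relative_risk > 1 ~ "risk_increasing",
      relative_risk < 1 ~ "risk_reducing",
      TRUE ~ "non_causal"
    )
  }
  causal <- match.arg(causal,
                      c("non_causal", "risk_increasing", "risk_reducing"),
                      several.ok = TRUE)
  causal <- rep_len(causal, m)
  if (any((causal == "non_causal") != (relative_risk == 1)) ||
      any((causal == "risk_reducing") != (relative_risk < 1))) {
    abort("`causal` labels must agree with `relative_risk` (non_causal <=> RR = 1, risk_reducing <=> RR < 1).")
  }
  if (!inherits(errors, "error_rates")) abort("`errors` must come from error_rates().")
  if (nrow(errors) == 1L) errors <- errors[rep(1L, m), ]
  if (nrow(errors) != m) abort("`errors` must have one row per variant site.")
  structure(
    list(
      variants = tibble::tibble(maf = maf, relative_risk = relative_risk,
                                causal = causal),
      n_cases = n_cases, n_controls = n_controls,
      errors = errors, label = label
    ),
    class = "gene_setting"
  )
}

#' @export
print.gene_setting <- function(x, ...) {
  cat("<gene_setting> ", x$label, ": ", nrow(x$variants), " sites, ",
      x$n_cases, " cases / ", x$n_controls, " controls\n", sep = "")
  print(dplyr::bind_cols(x$variants, x$errors), n = 8)
  invisible(x)
}

#' Simulate a case-control cohort under Hardy-Weinberg equilibrium
#'
#' Control genotypes are drawn from HWE at the population MAF; case genotypes
#' from HWE at [case_maf()] of the site's relative risk. Sites are
#' independent (no linkage disequilibrium). Misclassification is then applied
#' with the group-specific rates via [apply_errors()]. Both the clean and the
#' error-contaminated data are returned so the impact of errors can be
#' measured on matched samples.
#'
#' @param setting A [gene_setting()].
#' @param seed Optional integer; per-site, per-group substreams are derived
#'   from it so scenarios are reproducible site by site.
#' @return A list of class `rv_cohort` with elements `clean` and `observed`
#'   (both [genotype_data()]), and `setting`.
#' @examples
#' sim <- simulate_cohort(gene_setting(rep(0.01, 4), n_cases = 50, n_controls = 50), seed = 1)
#' count_alleles(sim$observed)
#' @export
simulate_cohort <- function(setting, seed = NULL) {
  stopifnot(inherits(setting, "gene_setting"))
  v <- setting$variants
  m <- nrow(v)
  np <- setting$n_cases
  nm <- setting$n_controls
  f_case <- case_maf(v$maf, v$relative_risk)
  dos <- matrix(0L, np + nm, m)
  for (j in seq_len(m)) {
    if (!is.null(seed)) set.seed(derive_seed(seed, "simcase", j))
    dos[seq_len(np), j] <- rbinom(np, 2L, f_case[j])
    if (!is.null(seed)) set.seed(derive_seed(seed, "simctrl", j))
    dos[np + seq_len(nm), j] <- rbinom(nm, 2L, v$maf[j])
  }
  clean <- genotype_data(dos, c(rep(1L, np), rep(0L, nm)))
  observed <- apply_errors(clean, setting$errors,
                           seed = if (is.null(seed)) NULL else derive_seed(seed, "obs"))
  structure(list(clean = clean, observed = observed, setting = setting),
            class = "rv_cohort")
}

#' @export
print.rv_cohort <- function(x, ...) {
  cat("<rv_cohort> setting ", x$setting$label, "\n", sep = "")
  print(x$observed)
  invisible(x)
}
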