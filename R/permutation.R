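# Fast phenotype-permutation engine. Only carriers (individuals with at least
# one minor allele) can change a count under relabelling, so permuted case
# counts are obtained by assigning each carrier a uniform rank among all N
# individuals and summing dosages of carriers ranked within the case block.
# This keeps cost proportional to the number of carriers, which is small for
# rare variants.
.perm_case_counts <- function(dosages, n_cases, n_perm) {
  n <- nrow(dosages)
  m <- ncol(dosages)
  carriers <- which(rowSums(dosages) > 0L)
  k <- length(carriers)
  if (k == 0L) return(matrix(0, n_perm, m))
  gc <- dosages[carriers, , drop = FALSE]
  storage.mode(gc) <- "double"
  z <- matrix(0, n_perm, k)
  for (b in seq_len(n_perm)) {
    z[b, ] <- sample.int(n, k) <= n_cases
  }
  z %*% gc
}

.observed_counts <- function(genotypes) {
  case <- genotypes$phenotype == 1L
  list(
    cc = matrix(colSums(genotypes$dosages[case, , drop = FALSE]), nrow = 1),
    nc = matrix(colSums(genotypes$dosages[!case, , drop = FALSE]), nrow = 1),
    n_cases = sum(case), n_controls = sum(!case)
  )
}

.stat_panel <- function(cc, nc, n_cases, n_controls, family, p, absolute = FALSE) {
  if (family == "length") .length_stat(cc, nc, n_cases, n_controls, p)
  else .joint_stat(cc, nc, n_cases, n_controls, p, absolute = absolute)
}

#' Permutation p-value for one statistic
#'
#' Recomputes the chosen statistic under random phenotype relabellings that
#' preserve the case and control sample sizes, and reports the proportion of
#' permuted statistics at least as large as the observed one (default) or
#' strictly larger (`tie_rule = "strictly_greater"`). The `>=` rule is
#' conservative and cannot produce a p-value of 0 on degenerate data; the
#' strict rule mirrors the common phrasing "proportion that exceeded the
#' observed value". No small-sample smoothing is applied; add-one (B+1)
#' smoothing can be emulated by the caller if desired.
#'
#' @param genotypes A [genotype_data()] object with both phenotypes present.
#' @param family `"length"` or `"joint"`.
#' @param norm Norm order (`>= 1`, `Inf` allowed).
#' @param n_permutations Number of relabellings `B` (default 1000).
#' @param seed Optional integer seed for the permutation stream.
#' @param tie_rule `"greater_or_equal"` (default) or `"strictly_greater"`.
#' @param absolute Passed to the joint statistic for `norm = Inf`.
#' @return A single p-value in `[0, 1]`.
#' @examples
#' g <- genotype_data(matrix(c(1, 0, 0, 0, 0, 0), ncol = 1), c(1, 1, 1, 0, 0, 0))
#' permutation_pvalue(g, "length", 1, n_permutations = 200, seed = 1)
#' @export
permutation_pvalue <- function(genotypes, family = c("length", "joint"),
                               norm = 1, n_permutations = 1000, seed = NULL,
                               tie_rule = c("greater_or_equal", "strictly_greater"),
                               absolute = FALSE) {
  family <- match.arg(family)
  res <- rv_permutation_test(
    genotypes,
    statistics = tibble::tibble(family = family, norm = norm),
    n_permutations = n_permutations, seed = seed,
    tie_rule = match.arg(tie_rule), absolute = absolute
  )
  res$p_value[1]
}

#' Permutation test over a panel of statistics
#'
#' Shares one set of phenotype relabellings across all requested statistics,
#' so a full panel costs little more than a single test.
#'
#' @inheritParams permutation_pvalue
#' @param statistics A tibble with columns `family` and `norm`; defaults to
#'   the length and joint families at norms 1, 2, 4, 8 and Inf.
#' @return A tibble with columns `family`, `norm`, `value` (observed
#'   statistic) and `p_value`.
#' @examples
#' g <- genotype_data(matrix(rbinom(200, 2, 0.05), 100, 2), rep(c(1, 0), each = 50))
#' rv_permutation_test(g, n_permutations = 99, seed = 1)
#' @export
rv_permutation_test <- function(genotypes,
                                statistics = tidyr::expand_grid(
                                  family = c("length", "joint"),
                                  norm = c(1, 2, 4, 8, Inf)
                                ),
                                n_permutations = 1000, seed = NULL,
                                tie_rule = c("greater_or_equal", "strictly_greater"),
                                absolute = FALSE) {
  stopifnot(inherits(genotypes, "genotype_data"))
  tie_rule <- match.arg(tie_rule)
  if (n_permutations < 1) abort("`n_permutations` must be at least 1.")
  case <- genotypes$phenotype == 1L
  if (!any(case) || all(case)) {
    abort("Permutation requires at least one case and one control.")
  }
  obs <- .observed_counts(genotypes)
  total <- obs$cc + obs$nc
  if (!is.null(seed)) set.seed(derive_seed(seed, "perm"))
  perm_cc <- .perm_case_counts(genotypes$dosages, obs$n_cases, n_permutations)
  perm_nc <- sweep(perm_cc, 2, total, FUN = function(a, b) b - a)
  statistics |>
    dplyr::mutate(
      value = purrr::map2_dbl(.data$family, .data$norm, function(fam, p) {
        .stat_panel(obs$cc, obs$nc, obs$n_cases, obs$n_controls, fam, p, absolute)
      }),
      p_value = purrr::pmap_dbl(
        list(.data$family, .data$norm, .data$value),
        function(fam, p, v) {
          perm <- .stat_panel(perm_cc, perm_nc, obs$n_cases, obs$n_controls,
                              fam, p, absolute)
          if (tie_rule == "greater_or_equal") mean(perm >= v) else mean(perm > v)
        }
      )
    )
}

#' Empirical power or type-I error for a simulation scenario
#'
#' Simulates `n_reps` cohorts from the scenario (errors applied), computes a
#' permutation p-value per replicate for each requested statistic, and
#' returns the proportion of replicates with `p < alpha`. When the scenario
#' contains causal variants this is empirical power; otherwise it is the
#' empirical type-I error rate. The binomial Monte-Carlo standard error
#' `sqrt(rate (1 - rate) / n_reps)` is attached.
#'
#' @param setting A [gene_setting()].
#' @param statistics Tibble of `family` / `norm` pairs (default the
#'   length/joint panel at norms 1, 2, 4, 8, Inf).
#' @param n_reps Number of simulated cohorts.
#' @param n_permutations Permutations per cohort.
#' @param alpha Nominal significance level (default 0.05).
#' @param seed Optional root seed; each replicate draws from a substream
#'   derived from `(seed, setting label, replicate index)`.
#' @param tie_rule,absolute Passed to [rv_permutation_test()].
#' @return A tibble with one row per statistic: `family`, `norm`, `rate`,
#'   `mc_se`, `n_reps`, `n_permutations`, `alpha`.
#' @examples
#' s <- gene_setting(rep(0.01, 4), n_cases = 100, n_controls = 100)
#' empirical_rate(s, n_reps = 20, n_permutations = 50, seed = 1)
#' @export
empirical_rate <- function(setting,
                           statistics = tidyr::expand_grid(
                             family = c("length", "joint"),
                             norm = c(1, 2, 4, 8, Inf)
                           ),
                           n_reps = 1000, n_permutations = 1000,
                           alpha = 0.05, seed = NULL,
                           tie_rule = c("greater_or_equal", "strictly_greater"),
                           absolute = FALSE) {
  stopifnot(inherits(setting, "gene_setting"))
  tie_rule <- match.arg(tie_rule)
  if (n_reps < 1) abort("`n_reps` must be at least 1.")
  if (alpha <= 0 || alpha > 1) abort("`alpha` must lie in (0, 1].")
  hits <- matrix(0, n_reps, nrow(statistics))
  for (r in seq_len(n_reps)) {
    rep_seed <- if (is.null(seed)) NULL else derive_seed(seed, setting$label, r)
    sim <- simulate_cohort(setting, seed = rep_seed)
    res <- rv_permutation_test(
      sim$observed, statistics = statistics,
      n_permutations = n_permutations,
      seed = if (is.null(rep_seed)) NULL else derive_seed(rep_seed, "p"),
      tie_rule = tie_rule, absolute = absolute
    )
    hits[r, ] <- res$p_value < alpha
  }
  rate <- colMeans(hits)
  statistics |>
    dplyr::mutate(
      rate = rate,
      mc_se = sqrt(rate * (1 - rate) / n_reps),
      n_reps = n_reps, n_permutations = n_permutations, alpha = alpha
    )
}
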