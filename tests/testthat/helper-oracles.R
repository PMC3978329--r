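# Brute-force implementations used as independent oracles: computed straight
# from the printed statistic definitions, sharing no code with the package's
# vectorised kernels.

naive_stat <- function(case_counts, control_counts, n_cases, n_controls,
                       family, p) {
  fp <- case_counts / (2 * n_cases)
  fm <- control_counts / (2 * n_controls)
  if (family == "length") {
    if (is.infinite(p)) max(fp) - max(fm)
    else sum(fp^p)^(1 / p) - sum(fm^p)^(1 / p)
  } else {
    d <- fp - fm
    if (is.infinite(p)) max(d) else sum(abs(d)^p)^(1 / p)
  }
}

# exact permutation p-value by full enumeration of case assignments
exact_perm_p <- function(dosages, phenotype, family, p,
                         strictly = FALSE) {
  dosages <- as.matrix(dosages)
  n <- nrow(dosages)
  n_cases <- sum(phenotype == 1)
  tot <- colSums(dosages)
  obs_cc <- colSums(dosages[phenotype == 1, , drop = FALSE])
  obs <- naive_stat(obs_cc, tot - obs_cc, n_cases, n - n_cases, family, p)
  sets <- utils::combn(n, n_cases)
  vals <- apply(sets, 2, function(idx) {
    cc <- colSums(dosages[idx, , drop = FALSE])
    naive_stat(cc, tot - cc, n_cases, n - n_cases, family, p)
  })
  if (strictly) mean(vals > obs) else mean(vals >= obs)
}

# random small genotype dataset for property loops
random_genotypes <- function(n, m, f = 0.2) {
  genotype_data(
    matrix(rbinom(n * m, 2, f), n, m),
    sample(rep(c(1L, 0L), length.out = n))
  )
}
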