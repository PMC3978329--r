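#' Case-control minor-allele counts
#'
#' `cohort_counts()` bundles the sufficient statistic for every test in the
#' package: per-site minor-allele counts in cases and controls together with
#' the two sample sizes. Counts are allele counts, so each is bounded by twice
#' the corresponding number of individuals.
#'
#' @param case_counts Integer vector of minor-allele counts in cases, one per
#'   variant site.
#' @param control_counts Integer vector of minor-allele counts in controls,
#'   same length as `case_counts`.
#' @param n_cases,n_controls Numbers of case and control individuals.
#'
#' @return An object of class `cohort_counts`: a list with elements `m`,
#'   `n_cases`, `n_controls`, `case_counts`, `control_counts`.
#' @examples
#' cohort_counts(c(4, 2), c(1, 1), n_cases = 100, n_controls = 100)
#' @export
cohort_counts <- function(case_counts, control_counts, n_cases, n_controls) {
  if (length(case_counts) != length(control_counts)) {
    abort("`case_counts` and `control_counts` must have the same length.")
  }
  if (length(case_counts) < 1L) abort("At least one variant site is required.")
  if (!is.numeric(n_cases) || !is.numeric(n_controls) ||
      n_cases < 1 || n_controls < 1) {
    abort("`n_cases` and `n_controls` must be positive.")
  }
  bad <- case_counts < 0 | case_counts > 2 * n_cases |
    control_counts < 0 | control_counts > 2 * n_controls
  if (any(bad)) {
    abort(paste0(
      "Allele counts out of range at site(s) ",
      paste(which(bad), collapse = ", "),
      ": each count must lie in [0, 2N] for its group."
    ))
  }
  structure(
    list(
      m = length(case_counts),
      n_cases = n_cases,
      n_controls = n_controls,
      case_counts = as.numeric(case_counts),
      control_counts = as.numeric(control_counts)
    ),
    class = "cohort_counts"
  )
}

#' @export
print.cohort_counts <- function(x, ...) {
  cat(
    "<cohort_counts> ", x$m, " sites, ", x$n_cases, " cases / ",
    x$n_controls, " controls\n",
    sep = ""
  )
  cat("  case counts:    ", paste(head(x$case_counts, 10), collapse = " "),
      if (x$m > 10) "...", "\n")
  cat("  control counts: ", paste(head(x$control_counts, 10), collapse = " "),
      if (x$m > 10) "...", "\n")
  invisible(x)
}

#' @export
as_tibble.cohort_counts <- function(x, ...) {
  tibble::tibble(
    site = seq_len(x$m),
    case_count = x$case_counts,
    control_count = x$control_counts,
    case_freq = x$case_counts / (2 * x$n_cases),
    control_freq = x$control_counts / (2 * x$n_controls)
  )
}

#' Genotype dosage data with phenotype labels
#'
#' A thin container for an individuals-by-variants matrix of minor-allele
#' dosages (0, 1 or 2 copies) plus a case/control label per individual.
#'
#' @param dosages Integer matrix, individuals in rows, variant sites in
#'   columns; entries must be 0, 1 or 2.
#' @param phenotype Vector of 0/1 labels (1 = case), one per row of `dosages`.
#'
#' @return An object of class `genotype_data` with elements `dosages` and
#'   `phenotype`.
#' @examples
#' g <- genotype_data(matrix(c(1, 0, 0, 0, 2, 0), nrow = 3), c(1, 1, 0))
#' count_alleles(g)
#' @export
genotype_data <- function(dosages, phenotype) {
  dosages <- as.matrix(dosages)
  if (anyNA(dosages) || !all(dosages %in% c(0, 1, 2))) {
    abort("`dosages` must contain only 0, 1 or 2 (no missing genotypes).")
  }
  if (anyNA(phenotype)) abort("Every individual needs a phenotype label.")
  phenotype <- as.integer(phenotype)
  if (!all(phenotype %in% c(0L, 1L))) {
    abort("`phenotype` must be coded 0 (control) / 1 (case).")
  }
  if (length(phenotype) != nrow(dosages)) {
    abort("`phenotype` must have one label per row of `dosages`.")
  }
  storage.mode(dosages) <- "integer"
  structure(list(dosages = dosages, phenotype = phenotype),
            class = "genotype_data")
}

#' @export
print.genotype_data <- function(x, ...) {
  cat(
    "<genotype_data> ", nrow(x$dosages), " individuals (",
    sum(x$phenotype == 1L), " cases) x ", ncol(x$dosages), " sites\n",
    sep = ""
  )
  invisible(x)
}

#' @export
as_tibble.genotype_data <- function(x, ...) {
  d <- tibble::as_tibble(x$dosages, .name_repair = ~ paste0("site_", seq_along(.x)))
  dplyr::bind_cols(
    tibble::tibble(sample = seq_len(nrow(x$dosages)), phenotype = x$phenotype),
    d
  )
}

#' Tally minor-allele counts from genotype data
#'
#' Sums dosages within cases and controls at every site, producing the
#' [cohort_counts()] object all test statistics consume.
#'
#' @param genotypes A [genotype_data()] object.
#' @return A [cohort_counts()] object.
#' @export
count_alleles <- function(genotypes) {
  stopifnot(inherits(genotypes, "genotype_data"))
  case <- genotypes$phenotype == 1L
  if (!any(case) || all(case)) {
    abort("Both cases and controls are required to form cohort counts.")
  }
  cohort_counts(
    case_counts = colSums(genotypes$dosages[case, , drop = FALSE]),
    control_counts = colSums(genotypes$dosages[!case, , drop = FALSE]),
    n_cases = sum(case),
    n_controls = sum(!case)
  )
}

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble
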