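#' Run a simulation grid
#'
#' Evaluates [empirical_rate()] for every setting of a grid and every
#' requested statistic, returning (and optionally streaming to TSV) one row
#' per setting-statistic pair together with the setting covariates used by
#' [summarize_grid()]. Each setting draws from a seed substream derived from
#' `(seed, label)`, so results are reproducible regardless of execution
#' order, and a partially written `out_file` is resumed by skipping labels
#' already present.
#'
#' @param grid A `setting_grid` tibble (see [nondifferential_grid()]).
#' @param statistics Tibble of `family` / `norm` pairs.
#' @param n_reps Simulated cohorts per setting.
#' @param n_permutations Permutations per cohort.
#' @param alpha Nominal level.
#' @param seed Root seed (integer).
#' @param out_file Optional TSV path; rows are appended as settings finish.
#' @param verbose Print per-setting progress.
#' @return A tibble: setting covariates (`label`, `kind`, `m`, `avg_maf`,
#'   `pct_increasing`, `pct_reducing`, `eps01`, `eps10`, `ratio`) plus
#'   `family`, `norm`, `rate`, `mc_se`, `n_reps`, `n_permutations`, `alpha`,
#'   `seed`.
#' @examples
#' g <- nondifferential_grid(n_cases = 50, n_controls = 50)[1:2, ]
#' run_grid(g, n_reps = 5, n_permutations = 20, seed = 1)
#' @export
run_grid <- function(grid,
                     statistics = tidyr::expand_grid(
                       family = c("length", "joint"),
                       norm = c(1, 2, 4, 8, Inf)
                     ),
                     n_reps = 1000, n_permutations = 1000, alpha = 0.05,
                     seed = 1, out_file = NULL, verbose = FALSE) {
  stopifnot(inherits(grid, "setting_grid") || is.data.frame(grid))
  done <- character(0)
  existing <- NULL
  if (!is.null(out_file) && file.exists(out_file)) {
    existing <- readr::read_tsv(out_file, show_col_types = FALSE)
    done <- unique(existing$label)
  }
  covar_cols <- c("label", "kind", "m", "n_cases", "n_controls",
                  "maf_setting", "error_setting", "causal_mix",
                  "avg_maf", "pct_increasing", "pct_reducing",
                  "eps01", "eps10", "ratio")
  rows <- list()
  for (i in seq_len(nrow(grid))) {
    lab <- grid$label[i]
    if (lab %in% done) next
    setting <- as_gene_setting(grid, i)
    res <- empirical_rate(
      setting, statistics = statistics, n_reps = n_reps,
      n_permutations = n_permutations, alpha = alpha,
      seed = derive_seed(seed, lab)
    )
    out <- dplyr::bind_cols(
      grid[rep(i, nrow(res)), covar_cols],
      res, tibble::tibble(seed = seed)
    )
    if (!is.null(out_file)) {
      readr::write_tsv(out, out_file, append = file.exists(out_file))
    }
    if (verbose) {
      message(sprintf("[%d/%d] %s done", i, nrow(grid), lab))
    }
    rows[[length(rows) + 1L]] <- out
  }
  dplyr::bind_rows(c(list(existing), rows))
}

# Covariate coding used by the meta-regressions (footnote units of the
# summary tables): error magnitude on a 0/1/5 ordinal scale (eps01 per 1%,
# eps10 per 10%; the paired settings 0.01/0.1 and 0.05/0.5 share one code),
# average MAF per 0.1%, causal percentages per 10 points, and the
# case:control rate ratio as relative difference per 10%.
.code_covariates <- function(results) {
  results |>
    dplyr::mutate(
      error_type = dplyr::case_when(
        .data$eps01 > 0 & .data$eps10 > 0 ~ "both",
        .data$eps01 > 0 ~ "eps01_only",
        .data$eps10 > 0 ~ "eps10_only",
        TRUE ~ "none"
      ),
      err_mag = pmax(100 * .data$eps01, 10 * .data$eps10),
      maf_unit = 1000 * .data$avg_maf,
      inc_unit = .data$pct_increasing / 10,
      red_unit = .data$pct_reducing / 10,
      ratio_unit = 10 * (.data$ratio - 1)
    )
}

#' Meta-regression of grid results on design factors
#'
#' Regresses empirical power (or type-I error) from [run_grid()] on the
#' design covariates, with one ordinary-least-squares fit per statistic and
#' error channel (`eps01` only, `eps10` only, both; no-error settings anchor
#' every channel at magnitude 0). Power models use error magnitude
#' (0/1/5 coding), average MAF (per 0.1%), and the percentages of
#' risk-increasing and risk-reducing variants (per 10 points); type-I models
#' replace the causal terms with the case:control error-rate ratio (relative
#' difference per 10%).
#'
#' @param results Tibble from [run_grid()].
#' @param response `"power"` (causal settings) or `"type1"` (null settings).
#' @return An object of class `rv_grid_summary`; use [tidy()] for the
#'   coefficient table and [glance()] for per-model fit statistics.
#' @examples
#' \dontrun{
#' res <- run_grid(nondifferential_grid(), n_reps = 1000, n_permutations = 1000)
#' tidy(summarize_grid(res, "power"))
#' }
#' @export
summarize_grid <- function(results, response = c("power", "type1")) {
  response <- match.arg(response)
  coded <- .code_covariates(results)
  if (response == "power") {
    coded <- dplyr::filter(coded, .data$pct_increasing + .data$pct_reducing > 0)
    form <- rate ~ err_mag + maf_unit + inc_unit + red_unit
  } else {
    coded <- dplyr::filter(coded, .data$pct_increasing + .data$pct_reducing == 0)
    if (all(is.na(coded$ratio_unit))) {
      form <- rate ~ err_mag + maf_unit
    } else {
      form <- rate ~ err_mag + maf_unit + ratio_unit
    }
  }
  if (nrow(coded) == 0) abort("No settings match the requested response kind.")
  groups <- coded |>
    dplyr::filter(.data$error_type != "none") |>
    dplyr::distinct(.data$family, .data$norm, .data$error_type)
  if (nrow(groups) == 0) {
    # degenerate input (e.g. only error-free settings): single pooled model
    groups <- dplyr::distinct(coded, .data$family, .data$norm) |>
      dplyr::mutate(error_type = "none")
  }
  models <- purrr::pmap(groups, function(family, norm, error_type) {
    dat <- coded[coded$family == family & coded$norm == norm &
                   (coded$error_type %in% c(error_type, "none")), ]
    fit <- lm(form, data = dat)
    if (anyNA(coef(fit))) {
      abort("Rank-deficient meta-regression design; supply a richer grid.")
    }
    fit
  })
  names(models) <- paste(groups$family, groups$norm, groups$error_type, sep = ".")
  structure(
    list(models = models, groups = groups, response = response, formula = form),
    class = "rv_grid_summary"
  )
}

#' @export
print.rv_grid_summary <- function(x, ...) {
  cat("<rv_grid_summary> response: ", x$response, ", ",
      length(x$models), " model(s)\n", sep = "")
  print(tidy(x), n = 20)
  invisible(x)
}

#' @rdname summarize_grid
#' @param x An `rv_grid_summary` object.
#' @param ... Unused.
#' @export
tidy.rv_grid_summary <- function(x, ...) {
  purrr::map2(x$models, seq_along(x$models), function(fit, i) {
    s <- summary(fit)$coefficients
    dplyr::bind_cols(
      x$groups[rep(i, nrow(s)), ],
      tibble::tibble(
        term = rownames(s), estimate = s[, 1], std.error = s[, 2],
        statistic = s[, 3], p.value = s[, 4]
      )
    )
  }) |>
    dplyr::bind_rows()
}

#' @rdname summarize_grid
#' @export
glance.rv_grid_summary <- function(x, ...) {
  purrr::map2(x$models, seq_along(x$models), function(fit, i) {
    s <- summary(fit)
    dplyr::bind_cols(
      x$groups[i, ],
      tibble::tibble(
        r.squared = s$r.squared, sigma = s$sigma,
        nobs = length(s$residuals), df.residual = fit$df.residual
      )
    )
  }) |>
    dplyr::bind_rows()
}
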