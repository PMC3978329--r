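# Study-condition enumerations. Fixed conventions (documented in the methods
# vignette): sites are listed in decreasing-MAF order; causal statuses are
# assigned from the largest-MAF site down, risk-increasing before
# risk-reducing before non-causal; the per-site relative risk follows the
# site's own MAF (1% -> 1.5, 0.1% -> 3, 0.01% -> 5; protective sites take the
# reciprocal).

.maf_settings <- function(m = 8) {
  half <- m / 4        # mixed settings: a quarter of sites at 1%
  rest <- m - half
  list(
    all_1pct    = rep(0.01, m),
    all_0.1pct  = rep(0.001, m),
    all_0.01pct = rep(0.0001, m),
    mix_1_0.1   = c(rep(0.01, half), rep(0.001, rest)),
    mix_1_0.01  = c(rep(0.01, half), rep(0.0001, rest))
  )
}

.error_settings <- function() {
  tibble::tibble(
    err_label = paste0("err", 1:7),
    eps01 = c(0, 0, 0, 0.01, 0.05, 0.01, 0.05),
    eps10 = c(0, 0.1, 0.5, 0, 0, 0.1, 0.5)
  )
}

.rr_for_maf <- function(f) {
  rr <- rep(NA_real_, length(f))
  rr[abs(f - 0.01) < 1e-12] <- 1.5
  rr[abs(f - 0.001) < 1e-12] <- 3
  rr[abs(f - 0.0001) < 1e-12] <- 5
  if (anyNA(rr)) abort("No relative-risk convention for this MAF value.")
  rr
}

# status vector for one causal mix over m sites (sites already ordered by
# decreasing MAF)
.mix_status <- function(mix, m) {
  h <- m / 2
  q <- m / 4
  switch(mix,
    all_non_causal = rep("non_causal", m),
    all_increasing = rep("risk_increasing", m),
    all_reducing = rep("risk_reducing", m),
    half_reducing_half_increasing =
      c(rep("risk_increasing", h), rep("risk_reducing", h)),
    half_non_causal_half_increasing =
      c(rep("risk_increasing", h), rep("non_causal", h)),
    half_non_causal_quarter_each =
      c(rep("risk_increasing", q), rep("risk_reducing", q), rep("non_causal", h)),
    abort(paste0("Unknown causal mix: ", mix))
  )
}

.causal_mixes <- function() {
  c("all_non_causal", "all_increasing", "all_reducing",
    "half_reducing_half_increasing", "half_non_causal_half_increasing",
    "half_non_causal_quarter_each")
}

.rr_vector <- function(maf, status) {
  base <- .rr_for_maf(maf)
  dplyr::case_when(
    status == "risk_increasing" ~ base,
    status == "risk_reducing" ~ 1 / base,
    TRUE ~ 1
  )
}

.grid_row <- function(label, kind, maf, rr, status, err, ratio,
                      n_cases, n_controls) {
  tibble::tibble(
    label = label, kind = kind, m = length(maf),
    n_cases = n_cases, n_controls = n_controls,
    maf_setting = NA_character_, error_setting = NA_character_,
    causal_mix = NA_character_,
    avg_maf = mean(maf),
    pct_increasing = 100 * mean(status == "risk_increasing"),
    pct_reducing = 100 * mean(status == "risk_reducing"),
    eps01 = err$eps01, eps10 = err$eps10, ratio = ratio,
    maf = list(maf), relative_risk = list(rr), causal = list(status),
    eps01_case = list(rep(err$eps01 * ifelse(is.na(ratio), 1, ratio), length(maf))),
    eps10_case = list(rep(err$eps10 * ifelse(is.na(ratio), 1, ratio), length(maf))),
    eps01_control = list(rep(err$eps01, length(maf))),
    eps10_control = list(rep(err$eps10, length(maf)))
  )
}

#' Simulation grid: non-differential errors
#'
#' Enumerates the 210 non-differential scenarios: six causal mixes (all
#' non-causal; all risk-increasing; all risk-reducing; half reducing + half
#' increasing; half non-causal + half increasing; half non-causal + a quarter
#' each increasing/reducing) crossed with five MAF configurations (all 1%,
#' all 0.1%, all 0.01%, 2 sites at 1% + 6 at 0.1%, 2 at 1% + 6 at 0.01%) and
#' seven `(eps01, eps10)` error settings `(0,0), (0,0.1), (0,0.5), (0.01,0),
#' (0.05,0), (0.01,0.1), (0.05,0.5)`. Eight variant sites, 1000 cases and
#' 1000 controls throughout; 35 of the settings carry no causal variant.
#'
#' @param n_cases,n_controls Sample sizes (defaults 1000/1000).
#' @param m Number of variant sites (default 8; must be divisible by 4).
#' @return A tibble of class `setting_grid`, one row per scenario, with
#'   per-site values in list-columns and scalar covariates (`avg_maf`,
#'   `pct_increasing`, `pct_reducing`, `eps01`, `eps10`) for summaries.
#' @examples
#' nrow(nondifferential_grid()) # 210
#' @seealso [differential_grid()], [followup_grid()], [as_gene_setting()]
#' @export
nondifferential_grid <- function(n_cases = 1000, n_controls = 1000, m = 8) {
  if (m %% 4 != 0) abort("`m` must be divisible by 4.")
  mafs <- .maf_settings(m)
  errs <- .error_settings()
  rows <- list()
  for (mix in .causal_mixes()) {
    status <- .mix_status(mix, m)
    for (ms in names(mafs)) {
      maf <- mafs[[ms]]
      rr <- .rr_vector(maf, status)
      for (e in seq_len(nrow(errs))) {
        row <- .grid_row(
          label = paste("nd", mix, ms, errs$err_label[e], sep = "-"),
          kind = "non_differential", maf = maf, rr = rr, status = status,
          err = errs[e, ], ratio = NA_real_,
          n_cases = n_cases, n_controls = n_controls
        )
        row$maf_setting <- ms
        row$error_setting <- errs$err_label[e]
        row$causal_mix <- mix
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("setting_grid", class(out))
  out
}

#' Simulation grid: differential errors
#'
#' Enumerates the 140 differential scenarios: five MAF configurations times
#' seven error settings times four case:control error-rate ratios (1.2, 1.5,
#' 1/1.2, 1/1.5). All sites are non-causal (relative risk 1); case rates are
#' the control rates multiplied by the ratio on both error channels, so any
#' departure of the empirical rejection rate from the nominal level is
#' type-I inflation caused by the differential errors alone.
#'
#' @inheritParams nondifferential_grid
#' @return A `setting_grid` tibble (140 rows), with column `ratio`.
#' @examples
#' nrow(differential_grid()) # 140
#' @export
differential_grid <- function(n_cases = 1000, n_controls = 1000, m = 8) {
  if (m %% 4 != 0) abort("`m` must be divisible by 4.")
  mafs <- .maf_settings(m)
  errs <- .error_settings()
  ratios <- c(1.2, 1.5, 1 / 1.2, 1 / 1.5)
  ratio_labels <- c("r1.2", "r1.5", "r1over1.2", "r1over1.5")
  status <- rep("non_causal", m)
  rows <- list()
  for (ms in names(mafs)) {
    maf <- mafs[[ms]]
    for (e in seq_len(nrow(errs))) {
      for (r in seq_along(ratios)) {
        row <- .grid_row(
          label = paste("diff", ms, errs$err_label[e], ratio_labels[r], sep = "-"),
          kind = "differential", maf = maf, rr = rep(1, m), status = status,
          err = errs[e, ], ratio = ratios[r],
          n_cases = n_cases, n_controls = n_controls
        )
        row$maf_setting <- ms
        row$error_setting <- errs$err_label[e]
        row$causal_mix <- "all_non_causal"
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("setting_grid", class(out))
  out
}

#' Simulation grid: single-causal-variant follow-up
#'
#' Enumerates the 70 follow-up scenarios used to probe norm choice: the same
#' 35 MAF-by-error combinations, each at 8 and at 16 variant sites, with
#' exactly one causal (risk-increasing) variant occupying a largest-MAF slot.
#' Errors are non-differential.
#'
#' @inheritParams nondifferential_grid
#' @return A `setting_grid` tibble (70 rows) with `m` values 8 and 16.
#' @examples
#' nrow(followup_grid()) # 70
#' @export
followup_grid <- function(n_cases = 1000, n_controls = 1000) {
  errs <- .error_settings()
  rows <- list()
  for (m in c(8L, 16L)) {
    mafs <- .maf_settings(m)
    for (ms in names(mafs)) {
      maf <- mafs[[ms]]
      status <- c("risk_increasing", rep("non_causal", m - 1L))
      rr <- .rr_vector(maf, status)
      for (e in seq_len(nrow(errs))) {
        row <- .grid_row(
          label = paste("fu", paste0("m", m), ms, errs$err_label[e], sep = "-"),
          kind = "followup", maf = maf, rr = rr, status = status,
          err = errs[e, ], ratio = NA_real_,
          n_cases = n_cases, n_controls = n_controls
        )
        row$maf_setting <- ms
        row$error_setting <- errs$err_label[e]
        row$causal_mix <- "one_increasing"
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("setting_grid", class(out))
  out
}

#' Materialise one grid row as a gene_setting
#'
#' @param grid A `setting_grid` tibble.
#' @param i Row index, or a setting label.
#' @return A [gene_setting()].
#' @examples
#' as_gene_setting(nondifferential_grid(), 1)
#' @export
as_gene_setting <- function(grid, i = 1) {
  if (is.character(i)) {
    i <- match(i, grid$label)
    if (is.na(i)) abort("Setting label not found in grid.")
  }
  row <- grid[i, ]
  gene_setting(
    maf = row$maf[[1]],
    relative_risk = row$relative_risk[[1]],
    causal = row$causal[[1]],
    n_cases = row$n_cases, n_controls = row$n_controls,
    errors = error_rates(
      eps01_case = row$eps01_case[[1]], eps10_case = row$eps10_case[[1]],
      eps01_control = row$eps01_control[[1]], eps10_control = row$eps10_control[[1]]
    ),
    label = row$label
  )
}

#' Write a grid manifest as TSV
#'
#' One row per setting with per-site vectors comma-joined, suitable for
#' archiving the exact study conditions next to result tables.
#'
#' @param grid A `setting_grid` tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_grid_manifest <- function(grid, path) {
  flat <- grid |>
    dplyr::mutate(dplyr::across(
      c("maf", "relative_risk", "causal",
        "eps01_case", "eps10_case", "eps01_control", "eps10_control"),
      ~ purrr::map_chr(.x, paste, collapse = ",")
    ))
  readr::write_tsv(flat, path)
  invisible(path)
}
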