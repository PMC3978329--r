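small_grid <- function() {
  g <- nondifferential_grid(n_cases = 40, n_controls = 40)
  g[g$label %in% c("nd-all_increasing-all_1pct-err1",
                   "nd-all_non_causal-all_1pct-err4"), ]
}

test_that("run_grid emits one well-formed row per setting-statistic pair", {
  stats <- tibble::tibble(family = c("length", "joint"), norm = c(1, 2))
  res <- run_grid(small_grid(), statistics = stats, n_reps = 4,
                  n_permutations = 10, seed = 11)
  expect_equal(nrow(res), 2 * 2)
  expect_true(all(res$rate >= 0 & res$rate <= 1))
  expect_true(all(c("label", "avg_maf", "pct_increasing", "eps01", "family",
                    "norm", "rate", "mc_se", "seed") %in% names(res)))
})

test_that("run_grid is deterministic in the root seed and resumable", {
  stats <- tibble::tibble(family = "length", norm = 1)
  g <- small_grid()
  a <- run_grid(g, statistics = stats, n_reps = 5, n_permutations = 20, seed = 7)
  b <- run_grid(g, statistics = stats, n_reps = 5, n_permutations = 20, seed = 7)
  expect_identical(a$rate, b$rate)

  out <- withr::local_tempfile(fileext = ".tsv")
  run_grid(g[1, ], statistics = stats, n_reps = 5, n_permutations = 20,
           seed = 7, out_file = out)
  res <- run_grid(g, statistics = stats, n_reps = 5, n_permutations = 20,
                  seed = 7, out_file = out)
  expect_equal(sort(unique(res$label)), sort(g$label))
  expect_equal(res$rate[match(g$label, res$label)], a$rate[match(g$label, a$label)])
  # settings already on disk are not recomputed
  expect_equal(nrow(readr::read_tsv(out, show_col_types = FALSE)), 2)
})

# minimal synthetic results table with the covariates summarize_grid needs
fake_results <- function(rates, eps01, eps10, avg_maf, pct_inc, pct_red,
                         ratio = NA_real_) {
  tibble::tibble(
    label = paste0("s", seq_along(rates)), kind = "synthetic", m = 8,
    n_cases = 1000, n_controls = 1000, maf_setting = NA, error_setting = NA,
    causal_mix = NA, avg_maf = avg_maf, pct_increasing = pct_inc,
    pct_reducing = pct_red, eps01 = eps01, eps10 = eps10, ratio = ratio,
    family = "joint", norm = 2, rate = rates, mc_se = 0,
    n_reps = 1000, n_permutations = 1000, alpha = 0.05, seed = 1
  )
}

test_that("summarize_grid recovers a planted linear relation exactly", {
  eps01 <- c(0, 0.01, 0.05, 0, 0.01, 0.05, 0, 0.01, 0.05, 0.05)
  maf <- c(0.001, 0.001, 0.001, 0.005, 0.005, 0.005, 0.01, 0.01, 0.01, 0.005)
  inc <- c(50, 50, 100, 100, 50, 50, 100, 50, 100, 100)
  red <- c(0, 50, 0, 0, 50, 0, 0, 50, 0, 50)
  rate <- 0.3 - 0.04 * (100 * eps01) + 0.02 * (1000 * maf) +
    0.05 * (inc / 10) - 0.01 * (red / 10)
  res <- fake_results(rate, eps01, eps10 = 0, avg_maf = maf,
                      pct_inc = inc, pct_red = red)
  fit <- suppressWarnings(summarize_grid(res, "power"))
  co <- suppressWarnings(tidy(fit))
  expect_equal(co$error_type, rep("eps01_only", 5))
  est <- setNames(co$estimate, co$term)
  expect_equal(est[["(Intercept)"]], 0.3, tolerance = 1e-10)
  expect_equal(est[["err_mag"]], -0.04, tolerance = 1e-10)
  expect_equal(est[["maf_unit"]], 0.02, tolerance = 1e-10)
  expect_equal(est[["inc_unit"]], 0.05, tolerance = 1e-10)
  expect_equal(est[["red_unit"]], -0.01, tolerance = 1e-10)
  expect_equal(suppressWarnings(glance(fit))$r.squared, 1, tolerance = 1e-10)
})

factorial_design <- function() {
  tidyr::expand_grid(eps01 = c(0, 0.01), avg_maf = c(0.001, 0.01),
                     pct_inc = c(50, 100), pct_red = c(0, 50))
}

test_that("a constant response yields zero slopes", {
  d <- factorial_design()
  res <- fake_results(rep(0.4, nrow(d)), eps01 = d$eps01, eps10 = 0,
                      avg_maf = d$avg_maf, pct_inc = d$pct_inc,
                      pct_red = d$pct_red)
  co <- suppressWarnings(tidy(summarize_grid(res, "power")))
  slopes <- co$estimate[co$term != "(Intercept)"]
  expect_true(all(abs(slopes) < 1e-12 | is.nan(slopes)))
})

test_that("type-1 summaries use the ratio covariate and reject deficient designs", {
  d <- tidyr::expand_grid(eps01 = c(0.01, 0.05),
                          ratio = c(1.2, 1.5, 1 / 1.2, 1 / 1.5),
                          avg_maf = c(0.001, 0.01))
  ratio <- d$ratio
  eps01 <- d$eps01
  rate <- 0.05 + 0.1 * (10 * (ratio - 1)) + 0.06 * (100 * eps01) +
    0.004 * (1000 * d$avg_maf)
  res <- fake_results(rate, eps01, eps10 = 0, avg_maf = d$avg_maf,
                      pct_inc = 0, pct_red = 0, ratio = ratio)
  co <- suppressWarnings(tidy(summarize_grid(res, "type1")))
  est <- setNames(co$estimate, co$term)
  expect_equal(est[["ratio_unit"]], 0.1, tolerance = 1e-10)
  expect_equal(est[["err_mag"]], 0.06, tolerance = 1e-10)
  expect_equal(est[["maf_unit"]], 0.004, tolerance = 1e-10)

  # all covariates constant -> rank deficient
  bad <- fake_results(rep(0.3, 4), eps01 = 0.01, eps10 = 0, avg_maf = 0.001,
                      pct_inc = 50, pct_red = 0)
  expect_error(summarize_grid(bad, "power"), "Rank-deficient")
})

test_that("covariate coding follows the 0/1/5 and footnote-unit conventions", {
  res <- fake_results(rep(0.1, 4), eps01 = c(0, 0.01, 0.05, 0.05),
                      eps10 = c(0, 0.1, 0.5, 0), avg_maf = 0.001,
                      pct_inc = 50, pct_red = 0, ratio = c(NA, NA, NA, 1.2))
  coded <- rvgeom:::.code_covariates(res)
  expect_equal(coded$err_mag, c(0, 1, 5, 5))
  expect_equal(coded$error_type, c("none", "both", "both", "eps01_only"))
  expect_equal(coded$maf_unit, rep(1, 4))
  expect_equal(coded$ratio_unit[4], 2)
})

test_that("plot helpers return ggplot objects", {
  d <- factorial_design()
  set.seed(91)
  res <- fake_results(runif(nrow(d), 0.2, 0.8), eps01 = d$eps01, eps10 = 0,
                      avg_maf = d$avg_maf, pct_inc = d$pct_inc,
                      pct_red = d$pct_red)
  expect_s3_class(plot_rate_by_error(res), "ggplot")
  expect_s3_class(plot_power_by_maf(maf = c(0.005, 0.01), m = 4), "ggplot")
  fit <- summarize_grid(res, "power")
  expect_s3_class(autoplot(fit), "ggplot")
})
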