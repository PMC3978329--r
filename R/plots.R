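#' Plot empirical rates against error magnitude
#'
#' Quick diagnostic for [run_grid()] output: empirical power or type-I error
#' versus the coded error magnitude, one panel per statistic family, colour
#' by norm. Error bars show +/- 2 Monte-Carlo standard errors.
#'
#' @param results Tibble from [run_grid()].
#' @return A ggplot object.
#' @export
plot_rate_by_error <- function(results) {
  coded <- .code_covariates(results)
  ggplot2::ggplot(coded, ggplot2::aes(
    x = .data$err_mag, y = .data$rate,
    colour = factor(.data$norm), group = factor(.data$norm)
  )) +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = pmax(0, .data$rate - 2 * .data$mc_se),
                   ymax = pmin(1, .data$rate + 2 * .data$mc_se)),
      position = ggplot2::position_dodge(width = 0.25), size = 0.3
    ) +
    ggplot2::stat_summary(fun = mean, geom = "line") +
    ggplot2::facet_wrap(~family) +
    ggplot2::labs(
      x = "error magnitude (0/1/5 coding)", y = "empirical rate",
      colour = "norm"
    ) +
    ggplot2::theme_minimal()
}

#' Analytic power across a MAF range
#'
#' Evaluates [l1_power()] and [j2_power()] over a grid of population MAFs at
#' fixed relative risk and error rates, illustrating how misclassification
#' bites harder as variants get rarer.
#'
#' @param maf Vector of population MAFs to scan.
#' @param relative_risk Per-allele relative risk applied at every site.
#' @param m Number of identical variant sites.
#' @param eps01,eps10 Non-differential error rates.
#' @param n_cases,k,alpha Design constants (see [design_spec()]).
#' @return A ggplot object; the underlying data is in its `data` slot.
#' @export
plot_power_by_maf <- function(maf = c(0.0005, 0.001, 0.002, 0.005, 0.01),
                              relative_risk = 1.5, m = 8,
                              eps01 = 0.01, eps10 = 0.1,
                              n_cases = 1000, k = 1, alpha = 0.05) {
  grid <- tidyr::expand_grid(f = maf, errors = c(FALSE, TRUE))
  dat <- purrr::pmap(grid, function(f, errors) {
    d <- design_spec(
      f_control = rep(f, m), relative_risk = relative_risk,
      eps01_case = if (errors) eps01 else 0,
      eps10_case = if (errors) eps10 else 0,
      n_cases = n_cases, k = k, alpha = alpha
    )
    tibble::tibble(
      maf = f, errors = errors,
      statistic = c("L1", "J2_scaled"),
      power = c(suppressWarnings(l1_power(d)$power),
                suppressWarnings(j2_power(d)$power))
    )
  }) |>
    dplyr::bind_rows()
  ggplot2::ggplot(dat, ggplot2::aes(
    x = .data$maf, y = .data$power,
    colour = .data$statistic, linetype = .data$errors
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "population MAF", y = "analytic power",
      linetype = "errors applied"
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.rv_grid_summary <- function(object, ...) {
  co <- tidy(object) |>
    dplyr::filter(.data$term != "(Intercept)")
  ggplot2::ggplot(co, ggplot2::aes(
    x = .data$estimate, y = .data$term, colour = .data$error_type
  )) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(
      ggplot2::aes(xmin = .data$estimate - 2 * .data$std.error,
                   xmax = .data$estimate + 2 * .data$std.error),
      position = ggplot2::position_dodge(width = 0.4)
    ) +
    ggplot2::facet_grid(family ~ norm) +
    ggplot2::labs(x = "coefficient (rate per covariate unit)", y = NULL) +
    ggplot2::theme_minimal()
}
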