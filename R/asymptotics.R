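#' Design specification for asymptotic calculations
#'
#' Collects the per-variant true frequencies and error rates plus the design
#' constants needed by the closed-form power, sample-size and
#' type-I-inflation calculators. Either `f_case` or `relative_risk` fixes the
#' alternative; omit both (or set `relative_risk = 1`) for a null design.
#'
#' @param f_control Vector of true control (population) MAFs, one per site.
#' @param f_case Vector of true case MAFs; default derived from
#'   `relative_risk` via [case_maf()].
#' @param relative_risk Per-allele relative risk(s); ignored when `f_case`
#'   is given. Default 1.
#' @param eps01_case,eps10_case,eps01_control,eps10_control Per-allele error
#'   rates (recycled across sites); defaults 0 and non-differential.
#' @param n_cases Number of cases `N+`.
#' @param k Control:case ratio `k = N-/N+` (default 1); `N- = k N+`.
#' @param alpha Nominal one-sided type-I rate (default 0.05).
#' @param target_power Power used by the sample-size calculators
#'   (default 0.8).
#' @return An object of class `rv_design` with a `variants` tibble and the
#'   design constants.
#' @examples
#' design_spec(f_control = 0.001, f_case = 0.003, n_cases = 1000)
#' @export
design_spec <- function(f_control, f_case = NULL, relative_risk = 1,
                        eps01_case = 0, eps10_case = 0,
                        eps01_control = eps01_case,
                        eps10_control = eps10_case,
                        n_cases = 1000, k = 1, alpha = 0.05,
                        target_power = 0.8) {
  m <- length(f_control)
  if (m < 1) abort("At least one variant site is required.")
  if (any(f_control <= 0 | f_control >= 1)) abort("`f_control` must lie in (0, 1).")
  if (is.null(f_case)) {
    f_case <- case_maf(f_control, rep_len(relative_risk, m))
  }
  f_case <- rep_len(f_case, m)
  if (any(f_case <= 0 | f_case >= 1)) abort("`f_case` must lie in (0, 1).")
  if (k <= 0) abort("`k` must be positive.")
  if (alpha <= 0 || alpha >= 1 || target_power <= 0 || target_power >= 1) {
    abort("`alpha` and `target_power` must lie in (0, 1).")
  }
  rates <- error_rates(eps01_case, eps10_case, eps01_control, eps10_control, m = m)
  structure(
    list(
      variants = dplyr::bind_cols(
        tibble::tibble(f_control = f_control, f_case = f_case), rates
      ),
      n_cases = n_cases, n_controls = k * n_cases, k = k,
      alpha = alpha, target_power = target_power
    ),
    class = "rv_design"
  )
}

#' @export
print.rv_design <- function(x, ...) {
  cat("<rv_design> ", nrow(x$variants), " sites, N+ = ", x$n_cases,
      ", k = ", x$k, ", alpha = ", x$alpha, "\n", sep = "")
  print(x$variants, n = 8)
  invisible(x)
}

# Per-site moment ingredients shared by all calculators. "HA" frequencies are
# the error-perturbed true case/control MAFs; "H0" frequencies perturb the
# control MAF with each group's own rates (what contaminated data look like
# under the null). t_i = (f+(1-f+) + f-(1-f-)/k)/2 so that sigma^2 = t / N+.
.design_moments <- function(design) {
  v <- design$variants
  np <- design$n_cases
  nm <- design$n_controls
  fps <- perturbed_maf(v$f_case, v$eps01_case, v$eps10_case)
  fms <- perturbed_maf(v$f_control, v$eps01_control, v$eps10_control)
  f0p <- perturbed_maf(v$f_control, v$eps01_case, v$eps10_case)
  f0m <- fms
  var_of <- function(fp, fm) fp * (1 - fp) / (2 * np) + fm * (1 - fm) / (2 * nm)
  t_of <- function(fp, fm) (fp * (1 - fp) + fm * (1 - fm) / design$k) / 2
  list(
    mu_star = fps - fms,
    mu0_star = f0p - f0m,
    mu_clean = v$f_case - v$f_control,
    var_alt = var_of(fps, fms),
    var_null_perturbed = var_of(f0p, f0m),
    var_null_clean = var_of(v$f_control, v$f_control),
    t_alt = t_of(fps, fms),
    t_null_perturbed = t_of(f0p, f0m),
    t_null_clean = t_of(v$f_control, v$f_control),
    t_alt_clean = t_of(v$f_case, v$f_control)
  )
}

.null_var <- function(mom, null_variance) {
  switch(null_variance,
    perturbed = mom$var_null_perturbed,
    clean = mom$var_null_clean
  )
}

.check_low_count <- function(design) {
  v <- design$variants
  fstar <- c(
    perturbed_maf(v$f_case, v$eps01_case, v$eps10_case),
    perturbed_maf(v$f_control, v$eps01_control, v$eps10_control)
  )
  n2 <- c(rep(2 * design$n_cases, nrow(v)), rep(2 * design$n_controls, nrow(v)))
  if (any(n2 * fstar < 5)) {
    warn(paste0(
      "Expected minor-allele count below 5 at some site(s); ",
      "normal/chi-square approximations may be inaccurate at this design."
    ))
  }
}

#' Asymptotic power of the L1 (burden) test
#'
#' Normal-approximation power of the one-sided L1 test applied to
#' error-contaminated data. The critical value is
#' `C = z_(1-alpha) * sqrt(sum_i sigma^2_(Di,H0))`, with the null variances
#' by default taken at the error-perturbed null frequencies (what the data
#' analysed actually look like under the null, and the convention under
#' which the sample-size formula inverts this one exactly);
#' `null_variance = "clean"` uses the error-free control frequencies instead.
#' Power is `1 - Phi((C - sum mu*_i) / sqrt(sum sigma*^2_i))` with
#' alternative moments at the error-perturbed design frequencies.
#'
#' @param design An [design_spec()] object.
#' @param null_variance `"perturbed"` (default) or `"clean"`; see Details.
#' @return A one-row tibble: `power`, `critical_value`, `z_beta`,
#'   `mean_alt`, `sd_null`, `sd_alt`, `alpha`.
#' @examples
#' d <- design_spec(0.001, f_case = 0.003, n_cases = 1000)
#' l1_power(d)$power # ~0.5995
#' @seealso [l1_sample_size()], [l1_inflated_alpha()], [j2_power()]
#' @export
l1_power <- function(design, null_variance = c("perturbed", "clean")) {
  stopifnot(inherits(design, "rv_design"))
  null_variance <- match.arg(null_variance)
  mom <- .design_moments(design)
  v0 <- sum(.null_var(mom, null_variance))
  va <- sum(mom$var_alt)
  if (v0 <= 0 || va <= 0) {
    abort("Degenerate design: every site has zero variance.")
  }
  .check_low_count(design)
  C <- qnorm(1 - design$alpha) * sqrt(v0)
  zb <- (C - sum(mom$mu_star)) / sqrt(va)
  tibble::tibble(
    power = 1 - pnorm(zb), critical_value = C, z_beta = zb,
    mean_alt = sum(mom$mu_star), sd_null = sqrt(v0), sd_alt = sqrt(va),
    alpha = design$alpha
  )
}

#' Sample size required by the L1 test under genotype errors
#'
#' Closed-form `N+*` achieving `target_power` at level `alpha` for the
#' one-sided L1 test, holding the control:case ratio `k` fixed:
#' `N+* = ((z_(1-alpha) sqrt(sum t*_(i,H0)) - z_beta sqrt(sum t*_(i,HA))) /
#' sum mu*_(i,HA))^2` with `t*_i = (f+(1-f+) + f-(1-f-)/k)/2`. The ratio to
#' the error-free requirement quantifies the enrolment inflation needed to
#' absorb misclassification; it is 1 when no errors are present.
#'
#' @inheritParams l1_power
#' @return A one-row tibble: `n_cases` (continuous), `n_cases_ceiling`,
#'   `n_controls`, `n_cases_error_free`, `ratio`.
#' @examples
#' d <- design_spec(0.001, f_case = 0.003, target_power = 0.8)
#' l1_sample_size(d)$n_cases # ~2006.2
#' @export
l1_sample_size <- function(design, null_variance = c("perturbed", "clean")) {
  stopifnot(inherits(design, "rv_design"))
  null_variance <- match.arg(null_variance)
  mom <- .design_moments(design)
  n_for <- function(t0, ta, mu) {
    s <- sum(mu)
    if (abs(s) < .Machine$double.eps) {
      abort("Infeasible design: the summed mean difference is zero.")
    }
    za <- qnorm(1 - design$alpha)
    zb <- qnorm(1 - design$target_power)
    ((za * sqrt(sum(t0)) - zb * sqrt(sum(ta))) / s)^2
  }
  t0 <- switch(null_variance, perturbed = mom$t_null_perturbed,
               clean = mom$t_null_clean)
  n_err <- n_for(t0, mom$t_alt, mom$mu_star)
  n_free <- n_for(mom$t_null_clean, mom$t_alt_clean, mom$mu_clean)
  tibble::tibble(
    n_cases = n_err, n_cases_ceiling = ceiling(n_err),
    n_controls = design$k * n_err,
    n_cases_error_free = n_free, ratio = n_err / n_free
  )
}

#' Type-I error of the L1 test under differential genotype errors
#'
#' For a null design (`f_case = f_control` at every site) analysed with a
#' critical value calibrated without errors, differential misclassification
#' shifts the null mean of the statistic off zero and inflates its variance.
#' The realised level is
#' `alpha* = 1 - Phi((C - sum mu*_(i,H0)) / sqrt(sum sigma*^2_(i,H0)))`,
#' where by default `C` comes from the clean (error-free) null — the analyst
#' believes the nominal calibration — and the starred moments use each
#' group's own error rates. With non-differential rates the mean term
#' vanishes; the residual departure of `alpha*` from `alpha` then only
#' reflects the variance mismatch between clean and contaminated data, and
#' disappears under `null_variance = "perturbed"` (the calibration a
#' permutation test performs implicitly).
#'
#' @inheritParams l1_power
#' @param null_variance `"clean"` (default) or `"perturbed"`; the variance
#'   used for the critical value `C`.
#' @return A one-row tibble: `alpha_star`, `critical_value`, `mean_null`,
#'   `sd_null_star`, `alpha`.
#' @examples
#' d <- design_spec(0.001, eps01_case = 0.012, eps01_control = 0.010)
#' l1_inflated_alpha(d)$alpha_star # ~0.541
#' @export
l1_inflated_alpha <- function(design, null_variance = c("clean", "perturbed")) {
  stopifnot(inherits(design, "rv_design"))
  null_variance <- match.arg(null_variance)
  v <- design$variants
  if (any(abs(v$f_case - v$f_control) > 1e-12)) {
    abort("Type-I inflation is defined for null designs (f_case = f_control).")
  }
  mom <- .design_moments(design)
  v0 <- sum(.null_var(mom, null_variance))
  vs <- sum(mom$var_null_perturbed)
  if (v0 <= 0 || vs <= 0) abort("Degenerate design: every site has zero variance.")
  C <- qnorm(1 - design$alpha) * sqrt(v0)
  z <- (C - sum(mom$mu0_star)) / sqrt(vs)
  tibble::tibble(
    alpha_star = 1 - pnorm(z), critical_value = C,
    mean_null = sum(mom$mu0_star), sd_null_star = sqrt(vs),
    alpha = design$alpha
  )
}

#' Asymptotic power of the scaled J2 test
#'
#' The variance-scaled J2 statistic is asymptotically noncentral chi-square
#' with `m` degrees of freedom and noncentrality
#' `lambda* = sum_i (mu*_(Di) / sigma*_(Di))^2` evaluated at the
#' error-perturbed design frequencies. Power is
#' `P(chisq_(m, lambda*) > chisq_(m, 1-alpha))`; it equals `alpha` exactly
#' when `lambda* = 0`.
#'
#' @inheritParams l1_power
#' @return A one-row tibble: `power`, `critical_value`, `noncentrality`,
#'   `m`, `alpha`.
#' @examples
#' d <- design_spec(0.001, f_case = 0.003, n_cases = 1000)
#' j2_power(d)$power # ~0.2936
#' @export
j2_power <- function(design) {
  stopifnot(inherits(design, "rv_design"))
  mom <- .design_moments(design)
  if (any(mom$var_alt <= 0)) {
    abort("Degenerate site: zero variance under the design frequencies.")
  }
  .check_low_count(design)
  m <- nrow(design$variants)
  lambda <- sum(mom$mu_star^2 / mom$var_alt)
  C <- qchisq(1 - design$alpha, df = m)
  tibble::tibble(
    power = pchisq(C, df = m, ncp = lambda, lower.tail = FALSE),
    critical_value = C, noncentrality = lambda, m = m, alpha = design$alpha
  )
}

#' Sample-size inflation for the scaled J2 test under genotype errors
#'
#' The case sample size scales the noncentrality linearly (at fixed `k`), so
#' maintaining power under errors requires
#' `N+*/N+ = sum(mu_i^2 / t_i) / sum(mu*_i^2 / t*_i)`. The ratio is 1 with
#' no errors, and at least 1 for non-differential errors on risk-increasing
#' designs.
#'
#' @inheritParams l1_power
#' @return A one-row tibble: `ratio`, `n_cases_required` (the current
#'   `n_cases` scaled by the ratio), `noncentrality_clean`,
#'   `noncentrality_error`.
#' @examples
#' d <- design_spec(0.001, f_case = 0.003, eps01_case = 0.01, eps01_control = 0.01)
#' j2_sample_size_ratio(d)$ratio
#' @export
j2_sample_size_ratio <- function(design) {
  stopifnot(inherits(design, "rv_design"))
  mom <- .design_moments(design)
  num <- sum(mom$mu_clean^2 / mom$t_alt_clean)
  den <- sum(mom$mu_star^2 / mom$t_alt)
  if (den <= .Machine$double.eps) {
    abort("Infeasible design: errors cancel the signal entirely.")
  }
  tibble::tibble(
    ratio = num / den,
    n_cases_required = design$n_cases * num / den,
    noncentrality_clean = num * design$n_cases,
    noncentrality_error = den * design$n_cases
  )
}

#' Type-I error of the scaled J2 test under differential genotype errors
#'
#' For a null design, differential errors make the perturbed case and
#' control frequencies differ, giving a positive noncentrality
#' `lambda* = sum_i (mu*_(Di,H0) / sigma*_(Di,H0))^2` and a realised level
#' `alpha* = P(chisq_(m, lambda*) > chisq_(m, 1-alpha)) >= alpha`, with
#' equality exactly when `lambda* = 0` (non-differential rates).
#'
#' @inheritParams l1_power
#' @return A one-row tibble: `alpha_star`, `critical_value`,
#'   `noncentrality`, `m`, `alpha`.
#' @examples
#' d <- design_spec(rep(0.001, 8), eps01_case = 0.012, eps01_control = 0.010)
#' j2_inflated_alpha(d)$alpha_star
#' @export
j2_inflated_alpha <- function(design) {
  stopifnot(inherits(design, "rv_design"))
  v <- design$variants
  if (any(abs(v$f_case - v$f_control) > 1e-12)) {
    abort("Type-I inflation is defined for null designs (f_case = f_control).")
  }
  mom <- .design_moments(design)
  if (any(mom$var_null_perturbed <= 0)) {
    abort("Degenerate site: zero variance under the null frequencies.")
  }
  m <- nrow(v)
  lambda <- sum(mom$mu0_star^2 / mom$var_null_perturbed)
  C <- qchisq(1 - design$alpha, df = m)
  tibble::tibble(
    alpha_star = pchisq(C, df = m, ncp = lambda, lower.tail = FALSE),
    critical_value = C, noncentrality = lambda, m = m, alpha = design$alpha
  )
}

#' Batch asymptotic summary for a design
#'
#' Convenience wrapper evaluating the applicable calculators for one design:
#' power for L1 and scaled J2 always; sample sizes when the design carries a
#' signal; type-I inflation when the design is null.
#'
#' @inheritParams l1_power
#' @return A tibble with columns `quantity`, `statistic`, `value`.
#' @export
asymptotic_summary <- function(design) {
  stopifnot(inherits(design, "rv_design"))
  v <- design$variants
  is_null <- all(abs(v$f_case - v$f_control) <= 1e-12)
  out <- list(
    tibble::tibble(quantity = "power", statistic = "L1",
                   value = l1_power(design)$power),
    tibble::tibble(quantity = "power", statistic = "J2_scaled",
                   value = j2_power(design)$power)
  )
  if (!is_null) {
    ss <- l1_sample_size(design)
    out <- c(out, list(
      tibble::tibble(quantity = "n_cases_required", statistic = "L1",
                     value = ss$n_cases),
      tibble::tibble(quantity = "sample_size_ratio", statistic = "L1",
                     value = ss$ratio),
      tibble::tibble(quantity = "sample_size_ratio", statistic = "J2_scaled",
                     value = j2_sample_size_ratio(design)$ratio)
    ))
  } else {
    out <- c(out, list(
      tibble::tibble(quantity = "inflated_alpha", statistic = "L1",
                     value = l1_inflated_alpha(design)$alpha_star),
      tibble::tibble(quantity = "inflated_alpha", statistic = "J2_scaled",
                     value = j2_inflated_alpha(design)$alpha_star)
    ))
  }
  dplyr::bind_rows(out)
}

#' Read a design table for batch asymptotics
#'
#' Reads a TSV with one row per variant: `f_control`, and either `f_case` or
#' `relative_risk`, plus optional error-rate columns `eps01_case`,
#' `eps10_case`, `eps01_control`, `eps10_control` (missing columns default
#' to 0 / non-differential). An optional `design` column splits rows into
#' several designs.
#'
#' @param path TSV file path.
#' @param n_cases,k,alpha,target_power Design constants applied to every
#'   design in the table.
#' @return A named list of [design_spec()] objects.
#' @export
read_design_table <- function(path, n_cases = 1000, k = 1, alpha = 0.05,
                              target_power = 0.8) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  if (!"f_control" %in% names(tab)) abort("Design table needs an `f_control` column.")
  if (!"design" %in% names(tab)) tab$design <- "design1"
  get0col <- function(d, nm, def) if (nm %in% names(d)) d[[nm]] else def
  tab |>
    dplyr::group_split(.data$design) |>
    purrr::map(function(d) {
      e01c <- get0col(d, "eps01_case", 0)
      e10c <- get0col(d, "eps10_case", 0)
      design_spec(
        f_control = d$f_control,
        f_case = if ("f_case" %in% names(d)) d$f_case else NULL,
        relative_risk = get0col(d, "relative_risk", 1),
        eps01_case = e01c, eps10_case = e10c,
        eps01_control = get0col(d, "eps01_control", e01c),
        eps10_control = get0col(d, "eps10_control", e10c),
        n_cases = n_cases, k = k, alpha = alpha, target_power = target_power
      )
    }) |>
    setNames(unique(tab$design))
}
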