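# The single-site reference design: f 0.001 -> 0.003, N+ = N- = 1000. Its
# expected minor-allele counts (2 and 6) sit below the normal-approximation
# comfort zone, so the calculators deliberately warn on it.
ref_design <- function(...) {
  design_spec(f_control = 0.001, f_case = 0.003, n_cases = 1000, ...)
}

test_that("reference-design quantities match frozen oracle-verified values", {
  d <- ref_design()
  expect_warning(p1 <- l1_power(d), "below 5")
  expect_equal(p1$power, 0.5994885, tolerance = 1e-6)
  expect_equal(p1$critical_value, qnorm(0.95) * sqrt(2 * 0.001 * 0.999 / 2000))
  expect_warning(p2 <- j2_power(d), "below 5")
  expect_equal(p2$power, 0.2935957, tolerance = 1e-6)
  expect_equal(p2$noncentrality, 0.002^2 / ((0.003 * 0.997 + 0.001 * 0.999) / 2000))

  ss <- l1_sample_size(ref_design(target_power = 0.8))
  expect_equal(ss$n_cases, 2006.153, tolerance = 1e-4)
  expect_equal(ss$n_cases_ceiling, 2007)
  expect_equal(ss$ratio, 1)

  dn <- design_spec(0.001, eps01_case = 0.012, eps01_control = 0.010)
  a <- l1_inflated_alpha(dn)
  expect_equal(a$mean_null, 0.001998, tolerance = 1e-9)
  expect_equal(a$sd_null_star^2, 1.184427e-5, tolerance = 1e-6)
  expect_equal(a$alpha_star, 0.5409596, tolerance = 1e-6)
})

test_that("analytic L1 power agrees with a binomial Monte-Carlo oracle", {
  # larger counts than the reference design so the lattice is fine enough
  d <- design_spec(rep(0.01, 4), f_case = rep(0.016, 4), n_cases = 800)
  res <- l1_power(d)
  set.seed(71)
  reps <- 4e4
  sims <- replicate(reps, {
    sum(rbinom(4, 1600, 0.016)) / 1600 - sum(rbinom(4, 1600, 0.01)) / 1600
  })
  mc <- mean(sims > res$critical_value)
  expect_lt(abs(res$power - mc), 4 * sqrt(mc * (1 - mc) / reps) + 0.01)
})

test_that("null designs realise their nominal size", {
  d <- design_spec(rep(0.01, 3), alpha = 0.07)
  expect_equal(l1_power(d)$power, 0.07)
  expect_equal(l1_power(d, null_variance = "clean")$power, 0.07)
  expect_equal(j2_power(d)$power, 0.07)
  expect_equal(j2_inflated_alpha(d)$alpha_star, 0.07)
  expect_equal(l1_inflated_alpha(d)$alpha_star, 0.07)
})

test_that("non-differential errors strictly reduce power", {
  base <- design_spec(rep(0.005, 8), relative_risk = 2, n_cases = 1000)
  err <- design_spec(rep(0.005, 8), relative_risk = 2, n_cases = 1000,
                     eps01_case = 0.01, eps10_case = 0.1)
  expect_lt(l1_power(err)$power, l1_power(base)$power)
  expect_lt(j2_power(err)$power, j2_power(base)$power)
})

test_that("l1_sample_size and l1_power round-trip to 1e-6", {
  grid <- list(
    list(f = 0.001, fc = 0.003, e01 = 0, e10 = 0),
    list(f = 0.001, fc = 0.003, e01 = 0.01, e10 = 0.1),
    list(f = 0.005, fc = 0.008, e01 = 0.05, e10 = 0.5),
    list(f = 0.01, fc = 0.013, e01 = 0.01, e10 = 0)
  )
  for (g in grid) {
    d <- design_spec(g$f, f_case = g$fc, eps01_case = g$e01, eps10_case = g$e10,
                     n_cases = 1000, k = 2, target_power = 0.85)
    n_star <- l1_sample_size(d)$n_cases
    d_at <- design_spec(g$f, f_case = g$fc, eps01_case = g$e01, eps10_case = g$e10,
                        n_cases = n_star, k = 2, target_power = 0.85)
    expect_equal(suppressWarnings(l1_power(d_at)$power), 0.85, tolerance = 1e-6)
  }
})

test_that("sample-size ratio exceeds 1 under non-differential errors", {
  err <- design_spec(rep(0.001, 8), relative_risk = 3,
                     eps01_case = 0.01, eps10_case = 0.1, target_power = 0.8)
  expect_gt(l1_sample_size(err)$ratio, 1)
  expect_gt(j2_sample_size_ratio(err)$ratio, 1)
  clean <- design_spec(rep(0.001, 8), relative_risk = 3)
  expect_equal(l1_sample_size(clean)$ratio, 1)
  expect_equal(j2_sample_size_ratio(clean)$ratio, 1)
})

test_that("j2 sample-size ratio matches numerical inversion of j2_power", {
  d_err <- function(n) design_spec(0.001, f_case = 0.003, n_cases = n,
                                   eps01_case = 0.01, eps01_control = 0.01)
  target <- suppressWarnings(j2_power(design_spec(0.001, f_case = 0.003,
                                                  n_cases = 1000))$power)
  ratio <- j2_sample_size_ratio(d_err(1000))$ratio
  inv <- uniroot(function(n) suppressWarnings(j2_power(d_err(n))$power) - target,
                 c(1000, 20000), tol = 1e-4)$root
  expect_equal(ratio, inv / 1000, tolerance = 0.01)
})

test_that("noncentrality shrinks by exactly the squared mean-shrinkage factor", {
  for (e01 in c(0.01, 0.05)) {
    for (e10 in c(0, 0.1, 0.5)) {
      f <- 0.004; fc <- 0.009; n <- 1500
      clean <- design_spec(f, f_case = fc, n_cases = n)
      err <- design_spec(f, f_case = fc, n_cases = n,
                         eps01_case = e01, eps10_case = e10)
      lam <- j2_power(clean)$noncentrality
      lam_star <- suppressWarnings(j2_power(err)$noncentrality)
      s2 <- diff_moments(fc, f, n, n)$variance
      s2_star <- diff_moments(perturbed_maf(fc, e01, e10),
                              perturbed_maf(f, e01, e10), n, n)$variance
      expect_equal(lam_star, lam * mean_shrinkage(e01, e10)^2 * s2 / s2_star)
    }
  }
})

test_that("eps01 errors cost more power than equal-rate eps10 errors", {
  # relative risk 1.3 keeps power off its ceiling at all three MAFs
  for (f in c(0.001, 0.005, 0.01)) {
    base <- design_spec(rep(f, 8), relative_risk = 1.3, n_cases = 1000)
    d01 <- design_spec(rep(f, 8), relative_risk = 1.3, n_cases = 1000,
                       eps01_case = 0.01)
    d10 <- design_spec(rep(f, 8), relative_risk = 1.3, n_cases = 1000,
                       eps10_case = 0.01)
    p0l <- suppressWarnings(l1_power(base)$power)
    p0j <- suppressWarnings(j2_power(base)$power)
    loss01_l <- p0l - suppressWarnings(l1_power(d01)$power)
    loss10_l <- p0l - suppressWarnings(l1_power(d10)$power)
    expect_gt(loss01_l, loss10_l)
    loss01_j <- p0j - suppressWarnings(j2_power(d01)$power)
    loss10_j <- p0j - suppressWarnings(j2_power(d10)$power)
    expect_gt(loss01_j, loss10_j)
  }
})

test_that("relative power loss grows as the MAF shrinks", {
  mafs <- c(0.01, 0.002, 0.0005)
  rel_loss <- vapply(mafs, function(f) {
    clean <- design_spec(rep(f, 8), relative_risk = 3, n_cases = 1000)
    err <- design_spec(rep(f, 8), relative_risk = 3, n_cases = 1000,
                       eps01_case = 0.01, eps10_case = 0.1)
    p0 <- suppressWarnings(j2_power(clean)$power)
    (p0 - suppressWarnings(j2_power(err)$power)) / p0
  }, numeric(1))
  expect_true(all(diff(rel_loss) > 0))
})

test_that("type-I inflation grows with the differential ratio and error size", {
  alpha_at <- function(ratio, e01 = 0.01) {
    d <- design_spec(rep(0.001, 8), eps01_case = e01 * ratio,
                     eps01_control = e01)
    j2_inflated_alpha(d)$alpha_star
  }
  a <- vapply(c(1, 1.1, 1.2, 1.5), alpha_at, numeric(1))
  expect_equal(a[1], 0.05)
  expect_true(all(diff(a) > 0))
  expect_gt(alpha_at(1.2, 0.05), alpha_at(1.2, 0.01))
  # L1: one-sided inflation when cases are noisier
  l1_at <- function(ratio) {
    d <- design_spec(rep(0.001, 8), eps01_case = 0.01 * ratio,
                     eps01_control = 0.01)
    l1_inflated_alpha(d)$alpha_star
  }
  b <- vapply(c(1.1, 1.2, 1.5), l1_at, numeric(1))
  expect_true(all(diff(b) > 0))
})

test_that("inflated alpha reduces to alpha in the calibrated conventions", {
  # non-differential rates: the mean shift vanishes; with the critical value
  # recalibrated to the contaminated null (as a permutation test does
  # implicitly) the level is exactly nominal
  d <- design_spec(rep(0.002, 4), eps01_case = 0.01, eps10_case = 0.1)
  expect_equal(l1_inflated_alpha(d, null_variance = "perturbed")$alpha_star, 0.05)
  expect_equal(j2_inflated_alpha(d)$alpha_star, 0.05)
  # under the clean-null calibration the variance mismatch leaks through
  expect_gt(l1_inflated_alpha(d)$alpha_star, 0.05)
})

test_that("swapping case and control rates reflects the null mean symmetrically", {
  d_fwd <- design_spec(rep(0.001, 4), eps01_case = 0.012, eps01_control = 0.010)
  d_rev <- design_spec(rep(0.001, 4), eps01_case = 0.010, eps01_control = 0.012)
  a_fwd <- l1_inflated_alpha(d_fwd)
  a_rev <- l1_inflated_alpha(d_rev)
  expect_equal(a_fwd$mean_null, -a_rev$mean_null)
  # the two z-scores straddle C / sd symmetrically
  z_fwd <- qnorm(1 - a_fwd$alpha_star)
  z_rev <- qnorm(1 - a_rev$alpha_star)
  expect_equal(z_fwd + z_rev, 2 * a_fwd$critical_value / a_fwd$sd_null_star)
})

test_that("degenerate and infeasible designs are signalled", {
  d_null <- design_spec(rep(0.001, 2))
  expect_error(l1_sample_size(d_null), "Infeasible")
  expect_error(j2_sample_size_ratio(d_null), "Infeasible")
  d_alt <- design_spec(0.001, f_case = 0.003)
  expect_error(l1_inflated_alpha(d_alt), "null designs")
  expect_error(j2_inflated_alpha(d_alt), "null designs")
})

test_that("asymptotic_summary and design tables drive the batch interface", {
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(
    design = c("a", "a", "b"),
    f_control = c(0.01, 0.005, 0.001),
    relative_risk = c(1.5, 2, 1),
    eps01_case = c(0.01, 0.01, 0.012),
    eps01_control = c(0.01, 0.01, 0.010)
  ), path)
  designs <- read_design_table(path, n_cases = 1000)
  expect_named(designs, c("a", "b"))
  s_alt <- asymptotic_summary(designs$a)
  expect_true(all(c("power", "sample_size_ratio") %in% s_alt$quantity))
  s_null <- suppressWarnings(asymptotic_summary(designs$b))
  expect_true("inflated_alpha" %in% s_null$quantity)
  expect_true(all(s_null$value[s_null$quantity == "inflated_alpha"] >= 0.05))
})
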