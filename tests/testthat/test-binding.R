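test_that("closed-form 1:1 speciation satisfies the quadratic and balance", {
  s <- solve_equilibrium_1to1(314, 314, 96)
  expect_equal(s$complex_pl, 181.8667, tolerance = 1e-6)
  expect_equal(s$pb, 0.5792, tolerance = 1e-4)
  ## detailed balance and mass conservation
  expect_equal(s$free_peptide * s$free_sh3 / s$complex_pl, 96,
               tolerance = 1e-9)
  expect_equal(s$free_peptide + s$complex_pl, 314, tolerance = 1e-9)
  expect_equal(s$free_sh3 + s$complex_pl, 314, tolerance = 1e-9)
  ## limits
  expect_true(solve_equilibrium_1to1(0, 100, 50)$pb_undefined)
  expect_lt(solve_equilibrium_1to1(100, 100, 1e12)$complex_pl, 1e-6)
  expect_error(solve_equilibrium_1to1(-1, 100, 50), "non-negative")
})

test_that("ODE integration reproduces the closed form over a parameter grid", {
  for (p in c(5, 50, 200, 700, 2000)) {
    for (l in c(10, 314)) {
      for (kd in c(10, 96, 1000)) {
        a <- solve_equilibrium_1to1(p, l, kd)
        b <- solve_equilibrium_ode(binding_model("1:1", kd), p, l)
        expect_equal(b$complex_pl, a$complex_pl,
                     tolerance = 1e-6, label = sprintf("P=%g L=%g Kd=%g", p, l, kd))
      }
    }
  }
})

test_that("1:2 speciation matches an independent polynomial-root oracle", {
  kd1 <- 100; kd2 <- 100; p <- 100; l <- 300
  ## oracle: polish the free-SH3 root of the coupled mass-action system
  ## with a fine bisection written independently of the package
  f <- function(x) {
    pf <- p / (1 + x / kd1 + x^2 / (kd1 * kd2))
    x + pf * x / kd1 + 2 * pf * x^2 / (kd1 * kd2) - l
  }
  lo <- 0; hi <- l
  for (i in 1:200) { mid <- (lo + hi) / 2; if (f(mid) > 0) hi <- mid else lo <- mid }
  x <- (lo + hi) / 2
  pf <- p / (1 + x / kd1 + x^2 / (kd1 * kd2))
  ode <- solve_equilibrium_ode(binding_model("1:2", c(kd1, kd2)), p, l)
  expect_equal(ode$free_sh3, x, tolerance = 1e-6)
  expect_equal(ode$complex_pl, pf * x / kd1, tolerance = 1e-6)
  expect_equal(ode$complex_pl2, pf * x^2 / (kd1 * kd2), tolerance = 1e-6)
  ## detailed balance per step
  expect_equal(ode$free_peptide * ode$free_sh3 / ode$complex_pl, kd1,
               tolerance = 1e-6)
  expect_equal(ode$complex_pl * ode$free_sh3 / ode$complex_pl2, kd2,
               tolerance = 1e-6)
  ## mass conservation
  expect_equal(ode$free_peptide + ode$complex_pl + ode$complex_pl2, p,
               tolerance = 1e-9 * p)
  expect_equal(ode$free_sh3 + ode$complex_pl + 2 * ode$complex_pl2, l,
               tolerance = 1e-9 * l)
  ## second step switched off reduces 1:2 to the 1:1 solution
  weak <- solve_equilibrium_ode(binding_model("1:2", c(96, 1e9)), 314, 314)
  expect_equal(weak$complex_pl, 181.8667, tolerance = 1e-4)
  expect_lt(weak$complex_pl2, 1e-4)
})

test_that("fast-exchange averaging interpolates between the state shifts", {
  s <- solve_equilibrium_1to1(314, 314, 96)
  expect_equal(predict_fast_exchange_shift(s, 0, 265), s$pb * 265)
  sat <- solve_equilibrium_1to1(1, 1e9, 1)
  expect_equal(predict_fast_exchange_shift(sat, 0, 265), 265, tolerance = 1e-6)
  free <- solve_equilibrium_1to1(100, 0, 96)
  expect_equal(predict_fast_exchange_shift(free, 7, 265), 7)
  expect_equal(predict_fast_exchange_shift(s, 0, 100, delta_bound2 = 300),
               s$pb * 100)  # no doubly bound state in 1:1
  expect_error(predict_fast_exchange_shift(solve_equilibrium_1to1(0, 10, 5),
                                           0, 1), "undefined")
})

test_that("composite CSP follows the weighted root-sum-square", {
  expect_equal(composite_csp(0, 0), 0)
  expect_equal(composite_csp(0.3, 0), 0.3)
  expect_equal(composite_csp(0.2, 0.05), sqrt(0.04 + 5 * 0.0025))
  expect_equal(composite_csp(0.2, 0.05, weight = 25),
               sqrt(0.04 + 25 * 0.0025))
})

test_that("reduced chi-square follows its definition and guards dof", {
  expect_equal(reduced_chi2(1:5, 1:5, 2), 0)
  expect_equal(reduced_chi2(rep(1, 5), rep(0, 5), 2), 5 / 3)
  expect_error(reduced_chi2(1:3, 1:3, 3), "more observations")
})

test_that("noiseless titrations are recovered exactly by the joint fit", {
  sim <- generate_titration(
    list(model = binding_model("1:1", 96), dnu_hz = c(F4 = 265, F8 = 218),
         csp_max_ppm = 0.1),
    generator_config(seed = 1, noise_shift_19f = 0, noise_csp_amide = 0,
                     conc_uncertainty_rel = 0))
  fit <- fit_titration(sim$data, binding_model("1:1", 150))
  expect_equal(coef(fit)[["kd_uM"]], 96, tolerance = 1e-4)
  expect_equal(coef(fit)[["dnu_F4"]], 265, tolerance = 1e-4)
  expect_equal(coef(fit)[["dnu_F8"]], 218, tolerance = 1e-4)
  expect_equal(coef(fit)[["csp_max"]], 0.1, tolerance = 1e-4)
  expect_lt(fit$reduced_chi2, 1e-8)
  expect_equal(predict(fit), fitted(fit), tolerance = 1e-8)
})

test_that("observed shift grows monotonically with SH3 at fixed peptide", {
  kd <- 96
  sh3 <- seq(0, 2000, by = 100)
  shifts <- vapply(sh3, function(l) {
    predict_fast_exchange_shift(solve_equilibrium_1to1(100, l, kd), 0, 265)
  }, numeric(1))
  expect_true(all(diff(shifts) > 0))
})

test_that("the fit is invariant to expressing 19F shifts in ppm", {
  f <- field_settings()
  sim <- generate_titration(
    list(model = binding_model("1:1", 96), dnu_hz = c(F4 = 265)),
    generator_config(seed = 4, conc_uncertainty_rel = 0))
  d_hz <- sim$data
  fit_hz <- fit_titration(d_hz, binding_model("1:1", 150))
  ## same data written in ppm and re-read through the unit-aware reader
  d_ppm <- d_hz
  d_ppm$value <- d_ppm$value / f$freq_F_mhz
  d_ppm$shift_unit <- "ppm"
  tmp <- tempfile(fileext = ".csv")
  write_titration_csv(d_ppm, tmp)
  back <- read_titration_csv(tmp, field = f)
  fit_ppm <- fit_titration(back, binding_model("1:1", 150))
  expect_equal(coef(fit_ppm)[["kd_uM"]], coef(fit_hz)[["kd_uM"]],
               tolerance = 1e-6)
})

test_that("Kd and shift differences are recovered under measurement noise", {
  ## measurement noise alone (1.6 Hz / 0.005 ppm): median relative errors
  ## on Kd and the shift differences stay small; the systematic 15 %
  ## stock bias widens the spread to the reported +/-30 uM band, which is
  ## exercised by the acceptance suite
  seeds <- mc_seeds(77, 40)
  res <- vapply(seeds, function(s) {
    sim <- generate_titration(
      list(model = binding_model("1:1", 96), dnu_hz = c(F4 = 265, F8 = 218),
           csp_max_ppm = 0.1),
      generator_config(seed = s, conc_uncertainty_rel = 0))
    fit <- suppressWarnings(fit_titration(sim$data, binding_model("1:1", 150)))
    c(coef(fit)[["kd_uM"]], coef(fit)[["dnu_F4"]])
  }, numeric(2))
  expect_lt(median(abs(res[1, ] - 96) / 96), 0.15)
  expect_lt(median(abs(res[2, ] - 265) / 265), 0.05)
})

test_that("a saturation-degenerate titration triggers the identifiability warning", {
  sched <- titration_schedule(peptide_targets_uM = c(1, 2, 3, 4, 5),
                              sh3_start_uM = 5000)
  sim <- generate_titration(
    list(model = binding_model("1:1", 5), dnu_hz = c(F4 = 265)),
    generator_config(seed = 2, schedule = sched, conc_uncertainty_rel = 0))
  expect_warning(fit_titration(sim$data, binding_model("1:1", 5)),
                 "saturation")
})
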