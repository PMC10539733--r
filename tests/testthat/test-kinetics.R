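test_that("exchange rate is linear in free SH3 with the Kd offset", {
  p <- exchange_params(1e8, 100, 265, 10, 70)
  expect_equal(kexc(p, 0), 1e4)
  expect_equal(kexc(p, 200) - kexc(p, 100), 1e8 * 100e-6)
  p0 <- exchange_params(1, 100, 265, 10, 70)
  expect_equal(kexc(p0, 50), 150e-6)
  expect_error(exchange_params(0, 100, 265, 10, 70), "positive")
})

test_that("apparent R2 combines intrinsic rates and the exchange term", {
  ## pf = pb = 0.5, kexc = 1e4: exchange term = 0.25 * (2 pi 100)^2 / 1e4
  conc <- solve_equilibrium_1to1(200, 1e9, 1)        # fully bound
  free <- solve_equilibrium_1to1(200, 0, 1)          # fully free
  p <- exchange_params(1e8, 100, 100, 5, 20)
  expect_equal(as.numeric(r2_apparent(p, free)), 5)
  expect_equal(as.numeric(r2_apparent(p, conc)), 20, tolerance = 1e-6)
  half <- solve_equilibrium_1to1(1, 1e9, 1)  # not half; construct manually
  half$pb <- 0.5; half$pf <- 0.5; half$free_sh3 <- 0; half$pb_undefined <- FALSE
  ke <- kexc(p, 0)  # 1e4
  expect_equal(as.numeric(r2_apparent(p, half)),
               12.5 + 0.25 * (2 * pi * 100)^2 / ke, tolerance = 1e-12)
  expect_equal(as.numeric(r2_apparent(p, half)), 22.4, tolerance = 1e-2)
  ## delta_omega = 0 removes the exchange term
  p0 <- exchange_params(1e8, 100, 0, 5, 20)
  expect_equal(as.numeric(r2_apparent(p0, half)), 12.5)
  ## validity flag reacts to slow exchange
  slow <- exchange_params(100, 10, 500, 5, 20)
  expect_false(attr(r2_apparent(slow, half), "fast_exchange_ok"))
})

test_that("exchange term vanishes at the population edges and is non-negative", {
  p <- exchange_params(1e8, 96, 265, 10, 70)
  pbs <- seq(0.01, 0.99, length.out = 25)
  vals <- vapply(pbs, function(pb) {
    conc <- solve_equilibrium_1to1(100, 0, 96)
    conc$pb <- pb; conc$pf <- 1 - pb; conc$free_sh3 <- 50
    conc$pb_undefined <- FALSE
    as.numeric(r2_apparent(p, conc)) - ((1 - pb) * 10 + pb * 70)
  }, numeric(1))
  expect_true(all(vals >= 0))
  expect_lt(vals[1], vals[13])   # grows toward pb = 1/2
})

test_that("Lorentzian line fits recover width, centre and R2app", {
  fr <- seq(-80, 80, by = 0.25)
  cfg0 <- generator_config(seed = 1, exponential_broadening = 0)
  ## single noiseless line: FWHM 6.366 Hz <-> R2app = 20 /s
  sp <- generate_spectrum(data.frame(centre_hz = 0, r2app_s1 = 20,
                                     amplitude = 2), fr, cfg0)
  fit <- fit_lorentzian_peaks(sp$freq_hz, sp$intensity, 1)
  expect_equal(fit$peaks$r2app_s1, 20, tolerance = 1e-6)
  expect_equal(fit$peaks$fwhm_hz, 20 / pi, tolerance = 1e-6)
  expect_equal(fit$peaks$centre_hz, 0, tolerance = 1e-8)
  ## two separated noisy peaks: centres to 0.1 Hz
  sp2 <- generate_spectrum(data.frame(centre_hz = c(-30, 25),
                                      r2app_s1 = c(25, 40),
                                      amplitude = c(1, 0.7)),
                           fr, generator_config(seed = 5,
                                                exponential_broadening = 0),
                           noise_sd = 0.005)
  fit2 <- fit_lorentzian_peaks(sp2$freq_hz, sp2$intensity, 2)
  expect_equal(fit2$peaks$centre_hz, c(-30, 25), tolerance = 0.1)
  ## pure noise: amplitude consistent with zero
  set.seed(8)
  fitn <- suppressWarnings(
    fit_lorentzian_peaks(fr, rnorm(length(fr), 0, 0.01), 1))
  expect_true(fitn$peaks$amplitude_consistent_with_zero)
})

test_that("kon refits recover the generating kinetics from R2app profiles", {
  kd <- 96; dnu <- 265
  sched <- titration_schedule()
  sched <- sched[sched$peptide_total_uM > 0, ]
  conc <- lapply(seq_len(nrow(sched)), function(i)
    solve_equilibrium_1to1(sched$peptide_total_uM[i], sched$sh3_total_uM[i], kd))
  truth <- exchange_params(1.2e8, kd, dnu, 10, 70)
  r2 <- vapply(conc, function(cc) as.numeric(r2_apparent(truth, cc)),
               numeric(1))
  fit <- fit_kon(r2, conc, dnu, kd)
  expect_equal(coef(fit)[["kon"]], 1.2e8, tolerance = 1e-3)
  expect_equal(coef(fit)[["r2_free"]], 10, tolerance = 1e-3)
  expect_equal(coef(fit)[["r2_bound"]], 70, tolerance = 1e-3)
  expect_true(fit$kon_identifiable)
  expect_error(fit_kon(r2, conc, 0, kd), "unidentifiable")
})

test_that("joint generation and refit of R2app profiles is self-consistent", {
  ## concentrations from the binding module drive both generation and refit
  kd <- 96
  sim <- generate_titration(
    list(model = binding_model("1:1", kd), dnu_hz = c(F4 = 265),
         kinetics = exchange_params(0.9e8, kd, 265, 12, 60)),
    generator_config(seed = 3, noise_shift_19f = 0, noise_linewidth_rel = 0,
                     conc_uncertainty_rel = 0))
  d <- sim$data[sim$data$observable == "shift_hz", ]
  conc <- lapply(seq_len(nrow(d)), function(i)
    solve_equilibrium_1to1(d$peptide_total_uM[i], d$sh3_total_uM[i], kd))
  r2app <- pi * (d$linewidth_hz - sim$config$exponential_broadening)
  fit <- fit_kon(r2app, conc, 265, kd)
  expect_equal(coef(fit)[["kon"]], 0.9e8, tolerance = 1e-4)
  expect_equal(coef(fit)[["r2_free"]], 12, tolerance = 1e-4)
  expect_equal(coef(fit)[["r2_bound"]], 60, tolerance = 1e-4)
})
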