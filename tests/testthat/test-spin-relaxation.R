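test_that("spectral density has the Lorentzian form and its known extremum", {
  expect_equal(spectral_density(0, 1e-9), 4e-10)
  expect_equal(spectral_density(1e9, 1e-9), 2e-10)
  ## argmax over tau_c sits at 1/omega (grid-search oracle)
  w <- 3.548e9
  tg <- 10^seq(-11, -8, length.out = 20000)
  t_star <- tg[which.max(spectral_density(w, tg))]
  expect_equal(t_star, 1 / w, tolerance = 1e-3)
  expect_error(spectral_density(1e9, 0), "positive")
  expect_error(spectral_density(1e9, -1e-9), "positive")
})

test_that("dipolar constant matches direct evaluation and scales as r^-3", {
  expect_equal(dipolar_constant(2.03), oracle_d(2.03), tolerance = 1e-12)
  expect_equal(dipolar_constant(2.03), 8.49e4, tolerance = 1e-3)
  ## halving r multiplies d^2 by 64
  expect_equal(dipolar_constant(1.0)^2 / dipolar_constant(2.0)^2, 64)
  expect_lt(dipolar_constant(9.9), 1e3)
  expect_error(dipolar_constant(0), "positive")
})

test_that("two-spin closed forms agree with the literal oracle to 1e-10", {
  f <- field_settings(14.1)
  g2 <- spin_geometry("two-spin", c(HG = 2.03))
  for (tc in c(1e-11, 1e-10, 0.5e-9, 2e-9, 1e-8, 1e-7)) {
    o <- oracle_rates(2.03, 0, 0, tc)
    expect_equal(r1_longitudinal(g2, tc, f), o$r1, tolerance = 1e-10)
    expect_equal(r2_transverse(g2, tc, f), o$r2, tolerance = 1e-10)
    expect_equal(cross_relaxation_sigma(2.03, tc, f), o$sigma_first,
                 tolerance = 1e-10)
  }
})

test_that("multi-spin rates with CSA agree with the term-by-term oracle", {
  f <- field_settings(14.1)
  g <- geom_exo_major()
  for (tc in c(1e-10, 0.5e-9, 4.47e-9, 2e-8)) {
    o <- oracle_rates(exo_major_distances, -74.2, 0.120, tc)
    expect_equal(r1_longitudinal(g, tc, f), o$r1, tolerance = 1e-10)
    expect_equal(r2_transverse(g, tc, f), o$r2, tolerance = 1e-10)
  }
  ## frozen oracle value at tau_c = 4.47 ns
  expect_equal(r1_longitudinal(g, 4.47e-9, f), 2.934553, tolerance = 1e-5)
})

test_that("rates vanish in the fast-motion limit and R2 grows monotonically", {
  f <- field_settings()
  for (g in fpro_geometries()) {
    expect_lt(r1_longitudinal(g, 1e-14, f), 1e-2)
    expect_lt(r2_transverse(g, 1e-14, f), 1e-2)
    ## monotonic R2 between 0.1 and 10 ns
    tcs <- 10^seq(-10, -8, length.out = 40)
    expect_true(all(diff(r2_transverse(g, tcs, f)) > 0))
    ## R2 >= R1 for tau_c >= 1 ns
    slow <- 10^seq(-9, -7, length.out = 20)
    expect_true(all(r2_transverse(g, slow, f) >=
                    r1_longitudinal(g, slow, f) * (1 - 1e-9)))
  }
})

test_that("extreme narrowing gives R2/R1 -> 1 for a dipolar two-spin pair", {
  f <- field_settings()
  g2 <- spin_geometry("two-spin", c(HG = 2.03))
  ratio <- r2_transverse(g2, 1e-12, f) / r1_longitudinal(g2, 1e-12, f)
  expect_equal(ratio, 1, tolerance = 1e-4)
})

test_that("cross-relaxation changes sign between the motional limits", {
  f <- field_settings()
  expect_equal(cross_relaxation_sigma(2.03, 0.5e-9, f), -0.2060382,
               tolerance = 1e-5)
  g2 <- spin_geometry("two-spin", c(HG = 2.03))
  ## sigma/rho -> +1/2 in extreme narrowing (all J equal)
  expect_equal(cross_relaxation_sigma(2.03, 1e-13, f) /
               r1_longitudinal(g2, 1e-13, f), 0.5, tolerance = 1e-3)
  ## slow tumbling: with J ~ 1/(omega^2 tau_c) the spectral-density
  ## ratios are frozen by the frequencies, so sigma/rho tends to
  ## (6 rS - 1)/(1 + 3 rF + 6 rS) -- close to, but above, the naive -1
  rF <- ((f$omega_H - f$omega_F) / f$omega_F)^2
  rS <- ((f$omega_H - f$omega_F) / (f$omega_H + f$omega_F))^2
  lim <- (6 * rS - 1) / (1 + 3 * rF + 6 * rS)
  expect_equal(cross_relaxation_sigma(2.03, 1e-6, f) /
               r1_longitudinal(g2, 1e-6, f), lim, tolerance = 1e-4)
  expect_lt(lim, -0.97)
  expect_gt(lim, -1)
})

test_that("steady-state NOE respects its theoretical bounds everywhere", {
  k <- nmr_constants()
  f <- field_settings()
  g2 <- spin_geometry("two-spin", c(HG = 2.03))
  expect_equal(noe_steady_state(g2, 1e-13, f), 0.531, tolerance = 1e-3)
  ## the slow-tumbling NOE approaches (but never reaches) -gamma_H/gamma_F
  noe_slow <- noe_steady_state(g2, 1e-6, f)
  expect_gt(noe_slow, -k$gamma_H / k$gamma_F)
  expect_equal(noe_slow, -1.039, tolerance = 1e-3)
  tcs <- 10^seq(-11, -7, length.out = 60)
  for (g in fpro_geometries()) {
    noe <- noe_steady_state(g, tcs, f)
    expect_true(all(noe > -k$gamma_H / k$gamma_F - 1e-12))
    expect_true(all(noe < k$gamma_H / (2 * k$gamma_F) + 1e-12))
  }
  expect_error(noe_steady_state(g2, 1e-9, f, saturated_proton = "HB2"),
               "not present")
})

test_that("CSA strictly shrinks the NOE magnitude at every tau_c", {
  f <- field_settings()
  tcs <- 10^seq(-11, -7, length.out = 40)
  g_no_csa <- spin_geometry("no CSA", exo_major_distances)
  g_csa <- geom_exo_major()
  expect_true(all(abs(noe_steady_state(g_csa, tcs, f)) <
                  abs(noe_steady_state(g_no_csa, tcs, f))))
})

test_that("the (4R)-exo major NOE at 0.5 ns is about -9 %", {
  expect_equal(noe_steady_state(geom_exo_major(), 0.5e-9), -0.0919,
               tolerance = 1e-3)
})

test_that("NOE is strictly decreasing on the inversion branch for all conformers", {
  f <- field_settings()
  tcs <- 10^seq(log10(1e-11), log10(4e-9), length.out = 120)
  for (g in fpro_geometries())
    expect_true(all(diff(noe_steady_state(g, tcs, f)) < 0), label = g$label)
})

test_that("NOE inversion round-trips and rejects unattainable values", {
  g <- geom_exo_major()
  f <- field_settings()
  for (tc in c(0.1e-9, 0.5e-9, 1e-9, 3e-9)) {
    noe <- noe_steady_state(g, tc, f)
    expect_equal(invert_tauc_from_noe(g, f, noe), tc, tolerance = 1e-6)
  }
  expect_error(invert_tauc_from_noe(g, f, -1.5), "attainable")
  expect_error(invert_tauc_from_noe(g, f, 0.5), "attainable")
})

test_that("R1 inversion returns every crossing, sorted", {
  g <- geom_exo_major()
  f <- field_settings()
  ## above the global maximum: no solution
  expect_length(invert_tauc_from_r1(g, f, observed_r1 = 10), 0)
  ## camel-hump curve: R1 = 2.2 has solutions below 1 ns and above 5 ns
  sols <- invert_tauc_from_r1(g, f, observed_r1 = 2.2)
  expect_gte(length(sols), 2)
  expect_true(any(sols < 1e-9) && any(sols > 5e-9))
  expect_true(!is.unsorted(sols))
  ## round trip through an arbitrary point on the curve
  tc_star <- 0.7e-9
  sols <- invert_tauc_from_r1(g, f, r1_longitudinal(g, tc_star, f))
  expect_true(any(abs(sols - tc_star) / tc_star < 1e-6))
})

test_that("relaxation curves locate the camel-hump maxima", {
  rc <- relaxation_curves(geom_exo_major())
  expect_s3_class(rc, "relax_curves")
  expect_length(rc$r1_maxima, 2)
  expect_equal(rc$r1_maxima[1] * 1e9, 0.299, tolerance = 0.02)
  expect_equal(rc$r1_maxima[2] * 1e9, 4.06, tolerance = 0.02)
  ## minor (4R) conformer: low-tau maximum much lower than the high one
  rc_min <- relaxation_curves(fpro_geometries("(4R)-endo minor"))
  g <- rc_min$grid
  low <- max(g$R1_s1[g$tau_c_s < 1e-9])
  high <- max(g$R1_s1[g$tau_c_s > 1e-9])
  expect_lt(low, 0.8 * high)
  expect_warning(relaxation_curves(geom_exo_major(), points_per_decade = 5),
                 "per decade")
  expect_error(spin_geometry("empty", numeric(0)), "at least one")
})

test_that("computed R1 band brackets the measured rates for the (4R)-exo conformer", {
  f <- field_settings()
  r1 <- r1_longitudinal(geom_exo_major(), seq(0.4e-9, 0.9e-9, length.out = 30), f)
  expect_true(all(r1 > 1.8 & r1 < 2.8))
})

test_that("inverting the measured NOEs orders the two polyproline segments", {
  f <- field_settings()
  rates <- fpro_relaxation_rates()
  tau <- vapply(seq_len(nrow(rates)), function(i) {
    invert_tauc_from_noe(fpro_geometries(rates$conformer[i]), f,
                         rates$noe_max_pct[i] / 100)
  }, numeric(1))
  names(tau) <- paste(rates$peptide, rates$position)
  ## position 8 tumbles slower than position 4 in both peptides
  expect_gt(tau[["MpRS 8"]], tau[["MpRS 4"]])
  expect_gt(tau[["MpSR 8"]], tau[["MpSR 4"]])
  ## and the estimates sit in the sub-nanosecond window
  expect_true(all(tau > 0.3e-9 & tau < 1.1e-9))
})
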