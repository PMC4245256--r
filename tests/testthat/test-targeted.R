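# DSMK targeted-effect channel

test_that("saturation transform: limits, monotone yield decline", {
  expect_equal(effective_z_saturation(0, 2.51), 0)
  z <- 2.51 / 100
  expect_equal(effective_z_saturation(z, 2.51), z, tolerance = 0.01)
  # overkill: z'/z non-increasing over [0, 10 z0]
  zz <- seq(1e-3, 25.1, length.out = 400)
  ratio <- effective_z_saturation(zz, 2.51) / zz
  expect_true(all(diff(ratio) <= 1e-12))
  # bounded by z0
  expect_lt(effective_z_saturation(1e4, 2.51), 2.51 + 1e-9)
  expect_identical(effective_z_saturation(zz, Inf), zz)
  expect_error(effective_z_saturation(-1, 2.51), "non-negative")
})

test_that("adaptive transform: limits and high-z decline", {
  expect_equal(effective_z_adaptive(0, 6.51), 0)
  z <- 6.51 / 100
  expect_equal(effective_z_adaptive(z, 6.51), z, tolerance = 0.02)
  expect_lt(effective_z_adaptive(50 * 6.51, 6.51),
            effective_z_adaptive(6.51, 6.51))
  expect_identical(effective_z_adaptive(c(1, 5), Inf), c(1, 5))
  expect_error(effective_z_adaptive(-1, 6.51), "non-negative")
})

test_that("survival_given_zn: zero field, LQ limit, null parameters", {
  p <- dsmk_params(0.2, 0.05, 0.1, Inf, 7.8)
  zero <- specific_energy_pd(0, 1)
  expect_equal(survival_given_zn(zero, p), 1)

  # delta domain PD with z0 = Inf collapses to the linear-quadratic law
  for (zn in c(0.5, 1, 2, 5))
    expect_equal(-log(survival_given_zn(delta_pd(zn), p)),
                 0.2 * zn + 0.05 * zn^2, tolerance = 1e-12)

  p0 <- dsmk_params(0, 0, 0.1, 993, 7.8)
  pd <- multi_event_pd(make_spectrum(100, 0.1), 3)
  expect_equal(survival_given_zn(pd, p0), 1)
})

test_that("survival_given_zn is non-increasing in z_n for non-negative coefficients", {
  p <- dsmk_params(0.1, 0.03, 0.1, 5, 7.8)
  s <- vapply(seq(0.1, 20, length.out = 60),
              function(z) survival_given_zn(delta_pd(z), p), numeric(1))
  expect_true(all(diff(s) <= 1e-12))
})

test_that("survival_vs_dose: zero dose, delta reduction, dilute microbeam", {
  p <- dsmk_params(0.454, 0, 0.3, 2.51, 7.8)
  dsp <- make_spectrum(2, 0.3)
  expect_equal(survival_vs_dose(specific_energy_pd(0, 1), dsp, p), 1)

  # nucleus PD concentrated at one z_n equals the conditional-PD route
  zn <- 1.5
  s_fast <- survival_vs_dose(delta_pd(zn), dsp, p)
  s_direct <- survival_given_zn(conditional_domain_pd(dsp, zn), p)
  expect_equal(s_fast, s_direct, tolerance = 1e-4)

  # microbeam with a tiny irradiated fraction: S_T ~ 1
  mb <- microbeam_pd(microbeam_design(5, 7e5, 0.93))
  expect_lt(abs(1 - survival_vs_dose(mb, dsp, p)), 1e-3)
})

test_that("quadrature of the dose response matches a Monte Carlo oracle", {
  # coarsen the nucleus PD into ~160 mass-preserving atoms (centroid per
  # bin), then compare the package quadrature on that distribution with a
  # 1e6-draw Monte Carlo average whose survivals come from the independent
  # conditional-PD route
  p <- dsmk_params(0.2, 0.03, 0.2, 10, 7.8)
  dsp <- make_spectrum(50, 0.2)
  nsp <- make_spectrum(50, 7.8)
  npd <- multi_event_pd(nsp, 2)

  g <- npd$grid
  w <- (c(diff(g) / 2, 0) + c(0, diff(g) / 2)) * npd$density
  qs <- quantile(rep(g, times = pmax(round(w * 4e4), 0)),
                 probs = seq(0, 1, length.out = 161))
  bin <- findInterval(g, qs, rightmost.closed = TRUE)
  mass <- tapply(w, bin, sum)
  zc <- tapply(w * g, bin, sum) / mass
  atoms <- data.frame(z = as.numeric(zc), mass = as.numeric(mass))
  atoms$mass <- atoms$mass / sum(atoms$mass) * (1 - npd$zero_mass)
  apd <- specific_energy_pd(dose = npd$zero_mass * 0 + sum(atoms$z * atoms$mass),
                            zero_mass = npd$zero_mass, atoms = atoms)

  s_quad <- survival_vs_dose(apd, dsp, p)

  sv <- c(1, vapply(atoms$z, function(z)
    survival_given_zn(conditional_domain_pd(dsp, z), p), numeric(1)))
  probs <- c(npd$zero_mass, atoms$mass)
  set.seed(99)
  draw <- sample.int(length(probs), 1e6, replace = TRUE, prob = probs)
  s_i <- sv[draw]
  mc_se <- sd(s_i) / sqrt(length(s_i))
  expect_lt(abs(s_quad - mean(s_i)), 3 * mc_se + 2e-4)
})

test_that("Bcl-2 channel survival rises towards 1 along an LET ladder", {
  p <- dsmk_params(0.454, 0, 0.3, 2.51, 7.8, method = "saturation")
  lets <- c(2, 20, 100, 400)
  s_b <- vapply(lets, function(let) {
    npd <- multi_event_pd(make_spectrum(let, 7.8), 2)
    survival_vs_dose(npd, make_spectrum(let, 0.3), p)
  }, numeric(1))
  expect_true(all(diff(s_b) > 0))
  p_ad <- dsmk_params(0.493, 0, 0.349, 6.51, 7.8, method = "adaptive")
  s_b2 <- vapply(lets, function(let) {
    npd <- multi_event_pd(make_spectrum(let, 7.8), 2)
    survival_vs_dose(npd, make_spectrum(let, 0.349), p_ad)
  }, numeric(1))
  expect_true(all(diff(s_b2) > 0))
})

test_that("bcl2_mixture endpoints and interior weighting", {
  expect_equal(bcl2_mixture(0.4, 0.5, 1), 0.4)
  expect_equal(bcl2_mixture(0.4, 0.5, 0), 0.2)
  expect_equal(bcl2_mixture(0.4, 0.5, 0.5), 0.3)
  expect_error(bcl2_mixture(1.4, 0.5, 0.5), "S_C")
  expect_error(bcl2_mixture(0.4, 0.5, 2), "'x'")
})

test_that("dsmk_params validates its domain", {
  expect_error(dsmk_params(0.1, 0.01, 0, 1, 7.8), "r_d")
  expect_error(dsmk_params(0.1, 0.01, 0.3, 0, 7.8), "z0")
  expect_error(dsmk_params(0.1, 0.01, 8, 1, 7.8), "r_n")
  expect_error(dsmk_params(0.1, -0.01, 0.3, 1, 7.8, method = "adaptive"),
               "beta0")
  # negative alpha0 is allowed (published conventional-channel fits)
  expect_silent(dsmk_params(-0.0596, 0.00413, 0.0654, 993, 7.8))
})
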