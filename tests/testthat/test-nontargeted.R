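# bystander (nontargeted) channel

wi38 <- function(z_thre = Inf)
  nt_params(a1 = 18500, a2 = 5.38, eta = 0.604, kappa = 0.106,
            z_thre = z_thre, n_population = 7e5)

test_that("trigger probability: zero, monotone, steep switch-on", {
  p <- wi38()
  expect_equal(trigger_probability(0, p), 0)
  z <- seq(0, 2, length.out = 300)
  pt <- trigger_probability(z, p)
  expect_true(all(pt >= 0 & pt <= 1))
  expect_true(all(diff(pt) >= 0))
  # switch-on around ~0.2 Gy with the published power index
  expect_gt(trigger_probability(0.3, p) / trigger_probability(0.1, p), 5)
  expect_error(trigger_probability(-1, p), "non-negative")
})

test_that("signal_fraction: zero field, microbeam closed form, delta field", {
  p <- wi38()
  expect_equal(signal_fraction(specific_energy_pd(0, 1), p), 0)
  mb <- microbeam_pd(microbeam_design(7, 7e5, 0.93))
  expect_equal(signal_fraction(mb, p),
               7 / 7e5 * trigger_probability(0.93, p), tolerance = 1e-12)
  expect_equal(signal_fraction(delta_pd(0.5), p),
               trigger_probability(0.5, p), tolerance = 1e-12)
})

test_that("escape probability equals the explicit binomial sum", {
  set.seed(11)
  for (i in 1:40) {
    n_w <- sample(2:20, 1)
    eta <- runif(1)
    ps <- runif(1)
    p <- nt_params(a1 = 1, a2 = 1, eta = eta, kappa = 0.1,
                   n_population = n_w)
    expect_equal(escape_probability(ps, p), oracle_escape(ps, eta, n_w),
                 tolerance = 1e-12)
  }
  p <- nt_params(a1 = 1, a2 = 1, eta = 0, kappa = 0.1, n_population = 100)
  expect_equal(escape_probability(0.7, p), 1)
  expect_equal(escape_probability(0, wi38()), 1)
})

test_that("escape probability survives population sizes in the millions", {
  p <- nt_params(a1 = 1, a2 = 1, eta = 0.0596, kappa = 0.147,
                 n_population = 2.68e6)
  pe <- escape_probability(1e-6, p)
  expect_equal(pe, exp((2.68e6 - 1) * log1p(-0.0596e-6)), tolerance = 1e-12)
  expect_gt(pe, 0)
  expect_lt(pe, 1)
})

test_that("survival_nt: trivial cases and the 1 - kappa asymptote", {
  p <- wi38()
  expect_equal(survival_nt(specific_energy_pd(0, 1), p), 1)
  p0 <- nt_params(a1 = 18500, a2 = 5.38, eta = 0.604, kappa = 0,
                  n_population = 7e5)
  pd <- multi_event_pd(make_spectrum(2, 7.8), 1)
  expect_equal(survival_nt(pd, p0), 1)
  # saturated broadbeam, no threshold: S_NT -> 1 - kappa
  pd10 <- multi_event_pd(make_spectrum(2, 7.8), 10)
  expect_lt(survival_nt(pd10, p) - (1 - p$kappa), 1e-3)
  # 1 mGy threshold at high dose: nearly all cells are above it, S_NT -> 1
  expect_lt(abs(1 - survival_nt(multi_event_pd(make_spectrum(2, 7.8), 5),
                                wi38(1e-3))), 1e-3)
})

test_that("S_NT stays within [1 - kappa, 1] for random fields and parameters", {
  set.seed(21)
  for (i in 1:25) {
    p <- nt_params(a1 = exp(runif(1, 0, 12)), a2 = runif(1, 0.5, 8),
                   eta = runif(1), kappa = runif(1),
                   z_thre = sample(c(1e-3, 0.1, Inf), 1),
                   n_population = 10^runif(1, 1, 6.5))
    pd <- if (runif(1) < 0.5)
      microbeam_pd(microbeam_design(sample(0:50, 1), 7e5, runif(1, 0, 3)))
    else multi_event_pd(make_spectrum(exp(runif(1, 0, 6)), 7.8),
                        runif(1, 0, 6))
    s <- survival_nt(pd, p)
    expect_gte(s, 1 - p$kappa - 1e-12)
    expect_lte(s, 1 + 1e-12)
  }
})

test_that("1 mGy threshold produces the low-dose hypersensitivity dip", {
  p <- wi38(1e-3)
  sp <- make_spectrum(100, 7.8)
  doses <- c(0, 0.002, 0.005, 0.01, 0.03, 0.1, 0.3, 1, 2, 5)
  s <- vapply(doses, function(d) survival_nt(multi_event_pd(sp, d), p),
              numeric(1))
  # non-monotone: starts at one, dips, then returns
  expect_equal(s[1], 1)
  expect_lt(min(s), 1 - 1e-3)
  expect_gt(which.min(s), 1)
  expect_lt(abs(1 - s[length(s)]), 1e-3)
  expect_gt(s[length(s)], min(s))
})

test_that("microbeam survival_nt equals the hand-composed closed form", {
  p <- tbl_nt_bcl2neo()
  for (ni in c(1, 10, 120)) {
    des <- microbeam_design(ni, 2.67e6, 3.1)
    pd <- microbeam_pd(des)
    ps <- ni / 2.67e6 * trigger_probability(3.1, p)
    pe <- escape_probability(ps, p)
    below <- 1 - ni / 2.67e6 + (3.1 < p$z_thre) * ni / 2.67e6
    expect_equal(survival_nt(pd, p), 1 - p$kappa * (1 - pe) * below,
                 tolerance = 1e-12)
  }
})

test_that("nt_params validates its domain", {
  expect_error(nt_params(-1, 1, 0.5, 0.5, n_population = 10), "a1")
  expect_error(nt_params(1, 0, 0.5, 0.5, n_population = 10), "a2")
  expect_error(nt_params(1, 1, 1.5, 0.5, n_population = 10), "eta")
  expect_error(nt_params(1, 1, 0.5, -0.5, n_population = 10), "kappa")
  expect_error(nt_params(1, 1, 0.5, 0.5, z_thre = 0, n_population = 10),
               "z_thre")
})
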