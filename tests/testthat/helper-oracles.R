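# Shared fixtures and independent oracles. The oracles deliberately use a
# different algorithm (explicit nu-term convolution on a uniform grid, brute
# binomial sums) from the package's FFT-exponent implementation.

trapz_ <- function(x, y) sum((y[-1] + y[-length(y)]) * diff(x)) / 2
cumtrapz_ <- function(x, y) c(0, cumsum((y[-1] + y[-length(y)]) * diff(x) / 2))

# Direct compound-Poisson oracle: bin-integrated single-event masses on a
# uniform grid, explicit nu-fold convolutions up to nu_max, Poisson-mixed.
# Returns bin masses on grid x (masses at x + h/2 bin centers idiom).
oracle_compound_poisson <- function(spec, dose, h_div = 200, nu_max = 30) {
  lam <- dose / spec$zbar_F
  h <- spec$zbar_F / h_div
  xmax <- min((nu_max + 1) * max(spec$grid), 60 * max(dose, spec$zbar_F))
  x <- seq(0, xmax, by = h)
  Fg <- cumtrapz_(spec$grid, spec$density)
  Fe <- stats::approx(c(0, spec$grid), c(0, Fg),
                      pmax(c(x - h / 2, x[length(x)] + h / 2), 0),
                      yleft = 0, yright = 1)$y
  p1 <- pmax(diff(Fe), 0)
  p1 <- p1 / sum(p1)
  acc <- numeric(length(x))
  pk <- p1
  for (nu in seq_len(nu_max)) {
    acc <- acc + stats::dpois(nu, lam) * pk
    pk <- stats::convolve(pk, rev(p1), type = "open")[seq_along(x)]
  }
  list(x = x, h = h, mass = acc, zero_mass = exp(-lam))
}

# Total-variation distance between a specific_energy_pd and the oracle,
# measured on common coarse bins (width zbar_F / 8).
tv_against_oracle <- function(pd, spec, oracle) {
  bins <- seq(0, max(oracle$x), by = spec$zbar_F / 8)
  o_cdf <- stats::approx(oracle$x + oracle$h / 2, cumsum(oracle$mass), bins,
                         yleft = 0, yright = sum(oracle$mass))$y
  p_cdf <- stats::approx(pd$grid, cumtrapz_(pd$grid, pd$density), bins,
                         yleft = 0, yright = 1 - pd$zero_mass)$y
  0.5 * (abs(oracle$zero_mass - pd$zero_mass) +
           sum(abs(diff(o_cdf) - diff(p_cdf))))
}

# Brute-force escape probability: explicit binomial sum over emitter counts.
oracle_escape <- function(P_S, eta, n_w) {
  k <- 0:(n_w - 1)
  sum(stats::dbinom(k, n_w - 1, P_S) * (1 - eta)^k)
}

# Delta PD at a single positive specific energy.
delta_pd <- function(z, dose = z) {
  specific_energy_pd(dose = dose, zero_mass = 0,
                     atoms = data.frame(z = z, mass = 1))
}

# Published parameter fixtures.
tbl_nt_wi38 <- function(z_thre = "inf") default_nt_params("wi38", z_thre)
tbl_nt_bcl2neo <- function(z_thre = "inf") default_nt_params("bcl2neo", z_thre)
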