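# Targeted-effect survival: double stochastic microdosimetric kinetic (DSMK)
# model with two lesion-yield transforms.
#
# A nucleus is a packing of sub-micron domains. The expected number of lethal
# lesions produced in a cell whose nucleus received specific energy z_n is
#
#   -ln S(z_n) = alpha0 * E[z'_d | z_n] + beta0 * E[z'_d^2 | z_n],
#
# the expectations taken over the domain specific-energy PD f_d(z_d, z_n),
# and z'_d an effective ("lesion-yield") specific energy. The linear term
# counts directly lethal lesions, the quadratic term pairwise interaction of
# sublethal lesions within a domain. Averaging exp over f_n(z_n, D) gives the
# dose response S_T(D). With a degenerate domain PD and no saturation the
# model collapses to the linear-quadratic form exp(-alpha0 z - beta0 z^2).

#' DSMK model parameters for one targeted-effect channel
#'
#' @param alpha0 lethal-lesion sensitivity, 1/Gy (may be negative; published
#'   fits of the conventional channel are slightly negative)
#' @param beta0 sublethal pair-interaction coefficient, 1/Gy^2
#' @param r_d domain radius, um (> 0)
#' @param z0 saturation (method `"saturation"`) or repair-induction (method
#'   `"adaptive"`) specific energy, Gy; `Inf` disables the transform
#' @param r_n nucleus radius, um (>= r_d)
#' @param method lesion-yield transform: `"saturation"` caps the yield at high
#'   specific energy (overkill), `"adaptive"` lets it vanish at high specific
#'   energy (repair-triggered loss of Bcl-2 protection)
#' @return object of class `dsmk_params`
#' @export
dsmk_params <- function(alpha0, beta0, r_d, z0, r_n,
                        method = c("saturation", "adaptive")) {
  method <- match.arg(method)
  assert_scalar_num(alpha0, "alpha0")
  assert_scalar_num(beta0, "beta0")
  assert_scalar_num(r_d, "r_d")
  assert_scalar_num(z0, "z0", allow_inf = TRUE)
  assert_scalar_num(r_n, "r_n")
  if (r_d <= 0) stop_domain("'r_d' must be positive")
  if (z0 <= 0) stop_domain("'z0' must be positive")
  if (r_n < r_d) stop_domain("'r_n' must be >= 'r_d'")
  if (method == "adaptive" && beta0 < 0)
    stop_domain("'beta0' must be non-negative for the adaptive method")
  structure(list(alpha0 = alpha0, beta0 = beta0, r_d = r_d, z0 = z0,
                 r_n = r_n, method = method),
            class = "dsmk_params")
}

#' @export
print.dsmk_params <- function(x, ...) {
  cat(sprintf(
    "<dsmk_params> method %s: alpha0 %.4g /Gy, beta0 %.4g /Gy^2, r_d %.4g um, z0 %.4g Gy, r_n %.4g um\n",
    x$method, x$alpha0, x$beta0, x$r_d, x$z0, x$r_n))
  invisible(x)
}

#' Saturation-corrected effective specific energy
#'
#' `z' = z0 * sqrt(1 - exp(-(z/z0)^2))`. Equals z for z << z0 and saturates
#' at z0 for z >> z0, expressing the declining lesion yield per dose at very
#' high LET (overkill).
#'
#' @param z_d domain specific energy, Gy (vectorized, >= 0)
#' @param z0 saturation parameter, Gy (> 0); `Inf` returns `z_d` unchanged
#' @return effective specific energy, Gy
#' @export
effective_z_saturation <- function(z_d, z0) {
  if (any(z_d < 0)) stop_domain("'z_d' must be non-negative")
  assert_scalar_num(z0, "z0", allow_inf = TRUE)
  if (z0 <= 0) stop_domain("'z0' must be positive")
  if (is.infinite(z0)) return(z_d)
  z0 * sqrt(-expm1(-(z_d / z0)^2))
}

#' Adaptive-response effective lesion yield
#'
#' `z'' = z_d * exp(-z_d / z0)`: lesions triggering the Bcl-2-inhibitable
#' apoptosis channel are produced in proportion to z_d but only count in
#' domains where no repair induction (Poisson mean `z_d / z0`) has occurred,
#' so the yield vanishes at high specific energy and the associated survival
#' tends to one at high LET.
#'
#' @param z_d domain specific energy, Gy (vectorized, >= 0)
#' @param z0 mean specific energy for inducing the repair that disables the
#'   Bcl-2-dependent protection, Gy (> 0); `Inf` returns `z_d`
#' @return effective lesion-yield variable, Gy
#' @export
effective_z_adaptive <- function(z_d, z0) {
  if (any(z_d < 0)) stop_domain("'z_d' must be non-negative")
  assert_scalar_num(z0, "z0", allow_inf = TRUE)
  if (z0 <= 0) stop_domain("'z0' must be positive")
  if (is.infinite(z0)) return(z_d)
  z_d * exp(-z_d / z0)
}

effective_z <- function(z, params) {
  switch(params$method,
         saturation = effective_z_saturation(z, params$z0),
         adaptive = effective_z_adaptive(z, params$z0))
}

#' Survival of a single cell given its nucleus specific energy
#'
#' Quadrature of the DSMK lesion count over a domain specific-energy PD:
#' `S = exp(-alpha0 E[z'] - beta0 E[z'^2])`, truncated at 1 (a negative
#' fitted `alpha0` can otherwise push degenerate inputs above unity).
#'
#' @param domain_pd domain-scale [specific_energy_pd()] conditional on the
#'   nucleus specific energy (see [conditional_domain_pd()])
#' @param params a [dsmk_params()]
#' @return surviving fraction in (0, 1]
#' @export
survival_given_zn <- function(domain_pd, params) {
  stopifnot(inherits(domain_pd, "specific_energy_pd"),
            inherits(params, "dsmk_params"))
  e1 <- pd_expect(domain_pd, function(z) effective_z(z, params))
  e2 <- pd_expect(domain_pd, function(z) effective_z(z, params)^2)
  min(exp(-params$alpha0 * e1 - params$beta0 * e2), 1)
}

# --- fast conditional-moment machinery -------------------------------------
#
# For the dose response we need E[z'|z_n] and E[z'^2|z_n] for every z_n on
# the nucleus grid. Under the compound-Poisson conditional PD these are
# Poisson mixtures of per-convolution moments
#   G_g(nu) = integral g(z) f1^{*nu}(z) dz,
# computed once per (spectrum, z0, method) on a uniform lattice via Parseval
# (G_g(nu) = Re(mean(phi^nu * Conj(fft(g))))), then mixed with dpois weights.

domain_effect_table <- function(spec_domain, params, zn) {
  zn <- as.numeric(zn)
  out <- list(A = numeric(length(zn)), B = numeric(length(zn)))
  pos <- zn > 0
  if (!any(pos)) return(out)
  mom <- spectrum_moments(spec_domain)
  lam_max <- max(zn[pos]) / mom$m1
  lat <- cp_lattice(spec_domain, cp_span(lam_max, mom))
  lambda <- zn[pos] / lat$m1
  lam_max <- max(lambda)
  nu_max <- poisson_truncation(lam_max)

  zp <- effective_z(lat$x, params)
  g1h <- Conj(stats::fft(zp))
  g2h <- Conj(stats::fft(zp^2))
  A <- numeric(sum(pos)); B <- numeric(sum(pos))
  psi <- rep(1 + 0i, lat$M)
  for (nu in seq_len(nu_max)) {
    psi <- psi * lat$phi
    G1 <- Re(sum(psi * g1h)) / lat$M
    G2 <- Re(sum(psi * g2h)) / lat$M
    w <- stats::dpois(nu, lambda)
    A <- A + w * G1
    B <- B + w * G2
  }
  out$A[pos] <- A
  out$B[pos] <- B
  out
}

#' Dose-averaged targeted-effect survival
#'
#' `S_T(D) = E[S(z_n)]` over a nucleus specific-energy PD, with the domain
#' PD conditional on each z_n built as the domain-scale compound-Poisson
#' distribution at mean z_n. The zero mass contributes survival one exactly,
#' so dilute microbeam fields give S_T ~ 1.
#'
#' @param nucleus_pd nucleus-scale [specific_energy_pd()] (broadbeam
#'   multi-event or microbeam two-point)
#' @param domain_spec domain-scale [single_event_spectrum()]
#' @param params a [dsmk_params()]
#' @return surviving fraction in (0, 1]
#' @export
survival_vs_dose <- function(nucleus_pd, domain_spec, params) {
  stopifnot(inherits(nucleus_pd, "specific_energy_pd"),
            inherits(domain_spec, "single_event_spectrum"),
            inherits(params, "dsmk_params"))
  s <- nucleus_pd$zero_mass
  zn_atoms <- nucleus_pd$atoms$z
  g <- nucleus_pd$grid
  # drop grid nodes carrying negligible probability before the heavy step
  keep <- logical(0)
  if (length(g) >= 2L) {
    w <- c(diff(g) / 2, 0) + c(0, diff(g) / 2)
    node_mass <- w * nucleus_pd$density
    tail_mass <- rev(cumsum(rev(node_mass)))
    keep <- tail_mass > 1e-13
  }
  zn_all <- c(zn_atoms, g[keep])
  if (length(zn_all)) {
    tab <- domain_effect_table(domain_spec, params, zn_all)
    surv <- pmin(exp(-params$alpha0 * tab$A - params$beta0 * tab$B), 1)
    n_at <- length(zn_atoms)
    if (n_at) s <- s + sum(nucleus_pd$atoms$mass * surv[seq_len(n_at)])
    if (any(keep)) {
      sg <- numeric(length(g))
      sg[keep] <- if (n_at) surv[-seq_len(n_at)] else surv
      s <- s + trapz(g, nucleus_pd$density * sg)
    }
  }
  min(s, 1)
}

#' Mix the Bcl-2 and conventional targeted channels over a cell population
#'
#' A fraction `x` of cells overexpresses Bcl-2 and is protected from the
#' apoptotic channel (survival `S_C`); the remaining `1 - x` is additionally
#' subject to it (survival `S_C * S_B`). The population survival is the
#' cell-number-weighted mean `x * S_C + (1 - x) * S_C * S_B`, with endpoints
#' `S_C` at x = 1 and `S_C * S_B` at x = 0.
#'
#' @param S_C conventional targeted-effect survival, in \[0, 1\] (vectorized)
#' @param S_B Bcl-2-channel survival, in \[0, 1\] (vectorized)
#' @param x fraction of Bcl-2 overexpressing cells, in \[0, 1\]
#' @return population targeted-effect survival
#' @export
bcl2_mixture <- function(S_C, S_B, x) {
  if (any(S_C < 0 | S_C > 1)) stop_domain("'S_C' must be in [0, 1]")
  if (any(S_B < 0 | S_B > 1)) stop_domain("'S_B' must be in [0, 1]")
  if (any(x < 0 | x > 1)) stop_domain("'x' must be in [0, 1]")
  x * S_C + (1 - x) * S_C * S_B
}
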