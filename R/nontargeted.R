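# Nontargeted (bystander) survival channel.
#
# Irradiated cells turn into apoptotic-signal emitters with a probability
# that rises steeply with their nucleus specific energy; signals propagate
# through the whole population; a cell that receives at least one signal is
# inactivated with probability kappa, but only if its own nucleus specific
# energy is below a threshold above which it is insensitive to the signal.

#' Nontargeted-effect model parameters
#'
#' @param a1 trigger-probability scale (z_n entered in Gy)
#' @param a2 trigger-probability power index (> 0)
#' @param eta fraction of cells receiving a signal from one emitting cell,
#'   in \[0, 1\]
#' @param kappa fraction of signal-receiving (below-threshold) cells that are
#'   actually inactivated, in \[0, 1\]
#' @param z_thre threshold nucleus specific energy above which a cell ignores
#'   apoptotic signals, Gy; `Inf` means no such self-protection
#' @param n_population number of cells in the whole population N_W (>= 1)
#' @return object of class `nt_params`
#' @export
nt_params <- function(a1, a2, eta, kappa, z_thre = Inf, n_population) {
  assert_scalar_num(a1, "a1", lower = 0)
  assert_scalar_num(a2, "a2")
  if (a2 <= 0) stop_domain("'a2' must be positive")
  assert_scalar_num(eta, "eta")
  assert_scalar_num(kappa, "kappa")
  if (eta < 0 || eta > 1) stop_domain("'eta' must be in [0, 1]")
  if (kappa < 0 || kappa > 1) stop_domain("'kappa' must be in [0, 1]")
  assert_scalar_num(z_thre, "z_thre", allow_inf = TRUE)
  if (z_thre <= 0) stop_domain("'z_thre' must be positive (or Inf)")
  assert_scalar_num(n_population, "n_population", lower = 1)
  structure(list(a1 = a1, a2 = a2, eta = eta, kappa = kappa,
                 z_thre = z_thre, n_population = n_population),
            class = "nt_params")
}

#' @export
print.nt_params <- function(x, ...) {
  cat(sprintf(
    "<nt_params> a1 %.4g, a2 %.4g, eta %.4g, kappa %.4g, z_thre %s Gy, N_W %.4g\n",
    x$a1, x$a2, x$eta, x$kappa,
    if (is.infinite(x$z_thre)) "Inf" else format(x$z_thre), x$n_population))
  invisible(x)
}

#' Trigger probability of becoming a signal-emitting cell
#'
#' `P_T(z_n) = 1 - exp(-a1 * z_n^a2)`: zero at z_n = 0, non-decreasing, and
#' bounded by one. The free power index a2 lets the probability switch on
#' steeply at a characteristic specific energy `a1^(-1/a2)`.
#'
#' @param z_n nucleus specific energy, Gy (vectorized, >= 0)
#' @param params an [nt_params()]
#' @return probability in \[0, 1\]
#' @export
trigger_probability <- function(z_n, params) {
  stopifnot(inherits(params, "nt_params"))
  if (any(z_n < 0)) stop_domain("'z_n' must be non-negative")
  -expm1(-params$a1 * z_n^params$a2)
}

#' Fraction of signal-emitting cells in a radiation field
#'
#' `P_S(D) = E[P_T(z_n)]` over the nucleus specific-energy PD of the field;
#' the zero mass contributes nothing since `P_T(0) = 0`. For a microbeam
#' two-point field this reduces to `(N_I/N_W) * P_T(D_I)`.
#'
#' @param nucleus_pd nucleus-scale [specific_energy_pd()]
#' @param params an [nt_params()]
#' @return probability in \[0, 1\]
#' @export
signal_fraction <- function(nucleus_pd, params) {
  stopifnot(inherits(nucleus_pd, "specific_energy_pd"))
  min(max(pd_expect(nucleus_pd, function(z) trigger_probability(z, params)), 0), 1)
}

#' Probability of escaping every emitted signal
#'
#' Each of the other `N_W - 1` cells is an emitter with probability `P_S` and,
#' if so, reaches the cell in question with probability `eta`; summing the
#' binomial probabilities of receiving no signal gives the closed form
#' `P_E = (1 - eta * P_S)^(N_W - 1)`, evaluated as
#' `exp((N_W - 1) * log1p(-eta * P_S))` to stay accurate for populations of
#' millions of cells.
#'
#' @param P_S signal-emitting fraction, in \[0, 1\]
#' @param params an [nt_params()]
#' @return escape probability in \[0, 1\]
#' @export
escape_probability <- function(P_S, params) {
  stopifnot(inherits(params, "nt_params"))
  if (any(P_S < 0 | P_S > 1)) stop_domain("'P_S' must be in [0, 1]")
  q <- params$eta * P_S
  ifelse(q >= 1, 0, exp((params$n_population - 1) * log1p(-q)))
}

#' Nontargeted-effect surviving fraction
#'
#' `S_NT(D) = 1 - kappa * (1 - P_E(D)) * P(z_n < z_thre)`: the probability of
#' receiving at least one signal, times the inactivation probability kappa,
#' acting only on the subpopulation still below the sensitivity threshold.
#' The below-threshold factor is the synergy correction between targeted and
#' nontargeted effects; with `z_thre = Inf` it is one and S_NT is bounded
#' below by `1 - kappa`.
#'
#' @param nucleus_pd nucleus-scale [specific_energy_pd()]
#' @param params an [nt_params()]
#' @return surviving fraction in \[1 - kappa, 1\]
#' @export
survival_nt <- function(nucleus_pd, params) {
  stopifnot(inherits(nucleus_pd, "specific_energy_pd"),
            inherits(params, "nt_params"))
  P_S <- signal_fraction(nucleus_pd, params)
  P_E <- escape_probability(P_S, params)
  below <- pd_mass_below(nucleus_pd, params$z_thre)
  1 - params$kappa * (1 - P_E) * below
}
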