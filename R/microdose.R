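# Probability densities of specific energy at the domain and nucleus scales.
#
# The central object is the multi-event distribution f(z; D) of specific
# energy z accumulated in a site after irradiation with mean absorbed dose D.
# Under the usual microdosimetric assumptions the number of energy-deposition
# events is Poisson with mean lambda = D / zbar_F (zbar_F the frequency-mean
# specific energy per event), so f(z; D) is a compound-Poisson mixture of
# nu-fold self-convolutions of the single-event density, with a discrete
# probability exp(-lambda) of exactly zero specific energy.

# ICRU unit-density sphere: z [Gy] = 0.204 * y [keV/um] / d^2 [um^2],
# from z = energy / mass with mean chord length 2d/3.
.z_per_y <- 0.204

#' Convert lineal energy to specific energy for a unit-density sphere
#'
#' For a sphere of diameter `d` (unit density, mean chord length 2d/3) a
#' single event of lineal energy `y` deposits the specific energy
#' `z = 0.204 * y / d^2` with `z` in Gy, `y` in keV/um and `d` in um.
#'
#' @param y lineal energy, keV/um (vectorized, must be >= 0)
#' @param diameter sphere diameter, um (> 0)
#' @return specific energy, Gy
#' @seealso [specific_to_lineal()] for the inverse
#' @export
#' @examples
#' lineal_to_specific(1, 1)      # 0.204 Gy
#' specific_to_lineal(2.51, 0.6) # ~4.43 keV/um
lineal_to_specific <- function(y, diameter) {
  assert_scalar_num(diameter, "diameter")
  if (diameter <= 0) stop_domain("'diameter' must be positive")
  if (any(y < 0)) stop_domain("'y' must be non-negative")
  .z_per_y * y / diameter^2
}

#' Convert specific energy to lineal energy for a unit-density sphere
#'
#' Inverse of [lineal_to_specific()].
#'
#' @param z specific energy, Gy (vectorized, must be >= 0)
#' @param diameter sphere diameter, um (> 0)
#' @return lineal energy, keV/um
#' @export
specific_to_lineal <- function(z, diameter) {
  assert_scalar_num(diameter, "diameter")
  if (diameter <= 0) stop_domain("'diameter' must be positive")
  if (any(z < 0)) stop_domain("'z' must be non-negative")
  z * diameter^2 / .z_per_y
}

#' Single-event specific-energy spectrum
#'
#' The probability density of specific energy imparted to a microscopic site
#' (domain or cell nucleus) by exactly one energy-deposition event. The
#' density lives on a strictly increasing grid of z values and integrates to
#' one; its first moment is the frequency-mean specific energy per event,
#' `zbar_F`, which sets the mean event count `dose / zbar_F` of multi-event
#' distributions built from it.
#'
#' @param site_radius site radius, um (> 0)
#' @param grid strictly increasing specific-energy values, Gy
#' @param density per-Gy probability density on `grid` (>= 0, integrates to 1)
#' @param zbar_F frequency-mean specific energy, Gy; defaults to the first
#'   moment of `density`
#' @param label optional radiation-quality label
#' @return object of class `single_event_spectrum`
#' @export
single_event_spectrum <- function(site_radius, grid, density, zbar_F = NULL,
                                  label = NULL) {
  assert_scalar_num(site_radius, "site_radius")
  if (site_radius <= 0) stop_domain("'site_radius' must be positive")
  grid <- as.numeric(grid); density <- as.numeric(density)
  if (length(grid) < 2L || length(grid) != length(density))
    stop_domain("'grid' and 'density' must be equal-length vectors (>= 2)")
  if (any(diff(grid) <= 0)) stop_domain("'grid' must be strictly increasing")
  if (any(grid <= 0)) stop_domain("'grid' values must be positive")
  if (any(density < 0)) stop_domain("'density' must be non-negative")
  tot <- trapz(grid, density)
  if (abs(tot - 1) > 1e-6)
    stop_domain(sprintf("single-event density must integrate to 1 (got %.8f)", tot))
  m1 <- trapz(grid, grid * density)
  if (is.null(zbar_F)) zbar_F <- m1
  if (abs(m1 - zbar_F) > 1e-4 * zbar_F)
    stop_domain(sprintf(
      "first moment of density (%.6g Gy) does not match zbar_F (%.6g Gy)", m1, zbar_F))
  structure(list(site_radius = site_radius, zbar_F = zbar_F,
                 grid = grid, density = density, label = label),
            class = "single_event_spectrum")
}

#' @export
print.single_event_spectrum <- function(x, ...) {
  cat(sprintf(
    "<single_event_spectrum>%s site radius %.4g um, zbar_F %.4g Gy, %d grid points on [%.3g, %.3g] Gy\n",
    if (is.null(x$label)) "" else paste0(" ", x$label, ":"),
    x$site_radius, x$zbar_F, length(x$grid), min(x$grid), max(x$grid)))
  invisible(x)
}

#' Rescale a single-event spectrum to a different site radius
#'
#' Specific energy scales as 1/d^2 at fixed event size (lineal energy), so a
#' spectrum computed for one site radius can be mapped to another by scaling
#' the z axis by `(radius_old / radius_new)^2`. This ignores any change of
#' track-structure shape with site size and is used when the site radius is a
#' fit parameter.
#'
#' @param spec a [single_event_spectrum()]
#' @param site_radius new site radius, um
#' @return a rescaled `single_event_spectrum`
#' @export
scale_spectrum <- function(spec, site_radius) {
  stopifnot(inherits(spec, "single_event_spectrum"))
  assert_scalar_num(site_radius, "site_radius")
  if (site_radius <= 0) stop_domain("'site_radius' must be positive")
  s <- (spec$site_radius / site_radius)^2
  single_event_spectrum(site_radius = site_radius,
                        grid = spec$grid * s, density = spec$density / s,
                        zbar_F = spec$zbar_F * s, label = spec$label)
}

# First/second moments and an effective (1 - eps quantile) upper support.
spectrum_moments <- function(spec, eps = 1e-9) {
  g <- spec$grid; f <- spec$density
  m1 <- trapz(g, g * f)
  m2 <- trapz(g, g^2 * f)
  cdf <- cumtrapz(g, f)
  i <- which(cdf >= (1 - eps) * cdf[length(cdf)])[1]
  list(m1 = m1, m2 = m2, sd = sqrt(max(m2 - m1^2, 0)), zmax = g[i])
}

#' Multi-event specific-energy probability density
#'
#' Container for the distribution of specific energy z in a site for mean
#' absorbed dose `dose`: a discrete probability `zero_mass` at z = 0, optional
#' discrete atoms at z > 0 (microbeam fields), and a continuous per-Gy
#' density on `grid`. The masses must total one.
#'
#' @param dose mean absorbed dose, Gy
#' @param zero_mass probability of exactly zero specific energy
#' @param grid strictly increasing z values, Gy (may be empty)
#' @param density per-Gy density on `grid`
#' @param atoms optional `data.frame(z, mass)` of discrete masses at z > 0
#' @return object of class `specific_energy_pd`
#' @export
specific_energy_pd <- function(dose, zero_mass, grid = numeric(),
                               density = numeric(), atoms = NULL) {
  assert_scalar_num(dose, "dose")
  if (dose < 0) stop_domain("'dose' must be non-negative")
  assert_scalar_num(zero_mass, "zero_mass")
  if (zero_mass < 0 || zero_mass > 1) stop_domain("'zero_mass' must be in [0, 1]")
  grid <- as.numeric(grid); density <- as.numeric(density)
  if (length(grid) != length(density))
    stop_domain("'grid' and 'density' must have equal length")
  if (length(grid) > 1L && any(diff(grid) <= 0))
    stop_domain("'grid' must be strictly increasing")
  if (any(density < 0)) stop_domain("'density' must be non-negative")
  if (is.null(atoms)) atoms <- data.frame(z = numeric(), mass = numeric())
  if (!all(c("z", "mass") %in% names(atoms)))
    stop_domain("'atoms' must have columns 'z' and 'mass'")
  if (any(atoms$z <= 0) || any(atoms$mass < 0))
    stop_domain("'atoms' must have z > 0 and mass >= 0")
  tot <- zero_mass + sum(atoms$mass) +
    if (length(grid) >= 2L) trapz(grid, density) else 0
  if (abs(tot - 1) > 1e-6)
    stop_domain(sprintf("PD masses must total 1 (got %.8f)", tot))
  structure(list(dose = dose, zero_mass = zero_mass, grid = grid,
                 density = density, atoms = atoms),
            class = "specific_energy_pd")
}

#' @export
print.specific_energy_pd <- function(x, ...) {
  cat(sprintf(
    "<specific_energy_pd> dose %.4g Gy, P(z = 0) = %.4g, %d atom(s), %d grid points\n",
    x$dose, x$zero_mass, nrow(x$atoms), length(x$grid)))
  invisible(x)
}

#' Expectation of a function under a specific-energy PD
#'
#' Computes `E[g(z)]` with the zero mass contributing `g(0)`, atoms summed
#' exactly and the continuous part integrated by the trapezoidal rule.
#'
#' @param pd a [specific_energy_pd()]
#' @param g vectorized function of z
#' @return numeric scalar
#' @export
pd_expect <- function(pd, g) {
  stopifnot(inherits(pd, "specific_energy_pd"))
  val <- pd$zero_mass * g(0)
  if (nrow(pd$atoms)) val <- val + sum(pd$atoms$mass * g(pd$atoms$z))
  if (length(pd$grid) >= 2L)
    val <- val + trapz(pd$grid, pd$density * g(pd$grid))
  val
}

#' Mean of a specific-energy PD
#' @param pd a [specific_energy_pd()]
#' @return mean specific energy, Gy
#' @export
pd_mean <- function(pd) pd_expect(pd, identity)

# Probability mass at z < z_thre (zero mass counts as below any positive
# threshold; the continuous part is cut with a linearly interpolated bin).
pd_mass_below <- function(pd, z_thre) {
  stopifnot(inherits(pd, "specific_energy_pd"))
  if (is.infinite(z_thre)) return(1)
  if (z_thre <= 0) return(0)
  val <- pd$zero_mass
  if (nrow(pd$atoms)) val <- val + sum(pd$atoms$mass[pd$atoms$z < z_thre])
  g <- pd$grid
  if (length(g) >= 2L && z_thre > g[1]) {
    if (z_thre >= g[length(g)]) {
      val <- val + trapz(g, pd$density)
    } else {
      keep <- g < z_thre
      gi <- c(g[keep], z_thre)
      di <- c(pd$density[keep], stats::approx(g, pd$density, z_thre)$y)
      val <- val + trapz(gi, di)
    }
  }
  min(val, 1)
}

# --- compound-Poisson machinery -------------------------------------------

# Uniform lattice discretization of a single-event spectrum, sized so that
# (a) the lattice spans z_total and (b) the single-event shape is resolved.
# Returns lattice abscissae x, step h, single-event probabilities p1 (sum 1)
# and their DFT phi.
cp_lattice <- function(spec, z_total, m_min = 2^12, m_max = 2^20) {
  mom <- spectrum_moments(spec)
  width <- max(min(mom$m1, if (mom$sd > 0) mom$sd else mom$m1), .Machine$double.xmin)
  h_target <- width / 64
  M <- 2^ceiling(log2(max(z_total / h_target, m_min)))
  M <- min(max(M, m_min), m_max)
  h <- z_total / M
  x <- (seq_len(M) - 1) * h
  # bin-integrated single-event masses: exact mass preservation per bin,
  # robust for densities that are steep near z = 0
  Fg <- cumtrapz(spec$grid, spec$density)
  edges <- pmax(c(x - h / 2, x[M] + h / 2), 0)
  Fe <- stats::approx(c(0, spec$grid), c(0, Fg), edges, yleft = 0,
                      yright = Fg[length(Fg)])$y
  p1 <- pmax(diff(Fe), 0)
  s <- sum(p1)
  if (s <= 0) stop_domain("single-event spectrum is not resolvable on the convolution lattice")
  p1 <- p1 / s
  list(x = x, h = h, M = M, p1 = p1, phi = stats::fft(p1),
       m1 = sum(x * p1))
}

# Total lattice span needed for the compound-Poisson distribution at event
# mean lambda: the lesser of the truncated-sum support and a mean + 15 sd
# Gaussian-type bound, padded with a few single-event supports.
cp_span <- function(lambda, mom) {
  nmax <- poisson_truncation(max(lambda, 1e-12))
  hard <- (nmax + 1) * mom$zmax
  soft <- lambda * mom$m1 + 15 * sqrt(max(lambda, 1) * mom$m2) + 3 * mom$zmax
  max(min(hard, soft), 2 * mom$zmax)
}

#' Multi-event PD by compound-Poisson convolution of a single-event spectrum
#'
#' Builds `f(z; D) = sum_nu P(nu; lambda) f1^{*nu}(z)` with Poisson event
#' count of mean `lambda = dose / zbar_F`. The zero-event probability
#' `exp(-lambda)` is kept as an exact discrete mass at z = 0; the continuous
#' part is computed by FFT on a uniform auxiliary lattice (equivalent to the
#' nu-term convolution sum truncated at cumulative Poisson mass 1 - 1e-9) and
#' resampled onto a geometric output grid.
#'
#' @param spec a [single_event_spectrum()]
#' @param dose mean absorbed dose, Gy (>= 0)
#' @param n_grid base number of output grid points (increased automatically
#'   when the many-event distribution is narrow relative to the grid)
#' @return a [specific_energy_pd()] with mean equal to `dose`
#' @export
#' @examples
#' sp <- make_spectrum(let = 100, site_radius = 0.3)
#' pd <- multi_event_pd(sp, dose = 2)
#' pd_mean(pd)  # ~2 Gy
multi_event_pd <- function(spec, dose, n_grid = 1024) {
  stopifnot(inherits(spec, "single_event_spectrum"))
  assert_scalar_num(dose, "dose")
  if (dose < 0) stop_domain("'dose' must be non-negative")
  if (dose == 0)
    return(specific_energy_pd(dose = 0, zero_mass = 1))

  mom <- spectrum_moments(spec)
  lambda0 <- dose / spec$zbar_F
  lat <- cp_lattice(spec, cp_span(lambda0, mom))
  # use the lattice first moment so that the compound mean is exactly `dose`
  lambda <- dose / lat$m1
  zero_mass <- exp(-lambda)

  # split off the zero- and one-event terms analytically; the FFT lattice
  # only carries the smooth nu >= 2 remainder (which vanishes towards z = 0,
  # so the lattice resolution there is uncritical)
  w1 <- lambda * zero_mass
  rest_hat <- exp(lambda * (lat$phi - 1)) - zero_mass * (1 + lambda * lat$phi)
  q2 <- Re(stats::fft(rest_hat, inverse = TRUE)) / lat$M
  q2[q2 < 0] <- 0

  # geometric output grid per the low-dose/high-LET span convention,
  # augmented with the spectrum grid (resolves the one-event term) and the
  # carrying lattice points (resolves structure narrower than the geometric
  # spacing, e.g. narrow many-event bulks at high event counts)
  z_lo <- spec$zbar_F / 1e3
  z_hi <- max(50 * dose, 50 * spec$zbar_F)
  zg <- geom_grid(z_lo, z_hi, n_grid)
  sig <- which(q2 > max(q2) * 1e-8 & lat$x > 0)
  if (length(sig)) {
    take <- sig[unique(round(seq(1, length(sig),
                                 length.out = min(length(sig), 12 * 1024))))]
    zg <- c(zg, lat$x[take])
  }
  if (w1 > 1e-15) zg <- c(zg, spec$grid)
  zg <- sort(unique(zg))
  zg <- zg[zg >= z_lo / 2 & zg <= z_hi]

  d1 <- stats::approx(spec$grid, spec$density, zg, yleft = 0, yright = 0)$y
  d1[is.na(d1)] <- 0
  d2 <- stats::approx(lat$x, q2 / lat$h, zg, yleft = 0, yright = 0)$y
  d2[is.na(d2)] <- 0
  dens <- w1 * d1 + d2
  tot <- trapz(zg, dens)
  if (tot <= 0)
    stop_domain("multi-event PD lost all continuous mass during resampling")
  dens <- dens * (1 - zero_mass) / tot
  specific_energy_pd(dose = dose, zero_mass = zero_mass, grid = zg,
                     density = dens)
}

#' Microbeam irradiation design
#'
#' `n_irradiated` cells out of a population of `n_population` each receive
#' mean nucleus dose `dose_per_cell`; the rest receive nothing.
#'
#' @param n_irradiated number of targeted cells N_I (0 <= N_I <= N_W)
#' @param n_population total number of cells N_W (>= 1)
#' @param dose_per_cell mean absorbed dose per targeted cell, Gy (>= 0)
#' @return object of class `microbeam_design`
#' @export
microbeam_design <- function(n_irradiated, n_population, dose_per_cell) {
  assert_scalar_num(n_irradiated, "n_irradiated", lower = 0)
  assert_scalar_num(n_population, "n_population", lower = 1)
  assert_scalar_num(dose_per_cell, "dose_per_cell", lower = 0)
  if (n_irradiated > n_population)
    stop_domain("'n_irradiated' cannot exceed 'n_population'")
  structure(list(n_irradiated = n_irradiated, n_population = n_population,
                 dose_per_cell = dose_per_cell),
            class = "microbeam_design")
}

#' Nucleus specific-energy PD for a microbeam field
#'
#' Two-point distribution: probability `N_I/N_W` of specific energy
#' `dose_per_cell` (all targeted cells receive exactly their mean dose; the
#' event-number spread within targeted cells is neglected because the particle
#' count per cell is controlled) and probability `1 - N_I/N_W` of zero.
#'
#' @param design a [microbeam_design()]
#' @return a [specific_energy_pd()]
#' @export
microbeam_pd <- function(design) {
  stopifnot(inherits(design, "microbeam_design"))
  frac <- design$n_irradiated / design$n_population
  dose <- frac * design$dose_per_cell
  if (frac == 0 || design$dose_per_cell == 0)
    return(specific_energy_pd(dose = 0, zero_mass = 1))
  specific_energy_pd(dose = dose, zero_mass = 1 - frac,
                     atoms = data.frame(z = design$dose_per_cell, mass = frac))
}

#' Domain specific-energy PD conditional on the nucleus specific energy
#'
#' Approximates the distribution of domain specific energy z_d given that the
#' surrounding nucleus received z_n, as the domain-scale compound-Poisson
#' multi-event PD with mean dose z_n (event mean `z_n / zbar_F` of the domain
#' single-event spectrum). This replaces the track-structure database used to
#' tabulate the conditional PD in full transport calculations; it preserves
#' the conditional mean and the event-count statistics of the domain scale.
#'
#' @param spec_domain domain-scale [single_event_spectrum()]
#' @param z_n nucleus specific energy, Gy (>= 0)
#' @param ... passed to [multi_event_pd()]
#' @return a [specific_energy_pd()] with mean `z_n`
#' @export
conditional_domain_pd <- function(spec_domain, z_n, ...) {
  assert_scalar_num(z_n, "z_n")
  if (z_n < 0) stop_domain("'z_n' must be non-negative")
  multi_event_pd(spec_domain, dose = z_n, ...)
}
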