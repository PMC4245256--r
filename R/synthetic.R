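# Synthetic inputs with known ground truth: moment-matched single-event
# spectra standing in for transport-code microdosimetry, irradiation designs
# emulating the published microbeam/broadbeam experiments, and noisy survival
# datasets for parameter-recovery studies.

#' Moment-matched synthetic single-event spectrum
#'
#' Gamma-shaped stand-in for a transport-calculated single-event
#' specific-energy spectrum. The frequency mean is set by the ICRU sphere
#' relation `zbar_F = 0.204 * let / (2 * site_radius)^2` (the frequency-mean
#' lineal energy is approximated by the LET), and the shape by the requested
#' dose-mean to frequency-mean ratio `zd_to_zf = zbar_D / zbar_F`, which
#' controls the relative event-size straggling. The two matched moments are
#' what drive the microdosimetric-kinetic family of responses.
#'
#' @param let linear energy transfer, keV/um (> 0)
#' @param site_radius site radius, um (> 0)
#' @param zd_to_zf dose-mean to frequency-mean specific-energy ratio (> 1);
#'   the default 2 is an exponential event-size distribution
#' @param n_grid number of geometric grid points
#' @param label optional radiation label
#' @return a [single_event_spectrum()]
#' @export
#' @examples
#' make_spectrum(let = 1, site_radius = 0.5)$zbar_F  # ~0.204 Gy
make_spectrum <- function(let, site_radius, zd_to_zf = 2, n_grid = 1024,
                          label = NULL) {
  assert_scalar_num(let, "let")
  assert_scalar_num(site_radius, "site_radius")
  if (let <= 0) stop_domain("'let' must be positive")
  if (site_radius <= 0) stop_domain("'site_radius' must be positive")
  assert_scalar_num(zd_to_zf, "zd_to_zf")
  if (zd_to_zf <= 1) stop_domain("'zd_to_zf' must exceed 1")
  zbar <- lineal_to_specific(let, 2 * site_radius)
  theta <- zbar * (zd_to_zf - 1)
  shape <- zbar / theta
  z_hi <- max(50 * zbar, stats::qgamma(1 - 1e-12, shape = shape, scale = theta))
  grid <- geom_grid(zbar / 1e3, z_hi, n_grid)
  dens <- stats::dgamma(grid, shape = shape, scale = theta)
  dens <- dens / trapz(grid, dens)
  single_event_spectrum(site_radius = site_radius, grid = grid, density = dens,
                        label = label)
}

#' Irradiation study design for the synthetic-data generator
#'
#' Describes one series of irradiation conditions for a single radiation
#' quality: a broadbeam dose schedule, or a microbeam schedule of targeted
#' cell counts and per-cell doses, plus a multiplicative lognormal noise
#' level and a seed.
#'
#' @param kind `"broadbeam"` or `"microbeam"`
#' @param radiation radiation label
#' @param let LET, keV/um
#' @param doses broadbeam dose schedule, Gy
#' @param n_irradiated microbeam targeted-cell counts (recycled against
#'   `dose_per_cell`)
#' @param dose_per_cell microbeam per-cell doses, Gy
#' @param n_population microbeam population size N_W
#' @param replicates independent replicate measurements per condition (>= 1)
#' @param sigma lognormal noise sigma on the surviving fraction (>= 0)
#' @param seed integer seed; fixed seed gives identical output
#' @return object of class `study_design`
#' @export
study_design <- function(kind = c("broadbeam", "microbeam"), radiation, let,
                         doses = NULL, n_irradiated = NULL,
                         dose_per_cell = NULL, n_population = NULL,
                         replicates = 1, sigma = 0.03, seed = NULL) {
  kind <- match.arg(kind)
  assert_scalar_num(let, "let")
  if (let <= 0) stop_domain("'let' must be positive")
  assert_scalar_num(replicates, "replicates", lower = 1)
  assert_scalar_num(sigma, "sigma", lower = 0)
  if (kind == "broadbeam") {
    if (is.null(doses) || !length(doses) || any(doses < 0))
      stop_domain("broadbeam design needs a non-empty, non-negative 'doses' schedule")
  } else {
    if (is.null(n_irradiated) || is.null(dose_per_cell) || is.null(n_population))
      stop_domain("microbeam design needs 'n_irradiated', 'dose_per_cell' and 'n_population'")
    n <- max(length(n_irradiated), length(dose_per_cell))
    n_irradiated <- rep_len(n_irradiated, n)
    dose_per_cell <- rep_len(dose_per_cell, n)
    if (any(n_irradiated < 0) || any(n_irradiated > n_population))
      stop_domain("'n_irradiated' must be in [0, n_population]")
    if (any(dose_per_cell < 0)) stop_domain("'dose_per_cell' must be non-negative")
  }
  structure(list(kind = kind, radiation = radiation, let = let, doses = doses,
                 n_irradiated = n_irradiated, dose_per_cell = dose_per_cell,
                 n_population = n_population,
                 replicates = as.integer(replicates), sigma = sigma,
                 seed = seed),
            class = "study_design")
}

#' Generate a noisy synthetic survival dataset from a model
#'
#' Evaluates the full model assembly at every condition of a [study_design()],
#' then multiplies the noise-free surviving fractions by lognormal noise
#' `exp(N(0, sigma^2))`. The reported uncertainty column is `sigma * sf`.
#' Ground truth (the model and the noise-free SF) is attached as attribute
#' `"truth"`.
#'
#' @param model a [cell_system_model()]
#' @param design a [study_design()]
#' @return `data.frame` with columns `condition_id`, `radiation`,
#'   `let_keV_um`, `dose_Gy`, `sf`, `sf_err` and, for microbeam designs,
#'   `n_irradiated`, `n_population`, `dose_per_cell_Gy`
#' @export
make_survival_dataset <- function(model, design) {
  stopifnot(inherits(model, "cell_system_model"),
            inherits(design, "study_design"))
  if (design$kind == "broadbeam") {
    fields <- lapply(design$doses, function(d)
      radiation_field(let = design$let, dose = d))
    dose <- design$doses
    extra <- NULL
  } else {
    fields <- mapply(function(ni, di)
      radiation_field(let = design$let,
                      design = microbeam_design(ni, design$n_population, di)),
      design$n_irradiated, design$dose_per_cell, SIMPLIFY = FALSE)
    dose <- design$n_irradiated * design$dose_per_cell / design$n_population
    extra <- data.frame(n_irradiated = design$n_irradiated,
                        n_population = design$n_population,
                        dose_per_cell_Gy = design$dose_per_cell)
  }
  sf_true <- vapply(fields, function(f) total_survival(model, f), numeric(1))
  rep_n <- design$replicates
  idx <- rep(seq_along(sf_true), each = rep_n)
  sf_true_r <- sf_true[idx]
  noise <- with_seed(design$seed,
                     exp(stats::rnorm(length(sf_true_r), 0, design$sigma)))
  sf <- sf_true_r * noise
  id <- sprintf("%s_%02d", design$radiation, idx)
  if (rep_n > 1L)
    id <- paste0(id, sprintf("_r%d", rep(seq_len(rep_n),
                                         times = length(sf_true))))
  out <- data.frame(condition_id = id, radiation = design$radiation,
                    let_keV_um = design$let, dose_Gy = dose[idx], sf = sf,
                    sf_err = design$sigma * sf, stringsAsFactors = FALSE)
  if (!is.null(extra)) out <- cbind(out, extra[idx, , drop = FALSE])
  rownames(out) <- NULL
  attr(out, "truth") <- list(model = model, sf_true = sf_true_r,
                             sigma = design$sigma, seed = design$seed)
  out
}
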