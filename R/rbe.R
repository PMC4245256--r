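# RBE-weighted dose: convert model survival into the iso-survival photon
# dose on a tabulated reference photon dose-response curve.

#' Reference photon dose-response curve
#'
#' Tabulates survival on a dose grid and extracts the invertible branch: the
#' strictly decreasing high-dose tail. A low-dose non-monotone region (the
#' bystander-driven hypersensitivity dip) is excised, because an iso-survival
#' dose is ill-defined there; inversion requests falling outside the branch
#' raise an error stating the attainable bounds.
#'
#' @param doses increasing dose grid, Gy
#' @param survival surviving fractions on `doses`, in (0, 1]
#' @return object of class `reference_curve`
#' @export
reference_curve <- function(doses, survival) {
  doses <- as.numeric(doses); survival <- as.numeric(survival)
  if (length(doses) < 4L || length(doses) != length(survival))
    stop_domain("need matching dose/survival vectors of length >= 4")
  if (any(diff(doses) <= 0)) stop_domain("'doses' must be strictly increasing")
  if (any(survival <= 0 | survival > 1))
    stop_domain("'survival' must be in (0, 1]")
  # strictly decreasing suffix: drop any point not above all later survivals
  n <- length(survival)
  cmax <- rev(cummax(rev(survival)))
  keep <- c(survival[-n] > cmax[-1], TRUE)
  if (sum(keep) < 4L)
    stop_domain("dose grid too narrow: no usable monotone branch")
  structure(list(doses = doses, survival = survival,
                 branch_doses = doses[keep], branch_survival = survival[keep],
                 spline = stats::splinefun(doses[keep], log(survival[keep]),
                                           method = "hyman")),
            class = "reference_curve")
}

#' @export
print.reference_curve <- function(x, ...) {
  cat(sprintf(
    "<reference_curve> %d points, invertible branch [%.3g, %.3g] Gy, SF [%.3g, %.3g]\n",
    length(x$doses), min(x$branch_doses), max(x$branch_doses),
    min(x$branch_survival), max(x$branch_survival)))
  invisible(x)
}

#' Build a photon reference curve from the model assembly
#'
#' Evaluates [total_survival()] for a broadbeam photon-like field on a dose
#' grid and wraps the result in a [reference_curve()].
#'
#' @param model a [cell_system_model()]
#' @param dose_grid increasing dose grid, Gy
#' @param photon_let LET of the reference photon radiation, keV/um
#' @param spectra optional spectra overrides (see [radiation_field()])
#' @return a [reference_curve()]
#' @export
build_reference <- function(model, dose_grid, photon_let = 2, spectra = NULL) {
  sf <- vapply(dose_grid, function(d)
    total_survival(model, radiation_field(let = photon_let, dose = d,
                                          spectra = spectra)),
    numeric(1))
  reference_curve(dose_grid, sf)
}

#' Evaluate the reference curve at given photon doses
#'
#' Interpolates log-survival on the monotone branch with a monotone cubic
#' spline (exact on linear-quadratic curves).
#'
#' @param ref a [reference_curve()]
#' @param dose photon doses within the branch, Gy (vectorized)
#' @return surviving fractions
#' @export
reference_survival <- function(ref, dose) {
  stopifnot(inherits(ref, "reference_curve"))
  lo <- min(ref$branch_doses); hi <- max(ref$branch_doses)
  if (any(dose < lo | dose > hi))
    stop_domain(sprintf("dose outside the invertible branch [%.4g, %.4g] Gy", lo, hi))
  exp(ref$spline(dose))
}

#' Iso-survival photon dose (RBE-weighted dose) for a survival level
#'
#' Finds the photon dose on the monotone branch of the reference curve that
#' gives the same surviving fraction, by bisection/Brent root finding on the
#' interpolated log-survival. The RBE at absorbed dose D is then
#' `rbe_weighted_dose(S) / D`.
#'
#' @param S surviving fraction(s) within the range of the branch
#' @param ref a [reference_curve()]
#' @return iso-survival photon dose(s), Gy
#' @export
rbe_weighted_dose <- function(S, ref) {
  stopifnot(inherits(ref, "reference_curve"))
  s_lo <- min(ref$branch_survival); s_hi <- max(ref$branch_survival)
  if (any(S < s_lo | S > s_hi))
    stop_domain(sprintf(
      "survival outside the attainable range [%.6g, %.6g] of the reference curve",
      s_lo, s_hi))
  d_lo <- min(ref$branch_doses); d_hi <- max(ref$branch_doses)
  vapply(S, function(s) {
    target <- log(s)
    f <- function(d) ref$spline(d) - target
    if (f(d_lo) <= 0) return(d_lo)
    if (f(d_hi) >= 0) return(d_hi)
    stats::uniroot(f, c(d_lo, d_hi), tol = 1e-13 * max(d_hi, 1))$root
  }, numeric(1))
}

#' Survival, RBE and RBE-weighted dose over a broadbeam dose schedule
#'
#' @param model a [cell_system_model()]
#' @param let LET of the test radiation, keV/um
#' @param doses absorbed doses, Gy (> 0)
#' @param ref a [reference_curve()] for the reference photon radiation
#' @return `data.frame` with columns `dose_Gy`, `sf`, `rbe_weighted_dose_Gy`,
#'   `rbe`
#' @export
rbe_table <- function(model, let, doses, ref) {
  if (any(doses <= 0)) stop_domain("'doses' must be positive")
  sf <- vapply(doses, function(d)
    total_survival(model, radiation_field(let = let, dose = d)), numeric(1))
  dw <- rbe_weighted_dose(sf, ref)
  data.frame(dose_Gy = doses, sf = sf, rbe_weighted_dose_Gy = dw,
             rbe = dw / doses)
}
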