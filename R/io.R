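# File formats: CSV with unit-bearing headers for tabular data, JSON for
# parameters and metadata. Spectra and PDs are a CSV table plus a JSON
# sidecar (same path with ".json" appended).

sidecar_path <- function(path) paste0(path, ".json")

#' Write / read a single-event spectrum
#'
#' CSV with header `z_Gy,density_per_Gy` plus a JSON sidecar
#' `{site_radius_um, zbar_F_Gy, label}` at `<path>.json`.
#'
#' @param spec a [single_event_spectrum()]
#' @param path CSV file path
#' @return `write_spectrum`: the path, invisibly; `read_spectrum`: a
#'   [single_event_spectrum()]
#' @export
write_spectrum <- function(spec, path) {
  stopifnot(inherits(spec, "single_event_spectrum"))
  utils::write.csv(data.frame(z_Gy = spec$grid, density_per_Gy = spec$density),
                   path, row.names = FALSE)
  jsonlite::write_json(list(site_radius_um = spec$site_radius,
                            zbar_F_Gy = spec$zbar_F,
                            label = spec$label %||% NA),
                       sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_spectrum
#' @export
read_spectrum <- function(path) {
  tab <- read_unit_csv(path, c("z_Gy", "density_per_Gy"))
  meta <- jsonlite::read_json(sidecar_path(path))
  single_event_spectrum(site_radius = meta$site_radius_um,
                        grid = tab$z_Gy, density = tab$density_per_Gy,
                        zbar_F = meta$zbar_F_Gy,
                        label = if (is.null(meta$label) || is.na(meta$label))
                          NULL else meta$label)
}

#' Write / read a specific-energy PD
#'
#' CSV with header `z_Gy,density_per_Gy` plus a JSON sidecar
#' `{dose_Gy, zero_mass, atoms}`.
#'
#' @param pd a [specific_energy_pd()]
#' @param path CSV file path
#' @return `write_pd`: the path, invisibly; `read_pd`: a
#'   [specific_energy_pd()]
#' @export
write_pd <- function(pd, path) {
  stopifnot(inherits(pd, "specific_energy_pd"))
  utils::write.csv(data.frame(z_Gy = pd$grid, density_per_Gy = pd$density),
                   path, row.names = FALSE)
  jsonlite::write_json(list(dose_Gy = pd$dose, zero_mass = pd$zero_mass,
                            atoms = pd$atoms),
                       sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_pd
#' @export
read_pd <- function(path) {
  tab <- read_unit_csv(path, c("z_Gy", "density_per_Gy"))
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  atoms <- meta$atoms
  if (is.null(atoms) || !length(atoms)) atoms <- NULL
  specific_energy_pd(dose = meta$dose_Gy, zero_mass = meta$zero_mass,
                     grid = tab$z_Gy, density = tab$density_per_Gy,
                     atoms = atoms)
}

read_unit_csv <- function(path, required) {
  if (!file.exists(path)) stop_domain(sprintf("file not found: %s", path))
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(tab))
  if (length(missing))
    stop_domain(sprintf("%s: missing unit-bearing column(s): %s", path,
                        paste(missing, collapse = ", ")))
  tab
}

#' Write / read DSMK channel parameters as JSON
#'
#' Keys: `alpha0_per_Gy`, `beta0_per_Gy2`, `r_d_um`, `z0_Gy` (`"inf"`
#' allowed), `r_n_um`, `method`.
#'
#' @param params a [dsmk_params()]
#' @param path JSON file path
#' @return `write_dsmk_params`: the path, invisibly; `read_dsmk_params`: a
#'   [dsmk_params()]
#' @export
write_dsmk_params <- function(params, path) {
  stopifnot(inherits(params, "dsmk_params"))
  jsonlite::write_json(list(alpha0_per_Gy = params$alpha0,
                            beta0_per_Gy2 = params$beta0,
                            r_d_um = params$r_d,
                            z0_Gy = if (is.infinite(params$z0)) "inf" else params$z0,
                            r_n_um = params$r_n, method = params$method),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_dsmk_params
#' @export
read_dsmk_params <- function(path) {
  if (!file.exists(path)) stop_domain(sprintf("file not found: %s", path))
  j <- jsonlite::read_json(path)
  z0 <- j$z0_Gy
  if (identical(z0, "inf")) z0 <- Inf
  dsmk_params(alpha0 = j$alpha0_per_Gy, beta0 = j$beta0_per_Gy2,
              r_d = j$r_d_um, z0 = as.numeric(z0), r_n = j$r_n_um,
              method = j$method)
}

#' Write / read nontargeted-effect parameters as JSON
#'
#' Keys: `a1`, `a2`, `eta`, `kappa`, `z_thre_Gy` (`"inf"` allowed),
#' `n_population`.
#'
#' @param params an [nt_params()]
#' @param path JSON file path
#' @return `write_nt_params`: the path, invisibly; `read_nt_params`: an
#'   [nt_params()]
#' @export
write_nt_params <- function(params, path) {
  stopifnot(inherits(params, "nt_params"))
  jsonlite::write_json(list(a1 = params$a1, a2 = params$a2, eta = params$eta,
                            kappa = params$kappa,
                            z_thre_Gy = if (is.infinite(params$z_thre)) "inf"
                            else params$z_thre,
                            n_population = params$n_population),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_nt_params
#' @export
read_nt_params <- function(path) {
  if (!file.exists(path)) stop_domain(sprintf("file not found: %s", path))
  j <- jsonlite::read_json(path)
  z <- j$z_thre_Gy
  if (identical(z, "inf")) z <- Inf
  nt_params(a1 = j$a1, a2 = j$a2, eta = j$eta, kappa = j$kappa,
            z_thre = as.numeric(z), n_population = j$n_population)
}

#' Write / read survival datasets
#'
#' CSV with required unit-bearing header
#' `condition_id,radiation,let_keV_um,dose_Gy,sf,sf_err`; microbeam datasets
#' additionally carry `n_irradiated,n_population,dose_per_cell_Gy`.
#'
#' @param dataset survival `data.frame`
#' @param path CSV file path
#' @return `write_survival_dataset`: the path, invisibly;
#'   `read_survival_dataset`: a `data.frame`
#' @export
write_survival_dataset <- function(dataset, path) {
  utils::write.csv(dataset, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_survival_dataset
#' @export
read_survival_dataset <- function(path) {
  read_unit_csv(path, c("condition_id", "radiation", "let_keV_um", "dose_Gy",
                        "sf", "sf_err"))
}

#' Published parameter sets bundled with the package
#'
#' `default_dsmk_params` returns a targeted-effect channel parameter set:
#' `"conventional_zthre_1mGy"` / `"conventional_zthre_inf"` (the conventional
#' channel as fitted with the two bystander-threshold conventions) or
#' `"bcl2_saturation"` / `"bcl2_adaptive"` (the Bcl-2 channel under the two
#' lesion-yield transforms). `default_nt_params` returns the bystander-channel
#' set for a cell system, with the threshold convention selected by `z_thre`.
#'
#' @param name targeted parameter set name
#' @return a [dsmk_params()] or [nt_params()]
#' @export
default_dsmk_params <- function(name = c("conventional_zthre_1mGy",
                                         "conventional_zthre_inf",
                                         "bcl2_saturation", "bcl2_adaptive")) {
  name <- match.arg(name)
  read_dsmk_params(system.file("extdata", paste0("dsmk_", name, ".json"),
                               package = "microsurv", mustWork = TRUE))
}

#' @rdname default_dsmk_params
#' @param cell_system `"wi38"` (normal fibroblasts, X-ray microbeam) or
#'   `"bcl2neo"` (the paired HeLa-derived lines, heavy-ion exposures)
#' @param z_thre threshold convention: `"inf"` (no self-protection) or
#'   `"1mGy"` (directly irradiated cells ignore apoptotic signals)
#' @export
default_nt_params <- function(cell_system = c("wi38", "bcl2neo"),
                              z_thre = c("inf", "1mGy")) {
  cell_system <- match.arg(cell_system)
  z_thre <- match.arg(z_thre)
  p <- read_nt_params(system.file("extdata",
                                  paste0("nt_", cell_system, ".json"),
                                  package = "microsurv", mustWork = TRUE))
  if (z_thre == "1mGy")
    p <- nt_params(a1 = p$a1, a2 = p$a2, eta = p$eta, kappa = p$kappa,
                   z_thre = 1e-3, n_population = p$n_population)
  p
}

#' Write a fit result as JSON plus a covariance CSV
#'
#' @param fit a [fit_result()]
#' @param path JSON file path (covariance goes to `<path>_cov.csv`)
#' @return the path, invisibly
#' @export
write_fit_result <- function(fit, path) {
  stopifnot(inherits(fit, "fit_result"))
  jsonlite::write_json(list(estimates = as.list(fit$estimates),
                            std_errors = as.list(fit$std_errors),
                            chi2 = fit$chi2, chi2_per_df = fit$chi2_per_df,
                            adj_r2 = fit$adj_r2,
                            n_conditions = fit$n_conditions,
                            n_params = fit$n_params,
                            fixed = lapply(fit$fixed, function(v)
                              if (is.numeric(v) && is.infinite(v)) "inf" else v)),
                       path, auto_unbox = TRUE, digits = NA)
  cov_path <- sub("\\.json$", "", path)
  utils::write.csv(as.data.frame(fit$covariance),
                   paste0(cov_path, "_cov.csv"), row.names = TRUE)
  invisible(path)
}
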