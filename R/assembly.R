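# Assembly of the survival channels: S = S_T * S_NT with
# S_T = x * S_C + (1 - x) * S_C * S_B, and the inverse (experimental)
# decomposition used to prepare channel-wise datasets for fitting.

#' Cell-system model: targeted channels, nontargeted channel, mixture ratio
#'
#' @param targeted_conventional [dsmk_params()] of the conventional targeted
#'   channel, or `NULL` to disable (S_C = 1)
#' @param targeted_bcl2 [dsmk_params()] of the Bcl-2 (apoptotic) channel, or
#'   `NULL` to disable (S_B = 1)
#' @param nontargeted [nt_params()] of the bystander channel, or `NULL` to
#'   disable (S_NT = 1)
#' @param x fraction of Bcl-2 overexpressing cells, in \[0, 1\]
#' @param r_n nucleus radius, um; taken from the targeted channels when
#'   present (they must agree), required otherwise
#' @return object of class `cell_system_model`
#' @export
cell_system_model <- function(targeted_conventional = NULL,
                              targeted_bcl2 = NULL, nontargeted = NULL,
                              x = 1, r_n = NULL) {
  if (!is.null(targeted_conventional))
    stopifnot(inherits(targeted_conventional, "dsmk_params"))
  if (!is.null(targeted_bcl2))
    stopifnot(inherits(targeted_bcl2, "dsmk_params"))
  if (!is.null(nontargeted)) stopifnot(inherits(nontargeted, "nt_params"))
  if (any(x < 0 | x > 1)) stop_domain("'x' must be in [0, 1]")
  rns <- c(targeted_conventional$r_n, targeted_bcl2$r_n)
  if (length(rns) == 2L && abs(rns[1] - rns[2]) > 1e-12)
    stop_domain("the two targeted channels must share the nucleus radius r_n")
  if (length(rns)) {
    if (!is.null(r_n) && abs(r_n - rns[1]) > 1e-12)
      stop_domain("'r_n' disagrees with the targeted channels")
    r_n <- rns[1]
  }
  if (is.null(r_n))
    stop_domain("'r_n' is required when no targeted channel is given")
  assert_scalar_num(r_n, "r_n")
  if (r_n <= 0) stop_domain("'r_n' must be positive")
  structure(list(targeted_conventional = targeted_conventional,
                 targeted_bcl2 = targeted_bcl2, nontargeted = nontargeted,
                 x = x, r_n = r_n),
            class = "cell_system_model")
}

#' Irradiation field descriptor
#'
#' A broadbeam field (mean dose, LET) or a microbeam field (a
#' [microbeam_design()] plus the LET setting the per-cell dose scale).
#' Single-event spectra default to [make_spectrum()] at the model radii; pass
#' `spectra` (named list with any of `nucleus`, `domain_conventional`,
#' `domain_bcl2`) to override with measured or transport-calculated spectra.
#'
#' @param let LET of the radiation, keV/um
#' @param dose broadbeam mean absorbed dose, Gy (omit for microbeam)
#' @param design a [microbeam_design()] (omit for broadbeam)
#' @param spectra optional named list of [single_event_spectrum()] overrides
#' @param zd_to_zf passed to [make_spectrum()] for synthetic spectra
#' @return object of class `radiation_field`
#' @export
radiation_field <- function(let, dose = NULL, design = NULL, spectra = NULL,
                            zd_to_zf = 2) {
  assert_scalar_num(let, "let")
  if (let <= 0) stop_domain("'let' must be positive")
  if (is.null(dose) == is.null(design))
    stop_domain("give exactly one of 'dose' (broadbeam) or 'design' (microbeam)")
  if (!is.null(dose)) {
    assert_scalar_num(dose, "dose", lower = 0)
    kind <- "broadbeam"
  } else {
    stopifnot(inherits(design, "microbeam_design"))
    kind <- "microbeam"
  }
  structure(list(kind = kind, let = let, dose = dose, design = design,
                 spectra = spectra, zd_to_zf = zd_to_zf),
            class = "radiation_field")
}

field_spectrum <- function(field, which, radius) {
  sp <- field$spectra[[which]]
  if (!is.null(sp)) {
    stopifnot(inherits(sp, "single_event_spectrum"))
    if (abs(sp$site_radius - radius) > 1e-9) sp <- scale_spectrum(sp, radius)
    return(sp)
  }
  make_spectrum(field$let, radius, zd_to_zf = field$zd_to_zf)
}

field_nucleus_pd <- function(model, field) {
  if (field$kind == "microbeam") return(microbeam_pd(field$design))
  if (field$dose == 0) return(specific_energy_pd(dose = 0, zero_mass = 1))
  multi_event_pd(field_spectrum(field, "nucleus", model$r_n), field$dose)
}

#' Total surviving fraction of the model assembly
#'
#' Composes the channels as `S = S_T * S_NT` with
#' `S_T = bcl2_mixture(S_C, S_B, x)`. Channel survivals are computed from the
#' nucleus specific-energy PD of the field (compound-Poisson for broadbeam,
#' two-point for microbeam) and, for the targeted channels, the conditional
#' domain PDs at each channel's domain radius.
#'
#' @param model a [cell_system_model()]
#' @param field a [radiation_field()]
#' @param detail if `TRUE` return a list with the channel survivals
#'   (`sf`, `s_t`, `s_c`, `s_b`, `s_nt`) instead of the total only
#' @return surviving fraction, or a list when `detail = TRUE`
#' @export
total_survival <- function(model, field, detail = FALSE) {
  stopifnot(inherits(model, "cell_system_model"),
            inherits(field, "radiation_field"))
  npd <- field_nucleus_pd(model, field)
  s_c <- if (is.null(model$targeted_conventional)) 1 else
    survival_vs_dose(npd, field_spectrum(field, "domain_conventional",
                                         model$targeted_conventional$r_d),
                     model$targeted_conventional)
  s_b <- if (is.null(model$targeted_bcl2)) 1 else
    survival_vs_dose(npd, field_spectrum(field, "domain_bcl2",
                                         model$targeted_bcl2$r_d),
                     model$targeted_bcl2)
  s_t <- bcl2_mixture(s_c, s_b, model$x)
  s_nt <- if (is.null(model$nontargeted)) 1 else
    survival_nt(npd, model$nontargeted)
  if (detail)
    list(sf = s_t * s_nt, s_t = s_t, s_c = s_c, s_b = s_b, s_nt = s_nt)
  else s_t * s_nt
}

#' Experimental Bcl-2-channel survival from paired cell-line data
#'
#' With x = 1 for a pure Bcl-2 overexpressing line and x = 0 for its control,
#' the Bcl-2-channel survival is the ratio `S_B = S_neo / S_bcl2` at the same
#' irradiation condition. Noise can push the ratio above one; such values are
#' clipped to 1 with a warning.
#'
#' @param S_neo control-line surviving fraction, in (0, 1\] (vectorized)
#' @param S_bcl2 Bcl-2-line surviving fraction, in (0, 1\] (vectorized)
#' @return Bcl-2-channel surviving fraction
#' @export
derive_SB_exp <- function(S_neo, S_bcl2) {
  if (any(S_bcl2 == 0)) stop_domain("'S_bcl2' must be non-zero")
  if (any(S_neo < 0) || any(S_bcl2 < 0)) stop_domain("survival must be non-negative")
  r <- S_neo / S_bcl2
  if (any(r > 1)) {
    warning(sprintf("%d S_B ratio(s) exceeded 1 and were clipped", sum(r > 1)),
            call. = FALSE)
    r <- pmin(r, 1)
  }
  r
}

#' Experimental conventional-channel survival with the nontargeted correction
#'
#' Removes the calculated nontargeted contribution from a measured Bcl-2-line
#' surviving fraction: `S_C = S_bcl2 / S_NT_cal`, clipped at one with a
#' warning when noise inverts the ratio.
#'
#' @param S_bcl2 measured surviving fraction (vectorized)
#' @param S_NT_cal calculated nontargeted surviving fraction, in (0, 1\]
#' @return conventional targeted-channel surviving fraction
#' @export
derive_SC_exp <- function(S_bcl2, S_NT_cal) {
  if (any(S_NT_cal <= 0)) stop_domain("'S_NT_cal' must be positive")
  if (any(S_NT_cal > 1)) stop_domain("'S_NT_cal' must be <= 1")
  r <- S_bcl2 / S_NT_cal
  if (any(r > 1)) {
    warning(sprintf("%d S_C ratio(s) exceeded 1 and were clipped", sum(r > 1)),
            call. = FALSE)
    r <- pmin(r, 1)
  }
  r
}

#' Model predictions for every condition of a survival dataset
#'
#' @param model a [cell_system_model()]
#' @param dataset a survival `data.frame` as produced by
#'   [make_survival_dataset()] or [read_survival_dataset()]
#' @return the dataset with columns `sf_model`, `s_c`, `s_b`, `s_nt` appended
#' @export
predict_dataset <- function(model, dataset) {
  stopifnot(is.data.frame(dataset))
  micro <- all(c("n_irradiated", "n_population", "dose_per_cell_Gy")
               %in% names(dataset)) && any(!is.na(dataset$n_irradiated))
  res <- lapply(seq_len(nrow(dataset)), function(i) {
    row <- dataset[i, ]
    f <- if (micro && !is.na(row$n_irradiated))
      radiation_field(let = row$let_keV_um,
                      design = microbeam_design(row$n_irradiated,
                                                row$n_population,
                                                row$dose_per_cell_Gy))
    else radiation_field(let = row$let_keV_um, dose = row$dose_Gy)
    total_survival(model, f, detail = TRUE)
  })
  dataset$sf_model <- vapply(res, `[[`, numeric(1), "sf")
  dataset$s_c <- vapply(res, `[[`, numeric(1), "s_c")
  dataset$s_b <- vapply(res, `[[`, numeric(1), "s_b")
  dataset$s_nt <- vapply(res, `[[`, numeric(1), "s_nt")
  dataset
}
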