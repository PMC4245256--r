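# Weighted least-squares estimation of the model parameters.
#
# The objective is chi^2 = sum ((S_exp - S_cal) / dS_exp)^2. Minimization
# uses seeded multi-start Nelder-Mead in a transformed (log/logit) space,
# polished by a small Levenberg-Marquardt loop; the asymptotic covariance is
# (J^T J)^{-1} * chi^2/df from the finite-difference Jacobian of the weighted
# residuals at the optimum, in the original parameter scale.

#' Chi-square of weighted survival residuals
#'
#' @param observed observed surviving fractions
#' @param errors their uncertainties (> 0)
#' @param predicted model surviving fractions
#' @return chi-square value
#' @export
chi_square <- function(observed, errors, predicted) {
  n <- length(observed)
  if (length(errors) != n || length(predicted) != n)
    stop_domain("'observed', 'errors' and 'predicted' must have equal length")
  if (any(errors <= 0)) stop_domain("'errors' must be positive")
  sum(((observed - predicted) / errors)^2)
}

#' Adjusted coefficient of determination for a weighted fit
#'
#' `R2` is computed from the error-weighted residual and total sums of squares
#' around the plain mean of the observed survival; the adjustment penalizes
#' the `m` fitted parameters through the degrees of freedom `df = n - m`:
#' `adj R2 = 1 - (1 - R2) * (n - 1) / (n - m)`.
#'
#' @inheritParams chi_square
#' @param m number of fitted parameters (df = n - m must be positive)
#' @return adjusted R-squared
#' @export
adjusted_r2 <- function(observed, errors, predicted, m) {
  n <- length(observed)
  if (length(errors) != n || length(predicted) != n)
    stop_domain("'observed', 'errors' and 'predicted' must have equal length")
  if (any(errors <= 0)) stop_domain("'errors' must be positive")
  if (n - m <= 0) stop_domain("degrees of freedom n - m must be positive")
  w <- 1 / errors^2
  ss_res <- sum(w * (observed - predicted)^2)
  ss_tot <- sum(w * (observed - mean(observed))^2)
  if (ss_tot == 0) stop_domain("observed survival has no variance around its mean")
  r2 <- 1 - ss_res / ss_tot
  1 - (1 - r2) * (n - 1) / (n - m)
}

#' Fit result container
#'
#' @param estimates named vector of fitted parameter values
#' @param std_errors named vector of asymptotic standard errors
#' @param covariance covariance matrix over the free parameters
#' @param chi2 chi-square at the optimum
#' @param n number of conditions
#' @param m number of free parameters
#' @param adj_r2 adjusted R-squared
#' @param fixed named vector/list of frozen parameters
#' @param convergence optimizer diagnostics
#' @return object of class `fit_result`
#' @export
fit_result <- function(estimates, std_errors, covariance, chi2, n, m, adj_r2,
                       fixed = NULL, convergence = NULL) {
  structure(list(estimates = estimates, std_errors = std_errors,
                 covariance = covariance, chi2 = chi2,
                 chi2_per_df = chi2 / (n - m), adj_r2 = adj_r2,
                 n_conditions = n, n_params = m, fixed = fixed,
                 convergence = convergence),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> n = %d, m = %d, chi2/df = %.4g, adj R2 = %.4g\n",
              x$n_conditions, x$n_params, x$chi2_per_df, x$adj_r2))
  for (nm in names(x$estimates))
    cat(sprintf("  %-8s %12.5g  (SE %.4g)\n", nm, x$estimates[[nm]],
                x$std_errors[[nm]]))
  if (length(x$fixed))
    cat("  fixed:", paste(names(x$fixed), unlist(x$fixed), sep = " = ",
                          collapse = ", "), "\n")
  invisible(x)
}

# --- transforms -------------------------------------------------------------

.trans_fwd <- function(v, kind) {
  switch(kind,
         log = log(v),
         logit = stats::qlogis(min(max(v, 1e-12), 1 - 1e-12)),
         identity = v)
}
.trans_bwd <- function(t, kind) {
  switch(kind, log = exp(t), logit = stats::plogis(t), identity = t)
}

fd_jacobian <- function(fn, x, rel = 1e-5, abs_step = 1e-8) {
  r0 <- fn(x)
  J <- matrix(0, length(r0), length(x))
  for (j in seq_along(x)) {
    h <- max(abs(x[j]) * rel, abs_step)
    xp <- x; xp[j] <- x[j] + h
    xm <- x; xm[j] <- x[j] - h
    J[, j] <- (fn(xp) - fn(xm)) / (2 * h)
  }
  J
}

# Multi-start Nelder-Mead + Levenberg-Marquardt on transformed coordinates.
# resid_fn takes the full named parameter vector (original scale).
wls_engine <- function(resid_fn, start, trans, free, n_restarts = 8,
                       seed = NULL, nm_maxit = 500, lm_maxit = 50) {
  full <- start
  tf <- vapply(free, function(nm) .trans_fwd(start[[nm]], trans[[nm]]),
               numeric(1))
  unpack <- function(t) {
    th <- full
    for (i in seq_along(free)) th[[free[i]]] <- .trans_bwd(t[i], trans[[free[i]]])
    th
  }
  obj <- function(t) {
    r <- tryCatch(resid_fn(unpack(t)), error = function(e) NULL)
    if (is.null(r) || any(!is.finite(r))) return(1e30)
    sum(r^2)
  }
  starts <- list(tf)
  if (n_restarts > 1)
    starts <- c(starts, with_seed(seed, lapply(seq_len(n_restarts - 1),
      function(i) tf + stats::rnorm(length(tf), 0, 0.7))))
  best <- NULL
  for (s in starts) {
    fit <- suppressWarnings(stats::optim(s, obj, method = "Nelder-Mead",
                                         control = list(maxit = nm_maxit)))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  # LM polish
  t_cur <- best$par
  r_cur <- resid_fn(unpack(t_cur))
  ssq <- sum(r_cur^2)
  lambda <- 1e-3
  for (it in seq_len(lm_maxit)) {
    J <- fd_jacobian(function(t) {
      r <- tryCatch(resid_fn(unpack(t)), error = function(e) rep(1e10, length(r_cur)))
      r[!is.finite(r)] <- 1e10
      r
    }, t_cur)
    jtj <- crossprod(J)
    g <- crossprod(J, r_cur)
    improved <- FALSE
    for (k in 1:8) {
      step <- tryCatch(solve(jtj + lambda * diag(diag(jtj) + 1e-12,
                                                 nrow(jtj)), g),
                       error = function(e) NULL)
      if (is.null(step)) { lambda <- lambda * 10; next }
      t_new <- t_cur - as.numeric(step)
      s_new <- obj(t_new)
      if (s_new < ssq - 1e-14) {
        t_cur <- t_new
        r_cur <- resid_fn(unpack(t_cur))
        ssq <- s_new
        lambda <- max(lambda / 5, 1e-10)
        improved <- TRUE
        break
      }
      lambda <- lambda * 10
    }
    if (!improved || lambda > 1e10) break
  }
  list(theta = unpack(t_cur), chi2 = ssq, nm = best)
}

# Covariance in original scale: (J^T J)^{-1} scaled by chi2/df.
wls_covariance <- function(resid_fn, theta, free, chi2, df) {
  x <- vapply(free, function(nm) theta[[nm]], numeric(1))
  J <- fd_jacobian(function(x2) {
    th <- theta
    for (i in seq_along(free)) th[[free[i]]] <- x2[i]
    resid_fn(th)
  }, x)
  jtj <- crossprod(J)
  # invert in correlation form: keeps well-determined parameters accurate
  # while flat directions (e.g. the trigger-curve scale) get properly large
  # variances instead of a misleading pseudo-inverse zero
  d <- diag(jtj)
  s <- sqrt(ifelse(d > 0 & is.finite(d), d, 1))
  C <- jtj / outer(s, s)
  Ci <- tryCatch(solve(C), error = function(e) MASS::ginv(C))
  cov <- Ci / outer(s, s) * chi2 / df
  cov <- (cov + t(cov)) / 2
  dimnames(cov) <- list(free, free)
  cov
}

finish_fit <- function(resid_fn, theta, free, fixed, n, obs, err, pred,
                       convergence = NULL) {
  m <- length(free)
  df <- n - m
  if (df <= 0) stop_domain("degrees of freedom n - m must be positive")
  chi2 <- sum(resid_fn(theta)^2)
  cov <- wls_covariance(resid_fn, theta, free, chi2, df)
  se <- sqrt(pmax(diag(cov), 0))
  names(se) <- free
  est <- vapply(free, function(nm) theta[[nm]], numeric(1))
  fit_result(estimates = est, std_errors = se, covariance = cov, chi2 = chi2,
             n = n, m = m, adj_r2 = adjusted_r2(obs, err, pred, m),
             fixed = fixed, convergence = convergence)
}

#' Fit the nontargeted-effect parameters to microbeam survival data
#'
#' Stage one of the estimation protocol: on microbeam data the targeted
#' contribution is negligible (the irradiated fraction is tiny), so the
#' measured survival is attributed entirely to the bystander channel and the
#' free parameters of S_NT are estimated by weighted least squares.
#'
#' @param dataset `data.frame` with columns `sf` and `sf_err`
#' @param fields per-condition list of [microbeam_design()] or
#'   [specific_energy_pd()] objects
#' @param init an [nt_params()] with starting values (its `z_thre` is kept
#'   fixed; `n_population` is taken from each design when available)
#' @param freeze names among `c("a1", "a2", "eta", "kappa")` to hold at their
#'   `init` values
#' @param n_restarts number of seeded optimizer restarts
#' @param seed integer seed for the restart jitter
#' @return a [fit_result()]
#' @export
fit_nontargeted <- function(dataset, fields, init, freeze = character(),
                            n_restarts = 8, seed = 1) {
  stopifnot(is.data.frame(dataset), inherits(init, "nt_params"))
  n <- nrow(dataset)
  if (length(fields) != n)
    stop_domain("'fields' must have one element per dataset row")
  pds <- lapply(fields, function(f) {
    if (inherits(f, "microbeam_design")) microbeam_pd(f) else f
  })
  nw <- vapply(fields, function(f) {
    if (inherits(f, "microbeam_design")) f$n_population else init$n_population
  }, numeric(1))
  all_names <- c("a1", "a2", "eta", "kappa")
  free <- setdiff(all_names, freeze)
  if (!length(free)) stop_domain("no free parameters left to fit")
  trans <- list(a1 = "log", a2 = "log", eta = "logit", kappa = "logit")
  start <- list(a1 = init$a1, a2 = init$a2, eta = init$eta, kappa = init$kappa)

  two_point <- all(vapply(pds, function(pd) length(pd$grid) == 0L &&
                            nrow(pd$atoms) <= 1L, logical(1)))
  if (two_point) {
    # microbeam fast path: vectorized closed form over all conditions
    frac <- vapply(pds, function(pd)
      if (nrow(pd$atoms)) pd$atoms$mass else 0, numeric(1))
    d_i <- vapply(pds, function(pd)
      if (nrow(pd$atoms)) pd$atoms$z else 0, numeric(1))
    below <- 1 - frac + frac * (d_i < init$z_thre)
    resid_fn <- function(th) {
      # clamp to the feasible region so that finite-difference steps taken
      # at a boundary optimum (e.g. eta ~ 1) stay evaluable
      a1 <- max(th$a1, 0); a2 <- max(th$a2, 1e-12)
      eta <- min(max(th$eta, 0), 1); kappa <- min(max(th$kappa, 0), 1)
      ps <- frac * -expm1(-a1 * d_i^a2)
      q <- pmin(eta * ps, 1)
      pe <- ifelse(q >= 1, 0, exp((nw - 1) * log1p(-q)))
      s <- 1 - kappa * (1 - pe) * below
      (dataset$sf - s) / dataset$sf_err
    }
  } else {
    resid_fn <- function(th) {
      vapply(seq_len(n), function(i) {
        p <- nt_params(a1 = max(th$a1, 0), a2 = max(th$a2, 1e-12),
                       eta = min(max(th$eta, 0), 1),
                       kappa = min(max(th$kappa, 0), 1),
                       z_thre = init$z_thre, n_population = nw[i])
        (dataset$sf[i] - survival_nt(pds[[i]], p)) / dataset$sf_err[i]
      }, numeric(1))
    }
  }
  opt <- wls_engine(resid_fn, start, trans, free, n_restarts = n_restarts,
                    seed = seed)
  pred <- dataset$sf - resid_fn(opt$theta) * dataset$sf_err
  fixed <- c(opt$theta[freeze],
             list(z_thre = init$z_thre))
  finish_fit(resid_fn, opt$theta, free, fixed, n, dataset$sf, dataset$sf_err,
             pred, convergence = opt$nm$convergence)
}

#' Fit a DSMK targeted-effect channel to channel-wise survival data
#'
#' Stage two of the protocol: weighted least squares over (alpha0, beta0,
#' r_d, z0) at each nucleus radius of `rn_grid`, returning the grid minimum
#' (the nucleus radius itself carries no uncertainty estimate). For the
#' `"bcl2"` channel the dataset holds S_B-type ratios and a negative
#' unconstrained beta0 is clamped to zero (refit with beta0 frozen, standard
#' error reported as zero).
#'
#' @param dataset `data.frame` with columns `dose_Gy`, `sf`, `sf_err` and
#'   (unless `spectra` is supplied) `let_keV_um`
#' @param spectra optional per-condition list of `list(domain =, nucleus =)`
#'   [single_event_spectrum()] pairs at the `init` radii; defaults to
#'   moment-matched synthetic spectra from the dataset LET column
#' @param init a [dsmk_params()] with starting values (its `method` selects
#'   the lesion-yield transform)
#' @param channel `"conventional"` (S_C data) or `"bcl2"` (S_B data)
#' @param rn_grid nucleus radii to scan, um; default is `init$r_n` only
#' @param freeze names among `c("alpha0", "beta0", "r_d", "z0")` to hold at
#'   their `init` values
#' @param n_restarts number of seeded optimizer restarts
#' @param seed integer seed for the restart jitter
#' @param zd_to_zf event-size ratio for synthetic spectra
#' @param nucleus_pds optional per-condition list of precomputed nucleus
#'   [specific_energy_pd()] objects, valid only when `rn_grid` has length
#'   one; avoids rebuilding identical PDs in repeated fits
#' @return a [fit_result()] (element `fixed` records `r_n`)
#' @export
fit_targeted <- function(dataset, spectra = NULL, init,
                         channel = c("conventional", "bcl2"), rn_grid = NULL,
                         freeze = character(), n_restarts = 4, seed = 1,
                         zd_to_zf = 2, nucleus_pds = NULL) {
  channel <- match.arg(channel)
  stopifnot(is.data.frame(dataset), inherits(init, "dsmk_params"))
  n <- nrow(dataset)
  if (is.null(rn_grid)) rn_grid <- init$r_n
  if (is.null(spectra)) {
    if (is.null(dataset$let_keV_um))
      stop_domain("dataset needs a 'let_keV_um' column when 'spectra' is not given")
    spectra <- lapply(seq_len(n), function(i) list(
      domain = make_spectrum(dataset$let_keV_um[i], init$r_d, zd_to_zf = zd_to_zf),
      nucleus = make_spectrum(dataset$let_keV_um[i], init$r_n, zd_to_zf = zd_to_zf)))
  }
  all_names <- c("alpha0", "beta0", "r_d", "z0")
  free <- setdiff(all_names, freeze)
  if (!length(free)) stop_domain("no free parameters left to fit")
  trans <- list(alpha0 = "identity", beta0 = "identity", r_d = "log",
                z0 = "log")
  start <- list(alpha0 = init$alpha0, beta0 = init$beta0, r_d = init$r_d,
                z0 = init$z0)

  if (!is.null(nucleus_pds) && length(rn_grid) != 1L)
    stop_domain("'nucleus_pds' requires a single-value 'rn_grid'")

  run_at_rn <- function(rn, free_loc, start_loc) {
    # nucleus PDs depend only on (rn, dose): compute once per grid value
    npds <- nucleus_pds %||% lapply(seq_len(n), function(i) {
      sp <- scale_spectrum(spectra[[i]]$nucleus, rn)
      multi_event_pd(sp, dataset$dose_Gy[i])
    })
    # per-condition quadrature nodes and weights over the nucleus PD
    nodes <- lapply(npds, function(pd) {
      g <- pd$grid
      w <- if (length(g) >= 2L)
        (c(diff(g) / 2, 0) + c(0, diff(g) / 2)) * pd$density else numeric(0)
      keep <- if (length(w)) rev(cumsum(rev(w))) > 1e-13 else logical(0)
      list(zn = c(pd$atoms$z, g[keep]),
           wt = c(pd$atoms$mass, w[keep]),
           zero = pd$zero_mass,
           n_atom = nrow(pd$atoms))
    })
    cache <- new.env(parent = emptyenv())
    cache$key <- NULL
    model_sf <- function(th) {
      th$r_d <- max(th$r_d, 1e-6)
      th$z0 <- max(th$z0, 1e-9)
      if (init$method == "adaptive" && th$beta0 < 0) th$beta0 <- 0
      key <- c(th$r_d, th$z0)
      if (is.null(cache$key) || !identical(cache$key, key)) {
        pr <- dsmk_params(alpha0 = 0, beta0 = 0, r_d = th$r_d, z0 = th$z0,
                          r_n = max(rn, th$r_d), method = init$method)
        cache$tabs <- lapply(seq_len(n), function(i) {
          if (!length(nodes[[i]]$zn)) return(list(A = numeric(0), B = numeric(0)))
          dsp <- scale_spectrum(spectra[[i]]$domain, th$r_d)
          domain_effect_table(dsp, pr, nodes[[i]]$zn)
        })
        cache$key <- key
      }
      vapply(seq_len(n), function(i) {
        nd <- nodes[[i]]
        if (!length(nd$zn)) return(min(nd$zero, 1))
        tab <- cache$tabs[[i]]
        s <- pmin(exp(-th$alpha0 * tab$A - th$beta0 * tab$B), 1)
        min(nd$zero + sum(nd$wt * s), 1)
      }, numeric(1))
    }
    resid_fn <- function(th) (dataset$sf - model_sf(th)) / dataset$sf_err
    opt <- wls_engine(resid_fn, start_loc, trans, free_loc,
                      n_restarts = n_restarts, seed = seed)
    list(opt = opt, resid_fn = resid_fn, model_sf = model_sf)
  }

  best <- NULL; best_rn <- NA_real_
  for (rn in rn_grid) {
    res <- run_at_rn(rn, free, start)
    if (is.null(best) || res$opt$chi2 < best$opt$chi2) {
      best <- res; best_rn <- rn
    }
  }
  free_fin <- free
  fixed <- c(best$opt$theta[freeze], list(r_n = best_rn))
  if (channel == "bcl2" && "beta0" %in% free_fin &&
      best$opt$theta$beta0 < 0) {
    start0 <- best$opt$theta
    start0$beta0 <- 0
    free_fin <- setdiff(free_fin, "beta0")
    if (!length(free_fin)) stop_domain("no free parameters left after beta0 clamp")
    best <- run_at_rn(best_rn, free_fin, start0)
    fixed <- c(best$opt$theta["beta0"], fixed)
  }
  pred <- best$model_sf(best$opt$theta)
  out <- finish_fit(best$resid_fn, best$opt$theta, free_fin, fixed, n,
                    dataset$sf, dataset$sf_err, pred,
                    convergence = best$opt$nm$convergence)
  if (channel == "bcl2" && !("beta0" %in% free_fin) && "beta0" %in% free) {
    # clamped at the boundary: report value and SE as exactly zero
    out$estimates <- c(out$estimates, beta0 = 0)
    out$std_errors <- c(out$std_errors, beta0 = 0)
  }
  out
}
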