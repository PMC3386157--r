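#' Fit result container
#'
#' Uniform return type of the assay fitters: point estimates with standard
#' errors, residual sum of squares, point count, convergence flag and
#' (optionally) the parameter covariance matrix. Standard errors are the
#' asymptotic least-squares errors from the Jacobian at the optimum.
#'
#' @param params Named numeric vector of estimates.
#' @param se Named numeric vector of standard errors (same names).
#' @param residual_ss Residual sum of squares.
#' @param n_points Number of fitted data points.
#' @param converged Logical.
#' @param covariance Optional covariance matrix.
#' @param flags Character vector of fit annotations (e.g. `"plateau_outlier"`).
#' @return An object of class `fit_result`.
#' @export
fit_result <- function(params, se = NULL, residual_ss = NA_real_,
                       n_points = NA_integer_, converged = TRUE,
                       covariance = NULL, flags = character()) {
  if (converged && !all(is.finite(params)))
    stop("converged fit must have finite estimates", call. = FALSE)
  if (!is.null(se) && any(se < 0, na.rm = TRUE))
    stop("standard errors must be >= 0", call. = FALSE)
  structure(list(params = params, se = se, residual_ss = residual_ss,
                 n_points = as.integer(n_points), converged = converged,
                 covariance = covariance, flags = flags),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> %s (n = %d, RSS = %.4g)\n",
              if (x$converged) "converged" else "NOT converged",
              x$n_points, x$residual_ss))
  est <- x$params
  se <- if (is.null(x$se)) rep(NA_real_, length(est)) else x$se[names(est)]
  for (i in seq_along(est))
    cat(sprintf("  %-12s %.6g +/- %.3g\n", names(est)[i], est[i], se[i]))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Serialize a fit result to JSON
#'
#' @param x A `fit_result`.
#' @param assay Assay label stored in the report.
#' @param path Optional file; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly if written to `path`).
#' @export
fit_result_json <- function(x, assay = "unknown", path = NULL) {
  stopifnot(inherits(x, "fit_result"))
  obj <- list(assay = assay, params = as.list(x$params),
              se = if (is.null(x$se)) NULL else as.list(x$se),
              n = x$n_points, converged = x$converged,
              residual_ss = x$residual_ss, flags = x$flags)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(as.character(js)))
  }
  as.character(js)
}

#' SPR binding kinetics
#'
#' Kinetic constants of a 1:1 Langmuir interaction. `k_D` is derived as
#' `k_d / k_a` and always consistent with the rates.
#'
#' @param k_a Association rate constant, M^-1 s^-1 (> 0).
#' @param k_d Dissociation rate constant, s^-1 (> 0).
#' @param r_max Saturating response, RU (> 0).
#' @return An object of class `binding_kinetics` with fields `k_a`, `k_d`,
#'   `r_max`, `k_D`.
#' @export
binding_kinetics <- function(k_a, k_d, r_max) {
  if (k_a <= 0 || k_d <= 0 || r_max <= 0)
    stop("k_a, k_d and r_max must all be > 0", call. = FALSE)
  structure(list(k_a = k_a, k_d = k_d, r_max = r_max, k_D = k_d / k_a),
            class = "binding_kinetics")
}

#' @export
print.binding_kinetics <- function(x, ...) {
  cat(sprintf("<binding_kinetics> k_a = %.3g /M/s, k_d = %.3g /s, K_D = %.3g M, R_max = %.3g RU\n",
              x$k_a, x$k_d, x$k_D, x$r_max))
  invisible(x)
}

#' Equilibrium dissociation constant from kinetic rates
#'
#' @param k_a Association rate constant, M^-1 s^-1 (> 0).
#' @param k_d Dissociation rate constant, s^-1.
#' @return `K_D = k_d / k_a`, M.
#' @examples
#' kd_from_rates(3.53e5, 6.16e-3)  # ~1.74e-8 M
#' @export
kd_from_rates <- function(k_a, k_d) {
  if (!is.numeric(k_a) || any(k_a <= 0))
    stop("k_a must be > 0", call. = FALSE)
  k_d / k_a
}

# Pool one time_course or a list of replicates into (t, y) vectors.
pool_traces <- function(tc) {
  if (inherits(tc, "time_course")) tc <- list(tc)
  stopifnot(all(vapply(tc, inherits, TRUE, "time_course")))
  list(t = unlist(lapply(tc, `[[`, "times")),
       y = unlist(lapply(tc, `[[`, "values")))
}

# Levenberg-Marquardt fit of y = plateau * (1 - exp(-k t)) with multi-start
# over log-spaced initial rates. Returns a fit_result with params k, plateau.
fit_exp_rise <- function(t, y, rate_name = "k") {
  if (length(t) < 4L)
    stop("at least 4 time points are required", call. = FALSE)
  if (diff(range(y)) == 0)
    stop("fit did not converge: signal is constant", call. = FALSE)
  ymax <- max(y)
  # initial rate: reciprocal of the time at which the signal first crosses
  # half its maximum (fall back to mid-range time)
  t_half <- suppressWarnings(min(t[y >= ymax / 2 & t > 0]))
  if (!is.finite(t_half) || t_half <= 0) t_half <- stats::median(t[t > 0])
  k0 <- log(2) / t_half
  starts <- k0 * c(0.3, 1, 3)

  resid_fn <- function(p) p[2] * (1 - exp(-exp(p[1]) * t)) - y
  best <- NULL
  for (s in starts) {
    fit <- try(minpack.lm::nls.lm(
      par = c(logk = log(s), plateau = ymax),
      fn = resid_fn,
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14,
                                           ptol = 1e-14)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best))
    stop("fit did not converge from any starting value", call. = FALSE)

  k_hat <- exp(best$par[["logk"]])
  plateau_hat <- best$par[["plateau"]]
  n <- length(y)
  # delta-method SEs on the (k, plateau) scale from the (logk, plateau) fit
  cov_lp <- try(solve(best$hessian) * best$deviance / max(n - 2, 1),
                silent = TRUE)
  if (inherits(cov_lp, "try-error")) {
    se <- c(NA_real_, NA_real_)
    cov_kp <- NULL
  } else {
    J <- diag(c(k_hat, 1))
    cov_kp <- J %*% cov_lp %*% t(J)
    se <- sqrt(pmax(diag(cov_kp), 0))
  }
  flags <- character()
  if (plateau_hat < 0.5 * ymax || plateau_hat > 2 * ymax)
    flags <- c(flags, "plateau_outlier")
  converged <- is.finite(k_hat) && k_hat > 0 && plateau_hat > 0
  if (!converged) flags <- c(flags, "nonpositive_estimate")
  params <- c(k_hat, plateau_hat)
  names(params) <- c(rate_name, "plateau")
  names(se) <- names(params)
  fit_result(params, se = se, residual_ss = best$deviance, n_points = n,
             converged = converged, covariance = cov_kp, flags = flags)
}

#' Fit a pseudo-first-order exponential association
#'
#' Estimates the apparent nucleotide exchange rate (K_obs) and plateau from a
#' GTPgammaS binding or fluorescence-rise time course by Levenberg-Marquardt
#' least squares on `y = plateau * (1 - exp(-k t))`. Three log-spaced
#' starting rates around `ln 2 / t_half` guard against local minima.
#' Replicates supplied as a list are fitted jointly on pooled residuals.
#'
#' @param tc A [time_course()] or list of replicate time courses.
#' @return A [fit_result()] with parameters `k_obs` and `plateau`.
#' @export
fit_exponential_association <- function(tc) {
  d <- pool_traces(tc)
  fit_exp_rise(d$t, d$y, rate_name = "k_obs")
}

#' Fit a single-turnover hydrolysis time course
#'
#' Same functional form as [fit_exponential_association()] — Pi release
#' follows `p0 * (1 - exp(-k_cat t))` — reported as `k_cat`.
#'
#' @param tc A [time_course()] or list of replicates.
#' @return A [fit_result()] with parameters `k_cat` and `plateau`.
#' @export
fit_single_turnover <- function(tc) {
  d <- pool_traces(tc)
  fit_exp_rise(d$t, d$y, rate_name = "k_cat")
}

#' Fit the steady-state turnover rate from a Pi progress curve
#'
#' Fits a straight line through the initial linear window of a multi-turnover
#' Pi-accumulation curve and reports the slope normalised by the Galpha
#' concentration as the per-Galpha turnover (min^-1). The linear window
#' comprises the points with cumulative Pi at most 20 % of the initial GTP
#' (substrate-depletion guard); if the initial GTP is unknown, all points are
#' used and the result is flagged.
#'
#' @param tc A [time_course()] (values in nM Pi) or list of replicates.
#' @param g_conc Galpha concentration, nM (> 0).
#' @param gtp0 Initial GTP, nM; defaults to `meta$gtp0` of the (first) trace.
#' @return A [fit_result()] with parameter `turnover` (min^-1 per Galpha)
#'   and `slope` (nM/min).
#' @export
fit_steady_state_rate <- function(tc, g_conc, gtp0 = NULL) {
  if (g_conc <= 0) stop("g_conc must be > 0", call. = FALSE)
  first <- if (inherits(tc, "time_course")) tc else tc[[1]]
  if (is.null(gtp0)) gtp0 <- first$meta$gtp0
  d <- pool_traces(tc)
  flags <- character()
  if (is.null(gtp0)) {
    keep <- rep(TRUE, length(d$t))
    flags <- c(flags, "no_gtp0_window_unrestricted")
  } else {
    keep <- d$y <= 0.2 * gtp0
  }
  if (sum(keep) < 3L)
    stop("fewer than 3 points in the initial linear window", call. = FALSE)
  fit <- stats::lm(y ~ t, data = data.frame(t = d$t[keep], y = d$y[keep]))
  slope <- unname(stats::coef(fit)["t"])
  if (!is.finite(slope) || slope <= 0)
    stop("non-physical progress curve: Pi does not increase over the window",
         call. = FALSE)
  # summary() warns on an exactly linear input; the SE is still valid (0)
  se_slope <- suppressWarnings(
    summary(fit)$coefficients["t", "Std. Error"])
  params <- c(turnover = slope / g_conc, slope = slope)
  se <- c(turnover = se_slope / g_conc, slope = se_slope)
  fit_result(params, se = se,
             residual_ss = sum(stats::residuals(fit)^2),
             n_points = sum(keep), converged = TRUE, flags = flags)
}

# Robust per-trace noise estimate: median absolute successive difference
# scaled to SD units (successive differences of iid noise have SD sqrt(2)).
trace_noise_sd <- function(response) {
  if (length(response) < 3L) return(0)
  stats::median(abs(diff(response))) / (sqrt(2) * 0.6745)
}

#' Global 1:1 Langmuir fit of an SPR sensorgram series
#'
#' Fits one shared (`k_a`, `k_d`, `R_max`) triple to sensorgrams recorded at
#' multiple analyte concentrations by pooled Levenberg-Marquardt least
#' squares over both phases of every curve. `R_max` may optionally vary per
#' curve (surface drift); `k_a` and `k_d` are always shared. A series whose
#' maximal response stays below 3x the estimated response noise is reported
#' as a non-binder rather than fitted.
#'
#' @param series List of [sensorgram()] objects (>= 2 distinct
#'   concentrations for a well-posed fit; a single concentration is fitted
#'   with a degeneracy warning).
#' @param shared_rmax If `FALSE`, each curve gets its own R_max.
#' @return A [binding_kinetics()] with attributes `fit` (the underlying
#'   [fit_result()]) and `non_binder = FALSE`; or, for a non-binder, a
#'   list of class `spr_nonbinder`.
#' @export
fit_spr_global <- function(series, shared_rmax = TRUE) {
  if (inherits(series, "sensorgram")) series <- list(series)
  stopifnot(length(series) >= 1L,
            all(vapply(series, inherits, TRUE, "sensorgram")))
  concs <- vapply(series, `[[`, 0, "conc")
  if (length(unique(concs)) < 2L)
    warning("single analyte concentration: k_a and k_d are degenerate",
            call. = FALSE)

  noise <- max(vapply(series, function(s) trace_noise_sd(s$response), 0))
  max_resp <- max(vapply(series, function(s) max(abs(s$response)), 0))
  if (max_resp < max(3 * noise, 1e-8)) {
    return(structure(list(non_binder = TRUE, max_response = max_resp,
                          noise_sd = noise),
                     class = "spr_nonbinder"))
  }

  n_cur <- length(series)
  rmax0 <- max_resp
  # k_d start from a log-linear fit of the strongest curve's dissociation tail
  top <- series[[which.max(concs)]]
  diss <- top$times > top$t_assoc & top$response > 0.05 * max_resp
  kd0 <- if (sum(diss) >= 3) {
    sl <- stats::coef(stats::lm(log(top$response[diss]) ~ top$times[diss]))[2]
    max(-unname(sl), 1e-6)
  } else 1e-2
  ka0 <- kd0 / (stats::median(concs))  # start near K_D ~ median conc

  model_resid <- function(p) {
    k_a <- exp(p[["log_ka"]]); k_d <- exp(p[["log_kd"]])
    unlist(lapply(seq_len(n_cur), function(i) {
      s <- series[[i]]
      rmax <- if (shared_rmax) p[["rmax"]] else p[[paste0("rmax", i)]]
      langmuir_response(s$times, k_a, k_d, rmax, s$conc, s$t_assoc) - s$response
    }))
  }

  par0 <- c(log_ka = log(ka0), log_kd = log(kd0))
  par0 <- if (shared_rmax) c(par0, rmax = rmax0)
          else c(par0, stats::setNames(rep(rmax0, n_cur),
                                       paste0("rmax", seq_len(n_cur))))
  best <- NULL
  for (mult in c(0.1, 1, 10)) {
    p <- par0
    p[["log_ka"]] <- log(ka0 * mult)
    fit <- try(minpack.lm::nls.lm(
      par = p, fn = model_resid,
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                           ptol = 1e-14)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best))
    stop("global SPR fit failed to converge", call. = FALSE)

  k_a <- exp(best$par[["log_ka"]]); k_d <- exp(best$par[["log_kd"]])
  rmax <- if (shared_rmax) best$par[["rmax"]]
          else mean(unlist(best$par[grep("^rmax", names(best$par))]))
  n <- sum(vapply(series, function(s) length(s$times), 0L))
  cov <- try(solve(best$hessian) * best$deviance / max(n - length(best$par), 1),
             silent = TRUE)
  se <- if (inherits(cov, "try-error")) NULL else {
    s <- sqrt(pmax(diag(cov), 0))
    # delta method back to the rate scale
    out <- c(k_a = k_a * s[["log_ka"]], k_d = k_d * s[["log_kd"]])
    if (shared_rmax) out <- c(out, r_max = s[["rmax"]])
    out
  }
  params <- c(k_a = k_a, k_d = k_d, r_max = rmax, k_D = k_d / k_a)
  fr <- fit_result(params, se = se, residual_ss = best$deviance,
                   n_points = n, converged = TRUE,
                   flags = if (length(unique(concs)) < 2L)
                     "single_concentration_degenerate" else character())
  kin <- binding_kinetics(k_a, k_d, rmax)
  attr(kin, "fit") <- fr
  attr(kin, "non_binder") <- FALSE
  kin
}

#' Fit the hyperbolic GAP dose response
#'
#' Fits `k_obs([RGS]) = k_cat + k_gap_max [RGS] / (k_half_gap + [RGS])` to
#' observed single-turnover rates at a series of RGS concentrations. A
#' zero-dose point is required to anchor `k_cat`. A fit whose saturating
#' stimulation `(k_cat + k_gap_max)/k_cat` stays below 1.5-fold is flagged
#' `rgs_insensitive`.
#'
#' @param doses Data frame with columns `rgs_conc` (nM) and `k_obs` (min^-1),
#'   or a two-column matrix in that order.
#' @return A [fit_result()] with parameters `k_cat`, `k_gap_max`,
#'   `k_half_gap`.
#' @export
fit_gap_dose_response <- function(doses) {
  doses <- as.data.frame(doses)
  if (!all(c("rgs_conc", "k_obs") %in% names(doses)))
    names(doses)[1:2] <- c("rgs_conc", "k_obs")
  if (nrow(doses) < 4L)
    stop("at least 4 dose points are required", call. = FALSE)
  if (!any(doses$rgs_conc == 0))
    stop("a zero-dose point is required (k_cat unidentifiable without it)",
         call. = FALSE)
  x <- doses$rgs_conc; y <- doses$k_obs
  kcat0 <- mean(y[x == 0])
  kmax0 <- max(max(y) - kcat0, 1e-6)
  kh0 <- max(stats::median(x[x > 0]), 1e-3)

  resid_fn <- function(p)
    p[["k_cat"]] + p[["k_gap_max"]] * x / (exp(p[["log_kh"]]) + x) - y
  best <- NULL
  for (mult in c(0.3, 1, 3)) {
    fit <- try(minpack.lm::nls.lm(
      par = c(k_cat = kcat0, k_gap_max = kmax0, log_kh = log(kh0 * mult)),
      fn = resid_fn,
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                           ptol = 1e-14)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) stop("GAP dose-response fit failed", call. = FALSE)
  kcat <- best$par[["k_cat"]]; kmax <- best$par[["k_gap_max"]]
  kh <- exp(best$par[["log_kh"]])
  flags <- character()
  if (kcat > 0 && (kcat + max(kmax, 0)) / kcat < 1.5)
    flags <- c(flags, "rgs_insensitive")
  n <- length(y)
  cov <- try(solve(best$hessian) * best$deviance / max(n - 3, 1),
             silent = TRUE)
  se <- if (inherits(cov, "try-error")) NULL else {
    s <- sqrt(pmax(diag(cov), 0))
    c(k_cat = s[["k_cat"]], k_gap_max = s[["k_gap_max"]],
      k_half_gap = kh * s[["log_kh"]])
  }
  fit_result(c(k_cat = kcat, k_gap_max = kmax, k_half_gap = kh),
             se = se, residual_ss = best$deviance, n_points = n,
             converged = TRUE, flags = flags)
}
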