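#' Intrinsic cycle rate constants of a Galpha subunit
#'
#' Bundles the first-order rate constants that define one Galpha protein's
#' nucleotide cycle: the apparent nucleotide exchange rate (GDP release /
#' GTPgammaS binding, often written K_obs), the intrinsic single-turnover GTP
#' hydrolysis rate (K_cat), and, optionally, the GAP (RGS) dose-response
#' parameters. Enzymology rates are in min^-1; RGS concentration in nM.
#'
#' @param k_exchange Apparent first-order nucleotide exchange rate, min^-1.
#'   Must be finite and >= 0 (and > 0 for any binding simulation).
#' @param k_cat Intrinsic single-turnover GTP hydrolysis rate, min^-1.
#' @param k_gap_max Maximal GAP-added hydrolysis rate above `k_cat`, min^-1,
#'   or `NA` if the protein's GAP response is not parameterised.
#' @param k_half_gap RGS concentration at half-maximal GAP effect, nM, or `NA`.
#' @return An object of class `rate_constants`.
#' @examples
#' rc <- rate_constants(k_exchange = 5.80, k_cat = 0.047)
#' fraction_gtp_bound(rc)
#' @export
rate_constants <- function(k_exchange, k_cat, k_gap_max = NA_real_,
                           k_half_gap = NA_real_) {
  for (nm in c("k_exchange", "k_cat")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      stop(sprintf("%s must be a single finite non-negative number", nm),
           call. = FALSE)
  }
  for (nm in c("k_gap_max", "k_half_gap")) {
    v <- get(nm)
    if (!is.na(v) && (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0))
      stop(sprintf("%s must be NA or a single finite non-negative number", nm),
           call. = FALSE)
  }
  structure(
    list(k_exchange = as.numeric(k_exchange), k_cat = as.numeric(k_cat),
         k_gap_max = as.numeric(k_gap_max), k_half_gap = as.numeric(k_half_gap)),
    class = "rate_constants"
  )
}

#' @export
print.rate_constants <- function(x, ...) {
  cat("Galpha cycle rate constants (min^-1):\n")
  cat(sprintf("  k_exchange (nucleotide exchange) : %.4g\n", x$k_exchange))
  cat(sprintf("  k_cat (GTP hydrolysis)           : %.4g\n", x$k_cat))
  if (!is.na(x$k_gap_max))
    cat(sprintf("  k_gap_max (maximal GAP boost)    : %.4g\n", x$k_gap_max))
  if (!is.na(x$k_half_gap))
    cat(sprintf("  k_half_gap (half-effect [RGS])   : %.4g nM\n", x$k_half_gap))
  invisible(x)
}

#' Nucleotide pool state for the finite-GTP cycle model
#'
#' State vector for [turnover_ode()]: total Galpha, GTP-occupied Galpha, and
#' the free GTP and GDP pools, all in nM. The remaining Galpha
#' (`g_total - g_gtp`) is taken to be GDP-occupied.
#'
#' @param g_total Total Galpha concentration, nM (> 0 for simulation).
#' @param g_gtp GTP-occupied Galpha, nM, in `[0, g_total]`.
#' @param free_gtp,free_gdp Free nucleotide pools, nM, >= 0.
#' @return An object of class `cycle_pools`.
#' @export
cycle_pools <- function(g_total, g_gtp = 0, free_gtp = 0, free_gdp = 0) {
  vals <- c(g_total = g_total, g_gtp = g_gtp,
            free_gtp = free_gtp, free_gdp = free_gdp)
  if (!all(is.finite(vals)))
    stop("all pool concentrations must be finite", call. = FALSE)
  if (any(vals < 0))
    stop("pool concentrations must be non-negative", call. = FALSE)
  if (g_gtp > g_total)
    stop("g_gtp cannot exceed g_total", call. = FALSE)
  structure(as.list(vals), class = "cycle_pools")
}

# Shared validation for time vectors used by the closed-form simulators.
check_times <- function(times) {
  if (!is.numeric(times) || length(times) == 0L)
    stop("times must be a non-empty numeric vector", call. = FALSE)
  bad <- which(times < 0)
  if (length(bad))
    stop(sprintf("negative time at index %d (t = %g)", bad[1], times[bad[1]]),
         call. = FALSE)
  if (any(diff(times) <= 0))
    stop("times must be strictly increasing", call. = FALSE)
  invisible(times)
}
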