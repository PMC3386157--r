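#' Closed-form GTPgammaS binding curve
#'
#' Pseudo-first-order association of a non-hydrolysable GTP analog to a
#' GDP-loaded Galpha: `B(t) = b_max * (1 - exp(-k_exchange * t))`. Because
#' GTPgammaS is not hydrolysed, the apparent rate is the nucleotide exchange
#' rate alone and the plateau is set by the amount of exchange-competent
#' protein (nominal concentration times specific activity).
#'
#' @param rc A [rate_constants()] object; `k_exchange` must be > 0.
#' @param b_max Binding plateau, nM-equivalent of bound label (>= 0).
#' @param times Sampling times, min.
#' @return A [time_course()] of kind `"gtpgs_binding"`.
#' @examples
#' tc <- gtpgs_binding_curve(rate_constants(5.80, 0.047), b_max = 460,
#'                           times = seq(0, 2, by = 0.1))
#' @export
gtpgs_binding_curve <- function(rc, b_max, times) {
  stopifnot(inherits(rc, "rate_constants"))
  if (rc$k_exchange <= 0)
    stop("k_exchange must be > 0 to simulate binding", call. = FALSE)
  if (b_max < 0) stop("b_max must be >= 0", call. = FALSE)
  check_times(times)
  vals <- b_max * (1 - exp(-rc$k_exchange * times))
  time_course(times, vals, assay_kind = "gtpgs_binding", unit = "min",
              meta = list(k_exchange = rc$k_exchange, b_max = b_max))
}

#' Closed-form single-turnover GTP hydrolysis curve
#'
#' Galpha preloaded with labelled GTP releases Pi in a single first-order
#' step: `Pi(t) = p0 * (1 - exp(-k_cat * t))`, where `p0` is the amount of
#' preloaded (hydrolysable) GTP.
#'
#' @param rc A [rate_constants()] object.
#' @param p0 Preloaded GTP, nM-equivalent (>= 0).
#' @param times Sampling times, min.
#' @return A [time_course()] of kind `"single_turnover"`.
#' @export
single_turnover_curve <- function(rc, p0, times) {
  stopifnot(inherits(rc, "rate_constants"))
  if (p0 < 0) stop("p0 must be >= 0", call. = FALSE)
  check_times(times)
  vals <- p0 * (1 - exp(-rc$k_cat * times))
  time_course(times, vals, assay_kind = "single_turnover", unit = "min",
              meta = list(k_cat = rc$k_cat, p0 = p0))
}

#' Steady-state turnover rate from the two-step series model
#'
#' Multi-turnover GTP hydrolysis cycles through two first-order steps —
#' nucleotide exchange, then hydrolysis — so the per-Galpha cycling rate is
#' the harmonic combination `v = 1 / (1/k_exchange + 1/k_cat)`. The slower
#' step dominates: `v < min(k_exchange, k_cat)` always.
#'
#' @param rc A [rate_constants()] object with both rates > 0.
#' @return Steady-state turnover, min^-1 per Galpha.
#' @examples
#' steady_state_turnover(rate_constants(5.80, 0.047))  # ~0.0466
#' @export
steady_state_turnover <- function(rc) {
  stopifnot(inherits(rc, "rate_constants"))
  if (rc$k_exchange <= 0 || rc$k_cat <= 0)
    stop("steady-state turnover undefined: both k_exchange and k_cat must be > 0",
         call. = FALSE)
  1 / (1 / rc$k_exchange + 1 / rc$k_cat)
}

#' Steady-state fraction of GTP-occupied Galpha
#'
#' With exchange loading GTP at rate `k_exchange` and hydrolysis clearing it
#' at `k_cat`, the cycle settles at occupancy
#' `k_exchange / (k_exchange + k_cat)`. A self-activating Galpha (exchange
#' faster than hydrolysis) sits mostly GTP-bound at steady state; note that
#' the in-vivo state additionally depends on the cellular GTP/GDP ratio and
#' interacting proteins.
#'
#' @param rc A [rate_constants()] object with `k_exchange + k_cat > 0`.
#' @return Fraction in `[0, 1]`.
#' @seealso [pct_gtp_bound()] for the integer-percent reporting helper.
#' @export
fraction_gtp_bound <- function(rc) {
  stopifnot(inherits(rc, "rate_constants"))
  if (rc$k_exchange + rc$k_cat <= 0)
    stop("occupancy undefined: k_exchange + k_cat must be > 0", call. = FALSE)
  rc$k_exchange / (rc$k_exchange + rc$k_cat)
}

# Integer rounding, half away from zero (commercial rounding). Used for
# reported percentages and fold changes so that e.g. 94.65 -> 95.
round_half_up <- function(x) floor(x + 0.5)

#' Percent GTP-bound, rounded to the nearest integer
#'
#' Reporting helper: [fraction_gtp_bound()] expressed as an integer percent,
#' rounded half-up.
#'
#' @inheritParams fraction_gtp_bound
#' @return Integer percent in `[0, 100]`.
#' @export
pct_gtp_bound <- function(rc) {
  as.integer(round_half_up(100 * fraction_gtp_bound(rc)))
}

#' GAP-stimulated single-turnover hydrolysis rate
#'
#' Hyperbolic dose response of the observed hydrolysis rate to RGS (GAP)
#' concentration:
#' `k_obs = k_cat + k_gap_max * [RGS] / (k_half_gap + [RGS])`.
#'
#' @param rc A [rate_constants()] with `k_gap_max` and `k_half_gap` set
#'   (required whenever `rgs_conc > 0`).
#' @param rgs_conc RGS concentration, nM (>= 0; vectorised).
#' @return Observed hydrolysis rate(s), min^-1.
#' @export
gap_hydrolysis_rate <- function(rc, rgs_conc) {
  stopifnot(inherits(rc, "rate_constants"))
  if (any(rgs_conc < 0)) stop("rgs_conc must be >= 0", call. = FALSE)
  if (any(rgs_conc > 0) && (is.na(rc$k_gap_max) || is.na(rc$k_half_gap)))
    stop("GAP parameters (k_gap_max, k_half_gap) are unset for this protein",
         call. = FALSE)
  if (all(rgs_conc == 0)) return(rep(rc$k_cat, length(rgs_conc)))
  rc$k_cat + rc$k_gap_max * rgs_conc / (rc$k_half_gap + rgs_conc)
}

#' Finite-GTP-pool nucleotide cycle ODE
#'
#' Integrates the cycle under a finite nucleotide pool, the situation in a
#' fluorescence cuvette where a fixed bolus of GTP is added to GDP-loaded
#' Galpha. GTP-occupancy follows
#' `d(g_gtp)/dt = k_exchange * (g_total - g_gtp) * phi - k_cat * g_gtp`
#' with the competition factor `phi = free_gtp / (free_gtp + free_gdp)`
#' (mass-action competition of GTP and accumulated GDP for the empty site).
#' Each productive exchange event consumes one free GTP and releases one
#' bound GDP, so `free_gtp + free_gdp` is conserved; hydrolysis converts
#' bound GTP to bound GDP without touching the free pool. Cumulative Pi
#' release (`pi_released`) is integrated alongside.
#'
#' @param rc A [rate_constants()] object.
#' @param pools0 Initial [cycle_pools()] state; `g_total` > 0.
#' @param times Output times, min (first may be 0).
#' @param hydrolysable If `FALSE`, the bound nucleotide is a GTPgammaS-like
#'   analog: the hydrolysis term is dropped.
#' @param unlimited_gtp If `TRUE`, the competition factor is pinned at 1
#'   (saturating GTP); the free pools are then bookkeeping only.
#' @return A data.frame with columns `time`, `g_gtp`, `free_gtp`, `free_gdp`,
#'   `pi_released`, plus attribute `g_total`.
#' @examples
#' p0 <- cycle_pools(g_total = 276, free_gtp = 800)
#' traj <- turnover_ode(rate_constants(1.84, 0.87), p0, seq(0, 30, 0.1))
#' @export
turnover_ode <- function(rc, pools0, times, hydrolysable = TRUE,
                         unlimited_gtp = FALSE) {
  stopifnot(inherits(rc, "rate_constants"), inherits(pools0, "cycle_pools"))
  if (pools0$g_total <= 0) stop("g_total must be > 0", call. = FALSE)
  if (!is.numeric(times) || any(times < 0) || any(diff(times) <= 0))
    stop("times must be non-negative and strictly increasing", call. = FALSE)
  k_cat_eff <- if (hydrolysable) rc$k_cat else 0
  g_total <- pools0$g_total

  deriv <- function(t, y, parms) {
    phi <- if (unlimited_gtp) 1 else {
      tot <- y[["free_gtp"]] + y[["free_gdp"]]
      if (tot <= 0) 0 else y[["free_gtp"]] / tot
    }
    exch <- rc$k_exchange * (g_total - y[["g_gtp"]]) * phi
    hyd <- k_cat_eff * y[["g_gtp"]]
    list(c(g_gtp = exch - hyd,
           free_gtp = -exch,
           free_gdp = exch,
           pi_released = hyd))
  }

  y0 <- c(g_gtp = pools0$g_gtp, free_gtp = pools0$free_gtp,
          free_gdp = pools0$free_gdp, pi_released = 0)
  # prepend t = 0 if absent so lsoda starts from the initial condition
  t_out <- if (times[1] > 0) c(0, times) else times
  sol <- deSolve::lsoda(y0, t_out, deriv, parms = NULL,
                        rtol = 1e-8, atol = 1e-10)
  if (attr(sol, "istate")[1] < 0)
    stop("ODE integration failed: ",
         paste(attr(sol, "istate"), collapse = " "), call. = FALSE)
  df <- as.data.frame(sol)
  names(df)[1] <- "time"
  if (times[1] > 0) df <- df[-1, , drop = FALSE]
  rownames(df) <- NULL
  # clip tiny negative round-off
  df$g_gtp <- pmin(pmax(df$g_gtp, 0), g_total)
  attr(df, "g_total") <- g_total
  df
}

#' Closed-form 1:1 Langmuir SPR sensorgram
#'
#' Association: `R(t) = R_eq * (1 - exp(-(k_a C + k_d) t))` with
#' `R_eq = k_a C R_max / (k_a C + k_d)`; dissociation decays from the
#' association endpoint at rate `k_d`. Times are seconds.
#'
#' @param kin A [binding_kinetics()] object.
#' @param analyte_conc Analyte concentration, M (> 0).
#' @param t_assoc,t_dissoc Phase durations, s (> 0).
#' @param dt Sampling interval, s (> 0).
#' @param bulk Optional additive bulk refractive-index offset during
#'   association only (RU), default 0.
#' @return A [sensorgram()].
#' @export
spr_sensorgram <- function(kin, analyte_conc, t_assoc = 180, t_dissoc = 300,
                           dt = 1, bulk = 0) {
  stopifnot(inherits(kin, "binding_kinetics"))
  if (analyte_conc <= 0) stop("analyte_conc must be > 0", call. = FALSE)
  if (t_assoc <= 0 || t_dissoc <= 0)
    stop("phase durations must be > 0", call. = FALSE)
  if (dt <= 0) stop("dt must be > 0", call. = FALSE)
  times <- seq(0, t_assoc + t_dissoc, by = dt)
  resp <- langmuir_response(times, kin$k_a, kin$k_d, kin$r_max,
                            analyte_conc, t_assoc)
  resp[times <= t_assoc] <- resp[times <= t_assoc] + bulk
  sensorgram(times, resp, conc = analyte_conc, t_assoc = t_assoc,
             meta = list(k_a = kin$k_a, k_d = kin$k_d, r_max = kin$r_max))
}

# Langmuir 1:1 model response at arbitrary times (shared by simulator and
# global fitter). Continuous at t_assoc by construction.
langmuir_response <- function(times, k_a, k_d, r_max, conc, t_assoc) {
  k_obs <- k_a * conc + k_d
  r_eq <- k_a * conc * r_max / k_obs
  r_end <- r_eq * (1 - exp(-k_obs * t_assoc))
  ifelse(times <= t_assoc,
         r_eq * (1 - exp(-k_obs * times)),
         r_end * exp(-k_d * (times - t_assoc)))
}
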