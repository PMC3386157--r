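#' Which cycle step limits the nucleotide cycle?
#'
#' Compares the nucleotide exchange rate with the hydrolysis rate: the slower
#' step names the rate-limiting step. Rates within 5 % of each other are
#' called `"balanced"` (a reporting band; any band below 2-fold keeps a
#' protein with a 2.1-fold rate ratio classified as hydrolysis-limited).
#'
#' @param k_exchange,k_cat Positive rates, min^-1.
#' @param balanced_band Relative half-width of the balanced band (default
#'   0.05).
#' @return `"exchange"`, `"hydrolysis"` or `"balanced"`.
#' @examples
#' rate_limiting_step(5.80, 0.047)  # "hydrolysis"
#' @export
rate_limiting_step <- function(k_exchange, k_cat, balanced_band = 0.05) {
  if (!is.numeric(k_exchange) || !is.numeric(k_cat) ||
      k_exchange <= 0 || k_cat <= 0)
    stop("both rates must be positive", call. = FALSE)
  if (abs(k_exchange - k_cat) <= balanced_band * max(k_exchange, k_cat))
    return("balanced")
  if (k_cat < k_exchange) "hydrolysis" else "exchange"
}

#' Classify a Galpha's activation mode
#'
#' A Galpha is *self-activating* when nucleotide exchange outpaces GTP
#' hydrolysis, so it accumulates in the active GTP-bound state with no GEF;
#' otherwise it is *GEF-dependent* (the animal-like regime). A fast
#' hydrolyser (`k_cat >= 0.5 min^-1`) is additionally flagged
#' *self-inactivating*: it resets its own inactive state without a GAP, the
#' behaviour of the liverwort Galpha.
#'
#' @param k_exchange,k_cat Positive rates, min^-1. A [rate_constants()]
#'   object may be given as the first argument instead.
#' @param self_inactivating_kcat Threshold on `k_cat` for the
#'   self-inactivating flag (min^-1, default 0.5; a reporting heuristic).
#' @return List with `activation_class` (`"self_activating"` or
#'   `"gef_dependent"`) and logical `self_inactivating`.
#' @export
classify_activation <- function(k_exchange, k_cat = NULL,
                                self_inactivating_kcat = 0.5) {
  if (inherits(k_exchange, "rate_constants")) {
    rc <- k_exchange
    k_exchange <- rc$k_exchange
    k_cat <- rc$k_cat
  }
  if (is.null(k_cat) || !is.numeric(k_exchange) || !is.numeric(k_cat) ||
      !is.finite(k_exchange) || !is.finite(k_cat))
    stop("both k_exchange and k_cat are required", call. = FALSE)
  list(
    activation_class = if (k_exchange > k_cat) "self_activating"
                       else "gef_dependent",
    self_inactivating = k_cat >= self_inactivating_kcat
  )
}

#' GAP fold-acceleration of steady-state hydrolysis
#'
#' Ratio of the steady-state turnover with RGS present to the turnover
#' without it. Ratios of at least 1.5-fold are flagged as RGS-stimulated;
#' the band separates an RGS-insensitive protein (~1.07-fold) from the
#' weakest genuinely stimulated case (~5-fold).
#'
#' @param v_minus Turnover without RGS, min^-1 (> 0).
#' @param v_plus Turnover with RGS, min^-1.
#' @param threshold Stimulation threshold on the ratio (default 1.5).
#' @return List with `fold` (exact ratio) and logical `rgs_stimulated`.
#' @examples
#' gap_fold_acceleration(0.025, 0.503)  # ~20-fold, stimulated
#' @export
gap_fold_acceleration <- function(v_minus, v_plus, threshold = 1.5) {
  if (!is.numeric(v_minus) || v_minus <= 0)
    stop("v_minus must be > 0", call. = FALSE)
  fold <- v_plus / v_minus
  list(fold = fold, rgs_stimulated = fold >= threshold)
}

#' Fold change in RGS binding affinity between two Galpha variants
#'
#' Ratio of dissociation constants, `kd_variant / kd_ref`. Values above 1
#' mean the variant binds RGS more weakly (affinity reduced); below 1, more
#' tightly (affinity increased, reported as the integer-rounded inverse).
#'
#' @param kd_ref,kd_variant Dissociation constants, same units, both > 0.
#' @return List with `ratio` (exact), `fold` (integer-rounded magnitude of
#'   the change, half-up), `direction` (`"weakened"`, `"strengthened"` or
#'   `"unchanged"`), and `label` like `"7-fold decrease in affinity"`.
#' @examples
#' affinity_fold_change(17.4e-9, 115e-9)  # 6.6 -> "7-fold" weakening
#' @export
affinity_fold_change <- function(kd_ref, kd_variant) {
  if (!is.numeric(kd_ref) || !is.numeric(kd_variant) ||
      kd_ref <= 0 || kd_variant <= 0)
    stop("both dissociation constants must be > 0", call. = FALSE)
  ratio <- kd_variant / kd_ref
  if (ratio >= 1) {
    fold <- as.integer(round_half_up(ratio))
    direction <- if (ratio == 1) "unchanged" else "weakened"
    label <- sprintf("%d-fold decrease in affinity", fold)
  } else {
    fold <- as.integer(round_half_up(1 / ratio))
    direction <- "strengthened"
    label <- sprintf("%d-fold increase in affinity", fold)
  }
  list(ratio = ratio, fold = fold, direction = direction, label = label)
}

#' Assemble a per-protein regulatory profile
#'
#' Collects fitted constants for one Galpha into the summary record the
#' package reports: intrinsic rates, derived occupancy, rate-limiting step,
#' activation classification, and the optional RGS-coupling measures.
#'
#' @param name Protein name.
#' @param k_obs_binding Nucleotide exchange rate from GTPgammaS binding,
#'   min^-1 (required).
#' @param k_cat Single-turnover hydrolysis rate, min^-1 (required).
#' @param k_obs_fluorescence Optional exchange rate from Trp fluorescence.
#' @param kd_rgs Optional RGS-binding K_D, M.
#' @param v_minus_rgs,v_plus_rgs Optional steady-state turnover without /
#'   with RGS, min^-1 (both needed for the GAP fold fields).
#' @return An object of class `galpha_profile`.
#' @export
build_profile <- function(name, k_obs_binding = NULL, k_cat = NULL,
                          k_obs_fluorescence = NA_real_, kd_rgs = NA_real_,
                          v_minus_rgs = NA_real_, v_plus_rgs = NA_real_) {
  missing_fields <- c(
    if (is.null(k_obs_binding) || !is.finite(k_obs_binding)) "k_obs_binding",
    if (is.null(k_cat) || !is.finite(k_cat)) "k_cat")
  if (length(missing_fields))
    stop("missing mandatory fit(s): ", paste(missing_fields, collapse = ", "),
         call. = FALSE)
  rc <- rate_constants(k_obs_binding, k_cat)
  act <- classify_activation(k_obs_binding, k_cat)
  gap <- if (is.finite(v_minus_rgs) && is.finite(v_plus_rgs))
    gap_fold_acceleration(v_minus_rgs, v_plus_rgs)
  else list(fold = NA_real_, rgs_stimulated = NA)
  structure(list(
    name = name,
    k_obs_binding = k_obs_binding,
    k_obs_fluorescence = k_obs_fluorescence,
    k_cat = k_cat,
    kd_rgs = kd_rgs,
    pct_gtp_bound = pct_gtp_bound(rc),
    rate_limiting = rate_limiting_step(k_obs_binding, k_cat),
    activation_class = act$activation_class,
    self_inactivating = act$self_inactivating,
    v_minus_rgs = v_minus_rgs,
    v_plus_rgs = v_plus_rgs,
    gap_fold = gap$fold,
    rgs_stimulated = gap$rgs_stimulated
  ), class = "galpha_profile")
}

#' @export
print.galpha_profile <- function(x, ...) {
  cat(sprintf("<galpha_profile> %s\n", x$name))
  cat(sprintf("  exchange %.3g /min, hydrolysis %.3g /min -> %d%% GTP-bound\n",
              x$k_obs_binding, x$k_cat, x$pct_gtp_bound))
  cat(sprintf("  rate-limiting: %s; %s%s\n", x$rate_limiting,
              x$activation_class,
              if (isTRUE(x$self_inactivating)) " (self-inactivating)" else ""))
  if (is.finite(x$gap_fold))
    cat(sprintf("  GAP fold-acceleration: %.3g (%s)\n", x$gap_fold,
                if (isTRUE(x$rgs_stimulated)) "RGS-stimulated"
                else "not stimulated"))
  if (is.finite(x$kd_rgs))
    cat(sprintf("  K_D for RGS: %.3g M\n", x$kd_rgs))
  invisible(x)
}

#' Tabulate profiles
#'
#' @param profiles List of `galpha_profile` objects (or a single one).
#' @return A data.frame, one row per protein, column order following the
#'   kinetics columns first, then the SPR / GAP extensions.
#' @export
profile_table <- function(profiles) {
  if (inherits(profiles, "galpha_profile")) profiles <- list(profiles)
  do.call(rbind, lapply(profiles, function(p) {
    data.frame(name = p$name,
               k_obs_binding = p$k_obs_binding,
               k_obs_fluorescence = p$k_obs_fluorescence,
               k_cat = p$k_cat,
               rate_limiting = p$rate_limiting,
               pct_gtp_bound = p$pct_gtp_bound,
               activation_class = p$activation_class,
               self_inactivating = p$self_inactivating,
               kd_rgs = p$kd_rgs,
               v_minus_rgs = p$v_minus_rgs,
               v_plus_rgs = p$v_plus_rgs,
               gap_fold = p$gap_fold,
               rgs_stimulated = p$rgs_stimulated,
               stringsAsFactors = FALSE)
  }))
}

#' Published kinetic constants for the plant Galpha reference panel
#'
#' Literature in-vitro constants for five plant Galpha subunits — the
#' Arabidopsis (AtGPA1) and rice (OsRGA1) wild types, their reciprocal
#' switch-I point mutants (T194N, N195T), the pine PtGa1 and the liverwort
#' MpGa1 — measured at 20 degC: GTPgammaS binding rate, fluorescence
#' exchange rate, single-turnover hydrolysis rate (all min^-1), SPR kinetics
#' against the Arabidopsis RGS domain (k_a in /M/s, k_d in /s), and
#' steady-state turnover without / with 750 nM RGS (min^-1). `NA` marks
#' quantities not measured for that protein.
#'
#' @return A data.frame with one row per protein.
#' @examples
#' panel <- galpha_reference_panel()
#' pct_gtp_bound(rate_constants(panel$k_obs_binding[1], panel$k_cat[1]))
#' @export
galpha_reference_panel <- function() {
  data.frame(
    name = c("AtGPA1", "AtGPA1 T194N", "OsRGA1", "OsRGA1 N195T",
             "PtGa1", "MpGa1"),
    k_obs_binding = c(5.80, 6.97, 0.92, 0.70, 6.85, 1.84),
    k_obs_fluorescence = c(3.63, NA, 2.38, NA, NA, 4.09),
    k_cat = c(0.047, 0.059, 0.052, 0.051, NA, 0.87),
    spr_ka = c(3.53e5, 1.17e5, 3.83e5, 1.21e6, NA, NA),
    spr_kd = c(6.16e-3, 1.34e-2, 2.17e-2, 5.84e-3, NA, NA),
    v_minus_rgs = c(0.025, 0.031, 0.019, 0.031, NA, 1.06),
    v_plus_rgs = c(0.503, 0.158, 0.127, 0.288, NA, 1.13),
    stringsAsFactors = FALSE
  )
}

#' Write a profile table to CSV and JSON
#'
#' @param profiles List of `galpha_profile` objects.
#' @param csv_path,json_path Output paths (`NULL` to skip either).
#' @return The table data.frame, invisibly.
#' @export
write_profile_table <- function(profiles, csv_path = NULL, json_path = NULL) {
  tab <- profile_table(profiles)
  if (!is.null(csv_path))
    utils::write.csv(tab, csv_path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(tab, json_path, auto_unbox = TRUE, digits = NA,
                         na = "null")
  invisible(tab)
}
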