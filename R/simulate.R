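# Run code with a private, seeded RNG stream, restoring the caller's state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

#' Noise model for synthetic assay data
#'
#' @param kind `"multiplicative_gaussian"` (sd is a fraction of the signal,
#'   the scintillation-counting regime) or `"additive_gaussian"` (sd in
#'   signal units, the SPR regime).
#' @param sd Noise magnitude, >= 0.
#' @param seed Integer seed; identical seed and parameters give bit-identical
#'   output.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(kind = c("multiplicative_gaussian",
                                 "additive_gaussian"),
                        sd = 0, seed = NULL) {
  kind <- match.arg(kind)
  if (!is.numeric(sd) || sd < 0) stop("noise sd must be >= 0", call. = FALSE)
  structure(list(kind = kind, sd = sd, seed = seed), class = "noise_model")
}

# Draw noise for a clean signal vector using the current RNG stream.
apply_noise <- function(values, nm) {
  if (nm$sd == 0) return(values)
  eps <- stats::rnorm(length(values), 0, nm$sd)
  if (nm$kind == "multiplicative_gaussian") values * (1 + eps)
  else values + eps
}

#' Default sampling times for an exponential assay
#'
#' Ten log-spaced points over the rise for fast rates (>= 1 min^-1, the
#' exchange regime); for slower rates, twelve linear points out to five
#' characteristic times, capped at 60 min (so the slowest hydrolysis assays
#' span 5-60 min).
#'
#' @param k Rate constant, min^-1.
#' @return Numeric vector of times, min.
#' @export
default_assay_times <- function(k) {
  if (k <= 0) stop("rate must be > 0 to choose sampling times", call. = FALSE)
  if (k >= 1) return(exp(seq(log(0.05 / k), log(4 / k), length.out = 10)))
  t_end <- min(60, 5 / k)
  seq(t_end / 12, t_end, length.out = 12)
}

#' Simulate GTPgammaS binding time courses
#'
#' Seeded noisy replicates of the pseudo-first-order binding curve. The
#' plateau is the exchange-competent protein: nominal concentration times
#' specific activity (mol GTPgammaS bound per mol protein).
#'
#' @param rc [rate_constants()]; `k_exchange` > 0.
#' @param g_conc Nominal Galpha concentration, nM.
#' @param specific_activity Fraction of protein competent to bind, mol/mol
#'   (in `[0, 1]`-ish; must be >= 0).
#' @param times Sampling times, min; default from [default_assay_times()].
#' @param noise A [noise_model()]; default 3 % multiplicative.
#' @param seed Integer seed.
#' @param replicates Number of replicate traces (>= 1).
#' @return List of [time_course()] objects.
#' @export
gen_gtpgs_binding <- function(rc, g_conc = 1000, specific_activity = 0.46,
                              times = NULL,
                              noise = noise_model("multiplicative_gaussian", 0.03),
                              seed = 1L, replicates = 1L) {
  stopifnot(inherits(rc, "rate_constants"))
  if (specific_activity < 0)
    stop("specific_activity must be >= 0", call. = FALSE)
  if (replicates < 1) stop("replicates must be >= 1", call. = FALSE)
  if (is.null(times)) times <- default_assay_times(rc$k_exchange)
  clean <- gtpgs_binding_curve(rc, b_max = g_conc * specific_activity, times)
  with_seed(seed, lapply(seq_len(replicates), function(i) {
    time_course(times, apply_noise(clean$values, noise),
                assay_kind = "gtpgs_binding", unit = "min",
                meta = list(g_conc = g_conc,
                            specific_activity = specific_activity,
                            k_exchange = rc$k_exchange,
                            noise_sd = noise$sd, seed = seed, replicate = i))
  }))
}

#' Simulate single-turnover GTP hydrolysis time courses
#'
#' @param rc [rate_constants()].
#' @param g_conc Preloaded Galpha (= preloaded GTP), nM.
#' @param specific_activity Fraction of protein carrying label, mol/mol.
#' @param times Sampling times, min; default from [default_assay_times()].
#' @param noise A [noise_model()]; default 3 % multiplicative.
#' @param seed Integer seed.
#' @param replicates Number of replicate traces.
#' @return List of [time_course()] objects.
#' @export
gen_single_turnover <- function(rc, g_conc = 800, specific_activity = 1,
                                times = NULL,
                                noise = noise_model("multiplicative_gaussian", 0.03),
                                seed = 1L, replicates = 1L) {
  stopifnot(inherits(rc, "rate_constants"))
  if (specific_activity < 0)
    stop("specific_activity must be >= 0", call. = FALSE)
  if (replicates < 1) stop("replicates must be >= 1", call. = FALSE)
  if (is.null(times)) times <- default_assay_times(rc$k_cat)
  clean <- single_turnover_curve(rc, p0 = g_conc * specific_activity, times)
  with_seed(seed, lapply(seq_len(replicates), function(i) {
    time_course(times, apply_noise(clean$values, noise),
                assay_kind = "single_turnover", unit = "min",
                meta = list(g_conc = g_conc, k_cat = rc$k_cat,
                            noise_sd = noise$sd, seed = seed, replicate = i))
  }))
}

#' Simulate a steady-state Pi-accumulation progress curve
#'
#' Multi-turnover hydrolysis under a finite (but excess) GTP pool, via
#' [turnover_ode()] with the hydrolysis rate boosted by
#' [gap_hydrolysis_rate()] when RGS is present. Values are cumulative Pi in
#' nM; the initial slope equals
#' `steady_state_turnover(effective rates) * g_conc` before appreciable
#' substrate depletion.
#'
#' @param rc [rate_constants()]; GAP fields required when `rgs_conc > 0`.
#' @param g_conc Galpha concentration, nM.
#' @param gtp0 Initial GTP, nM; must exceed `g_conc`.
#' @param rgs_conc RGS concentration, nM.
#' @param times Sampling times, min.
#' @param noise A [noise_model()]; default 3 % multiplicative.
#' @param seed Integer seed.
#' @param replicates Number of replicate traces.
#' @return List of [time_course()] objects (values nM Pi; `meta$gtp0` set).
#' @export
gen_steady_state <- function(rc, g_conc = 500, gtp0 = 25000, rgs_conc = 0,
                             times = seq(0.5, 10, by = 0.5),
                             noise = noise_model("multiplicative_gaussian", 0.03),
                             seed = 1L, replicates = 1L) {
  stopifnot(inherits(rc, "rate_constants"))
  if (gtp0 <= g_conc)
    stop("gtp0 must exceed g_conc for a multi-turnover assay", call. = FALSE)
  k_cat_eff <- gap_hydrolysis_rate(rc, rgs_conc)  # errors if GAP unset
  rc_eff <- rate_constants(rc$k_exchange, k_cat_eff)
  traj <- turnover_ode(rc_eff, cycle_pools(g_total = g_conc, free_gtp = gtp0),
                       times)
  clean <- traj$pi_released
  with_seed(seed, lapply(seq_len(replicates), function(i) {
    time_course(traj$time, apply_noise(clean, noise),
                assay_kind = "steady_state", unit = "min",
                meta = list(g_conc = g_conc, gtp0 = gtp0,
                            rgs_conc = rgs_conc, k_cat_eff = k_cat_eff,
                            noise_sd = noise$sd, seed = seed, replicate = i))
  }))
}

#' Simulate a seven-concentration SPR sensorgram series
#'
#' 1:1 Langmuir sensorgrams at the standard analyte dilution series
#' (6.25-400 nM), 3 min association and 5 min dissociation, with additive
#' Gaussian instrument noise (default 0.5 RU).
#'
#' @param kin [binding_kinetics()].
#' @param concs Analyte concentrations, M.
#' @param t_assoc,t_dissoc Phase durations, s.
#' @param dt Sampling interval, s.
#' @param noise A [noise_model()]; default additive 0.5 RU.
#' @param seed Integer seed.
#' @return List of [sensorgram()] objects, one per concentration.
#' @export
gen_spr_series <- function(kin,
                           concs = c(6.25, 12.5, 25, 50, 100, 200, 400) * 1e-9,
                           t_assoc = 180, t_dissoc = 300, dt = 2,
                           noise = noise_model("additive_gaussian", 0.5),
                           seed = 1L) {
  stopifnot(inherits(kin, "binding_kinetics"))
  with_seed(seed, lapply(concs, function(C) {
    s <- spr_sensorgram(kin, C, t_assoc = t_assoc, t_dissoc = t_dissoc,
                        dt = dt)
    sensorgram(s$times, apply_noise(s$response, noise), conc = C,
               t_assoc = t_assoc,
               meta = c(s$meta, list(noise_sd = noise$sd, seed = seed)))
  }))
}

# ---- synthetic Galpha family ---------------------------------------------

# Synthetic Galpha-like reference protein, 380 aa. Built once with canonical
# G-box motifs (P-loop G1, switch I, switch II/G3, G4, G5) on a fixed random
# background; the switch-I threonine sits at position 194, matching the
# Arabidopsis AtGPA1 numbering of the RGS-coupling determinant. This is a
# synthetic stand-in, not a natural sequence.
GALPHA_SYNTH_REF <- paste0(
  "MGLLCSRSRHHTNAQNTDQQESVAEEPCITMNIRNAVKCQPYVLLLLGAGESGKSTIFKQTAKTLIFRDCAMPAET",
  "CIDRPESKIFLSKRYWSKQEKVCYRKGQQTWLDGWGTVWPYVCTPPYPIEGINCIESAKFWTFALENHEFARSEMY",
  "EKDIHWEPGIDVEVGNSVNDHNQGVSFVAEYQPEAELRVKTTGIVETQFCMYYEFGKIYDMHYLQDVGGQRGVNWG",
  "IACFYGSDDQKDRSRYKIESAEDYLAFKYPQRKMTAWKNSFRIMYYMEHSENFFTCEMYFLNKKDCFICANSSVHE",
  "HGDSSISPEMHCAQIMLEFNTCATDTITRDMEPGQVENVCMREYDVCVNFPPAFGQSQNKWQFRQCHDFYHFIPGV")

#' Synthetic Galpha reference sequence
#'
#' The bundled synthetic Galpha-like reference (380 aa) used by
#' [gen_galpha_family()] and as the default alignment reference for
#' [switch1_residue()]. Its switch-I threonine is at position 194.
#'
#' @return A [protein_record()] with id `"GalphaRef_synthetic"`.
#' @export
galpha_synthetic_reference <- function() {
  protein_record("GalphaRef_synthetic", GALPHA_SYNTH_REF)
}

# Inverse genetic code: codons per amino acid (sense codons only).
codons_for_aa <- function() {
  code <- Biostrings::GENETIC_CODE
  split(names(code), code)
}

# Back-translate a protein with uniform synonymous codon choice drawn from
# the current RNG stream.
back_translate <- function(protein) {
  tab <- codons_for_aa()
  aa <- strsplit(protein, "")[[1]]
  paste(vapply(aa, function(a) {
    opts <- tab[[a]]
    if (is.null(opts)) stop("cannot back-translate residue ", a,
                            call. = FALSE)
    opts[sample.int(length(opts), 1L)]
  }, ""), collapse = "")
}

# Random codon for one amino acid from the current RNG stream.
random_codon <- function(a, tab) {
  opts <- tab[[a]]
  opts[sample.int(length(opts), 1L)]
}

#' Generate a synthetic Galpha family with controlled determinant states
#'
#' Derives `n` variants of the synthetic reference: exactly
#' `round(n * grass_fraction)` carry Asn at the switch-I determinant
#' (position 194), the rest keep Thr. All other positions mutate
#' independently at `mutation_rate` per site (the determinant site is
#' otherwise left untouched so the construction truth is exact). Paired
#' coding sequences descend from one seeded uniform-codon back-translation
#' of the reference: amino-acid changes get a random codon of the new
#' residue, and unchanged sites pick up synonymous codon changes at the same
#' per-site rate, so family members diverge at both the protein and the
#' silent level.
#'
#' @param n Number of family members (>= 1).
#' @param grass_fraction Fraction carrying the Asn substitution, in `[0, 1]`.
#' @param mutation_rate Per-site substitution probability, in `[0, 0.2]`
#'   (bounded to keep alignments reliable).
#' @param seed Integer seed.
#' @return List with `proteins` (list of [protein_record()]), `cds` (named
#'   character vector of coding sequences), and `truth` (data.frame: `id`,
#'   `grass` flag, `determinant_pos`).
#' @export
gen_galpha_family <- function(n, grass_fraction = 0.5, mutation_rate = 0.02,
                              seed = 1L) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  if (grass_fraction < 0 || grass_fraction > 1)
    stop("grass_fraction must be in [0, 1]", call. = FALSE)
  if (mutation_rate < 0 || mutation_rate > 0.2)
    stop("mutation_rate must be in [0, 0.2]", call. = FALSE)
  ref <- strsplit(GALPHA_SYNTH_REF, "")[[1]]
  det <- 194L
  n_grass <- round(n * grass_fraction)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  with_seed(seed, {
    tab <- codons_for_aa()
    ref_codons <- substring(back_translate(paste(ref, collapse = "")),
                            3 * seq_along(ref) - 2, 3 * seq_along(ref))
    proteins <- vector("list", n)
    cds <- character(n)
    ids <- sprintf("Galpha_synth_%02d", seq_len(n))
    for (i in seq_len(n)) {
      s <- ref
      cods <- ref_codons
      mut <- setdiff(which(stats::runif(length(s)) < mutation_rate), det)
      for (j in mut) {
        s[j] <- sample(setdiff(aas, s[j]), 1L)
        cods[j] <- random_codon(s[j], tab)
      }
      # silent divergence at unchanged sites, same per-site rate
      silent <- setdiff(which(stats::runif(length(s)) < mutation_rate),
                        c(mut, det))
      for (j in silent) cods[j] <- random_codon(s[j], tab)
      s[det] <- if (i <= n_grass) "N" else "T"
      cods[det] <- random_codon(s[det], tab)
      proteins[[i]] <- protein_record(ids[i], paste(s, collapse = ""))
      cds[i] <- paste(cods, collapse = "")
    }
    names(cds) <- ids
    list(proteins = stats::setNames(proteins, ids), cds = cds,
         truth = data.frame(id = ids, grass = seq_len(n) <= n_grass,
                            determinant_pos = det,
                            stringsAsFactors = FALSE))
  })
}
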