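---
title: "Modelling the self-activating nucleotide cycle of plant Galpha subunits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the self-activating nucleotide cycle of plant Galpha subunits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(galphakin)
```

## The model

A Galpha subunit cycles between a GDP-bound (inactive) and a GTP-bound
(active) state. Two first-order steps govern the cycle in vitro:

* **nucleotide exchange** — GDP release followed by (fast) GTP binding,
  observed as a single apparent rate `k_exchange` (the K_obs of a GTPgammaS
  binding assay), and
* **GTP hydrolysis** — the intrinsic GTPase step, rate `k_cat`, measured in
  a single-turnover assay on preloaded protein.

Animal Galpha proteins exchange slowly and need a receptor GEF to activate;
the plant proteins modelled here exchange fast and hydrolyse slowly, so they
*self-activate*. Three derived quantities summarise a protein:

* steady-state occupancy `k_exchange / (k_exchange + k_cat)` — the fraction
  of protein sitting in the active state when the cycle free-runs,
* the **rate-limiting step** — whichever of the two rates is smaller
  (reported as `balanced` within a 5 % band; no real protein in the bundled
  panel falls inside it, and any band below 2-fold keeps the liverwort
  protein, whose rates differ 2.1-fold, hydrolysis-limited),
* the **steady-state turnover** of the free-running cycle, the harmonic
  series `1/(1/k_exchange + 1/k_cat)` of the two steps — always slower than
  either step alone.

These are in-vitro statements: the cellular GTP/GDP ratio and Galpha-binding
proteins shift the balance in vivo.

### Finite GTP pools

In a fluorescence cuvette a fixed GTP bolus competes with the GDP that
accumulates as the cycle runs. `turnover_ode()` integrates

```
d(g_gtp)/dt = k_exchange * (g_total - g_gtp) * phi - k_cat * g_gtp,
phi = free_gtp / (free_gtp + free_gdp)
```

where each productive exchange consumes one free GTP and releases one bound
GDP (so the free pool is conserved), and hydrolysis converts bound GTP to
bound GDP without touching the free pool. The competition factor `phi` is
the simplest mass-action account of GTP/GDP rebinding competition; no
explicit published equation exists for these cuvette experiments, so the
model is validated by qualitative shape properties only: with hydrolysis
active and a finite pool the active fraction rises to an interior maximum
and decays (fast-hydrolysing proteins re-inactivate almost completely),
while with a non-hydrolysable analog the rise is monotone to saturation.
Two quantitative invariants pin the model to the closed forms: with
unlimited GTP (`phi = 1`) the long-time occupancy equals the occupancy
equation, and the asymptotic Pi production rate equals the series turnover.
Integration uses `deSolve::lsoda` at relative tolerance 1e-8 and absolute
tolerance 1e-10 nM, appropriate for rates spanning roughly 0.02-7 min^-1.

Initial free GDP is zero (the assay buffer contains none); the GDP loaded
on the protein enters the free pool through the first exchange. The
reactive protein concentration is the nominal concentration times the
specific activity (mol exchange-competent protein per mol protein,
typically 0.4-0.7 for recombinant preparations), which sets plateaus and
effective pool sizes.

### GAP action and SPR binding

An RGS protein accelerates hydrolysis as a hyperbola,
`k_obs = k_cat + k_gap_max * [RGS] / (k_half_gap + [RGS])`. No published
EC50 anchors `k_half_gap`, so it has no default and must be supplied or
fitted. Binding of activated Galpha to an immobilised RGS domain follows a
1:1 Langmuir model; `K_D = k_d / k_a` throughout, and times switch from
minutes (enzymology) to seconds (SPR) at the module boundary.

## Fitting

All fitters are damped least squares (`minpack.lm`), with three log-spaced
starting rates around `ln 2 / t_half` to avoid local minima. Replicates are
fitted jointly on pooled residuals rather than averaged first, preserving
the error structure. Reported standard errors are asymptotic least-squares
errors; replicate spread can be compared against them but no claim is made
about which convention published tables use.

Specific choices:

* **Steady-state slope** — straight line (with free intercept, which
  absorbs the brief pre-steady-state lag) through the points with
  cumulative Pi at most 20 % of the initial GTP; fewer than three points in
  that window is an error, as is a non-increasing progress curve.
* **SPR global fit** — one shared `(k_a, k_d, R_max)` across all analyte
  concentrations by default, since one immobilised surface underlies a
  series; per-curve `R_max` is available for drifting surfaces, and the
  dissociation phase alone still pins `k_d`. A series whose maximal
  response stays under 3x the estimated response noise (robust
  successive-difference estimator) is reported as a **non-binder** rather
  than fitted — the behaviour of a Gbetagamma negative control.
* **GAP dose-response** — requires a zero-dose point (otherwise `k_cat` is
  unidentifiable); a fitted saturating stimulation below 1.5-fold is
  flagged `rgs_insensitive`.

## Derived classifications

* `self_activating` iff `k_exchange > k_cat`; the converse is the
  animal-like `gef_dependent` regime.
* `self_inactivating` flag at `k_cat >= 0.5 min^-1`: a reporting heuristic
  that separates a fast hydrolyser (0.87 min^-1), which resets itself
  without a GAP, from the slow hydrolysers (~0.05 min^-1). It is a label,
  not a mechanistic claim.
* `rgs_stimulated` at a GAP fold-acceleration of at least 1.5: the
  insensitive case in the bundled panel sits at 1.07 and the weakest
  genuinely stimulated case at 5.1, so the exact bar is uncritical.
* Fold changes are reported both exact and integer-rounded (half-up),
  because binding studies quote integers ("7-fold"); percentages round
  half-up for the same reason (94.65 % prints as 95 %).

## Synthetic data

The generators emulate the study conditions of the assays they stand in
for: 1 uM protein for GTPgammaS binding with plateau set by specific
activity; 800 nM preloaded protein for single turnover; 500 nM protein with
excess GTP for steady state; seven analyte concentrations
(6.25-400 nM, two-fold steps), 3 min association and 5 min dissociation for
SPR. Noise defaults are multiplicative Gaussian at 3 % for
counting-based assays (5 % used in the harder single-turnover recovery
checks) and additive 0.5 RU for SPR; no published noise magnitudes exist,
so these are documented defaults, overridable via `noise_model()`. Sampling
defaults place 10 log-spaced points across the rise for fast rates
(>= 1 min^-1) and 12 linear points out to five characteristic times
(capped at 60 min) for slow ones.

For the steady-state recovery exercise the generator needs cycle rates, not
a composite turnover, so the target per-protein turnover is realised by
fixing the exchange rate at the wild-type value and solving the series
model for the GAP-boosted hydrolysis rate; 20 replicates at 5 % noise over
a 6-minute window (50 uM GTP, about 3 % substrate consumed) keep the
initial-slope estimate unbiased to well under the replicate scatter.

The sequence generator derives families from a bundled **synthetic**
380-residue Galpha-like reference (canonical G-box motifs on a fixed random
background, switch-I threonine at position 194 to match the Arabidopsis
numbering). It is a construction, not a natural sequence: alignments and
determinant calls exercise real homology logic (the bundled rice-like demo
sequence carries a one-residue insertion so the determinant falls at 195),
but conservation patterns, domain architecture and phylogenetic signal of
real Galpha families are not represented. Passing tests therefore
demonstrate correctness of the mapping and counting machinery, not recovery
of biological conclusions from real data. Coding sequences descend from a
single seeded back-translation with uniform synonymous codon choice;
amino-acid changes take a random codon of the new residue and silent
changes accrue at the same per-site rate, giving families both
nonsynonymous and synonymous divergence. Real codon usage bias is not
modelled, which Nei-Gojobori counting does not require.

## Sequence statistics

The switch-I determinant classifier reads the residue homologous to
reference position 194 through a Needleman-Wunsch global alignment
(BLOSUM62, gap open 10, gap extend 0.5): Thr/Ser couple to RGS (Ser is
accepted as a conservative substitution at this hydrogen-bonding site, an
extension beyond the strict Thr/Asn/Lys discussion), Asn marks the
grass-type uncoupled state, Lys the animal Galpha12/13-type state. The
alignment is verified against exhaustive enumeration of all global
alignments on short sequences.

dN/dS uses Nei-Gojobori (1986) pathway counting: per-codon
synonymous/nonsynonymous site fractions (summing to three per codon, with
mutations to stop codons counted nonsynonymous), equal-weight averaging
over mutational pathways that avoid stop codons, site totals averaged
between the two sequences, and the Jukes-Cantor correction
`d = -3/4 ln(1 - 4p/3)`. Degenerate outcomes are flagged rather than
silently propagated: `p >= 3/4` makes the correction undefined; `dS = 0`
with `dN > 0` reports an infinite ratio; no differences at all reports the
ratio as undefined. Codons containing gaps or ambiguous bases are excluded
and counted. Published domain-wise dn/ds values for the millet RGS locus
cannot be reproduced without the underlying sequences and alignment
choices, so the statistic is validated by hand-enumerated codon oracles
and property tests (pure synonymous change gives dN = 0, pure
nonsynonymous change gives dS = 0).

## Problem sizes and numerical choices

The test suite and the acceptance script run on deliberately small
problems: 10-14 points per kinetic trace, 20 seeded replicates per
recovery estimate, 7-curve SPR series at 2 s sampling, families of 5-10
synthetic sequences, and brute-force alignment enumeration only up to
length 5 (Delannoy growth makes longer enumeration pointless). These sizes
give sub-percent Monte-Carlo error on every recovery mean while keeping
the whole suite in seconds. Ties in the balanced-band classifier resolve
by the stated band; the ODE clips sub-tolerance negative concentrations to
zero; all percent and fold rounding is half-up.

## Known limitations

* No receptor/GEF kinetics, no Gbetagamma heterotrimer assembly, no GDI
  action: the model covers the free Galpha cycle and its GAP.
* No mass-transport limitation in the SPR model; bulk refractive-index
  jumps reduce to an optional additive constant.
* Trp fluorescence is assumed proportional to the GTP-occupied fraction;
  that proportionality is untested.
* Published steady-state rates measured without RGS sit about 2-fold below
  the series-model prediction from the separately measured exchange and
  hydrolysis rates; the sources do not reconcile this and the package does
  not attempt to — the series model is used as stated and no test asserts
  that particular cross-table identity.
* The `balanced`, `self_inactivating` and `rgs_stimulated` bands are
  reporting heuristics chosen once (5 %, 0.5 min^-1, 1.5-fold) and
  documented; they are not published thresholds.

## A worked pass through the pipeline

```{r pipeline, eval = FALSE}
rc <- rate_constants(k_exchange = 5.80, k_cat = 0.047,
                     k_gap_max = 0.55, k_half_gap = 100)

# simulate -> fit -> profile
tcs <- gen_gtpgs_binding(rc, g_conc = 1000, specific_activity = 0.46,
                         seed = 1, replicates = 3)
fit <- fit_exponential_association(tcs)

kin <- fit_spr_global(gen_spr_series(binding_kinetics(3.53e5, 6.16e-3, 100),
                                     seed = 1))

build_profile("AtGPA1",
              k_obs_binding = fit$params[["k_obs"]],
              k_cat = 0.047, kd_rgs = kin$k_D,
              v_minus_rgs = 0.025, v_plus_rgs = 0.503)
```
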