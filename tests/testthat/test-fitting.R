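test_that("noise-free exponential fits recover generating rates across the panel grid", {
  for (k in c(0.047, 0.052, 0.70, 0.87, 0.92, 1.84, 5.80, 6.85, 6.97)) {
    rc <- rate_constants(k, k)  # k reused for both roles below
    tcb <- gtpgs_binding_curve(rc, b_max = 460, times = default_assay_times(k))
    frb <- fit_exponential_association(tcb)
    expect_equal(unname(frb$params["k_obs"]), k, tolerance = 1e-5)
    expect_equal(unname(frb$params["plateau"]), 460, tolerance = 1e-5)

    tcs <- single_turnover_curve(rc, p0 = 800, times = default_assay_times(k))
    frs <- fit_single_turnover(tcs)
    expect_equal(unname(frs$params["k_cat"]), k, tolerance = 1e-5)
  }
})

test_that("degenerate exponential inputs are rejected", {
  expect_error(fit_exponential_association(
    time_course(1:10, rep(0, 10), "gtpgs_binding")), "constant")
  expect_error(fit_exponential_association(
    time_course(1:3, c(1, 2, 3), "gtpgs_binding")), "4 time points")
  expect_error(fit_single_turnover(
    time_course(c(1, 2), c(0.1, 0.2), "single_turnover")), "4 time points")
})

test_that("noisy replicate means land within 5% of truth (seeded)", {
  # exchange at the rice wild-type rate, 3% counting noise
  k <- 0.92
  rc <- rate_constants(k, 0.052)
  ests <- vapply(1:20, function(s) {
    tc <- gen_gtpgs_binding(rc, g_conc = 1000, specific_activity = 0.55,
                            seed = s)[[1]]
    unname(fit_exponential_association(tc)$params["k_obs"])
  }, 0)
  expect_lt(abs(mean(ests) - k) / k, 0.05)
  # empirical SE of the mean should bracket the replicate spread
  expect_lt(sd(ests) / sqrt(20), 0.05 * k)

  # hydrolysis at the liverwort rate, 5% noise
  kcat <- 0.87
  rc2 <- rate_constants(1.84, kcat)
  nm <- noise_model("multiplicative_gaussian", 0.05)
  ests2 <- vapply(1:20, function(s) {
    tc <- gen_single_turnover(rc2, g_conc = 800, noise = nm, seed = s)[[1]]
    unname(fit_single_turnover(tc)$params["k_cat"])
  }, 0)
  expect_lt(abs(mean(ests2) - kcat) / kcat, 0.05)
})

test_that("steady-state slope fitting is exact on linear input and guards misuse", {
  v <- 0.25; g <- 500
  tc <- time_course(seq(1, 10), v * g * seq(1, 10), "steady_state",
                    meta = list(gtp0 = 25000))
  fr <- fit_steady_state_rate(tc, g_conc = g)
  expect_equal(unname(fr$params["turnover"]), v, tolerance = 1e-10)

  dec <- time_course(1:5, c(5, 4, 3, 2, 1) * 100, "steady_state",
                     meta = list(gtp0 = 25000))
  expect_error(fit_steady_state_rate(dec, g_conc = g), "non-physical")

  # window too small: almost all points beyond 20% substrate consumption
  tc2 <- time_course(1:6, c(100, 6000, 7000, 8000, 9000, 9500),
                     "steady_state", meta = list(gtp0 = 10000))
  expect_error(fit_steady_state_rate(tc2, g_conc = g), "window")
})

test_that("global SPR fits recover published constants from noiseless series", {
  panel <- galpha_reference_panel()
  spr_rows <- panel[is.finite(panel$spr_ka), ]
  for (i in seq_len(nrow(spr_rows))) {
    kin <- binding_kinetics(spr_rows$spr_ka[i], spr_rows$spr_kd[i],
                            r_max = 120)
    series <- gen_spr_series(kin, noise = noise_model("additive_gaussian", 0),
                             seed = 1)
    fitk <- fit_spr_global(series)
    expect_equal(fitk$k_D, kin$k_D, tolerance = 1e-4)
    expect_equal(fitk$k_a, kin$k_a, tolerance = 1e-4)
  }
})

test_that("a flat series is called a non-binder, not fitted", {
  flat <- lapply(c(6.25, 50, 400) * 1e-9, function(C)
    sensorgram(seq(0, 480, by = 2), rep(0, 241), conc = C, t_assoc = 180))
  res <- fit_spr_global(flat)
  expect_s3_class(res, "spr_nonbinder")
  expect_true(res$non_binder)
})

test_that("dissociation rate survives per-curve R_max heterogeneity", {
  kin <- binding_kinetics(3.53e5, 6.16e-3, r_max = 100)
  concs <- c(6.25, 12.5, 25, 50, 100, 200, 400) * 1e-9
  rmaxes <- seq(80, 120, length.out = 7)  # surface drift across injections
  series <- lapply(seq_along(concs), function(i) {
    k2 <- binding_kinetics(kin$k_a, kin$k_d, rmaxes[i])
    spr_sensorgram(k2, concs[i], t_assoc = 180, t_dissoc = 300, dt = 2)
  })
  fitk <- fit_spr_global(series, shared_rmax = FALSE)
  expect_equal(fitk$k_d, kin$k_d, tolerance = 0.02)
})

test_that("single-concentration SPR input warns about rate degeneracy", {
  kin <- binding_kinetics(3.53e5, 6.16e-3, r_max = 100)
  one <- spr_sensorgram(kin, 100e-9, t_assoc = 180, t_dissoc = 300, dt = 2)
  expect_warning(fit_spr_global(list(one)), "degenerate")
})

test_that("GAP dose-response fitting round-trips and flags insensitivity", {
  rc <- rate_constants(5.80, 0.047, k_gap_max = 0.6, k_half_gap = 40)
  doses <- c(0, 5, 12.5, 50, 125, 500, 750)
  df <- data.frame(rgs_conc = doses, k_obs = gap_hydrolysis_rate(rc, doses))
  fr <- fit_gap_dose_response(df)
  expect_equal(unname(fr$params["k_cat"]), 0.047, tolerance = 1e-6)
  expect_equal(unname(fr$params["k_gap_max"]), 0.6, tolerance = 1e-5)
  expect_equal(unname(fr$params["k_half_gap"]), 40, tolerance = 1e-4)
  expect_false("rgs_insensitive" %in% fr$flags)

  # liverwort-like: fast intrinsic hydrolysis, no further stimulation
  flat <- data.frame(rgs_conc = doses, k_obs = rep(1.06, length(doses)))
  fr2 <- fit_gap_dose_response(flat)
  expect_true("rgs_insensitive" %in% fr2$flags)
  expect_lt(unname(fr2$params["k_gap_max"]), 0.05)

  expect_error(fit_gap_dose_response(df[df$rgs_conc > 0, ]), "zero-dose")

  # conflicting duplicate doses: fit proceeds, residuals are reported
  dup <- rbind(df, data.frame(rgs_conc = 50, k_obs = 0.5))
  fr3 <- fit_gap_dose_response(dup)
  expect_true(fr3$converged)
  expect_gt(fr3$residual_ss, 0)
})

test_that("K_D is the exact quotient of the kinetic rates", {
  expect_equal(kd_from_rates(3.53e5, 6.16e-3), 1.74e-8, tolerance = 0.01)
  expect_equal(kd_from_rates(1.17e5, 1.34e-2), 115e-9, tolerance = 0.01)
  expect_equal(kd_from_rates(2.5, 2.5), 1.0)
  expect_error(kd_from_rates(0, 1e-3), "k_a")
})
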