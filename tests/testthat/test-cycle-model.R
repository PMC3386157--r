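test_that("binding and single-turnover curves satisfy their closed forms", {
  rc <- rate_constants(5.80, 0.047)

  tc <- gtpgs_binding_curve(rc, b_max = 1, times = c(0.5, 1, 2))
  expect_equal(tc$values[2], 1 - exp(-5.80), tolerance = 1e-12)
  expect_equal(tc$values[2], 0.9970, tolerance = 1e-3)

  # time zero gives zero signal; half-time identity is exact
  tc0 <- gtpgs_binding_curve(rc, b_max = 460, times = c(0, log(2) / 5.80, 10))
  expect_identical(tc0$values[1], 0)
  expect_equal(tc0$values[2], 230, tolerance = 1e-12)
  expect_true(all(diff(tc0$values) >= 0))

  st <- single_turnover_curve(rc, p0 = 1, times = c(5, 10))
  expect_equal(st$values[2], 1 - exp(-0.47), tolerance = 1e-12)
  expect_equal(st$values[2], 0.375, tolerance = 1e-2)
  st_half <- single_turnover_curve(rate_constants(1.84, 0.87), p0 = 8,
                                   times = log(2) / 0.87)
  expect_equal(st_half$values, 4, tolerance = 1e-12)
})

test_that("negative or disordered times are rejected with the offending index", {
  rc <- rate_constants(1, 0.1)
  expect_error(gtpgs_binding_curve(rc, 1, c(1, -2, 3)), "index 2")
  expect_error(single_turnover_curve(rc, 1, c(-1, 2)), "index 1")
  expect_error(gtpgs_binding_curve(rc, 1, c(2, 1)), "strictly increasing")
})

test_that("steady-state turnover follows the two-step series model", {
  expect_equal(steady_state_turnover(rate_constants(2, 2)), 1)
  # hydrolysis-limited regime: the composite approaches k_cat
  expect_equal(steady_state_turnover(rate_constants(1000, 0.05)), 0.05,
               tolerance = 1e-4)
  expect_equal(steady_state_turnover(rate_constants(5.80, 0.047)),
               0.04662, tolerance = 1e-4)
  # symmetric in its two arguments
  expect_equal(steady_state_turnover(rate_constants(0.3, 1.7)),
               steady_state_turnover(rate_constants(1.7, 0.3)))
  # slower than either step
  expect_lt(steady_state_turnover(rate_constants(0.9, 1.1)), 0.9)
  expect_error(steady_state_turnover(rate_constants(0, 1)), "undefined")
})

test_that("GTP-bound fraction is the exchange share of the cycle", {
  expect_equal(fraction_gtp_bound(rate_constants(3, 3)), 0.5)
  expect_equal(pct_gtp_bound(rate_constants(5.80, 0.047)), 99L)
  expect_equal(pct_gtp_bound(rate_constants(1.84, 0.87)), 68L)
  expect_error(fraction_gtp_bound(rate_constants(0, 0)), "undefined")
  # strictly increasing in exchange, decreasing in hydrolysis
  ks <- c(0.1, 0.5, 1, 3, 7)
  occ_up <- vapply(ks, function(k) fraction_gtp_bound(rate_constants(k, 0.5)), 0)
  occ_dn <- vapply(ks, function(k) fraction_gtp_bound(rate_constants(0.5, k)), 0)
  expect_true(all(diff(occ_up) > 0))
  expect_true(all(diff(occ_dn) < 0))
})

test_that("GAP dose response is hyperbolic with the expected landmarks", {
  rc <- rate_constants(5.80, 0.047, k_gap_max = 0.6, k_half_gap = 50)
  expect_equal(gap_hydrolysis_rate(rc, 0), 0.047)
  expect_equal(gap_hydrolysis_rate(rc, 50), 0.047 + 0.3)
  expect_equal(gap_hydrolysis_rate(rc, 1e9), 0.647, tolerance = 1e-6)
  doses <- c(0, 5, 12.5, 50, 125, 500, 750)
  expect_true(all(diff(gap_hydrolysis_rate(rc, doses)) >= 0))
  expect_true(all(gap_hydrolysis_rate(rc, doses) <= 0.047 + 0.6))
  rc_nogap <- rate_constants(5.80, 0.047)
  expect_error(gap_hydrolysis_rate(rc_nogap, 10), "unset")
})

test_that("finite-pool ODE conserves nucleotide and respects bounds", {
  grid <- list(c(5.80, 0.047), c(0.92, 0.052), c(1.84, 0.87))
  for (g in grid) {
    rc <- rate_constants(g[1], g[2])
    traj <- turnover_ode(rc, cycle_pools(g_total = 276, free_gtp = 800),
                         seq(0.1, 40, by = 0.1))
    free_tot <- traj$free_gtp + traj$free_gdp
    expect_lt(max(abs(free_tot - 800)) / 800, 1e-6)
    expect_true(all(traj$g_gtp >= 0 & traj$g_gtp <= 276))
    expect_true(all(diff(traj$pi_released) >= 0))
  }
})

test_that("GTPgammaS mode rises monotonically; no substrate means no activation", {
  rc <- rate_constants(1.84, 0.87)
  gs <- turnover_ode(rc, cycle_pools(g_total = 276, free_gtp = 5000),
                     seq(0.1, 10, by = 0.1), hydrolysable = FALSE)
  expect_true(all(diff(gs$g_gtp) > -1e-9))
  expect_equal(gs$g_gtp[nrow(gs)], 276, tolerance = 1e-3)

  none <- turnover_ode(rc, cycle_pools(g_total = 276, free_gtp = 0),
                       seq(0.1, 5, by = 0.1))
  expect_true(all(none$g_gtp < 1e-9))
})

test_that("liverwort-like kinetics under finite GTP peak and then self-inactivate", {
  rc <- rate_constants(1.84, 0.87)
  traj <- turnover_ode(rc, cycle_pools(g_total = 400 * 0.69, free_gtp = 800),
                       seq(0.05, 60, by = 0.05))
  pk <- which.max(traj$g_gtp)
  expect_gt(pk, 1)                      # interior maximum...
  expect_lt(pk, nrow(traj))
  expect_lt(traj$g_gtp[nrow(traj)], 0.5 * traj$g_gtp[pk])  # ...then decay
})

test_that("unlimited-GTP ODE settles at the occupancy-equation steady state", {
  for (rc in panel_rcs()) {
    traj <- turnover_ode(rc, cycle_pools(g_total = 100, free_gtp = 1e6),
                         seq(1, 20 / min(rc$k_exchange, rc$k_cat),
                             length.out = 50),
                         unlimited_gtp = TRUE)
    occ <- traj$g_gtp[nrow(traj)] / 100
    expect_equal(occ, fraction_gtp_bound(rc), tolerance = 1e-4)
  }
})

test_that("asymptotic Pi production rate matches the series turnover", {
  for (rc in panel_rcs()[c("AtGPA1", "MpGa1")]) {
    k_slow <- min(rc$k_exchange, rc$k_cat)
    times <- seq(5 / k_slow, 10 / k_slow, length.out = 30)
    traj <- turnover_ode(rc, cycle_pools(g_total = 100, free_gtp = 1e9),
                         times, unlimited_gtp = TRUE)
    slope <- coef(lm(traj$pi_released ~ traj$time))[2]
    expect_equal(unname(slope) / 100, steady_state_turnover(rc),
                 tolerance = 0.02)
  }
})

test_that("Langmuir sensorgram has the right landmarks and continuity", {
  kin <- binding_kinetics(3.53e5, 6.16e-3, r_max = 100)
  # analyte at K_D gives half-saturating equilibrium response
  s_kd <- spr_sensorgram(kin, analyte_conc = kin$k_D, t_assoc = 5000,
                         t_dissoc = 10, dt = 1)
  expect_equal(max(s_kd$response), 50, tolerance = 1e-3)
  s <- spr_sensorgram(kin, 400e-9, t_assoc = 180, t_dissoc = 300, dt = 0.5)
  expect_identical(s$response[1], 0)
  assoc <- s$times <= 180
  expect_true(all(diff(s$response[assoc]) > 0))
  expect_true(all(diff(s$response[!assoc]) < 0))
  # continuity across the phase boundary
  i <- max(which(assoc))
  expect_lt(abs(s$response[i + 1] - s$response[i]), 0.02 * max(s$response))
  # equilibrium ratio at 400 nM from the published wild-type constants
  r_eq_ratio <- max(s$response) / kin$r_max
  expect_equal(r_eq_ratio, 0.1412 / (0.1412 + 6.16e-3), tolerance = 5e-3)
  expect_equal(r_eq_ratio, 0.958, tolerance = 1e-2)
  expect_error(spr_sensorgram(kin, 400e-9, dt = 0), "dt")
  expect_error(spr_sensorgram(kin, 0), "analyte_conc")
})
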