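test_that("generators are bit-reproducible under a fixed seed", {
  rc <- rate_constants(5.80, 0.047, k_gap_max = 0.5, k_half_gap = 100)
  a <- gen_gtpgs_binding(rc, seed = 42, replicates = 3)
  b <- gen_gtpgs_binding(rc, seed = 42, replicates = 3)
  expect_identical(lapply(a, `[[`, "values"), lapply(b, `[[`, "values"))
  expect_false(identical(gen_gtpgs_binding(rc, seed = 43)[[1]]$values,
                         a[[1]]$values))

  kin <- binding_kinetics(3.53e5, 6.16e-3, 100)
  s1 <- gen_spr_series(kin, seed = 5)
  s2 <- gen_spr_series(kin, seed = 5)
  expect_identical(lapply(s1, `[[`, "response"),
                   lapply(s2, `[[`, "response"))

  f1 <- gen_galpha_family(5, 0.4, 0.05, seed = 9)
  f2 <- gen_galpha_family(5, 0.4, 0.05, seed = 9)
  expect_identical(f1$cds, f2$cds)
})

test_that("noiseless generation reduces to the closed forms", {
  rc <- rate_constants(5.80, 0.047)
  quiet <- noise_model("multiplicative_gaussian", 0)
  tb <- gen_gtpgs_binding(rc, g_conc = 1000, specific_activity = 0.46,
                          noise = quiet, seed = 1)[[1]]
  ref <- gtpgs_binding_curve(rc, b_max = 460, times = tb$times)
  expect_equal(tb$values, ref$values)
  # plateau is protein concentration times specific activity
  expect_equal(tb$values, 460 * (1 - exp(-5.80 * tb$times)))

  ts <- gen_single_turnover(rc, g_conc = 800, noise = quiet, seed = 1)[[1]]
  ref2 <- single_turnover_curve(rc, p0 = 800, times = ts$times)
  expect_equal(ts$values, ref2$values)

  kin <- binding_kinetics(1.21e6, 5.84e-3, 80)
  s <- gen_spr_series(kin, noise = noise_model("additive_gaussian", 0),
                      seed = 1)
  direct <- spr_sensorgram(kin, s[[3]]$conc, dt = 2)
  expect_equal(s[[3]]$response, direct$response)
})

test_that("steady-state progress curves carry the series-model slope", {
  rc <- rate_constants(5.80, 0.047, k_gap_max = 0.504, k_half_gap = 10)
  quiet <- noise_model("multiplicative_gaussian", 0)
  # with RGS: effective hydrolysis is GAP-boosted
  st <- gen_steady_state(rc, g_conc = 500, gtp0 = 25000, rgs_conc = 750,
                         noise = quiet, seed = 1)[[1]]
  k_eff <- gap_hydrolysis_rate(rc, 750)
  v_pred <- steady_state_turnover(rate_constants(rc$k_exchange, k_eff))
  fit <- fit_steady_state_rate(st, g_conc = 500)
  expect_equal(unname(fit$params["turnover"]), v_pred, tolerance = 0.02)

  # without RGS it reduces to the intrinsic rates
  st0 <- gen_steady_state(rc, g_conc = 500, gtp0 = 25000, rgs_conc = 0,
                          times = seq(2, 120, by = 2), noise = quiet,
                          seed = 1)[[1]]
  v0 <- steady_state_turnover(rc)
  fit0 <- fit_steady_state_rate(st0, g_conc = 500)
  expect_equal(unname(fit0$params["turnover"]), v0, tolerance = 0.02)

  expect_error(gen_steady_state(rc, g_conc = 500, gtp0 = 400), "exceed")
  rc_nogap <- rate_constants(5.80, 0.047)
  expect_error(gen_steady_state(rc_nogap, rgs_conc = 750), "unset")
})

test_that("substrate exhaustion drives cumulative Pi to the initial GTP", {
  rc <- rate_constants(1.84, 0.87)
  st <- gen_steady_state(rc, g_conc = 400, gtp0 = 800,
                         times = seq(1, 120, by = 1),
                         noise = noise_model("multiplicative_gaussian", 0),
                         seed = 1)[[1]]
  expect_equal(max(st$values), 800, tolerance = 0.02)
})

test_that("simulate-fit loops recover hydrolysis rates from noisy data", {
  kcat <- 0.052
  rc <- rate_constants(0.92, kcat)
  nm <- noise_model("multiplicative_gaussian", 0.05)
  ests <- vapply(1:20, function(s) {
    tc <- gen_single_turnover(rc, noise = nm, seed = s)[[1]]
    unname(fit_single_turnover(tc)$params["k_cat"])
  }, 0)
  expect_lt(abs(mean(ests) - kcat) / kcat, 0.05)
})

test_that("family construction places the determinant exactly as requested", {
  ref <- galpha_synthetic_reference()
  # all-couplable and all-uncoupled limits
  f0 <- gen_galpha_family(6, grass_fraction = 0, mutation_rate = 0.02,
                          seed = 3)
  calls0 <- vapply(f0$proteins,
                   function(p) switch1_residue(p, ref)$coupling_class, "")
  expect_true(all(calls0 == "rgs_couplable"))
  f1 <- gen_galpha_family(6, grass_fraction = 1, mutation_rate = 0.02,
                          seed = 3)
  calls1 <- vapply(f1$proteins,
                   function(p) switch1_residue(p, ref)$coupling_class, "")
  expect_true(all(calls1 == "grass_uncoupled"))

  # exact count at a fractional mix, and scan agrees with construction truth
  for (s in c(1, 12, 123)) {
    fam <- gen_galpha_family(10, grass_fraction = 0.3, mutation_rate = 0.05,
                             seed = s)
    expect_equal(sum(fam$truth$grass), 3L)
    calls <- vapply(fam$proteins,
                    function(p) switch1_residue(p, ref)$coupling_class, "")
    expect_equal(unname(calls == "grass_uncoupled"), fam$truth$grass)
  }
  expect_error(gen_galpha_family(5, mutation_rate = 0.5), "mutation_rate")
  expect_error(gen_galpha_family(5, grass_fraction = 2), "grass_fraction")
})

test_that("coding sequences are consistent back-translations", {
  fam <- gen_galpha_family(3, grass_fraction = 0.5, mutation_rate = 0.03,
                           seed = 21)
  for (i in seq_along(fam$cds)) {
    aa <- as.character(Biostrings::translate(
      Biostrings::DNAString(fam$cds[[i]])))
    expect_equal(aa, fam$proteins[[i]]$sequence)
  }
})

test_that("time-course CSV round-trips through the on-disk dialect", {
  rc <- rate_constants(0.92, 0.052)
  tcs <- gen_gtpgs_binding(rc, seed = 8, replicates = 2)
  path <- tempfile(fileext = ".csv")
  write_time_course_csv(tcs, path)
  back <- read_time_course_csv(path)
  expect_length(back, 2L)
  expect_equal(back[[1]]$values, tcs[[1]]$values, tolerance = 1e-12)
  expect_equal(back[[1]]$assay_kind, "gtpgs_binding")
  expect_equal(back[[1]]$unit, "min")

  kin <- binding_kinetics(3.83e5, 2.17e-2, 90)
  ser <- gen_spr_series(kin, seed = 2)
  spath <- tempfile(fileext = ".csv")
  write_sensorgram_csv(ser, spath)
  back2 <- read_sensorgram_csv(spath)
  expect_length(back2, 7L)
  expect_equal(back2[[1]]$conc, 6.25e-9)
  expect_equal(back2[[7]]$response, ser[[7]]$response, tolerance = 1e-10)
})
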