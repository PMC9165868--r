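test_that("PCSK9 decoupled from the receptor yields no threshold", {
  p <- hl_params(alpha_p = 0)
  scan <- pcsk9_threshold_scan(decades = c(1e12, 1e14), params = p)
  expect_true(is.na(scan$threshold))
  expect_lt(max(abs(scan$curve$elevation)), 1e-6)
})

test_that("late-time LDL is non-decreasing along the PCSK9 decade grid", {
  scan <- threshold_scan_cached()
  expect_true(all(diff(scan$curve$l_E) > 0))
  expect_true(all(diff(scan$curve$v_E) > 0))
})

test_that("statin dose zero leaves the trajectory unchanged", {
  res <- statin_scenario(dose = 0, params = default_params(),
                         horizon_h = 60)
  expect_identical(res$sim$y, res$baseline$y)
  expect_equal(res$metrics$pct_reduction_LDL, 0)
})

test_that("a statin dose lowers LDL/VLDL and up-regulates transcription", {
  res <- statin_scenario(dose = 1e12, t_dose_h = 10,
                         params = default_params())
  m <- res$metrics
  expect_lt(m$l_E, m$l_E_baseline)
  expect_lt(m$v_E, m$v_E_baseline)
  expect_gt(m$t_half_LDL_h, 0)
  late <- res$sim$times_h >= 50
  for (v in c("m_h", "m_r", "m_p"))
    expect_true(all(res$sim$y[late, v] > res$baseline$y[late, v]), info = v)
  n <- nrow(res$sim$y)
  expect_lt(res$sim$y[n, "h"], res$baseline$y[n, "h"])
})

test_that("free HMGCR decreases monotonically with statin dose", {
  p <- default_params()
  doses <- c(0, 3e11, 1e12, 3e12, 1e13)
  h_end <- vapply(doses, function(d) {
    s <- scenario(p, events = if (d > 0)
      list(dose_event(10, "statin_E", "bolus", d)) else list(),
      horizon_h = 200, dt_out_h = 20)
    sim <- simulate_scenario(s)
    sim$y[nrow(sim$y), "h"]
  }, numeric(1))
  expect_true(all(diff(h_end) < 0))
})

test_that("anti-PCSK9 dose response is monotone", {
  p <- default_params()
  doses <- c(0, 5e13, 2e14, 1e15)
  lE <- vapply(doses, function(d)
    anti_pcsk9_scenario("antibody", dose = d, pcsk9_init = 1e14,
                        params = p)$metrics$l_E, numeric(1))
  expect_true(all(diff(lE) < 0))
  # dose 0 equals the high-PCSK9 scenario unchanged
  z <- anti_pcsk9_scenario("antibody", dose = 0, pcsk9_init = 1e14,
                           params = p)
  expect_identical(z$sim$y, z$baseline$y)
})

test_that("small molecule dominates the antibody pointwise and in speed", {
  p <- default_params()
  ab <- anti_pcsk9_scenario("antibody", dose = 2e14, pcsk9_init = 1e14,
                            params = p)
  sm <- anti_pcsk9_scenario("small_molecule", dose = 2e14,
                            pcsk9_init = 1e14, params = p)
  post <- ab$sim$times_h > 0
  expect_true(all(sm$sim$y[post, "l_E"] <=
                    ab$sim$y[post, "l_E"] * (1 + 1e-9)))
  expect_lt(sm$metrics$t_half_LDL_h, ab$metrics$t_half_LDL_h)
  expect_gt(sm$metrics$pct_reduction_LDL, ab$metrics$pct_reduction_LDL)
})

test_that("combined therapy is additive within the expected band", {
  p <- default_params()
  res <- combined_therapy_scenario(1e12, 2e14, 1e14, params = p)
  expect_lte(res$combined$l_E, min(res$statin$l_E, res$antibody$l_E))
  expect_lte(res$combined$v_E, min(res$statin$v_E, res$antibody$v_E))
  # combined reduction >= max single across a small dose grid; the two
  # mechanisms are mildly synergistic (antibody protects statin-induced
  # receptors), so a strict sum-of-singles upper bound does not hold —
  # only the qualitative cap of 100% applies
  for (st in c(0, 1e12)) {
    for (ab in c(0, 2e14)) {
      r <- combined_therapy_scenario(st, ab, 1e14, params = p)
      lo <- max(r$statin$pct_reduction_LDL, r$antibody$pct_reduction_LDL)
      expect_gte(r$combined$pct_reduction_LDL, lo - 1e-6)
      expect_lte(r$combined$pct_reduction_LDL, 100)
    }
  }
  # both doses zero: three identical baselines
  r0 <- combined_therapy_scenario(0, 0, 1e14, params = p)
  expect_equal(r0$combined$pct_reduction_LDL, 0)
  expect_equal(r0$statin$l_E, r0$antibody$l_E)
})

test_that("PCSK9 load maps onto reduced recycling efficiency", {
  p <- default_params()
  rc <- recycling_fraction_comparison(c(0, 1e13, 1e14), params = p)
  # no PCSK9: the matched f is the default (no extra degradation burden)
  expect_lt(abs(rc$f_matched[1] - p$f), 0.01)
  expect_lt(rc$discrepancy[1], 0.01)
  # the matched f decreases as the PCSK9 load grows
  expect_true(all(diff(rc$f_matched) < 0))
})

test_that("presets build valid scenarios with their documented events", {
  s <- hl_preset("pcsk9_pulse")
  expect_s3_class(s, "hl_scenario")
  expect_equal(s$events[[1]]$time_h, 100)
  expect_equal(s$events[[1]]$mode, "influx")
  expect_equal(s$events[[1]]$duration_h * 60, 10, tolerance = 1e-12)
  # influx rate integrates back to the documented total of 1e12 molec/mL
  expect_equal(s$events[[1]]$amount * s$events[[1]]$duration_h * 3600,
               1e12, tolerance = 1e-12)
  expect_s3_class(hl_preset("combined"), "hl_scenario")
  b <- hl_preset("baseline")
  expect_equal(b$init[["p_E"]], 1e12)
})
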