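test_that("lipoprotein-free subspace is invariant", {
  p <- hl_params(omega_V = 0)
  s <- scenario(p, horizon_h = 50, dt_out_h = 5)
  sim <- simulate_scenario(s)
  lip <- c("l_E", "l_RB", "l_I", "v_E", "v_RB", "v_I")
  expect_true(all(sim$y[, lip] == 0))
  # the rest of the cell still runs
  expect_gt(sim$y[nrow(sim$y), "c"], 0)
})

test_that("simulation is deterministic and grid-refinement consistent", {
  p <- default_params()
  s <- scenario(p, init = hl_state(p_E = 1e12), horizon_h = 40,
                dt_out_h = 4)
  a <- simulate_scenario(s)
  b <- simulate_scenario(s)
  expect_identical(a$y, b$y)

  s2 <- scenario(p, init = hl_state(p_E = 1e12), horizon_h = 40,
                 dt_out_h = 2)
  cfine <- simulate_scenario(s2)
  shared <- match(a$times_h, cfine$times_h)
  # halving the output step must not move the solution at shared times
  # beyond interpolation-level differences
  expect_lt(max(abs(cfine$y[shared, ] - a$y) /
                  pmax(abs(a$y), 1)), 1e-6)
})

test_that("chaining two integrations equals one integration", {
  p <- default_params()
  sA <- scenario(p, init = hl_state(p_E = 1e12), horizon_h = 100,
                 times_h = c(0, 37, 100))
  rA <- simulate_scenario(sA)
  mid <- stats::setNames(rA$y[2, ], hl_state_names())
  sB <- scenario(p, init = hl_state(values = mid), horizon_h = 63,
                 times_h = c(0, 63))
  rB <- simulate_scenario(sB)
  expect_lt(max(abs(rB$y[2, ] - rA$y[3, ]) / pmax(abs(rA$y[3, ]), 1)),
            1e-6)
})

test_that("adaptive stiff and fixed-step explicit integrations agree", {
  p <- default_params()
  q <- nondimensionalize(p)
  y0 <- as.numeric(state_to_dimensionless(hl_state(p_E = 1e12), p))
  tt <- seq(0, 50, by = 2) * 3600 / p$tau
  a <- hepatolip:::ros23_dimless(y0, tt, q, rtol = 1e-10, atol = 1e-14)$y
  b <- hepatolip:::.hl_rk4_cpp(y0, tt, as.numeric(q), rep(0, 5),
                               1e-3 * 3600 / p$tau)
  expect_lt(max(abs(a - b) / pmax(abs(a), 1e-8)), 1e-4)
})

test_that("steady state satisfies its defining contract", {
  ss <- baseline_steady()
  expect_lt(ss$residual, 1e-10)
  expect_true(ss$stable)
  expect_lte(ss$n_neutral, 2)
  non_drug <- setdiff(hl_state_names(),
                      c("A_E", "p_AB", "S_E", "S_i", "S_ih"))
  expect_true(all(as.numeric(ss$state[non_drug]) > 0))
})

test_that("long_run and root steady-state methods agree", {
  p <- default_params()
  s <- scenario(p, init = hl_state(p_E = 1e12), horizon_h = 200)
  ss_root <- baseline_steady()
  ss_long <- find_steady_state(s, method = "long_run")
  expect_lt(ss_long$residual, 1e-10)
  nz <- abs(ss_root$state_dimless) > 1e-9
  expect_lt(max_rel_dev(ss_long$state_dimless[nz],
                        ss_root$state_dimless[nz]), 1e-6)
})

test_that("random positive initial conditions reach the same fixed point", {
  p <- default_params()
  ss <- baseline_steady()
  ref <- ss$state_dimless
  nz <- abs(ref) > 1e-9
  set.seed(2024)
  for (i in 1:6) {
    fac <- 10^stats::runif(21, -1, 1)
    v <- stats::setNames(as.numeric(ss$state) * fac, hl_state_names())
    ssi <- find_steady_state(scenario(p, init = hl_state(values = v),
                                      horizon_h = 200), method = "root")
    expect_lt(max_rel_dev(ssi$state_dimless[nz], ref[nz]), 1e-4)
  }
})

test_that("steady-state search rejects pending influx events", {
  p <- default_params()
  s <- scenario(p, events = list(
    dose_event(10, "PCSK9_E", "influx", 1e8, duration_h = 1)),
    horizon_h = 50)
  expect_error(find_steady_state(s), "influx")
})

test_that("PCSK9-disabled reduction reproduces the shared variables", {
  p <- default_params()
  s <- scenario(p, horizon_h = 10, dt_out_h = 0.5)
  cmp <- compare_with_reduced_model(s)
  expect_lt(cmp$max_deviation, 0.01)
  # PCSK9 states identically zero in the reduced run
  expect_true(all(cmp$reduced$y[, c("m_p", "p_I", "p_E", "p_RB",
                                    "p_AB")] == 0))
})

test_that("reduction deviation grows with the external PCSK9 load", {
  p <- default_params()
  devs <- vapply(c(1e11, 1e12, 1e13), function(p0) {
    s <- scenario(p, init = hl_state(p_E = p0), horizon_h = 50,
                  dt_out_h = 5)
    compare_with_reduced_model(s)$max_deviation
  }, numeric(1))
  expect_true(all(diff(devs) > 0))
})

test_that("trajectory CSV and metadata sidecar round-trip", {
  p <- default_params()
  s <- scenario(p, init = hl_state(p_E = 1e12), horizon_h = 10,
                dt_out_h = 1,
                events = list(dose_event(5, "statin_E", "bolus", 1e12)))
  sim <- simulate_scenario(s)
  f <- file.path(tempdir(), "traj.csv")
  write_trajectory(sim, f)
  df <- utils::read.csv(f, check.names = FALSE)
  expect_identical(names(df), c("time_h", hl_state_names()))
  expect_equal(as.matrix(df[, -1]), sim$y, tolerance = 1e-12,
               ignore_attr = TRUE)
  meta <- jsonlite::read_json(paste0(f, ".meta.json"))
  expect_identical(meta$scenario_hash, scenario_hash(s))
  expect_equal(length(meta$events), 1L)
  # equal scenario hashes imply byte-identical CSVs
  f2 <- file.path(tempdir(), "traj2.csv")
  write_trajectory(simulate_scenario(s), f2)
  expect_identical(readLines(f), readLines(f2))
})
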