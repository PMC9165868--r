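test_that("transcription rate matches the Hill form at pinned points", {
  # c = 0, kappa = 1, x_gene = 1, mu* = 1: 1/(1 + (1*(1+0))^1) = 1/2
  expect_equal(transcription_rate(0, mu_star = 1, kappa = 1, kc = 1,
                                  xc = 1, x_gene = 1), 0.5)
  # c = kc, kappa = 1, xc = 1, x_gene = 1: 1/(1 + (1*(1+1))^1) = 1/3
  expect_equal(transcription_rate(1, mu_star = 1, kappa = 1, kc = 1,
                                  xc = 1, x_gene = 1), 1 / 3)
  # upper bound mu*/(1 + kappa^x) attained at c = 0, approached from below
  q <- nondimensionalize(default_params())
  for (g in c("HMGCR", "LDLR", "PCSK9")) {
    r0 <- transcription_rate(0, g, p = q)
    expect_gt(r0, 0)
    expect_true(all(transcription_rate(c(1, 10, 100), g, p = q) < r0))
  }
})

test_that("transcription rate is strictly decreasing in cholesterol", {
  q <- nondimensionalize(default_params())
  cc <- seq(0, 5, length.out = 200)
  for (g in c("HMGCR", "LDLR", "PCSK9"))
    expect_true(all(diff(transcription_rate(cc, g, p = q)) < 0))
})

test_that("transcription rate rejects invalid inputs", {
  expect_error(transcription_rate(-1, mu_star = 1, kappa = 1, kc = 1,
                                  xc = 1, x_gene = 1), "non-negative")
  expect_error(transcription_rate(1, mu_star = 1, kappa = 1, kc = 0,
                                  xc = 1, x_gene = 1), "kc")
})

test_that("all-zero state with sources off drives only mRNA (and omega_V)", {
  p <- hl_params_no_vldl_source()
  q <- nondimensionalize(p)
  d <- rhs_dimensionless(0, hl_state(), q)
  mrna <- c("m_h", "m_r", "m_p")
  expect_true(all(d[mrna] > 0))
  expect_true(all(d[setdiff(names(d), mrna)] == 0))

  db <- rhs_dimensional(0, hl_state(), p)
  expect_true(all(db[mrna] > 0))
  expect_true(all(db[setdiff(names(db), mrna)] == 0))
})

test_that("antibody and statin sub-systems satisfy their exact identities", {
  p <- default_params()
  q <- nondimensionalize(p)
  set.seed(101)
  for (i in 1:25) {
    y <- random_state()
    y["r_f"] <- stats::runif(1, 0, 0.9)
    d <- rhs_dimensionless(0, y, q)
    # W dA_E/dt + dp_AB/dt = W*omega_A (zero here), Eqs for the 1:1 complex
    expect_equal(p$W * d[["A_E"]] + d[["p_AB"]], 0, tolerance = 1e-12)
    # statin bookkeeping: d/dt (W S_E + S_i + S_ih) = W*omega_S = 0
    expect_equal(p$W * d[["S_E"]] + d[["S_i"]] + d[["S_ih"]], 0,
                 tolerance = 1e-12)
    # with an active antibody source the identity picks up W*omega_A
    sA <- c(A_E = 0.37)
    dA <- rhs_dimensionless(0, y, q, sources = sA)
    expect_equal(p$W * dA[["A_E"]] + dA[["p_AB"]], p$W * 0.37,
                 tolerance = 1e-9)
    # same identities in the dimensional system, judged relative to the
    # size of the cancelling binding fluxes
    yb <- as.numeric_dim_state(y, p)
    db <- rhs_dimensional(0, yb, p)
    flux_ab <- p$eps_p * yb[["A_E"]] * yb[["p_E"]] + 1
    flux_st <- p$eps_S * yb[["S_i"]] * yb[["h"]] + 1
    expect_lt(abs(p$W * db[["A_E"]] + db[["p_AB"]]) / flux_ab, 1e-10)
    expect_lt(abs(p$W * db[["S_E"]] + db[["S_i"]] + db[["S_ih"]]) / flux_st,
              1e-10)
  }
})

test_that("cholesterol balance matches the termwise oracle", {
  q <- nondimensionalize(default_params())
  y <- hl_state(l_I = 1, v_I = 1, h = 1, c = 1)
  d <- rhs_dimensionless(0, y, q)
  qq <- stats::setNames(as.numeric(q), names(q))
  expected <- qq["R_l_chol"] * qq["sigma_l"] * qq["gamma_l"] +
    qq["R_v_chol"] * qq["sigma_v"] * qq["gamma_v"] +
    qq["mu_c"] - qq["delta_c"]
  expect_equal(d[["c"]], unname(expected), tolerance = 1e-14)
})

test_that("non-negativity: zero components never get negative derivatives", {
  q <- nondimensionalize(default_params())
  set.seed(7)
  for (i in 1:40) {
    y <- random_state()
    y["r_f"] <- stats::runif(1, 0, 0.9)
    zero_idx <- sample(21, sample(1:6, 1))
    y[zero_idx] <- 0
    d <- rhs_dimensionless(0, y, q)
    expect_true(all(d[zero_idx] >= 0),
                info = paste("negative derivative at zero component, i =", i))
  }
})

test_that("RHS rejects invalid states and guards the occupancy singularity", {
  q <- nondimensionalize(default_params())
  y <- hl_state()
  y_neg <- as.numeric(y); y_neg[1] <- -1
  expect_error(hepatolip:::.hl_rhs_cpp(0, y_neg, as.numeric(q), rep(0, 5)),
               "negative")
  y_sing <- hl_state(r_f = 1)
  expect_error(rhs_dimensionless(0, y_sing, q), "occupancy singularity")
  p <- default_params()
  expect_error(rhs_dimensional(0, hl_state(r_f = p$rf0), p),
               "occupancy singularity")
})

test_that("nondimensionalize with identity scales is the identity on rates", {
  p <- hl_params(tau = 1, m0 = 1, s0 = 1, c0 = 1, l0 = 1, v0 = 1,
                 pE0_ref = 1, sE0 = 1, rf0 = 1, W = 1, J = 1,
                 kappa_mh = 2, kappa_mr = 2, kappa_mp = 2, kc = 3)
  q <- nondimensionalize(p)
  for (nm in c("delta_mh", "mu_h", "alpha_l", "beta_p", "chi_v", "mu_c",
               "CL_S", "eps_minus_p", "gamma_r"))
    expect_equal(unname(q[nm]), p[[nm]], info = nm)
  expect_equal(unname(q["kappa_mp"]), 2)
  expect_equal(unname(q["kc"]), 3)
  expect_equal(unname(q["nu_l"]), 1)
  expect_equal(unname(q["zeta_S"]), 1)
})

test_that("dimensionalize inverts nondimensionalize", {
  p <- default_params()
  p2 <- dimensionalize(nondimensionalize(p), template = p)
  for (nm in hl_dimensional_names_exported())
    expect_equal(p2[[nm]], p[[nm]], tolerance = 1e-14, info = nm)
})

test_that("dimensional and dimensionless trajectories coincide under the rescaling", {
  p <- default_params()
  q <- nondimensionalize(p)
  y0_dimless <- hl_state(p_E = 1)  # 1e12 molec/mL on the PCSK9 scale
  y0_dim <- state_to_dimensional(y0_dimless, p)

  # independent route: pure-R integrator on the pure-R dimensional RHS,
  # time in seconds (short horizon here; the acceptance suite runs the
  # full 50 h version)
  times_s <- seq(0, 10 * 3600, length.out = 11)
  f_dim <- function(t, y)
    rhs_dimensional(t, pmax(y, 0), p, validate = FALSE)
  traj_dim <- ros23_r(f_dim, as.numeric(y0_dim), times_s,
                      rtol = 1e-7, atol = 1e2)

  # production route: compiled integrator on the dimensionless system
  res <- rhs_dimless_traj(y0_dimless, times_s / p$tau, q)
  sc <- state_scales_exported(p)
  mapped <- sweep(res, 2, sc, `*`)

  relc <- vapply(seq_len(21), function(j)
    max(abs(mapped[, j] - traj_dim[, j]) / max(abs(traj_dim[, j]), 1e-30)),
    numeric(1))
  expect_lt(max(relc), 1e-6)
})
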