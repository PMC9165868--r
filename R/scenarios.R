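#' Scenario presets for the packaged in silico experiments
#'
#' Builders reproducing the package's canonical dosing experiments:
#' \describe{
#'   \item{baseline}{growth from the empty state with the constant VLDL
#'     source and an initial extracellular PCSK9 concentration (default
#'     1e12 molec./mL).}
#'   \item{parent_comparison}{baseline with no external PCSK9, for
#'     comparison against the PCSK9-free reduction.}
#'   \item{pcsk9_pulse}{a 10-minute extracellular PCSK9 influx of
#'     1e12 molec./(mL) equivalent starting at 100 h.}
#'   \item{statin}{a single statin dose at 10 h.}
#'   \item{antibody / small_molecule}{an anti-PCSK9 agent applied at t = 0
#'     together with a high PCSK9 load (1e14 molec./mL).}
#'   \item{combined}{simultaneous statin and antibody under the high PCSK9
#'     load.}
#' }
#'
#' @param name Preset name (see above).
#' @param params Base parameters.
#' @param ... Overrides passed to the specific builder (`pcsk9_init`,
#'   `dose`, `t_dose_h`, `horizon_h`, ...).
#' @return An [scenario()].
#' @export
hl_preset <- function(name = c("baseline", "parent_comparison",
                               "pcsk9_pulse", "statin", "antibody",
                               "small_molecule", "combined"),
                      params = hl_params(), ...) {
  name <- match.arg(name)
  args <- list(...)
  horizon_h <- args$horizon_h %||% 200
  pcsk9_init <- args$pcsk9_init %||% 1e12
  switch(name,
    baseline = scenario(params,
      init = hl_state(p_E = pcsk9_init), horizon_h = horizon_h),
    parent_comparison = scenario(params, horizon_h = horizon_h),
    pcsk9_pulse = scenario(params, horizon_h = args$horizon_h %||% 400,
      events = list(dose_event(args$t_dose_h %||% 100, "PCSK9_E",
                               "influx",
                               amount = (args$dose %||% 1e12) / 600,
                               duration_h = 600 / 3600))),
    statin = statin_scenario(dose = args$dose %||% 1e12,
      t_dose_h = args$t_dose_h %||% 10, params = params,
      horizon_h = args$horizon_h %||% 500)$scenario,
    antibody = anti_pcsk9_scenario("antibody", dose = args$dose %||% 2e14,
      pcsk9_init = args$pcsk9_init %||% 1e14, params = params,
      horizon_h = args$horizon_h %||% 500)$scenario,
    small_molecule = anti_pcsk9_scenario("small_molecule",
      dose = args$dose %||% 2e14, pcsk9_init = args$pcsk9_init %||% 1e14,
      params = params, horizon_h = args$horizon_h %||% 500)$scenario,
    combined = scenario(params, init = hl_state(p_E = args$pcsk9_init %||% 1e14),
      events = list(
        dose_event(0, "statin_E", "bolus", args$statin_dose %||% 1e12),
        dose_event(0, "antibody_E", "bolus", args$antibody_dose %||% 2e14)),
      horizon_h = args$horizon_h %||% 500)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# therapy metrics are read at this pseudo-steady horizon: a PCSK9 or drug
# bolus has no influence on the true fixed point (it washes out), so the
# operative quantity is the late-time plateau of the dosing experiment
METRIC_READ_H <- 500

endpoint_lipoproteins <- function(sim) {
  n <- nrow(sim$y)
  c(l_E = unname(sim$y[n, "l_E"]), v_E = unname(sim$y[n, "v_E"]))
}

#' Therapy outcome metrics
#'
#' Summarises a therapy run against its baseline: late-time (500 h)
#' extracellular LDL and VLDL, percent reduction versus baseline, and the
#' time from dosing to half-maximal LDL reduction.
#'
#' @param sim Therapy run (`hl_sim`).
#' @param baseline Baseline run on the same output grid.
#' @param t_dose_h Dosing time (hours) for the half-response clock.
#' @return List of class `hl_therapy_metrics`.
#' @export
therapy_metrics <- function(sim, baseline, t_dose_h = 0) {
  stopifnot(identical(sim$times_h, baseline$times_h))
  ep <- endpoint_lipoproteins(sim)
  eb <- endpoint_lipoproteins(baseline)
  red <- function(a, b) if (b > 0) unname(100 * (1 - a / b)) else 0
  reduction <- sim$times_h >= t_dose_h
  dl <- baseline$y[, "l_E"] - sim$y[, "l_E"]
  dl[!reduction] <- 0
  t_half <- NA_real_
  if (max(dl) > 0) {
    i <- which(dl >= 0.5 * max(dl))[1]
    t_half <- sim$times_h[i] - t_dose_h
  }
  structure(list(
    l_E = unname(ep["l_E"]), v_E = unname(ep["v_E"]),
    l_E_baseline = unname(eb["l_E"]), v_E_baseline = unname(eb["v_E"]),
    pct_reduction_LDL = red(ep["l_E"], eb["l_E"]),
    pct_reduction_VLDL = red(ep["v_E"], eb["v_E"]),
    t_half_LDL_h = t_half), class = "hl_therapy_metrics")
}

#' @export
print.hl_therapy_metrics <- function(x, ...) {
  cat(sprintf(
    "<therapy metrics> LDL %.3g (%.1f%% vs baseline), VLDL %.3g (%.1f%%), t1/2 = %s h\n",
    x$l_E, x$pct_reduction_LDL, x$v_E, x$pct_reduction_VLDL,
    format(x$t_half_LDL_h)))
  invisible(x)
}

#' Scan initial extracellular PCSK9 for the LDL-elevation threshold
#'
#' Runs the baseline experiment across a grid of initial extracellular PCSK9
#' concentrations and reports the smallest concentration whose late-time
#' (500 h) extracellular LDL exceeds the PCSK9-free baseline by at least
#' `elevation_frac`, together with the full metric curve.
#'
#' @param decades Ascending PCSK9 concentrations, molec./mL (default the
#'   decade grid 1e10 to 1e15).
#' @param elevation_frac Threshold elevation over baseline (default 0.10,
#'   i.e. a 10 percent "noticeable effect").
#' @param params Base parameters.
#' @param read_h Read-out time, hours.
#' @return List: `threshold` (concentration, or `NA` if no decade
#'   qualifies), `curve` (data frame of concentration, LDL, VLDL,
#'   elevation), `baseline_l_E`.
#' @export
pcsk9_threshold_scan <- function(decades = 10^(10:15),
                                 elevation_frac = 0.10,
                                 params = hl_params(),
                                 read_h = METRIC_READ_H) {
  stopifnot(all(diff(decades) > 0), elevation_frac > 0)
  run_one <- function(p0) {
    s <- scenario(params, init = hl_state(p_E = p0), horizon_h = read_h,
                  dt_out_h = read_h / 100)
    endpoint_lipoproteins(simulate_scenario(s))
  }
  base <- run_one(0)
  curve <- t(vapply(decades, run_one, c(l_E = 0, v_E = 0)))
  elev <- curve[, "l_E"] / base["l_E"] - 1
  qualifies <- elev >= elevation_frac
  threshold <- if (any(qualifies)) decades[which(qualifies)[1]] else NA_real_
  list(threshold = threshold,
       curve = data.frame(pcsk9 = decades, l_E = curve[, "l_E"],
                          v_E = curve[, "v_E"], elevation = elev),
       baseline_l_E = unname(base["l_E"]))
}

#' Statin therapy experiment
#'
#' Applies a single statin dose to the baseline experiment. Statin enters
#' the cell via the uptake clearance, sequesters HMGCR and thereby
#' suppresses cholesterol synthesis; the SREBP-2 feedback then up-regulates
#' all three mRNAs, and the extra LDL receptor lowers extracellular LDL and
#' VLDL.
#'
#' @param dose Statin bolus, molec./mL (default 1e12).
#' @param t_dose_h Dosing time, hours (default 10).
#' @param params Base parameters.
#' @param pcsk9_init Initial extracellular PCSK9, molec./mL.
#' @param horizon_h Horizon (>= 500 h recommended for settled metrics).
#' @param mode `"bolus"` (default) or `"influx"` over `influx_duration_h`.
#' @param influx_duration_h Influx length if `mode = "influx"`.
#' @return List: `sim`, `baseline`, `metrics`, `scenario`.
#' @export
statin_scenario <- function(dose = 1e12, t_dose_h = 10,
                            params = hl_params(), pcsk9_init = 0,
                            horizon_h = METRIC_READ_H,
                            mode = c("bolus", "influx"),
                            influx_duration_h = 0.5) {
  mode <- match.arg(mode)
  stopifnot(dose >= 0)
  ev <- if (dose > 0) {
    if (mode == "bolus")
      list(dose_event(t_dose_h, "statin_E", "bolus", dose))
    else
      list(dose_event(t_dose_h, "statin_E", "influx",
                      amount = dose / (influx_duration_h * 3600),
                      duration_h = influx_duration_h))
  } else list()
  init <- hl_state(p_E = pcsk9_init)
  s <- scenario(params, init = init, events = ev, horizon_h = horizon_h)
  sim <- simulate_scenario(s)
  base <- simulate_scenario(scenario(params, init = init,
                                     horizon_h = horizon_h))
  list(sim = sim, baseline = base,
       metrics = therapy_metrics(sim, base, t_dose_h), scenario = s)
}

#' Anti-PCSK9 therapy experiment
#'
#' Applies an anti-PCSK9 agent at t = 0 together with a high extracellular
#' PCSK9 load. The agent binds PCSK9 1:1 and prevents PCSK9-LDLR binding.
#' The small-molecule variant differs from the antibody purely in its
#' binding kinetics: a larger association rate (times `on_factor`) and a
#' smaller dissociation rate (divided by `off_factor`), reflecting its
#' smaller size and higher diffusivity.
#'
#' @param agent `"antibody"` or `"small_molecule"`.
#' @param dose Agent bolus at t = 0, molec./mL.
#' @param pcsk9_init Initial extracellular PCSK9 (default 1e14 molec./mL).
#' @param params Base parameters.
#' @param on_factor,off_factor Small-molecule kinetic modifiers
#'   (defaults 10 and 10).
#' @param horizon_h Horizon, hours.
#' @return List: `sim`, `baseline` (no agent), `metrics`, `scenario`.
#' @export
anti_pcsk9_scenario <- function(agent = c("antibody", "small_molecule"),
                                dose = 2e14, pcsk9_init = 1e14,
                                params = hl_params(),
                                on_factor = 10, off_factor = 10,
                                horizon_h = METRIC_READ_H) {
  agent <- match.arg(agent)
  stopifnot(dose >= 0)
  p <- params
  if (agent == "small_molecule")
    p <- hl_params_update(p, eps_p = p$eps_p * on_factor,
                          eps_minus_p = p$eps_minus_p / off_factor)
  init <- hl_state(p_E = pcsk9_init, A_E = dose)
  s <- scenario(p, init = init, horizon_h = horizon_h)
  sim <- simulate_scenario(s)
  base <- simulate_scenario(scenario(params,
                                     init = hl_state(p_E = pcsk9_init),
                                     horizon_h = horizon_h))
  list(sim = sim, baseline = base,
       metrics = therapy_metrics(sim, base, 0), scenario = s)
}

#' Combined statin plus anti-PCSK9 therapy
#'
#' Runs statin-only, antibody-only and combined arms (all doses at t = 0,
#' under the same PCSK9 load) and reports the three metric sets. The
#' combined arm acts through two complementary mechanisms and its late-time
#' LDL does not exceed either monotherapy's.
#'
#' @param statin_dose,antibody_dose Doses at t = 0, molec./mL.
#' @param pcsk9_init Initial extracellular PCSK9, molec./mL.
#' @param params Base parameters.
#' @param horizon_h Horizon, hours.
#' @return List with `statin`, `antibody`, `combined` metric sets and the
#'   underlying `hl_sim` objects.
#' @export
combined_therapy_scenario <- function(statin_dose = 1e12,
                                      antibody_dose = 2e14,
                                      pcsk9_init = 1e14,
                                      params = hl_params(),
                                      horizon_h = METRIC_READ_H) {
  stopifnot(statin_dose >= 0, antibody_dose >= 0)
  init <- hl_state(p_E = pcsk9_init)
  run <- function(st, ab) {
    ev <- list()
    if (st > 0) ev <- c(ev, list(dose_event(0, "statin_E", "bolus", st)))
    if (ab > 0) ev <- c(ev, list(dose_event(0, "antibody_E", "bolus", ab)))
    simulate_scenario(scenario(params, init = init, events = ev,
                               horizon_h = horizon_h))
  }
  base <- run(0, 0)
  sim_s <- run(statin_dose, 0)
  sim_a <- run(0, antibody_dose)
  sim_c <- run(statin_dose, antibody_dose)
  list(statin = therapy_metrics(sim_s, base, 0),
       antibody = therapy_metrics(sim_a, base, 0),
       combined = therapy_metrics(sim_c, base, 0),
       sims = list(baseline = base, statin = sim_s, antibody = sim_a,
                   combined = sim_c))
}

#' Match PCSK9 load against reduced recycling efficiency
#'
#' PCSK9-mediated receptor degradation mimics a loss of recycling
#' efficiency. For each PCSK9 concentration this routine finds, by scalar
#' search over the recycled fraction `f`, the PCSK9-free run whose
#' late-time extracellular LDL best matches the PCSK9-laden run at the
#' default `f`.
#'
#' @param pcsk9_values PCSK9 concentrations to match, molec./mL.
#' @param f_range Search interval for `f` (subset of `[0, 1]`).
#' @param params Base parameters.
#' @param read_h Read-out time, hours.
#' @return Data frame: `pcsk9`, `l_E_target`, `f_matched`, `discrepancy`
#'   (relative LDL mismatch at the optimum; `NA` f if unmatched).
#' @export
recycling_fraction_comparison <- function(pcsk9_values = c(0, 1e13, 1e14),
                                          f_range = c(0, NA),
                                          params = hl_params(),
                                          read_h = METRIC_READ_H) {
  if (is.na(f_range[2])) f_range[2] <- params$f
  lE_for <- function(p0, fval) {
    pp <- hl_params_update(params, f = fval)
    s <- scenario(pp, init = hl_state(p_E = p0), horizon_h = read_h,
                  dt_out_h = read_h / 50)
    endpoint_lipoproteins(simulate_scenario(s))[["l_E"]]
  }
  rows <- lapply(pcsk9_values, function(p0) {
    target <- lE_for(p0, params$f)
    obj <- function(fv) abs(lE_for(0, fv) - target) / target
    opt <- stats::optimize(obj, interval = f_range, tol = 1e-3)
    data.frame(pcsk9 = p0, l_E_target = target, f_matched = opt$minimum,
               discrepancy = opt$objective)
  })
  do.call(rbind, rows)
}
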