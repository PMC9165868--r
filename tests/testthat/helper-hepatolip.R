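# shared fixtures: the default parameter set and lazily cached expensive
# objects (baseline steady state, scan curve) reused across test files
hl_cache <- new.env(parent = emptyenv())

default_params <- function() {
  if (is.null(hl_cache$params)) hl_cache$params <- hl_params()
  hl_cache$params
}

baseline_steady <- function() {
  if (is.null(hl_cache$steady)) {
    s <- scenario(default_params(), init = hl_state(p_E = 1e12),
                  horizon_h = 200)
    hl_cache$steady <- find_steady_state(s, method = "root")
  }
  hl_cache$steady
}

threshold_scan_cached <- function() {
  if (is.null(hl_cache$scan))
    hl_cache$scan <- pcsk9_threshold_scan(decades = 10^(10:15),
                                          elevation_frac = 0.10,
                                          params = default_params())
  hl_cache$scan
}

# random non-negative state with a sensible magnitude profile (dimensionless)
random_state <- function() {
  stats::setNames(stats::runif(21, 0, 5), hl_state_names())
}

# max relative deviation over components that are meaningfully non-zero
max_rel_dev <- function(a, b, floor = 1e-9) {
  max(abs(a - b) / pmax(abs(b), floor))
}

hl_params_no_vldl_source <- function() hl_params(omega_V = 0)

as.numeric_dim_state <- function(y, p) {
  v <- as.numeric(state_to_dimensional(hl_state(values =
    stats::setNames(as.numeric(y), hl_state_names())), p))
  stats::setNames(v, hl_state_names())
}

hl_dimensional_names_exported <- function() hepatolip:::hl_dimensional_names()

state_scales_exported <- function(p) hepatolip:::state_scales(p)

rhs_dimless_traj <- function(y0, tt, q, rtol = 1e-10, atol = 1e-14) {
  hepatolip:::ros23_dimless(as.numeric(hl_state(values =
    stats::setNames(as.numeric(y0), hl_state_names()))), tt, q,
    rtol = rtol, atol = atol)$y
}
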