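#' Dimensionless parameter names
#'
#' Order of the dimensionless parameter vector used by the compiled
#' right-hand side. Includes the scaling ratios `nu_l`, `nu_v`, `nu_p`,
#' `rho_v`, `sigma_l`, `sigma_v` that only exist in the non-dimensionalised
#' system, and `zeta_S`, the statin-to-protein scale ratio entering the
#' HMGCR-statin terms.
#'
#' @return Character vector of length 58.
#' @export
hl_par_names <- function() {
  c("J", "W", "P", "f",
    "mu_mh_star", "mu_mr_star", "mu_mp_star",
    "delta_mh", "delta_mr", "delta_mp",
    "kappa_mh", "kappa_mr", "kappa_mp",
    "kc", "xc", "xh", "xr", "xp",
    "mu_h", "mu_r", "mu_p",
    "delta_h", "delta_p", "delta_c",
    "gamma_r", "gamma_p", "gamma_l", "gamma_v",
    "beta_0", "beta_l", "beta_v", "beta_p",
    "alpha_l", "alpha_minus_l", "alpha_v", "alpha_minus_v",
    "alpha_p", "alpha_minus_p",
    "M_l", "M_v", "M_p",
    "chi_v", "omega_v",
    "R_l_chol", "R_v_chol", "mu_c",
    "sigma_l", "sigma_v", "nu_l", "nu_v", "nu_p", "rho_v",
    "CL_S", "eps_S", "eps_minus_S", "zeta_S",
    "eps_p", "eps_minus_p")
}

# per-component state scales, in canonical state order
state_scales <- function(p) {
  c(m_h = p$m0, m_r = p$m0, m_p = p$m0,
    h = p$s0, p_I = p$pE0_ref, r_I = p$rf0, r_f = p$rf0,
    l_E = p$l0, l_RB = p$l0, l_I = p$l0,
    v_E = p$v0, v_RB = p$v0, v_I = p$v0,
    c = p$c0,
    p_E = p$pE0_ref, p_RB = p$pE0_ref,
    A_E = p$pE0_ref, p_AB = p$pE0_ref,
    S_E = p$sE0, S_i = p$sE0, S_ih = p$sE0)
}

#' Non-dimensionalise the model parameters
#'
#' Maps the dimensional parameter set onto the dimensionless parameters of
#' the final system. The rescaling uses the time scale `tau` and the
#' per-species reference concentrations carried in the parameter set
#' (`m0` for mRNAs, `s0` for HMGCR, `rf0` for receptors, `l0`/`v0` for
#' LDL/VLDL, `c0` for cholesterol, `pE0_ref` for all PCSK9/antibody pools and
#' `sE0` for statin pools). The defining contract of this map — that
#' trajectories of the dimensional system, rescaled, coincide with
#' trajectories of the dimensionless system — is enforced by the package's
#' consistency tests.
#'
#' @param p An [hl_params()] object.
#' @return Object of class `hl_dimless`: named numeric vector in
#'   [hl_par_names()] order, with the scales kept as an attribute.
#' @export
nondimensionalize <- function(p) {
  validate_params(p)
  tau <- p$tau
  sc <- state_scales(p)
  q <- c(
    J = p$J, W = p$W, P = p$P, f = p$f,
    mu_mh_star = p$mu_mh_star * tau / p$m0,
    mu_mr_star = p$mu_mr_star * tau / p$m0,
    mu_mp_star = p$mu_mp_star * tau / p$m0,
    delta_mh = p$delta_mh * tau,
    delta_mr = p$delta_mr * tau,
    delta_mp = p$delta_mp * tau,
    kappa_mh = p$kappa_mh / p$s0,
    kappa_mr = p$kappa_mr / p$s0,
    kappa_mp = p$kappa_mp / p$s0,
    kc = p$kc / p$c0,
    xc = p$xc, xh = p$xh, xr = p$xr, xp = p$xp,
    mu_h = p$mu_h * tau * p$m0 / p$s0,
    mu_r = p$mu_r * tau * p$m0 / p$rf0,
    mu_p = p$mu_p * tau * p$m0 / p$pE0_ref,
    delta_h = p$delta_h * tau,
    delta_p = p$delta_p * tau,
    delta_c = p$delta_c * tau,
    gamma_r = p$gamma_r * tau,
    gamma_p = p$gamma_p * tau,
    gamma_l = p$gamma_l * tau,
    gamma_v = p$gamma_v * tau,
    beta_0 = p$beta_0 * tau,
    beta_l = p$beta_l * tau,
    beta_v = p$beta_v * tau,
    beta_p = p$beta_p * tau,
    alpha_l = p$alpha_l * p$rf0 * tau,
    alpha_minus_l = p$alpha_minus_l * tau,
    alpha_v = p$alpha_v * p$rf0 * tau,
    alpha_minus_v = p$alpha_minus_v * tau,
    alpha_p = p$alpha_p * p$rf0 * tau,
    alpha_minus_p = p$alpha_minus_p * tau,
    M_l = p$M_l, M_v = p$M_v, M_p = p$M_p,
    chi_v = p$chi_v * tau,
    omega_v = p$omega_V * tau / p$v0,
    R_l_chol = p$R_l_chol, R_v_chol = p$R_v_chol,
    mu_c = p$mu_c * tau * p$s0 / p$c0,
    sigma_l = p$l0 / p$c0,
    sigma_v = p$v0 / p$c0,
    nu_l = p$l0 / p$rf0,
    nu_v = p$v0 / p$rf0,
    nu_p = p$pE0_ref / p$rf0,
    rho_v = p$v0 / p$l0,
    CL_S = p$CL_S * tau,
    eps_S = p$eps_S * tau * p$s0,
    eps_minus_S = p$eps_minus_S * tau,
    zeta_S = p$sE0 / p$s0,
    eps_p = p$eps_p * tau * p$pE0_ref,
    eps_minus_p = p$eps_minus_p * tau
  )
  q <- q[hl_par_names()]
  structure(q, scales = c(tau = tau, sc),
            baseline_sources = c(omega_P = p$omega_P, omega_A = p$omega_A,
                                 omega_S = p$omega_S),
            class = c("hl_dimless", "numeric"))
}

#' Recover dimensional parameters from a dimensionless set
#'
#' Exact inverse of [nondimensionalize()] given the same reference scales.
#'
#' @param q An `hl_dimless` object produced by [nondimensionalize()].
#' @param template An [hl_params()] object providing the reference scales
#'   (and provenance metadata); defaults to the packaged set.
#' @return An [hl_params()] object; round-trips bit-exactly up to floating
#'   division/multiplication.
#' @export
dimensionalize <- function(q, template = hl_params()) {
  stopifnot(inherits(q, "hl_dimless"))
  p <- template
  tau <- p$tau
  q <- as.numeric_named(q)
  p$mu_mh_star <- q[["mu_mh_star"]] * p$m0 / tau
  p$mu_mr_star <- q[["mu_mr_star"]] * p$m0 / tau
  p$mu_mp_star <- q[["mu_mp_star"]] * p$m0 / tau
  p$delta_mh <- q[["delta_mh"]] / tau
  p$delta_mr <- q[["delta_mr"]] / tau
  p$delta_mp <- q[["delta_mp"]] / tau
  p$kappa_mh <- q[["kappa_mh"]] * p$s0
  p$kappa_mr <- q[["kappa_mr"]] * p$s0
  p$kappa_mp <- q[["kappa_mp"]] * p$s0
  p$kc <- q[["kc"]] * p$c0
  p$xc <- q[["xc"]]; p$xh <- q[["xh"]]; p$xr <- q[["xr"]]; p$xp <- q[["xp"]]
  p$mu_h <- q[["mu_h"]] * p$s0 / (tau * p$m0)
  p$mu_r <- q[["mu_r"]] * p$rf0 / (tau * p$m0)
  p$mu_p <- q[["mu_p"]] * p$pE0_ref / (tau * p$m0)
  p$delta_h <- q[["delta_h"]] / tau
  p$delta_p <- q[["delta_p"]] / tau
  p$delta_c <- q[["delta_c"]] / tau
  p$gamma_r <- q[["gamma_r"]] / tau
  p$gamma_p <- q[["gamma_p"]] / tau
  p$gamma_l <- q[["gamma_l"]] / tau
  p$gamma_v <- q[["gamma_v"]] / tau
  p$beta_0 <- q[["beta_0"]] / tau
  p$beta_l <- q[["beta_l"]] / tau
  p$beta_v <- q[["beta_v"]] / tau
  p$beta_p <- q[["beta_p"]] / tau
  p$alpha_l <- q[["alpha_l"]] / (p$rf0 * tau)
  p$alpha_minus_l <- q[["alpha_minus_l"]] / tau
  p$alpha_v <- q[["alpha_v"]] / (p$rf0 * tau)
  p$alpha_minus_v <- q[["alpha_minus_v"]] / tau
  p$alpha_p <- q[["alpha_p"]] / (p$rf0 * tau)
  p$alpha_minus_p <- q[["alpha_minus_p"]] / tau
  p$M_l <- q[["M_l"]]; p$M_v <- q[["M_v"]]; p$M_p <- q[["M_p"]]
  p$chi_v <- q[["chi_v"]] / tau
  p$omega_V <- q[["omega_v"]] * p$v0 / tau
  p$R_l_chol <- q[["R_l_chol"]]; p$R_v_chol <- q[["R_v_chol"]]
  p$mu_c <- q[["mu_c"]] * p$c0 / (tau * p$s0)
  p$CL_S <- q[["CL_S"]] / tau
  p$eps_S <- q[["eps_S"]] / (tau * p$s0)
  p$eps_minus_S <- q[["eps_minus_S"]] / tau
  p$eps_p <- q[["eps_p"]] / (tau * p$pE0_ref)
  p$eps_minus_p <- q[["eps_minus_p"]] / tau
  p$f <- q[["f"]]; p$W <- q[["W"]]; p$J <- q[["J"]]; p$P <- q[["P"]]
  validate_params(p)
  p
}

as.numeric_named <- function(x) stats::setNames(as.numeric(x), names(x))

#' Rescale a dimensional state to dimensionless units (and back)
#'
#' @param y_bar Dimensional state (named, canonical order), molec./mL.
#' @param p An [hl_params()] object carrying the reference scales.
#' @return Named state vector in the other unit system.
#' @export
state_to_dimensionless <- function(y_bar, p) {
  y_bar <- as_state(y_bar)
  sc <- state_scales(p)
  hl_state(values = as.numeric_named(y_bar) / sc)
}

#' @rdname state_to_dimensionless
#' @param y Dimensionless state (named, canonical order).
#' @export
state_to_dimensional <- function(y, p) {
  y <- as_state(y)
  sc <- state_scales(p)
  hl_state(values = as.numeric_named(y) * sc)
}
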