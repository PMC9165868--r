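#' Transcriptional activation rate under SREBP-2/cholesterol feedback
#'
#' Transcription of the HMGCR, LDLR and PCSK9 genes is activated by SREBP-2
#' and repressed indirectly by cholesterol, which sequesters SREBP-2. The
#' rate takes the Hill-type form
#' \deqn{\mu^* / \left(1 + \left[\kappa\,(1 + (c/k_c)^{x_c})\right]^{x_g}\right)}
#' where `kappa` is the (dimensionless) gene binding affinity, `kc` the
#' SREBP-2-cholesterol dissociation scale, `xc` the number of cholesterol
#' molecules inactivating SREBP-2, and `x_gene` the number of SREBP-2 binding
#' sites on the gene. Strictly decreasing in `c`; bounded above by
#' `mu_star / (1 + kappa^x_gene)`.
#'
#' @param c Cholesterol level (same units as `kc`), non-negative scalar or
#'   vector.
#' @param gene One of `"HMGCR"`, `"LDLR"`, `"PCSK9"`; selects `mu_star`,
#'   `kappa` and `x_gene` from `p` unless given explicitly.
#' @param p Dimensionless parameters ([nondimensionalize()]); optional if
#'   `mu_star`, `kappa`, `kc`, `xc`, `x_gene` are all supplied.
#' @param mu_star,kappa,kc,xc,x_gene Explicit Hill parameters (override `p`).
#' @return Transcription rate(s), same length as `c`.
#' @export
transcription_rate <- function(c, gene = c("HMGCR", "LDLR", "PCSK9"),
                               p = NULL, mu_star = NULL, kappa = NULL,
                               kc = NULL, xc = NULL, x_gene = NULL) {
  if (!is.null(p)) {
    gene <- match.arg(gene)
    sfx <- switch(gene, HMGCR = "h", LDLR = "r", PCSK9 = "p")
    q <- as.numeric_named(p)
    if (is.null(mu_star)) mu_star <- q[[paste0("mu_m", sfx, "_star")]]
    if (is.null(kappa)) kappa <- q[[paste0("kappa_m", sfx)]]
    if (is.null(kc)) kc <- q[["kc"]]
    if (is.null(xc)) xc <- q[["xc"]]
    if (is.null(x_gene)) x_gene <- q[[paste0("x", sfx)]]
  }
  if (any(is.null(mu_star), is.null(kappa), is.null(kc), is.null(xc),
          is.null(x_gene)))
    stop("supply either `p` or all of mu_star, kappa, kc, xc, x_gene",
         call. = FALSE)
  if (any(c < 0)) stop("cholesterol level must be non-negative", call. = FALSE)
  if (kc <= 0) stop("kc must be positive", call. = FALSE)
  if (mu_star < 0 || kappa < 0 || xc < 1 || x_gene < 1)
    stop("invalid Hill parameters", call. = FALSE)
  mu_star / (1 + (kappa * (1 + (c / kc)^xc))^x_gene)
}

zero_sources <- function() {
  c(l_E = 0, v_E = 0, p_E = 0, A_E = 0, S_E = 0)
}

as_sources <- function(sources) {
  s <- zero_sources()
  if (is.null(sources)) return(s)
  if (is.null(names(sources)))
    stop("sources must be named (subset of l_E, v_E, p_E, A_E, S_E)",
         call. = FALSE)
  unknown <- setdiff(names(sources), names(s))
  if (length(unknown))
    stop("unknown source species: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  s[names(sources)] <- as.numeric(sources)
  if (any(s < 0)) stop("source strengths must be non-negative", call. = FALSE)
  s
}

#' Right-hand side of the non-dimensionalised system
#'
#' Evaluates the 21 time derivatives of the final (dimensionless) system at
#' state `y`. This is the authoritative production RHS (compiled); the
#' dimensional form [rhs_dimensional()] exists as an independent cross-check
#' route.
#'
#' @param t Time (dimensionless; the system is autonomous, `t` is accepted
#'   for interface compatibility).
#' @param y State vector (21 named non-negative components, canonical
#'   order).
#' @param p Dimensionless parameters from [nondimensionalize()].
#' @param sources Optional named vector of active dimensionless source
#'   strengths for `l_E`, `v_E`, `p_E`, `A_E`, `S_E` (from dosing events;
#'   the constant VLDL source `omega_v` lives in `p`).
#' @return Named numeric vector of 21 derivatives.
#' @export
rhs_dimensionless <- function(t, y, p, sources = NULL) {
  stopifnot(inherits(p, "hl_dimless"))
  y <- as_state(y)
  s <- as_sources(sources)
  d <- .hl_rhs_cpp(t, as.numeric(y), as.numeric(p), as.numeric(s))
  stats::setNames(as.numeric(d), hl_state_names())
}

#' Right-hand side of the dimensional system
#'
#' Pure-R evaluation of the dimensional (barred) equations, time in seconds
#' and concentrations in molec./mL. Serves as the independent oracle for the
#' rescaling map: trajectories of this system, rescaled through
#' [state_to_dimensionless()], must coincide with trajectories of
#' [rhs_dimensionless()].
#'
#' @param t Time in seconds (system is autonomous).
#' @param y_bar Dimensional state (21 named non-negative components).
#' @param p An [hl_params()] object.
#' @param sources Optional named vector of dimensional source strengths
#'   (molec./(mL s)) for `l_E`, `v_E`, `p_E`, `A_E`, `S_E`, added on top of
#'   the constant parameters `omega_V`, `omega_P`, `omega_A`, `omega_S`.
#' @param validate Re-validate parameters and state on every call (default
#'   `TRUE`); integrators that call the RHS in a tight loop validate once
#'   and pass `FALSE`.
#' @return Named numeric vector of 21 derivatives (molec./(mL s)).
#' @export
rhs_dimensional <- function(t, y_bar, p, sources = NULL, validate = TRUE) {
  if (validate) {
    validate_params(p)
    y <- as_state(y_bar)
    s <- as_sources(sources)
  } else {
    y <- y_bar
    if (is.null(names(y))) names(y) <- hl_state_names()
    s <- if (is.null(sources)) zero_sources() else sources
  }
  if (any(!is.finite(y))) stop("non-finite state", call. = FALSE)
  if (any(y < 0)) stop("negative state component", call. = FALSE)

  occ_deficit <- p$rf0 - y[["r_f"]]
  if (occ_deficit < p$rf0 * 1e-10)
    stop("receptor occupancy singularity: r_f has reached the surface ",
         "capacity rf0", call. = FALSE)

  act <- 1 + (y[["c"]] / p$kc)^p$xc
  T_h <- p$mu_mh_star / (1 + (p$kappa_mh * act / p$s0)^p$xh)
  T_r <- p$mu_mr_star / (1 + (p$kappa_mr * act / p$s0)^p$xr)
  T_p <- p$mu_mp_star / (1 + (p$kappa_mp * act / p$s0)^p$xp)

  r_f <- y[["r_f"]]
  # receptors internalised with bound-particle vesicles: the M bound
  # receptors per particle plus co-captured free receptors in proportion
  # r_f : (rf0 - r_f); total per particle M * rf0/(rf0 - r_f)
  rec_l <- p$beta_l * y[["l_RB"]] / occ_deficit
  rec_v <- p$beta_v * y[["v_RB"]] / occ_deficit
  rec_p <- p$beta_p * y[["p_RB"]] / occ_deficit

  d <- numeric(21)
  names(d) <- hl_state_names()
  d["m_h"] <- (T_h - p$delta_mh * y[["m_h"]]) / p$J
  d["m_r"] <- (T_r - p$delta_mr * y[["m_r"]]) / p$J
  d["m_p"] <- (T_p - p$delta_mp * y[["m_p"]]) / p$J
  d["h"] <- p$mu_h * y[["m_h"]] - p$delta_h * y[["h"]] -
    p$eps_S * y[["S_i"]] * y[["h"]] + p$eps_minus_S * y[["S_ih"]]
  d["p_I"] <- p$mu_p * y[["m_p"]] - (p$gamma_p + p$delta_p) * y[["p_I"]]
  d["r_I"] <- p$mu_r * y[["m_r"]] - p$gamma_r * y[["r_I"]] +
    p$f * p$beta_0 * r_f / p$P +
    p$f * p$M_l * rec_l * p$rf0 +
    p$f * p$M_v * rec_v * p$rf0
  d["r_f"] <- p$gamma_r * y[["r_I"]] - p$beta_0 * r_f / p$P +
    (-p$M_l * rec_l * r_f - p$M_l * p$alpha_l * r_f * y[["l_E"]] +
       p$M_l * p$alpha_minus_l * y[["l_RB"]]) +
    (-p$M_v * rec_v * r_f - p$M_v * p$alpha_v * r_f * y[["v_E"]] +
       p$M_v * p$alpha_minus_v * y[["v_RB"]]) +
    (-p$M_p * rec_p * r_f - p$M_p * p$alpha_p * r_f * y[["p_E"]] +
       p$M_p * p$alpha_minus_p * y[["p_RB"]])
  d["l_E"] <- (-p$alpha_l * r_f * y[["l_E"]] +
                 p$alpha_minus_l * y[["l_RB"]]) / p$W +
    p$chi_v * y[["v_E"]] + s[["l_E"]]
  d["l_RB"] <- p$alpha_l * r_f * y[["l_E"]] -
    p$alpha_minus_l * y[["l_RB"]] - p$beta_l * y[["l_RB"]]
  d["l_I"] <- p$beta_l * y[["l_RB"]] - p$gamma_l * y[["l_I"]]
  d["v_E"] <- (-p$alpha_v * r_f * y[["v_E"]] +
                 p$alpha_minus_v * y[["v_RB"]]) / p$W -
    p$chi_v * y[["v_E"]] + p$omega_V + s[["v_E"]]
  d["v_RB"] <- p$alpha_v * r_f * y[["v_E"]] -
    p$alpha_minus_v * y[["v_RB"]] - p$beta_v * y[["v_RB"]]
  d["v_I"] <- p$beta_v * y[["v_RB"]] - p$gamma_v * y[["v_I"]]
  d["c"] <- p$R_l_chol * p$gamma_l * y[["l_I"]] +
    p$R_v_chol * p$gamma_v * y[["v_I"]] +
    p$mu_c * y[["h"]] - p$delta_c * y[["c"]]
  d["p_E"] <- (-p$alpha_p * r_f * y[["p_E"]] +
                 p$alpha_minus_p * y[["p_RB"]] +
                 p$gamma_p * y[["p_I"]] -
                 p$eps_p * y[["A_E"]] * y[["p_E"]] +
                 p$eps_minus_p * y[["p_AB"]]) / p$W +
    p$omega_P + s[["p_E"]]
  d["p_RB"] <- p$alpha_p * r_f * y[["p_E"]] -
    p$alpha_minus_p * y[["p_RB"]] - p$beta_p * y[["p_RB"]]
  d["A_E"] <- (-p$eps_p * y[["A_E"]] * y[["p_E"]] +
                 p$eps_minus_p * y[["p_AB"]]) / p$W +
    p$omega_A + s[["A_E"]]
  d["p_AB"] <- p$eps_p * y[["A_E"]] * y[["p_E"]] -
    p$eps_minus_p * y[["p_AB"]]
  d["S_E"] <- -p$CL_S * y[["S_E"]] / p$W + p$omega_S + s[["S_E"]]
  d["S_i"] <- p$CL_S * y[["S_E"]] -
    p$eps_S * y[["S_i"]] * y[["h"]] + p$eps_minus_S * y[["S_ih"]]
  d["S_ih"] <- p$eps_S * y[["S_i"]] * y[["h"]] -
    p$eps_minus_S * y[["S_ih"]]
  d
}
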