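#' Dimensional model parameters
#'
#' Loads the packaged dimensional parameter set (rates in 1/s, concentrations
#' in molec./mL) and applies optional overrides. Every parameter carries a
#' provenance tag: `table1` (from the published table of newly introduced
#' parameters), `parent_model` (attributed there to the
#' parent cholesterol-metabolism model), or `assumed` (fixed by this package;
#' see the methods vignette for the rationale of each choice). `assumed`
#' values are the ones a user would most plausibly want to override.
#'
#' @param ... Named scalar overrides, e.g. `f = 0.5`.
#' @param file Optional path to an alternative flat parameter file
#'   (tab-separated with columns name, value, units, provenance).
#' @return An object of class `hl_params`: a named list of numeric values
#'   with a `provenance` data frame attached as an attribute.
#' @examples
#' p <- hl_params()
#' p$kappa_mp
#' @export
hl_params <- function(..., file = NULL) {
  if (is.null(file))
    file <- system.file("extdata", "parameters_default.tsv",
                        package = "hepatolip", mustWork = TRUE)
  tab <- utils::read.delim(file, stringsAsFactors = FALSE)
  need <- c("name", "value", "units", "provenance")
  if (!all(need %in% names(tab)))
    stop("parameter file must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  p <- as.list(stats::setNames(as.numeric(tab$value), tab$name))

  ov <- list(...)
  if (length(ov)) {
    unknown <- setdiff(names(ov), names(p))
    if (length(unknown))
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
           suggest_names(unknown, names(p)), call. = FALSE)
    for (nm in names(ov)) p[[nm]] <- as.numeric(ov[[nm]])
  }
  attr(p, "provenance") <- tab[, c("name", "units", "provenance")]
  class(p) <- "hl_params"
  validate_params(p)
  p
}

hl_dimensional_names <- function() {
  c("mu_mh_star", "mu_mr_star", "mu_mp_star",
    "delta_mh", "delta_mr", "delta_mp",
    "kappa_mh", "kappa_mr", "kappa_mp",
    "s0", "kc", "xc", "xh", "xr", "xp",
    "mu_h", "mu_r", "mu_p",
    "delta_h", "delta_p", "delta_c",
    "gamma_r", "gamma_p", "gamma_l", "gamma_v",
    "f", "P", "beta_0", "M_l", "M_v", "M_p",
    "alpha_l", "alpha_minus_l", "alpha_v", "alpha_minus_v",
    "alpha_p", "alpha_minus_p",
    "beta_l", "beta_v", "beta_p",
    "chi_v", "omega_V", "omega_P", "omega_A", "omega_S",
    "R_l_chol", "R_v_chol", "mu_c",
    "eps_S", "eps_minus_S", "CL_S", "eps_p", "eps_minus_p",
    "W", "J",
    "rf0", "sE0", "pE0_ref", "tau", "m0", "c0", "l0", "v0")
}

validate_params <- function(p) {
  nm <- hl_dimensional_names()
  missing <- setdiff(nm, names(p))
  if (length(missing))
    stop("missing parameter(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  vals <- unlist(p[nm])
  if (any(!is.finite(vals)))
    stop("non-finite parameter(s): ", paste(nm[!is.finite(vals)],
         collapse = ", "), call. = FALSE)
  if (any(vals < 0))
    stop("negative parameter(s): ", paste(nm[vals < 0], collapse = ", "),
         call. = FALSE)
  hill <- c("xc", "xh", "xr", "xp")
  hv <- unlist(p[hill])
  if (any(hv < 1) || any(hv != round(hv)))
    stop("Hill exponents must be positive integers: ",
         paste(hill[hv < 1 | hv != round(hv)], collapse = ", "),
         call. = FALSE)
  if (p$f < 0 || p$f > 1)
    stop("recycled fraction f must lie in [0, 1]", call. = FALSE)
  if (any(unlist(p[c("M_l", "M_v", "M_p")]) < 1))
    stop("receptor coverage numbers M_l, M_v, M_p must be >= 1",
         call. = FALSE)
  scales <- c("s0", "kc", "rf0", "sE0", "pE0_ref", "tau", "m0",
              "c0", "l0", "v0")
  zero <- scales[unlist(p[scales]) <= 0]
  if (length(zero))
    stop("reference scale(s) must be positive: ",
         paste(zero, collapse = ", "), call. = FALSE)
  invisible(p)
}

#' @export
print.hl_params <- function(x, ...) {
  prov <- attr(x, "provenance")
  cat("<hl_params> dimensional model parameters (", length(x), ")\n", sep = "")
  df <- data.frame(value = unlist(x)[prov$name], units = prov$units,
                   provenance = prov$provenance, row.names = prov$name)
  print(df)
  invisible(x)
}

# closest-name hint for error messages
suggest_names <- function(bad, good) {
  hints <- vapply(bad, function(b) {
    d <- utils::adist(b, good)
    g <- good[which.min(d)]
    if (min(d) <= 3) sprintf(" (did you mean '%s'?)", g) else ""
  }, character(1))
  paste(hints, collapse = "")
}
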