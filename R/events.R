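#' Timed dosing events
#'
#' A dose event perturbs one extracellular species, either instantaneously
#' (`bolus`: a concentration added at `time_h`) or as a finite-duration
#' influx (`influx`: a constant source rate over
#' `[time_h, time_h + duration_h)`, half-open so that back-to-back windows
#' never double-count a boundary). This mirrors the in vitro protocol of
#' adding components to the cell medium at selected time points.
#'
#' @param time_h Event start time in hours (>= 0).
#' @param species One of `"PCSK9_E"`, `"antibody_E"`, `"statin_E"`,
#'   `"LDL_E"`, `"VLDL_E"`.
#' @param mode `"bolus"` or `"influx"`.
#' @param amount For a bolus: concentration added. For an influx: source
#'   rate. Units per `units`.
#' @param duration_h Influx duration in hours (must be 0 for a bolus).
#' @param units `"molec/mL"` (default; rate `"molec/mL/s"` for influx) or
#'   `"ng/mL"` (`"ng/mL/s"`), converted on construction using
#'   `molar_mass_kDa`.
#' @param molar_mass_kDa Molar mass used for mass-unit conversion
#'   (default 60 kDa, the packaged PCSK9 convention under which
#'   1e12 molec./mL is approximately 100 ng/mL).
#' @return Object of class `hl_dose_event` (amounts stored in molec./mL and
#'   molec./(mL s)).
#' @export
dose_event <- function(time_h, species, mode = c("bolus", "influx"),
                       amount, duration_h = 0, units = "molec/mL",
                       molar_mass_kDa = 60) {
  mode <- match.arg(mode)
  species <- match.arg(species, names(species_state_map()))
  stopifnot(is.numeric(time_h), length(time_h) == 1, time_h >= 0,
            is.numeric(amount), length(amount) == 1, amount >= 0,
            is.numeric(duration_h), length(duration_h) == 1, duration_h >= 0)
  if (mode == "bolus" && duration_h != 0)
    stop("a bolus must have duration_h = 0", call. = FALSE)
  if (grepl("^ng/mL", units))
    amount <- convert_concentration(amount, "ng/mL", "molec/mL",
                                    molar_mass_kDa)
  else if (!grepl("^molec/mL", units))
    stop("unknown units: ", units, call. = FALSE)
  structure(list(time_h = time_h, species = species, mode = mode,
                 amount = amount, duration_h = duration_h),
            class = "hl_dose_event")
}

species_state_map <- function() {
  c(PCSK9_E = "p_E", antibody_E = "A_E", statin_E = "S_E",
    LDL_E = "l_E", VLDL_E = "v_E")
}

#' @export
print.hl_dose_event <- function(x, ...) {
  cat(sprintf("<dose_event> %s %s at %g h: %g molec/mL%s\n", x$mode,
              x$species, x$time_h, x$amount,
              if (x$mode == "influx")
                sprintf("/s for %g h", x$duration_h) else ""))
  invisible(x)
}

#' Apply an instantaneous bolus to a dimensionless state
#'
#' Increments only the event's species by the event amount converted to the
#' dimensionless scale of that species; all other components are unchanged.
#'
#' @param y Dimensionless model state (canonical order).
#' @param e An [dose_event()] with `mode = "bolus"`.
#' @param p An [hl_params()] object supplying the reference scales.
#' @return The updated state.
#' @export
apply_bolus <- function(y, e, p) {
  stopifnot(inherits(e, "hl_dose_event"))
  if (e$mode != "bolus") stop("event is not a bolus", call. = FALSE)
  y <- as_state(y)
  target <- species_state_map()[[e$species]]
  sc <- state_scales(p)[[target]]
  y[target] <- y[[target]] + e$amount / sc
  hl_state(values = as.numeric_named(y))
}

#' Sum of influx source strengths active at a time point
#'
#' Influx windows are half-open `[start, start + duration)`; overlapping
#' influxes on the same species add. Bolus events contribute nothing here
#' (they are applied as state jumps by the integrator driver).
#'
#' @param t_h Time in hours.
#' @param events List of [dose_event()] objects.
#' @param p An [hl_params()] object (scales for the dimensionless
#'   conversion); if `NULL`, dimensional rates (molec./(mL s)) are returned.
#' @return Named vector of source strengths for `l_E`, `v_E`, `p_E`, `A_E`,
#'   `S_E` — dimensionless rates if `p` is given.
#' @export
active_sources <- function(t_h, events, p = NULL) {
  src <- zero_sources()
  for (e in events) {
    if (e$mode != "influx") next
    if (t_h >= e$time_h && t_h < e$time_h + e$duration_h) {
      target <- species_state_map()[[e$species]]
      src[target] <- src[target] + e$amount
    }
  }
  if (!is.null(p)) {
    sc <- state_scales(p)[names(src)]
    src <- src * p$tau / sc
  }
  src
}

# all time points at which the integrator must be restarted
event_boundaries <- function(events, horizon_h) {
  tt <- numeric(0)
  for (e in events) {
    tt <- c(tt, e$time_h)
    if (e$mode == "influx") tt <- c(tt, e$time_h + e$duration_h)
  }
  sort(unique(tt[tt > 0 & tt < horizon_h]))
}
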