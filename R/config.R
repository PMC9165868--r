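#' Convert between particle-count and mass concentrations
#'
#' Mass-count conversion through Avogadro's number. Under the packaged
#' 60 kDa PCSK9 molar-mass convention, 1e12 molec./mL is approximately
#' 100 ng/mL.
#'
#' @param value Concentration value(s).
#' @param from_units,to_units `"molec/mL"` or `"ng/mL"`.
#' @param molar_mass_kDa Molar mass in kDa (> 0), default 60.
#' @return Converted value(s); exact round trip.
#' @examples
#' convert_concentration(1e12, "molec/mL", "ng/mL")  # ~ 99.6 ng/mL
#' @export
convert_concentration <- function(value, from_units, to_units,
                                  molar_mass_kDa = 60) {
  stopifnot(molar_mass_kDa > 0)
  known <- c("molec/mL", "ng/mL")
  if (!from_units %in% known || !to_units %in% known)
    stop("unknown units (use 'molec/mL' or 'ng/mL')", call. = FALSE)
  if (from_units == to_units) return(value)
  avogadro <- 6.02214076e23
  ng_per_molec <- molar_mass_kDa * 1000 / avogadro * 1e9
  if (from_units == "molec/mL") value * ng_per_molec
  else value / ng_per_molec
}

#' Load a run configuration
#'
#' Parses a flat key-value configuration file. Lines are `key = value`;
#' blank lines and `#` comments are ignored. Dosing events use the record
#' form `event = time_h species mode amount units duration_h`. Unknown keys
#' are hard errors with a nearest-name suggestion, so typos never pass
#' silently.
#'
#' Recognised keys: `scenario` (preset name), any dimensional parameter
#' name (override), `init.<state>` (initial concentration, molec./mL),
#' `horizon_h`, `dt_out_h`, `rtol`, `atol`, `hmax_h`, `neg_tol`,
#' `out_dir`, `seed`, `verbose`, `molar_mass_kDa`, and `event` records.
#'
#' @param path Path to the configuration file.
#' @return Object of class `hl_config`: a list with `scenario_name`,
#'   `param_overrides`, `init`, `events`, `horizon_h`, `dt_out_h`,
#'   `solver`, `out_dir`, `seed`, `verbose`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]

  cfg <- list(scenario_name = NULL, param_overrides = list(),
              init = list(), events = list(), horizon_h = NULL,
              dt_out_h = NULL, solver = list(), out_dir = ".",
              seed = NULL, verbose = FALSE, molar_mass_kDa = 60)
  par_names <- hl_dimensional_names()
  state_names <- hl_state_names()
  solver_keys <- c("rtol", "atol", "hmax_h", "neg_tol")
  scalar_keys <- c("scenario", "horizon_h", "dt_out_h", "out_dir", "seed",
                   "verbose", "molar_mass_kDa")

  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE))
      stop("config line is not 'key = value': '", ln, "'", call. = FALSE)
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    if (key == "event") {
      f <- strsplit(val, "[[:space:]]+")[[1]]
      if (length(f) != 6)
        stop("event record needs 6 fields ",
             "(time_h species mode amount units duration_h): '", val, "'",
             call. = FALSE)
      cfg$events[[length(cfg$events) + 1L]] <-
        dose_event(as.numeric(f[1]), f[2], f[3], as.numeric(f[4]),
                   duration_h = as.numeric(f[6]), units = f[5],
                   molar_mass_kDa = cfg$molar_mass_kDa)
    } else if (key %in% par_names) {
      cfg$param_overrides[[key]] <- as.numeric(val)
    } else if (grepl("^init\\.", key)) {
      st <- sub("^init\\.", "", key)
      if (!st %in% state_names)
        stop("unknown state in '", key, "'",
             suggest_names(st, state_names), call. = FALSE)
      cfg$init[[st]] <- as.numeric(val)
    } else if (key %in% solver_keys) {
      cfg$solver[[key]] <- as.numeric(val)
    } else if (key %in% scalar_keys) {
      cfg[[switch(key, scenario = "scenario_name", key)]] <-
        switch(key,
               scenario = val, out_dir = val,
               verbose = as.logical(val),
               as.numeric(val))
    } else {
      stop("unknown config key '", key, "'",
           suggest_names(key, c(par_names, scalar_keys, solver_keys,
                                paste0("init.", state_names), "event")),
           call. = FALSE)
    }
  }
  structure(cfg, class = "hl_config")
}

#' Save a run configuration
#'
#' Writes an [load_config()]-compatible file; numeric values are written
#' with full precision (`format(..., digits = 17)`) so overrides round-trip
#' bit-exactly.
#'
#' @param cfg An `hl_config` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "hl_config"))
  num <- function(x) format(x, digits = 17, scientific = TRUE)
  out <- character(0)
  if (!is.null(cfg$scenario_name))
    out <- c(out, paste("scenario =", cfg$scenario_name))
  for (nm in names(cfg$param_overrides))
    out <- c(out, paste(nm, "=", num(cfg$param_overrides[[nm]])))
  for (nm in names(cfg$init))
    out <- c(out, paste0("init.", nm, " = ", num(cfg$init[[nm]])))
  for (nm in names(cfg$solver))
    out <- c(out, paste(nm, "=", num(cfg$solver[[nm]])))
  if (!is.null(cfg$horizon_h)) out <- c(out, paste("horizon_h =",
                                                   num(cfg$horizon_h)))
  if (!is.null(cfg$dt_out_h)) out <- c(out, paste("dt_out_h =",
                                                  num(cfg$dt_out_h)))
  for (e in cfg$events)
    out <- c(out, sprintf("event = %s %s %s %s molec/mL %s",
                          num(e$time_h), e$species, e$mode, num(e$amount),
                          num(e$duration_h)))
  if (!is.null(cfg$seed)) out <- c(out, paste("seed =", cfg$seed))
  writeLines(out, path)
  invisible(path)
}

#' Build a scenario from a configuration
#'
#' @param cfg An `hl_config` from [load_config()].
#' @return An [scenario()].
#' @export
config_to_scenario <- function(cfg) {
  stopifnot(inherits(cfg, "hl_config"))
  params <- do.call(hl_params, cfg$param_overrides)
  if (!is.null(cfg$scenario_name)) {
    extra <- list(params = params)
    if (!is.null(cfg$horizon_h)) extra$horizon_h <- cfg$horizon_h
    s <- do.call(hl_preset, c(list(cfg$scenario_name), extra))
    if (length(cfg$events)) s$events <- c(s$events, cfg$events)
    return(s)
  }
  init <- do.call(hl_state, cfg$init)
  scenario(params, init = init, events = cfg$events,
           horizon_h = cfg$horizon_h %||% 200,
           dt_out_h = cfg$dt_out_h %||% 0.5,
           solver = cfg$solver)
}
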