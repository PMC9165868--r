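#' Canonical state variable names
#'
#' The model tracks 21 quantities in a fixed canonical order. All interfaces
#' (trajectories, steady states, configs) use these names, never bare indices.
#'
#' The components are: the three mRNAs (`m_h`, `m_r`, `m_p` for HMGCR, LDLR
#' and PCSK9), HMG-CoA reductase `h`, intracellular PCSK9 `p_I`, internal and
#' free-surface LDL receptor (`r_I`, `r_f`), LDL in the extracellular /
#' receptor-bound / internalised pools (`l_E`, `l_RB`, `l_I`), the same three
#' pools for VLDL (`v_E`, `v_RB`, `v_I`), intracellular cholesterol `c`,
#' extracellular and receptor-bound PCSK9 (`p_E`, `p_RB`), free anti-PCSK9
#' agent `A_E` and its PCSK9 complex `p_AB`, and statin in the extracellular,
#' intracellular-free and HMGCR-bound pools (`S_E`, `S_i`, `S_ih`).
#'
#' @return Character vector of length 21.
#' @export
hl_state_names <- function() {
  c("m_h", "m_r", "m_p",
    "h", "p_I", "r_I", "r_f",
    "l_E", "l_RB", "l_I",
    "v_E", "v_RB", "v_I",
    "c",
    "p_E", "p_RB",
    "A_E", "p_AB",
    "S_E", "S_i", "S_ih")
}

#' Construct a model state vector
#'
#' Builds a named, validated 21-component state vector in canonical order.
#' Unspecified components default to zero.
#'
#' @param ... Named scalar components (must be a subset of
#'   [hl_state_names()]).
#' @param values Optionally, a full named numeric vector instead of `...`.
#' @return Named numeric vector of length 21, class `hl_state`.
#' @examples
#' hl_state(p_E = 1.0)
#' @export
hl_state <- function(..., values = NULL) {
  nm <- hl_state_names()
  y <- stats::setNames(numeric(length(nm)), nm)
  given <- if (is.null(values)) unlist(list(...)) else values
  if (length(given)) {
    if (is.null(names(given)) || any(!nzchar(names(given))))
      stop("state components must be named", call. = FALSE)
    unknown <- setdiff(names(given), nm)
    if (length(unknown))
      stop("unknown state component(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    y[names(given)] <- as.numeric(given)
  }
  validate_state(y)
  class(y) <- c("hl_state", "numeric")
  y
}

validate_state <- function(y) {
  nm <- hl_state_names()
  if (length(y) != 21L)
    stop("state must have exactly 21 components, got ", length(y),
         call. = FALSE)
  if (!is.null(names(y)) && !identical(names(y), nm))
    stop("state names must be in canonical order; see hl_state_names()",
         call. = FALSE)
  if (any(!is.finite(y)))
    stop("state contains non-finite values: ",
         paste(nm[!is.finite(y)], collapse = ", "), call. = FALSE)
  if (any(y < 0))
    stop("state contains negative values: ",
         paste(nm[y < 0], collapse = ", "), call. = FALSE)
  invisible(y)
}

as_state <- function(y) {
  if (inherits(y, "hl_state")) return(y)
  if (is.null(names(y))) {
    if (length(y) != 21L) stop("unnamed state must have length 21")
    names(y) <- hl_state_names()
  }
  hl_state(values = y[hl_state_names()])
}

#' @export
print.hl_state <- function(x, ...) {
  cat("<hl_state> (21 components)\n")
  print(stats::setNames(as.numeric(x), names(x)))
  invisible(x)
}
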