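# Constant-trajectory reduction: states whose known initial condition is a
# fixed point of their own equation (given the other constant states) stay at
# that value for all time, so they can be substituted out before the
# input-output equations are formed. This is how particular ("inaccessible")
# initial conditions such as starting an autocatalytic species at zero change
# identifiability results.

#' Detect constant solution trajectories and reduce the model
#'
#' Finds the maximal set of states with known initial conditions whose
#' trajectories are identically equal to those initial values: starting from
#' all states with known initial conditions, states whose equations do not
#' vanish identically (as rational functions, after substituting the candidate
#' constants) are removed until a fixed point is reached. The surviving states
#' are replaced by their initial values throughout the model.
#'
#' @param m An `icb_model`.
#' @return A list of class `icb_reduction` with `constant_states`,
#'   `reduced_model` and `reducible`.
#' @export
detect_constant_states <- function(m) {
  stopifnot(inherits(m, "icb_model"))
  cand <- names(m$ics)
  repeat {
    if (length(cand) == 0) break
    keep <- logical(length(cand))
    vars <- c(setdiff(m$states, cand), m$inputs, m$parameters)
    if (length(vars) == 0) vars <- "p1"   # degenerate: no free symbols left
    for (i in seq_along(cand)) {
      ode <- m$odes[[cand[i]]]
      for (s in cand) ode <- ast_substitute(ode, s, m$ics[[s]])
      rf <- ast_to_rf(ode, vars)
      keep[i] <- poly_is_zero(rf$num)
    }
    if (all(keep)) break
    cand <- cand[keep]
  }
  constant_states <- cand
  if (length(constant_states) == 0) {
    return(structure(list(constant_states = character(0), reduced_model = m,
                          reducible = FALSE), class = "icb_reduction"))
  }

  remaining <- setdiff(m$states, constant_states)
  subst_all <- function(ast) {
    for (s in constant_states) ast <- ast_substitute(ast, s, m$ics[[s]])
    ast
  }
  if (length(remaining) == 0) {
    # every trajectory is frozen: the outputs are constants and the model has
    # no dynamics left to analyse
    frozen <- m
    frozen$states <- character(0)
    frozen$odes <- list()
    frozen$output_eqs <- lapply(m$output_eqs, subst_all)
    frozen$ics <- list()
    return(structure(list(constant_states = constant_states,
                          reduced_model = frozen, reducible = TRUE),
                     class = "icb_reduction"))
  }
  odes <- lapply(m$odes[remaining], subst_all)
  outs <- lapply(m$output_eqs, subst_all)
  ics <- m$ics[setdiff(names(m$ics), constant_states)]

  # renumber remaining states contiguously
  newnames <- paste0("x", seq_along(remaining))
  ren <- as.list(setNames(newnames, remaining))
  odes <- lapply(odes, ast_rename, map = ren)
  outs <- lapply(outs, ast_rename, map = ren)
  names(odes) <- newnames
  if (length(ics)) names(ics) <- vapply(names(ics), function(s) ren[[s]], "")

  red <- structure(list(
    states = newnames, inputs = m$inputs, outputs = m$outputs,
    parameters = m$parameters, user_parameters = m$user_parameters,
    name_map = m$name_map, odes = odes, output_eqs = outs, ics = ics,
    const_inputs = m$const_inputs,
    source = m$source
  ), class = "icb_model")

  structure(list(constant_states = constant_states, reduced_model = red,
                 reducible = TRUE), class = "icb_reduction")
}

#' @export
print.icb_reduction <- function(x, ...) {
  if (x$reducible) {
    cat("Model is reducible: constant solution trajectories for",
        paste(x$constant_states, collapse = ", "), "\n")
  } else {
    cat("Model is not reducible (no constant solution trajectories)\n")
  }
  invisible(x)
}
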