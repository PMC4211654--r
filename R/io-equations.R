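# Input-output equations by differential elimination.
#
# Output derivatives are formed by repeated total differentiation of the
# output maps along the vector field (inputs contribute free derivative
# symbols). Each derivative gives a polynomial relation between states,
# input/output derivative symbols and parameters; a Groebner basis under a
# block order ranking states first yields the state-free relations -- the
# input-output equations -- plus, as a by-product, relations solving
# individual states in terms of the data, which carry known initial
# conditions into the fiber system.

deriv_layout <- function(m, K) {
  ug <- character(0)
  for (u in m$inputs) ug <- c(ug, u, if (K >= 1) paste0(u, ".d", seq_len(K)))
  c(m$states, ug, m$parameters)
}

#' Output derivatives along the model vector field
#'
#' Expresses each output derivative \eqn{y_j^{(k)}}, k = 0..`max_order`, as a
#' rational function of the states, the input derivative symbols and the
#' parameters, by substituting the state equations for state derivatives at
#' each differentiation step.
#'
#' @param m An `icb_model` (already reduced if it had constant trajectories).
#' @param max_order Highest derivative order required.
#' @return An object of class `icb_derivs`.
#' @export
derive_output_derivatives <- function(m, max_order) {
  stopifnot(inherits(m, "icb_model"), max_order >= 1)
  n <- length(m$states); r <- length(m$inputs); P <- length(m$parameters)
  vars <- deriv_layout(m, max_order)
  f <- lapply(m$states, function(s) ast_to_rf(m$odes[[s]], vars))
  g <- lapply(m$outputs, function(o) ast_to_rf(m$output_eqs[[o]], vars))
  cflags <- m$inputs %in% m$const_inputs
  rfs <- eng_total_derivs(f, g, n, r, P, max_order, as.logical(cflags))
  structure(list(rfs = rfs, layout = vars, n = n, r = r, P = P, K = max_order,
                 model = m), class = "icb_derivs")
}

ext_layout <- function(d) {
  m <- d$model
  yg <- character(0)
  for (o in m$outputs) yg <- c(yg, paste0(o, ".d", 0:d$K))
  list(
    vars = c(m$states, yg, d$layout[-seq_len(d$n)]),
    x_cols = seq_len(d$n),
    y_cols = d$n + seq_len(length(m$outputs) * (d$K + 1)),
    u_cols = if (d$r > 0) d$n + length(m$outputs) * (d$K + 1) + seq_len(d$r * (d$K + 1)) else integer(0),
    p_cols = d$n + length(m$outputs) * (d$K + 1) + d$r * (d$K + 1) + seq_len(d$P)
  )
}

#' Eliminate the states from the derivative relations
#'
#' Builds the polynomial relations `num(y_j^(k)) - Y_jk * den(y_j^(k)) = 0`
#' and computes a Groebner basis under a block order that ranks all state
#' variables above the derivative symbols and parameters. Basis elements free
#' of states are the input-output equations; for each output the minimal
#' relation (lowest leading derivative order, then fewest terms) is selected.
#' Elements linear in a single state are retained to carry known initial
#' conditions.
#'
#' @param derivs An `icb_derivs` object.
#' @param m The model (defaults to the one inside `derivs`).
#' @param max_steps,max_seconds Budget for the basis computation.
#' @return An `icb_ioset`, or an error if some output admits no state-free
#'   relation at this derivative order ("differential elimination did not
#'   complete" at the order cap).
#' @export
eliminate_states <- function(derivs, m = derivs$model, max_steps = 5e6,
                             max_seconds = 300) {
  d <- derivs
  lay <- ext_layout(d)
  nv <- length(lay$vars)
  # old deriv layout -> extended layout column map
  old_map <- c(lay$x_cols, lay$u_cols, lay$p_cols)
  rels <- list()
  for (j in seq_along(m$outputs)) {
    for (k in 0:d$K) {
      rf <- d$rfs[[j]][[k + 1]]
      num <- poly_remap(rf$num, old_map, nv)
      den <- poly_remap(rf$den, old_map, nv)
      ycol <- d$n + (j - 1) * (d$K + 1) + k + 1
      rels[[length(rels) + 1L]] <- poly_sub(num, poly_mul(poly_var(nv, ycol), den))
    }
  }
  # states occurring linearly with state-free coefficients are removed by
  # solve-and-substitute; a Groebner basis only handles whatever remains
  pre <- eng_presolve(rels, d$n, max_steps)
  state_free <- pre$free
  gb <- list()
  unsolved <- Filter(Negate(is.null), pre$solves)
  unsolved <- Filter(function(g) {
    e <- g$exp[, lay$x_cols, drop = FALSE]
    sum(colSums(e) > 0) > 1L
  }, unsolved)
  if (length(pre$rest) || length(unsolved)) {
    blocks <- list(lay$x_cols, c(lay$y_cols, lay$u_cols), lay$p_cols)
    blocks <- blocks[lengths(blocks) > 0]
    gb <- eng_groebner_z(c(pre$rest, unsolved), blocks, max_steps, max_seconds)
    state_free <- c(state_free,
                    Filter(function(g) all(g$exp[, lay$x_cols, drop = FALSE] == 0L), gb))
  }
  # leader = highest (order, output) derivative symbol present
  leader_of <- function(g) {
    ycols <- lay$y_cols[colSums(g$exp[, lay$y_cols, drop = FALSE]) > 0]
    if (length(ycols) == 0) return(NULL)
    ks <- (ycols - d$n - 1) %% (d$K + 1)
    js <- (ycols - d$n - 1) %/% (d$K + 1) + 1
    best <- order(ks, js, decreasing = TRUE)[1]
    c(j = js[best], k = ks[best])
  }
  equations <- vector("list", length(m$outputs))
  lead_info <- vector("list", length(m$outputs))
  for (g in state_free) {
    ld <- leader_of(g)
    if (is.null(ld)) next
    j <- ld["j"]
    if (is.null(equations[[j]]) ||
        ld["k"] < lead_info[[j]]["k"] ||
        (ld["k"] == lead_info[[j]]["k"] && nrow(g$exp) < nrow(equations[[j]]$exp))) {
      equations[[j]] <- g
      lead_info[[j]] <- ld
    }
  }
  if (any(vapply(equations, is.null, TRUE)))
    return(structure(list(ok = FALSE), class = "icb_ioset_failure"))

  # state-solving relations: linear in one state, free of the others
  state_solve <- vector("list", d$n)
  for (i in seq_len(d$n)) {
    ok_solve <- function(g) {
      if (is.null(g)) return(FALSE)
      e <- g$exp[, lay$x_cols, drop = FALSE]
      all(e[, -i] == 0L) && all(e[, i] <= 1L) && any(e[, i] == 1L)
    }
    if (ok_solve(pre$solves[[i]])) {
      state_solve[[i]] <- pre$solves[[i]]
    } else {
      cands <- Filter(ok_solve, gb)
      if (length(cands))
        state_solve[[i]] <- cands[[which.min(vapply(cands, function(g) nrow(g$exp), 0))]]
    }
  }
  names(state_solve) <- m$states

  structure(list(ok = TRUE, equations = equations, layout = lay, K = d$K,
                 state_solve = state_solve, derivs = d, model = m),
            class = "icb_ioset")
}

# ranking of derivative monomials: y-derivative order descending, then total
# degree in the derivative symbols, then lexicographic
rank_monomials <- function(mono_exp, lay, d) {
  maxk <- apply(mono_exp, 1, function(e) {
    yc <- lay$y_cols[e[lay$y_cols] > 0]
    if (length(yc) == 0) return(-1)
    max((yc - d$n - 1) %% (d$K + 1))
  })
  totdeg <- rowSums(mono_exp[, c(lay$y_cols, lay$u_cols), drop = FALSE])
  lexkey <- apply(mono_exp, 1, paste, collapse = ",")
  order(-maxk, -totdeg, lexkey)
}

#' Normalize an input-output equation
#'
#' Divides a state-free relation by the parameter coefficient of its
#' highest-ranked derivative monomial, making the equation monic; the
#' remaining coefficients become rational functions of the parameters.
#'
#' @param eq A polynomial in the extended layout (as produced by
#'   [eliminate_states()]), or an `icb_ioset` whose equations are all
#'   normalized.
#' @param ioset The `icb_ioset` providing the variable layout.
#' @return A list with `monomials` (exponent matrix over derivative symbols),
#'   `coeffs` (parameter polynomials, one per monomial), `normalizer` (the
#'   coefficient divided out) and `lead` (row index of the leading monomial).
#' @export
normalize_io_equation <- function(eq, ioset) {
  lay <- ioset$layout
  d <- ioset$derivs
  dcols <- c(lay$y_cols, lay$u_cols)
  mono_part <- eq$exp[, dcols, drop = FALSE]
  key <- apply(mono_part, 1, paste, collapse = ",")
  groups <- split(seq_len(nrow(eq$exp)), key)
  monos <- t(vapply(groups, function(ix) mono_part[ix[1], ], numeric(ncol(mono_part))))
  P <- length(lay$p_cols)
  coeffs <- lapply(groups, function(ix) {
    poly_canon(list(exp = eq$exp[ix, lay$p_cols, drop = FALSE] * 1L,
                    c = eq$c[ix]))
  })
  # put monomials in ranking order
  full <- matrix(0L, nrow(monos), length(lay$vars))
  full[, dcols] <- as.integer(monos)
  ord <- rank_monomials(full, lay, d)
  monos <- monos[ord, , drop = FALSE]
  coeffs <- coeffs[ord]
  list(monomials = monos, coeffs = coeffs, normalizer = coeffs[[1]], lead = 1L)
}

#' Extract the coefficient map (exhaustive summary)
#'
#' Collects the parameter-dependent coefficients of the normalized
#' input-output equations across all outputs, as rational functions of the
#' parameters, deduplicated, with constant (parameter-free) coefficients
#' dropped.
#'
#' @param ioset An `icb_ioset`.
#' @return An `icb_coeffmap` with `coefficients` (list of rational functions
#'   in parameter space), `normalizers`, and the source objects needed later
#'   for initial-condition handling.
#' @export
extract_coefficients <- function(ioset) {
  stopifnot(inherits(ioset, "icb_ioset"))
  P <- length(ioset$layout$p_cols)
  coefficients <- list()
  keys <- character(0)
  normalizers <- list()
  for (eq in ioset$equations) {
    ne <- normalize_io_equation(eq, ioset)
    L <- ne$normalizer
    normalizers[[length(normalizers) + 1L]] <- L
    for (i in seq_along(ne$coeffs)[-ne$lead]) {
      A <- ne$coeffs[[i]]
      if (poly_proportional(A, L)) next   # constant coefficient: no parameter content
      key <- paste(poly_key(poly_canon(A)), poly_key(poly_canon(L)), sep = "|")
      if (key %in% keys) next
      keys <- c(keys, key)
      coefficients[[length(coefficients) + 1L]] <- list(num = A, den = L)
    }
  }
  structure(list(coefficients = coefficients, normalizers = normalizers,
                 ioset = ioset, model = ioset$model, has_ics = FALSE),
            class = "icb_coeffmap")
}

#' Attach known initial conditions to the coefficient map
#'
#' Known initial conditions enter the analysis through the state-solving
#' relations produced during elimination: each relation, evaluated at t = 0
#' with the output/input derivative symbols valued on the true trajectory,
#' becomes an extra polynomial constraint on the parameters that joins the
#' fiber system. States that could not be expressed linearly in terms of the
#' data produce a warning and their initial conditions are ignored.
#'
#' @param m The model carrying the known initial conditions.
#' @param ioset An `icb_ioset` for `m`.
#' @return An `icb_coeffmap` with initial-condition handling enabled.
#' @export
incorporate_initial_conditions <- function(m, ioset) {
  cm <- extract_coefficients(ioset)
  if (length(m$ics) == 0) return(cm)
  usable <- character(0)
  for (s in names(m$ics)) {
    if (is.null(ioset$state_solve[[s]])) {
      warning("known initial condition for ", s, " ignored: state is not ",
              "linearly solvable from the outputs", call. = FALSE)
    } else usable <- c(usable, s)
  }
  cm$has_ics <- length(usable) > 0
  cm$ic_states <- usable
  cm
}

#' Compute the input-output equations of a model
#'
#' Convenience pipeline: reduces the model (constant trajectories), derives
#' output derivatives starting at order n (the state dimension), eliminates
#' states, and retries at increasing order up to 2n if elimination does not
#' produce a relation for every output.
#'
#' @param m An `icb_model`.
#' @param max_steps,max_seconds Budget per basis computation.
#' @return An `icb_ioset`.
#' @export
io_equations <- function(m, max_steps = 5e6, max_seconds = 300) {
  n <- length(m$states)
  for (K in seq(max(n, 1), max(2 * n, 1))) {
    d <- derive_output_derivatives(m, K)
    io <- eliminate_states(d, m, max_steps, max_seconds)
    if (inherits(io, "icb_ioset") && isTRUE(io$ok)) return(io)
  }
  stop("differential elimination did not complete: no state-free relation ",
       "for every output up to derivative order ", 2 * n)
}
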