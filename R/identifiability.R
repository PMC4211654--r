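# Fiber analysis of the coefficient map: a pseudo-random positive integer
# parameter point p* is chosen, the polynomial system c(p) = c(p*) (plus any
# initial-condition relations) is formed with denominators constrained
# nonzero through a saturation variable, and each parameter is classified by
# the univariate eliminant it admits: degree of the squarefree part = maximum
# number of distinct solutions (counted over the complex numbers); no
# eliminant = structurally unidentifiable.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Sample a pseudo-random parameter point
#'
#' Draws distinct small positive integers (default range 2..97) for the
#' parameters, deterministically under `seed`. Points where any coefficient
#' denominator vanishes, or where the Jacobian of the coefficient map drops
#' below its generic rank (estimated at a second random point), are rejected
#' and resampled.
#'
#' @param cm An `icb_coeffmap` (or an integer parameter count, in which case
#'   no degeneracy guards can be applied).
#' @param seed Integer seed.
#' @param range Candidate integer values.
#' @param prime Word-size prime for modular rank computations.
#' @return A list with `values` (named integer vector) and `seed`.
#' @export
sample_parameter_point <- function(cm, seed = 0L, range = 2:97,
                                   prime = default_prime()) {
  if (is.numeric(cm) && length(cm) == 1) {
    P <- as.integer(cm)
    vals <- with_seed(seed, sample(range, P))
    return(list(values = setNames(vals, paste0("p", seq_len(P))), seed = seed))
  }
  stopifnot(inherits(cm, "icb_coeffmap"))
  P <- length(cm$model$parameters)
  dens <- unique_polys(lapply(cm$coefficients, `[[`, "den"))
  rfs <- coefficient_rfs(cm)
  grank <- generic_rank(rfs, P, prime, seed)
  pt <- with_seed(seed, {
    for (attempt in 1:100) {
      vals <- sample(range, P)
      ok <- all(vapply(dens, function(d) poly_eval(d, vals) != "0", TRUE))
      if (ok && length(rfs)) {
        rk <- tryCatch(eng_rank_p(eng_jacobian_p(rfs, vals, prime), prime),
                       error = function(e) -1L)
        ok <- rk == grank
      }
      if (ok) break
      vals <- NULL
    }
    vals
  })
  if (is.null(pt)) stop("could not find a non-degenerate parameter point")
  list(values = setNames(as.integer(pt), cm$model$parameters), seed = seed)
}

unique_polys <- function(lst) {
  keys <- vapply(lst, function(p) poly_key(poly_canon(p)), "")
  keep <- !duplicated(keys)
  # drop constants
  lst <- lst[keep]
  Filter(function(p) length(poly_vars_used(p)) > 0, lst)
}

coefficient_rfs <- function(cm) cm$coefficients

# generic rank of the coefficient map: max Jacobian rank over a few random points
generic_rank <- function(rfs, P, prime = default_prime(), seed = 0L) {
  if (length(rfs) == 0) return(0L)
  with_seed(seed + 777L, {
    best <- 0L
    for (i in 1:3) {
      pt <- sample(2:999983, P)
      rk <- tryCatch(eng_rank_p(eng_jacobian_p(rfs, pt, prime), prime),
                     error = function(e) 0L)
      best <- max(best, rk)
    }
    best
  })
}

#' Build the fiber system c(p) = c(p*)
#'
#' Forms the cleared-denominator equations `num_i(p) den_i(p*) - num_i(p*)
#' den_i(p) = 0` for every coefficient of the input-output equations, joined,
#' when known initial conditions are present, by the state-solving relations
#' evaluated at t = 0 on the true trajectory of p*.
#'
#' @param cm An `icb_coeffmap`.
#' @param point A parameter point from [sample_parameter_point()].
#' @param prime Prime used downstream.
#' @return An object of class `icb_fiber`.
#' @export
fiber_system <- function(cm, point, prime = default_prime()) {
  stopifnot(inherits(cm, "icb_coeffmap"))
  pstar <- point$values
  P <- length(cm$model$parameters)
  eqs <- list()
  for (co in cm$coefficients) {
    Astar <- poly_eval(co$num, pstar)
    Lstar <- poly_eval(co$den, pstar)
    eq <- poly_sub(eng_poly_scale(co$num, Lstar), eng_poly_scale(co$den, Astar))
    eq <- poly_canon(eq)
    if (!poly_is_zero(eq)) eqs[[length(eqs) + 1L]] <- eq
  }
  sat <- unique_polys(lapply(cm$coefficients, `[[`, "den"))
  n_ic <- 0L
  if (isTRUE(cm$has_ics)) {
    ics <- build_ic_relations(cm, pstar)
    eqs <- c(eqs, ics$eqs)
    sat <- c(sat, ics$sat)
    n_ic <- length(ics$eqs)
  }
  structure(list(eqs = eqs, sat = unique_polys(sat), pstar = pstar,
                 seed = point$seed, prime = prime, cm = cm, n_ic = n_ic),
            class = "icb_fiber")
}

# initial-condition relations: value the derivative symbols at t = 0 on the
# p* trajectory, substitute into the state-solving relations, equate to the
# known initial values
build_ic_relations <- function(cm, pstar) {
  io <- cm$ioset
  d <- io$derivs
  m <- io$model
  lay <- io$layout
  P <- length(m$parameters)
  seed <- attr(pstar, "seed")
  x0 <- character(length(m$states))
  names(x0) <- m$states
  extra <- with_seed(sum(pstar) + 1099L, sample(2:97, length(m$states) + length(lay$u_cols)))
  ei <- 1L
  ic_num <- ic_den <- list()
  for (s in m$states) {
    if (s %in% names(m$ics)) {
      rf <- ast_to_rf(m$ics[[s]], m$parameters)
      v <- rf_eval(rf, pstar)
      if (is.null(v)) stop("initial condition for ", s, " undefined at p*")
      x0[s] <- v
      ic_num[[s]] <- rf$num
      ic_den[[s]] <- rf$den
    } else {
      x0[s] <- as.character(extra[ei]); ei <- ei + 1L
    }
  }
  uvals <- character(length(lay$u_cols))
  if (length(lay$u_cols)) {
    unames <- lay$vars[lay$u_cols]
    base <- sub("\\.d[0-9]+$", "", unames)
    ord <- integer(length(unames))
    hasd <- grepl("\\.d", unames)
    ord[hasd] <- as.integer(sub("^.*\\.d", "", unames[hasd]))
    for (i in seq_along(unames)) {
      if (base[i] %in% m$const_inputs && ord[i] >= 1) uvals[i] <- "0"
      else { uvals[i] <- as.character(extra[ei]); ei <- ei + 1L }
    }
  }
  # derivative symbol values on the true trajectory
  dv_point <- c(x0, uvals, as.character(pstar))   # deriv layout order
  yvals <- matrix("", length(m$outputs), d$K + 1)
  for (j in seq_along(m$outputs)) for (k in 0:d$K) {
    v <- rf_eval(d$rfs[[j]][[k + 1]], dv_point)
    if (is.null(v)) stop("output derivative undefined at the sampled initial state")
    yvals[j, k + 1] <- v
  }
  eqs <- list()
  sat <- list()
  for (s in cm$ic_states) {
    S <- io$state_solve[[s]]
    i <- match(s, m$states)
    # substitute numeric Y and U values
    numcols <- c(lay$y_cols, lay$u_cols)
    numvals <- c(as.vector(t(yvals)), uvals)
    Sx <- eng_poly_eval_partial(S, numcols, numvals)
    rows_lin <- Sx$exp[, i] == 1L
    A <- list(exp = Sx$exp[rows_lin, , drop = FALSE], c = Sx$c[rows_lin])
    A$exp[, i] <- 0L
    B <- list(exp = Sx$exp[!rows_lin, , drop = FALSE], c = Sx$c[!rows_lin])
    pmap <- lay$p_cols
    to_p <- function(q) {
      list(exp = q$exp[, pmap, drop = FALSE] * 1L, c = q$c)
    }
    A <- to_p(A); B <- to_p(B)
    rel <- poly_canon(poly_add(poly_mul(A, ic_num[[s]]), poly_mul(B, ic_den[[s]])))
    if (poly_is_zero(rel)) next
    if (poly_eval(rel, pstar) != "0") {
      warning("initial-condition relation for ", s,
              " inconsistent at p*; dropped", call. = FALSE)
      next
    }
    eqs[[length(eqs) + 1L]] <- rel
    sat[[length(sat) + 1L]] <- poly_canon(A)
  }
  list(eqs = eqs, sat = Filter(Negate(poly_is_zero), sat))
}

saturation_poly <- function(fs, extra_den = NULL, nv, zcol) {
  dens <- fs$sat
  if (!is.null(extra_den) && length(poly_vars_used(extra_den)) > 0)
    dens <- c(dens, list(extra_den))
  if (length(dens) == 0) return(NULL)
  D <- poly_prod(lapply(dens, poly_remap, map = seq_len(poly_nv(dens[[1]])), nv_new = nv))
  poly_sub(poly_mul(poly_var(nv, zcol), D), poly_const(nv, "1"))
}

univariate_from_gb <- function(gb, col, nv) {
  best <- NULL
  for (g in gb) {
    other <- g$exp[, -col, drop = FALSE]
    if (any(other != 0L)) next
    deg <- max(g$exp[, col])
    if (is.null(best) || deg < best$deg) best <- list(deg = deg, g = g)
  }
  if (is.null(best)) return(NULL)
  co <- numeric(best$deg + 1)
  for (i in seq_len(nrow(best$g$exp))) co[best$g$exp[i, col] + 1] <- best$g$res[i]
  co
}

#' Classify each parameter from the fiber system
#'
#' For every parameter, computes the elimination ideal retaining only that
#' parameter (Groebner basis modulo a word-size prime under an elimination
#' order, with denominators saturated). A nonzero univariate eliminant gives
#' the maximum number of distinct solutions as the degree of its squarefree
#' part; parameters with no eliminant are structurally unidentifiable.
#'
#' @param fs An `icb_fiber`.
#' @param params Canonical parameter names (defaults to all).
#' @param max_steps,max_seconds Budget per basis computation; exceeding it
#'   marks the parameter `undetermined`.
#' @return A tibble with columns `parameter`, `status`, `max_solutions`.
#' @export
classify_parameters <- function(fs, params = NULL, max_steps = 5e6,
                                max_seconds = 300) {
  stopifnot(inherits(fs, "icb_fiber"))
  allp <- names(fs$pstar)
  if (is.null(params)) params <- allp
  P <- length(allp)
  nv <- P + 1L
  z <- P + 1L
  eqs <- lapply(fs$eqs, poly_remap, map = seq_len(P), nv_new = nv)
  satp <- saturation_poly(fs, NULL, nv, z)
  if (!is.null(satp)) eqs <- c(eqs, list(satp))
  res <- lapply(params, function(pn) {
    i <- match(pn, allp)
    blocks <- list(c(z, setdiff(seq_len(P), i)), i)
    out <- tryCatch({
      gb <- eng_groebner_p(eqs, blocks, fs$prime, max_steps, max_seconds)
      co <- univariate_from_gb(gb, i, nv)
      if (is.null(co)) list(status = "unidentifiable", k = Inf)
      else {
        k <- eng_sqfree_deg_p(co, fs$prime)
        list(status = if (k == 1) "unique" else "local", k = k)
      }
    }, error = function(e) list(status = "undetermined", k = NA_real_))
    tibble::tibble(parameter = pn, status = out$status, max_solutions = out$k)
  })
  do.call(rbind, res)
}

#' Count solutions for a parameter combination on the fiber
#'
#' Adjoins `w = expr(p)` to the fiber system, eliminates all parameters, and
#' counts the distinct roots of the squarefree part of the univariate
#' eliminant in `w`; infinite when no eliminant exists.
#'
#' @param fs An `icb_fiber`.
#' @param expr A polynomial (or rational function as `list(num, den)`) in
#'   parameter space.
#' @param max_steps,max_seconds Basis budget.
#' @return A positive count, or `Inf`.
#' @export
count_solutions_for <- function(fs, expr, max_steps = 5e6, max_seconds = 300) {
  stopifnot(inherits(fs, "icb_fiber"))
  P <- length(fs$pstar)
  if (!is.null(expr$exp)) expr <- list(num = expr, den = poly_const(P, "1"))
  nv <- P + 2L
  z <- P + 1L; w <- P + 2L
  eqs <- lapply(fs$eqs, poly_remap, map = seq_len(P), nv_new = nv)
  num <- poly_remap(expr$num, seq_len(P), nv)
  den <- poly_remap(expr$den, seq_len(P), nv)
  eqs <- c(eqs, list(poly_sub(poly_mul(poly_var(nv, w), den), num)))
  satp <- saturation_poly(fs, poly_canon(expr$den), nv, z)
  if (!is.null(satp)) eqs <- c(eqs, list(satp))
  blocks <- list(c(z, seq_len(P)), w)
  gb <- eng_groebner_p(eqs, blocks, fs$prime, max_steps, max_seconds)
  co <- univariate_from_gb(gb, w, nv)
  if (is.null(co)) return(Inf)
  eng_sqfree_deg_p(co, fs$prime)
}

#' Combine per-parameter statuses into a model verdict
#'
#' @param statuses Tibble from [classify_parameters()].
#' @return One of `"globally identifiable"`, `"locally identifiable"`,
#'   `"unidentifiable"`.
#' @export
classify_model <- function(statuses) {
  if (any(statuses$status == "undetermined"))
    return("undetermined")
  if (all(statuses$status == "unique")) return("globally identifiable")
  if (all(is.finite(statuses$max_solutions))) return("locally identifiable")
  "unidentifiable"
}
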