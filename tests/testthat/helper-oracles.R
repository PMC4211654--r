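# Independent numeric oracles used across the suite.

# ---- numeric evaluation of model expressions -------------------------------

ast_num_eval <- function(ast, env) {
  if (ast$k == "n") return(identicombo:::rat_to_num(ast$v))
  if (ast$k == "s") return(env[[ast$name]])
  a <- ast$a
  switch(ast$op,
    "+" = ast_num_eval(a[[1]], env) + ast_num_eval(a[[2]], env),
    "-" = ast_num_eval(a[[1]], env) - ast_num_eval(a[[2]], env),
    "*" = ast_num_eval(a[[1]], env) * ast_num_eval(a[[2]], env),
    "/" = ast_num_eval(a[[1]], env) / ast_num_eval(a[[2]], env),
    "neg" = -ast_num_eval(a[[1]], env),
    "^" = ast_num_eval(a[[1]], env)^a[[2]])
}

poly_eval_num <- function(p, vals) {
  if (nrow(p$exp) == 0) return(0)
  co <- vapply(p$c, identicombo:::rat_to_num, 0)
  sum(vapply(seq_len(nrow(p$exp)), function(i) {
    co[i] * prod(vals^p$exp[i, ])
  }, 0))
}

rf_eval_num <- function(f, vals) poly_eval_num(f$num, vals) / poly_eval_num(f$den, vals)

# ---- trajectory residual oracle -------------------------------------------
# integrate the model at a fixed numeric parameter point with a polynomial
# input, then check that the input-output equations vanish along the
# trajectory (output derivatives computed symbolically, not by differencing)

traj_residual <- function(m, p_num, u_coefs = c(1, 0.7, -0.3), tmax = 1,
                          x0 = NULL) {
  io <- io_equations(m)
  d <- io$derivs
  n <- length(m$states)
  if (is.null(x0)) x0 <- seq(0.5, by = 0.25, length.out = n)
  pars <- as.list(p_num)
  names(pars) <- m$user_parameters
  # canonical names are what the stored ASTs use
  canon <- as.list(p_num)
  names(canon) <- m$parameters
  uval <- function(t, k) {
    # polynomial input and its derivatives; constant inputs freeze at u(0)
    if (length(m$const_inputs)) {
      if (k == 0) return(u_coefs[1])
      return(0)
    }
    co <- u_coefs
    for (i in seq_len(k)) {
      co <- co[-1] * seq_along(co[-1])
      if (length(co) == 0) return(0)
    }
    sum(co * t^(seq_along(co) - 1))
  }
  derivfun <- function(t, x, parms) {
    env <- c(as.list(setNames(x, m$states)), canon, list(u1 = uval(t, 0)))
    list(vapply(m$states, function(s) ast_num_eval(m$odes[[s]], env), 0))
  }
  times <- seq(0.05, tmax, length.out = 8)
  sol <- deSolve::ode(y = setNames(x0, m$states), times = c(0, times),
                      func = derivfun, parms = NULL,
                      rtol = 1e-11, atol = 1e-11)
  lay <- io$layout
  worst <- 0
  for (ti in seq_along(times)) {
    xrow <- sol[ti + 1, m$states]
    uderivs <- vapply(0:d$K, function(k) uval(times[ti], k), 0)
    dvals <- c(as.numeric(xrow), if (d$r > 0) uderivs else numeric(0), p_num)
    for (j in seq_along(m$outputs)) for (k in 0:d$K) {
      # fill Y values in the extended layout
      if (j == 1 && k == 0) yv <- matrix(0, length(m$outputs), d$K + 1)
      yv[j, k + 1] <- rf_eval_num(d$rfs[[j]][[k + 1]], dvals)
    }
    ext_vals <- numeric(length(lay$vars))
    ext_vals[lay$x_cols] <- 0                       # equations are state-free
    ext_vals[lay$y_cols] <- as.vector(t(yv))
    if (length(lay$u_cols)) ext_vals[lay$u_cols] <- uderivs
    ext_vals[lay$p_cols] <- p_num
    for (eq in io$equations) {
      co <- vapply(eq$c, identicombo:::rat_to_num, 0)
      terms <- vapply(seq_len(nrow(eq$exp)), function(i) {
        co[i] * prod(ext_vals^eq$exp[i, ])
      }, 0)
      scale <- max(abs(terms), 1)
      worst <- max(worst, abs(sum(terms)) / scale)
    }
  }
  worst
}

# ---- transfer-function oracle for linear SISO compartmental models --------
# For xdot = A x + b u, y = c x: the strictly proper transfer function is
# N(s)/D(s) with D = det(sI - A) and N = det(sI - A + b c) - det(sI - A).
# Its coefficients (denominator monic) are exactly the identifiable
# input-output quantities the normalized equations must reproduce.

tf_coefficients <- function(A, b, cvec) {
  D <- pracma::charpoly(A)
  N <- pracma::charpoly(A - b %*% t(cvec)) - D
  list(den = D[-1], num = N[-1])
}

# numeric A, b, c for the builtin linear compartmental examples at a point
linear_realization <- function(name, p) {
  switch(name,
    "2comp" = list(
      A = matrix(c(-(p["k01"] + p["k21"]), p["k12"],
                   p["k21"], -(p["k02"] + p["k12"])), 2, 2, byrow = TRUE),
      b = c(1, 0), cvec = c(1 / p["V1"], 0)),
    "3comp" = list(
      A = matrix(c(-(p["k21"] + p["k31"]), p["k12"], p["k13"],
                   p["k21"], -(p["k02"] + p["k12"]), 0,
                   p["k31"], 0, -(p["k03"] + p["k13"])), 3, 3, byrow = TRUE),
      b = c(1, 0, 0), cvec = c(1 / p["V1"], 0, 0)),
    "mammillary4" = list(
      A = matrix(c(-(p["k01"] + p["k21"] + p["k31"] + p["k41"]),
                   p["k12"], p["k13"], p["k14"],
                   p["k21"], -p["k12"], 0, 0,
                   p["k31"], 0, -p["k13"], 0,
                   p["k41"], 0, 0, -p["k14"]), 4, 4, byrow = TRUE),
      b = c(1, 0, 0, 0), cvec = c(1, 0, 0, 0)),
    stop("no realization for ", name))
}

random_point <- function(m, seed, range = 2:97) {
  set.seed(seed)
  setNames(sample(range, length(m$parameters)), m$user_parameters)
}

# ---- combo expressions ----------------------------------------------------

# parse a combination written in user parameter names into a rational
# function over canonical parameter space
combo_rf <- function(m, text) {
  ast <- identicombo:::parse_expr_text(text)
  identicombo:::ast_to_rf(ast, m$user_parameters)
}

combo_count <- function(fs, m, text) {
  count_solutions_for(fs, combo_rf(m, text))
}

# Jacobian rank of a set of combination expressions at p*
combo_rank <- function(fs, m, texts) {
  rfs <- lapply(texts, combo_rf, m = m)
  J <- identicombo:::eng_jacobian_p(rfs, as.numeric(fs$pstar), fs$prime)
  identicombo:::eng_rank_p(J, fs$prime)
}

# full pipeline up to the fiber, at a given or sampled point
fiber_for <- function(m, seed = 1, pstar = NULL) {
  io <- io_equations(m)
  cm <- incorporate_initial_conditions(m, io)
  pt <- if (is.null(pstar)) sample_parameter_point(cm, seed)
        else list(values = setNames(as.integer(pstar), m$parameters), seed = seed)
  fiber_system(cm, pt)
}
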