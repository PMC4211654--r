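# Model text parsing: the plain-text syntax for system-experiment models.
#
# Statements (separated by ";" or newlines, "#" starts a comment):
#   x1' = <expr>      or   dx1/dt = <expr>      state equation
#   y1  = <expr>                                output equation
#   x1(0) = <expr>                              known initial condition
#
# Naming rules: states are x1, x2, ...; inputs u1, u2, ...; outputs y1, ...;
# time is "t"; every other identifier (letter followed by letters, digits, or
# a comma placed before digits, e.g. k0,1 or Vmax) is an unknown parameter.
# Numeric literals are known constants, converted exactly to rationals.

TRANSCENDENTAL_NAMES <- c("sin", "cos", "tan", "exp", "log", "ln", "sqrt",
                          "pi", "e", "abs", "sinh", "cosh", "tanh")

# ---- expression AST -------------------------------------------------------
# list(k = "n", v = "num/den") | list(k = "s", name = sym) |
# list(k = "c", op = "+-*/^neg", a = list(children)); "^" has integer 2nd arg

ast_num <- function(v) list(k = "n", v = v)
ast_sym <- function(name) list(k = "s", name = name)
ast_call <- function(op, ...) list(k = "c", op = op, a = list(...))

decimal_to_rat <- function(s) {
  if (!grepl(".", s, fixed = TRUE)) return(sub("^0+(?=[0-9])", "", s, perl = TRUE))
  parts <- strsplit(s, ".", fixed = TRUE)[[1]]
  frac <- parts[2]
  paste0(parts[1], frac, "/1", strrep("0", nchar(frac)))
}

tokenize_expr <- function(s, stmt = s) {
  toks <- list()
  i <- 1L
  n <- nchar(s)
  while (i <= n) {
    rest <- substr(s, i, n)
    if (grepl("^\\s", rest)) { i <- i + 1L; next }
    m <- regmatches(rest, regexpr("^[0-9]+(\\.[0-9]+)?", rest))
    if (length(m)) {
      toks[[length(toks) + 1L]] <- list(t = "num", v = m)
      i <- i + nchar(m); next
    }
    m <- regmatches(rest, regexpr("^[a-zA-Z][a-zA-Z0-9]*(,[0-9][a-zA-Z0-9]*)*", rest))
    if (length(m)) {
      toks[[length(toks) + 1L]] <- list(t = "sym", v = m)
      i <- i + nchar(m); next
    }
    ch <- substr(rest, 1, 1)
    if (ch %in% c("+", "-", "*", "/", "^", "(", ")")) {
      toks[[length(toks) + 1L]] <- list(t = "op", v = ch)
      i <- i + 1L; next
    }
    stop("malformed expression near '", substr(rest, 1, 12), "' in statement: ", stmt)
  }
  toks
}

parse_expr_text <- function(s, stmt = s) {
  toks <- tokenize_expr(s, stmt)
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[[pos]] else NULL
  take <- function() { t <- toks[[pos]]; pos <<- pos + 1L; t }
  expect_op <- function(v) {
    t <- peek()
    if (is.null(t) || t$t != "op" || t$v != v)
      stop("expected '", v, "' in statement: ", stmt)
    take()
  }
  parse_sum <- function() {
    node <- parse_prod()
    repeat {
      t <- peek()
      if (is.null(t) || t$t != "op" || !(t$v %in% c("+", "-"))) return(node)
      take()
      node <- ast_call(t$v, node, parse_prod())
    }
  }
  parse_prod <- function() {
    node <- parse_unary()
    repeat {
      t <- peek()
      if (is.null(t) || t$t != "op" || !(t$v %in% c("*", "/"))) return(node)
      take()
      node <- ast_call(t$v, node, parse_unary())
    }
  }
  parse_unary <- function() {
    t <- peek()
    if (!is.null(t) && t$t == "op" && t$v %in% c("-", "+")) {
      take()
      child <- parse_unary()
      if (t$v == "-") return(ast_call("neg", child))
      return(child)
    }
    parse_power()
  }
  parse_power <- function() {
    base <- parse_atom()
    t <- peek()
    if (!is.null(t) && t$t == "op" && t$v == "^") {
      take()
      e <- parse_int_exponent()
      return(ast_call("^", base, e))
    }
    base
  }
  parse_int_exponent <- function() {
    sign <- 1L
    parens <- FALSE
    t <- peek()
    if (!is.null(t) && t$t == "op" && t$v == "(") { take(); parens <- TRUE; t <- peek() }
    if (!is.null(t) && t$t == "op" && t$v == "-") { take(); sign <- -1L; t <- peek() }
    if (is.null(t) || t$t != "num" || grepl(".", t$v, fixed = TRUE))
      stop("exponent must be an integer in statement: ", stmt)
    take()
    if (parens) expect_op(")")
    sign * as.integer(t$v)
  }
  parse_atom <- function() {
    t <- peek()
    if (is.null(t)) stop("unexpected end of expression in statement: ", stmt)
    if (t$t == "num") { take(); return(ast_num(decimal_to_rat(t$v))) }
    if (t$t == "sym") { take(); return(ast_sym(t$v)) }
    if (t$t == "op" && t$v == "(") {
      take()
      node <- parse_sum()
      expect_op(")")
      return(node)
    }
    stop("unexpected '", t$v, "' in statement: ", stmt)
  }
  node <- parse_sum()
  if (pos <= length(toks))
    stop("trailing input after expression in statement: ", stmt)
  node
}

ast_symbols <- function(ast) {
  if (ast$k == "s") return(ast$name)
  if (ast$k == "c") {
    if (ast$op == "^") return(ast_symbols(ast$a[[1]]))
    return(unique(unlist(lapply(ast$a, ast_symbols))))
  }
  character(0)
}

# symbols in deterministic left-to-right order, with repeats removed
ast_symbols_ordered <- function(ast) unique(ast_symbols_all(ast))
ast_symbols_all <- function(ast) {
  if (ast$k == "s") return(ast$name)
  if (ast$k == "c") {
    if (ast$op == "^") return(ast_symbols_all(ast$a[[1]]))
    return(unlist(lapply(ast$a, ast_symbols_all)))
  }
  character(0)
}

ast_rename <- function(ast, map) {
  if (ast$k == "s") {
    if (!is.null(map[[ast$name]])) return(ast_sym(map[[ast$name]]))
    return(ast)
  }
  if (ast$k == "c") {
    if (ast$op == "^") return(ast_call("^", ast_rename(ast$a[[1]], map), ast$a[[2]]))
    ast$a <- lapply(ast$a, ast_rename, map = map)
    return(ast)
  }
  ast
}

# substitute symbol -> AST
ast_substitute <- function(ast, name, value) {
  if (ast$k == "s") {
    if (identical(ast$name, name)) return(value)
    return(ast)
  }
  if (ast$k == "c") {
    if (ast$op == "^")
      return(ast_call("^", ast_substitute(ast$a[[1]], name, value), ast$a[[2]]))
    ast$a <- lapply(ast$a, ast_substitute, name = name, value = value)
    return(ast)
  }
  ast
}

# convert symbolic AST to the indexed form the kernel evaluates
ast_index <- function(ast, vars) {
  if (ast$k == "n") return(ast)
  if (ast$k == "s") {
    i <- match(ast$name, vars)
    if (is.na(i)) stop("unknown symbol in expression: ", ast$name)
    return(list(k = "v", i = as.integer(i)))
  }
  if (ast$op == "^") return(list(k = "c", op = "^", a = list(ast_index(ast$a[[1]], vars), ast$a[[2]])))
  list(k = "c", op = ast$op, a = lapply(ast$a, ast_index, vars = vars))
}

ast_to_rf <- function(ast, vars) eng_ast_to_rf(ast_index(ast, vars), length(vars))

ast_prec <- function(ast) {
  if (ast$k != "c") return(4L)
  switch(ast$op, "+" = 1L, "-" = 1L, "*" = 2L, "/" = 2L, "neg" = 2L, "^" = 3L)
}

ast_to_string <- function(ast) {
  if (ast$k == "n") {
    if (grepl("/", ast$v)) return(paste0("(", ast$v, ")"))
    return(ast$v)
  }
  if (ast$k == "s") return(ast$name)
  wrap <- function(child, minprec) {
    s <- ast_to_string(child)
    if (ast_prec(child) < minprec) paste0("(", s, ")") else s
  }
  switch(ast$op,
    "+" = paste0(wrap(ast$a[[1]], 1L), " + ", wrap(ast$a[[2]], 2L)),
    "-" = paste0(wrap(ast$a[[1]], 1L), " - ", wrap(ast$a[[2]], 2L)),
    "*" = paste0(wrap(ast$a[[1]], 2L), "*", wrap(ast$a[[2]], 3L)),
    "/" = paste0(wrap(ast$a[[1]], 2L), "/", wrap(ast$a[[2]], 4L)),
    "neg" = paste0("-", wrap(ast$a[[1]], 3L)),
    "^" = paste0(wrap(ast$a[[1]], 4L), "^", ast$a[[2]])
  )
}

# ---- statements and model assembly ---------------------------------------

split_statements <- function(text) {
  text <- paste(text, collapse = "\n")
  text <- gsub("#[^\n]*", "", text)
  stmts <- unlist(strsplit(text, "[;\n]"))
  stmts <- trimws(stmts)
  stmts[nzchar(stmts)]
}

classify_statement <- function(s) {
  m <- regmatches(s, regexec("^x([0-9]+)\\s*\\(\\s*0\\s*\\)\\s*=(.*)$", s))[[1]]
  if (length(m)) return(list(type = "ic", idx = as.integer(m[2]), rhs = m[3]))
  m <- regmatches(s, regexec("^x([0-9]+)\\s*'\\s*=(.*)$", s))[[1]]
  if (length(m)) return(list(type = "ode", idx = as.integer(m[2]), rhs = m[3]))
  m <- regmatches(s, regexec("^d\\s*x([0-9]+)\\s*/\\s*d\\s*t\\s*=(.*)$", s))[[1]]
  if (length(m)) return(list(type = "ode", idx = as.integer(m[2]), rhs = m[3]))
  m <- regmatches(s, regexec("^y([0-9]+)\\s*=(.*)$", s))[[1]]
  if (length(m)) return(list(type = "output", idx = as.integer(m[2]), rhs = m[3]))
  stop("unrecognized statement (expected x<i>' = ..., y<j> = ... or x<i>(0) = ...): ", s)
}

symbol_class <- function(sym) {
  if (grepl("^x[0-9]+$", sym)) return("state")
  if (grepl("^u[0-9]+$", sym)) return("input")
  if (grepl("^y[0-9]+$", sym)) return("output")
  if (sym == "t") return("time")
  if (grepl("^[xuyt]", sym)) return("reserved")
  "parameter"
}

check_contiguous <- function(idx, what) {
  idx <- sort(unique(idx))
  if (length(idx) == 0) return(invisible())
  if (!identical(idx, seq_len(max(idx))) || idx[1] != 1L)
    stop(what, " numbering must start at 1 and be contiguous; found: ",
         paste(idx, collapse = ", "))
  invisible()
}

#' Parse a model description
#'
#' Reads a plain-text system-experiment model (state equations, output
#' equations and optional known initial conditions) and returns a validated
#' model object with user parameter names mapped to canonical symbols
#' `p1..pP` in order of first appearance.
#'
#' @param text Model source: a single string with statements separated by
#'   semicolons or newlines (copy/paste form), or a character vector with one
#'   statement per element (fill-in form).
#' @param constant_inputs Names of inputs to be treated as constant in time
#'   (steps of unknown magnitude), so that their derivatives vanish.
#' @param max_parameters Cap on the number of unknown parameters.
#' @return An object of class `icb_model` with components `states`, `inputs`,
#'   `outputs`, `parameters` (canonical), `name_map`, `odes`, `output_eqs`,
#'   `ics`, `const_inputs`.
#' @examples
#' m <- parse_model("x1' = -k*x1 + u1 ; y1 = x1/V")
#' m$name_map
#' @export
parse_model <- function(text, constant_inputs = character(0), max_parameters = 60L) {
  stmts <- split_statements(text)
  if (length(stmts) == 0) stop("empty model description")
  parsed <- lapply(stmts, classify_statement)
  types <- vapply(parsed, `[[`, "", "type")
  idxs <- vapply(parsed, `[[`, 0L, "idx")

  for (tp in c("ode", "output", "ic")) {
    dup <- duplicated(idxs[types == tp])
    if (any(dup)) stop("duplicate ", tp, " statement for index ",
                       idxs[types == tp][dup][1])
  }
  ode_i <- which(types == "ode")
  out_i <- which(types == "output")
  ic_i <- which(types == "ic")
  if (length(ode_i) == 0) stop("model has no state equations")
  if (length(out_i) == 0) stop("model has no output equations")
  check_contiguous(idxs[ode_i], "state")
  check_contiguous(idxs[out_i], "output")

  n <- max(idxs[ode_i])
  m <- max(idxs[out_i])
  states <- paste0("x", seq_len(n))
  outputs <- paste0("y", seq_len(m))

  if (any(!idxs[ic_i] %in% seq_len(n)))
    stop("initial condition given for undefined state x", setdiff(idxs[ic_i], seq_len(n))[1])

  # canonical statement order: odes by state, outputs by index, ics by state
  odes <- vector("list", n); names(odes) <- states
  for (k in ode_i) odes[[idxs[k]]] <- parse_expr_text(parsed[[k]]$rhs, stmts[k])
  outs <- vector("list", m); names(outs) <- outputs
  for (k in out_i) outs[[idxs[k]]] <- parse_expr_text(parsed[[k]]$rhs, stmts[k])
  ics <- list()
  for (k in ic_i[order(idxs[ic_i])])
    ics[[paste0("x", idxs[k])]] <- parse_expr_text(parsed[[k]]$rhs, stmts[k])

  # collect and classify symbols in canonical order
  all_asts <- c(odes, outs, ics)
  syms <- unique(unlist(lapply(all_asts, ast_symbols_ordered)))
  cls <- vapply(syms, symbol_class, "")
  if (any(cls == "reserved"))
    stop("reserved-letter misuse: identifiers starting with x, u, y or t must ",
         "be states, inputs, outputs or time, found: ",
         paste(syms[cls == "reserved"], collapse = ", "))
  if (any(cls == "time"))
    stop("explicit time dependence ('t' in an expression) is not supported: ",
         "the model class is time-invariant rational ODEs")
  bad_state <- setdiff(syms[cls == "state"], states)
  if (length(bad_state)) stop("undefined state referenced: ", bad_state[1])
  bad_out <- syms[cls == "output"]
  if (length(bad_out)) stop("outputs may not appear inside expressions: ", bad_out[1])

  inputs_used <- syms[cls == "input"]
  check_contiguous(as.integer(sub("^u", "", inputs_used)), "input")
  r <- if (length(inputs_used)) max(as.integer(sub("^u", "", inputs_used))) else 0L
  inputs <- if (r > 0) paste0("u", seq_len(r)) else character(0)

  # expression-level placement rules
  for (s in names(ics)) {
    isyms <- ast_symbols(ics[[s]])
    icls <- vapply(isyms, symbol_class, "")
    if (any(icls != "parameter"))
      stop("initial condition for ", s, " may only involve parameters and ",
           "numbers, found: ", paste(isyms[icls != "parameter"], collapse = ", "))
  }
  for (o in outputs) {
    osyms <- ast_symbols(outs[[o]])
    ocls <- vapply(osyms, symbol_class, "")
    if (any(ocls == "input"))
      stop("output equations are functions of states and parameters only; ",
           o, " references an input")
  }

  user_pars <- unique(unlist(lapply(all_asts, function(a) {
    s <- ast_symbols_ordered(a)
    s[vapply(s, symbol_class, "") == "parameter"]
  })))
  if (length(user_pars) > max_parameters)
    stop("model has ", length(user_pars), " parameters, above the limit of ",
         max_parameters)
  if (length(user_pars) == 0) stop("model has no unknown parameters")
  canon <- paste0("p", seq_along(user_pars))
  map <- as.list(setNames(canon, user_pars))

  odes <- lapply(odes, ast_rename, map = map)
  outs <- lapply(outs, ast_rename, map = map)
  ics <- lapply(ics, ast_rename, map = map)

  bad_const <- setdiff(constant_inputs, inputs)
  if (length(bad_const)) stop("constant_inputs refers to unknown input: ", bad_const[1])

  structure(list(
    states = states, inputs = inputs, outputs = outputs,
    parameters = canon, user_parameters = user_pars,
    name_map = tibble::tibble(user = user_pars, canonical = canon),
    odes = odes, output_eqs = outs, ics = ics,
    const_inputs = constant_inputs,
    source = paste(stmts, collapse = " ; ")
  ), class = "icb_model")
}

#' Validate a parsed model
#'
#' Re-checks the syntax invariants on a parsed model and returns a character
#' vector of diagnostics (empty when the model is clean). Unlike
#' [parse_model()], which raises on structural errors, this returns advisory
#' diagnostics such as parameter names that shadow common transcendental
#' function names (the parser has no function syntax, so `sin` would be
#' treated as an unknown parameter).
#'
#' @param m An `icb_model`.
#' @return Character vector of diagnostics.
#' @export
validate_model <- function(m) {
  stopifnot(inherits(m, "icb_model"))
  diags <- character(0)
  shadowed <- intersect(tolower(m$user_parameters), TRANSCENDENTAL_NAMES)
  for (s in shadowed)
    diags <- c(diags, paste0(
      "identifier '", s, "' looks like a transcendental function name but is ",
      "treated as an unknown parameter; only rational expressions are supported"))
  if (length(m$parameters) > 50)
    diags <- c(diags, paste0("large parameter count (", length(m$parameters),
                             "): analysis may be slow"))
  for (s in names(m$ics)) {
    isyms <- ast_symbols(m$ics[[s]])
    bad <- isyms[!isyms %in% m$parameters]
    if (length(bad))
      diags <- c(diags, paste0("initial condition for ", s,
                               " references non-parameter symbol: ", bad[1]))
  }
  diags
}

#' Render a model in copy/paste form
#'
#' Produces the semicolon-delimited text form of a model, in the user's
#' original parameter names, listing only the known initial conditions.
#' Parsing the result yields a model equal to the input.
#'
#' @param m An `icb_model`.
#' @return A single string.
#' @export
render_copy_paste <- function(m) {
  stopifnot(inherits(m, "icb_model"))
  back <- as.list(setNames(m$name_map$user, m$name_map$canonical))
  stmts <- character(0)
  for (s in m$states)
    stmts <- c(stmts, paste0(s, "' = ", ast_to_string(ast_rename(m$odes[[s]], back))))
  for (o in m$outputs)
    stmts <- c(stmts, paste0(o, " = ", ast_to_string(ast_rename(m$output_eqs[[o]], back))))
  for (s in names(m$ics))
    stmts <- c(stmts, paste0(s, "(0) = ", ast_to_string(ast_rename(m$ics[[s]], back))))
  paste(stmts, collapse = " ; ")
}

# symbolic model equality: same interface and identical equations as rational
# functions (used for round-trip checks)
model_equal <- function(a, b) {
  if (!identical(a$states, b$states) || !identical(a$inputs, b$inputs) ||
      !identical(a$outputs, b$outputs) || !identical(sort(names(a$ics)), sort(names(b$ics))))
    return(FALSE)
  if (!identical(a$name_map$user, b$name_map$user)) return(FALSE)
  vars <- c(a$states, a$inputs, a$parameters)
  same_expr <- function(e1, e2) {
    d <- eng_rf_op("-", ast_to_rf(e1, vars), ast_to_rf(e2, vars))
    poly_is_zero(d$num)
  }
  for (s in a$states) if (!same_expr(a$odes[[s]], b$odes[[s]])) return(FALSE)
  for (o in a$outputs) if (!same_expr(a$output_eqs[[o]], b$output_eqs[[o]])) return(FALSE)
  for (s in names(a$ics)) if (!same_expr(a$ics[[s]], b$ics[[s]])) return(FALSE)
  TRUE
}

#' @export
print.icb_model <- function(x, ...) {
  cat("System-experiment model:", length(x$states), "states,",
      length(x$inputs), "inputs,", length(x$outputs), "outputs,",
      length(x$parameters), "parameters\n")
  cat(render_copy_paste(x), "\n")
  if (length(x$const_inputs))
    cat("constant inputs:", paste(x$const_inputs, collapse = ", "), "\n")
  invisible(x)
}
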