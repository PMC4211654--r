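# Built-in model families used throughout the tests and documentation:
# generic linear benchmark families of growing dimension, and the classical
# compartmental / disease-dynamics examples. Everything is generated
# programmatically as model text and parsed, so fixtures and user models go
# through exactly the same code path.

#' Generate a linear benchmark test model
#'
#' Family semantics (all share the ODE system xdot = P x + e_1 u with a full
#' n-by-n parameter matrix `pij` and a single input, placed in the first
#' state equation, the compartment numbering the published results use):
#' \describe{
#'   \item{1}{all states measured: y_i = x_i}
#'   \item{2}{one less output: y_1..y_{n-1} = x_1..x_{n-1}}
#'   \item{3}{single output in the input compartment: y_1 = x_1}
#'   \item{4}{single output in a different compartment: y_1 = x_n}
#'   \item{5}{two outputs: y_1 = x_1 (with the input), y_2 = x_n}
#' }
#'
#' @param family Integer 1..5.
#' @param n State dimension (n^2 parameters; capped at 60).
#' @return An `icb_model`.
#' @export
generate_test_model <- function(family, n) {
  stopifnot(family %in% 1:5, n >= 1)
  if (n * n > 60) stop("n^2 = ", n * n, " parameters exceeds the limit of 60")
  odes <- vapply(seq_len(n), function(i) {
    terms <- paste0("p", i, j_suffix(seq_len(n), n), "*x", seq_len(n))
    rhs <- paste(terms, collapse = " + ")
    if (i == 1) rhs <- paste(rhs, "+ u1")
    paste0("x", i, "' = ", rhs)
  }, "")
  outs <- switch(as.character(family),
    "1" = paste0("y", seq_len(n), " = x", seq_len(n)),
    "2" = if (n == 1) stop("family 2 needs n >= 2 (n-1 outputs)")
          else paste0("y", seq_len(n - 1), " = x", seq_len(n - 1)),
    "3" = "y1 = x1",
    "4" = paste0("y1 = x", n),
    "5" = if (n == 1) "y1 = x1" else c("y1 = x1", paste0("y2 = x", n)))
  parse_model(paste(c(odes, outs), collapse = " ; "))
}

# parameter naming pij: for n < 10 plain digit pairs (p11, p23, ...)
j_suffix <- function(j, n) if (n < 10) j else sprintf("%02d", j)

example_texts <- function() {
  list(
    # 2-compartment exchange model, input and output in compartment 1,
    # concentration measured (volume V1): unidentifiable, V1 and three sums /
    # products of rate constants are uniquely identifiable
    "2comp" = "
      x1' = -(k01 + k21)*x1 + k12*x2 + u1
      x2' = k21*x1 - (k02 + k12)*x2
      y1 = x1/V1",
    "2comp_k01_0" = "
      x1' = -k21*x1 + k12*x2 + u1
      x2' = k21*x1 - (k02 + k12)*x2
      y1 = x1/V1",
    "2comp_k02_0" = "
      x1' = -(k01 + k21)*x1 + k12*x2 + u1
      x2' = k21*x1 - k12*x2
      y1 = x1/V1",
    # the same model rewritten in its identifiable combinations (scaled x2):
    # a11 = k01+k21, a12 = k12*k21, a22 = k02+k12
    "2comp_repar" = "
      x1' = -a11*x1 + a12*x2 + u1
      x2' = x1 - a22*x2
      y1 = x1/V1",
    # 3-compartment mammillary model, leaks from the peripheral compartments,
    # input and output (concentration) in compartment 1
    "3comp" = "
      x1' = -(k21 + k31)*x1 + k12*x2 + k13*x3 + u1
      x2' = k21*x1 - (k02 + k12)*x2
      x3' = k31*x1 - (k03 + k13)*x3
      y1 = x1/V1",
    "3comp_k03_0" = "
      x1' = -(k21 + k31)*x1 + k12*x2 + k13*x3 + u1
      x2' = k21*x1 - (k02 + k12)*x2
      x3' = k31*x1 - k13*x3
      y1 = x1/V1",
    # 3-compartment model with a central leak as well, one input, one output;
    # analysed with and without full initial conditions
    "3comp_io" = "
      x1' = -(k01 + k21 + k31)*x1 + k12*x2 + k13*x3 + u1
      x2' = k21*x1 - (k02 + k12)*x2
      x3' = k31*x1 - k13*x3
      y1 = x1/V1",
    "3comp_io_ic" = "
      x1' = -(k01 + k21 + k31)*x1 + k12*x2 + k13*x3 + u1
      x2' = k21*x1 - (k02 + k12)*x2
      x3' = k31*x1 - k13*x3
      y1 = x1/V1
      x1(0) = 1 ; x2(0) = 2 ; x3(0) = 3",
    # 4-compartment mammillary model, leak from the central compartment only,
    # input and output in compartment 1
    "mammillary4" = "
      x1' = -(k01 + k21 + k31 + k41)*x1 + k12*x2 + k13*x3 + k14*x4 + u1
      x2' = k21*x1 - k12*x2
      x3' = k31*x1 - k13*x3
      x4' = k41*x1 - k14*x4
      y1 = x1",
    "mammillary4_ic" = "
      x1' = -(k01 + k21 + k31 + k41)*x1 + k12*x2 + k13*x3 + k14*x4 + u1
      x2' = k21*x1 - k12*x2
      x3' = k31*x1 - k13*x3
      x4' = k41*x1 - k14*x4
      y1 = x1
      x2(0) = 2 ; x3(0) = 3",
    # nonlinear HIV dynamics: uninfected cells x1, latently infected x2,
    # actively infected x3, free virus x4; CD4 count and viral load measured
    "hiv" = "
      x1' = s0*u1 - d1*x1 - b1*x1*x4
      x2' = q1*b1*x1*x4 - k1*x2 - m1*x2
      x3' = q2*b1*x1*x4 + k1*x2 - m2*x3
      x4' = c1*x3 - b1*x1*x4 - m3*x4
      y1 = x1
      y2 = x4",
    # simple nonlinear model with one input and two outputs whose special
    # initial conditions x1(0) = x3(0) = 0 freeze two trajectories
    "nl2out" = "
      x1' = p1*x3 - p2*x1
      x2' = u1
      x3' = p3*x1*x2
      y1 = x1
      y2 = x2",
    "nl2out_ic" = "
      x1' = p1*x3 - p2*x1
      x2' = u1
      x3' = p3*x1*x2
      y1 = x1
      y2 = x2
      x1(0) = 0 ; x3(0) = 0",
    # target-cell-limited viral dynamics (target cells x1, infected cells x2,
    # virions x3) with a constant input of unknown magnitude and scaled
    # viral-load measurement
    "viral" = "
      x1' = p1*u1 - p2*x1 - p3*x1*x3
      x2' = p4*x1*x3 - p5*x2
      x3' = p6*x2 - p7*x3
      y1 = p8*x3",
    # the same model rewritten in its identifiable combinations
    "viral_repar" = "
      x1' = q1*u1 - q2*x1 - q3*x1*x3
      x2' = x1*x3 - q4*x2
      x3' = x2 - q5*x3
      y1 = x3"
  )
}

#' Built-in example models
#'
#' A registry of the classical example models: 2- and 3-compartment exchange
#' models and identifiable variants, a 4-compartment mammillary model with
#' and without initial conditions, a nonlinear HIV dynamics model, a
#' reducible nonlinear model, and a viral disease dynamics model with a
#' constant (step) input, plus reparameterized closure fixtures.
#'
#' @param name Optional registry key; omit to get the full named list.
#' @return An `icb_model`, or a named list of them.
#' @export
builtin_examples <- function(name = NULL) {
  texts <- example_texts()
  build <- function(key) {
    const <- if (key %in% c("viral", "viral_repar")) "u1" else character(0)
    parse_model(texts[[key]], constant_inputs = const)
  }
  if (!is.null(name)) {
    if (!name %in% names(texts))
      stop("unknown example '", name, "'; available: ",
           paste(names(texts), collapse = ", "))
    return(build(name))
  }
  setNames(lapply(names(texts), build), names(texts))
}
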