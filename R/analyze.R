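# Full pipeline: parse -> reduce -> input-output equations -> coefficient map
# -> fiber classification -> (for unidentifiable models) combination search.

#' Run a complete structural identifiability analysis
#'
#' Executes the pipeline on a model: constant-trajectory reduction,
#' input-output equation computation, coefficient (exhaustive summary)
#' extraction with optional initial-condition relations, per-parameter
#' classification on the fiber at a pseudo-random point, and -- only when the
#' model is unidentifiable -- the search for identifiable parameter
#' combinations over the 3P ordering schedule. Identifiable models
#' short-circuit: their "combinations" are the parameters themselves.
#'
#' @param m An `icb_model`, or model text to be parsed.
#' @param seed Integer seed driving every random choice (parameter point,
#'   generic evaluation points, sampled unknown initial values).
#' @param orderings Number of orderings to use (default the full 3P schedule).
#' @param prime Word-size prime for modular computations.
#' @param gb_steps,gb_seconds Budget per Groebner basis; exceeding it aborts
#'   that stage (per-parameter: status `undetermined`; per-ordering: skipped).
#' @param progress Print stage progress.
#' @return An object of class `icb_report`.
#' @examples
#' \donttest{
#' rep <- run_analysis("x1' = -a*x1 + u1 ; y1 = x1/V", seed = 1)
#' rep$model_status
#' }
#' @export
run_analysis <- function(m, seed = 0L, orderings = NULL,
                         prime = default_prime(), gb_steps = 5e6,
                         gb_seconds = 300, progress = FALSE) {
  t0 <- Sys.time()
  if (is.character(m)) m <- parse_model(m)
  stopifnot(inherits(m, "icb_model"))
  stages <- character(0)
  note <- function(s) {
    stages <<- c(stages, s)
    if (progress) message("[", format(Sys.time() - t0, digits = 3), "] ", s)
  }
  diagnostics <- validate_model(m)

  note("reduction")
  red <- detect_constant_states(m)
  mw <- red$reduced_model

  if (length(mw$states) == 0) {
    # fully frozen model: outputs are constants, nothing is recoverable from
    # input-output dynamics
    statuses <- tibble::tibble(parameter = m$parameters,
                               status = "unidentifiable", max_solutions = Inf)
    par_tbl <- tibble::tibble(name = m$user_parameters,
                              canonical = m$parameters,
                              status = statuses$status,
                              max_solutions = statuses$max_solutions)
    return(structure(list(
      model = m, model_copy_paste = render_copy_paste(m),
      name_map = m$name_map, diagnostics = diagnostics,
      reducible = TRUE, constant_states = red$constant_states,
      model_status = "unidentifiable", parameters = par_tbl,
      combos = tibble::tibble(expression = character(0),
                              max_solutions = numeric(0),
                              value = character(0), provenance = character(0)),
      rank = NA_integer_, seed = seed, pstar = NULL, orderings_used = 0L,
      n_groebner = 0L, stages = c(stages, "frozen model"),
      wall_time = as.numeric(difftime(Sys.time(), t0, units = "secs")),
      aborted = FALSE
    ), class = "icb_report"))
  }

  note("io-equations")
  io <- io_equations(mw, max_steps = gb_steps, max_seconds = gb_seconds)
  note(paste0("io-equations complete (derivative order ", io$K, ")"))
  cm <- incorporate_initial_conditions(mw, io)

  P <- length(m$parameters)
  statuses <- NULL
  combos <- NULL
  pstar <- NULL
  verdict <- NULL
  n_gb <- 0L

  if (length(cm$coefficients) == 0) {
    # outputs carry no parameter information (e.g. fully reduced dynamics)
    statuses <- tibble::tibble(parameter = m$parameters,
                               status = "unidentifiable", max_solutions = Inf)
    verdict <- "unidentifiable"
    note("coefficient map empty: all parameters unidentifiable")
  } else {
    note("parameter point")
    point <- sample_parameter_point(cm, seed = seed, prime = prime)
    pstar <- point$values
    note("fiber system")
    fs <- fiber_system(cm, point, prime = prime)
    # one basis of the full fiber system decides finite-to-one quickly
    note("fiber groebner basis")
    fiber_dim0 <- tryCatch({
      nvv <- P + 1L
      eqs <- lapply(fs$eqs, poly_remap, map = seq_len(P), nv_new = nvv)
      satp <- saturation_poly(fs, NULL, nvv, P + 1L)
      if (!is.null(satp)) eqs <- c(eqs, list(satp))
      gb <- eng_groebner_p(eqs, list(seq_len(nvv)), prime, gb_steps, gb_seconds)
      n_gb <- n_gb + 1L
      leads <- t(vapply(gb, function(g) g$exp[poly_term_order(g$exp)[1], ],
                        numeric(nvv)))
      all(vapply(seq_len(nvv), function(v) {
        any(apply(leads, 1, function(e) e[v] > 0 && sum(e[-v]) == 0))
      }, TRUE))
    }, error = function(e) NA)
    note(paste0("fiber zero-dimensional: ", fiber_dim0))

    note("classify parameters")
    statuses <- classify_parameters(fs, max_steps = gb_steps,
                                    max_seconds = gb_seconds)
    n_gb <- n_gb + P
    verdict <- classify_model(statuses)

    if (verdict == "unidentifiable") {
      note("combination search")
      sched <- generate_orderings(P)
      if (!is.null(orderings)) sched <- sched[seq_len(min(orderings, nrow(sched))), , drop = FALSE]
      cands <- harvest_candidates(fs, sched, max_steps = gb_steps,
                                  max_seconds = min(gb_seconds, 60),
                                  progress = progress)
      n_gb <- n_gb + nrow(sched)
      combos <- select_independent_set(cands, fs)
    }
  }

  # combos table in user names
  nm_user <- m$user_parameters
  if (!is.null(combos)) {
    combo_tbl <- tibble::tibble(
      expression = vapply(combos$combos, combo_string, "", names = nm_user),
      max_solutions = combos$max_solutions,
      value = combos$values,
      provenance = vapply(combos$combos, `[[`, "", "provenance"))
    rank <- combos$rank
  } else if (!is.null(verdict) && verdict %in% c("globally identifiable", "locally identifiable")) {
    combo_tbl <- tibble::tibble(
      expression = nm_user,
      max_solutions = statuses$max_solutions[match(m$parameters, statuses$parameter)],
      value = if (!is.null(pstar)) as.character(pstar) else NA_character_,
      provenance = "parameter")
    rank <- P
  } else {
    combo_tbl <- tibble::tibble(expression = character(0),
                                max_solutions = numeric(0),
                                value = character(0), provenance = character(0))
    rank <- NA_integer_
  }

  par_tbl <- tibble::tibble(
    name = nm_user,
    canonical = m$parameters,
    status = statuses$status[match(m$parameters, statuses$parameter)],
    max_solutions = statuses$max_solutions[match(m$parameters, statuses$parameter)])

  structure(list(
    model = m,
    model_copy_paste = render_copy_paste(m),
    name_map = m$name_map,
    diagnostics = diagnostics,
    reducible = red$reducible,
    constant_states = red$constant_states,
    model_status = verdict,
    parameters = par_tbl,
    combos = combo_tbl,
    rank = rank,
    seed = seed,
    pstar = if (!is.null(pstar)) setNames(as.integer(pstar), nm_user) else NULL,
    orderings_used = if (!is.null(combos)) 3L * P else 0L,
    n_groebner = n_gb,
    stages = stages,
    wall_time = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    aborted = any(statuses$status == "undetermined")
  ), class = "icb_report")
}

#' Format an identifiability report
#'
#' @param r An `icb_report`.
#' @param mode `"text"` for a human-readable report, `"json"` for the stable
#'   machine form (schema version field included).
#' @return A string.
#' @export
format_report <- function(r, mode = c("text", "json")) {
  mode <- match.arg(mode)
  if (mode == "json") {
    obj <- list(
      schema = "identicombo-report/1",
      model = r$model_copy_paste,
      parameter_mapping = as.data.frame(r$name_map),
      reducible = r$reducible,
      constant_states = r$constant_states,
      model_status = r$model_status,
      parameters = as.data.frame(r$parameters[, c("name", "status", "max_solutions")]),
      combos = as.data.frame(r$combos[, c("expression", "max_solutions", "provenance")]),
      rank = r$rank,
      seed = r$seed,
      pstar = as.list(r$pstar),
      orderings_used = r$orderings_used,
      aborted = r$aborted
    )
    return(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null"))
  }
  fmt_sol <- function(k) ifelse(is.finite(k), format(k), "infinite")
  lines <- c(
    "Structural identifiability analysis",
    "===================================",
    paste0("Model: ", r$model_copy_paste),
    if (r$reducible) paste0("Reducible: constant trajectories for ",
                            paste(r$constant_states, collapse = ", ")),
    paste0("Verdict: ", r$model_status),
    "",
    "Parameters:",
    sprintf("  %-12s %-16s %s", r$parameters$name, r$parameters$status,
            paste0("solutions: ", fmt_sol(r$parameters$max_solutions))),
    "",
    if (nrow(r$combos)) c(
      if (identical(r$combos$provenance[1], "parameter"))
        "Identifiable quantities (the parameters themselves):"
      else "Identifiable parameter combinations:",
      sprintf("  %-40s %s", r$combos$expression,
              paste0("solutions: ", fmt_sol(r$combos$max_solutions)))),
    "",
    paste0("seed: ", r$seed,
           if (!is.null(r$pstar)) paste0("  p* = (", paste(r$pstar, collapse = ", "), ")"),
           "  wall: ", sprintf("%.1fs", r$wall_time))
  )
  paste(unlist(lines), collapse = "\n")
}

#' @export
print.icb_report <- function(x, ...) {
  cat(format_report(x, "text"), "\n")
  invisible(x)
}

#' Tidy a report into a per-parameter tibble
#'
#' @param x An `icb_report`.
#' @param ... Unused.
#' @export
tidy.icb_report <- function(x, ...) x$parameters

#' One-row model-level summary of a report
#'
#' @param x An `icb_report`.
#' @param ... Unused.
#' @export
glance.icb_report <- function(x, ...) {
  tibble::tibble(
    model_status = x$model_status,
    n_parameters = nrow(x$parameters),
    n_unique = sum(x$parameters$status == "unique"),
    n_local = sum(x$parameters$status == "local"),
    n_unidentifiable = sum(x$parameters$status == "unidentifiable"),
    reducible = x$reducible,
    rank = x$rank,
    seed = x$seed,
    wall_time = x$wall_time)
}

#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @export
glance <- function(x, ...) UseMethod("glance")
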