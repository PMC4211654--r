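# Identifiable parameter combinations for unidentifiable models: additional
# lexicographic Groebner bases of the fiber system are computed under a
# schedule of 3P parameter orderings (P cyclic shifts of the identity, of the
# reordered vector, and of the twice-reordered vector). Basis elements free
# of the saturation variable are mined for "decoupled" forms -- a rational
# multiple of a polynomial plus a constant, binomials giving monomial ratios,
# and quadratics in their leading variable giving linear cores -- and the
# simplest algebraically independent subset of the harvested candidates (plus
# the original coefficients) is selected greedily under a Jacobian rank test.

reorder_once <- function(v) {
  P <- length(v)
  if (P == 1) return(v)
  if (P %% 2 == 0) c(v[seq(1, P - 1, by = 2)], v[seq(2, P, by = 2)])
  else c(v[seq(1, P, by = 2)], v[seq(2, P - 1, by = 2)])
}

shifts_of <- function(v) {
  P <- length(v)
  t(vapply(seq_len(P) - 1L,
           function(s) if (s == 0) v else c(v[-seq_len(s)], v[seq_len(s)]),
           numeric(P)))
}

#' Generate the 3P-ordering schedule
#'
#' Block 1 is the P cyclic shifts of (p1, ..., pP); blocks 2 and 3 are the P
#' cyclic shifts of the reordered vector, the reordering (interleaving odd
#' positions before even ones) applied once and then twice. Each ordering is
#' used as a lexicographic parameter ranking, which eliminates its first
#' parameters earliest and its last parameter not at all.
#'
#' @param P Number of parameters.
#' @return An integer matrix with 3P rows, each a permutation of 1..P.
#' @export
generate_orderings <- function(P) {
  stopifnot(P >= 1)
  v <- seq_len(P)
  r1 <- reorder_once(v)
  r2 <- reorder_once(r1)
  out <- rbind(shifts_of(v), shifts_of(r1), shifts_of(r2))
  storage.mode(out) <- "integer"
  out
}

gcd_vec <- function(v) {
  g <- 0
  for (x in v) { g <- num_gcd(g, x); if (g == 1) break }
  g
}

num_gcd <- function(a, b) {
  a <- abs(a); b <- abs(b)
  if (a > 2^49 || b > 2^49) return(1)   # beyond exact double arithmetic
  while (b > 0.5) { t <- a %% b; a <- b; b <- t }
  a
}

# normalize a small-integer-coefficient polynomial given as exp matrix +
# numeric coeffs: strip monomial gcd, divide content, positive lead under
# descending lex
normalize_candidate <- function(exp, co, strip_monomial = TRUE) {
  keep <- abs(co) > 0.5
  exp <- exp[keep, , drop = FALSE]; co <- co[keep]
  if (nrow(exp) == 0) return(NULL)
  if (strip_monomial) {
    mins <- apply(exp, 2, min)
    if (any(mins > 0)) exp <- sweep(exp, 2, mins)
  }
  g <- 0
  for (v in co) { g <- num_gcd(g, v); if (g == 1) break }
  if (g > 1) co <- co / g
  ord <- poly_term_order(exp)
  exp <- exp[ord, , drop = FALSE]; co <- co[ord]
  if (co[1] < 0) co <- -co
  list(exp = exp, c = as.character(co))
}

cand_key <- function(cand) {
  if (is.null(cand$den)) return(paste0("P:", poly_key(cand$num)))
  k1 <- poly_key(cand$num); k2 <- poly_key(cand$den)
  if (k1 < k2) paste0("R:", k1, "|", k2) else paste0("R:", k2, "|", k1)
}

cand_score <- function(cand) {
  deg <- function(p) if (poly_is_zero(p)) 0 else max(rowSums(p$exp))
  nt <- nrow(cand$num$exp) + if (is.null(cand$den)) 0 else nrow(cand$den$exp)
  vars <- union(poly_vars_used(cand$num),
                if (is.null(cand$den)) integer(0) else poly_vars_used(cand$den))
  d <- max(deg(cand$num), if (is.null(cand$den)) 0 else deg(cand$den))
  maxco <- max(abs(suppressWarnings(vapply(
    c(cand$num$c, if (is.null(cand$den)) character(0) else cand$den$c),
    rat_to_num, 0))), 1)
  c(d, nt, length(vars), maxco)
}

make_candidate <- function(num, den = NULL, provenance = "") {
  cand <- list(num = num, den = den, provenance = provenance)
  cand$key <- cand_key(cand)
  cand$score <- cand_score(cand)
  cand
}

# mine one reconstructed z-free basis element for candidate combinations
mine_element <- function(exp, co, P, provenance, ordering = seq_len(P)) {
  cands <- list()
  nc <- normalize_candidate(exp, co)
  if (is.null(nc) || nrow(nc$exp) == 0) return(cands)
  exp <- nc$exp; co <- as.numeric(nc$c)
  td <- rowSums(exp)
  is_const <- td == 0
  push <- function(cand) cands[[length(cands) + 1L]] <<- cand
  # decoupled form a*q(p) + b: the nonconstant part is constant on the fiber
  if (any(!is_const)) {
    nc2 <- normalize_candidate(exp[!is_const, , drop = FALSE], co[!is_const],
                               strip_monomial = FALSE)
    if (!is.null(nc2) && any(rowSums(nc2$exp) > 0))
      push(make_candidate(list(exp = nc2$exp, c = nc2$c), NULL, provenance))
  }
  # element univariate in a single monomial m (all exponent rows integer
  # multiples of a primitive direction): m itself takes finitely many values
  nc_rows <- which(!is_const)
  if (length(nc_rows) >= 1) {
    sub <- exp[nc_rows, , drop = FALSE]
    base <- sub[which.min(rowSums(sub)), ]
    prim <- base / max(1, gcd_vec(base))
    lam <- rowSums(sub) / sum(prim)
    mono_ok <- all(lam == round(lam)) &&
      all(sub == outer(lam, prim)) && max(lam) >= 2
    if (mono_ok && sum(prim) >= 1)
      push(make_candidate(list(exp = matrix(as.integer(prim), 1), c = "1"),
                          NULL, provenance))
  }
  # binomial with no constant: the monomial ratio is fixed on the fiber
  if (sum(!is_const) == 2 && !any(is_const)) {
    rows <- which(!is_const)
    o <- poly_term_order(exp[rows, , drop = FALSE])
    m1 <- list(exp = exp[rows[o[1]], , drop = FALSE] * 1L, c = "1")
    m2 <- list(exp = exp[rows[o[2]], , drop = FALSE] * 1L, c = "1")
    push(make_candidate(m1, m2, provenance))
  }
  # quadratic in its leading variable with constant leading coefficient:
  # emit the linear core 2*A*v + B, whose square is fixed on the fiber
  for (v in ordering) {
    dv <- exp[, v]
    if (max(dv) != 2) next
    sq <- which(dv == 2)
    if (length(sq) != 1 || sum(exp[sq, ]) != 2) next
    A <- co[sq]
    lin <- which(dv == 1)
    lexp <- exp[c(sq, lin), , drop = FALSE]
    lexp[1, ] <- 0L; lexp[1, v] <- 1L
    if (length(lin)) lexp[-1, v] <- 0L
    lco <- c(2 * A, co[lin])
    nc3 <- normalize_candidate(lexp, lco, strip_monomial = FALSE)
    if (!is.null(nc3)) {
      tdd <- rowSums(nc3$exp)
      if (any(tdd > 0)) {
        nc4 <- normalize_candidate(nc3$exp[tdd > 0, , drop = FALSE],
                                   as.numeric(nc3$c)[tdd > 0], strip_monomial = FALSE)
        if (!is.null(nc4))
          push(make_candidate(list(exp = nc4$exp, c = nc4$c), NULL, provenance))
      }
    }
    break
  }
  cands
}

#' Harvest combination candidates from scheduled Groebner bases
#'
#' For each parameter ordering in the schedule, computes a lexicographic
#' Groebner basis of the fiber system modulo a prime (saturation variable
#' eliminated first), reconstructs rational coefficients, and extracts
#' candidate identifiable combinations from every basis element. The original
#' input-output coefficients are added to the candidate pool.
#'
#' @param fs An `icb_fiber`.
#' @param schedule Ordering matrix from [generate_orderings()].
#' @param max_steps,max_seconds Budget per ordering; orderings whose basis
#'   exceeds it are skipped.
#' @param progress Print progress lines.
#' @return A list of deduplicated candidates sorted by simplicity.
#' @export
harvest_candidates <- function(fs, schedule = NULL, max_steps = 5e6,
                               max_seconds = 60, progress = FALSE) {
  stopifnot(inherits(fs, "icb_fiber"))
  P <- length(fs$pstar)
  if (is.null(schedule)) schedule <- generate_orderings(P)
  nv <- P + 1L
  z <- P + 1L
  eqs <- lapply(fs$eqs, poly_remap, map = seq_len(P), nv_new = nv)
  satp <- saturation_poly(fs, NULL, nv, z)
  if (!is.null(satp)) eqs <- c(eqs, list(satp))
  seen <- character(0)
  out <- list()
  add <- function(cand) {
    if (is.null(cand)) return()
    if (cand$key %in% seen) return()
    seen <<- c(seen, cand$key)
    out[[length(out) + 1L]] <<- cand
  }
  # the normalized coefficients themselves are identifiable combinations
  for (co in fs$cm$coefficients) {
    num <- poly_canon(co$num); den <- poly_canon(co$den)
    if (length(poly_vars_used(den)) == 0)
      add(make_candidate(num, NULL, "coefficient"))
    else add(make_candidate(num, den, "coefficient"))
  }
  skipped <- 0L
  for (oi in seq_len(nrow(schedule))) {
    ordn <- schedule[oi, ]
    blocks <- c(list(z), as.list(ordn))
    gb <- tryCatch(
      eng_groebner_p(eqs, blocks, harvest_prime(), max_steps, max_seconds),
      error = function(e) NULL)
    if (is.null(gb)) { skipped <- skipped + 1L; next }
    for (g in gb) {
      if (any(g$exp[, z] != 0L)) next
      if (!all(g$ok)) next                   # coefficient reconstruction failed
      co <- g$rnum / g$rden
      exp <- g$exp[, seq_len(P), drop = FALSE]
      den_lcm <- 1
      for (dd in g$rden) den_lcm <- den_lcm * dd / num_gcd(den_lcm, dd)
      co <- co * den_lcm
      for (cand in mine_element(exp, co, P, paste0("ordering ", oi), ordn)) add(cand)
    }
    if (progress) message("ordering ", oi, "/", nrow(schedule), ": ",
                          length(out), " candidates")
  }
  attr(out, "skipped_orderings") <- skipped
  ord <- order(vapply(out, function(c) c$score[1], 0),
               vapply(out, function(c) c$score[2], 0),
               vapply(out, function(c) c$score[3], 0),
               vapply(out, function(c) c$score[4], 0),
               vapply(out, function(c) c$key, ""))
  out[ord]
}

cand_rf <- function(cand, P) {
  den <- if (is.null(cand$den)) poly_const(P, "1") else cand$den
  list(num = cand$num, den = den)
}

#' Select the simplest algebraically independent combination set
#'
#' Greedily walks the candidates in simplicity order (total degree, number of
#' terms, number of parameters involved, canonical string) and keeps those
#' that increase the rank of the Jacobian of the selected set, stopping at
#' the generic rank of the coefficient map. Each selected combination then
#' receives its maximum solution count on the fiber.
#'
#' @param cands Candidates from [harvest_candidates()].
#' @param fs An `icb_fiber`.
#' @param rank Target rank; defaults to the generic Jacobian rank of the
#'   coefficient map.
#' @param count_budget Basis budget per solution count.
#' @return An object of class `icb_comboset`.
#' @export
select_independent_set <- function(cands, fs, rank = NULL,
                                   count_budget = c(5e6, 120)) {
  P <- length(fs$pstar)
  rfs <- coefficient_rfs(fs$cm)
  if (is.null(rank)) rank <- generic_rank(rfs, P, fs$prime, fs$seed)
  # independence is judged at p* itself: candidates that degenerate on the
  # fiber (e.g. linear relations that vanish there) are collinear at p* with
  # the combinations they duplicate, and are correctly rejected
  pt <- as.numeric(fs$pstar)
  selected <- list()
  counts <- numeric(0)
  J <- NULL
  cur_rank <- 0L
  for (cand in cands) {
    if (cur_rank >= rank) break
    row <- tryCatch(eng_jacobian_p(list(cand_rf(cand, P)), pt, fs$prime),
                    error = function(e) NULL)
    if (is.null(row)) next
    J2 <- rbind(J, row)
    rk <- eng_rank_p(J2, fs$prime)
    if (rk > cur_rank) {
      # accept only candidates that take finitely many values on the fiber
      k <- tryCatch(
        count_solutions_for(fs, cand_rf(cand, P),
                            max_steps = count_budget[1],
                            max_seconds = count_budget[2]),
        error = function(e) Inf)
      if (!is.finite(k)) next
      J <- J2
      cur_rank <- rk
      selected[[length(selected) + 1L]] <- cand
      counts <- c(counts, k)
    }
  }
  complete <- cur_rank >= rank
  if (!complete)
    warning("found ", cur_rank, " independent combinations but the ",
            "coefficient map has rank ", rank,
            "; the reported set may be incomplete", call. = FALSE)
  values <- vapply(selected, function(cand) {
    v <- rf_eval(cand_rf(cand, P), fs$pstar)
    if (is.null(v)) NA_character_ else v
  }, "")
  structure(list(combos = selected, max_solutions = counts, values = values,
                 rank = rank, achieved_rank = cur_rank, fs = fs),
            class = "icb_comboset")
}

combo_string <- function(cand, names) {
  if (is.null(cand$den)) return(poly_to_string(cand$num, names))
  num <- poly_to_string(cand$num, names)
  den <- poly_to_string(cand$den, names)
  if (nrow(cand$num$exp) == 1) paste0(num, "/", if (nrow(cand$den$exp) == 1) den else paste0("(", den, ")"))
  else paste0("(", num, ")/(", den, ")")
}

#' @export
print.icb_comboset <- function(x, ...) {
  nm <- x$fs$cm$model$user_parameters
  cat("Identifiable parameter combinations (rank ", x$rank, "):\n", sep = "")
  for (i in seq_along(x$combos)) {
    cat("  ", combo_string(x$combos[[i]], nm), "  [",
        if (is.finite(x$max_solutions[i])) paste0(x$max_solutions[i], " solution",
                                                  if (x$max_solutions[i] > 1) "s" else "")
        else "infinite", "]\n", sep = "")
  }
  invisible(x)
}
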