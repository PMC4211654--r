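# Internal helpers around the C++ kernel's serialized polynomial form:
# a polynomial is list(exp = integer matrix (terms x vars), c = character
# coefficients "n" or "n/d"); a rational function is list(num, den).

poly_zero <- function(nv) list(exp = matrix(integer(0), 0, nv), c = character(0))

poly_const <- function(nv, c) {
  if (identical(c, "0")) return(poly_zero(nv))
  list(exp = matrix(0L, 1, nv), c = as.character(c))
}

poly_var <- function(nv, i, pow = 1L) {
  e <- matrix(0L, 1, nv)
  e[1, i] <- as.integer(pow)
  list(exp = e, c = "1")
}

poly_nv <- function(p) ncol(p$exp)
poly_is_zero <- function(p) nrow(p$exp) == 0L

poly_vars_used <- function(p) {
  if (poly_is_zero(p)) return(integer(0))
  which(colSums(p$exp) > 0L)
}

# embed a polynomial into a larger variable space; map[i] = new column of old var i
poly_remap <- function(p, map, nv_new) {
  e <- matrix(0L, nrow(p$exp), nv_new)
  if (nrow(p$exp)) e[, map] <- p$exp
  list(exp = e, c = p$c)
}

rf_remap <- function(f, map, nv_new) {
  list(num = poly_remap(f$num, map, nv_new), den = poly_remap(f$den, map, nv_new))
}

poly_add <- function(a, b) eng_poly_op("+", a, b)
poly_sub <- function(a, b) eng_poly_op("-", a, b)
poly_mul <- function(a, b) eng_poly_op("*", a, b)

poly_prod <- function(lst) {
  stopifnot(length(lst) > 0)
  out <- lst[[1]]
  for (p in lst[-1]) out <- poly_mul(out, p)
  out
}

# canonical primitive integer form; canonical key for deduplication
poly_canon <- function(p) eng_poly_canon(p)

poly_key <- function(p) {
  if (poly_is_zero(p)) return("0")
  paste(apply(p$exp, 1, paste, collapse = ","), p$c, sep = ":", collapse = ";")
}

# exact evaluation of a polynomial at a full rational point
poly_eval <- function(p, vals) {
  nv <- poly_nv(p)
  if (poly_is_zero(p)) return("0")
  v <- eng_poly_eval_partial(p, seq_len(nv), as.character(vals))
  if (poly_is_zero(v)) "0" else v$c[[1]]
}

rf_eval <- function(f, vals) {
  r <- eng_rf_eval(f, as.character(vals))
  if (!r$ok) return(NULL)
  r$value
}

rat_to_num <- function(s) {
  parts <- strsplit(s, "/", fixed = TRUE)[[1]]
  if (length(parts) == 1) as.numeric(parts) else as.numeric(parts[1]) / as.numeric(parts[2])
}

# order of terms: descending lexicographic on exponent rows
poly_term_order <- function(exp) {
  if (nrow(exp) <= 1) return(seq_len(nrow(exp)))
  do.call(order, c(lapply(seq_len(ncol(exp)), function(j) -exp[, j])))
}

format_coef <- function(c, first, product_follows) {
  neg <- startsWith(c, "-")
  mag <- sub("^-", "", c)
  op <- if (first) (if (neg) "-" else "") else (if (neg) " - " else " + ")
  if (mag == "1" && product_follows) return(op)
  if (grepl("/", mag) && product_follows) mag <- paste0("(", mag, ")")
  paste0(op, mag, if (product_follows) "*" else "")
}

poly_to_string <- function(p, names) {
  if (poly_is_zero(p)) return("0")
  ord <- poly_term_order(p$exp)
  out <- ""
  for (k in seq_along(ord)) {
    i <- ord[k]
    e <- p$exp[i, ]
    mono <- character(0)
    for (j in which(e > 0)) {
      mono <- c(mono, if (e[j] == 1) names[j] else paste0(names[j], "^", e[j]))
    }
    mono_str <- paste(mono, collapse = "*")
    out <- paste0(out, format_coef(p$c[i], k == 1, length(mono) > 0), mono_str)
  }
  out
}

rf_to_string <- function(f, names) {
  num <- poly_to_string(f$num, names)
  if (nrow(f$den$exp) == 1 && all(f$den$exp == 0) && f$den$c[[1]] == "1") return(num)
  den <- poly_to_string(f$den, names)
  paste0("(", num, ")/(", den, ")")
}

# do two integer-canonical polynomials differ only by a rational scalar?
poly_proportional <- function(a, b) {
  ca <- poly_canon(a); cb <- poly_canon(b)
  if (poly_is_zero(ca) || poly_is_zero(cb)) return(poly_is_zero(ca) && poly_is_zero(cb))
  identical(poly_key(ca), poly_key(cb))
}

default_prime <- function() 2147483647

# wide prime (largest below 2^53, exactly representable as a double) used for
# combination harvesting, where reconstructed coefficients can be large
harvest_prime <- function() 9007199254740881
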