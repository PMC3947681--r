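# Truncated bivariate-structure polynomials: polynomials in the event
# transform arguments z_1..z_E whose coefficients are polynomials in time.
# Terms are stored in a named list keyed by the z multi-index; each value
# is the dense vector of t-coefficients (constant term first).  The
# truncation used by the Picard scheme is a Maclaurin truncation in t
# only; because every term of total z-degree p has leading time order
# t^p, capping the total z-degree at the t-cap loses nothing.

tp_key <- function(expo) paste(expo, collapse = ",")
tp_expo <- function(key) as.integer(strsplit(key, ",", fixed = TRUE)[[1]])

tp_zero <- function(E, tcap) {
  structure(list(E = E, tcap = tcap, terms = list()), class = "tpoly")
}

tp_const <- function(E, tcap, value = 1) {
  p <- tp_zero(E, tcap)
  if (value != 0) {
    co <- numeric(tcap + 1); co[1] <- value
    p$terms[[tp_key(integer(E))]] <- co
  }
  p
}

tp_is_zero_coef <- function(co) all(co == 0)

tp_add <- function(a, b) {
  stopifnot(a$E == b$E, a$tcap == b$tcap)
  out <- a
  for (k in names(b$terms)) {
    co <- if (!is.null(out$terms[[k]])) out$terms[[k]] + b$terms[[k]]
          else b$terms[[k]]
    if (tp_is_zero_coef(co)) out$terms[[k]] <- NULL else out$terms[[k]] <- co
  }
  out
}

tp_scale <- function(a, s) {
  if (s == 0) return(tp_zero(a$E, a$tcap))
  a$terms <- lapply(a$terms, function(co) co * s)
  a
}

# multiply two t-coefficient vectors, truncating at tcap
tcoef_mul <- function(x, y, tcap) {
  out <- numeric(tcap + 1)
  for (i in seq_along(x)) {
    if (x[i] == 0) next
    jmax <- tcap + 2 - i
    if (jmax < 1) break
    idx <- seq_len(min(length(y), jmax))
    out[i + idx - 1] <- out[i + idx - 1] + x[i] * y[idx]
  }
  out
}

tp_mul <- function(a, b) {
  stopifnot(a$E == b$E, a$tcap == b$tcap)
  out <- tp_zero(a$E, a$tcap)
  zcap <- a$tcap                        # z total degree beyond tcap is O(t^{tcap+1})
  for (ka in names(a$terms)) {
    ea <- tp_expo(ka)
    for (kb in names(b$terms)) {
      eb <- tp_expo(kb)
      ee <- ea + eb
      if (sum(ee) > zcap) next
      co <- tcoef_mul(a$terms[[ka]], b$terms[[kb]], a$tcap)
      if (tp_is_zero_coef(co)) next
      k <- tp_key(ee)
      prev <- out$terms[[k]]
      out$terms[[k]] <- if (is.null(prev)) co else prev + co
    }
  }
  out
}

# reciprocal of a polynomial with unit constant term: geometric series in
# u = 1 - a, which has positive leading t-order, so the series terminates
# at the t-cap.
tp_inv <- function(a) {
  one <- tp_const(a$E, a$tcap)
  u <- tp_add(one, tp_scale(a, -1))     # 1 - a
  out <- one
  pw <- one
  for (k in seq_len(a$tcap)) {
    pw <- tp_mul(pw, u)
    if (length(pw$terms) == 0) break
    out <- tp_add(out, pw)
  }
  out
}

tp_pow_int <- function(a, d) {
  if (d == 0) return(tp_const(a$E, a$tcap))
  if (d < 0) { a <- tp_inv(a); d <- -d }
  out <- a
  for (i in seq_len(d - 1)) out <- tp_mul(out, a)
  out
}

# Maclaurin truncation [.]_m in t: drop coefficients of t^{m+1} and higher
tp_trunc_t <- function(a, m) {
  a$terms <- lapply(a$terms, function(co) {
    if (m + 2 <= length(co)) co[(m + 2):length(co)] <- 0
    co
  })
  a$terms <- Filter(Negate(tp_is_zero_coef), a$terms)
  a
}

# definite t-integration from 0: shifts coefficients up one t-order
tp_integrate_t <- function(a) {
  a$terms <- lapply(a$terms, function(co) {
    out <- numeric(a$tcap + 1)
    n <- min(length(co) - 1, a$tcap - 1)
    idx <- 0:n
    out[idx + 2] <- co[idx + 1] / (idx + 1)
    out
  })
  a$terms <- Filter(Negate(tp_is_zero_coef), a$terms)
  a
}

tp_eval <- function(a, z, t) {
  z <- as.complex(z)
  acc <- 0 + 0i
  tp <- t^(0:a$tcap)
  for (k in names(a$terms)) {
    e <- tp_expo(k)
    acc <- acc + prod(z^e) * sum(a$terms[[k]] * tp)
  }
  acc
}

# evaluate t-coefficients at a time, returning named numeric vector over
# z multi-indices
tp_coeffs_at <- function(a, t) {
  tp <- t^(0:a$tcap)
  vapply(a$terms, function(co) sum(co * tp), numeric(1))
}

#' @export
print.tpoly <- function(x, ...) {
  cat("<tpoly> ", length(x$terms), " z-term(s), t-degree cap ", x$tcap,
      "\n", sep = "")
  ord <- names(x$terms)[order(vapply(names(x$terms),
                                     function(k) sum(tp_expo(k)), numeric(1)))]
  for (k in head(ord, 12)) {
    cat("  z^(", k, "): t-coeffs ", paste(signif(x$terms[[k]], 4),
                                          collapse = " "), "\n", sep = "")
  }
  if (length(ord) > 12) cat("  ...\n")
  invisible(x)
}
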