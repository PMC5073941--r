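# Internal sparse polynomial algebra over species counts.
# A polynomial is list(coef = numeric, expo = integer matrix terms x n);
# used only during symbolic derivation of moment systems, so plain R is fast
# enough (n <= 5, order <= 6 here).

poly_zero <- function(n) list(coef = numeric(0),
                              expo = matrix(integer(0), 0L, n))

poly_const <- function(n, c = 1) list(coef = as.numeric(c),
                                      expo = matrix(0L, 1L, n))

poly_mono <- function(expo, c = 1) {
  list(coef = as.numeric(c), expo = matrix(as.integer(expo), 1L))
}

# merge duplicate exponent rows, drop exact zeros
poly_norm <- function(p) {
  if (!length(p$coef)) return(p)
  key <- apply(p$expo, 1L, paste, collapse = ",")
  agg <- rowsum(p$coef, key, reorder = FALSE)
  keep <- match(rownames(agg), key)
  coef <- as.numeric(agg)
  nz <- coef != 0
  list(coef = coef[nz], expo = p$expo[keep, , drop = FALSE][nz, , drop = FALSE])
}

poly_add <- function(p, q) {
  poly_norm(list(coef = c(p$coef, q$coef), expo = rbind(p$expo, q$expo)))
}

poly_scale <- function(p, s) { p$coef <- p$coef * s; p }

poly_mul <- function(p, q) {
  np <- length(p$coef); nq <- length(q$coef)
  if (!np || !nq) return(poly_zero(ncol(p$expo)))
  coef <- as.numeric(outer(q$coef, p$coef))          # nq*np, p-major
  expo <- p$expo[rep(seq_len(np), each = nq), , drop = FALSE] +
    q$expo[rep.int(seq_len(nq), np), , drop = FALSE]
  poly_norm(list(coef = coef, expo = expo))
}

# (x_i + v)^a as a univariate polynomial embedded in n dimensions
poly_shift_uni <- function(i, v, a, n) {
  s <- 0:a
  coef <- choose(a, s) * v^(a - s)
  expo <- matrix(0L, length(s), n)
  expo[, i] <- as.integer(s)
  poly_norm(list(coef = coef, expo = expo))
}

# (x + v)^alpha = prod_i (x_i + v_i)^{alpha_i}
poly_shift_pow <- function(alpha, v, n) {
  p <- poly_const(n)
  for (i in seq_len(n)) {
    if (alpha[i] > 0)
      p <- poly_mul(p, poly_shift_uni(i, v[i], alpha[i], n))
  }
  p
}

# x^alpha
poly_pow <- function(alpha) poly_mono(alpha)

# evaluate at a numeric point
poly_eval <- function(p, x) {
  if (!length(p$coef)) return(0)
  sum(p$coef * apply(p$expo, 1L, function(e) prod(x^e)))
}

# substitute fixed numeric values for a subset of variables, returning a
# polynomial over the remaining variables
poly_substitute <- function(p, fixed_idx, fixed_val) {
  keep <- setdiff(seq_len(ncol(p$expo)), fixed_idx)
  if (!length(p$coef))
    return(list(coef = numeric(0),
                expo = matrix(integer(0), 0L, length(keep))))
  fac <- apply(p$expo[, fixed_idx, drop = FALSE], 1L,
               function(e) prod(fixed_val^e))
  poly_norm(list(coef = p$coef * fac,
                 expo = p$expo[, keep, drop = FALSE]))
}
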