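# Small fixture networks built in code, plus an independent R-level
# evaluator for compiled moment systems (used to check the symbolic
# derivation against hand formulas without going through the C++ path).

fix_birth <- function(c_val = NA) {
  parse_network(c("[species]", "X 0 high",
                  "[reactions]", "0 -> X : c",
                  "[parameters]",
                  if (is.na(c_val)) "c 0 10" else paste("c", c_val)))
}

fix_death <- function(d_val = NA, x0 = 1) {
  parse_network(c("[species]", paste("X", x0, "high"),
                  "[reactions]", "X -> 0 : d",
                  "[parameters]",
                  if (is.na(d_val)) "d 0 1" else paste("d", d_val)))
}

fix_birth_death <- function() {
  parse_network(c("[species]", "X 0 high",
                  "[reactions]", "0 -> X : c", "X -> 0 : d",
                  "[parameters]", "c 0 10", "d 0 1"))
}

# bimolecular test model: birth plus dimerization decay
fix_dimer <- function() {
  parse_network(c("[species]", "X 0 high",
                  "[reactions]", "0 -> X : c1", "2 X -> 0 : c2",
                  "[parameters]", "c1 0 10", "c2 0 1"))
}

theta_gene <- c(a = 0.3, b = 0.2, c = 0.4)
theta_switch <- c(p1 = 1, p2 = 1, d1 = 0.02, d2 = 0.02,
                  b1 = 0.05, b2 = 0.05, u1 = 0.05, u2 = 0.05)

# evaluate d/dt of a (possibly pre-closure) moment system at a given state
# vector y; for pre-closure systems y must cover main + overhang indices
eval_rhs <- function(system, theta, y) {
  terms <- system$terms
  vals <- theta[system$par_names]
  neq <- if (inherits(system, "hybrid_moment_system")) system$n_equations
         else nrow(system$indices)
  dy <- numeric(neq)
  for (i in seq_along(terms$eq)) {
    v <- terms$coeff[i] * vals[[terms$par[i]]]
    f <- terms$factors[[i]]
    if (nrow(f)) v <- v * prod(y[f[, 1]]^f[, 2])
    dy[terms$eq[i]] <- dy[terms$eq[i]] + v
  }
  dy
}

# build a snapshot_dataset directly from matrices (test doubles)
make_dataset <- function(samples_list, times, species) {
  samples <- lapply(samples_list, function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "integer"
    colnames(m) <- species
    m
  })
  names(samples) <- as.character(times)
  structure(list(times = as.numeric(times), observed_species = species,
                 samples = samples, seed = NA_integer_,
                 provenance = "synthetic test double"),
            class = "snapshot_dataset")
}

# finite-state CME propagator (dense RK4) for tiny one-species systems:
# returns function p(t) over states 0..smax starting from a point mass
cme_propagate <- function(network, theta, smax, x0, t_end, nstep = 2000) {
  states <- 0:smax
  Q <- matrix(0, smax + 1, smax + 1)
  for (s in states) {
    for (j in seq_along(network$reactions)) {
      a <- propensity(network, j, s, theta)
      if (a <= 0) next
      s2 <- s + network$reactions[[j]]$net_change
      if (s2 < 0 || s2 > smax) next  # box truncation
      Q[s + 1, s + 1] <- Q[s + 1, s + 1] - a
      Q[s2 + 1, s + 1] <- Q[s2 + 1, s + 1] + a
    }
  }
  p <- numeric(smax + 1); p[x0 + 1] <- 1
  h <- t_end / nstep
  for (i in seq_len(nstep)) {
    k1 <- Q %*% p
    k2 <- Q %*% (p + h / 2 * k1)
    k3 <- Q %*% (p + h / 2 * k2)
    k4 <- Q %*% (p + h * k3)
    p <- p + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  as.numeric(p)
}

cme_moment <- function(p, order, smax) sum((0:smax)^order * p)
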