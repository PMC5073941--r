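# Symbolic derivation of raw-moment ODEs and zero central-moment closure.
#
# For a polynomial test function T the master equation implies
#   d/dt E[T(X)] = sum_j E[ alpha_j(X) (T(X + v_j) - T(X)) ].
# With T(x) = x^alpha and mass-action propensities the right side is an exact
# finite polynomial in raw moments (the Taylor sum about the mean is finite
# for polynomials, so expanding the polynomial exactly and taking
# expectations term by term is the same operation with less bookkeeping).
# Bimolecular reactions make moments of order k+1 appear in the equations of
# order k; closure rewrites those via the central-moment expansion about the
# mean with all central moments of order > k set to zero.

# ---- shared closure expansion -------------------------------------------
#
# E[X^beta] (|beta| > k) -> sum over gamma <= beta, |gamma| <= k of
#   prod(choose(beta,gamma)) * mu^(beta-gamma) * C_gamma,
# C_gamma re-expanded in raw moments.  Returns a list of terms, each
# list(coeff, factors) with factors a named integer vector mapping a
# multi-index key (see index_key) to its power.  Used for unconditional
# moments (standard engine) and conditional moments (hybrid engine) alike.
closure_expansion <- function(beta, k) {
  d <- length(beta)
  grids <- lapply(beta, function(b) 0:b)
  gammas <- as.matrix(expand.grid(grids))
  terms <- list()
  add_term <- function(coeff, factors) {
    factors <- factors[factors != 0]
    sig <- paste(names(factors)[order(names(factors))],
                 factors[order(names(factors))], collapse = "|")
    if (!is.null(terms[[sig]])) {
      terms[[sig]]$coeff <<- terms[[sig]]$coeff + coeff
    } else {
      terms[[sig]] <<- list(coeff = coeff, factors = factors)
    }
  }
  unit_keys <- vapply(seq_len(d), function(i)
    index_key(as.integer(seq_len(d) == i)), "")
  mu_factors <- function(expo) {
    f <- as.integer(expo)
    names(f) <- unit_keys
    f
  }
  fac_merge <- function(a, b) {
    for (nm in names(b)) a[nm] <- (if (nm %in% names(a)) a[[nm]] else 0L) + b[[nm]]
    a
  }
  for (g in seq_len(nrow(gammas))) {
    gamma <- as.integer(gammas[g, ])
    if (sum(gamma) > k) next
    Bg <- prod(choose(beta, gamma))
    mu1 <- mu_factors(beta - gamma)
    if (sum(gamma) == 0) {
      add_term(Bg, mu1)
      next
    }
    # C_gamma = sum_{delta <= gamma} prod(choose(gamma,delta)) (-mu)^{gamma-delta} E[X^delta]
    dgrids <- lapply(gamma, function(b) 0:b)
    deltas <- as.matrix(expand.grid(dgrids))
    for (dd in seq_len(nrow(deltas))) {
      delta <- as.integer(deltas[dd, ])
      c2 <- prod(choose(gamma, delta)) * (-1)^(sum(gamma - delta))
      fac <- fac_merge(mu1, mu_factors(gamma - delta))
      if (sum(delta) > 0) {
        dk <- index_key(delta)
        fac[dk] <- (if (dk %in% names(fac)) fac[[dk]] else 0L) + 1L
      }
      add_term(Bg * c2, fac)
    }
  }
  terms <- unname(terms)
  terms[vapply(terms, function(t) t$coeff != 0, TRUE)]
}

# ---- moment system object -----------------------------------------------

new_moment_system <- function(network, max_order, indices, ext_indices,
                              terms, closed) {
  structure(list(network = network, max_order = max_order,
                 indices = indices, ext_indices = ext_indices,
                 terms = terms, closed = closed,
                 par_names = param_names(network)),
            class = "moment_system")
}

empty_terms <- function() list(eq = integer(0), coeff = numeric(0),
                               par = integer(0), factors = list())

add_raw_term <- function(terms, eq, coeff, par, factors) {
  i <- length(terms$eq) + 1L
  terms$eq[i] <- eq; terms$coeff[i] <- coeff; terms$par[i] <- par
  terms$factors[[i]] <- factors
  terms
}

# merge terms with identical (eq, par, factor signature)
aggregate_terms <- function(terms) {
  nt <- length(terms$eq)
  if (!nt) return(terms)
  sig <- vapply(seq_len(nt), function(i) {
    f <- terms$factors[[i]]
    fs <- if (nrow(f)) paste(f[order(f[, 1]), 1], f[order(f[, 1]), 2],
                             sep = "^", collapse = "*") else ""
    paste(terms$eq[i], terms$par[i], fs, sep = "::")
  }, "")
  agg <- rowsum(terms$coeff, sig, reorder = FALSE)
  keep <- match(rownames(agg), sig)
  coef <- as.numeric(agg)
  nz <- abs(coef) > 0
  list(eq = terms$eq[keep][nz], coeff = coef[nz], par = terms$par[keep][nz],
       factors = terms$factors[keep][nz])
}

#' Derive the raw-moment ODE system of a mass-action network
#'
#' Produces, for every multi-index with order between 1 and `max_order`, the
#' exact polynomial right-hand side in raw moments.  Networks containing
#' bimolecular reactions yield right-hand sides that reference moments of
#' order `max_order + 1` ("overhanging" moments); such a system must be
#' closed with [apply_zero_closure()] before it can be integrated.  For
#' networks whose reactions are at most monomolecular no overhang occurs and
#' closure is a no-op.
#'
#' @param network a [reaction_network()].
#' @param max_order highest moment order `k` kept as state.
#' @return a `moment_system` (fields `indices`, `terms`, `closed`).
#' @export
derive_moment_odes <- function(network, max_order) {
  stopifnot(max_order >= 1)
  n <- n_species(network)
  idx <- enumerate_moment_indices(n, 1L, max_order)
  ext <- compositions_grlex(max_order + 1L, n)
  keys <- c(index_keys(idx), index_keys(ext))
  pars <- param_names(network)
  terms <- empty_terms()
  for (r in seq_len(nrow(idx))) {
    alpha <- idx[r, ]
    for (j in seq_along(network$reactions)) {
      v <- network$reactions[[j]]$net_change
      shift <- poly_add(poly_shift_pow(alpha, v, n),
                        poly_scale(poly_pow(alpha), -1))
      rhs <- poly_mul(propensity_poly(network, j), shift)
      if (!length(rhs$coef)) next
      pj <- match(network$reactions[[j]]$rate_parameter, pars)
      for (tt in seq_along(rhs$coef)) {
        beta <- rhs$expo[tt, ]
        fac <- if (sum(beta) == 0) {
          matrix(integer(0), 0L, 2L)
        } else {
          ref <- match(index_key(beta), keys)
          if (is.na(ref))
            stop("internal: rhs moment of order > max_order + 1")
          matrix(c(ref, 1L), 1L, 2L)
        }
        terms <- add_raw_term(terms, r, rhs$coef[tt], pj, fac)
      }
    }
  }
  terms <- aggregate_terms(terms)
  used_ext <- any(vapply(terms$factors, function(f)
    any(f[, 1] > nrow(idx)), TRUE))
  new_moment_system(network, max_order, idx,
                    if (used_ext) ext else ext[0, , drop = FALSE],
                    terms, closed = !used_ext)
}

#' Close a moment system by zeroing high-order central moments
#'
#' Every raw moment of order `k + 1` appearing in a right-hand side is
#' rewritten through the central-moment expansion about the mean with all
#' central moments of order greater than `k` set to zero, leaving a
#' polynomial in moments of order at most `k`.  Systems already free of
#' overhanging moments are returned unchanged.
#'
#' @param system a `moment_system` from [derive_moment_odes()].
#' @param k closure order; defaults to the system's `max_order`.
#' @return a closed `moment_system`.
#' @export
apply_zero_closure <- function(system, k = system$max_order) {
  stopifnot(inherits(system, "moment_system"))
  if (system$closed) return(system)
  if (k != system$max_order)
    stop("closure order must equal the system's max_order")
  M <- nrow(system$indices)
  keys_main <- index_keys(system$indices)
  ext <- system$ext_indices
  if (nrow(ext) && any(index_order(ext) > k + 1L))
    stop("rhs contains a moment of order > k + 1; not a mass-action system")
  out <- empty_terms()
  cache <- new.env(parent = emptyenv())
  for (i in seq_along(system$terms$eq)) {
    f <- system$terms$factors[[i]]
    over <- which(f[, 1] > M)
    if (!length(over)) {
      out <- add_raw_term(out, system$terms$eq[i], system$terms$coeff[i],
                          system$terms$par[i], f)
      next
    }
    stopifnot(nrow(f) == 1L, f[1, 2] == 1L)  # pre-closure terms are linear
    beta <- ext[f[1, 1] - M, ]
    bk <- index_key(beta)
    cl <- if (!is.null(cache[[bk]])) cache[[bk]] else {
      cache[[bk]] <- closure_expansion(beta, k); cache[[bk]]
    }
    for (ct in cl) {
      refs <- match(names(ct$factors), keys_main)
      if (anyNA(refs)) stop("internal: closure factor above closure order")
      fac <- cbind(as.integer(refs), as.integer(ct$factors), deparse.level = 0)
      out <- add_raw_term(out, system$terms$eq[i],
                          system$terms$coeff[i] * ct$coeff,
                          system$terms$par[i], fac)
    }
  }
  out <- aggregate_terms(out)
  new_moment_system(system$network, system$max_order, system$indices,
                    system$ext_indices[0, , drop = FALSE], out, closed = TRUE)
}

# convenience: derive + close in one call
derive_closed_moment_system <- function(network, max_order) {
  apply_zero_closure(derive_moment_odes(network, max_order))
}

# flatten to the CSR layout consumed by dp45_integrate_cpp
compile_terms <- function(terms, nstate) {
  nt <- length(terms$eq)
  fptr <- integer(nt + 1L)
  fidx <- integer(0); fpow <- integer(0)
  for (i in seq_len(nt)) {
    f <- terms$factors[[i]]
    fptr[i + 1L] <- fptr[i] + nrow(f)
    if (nrow(f)) { fidx <- c(fidx, f[, 1] - 1L); fpow <- c(fpow, f[, 2]) }
  }
  if (nt && max(terms$eq) > nstate) stop("internal: term references beyond state")
  list(nstate = as.integer(nstate), eq = terms$eq - 1L,
       coeff = terms$coeff, par = terms$par - 1L,
       fptr = fptr, fidx = fidx, fpow = fpow)
}

run_dp45 <- function(compiled, theta, y0, times, rtol, atol, guard = 0,
                     max_steps = 500000L, ymax = 1e15) {
  res <- dp45_integrate_cpp(compiled$nstate, compiled$eq, compiled$coeff,
                            compiled$par, compiled$fptr, compiled$fidx,
                            compiled$fpow, as.numeric(theta),
                            as.numeric(y0), 0, as.numeric(times),
                            rtol, atol, guard, max_steps, ymax)
  if (!res$success)
    stop("ODE integration failed (step-size collapse or non-finite state; ",
         "possible stiffness) at t = ", signif(res$t_reached, 6),
         call. = FALSE)
  res$values
}

#' Integrate a closed moment system
#'
#' Adaptive Dormand-Prince Runge-Kutta 5(4) integration of the closed
#' raw-moment ODEs from the point-mass initial condition
#' \eqn{E[X^\alpha](0) = x_0^\alpha}.
#'
#' @param system a closed `moment_system`.
#' @param theta named parameter values.
#' @param times increasing output times (t = 0 is the initial state).
#' @param initial_state optional integer state overriding the network's.
#' @param rtol,atol relative / absolute integration tolerances.
#' @return a `moment_trajectory`: list with `times`, `values`
#'   (times x moments), `indices` and `names`.
#' @export
integrate_moment_system <- function(system, theta, times,
                                    initial_state = NULL,
                                    rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(system, "moment_system"))
  if (!system$closed)
    stop("system must be closed first (apply_zero_closure)")
  x0 <- if (is.null(initial_state)) system$network$initial_state
        else as.numeric(initial_state)
  vals <- resolve_theta(system$network, theta)[system$par_names]
  y0 <- apply(system$indices, 1L, function(a) prod(x0^a))
  compiled <- compile_terms(system$terms, nrow(system$indices))
  values <- run_dp45(compiled, vals, y0, times, rtol, atol)
  nms <- apply(system$indices, 1L, moment_label,
               names = system$network$species$name)
  colnames(values) <- nms
  structure(list(times = as.numeric(times), values = values,
                 indices = system$indices, names = nms),
            class = "moment_trajectory")
}

# pull the columns for given multi-indices (matrix or single vector)
trajectory_moments <- function(traj, indices) {
  if (is.null(dim(indices))) indices <- matrix(indices, 1L)
  pos <- match(index_keys(indices), index_keys(traj$indices))
  if (anyNA(pos)) stop("requested moment not present in trajectory")
  traj$values[, pos, drop = FALSE]
}

#' Human-readable listing of a moment ODE system
#'
#' One line per equation, suitable for inspection and regression tests.
#'
#' @param system a `moment_system` or `hybrid_moment_system`.
#' @return character vector, one equation per line.
#' @export
moment_system_listing <- function(system) UseMethod("moment_system_listing")

format_terms_for <- function(terms, eq, par_names, state_names) {
  sel <- which(terms$eq == eq)
  if (!length(sel)) return("0")
  parts <- vapply(sel, function(i) {
    f <- terms$factors[[i]]
    fs <- if (nrow(f)) paste0(state_names[f[, 1]],
                              ifelse(f[, 2] == 1, "", paste0("^", f[, 2])),
                              collapse = "*") else "1"
    co <- terms$coeff[i]
    sprintf("%s%.10g*%s*%s", if (co >= 0) "+ " else "- ", abs(co),
            par_names[terms$par[i]], fs)
  }, "")
  paste(parts, collapse = " ")
}

#' @export
moment_system_listing.moment_system <- function(system) {
  nm_sp <- system$network$species$name
  st_names <- c(apply(system$indices, 1L, moment_label, names = nm_sp),
                apply(system$ext_indices, 1L, moment_label, names = nm_sp))
  vapply(seq_len(nrow(system$indices)), function(r) {
    paste0("d/dt ", st_names[r], " = ",
           format_terms_for(system$terms, r, system$par_names, st_names))
  }, "")
}

#' @export
print.moment_system <- function(x, ...) {
  cat("moment_system: order", x$max_order, "-", nrow(x$indices), "equations,",
      if (x$closed) "closed" else "pre-closure (overhanging moments present)",
      "\n")
  cat(utils::head(moment_system_listing(x), 8), sep = "\n")
  if (nrow(x$indices) > 8) cat("... (", nrow(x$indices) - 8, " more)\n")
  invisible(x)
}
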