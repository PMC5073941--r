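# Hybrid method of conditional moments: a discrete distribution over the
# low-copy "modes" (e.g. promoter occupancy), coupled to moments of the
# high-copy species conditioned on each mode.  The integrated state consists
# of mode probabilities p_t(xhat) and *partial* moments
#   M_{xhat,alpha} = E[Xtilde^alpha | xhat] p_t(xhat),
# so the system stays an ODE system even when a mode probability vanishes:
# every right-hand-side term scales with the source mode's probability, and
# closure monomials (which formally divide by p) are dropped once p falls
# below the truncation threshold.

#' Enumerate the reachable low-copy modes of a network
#'
#' Breadth-first reachability over the low-copy subvector \eqn{\hat x},
#' applying every reaction whose low-copy change vector \eqn{\hat v_j} is
#' non-zero.  Feasibility is checked on the low-copy reactants only (high
#' copy species are assumed available), which can only over-approximate the
#' reachable mode set.
#'
#' @param network a [reaction_network()].
#' @param low_species indices or names of the low-copy species; defaults to
#'   the species declared `copy_class = "low"`.
#' @param initial_state optional full state overriding the network's.
#' @param cap maximum number of modes before an error is raised (a larger
#'   reachable set indicates species misclassified as low copy).
#' @return a `mode_space`: list with `low`, `high` (species indices),
#'   `modes` (matrix, one mode per row) and `mode_change` (per-reaction
#'   low-copy net change vectors).
#' @export
enumerate_modes <- function(network, low_species = NULL, initial_state = NULL,
                            cap = 1024L) {
  low <- if (is.null(low_species)) low_species_indices(network)
         else species_index(network, low_species)
  if (!length(low)) stop("no low-copy species: nothing to condition on")
  high <- setdiff(seq_len(n_species(network)), low)
  x0 <- if (is.null(initial_state)) network$initial_state
        else as.integer(initial_state)
  m <- length(network$reactions)
  vhat <- matrix(0L, m, length(low))
  vhat_minus <- matrix(0L, m, length(low))
  for (j in seq_len(m)) {
    vhat[j, ] <- network$reactions[[j]]$net_change[low]
    vhat_minus[j, ] <- network$reactions[[j]]$reactant_change[low]
  }
  root <- x0[low]
  modes <- list(root)
  keys <- index_key(root)
  queue <- list(root)
  while (length(queue)) {
    cur <- queue[[1]]; queue <- queue[-1]
    for (j in seq_along(network$reactions)) {
      if (all(vhat[j, ] == 0)) next
      if (any(cur + vhat_minus[j, ] < 0)) next
      succ <- cur + vhat[j, ]
      k <- index_key(succ)
      if (!k %in% keys) {
        modes[[length(modes) + 1L]] <- succ
        keys <- c(keys, k)
        queue[[length(queue) + 1L]] <- succ
        if (length(modes) > cap)
          stop("mode count exceeds cap (", cap,
               "): are these species really low copy?")
      }
    }
  }
  structure(list(low = low, high = high,
                 modes = do.call(rbind, modes),
                 mode_change = vhat,
                 low_names = network$species$name[low],
                 high_names = network$species$name[high]),
            class = "mode_space")
}

#' @export
print.mode_space <- function(x, ...) {
  cat("mode_space:", nrow(x$modes), "modes over (",
      paste(x$low_names, collapse = ", "), ")\n")
  for (a in seq_len(nrow(x$modes)))
    cat("  mode", a, ": (", paste(x$modes[a, ], collapse = ","), ")\n")
  invisible(x)
}

hyb_pos_p <- function(a, H) (a - 1L) * (H + 1L) + 1L
hyb_pos_m <- function(a, r, H) (a - 1L) * (H + 1L) + 1L + r

#' Derive the hybrid conditional-moment ODE system
#'
#' For every mode, one equation for the mode probability and one for each
#' partial moment of the high-copy species up to `max_order`.  Conditional
#' expectations of propensities are expanded exactly in conditional raw
#' moments (propensities are polynomial), and conditional raw moments of
#' order above `max_order` are eliminated by the zero central-moment closure
#' applied conditionally within each mode.
#'
#' @param network a [reaction_network()].
#' @param mode_space from [enumerate_modes()]; defaults to the modes implied
#'   by the network's `copy_class` annotations.
#' @param max_order conditional-moment closure order `k`.
#' @param truncation_threshold mode probabilities below this value are
#'   treated as zero inside closure terms (no renormalization is applied).
#' @return a `hybrid_moment_system` with `|modes| * (1 + H)` equations where
#'   `H` is the number of high-copy moment indices of order 1..k.
#' @export
derive_hybrid_system <- function(network, mode_space = NULL, max_order,
                                 truncation_threshold = 1e-12) {
  stopifnot(max_order >= 1)
  ms <- if (is.null(mode_space)) enumerate_modes(network) else mode_space
  n <- n_species(network)
  nh <- length(ms$high)
  if (!nh) stop("hybrid system needs at least one high-copy species")
  hidx <- enumerate_moment_indices(nh, 1L, max_order)
  hkeys <- index_keys(hidx)
  H <- nrow(hidx)
  M <- nrow(ms$modes)
  mode_keys <- index_keys(ms$modes)
  pars <- param_names(network)
  nstate <- M * (H + 1L)

  cond_prop <- function(a, j)
    poly_substitute(propensity_poly(network, j), ms$low, ms$modes[a, ])

  cl_cache <- new.env(parent = emptyenv())
  terms <- empty_terms()

  # add sum_beta c_beta * E[Xtilde^beta | src] p(src) to equation `eq`
  add_phi <- function(eq, sign, j, src, ph) {
    pj <- match(network$reactions[[j]]$rate_parameter, pars)
    for (tt in seq_along(ph$coef)) {
      beta <- ph$expo[tt, ]
      co <- sign * ph$coef[tt]
      o <- sum(beta)
      if (o == 0) {
        fac <- matrix(c(hyb_pos_p(src, H), 1L), 1L, 2L)
        terms <<- add_raw_term(terms, eq, co, pj, fac)
      } else if (o <= max_order) {
        r <- match(index_key(beta), hkeys)
        fac <- matrix(c(hyb_pos_m(src, r, H), 1L), 1L, 2L)
        terms <<- add_raw_term(terms, eq, co, pj, fac)
      } else {
        bk <- index_key(beta)
        cl <- if (!is.null(cl_cache[[bk]])) cl_cache[[bk]] else {
          cl_cache[[bk]] <- closure_expansion(beta, max_order); cl_cache[[bk]]
        }
        for (ct in cl) {
          refs <- match(names(ct$factors), hkeys)
          if (anyNA(refs)) stop("internal: conditional closure factor lookup")
          d_tot <- sum(ct$factors)
          fac <- cbind(hyb_pos_m(src, as.integer(refs), H),
                       as.integer(ct$factors), deparse.level = 0)
          p_pow <- 1L - as.integer(d_tot)
          if (p_pow != 0L)
            fac <- rbind(fac, c(hyb_pos_p(src, H), p_pow))
          terms <<- add_raw_term(terms, eq, co * ct$coeff, pj, fac)
        }
      }
    }
  }

  for (a in seq_len(M)) {
    # mode probability equation (mode-changing reactions only; others cancel)
    eq_p <- hyb_pos_p(a, H)
    for (j in seq_along(network$reactions)) {
      if (all(ms$mode_change[j, ] == 0)) next
      add_phi(eq_p, -1, j, a, cond_prop(a, j))
      src_hat <- ms$modes[a, ] - ms$mode_change[j, ]
      src <- match(index_key(src_hat), mode_keys)
      if (!is.na(src)) add_phi(eq_p, +1, j, src, cond_prop(src, j))
    }
    # partial moment equations
    for (r in seq_len(H)) {
      alpha <- hidx[r, ]
      eq_m <- hyb_pos_m(a, r, H)
      for (j in seq_along(network$reactions)) {
        vtil <- network$reactions[[j]]$net_change[ms$high]
        add_phi(eq_m, -1, j, a,
                poly_mul(cond_prop(a, j), poly_pow(alpha)))
        src_hat <- ms$modes[a, ] - ms$mode_change[j, ]
        src <- match(index_key(src_hat), mode_keys)
        if (!is.na(src))
          add_phi(eq_m, +1, j, src,
                  poly_mul(cond_prop(src, j),
                           poly_shift_pow(alpha, vtil, nh)))
      }
    }
  }

  terms <- aggregate_terms(terms)
  structure(list(network = network, mode_space = ms, max_order = max_order,
                 high_indices = hidx, n_equations = nstate, terms = terms,
                 truncation_threshold = truncation_threshold,
                 par_names = pars),
            class = "hybrid_moment_system")
}

hybrid_state_names <- function(system) {
  ms <- system$mode_space
  H <- nrow(system$high_indices)
  unlist(lapply(seq_len(nrow(ms$modes)), function(a) {
    mode_lab <- paste0("(", paste(ms$modes[a, ], collapse = ","), ")")
    c(paste0("p", mode_lab),
      vapply(seq_len(H), function(r)
        paste0("PM[", moment_label(system$high_indices[r, ], ms$high_names),
               "|", mode_lab, "]"), ""))
  }))
}

#' @export
moment_system_listing.hybrid_moment_system <- function(system) {
  st <- hybrid_state_names(system)
  vapply(seq_len(system$n_equations), function(eq) {
    paste0("d/dt ", st[eq], " = ",
           format_terms_for(system$terms, eq, system$par_names, st))
  }, "")
}

#' @export
print.hybrid_moment_system <- function(x, ...) {
  cat("hybrid_moment_system: order", x$max_order, "-",
      nrow(x$mode_space$modes), "modes x (1 +", nrow(x$high_indices),
      "partial moments) =", x$n_equations, "equations\n")
  cat(utils::head(moment_system_listing(x), 6), sep = "\n")
  if (x$n_equations > 6) cat("... (", x$n_equations - 6, " more)\n")
  invisible(x)
}

#' Integrate a hybrid conditional-moment system
#'
#' Starts from probability one on the initial mode with partial moments
#' equal to the high-copy initial monomials, and integrates with the same
#' Dormand-Prince 5(4) scheme as [integrate_moment_system()].
#'
#' @inheritParams integrate_moment_system
#' @param system a `hybrid_moment_system`.
#' @return a `hybrid_trajectory` with the raw state matrix plus accessors
#'   via [hybrid_mode_probabilities()], [hybrid_conditional_moments()] and
#'   [reconstruct_unconditional_moments()].
#' @export
integrate_hybrid_system <- function(system, theta, times,
                                    initial_state = NULL,
                                    rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(system, "hybrid_moment_system"))
  ms <- system$mode_space
  x0 <- if (is.null(initial_state)) system$network$initial_state
        else as.integer(initial_state)
  H <- nrow(system$high_indices)
  M <- nrow(ms$modes)
  root <- match(index_key(x0[ms$low]), index_keys(ms$modes))
  if (is.na(root))
    stop("initial low-copy state is not among the enumerated modes")
  y0 <- numeric(M * (H + 1L))
  y0[hyb_pos_p(root, H)] <- 1
  xt0 <- x0[ms$high]
  for (r in seq_len(H))
    y0[hyb_pos_m(root, r, H)] <- prod(xt0^system$high_indices[r, ])
  vals <- resolve_theta(system$network, theta)[system$par_names]
  compiled <- compile_terms(system$terms, M * (H + 1L))
  values <- run_dp45(compiled, vals, y0, times, rtol, atol,
                     guard = system$truncation_threshold)
  colnames(values) <- hybrid_state_names(system)
  structure(list(times = as.numeric(times), values = values,
                 system = system),
            class = "hybrid_trajectory")
}

#' Mode probabilities of a hybrid trajectory
#' @param traj a `hybrid_trajectory`.
#' @return matrix times x modes.
#' @export
hybrid_mode_probabilities <- function(traj) {
  H <- nrow(traj$system$high_indices)
  M <- nrow(traj$system$mode_space$modes)
  p <- traj$values[, hyb_pos_p(seq_len(M), H), drop = FALSE]
  colnames(p) <- paste0("p(", apply(traj$system$mode_space$modes, 1L,
                                    paste, collapse = ","), ")")
  p
}

#' Conditional moments of a hybrid trajectory
#'
#' Divides partial moments by the mode probability; entries for modes whose
#' probability is below the truncation threshold are reported as `NA`
#' (the conditional moment is undefined there).
#'
#' @param traj a `hybrid_trajectory`.
#' @return list per mode of matrices times x high-copy moment indices.
#' @export
hybrid_conditional_moments <- function(traj) {
  sys <- traj$system
  H <- nrow(sys$high_indices)
  M <- nrow(sys$mode_space$modes)
  thr <- sys$truncation_threshold
  out <- vector("list", M)
  for (a in seq_len(M)) {
    p <- traj$values[, hyb_pos_p(a, H)]
    cm <- traj$values[, hyb_pos_m(a, seq_len(H), H), drop = FALSE] / p
    cm[p < thr, ] <- NA_real_
    colnames(cm) <- apply(sys$high_indices, 1L, moment_label,
                          names = sys$mode_space$high_names)
    out[[a]] <- cm
  }
  names(out) <- paste0("(", apply(sys$mode_space$modes, 1L, paste,
                                  collapse = ","), ")")
  out
}

# linear map from the hybrid state vector to unconditional raw moments for
# full-species multi-indices: E[X^gamma] = sum_a xhat_a^gamma_low * M_{a,gamma_high}
hybrid_reconstruction_map <- function(system, indices) {
  ms <- system$mode_space
  H <- nrow(system$high_indices)
  M <- nrow(ms$modes)
  hkeys <- index_keys(system$high_indices)
  W <- matrix(0, nrow(indices), M * (H + 1L))
  for (r in seq_len(nrow(indices))) {
    gl <- indices[r, ms$low]
    gh <- indices[r, ms$high]
    if (sum(gh) > system$max_order)
      stop("high-copy part of requested moment exceeds the closure order")
    col_off <- if (sum(gh) == 0) 0L else match(index_key(gh), hkeys)
    for (a in seq_len(M)) {
      w <- prod(ms$modes[a, ]^gl)
      if (w == 0) next
      pos <- if (col_off == 0L) hyb_pos_p(a, H) else hyb_pos_m(a, col_off, H)
      W[r, pos] <- W[r, pos] + w
    }
  }
  W
}

#' Unconditional moments from a hybrid trajectory
#'
#' Applies the law of total expectation: an unconditional raw moment is the
#' sum over modes of the corresponding partial moments, with low-copy factors
#' entering through the (discrete, exact) mode values:
#' \eqn{E[\hat X^\beta \tilde X^\alpha] = \sum_{\hat x} \hat x^\beta
#' E[\tilde X^\alpha \mid \hat x]\, p_t(\hat x)}.
#'
#' @param traj a `hybrid_trajectory`.
#' @param indices optional matrix of full-species multi-indices; defaults to
#'   all indices of order 1..k (k the hybrid closure order).
#' @return a `moment_trajectory` comparable with [integrate_moment_system()]
#'   output.
#' @export
reconstruct_unconditional_moments <- function(traj, indices = NULL) {
  sys <- traj$system
  n <- n_species(sys$network)
  if (is.null(indices)) {
    indices <- enumerate_moment_indices(n, 1L, sys$max_order)
    hi_ord <- rowSums(indices[, sys$mode_space$high, drop = FALSE])
    indices <- indices[hi_ord <= sys$max_order, , drop = FALSE]
  }
  W <- hybrid_reconstruction_map(sys, indices)
  values <- traj$values %*% t(W)
  nms <- apply(indices, 1L, moment_label, names = sys$network$species$name)
  colnames(values) <- nms
  structure(list(times = traj$times, values = values,
                 indices = indices, names = nms),
            class = "moment_trajectory")
}
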