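# Reaction-network model definition: species, mass-action reactions with
# consumed/produced stoichiometry, rate parameters with bounds.

#' Construct a stochastic reaction network
#'
#' A network is a continuous-time Markov chain over molecular counts
#' \eqn{X(t) = (X_1(t), \ldots, X_n(t))}.  Each reaction \eqn{j} has a change
#' vector \eqn{v_j = v_j^- + v_j^+} split into a consumed part (non-positive
#' entries) and a produced part (non-negative entries), and a mass-action
#' propensity \eqn{\alpha_j(x) = c_j \cdot} (number of distinct reactant
#' combinations in state \eqn{x}).  Only mass-action kinetics up to
#' bimolecular reactions are supported; the propensity form is derived from
#' \eqn{v_j^-}, never user-supplied, because the moment derivation requires
#' polynomial propensities.
#'
#' @param species data.frame with columns `name`, `initial` (nonnegative
#'   integer counts) and optionally `copy_class` (`"low"` or `"high"`,
#'   default `"high"`).  Low-copy species define the discrete modes of the
#'   hybrid conditional-moment engine (e.g. promoter occupancy states).
#' @param reactions list of reactions, each a list with integer vectors
#'   `reactant_change` (entries <= 0), `product_change` (entries >= 0) and a
#'   string `rate_parameter`.
#' @param parameters data.frame with columns `name`, `value` (numeric or NA
#'   when unknown), `lo`, `hi` (box bounds used by the estimator).
#' @return an object of class `reaction_network`.
#' @seealso [builtin_model()], [parse_network()], [propensity()]
#' @export
reaction_network <- function(species, reactions, parameters) {
  species <- as.data.frame(species, stringsAsFactors = FALSE)
  if (is.null(species$copy_class)) species$copy_class <- "high"
  stopifnot(all(c("name", "initial") %in% names(species)))
  n <- nrow(species)
  if (n < 1) stop("network must contain at least one species")
  if (anyDuplicated(species$name))
    stop("duplicate species name: ",
         paste(unique(species$name[duplicated(species$name)]), collapse = ", "))
  if (!all(species$copy_class %in% c("low", "high")))
    stop("copy_class must be 'low' or 'high'")
  if (any(species$initial < 0) || any(species$initial != round(species$initial)))
    stop("initial counts must be nonnegative integers")
  species$initial <- as.integer(species$initial)

  if (!length(reactions)) stop("network must contain at least one reaction")
  seen <- character(0)
  for (j in seq_along(reactions)) {
    rx <- reactions[[j]]
    rm_ <- as.integer(rx$reactant_change); pm <- as.integer(rx$product_change)
    if (length(rm_) != n || length(pm) != n)
      stop("reaction ", j, ": change vectors must have length ", n)
    if (any(rm_ > 0) || any(pm < 0))
      stop("reaction ", j, ": reactant_change must be <= 0 and product_change >= 0")
    v <- rm_ + pm
    if (all(v == 0))
      stop("reaction ", j, ": change vector must be non-zero")
    if (sum(-rm_) > 2)
      stop("reaction ", j, ": stoichiometry above bimolecular is not mass action")
    key <- paste(c(rm_, pm), collapse = ",")
    if (key %in% seen)
      stop("reaction ", j, ": duplicate change vector (identical v-, v+ pair)")
    seen <- c(seen, key)
    reactions[[j]]$reactant_change <- rm_
    reactions[[j]]$product_change <- pm
    reactions[[j]]$net_change <- v
  }

  pars_used <- unique(vapply(reactions, `[[`, "", "rate_parameter"))
  parameters <- as.data.frame(parameters, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "lo", "hi") %in% names(parameters)))
  if (is.null(parameters$value)) parameters$value <- NA_real_
  missing_par <- setdiff(pars_used, parameters$name)
  if (length(missing_par))
    stop("parameters referenced by reactions but not declared: ",
         paste(missing_par, collapse = ", "))
  unused <- setdiff(parameters$name, pars_used)
  if (length(unused))
    stop("declared parameters not referenced by any reaction: ",
         paste(unused, collapse = ", "))
  bad <- !is.na(parameters$value) &
    (parameters$value < parameters$lo | parameters$value > parameters$hi)
  if (any(bad))
    stop("parameter value outside its bounds: ",
         paste(parameters$name[bad], collapse = ", "))
  if (any(parameters$lo > parameters$hi) || any(parameters$lo < 0))
    stop("parameter bounds must satisfy 0 <= lo <= hi")

  structure(list(species = species, reactions = reactions,
                 parameters = parameters,
                 initial_state = as.integer(species$initial)),
            class = "reaction_network")
}

#' @export
print.reaction_network <- function(x, ...) {
  cat("reaction_network:", nrow(x$species), "species,",
      length(x$reactions), "reactions,", nrow(x$parameters), "parameters\n")
  cat("species:", paste0(x$species$name, "(", x$species$copy_class, "=",
                         x$species$initial, ")", collapse = " "), "\n")
  for (ln in reaction_labels(x)) cat(" ", ln, "\n")
  invisible(x)
}

n_species <- function(network) nrow(network$species)

species_index <- function(network, species) {
  if (is.numeric(species)) return(as.integer(species))
  idx <- match(species, network$species$name)
  if (anyNA(idx)) stop("unknown species: ",
                       paste(species[is.na(idx)], collapse = ", "))
  idx
}

low_species_indices <- function(network) {
  which(network$species$copy_class == "low")
}

param_names <- function(network) network$parameters$name

param_bounds <- function(network, pars = param_names(network)) {
  i <- match(pars, network$parameters$name)
  if (anyNA(i)) stop("unknown parameter: ", paste(pars[is.na(i)], collapse = ", "))
  cbind(lo = network$parameters$lo[i], hi = network$parameters$hi[i])
}

# full named rate vector for simulation/integration; `theta` overrides and
# completes declared values, and must respect the declared bounds
resolve_theta <- function(network, theta = NULL) {
  vals <- stats::setNames(network$parameters$value, network$parameters$name)
  if (!is.null(theta)) {
    if (is.null(names(theta)) || any(!nzchar(names(theta))))
      stop("theta must be a named numeric vector")
    unknown <- setdiff(names(theta), names(vals))
    if (length(unknown)) stop("unknown parameter: ", paste(unknown, collapse = ", "))
    vals[names(theta)] <- theta
  }
  if (anyNA(vals))
    stop("missing parameter value for: ",
         paste(names(vals)[is.na(vals)], collapse = ", "))
  if (any(vals < 0)) stop("rate constants must be nonnegative")
  b <- param_bounds(network)
  out <- vals < b[, "lo"] - 1e-12 | vals > b[, "hi"] + 1e-12
  if (any(out))
    stop("parameter value outside declared bounds: ",
         paste(names(vals)[out], collapse = ", "))
  vals
}

# |v-| as a nonnegative reactant-count matrix (reactions x species)
reactant_matrix <- function(network) {
  m <- length(network$reactions)
  out <- matrix(0L, m, n_species(network))
  for (j in seq_len(m)) out[j, ] <- -network$reactions[[j]]$reactant_change
  out
}

net_change_matrix <- function(network) {
  m <- length(network$reactions)
  out <- matrix(0L, m, n_species(network))
  for (j in seq_len(m)) out[j, ] <- network$reactions[[j]]$net_change
  out
}

# mass-action propensity polynomial in x, excluding the rate constant
propensity_poly <- function(network, j) {
  n <- n_species(network)
  r <- -network$reactions[[j]]$reactant_change
  p <- poly_const(n)
  for (i in which(r > 0)) {
    if (r[i] == 1L) {
      p <- poly_mul(p, poly_mono(as.integer(seq_len(n) == i)))
    } else {
      # homodimer: x(x-1)/2 distinct pairs
      e1 <- as.integer(seq_len(n) == i)
      quad <- poly_add(poly_mono(2L * e1, 0.5), poly_mono(e1, -0.5))
      p <- poly_mul(p, quad)
    }
  }
  p
}

#' Mass-action propensity of one reaction in a given state
#'
#' Computes \eqn{\alpha_j(x)}: the rate constant times the number of distinct
#' reactant combinations (\eqn{x_i} for a single reactant, \eqn{x_i x_k} for
#' two distinct reactants, \eqn{x_i(x_i-1)/2} for a homodimer pair).  Zero
#' whenever a required reactant is absent.
#'
#' @param network a [reaction_network()].
#' @param j reaction index.
#' @param x nonnegative integer state vector.
#' @param theta optional named parameter values overriding declared ones.
#' @return a nonnegative number.
#' @export
propensity <- function(network, j, x, theta = NULL) {
  stopifnot(j >= 1, j <= length(network$reactions))
  x <- as.numeric(x)
  if (length(x) != n_species(network) || any(x < 0))
    stop("x must be a nonnegative state vector of length ", n_species(network))
  pn <- network$reactions[[j]]$rate_parameter
  rate <- if (!is.null(theta) && pn %in% names(theta)) theta[[pn]] else
    network$parameters$value[match(pn, network$parameters$name)]
  if (is.na(rate)) stop("missing parameter value for: ", pn)
  if (any(x + network$reactions[[j]]$reactant_change < 0)) return(0)
  rate * poly_eval(propensity_poly(network, j), x)
}

reaction_labels <- function(network) {
  nm <- network$species$name
  side <- function(v) {
    v <- abs(v)
    if (!any(v > 0)) return("0")
    parts <- ifelse(v[v > 0] == 1, nm[v > 0], paste(v[v > 0], nm[v > 0]))
    paste(parts, collapse = " + ")
  }
  vapply(network$reactions, function(r) {
    paste0(side(r$reactant_change), " -> ", side(r$product_change),
           " : ", r$rate_parameter)
  }, "")
}
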