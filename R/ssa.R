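# Exact stochastic simulation (Gillespie direct method) and snapshot datasets.

#' Simulate one exact trajectory and return the final state
#'
#' Gillespie's direct method: exponential waiting times with rate
#' \eqn{\alpha_0(x) = \sum_j \alpha_j(x)} and categorical reaction choice
#' proportional to \eqn{\alpha_j(x)}.  The result is an exact sample of
#' `X(t_end)` under the chemical master equation and a deterministic
#' function of `seed`.
#'
#' @param network a [reaction_network()].
#' @param theta named vector assigning a value to every rate constant.
#' @param t_end simulation horizon, `>= 0`.
#' @param seed integer seed (counter-based substream; independent of R's RNG).
#' @return integer vector of final molecule counts.
#' @export
simulate_ssa <- function(network, theta, t_end, seed) {
  stopifnot(t_end >= 0)
  vals <- resolve_theta(network, theta)
  rates <- vals[vapply(network$reactions, `[[`, "", "rate_parameter")]
  ssa_final_state_cpp(reactant_matrix(network), net_change_matrix(network),
                      as.numeric(rates), network$initial_state,
                      t_end, as.integer(seed), 0L, 0L)
}

#' Generate a population snapshot dataset by stochastic simulation
#'
#' Draws `n_samples` independent trajectories per time point (fresh runs for
#' every time point, so samples at different times are independent, as the
#' multi-time GMM objective assumes) and records the observed species
#' counts, mimicking flow-cytometry style population snapshots.
#'
#' @inheritParams simulate_ssa
#' @param times increasing nonnegative observation times.
#' @param observed_species species names or indices to record.
#' @param n_samples number of cells per time point (`N`).
#' @return a `snapshot_dataset`: list with `times`, `observed_species`
#'   (names), `samples` (one `N x |observed|` integer matrix per time),
#'   `seed`, and free-text `provenance`.
#' @export
sample_snapshots <- function(network, theta, times, observed_species,
                             n_samples, seed) {
  stopifnot(n_samples >= 1, length(times) >= 1, !is.unsorted(times),
            all(times >= 0))
  obs <- species_index(network, observed_species)
  vals <- resolve_theta(network, theta)
  rates <- vals[vapply(network$reactions, `[[`, "", "rate_parameter")]
  raw <- ssa_snapshots_cpp(reactant_matrix(network),
                           net_change_matrix(network), as.numeric(rates),
                           network$initial_state, as.numeric(times),
                           obs - 1L, as.integer(n_samples), as.integer(seed))
  nm <- network$species$name[obs]
  samples <- lapply(raw, function(m) { colnames(m) <- nm; m })
  names(samples) <- as.character(times)
  structure(list(times = as.numeric(times), observed_species = nm,
                 samples = samples, seed = as.integer(seed),
                 provenance = sprintf(
                   "ssa network=<%d species/%d reactions> theta=%s",
                   n_species(network), length(network$reactions),
                   paste(names(vals), vals, sep = "=", collapse = ";"))),
            class = "snapshot_dataset")
}

#' @export
print.snapshot_dataset <- function(x, ...) {
  cat("snapshot_dataset:", nrow(x$samples[[1]]), "samples x",
      length(x$observed_species), "species at",
      length(x$times), "time point(s)\n")
  cat("times:", paste(x$times, collapse = ", "),
      " species:", paste(x$observed_species, collapse = ", "), "\n")
  invisible(x)
}

#' Write / read a snapshot dataset as a TSV table
#'
#' Columns `time`, `sample_id`, then one column per observed species;
#' provenance and the generating seed are preserved in `#`-prefixed header
#' comments.  The round trip is lossless.
#'
#' @param dataset a `snapshot_dataset`.
#' @param path file path.
#' @export
write_snapshots <- function(dataset, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# provenance: ", dataset$provenance),
               paste0("# seed: ", dataset$seed)), con)
  header <- c("time", "sample_id", dataset$observed_species)
  writeLines(paste(header, collapse = "\t"), con)
  for (ti in seq_along(dataset$times)) {
    m <- dataset$samples[[ti]]
    tab <- cbind(format(dataset$times[ti], scientific = FALSE),
                 seq_len(nrow(m)), m)
    utils::write.table(tab, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_snapshots
#' @param network optional [reaction_network()]; if given, observed species
#'   columns are validated against its species names.
#' @export
read_snapshots <- function(path, network = NULL) {
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  body <- body[nzchar(body)]
  if (length(body) < 2) stop("snapshot file has no data rows")
  fields <- strsplit(body, "\t", fixed = TRUE)
  header <- fields[[1]]
  if (length(header) < 3 || header[1] != "time" || header[2] != "sample_id")
    stop("snapshot header must start with 'time', 'sample_id'")
  obs <- header[-(1:2)]
  if (!is.null(network)) {
    bad <- setdiff(obs, network$species$name)
    if (length(bad))
      stop("unknown species column in snapshot file: ",
           paste(bad, collapse = ", "))
  }
  ncols <- length(header)
  ragged <- vapply(fields[-1], length, 0L) != ncols
  if (any(ragged))
    stop("malformed snapshot table: ragged row(s) ",
         paste(utils::head(which(ragged), 3), collapse = ", "))
  dat <- do.call(rbind, fields[-1])
  time <- as.numeric(dat[, 1])
  counts <- apply(dat[, -(1:2), drop = FALSE], 2, as.numeric)
  counts <- matrix(counts, ncol = length(obs))
  if (anyNA(time) || anyNA(counts) || any(counts < 0) ||
      any(counts != round(counts)))
    stop("malformed snapshot table: counts must be nonnegative integers")
  times <- unique(time)
  samples <- lapply(times, function(tt) {
    m <- matrix(as.integer(counts[time == tt, , drop = FALSE]),
                ncol = length(obs))
    colnames(m) <- obs
    m
  })
  Ns <- vapply(samples, nrow, 0L)
  if (length(unique(Ns)) != 1)
    stop("inconsistent sample count across time points: ",
         paste(Ns, collapse = ", "))
  names(samples) <- as.character(times)
  seed <- sub("^# seed: ", "", grep("^# seed: ", meta, value = TRUE))
  structure(list(times = times, observed_species = obs, samples = samples,
                 seed = if (length(seed)) as.integer(seed[1]) else NA_integer_,
                 provenance = paste(sub("^# provenance: ", "", meta),
                                    collapse = "; ")),
            class = "snapshot_dataset")
}
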