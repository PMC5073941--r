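# Plain-text model-definition format.
#
# Three sections, one record per line, '#' comments allowed:
#
#   [species]
#   <name> <initial count> <low|high>
#
#   [reactions]
#   <reactants> -> <products> : <parameter>     (sides like "DNA + P1", "2 X",
#                                                "0" for no molecules)
#   [parameters]
#   <name> <value>            known rate constant (bounds collapse to value)
#   <name> <lo> <hi>          unknown rate constant with box bounds

#' Parse a model-definition document into a reaction network
#'
#' @param config_text character scalar or vector of lines.
#' @return a [reaction_network()].
#' @seealso [write_network_config()], [read_network()]
#' @export
parse_network <- function(config_text) {
  lines <- unlist(strsplit(paste(config_text, collapse = "\n"), "\n"))
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  section <- NA_character_
  sp <- list(); rx <- list(); pa <- list()
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      section <- sub("^\\[(.*)\\]$", "\\1", ln)
      if (!section %in% c("species", "reactions", "parameters"))
        stop("unknown section [", section, "] in model definition")
      next
    }
    if (is.na(section)) stop("content before first section header: ", ln)
    if (section == "species") {
      f <- strsplit(ln, "[[:space:]]+")[[1]]
      if (length(f) < 2 || length(f) > 3)
        stop("species line must be '<name> <initial> [low|high]': ", ln)
      cc <- if (length(f) == 3) f[3] else "high"
      sp[[length(sp) + 1L]] <- list(name = f[1], initial = as.numeric(f[2]),
                                    copy_class = cc)
    } else if (section == "reactions") {
      rx[[length(rx) + 1L]] <- ln
    } else {
      f <- strsplit(ln, "[[:space:]]+")[[1]]
      if (length(f) == 2) {
        v <- as.numeric(f[2])
        pa[[length(pa) + 1L]] <- list(name = f[1], value = v, lo = v, hi = v)
      } else if (length(f) == 3) {
        pa[[length(pa) + 1L]] <- list(name = f[1], value = NA_real_,
                                      lo = as.numeric(f[2]),
                                      hi = as.numeric(f[3]))
      } else {
        stop("parameter line must be '<name> <value>' or '<name> <lo> <hi>': ", ln)
      }
    }
  }
  if (!length(sp)) stop("model definition contains no species")
  if (!length(rx)) stop("model definition contains no reactions")
  species <- do.call(rbind.data.frame, c(sp, stringsAsFactors = FALSE))
  names_ <- species$name
  reactions <- lapply(rx, parse_reaction_line, species_names = names_)
  parameters <- do.call(rbind.data.frame, c(pa, stringsAsFactors = FALSE))
  reaction_network(species, reactions, parameters)
}

parse_side <- function(txt, species_names) {
  n <- length(species_names)
  counts <- integer(n)
  txt <- trimws(txt)
  if (txt %in% c("0", "")) return(counts)
  for (term in trimws(strsplit(txt, "\\+")[[1]])) {
    m <- regmatches(term, regexec("^([0-9]+)?[[:space:]]*(.+)$", term))[[1]]
    mult <- if (nzchar(m[2])) as.integer(m[2]) else 1L
    i <- match(m[3], species_names)
    if (is.na(i)) stop("unknown species in reaction: ", m[3])
    counts[i] <- counts[i] + mult
  }
  counts
}

parse_reaction_line <- function(ln, species_names) {
  m <- regmatches(ln, regexec("^(.*)->(.*):(.*)$", ln))[[1]]
  if (length(m) != 4)
    stop("reaction line must be '<reactants> -> <products> : <parameter>': ", ln)
  list(reactant_change = -parse_side(m[2], species_names),
       product_change = parse_side(m[3], species_names),
       rate_parameter = trimws(m[4]))
}

#' Render a reaction network in the model-definition format
#'
#' Writing and re-parsing round-trips a network exactly.
#'
#' @param network a [reaction_network()].
#' @return character vector of lines.
#' @export
write_network_config <- function(network) {
  sp <- network$species
  out <- c("[species]",
           sprintf("%s %d %s", sp$name, as.integer(sp$initial), sp$copy_class),
           "", "[reactions]", reaction_labels(network), "", "[parameters]")
  pa <- network$parameters
  for (i in seq_len(nrow(pa))) {
    out <- c(out, if (!is.na(pa$value[i]) && pa$lo[i] == pa$value[i] &&
                      pa$hi[i] == pa$value[i])
      sprintf("%s %.15g", pa$name[i], pa$value[i])
      else sprintf("%s %.15g %.15g", pa$name[i], pa$lo[i], pa$hi[i]))
  }
  out
}

#' @rdname parse_network
#' @param path file to read.
#' @export
read_network <- function(path) parse_network(readLines(path))

#' @rdname write_network_config
#' @param path file to write.
#' @export
write_network <- function(network, path) {
  writeLines(write_network_config(network), path)
  invisible(path)
}
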