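# The two bundled case-study models.

#' Built-in fixture models
#'
#' `gene_expression`: a telegraph-type model in which the promoter switches
#' between an active (`DNA_ON`) and inactive (`DNA_OFF`) state and active DNA
#' transcribes mRNA.  All propensities are linear, so its moment equations
#' are exact at any closure order.  The default initial state has the
#' promoter off and 10 mRNA molecules present.  Rate bounds: a, b, c all in
#' \[0, 0.5\].
#'
#' `exclusive_switch`: two proteins P1 and P2 are produced from a shared
#' promoter region; either protein can bind the free promoter and, while
#' bound, represses production of the other.  The stationary distribution is
#' bimodal, which makes the standard moment closure inaccurate and the hybrid
#' conditional-moment engine worthwhile.  Species: DNA, DNA.P1, DNA.P2
#' (low copy), P1, P2 (high copy); for each i in {1,2} the reactions are
#' production from the free and self-bound promoter (rate p_i in
#' \[0.5, 1.5\]), degradation (d_i in \[0, 0.05\]), binding (b_i in \[0, 0.1\])
#' and unbinding (u_i in \[0, 0.1\]).  The initial state (not fixed by the
#' source model description) defaults to one free promoter and no proteins.
#'
#' Rate constants of both models are declared unknown-with-bounds; supply
#' values via `theta` arguments when simulating or integrating.
#'
#' @param name `"gene_expression"` or `"exclusive_switch"`.
#' @return a [reaction_network()].
#' @examples
#' net <- builtin_model("gene_expression")
#' propensity(net, 1, c(1, 0, 5), theta = c(a = 0.3, b = 0.2, c = 0.4))
#' @export
builtin_model <- function(name = c("gene_expression", "exclusive_switch")) {
  name <- match.arg(name)
  if (name == "gene_expression") {
    species <- data.frame(
      name = c("DNA_ON", "DNA_OFF", "mRNA"),
      initial = c(0L, 1L, 10L),
      copy_class = c("low", "low", "high"),
      stringsAsFactors = FALSE)
    reactions <- list(
      list(reactant_change = c(-1L, 0L, 0L), product_change = c(0L, 1L, 0L),
           rate_parameter = "b"),                       # DNA_ON -> DNA_OFF
      list(reactant_change = c(0L, -1L, 0L), product_change = c(1L, 0L, 0L),
           rate_parameter = "a"),                       # DNA_OFF -> DNA_ON
      list(reactant_change = c(-1L, 0L, 0L), product_change = c(1L, 0L, 1L),
           rate_parameter = "c"))                       # DNA_ON -> DNA_ON + mRNA
    parameters <- data.frame(
      name = c("b", "a", "c"), value = NA_real_,
      lo = c(0, 0, 0), hi = c(0.5, 0.5, 0.5), stringsAsFactors = FALSE)
    return(reaction_network(species, reactions, parameters))
  }

  # exclusive switch
  nm <- c("DNA", "DNA.P1", "DNA.P2", "P1", "P2")
  species <- data.frame(
    name = nm, initial = c(1L, 0L, 0L, 0L, 0L),
    copy_class = c("low", "low", "low", "high", "high"),
    stringsAsFactors = FALSE)
  e <- function(i) { v <- integer(5); v[i] <- 1L; v }
  reactions <- list()
  for (i in 1:2) {
    Pi <- 3L + i; DPi <- 1L + i
    reactions <- c(reactions, list(
      # DNA -> DNA + P_i
      list(reactant_change = -e(1), product_change = e(1) + e(Pi),
           rate_parameter = paste0("p", i)),
      # DNA.P_i -> DNA.P_i + P_i
      list(reactant_change = -e(DPi), product_change = e(DPi) + e(Pi),
           rate_parameter = paste0("p", i)),
      # P_i -> 0
      list(reactant_change = -e(Pi), product_change = integer(5),
           rate_parameter = paste0("d", i)),
      # DNA + P_i -> DNA.P_i
      list(reactant_change = -(e(1) + e(Pi)), product_change = e(DPi),
           rate_parameter = paste0("b", i)),
      # DNA.P_i -> DNA + P_i
      list(reactant_change = -e(DPi), product_change = e(1) + e(Pi),
           rate_parameter = paste0("u", i))))
  }
  parameters <- data.frame(
    name = c("p1", "d1", "b1", "u1", "p2", "d2", "b2", "u2"),
    value = NA_real_,
    lo = c(0.5, 0, 0, 0, 0.5, 0, 0, 0),
    hi = c(1.5, 0.05, 0.1, 0.1, 1.5, 0.05, 0.1, 0.1),
    stringsAsFactors = FALSE)
  reaction_network(species, reactions, parameters)
}
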