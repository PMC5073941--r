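# Multi-index bookkeeping for raw moments E[X^alpha].

#' Enumerate moment multi-indices in graded lexicographic order
#'
#' A raw moment of a vector of `n_species` counts is indexed by a multi-index
#' \eqn{\alpha \in \mathbb{Z}_{\ge 0}^n} with \eqn{E[X^\alpha] = E[\prod_i
#' X_i^{\alpha_i}]}; its order is \eqn{|\alpha| = \sum_i \alpha_i}.  Indices
#' are returned graded by order and, within an order, lexicographically with
#' the first species' exponent decreasing, e.g. for two species and order 2:
#' (2,0), (1,1), (0,2).
#'
#' The number of indices with `min_order <= |alpha| <= max_order` is
#' \eqn{\binom{n + k_{max}}{n} - \binom{n + k_{min} - 1}{n}}.  For two
#' species and orders 1..1, 1..2, 1..3, 1..4 this gives 2, 5, 9 and 14
#' moments; for five species and orders 0..4 it gives 126.
#'
#' @param n_species number of species (length of each index).
#' @param min_order,max_order inclusive order range, `0 <= min <= max`.
#' @return integer matrix with one index per row and `n_species` columns.
#' @examples
#' enumerate_moment_indices(2, 1, 2)  # the five conditions g1..g5
#' nrow(enumerate_moment_indices(5, 0, 4))  # 126
#' @export
enumerate_moment_indices <- function(n_species, min_order, max_order) {
  if (n_species < 1 || min_order < 0 || max_order < 0)
    stop("enumerate_moment_indices: arguments must be nonnegative (n_species >= 1)")
  if (min_order > max_order)
    return(matrix(integer(0), nrow = 0, ncol = n_species))
  do.call(rbind, lapply(min_order:max_order, compositions_grlex,
                        parts = n_species))
}

# all compositions of `total` into `parts` nonnegative parts,
# first component decreasing (lexicographic within the grade)
compositions_grlex <- function(total, parts) {
  if (parts == 1L) return(matrix(as.integer(total), 1L, 1L))
  blocks <- lapply(seq(total, 0L), function(i) {
    rest <- compositions_grlex(total - i, parts - 1L)
    cbind(as.integer(i), rest, deparse.level = 0)
  })
  do.call(rbind, blocks)
}

index_order <- function(indices) as.integer(rowSums(indices))

index_key <- function(alpha) paste(alpha, collapse = ",")

index_keys <- function(indices) apply(indices, 1L, index_key)

# human-readable moment label, e.g. "E[mRNA^2*DNA_ON]"
moment_label <- function(alpha, names) {
  nz <- which(alpha > 0)
  if (!length(nz)) return("1")
  parts <- ifelse(alpha[nz] == 1L, names[nz],
                  paste0(names[nz], "^", alpha[nz]))
  paste0("E[", paste(parts, collapse = "*"), "]")
}
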