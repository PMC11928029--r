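# Small numeric helpers shared across the package.

# Log floor: keeps every logarithm finite on probability-zero cells.
.LOG_FLOOR <- 1e-16

.safe_log <- function(x) log(pmax(x, .LOG_FLOOR))

#' Softmax over a numeric vector
#'
#' Numerically stable softmax, used for policy and action selection
#' throughout the package.
#'
#' @param x numeric vector.
#' @return probability vector of the same length (and names) as `x`.
#' @keywords internal
.softmax <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

.clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

.is_prob_vector <- function(p, tol = 1e-8) {
  is.numeric(p) && all(p >= -tol) && abs(sum(p) - 1) <= tol
}

# Generic KL divergence between two Dirichlet distributions with
# concentration vectors a1 (posterior) and a0 (prior).
.dirichlet_kl <- function(a1, a0) {
  s1 <- sum(a1)
  s0 <- sum(a0)
  lgamma(s1) - lgamma(s0) - sum(lgamma(a1) - lgamma(a0)) +
    sum((a1 - a0) * (digamma(a1) - digamma(s1)))
}

# Sum of column-wise Dirichlet KL divergences between two concentration
# matrices (posterior vs prior likelihood beliefs).
.dirichlet_kl_matrix <- function(a1, a0) {
  tot <- 0
  for (j in seq_len(ncol(a0))) {
    if (any(a1[, j] != a0[, j])) tot <- tot + .dirichlet_kl(a1[, j], a0[, j])
  }
  tot
}
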