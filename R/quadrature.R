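#' Gauss-Hermite quadrature in standard-normal form
#'
#' Nodes and weights for integrating against the standard normal density:
#' `sum(w * f(u)) ~ E[f(U)]`, `U ~ N(0,1)`. Computed by the Golub-Welsch
#' eigen-decomposition of the Jacobi matrix of the (probabilists') Hermite
#' polynomials, so no special-function code is needed. Weights are normalized
#' to sum to one.
#'
#' @param K number of nodes (>= 15 recommended for graded-response marginal
#'   likelihoods; the fitting default is 21).
#' @return list with `nodes` and `weights`, both length K.
#' @export
gauss_hermite_normal <- function(K) {
  K <- as.integer(K)
  if (K < 1) stop("K must be >= 1")
  if (K == 1L) return(list(nodes = 0, weights = 1))
  off <- sqrt(seq_len(K - 1))
  Jm <- matrix(0, K, K)
  Jm[cbind(seq_len(K - 1), 2:K)] <- off
  Jm[cbind(2:K, seq_len(K - 1))] <- off
  e <- eigen(Jm, symmetric = TRUE)
  ord <- order(e$values)
  w <- e$vectors[1, ord]^2
  list(nodes = e$values[ord], weights = w / sum(w))
}
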