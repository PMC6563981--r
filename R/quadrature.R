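#' Gauss-Hermite quadrature rule on the standard-normal scale
#'
#' Nodes and weights for integrals of the form
#' \eqn{\int f(\theta)\,\phi(\theta)\,d\theta} with \eqn{\phi} the standard
#' normal density: physicists' Gauss-Hermite abscissae are rescaled by
#' \eqn{\sqrt 2} and the weights normalized to sum to one. Integrals
#' against \eqn{N(0,\sigma^2)} use \eqn{\theta_k = \sigma \cdot} `nodes`.
#'
#' @param n_nodes Number of quadrature nodes (default 41).
#' @return Object of class `quadrature_rule`: list with `n_nodes`, `nodes`
#'   (symmetric about 0) and `weights` (positive, sum 1).
#' @export
gh_rule <- function(n_nodes = 41) {
  stopifnot(n_nodes >= 2)
  gh <- pracma::gaussHermite(n_nodes)
  w <- gh$w / sqrt(pi)
  structure(list(n_nodes = n_nodes,
                 nodes = gh$x * sqrt(2),
                 weights = w / sum(w)),
            class = "quadrature_rule")
}

#' @export
print.quadrature_rule <- function(x, ...) {
  cat("Gauss-Hermite rule:", x$n_nodes, "nodes on [",
      round(min(x$nodes), 3), ",", round(max(x$nodes), 3), "]\n")
  invisible(x)
}
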