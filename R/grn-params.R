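#' Model parameters for the regulatory-network genotype space
#'
#' Bundles the dimensions of the genotype space and the parameters of the
#' gene response function.  The dynamics are the discrete-time map
#' \eqn{x_i(t+1) = R(I\,\delta_{i,0} + \sum_j J_{ij} x_j(t))} with the
#' sigmoidal response \eqn{R(x) = 1/(1+e^{-\beta(x-\mu)})}.  Node ids are
#' 0-based; node 0 is the input gene and, by default, node
#' `n_nodes - 1` is the output gene (the model itself does not single out
#' an output node, so any fixed choice is statistically equivalent under
#' random topology).
#'
#' @param n_nodes Number of genes \eqn{N} (default 32).
#' @param n_edges Number of regulatory edges \eqn{K} (default 80).
#' @param beta Steepness \eqn{\beta} of the response function (default 2).
#' @param mu Threshold \eqn{\mu} of the response function (default 0).
#' @param output_index 0-based id of the output gene (default `n_nodes - 1`).
#' @param tol Convergence tolerance on the max per-node change of the
#'   dynamics (default `1e-9`).
#' @param max_iter Iteration cap for the steady-state solve (default 10000).
#'
#' @return An object of class `grn_params`.
#' @examples
#' grn_params()
#' grn_params(n_nodes = 3, n_edges = 2)
#' @export
grn_params <- function(n_nodes = 32, n_edges = 80, beta = 2, mu = 0,
                       output_index = n_nodes - 1, tol = 1e-9,
                       max_iter = 10000L) {
  stopifnot(n_nodes >= 2, n_edges >= 1, n_edges <= n_nodes^2,
            beta > 0, tol > 0, max_iter >= 1)
  input_index <- 0L
  output_index <- as.integer(output_index)
  if (output_index == input_index || output_index < 0 ||
      output_index >= n_nodes) {
    stop("output_index must be a node id distinct from the input node 0")
  }
  structure(
    list(n_nodes = as.integer(n_nodes), n_edges = as.integer(n_edges),
         beta = beta, mu = mu, input_index = input_index,
         output_index = output_index, tol = tol,
         max_iter = as.integer(max_iter)),
    class = "grn_params"
  )
}

#' @export
print.grn_params <- function(x, ...) {
  cat(sprintf(
    "<grn_params> N = %d, K = %d, beta = %g, mu = %g, input = %d, output = %d\n",
    x$n_nodes, x$n_edges, x$beta, x$mu, x$input_index, x$output_index))
  invisible(x)
}

#' Size of the genotype space on the log10 scale
#'
#' The number of distinct genotypes is \eqn{\binom{N^2}{K} 2^K}: choose
#' which of the \eqn{N^2} ordered node pairs carry an edge, and a sign for
#' each.  Computed via `lchoose()` so it never overflows.
#'
#' @param params A [grn_params()] object.
#' @return `log10` of the genotype count.
#' @examples
#' genotype_space_size(grn_params())           # ~145
#' genotype_space_size(grn_params(3, 2))       # log10(144)
#' @export
genotype_space_size <- function(params) {
  (lchoose(params$n_nodes^2, params$n_edges) +
     params$n_edges * log(2)) / log(10)
}
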