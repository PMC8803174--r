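#' Mutational robustness by single-edge deletion
#'
#' For each of the K edges the fitness \eqn{f'_i} of the (K-1)-edge
#' network with that edge removed (no replacement) is evaluated.  The
#' robustness measure is the arithmetic mean
#' \eqn{r = \frac{1}{K}\sum_i f'_i}; an edge is "essential" when its
#' deletion drops fitness below `threshold` (default 0.8 — for
#' high-fitness networks the deletion fitnesses are strongly bimodal, so
#' the exact cut hardly matters).
#'
#' @param net A [grn_network()] with at least one edge.
#' @param threshold Essentiality cut on the deletion fitness.
#' @return An object of class `grn_robustness`: a list with `r`,
#'   `n_essential`, `fitness` (of the intact network), `threshold` and
#'   `per_edge` (tibble `source`, `target`, `sign`, `f_prime`,
#'   `essential`).  `tidy()` returns the per-edge tibble, `glance()` the
#'   scalar summary.
#' @examples
#' robustness(chain_grn(3))  # both deletions disconnect: r = 0
#' @export
robustness <- function(net, threshold = 0.8) {
  fp <- deletion_fitness(net)
  per_edge <- net$edges
  per_edge$f_prime <- fp
  per_edge$essential <- fp < threshold
  structure(
    list(r = mean(fp), n_essential = sum(fp < threshold),
         fitness = grn_fitness(net), threshold = threshold,
         per_edge = per_edge),
    class = "grn_robustness"
  )
}

#' @export
print.grn_robustness <- function(x, ...) {
  cat(sprintf("<grn_robustness> f = %.4f, r = %.4f, %d/%d essential edges (f' < %g)\n",
              x$fitness, x$r, x$n_essential, nrow(x$per_edge), x$threshold))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.grn_robustness <- function(x, ...) x$per_edge

#' @exportS3Method generics::glance
glance.grn_robustness <- function(x, ...) {
  tibble(fitness = x$fitness, r = x$r, n_essential = x$n_essential,
         n_edges = nrow(x$per_edge), threshold = x$threshold)
}

#' @rdname robustness
#' @return `essential_edge_count()`: the number of edges whose deletion
#'   fitness falls below `threshold`.
#' @export
essential_edge_count <- function(net, threshold = 0.8) {
  sum(deletion_fitness(net) < threshold)
}
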