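#' Gene response function
#'
#' The sigmoidal response \eqn{R(x) = 1/(1+e^{-\beta(x-\mu)})}: strictly
#' increasing, with spontaneous expression `R(mu) = 0.5`.
#'
#' @param x Total regulatory input (vectorised).
#' @param beta Steepness (> 0).
#' @param mu Threshold.
#' @return Expression level(s) in (0, 1).
#' @examples
#' response(0)            # 0.5 at the defaults beta = 2, mu = 0
#' response(1, beta = 2)  # 1/(1 + exp(-2))
#' @export
response <- function(x, beta = 2, mu = 0) {
  stopifnot(beta > 0)
  1 / (1 + exp(-beta * (x - mu)))
}

#' One synchronous update of the network dynamics
#'
#' Applies \eqn{x_i(t+1) = R(I\,\delta_{i,0} + \sum_j J_{ij} x_j(t))} to all
#' nodes at once.  The input node receives the signal `input` on top of any
#' incoming regulation.
#'
#' @param net A [grn_network()].
#' @param state Numeric vector of expression levels, length `n_nodes`.
#' @param input Input signal \eqn{I \in [0, 1]}.
#' @return The next expression state.
#' @export
grn_step <- function(net, state, input) {
  p <- net$params
  if (length(state) != p$n_nodes) {
    stop("state length does not match the number of nodes")
  }
  total <- numeric(p$n_nodes)
  e <- net$edges
  contrib <- e$sign * state[e$source + 1L]
  for (k in seq_len(nrow(e))) {
    total[e$target[k] + 1L] <- total[e$target[k] + 1L] + contrib[k]
  }
  total[p$input_index + 1L] <- total[p$input_index + 1L] + input
  response(total, p$beta, p$mu)
}

#' Steady-state expression of the output gene
#'
#' Iterates the dynamics from the spontaneous-expression state (all nodes
#' at 0.5, unless `init` is given) until the maximum per-node change drops
#' below `tol`.  If instead a limit cycle (period up to 64) is detected by
#' state recurrence, the output is the temporal average over one period; if
#' the iteration cap is reached without either, the average over the
#' trailing 1000 iterates is reported.  Non-convergence is reported through
#' the flags, never as an error.
#'
#' @inheritParams grn_step
#' @param tol,max_iter Override the values stored in `net$params`.
#' @param init Optional initial state (used by warm-started hysteresis
#'   sweeps).
#' @return A one-row tibble with `output_level`, `converged`,
#'   `cycle_detected` and `iterations`.
#' @examples
#' steady_output(chain_grn(3), input = 1)
#' @export
steady_output <- function(net, input, tol = net$params$tol,
                          max_iter = net$params$max_iter, init = NULL) {
  p <- net$params
  if (is.null(init)) init <- rep(0.5, p$n_nodes)
  r <- cpp_steady(net_codes(net), net$edges$sign, p$n_nodes, input,
                  p$beta, p$mu, tol, as.integer(max_iter),
                  p$output_index, init)
  tibble(output_level = r$output_level, converged = r$converged,
         cycle_detected = r$cycle_detected, iterations = r$iterations)
}

#' Fitness of a network
#'
#' The fitness is the input sensitivity of the output gene,
#' \eqn{f = |\bar{x}_{out}(0) - \bar{x}_{out}(1)|}, where
#' \eqn{\bar{x}_{out}(I)} is the steady-state (or cycle-averaged) output at
#' fixed input \eqn{I}.  `f` lies in \[0, 1\] and is exactly 0 whenever no
#' directed path connects input to output.
#'
#' @param net A [grn_network()].
#' @return Fitness in \[0, 1\].
#' @examples
#' grn_fitness(chain_grn(3))
#' @export
grn_fitness <- function(net) {
  p <- net$params
  cpp_fitness(net_codes(net), net$edges$sign, p$n_nodes, p$beta, p$mu,
              p$tol, p$max_iter, p$output_index)
}

# fitness after deleting each edge in turn (internal; exposed via robustness())
deletion_fitness <- function(net) {
  p <- net$params
  cpp_deletion_fitness(net_codes(net), net$edges$sign, p$n_nodes, p$beta,
                       p$mu, p$tol, p$max_iter, p$output_index)
}
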