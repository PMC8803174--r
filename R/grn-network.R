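#' Construct a regulatory network genotype
#'
#' A genotype is a signed directed graph on `params$n_nodes` genes with
#' exactly `params$n_edges` edges, at most one edge per ordered
#' (source, target) pair; self-loops are allowed, as are edges into the
#' input node and out of the output node.
#'
#' @param edges A data frame with columns `source`, `target` (0-based node
#'   ids) and `sign` (+1 or -1).
#' @param params A [grn_params()] object; `n_edges` must equal `nrow(edges)`.
#'
#' @return An object of class `grn_network`: a list with elements `edges`
#'   (a tibble) and `params`.
#' @examples
#' chain <- grn_network(
#'   data.frame(source = c(0, 1), target = c(1, 2), sign = c(1, 1)),
#'   grn_params(n_nodes = 3, n_edges = 2)
#' )
#' grn_fitness(chain)
#' @export
grn_network <- function(edges, params) {
  edges <- tibble::as_tibble(edges)[, c("source", "target", "sign")]
  edges$source <- as.integer(edges$source)
  edges$target <- as.integer(edges$target)
  edges$sign <- as.integer(edges$sign)
  validate_edges(edges, params)
  structure(list(edges = edges, params = params), class = "grn_network")
}

validate_edges <- function(edges, params) {
  N <- params$n_nodes
  if (nrow(edges) != params$n_edges) {
    stop(sprintf("expected %d edges, got %d", params$n_edges, nrow(edges)))
  }
  if (any(edges$source < 0 | edges$source >= N |
          edges$target < 0 | edges$target >= N)) {
    stop("node ids must be in 0..N-1")
  }
  if (!all(edges$sign %in% c(-1L, 1L))) stop("signs must be +1 or -1")
  code <- edges$source * N + edges$target
  if (anyDuplicated(code)) {
    stop("duplicate ordered (source, target) pair")
  }
  invisible(edges)
}

#' @export
print.grn_network <- function(x, ...) {
  p <- x$params
  cat(sprintf("<grn_network> N = %d, K = %d (input %d -> output %d)\n",
              p$n_nodes, p$n_edges, p$input_index, p$output_index))
  print(x$edges, n = 6)
  invisible(x)
}

#' @exportS3Method tibble::as_tibble
as_tibble.grn_network <- function(x, ...) x$edges

# internal packed representation: code = source * N + target
net_codes <- function(net) {
  net$edges$source * net$params$n_nodes + net$edges$target
}

net_from_codes <- function(codes, signs, params) {
  N <- params$n_nodes
  grn_network(
    tibble(source = codes %/% N, target = codes %% N, sign = as.integer(signs)),
    params
  )
}

# genotype matrix (K x 2: code, sign) as returned by the C++ engines
net_from_matrix <- function(m, params) {
  net_from_codes(m[, 1], m[, 2], params)
}

#' Draw a uniformly random network
#'
#' `n_edges` ordered pairs are drawn uniformly without replacement from the
#' \eqn{N^2} possibilities (self-loops included); each edge gets sign +1 or
#' -1 with probability 1/2.
#'
#' @param params A [grn_params()] object.
#' @return A [grn_network()].
#' @examples
#' set.seed(1)
#' random_grn(grn_params(n_nodes = 4, n_edges = 3))
#' @export
random_grn <- function(params) {
  N <- params$n_nodes
  codes <- sample.int(N^2, params$n_edges) - 1L
  signs <- sample(c(-1L, 1L), params$n_edges, replace = TRUE)
  net_from_codes(codes, signs, params)
}

#' Elementary mutation: rewire one edge
#'
#' Deletes one uniformly chosen edge and adds an edge at a uniformly chosen
#' currently-unlinked ordered pair (the freed pair may be redrawn) with a
#' fresh equiprobable sign.  The edge count is preserved and the input
#' network is left unmodified.
#'
#' @param net A [grn_network()].
#' @return A new [grn_network()] one move away from `net`.
#' @export
rewire <- function(net) {
  N <- net$params$n_nodes
  K <- net$params$n_edges
  if (K >= N^2) stop("saturated network: no unlinked ordered pair")
  codes <- net_codes(net)
  slot <- sample.int(K, 1)
  remaining <- codes[-slot]
  repeat {
    cand <- sample.int(N^2, 1) - 1L
    if (!(cand %in% remaining)) break
  }
  codes[slot] <- cand
  signs <- net$edges$sign
  signs[slot] <- sample(c(-1L, 1L), 1)
  net_from_codes(codes, signs, net$params)
}

#' Hand-built fixture networks
#'
#' `chain_grn()` builds the linear activation chain
#' 0 -> 1 -> ... -> N-1; deleting any edge disconnects input from output,
#' so every edge is essential.  `bistable_grn()` builds a three-node
#' relay 0 -> 1 -> 2 with a self-activating middle gene at steep response
#' (`beta = 6`, `mu = 0.75`).  At this steepness the auto-activation map
#' has two stable fixed points over a window of input drive, and the
#' raised threshold keeps the off state reachable from the
#' spontaneous-expression start, so both saddle-node folds fall inside
#' the input range and the circuit is a genuine toggle under the strict
#' hysteresis criterion.
#'
#' @param n_nodes Chain length for `chain_grn()`.
#' @return A [grn_network()].
#' @examples
#' robustness(chain_grn(3))
#' @export
chain_grn <- function(n_nodes = 3) {
  params <- grn_params(n_nodes = n_nodes, n_edges = n_nodes - 1)
  grn_network(
    tibble(source = 0:(n_nodes - 2), target = 1:(n_nodes - 1),
           sign = 1L),
    params
  )
}

#' @rdname chain_grn
#' @export
bistable_grn <- function() {
  params <- grn_params(n_nodes = 3, n_edges = 3, beta = 6, mu = 0.75)
  grn_network(
    tibble(source = c(0L, 1L, 1L), target = c(1L, 1L, 2L), sign = 1L),
    params
  )
}
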