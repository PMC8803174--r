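#' Number of effective nodes
#'
#' A node is effective when at least one directed path (length >= 0, so
#' the output node counts itself) leads from it to the output node.
#' Computed as reverse reachability from the output over the edge graph.
#'
#' @param net A [grn_network()].
#' @return Count in 1..N.
#' @examples
#' effective_node_count(chain_grn(4))  # 4: every chain node reaches the end
#' @export
effective_node_count <- function(net) {
  p <- net$params
  g <- igraph::graph_from_edgelist(
    cbind(net$edges$source, net$edges$target) + 1L, directed = TRUE)
  g <- igraph::add_vertices(g, max(0, p$n_nodes - igraph::vcount(g)))
  length(igraph::subcomponent(g, p$output_index + 1L, mode = "in"))
}

#' Number of simple input-to-output paths
#'
#' Counts directed paths from the input to the output node that visit no
#' node twice, by exhaustive depth-first search.  Counting aborts at
#' `cap` and sets the saturation flag (the count is then a lower bound).
#'
#' @param net A [grn_network()].
#' @param cap Abort threshold (default 1e6).
#' @return A list with `n_path` and `saturated`.
#' @examples
#' count_paths(chain_grn(3))$n_path  # 1
#' @export
count_paths <- function(net, cap = 1e6) {
  p <- net$params
  cpp_count_paths(net_codes(net), p$n_nodes, p$input_index,
                  p$output_index, cap)
}

#' Signed network motif census
#'
#' Counts the local regulation patterns compared between ensembles:
#' auto-activation and auto-repression (signed self-loops); mutual
#' activation/repression (unordered node pairs regulating each other with
#' both signs +/both signs -); coherent feed-forward loops (ordered
#' distinct triples a -> b -> c with a direct edge a -> c whose sign
#' equals the product of the indirect signs); positive feedback loops
#' (directed 3-cycles with positive sign product, each cycle counted
#' once; 2-node positive loops appear separately under the mutual
#' counts); and mutual activation/repression with auto-activation of
#' both pair members.
#'
#' @param net A [grn_network()].
#' @return A one-row tibble of the eight motif counts.
#' @examples
#' count_motifs(bistable_grn())
#' @export
count_motifs <- function(net) {
  N <- net$params$n_nodes
  A <- matrix(0L, N, N)  # A[i, j] = sign of edge i -> j
  A[cbind(net$edges$source, net$edges$target) + 1L] <- net$edges$sign
  diagA <- diag(A)

  auto_activation <- sum(diagA == 1L)
  auto_repression <- sum(diagA == -1L)

  pairs <- which(upper.tri(A), arr.ind = TRUE)
  fwd <- A[pairs]
  rev <- A[pairs[, c(2, 1), drop = FALSE]]
  mutual_activation <- sum(fwd == 1L & rev == 1L)
  mutual_repression <- sum(fwd == -1L & rev == -1L)
  both_auto <- diagA[pairs[, 1]] == 1L & diagA[pairs[, 2]] == 1L
  mutual_activation_with_auto <- sum(fwd == 1L & rev == 1L & both_auto)
  mutual_repression_with_auto <- sum(fwd == -1L & rev == -1L & both_auto)

  # triangles: iterate over edge pairs a -> b, b -> c with a, b, c distinct
  e <- net$edges
  ffl <- 0L
  fbl <- 0L
  by_source <- split(seq_len(nrow(e)), e$source)
  for (k in seq_len(nrow(e))) {
    a <- e$source[k]; b <- e$target[k]
    if (a == b) next
    for (m in by_source[[as.character(b)]]) {
      cc <- e$target[m]
      if (cc == a || cc == b) next
      s_indirect <- e$sign[k] * e$sign[m]
      direct <- A[a + 1L, cc + 1L]
      if (direct != 0L && direct == s_indirect) ffl <- ffl + 1L
      closing <- A[cc + 1L, a + 1L]
      if (closing != 0L && s_indirect * closing == 1L) fbl <- fbl + 1L
    }
  }
  tibble(auto_activation = auto_activation,
         auto_repression = auto_repression,
         mutual_activation = mutual_activation,
         mutual_repression = mutual_repression,
         ffl_coherent = ffl,
         fbl_positive = fbl %/% 3L,  # each 3-cycle found from all 3 rotations
         mutual_activation_with_auto = mutual_activation_with_auto,
         mutual_repression_with_auto = mutual_repression_with_auto)
}

#' Per-genotype analysis table
#'
#' Maps the structural and robustness statistics over a collection of
#' genotypes and returns one tidy row per genotype — the working table
#' for ensemble comparisons.
#'
#' @param networks A list of [grn_network()] objects or a tibble with a
#'   `genotype` list-column (e.g. from [run_evolution_replicates()] or a
#'   `grn_archive`'s samples).
#' @param threshold Essential-edge threshold passed to [robustness()].
#' @param criterion Optional [bistability_criterion()]; when supplied a
#'   `verdict` column is added (hysteresis sweeps are comparatively
#'   expensive).
#' @param motifs Add the motif census columns (default `FALSE`).
#' @param path_cap Cap for [count_paths()].
#' @return A tibble with columns `id`, `fitness`, `r`, `n_essential`,
#'   `n_effective`, `n_path`, plus optional `verdict` and motif columns.
#' @export
analyze_networks <- function(networks, threshold = 0.8, criterion = NULL,
                             motifs = FALSE, path_cap = 1e6) {
  nets <- if (is.data.frame(networks)) networks$genotype else networks
  nets <- nets[!vapply(nets, is.null, TRUE)]
  rows <- purrr::imap_dfr(nets, function(net, i) {
    rob <- robustness(net, threshold)
    out <- tibble(id = i, fitness = rob$fitness, r = rob$r,
                  n_essential = rob$n_essential,
                  n_effective = effective_node_count(net),
                  n_path = count_paths(net, path_cap)$n_path)
    if (!is.null(criterion)) {
      out$verdict <- hysteresis_sweep(net, criterion)$verdict
    }
    if (motifs) out <- dplyr::bind_cols(out, count_motifs(net))
    out
  })
  rows
}
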