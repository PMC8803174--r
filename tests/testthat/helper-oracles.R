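# Independent brute-force oracles, deliberately implemented with none of
# the package's compiled code paths.

# pure-R synchronous dynamics on the edge list
oracle_step <- function(net, state, input) {
  p <- net$params
  total <- numeric(p$n_nodes)
  for (k in seq_len(nrow(net$edges))) {
    tgt <- net$edges$target[k] + 1
    total[tgt] <- total[tgt] + net$edges$sign[k] * state[net$edges$source[k] + 1]
  }
  total[1] <- total[1] + input
  1 / (1 + exp(-p$beta * (total - p$mu)))
}

oracle_steady <- function(net, input, tol = 1e-9, max_iter = 10000) {
  x <- rep(0.5, net$params$n_nodes)
  for (i in seq_len(max_iter)) {
    xn <- oracle_step(net, x, input)
    if (max(abs(xn - x)) < tol) return(xn[net$params$output_index + 1])
    x <- xn
  }
  xn[net$params$output_index + 1]
}

oracle_fitness <- function(net) {
  abs(oracle_steady(net, 0) - oracle_steady(net, 1))
}

# nodes with a directed path (length >= 0) to the output, by adjacency
# matrix powers
oracle_effective_nodes <- function(net) {
  N <- net$params$n_nodes
  A <- matrix(FALSE, N, N)
  A[cbind(net$edges$source, net$edges$target) + 1] <- TRUE
  reach <- A  # transitive closure: paths of length >= 1
  for (i in seq_len(N)) reach <- reach | (reach %*% A > 0)
  out <- net$params$output_index + 1
  sum(reach[-out, out]) + 1L  # the output node counts itself (length 0)
}

# simple directed paths input -> output by plain recursion
oracle_simple_paths <- function(net) {
  N <- net$params$n_nodes
  adj <- lapply(seq_len(N), function(i) {
    unique(net$edges$target[net$edges$source == i - 1 &
                            net$edges$target != net$edges$source] + 1)
  })
  from <- net$params$input_index + 1
  to <- net$params$output_index + 1
  count <- 0L
  visit <- function(v, seen) {
    if (v == to) {
      count <<- count + 1L
      return(invisible())
    }
    for (w in adj[[v]]) if (!(w %in% seen)) visit(w, c(seen, w))
  }
  if (from == to) return(1L)
  visit(from, from)
  count
}

# motif census by explicit loops over pairs and triples
oracle_motifs <- function(net) {
  N <- net$params$n_nodes
  A <- matrix(0L, N, N)
  A[cbind(net$edges$source, net$edges$target) + 1] <- net$edges$sign
  out <- c(auto_activation = 0, auto_repression = 0, mutual_activation = 0,
           mutual_repression = 0, ffl_coherent = 0, fbl_positive = 0,
           mutual_activation_with_auto = 0, mutual_repression_with_auto = 0)
  for (i in 1:N) {
    if (A[i, i] == 1) out["auto_activation"] <- out["auto_activation"] + 1
    if (A[i, i] == -1) out["auto_repression"] <- out["auto_repression"] + 1
  }
  for (i in 1:(N - 1)) for (j in (i + 1):N) {
    if (A[i, j] == 1 && A[j, i] == 1) {
      out["mutual_activation"] <- out["mutual_activation"] + 1
      if (A[i, i] == 1 && A[j, j] == 1) {
        out["mutual_activation_with_auto"] <-
          out["mutual_activation_with_auto"] + 1
      }
    }
    if (A[i, j] == -1 && A[j, i] == -1) {
      out["mutual_repression"] <- out["mutual_repression"] + 1
      if (A[i, i] == 1 && A[j, j] == 1) {
        out["mutual_repression_with_auto"] <-
          out["mutual_repression_with_auto"] + 1
      }
    }
  }
  for (a in 1:N) for (b in 1:N) for (cc in 1:N) {
    if (length(unique(c(a, b, cc))) < 3) next
    if (A[a, b] != 0 && A[b, cc] != 0 && A[a, cc] != 0 &&
        A[a, cc] == A[a, b] * A[b, cc]) {
      out["ffl_coherent"] <- out["ffl_coherent"] + 1
    }
    # 3-cycles counted once: enumerate with a as the smallest label
    if (a < b && a < cc &&
        A[a, b] != 0 && A[b, cc] != 0 && A[cc, a] != 0 &&
        A[a, b] * A[b, cc] * A[cc, a] == 1) {
      out["fbl_positive"] <- out["fbl_positive"] + 1
    }
  }
  out
}

random_small_net <- function(n_nodes = 6, n_edges = 10, beta = 2, mu = 0) {
  random_grn(grn_params(n_nodes = n_nodes, n_edges = n_edges,
                        beta = beta, mu = mu))
}
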