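#' Read and write networks as plain edge lists
#'
#' The on-disk format is a tab-separated edge list with header
#' `source  target  sign` (0-based node ids, one edge per line), preceded
#' by `#`-comment lines carrying the model parameters
#' (`# n_nodes=32`, `# n_edges=80`, `# beta=2`, ...).  The round trip is
#' lossless; malformed files are rejected with the offending line.
#'
#' @param path File path.
#' @param net A [grn_network()].
#' @return `read_grn()` a [grn_network()]; `write_grn()` `path`,
#'   invisibly.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' write_grn(chain_grn(3), f)
#' read_grn(f)
#' @export
read_grn <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  kv <- list()
  for (h in hdr) {
    m <- regmatches(h, regexec("^#\\s*([A-Za-z_]+)\\s*=\\s*(\\S+)", h))[[1]]
    if (length(m) == 3) kv[[m[2]]] <- as.numeric(m[3])
  }
  need <- c("n_nodes", "n_edges")
  if (!all(need %in% names(kv))) {
    stop("missing header comments: need at least # n_nodes= and # n_edges=")
  }
  params <- grn_params(
    n_nodes = kv$n_nodes, n_edges = kv$n_edges,
    beta = if (is.null(kv$beta)) 2 else kv$beta,
    mu = if (is.null(kv$mu)) 0 else kv$mu,
    output_index = if (is.null(kv$output_index)) kv$n_nodes - 1
                   else kv$output_index,
    tol = if (is.null(kv$tol)) 1e-9 else kv$tol,
    max_iter = if (is.null(kv$max_iter)) 10000L else kv$max_iter
  )
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(body) == 0) stop("no edge lines found")
  if (trimws(body[1]) != paste("source", "target", "sign", sep = "\t")) {
    stop("first non-comment line must be the header 'source\\ttarget\\tsign'")
  }
  edge_lines <- body[-1]
  parts <- strsplit(edge_lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 3)
  if (length(bad) > 0) {
    stop(sprintf("malformed edge line %d: '%s'", bad[1], edge_lines[bad[1]]))
  }
  m <- matrix(suppressWarnings(as.integer(unlist(parts))),
              ncol = 3, byrow = TRUE)
  if (anyNA(m)) {
    stop(sprintf("non-integer field on edge line %d",
                 which(rowSums(is.na(m)) > 0)[1]))
  }
  edges <- tibble(source = m[, 1], target = m[, 2], sign = m[, 3])
  code <- edges$source * params$n_nodes + edges$target
  dup <- which(duplicated(code))
  if (length(dup) > 0) {
    stop(sprintf("duplicate ordered pair on edge line %d", dup[1]))
  }
  grn_network(edges, params)
}

#' @rdname read_grn
#' @export
write_grn <- function(net, path) {
  p <- net$params
  hdr <- c(
    sprintf("# n_nodes=%d", p$n_nodes),
    sprintf("# n_edges=%d", p$n_edges),
    sprintf("# beta=%.17g", p$beta),
    sprintf("# mu=%.17g", p$mu),
    sprintf("# output_index=%d", p$output_index),
    sprintf("# tol=%.17g", p$tol),
    sprintf("# max_iter=%d", p$max_iter),
    paste("source", "target", "sign", sep = "\t")
  )
  body <- sprintf("%d\t%d\t%d", net$edges$source, net$edges$target,
                  net$edges$sign)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read and write per-bin weight tables
#'
#' CSV with columns `bin_index, f_lo, f_hi, log_weight, visits`.
#'
#' @param weights A `grn_weights` object.
#' @param path File path.
#' @return `read_weights()` a `grn_weights` object.
#' @export
write_weights <- function(weights, path) {
  readr::write_csv(
    tidy(weights) |>
      dplyr::rename(bin_index = "bin"),
    path
  )
  invisible(path)
}

#' @rdname write_weights
#' @export
read_weights <- function(path) {
  tb <- readr::read_csv(path, show_col_types = FALSE)
  binning <- fitness_binning(nrow(tb))
  w <- new_weight_table(tb$log_weight, tb$visits, binning,
                        converged = NA, ln_f = NA_real_)
  w$visited <- tb$visits > 0 | tb$log_weight != 0
  w
}

#' Write an entropy estimate table
#'
#' CSV with columns `bin_index, f_lo, f_hi, omega, log10_omega`.
#'
#' @param entropy Tibble from [estimate_entropy()].
#' @param path File path.
#' @export
write_entropy <- function(entropy, path) {
  readr::write_csv(
    entropy |>
      dplyr::rename(bin_index = "bin") |>
      dplyr::select("bin_index", "f_lo", "f_hi", "omega", "log10_omega"),
    path
  )
  invisible(path)
}

#' Read and write sample archives
#'
#' Newline-delimited records, one per sampled genotype: the Monte Carlo
#' step index, the fitness at full precision, and the serialized edge
#' list (`source:target:sign` triples separated by spaces).
#'
#' @param archive A `grn_archive`.
#' @param path File path (a `.gz` suffix gives a compressed file).
#' @return `read_archive()` a `grn_archive` (without weight metadata).
#' @export
write_archive <- function(archive, path) {
  p <- archive$params
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# n_nodes=%d n_edges=%d beta=%.17g mu=%.17g output_index=%d",
                     p$n_nodes, p$n_edges, p$beta, p$mu, p$output_index), con)
  N <- p$n_nodes
  for (i in seq_len(nrow(archive$samples))) {
    g <- archive$samples$genotype[[i]]
    m <- if (inherits(g, "grn_network")) {
      cbind(g$edges$source * N + g$edges$target, g$edges$sign)
    } else g
    writeLines(sprintf(
      "%d\t%.17g\t%s", archive$samples$mcs[i], archive$samples$fitness[i],
      paste(sprintf("%d:%d:%d", m[, 1] %/% N, m[, 1] %% N, m[, 2]),
            collapse = " ")), con)
  }
  invisible(path)
}

#' @rdname write_archive
#' @export
read_archive <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "r") else file(path, "r")
  on.exit(close(con))
  lines <- readLines(con)
  hdr <- lines[1]
  gv <- function(key) {
    as.numeric(sub(sprintf(".*%s=([-0-9.eE+]+).*", key), "\\1", hdr))
  }
  params <- grn_params(n_nodes = gv("n_nodes"), n_edges = gv("n_edges"),
                       beta = gv("beta"), mu = gv("mu"),
                       output_index = gv("output_index"))
  N <- params$n_nodes
  body <- lines[-1]
  recs <- strsplit(body, "\t", fixed = TRUE)
  genos <- lapply(recs, function(r) {
    tri <- do.call(rbind, strsplit(strsplit(r[3], " ", fixed = TRUE)[[1]],
                                   ":", fixed = TRUE))
    storage.mode(tri) <- "integer"
    cbind(tri[, 1] * N + tri[, 2], tri[, 3])
  })
  structure(
    list(samples = tibble(
           mcs = vapply(recs, function(r) as.integer(r[1]), 0L),
           fitness = vapply(recs, function(r) as.numeric(r[2]), 0),
           genotype = genos),
         visits = NULL, acceptance_rate = NA_real_,
         log_weights = NULL, binning = fitness_binning(), params = params),
    class = "grn_archive"
  )
}

#' Run configuration files
#'
#' YAML key-value files carrying the model parameters, sampler schedule,
#' evolution settings and the master seed; the round trip through
#' [write_run_config()]/[read_run_config()] is lossless.
#'
#' @param config A named list, e.g. from [default_run_config()].
#' @param path File path.
#' @return `read_run_config()` the named list.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  yaml::read_yaml(path)
}

#' @rdname write_run_config
#' @param profile `"desk"` (reduced Monte Carlo length and replicate
#'   counts, minutes on one core) or `"full"` (the production protocol:
#'   10 runs of 1e7 MCS and 1e5 Evo50 lineages, cluster scale).
#' @export
default_run_config <- function(profile = c("desk", "full")) {
  profile <- match.arg(profile)
  full <- profile == "full"
  list(
    seed = 1L,
    model = list(n_nodes = 32L, n_edges = 80L, beta = 2, mu = 0,
                 output_index = 31L, tol = 1e-9, max_iter = 10000L),
    sampler = list(n_bins = 100L, ln_f_init = 1.0, flatness = 0.8,
                   ln_f_min = 1e-6,
                   wl_max_mcs = if (full) 2e6 else 2e4,
                   runs = if (full) 10L else 1L,
                   n_mcs = if (full) 1e7 else 2e4,
                   sample_every = 20L, burn_in = 1000L),
    evolution = list(population_size = 1000L,
                     evo50_generations = 150L, evo90_generations = 200L,
                     replicates = if (full) 100000L else 100L),
    analysis = list(essential_threshold = 0.8, path_cap = 1e6,
                    criterion = "strict", n_sub = 10L)
  )
}

#' Derive child seeds from a master seed
#'
#' One master seed spawns one child seed per independent stochastic
#' component (replicates, runs); children are drawn from a seeded stream
#' and kept below 2^31 so they are valid R seeds.
#'
#' @param master_seed Integer master seed.
#' @param n Number of child seeds.
#' @return Integer vector of length `n`.
#' @export
derive_seeds <- function(master_seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(master_seed)
  sample.int(.Machine$integer.max - 1L, n)
}
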