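#' Fitness binning
#'
#' Fitness in \[0, 1\] is divided into `n_bins` equal bins; bin `i` covers
#' `[i/n, (i+1)/n)` except the last bin, which is closed at 1.
#'
#' @param n_bins Number of bins (default 100).
#' @return An object of class `fitness_binning`.
#' @export
fitness_binning <- function(n_bins = 100) {
  stopifnot(n_bins >= 1)
  structure(list(n_bins = as.integer(n_bins),
                 edges = seq(0, 1, length.out = n_bins + 1)),
            class = "fitness_binning")
}

#' @rdname fitness_binning
#' @param f Fitness value(s) in \[0, 1\].
#' @param binning A [fitness_binning()].
#' @return `bin_of()`: 0-based bin index (f = 1 falls in the last bin).
#' @examples
#' b <- fitness_binning(100)
#' bin_of(c(0, 0.9899, 0.99, 0.995, 1), b)
#' @export
bin_of <- function(f, binning = fitness_binning()) {
  if (any(f < 0 | f > 1)) stop("fitness outside [0, 1]")
  pmin(as.integer(floor(f * binning$n_bins)), binning$n_bins - 1L)
}

new_weight_table <- function(log_w, visits, binning, converged, ln_f) {
  structure(list(log_weights = log_w, visits = visits, binning = binning,
                 converged = converged, final_ln_f = ln_f),
            class = "grn_weights")
}

#' @export
print.grn_weights <- function(x, ...) {
  cat(sprintf("<grn_weights> %d bins, %d visited, final ln(f) = %.2g%s\n",
              x$binning$n_bins, sum(x$visits > 0), x$final_ln_f,
              if (x$converged) "" else " (schedule not converged)"))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.grn_weights <- function(x, ...) {
  n <- x$binning$n_bins
  tibble(bin = 0:(n - 1),
         f_lo = x$binning$edges[-(n + 1)],
         f_hi = x$binning$edges[-1],
         log_weight = x$log_weights,
         visits = x$visits)
}

#' Wang-Landau determination of multicanonical weights
#'
#' Builds per-fitness-bin log-weights `log_w` (an estimate of
#' \eqn{-\log \Omega}) such that a Metropolis chain accepting rewire moves
#' with probability `min(1, exp(log_w[new bin] - log_w[old bin]))` visits
#' the fitness bins near-uniformly.  The schedule is the conventional one:
#' after every elementary update the current bin is penalised by `ln_f`;
#' when the visit histogram over the already-visited bins is flat (minimum
#' count at least `flatness` times the mean) `ln_f` is halved and the
#' histogram reset; the run stops when `ln_f < ln_f_min` or the update
#' budget is exhausted (in which case the partial result is returned with
#' `converged = FALSE`).  Bins never visited keep the initial weight 0,
#' which is the maximum, so proposals into unexplored bins are always
#' accepted and the chain is driven toward them.
#'
#' @param params A [grn_params()] object.
#' @param binning A [fitness_binning()].
#' @param ln_f_init Initial modification factor (natural log scale).
#' @param flatness Flatness criterion (fraction of the mean count).
#' @param ln_f_min Stop threshold for the modification factor.
#' @param mcs_per_check Monte Carlo steps (1 MCS = K updates) between
#'   flatness checks.
#' @param max_mcs Total MCS budget.
#' @param init Optional starting [grn_network()]; a random draw otherwise.
#' @return A `grn_weights` object; `tidy()` gives the per-bin table.
#' @export
wang_landau <- function(params, binning = fitness_binning(),
                        ln_f_init = 1.0, flatness = 0.8, ln_f_min = 1e-6,
                        mcs_per_check = 200L, max_mcs = 1e5, init = NULL) {
  net <- if (is.null(init)) random_grn(params) else init
  nb <- binning$n_bins
  log_w <- numeric(nb)
  hist <- integer(nb)
  visited <- logical(nb)
  ln_f <- ln_f_init
  codes <- net_codes(net)
  signs <- net$edges$sign
  f <- -1
  used <- 0
  while (used < max_mcs && ln_f >= ln_f_min) {
    chunk <- as.integer(min(mcs_per_check, max_mcs - used))
    r <- cpp_mc_run(codes, signs, params$n_nodes, log_w, hist, chunk,
                    TRUE, ln_f, 0L, params$beta, params$mu, params$tol,
                    params$max_iter, params$output_index, f)
    codes <- r$codes; signs <- r$signs; f <- r$fitness
    log_w <- r$log_w; hist <- r$hist
    used <- used + chunk
    visited <- visited | hist > 0
    h <- hist[visited]
    if (length(h) > 0 && min(h) >= flatness * mean(h)) {
      ln_f <- ln_f / 2
      hist <- integer(nb)
    }
  }
  converged <- ln_f < ln_f_min
  if (!converged) {
    warning("Wang-Landau schedule did not converge within the MCS budget; ",
            "returning partial weights")
  }
  w <- new_weight_table(log_w, as.integer(visited), binning, converged, ln_f)
  w$visits <- hist
  w$visited <- visited
  w$state <- list(codes = codes, signs = signs, fitness = f)
  w$params <- params
  w
}

#' Entropic (multicanonical) production sampling
#'
#' Runs the Metropolis chain with fixed weights and records the genotype
#' every `sample_every` MCS after a burn-in.  With converged weights the
#' visit histogram is flat and the recorded genotypes are, within each
#' bin, uniform random draws from that fitness class.
#'
#' @param params A [grn_params()] object.
#' @param weights A `grn_weights` object from [wang_landau()] (or a
#'   numeric vector of per-bin log-weights).
#' @param n_mcs Number of Monte Carlo steps (1 MCS = K elementary updates).
#' @param sample_every Recording interval in MCS (default 20).
#' @param burn_in MCS discarded before recording starts (default 1000).
#' @param binning A [fitness_binning()]; taken from `weights` when absent.
#' @param init Optional starting [grn_network()].
#' @return A `grn_archive`: `$samples` is a tibble with columns `mcs`,
#'   `fitness` and a `genotype` list-column; `$visits` holds the per-bin
#'   visit histogram of the production phase.
#' @export
mucamc_sample <- function(params, weights, n_mcs, sample_every = 20L,
                          burn_in = 1000L, binning = NULL, init = NULL) {
  if (inherits(weights, "grn_weights")) {
    if (is.null(binning)) binning <- weights$binning
    log_w <- weights$log_weights
  } else {
    log_w <- as.numeric(weights)
    if (is.null(binning)) binning <- fitness_binning(length(log_w))
  }
  net <- if (is.null(init)) random_grn(params) else init
  codes <- net_codes(net)
  signs <- net$edges$sign
  f <- -1
  if (burn_in > 0) {
    r <- cpp_mc_run(codes, signs, params$n_nodes, log_w, integer(binning$n_bins),
                    as.integer(burn_in), FALSE, 0, 0L, params$beta, params$mu,
                    params$tol, params$max_iter, params$output_index, f)
    codes <- r$codes; signs <- r$signs; f <- r$fitness
  }
  r <- cpp_mc_run(codes, signs, params$n_nodes, log_w, integer(binning$n_bins),
                  as.integer(n_mcs), FALSE, 0, as.integer(sample_every),
                  params$beta, params$mu, params$tol, params$max_iter,
                  params$output_index, f)
  structure(
    list(samples = tibble(mcs = r$sample_mcs, fitness = r$sample_f,
                          genotype = r$samples),
         visits = r$hist,
         acceptance_rate = r$acceptance_rate,
         log_weights = log_w, binning = binning, params = params),
    class = "grn_archive"
  )
}

#' @export
print.grn_archive <- function(x, ...) {
  cat(sprintf("<grn_archive> %d samples, %d bins visited, acceptance %.2f\n",
              nrow(x$samples), sum(x$visits > 0), x$acceptance_rate))
  invisible(x)
}

#' @exportS3Method tibble::as_tibble
as_tibble.grn_archive <- function(x, ...) x$samples

#' Merge production archives from independent runs
#'
#' @param ... `grn_archive` objects produced with the same weights.
#' @return A single `grn_archive` with concatenated samples and summed
#'   visit histograms.
#' @export
combine_archives <- function(...) {
  xs <- list(...)
  if (length(xs) == 1 && is.list(xs[[1]]) && !inherits(xs[[1]], "grn_archive")) {
    xs <- xs[[1]]
  }
  out <- xs[[1]]
  out$samples <- dplyr::bind_rows(lapply(xs, function(a) a$samples))
  out$visits <- Reduce(`+`, lapply(xs, function(a) a$visits))
  out$acceptance_rate <- mean(vapply(xs, function(a) a$acceptance_rate, 0))
  out
}

#' Genotypic entropy estimate
#'
#' Converts flat-histogram visitation into the appearance probability
#' \eqn{\Omega(f)} of each fitness bin under uniform random sampling: the
#' per-bin counts are reweighted by \eqn{e^{-\log w}} (undoing the
#' multicanonical bias) and normalised to total probability 1 over the
#' visited bins.
#'
#' @param x A `grn_archive` (counts taken from the recorded samples) or a
#'   `grn_weights` object (counts taken as the flat-histogram visitation,
#'   i.e. uniform over visited bins).
#' @param binning A [fitness_binning()]; taken from `x` when absent.
#' @return A tibble with columns `bin`, `f_lo`, `f_hi`, `n`, `omega`,
#'   `log10_omega`; unvisited bins carry `NA`.
#' @export
estimate_entropy <- function(x, binning = NULL) {
  if (inherits(x, "grn_archive")) {
    if (is.null(binning)) binning <- x$binning
    counts <- tabulate(bin_of(x$samples$fitness, binning) + 1L,
                       nbins = binning$n_bins)
    if (sum(counts) == 0) stop("empty archive")
    log_w <- x$log_weights
  } else if (inherits(x, "grn_weights")) {
    if (is.null(binning)) binning <- x$binning
    counts <- as.integer(x$visited)
    log_w <- x$log_weights
  } else {
    stop("x must be a grn_archive or grn_weights object")
  }
  occupied <- counts > 0
  # log Omega_b (up to a constant) = log n_b - log_w_b
  lo <- ifelse(occupied, log(counts) - log_w, NA_real_)
  m <- max(lo, na.rm = TRUE)
  omega <- exp(lo - m)
  omega <- omega / sum(omega, na.rm = TRUE)
  n <- binning$n_bins
  tibble(bin = 0:(n - 1),
         f_lo = binning$edges[-(n + 1)],
         f_hi = binning$edges[-1],
         n = counts,
         omega = omega,
         log10_omega = log10(omega))
}

#' Expected samples per bin for a sampling protocol
#'
#' Book-keeping of the recording schedule: `runs` independent runs of
#' `n_mcs` MCS each, one genotype recorded every `sample_every` MCS,
#' spread over `n_bins` near-uniformly visited bins.
#'
#' @param runs,n_mcs,sample_every,n_bins Protocol parameters.
#' @return Average number of recorded genotypes per fitness bin.
#' @examples
#' samples_per_bin(runs = 10, n_mcs = 1e7)  # 50,000
#' @export
samples_per_bin <- function(runs, n_mcs, sample_every = 20, n_bins = 100) {
  runs * n_mcs / sample_every / n_bins
}

#' Exhaustively enumerate a small genotype space
#'
#' Lists every genotype (all \eqn{\binom{N^2}{K} 2^K} of them) with its
#' exact fitness.  Intended as the brute-force oracle for the Monte Carlo
#' machinery on toy spaces; refuses spaces larger than `guard`.
#'
#' @param params A [grn_params()] object.
#' @param guard Maximum admissible genotype count (default 1e5).
#' @return A tibble with columns `id`, `fitness` and a `genotype`
#'   list-column of [grn_network()] objects.
#' @examples
#' nrow(enumerate_genotypes(grn_params(3, 2)))  # 144
#' @export
enumerate_genotypes <- function(params, guard = 1e5) {
  total <- choose(params$n_nodes^2, params$n_edges) * 2^params$n_edges
  if (total > guard) {
    stop(sprintf("genotype space has %.3g members, above the guard of %g",
                 total, guard))
  }
  K <- params$n_edges
  topo <- utils::combn(params$n_nodes^2, K) - 1L
  sign_grid <- as.matrix(expand.grid(rep(list(c(-1L, 1L)), K)))
  nets <- vector("list", as.integer(total))
  fit <- numeric(as.integer(total))
  id <- 0L
  for (t in seq_len(ncol(topo))) {
    for (s in seq_len(nrow(sign_grid))) {
      id <- id + 1L
      net <- net_from_codes(topo[, t], sign_grid[s, ], params)
      nets[[id]] <- net
      fit[id] <- grn_fitness(net)
    }
  }
  tibble(id = seq_len(id), fitness = fit, genotype = nets)
}

#' Single multicanonical Metropolis update
#'
#' Proposes one rewire move and accepts it with probability
#' `min(1, exp(log_w[new bin] - log_w[old bin]))`.  On rejection the input
#' genotype is returned unchanged.  This is the elementary update of the
#' chain; the compiled engine used by [wang_landau()] and
#' [mucamc_sample()] applies exactly this rule.
#'
#' @param net A [grn_network()].
#' @param f Cached fitness of `net` (recomputed when `NULL`).
#' @param weights A `grn_weights` object or per-bin log-weight vector.
#' @param binning A [fitness_binning()]; taken from `weights` when absent.
#' @return A list with `net`, `fitness` and `accepted`.
#' @export
metropolis_update <- function(net, f = NULL, weights,
                              binning = NULL) {
  if (inherits(weights, "grn_weights")) {
    if (is.null(binning)) binning <- weights$binning
    log_w <- weights$log_weights
  } else {
    log_w <- as.numeric(weights)
    if (is.null(binning)) binning <- fitness_binning(length(log_w))
  }
  if (is.null(f)) f <- grn_fitness(net)
  prop <- rewire(net)
  fp <- grn_fitness(prop)
  la <- log_w[bin_of(fp, binning) + 1L] - log_w[bin_of(f, binning) + 1L]
  if (la >= 0 || stats::runif(1) < exp(la)) {
    list(net = prop, fitness = fp, accepted = TRUE)
  } else {
    list(net = net, fitness = f, accepted = FALSE)
  }
}

#' Materialise archive samples as network objects
#'
#' @param archive A `grn_archive`.
#' @return A list of [grn_network()] objects, one per recorded sample.
#' @export
archive_networks <- function(archive) {
  lapply(archive$samples$genotype, function(g) {
    if (inherits(g, "grn_network")) g
    else net_from_matrix(g, archive$params)
  })
}
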