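#' Configuration for a truncation-selection evolutionary run
#'
#' Two protocols act on a fixed-size population (default 1000 random
#' founders).  Each generation the population is ranked by fitness.
#' `evo50` preserves the top half unchanged and lets each preserved
#' individual parent one mutated copy (one rewire move).  `evo90`
#' preserves the top 90% and draws 100 parents uniformly with replacement
#' from the preserved set, each parenting one mutated copy.  An optional
#' fitness cap truncates fitness at `fitness_cap` for both selection and
#' reporting, which makes selection among capped individuals neutral.
#'
#' @param mode `"evo50"` or `"evo90"`.
#' @param population_size Number of individuals (default 1000).
#' @param generations Number of generations; defaults to 150 for `evo50`
#'   and 200 for `evo90`.
#' @param fitness_cap Optional cap in (0, 1\]; `NULL` for none.
#' @param snapshot_every For capped runs, record all individuals sitting
#'   at the cap every this many generations (`NULL` to disable).
#' @return An object of class `evolution_config`.
#' @export
evolution_config <- function(mode = c("evo50", "evo90"),
                             population_size = 1000L,
                             generations = NULL,
                             fitness_cap = NULL,
                             snapshot_every = NULL) {
  mode <- match.arg(mode)
  population_size <- as.integer(population_size)
  n_keep <- if (mode == "evo50") population_size %/% 2L
            else as.integer(round(0.9 * population_size))
  n_off <- population_size - n_keep
  if (mode == "evo90") n_off <- population_size %/% 10L
  if (n_keep + n_off != population_size) {
    stop("population_size incompatible with the mode arithmetic")
  }
  if (is.null(generations)) generations <- if (mode == "evo50") 150L else 200L
  if (!is.null(fitness_cap)) {
    stopifnot(fitness_cap > 0, fitness_cap <= 1)
  }
  structure(list(mode = mode, population_size = population_size,
                 n_keep = n_keep, n_offspring = n_off,
                 generations = as.integer(generations),
                 fitness_cap = fitness_cap,
                 snapshot_every = snapshot_every),
            class = "evolution_config")
}

#' @export
print.evolution_config <- function(x, ...) {
  cat(sprintf("<evolution_config> %s: %d individuals (%d preserved + %d offspring), %d generations%s\n",
              x$mode, x$population_size, x$n_keep, x$n_offspring,
              x$generations,
              if (is.null(x$fitness_cap)) ""
              else sprintf(", fitness cap %.3g", x$fitness_cap)))
  invisible(x)
}

#' One generation of truncation selection
#'
#' Pure-R reference implementation of the generation step, operating on a
#' population tibble.  Ranking is a stable sort on fitness (descending)
#' with index tie-break; preserved individuals keep their identity and
#' each offspring differs from its parent by one `mutate_fn` application.
#' The compiled driver behind [run_evolution()] applies exactly the same
#' rule; this function exists for small populations, experimentation and
#' testing (where `mutate_fn` can be stubbed).
#'
#' @param population A tibble with columns `fitness` and `network`
#'   (list-column of [grn_network()]).
#' @param config An [evolution_config()].
#' @param mutate_fn Mutation operator applied to each offspring
#'   (default [rewire()]).
#' @return A tibble of the same shape with an added `parent` column: the
#'   row index in the input population of the individual itself (for
#'   preserved rows) or of its parent (for offspring rows).
#' @export
evolve_generation <- function(population, config, mutate_fn = rewire) {
  stopifnot(nrow(population) == config$population_size)
  cap <- config$fitness_cap
  f <- population$fitness
  if (!is.null(cap)) f <- pmin(f, cap)
  ord <- order(-f, seq_along(f))
  keep <- ord[seq_len(config$n_keep)]
  parents <- if (config$mode == "evo50") {
    keep[seq_len(config$n_offspring)]
  } else {
    keep[sample.int(config$n_keep, config$n_offspring, replace = TRUE)]
  }
  offspring <- lapply(population$network[parents], mutate_fn)
  off_f <- vapply(offspring, grn_fitness, 0)
  if (!is.null(cap)) off_f <- pmin(off_f, cap)
  tibble(
    fitness = c(f[keep], off_f),
    network = c(population$network[keep], offspring),
    parent = c(keep, parents)
  )
}

#' Run an evolutionary simulation and trace the winning lineage
#'
#' Evolves a random founder population under the configured protocol,
#' then takes the highest-fitness individual of the final generation and
#' traces its ancestors back to the founding genotype.  Consecutive
#' lineage genotypes differ by at most one rewire move (exactly one where
#' the ancestor was an offspring that generation).
#'
#' @param config An [evolution_config()].
#' @param params A [grn_params()] object.
#' @param store_genotypes Keep the lineage genotypes (default `TRUE`);
#'   with `FALSE` only fitness trajectories are returned.
#' @return An object of class `grn_evolution` with `$lineage` (tibble:
#'   `generation`, `fitness`, `genotype` list-column of [grn_network()]),
#'   `$summary` (tibble: per-generation population `mean_fitness`,
#'   `max_fitness`), and for capped runs `$snapshots` and
#'   `$first_all_capped`.  `tidy()` returns the lineage rows,
#'   `glance()` a one-row run summary.
#' @examples
#' \donttest{
#' set.seed(1)
#' cfg <- evolution_config("evo50", population_size = 20, generations = 5)
#' run <- run_evolution(cfg, grn_params(n_nodes = 6, n_edges = 8))
#' glance(run)
#' }
#' @export
run_evolution <- function(config, params = grn_params(),
                          store_genotypes = TRUE) {
  cap <- if (is.null(config$fitness_cap)) -1 else config$fitness_cap
  snap <- if (is.null(config$snapshot_every)) 0L
          else as.integer(config$snapshot_every)
  r <- cpp_evolve(params$n_nodes, params$n_edges, config$population_size,
                  config$n_keep, config$n_offspring,
                  if (config$mode == "evo50") 0L else 1L,
                  config$generations, params$beta, params$mu, params$tol,
                  params$max_iter, params$output_index, cap, snap,
                  store_genotypes)
  G <- config$generations
  lineage <- tibble(
    generation = 0:G,
    fitness = r$lineage_fitness,
    genotype = if (store_genotypes) {
      lapply(r$lineage_genotypes, net_from_matrix, params = params)
    } else {
      vector("list", G + 1)
    }
  )
  snapshots <- NULL
  if (snap > 0 && length(r$snapshots) > 0) {
    snapshots <- purrr::map_dfr(r$snapshots, function(s) {
      tibble(generation = s$generation, fitness = s$fitness,
             genotype = lapply(s$genotypes, net_from_matrix, params = params))
    })
  }
  structure(
    list(lineage = lineage,
         summary = tibble(generation = 0:G, mean_fitness = r$mean_fitness,
                          max_fitness = r$max_fitness),
         snapshots = snapshots,
         first_all_capped = if (r$first_all_capped < 0) NA_integer_
                            else r$first_all_capped,
         config = config, params = params),
    class = "grn_evolution"
  )
}

#' @export
print.grn_evolution <- function(x, ...) {
  cat(sprintf("<grn_evolution> %s, %d generations; final lineage fitness %.4f\n",
              x$config$mode, x$config$generations,
              x$lineage$fitness[nrow(x$lineage)]))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.grn_evolution <- function(x, ...) {
  x$lineage[, c("generation", "fitness")]
}

#' @exportS3Method generics::glance
glance.grn_evolution <- function(x, ...) {
  tibble(mode = x$config$mode,
         generations = x$config$generations,
         population_size = x$config$population_size,
         final_fitness = x$lineage$fitness[nrow(x$lineage)],
         final_max_fitness = x$summary$max_fitness[nrow(x$summary)],
         first_all_capped = x$first_all_capped)
}

#' Replicated evolutionary runs
#'
#' Runs `replicates` independent simulations and row-binds the traced
#' lineages.  Lineage genotypes are kept only for rows with fitness at or
#' above `keep_genotypes_above` to bound memory across many replicates.
#'
#' @param replicates Number of independent runs.
#' @param config An [evolution_config()].
#' @param params A [grn_params()] object.
#' @param keep_genotypes_above Fitness threshold above which lineage
#'   genotypes are retained (default 0, keeping all).
#' @return A tibble with columns `replicate`, `generation`, `fitness`,
#'   `genotype` (list-column, `NULL` where dropped).
#' @export
run_evolution_replicates <- function(replicates, config,
                                     params = grn_params(),
                                     keep_genotypes_above = 0) {
  purrr::map_dfr(seq_len(replicates), function(rep) {
    run <- run_evolution(config, params)
    lin <- run$lineage
    drop <- lin$fitness < keep_genotypes_above
    lin$genotype[drop] <- list(NULL)
    lin$replicate <- rep
    lin[, c("replicate", "generation", "fitness", "genotype")]
  })
}

#' Fitness-capped long run reaching the neutral steady state
#'
#' Convenience wrapper for the capped protocol: `evo90` with
#' `fitness_cap` (default 0.99) run for `generations`, recording every
#' `snapshot_every` generations all individuals whose capped fitness sits
#' at the cap.  Once every preserved individual reaches the cap,
#' selection among them is neutral and the population drifts; the
#' returned `first_all_capped` marks the generation where that regime
#' starts.
#'
#' @param params A [grn_params()] object.
#' @param generations Total generations to run.
#' @param fitness_cap The cap (default 0.99).
#' @param snapshot_every Snapshot interval in generations (default 2000).
#' @param population_size Population size (default 1000).
#' @return A `grn_evolution` object whose `$snapshots` tibble holds the
#'   capped individuals at each snapshot.
#' @export
run_capped_evolution <- function(params = grn_params(), generations,
                                 fitness_cap = 0.99, snapshot_every = 2000L,
                                 population_size = 1000L) {
  cfg <- evolution_config("evo90", population_size = population_size,
                          generations = generations,
                          fitness_cap = fitness_cap,
                          snapshot_every = snapshot_every)
  run_evolution(cfg, params)
}
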