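#' Bistability detection criteria
#'
#' The strict criterion (`delta_I = 0.001`, `x_th = 1e-6`) separates
#' monostable from bistable dynamical systems as sharply as the grid
#' allows; the loose criterion (`delta_I = 0.01`, `x_th = 0.5`) keeps only
#' differences large enough to matter biologically.
#'
#' @param delta_I Input grid spacing (must divide 1 evenly).
#' @param x_th Threshold on the branch gap in the output level.
#' @return A list with `delta_I` and `x_th`.
#' @export
bistability_criterion <- function(delta_I = 0.001, x_th = 1e-6) {
  stopifnot(delta_I > 0, x_th > 0,
            abs(1 / delta_I - round(1 / delta_I)) < 1e-9)
  list(delta_I = delta_I, x_th = x_th)
}

#' @rdname bistability_criterion
#' @export
strict_criterion <- function() bistability_criterion(0.001, 1e-6)

#' @rdname bistability_criterion
#' @export
loose_criterion <- function() bistability_criterion(0.01, 0.5)

#' Hysteresis sweep over the input range
#'
#' The up-sweep starts from the steady state reached from spontaneous
#' expression (all nodes 0.5) at `I = 0`, then raises `I` by `delta_I`
#' per step, warm-starting each solve from the previous steady state up
#' to `I = 1`.  The down-sweep mirrors the protocol from its own cold
#' start at `I = 1`.  The network is bistable when the two branches
#' differ by more than `x_th` anywhere on the grid.
#'
#' @param net A [grn_network()].
#' @param criterion A [bistability_criterion()] (default strict).
#' @return An object of class `grn_bistability`: `verdict`
#'   (`"monostable"`/`"bistable"`), `max_gap`, `branches` (tibble `I`,
#'   `up`, `down`), `all_converged`, and the criterion used.
#' @examples
#' hysteresis_sweep(bistable_grn(), loose_criterion())
#' @export
hysteresis_sweep <- function(net, criterion = strict_criterion()) {
  p <- net$params
  r <- cpp_hysteresis(net_codes(net), net$edges$sign, p$n_nodes,
                      criterion$delta_I, p$beta, p$mu, p$tol, p$max_iter,
                      p$output_index)
  structure(
    list(verdict = if (r$max_gap > criterion$x_th) "bistable" else "monostable",
         max_gap = r$max_gap,
         branches = tibble(I = r$I, up = r$up, down = r$down),
         all_converged = r$all_converged,
         criterion = criterion),
    class = "grn_bistability"
  )
}

#' @export
print.grn_bistability <- function(x, ...) {
  cat(sprintf("<grn_bistability> %s (max branch gap %.3g, dI = %g, x_th = %g)\n",
              x$verdict, x$max_gap, x$criterion$delta_I, x$criterion$x_th))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.grn_bistability <- function(x, ...) x$branches

#' Is a network bistable?
#'
#' @inheritParams hysteresis_sweep
#' @return Logical.
#' @export
is_bistable <- function(net, criterion = strict_criterion()) {
  hysteresis_sweep(net, criterion)$verdict == "bistable"
}

#' Classify a bistable switch
#'
#' A saddle-node bifurcation shows up in a sweep as a discontinuous jump
#' of the followed branch between adjacent grid points.  With jumps in
#' both sweeps inside the input range the network is a toggle switch;
#' with a jump in exactly one sweep it is a one-way switch; with
#' diverging branches but no jump both folds lie outside \[0, 1\] and the
#' switch is unswitchable within the admissible input range.
#'
#' @param report A `grn_bistability` from [hysteresis_sweep()] with a
#'   bistable verdict.
#' @param jump_threshold Jump size separating branch-following drift from
#'   a saddle-node jump (default 0.1).
#' @return `"toggle"`, `"one_way"` or `"unswitchable"`.
#' @export
classify_switch <- function(report, jump_threshold = 0.1) {
  if (report$verdict != "bistable") {
    stop("switch classification is defined for bistable reports only")
  }
  b <- report$branches
  up_jump <- any(abs(diff(b$up)) > jump_threshold)
  down_jump <- any(abs(diff(b$down)) > jump_threshold)
  if (up_jump && down_jump) "toggle"
  else if (up_jump || down_jump) "one_way"
  else "unswitchable"
}

#' Fraction of bistable networks per fitness bin
#'
#' @param networks A list of [grn_network()] objects, or a tibble with a
#'   `genotype` list-column and optionally a `fitness` column (recomputed
#'   when absent).
#' @param binning A [fitness_binning()].
#' @param criterion A [bistability_criterion()].
#' @return A tibble with one row per non-empty bin: `bin`, `f_lo`,
#'   `f_hi`, `n`, `n_bistable`, `p2` and the binomial standard error
#'   `se`.  Empty bins are absent, not zero.
#' @export
bistable_fraction <- function(networks, binning = fitness_binning(),
                              criterion = strict_criterion()) {
  if (is.data.frame(networks)) {
    nets <- networks$genotype
    f <- if ("fitness" %in% names(networks)) networks$fitness
         else vapply(nets, grn_fitness, 0)
  } else {
    nets <- networks
    f <- vapply(nets, grn_fitness, 0)
  }
  bi <- vapply(nets, is_bistable, FALSE, criterion = criterion)
  tibble(bin = bin_of(f, binning), bistable = bi) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(n = dplyr::n(), n_bistable = sum(.data$bistable),
                     .groups = "drop") |>
    dplyr::mutate(
      f_lo = binning$edges[.data$bin + 1L],
      f_hi = binning$edges[.data$bin + 2L],
      p2 = .data$n_bistable / .data$n,
      se = sqrt(.data$p2 * (1 - .data$p2) / .data$n)
    ) |>
    dplyr::select("bin", "f_lo", "f_hi", "n", "n_bistable", "p2", "se")
}
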