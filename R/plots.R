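#' Plot a genotypic-entropy estimate
#'
#' log10 of the per-bin appearance probability against fitness, the
#' standard view of how rapidly high-fitness genotypes thin out.
#'
#' @param object A tibble from [estimate_entropy()].
#' @param ... Ignored.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.grn_entropy <- function(object, ...) {
  df <- dplyr::filter(object, !is.na(.data$omega))
  ggplot2::ggplot(df, ggplot2::aes((.data$f_lo + .data$f_hi) / 2,
                                   .data$log10_omega)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "fitness f", y = expression(log[10] ~ Omega(f)),
                  title = "Genotypic entropy") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.grn_entropy
#' @param entropy A tibble from [estimate_entropy()].
#' @export
plot_entropy <- function(entropy, ...) {
  class(entropy) <- c("grn_entropy", class(entropy))
  autoplot.grn_entropy(entropy, ...)
}

#' Plot the fitness trajectory of an evolutionary run
#'
#' @param object A `grn_evolution` from [run_evolution()].
#' @param ... Ignored.
#' @return A ggplot with the lineage fitness and the population mean/max.
#' @exportS3Method ggplot2::autoplot
autoplot.grn_evolution <- function(object, ...) {
  lin <- tidy(object)
  s <- object$summary |>
    tidyr::pivot_longer(c("mean_fitness", "max_fitness"),
                        names_to = "series", values_to = "fitness")
  ggplot2::ggplot(s, ggplot2::aes(.data$generation, .data$fitness,
                                  colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_line(data = lin,
                       ggplot2::aes(.data$generation, .data$fitness),
                       colour = "black", linetype = 2,
                       inherit.aes = FALSE) +
    ggplot2::labs(x = "generation", y = "fitness",
                  title = "Evolutionary trajectory (dashed: traced lineage)") +
    ggplot2::theme_minimal()
}

#' Plot a hysteresis sweep
#'
#' Up- and down-branches of the steady-state output against the input;
#' a visible loop is the signature of bistability.
#'
#' @param object A `grn_bistability` from [hysteresis_sweep()].
#' @param ... Ignored.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.grn_bistability <- function(object, ...) {
  b <- object$branches |>
    tidyr::pivot_longer(c("up", "down"), names_to = "sweep",
                        values_to = "x_out")
  ggplot2::ggplot(b, ggplot2::aes(.data$I, .data$x_out,
                                  colour = .data$sweep)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "input I", y = expression(bar(x)[out]),
                  title = sprintf("Hysteresis sweep: %s", object$verdict)) +
    ggplot2::theme_minimal()
}

#' Compare per-bin bistable fractions between ensembles
#'
#' @param ... Named tibbles from [bistable_fraction()] (e.g.
#'   `reference = ..., evo50 = ...`).
#' @return A ggplot of P2(f) per ensemble.
#' @export
plot_bistable_fraction <- function(...) {
  dfs <- list(...)
  df <- dplyr::bind_rows(dfs, .id = "ensemble")
  ggplot2::ggplot(df, ggplot2::aes((.data$f_lo + .data$f_hi) / 2, .data$p2,
                                   colour = .data$ensemble)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = pmax(0, .data$p2 - .data$se),
                                          ymax = pmin(1, .data$p2 + .data$se)),
                             size = 0.2) +
    ggplot2::labs(x = "fitness f", y = expression(P[2](f)),
                  title = "Fraction of bistable networks per fitness bin") +
    ggplot2::theme_minimal()
}
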