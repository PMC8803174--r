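#' Sub-bin reweighting for matched-fitness comparisons
#'
#' Within one fitness bin the fitness distributions of an evolved
#' collection and of the reference ensemble generally differ, which
#' biases any statistic compared between them.  The bin is split into
#' `n_sub` equal sub-bins and each evolved sample in sub-bin `s` receives
#' weight proportional to (reference count in `s`) / (evolved count in
#' `s`), so that the weighted fitness distribution of the evolved set
#' coincides with the reference one.  The weighted distribution of the
#' statistic is returned, normalised to total weight 1.
#'
#' @param es_samples Tibble with columns `fitness` and `statistic` for
#'   the evolved collection.
#' @param ref_samples Same, for the reference ensemble.
#' @param target_bin 0-based fitness-bin index to compare within.
#' @param binning A [fitness_binning()].
#' @param n_sub Number of sub-bins (default 10).
#' @param breaks Optional break points for the statistic histogram; by
#'   default every distinct value becomes its own class (natural for
#'   integer statistics such as essential-edge counts).
#' @return An object of class `grn_reweighted`: `$histogram` (tibble
#'   `statistic`, `weight`), `$weights` (per-evolved-sample weights),
#'   `$sub_bins` (per-sub-bin counts), `$coverage_gap` (`TRUE` when a
#'   populated reference sub-bin has no evolved counterpart).
#' @export
reweight_histogram <- function(es_samples, ref_samples, target_bin,
                               binning = fitness_binning(), n_sub = 10L,
                               breaks = NULL) {
  lo <- binning$edges[target_bin + 1L]
  hi <- binning$edges[target_bin + 2L]
  es <- es_samples[bin_of(es_samples$fitness, binning) == target_bin, ]
  ref <- ref_samples[bin_of(ref_samples$fitness, binning) == target_bin, ]
  if (nrow(es) == 0 || nrow(ref) == 0) {
    stop("both sample sets must be non-empty within the target bin")
  }
  sub <- function(f) pmin(floor((f - lo) / (hi - lo) * n_sub), n_sub - 1)
  es_sub <- sub(es$fitness)
  ref_sub <- sub(ref$fitness)
  es_n <- tabulate(es_sub + 1L, nbins = n_sub)
  ref_n <- tabulate(ref_sub + 1L, nbins = n_sub)
  orphan <- es_n > 0 & ref_n == 0
  if (any(orphan)) {
    warning("evolved samples in sub-bin(s) ",
            paste(which(orphan) - 1L, collapse = ", "),
            " have no reference counterpart; weighted 0")
  }
  coverage_gap <- any(ref_n > 0 & es_n == 0)
  if (coverage_gap) {
    warning("reference-populated sub-bin(s) without evolved samples: ",
            "coverage gap flagged")
  }
  w_sub <- ifelse(es_n > 0, ref_n / es_n, 0)
  w <- w_sub[es_sub + 1L]
  if (sum(w) == 0) stop("all evolved samples fell in orphan sub-bins")
  w <- w / sum(w)
  stat <- es$statistic
  hist <- if (is.null(breaks)) {
    tibble(statistic = stat, weight = w) |>
      dplyr::group_by(.data$statistic) |>
      dplyr::summarise(weight = sum(.data$weight), .groups = "drop")
  } else {
    cls <- cut(stat, breaks = breaks, include.lowest = TRUE)
    tibble(statistic = cls, weight = w) |>
      dplyr::group_by(.data$statistic, .drop = FALSE) |>
      dplyr::summarise(weight = sum(.data$weight), .groups = "drop")
  }
  structure(
    list(histogram = hist, weights = w,
         sub_bins = tibble(sub_bin = 0:(n_sub - 1), es_n = es_n,
                           ref_n = ref_n, weight = w_sub),
         coverage_gap = coverage_gap,
         target_bin = target_bin, n_sub = n_sub),
    class = "grn_reweighted"
  )
}

#' @export
print.grn_reweighted <- function(x, ...) {
  cat(sprintf("<grn_reweighted> bin %d, %d sub-bins%s\n", x$target_bin,
              x$n_sub, if (x$coverage_gap) " (coverage gap)" else ""))
  print(x$histogram, n = 10)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.grn_reweighted <- function(x, ...) x$histogram
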