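#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL

#' Plot the breadth-of-coverage curve
#'
#' Percentage of regions covered at least a given fraction at the depth
#' threshold, as a function of that fraction. Pass several samples' curves
#' bound together with a `sample_id` column to overlay them.
#'
#' @param curve Tibble from [coverage_fraction_curve()], optionally with a
#'   `sample_id` column.
#' @return A ggplot.
#' @export
plot_coverage_curve <- function(curve) {
  p <- ggplot2::ggplot(curve, ggplot2::aes(x = .data$min_pct_covered,
                                           y = .data$pct_regions))
  if ("sample_id" %in% names(curve)) {
    p <- p + ggplot2::geom_line(ggplot2::aes(group = .data$sample_id,
                                             colour = .data$sample_id))
  } else {
    p <- p + ggplot2::geom_line()
  }
  p + ggplot2::labs(x = "minimal percentage of region covered (%)",
                    y = "percentage of regions (%)")
}

#' @method autoplot coverage_summary
#' @export
autoplot.coverage_summary <- function(object, grid = 0:100, ...) {
  plot_coverage_curve(coverage_fraction_curve(object, grid = grid))
}

#' Plot per-group GC distributions with cut-offs
#'
#' Box plots of per-region GC content by performance group, shown for all
#' regions and after dropping predicted-unsequenceable regions and all
#' Ns/repeat-excluded regions, with the sequenceable-GC cut-offs as
#' horizontal lines.
#'
#' @param object A `gc_risk_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot gc_risk_report
#' @export
autoplot.gc_risk_report <- function(object, ...) {
  reg <- object$regions
  d <- dplyr::bind_rows(
    dplyr::mutate(reg, subset = "all regions"),
    dplyr::mutate(reg[!reg$predicted_unseq, ],
                  subset = "minus predicted-unsequenceable"),
    dplyr::mutate(reg[!reg$any_exclusion, ], subset = "minus Ns/repeats")
  )
  d$subset <- factor(d$subset, levels = c(
    "all regions", "minus predicted-unsequenceable", "minus Ns/repeats"))
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$group), y = .data$gc,
                                  fill = .data$subset)) +
    ggplot2::geom_boxplot(outlier.size = 0.4, na.rm = TRUE) +
    ggplot2::geom_hline(yintercept = object$cutoffs, linetype = "dashed") +
    ggplot2::labs(x = "performance group", y = "% GC", fill = NULL)
}

#' Box-plot summary statistics of per-group GC
#'
#' Quartiles, whiskers at 1.5 x IQR and outlier counts of the per-region GC
#' values, per group and per region subset — a tabular equivalent of
#' [autoplot.gc_risk_report()].
#'
#' @param report A `gc_risk_report`.
#' @return Tibble with one row per (group, subset).
#' @export
gc_boxplot_stats <- function(report) {
  stopifnot(inherits(report, "gc_risk_report"))
  reg <- report$regions
  subsets <- list(
    "all" = reg,
    "drop_predicted" = reg[!reg$predicted_unseq, ],
    "drop_exclusion" = reg[!reg$any_exclusion, ]
  )
  purrr::map_dfr(names(subsets), function(nm) {
    purrr::map_dfr(split(subsets[[nm]], subsets[[nm]]$group), function(d) {
      gc <- d$gc[!is.na(d$gc)]
      q1 <- stats::quantile(gc, 0.25, names = FALSE)
      q3 <- stats::quantile(gc, 0.75, names = FALSE)
      lo <- max(min(gc), q1 - 1.5 * (q3 - q1))
      hi <- min(max(gc), q3 + 1.5 * (q3 - q1))
      tibble::tibble(group = d$group[1], subset = nm, n = nrow(d),
                     q1 = q1, median = stats::median(gc), q3 = q3,
                     whisker_lo = lo, whisker_hi = hi,
                     n_outliers = sum(gc < lo | gc > hi))
    })
  })
}
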