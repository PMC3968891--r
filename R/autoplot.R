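# ggplot2 views of decoded objects.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the intensity distribution of a decoded IDAT
#'
#' For a binary channel: histogram of log2 mean intensities. For an
#' expression array: foreground vs local-background mean intensity
#' densities, the first thing to inspect when judging signal over
#' background. For a comparison report: per-column agreement counts.
#'
#' @param object A decoded object.
#' @param bins Histogram bin count.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.binary_idat <- function(object, bins = 60, ...) {
  tbl <- generics::tidy(object)
  ggplot2::ggplot(tbl, ggplot2::aes(x = log2(mean + 1))) +
    ggplot2::geom_histogram(bins = bins, fill = "grey35") +
    ggplot2::labs(
      x = "log2(mean intensity + 1)", y = "bead-types",
      title = sprintf("%s %s", object$barcode, object$position),
      subtitle = object$chip_type
    ) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.binary_idat
#' @export
autoplot.expression_idat <- function(object, ...) {
  tbl <- generics::tidy(object)
  long <- tibble::tibble(
    intensity = c(tbl$mean, tbl$bg_mean),
    component = rep(c("foreground", "background"), each = nrow(tbl))
  )
  ggplot2::ggplot(long, ggplot2::aes(x = log2(intensity + 1), colour = component)) +
    ggplot2::geom_density() +
    ggplot2::labs(
      x = "log2(mean intensity + 1)", y = "density",
      title = "Foreground vs local background"
    ) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.binary_idat
#' @export
autoplot.idat_comparison <- function(object, ...) {
  long <- tidyr_pivot_counts(object$by_column)
  ggplot2::ggplot(long, ggplot2::aes(x = column, y = n, fill = status)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::labs(
      x = NULL, y = "rows",
      title = sprintf("Agreement at %d decimal place(s)", object$decimals)
    ) +
    ggplot2::theme_minimal()
}

# small reshape kept local to avoid a tidyr dependency for one call
tidyr_pivot_counts <- function(by_column) {
  dplyr::bind_rows(lapply(c("n_exact", "n_within_rounding", "n_discordant"), function(s) {
    tibble::tibble(
      column = by_column$column,
      status = sub("^n_", "", s),
      n = by_column[[s]]
    )
  }))
}
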