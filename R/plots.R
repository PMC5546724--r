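#' @importFrom ggplot2 autoplot ggplot aes geom_step geom_line geom_point
#'   geom_hline geom_segment geom_raster labs scale_fill_gradient theme_minimal
NULL

#' Plot a boundary-score track
#'
#' @param object a `boundary_track`.
#' @param cutoff consensus cutoff drawn as a reference line.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.boundary_track <- function(object, cutoff = 0.9, ...) {
  df <- tidy(object)
  ggplot(df, aes(x = .data$coord / 1e6, y = .data$score)) +
    geom_step() +
    geom_hline(yintercept = cutoff, linetype = "dashed", colour = "red") +
    labs(x = paste0(object$chrom, " position (Mb)"), y = "boundary score",
         title = paste0("Boundary scores over ", object$n_trials,
                        " trials")) +
    theme_minimal()
}

#' Plot called TADs over the boundary-score track
#'
#' @param object a `tad_call`.
#' @param ... passed to [autoplot.boundary_track()].
#' @return a ggplot.
#' @export
autoplot.tad_call <- function(object, ...) {
  p <- autoplot(object$track, cutoff = object$config$cutoff, ...)
  if (nrow(object$tads) > 0)
    p <- p + geom_segment(
      data = object$tads,
      aes(x = .data$start / 1e6, xend = .data$end / 1e6,
          y = -0.05, yend = -0.05),
      linewidth = 3, colour = "steelblue", inherit.aes = FALSE)
  p
}

#' Plot a resolution sweep summary
#'
#' Number of TADs and median TAD size against the resolution parameter.
#'
#' @param object a `resolution_sweep`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.resolution_sweep <- function(object, ...) {
  df <- object$summary
  df_long <- tibble::tibble(
    gamma = rep(df$gamma, 2),
    value = c(df$n_tads, df$median_size_bp / 1e3),
    metric = rep(c("number of TADs", "median size (kb)"),
                 each = nrow(df)))
  ggplot(df_long, aes(x = .data$gamma, y = .data$value)) +
    geom_line() + geom_point() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    labs(x = "resolution parameter", y = NULL) +
    theme_minimal()
}

#' Plot a boundary enrichment profile
#'
#' @param object an `enrichment_profile`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.enrichment_profile <- function(object, ...) {
  ggplot(object, aes(x = .data$offset_bp / 1e3, y = .data$enrichment)) +
    geom_line() + geom_point() +
    geom_hline(yintercept = 1, linetype = "dashed") +
    labs(x = "offset from boundary (kb)", y = "observed / expected") +
    theme_minimal()
}

#' Heatmap of a contact map with optional TADs
#'
#' @param map a [contact_map()].
#' @param tads optional `tad_set` whose domain extents are drawn along the
#'   diagonal.
#' @param max_quantile contacts above this quantile are clipped to keep the
#'   color scale informative.
#' @return a ggplot.
#' @export
plot_contact_map <- function(map, tads = NULL, max_quantile = 0.98) {
  stopifnot(inherits(map, "contact_map"))
  W <- map$W
  cap <- stats::quantile(W[W > 0], max_quantile)
  df <- expand.grid(i = seq_len(map$n), j = seq_len(map$n))
  df$w <- pmin(as.numeric(W), cap)
  p <- ggplot(df, aes(x = .data$i, y = .data$j, fill = .data$w)) +
    geom_raster() +
    scale_fill_gradient(low = "white", high = "darkred",
                        name = "contacts") +
    labs(x = "bin", y = "bin") +
    theme_minimal()
  if (!is.null(tads) && nrow(tads) > 0)
    p <- p + geom_segment(
      data = tads,
      aes(x = .data$start_bin + 1, xend = .data$end_bin,
          y = .data$start_bin + 1, yend = .data$end_bin),
      colour = "black", inherit.aes = FALSE)
  p
}
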