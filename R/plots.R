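#' Plot a force curve
#'
#' Deflection-derived force against piezo position, one colour per
#' segment.
#'
#' @param object A `force_curve`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.force_curve <- function(object, ...) {
  d <- object$data
  d$force_nN <- object$k * d$deflection_nm
  ggplot2::ggplot(d, ggplot2::aes(.data$z_nm, .data$force_nN,
                                  colour = .data$segment)) +
    ggplot2::geom_path() +
    ggplot2::labs(x = "piezo z (nm)", y = "force (nN)",
                  title = object$curve_id) +
    ggplot2::theme_minimal()
}

#' Plot an intensity profile
#'
#' The pixel-intensity density with the threshold window shaded and the
#' peak marked.
#'
#' @param object An `intensity_profile`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.intensity_profile <- function(object, ...) {
  thr <- object$thresholds
  ggplot2::ggplot(object$kde, ggplot2::aes(.data$intensity, .data$density)) +
    ggplot2::annotate("rect", xmin = thr[["lower"]], xmax = thr[["upper"]],
                      ymin = -Inf, ymax = Inf, alpha = 0.1, fill = "steelblue") +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$peak_intensity,
                        linetype = "dashed") +
    ggplot2::labs(x = "pixel intensity", y = "density") +
    ggplot2::theme_minimal()
}

#' Plot group means with standard-error bars
#'
#' Point-range plot of a measurement aggregated by [aggregate_hierarchy()],
#' one panel-free x position per age x volume cell.
#'
#' @param aggregate An `ecm_aggregate`.
#' @param value Measurement name (e.g. `"E_Pa"`).
#' @return A ggplot.
#' @export
plot_group_summary <- function(aggregate, value = "E_Pa") {
  stopifnot(inherits(aggregate, "ecm_aggregate"))
  g <- aggregate$group
  mcol <- paste0(value, "_mean"); scol <- paste0(value, "_se")
  if (!mcol %in% names(g)) abort(paste("no aggregated column for", value))
  grp_cols <- setdiff(names(g), c("n", grep("_(mean|se)$", names(g),
                                            value = TRUE)))
  g$group <- do.call(paste, c(g[grp_cols], sep = " / "))
  ggplot2::ggplot(g, ggplot2::aes(.data$group, .data[[mcol]])) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data[[mcol]] - .data[[scol]],
      ymax = .data[[mcol]] + .data[[scol]])) +
    ggplot2::labs(x = NULL, y = paste(value, "(mean ± SE)")) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
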