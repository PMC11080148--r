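# The two audit-style cross-center comparison figures, drawn the way the
# registry's feedback environment presents them: per-center points against
# a cross-center mean reference line, no funnel control limits.

open_device <- function(path, format, width = 7, height = 5) {
  switch(format,
         png = grDevices::png(path, width = width, height = height, units = "in",
                              res = 150, type = "cairo"),
         svg = grDevices::svg(path, width = width, height = height),
         stop("unknown image format '", format, "' (use png or svg)", call. = FALSE))
}

plot_points <- function(global) {
  locals <- global$local_results
  df <- data.frame(
    center = vapply(locals, function(x) x$center_id, character(1L)),
    denominator = vapply(locals, function(x) as.numeric(x$denominator), numeric(1L)),
    ratio = vapply(locals, function(x) x$ratio, numeric(1L)),
    stringsAsFactors = FALSE
  )
  dropped <- is.na(df$ratio)
  if (any(dropped)) {
    message("omitted from plot (undefined ratio): ",
            paste(df$center[dropped], collapse = ", "))
  }
  df[!dropped, , drop = FALSE]
}

#' Plot the short-waiting-time indicator across centers
#'
#' One point per center: cohort size (the indicator denominator) on the
#' x-axis, the percentage of patients whose therapy started within 5 weeks
#' of diagnosis on the y-axis, with a green horizontal line at the
#' cross-center mean percentage.
#'
#' @param global a `global_result` from a 2b train.
#' @param path output image path.
#' @param format `"png"` or `"svg"` (default by file extension).
#' @param labels optional named vector of per-center display names.
#' @return `path`, invisibly.
#' @export
plot_qi2b <- function(global, path, format = NULL, labels = NULL) {
  stopifnot(inherits(global, "global_result"))
  if (global$indicator_id != "qi2b") {
    stop("plot_qi2b needs a qi2b global result, got '", global$indicator_id, "'",
         call. = FALSE)
  }
  df <- plot_points(global)
  if (nrow(df) == 0L) stop("no plottable centers (all ratios undefined)", call. = FALSE)
  if (!is.null(labels)) df$center <- ifelse(df$center %in% names(labels),
                                            labels[df$center], df$center)
  df$pct <- 100 * df$ratio
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$denominator, y = .data$pct)) +
    ggplot2::geom_hline(yintercept = 100 * global$mean_ratio,
                        color = "darkgreen", linewidth = 0.8) +
    ggplot2::geom_point(size = 3, color = "grey20") +
    ggplot2::geom_text(ggplot2::aes(label = .data$center), vjust = -1, size = 3) +
    ggplot2::scale_y_continuous(limits = c(0, 105)) +
    ggplot2::labs(
      x = "Number of patients in center cohort",
      y = "Patients with time to treatment initiation < 5 weeks (%)",
      title = "Quality indicator 2b: short waiting time",
      subtitle = sprintf("mean = %d%%", as.integer(round(100 * global$mean_ratio)))) +
    ggplot2::theme_bw()
  render_plot(p, path, format)
}

#' Plot the complication-rate indicator across centers
#'
#' One point per center: expected events (cross-center mean rate times the
#' center's cohort size) on the x-axis and the center's rate as a multiple
#' of the mean rate on the y-axis, with a blue horizontal reference line at
#' the mean level (rate-of-mean = 1).
#'
#' @inheritParams plot_qi2b
#' @param global a `global_result` from a qi8 train.
#' @return `path`, invisibly.
#' @export
plot_qi8 <- function(global, path, format = NULL, labels = NULL) {
  stopifnot(inherits(global, "global_result"))
  if (global$indicator_id != "qi8") {
    stop("plot_qi8 needs a qi8 global result, got '", global$indicator_id, "'",
         call. = FALSE)
  }
  df <- plot_points(global)
  if (nrow(df) == 0L) stop("no plottable centers (all ratios undefined)", call. = FALSE)
  if (!is.null(labels)) df$center <- ifelse(df$center %in% names(labels),
                                            labels[df$center], df$center)
  df$expected <- global$mean_ratio * df$denominator
  df$rate_of_mean <- df$ratio / global$mean_ratio
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$expected, y = .data$rate_of_mean)) +
    ggplot2::geom_hline(yintercept = 1, color = "steelblue", linewidth = 0.8) +
    ggplot2::geom_point(size = 3, color = "grey20") +
    ggplot2::geom_text(ggplot2::aes(label = .data$center), vjust = -1, size = 3) +
    ggplot2::labs(
      x = "Expected events (mean rate x center population)",
      y = "Complication rate relative to the mean",
      title = "Quality indicator 8: postoperative complication rate",
      subtitle = sprintf("mean rate = %.3f", global$mean_ratio)) +
    ggplot2::theme_bw()
  render_plot(p, path, format)
}

render_plot <- function(p, path, format) {
  if (is.null(format)) {
    format <- if (grepl("\\.svg$", path, ignore.case = TRUE)) "svg" else "png"
  }
  open_device(path, format)
  on.exit(grDevices::dev.off(), add = TRUE)
  print(p)
  invisible(path)
}
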