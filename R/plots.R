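# The three instability plots. Base graphics; every figure's numbers are
# also written as CSV by write_report(), so plots are derived views.

open_devices <- function(out, width = 7, height = 6) {
  # write both a vector (SVG) and raster (PNG) rendering side by side
  paths <- c(svg = paste0(out, ".svg"), png = paste0(out, ".png"))
  list(paths = paths,
       open = list(
         function() grDevices::svg(paths[["svg"]], width = width, height = height),
         function() grDevices::png(paths[["png"]], width = width * 110,
                                   height = height * 110, res = 110)))
}

render_to <- function(out, draw, width = 7, height = 6) {
  if (is.null(out)) {
    draw()
    return(invisible(NULL))
  }
  dev <- open_devices(out, width, height)
  for (op in dev$open) {
    op()
    ok <- tryCatch({ draw(); TRUE }, finally = grDevices::dev.off())
    if (!ok) break
  }
  invisible(unname(dev$paths))
}

#' Prediction instability plot
#'
#' Scatter of every bootstrap-model prediction against the individual's
#' original-model prediction, with the solid diagonal marking perfect
#' agreement and dashed lines tracing the per-individual 2.5th/97.5th
#' percentile band. Vertical spread is the instability of that
#' individual's prediction across the multiverse.
#'
#' Above `max_points` scatter points a fixed-seed sub-sample is drawn for
#' plotting (noted on the figure); the percentile band is always computed
#' from all points.
#'
#' @param report an [instability()] report.
#' @param out optional output path prefix; writes `<out>.svg` and
#'   `<out>.png`. `NULL` draws on the current device.
#' @param level band coverage (default the report's interval level).
#' @param max_points scatter density cap.
#' @return File paths (invisibly) when `out` is given.
#' @export
plot_prediction_instability <- function(report, out = NULL, level = NULL,
                                        max_points = 2e6) {
  stopifnot(inherits(report, "instability_report"))
  p <- report$preds$original
  M <- report$preds$multiverse
  ints <- if (is.null(level) || identical(level, attr(report$intervals, "level")))
    report$intervals else prediction_intervals(report$preds, level)
  ord <- order(p)
  npts <- length(M)
  draw <- function() {
    graphics::plot(NA, xlim = c(0, 1), ylim = c(0, 1),
                   xlab = "Original model prediction",
                   ylab = "Bootstrap model predictions",
                   main = "Prediction instability")
    x <- rep(p, times = ncol(M))
    y <- as.vector(M)
    sub <- npts > max_points
    if (sub) {
      keep <- with_seed(1L, sample.int(npts, max_points))
      x <- x[keep]; y <- y[keep]
    }
    graphics::points(x, y, pch = ".", col = grDevices::grey(0.35, 0.35))
    graphics::abline(0, 1, lwd = 1.5)
    graphics::lines(p[ord], ints[ord, "lower"], lty = 2, col = "firebrick", lwd = 1.5)
    graphics::lines(p[ord], ints[ord, "upper"], lty = 2, col = "firebrick", lwd = 1.5)
    if (sub) {
      graphics::mtext(sprintf("scatter thinned to %g of %g points (bands use all)",
                              max_points, npts), side = 3, cex = 0.7)
    }
  }
  render_to(out, draw)
}

#' Classification instability plot
#'
#' Scatter of each individual's classification instability index against
#' their original-model prediction, with a vertical reference line at the
#' decision threshold. The index peaks for individuals whose original
#' prediction sits near the threshold.
#'
#' @param report an [instability()] report.
#' @param threshold decision threshold; must be one the report computed.
#' @param out optional output path prefix (SVG + PNG), `NULL` for the
#'   current device.
#' @return File paths (invisibly) when `out` is given.
#' @export
plot_classification_instability <- function(report,
                                            threshold = report$config$thresholds[1],
                                            out = NULL) {
  stopifnot(inherits(report, "instability_report"))
  key <- sprintf("t=%g", threshold)
  if (!key %in% colnames(report$cii)) {
    stop(sprintf("threshold %g was not computed in this report (have: %s)",
                 threshold, paste(colnames(report$cii), collapse = ", ")),
         call. = FALSE)
  }
  cii <- report$cii[, key]
  p <- report$preds$original
  draw <- function() {
    graphics::plot(p, cii, xlim = c(0, 1), ylim = c(0, 1), pch = 16,
                   col = grDevices::grey(0.3, 0.5), cex = 0.5,
                   xlab = "Original model prediction",
                   ylab = "Classification instability index",
                   main = sprintf("Classification instability (threshold %g)",
                                  threshold))
    graphics::abline(v = threshold, lty = 3)
  }
  render_to(out, draw)
}

#' Calibration instability plot
#'
#' Overlay of the smoothed calibration curves of the bootstrap models
#' applied to the original cohort (light), the original model's curve
#' (dashed) and the ideal-calibration diagonal (solid). Curves are
#' clipped to their own support ranges.
#'
#' @param bundle a [calibration_instability()] bundle, or an
#'   [instability()] report containing one.
#' @param out optional output path prefix (SVG + PNG), `NULL` for the
#'   current device.
#' @return File paths (invisibly) when `out` is given.
#' @export
plot_calibration_instability <- function(bundle, out = NULL) {
  if (inherits(bundle, "instability_report")) bundle <- bundle$calibration
  if (is.null(bundle) || !inherits(bundle, "calibration_bundle") ||
      !length(bundle$curves)) {
    stop("no calibration curves available to plot", call. = FALSE)
  }
  lim <- range(bundle$original$grid,
               unlist(lapply(bundle$curves, function(cv) cv$support_range)))
  lim <- c(max(0, lim[1] - 0.01), min(1, lim[2] + 0.01))
  draw <- function() {
    graphics::plot(NA, xlim = lim, ylim = lim,
                   xlab = "Predicted risk", ylab = "Smoothed observed risk",
                   main = "Calibration instability")
    for (cv in bundle$curves) {
      graphics::lines(cv$grid, cv$smoothed_observed,
                      col = grDevices::grey(0.4, 0.25))
    }
    graphics::abline(0, 1, lwd = 1.5)
    graphics::lines(bundle$original$grid, bundle$original$smoothed_observed,
                    lty = 2, lwd = 2, col = "firebrick")
    graphics::mtext(sprintf("%d bootstrap curves; mean band width %.4f",
                            length(bundle$curves), mean(bundle$spread$width)),
                    side = 3, cex = 0.7)
  }
  render_to(out, draw)
}

#' Plot method for instability reports
#'
#' @param x an [instability()] report.
#' @param type which instability plot to draw.
#' @param ... passed to the underlying `plot_*` function.
#' @return Invisibly, whatever the underlying plot function returns.
#' @export
plot.instability_report <- function(x, type = c("prediction",
                                                "classification",
                                                "calibration"), ...) {
  type <- match.arg(type)
  switch(type,
         prediction = plot_prediction_instability(x, ...),
         classification = plot_classification_instability(x, ...),
         calibration = plot_calibration_instability(x, ...))
}
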