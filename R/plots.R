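#' Plot a read-count profile with optional segments and thresholds
#'
#' Density-style scatter of working values along the genome (chromosome
#' boundaries as vertical lines), with segment levels overlaid in green
#' and calling thresholds as red horizontal lines.
#'
#' @param profile an `rc_profile`.
#' @param segments optional `segment_set`.
#' @param thresholds optional numeric calling thresholds.
#' @param show_masked plot masked windows in grey (default `TRUE`).
#' @param ... passed to [graphics::plot()].
#' @return invisibly, `NULL`.
#' @export
plot_profile <- function(profile, segments = NULL, thresholds = NULL,
                         show_masked = TRUE, ...) {
  v <- profile_values(profile)
  mask <- combined_mask(profile)
  n <- length(v)
  col <- grDevices::adjustcolor("black", alpha.f = min(1, 4000 / n))
  graphics::plot(seq_len(n), ifelse(mask & !show_masked, NA, v),
                 pch = 16, cex = 0.3,
                 col = ifelse(mask, "grey70", col),
                 xlab = "window", ylab = "value", ...)
  bounds <- cumsum(table(factor(profile$windows$chrom,
                                levels = unique(profile$windows$chrom))))
  graphics::abline(v = bounds[-length(bounds)] + 0.5, col = "black")
  if (!is.null(segments)) {
    graphics::segments(segments$start_win, segments$level,
                       segments$end_win, segments$level,
                       col = "green3", lwd = 2)
  }
  if (!is.null(thresholds)) {
    graphics::abline(h = thresholds, col = "red", lty = 2)
  }
  invisible(NULL)
}

#' Plot values against GC content with fitted effect curves
#'
#' Density scatter of working value versus window GC, with one or more
#' fitted `gc_curve`s overlaid (e.g. the single-pass and the two-pass
#' estimate), each scaled to the median value.
#'
#' @param profile an `rc_profile` with GC annotation.
#' @param curves named list of `gc_curve` objects.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, `NULL`.
#' @export
plot_gc_fit <- function(profile, curves = list(), ...) {
  w <- profile$windows
  keep <- is.finite(w$gc) & is.finite(w$value)
  col <- grDevices::adjustcolor("black", alpha.f = min(1, 4000 / sum(keep)))
  graphics::plot(w$gc[keep], w$value[keep], pch = 16, cex = 0.3, col = col,
                 xlab = "GC fraction", ylab = "value", ...)
  med <- stats::median(w$value[keep])
  pal <- c("orange", "blue", "green3", "purple")
  for (i in seq_along(curves)) {
    graphics::lines(curves[[i]]$gc, curves[[i]]$effect * med,
                    col = pal[(i - 1) %% length(pal) + 1], lwd = 2)
  }
  if (length(curves) && !is.null(names(curves))) {
    graphics::legend("topleft", legend = names(curves), lwd = 2,
                     col = pal[seq_along(curves)], bty = "n")
  }
  invisible(NULL)
}

#' Write a GC curve as a two-column table
#' @param curve a `gc_curve`.
#' @param path output path (TSV: gc, effect, support).
#' @return `path`, invisibly.
#' @export
write_gc_curve <- function(curve, path) {
  data.table::fwrite(as.data.frame(curve), path, sep = "\t")
  invisible(path)
}
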