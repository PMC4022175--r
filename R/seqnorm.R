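#' Select segments suitable for segment-wise GC regression
#'
#' Segments with the highest value variability, or spanning few windows,
#' do not give robust fits; segments with little GC variability cannot
#' constrain the effect of extreme GC. A segment is selected iff it has
#' at least `min_windows` members, its robust value variability (MAD) is
#' at or below the `rc_var_quantile` of all segments' variabilities, and
#' its GC standard deviation is at or above the `gc_var_quantile`
#' (ties kept on both cuts). If fewer than 3 segments survive, the
#' quantile cuts are relaxed stepwise by 0.05 until at least 3 do; if
#' that fails, `ok` is `FALSE` and the caller should fall back to the
#' single-pass correction.
#'
#' @param segments a `segment_set`.
#' @param values per-window values the segments were fitted on.
#' @param gc per-window GC fractions.
#' @param usable logical; windows eligible for fitting (unmasked,
#'   finite). Default: all finite.
#' @param min_windows minimum members per selected segment (default 20).
#' @param rc_var_quantile upper cut on value variability (default 0.75).
#' @param gc_var_quantile lower cut on GC variability (default 0.25).
#' @return data.frame of class `segment_selection`: per-segment
#'   `n_windows`, `rc_variability`, `gc_variability`, `selected`; with
#'   attributes `ok` and the quantiles actually used after relaxation.
#' @export
select_segments <- function(segments, values, gc, usable = NULL,
                            min_windows = 20L, rc_var_quantile = 0.75,
                            gc_var_quantile = 0.25) {
  if (is.null(usable)) usable <- is.finite(values) & is.finite(gc)
  stats_per_seg <- lapply(seq_len(nrow(segments)), function(k) {
    idx <- segments$start_win[k]:segments$end_win[k]
    idx <- idx[usable[idx]]
    data.frame(n_windows = length(idx),
               rc_variability = if (length(idx) > 1)
                 stats::mad(values[idx]) else Inf,
               gc_variability = if (length(idx) > 1)
                 stats::sd(gc[idx]) else 0)
  })
  sel <- do.call(rbind, stats_per_seg)
  rcq <- rc_var_quantile
  gcq <- gc_var_quantile
  big <- sel$n_windows >= min_windows
  repeat {
    rc_cut <- stats::quantile(sel$rc_variability[is.finite(sel$rc_variability)],
                              min(rcq, 1), names = FALSE)
    gc_cut <- stats::quantile(sel$gc_variability, max(gcq, 0), names = FALSE)
    sel$selected <- big & sel$rc_variability <= rc_cut &
      sel$gc_variability >= gc_cut
    if (sum(sel$selected) >= 3 || (rcq >= 1 && gcq <= 0)) break
    rcq <- rcq + 0.05
    gcq <- gcq - 0.05
  }
  attr(sel, "ok") <- sum(sel$selected) >= 3
  attr(sel, "rc_var_quantile") <- min(rcq, 1)
  attr(sel, "gc_var_quantile") <- max(gcq, 0)
  class(sel) <- c("segment_selection", "data.frame")
  sel
}

# fit one local regression per selected segment on median-centered raw
# values, evaluate on the common grid restricted to the segment's
# observed covariate range, then take an aligned pointwise median.
segmentwise_median_curve <- function(raw, covariate, segments, selection,
                                     usable, span, grid) {
  sel_idx <- which(selection$selected)
  mats <- matrix(NA_real_, nrow = length(grid), ncol = length(sel_idx))
  for (j in seq_along(sel_idx)) {
    k <- sel_idx[j]
    idx <- segments$start_win[k]:segments$end_win[k]
    idx <- idx[usable[idx]]
    centered <- raw[idx] / stats::median(raw[idx])
    fl <- robust_log_loess(centered, covariate[idx], span)
    rng <- range(fl$x)
    inside <- grid >= rng[1] & grid <= rng[2]
    if (!any(inside)) next
    mats[inside, j] <- suppressWarnings(
      stats::predict(fl$fit, newdata = data.frame(x = grid[inside])))
  }
  keep <- colSums(is.finite(mats)) > 0
  mats <- mats[, keep, drop = FALSE]
  if (!ncol(mats)) stop("no segment curve overlaps the covariate grid")
  # Curves fitted on segment-median-centered values differ by a constant
  # log offset (each is pinned near its own median covariate). Align by
  # iterating offsets toward the provisional pointwise median; a no-op
  # when the curves already agree on their shared range.
  off <- rep(0, ncol(mats))
  for (it in 1:3) {
    al <- sweep(mats, 2, off, `+`)
    med <- apply(al, 1, stats::median, na.rm = TRUE)
    off <- off + vapply(seq_len(ncol(mats)), function(j) {
      d <- med - (mats[, j] + off[j])
      mean(d[is.finite(d)])
    }, numeric(1))
  }
  al <- sweep(mats, 2, off, `+`)
  support <- rowSums(is.finite(al))
  med <- rep(NA_real_, length(grid))
  hi <- support >= 2
  med[hi] <- apply(al[hi, , drop = FALSE], 1, stats::median, na.rm = TRUE)
  eff <- fill_nearest(exp(med))
  curve <- data.frame(gc = grid, effect = eff, support = support)
  ref_cov <- stats::median(covariate[usable], na.rm = TRUE)
  normalize_curve(curve, ref_cov)
}

#' Two-pass segment-wise GC correction (seqnorm)
#'
#' GC correction that stays unbiased when GC content and copy number are
#' correlated. A plain regression of value on GC absorbs copy-number
#' signal into the GC curve when, say, amplified regions are GC-rich.
#' seqnorm therefore proceeds in two passes:
#' (1) a first-pass [single_pass_correct()] removes most of the GC bias;
#' (2) the corrected profile is segmented ([segment_profile()]) into
#' constant-copy-number pieces; (3) segments are screened by
#' [select_segments()]; (4) within each selected segment the *raw*
#' values are divided by the segment's median raw value — centering that
#' removes the read-count differences due to copy number, and with them
#' the undesired correlation; (5) a local regression is fitted per
#' selected segment on its centered values; (6) the pointwise median of
#' the per-segment curves (at grid points supported by at least two
#' segments; nearest supported value elsewhere) is the final GC effect;
#' (7) raw values are divided by the final curve and rescaled to the
#' input median. Second-pass fits use re-centered raw values, not
#' first-pass residuals, so a biased first pass cannot compound into the
#' final estimate. On segment-selection failure the function falls back
#' to the single-pass result with a warning (never silently).
#'
#' @param profile a GC-annotated `rc_profile` (filters applied).
#' @param span loess span for both passes.
#' @param penalty segmentation penalty (default as in
#'   [segment_profile()]).
#' @param min_windows,rc_var_quantile,gc_var_quantile see
#'   [select_segments()].
#' @return the corrected `rc_profile`; `$gc_curve` holds the final
#'   curve, `$selection` the segment screen, `$method` is `"seqnorm"`
#'   (or `"single_pass"` after fallback, with `$fallback` giving the
#'   reason).
#' @export
seqnorm <- function(profile, span = 0.3, penalty = NULL, min_windows = 20L,
                    rc_var_quantile = 0.75, gc_var_quantile = 0.25) {
  w <- profile$windows
  mask <- combined_mask(profile)
  raw <- w$value
  p1 <- single_pass_correct(profile, span = span)
  segs <- segment_profile(p1, penalty = penalty)
  if (nrow(segs) < 3) {
    warning("fewer than 3 segments: falling back to single-pass correction")
    p1$fallback <- "fewer than 3 segments"
    return(p1)
  }
  usable <- !mask & is.finite(raw) & is.finite(w$gc) & raw > 0
  selection <- select_segments(segs, profile_values(p1), w$gc,
                               usable = usable, min_windows = min_windows,
                               rc_var_quantile = rc_var_quantile,
                               gc_var_quantile = gc_var_quantile)
  if (!attr(selection, "ok")) {
    warning("segment selection failed: falling back to single-pass correction")
    p1$fallback <- "segment selection failed"
    return(p1)
  }
  curve <- segmentwise_median_curve(raw, w$gc, segs, selection, usable,
                                    span, grid = seq(0.20, 0.70, by = 0.005))
  v <- raw
  has_gc <- is.finite(w$gc)
  v[has_gc] <- raw[has_gc] / curve_effect(curve, w$gc[has_gc])
  med_in <- stats::median(raw[!mask & is.finite(raw)])
  med_out <- stats::median(v[!mask & is.finite(v)])
  if (is.finite(med_out) && med_out > 0) v <- v * med_in / med_out
  out <- profile
  out$windows$value <- v
  out$gc_curve <- curve
  out$first_pass_curve <- p1$gc_curve
  out$segments <- segs
  out$selection <- selection
  out$method <- "seqnorm"
  out
}

#' Normalize a tumour profile against a matched normal
#'
#' `mode = "ratio"`: per-window tumour/normal ratio, rescaled to median
#' 1 — the normal carries the GC effect and other window-specific
#' biases, so the ratio cancels them. Zero-count normal windows get a
#' pseudocount of 0.5 and are flagged in the log.
#' `mode = "seqnorm"`: the seqnorm machinery with the normal's value in
#' place of GC as the regression covariate (segment-wise local
#' regression of tumour on normal, aligned median curve, correction).
#'
#' @param tumor,normal `rc_profile`s on the identical window grid
#'   (hard error otherwise).
#' @param mode `"ratio"` or `"seqnorm"`.
#' @param span loess span (seqnorm mode).
#' @param penalty segmentation penalty (seqnorm mode).
#' @return the corrected tumour `rc_profile`.
#' @export
paired_normalize <- function(tumor, normal, mode = c("ratio", "seqnorm"),
                             span = 0.3, penalty = NULL) {
  mode <- match.arg(mode)
  tw <- tumor$windows; nw <- normal$windows
  if (nrow(tw) != nrow(nw) || !all(tw$chrom == nw$chrom) ||
      !all(tw$start == nw$start) || !all(tw$end == nw$end)) {
    stop("tumor and normal are on different window grids")
  }
  nv <- nw$value
  zero <- is.finite(nv) & nv == 0
  if (any(zero)) {
    nv[zero] <- 0.5
    tumor$log <- c(tumor$log,
                   sprintf("%d zero-count normal window(s) given pseudocount 0.5",
                           sum(zero)))
  }
  mask <- combined_mask(tumor)
  if (mode == "ratio") {
    v <- tw$value / nv
    med <- stats::median(v[!mask & is.finite(v)])
    tumor$windows$value <- v / med
    tumor$method <- "paired_ratio"
    return(tumor)
  }
  # seqnorm with the normal as covariate: swap it into the gc slot and
  # use a quantile grid over the normal's values
  cov <- nv
  grid <- unique(stats::quantile(cov[is.finite(cov)],
                                 seq(0.01, 0.99, length.out = 101),
                                 names = FALSE))
  surrogate <- tumor
  surrogate$windows$gc <- cov
  raw <- tw$value
  p1 <- local({
    use <- !mask & is.finite(raw) & is.finite(cov) & raw > 0
    curve <- gc_local_fit(raw[use], cov[use], span = span, grid = grid)
    v <- raw / curve_effect(curve, cov)
    med_in <- stats::median(raw[!mask & is.finite(raw)])
    v <- v * med_in / stats::median(v[!mask & is.finite(v)])
    pp <- surrogate
    pp$windows$value <- v
    pp$gc_curve <- curve
    pp
  })
  segs <- segment_profile(p1, penalty = penalty)
  usable <- !mask & is.finite(raw) & is.finite(cov) & raw > 0
  selection <- select_segments(segs, profile_values(p1), cov, usable = usable)
  if (nrow(segs) < 3 || !attr(selection, "ok")) {
    warning("paired seqnorm: segment selection failed, using first-pass fit")
    p1$method <- "paired_seqnorm_fallback"
    p1$windows$gc <- tw$gc
    return(p1)
  }
  curve <- segmentwise_median_curve(raw, cov, segs, selection, usable,
                                    span, grid = grid)
  v <- raw / curve_effect(curve, cov)
  med_in <- stats::median(raw[!mask & is.finite(raw)])
  v <- v * med_in / stats::median(v[!mask & is.finite(v)])
  out <- tumor
  out$windows$value <- v
  out$gc_curve <- curve
  out$method <- "paired_seqnorm"
  out
}
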