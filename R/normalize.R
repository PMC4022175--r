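# robust loess of log(value) on a covariate, with automatic span
# widening when the neighborhood is too sparse for the requested span
robust_log_loess <- function(values, covariate, span) {
  keep <- is.finite(values) & is.finite(covariate) & values > 0
  df <- data.frame(y = log(values[keep]), x = covariate[keep])
  fit <- NULL
  s <- span
  while (is.null(fit) && s <= 1) {
    fit <- tryCatch(
      suppressWarnings(stats::loess(y ~ x, data = df, span = s, degree = 2,
                                    family = "symmetric")),
      error = function(e) NULL)
    if (is.null(fit)) s <- s * 1.5
  }
  if (is.null(fit)) stop("local regression failed at every span up to 1")
  if (s > span) {
    warning(sprintf("local-regression span widened from %.2f to %.2f", span, s))
  }
  list(fit = fit, span = s, x = df$x)
}

#' Fit the multiplicative GC effect by local regression
#'
#' Locally-weighted regression of log(value) on GC content, evaluated on
#' a fixed GC grid and exponentiated. The curve is normalized so that
#' its value at the median GC of the contributing windows is 1; grid
#' points outside the observed GC range carry the nearest estimated
#' value and zero support.
#'
#' @param values positive working values (log scale internally).
#' @param gc GC fractions in \[0, 1\].
#' @param span loess span (widened automatically, with a warning, if the
#'   data are too sparse for it).
#' @param grid ascending GC grid (default 0.20-0.70 step 0.005).
#' @return data.frame of class `gc_curve`: `gc`, `effect` (> 0),
#'   `support` (observations near each grid point; 0 outside the
#'   observed range).
#' @export
gc_local_fit <- function(values, gc, span = 0.3,
                         grid = seq(0.20, 0.70, by = 0.005)) {
  keep <- is.finite(values) & is.finite(gc) & values > 0
  if (sum(keep) < 100) stop("need >= 100 finite positive (value, gc) pairs")
  fl <- robust_log_loess(values, gc, span)
  rng <- range(fl$x)
  inside <- grid >= rng[1] & grid <= rng[2]
  eff <- rep(NA_real_, length(grid))
  eff[inside] <- exp(suppressWarnings(
    stats::predict(fl$fit, newdata = data.frame(x = grid[inside]))))
  if (!any(inside)) stop("GC grid does not intersect the observed GC range")
  # nearest estimated value outside the observed range, zero support
  eff <- fill_nearest(eff)
  half <- if (length(grid) > 1) diff(grid[1:2]) / 2 else 0.0025
  support <- vapply(grid, function(g) {
    if (g < rng[1] - half || g > rng[2] + half) 0L
    else sum(abs(fl$x - g) <= half * 2)
  }, integer(1))
  curve <- data.frame(gc = grid, effect = eff, support = support)
  normalize_curve(curve, stats::median(fl$x))
}

# replace non-finite entries by the nearest finite entry (by index)
fill_nearest <- function(x) {
  idx <- which(is.finite(x))
  if (!length(idx) || length(idx) == length(x)) return(x)
  pos <- seq_along(x)
  fi <- findInterval(pos, idx)
  left <- idx[pmax(fi, 1L)]
  right <- idx[pmin(fi + 1L, length(idx))]
  pick <- ifelse(fi == 0L, right,
          ifelse(fi == length(idx), left,
                 ifelse(pos - left <= right - pos, left, right)))
  x[pick]
}

normalize_curve <- function(curve, at_gc) {
  ref <- stats::approx(curve$gc, curve$effect, xout = at_gc, rule = 2)$y
  curve$effect <- curve$effect / ref
  class(curve) <- c("gc_curve", "data.frame")
  curve
}

# evaluate a gc_curve at arbitrary GC values (linear interpolation,
# nearest value beyond the grid ends)
curve_effect <- function(curve, gc) {
  stats::approx(curve$gc, curve$effect, xout = gc, rule = 2)$y
}

#' Single-pass GC correction
#'
#' The classical approach: one local regression of value on GC over the
#' whole (unmasked) profile, followed by division by the fitted effect.
#' Adequate when gains and losses are balanced and GC is distributed
#' similarly across copy-number states; biased when GC content and copy
#' number are correlated (the regression absorbs copy-number signal), a
#' bias the two-pass [seqnorm()] removes. The output is rescaled so its
#' median over unmasked windows equals the input median. Windows with
#' missing GC pass through uncorrected and are recorded in the profile
#' log.
#'
#' @param profile a GC-annotated `rc_profile`.
#' @param span loess span.
#' @return the corrected `rc_profile`, with the fitted `gc_curve` in
#'   `$gc_curve`.
#' @export
single_pass_correct <- function(profile, span = 0.3) {
  w <- profile$windows
  mask <- combined_mask(profile)
  use <- !mask & is.finite(w$value) & is.finite(w$gc) & w$value > 0
  curve <- gc_local_fit(w$value[use], w$gc[use], span = span)
  v <- w$value
  has_gc <- is.finite(w$gc)
  v[has_gc] <- w$value[has_gc] / curve_effect(curve, w$gc[has_gc])
  med_in <- stats::median(w$value[!mask & is.finite(w$value)])
  med_out <- stats::median(v[!mask & is.finite(v)])
  if (is.finite(med_out) && med_out > 0) v <- v * med_in / med_out
  if (any(!has_gc)) {
    profile$log <- c(profile$log,
                     sprintf("%d window(s) without GC left uncorrected",
                             sum(!has_gc)))
  }
  profile$windows$value <- v
  profile$gc_curve <- curve
  profile$method <- "single_pass"
  profile
}

#' Robust signal-to-noise ratio of a profile
#'
#' Signal is the median working value over unmasked windows; noise is
#' the derivative-based robust standard deviation
#' `median(|v[i+1] - v[i]|) / (0.6745 * sqrt(2))` computed over
#' consecutive unmasked windows within each chromosome (chromosome
#' boundaries never contribute a difference). The ratio is invariant to
#' rescaling the profile. A constant profile has infinite SNR (flagged,
#' not an error).
#'
#' @param profile an `rc_profile`, or a numeric vector of values (then
#'   `chrom` and `mask` may be given explicitly).
#' @param chrom chromosome labels when `profile` is a vector.
#' @param mask logical exclusion mask when `profile` is a vector.
#' @return list of class `snr_value`: `signal`, `noise`, `snr`,
#'   `constant`.
#' @export
profile_snr <- function(profile, chrom = NULL, mask = NULL) {
  if (inherits(profile, "rc_profile")) {
    v <- profile_values(profile)
    chrom <- profile$windows$chrom
    mask <- combined_mask(profile)
  } else {
    v <- as.numeric(profile)
    if (is.null(chrom)) chrom <- rep("chr1", length(v))
    if (is.null(mask)) mask <- rep(FALSE, length(v))
  }
  keep <- !mask & is.finite(v)
  diffs <- unlist(lapply(split(v[keep], chrom[keep]), diff), use.names = FALSE)
  if (!length(diffs)) stop("need >= 2 unmasked windows on some chromosome")
  noise <- stats::median(abs(diffs)) / (0.6745 * sqrt(2))
  signal <- stats::median(v[keep])
  constant <- noise == 0
  structure(list(signal = signal, noise = noise,
                 snr = if (constant) Inf else signal / noise,
                 constant = constant),
            class = "snr_value")
}
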