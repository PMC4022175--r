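# Exact penalized least-squares changepoint detection (PELT pruning).
# Minimizes sum of within-segment squared errors + penalty * (#segments).
# Returns the segment start indices (1-based, first always 1).
pelt_changepoints <- function(y, penalty) {
  n <- length(y)
  if (n < 2L) return(1L)
  cs <- c(0, cumsum(y))
  cs2 <- c(0, cumsum(y * y))
  # cost of segment covering prefix positions (s+1)..t
  segcost <- function(s, t) {
    len <- t - s
    su <- cs[t + 1] - cs[s + 1]
    (cs2[t + 1] - cs2[s + 1]) - su * su / len
  }
  F <- c(-penalty, rep(NA_real_, n))
  prev <- integer(n + 1)
  cand <- 0L
  for (t in 1:n) {
    costs <- F[cand + 1L] + segcost(cand, t) + penalty
    best <- which.min(costs)
    F[t + 1L] <- costs[best]
    prev[t + 1L] <- cand[best]
    cand <- c(cand[costs <= F[t + 1L] + penalty], t)
  }
  # backtrack
  bp <- integer(0)
  t <- n
  while (t > 0L) {
    bp <- c(prev[t + 1L], bp)
    t <- prev[t + 1L]
  }
  bp + 1L
}

#' Segment a profile into piecewise-constant levels
#'
#' Per-chromosome exact penalized least-squares changepoint
#' segmentation: the fit minimizing squared error plus
#' `penalty * (number of segments)`, solved by pruned dynamic
#' programming. This plays the role of a model-based segmenter:
#' segments are the maximal neighbourhoods over which a locally constant
#' level holds. Masked windows are excluded from the fit and bridged:
#' a segment may span the gap they leave, and its reported window range
#' includes them.
#'
#' @param profile an `rc_profile` with normalized (or raw) values.
#' @param penalty positive scalar; default `3 * noise^2 * log(n)` with
#'   noise from the derivative-based estimator of [profile_snr()].
#' @return data.frame of class `segment_set`: `chrom`, `start_win`,
#'   `end_win` (global window indices, inclusive), `start`, `end`
#'   (base-pair coordinates), `n_windows` (unmasked members), `level`
#'   (median of member values).
#' @export
segment_profile <- function(profile, penalty = NULL) {
  w <- profile$windows
  mask <- combined_mask(profile) | !is.finite(w$value)
  if (is.null(penalty)) {
    noise <- profile_snr(profile)$noise
    noise <- max(noise, 1e-9 * (abs(stats::median(w$value[!mask])) + 1))
    penalty <- 3 * noise^2 * log(sum(!mask))
  }
  stopifnot(penalty > 0)
  chroms <- unique(w$chrom)
  segs <- lapply(chroms, function(ch) {
    gl <- which(w$chrom == ch & !mask)  # global indices of usable windows
    if (length(gl) < 2L) {
      all_idx <- which(w$chrom == ch)
      if (!length(all_idx)) return(NULL)
      lev <- if (length(gl)) w$value[gl] else NA_real_
      return(data.frame(chrom = ch, start_win = min(all_idx),
                        end_win = max(all_idx), n_windows = length(gl),
                        level = lev, stringsAsFactors = FALSE))
    }
    y <- w$value[gl]
    starts <- pelt_changepoints(y, penalty)
    ends <- c(starts[-1] - 1L, length(y))
    data.frame(chrom = ch,
               start_win = gl[starts], end_win = gl[ends],
               n_windows = ends - starts + 1L,
               level = vapply(seq_along(starts), function(k) {
                 stats::median(y[starts[k]:ends[k]])
               }, numeric(1)),
               stringsAsFactors = FALSE)
  })
  segs <- do.call(rbind, segs[!vapply(segs, is.null, logical(1))])
  segs$start <- w$start[segs$start_win]
  segs$end <- w$end[segs$end_win]
  rownames(segs) <- NULL
  class(segs) <- c("segment_set", "data.frame")
  segs
}

#' Call integer copy numbers from segment levels and thresholds
#'
#' A segment whose level lies in `[thresholds[k], thresholds[k+1])`
#' receives copy number `k` (left-inclusive boundaries); below the first
#' threshold the call is 0. Calls are non-decreasing in level. Calling
#' is deliberately threshold-driven and explicit — thresholds encode the
#' analyst's judgment (see [suggest_thresholds()] for a starting point).
#'
#' @param segments a `segment_set`.
#' @param thresholds strictly ascending numeric boundaries on the
#'   normalized-value scale.
#' @return the `segment_set` with a `call` column (class `cn_call_set`),
#'   with `thresholds` attached as an attribute.
#' @export
call_copy_number <- function(segments, thresholds) {
  thresholds <- as.numeric(thresholds)
  if (length(thresholds) < 1 || is.unsorted(thresholds, strictly = TRUE)) {
    stop("thresholds must be strictly ascending")
  }
  segments$call <- findInterval(segments$level, thresholds)
  attr(segments, "thresholds") <- thresholds
  class(segments) <- unique(c("cn_call_set", class(segments)))
  segments
}

#' Suggest calling thresholds from the segment level distribution
#'
#' Identifies the modal segment level (weighted by windows spanned),
#' maps it to `baseline_cn` copies, and places boundaries at odd
#' multiples of half the implied per-copy step. The result is only a
#' suggestion for visual assessment, never applied automatically:
#' copy-number calling legitimately remains a human decision.
#'
#' Segment levels are clustered with a 5% relative tolerance; the
#' heaviest cluster is the mode. With a single segment, or when the two
#' heaviest clusters carry practically identical weight (within 2% —
#' multimodality too flat to pick a mode), no suggestion is made and
#' `NULL` is returned.
#'
#' @param segments a `segment_set`.
#' @param baseline_cn integer copy number assigned to the modal level
#'   (default 2).
#' @return ascending numeric thresholds, or `NULL` with a message.
#' @export
suggest_thresholds <- function(segments, baseline_cn = 2L) {
  stopifnot(nrow(segments) >= 1)
  if (nrow(segments) < 2) {
    message("single segment: per-copy step undefined, no suggestion")
    return(NULL)
  }
  lv <- segments$level
  wt <- segments$n_windows
  ok <- is.finite(lv)
  lv <- lv[ok]; wt <- wt[ok]
  o <- order(lv)
  lv <- lv[o]; wt <- wt[o]
  tol <- 0.05 * stats::median(lv)
  cl <- cumsum(c(1L, as.integer(diff(lv) > tol)))
  cw <- tapply(wt, cl, sum)
  if (length(cw) < 2) {
    message("all segment levels in one cluster: no suggestion")
    return(NULL)
  }
  top2 <- sort(cw, decreasing = TRUE)[1:2]
  if (top2[2] / top2[1] > 0.98) {
    message("level distribution too flat to pick a mode: no suggestion")
    return(NULL)
  }
  mode_cl <- as.integer(names(cw)[which.max(cw)])
  in_mode <- cl == mode_cl
  mode_level <- stats::weighted.mean(lv[in_mode], wt[in_mode])
  step <- mode_level / baseline_cn
  max_call <- round(max(lv) / step)
  (seq_len(max_call + 1L) - 0.5) * step
}

#' Write segments in tab-delimited SEG format
#' @param segments a `segment_set` (optionally with calls).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_seg <- function(segments, path) {
  cols <- intersect(c("chrom", "start", "end", "n_windows", "level", "call"),
                    names(segments))
  data.table::fwrite(as.data.frame(segments)[cols], path, sep = "\t",
                     quote = FALSE)
  invisible(path)
}

#' Assign each window the call of the segment spanning it
#'
#' Masked windows bridged by a segment inherit its call; windows outside
#' every segment get `NA`.
#'
#' @param profile the `rc_profile` the segments were computed from.
#' @param calls a `cn_call_set` from [call_copy_number()].
#' @param fill `"nearest"` (default) assigns windows between segments
#'   (masked at segmentation time) the call of the nearest segment on
#'   the same chromosome; `"none"` leaves them `NA`.
#' @return integer vector of per-window copy-number calls.
#' @export
window_calls <- function(profile, calls, fill = c("nearest", "none")) {
  fill <- match.arg(fill)
  out <- rep(NA_real_, n_windows(profile))
  for (k in seq_len(nrow(calls))) {
    out[calls$start_win[k]:calls$end_win[k]] <- calls$call[k]
  }
  if (fill == "nearest") {
    for (ch in unique(profile$windows$chrom)) {
      i <- profile$windows$chrom == ch
      out[i] <- fill_nearest(out[i])
    }
  }
  as.integer(out)
}
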