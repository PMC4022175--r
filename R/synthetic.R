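# smooth spatially-autocorrelated GC track: AR(1) backbone plus
# window-scale jitter, clamped to a realistic range for ~100 kb-1 Mb
# windows of a mammalian genome
simulate_gc <- function(n, mean_gc = 0.45, ar_sd = 0.04, ar_rho = 0.7,
                        jitter_sd = 0.015, range = c(0.25, 0.68)) {
  e <- stats::rnorm(n, 0, ar_sd * sqrt(1 - ar_rho^2))
  x <- numeric(n)
  x[1] <- stats::rnorm(1, 0, ar_sd)
  for (i in seq_len(n - 1)) x[i + 1] <- ar_rho * x[i] + e[i + 1]
  gc <- mean_gc + x + stats::rnorm(n, 0, jitter_sd)
  pmin(pmax(gc, range[1]), range[2])
}

# Reassign the GC values across windows so that Spearman(GC, CN) hits
# the target, preserving (i) the marginal GC distribution exactly and
# (ii) the original within-segment ordering (local smoothness); only the
# segment-to-segment allocation of GC values changes. The blend weight
# is found by bisection on the achieved correlation.
rank_shift_gc <- function(gc, cn, target, tol = 0.05) {
  n <- length(gc)
  if (target == 0 || stats::sd(cn) == 0) return(gc)
  u <- stats::runif(n)
  r_cn <- rank(cn, ties.method = "average") / n
  sorted_gc <- sort(gc)
  build <- function(w) {
    score <- w * scale(r_cn)[, 1] + sqrt(max(0, 1 - w^2)) * scale(u)[, 1]
    out <- numeric(n)
    out[order(score)] <- sorted_gc
    # restore within-segment ordering (CN constant in a segment, so
    # Spearman(GC, CN) is unchanged by within-segment permutation)
    for (s in split(seq_len(n), cumsum(c(1L, as.integer(diff(cn) != 0))))) {
      out[s] <- sort(out[s])[rank(gc[s], ties.method = "first")]
    }
    out
  }
  sgn <- sign(target)
  lo <- 0; hi <- 1
  best <- build(sgn * 1)
  for (it in 1:25) {
    mid <- (lo + hi) / 2
    cand <- build(sgn * mid)
    rho <- stats::cor(cand, cn, method = "spearman")
    if (abs(rho - target) <= tol / 2) return(cand)
    if (abs(rho) < abs(target)) lo <- mid else hi <- mid
    best <- cand
  }
  rho <- stats::cor(best, cn, method = "spearman")
  if (abs(rho - target) > tol) {
    warning(sprintf("requested GC-CN Spearman %.2f, achieved %.2f", target, rho))
  }
  best
}

#' Random copy-number segment layout
#'
#' Draws a piecewise-constant copy-number structure: segment lengths
#' from a symmetric Dirichlet (each at least `min_frac` of the genome),
#' copy numbers from `cn_pool` with optional constraints on the number
#' of distinct values and the top copy number. A copy number of 2
#' (the diploid baseline) is always included.
#'
#' @param n_windows total windows.
#' @param n_segments number of segments (default 6).
#' @param cn_pool integer copy numbers to draw from (default 1:5).
#' @param n_distinct optional required count of distinct copy numbers.
#' @param top_cn optional required maximum copy number.
#' @param min_frac minimum segment length as a fraction of the genome.
#' @return data.frame `length`, `cn` with `sum(length) == n_windows`.
#' @export
random_cn_segments <- function(n_windows, n_segments = 6L, cn_pool = 1:5,
                               n_distinct = NULL, top_cn = NULL,
                               min_frac = 0.05) {
  raw <- stats::rgamma(n_segments, 2)
  frac <- min_frac + (1 - n_segments * min_frac) * raw / sum(raw)
  len <- floor(frac * n_windows)
  len[1] <- len[1] + n_windows - sum(len)
  tries <- 0L
  repeat {
    tries <- tries + 1L
    if (tries > 1000L) stop("cannot satisfy copy-number constraints")
    cns <- sample(cn_pool, n_segments, replace = TRUE)
    if (!2 %in% cns) cns[sample(n_segments, 1)] <- 2L
    if (!is.null(top_cn)) {
      if (max(cns) > top_cn) next
      if (max(cns) < top_cn) cns[which.max(len * (cns != 2))] <- as.integer(top_cn)
    }
    if (!is.null(n_distinct) && length(unique(cns)) != n_distinct) next
    if (length(unique(cns)) < 2) next
    break
  }
  data.frame(length = as.integer(len), cn = as.integer(cns))
}

#' Simulate a window read-count profile with known truth
#'
#' Emulates the structure of real tumour read-count data: a smooth
#' spatially-autocorrelated GC track, piecewise-constant copy number,
#' a multiplicative exponential GC effect on counts, negative-binomial
#' counting noise, isolated outlier windows, and a tunable Spearman
#' correlation between GC content and copy number (induced by
#' rank-shifting GC between segments while preserving the GC marginal —
#' exactly the confounding the two-pass correction targets).
#'
#' Counts have mean `(mean_count / 2) * cn * effect(gc)` with
#' `effect(gc) = exp(gc_coef * gc)` normalized to mean 1 over windows,
#' and negative-binomial variance `mu + dispersion * mu^2`
#' (`dispersion = 0` is the deterministic noiseless limit). Outliers are
#' isolated windows whose counts are multiplied by U(3, 8).
#'
#' @param n_windows total windows (default 10,000, split over
#'   `n_chrom` chromosomes).
#' @param cn_segments data.frame `length`, `cn` (see
#'   [random_cn_segments()]); by default 6 random segments with copy
#'   numbers in 1..5.
#' @param gc_coef exponential GC-effect coefficient (default 4).
#' @param gc_cn_correlation target Spearman correlation between GC and
#'   copy number, in \[-1, 1\] (default 0). If unreachable, the achieved
#'   value is reported with a warning and stored in the truth.
#' @param mean_count expected reads per window at copy number 2
#'   (default 300).
#' @param dispersion negative-binomial overdispersion (default 0.01).
#' @param outlier_rate fraction of windows planted as isolated outliers
#'   (default 0.005).
#' @param n_chrom chromosomes of equal size (default 2).
#' @param window_size nominal window width in bases (default 200 kb).
#' @param seed RNG seed; same seed, same profile.
#' @return list with `profile` (an `rc_profile`, `value` = counts) and
#'   `truth` (class `sim_truth`): per-window `cn`, `gc`, `gc_coef`,
#'   `outliers` (indices), `achieved_correlation`, `segments`, `seed`.
#' @export
simulate_profile <- function(n_windows = 10000L, cn_segments = NULL,
                             gc_coef = 4, gc_cn_correlation = 0,
                             mean_count = 300, dispersion = 0.01,
                             outlier_rate = 0.005, n_chrom = 2L,
                             window_size = 200000L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(mean_count > 0, dispersion >= 0,
            abs(gc_cn_correlation) <= 1)
  if (is.null(cn_segments)) {
    cn_segments <- random_cn_segments(n_windows)
  }
  stopifnot(sum(cn_segments$length) == n_windows)
  cn <- rep(cn_segments$cn, cn_segments$length)
  per_chrom <- rep(n_windows %/% n_chrom, n_chrom)
  per_chrom[n_chrom] <- per_chrom[n_chrom] + n_windows %% n_chrom
  chrom <- rep(paste0("chr", seq_len(n_chrom)), per_chrom)
  gc <- unlist(lapply(per_chrom, simulate_gc), use.names = FALSE)
  gc <- rank_shift_gc(gc, cn, gc_cn_correlation)
  achieved <- if (stats::sd(cn) > 0) {
    stats::cor(gc, cn, method = "spearman")
  } else NA_real_
  eff <- exp(gc_coef * gc)
  eff <- eff / mean(eff)
  mu <- (mean_count / 2) * cn * eff
  counts <- if (dispersion == 0) mu else {
    stats::rnbinom(n_windows, mu = mu, size = 1 / dispersion)
  }
  outliers <- integer(0)
  if (outlier_rate > 0) {
    n_out <- round(outlier_rate * n_windows)
    cand <- sample(n_windows, min(3 * n_out + 10, n_windows))
    # keep outliers isolated: no two adjacent
    outliers <- integer(0)
    for (i in cand) {
      if (!any(abs(outliers - i) <= 1)) outliers <- c(outliers, i)
      if (length(outliers) >= n_out) break
    }
    counts[outliers] <- counts[outliers] * stats::runif(length(outliers), 3, 8)
  }
  loc <- unlist(lapply(per_chrom, seq_len), use.names = FALSE)
  windows <- data.frame(chrom = chrom,
                        start = (loc - 1L) * window_size + 1L,
                        end = loc * window_size,
                        gc = gc,
                        count = as.integer(round(counts)),
                        value = counts,
                        stringsAsFactors = FALSE)
  prof <- rc_profile(windows, window_size = window_size)
  truth <- structure(list(cn = cn, gc = gc, gc_coef = gc_coef,
                          outliers = sort(outliers),
                          achieved_correlation = achieved,
                          segments = cn_segments, seed = seed,
                          mean_count = mean_count,
                          dispersion = dispersion),
                     class = "sim_truth")
  list(profile = prof, truth = truth)
}

#' Generating GC-effect curve of a simulated profile
#'
#' The true multiplicative effect `exp(gc_coef * gc)` on the package's
#' GC grid, normalized at the median simulated GC — directly comparable
#' to fitted `gc_curve` objects.
#'
#' @param truth a `sim_truth`.
#' @param grid GC grid.
#' @return a `gc_curve` data.frame.
#' @export
true_gc_curve <- function(truth, grid = seq(0.20, 0.70, by = 0.005)) {
  curve <- data.frame(gc = grid, effect = exp(truth$gc_coef * grid),
                      support = as.integer(grid >= min(truth$gc) &
                                             grid <= max(truth$gc)))
  normalize_curve(curve, stats::median(truth$gc))
}

#' Write a simulation truth beside its data
#' @param truth a `sim_truth`.
#' @param prefix output path prefix; writes `<prefix>.truth.tsv`
#'   (per-window cn, gc, outlier flag) and `<prefix>.truth.json`
#'   (parameters).
#' @return invisibly, the two paths.
#' @export
write_truth <- function(truth, prefix) {
  tsv <- paste0(prefix, ".truth.tsv")
  js <- paste0(prefix, ".truth.json")
  out <- rep(FALSE, length(truth$cn))
  out[truth$outliers] <- TRUE
  data.table::fwrite(data.frame(cn = truth$cn, gc = truth$gc, outlier = out),
                     tsv, sep = "\t")
  jsonlite::write_json(list(gc_coef = truth$gc_coef,
                            achieved_correlation = truth$achieved_correlation,
                            seed = truth$seed,
                            mean_count = truth$mean_count,
                            dispersion = truth$dispersion,
                            segments = truth$segments),
                       js, auto_unbox = TRUE, digits = NA)
  invisible(c(tsv, js))
}

#' Generate a toy SAM file with known per-window composition
#'
#' Emits a valid SAM header and one record per requested read. Proper
#' reads carry flag 99 (paired, properly paired, mate reverse, first in
#' pair); improper reads carry flag 97 (properly-paired bit cleared,
#' mate displaced 100 kb). Positions are uniform within each window, so
#' a round trip through [summarize_sam()] recovers the requested counts
#' and improper proportions exactly. Base sequences are placeholders.
#'
#' @param n_proper,n_improper integer vectors, reads per window.
#' @param window_size window width in bases.
#' @param chrom chromosome name for all windows (single-chromosome toy
#'   files) or a vector, one entry per window.
#' @param mapq either a single value, a pool to sample from, or a
#'   `function(n)` returning `n` qualities (default constant 60).
#' @param read_len read length in bases.
#' @param seed RNG seed; fixed seed gives a byte-identical file.
#' @param path optional output path.
#' @return character vector of SAM lines (invisibly if `path` given).
#' @export
simulate_sam <- function(n_proper, n_improper = 0L, window_size = 200000L,
                         chrom = "chr1", mapq = 60L, read_len = 50L,
                         seed = NULL, path = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nw <- max(length(n_proper), length(n_improper))
  n_proper <- rep_len(as.integer(n_proper), nw)
  n_improper <- rep_len(as.integer(n_improper), nw)
  chrom <- rep_len(chrom, nw)
  draw_mapq <- if (is.function(mapq)) mapq
    else function(n) sample(rep_len(as.integer(mapq), max(n, 1)), n,
                            replace = TRUE)
  chrom_len <- tapply(seq_len(nw), chrom, max)
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_len),
                      as.integer(chrom_len) * window_size))
  seq_str <- paste(rep("A", read_len), collapse = "")
  qual_str <- paste(rep("I", read_len), collapse = "")
  recs <- character(0)
  local_win <- stats::ave(seq_len(nw), chrom, FUN = seq_along)
  for (i in seq_len(nw)) {
    tot <- n_proper[i] + n_improper[i]
    if (tot == 0L) next
    lo <- (local_win[i] - 1L) * window_size + 1L
    hi <- local_win[i] * window_size - read_len
    pos <- sort(sample(lo:hi, tot, replace = TRUE))
    fl <- c(rep(99L, n_proper[i]), rep(97L, n_improper[i]))
    mq <- draw_mapq(tot)
    mate <- ifelse(fl == 99L, pos + 200L, pos + 100000L)
    recs <- c(recs, sprintf(
      "r%s_%d\t%d\t%s\t%d\t%d\t%dM\t=\t%d\t%d\t%s\t%s",
      gsub("[^A-Za-z0-9]", "", chrom[i]), seq_len(tot) + i * 10^6,
      fl, chrom[i], pos, mq, read_len, mate,
      ifelse(fl == 99L, 250L, 0L), seq_str, qual_str))
  }
  lines <- c(header, recs)
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
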