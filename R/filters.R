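#' Wald-Wolfowitz runs test statistic for a binary sequence
#'
#' Counts the observed runs R in a 0/1 sequence and compares them with
#' the conditional moments given the number of successes `n1` and
#' failures `n0`:
#' `mu_R = 2 n1 n0 / n + 1` and
#' `sigma_R = sqrt(2 n1 n0 (2 n1 n0 - n) / (n^2 (n - 1)))`.
#' A negative z means fewer runs than expected, i.e. the successes are
#' clustered (adjacent) rather than randomly scattered.
#'
#' @param indicator logical or 0/1 vector, length >= 2.
#' @return list of class `runs_test` with `n1`, `n0`, `R`, `mu_R`,
#'   `sigma_R`, `z` and `degenerate`. For an all-zero or all-one sequence
#'   `z` is `NA` and `degenerate` is `TRUE`.
#' @examples
#' runs_test_z(rep(c(0, 1), 5))$z  # +2.683: perfectly alternating
#' @export
runs_test_z <- function(indicator) {
  x <- as.integer(as.logical(indicator))
  if (anyNA(x)) stop("indicator contains NA")
  n <- length(x)
  if (n < 2L) stop("sequence length must be >= 2")
  n1 <- sum(x); n0 <- n - n1
  R <- 1L + sum(x[-1] != x[-n])
  if (n1 == 0L || n0 == 0L) {
    return(structure(list(n1 = n1, n0 = n0, R = R, mu_R = NA_real_,
                          sigma_R = NA_real_, z = NA_real_,
                          degenerate = TRUE), class = "runs_test"))
  }
  mu <- 2 * n1 * n0 / n + 1
  s2 <- 2 * n1 * n0 * (2 * n1 * n0 - n) / (n^2 * (n - 1))
  structure(list(n1 = n1, n0 = n0, R = R, mu_R = mu,
                 sigma_R = sqrt(s2), z = (R - mu) / sqrt(s2),
                 degenerate = FALSE), class = "runs_test")
}

#' Automatic trimming threshold from the runs test
#'
#' Scans candidate thresholds at upper-tail quantiles of the values,
#' from the most extreme quantile inward. For each candidate with at
#' least `min_exceed` exceeding windows, the |z| of the runs test on the
#' exceedance indicator (in genome order) is computed. Isolated outliers
#' exceed thresholds at random positions (|z| small); once the threshold
#' drops into the level of an adjacent block of windows — a copy-number
#' alteration, not outliers — runs become far fewer than expected and
#' |z| rises suddenly. The threshold returned is the candidate
#' immediately preceding the first step whose |z| increase is at least
#' `jump` (about two standard errors). If no such sudden change occurs,
#' the innermost scanned quantile is returned (pure-outlier regime). If
#' fewer than `min_exceed` windows ever exceed the most extreme
#' candidate, that candidate is returned (nothing to trim beyond it).
#'
#' @param values numeric vector in genome order (GC-pre-corrected; see
#'   [trim_filter()]). Non-finite entries are ignored.
#' @param tail `"upper"` or `"lower"`; the lower tail applies the
#'   identical algorithm to the negated values.
#' @param quantile_range innermost and outermost scanned quantiles.
#' @param n_steps number of evenly spaced quantile candidates.
#' @param min_exceed minimum exceeding windows for a defined statistic.
#' @param jump sudden-change floor on the |z| step increase.
#' @return list with `threshold` (value scale), and `trace`, a
#'   data.frame of scanned `(quantile, threshold, n_exceed, abs_z)`.
#' @export
auto_trim_threshold <- function(values, tail = c("upper", "lower"),
                                quantile_range = c(0.95, 0.9999),
                                n_steps = 200L, min_exceed = 5L, jump = 2) {
  tail <- match.arg(tail)
  v <- values
  ok <- is.finite(v)
  if (sum(ok) < 200L) stop("need >= 200 finite values for auto trimming")
  sign <- if (tail == "lower") -1 else 1
  x <- sign * v[ok]
  qs <- seq(quantile_range[2], quantile_range[1], length.out = n_steps)
  cand <- stats::quantile(x, qs, names = FALSE, type = 7)
  absz <- rep(NA_real_, n_steps)
  nexc <- integer(n_steps)
  for (i in seq_len(n_steps)) {
    ind <- x > cand[i]
    nexc[i] <- sum(ind)
    if (nexc[i] >= min_exceed && nexc[i] < length(x)) {
      absz[i] <- abs(runs_test_z(ind)$z)
    }
  }
  trace <- data.frame(quantile = qs, threshold = sign * cand,
                      n_exceed = nexc, abs_z = absz)
  comp <- which(!is.na(absz))
  thr <- if (!length(comp)) {
    cand[1]  # nothing ever exceeds the most extreme candidate
  } else {
    d <- diff(absz[comp])
    hit <- which(d >= jump)
    if (length(hit)) cand[comp[hit[1]]] else cand[n_steps]
  }
  list(threshold = sign * thr, trace = trace)
}

#' Trimming filter: mask extreme values, GC- and CNA-aware
#'
#' Removes windows with extreme working values, with two distinctive
#' features: (i) values are first corrected against GC content by a
#' single-pass local regression so that extremes due only to extreme GC
#' are not trimmed, and (ii) thresholds are set by the runs-test scan of
#' [auto_trim_threshold()], which tells adjacent CNA blocks apart from
#' scattered outliers on unpaired tumour profiles. When a matched normal
#' profile is supplied, thresholds are instead estimated on the normal's
#' corrected values (CNA-free by construction) and applied to the tumour.
#' Windows already masked by other filters are excluded from threshold
#' estimation; the thresholds are then applied to all windows.
#'
#' @param profile an `rc_profile` (GC-annotated unless
#'   `gc_correct = FALSE`).
#' @param normal optional matched-normal `rc_profile` on the same grid.
#' @param gc_correct perform the prior GC correction (default `TRUE`).
#'   If GC is missing on more than half the windows the correction is
#'   refused and trimming runs on raw values with a loud warning.
#' @param span local-regression span for the prior correction.
#' @param ... passed on to [auto_trim_threshold()].
#' @return list of class `trim_result`: `mask` (logical per window,
#'   `TRUE` where the examined corrected value — the tumour's, or the
#'   normal's in paired mode — falls outside `[lower, upper]`), `lower`,
#'   `upper`, `traces`, and the `corrected` tumour values.
#' @export
trim_filter <- function(profile, normal = NULL, gc_correct = TRUE,
                        span = 0.3, ...) {
  pre_mask <- combined_mask(profile)
  gc_ok <- mean(is.finite(profile$windows$gc)) > 0.5
  if (gc_correct && !gc_ok) {
    warning("GC missing on > 50% of windows: trimming on raw values, ",
            "extreme-GC windows may be trimmed spuriously")
    gc_correct <- FALSE
  }
  corrected <- function(p) {
    if (gc_correct) profile_values(single_pass_correct(p, span = span))
    else profile_values(p)
  }
  v_t <- corrected(profile)
  est <- if (is.null(normal)) v_t else {
    if (n_windows(normal) != n_windows(profile)) {
      stop("normal profile is on a different window grid")
    }
    corrected(normal)
  }
  est_masked <- est
  est_masked[pre_mask] <- NA_real_  # excluded from threshold estimation
  up <- auto_trim_threshold(est_masked, tail = "upper", ...)
  lo <- auto_trim_threshold(est_masked, tail = "lower", ...)
  # thresholds are applied to the values they were estimated on: in
  # paired mode a window is masked when it is extreme in the NORMAL
  # (technical artifact), so tumour CNAs never trim themselves away
  mask <- is.finite(est) & (est > up$threshold | est < lo$threshold)
  structure(list(mask = mask, lower = lo$threshold, upper = up$threshold,
                 traces = list(upper = up$trace, lower = lo$trace),
                 corrected = v_t, gc_corrected = gc_correct),
            class = "trim_result")
}

#' Improper-read (paired-end mapping) filter
#'
#' Windows with an elevated proportion of improper reads tend to be
#' outliers in the profile, likely marking intra-window structural
#' polymorphisms.
#'
#' @param profile a paired-end `rc_profile`.
#' @param max_improper_prop windows with a defined improper proportion
#'   strictly above this are masked; in (0, 1].
#' @return logical mask (zero-read windows unmasked).
#' @export
pem_filter <- function(profile, max_improper_prop) {
  if (!profile$paired) {
    stop("pem_filter unavailable: profile is not paired-end")
  }
  stopifnot(max_improper_prop > 0, max_improper_prop <= 1)
  ip <- improper_prop(profile)
  !is.na(ip) & ip > max_improper_prop
}

#' Mean mapping-quality filter
#'
#' Masks windows whose mean proper-read mapping quality is below
#' `min_mean_mapq` (strict), replacing read-level quality filtering.
#' Windows with no proper reads are masked: they carry no evidence of
#' mappable sequence.
#'
#' @param profile an `rc_profile`.
#' @param min_mean_mapq quality threshold.
#' @return logical mask.
#' @export
mapq_filter <- function(profile, min_mean_mapq) {
  mq <- profile$windows$mean_mapq
  is.na(mq) | mq < min_mean_mapq
}

#' Common-CNV overlap filter
#'
#' Masks windows overlapping population copy-number variants, which
#' would otherwise contaminate somatic calls.
#'
#' @param profile an `rc_profile` with `cnv_overlap` annotated.
#' @param max_cnv_overlap masked iff overlap fraction is strictly above
#'   this; default 0 (any overlap masks).
#' @return logical mask.
#' @export
cnv_filter <- function(profile, max_cnv_overlap = 0) {
  ov <- profile$windows$cnv_overlap
  !is.na(ov) & ov > max_cnv_overlap
}

#' Mappability filter
#'
#' Masks windows whose mappability (fraction of uniquely mapping 35-mers)
#' is below `min_mappability`. Windows with missing mappability are left
#' unmasked by this filter and flagged in the report.
#'
#' @param profile an `rc_profile` with mappability annotated.
#' @param min_mappability fraction in \[0, 1\].
#' @return logical mask.
#' @export
mappability_filter <- function(profile, min_mappability) {
  mp <- profile$windows$mappability
  !is.na(mp) & mp < min_mappability
}

#' Apply a configured set of window filters
#'
#' Runs the requested filters, attaches their masks to the profile
#' (combined mask = logical OR, so application order is irrelevant) and
#' builds a report with per-filter counts and all Venn overlap cells.
#' Filters that cannot run (single-end data, missing annotation) are
#' reported as skipped; requesting the improper-read filter on
#' single-end data is an error unless `skip_unavailable = TRUE`.
#'
#' @param profile an `rc_profile`.
#' @param pem_max,mapq_min,cnv_max,mappability_min thresholds; a filter
#'   runs iff its threshold is non-`NULL` (`trim = TRUE` for trimming).
#' @param trim logical; run the trimming filter.
#' @param normal optional matched normal for [trim_filter()].
#' @param skip_unavailable skip (and log) unavailable filters instead of
#'   erroring.
#' @param span prior-correction span for trimming.
#' @return list with `profile` (masks attached) and `report` (class
#'   `filter_report`: per-filter counts, Venn cells, thresholds used,
#'   trim traces, skipped filters, fraction retained).
#' @export
apply_filters <- function(profile, pem_max = NULL, mapq_min = NULL,
                          trim = FALSE, cnv_max = NULL,
                          mappability_min = NULL, normal = NULL,
                          skip_unavailable = FALSE, span = 0.3) {
  masks <- list()
  skipped <- character()
  thresholds <- list()
  if (!is.null(pem_max)) {
    if (!profile$paired) {
      if (!skip_unavailable) {
        stop("pem filter requested on single-end data ",
             "(use skip_unavailable = TRUE to proceed)")
      }
      skipped <- c(skipped, "pem: single-end data")
    } else {
      masks$pem <- pem_filter(profile, pem_max)
      thresholds$pem_max <- pem_max
    }
  }
  if (!is.null(mapq_min)) {
    if (all(is.na(profile$windows$mean_mapq))) {
      skipped <- c(skipped, "mapq: no mapping-quality information")
    } else {
      masks$mapq <- mapq_filter(profile, mapq_min)
      thresholds$mapq_min <- mapq_min
    }
  }
  if (!is.null(cnv_max)) {
    if (all(is.na(profile$windows$cnv_overlap))) {
      skipped <- c(skipped, "cnv: no CNV annotation")
    } else {
      masks$cnv <- cnv_filter(profile, cnv_max)
      thresholds$cnv_max <- cnv_max
    }
  }
  if (!is.null(mappability_min)) {
    if (all(is.na(profile$windows$mappability))) {
      skipped <- c(skipped, "mappability: no annotation")
    } else {
      masks$mappability <- mappability_filter(profile, mappability_min)
      thresholds$mappability_min <- mappability_min
    }
  }
  trim_res <- NULL
  if (isTRUE(trim)) {
    # other filters' masks are attached first so threshold estimation
    # excludes windows they removed
    profile$filters <- masks
    trim_res <- trim_filter(profile, normal = normal, span = span)
    masks$trim <- trim_res$mask
    thresholds$trim_lower <- trim_res$lower
    thresholds$trim_upper <- trim_res$upper
  }
  profile$filters <- masks
  report <- filter_report(masks, n_windows(profile), thresholds,
                          skipped, trim_res)
  list(profile = profile, report = report)
}

filter_report <- function(masks, n, thresholds, skipped, trim_res = NULL) {
  counts <- vapply(masks, sum, integer(1))
  union_mask <- Reduce(`|`, masks, rep(FALSE, n))
  venn <- list()
  if (length(masks)) {
    membership <- vapply(masks, function(m) m, logical(n))
    if (is.null(dim(membership))) membership <- matrix(membership, nrow = n)
    key <- apply(membership, 1, function(r) {
      paste(names(masks)[r], collapse = "&")
    })
    key <- key[nzchar(key)]
    venn <- as.list(table(key))
  }
  structure(list(n_windows = n,
                 masked = as.list(counts),
                 venn = venn,
                 union = sum(union_mask),
                 retained_fraction = 1 - sum(union_mask) / n,
                 thresholds = thresholds,
                 skipped = skipped,
                 trim_traces = if (!is.null(trim_res)) trim_res$traces),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("filter_report: %d/%d windows masked (%.1f%% retained)\n",
              x$union, x$n_windows, 100 * x$retained_fraction))
  for (nm in names(x$masked)) {
    cat(sprintf("  %-12s %d\n", nm, x$masked[[nm]]))
  }
  if (length(x$skipped)) {
    cat("  skipped:", paste(x$skipped, collapse = "; "), "\n")
  }
  invisible(x)
}
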