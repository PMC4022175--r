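#' Window read-count profile
#'
#' The central container of the package: a fixed-width window grid with
#' per-window read statistics, annotation, a working value and filter
#' masks. Windows within a chromosome are contiguous, non-overlapping and
#' of fixed width (the last window of a chromosome may be short).
#'
#' @param windows data.frame with columns `chrom`, `start`, `end`
#'   (1-based inclusive) and optionally `gc`, `mappability`,
#'   `cnv_overlap`, `count`, `proper_count`, `improper_count`,
#'   `mean_mapq`, `value`.
#' @param window_size window width in bases.
#' @param paired logical; whether the profile came from paired-end data
#'   (enables the improper-read filter).
#' @return An object of class `rc_profile`.
#' @export
rc_profile <- function(windows, window_size, paired = FALSE) {
  stopifnot(is.data.frame(windows),
            all(c("chrom", "start", "end") %in% names(windows)))
  windows <- as.data.frame(windows, stringsAsFactors = FALSE)
  windows$chrom <- as.character(windows$chrom)
  defaults <- list(gc = NA_real_, mappability = NA_real_, cnv_overlap = 0,
                   count = 0L, proper_count = 0L, improper_count = 0L,
                   mean_mapq = NA_real_, value = NA_real_)
  for (nm in names(defaults)) {
    if (is.null(windows[[nm]])) windows[[nm]] <- defaults[[nm]]
  }
  if (all(is.na(windows$value))) windows$value <- as.numeric(windows$count)
  bad <- windows$end - windows$start + 1L > window_size
  if (any(bad)) stop("window(s) wider than window_size")
  structure(list(windows = windows,
                 window_size = as.integer(window_size),
                 paired = isTRUE(paired),
                 filters = list(),
                 log = character()),
            class = "rc_profile")
}

#' Number of windows in a profile
#' @param profile an `rc_profile`.
#' @return integer count of windows.
#' @export
n_windows <- function(profile) nrow(profile$windows)

#' Working values of a profile
#' @param profile an `rc_profile`.
#' @return numeric vector of per-window working values (raw counts,
#'   ratios, or normalized values depending on the processing stage).
#' @export
profile_values <- function(profile) profile$windows$value

#' Combined filter mask
#'
#' Union (logical OR) of all individual filter masks attached to the
#' profile. `TRUE` marks a window removed from downstream analysis.
#'
#' @param profile an `rc_profile`.
#' @return logical vector, one element per window.
#' @export
combined_mask <- function(profile) {
  m <- rep(FALSE, n_windows(profile))
  for (f in profile$filters) m <- m | f
  m
}

#' Per-window improper-read proportion
#'
#' improper / (proper + improper); `NA` where the window has no reads.
#' @param profile an `rc_profile`.
#' @return numeric vector in \[0, 1\] or `NA`.
#' @export
improper_prop <- function(profile) {
  w <- profile$windows
  tot <- w$proper_count + w$improper_count
  ifelse(tot > 0, w$improper_count / tot, NA_real_)
}

#' @export
print.rc_profile <- function(x, ...) {
  w <- x$windows
  cat(sprintf("rc_profile: %d windows of %d bp on %d chromosome(s)%s\n",
              nrow(w), x$window_size, length(unique(w$chrom)),
              if (x$paired) " [paired-end]" else ""))
  cat(sprintf("  total reads: %d (proper %d, improper %d)\n",
              sum(w$count), sum(w$proper_count), sum(w$improper_count)))
  if (length(x$filters)) {
    cat(sprintf("  filters: %s; %d/%d windows masked\n",
                paste(names(x$filters), collapse = ", "),
                sum(combined_mask(x)), nrow(w)))
  }
  if (!all(is.na(w$gc))) cat("  GC annotation present\n")
  invisible(x)
}

#' Write a profile to a tab-delimited file
#'
#' One row per window; filter masks become one logical column per filter
#' plus a combined `filtered` column. The format round-trips through
#' [read_profile()].
#'
#' @param profile an `rc_profile`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  w <- profile$windows
  for (nm in names(profile$filters)) {
    w[[paste0("filter_", nm)]] <- profile$filters[[nm]]
  }
  w$filtered <- combined_mask(profile)
  w <- cbind(w, window_size = profile$window_size, paired = profile$paired)
  data.table::fwrite(w, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

#' Read a profile written by [write_profile()]
#' @param path file path.
#' @return an `rc_profile`.
#' @export
read_profile <- function(path) {
  w <- as.data.frame(data.table::fread(path, sep = "\t", na.strings = "NA"))
  ws <- w$window_size[1]
  paired <- isTRUE(as.logical(w$paired[1]))
  fcols <- grep("^filter_", names(w), value = TRUE)
  filters <- lapply(w[fcols], as.logical)
  names(filters) <- sub("^filter_", "", fcols)
  w <- w[setdiff(names(w), c(fcols, "filtered", "window_size", "paired"))]
  p <- rc_profile(w, window_size = ws, paired = paired)
  p$filters <- filters
  p
}
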