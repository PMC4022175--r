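# SAM flag bits
FLAG_PAIRED      <- 0x1L
FLAG_PROPER_PAIR <- 0x2L
FLAG_UNMAPPED    <- 0x4L
FLAG_SECONDARY   <- 0x100L
FLAG_DUP         <- 0x400L
FLAG_SUPP        <- 0x800L

#' Classify aligned reads from their SAM flag
#'
#' Reads are `"discarded"` when unmapped, secondary, supplementary or
#' duplicate. Paired reads are `"proper"` iff the properly-paired bit is
#' set, otherwise `"improper"` (pair separation/orientation wrong).
#' Single-end mapped reads are `"proper"`. Mapping quality never
#' discards a read: quality handling is deferred to the window-level
#' mean-MAPQ filter, because removing low-quality reads outright lowers
#' the signal-to-noise ratio of the profile.
#'
#' @param flag integer vector of SAM bitwise flags.
#' @return character vector: `"proper"`, `"improper"` or `"discarded"`.
#' @examples
#' classify_read(c(99L, 97L, 4L))
#' @export
classify_read <- function(flag) {
  flag <- as.integer(flag)
  if (any(is.na(flag)) || any(flag < 0L)) stop("invalid SAM flag")
  drop <- bitwAnd(flag, FLAG_UNMAPPED + FLAG_SECONDARY +
                          FLAG_DUP + FLAG_SUPP) != 0L
  paired <- bitwAnd(flag, FLAG_PAIRED) != 0L
  proper_bit <- bitwAnd(flag, FLAG_PROPER_PAIR) != 0L
  out <- ifelse(paired & !proper_bit, "improper", "proper")
  out[drop] <- "discarded"
  out
}

#' Summarize a SAM stream into a window read-count profile
#'
#' Parses SAM text, classifies each record with [classify_read()], and
#' assigns every retained read to the window containing its 1-based
#' leftmost position (`floor((pos - 1) / window_size)`). Per-window
#' totals, proper/improper counts and the mean mapping quality of proper
#' reads are accumulated. Input order is irrelevant; sorted and unsorted
#' files give identical profiles.
#'
#' @param sam path to a SAM file, or a character vector of SAM lines.
#' @param window_size window width in bases (default 200 kb).
#' @param chrom_lengths optional named vector of chromosome lengths;
#'   taken from the `@SQ` header lines when absent.
#' @return an `rc_profile`; reads on chromosomes absent from the header
#'   are skipped with a warning and counted in the profile `log`.
#' @export
summarize_sam <- function(sam, window_size = 200000L, chrom_lengths = NULL) {
  lines <- if (length(sam) == 1L && file.exists(sam)) readLines(sam) else sam
  hdr <- lines[startsWith(lines, "@")]
  body <- lines[!startsWith(lines, "@") & nzchar(lines)]
  if (is.null(chrom_lengths)) {
    sq <- hdr[startsWith(hdr, "@SQ")]
    if (!length(sq)) stop("no @SQ header lines and no chrom_lengths given")
    sn <- sub(".*\tSN:([^\t]+).*", "\\1", sq)
    ln <- as.numeric(sub(".*\tLN:([0-9]+).*", "\\1", sq))
    chrom_lengths <- stats::setNames(ln, sn)
  }
  grid <- window_grid(chrom_lengths, window_size)
  prof <- rc_profile(grid, window_size = window_size)
  if (!length(body)) {
    prof$log <- "0 records"
    return(prof)
  }
  f <- strsplit(body, "\t", fixed = TRUE)
  flag <- vapply(f, function(x) as.integer(x[2]), integer(1))
  chrom <- vapply(f, `[`, character(1), 3)
  pos <- vapply(f, function(x) as.integer(x[4]), integer(1))
  mapq <- vapply(f, function(x) as.integer(x[5]), integer(1))
  cls <- classify_read(flag)

  keep <- cls != "discarded"
  unknown <- keep & !(chrom %in% names(chrom_lengths))
  if (any(unknown)) {
    warning(sprintf("%d read(s) on chromosome(s) absent from header skipped",
                    sum(unknown)))
    keep <- keep & !unknown
  }
  prof$paired <- any(bitwAnd(flag, FLAG_PAIRED) != 0L)
  # global window index = chromosome offset + local window
  offs <- cumsum(c(0L, tapply(rep(1L, nrow(grid)), factor(grid$chrom,
                  levels = unique(grid$chrom)), sum)))
  names(offs) <- c(unique(grid$chrom), "")
  nwin_chr <- table(factor(grid$chrom, levels = unique(grid$chrom)))
  loc <- (pos[keep] - 1L) %/% as.integer(window_size) + 1L
  loc <- pmin(loc, as.integer(nwin_chr[chrom[keep]]))  # clamp reads past chrom end
  gidx <- offs[chrom[keep]] + loc
  proper <- cls[keep] == "proper"
  nw <- nrow(grid)
  prof$windows$count <- as.integer(tabulate(gidx, nw))
  prof$windows$proper_count <- as.integer(tabulate(gidx[proper], nw))
  prof$windows$improper_count <- prof$windows$count - prof$windows$proper_count
  msum <- rep(0, nw)
  if (any(proper)) {
    agg <- tapply(mapq[keep][proper], gidx[proper], sum)
    msum[as.integer(names(agg))] <- agg
  }
  prof$windows$mean_mapq <- ifelse(prof$windows$proper_count > 0,
                                   msum / prof$windows$proper_count, NA_real_)
  prof$windows$value <- as.numeric(prof$windows$count)
  prof$log <- sprintf("%d records: %d proper, %d improper, %d discarded, %d unknown-chrom",
                      length(body), sum(cls == "proper" & !unknown),
                      sum(cls == "improper" & !unknown),
                      sum(cls == "discarded"), sum(unknown))
  prof
}

#' Build a fixed-width window grid from chromosome lengths
#' @param chrom_lengths named numeric vector of chromosome lengths.
#' @param window_size window width in bases.
#' @return data.frame with `chrom`, `start`, `end` (1-based inclusive);
#'   the last window of each chromosome may be short.
#' @export
window_grid <- function(chrom_lengths, window_size) {
  window_size <- as.integer(window_size)
  out <- lapply(names(chrom_lengths), function(ch) {
    len <- chrom_lengths[[ch]]
    nw <- ceiling(len / window_size)
    start <- (seq_len(nw) - 1L) * window_size + 1L
    data.frame(chrom = ch, start = start,
               end = pmin(start + window_size - 1L, as.integer(len)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

windows_granges <- function(windows) {
  GenomicRanges::GRanges(windows$chrom,
                         IRanges::IRanges(windows$start, windows$end))
}

# coverage-weighted mean of a per-interval score over each window;
# NA where nothing overlaps (never a silent zero)
weighted_overlap_mean <- function(windows, tab, col) {
  wgr <- windows_granges(windows)
  agr <- GenomicRanges::GRanges(tab$chrom, IRanges::IRanges(tab$start, tab$end))
  hits <- GenomicRanges::findOverlaps(wgr, agr)
  if (!length(hits)) return(rep(NA_real_, nrow(windows)))
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  ov <- IRanges::width(IRanges::pintersect(
    IRanges::ranges(wgr)[qi], IRanges::ranges(agr)[si]))
  val <- tab[[col]][si]
  num <- tapply(ov * val, qi, sum)
  den <- tapply(ov, qi, sum)
  out <- rep(NA_real_, nrow(windows))
  out[as.integer(names(num))] <- num / den
  out
}

# fraction of each window covered by any interval in tab
overlap_fraction <- function(windows, tab) {
  wgr <- windows_granges(windows)
  agr <- GenomicRanges::reduce(GenomicRanges::GRanges(
    tab$chrom, IRanges::IRanges(tab$start, tab$end)))
  hits <- GenomicRanges::findOverlaps(wgr, agr)
  out <- rep(0, nrow(windows))
  if (!length(hits)) return(out)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  ov <- IRanges::width(IRanges::pintersect(
    IRanges::ranges(wgr)[qi], IRanges::ranges(agr)[si]))
  cov <- tapply(ov, qi, sum)
  out[as.integer(names(cov))] <-
    cov / IRanges::width(IRanges::ranges(wgr))[as.integer(names(cov))]
  out
}

#' Read a tab-delimited annotation table
#'
#' Expected columns: `chrom`, `start`, `end` (1-based inclusive) and one
#' or both of `gc`, `mappability`. A header line is optional.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_annotation <- function(path) {
  first <- readLines(path, n = 1)
  has_header <- grepl("chrom", first, fixed = TRUE)
  tab <- as.data.frame(data.table::fread(path, sep = "\t", header = has_header))
  if (!has_header) {
    names(tab)[1:3] <- c("chrom", "start", "end")
    extra <- c("gc", "mappability")
    names(tab)[seq(4, length.out = ncol(tab) - 3)] <-
      extra[seq_len(ncol(tab) - 3)]
  }
  tab$chrom <- as.character(tab$chrom)
  tab
}

#' Read a BED file of intervals
#'
#' Standard BED dialect: 0-based half-open coordinates, converted to the
#' package's 1-based inclusive convention on read.
#'
#' @param path file path.
#' @return data.frame with `chrom`, `start`, `end` (1-based inclusive).
#' @export
read_bed <- function(path) {
  tab <- as.data.frame(data.table::fread(path, sep = "\t", header = FALSE))
  out <- data.frame(chrom = as.character(tab[[1]]),
                    start = as.integer(tab[[2]]) + 1L,
                    end = as.integer(tab[[3]]),
                    stringsAsFactors = FALSE)
  out
}

#' Attach GC, mappability and common-CNV annotation to a profile
#'
#' GC and mappability are attached by exact window match when the
#' annotation rows coincide with the grid, otherwise by coverage-weighted
#' mean of overlapping intervals. `cnv_overlap` is the fraction of each
#' window covered by any CNV interval. Windows with no overlapping
#' annotation get `NA` (and are later excluded from GC-dependent steps).
#'
#' @param profile an `rc_profile`.
#' @param gc_table data.frame (`chrom`,`start`,`end`,`gc`) or path; optional.
#' @param mappability_table data.frame (`chrom`,`start`,`end`,`mappability`)
#'   or path; optional (may be the same table as `gc_table`).
#' @param cnv_bed data.frame (1-based, e.g. from [read_bed()]) or BED
#'   file path; optional.
#' @return the annotated `rc_profile`.
#' @export
annotate_profile <- function(profile, gc_table = NULL,
                             mappability_table = NULL, cnv_bed = NULL) {
  w <- profile$windows
  attach_col <- function(tab, col) {
    if (is.character(tab)) tab <- read_annotation(tab)
    key_w <- paste(w$chrom, w$start, w$end)
    key_t <- paste(tab$chrom, tab$start, tab$end)
    m <- match(key_w, key_t)
    if (!anyNA(m)) tab[[col]][m] else weighted_overlap_mean(w, tab, col)
  }
  if (!is.null(gc_table)) w$gc <- attach_col(gc_table, "gc")
  if (!is.null(mappability_table)) {
    w$mappability <- attach_col(mappability_table, "mappability")
  }
  if (!is.null(cnv_bed)) {
    if (is.character(cnv_bed)) cnv_bed <- read_bed(cnv_bed)
    w$cnv_overlap <- overlap_fraction(w, cnv_bed)
  }
  profile$windows <- w
  profile
}
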