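test_that("classify_read follows the SAM flag semantics", {
  # paired + properly-paired -> proper; paired without 0x2 -> improper
  expect_equal(classify_read(99L), "proper")
  expect_equal(classify_read(97L), "improper")
  expect_equal(classify_read(4L), "discarded")       # unmapped
  expect_equal(classify_read(0L), "proper")          # single-end mapped
  expect_equal(classify_read(16L), "proper")         # single-end reverse
  expect_equal(classify_read(1024L), "discarded")    # duplicate
  expect_equal(classify_read(256L + 1L), "discarded")  # secondary
  expect_equal(classify_read(2048L + 99L), "discarded")  # supplementary
  # low mapping quality never discards a read (window filter does that)
  expect_equal(classify_read(c(99L, 97L, 4L)),
               c("proper", "improper", "discarded"))
  expect_error(classify_read(-1L), "flag")
})

test_that("summarize_sam assigns reads to windows and conserves totals", {
  prof <- summarize_sam(toy_sam(), window_size = 1000000L)
  w <- prof$windows
  expect_equal(nrow(w), 2L)
  expect_equal(w$count, c(5L, 1L))
  expect_equal(improper_prop(prof)[1], 0.2)
  expect_equal(w$proper_count, c(4L, 1L))
  expect_true(prof$paired)
  # conservation: proper + improper + discarded == records
  expect_match(prof$log, "^6 records: 5 proper, 1 improper, 0 discarded")
})

test_that("empty SAM gives an all-zero profile, not an error", {
  prof <- summarize_sam(c("@HD\tVN:1.6", "@SQ\tSN:chr1\tLN:500000"),
                        window_size = 100000L)
  expect_equal(sum(prof$windows$count), 0L)
  expect_equal(nrow(prof$windows), 5L)
  expect_true(all(is.na(prof$windows$mean_mapq)))
})

test_that("mean mapping quality averages proper reads only", {
  sam <- c("@SQ\tSN:chr1\tLN:1000",
           "a\t99\tchr1\t10\t20\t50M\t=\t210\t250\tA\tI",
           "b\t99\tchr1\t20\t40\t50M\t=\t220\t250\tA\tI",
           "c\t97\tchr1\t30\t2\t50M\t=\t90000\t0\tA\tI")
  prof <- summarize_sam(sam, window_size = 1000L)
  expect_equal(prof$windows$mean_mapq, 30)  # improper mapq 2 excluded
})

test_that("summarization is invariant to record order", {
  sam <- simulate_sam(n_proper = c(30, 10, 25), n_improper = c(3, 0, 7),
                      window_size = 5000L, mapq = c(10L, 30L, 60L), seed = 4)
  hdr <- sam[startsWith(sam, "@")]
  body <- sam[!startsWith(sam, "@")]
  set.seed(99)
  shuffled <- c(hdr, sample(body))
  p1 <- summarize_sam(sam, window_size = 5000L)
  p2 <- summarize_sam(shuffled, window_size = 5000L)
  expect_identical(p1$windows, p2$windows)
  expect_equal(p1$windows$count, c(33L, 10L, 32L))
})

test_that("reads on unknown chromosomes are skipped with a warning", {
  sam <- c("@SQ\tSN:chr1\tLN:1000",
           "a\t0\tchr1\t10\t60\t50M\t*\t0\t0\tA\tI",
           "b\t0\tchrUn\t10\t60\t50M\t*\t0\t0\tA\tI")
  expect_warning(prof <- summarize_sam(sam, window_size = 1000L),
                 "absent from header")
  expect_equal(prof$windows$count, 1L)
})

test_that("window_grid shortens the last window of a chromosome", {
  g <- window_grid(c(chr1 = 2500), 1000)
  expect_equal(g$start, c(1, 1001, 2001))
  expect_equal(g$end, c(1000, 2000, 2500))
})

test_that("annotation attaches by exact match and by weighted overlap", {
  prof <- summarize_sam(c("@SQ\tSN:chr1\tLN:2000"), window_size = 1000L)
  # exact match: identity
  exact <- data.frame(chrom = "chr1", start = c(1, 1001), end = c(1000, 2000),
                      gc = c(0.41, 0.55))
  p <- annotate_profile(prof, gc_table = exact)
  expect_equal(p$windows$gc, c(0.41, 0.55))
  # two equal-length intervals over one window: mean of 0.3, 0.5 -> 0.4
  halves <- data.frame(chrom = "chr1", start = c(1, 501), end = c(500, 1000),
                       gc = c(0.3, 0.5))
  p2 <- annotate_profile(prof, gc_table = halves)
  expect_equal(p2$windows$gc[1], 0.4)
  expect_true(is.na(p2$windows$gc[2]))  # no overlap -> missing, never zero
  # CNV interval covering half a window -> overlap 0.5 (BED is 0-based)
  cnv <- data.frame(chrom = "chr1", start = 1L, end = 500L)
  p3 <- annotate_profile(prof, cnv_bed = cnv)
  expect_equal(p3$windows$cnv_overlap, c(0.5, 0))
})

test_that("BED coordinates are converted to 1-based inclusive", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t0\t500", path)
  bed <- read_bed(path)
  expect_equal(bed$start, 1L)
  expect_equal(bed$end, 500L)
})

test_that("profile TSV round-trips", {
  sam <- simulate_sam(n_proper = c(12, 8), n_improper = c(2, 1),
                      window_size = 2000L, seed = 5)
  p <- summarize_sam(sam, window_size = 2000L)
  p$filters$mapq <- c(TRUE, FALSE)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_profile(p, path)
  q <- read_profile(path)
  expect_equal(q$windows$count, p$windows$count)
  expect_equal(q$filters, p$filters)
  expect_equal(q$window_size, p$window_size)
  expect_equal(q$paired, p$paired)
})
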