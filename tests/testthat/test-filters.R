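test_that("runs test matches the closed form on frozen examples", {
  # alternating 10-element sequence: R = 10, mu = 6, z = +2.683
  r <- runs_test_z(rep(c(0, 1), 5))
  expect_equal(r$R, 10L)
  expect_equal(r$mu_R, 6)
  expect_equal(r$z, 2.683282, tolerance = 1e-6)
  # fully blocked: R = 2, symmetric
  r2 <- runs_test_z(c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0))
  expect_equal(r2$R, 2L)
  expect_equal(r2$z, -2.683282, tolerance = 1e-6)
  # one-class sequence is degenerate, z undefined
  r3 <- runs_test_z(c(1, 1, 1, 1))
  expect_true(r3$degenerate)
  expect_true(is.na(r3$z))
  expect_error(runs_test_z(1), "length")
})

test_that("runs-test moments agree with exhaustive enumeration (n <= 10)", {
  # oracle: enumerate every arrangement for each (n, n1), tabulate the
  # exact runs distribution, compare its moments with the formulas
  for (n in c(4L, 6L, 8L, 10L)) {
    combos <- expand.grid(rep(list(c(0L, 1L)), n))
    runs <- apply(combos, 1, function(x) 1L + sum(x[-1] != x[-n]))
    n1s <- rowSums(combos)
    for (n1 in 1:(n - 1)) {
      sel <- n1s == n1
      mu_emp <- mean(runs[sel])
      sd_emp <- sqrt(mean((runs[sel] - mu_emp)^2))
      r <- runs_test_z(c(rep(1, n1), rep(0, n - n1)))
      expect_equal(r$mu_R, mu_emp, tolerance = 1e-12)
      expect_equal(r$sigma_R, sd_emp, tolerance = 1e-12)
    }
  }
})

test_that("pem filter masks by improper proportion", {
  p <- quick_profile(rep(1, 3))
  p$paired <- TRUE
  p$windows$proper_count <- c(4L, 10L, 0L)
  p$windows$improper_count <- c(6L, 0L, 0L)
  m <- pem_filter(p, 0.5)
  expect_equal(m, c(TRUE, FALSE, FALSE))  # zero-read windows unmasked
  expect_error(pem_filter(quick_profile(1:5), 0.5), "paired")
})

test_that("pem filter masks the expected fraction under uniform draws", {
  set.seed(42)
  n <- 10000
  p <- quick_profile(rep(1, n))
  p$paired <- TRUE
  u <- runif(n)
  p$windows$improper_count <- as.integer(round(u * 1000))
  p$windows$proper_count <- 1000L - p$windows$improper_count
  expect_lt(abs(mean(pem_filter(p, 0.9)) - 0.1), 0.02)
})

test_that("mapq filter is strict and masks no-proper-read windows", {
  p <- quick_profile(rep(1, 4))
  p$windows$mean_mapq <- c(10, 30, 60, NA)
  expect_equal(mapq_filter(p, 30), c(TRUE, FALSE, FALSE, TRUE))
  p$windows$mean_mapq <- rep(60, 4)
  expect_equal(sum(mapq_filter(p, 30)), 0L)
})

test_that("cnv and mappability filters apply their thresholds", {
  p <- quick_profile(rep(1, 3))
  p$windows$cnv_overlap <- c(0.5, 0, 0.3)
  expect_equal(cnv_filter(p, 0), c(TRUE, FALSE, TRUE))
  expect_equal(cnv_filter(p, 0.5), c(FALSE, FALSE, FALSE))
  p$windows$mappability <- c(0.2, 1.0, NA)
  expect_equal(mappability_filter(p, 0.5), c(TRUE, FALSE, FALSE))
})

test_that("auto trimming finds the sudden randomness change", {
  fx <- block_outlier_values(seed = 1)
  at <- auto_trim_threshold(fx$values, tail = "upper")
  # threshold between the CNA block level and the outlier level:
  # block survives (majority), scattered outliers masked
  expect_gt(at$threshold, 3)
  expect_lt(at$threshold, 6)
  expect_gt(mean(fx$values[fx$block] <= at$threshold), 0.5)
  expect_equal(mean(fx$values[fx$outliers] > at$threshold), 1)
  # z-trace recorded for inspection
  expect_true(all(c("quantile", "threshold", "abs_z") %in% names(at$trace)))
})

test_that("auto trimming falls to the innermost quantile on pure noise", {
  set.seed(8)
  v <- rnorm(2000, 1, 0.05)
  at <- auto_trim_threshold(v, tail = "upper")
  expect_lte(mean(v > at$threshold), 0.055)  # ~5% on that tail
})

test_that("a shuffled CNA block is treated as outliers", {
  fx <- block_outlier_values(seed = 3)
  v <- fx$values
  set.seed(33)
  new_pos <- sample(setdiff(seq_along(v), fx$outliers), length(fx$block))
  shuffled <- v
  shuffled[fx$block] <- rnorm(length(fx$block), 1, 0.05)
  shuffled[new_pos] <- v[fx$block]
  at <- auto_trim_threshold(shuffled, tail = "upper")
  # no adjacency-driven jump at level 3: threshold drops to the
  # innermost quantile and masks the former block windows
  expect_gt(mean(shuffled[new_pos] > at$threshold), 0.9)
})

test_that("trimming pre-corrects GC so GC-extreme windows survive", {
  prof <- gc_effect_profile(n = 5000, coef = 5, seed = 7)
  v <- profile_values(prof)
  gc <- prof$windows$gc
  top1 <- order(v, decreasing = TRUE)[1:50]  # all high-GC under pure effect
  tr_on <- trim_filter(prof)
  tr_off <- suppressWarnings(trim_filter(prof, gc_correct = FALSE))
  expect_lt(mean(tr_on$mask[top1]), 0.3)
  expect_gt(mean(tr_off$mask[top1]), 0.5)
  # unpaired, no outliers: masked fraction bounded by the scan range
  expect_lte(mean(tr_on$mask), 2 * (1 - 0.95) + 0.01)
})

test_that("trimming refuses GC pre-correction when GC is mostly missing", {
  set.seed(10)
  p <- quick_profile(rnorm(1000, 100, 5))
  expect_warning(tr <- trim_filter(p), "GC missing")
  expect_false(tr$gc_corrected)
})

test_that("trim GC-neutrality: masked windows are not GC-extreme", {
  prof <- gc_effect_profile(n = 2000, coef = 5, seed = 21)
  tr <- trim_filter(prof)
  gc <- prof$windows$gc
  dev <- abs(gc - median(gc))
  skip_if(sum(tr$mask) < 5)
  p <- wilcox.test(dev[tr$mask], dev[!tr$mask])$p.value
  expect_gt(p, 0.01)
})

test_that("paired trimming estimates thresholds on the normal", {
  set.seed(12)
  n <- 3000
  base <- rnorm(n, 100, 5)
  normal <- quick_profile(base)
  tumor_v <- rnorm(n, 100, 5)
  amp <- 1001:1200  # 200-window amplification, a real CNA
  tumor_v[amp] <- rnorm(200, 300, 5)
  tumor <- quick_profile(tumor_v)
  tr <- suppressWarnings(trim_filter(tumor, normal = normal,
                                     gc_correct = FALSE))
  # thresholds come from the clean normal and mask windows extreme in
  # the normal, so the tumour amplification is never trimmed away
  expect_equal(which(tr$mask[amp]),
               which(base[amp] > tr$upper | base[amp] < tr$lower))
  expect_lt(mean(tr$mask[amp]), 0.2)
  expect_lt(tr$upper, 150)
  expect_gt(tr$upper, quantile(base, 0.9))
})

test_that("apply_filters combines masks order-independently with a report", {
  set.seed(13)
  p <- quick_profile(rnorm(10, 100, 5))
  p$paired <- TRUE
  p$windows$proper_count <- rep(10L, 10)
  p$windows$improper_count <- c(15L, 15L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L)
  p$windows$mean_mapq <- c(60, 10, 10, 60, 60, 60, 60, 60, 60, 60)
  p$windows$cnv_overlap <- c(0, 0, 0, 0.8, 0, 0, 0, 0, 0, 0)
  res <- apply_filters(p, pem_max = 0.5, mapq_min = 30, cnv_max = 0)
  # masks: pem {1,2}, mapq {2,3}, cnv {4}
  expect_equal(which(combined_mask(res$profile)), 1:4)
  expect_equal(res$report$masked$pem, 2L)
  expect_equal(res$report$masked$mapq, 2L)
  # Venn cells sum to the union size
  expect_equal(sum(unlist(res$report$venn)), res$report$union)
  expect_equal(res$report$venn[["pem&mapq"]], 1L)
  # order independence: OR of individual masks equals the combined mask
  ord <- Reduce(`|`, rev(res$profile$filters))
  expect_identical(ord, combined_mask(res$profile))
})

test_that("unavailable filters error or are reported as skipped", {
  p <- quick_profile(rnorm(300, 100, 5))  # single-end
  expect_error(apply_filters(p, pem_max = 0.5), "single-end")
  res <- apply_filters(p, pem_max = 0.5, skip_unavailable = TRUE)
  expect_match(res$report$skipped, "pem", all = FALSE)
  expect_equal(res$report$retained_fraction, 1)
})

test_that("all filters disabled retains everything", {
  p <- quick_profile(rnorm(50, 100, 5))
  res <- apply_filters(p)
  expect_equal(sum(combined_mask(res$profile)), 0L)
  expect_equal(res$report$retained_fraction, 1)
})
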