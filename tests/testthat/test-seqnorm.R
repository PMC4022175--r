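test_that("seqnorm matches single-pass when GC and CN are uncorrelated", {
  rms <- vapply(1:3, function(s) {
    sim <- simulate_profile(5000, gc_cn_correlation = 0, outlier_rate = 0,
                            seed = s)
    a <- profile_values(single_pass_correct(sim$profile))
    b <- profile_values(seqnorm(sim$profile))
    sqrt(mean(((b - a) / a)^2))
  }, numeric(1))
  expect_lt(median(rms), 0.03)
})

test_that("seqnorm recovers exact proportionality on noiseless data", {
  sim <- simulate_profile(4000, cn_segments = data.frame(
    length = rep(1000, 4), cn = c(2L, 4L, 2L, 4L)),
    gc_cn_correlation = 0, dispersion = 0, outlier_rate = 0, seed = 11)
  b <- seqnorm(sim$profile)
  expect_identical(b$method, "seqnorm")
  # curve within 1% of the generating curve on the supported grid
  tc <- true_gc_curve(sim$truth)
  supp <- b$gc_curve$support >= 2
  expect_lt(max(abs(b$gc_curve$effect[supp] / tc$effect[supp] - 1)), 0.01)
  # corrected values proportional to planted copy number where the
  # curve is estimated (not nearest-filled)
  gcr <- range(b$gc_curve$gc[supp])
  inw <- sim$truth$gc >= gcr[1] & sim$truth$gc <= gcr[2]
  ratio <- profile_values(b)[inw] / sim$truth$cn[inw]
  expect_lt(diff(range(ratio)) / median(ratio), 0.01)
})

test_that("seqnorm halves the curve error under GC-CN correlation", {
  errs <- vapply(1:3, function(s) {
    set.seed(s)
    segs <- random_cn_segments(10000, n_distinct = 4, top_cn = 4)
    sim <- simulate_profile(10000, cn_segments = segs,
                            gc_cn_correlation = 0.6, mean_count = 300,
                            outlier_rate = 0, seed = s)
    a <- single_pass_correct(sim$profile)
    b <- seqnorm(sim$profile)
    tc <- true_gc_curve(sim$truth)
    gcr <- quantile(sim$truth$gc, c(0.05, 0.95))
    sel <- tc$gc >= gcr[1] & tc$gc <= gcr[2]
    c(sp = max(abs(a$gc_curve$effect[sel] / tc$effect[sel] - 1)),
      sn = max(abs(b$gc_curve$effect[sel] / tc$effect[sel] - 1)))
  }, numeric(2))
  expect_lt(median(errs["sn", ]), 0.5 * median(errs["sp", ]))
})

test_that("seqnorm preserves the median and falls back loudly", {
  sim <- simulate_profile(3000, gc_cn_correlation = 0, seed = 14)
  b <- seqnorm(sim$profile)
  expect_equal(median(profile_values(b)),
               median(profile_values(sim$profile)), tolerance = 1e-9)
  expect_true(all(profile_values(b) >= 0))
  # a flat single-chromosome profile segments into < 3 pieces:
  # fallback to single pass with a warning
  sim2 <- simulate_profile(2000, cn_segments = data.frame(
    length = 2000L, cn = 2L), n_chrom = 1L,
    gc_cn_correlation = 0, dispersion = 0.005, outlier_rate = 0, seed = 15)
  expect_warning(f <- seqnorm(sim2$profile), "falling back")
  expect_identical(f$method, "single_pass")
  expect_match(f$fallback, "segments")
})

test_that("paired ratio normalization cancels shared window effects", {
  # tumor exactly 2x normal -> constant ratio 1 after median rescale
  set.seed(16)
  nv <- rnorm(2000, 100, 10)
  normal <- quick_profile(nv)
  tumor <- quick_profile(2 * nv)
  out <- paired_normalize(tumor, normal, mode = "ratio")
  expect_equal(profile_values(out), rep(1, 2000), tolerance = 1e-12)
  # normal carries the GC effect; ratio removes the GC correlation
  prof_n <- gc_effect_profile(n = 4000, coef = 5, seed = 17, noise_sd = 0.02)
  cn <- rep(c(2, 4, 2, 3), each = 1000)
  set.seed(18)
  prof_t <- prof_n  # same window grid
  prof_t$windows$value <- profile_values(prof_n) * (cn / 2) *
    exp(rnorm(4000, 0, 0.02))
  out2 <- paired_normalize(prof_t, prof_n, mode = "ratio")
  expect_lt(abs(cor(profile_values(out2), prof_n$windows$gc)), 0.05)
})

test_that("paired normalization handles zero-count normals and grid mismatch", {
  set.seed(19)
  nv <- rnorm(500, 100, 5)
  nv[7] <- 0
  normal <- quick_profile(nv)
  tumor <- quick_profile(rnorm(500, 100, 5))
  out <- paired_normalize(tumor, normal, mode = "ratio")
  expect_match(out$log, "pseudocount", all = FALSE)
  expect_true(is.finite(profile_values(out)[7]))
  expect_error(paired_normalize(quick_profile(rnorm(400, 100, 5)), normal),
               "different window grids")
})

test_that("paired seqnorm regresses tumour on the normal segment-wise", {
  prof_n <- gc_effect_profile(n = 6000, coef = 4, seed = 20, noise_sd = 0.02)
  cn <- rep(c(2, 4, 2, 3, 2, 5), each = 1000)
  set.seed(21)
  prof_t <- prof_n  # same window grid
  prof_t$windows$value <- profile_values(prof_n) * (cn / 2) *
    exp(rnorm(6000, 0, 0.02))
  out <- paired_normalize(prof_t, prof_n, mode = "seqnorm")
  expect_true(out$method %in% c("paired_seqnorm", "paired_seqnorm_fallback"))
  expect_lt(abs(cor(profile_values(out), prof_n$windows$gc)), 0.1)
  # corrected values track copy number
  expect_gt(cor(profile_values(out), cn), 0.9)
})
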