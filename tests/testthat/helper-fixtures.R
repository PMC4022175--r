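# Fixtures are built in code at test time; nothing is stored on disk.

# hand-written toy SAM (independent of simulate_sam)
toy_sam <- function() {
  c("@HD\tVN:1.6\tSO:unsorted",
    "@SQ\tSN:chr1\tLN:2000000",
    # 5 proper (flag 99), 1 improper (flag 97, paired without 0x2):
    # first window holds 4 proper + 1 improper, second window 1 proper
    "r1\t99\tchr1\t100\t60\t50M\t=\t300\t250\tAAAA\tIIII",
    "r2\t99\tchr1\t150\t60\t50M\t=\t350\t250\tAAAA\tIIII",
    "r3\t97\tchr1\t120\t60\t50M\t=\t900000\t0\tAAAA\tIIII",
    "r4\t99\tchr1\t250\t60\t50M\t=\t450\t250\tAAAA\tIIII",
    "r5\t99\tchr1\t300\t60\t50M\t=\t500\t250\tAAAA\tIIII",
    "r6\t99\tchr1\t1000050\t60\t50M\t=\t1000250\t250\tAAAA\tIIII")
}

# profile with a smooth GC track and a pure multiplicative GC effect
gc_effect_profile <- function(n = 5000, coef = 5, noise_sd = 0.03,
                              base = 100, seed = 1, cn = rep(1, n)) {
  set.seed(seed)
  ar <- as.numeric(stats::arima.sim(list(ar = 0.7), n, sd = 0.5 * 0.08))
  gc <- pmin(pmax(0.45 + 0.08 * ar + stats::rnorm(n, 0, 0.015), 0.25), 0.68)
  v <- base * cn * exp(coef * (gc - stats::median(gc))) *
    exp(stats::rnorm(n, 0, noise_sd))
  half <- ceiling(n / 2)
  rc_profile(data.frame(chrom = rep(c("chr1", "chr2"),
                                    c(half, n - half)),
                        start = c(seq_len(half), seq_len(n - half)),
                        end = c(seq_len(half), seq_len(n - half)),
                        gc = gc, value = v),
             window_size = 1)
}

# flat noise + one adjacent CNA block + scattered outliers
block_outlier_values <- function(seed, n = 2026, block_at = 1001,
                                 block_len = 20, n_out = 6) {
  set.seed(seed)
  v <- stats::rnorm(n, 1, 0.05)
  block <- block_at:(block_at + block_len - 1)
  v[block] <- stats::rnorm(block_len, 3, 0.05)
  forbidden <- c(block, block - 1, block + 1)
  out <- sample(setdiff(seq_len(n), forbidden), n_out)
  v[out] <- stats::rnorm(n_out, 6, 0.05)
  list(values = v, block = block, outliers = out)
}

# exhaustive minimum of squared-error + penalty * segments over all
# breakpoint placements (oracle for the pruned dynamic program)
exhaustive_segment_cost <- function(y, penalty) {
  n <- length(y)
  sse <- function(z) sum((z - mean(z))^2)
  best <- Inf
  for (m in 0:(2^(n - 1) - 1)) {
    bp <- which(bitwAnd(m, bitwShiftL(1L, 0:(n - 2))) != 0L)
    starts <- c(1L, bp + 1L)
    ends <- c(bp, n)
    cost <- sum(vapply(seq_along(starts), function(k) {
      sse(y[starts[k]:ends[k]])
    }, numeric(1))) + penalty * length(starts)
    if (cost < best) best <- cost
  }
  best
}

pelt_total_cost <- function(y, penalty) {
  prof <- rc_profile(data.frame(chrom = "c", start = seq_along(y),
                                end = seq_along(y), value = y), 1)
  s <- segment_profile(prof, penalty = penalty)
  cost <- 0
  for (k in seq_len(nrow(s))) {
    z <- y[s$start_win[k]:s$end_win[k]]
    cost <- cost + sum((z - mean(z))^2)
  }
  cost + penalty * nrow(s)
}

quick_profile <- function(values, chrom = NULL, gc = NULL) {
  n <- length(values)
  if (is.null(chrom)) chrom <- rep("chr1", n)
  df <- data.frame(chrom = chrom, start = stats::ave(seq_len(n), chrom,
                                                     FUN = seq_along),
                   end = stats::ave(seq_len(n), chrom, FUN = seq_along),
                   value = values)
  if (!is.null(gc)) df$gc <- gc
  rc_profile(df, window_size = 1)
}
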