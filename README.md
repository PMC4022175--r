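# cnaprep

Windowed read-count preprocessing, GC-bias correction and copy-number
calling for tumour high-throughput sequencing data.

## The problem

Somatic copy-number alterations (CNAs) are detected from sequencing
read depth: reads are counted in fixed-width genomic windows, giving a
read-count (RC) profile that is a proxy for copy number. Two
preprocessing issues dominate the quality of the final calls:

* **False-positive windows.** Structural polymorphisms, poorly mappable
  sequence, germline copy-number variants (CNVs) and isolated technical
  outliers all masquerade as CNAs. `cnaprep` applies five independent
  window filters: maximum improper-read proportion (paired-end flags),
  minimum mean mapping quality of proper reads (instead of discarding
  low-quality reads, which lowers the signal-to-noise ratio), automatic
  trimming of extreme values, common-CNV overlap and minimum
  mappability. Trimming is GC-aware (values are pre-corrected against
  GC so windows that are extreme only because of extreme GC survive)
  and CNA-aware: a Wald–Wolfowitz runs-test scan distinguishes adjacent
  CNA blocks from scattered outliers, so real alterations are not
  trimmed away on unpaired tumour profiles.

* **GC bias under GC–copy-number correlation.** Read counts depend
  non-linearly on window GC content, classically corrected with one
  local regression (LOESS) of count on GC. In cancer genomes, copy
  number is often itself correlated with GC content, and the pooled
  regression then absorbs copy-number signal into the GC curve,
  under- or over-correcting. The two-pass estimator here (`seqnorm`)
  first applies the single-pass correction, segments the result into
  constant-copy-number pieces, screens the segments (enough windows,
  low value variability, enough GC spread), centers each selected
  segment's *raw* values by its median — removing the copy-number
  differences and with them the correlation — then fits one local
  regression per segment and takes their aligned pointwise median as
  the genome-wide GC effect:

  effect(gc) = median over selected segments s of f̂ₛ(gc),
  f̂ₛ fitted on RCᵢ / median(RC in s) for windows i in s.

The normalized profile is segmented by exact penalized least-squares
changepoint detection (squared error + λ·#segments, λ = 3σ̂²·log n with
σ̂ the derivative-based robust noise), and integer copy numbers are
assigned from explicit, analyst-controlled thresholds
(`suggest_thresholds()` offers a starting point by mapping the modal
segment level to a baseline copy number).

A synthetic-data generator produces RC profiles with known truth
(piecewise-constant CN, smooth GC track, exponential GC effect,
negative-binomial noise, isolated outliers, and a *tunable Spearman
correlation between GC and CN*) plus toy SAM files, so the whole
pipeline is testable without external data.

## Worked example

```r
library(cnaprep)

# simulate a tumour profile: 10,000 windows, GC-CN Spearman 0.6
sim <- simulate_profile(10000, gc_cn_correlation = 0.6,
                        mean_count = 300, seed = 3)

# filter, normalize both ways, compare SNR
f  <- apply_filters(sim$profile, trim = TRUE)
sp <- single_pass_correct(f$profile)
sn <- seqnorm(f$profile)
c(single_pass = profile_snr(sp)$snr, seqnorm = profile_snr(sn)$snr)
#> single_pass     seqnorm
#>    8.440361   10.547630

# segment and call (the analyst assigns the modal level a copy number;
# here the truth says the modal state is 5 copies)
segs  <- segment_profile(sn)
thr   <- suggest_thresholds(segs, baseline_cn = 5)
calls <- call_copy_number(segs, thr)
table(called = window_calls(f$profile, calls), truth = sim$truth$cn)
#>       truth
#> called    2    4    5
#>      2 1486    0    0
#>      4    0 2407    1
#>      5    0    0 6105
#>      6    1    0    0
```

The SNR (median signal over derivative-based robust noise) rises from
8.4 to 10.5 because the single-pass curve is tilted by the GC–CN
correlation while the two-pass curve is not; the confusion table shows
the planted copy numbers recovered essentially perfectly (2 of 10,000
windows miscalled, both at single outlier windows).

The same workflow runs from the command line via `inst/scripts/cnaprep`
(`summarize`, `filter`, `normalize`, `segment`, `call`, `simulate`,
`run --config FILE`), reading SAM alignments, tab-delimited annotation
and BED CNV tracks, and writing profile TSV, SEG and JSON reports.

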