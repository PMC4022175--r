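---
title: "cnaprep: methods, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cnaprep: methods, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of its models and the
decisions behind them: what each stage assumes, which parameters
matter, what the synthetic generator does and does not emulate, and
where the design was genuinely open.

# The model

Read depth is treated as a proxy for copy number: the count of reads
whose leftmost position falls in window $i$ is modelled as

$$ RC_i \;\approx\; \frac{m}{2}\, c_i \, f(gc_i)\, \varepsilon_i $$

with $c_i$ the (unknown) integer copy number, $m$ the expected count at
two copies, $f$ a smooth positive GC-effect curve, and $\varepsilon_i$
multiplicative noise. Everything downstream — filtering, the two
GC-correction routes, segmentation, calling — operates on this
per-window working value.

# Summarization

Reads are classified from SAM flags only: unmapped, secondary,
supplementary and duplicate records are discarded (counting them would
double-count fragments); paired records are *proper* iff the
properly-paired bit is set, otherwise *improper*; single-end mapped
reads are proper. Mapping quality never removes a read — discarding
low-quality reads demonstrably lowers the profile's signal-to-noise
ratio, so quality is handled at the window level instead (mean MAPQ
filter). Each retained read contributes to exactly one window by its
1-based leftmost position, making the count independent of input order.
The default window size is 200 kb; the paper trail behind this package
leaves window size to the user, and 200 kb keeps human-genome profiles
near $1.5\times10^4$ windows — large enough for quantile-based
trimming, small enough for interactive work.

# The five window filters

All filters are independent boolean masks; the combined mask is their
union, so application order is irrelevant. Suggested starting
thresholds (improper proportion 0.5, mean MAPQ 30) are documented but
never silently applied; CNV overlap defaults to "any overlap masks".

**Automatic trimming** is the interesting one. Raw extremes may be real
CNAs (adjacent windows) or technical outliers (scattered windows). The
trim scan walks candidate thresholds from the extreme tail inward
(quantiles 0.9999 down to 0.95, 200 steps — resolving single-window
changes on $10^4$-window genomes), and at each candidate computes the
Wald–Wolfowitz runs statistic of the exceedance indicator in genome
order:

$$ z = \frac{R - \mu_R}{\sigma_R}, \quad
   \mu_R = \frac{2 n_1 n_0}{n} + 1 . $$

Scattered outliers exceed candidates at random positions ($|z|$
small); when the candidate drops into the level of an adjacent block,
runs collapse and $|z|$ jumps. The threshold is the candidate
preceding the **first** step whose $|z|$ increase reaches the jump
floor of 2 (about two standard errors). We deliberately use the first
sudden change, not the globally largest one: a noisy block's windows
enter the scan one at a time, and the largest step tends to occur
mid-block, which would trim up to half of a real CNA. In the
pure-outlier regime (no jump anywhere) the innermost quantile is
returned, bounding the masked fraction at roughly 5% per tail. With
fewer than 5 windows ever exceeding the most extreme candidate, that
candidate is returned — there is nothing to trim beyond it.

Before the scan, values are corrected by a single-pass GC regression so
that windows extreme *only because of extreme GC* are not trimmed; if
GC is missing on more than half the genome this pre-correction is
refused with a loud warning rather than silently skipped. Windows
masked by the other filters are excluded from threshold estimation
(mapping artifacts would corrupt the z-trace) but the thresholds are
then applied to every window. Both tails are scanned (the lower tail by
negating values); one open question in the source material is whether
trimming is one- or two-sided, and we chose two-sided because losses
are as real as gains. With a matched normal, thresholds are estimated
on the normal's corrected values and windows extreme *in the normal*
are masked — this is what prevents tumour CNAs from trimming
themselves away, and it is why a normal is preferable for this filter.

Two structural caveats a user should know. First, even at the correct
threshold the top few windows of a genuine CNA block are masked: block
windows enter the scan in random value order, and adjacency only
becomes statistically visible after 2–5 of them are in, so "the block
is retained" means the block minus a handful of its most extreme
windows (masked windows are bridged at segmentation and inherit the
segment's call). Second, when the lowest copy-number state spans more
than ~5% of the genome, the lower-tail scan sees adjacency from its
first candidate onward, detects no *change*, and falls to the
innermost quantile — masking the bottom 5% of windows, all inside that
state. Both behaviours are inherent to a genome-wide two-sided scan and
are visible in the filter report's z-traces.

# GC correction

**Single pass** (`single_pass_correct`): one loess of $\log RC$ on GC
(span 0.3, degree 2, symmetric family for robustness to outliers),
evaluated on a fixed GC grid (0.20–0.70, step 0.005), exponentiated,
normalized to 1 at the median GC, applied by division. Log scale and a
multiplicative effect were chosen because counts are non-negative and
the GC effect is proportional, not additive. Outside the observed GC
range the curve carries the nearest estimated value with zero support
— never an extrapolated oscillation. If loess cannot support the
requested span, the span is widened stepwise with a warning.

**Why a second pass.** When copy number correlates with GC (amplified
regions sitting on GC-rich sequence, say), the pooled regression
absorbs copy-number signal: the fitted curve is tilted, and the
correction compresses real CNA contrast while adding noise wherever
neighbouring windows differ in GC. `seqnorm` therefore:

1. applies the single-pass correction (it removes *most* of the bias);
2. segments the corrected profile into constant-level pieces;
3. screens segments: at least 20 windows (robust fits), value MAD at or
   below the 75% quantile of all segments (high-variability segments fit
   poorly), GC standard deviation at or above the 25% quantile (a
   segment with no GC spread cannot constrain the curve). Ties are
   kept; if fewer than 3 segments survive, the two quantile cuts are
   relaxed in 0.05 steps, and if that fails the function falls back to
   the single-pass result with a warning — never silently;
4. divides each selected segment's **raw** values by the segment's
   median raw value. Centering removes the count differences due to
   copy number — and with them the GC–CN correlation. The median, not
   the mean, so residual outliers cannot shift a segment. Raw values
   are re-centered rather than reusing first-pass residuals, so a
   biased first pass cannot compound into the final estimate;
5. fits one loess per selected segment on its centered values,
   evaluated on the common grid restricted to the segment's observed
   GC range;
6. takes the pointwise median across segments at grid points supported
   by at least two segments (nearest supported value elsewhere).
   Because each segment's centering pins its curve near its own median
   GC, the per-segment curves differ by constant log offsets; before
   the median we align them by three iterations of
   offset-toward-the-provisional-median in log space. This alignment
   is exactly a no-op when segments share a GC range (the noiseless
   recovery tests run through it unchanged) and removes an otherwise
   systematic distortion when, under correlation, amplified segments
   occupy a shifted GC range;
7. corrects the raw values by the final curve and rescales so the
   output median equals the input median (whether to rescale to 1 or
   to the input median was open; preserving the input median keeps raw
   and corrected profiles directly comparable, and the scale is
   irrelevant to the threshold-based caller, which adapts via the
   suggested step).

The supplementary material behind the original method does not print
its segment-selection cutoffs, aggregation rule or bandwidth; the
quantile-based screen, the support-2 median and span 0.3 are this
package's documented concretizations.

**Paired normalization** divides tumour by normal (ratio mode,
pseudocount 0.5 on zero-count normal windows, flagged) or runs the
same two-pass machinery with the normal's value replacing GC as the
covariate, on a quantile grid over the normal's values.

**SNR.** Profile quality is summarized as median signal over a
derivative-based robust noise,
$\mathrm{median}(|v_{i+1}-v_i|)/(0.6745\sqrt{2})$, within chromosomes
and over unmasked windows only. The estimator ignores piecewise level
structure (breakpoints contribute $O(\#segments/n)$ terms to a
median), is consistent for $\sigma$ under i.i.d. noise, and is scale
invariant. The original work cites an external reference for its SNR;
this definition is ours and is isolated in one function
(`profile_snr`) so it can be swapped.

# Segmentation and calling

Segmentation minimizes within-segment squared error plus
$\lambda\cdot\#\mathrm{segments}$ per chromosome, solved exactly by
pruned dynamic programming (PELT-style pruning keeps it effectively
linear; the exactness is tested against exhaustive search). The
default penalty $\lambda = 3\hat\sigma^2\log n$ uses the derivative
noise estimate, in the spirit of BIC inflated threefold to resist
overdispersion. This is a documented substitution for the model-based
segmenter used by the original pipeline: all downstream steps need
only *maximal neighbourhoods of constant level*, which any consistent
least-squares segmenter provides, and the segmenter sits behind
`segment_profile()` so alternatives can be plugged in. Masked windows
are excluded from the fit and bridged — a segment may span the gap,
and bridged windows inherit its call.

Calling is threshold-driven and explicit: a segment with level in
$[t_k, t_{k+1})$ gets copy number $k$ (left-inclusive). Automation is
deliberately limited to a suggestion: `suggest_thresholds()` clusters
segment levels (5% relative tolerance), takes the heaviest cluster as
the mode, maps it to a user-stated baseline copy number, and places
boundaries at odd multiples of half the implied per-copy step. With a
single segment, or two top clusters of practically identical weight
(within 2%), it declines — copy-number calling legitimately remains
the analyst's judgment.

# The synthetic generator

`simulate_profile` emulates the structure the pipeline must survive:

* **GC track**: AR(1) backbone ($\rho = 0.7$, marginal sd 0.04) plus
  window-scale jitter (sd 0.015), mean 0.45, clamped to $[0.25,
  0.68]$ — realistic marginal spread and window-to-window variation
  for 200 kb windows of a mammalian genome.
* **Copy number**: piecewise constant, default 6 segments with copy
  numbers in 1–5 (diploid state always present), each at least 5% of
  the genome.
* **GC–CN correlation** (the confounding seqnorm targets): GC values
  are re-allocated between segments by blending the CN rank with
  uniform noise, with the blend weight bisected until the requested
  Spearman correlation is met within ±0.05. The GC *marginal* is
  preserved exactly, and the original within-segment ordering is
  restored afterwards (copy number is constant within a segment, so
  this cannot change the correlation) — the correlation is isolated
  from every other property of the track.
* **Counts**: negative binomial with mean
  $(m/2)\,c_i\,e^{\beta gc_i}/\overline{e^{\beta gc}}$ and variance
  $\mu + d\mu^2$. Defaults $m = 300$, $\beta = 4$, $d = 0.01$: a
  high-coverage regime (the two-pass correction is most valuable at
  high SNR), a curve spanning roughly a 3-fold effect across the GC
  range, and mild overdispersion as seen in real non-tumoural
  read-count variability. $d = 0$ is defined as the exact noiseless
  limit (counts equal their means); the Poisson limit is approached as
  $d \to 0^+$.
* **Outliers**: isolated (never adjacent) windows at rate 0.005,
  counts multiplied by $U(3, 8)$.

What the generator does **not** emulate: real mappability structure,
reference artifacts, subclonal mixtures, allele-specific signal,
wave artifacts, or the empirical noise of any particular instrument. A
green test therefore establishes that the algorithms do what they claim
under the stated generative model — not that any biological claim holds
on a given real dataset.

`simulate_sam` writes toy SAM files (flag 99 proper / flag 97 improper,
placeholder bases) whose round trip through `summarize_sam` recovers
the planted per-window composition exactly; it exercises the
flag-based classifier, not aligner realism.

# Numerical choices and degenerate inputs

* Trimming requires at least 200 finite values; the runs statistic is
  degenerate (flagged, not an error) on one-class sequences.
* A constant profile has infinite SNR — returned as `Inf` with a
  `constant` flag, not an exception.
* Noiseless profiles would give a zero segmentation penalty; the noise
  estimate is floored at a tiny scale-relative value so exact ties
  resolve toward fewer segments.
* Zero-read windows are masked by the MAPQ filter (no evidence of
  mappable sequence), not by trimming — this keeps the tail scan
  well-defined.
* Windows with missing GC pass through corrections unchanged and are
  logged; missing annotation yields `NA`, never a silent zero.
* All randomness flows from a single seed; per-chromosome work is
  merged in grid order, so outputs are identical for any worker count.

# Known limitations

* The trimming caveats above (top-of-block masking; lower-tail
  masking when the lowest CN state is large and adjacent).
* Global trim thresholds cannot catch outliers that are extreme only
  relative to their local copy-number level.
* `seqnorm` needs at least 3 usable segments and honest GC spread
  within them; profiles without that structure fall back (with a
  warning) to the single-pass estimate.
* Calling assumes levels proportional to copy number after correction;
  heavy subclonality or ploidy shifts compress the step and are out of
  scope.
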