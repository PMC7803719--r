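---
title: "Testing temporal additivity of BOLD responses across cortical depth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing temporal additivity of BOLD responses across cortical depth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(laminarity)
```

## The scientific question

Nearly every model-based analysis of fMRI treats the BOLD response as the
output of a linear time-invariant system: the response to a long stimulus
should equal the sum of time-shifted responses to shorter stimuli (temporal
additivity). At sub-millimeter ("laminar") resolution this assumption is not
obviously safe, because the signal at a given cortical depth is not
independent of other depths: venous blood drains from the gray/white border
toward the pial surface, so superficial depths inherit hemodynamic signal
from deeper ones. `laminarity` implements a complete pipeline to test
whether temporal additivity holds *equally well at every cortical depth*,
together with a forward simulator in which the ground truth is known.

## The forward model

The simulator composes four stages, each available as a public function:

1. **Neuronal drive** (`neuronal_drive`): each stimulus block is a sustained
   boxcar, 1 during stimulation and 0 otherwise, on a 1.3 s grid. Finer
   within-block structure (sub-second stimulus refreshes) is deliberately not
   modeled: it lies below the sampling grid and is invisible to the
   additivity statistic.
2. **Local hemodynamic response** (`local_response`): the drive is convolved
   with a canonical double-gamma HRF (difference of two gamma densities,
   response lobe shape 6, undershoot lobe shape 16, peak:undershoot ratio
   6, unit rate), normalized to unit integral so that a sustained stimulus
   plateaus at the depth's `local_amplitude` in percent BOLD. All HRF
   parameters are exposed in `hrf_params`; the additivity statistic itself is
   HRF-agnostic, so the exact shape is a free choice.
3. **Draining mixture** (`apply_draining`): the measured response is the
   local response plus a weighted sum of measured responses at deeper
   depths,
   `H[i, ] = L[i, ] + (1/n_depths) * sum_{j<i} w[j] * H[j, ]`.
   The continuous model underlying this is an integral from the gray/white
   border up to the current depth; we discretize it deep-to-superficial with
   the weight indexed by the **source** depth (the depth being drained
   *from*). The destination-indexed reading is equally compatible with the
   continuous form; source indexing was chosen because the weight is meant
   to describe how much deoxyhemoglobin a depth passes upward, which is a
   property of the source compartment.
4. **Noise and rendering** (`add_noise`, `render_voxels`): polynomial drift
   plus AR(1) Gaussian noise around a raw baseline of 100 (so percent and
   raw units coincide), sampled at the volume TR. Voxels inherit their depth
   bin's series with independent noise; their normalized depths are drawn
   uniformly inside the bin's interval.

`simulate_depth_series` handles one deliberate model subtlety: when
per-duration draining weights are configured (`drain_weights_alt`), the
drive is split by stimulus duration and each class is drained separately
before summation. With equal weights this reduces *exactly* to the
single-pass model, which is itself a regression test of the recursion's
linearity.

### What the default study emulates

The defaults reproduce the acquisition geometry of a block-design laminar
7T experiment: 8 runs of 102 volumes at TR 2.6 s (4 min 25.2 s per run);
12 stimulus blocks per run, four each of 2.6/5.2/10.4 s in seeded
counterbalanced order; each run opening with a rest block; rest periods on
the 1.3 s grid averaging ~14.6 s against a nominal 15.6 s; and a +1.3 s
onset jitter on half the blocks, assigned pseudo-randomly per run. One
arithmetic constraint is worth stating: thirteen rest periods of exactly
15.6 s plus 72.8 s of stimulation would need 275.6 s, more than the
265.2 s run, so exactly-equal rests cannot fit — the scheduler instead
spreads the available rest budget near-equally on the grid, reserving a
full post-stimulus window (plus the jitter and one resampling step) after
the final block so every epoch fits on the acquired sample grid.

Response amplitudes rise toward the cortical surface both through the
`local_amplitude` profile (default 1 to 1.4 %BOLD) and through draining
(default weights 1 at every depth, roughly doubling the superficial
amplitude at 5 depths); long-stimulus peaks then span ~1.1–3 %BOLD from
deep to superficial, matching the range reported for visual cortex at 7T.

### The noise model, and why it scales with depth

Per-voxel noise defaults to sigma = 4 %BOLD with lag-1 autocorrelation 0.3
and a quartic drift — a temporal SNR of ~25, typical for sub-millimeter
gradient-echo EPI. By default (`noise_amp_scale = TRUE`) the noise sd of a
voxel additionally follows its depth's response-amplitude profile. This
emulates physiological noise, which grows with signal strength and
dominates at high field. The alternative — constant noise with
depth-rising amplitude — produces a depth-rising SNR, and the
cross-validated correlation then rises with depth *even when additivity
holds perfectly*; on default-sized simulations that SNR gradient alone
drives the horizontality test to "violated" essentially always. This is a
real property of the correlation statistic, not a bug, and it is exactly
why the analysis reports the split-half noise ceiling next to every
correlation. For battery-style simulations at the depth-bin level the
noise sd of 0.4 %BOLD (AR(1) 0.3) was chosen so that the simulated noise
ceiling spans r = 0.90–0.99, bracketing the ceiling range published for
this kind of data.

## The analysis chain

**Conditioning** (`condition_run`) applies, per run and per voxel, in a
fixed non-configurable order: despiking, percent-signal scaling
(`100·x/mean(x) − 100`, exact zero mean), polynomial detrending (default
degree 4), and linear temporal resampling from the 2.6 s TR to 1.3 s —
the resampled grid starts at 0, keeps shared grid points exactly, and ends
at the last acquired sample. Despiking flags samples whose residual from a
running-median (k = 5) baseline exceeds `z_thresh` (default 5) noise
units, with the noise scale estimated as `mad(diff(x))/sqrt(2)`. Two
numerical details matter here: a least-squares polynomial fit is *not*
used for spike detection because a large spike leverages the fit enough to
hide itself on short series; and the residual's own MAD is not used as the
scale because a running median passes through a large fraction of the
samples, collapsing the MAD and roughly doubling the z-scores on white
noise. When the scale is zero (constant background) any nonzero residual
counts as a spike, which makes behavior on degenerate inputs predictable.

**Depth sampling** (`depth_quantile_bins`, `roi_depth_timecourse`) bins
in-mask voxels into `n_bins` (default 5) equal-count quantile bins of
normalized depth, separately per ROI (so edges differ between ROIs), with
boundary ties going to the deeper bin; hemispheres are not distinguished.
Bin time courses are unweighted voxel means, reported with per-bin voxel
counts and mean normalized depth — the depth regressor used later is this
mean depth, not the bin index.

**Epoching** (`extract_blocks`, `average_blocks`) cuts onset-locked
windows of stimulus duration plus a 15.6 s post-stimulus baseline
(14/16/20 samples at 1.3 s for the three default durations). Onsets land
on the grid exactly because the jitter equals the resampled step. No
per-block baseline re-zeroing is applied: the series are already zero-mean
per run, and re-zeroing would break the additivity algebra. Averages carry
a Student-t 95% confidence interval across trials (`t(0.975, n−1)·sd/√n`
per sample); the same t-interval is used across subjects at the group
level. The opening rest block serves only as pre-stimulus buffer.

**Additivity test** (`shift_sum_predict`, `crossval_correlation`,
`noise_ceiling`): a predicted long response is the sum of
`k = target/source` copies of the mean short response, each shifted by a
multiple of the source duration, with the short window zero-padded on the
right (assumed returned to baseline beyond its window). Predictions are
built from the mean response of 4 training runs and scored by Pearson
correlation, over the full target window, against the mean observed
response of the 4 held-out runs; all 70 ordered 4+4 partitions of the 8
runs are used and the median per-split r is the summary, computed
separately per (ROI, bin, condition). The noise ceiling is the same
split-half machinery applied to the observed target response on both
sides. Splits with a zero-variance vector are excluded with a warning.
Because Pearson correlation is scale-invariant, this statistic tests the
*shape* of the response, not its amplitude — a deliberate property shared
with the original formulation, and the reason purely multiplicative
violations (e.g. per-duration draining weights in this model, where every
depth shares one temporal shape per duration) are invisible to it. An
amplitude-sensitive test is intentionally out of scope.

**Depth trend** (`fit_depth_trend`, `test_horizontal`): per ROI, ordinary
least squares of the correlations on mean normalized depth, pooling
conditions (and subjects when present), with two-sided t-tests of slope
and intercept at n − 2 df. The verdict is `consistent-with-additivity`
when the slope's p-value is at least alpha (default 0.05); the intercept
test describes overall fit quality and never enters the verdict. No
multiple-testing correction is applied across ROIs, matching how such
per-ROI tests are conventionally reported. When the residual sd falls
below 1e-6 the fit is declared numerically exact and p is 1 or 0 by
whether the coefficient is below 1e-6 in magnitude — correlations are
order-1 quantities, so sub-1e-6 structure is floating-point noise, and
without this rule a noise-free simulation would hand the t-test a 0/0.

## Fixtures used by the test batteries

The linearity oracle demands cross-validated r = 1 to 1e-9 on noise-free
data. That is only achievable when the shift-and-sum algebra is exact,
which requires (a) an HRF whose support fits inside the 15.6 s
post-stimulus window — otherwise the zero-padding truncates a genuine
undershoot tail — and (b) inter-block gaps of at least that window, so no
epoch is contaminated by a neighboring block's response. The oracle
therefore uses an HRF truncated at 15.6 s support and 2 blocks per
duration per run (~35 s gaps), and enters the analysis at the depth-series
level. Percent scaling and detrending are excluded from this path for a
reason worth understanding: removing the run mean leaves every trial with
a constant negative offset, and the shift-and-sum turns a constant offset
into a staircase, a systematic prediction artifact (visible as an
overestimated undershoot and correlations below the ceiling — also visible
in published applications of this method). The artifact scales uniformly
with a depth's amplitude, so it does not tilt the depth profile, but it
would swamp a 1e-9 tolerance.

Violation power is assessed with two injected nonlinearities
(`inject_nonlinearity`): *adaptation* decays the drive within each block
at 0.3 s^-1 (the long block ends at ~6% of its initial drive), producing a
large shape difference between observed and predicted long responses at
every depth; and *saturation* compresses local responses as
`x/(1 + s·x)` with per-depth strengths 0–2 %^-1, producing a depth-graded
shape violation that the horizontality test must catch. The configured
strengths are fixture parameters chosen to represent a clearly nonlinear
regime, not estimates of any empirical effect size. With three simulated
subjects and the amplitude-scaled noise model, the saturation gradient is
flagged in ≥80% of replicates while a matched linear arm stays below a 20%
false-alarm rate; the adaptation battery compares paired noisy replicates
and requires the adapted median r to fall below the linear arm at every
depth.

Problem sizes throughout the test suite (runs, voxels per depth, replicate
counts of 100 for power batteries and 2000 for CI coverage) were chosen as
the smallest sizes at which the Monte-Carlo error is comfortably inside
the asserted tolerances.

## What passing tests do and do not show

The simulator shares the analysis's linear skeleton, so the oracle tests
demonstrate correctness of the implementation, not truth of additivity in
brains. Real laminar data differ in ways the generator deliberately omits:
no spatial point-spread or motion, no distortion or registration error
(depth maps and masks are inputs here), a single HRF shape for all depths,
and noise that is AR(1)+drift rather than structured physiology. The
draining model is a first-order mixture — no vascular biophysics beyond
it. Conclusions from this package about real data rest on the statistic's
behavior (sensitivity, ceiling, SNR confound) characterized under these
controlled conditions.

## Reproducing the headline numbers

`scripts/acceptance.R --seed <s> --out <path>` regenerates every quantity
discussed above from scratch — design counts, epoch window lengths, the
linearity oracle's correlations, ceiling, and trend slope, the adaptation
detection power, the permutation-vs-OLS p-value agreement, and the CI
coverage — and writes them as JSON.
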