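---
title: "Frequency-tagged analysis of auditory statistical learning: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Frequency-tagged analysis of auditory statistical learning: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triplettag)
```

## The paradigm and the measurement model

Six tones are arranged into two hidden triplets and presented as a
continuous stream at a constant stimulus onset asynchrony of 300 ms
(220 ms tone + 80 ms silence). Triplet identities are drawn
independently with probability 0.5 each, so transitional probabilities
are the only segmentation cue: 100% from the first to the second tone
of a triplet, 90% from the second to the third (because 8% of triplets
carry a statistical deviant and 2% a double deviant, both of which
replace the final tone with the other triplet's final tone), and 50%
across triplet boundaries. Tones therefore recur at 3.33 Hz and
triplets at 1.11 Hz.

A brain that merely responds to tones phase-locks at 3.33 Hz; a brain
that has learnt the chunk structure additionally shows phase
consistency at 1.11 Hz. Both are quantified by inter-trial coherence
(ITC): epochs of 5.4 s (six triplets) are Hanning-windowed and Fourier
transformed, and for each frequency the unit-magnitude phasors of the
per-epoch phases are averaged; ITC is the modulus of that average
(0 = random phase, 1 = perfect locking). The 5.4-s epoch length is
load-bearing: it makes the spectral resolution 1/5.4 Hz so that the
triplet rate and the tone rate fall exactly on bins 6 and 18, and no
interpolation is ever needed. The Triplet Learning Index is the ratio

$$\mathrm{TLI} = \frac{\mathrm{ITC}_{1.11\,\mathrm{Hz}}}{\mathrm{ITC}_{3.33\,\mathrm{Hz}}},$$

which normalizes chunk-level tracking by element-level tracking within
subject.

One published description of the estimator is ambiguous: averaging the
*complex* FFT coefficients across epochs before extracting phase yields
a normalized evoked amplitude, not an inter-trial coherence. The
package implements the standard ITC reading by default and exposes the
literal complex-average variant ($|\bar Z| / \overline{|Z|}$) behind
`itc_mode = "complex_average"` so both conventions can be compared.

## Epoch construction

Only standard triplets enter the analysis. Triplets containing any
deviant, triplets immediately following a deviant triplet (within the
same block; blocks are separated by breaks), and triplets containing a
behavioral target are excised from the continuous record
(`select_standard_triplets()`, `excise_and_concatenate()`). Retained
0.9-s spans are concatenated bit-identically in their original order.
To attenuate the splice discontinuities this creates, the stream is
de-meaned per tone in the half-open window [onset, onset + 300 ms)
after mastoid re-referencing. Consecutive groups of six retained
triplets then form non-overlapping epochs; leftovers (< 6) at a block
end are discarded rather than carried across blocks. Any epoch whose
peak-to-peak amplitude exceeds 300 µV is rejected. The stage order is
fixed: select → excise → re-reference → de-mean → epoch → reject.

Two conventions are deliberately configurable because the procedure
does not pin them down: the rejection criterion can be evaluated on the
fronto-central cluster average (the analysis signal; default) or on
every channel (`reject_on = "channels"`), and a triplet following a
dropped *target* triplet is not excluded — the post-exclusion rule
applies only after deviants.

## Preprocessing choices

Bad channels are those whose signal variance, z-scored across channels,
exceeds 3.0 in absolute value; they are replaced by the
inverse-distance weighted mean of their four nearest good channels (a
simplification of spherical-spline interpolation; the interpolation
backend is isolated so it can be swapped). Filtering uses
Kaiser-windowed linear-phase FIR filters — high-pass 0.2 Hz (transition
0.4 Hz) then low-pass 30 Hz (transition 5 Hz), maximum deviation 0.001
— applied in a single pass with exact group-delay compensation, so the
net filter is zero-phase. Zero-phase application matters because the
downstream statistic is a phase statistic; a forward–backward
application was rejected because it squares the magnitude response and
doubles the designed passband deviation. Filter orders are derived from
the Kaiser design formula rather than hard-coded, so they adapt to the
sampling rate. The high-pass is built by spectral inversion of a
unit-DC-gain low-pass, which gives an exact null at 0 Hz. Mastoid
re-referencing subtracts the algebraic mean of M1 and M2 from every
channel; it is not idempotent in the conceptual sense (after one
application the mastoid mean is identically zero).

## The synthetic cohort: what it emulates and what it does not

Real recordings for this paradigm are not publicly deposited, so the
package ships a forward model whose *statistical structure* matches the
phenomenon: every tone evokes a damped ~10 Hz oscillation (~100 ms
decay, ~5 µV at the fronto-central maximum) projected through a
Gaussian scalp gain centered near FCz, with near-zero gain on the
mastoids. Tone-rate phase consistency is degraded by per-tone latency
jitter whose scale is the `tone_lock` parameter (radians at 3.33 Hz).
Sensitivity to the triplet structure is injected as a period-3
modulation of tone responses — never as an added 1.11 Hz sinusoid —
so harmonics at 2.22 and 4.44 Hz arise naturally: triplet-initial
tones evoke an additional slow chunk-onset component (a damped 2.5 Hz
oscillation spanning the 0.9-s triplet) and a small latency advance,
both scaled by `triplet_lock` times the latent learning curve
$g(a\log x + b)$ with $g(u) = \max(u, 0)$, evaluated at the number of
triplets presented so far. The chunk-onset kernel is orthogonalized to
3.33 Hz over the triplet period, so injecting triplet-rate coherence
does not move the tone-rate denominator of the TLI; without this the
injection both leaks into the tone bin and is largely removed by the
per-tone de-meaning, and the TLI responds in the wrong direction.
Background noise is 1/f (exponent 1) at 10 µV RMS per channel —
comparable to band-limited resting EEG against a ~5 µV evoked response
— and artifacts are 0.5-s high-amplitude transients at Poisson times
with a fronto-centrally weighted topography, so they survive mastoid
re-referencing and are caught by the 300 µV rule, as real movement
artifacts would be.

Cohorts (`simulate_cohort()`) draw a standardized latent triplet
sensitivity per subject: the group means differ by `d` (default 0.64,
control > dyslexia), `triplet_lock` and the learning slope inherit the
latent ordering, the control group receives extra tone-rate jitter
(`tone_lock_diff`) so its tone-rate ITC is *lower* — the direction the
group difference takes in this paradigm — and spelling scores satisfy
$z_{\mathrm{spell}} = \rho\,\tilde T + \sqrt{1-\rho^2}\,\varepsilon$
with $\rho = 0.35$ against the standardized latent sensitivity, with
reading scores uncorrelated by default.

What the model does *not* emulate: volume conduction from a realistic
head model, ocular or muscular artifact topographies (independent
component analysis is outside the package's scope; artifact handling
relies on the peak-to-peak rule plus channel repair), line noise, and
any nonstationarity beyond the logarithmic learning trend. Passing
tests therefore demonstrate that the *analysis* is correct and
well-calibrated, not that the forward model reproduces every property
of real EEG.

## Learning curves and group inference

The time-resolved TLI slides a window of 30 consecutive epochs (162 s)
in steps of one epoch across the first block. The learning coordinate
`x` is, by default, counted in retained standard triplets (six per
epoch, at the window's last epoch) — the quantity the analyzed data
actually contains; `x_convention = "presented"` switches to the
experiment-level index including excluded triplets. Windows shorter
than 30 epochs at the block tail are dropped, not shrunk. The
logarithmic fit `y = a*log(x) + b` uses the natural logarithm (the
base only rescales `a`) and ordinary least squares; both per-subject
and group-mean fitting are possible since the fit accepts any curve.

Group comparisons use pooled-variance t-tests (degrees of freedom
$n_1 + n_2 - 2$, consistent with the reported df in this literature),
one-sided for the directional TLI hypothesis (control > dyslexia),
two-sided for raw ITC at a bin. Cohen's d uses the pooled SD with n−1
denominators, and z-standardization likewise. TLI time courses are
compared with a cluster-based permutation test: pointwise pooled t
per timepoint; runs of at least two adjacent points with pointwise
p < 0.05 and a common sign form clusters scored by their summed t; the
null is the maximum absolute cluster sum over 1,000 random relabelings
(zero when a relabeling yields no cluster), and each cluster's p-value
is `(1 + #{null >= |sum|}) / (n_perm + 1)` so p can never be zero.
Collecting clusters of both signs makes the family-wise control
two-sided; the directional group hypothesis is applied at reporting.
For small designs an exhaustive mode enumerates all
$\binom{n}{n_1}$ relabelings and returns exact p-values. Note that with
`alpha = 1` the statistic degenerates to the maximum absolute
*sign-run* sum, not the maximum |t| — a consequence of the
run-merging convention.

Peak-vs-control-bin contrasts subtract the mean ITC at ±2 bins from the
peak bin; at 5.4-s epochs the tone-rate controls are 2.96 and 3.70 Hz.
For the triplet rate the same rule gives 0.74 and 1.48 Hz; a published
control-bin value of 0.75 Hz cannot be produced from this grid, so the
±2-bin rule is applied uniformly and the discrepancy is noted rather
than silently adjusted. Brain–behavior correlations are Pearson
correlations of the per-subject mean TLI with each z-standardized
score, tested one-sided for positivity via
$t = r\sqrt{(n-2)/(1-r^2)}$, and reported uncorrected for the three
comparisons.

## Numerical conventions and degenerate inputs

- Event onsets are rounded to the nearest sample; the sampling rate
  must place the 300-ms SOA on an integer number of samples (multiples
  of 10/3 Hz: 500 Hz as acquired, 150 or 250 Hz for fast simulation),
  otherwise tone windows cannot tile epochs exactly and the target
  rates leave the FFT grid.
- Exact-count deviant assignment (rounding `p * triplets_per_block`)
  makes the 8%/90% design figures deterministic in every block; a spec
  that cannot be partitioned after rounding is rejected.
- ITC requires at least two epochs per contributing block; blocks below
  that are skipped, and an error is raised only when no block
  qualifies. A zero tone-rate ITC makes the TLI undefined and raises an
  error rather than emitting infinity.
- A degenerate peak-vs-neighbor sample with all contrasts equal to zero
  reports t = 0, p = 0.5; constant time courses make the cluster test
  error out rather than divide by zero.
- All randomness is seeded and every simulated object regenerates
  bit-identically from its seed; the pipeline derives stage seeds from
  one master seed, so identical configurations give identical reports.

## Problem sizes used in the shipped checks

The package's own test battery runs entirely on simulated data, sized
for a single desktop core: miniature cohorts of 8 + 8 subjects with one
or two blocks of 80–120 triplets at 150 Hz for end-to-end runs;
10,000-replicate Monte-Carlo oracles for the Rayleigh null
($E[\mathrm{ITC}] = \sqrt{\pi}/(2\sqrt{N})$ under uniform phases);
exhaustive enumeration of all 70 relabelings for the 4 + 4 cluster-test
oracle; 1,000 null cohorts for the type-I error of the one-sided group
test and 200 replicates for the family-wise error of the cluster test;
and 200 cohorts at the study's group sizes (19 + 17) for recovery of
the standardized group difference (0.64) and the TLI–spelling
correlation (0.35). Statistical-property checks at these scales
calibrate error rates to within about ±2 percentage points.

## Known limitations

The forward model's absolute ITC values depend on its invented kernel
and noise parameters; only standardized effects (d, correlation) are
calibrated, so raw ITC magnitudes should not be compared against
empirical recordings. Counterbalancing is implemented as six enumerated
tone-rotation schemes, a minimal stand-in for full cross-participant
counterbalancing. Spherical-spline channel interpolation is simplified
to inverse-distance weighting. The package deliberately omits ICA-based
artifact decomposition, audio rendering of the stimuli, and
event-related potential analyses of the deviants.
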