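---
title: "Phase-lag connectivity and Lempel-Ziv complexity for multichannel EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase-lag connectivity and Lempel-Ziv complexity for multichannel EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegpli)
```

## The problem

General anesthesia is expected to weaken three electrophysiological
signatures of the conscious brain: feedback-dominant (anterior-to-posterior)
directed connectivity in the alpha band (8–13 Hz), anterior network hubs,
and rich spatiotemporal signal complexity.  In patients with severely
injured brains these markers can move the *opposite* way under anesthetic
exposure.  This package provides the full estimation chain needed to ask
that question of a baseline/anesthesia recording pair — surrogate-corrected
weighted and directed phase lag indices, node-degree hub topography,
frontoparietal feedback summaries, and three Lempel-Ziv complexity
estimators — together with a synthetic-EEG generator whose recordings have
*known* directed-lag structure and compressibility, so every stage can be
validated against ground truth.

## Estimators

### Weighted phase lag index (wPLI)

For channels $i, j$ the per-sample cross-spectrum is formed from the
analytic (Hilbert) signals, $C_{ij}(t) = a_i(t)\,\overline{a_j(t)}$, and

$$\mathrm{wPLI}_{ij} \;=\;
\frac{\bigl|E\{\Im(C_{ij})\}\bigr|}{E\{|\Im(C_{ij})|\}},$$

with the expectation taken over the samples of one 10-s window.  Weighting
by the magnitude of the imaginary cross-spectrum makes the index blind to
zero-lag (volume-conducted) coupling: for channels that are scalar
multiples of one common source, $\Im(C_{ij})$ is identically zero.
Numerically we declare a pair lag-free when $E\{|\Im C|\}$ falls below
$10^{-4} \times E\{|C|\}$; the imaginary part of a genuinely interacting
pair sits orders of magnitude above this, while exact zero-lag copies sit
orders of magnitude below it regardless of jitter amplitude (the ratio is
scale-free, so an absolute threshold would not work).

### Directed phase lag index (dPLI)

$$\mathrm{dPLI}_{ij} \;=\; \frac{1}{N}\sum_{t=1}^{N}
H\!\bigl(\Delta\phi_{ij}(t)\bigr), \qquad
\Delta\phi_{ij} = \phi_i - \phi_j \in (-\pi, \pi],$$

with $H(x>0)=1$, $H(0)=\tfrac12$, $H(x<0)=0$.  Values above 0.5 mean
channel $i$ phase-leads channel $j$.  Because
$\operatorname{sign}(\sin\Delta\phi_{ij}) = \operatorname{sign}(\Im
C_{ij})$, both indices are computed from the same imaginary cross-spectrum
samples.  The half-weight tie convention keeps the diagonal at 0.5 and, with
the matrix filled on the upper triangle and mirrored as
$\mathrm{dPLI}_{ji} = 1 - \mathrm{dPLI}_{ij}$, the antisymmetry
$\mathrm{dPLI}_{ij} + \mathrm{dPLI}_{ji} = 1$ holds exactly on every window
and every input.

### Surrogate correction

Spurious connectivity is controlled per pair and per window by 20
surrogates that keep channel $i$ and scramble channel $j$.  The default
scrambling is a circular shift by a uniform random offset of at least 1 s:
it preserves the channel's spectrum and autocorrelation exactly while
destroying its phase relation to channel $i$.  (A sample-shuffle
alternative is available; it whitens the surrogate, which makes the test
anticonservative for autocorrelated signals, so the shift is the default.)
Observed values are first bias-corrected by the surrogate mean —
$\mathrm{wPLI}' = \max(0, \mathrm{wPLI} - \bar s)$, and
$\mathrm{dPLI}' = 0.5 + (\mathrm{dPLI} - \bar s)$, a recentering that
preserves antisymmetry — and retained only when the rank-based empirical
p-value is at or below $\alpha = 0.05$ (one-sided upper for wPLI,
two-sided on $|\mathrm{dPLI}-0.5|$ for dPLI; one-sided is available by
flag).  With 20 surrogates the smallest attainable p is $1/21 \approx
0.048$, so a value must exceed every surrogate to survive.  Non-significant
connections are set to 0 (wPLI) and 0.5 (dPLI), and windows are averaged
after correction.  No correction for multiple comparisons is applied
across pairs; the type-I calibration test verifies the per-pair retention
rate stays at the nominal level.

### Network summaries

* **Node degree**: row sums of the corrected, time-averaged wPLI matrix;
  the highest-degree electrode is the network hub.
* **Frontoparietal feedback**: the mean time-averaged dPLI over all
  frontal-to-parietal channel pairs within each lateral hemisphere; a mean
  above 0.5 is feedback-dominant.  A hemisphere without frontal or parietal
  coverage is reported as missing rather than failing the run.
* **Hub index**: the degree-weighted mean of the montage's
  anterior–posterior coordinate, $\sum_i d_i y_i / \sum_i d_i \in [-1,1]$.
  This scalar "anteriorization" statistic is this package's own
  construction (no standard quantitative definition exists) and is labeled
  as such in reports; it is undefined (NA) when all degrees are zero.
* **Hub directionality**: per channel, the mean dPLI to all other
  channels; above 0.5 the node is a source, below 0.5 a target.

### Lempel-Ziv complexity

Each 10-s window of the *broadband* (0.1–45 Hz) signal is binarized
against the within-window mean of its instantaneous amplitude (Hilbert
envelope), per channel.  The per-channel threshold avoids leaking
between-state amplitude differences into the symbolization.  The strict
inequality is applied with a $10^{-9}$ relative guard so a constant
envelope maps to all zeros despite machine-epsilon FFT ripple.  Broadband
rather than alpha-filtered input is used because complexity is a
whole-signal property; the alpha filter exists only for the phase-lag
estimators.

Three variants of the Lempel-Ziv 1976 exhaustive-history phrase count
(`lz76`) are reported per window and averaged:

1. **median univariate** — median over channels of the per-channel count
   (median across channels, then mean across windows; a mean-across-
   channels switch is not provided because the median is what the three
   estimators' joint interpretation expects, and the two differ only under
   heavy channel skew);
2. **concatenated** — channels joined end-to-end in montage label order
   (order-dependent by construction, therefore fixed and recorded);
3. **joint** — the time-ordered sequence of per-sample channel bit-vectors
   parsed as single symbols: a directly multivariate compression that
   collapses inter-channel redundancy and reduces to the univariate count
   for one channel.

`lz76` is the 1976 exhaustive-history complexity (phrase count with
overlapping copy sources), not LZ78 token parsing — the variant used
throughout the anesthesia-complexity literature.  It is implemented via a
suffix-array longest-previous-factor factorization ($O(n\log n)$), and is
checked in the tests against a brute-force parser written directly from
the definition, exhaustively on all binary strings up to length 12.

Raw phrase counts are normalized by phase-randomized surrogates: each
window is divided by the mean count over 10 surrogate versions with
identical power spectra but uniformly random Fourier phases.  This
minimizes the influence of purely spectral change: a linear Gaussian
signal is its own surrogate class and normalizes to about 1, while
amplitude structure that the surrogates destroy pushes the ratio below 1.
Raw counts are reported alongside so either convention can be compared;
no $n/\log_2 n$ asymptotic factor is applied to raw counts.  Ten
normalization surrogates are the default (the count is not standardized in
the literature); it is configurable and seeded.

## Signal conditioning

The conditioning chain is: drop listed bad channels, average-reference the
retained ones, downsample to 250 Hz with anti-alias (polyphase) filtering
when the input rate is at least 500 Hz, then high-pass 0.1 Hz, low-pass
45 Hz, and a 60 Hz notch.  All filters are 4th-order Butterworth run
forward–backward (`filtfilt`), with the notch a 2nd-order IIR biquad at
Q = 30: zero-phase filtering is a prerequisite for unbiased dPLI, since a
causal filter would introduce artificial phase leads.  The tests verify a
band-centered sinusoid is phase-shifted by less than 1°.

Bad channels are removed by an input drop list; there is no automatic
detection.  Manual artifact inspection is replaced by a reproducible
amplitude-threshold window rejector (default 150 µV, configurable, with
rejected windows logged); manual inspection cannot be reproduced by code.

Band order matters in one place: the alpha filter is applied to the
*continuous* preprocessed signal and the 10-s windows are cut afterwards.
Filtering each window separately leaves forward–backward edge transients
inside every window; they are shared between channels and measurably
inflate the surrogate false-positive rate.  Filtering first makes the
per-window type-I retention sit at its nominal $1/21$ level.

## The synthetic generator and what it does (not) show

Recordings are built from three ingredients, each directly tied to one
estimator's ground truth:

* **Directed lag graphs** (`gen_lagged_oscillators`): each coupled pair
  shares one stochastic narrowband process spanning 8–13 Hz; the lagging
  channel receives the analytic signal rotated by $-\delta$, so the
  instantaneous phase difference equals the requested lag exactly before
  noise.  Every channel adds independent 1/f-shaped Gaussian noise scaled
  to a requested in-band SNR.  Rotating the analytic signal (rather than
  delay-coupling oscillators) gives exact expected dPLI.
* **Common-source mixing** (`gen_common_source`): all channels are
  positive multiples of one band-limited source — the volume-conduction
  stand-in with exactly zero phase lag, and analytically zero imaginary
  cross-spectrum before jitter.
* **Markov amplitude modulation** (`gen_complexity_signal`): a 10 Hz
  carrier (random phase per channel) modulated by an independent binary
  chain with per-sample flip probability `p_flip`; expected complexity
  rises monotonically with `p_flip`, and `p_flip = 0` gives the
  constant-envelope floor.

Six `scenario_spec` names pair these into baseline/anesthesia contrasts
with known directions of change: `feedback_increase`/`feedback_decrease`
(frontal→parietal lead pairs present in one state), `hub_anteriorize`/
`hub_posteriorize` (coupling chains concentrated on anterior or posterior
sites), and `complexity_up`/`complexity_down` (`p_flip` 0.05 vs 0.45).
Ground truth stores *signs* only: the motivating observations are
directions of change, not effect sizes, so scenario effect sizes are free
parameters chosen once for detectability (coupling 0.9, lag $\pi/4$,
in-band SNR 10 dB).

Defaults are 10 channels (the minimal montage covering all five regions
per hemisphere), 250 Hz, and 60 s per state.  The test and scenario suites
run at 125 Hz and 30 s per state (three 10-s windows) with five
normalization surrogates — enough windows for every estimator while
keeping the parameter-recovery suite (6 scenarios × 20 seeds × 2 states)
quick; the classification accuracy criterion is met at these sizes.

What passing scenarios show: the estimation chain recovers known directed
lags, hub placements and compressibility orderings through the full
pipeline, including preprocessing and both surrogate layers.  What they do
not show: real EEG has aperiodic (1/f-exponent) shifts, non-stationary
artifacts, volume conduction that is only approximately zero-lag, and
oscillations that wax and wane — none of which the generator emulates
(and head-model projection and neural-mass dynamics are deliberately out
of scope).  Passing here validates the *estimators*, not any clinical
claim.

## Classification of a case

`run_case` analyzes each state and classifies the anesthesia-minus-baseline
delta per metric.  Canonical anesthetic responses are: frontoparietal
feedback drop, hub anteriorization, complexity decrease; the opposite
directions are paradoxical; deltas inside the null tolerances
($|\Delta\,\mathrm{FP\ dPLI}| < 0.01$, $|\Delta\,\mathrm{hub}| < 0.05$,
$|\Delta\,\mathrm{LZC_{norm}}| < 0.01$, all configurable and recorded in
the report) are null.  The tolerances exist because the motivating
observations report directions only; they are set well below the scenario
effect sizes but above numeric noise.  With a post-anesthetic recording,
each metric is additionally marked reversed when its post value returns to
within the same tolerance of baseline.  Reports embed the full effective
configuration and its MD5 hash, and identical inputs, configuration and
seeds give byte-identical report JSON.

A companion check, `alpha_power_degree_check`, computes the Spearman
correlation between per-channel changes in alpha power and in node degree
(with a seeded permutation p-value), to ask whether apparent hub
reorganization merely tracks alpha-power change.

## Numerical choices and degenerate inputs

* Analytic signals via FFT half-spectrum doubling; windows are long
  (1250–2500 samples), so edge ripple is negligible away from the ends.
* wPLI denominators below $10^{-4}$ of the cross-spectrum magnitude →
  pair treated as lag-free (0 / 0.5), see above.
* All-zero channels: their pairs get wPLI 0 / dPLI 0.5 with a warning,
  not an exception.
* Degenerate constant windows normalize LZC against a surrogate mean of
  zero → value NA with a warning.
* Hub index with all-zero degree → NA with a warning.
* Degree ties at the hub argmax break by label order.
* Empirical p-values use the $(1 + \#\{s \ge o\})/(n+1)$ rank form, so
  surrogate counts below 19 cannot resolve $\alpha = 0.05$ and are
  rejected at configuration time.

## Known limitations

* The dPLI surrogate test's sidedness is a genuine modeling choice;
  two-sided on $|\mathrm{dPLI}-0.5|$ is the default, switchable.
* The EDF writer is minimal (16-bit, 1-s records, integer sampling rates,
  one rate per file); it exists for interoperability of the simulator
  output, not as a general EDF implementation.
* No aperiodic/oscillatory decomposition, source localization, ICA, or
  graph metrics beyond degree; single frequency band (configurable edges).
* A three-window state is the validated minimum; estimates at that length
  are direction-reliable but not magnitude-stable.
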