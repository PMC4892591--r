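---
title: "Methods: chronology building, network synchrony and nonlinear climate response"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chronology building, network synchrony and nonlinear climate response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`ringsync` implements the analysis chain used to study synchronized
growth of temperature-limited alpine conifers: site chronologies from
raw ring widths, network-wide shared variance and its change through
time, monthly climate screening with stability testing, a fuzzy
partition of site responses under cold versus warm winters, and two
nonlinearity diagnostics. This vignette is the package's account of the
statistical choices behind each stage, with the reasoning for every
default that the underlying methods literature leaves open.

## Chronology model

A core's ring widths are modeled multiplicatively, `x_t = G_t · I_t`,
where `G_t` is the biological age/size trend and `I_t` a dimensionless
growth index. Detrending fits `G_t` and returns `I_t = x_t / G_t`, which
preserves positivity and keeps a well-behaved index mean near 1.

The fit strategy is deliberately conservative, to retain low-frequency
climate variability:

1. **negative exponential** `G_t = a·e^(−b·t) + k` with `a > 0`,
   `b > 0`, `k ≥ 0` (nonlinear least squares via `minpack.lm`, bounded);
2. **straight line with non-positive slope** if the exponential fails;
3. **stiff smoothing spline** otherwise.

"Fails" is made explicit, since classic descriptions of this fallback
leave it to the analyst's judgment: non-convergence, a
constraint hit (`a` or `b` within 1e−5 of zero — a constant in
disguise), or any fitted value at or below the 0.01 mm width floor. A
strictly increasing series therefore falls through to the spline, which
is the desired conservative behavior.

The spline is a discrete penalized smoother for annual data (a
Whittaker-type second-difference penalty), parameterized by its
frequency response rather than by a smoothing constant: the gain is
`H(f) = 1 / (1 + λ (2 sin πf)^4)`, so requiring 50% gain at period `p`
gives `λ = (2 sin(π/p))^−4`. The default `p` is 0.67 × the site's mean
segment length, the standard stiff cutoff. Parameterizing by the 50%
cutoff makes the spline's behavior independent of series length and
matches how such splines are specified in dendrochronology.

Cores are averaged year-by-year with the **Tukey biweight** (c = 9,
MAD scale, iterated to |Δm| < 1e−6, at most 50 iterations; one value
returns itself, two values their mean, zero MAD the median). rbar is the
mean pairwise Pearson correlation over core overlaps of ≥ 30 shared
years — shorter pairs are excluded and recorded — computed once per
site, because the reliability truncation below uses a single cut per
site. `EPS = N·r̄ / (N·r̄ + 1 − r̄)` and the per-year subsample signal
strength `SSS(t) = n_t (1 + (N−1) r̄) / (N (1 + (n_t−1) r̄))` follow;
the reliable span starts at the earliest year from which SSS stays at or
above 0.85 (the conventional cutoff) through the end of the record.
rbar ≤ 0 is refused rather than silently clamped: SSS is undefined for
signal-free sites, and the caller should know.

## Network synchrony

Shared variance is quantified by PCA **on the correlation matrix**
(eigendecomposition, not SVD of anomalies): shares are `100·λ_i/p`, and
each component is oriented so its mean loading is positive, which fixes
the sign indeterminacy reproducibly. Temporal change uses 50-year
windows lagged by 10 years, standardizing within each window; the final
window is anchored to the period end and may exceed 50 years (an
1825–2005 period ends with the 51-year "1955-2005" window), so the most
recent data always appear in a full window. Extreme rings use one pair
of limits per chronology — mean ± 1.5 SD over the whole analysis
period — because the frequency of exceedances through time is the
signal of interest; per-window limits would absorb exactly the change
being measured.

## Climate response and its stability

Monthly predictors are screened over the 17-month dendroclimatic year
(previous May … current September), the window within which the previous
growing season, winter, and current growing season can all influence a
ring. Correlation functions report Pearson r per month with two-tailed
critical values `r_crit = t / √(df + t²)`, `df = n − 2`, at 95% and
99%. Moving correlations use a fixed 30-year window assigned to the
center year (lower-middle for even windows — documented and fixed), with
a 95% band from the Fisher transform, `tanh(atanh r ± 1.96/√(w−3))`.

Whether a moving correlation wanders more than chance allows is tested
with a Monte Carlo construction in the spirit of Gershunov's test: the
statistic is the **variance of the moving-correlation track**; the null
draws M = 1000 surrogate pairs of bivariate AR(1) processes whose lag-1
autocorrelations are fitted from the two inputs and whose innovation
correlation `ρ_e = r (1 − ab) / √((1−a²)(1−b²))` reproduces the observed
full-period correlation; `p = (1 + #{null ≥ observed}) / (M + 1)`.
Variance (rather than range) of the track and M = 1000 are fixed here
because the original description leaves both open; the construction is
seeded and fully reproducible. The test suite checks both calibration
(rejection rate at α = 0.05 within [3%, 7%] under a stationary null,
500 replicates at n = 100, window 30, M = 500) and power (≥ 50% against
a mid-series correlation collapse 0.6 → 0).

## Fuzzy partition of site responses

Site index vectors over the 16-year cold (1965–1980) and warm
(1990–2005) winter intervals are clustered with fuzzy C-means. The
method canon supplies the defaults the source description omits:
fuzzifier m = 2, Euclidean distance, per-row z-scoring (so a site's
index level and variance do not drive the partition), 10 seeded
restarts keeping the lowest final objective. Initialization samples k
distinct data rows as centroids — starting from near-uniform random
memberships stalls at the degenerate coincident-centroid fixed point.
The objective `J = ΣΣ u_ij^m ‖x_i − c_j‖²` is recorded per iteration
and asserted non-increasing on every run; a site exactly on a centroid
gets membership 1 there; clusters are reported in descending fuzzy
cardinality order, which fixes the labeling.

Partition quality is the fuzzy Calinski–Harabasz pseudo-F
(membership-weighted between/within dispersion ratio); zero within-
dispersion reports +Inf with a degeneracy flag. "Cluster distance" is
the Euclidean distance between the two centroids of the z-scored data —
a defined quantity, not expected to match any particular published
scale whose construction is unstated. The count of years with
significant between-cluster differences uses Welch's t-test per year at
α = 0.05 on the hard (maximum-membership) labels; singleton clusters
are refused because the test is undefined there.

## Nonlinear diagnostics

**EMD/EEMD.** Sifting uses cubic-spline envelopes through local extrema
(plateaus contribute their midpoints; the two outermost extrema are
mirrored about each boundary). A component is accepted once the
normalized squared difference between successive siftings is below 0.2
— or a soft cap of 10 siftings is reached — *and* it satisfies the IMF
mode condition (extrema and zero-crossing counts differ by at most 1),
with a hard cap of 30 siftings. The mode condition is part of the stop
rule because it is the defining property of an IMF; the classic SD-only
rule can emit components that violate it.
Decomposition stops when the residual can no longer form both
envelopes, which makes the residual the nonlinear trend and the
decomposition exactly additive. EEMD averages the decompositions of 100
noise-added copies (noise SD = 0.2 of the series SD, the canonical
values), aligning IMFs by index and zero-padding to a common count;
with ensemble 1 and noise 0 it reduces exactly to EMD.

**Neural response surface.** A 2-input / one-hidden-layer (4 logistic
units) / linear-output network maps previous Nov–Dec mean temperature
and current January temperature to the growth index. Inputs and target
are standardized; training minimizes squared error plus a small ridge
penalty (1e−3) by BFGS with analytic backpropagation gradients, run in
100-iteration chunks with early stopping on a 20% validation split
(best-validation weights kept; patience 4 chunks); the best of 5 seeded
restarts by validation loss wins. Quasi-Newton training with decay is
the field's standard for this architecture (it is what `nnet` does);
plain gradient descent underfits this problem badly. Given weights,
prediction is deterministic and the standardization invertible.

The response surface evaluates the network over a regular temperature
grid (0.1 °C steps); grids beyond 3 °C of the training envelope are
refused and cells outside the envelope itself are flagged as
extrapolation. The sensitivity threshold is estimated from the
axis-mean profile by a continuous two-segment piecewise-linear fit with
the knot searched over interior grid points; the breakpoint is the
least-squares knot and the below/above slope ratio is reported. The
breakpoint is flagged unidentifiable when the broken line improves on a
single straight line by less than 5% of its residual sum of squares.
When the goal is threshold recovery, the scan should use the
well-supported center of the predictor distribution (January 10–90%
quantiles, Nov–Dec interquartile range, as in the acceptance script):
at sparse extremes the saturating hidden units flatten the profile and
drag the knot cold.

## The synthetic generator as study design

The generator defines the conditions under which the package's claims
are tested. A core's index is

```
I_{s,c,t} = 1 + a_t C_t + b_t G_{g(s),t} + σ_site η_{s,t} + σ_core ξ_{s,c,t}
```

with `C` the network-wide signal, `G` a two-group site signal, `η`
site-level noise shared by a site's cores and `ξ` per-core noise.
`a_t = σ_site √(f_t/(1−f_t))` makes `f_t` the fraction of site-level
variance carried by the common signal, so between-site correlation tends
to `f` as cores accumulate and the expected PC1 share is
`f + (1−f)/p` — the closed form the recovery tests check. Defaults:

* 17 sites × 5 cores, 1700–2005, cores staggered over the first 35% of
  the span, so sample depth grows toward the present while reliable
  spans still cover 1825 — the geometry of the published network;
* `f_t` stepping 0.3 → 0.6 at 1985: the published record locates the
  regime shift in climate–growth response in the early 1980s, which
  also places the cold partition interval (1965–80) in the
  low-synchrony regime and the warm one (1990–2005) in the high regime;
* `σ_site = 0.1`, `σ_core = 1.5 σ_site` (within-site rbar ≈ 0.4,
  typical of conifer networks), group amplitude `b = 0.8 a` (puts the
  secondary loading axis near an 11% variance share);
* extreme years as ±3 SD shocks to the common signal at probability
  0.02/yr, so they propagate network-wide;
* age trend `1.5·e^(−0.02·age) + 0.3` mm, widths floored at 0.01 mm
  (the `.rwl` precision unit) with the configuration rejected if more
  than 5% of values need flooring.

Monthly climate is a fixed highland-continental climatology plus
piecewise-linear trends plus unit-variance AR(1) anomalies; selected
year-month cells are coupled to the network signal at a configured
correlation (winter minimum temperature at r = 0.6 in the demo,
matching the strength of winter temperature control reported for such
networks). The threshold generator produces 55 years — an instrumental-
era overlap — with the January slope collapsing to 20% of its value
below −7 °C and noise leaving a multiple R² near 0.75.

What the generator does **not** emulate: spatial structure and
distance-dependent coupling between sites; cross-correlation among
climate variables (each variable is generated independently, so "which
variable correlates most" tests are structural, not competitive);
age-dependent index variance; missing rings; daily climate; and any
process-based growth mechanism. Passing the recovery tests therefore
shows the estimators do their statistical job under realistic noise and
network geometry — not that the biological interpretation of any real
network is settled.

## Numerical conventions and degenerate inputs

* Seeds: every stochastic routine takes an explicit seed; the pipeline
  derives per-stage seeds from one master seed (`(7919·seed + 104729·k)
  mod (2^31−19)`), so whole-run reproducibility coexists with
  stage-level independence and every derived seed stays a valid 32-bit
  integer.
* FCM membership updates scale distances by the row minimum before the
  `−1/(m−1)` power, so near-crisp fuzzifiers (m → 1) cannot overflow.
* The stability test counts `null ≥ observed − 1e−15`, so a
  deterministic tie (observed variance exactly 0) yields p = 1.
* Biweight with zero MAD returns the median; empty input is an error.
* `read_rwl` accepts both `999` and `−9999` terminators (recording
  which), skips up to three leading header lines, and reports the line
  number of anything malformed mid-file.
* Degenerate FCM inputs (all rows identical, constant rows under
  z-scoring, p ≤ k) are refused with specific errors, as are
  correlation functions with under 20 overlapping years and moving
  windows longer than the overlap.

## Problem sizes in the test suite

The suite exercises the full chain at sizes chosen to make sampling
error, not runtime, the binding constraint: 100-replicate recovery runs
for the synchrony step, EEMD slope and sensitivity threshold;
500-replicate calibration (and 400-replicate uniformity) checks for the
stability test at n = 100, window 30, M = 500; 17-site demonstrations
for the structural checks. The complete suite runs in a few minutes on
one CPU.

## Known limitations

* Per-site detrending model choices of any particular published network
  cannot be reproduced exactly (they are unrecorded); only the default
  fallback order is available, so chronology-level statistics match
  published tables approximately at best.
* rbar is computed once per site, not in running windows; networks with
  strongly time-varying inter-core correlation will see that averaged.
* The Gershunov-style null matches lag-1 persistence and overall
  cross-correlation only; longer-memory persistence inflates the test's
  size slightly.
* The ANN stage is a two-predictor diagnostic, not a general regression
  surface; with collinear winter predictors the attribution between
  them is unstable even when the joint surface is well determined.
* EEMD trends at series ends rely on mirrored-extrema envelopes and
  should be read cautiously in the last ~half oscillation of the
  slowest mode.
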