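---
title: "Methods: time-separated mutual information for leader–follower inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: time-separated mutual information for leader–follower inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(misep)
```

This vignette records the model, the estimators, and the design and
numerical choices behind `misep`, in the spirit of a methods section: what
is computed, under which assumptions, and where the soft spots are.

## The leader–follower model on a ring

Two point agents move on a circle. The leader performs a drift–diffusion
step each frame; the follower copies the leader's angular position a fixed
delay $T$ (in steps) earlier, plus its own noise:

$$
\theta_L(t) = \theta_L(t-1) + \Omega + W_\sigma(t), \qquad
\theta_F(t) = \theta_L(t-T) + W'_\sigma(t),
$$

both taken modulo $2\pi$, with $W_\sigma$ independent zero-mean Gaussian
noises of standard deviation $\sigma$. Before step $T$ the follower reads
the leader's initial position (the agents are treated as immobile before
the start). With probability $\alpha$ per step the *labels* swap; both
agents' full histories are kept, and after a swap the follower equation
reads the **new** leader agent's recorded history at $t-T$, which can
produce a position jump of up to the current separation. This literal
reading is a modelling choice; nothing constrains what the "right"
behaviour at the swap step would be, and the jump is visible in simulated
trajectories as a small discontinuity at each leadership change. A swap
that occurs before step $T$ (possible, though with probability
$\approx \alpha T$) reads the new leader's position at time 0 — the
minimal consistent extension of the initialisation rule.

Parameters and defaults (all settable in `lf_config()`):

| parameter | meaning | unit | study value |
|---|---|---|---|
| `omega` | leader drift | rad/step | 0.0067 |
| `sigma` | step noise SD | rad/step | 0.0039 |
| `delay` | follower delay $T$ | steps | 20 (0.5 s) |
| `alpha` | swap probability | per step | 0 or 0.00021 |
| `fps` | steps per second | 1/s | 40 |
| `phi` | initial offset | rad | 0.5 (0.1 for controls) |

The swap rate 0.00021 makes the expected number of leadership changes in a
thirty-minute recording ($72000$ steps) equal fifteen, matching what is
seen in tank experiments with paired fish. The time-separated mutual
information $MI(\theta_1(t); \theta_0(t-\tau))$ of this model peaks at
$\tau = T$ and decreases monotonically in $|\tau - T|$ (a data-processing
argument: each extra leader increment adds independent noise), which is
what makes the peak location an estimator of the follower's reaction
timescale. Positive $\tau$ presumes agent 0 leads; the index-swapped
pairing is, at steady state, the mirror image across $\tau = 0$ and is
plotted on the negative axis (`mirror_combine()`).

Random numbers: leader noise, follower noise, swap draws and the initial
angle use four sub-streams derived from one seed, so changing `alpha`
leaves the noise sequences untouched — useful for ablations.

## KSG estimation and its finite-sample behaviour

`ksg_mi()` implements the k-nearest-neighbour estimator (variant
$I^{(1)}$, max-norm in the joint space), $k = 4$ by default. Estimates are
in nats and deliberately unclipped: small negative values are ordinary
fluctuations, and clipping would bias curve comparisons. Exact ties make
neighbour counts ill-defined, so a deterministic seeded jitter of relative
magnitude $10^{-10}$ is added.

Angles are treated as points on the line by default — a naive application,
but the one that matches common practice; pairs that straddle the
$0/2\pi$ cut lose their neighbourhood. An optional chord embedding
$\theta \mapsto (\cos\theta, \sin\theta)$ (`metric = "chord"`) removes the
cut at the cost of changing the estimator's geometry; for the study
configurations the peak location is insensitive to the choice.

Two finite-sample properties matter for everything downstream:

1. **Saturation.** For strongly dependent pairs the estimate is capped
   near $\ln N + \psi(k) - 2\psi(k+1)$: with $N = 250$ and $k = 4$ that is
   about 3.8 nats, while the model's true peak information is near 6. Peak
   *locations* are unaffected, but absolute curve heights depend on the
   sample count. Consequently, curves are only comparable at matched
   sample counts, and the test problem sizes are chosen so that
   single-trajectory estimates (250 windows) match the ensemble subsets
   (250 pairs).
2. **Error bars.** The ensemble procedure estimates each grid point on ten
   random subsets of 250 of the 300 available pairs. Those subsets share
   ~83% of their members, so the naive standard error
   $\mathrm{sd}/\sqrt{10}$ shrinks with the subset count while the true
   uncertainty does not; in a calibration experiment two fully independent
   300-replicate ensembles differed by many such "SEs".
   `mi_curve_ensemble()` therefore reports the delete-$d$ jackknife
   standard error, $SE^2 = \frac{n-d}{d}\overline{(\widehat{MI}_i -
   \overline{MI})^2}$ with $d = n - 250 = 50$, which reproduced the
   observed independent-ensemble spread (~0.04 nats). Single-trajectory
   curves report the plain SD across resamples, since resamples share one
   trajectory and are not independent draws.

## Single-trajectory estimation

Experiments yield one trajectory, not an ensemble. Treating its time
points as independent samples requires (a) stationarity — guaranteed here
by confinement to the ring — and (b) sampling points far enough apart that
their correlations have decayed. `mi_curve_single()` divides the series
into windows of $W$ steps and draws one point per window from the
symmetric triangular density

$$
f(t) = \frac{4(t - t_i)}{W^2} \; (t \le \text{mid}), \qquad
f(t) = \frac{4(t_{i+1} - t)}{W^2} \; (t > \text{mid}),
$$

so consecutive samples are $W$ apart *on average* while every window
contributes. The continuous draw is rounded to the nearest integer index
inside the window; $W = 1$ degenerates to "use every point", which doubles
as the naive estimator. Redrawing the points (boundaries fixed) gives
replicate datasets without shrinking them; ten resamples by default,
mirroring the ensemble's ten subsets.

For a ring walker with $\sigma^2 = 0.1$, windows of 300 steps reproduce
the ensemble curve within error bars, while a matched-count *naive*
estimate — 250 consecutive time points — overshoots it badly: a short
contiguous chunk has not explored the ring, so its narrow marginals fake
extra dependence. (A naive estimate over the *entire* long trajectory is
barely inflated for this walker; the failure mode the windowing guards
against is the realistic one of limited data.)

For the leader–follower dyad the situation is harsher: with
$\sigma = 0.0039$ rad/step the angular position decorrelates only on the
timescale $(2\pi)^2/\sigma^2 \sim 10^6$ steps — that is what the nonzero
plateau of the MI curve records — so no practical window fully
decorrelates the samples. At $W = 100$ (2.5 s) the residual inflation is
about 1–2% of the curve height (a few hundredths of a nat), visually
negligible and without effect on the peak location, but detectable against
well-calibrated error bars; at $W = 5$ the tail of the curve is grossly
overestimated while the peak location survives. This is a known limitation
of single-trajectory estimation in slowly-mixing systems, not a property a
larger $W$ can purchase back at realistic data lengths.

## Preprocessing of planar tracks

Input is the tabular output of video tracking: per-frame centroid and head
positions at 40 frames/s, with occasional failures. Choices:

- **Missing frames are masked, never interpolated**; paired operations
  drop a pair when either member is masked.
- **Polar transform** about the tank centre; the unwrapped angle
  accumulates wrapped frame-to-frame differences across valid frames, so
  laps survive gaps.
- **Heading repair**: trackers sometimes mistake tail for head, flipping
  the heading by nearly $\pi$. Scanning forward, a wrapped jump larger
  than $\pi - 0.6$ rad from the previous valid *corrected* heading is
  replaced by that heading. Measuring jumps on wrapped differences and
  cascading corrections makes the rule stable for runs of consecutive
  flips and idempotent.
- **Alignment** $A_{ij}$: unsigned angle between $i$'s heading and the
  centroid-to-centroid vector, in $[0, \pi]$; smoothed with a centred,
  mask-aware rolling mean of exactly `round(window * fps)` frames (600
  frames for the default 15 s at 40 fps). Leader–follower intervals show
  $A_{ij} \approx 0$ with $A_{ji} \approx \pi$.
- **Drift and noise**: $\Delta\theta$ is wrapped into $(-\pi, \pi]$ before
  averaging — raw differencing would corrupt the drift at every lap
  boundary. $\Omega$ is the pooled mean, $\sigma$ the pooled SD. Note that
  on *model* dyad output the pooled SD is $\sqrt{2}\sigma$, not $\sigma$:
  the follower's increment contains a difference of two noise draws
  (leader increments have SD $\sigma$, follower increments
  $\sqrt{3}\sigma$). The estimator is consistent for the printed
  parameters exactly when increments are iid — the leader series, or a
  non-interacting pair.

## Synthetic tracking data

`render_planar()` bridges the one-dimensional model to the planar data
format: centroids at radius $r_i(t)$ (mean 30 cm inside the 125.1/26.2 cm
annulus, plus AR(1) jitter with coefficient 0.95 so the radius is smooth),
heads half a body length along the direction of angular motion (the
tangent, signed by the increment smoothed over 0.5 s — a body cannot flip
orientation on one noisy frame), head/tail flips with probability
`p_flip`, and blank frames with probability `p_miss`. It emulates exactly
the statistical structure the analysis relies on — angles, headings,
flips, gaps — and nothing else: no burst-and-coast kinematics, no wall
interactions, no hydrodynamics. Passing tests on rendered data therefore
show the *pipeline* is sound, not that the model captures real fish.

## Peak localisation and significance

LOESS is implemented directly: for each grid point, a degree-2 polynomial
is fitted by tricube-weighted least squares to the nearest
$\lceil fN \rceil$ points and evaluated there; one pass, no robustness
iterations (`stats::loess` serves as an independent cross-check in the
tests). Quadratic local fits preserve curvature at peaks; degree is
configurable. The branch peak is the argmax of the smoothed values, and a
maximum on the branch boundary is flagged as "no interior peak" rather
than reported. Scanning the data fraction $f$ over 0.05–0.5 probes whether
the peak is robust to smoothing scale; the reaction timescale
$\hat T$ is the mean $|\tau|$ of the retained interior peaks and the band
width their spread. Significance is a package convention, stated openly: a
peak is significant when it exceeds the curve's plateau (largest 25% of
$|\tau|$) by $z = 2$ combined standard errors. A flat curve from
non-interacting agents fails this test by construction.

## Numerical details

- The default $\tau$ grid has 81 points on $[-2.5, 2.5]$ s. At 40 fps the
  0.0625 s spacing is 2.5 steps, so lags are rounded to the nearest
  integer step when indexing; the rounding error (≤ 0.0125 s) is a fifth
  of a grid step.
- `mirror_combine()` keeps the agent-0-presumed-leader estimate at
  $\tau = 0$ (the two orderings estimate the same quantity there).
- Grid points left with fewer than $k + 2$ valid pairs are reported `NA`
  with a warning, never silently dropped.
- All estimation functions accept a seed and restore the caller's RNG
  state; identical seeds give bit-identical output.

## Problem sizes used by the test suite

The suite re-runs the analysis at the study scale: 300-replicate
ensembles of 24000-step simulations sampled at step 24000, ten jackknife
subsets of 250 pairs, a 25000-step single trajectory (250 windows of
$W = 100$), a 75000-step ring-walker trajectory for the decorrelation
checks, and end-to-end recovery for delays of 10, 20 and 40 steps. These
sizes make every stochastic check reproducible in minutes on one core
while keeping each estimate at the sample counts discussed above; the
vignette's saturation caveat explains why sample counts, once chosen, must
be matched across compared curves.

## Known limitations

- Single-trajectory estimates in this slowly-mixing model carry a small
  positive bias at any feasible window (see above); peak locations are
  unaffected.
- Absolute MI magnitudes depend on the sample count through KSG
  saturation and should not be compared across different $N$.
- The significance rule is a two-point z-test, not a calibrated
  hypothesis test; it is meant to separate "clearly peaked" from "flat",
  not to provide p-values.
- Only two-agent systems are modelled; radial dynamics are ignored by the
  angular analysis; behavioural-mode segmentation (smooth vs irregular
  laps) is out of scope.
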