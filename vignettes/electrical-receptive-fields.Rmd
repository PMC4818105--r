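---
title: "Estimating electrical receptive fields with spike-triggered covariance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating electrical receptive fields with spike-triggered covariance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(elstim)
```

## The problem

Neural prostheses such as retinal implants stimulate tissue through arrays
of electrodes, almost always one electrode at a time, because predicting
the effect of concurrent stimulation across many electrodes has been
intractable by psychophysics alone. `elstim` implements a system
identification approach: drive all electrodes simultaneously with Gaussian
white-noise current pulses, record a single cell's spikes, and fit a
linear-nonlinear (LN) cascade that predicts the probability of a
short-latency (directly evoked) spike for *any* stimulation pattern.

A stimulus is a vector $\vec{S}_t \in \mathbb{R}^{E}$ of signed biphasic
pulse amplitudes in $\mu A$, one per electrode (positive = anodic-first).
The model is

$$P(\text{spike} \mid \vec{S}_t) \;=\;
  N^+(\vec{w}^+ \!\cdot\! \vec{S}_t) \;+\;
  N^-(\vec{w}^- \!\cdot\! \vec{S}_t) \;+\; p_0,$$

where $\vec{w}^+$ and $\vec{w}^-$ are the *electrical receptive fields*
(ERFs) for net anodic-first and net cathodic-first stimulation, $N^\pm$
are saturating sigmoids, and $p_0$ is a spontaneous-rate offset (default
0). The ERFs say *which* electrodes drive the cell and in what proportion;
the sigmoids say *how strongly*.

## Pipeline

### Stimulus generation and calibration (`sample_white_noise`, `calibrate_sigma`)

Amplitudes are drawn i.i.d. $\mathcal{N}(0, \sigma^2)$ and redrawn
whenever a sample exceeds the $\pm 300\,\mu A$ compliance limit.
Rejection, not clipping, preserves the (truncated-)Gaussian shape that the
covariance analysis relies on; `truncated_normal_sd()` gives the exact SD
for checking the sampler. Non-operational electrodes are masked to zero
and excluded from all eigen-analyses, then re-inserted as zeros in
reported ERFs.

$\sigma$ sets the operating point of the experiment. It is calibrated per
cell: short trains are presented at $\sigma = 50, \dots, 250\,\mu A$, a
three-parameter sigmoid
$p(\sigma) = p_{max}/(1 + e^{-g(\sigma - m)})$ is fitted to response
probability versus $\sigma$ (unweighted least squares; initialization
$p_{max} = \max p$, $m$ = grid point nearest half max, $g = 4/\text{span}$
— robust on 5-point grids), and the working $\sigma$ is where the fit
reaches half its own saturation. Cells that saturate below probability 1
therefore get a proportionally lower operating probability, exactly as
intended by the half-of-saturation rule.

### Response labelling (`detect_spikes`, `cluster_latencies`, `label_responses`)

Stimulation artefacts are blanked by holding the trace at the blank-start
value; spikes are local maxima above threshold, one per supra-threshold
excursion, with plateau ties broken at the first maximal sample
(deterministic). Latencies are measured from the stimulus *offset*
(onset $+ 2 \times$ phase $+$ gap when only onsets are recorded).
Direct activation produces a short-latency cluster (means around
1–4 ms) and network-mediated activation a long-latency cluster (around
5–20 ms); 1-D k-means (10 restarts, fixed seed) separates them. The
number of clusters was set by eye in the original experiments; the
package defaults to $k = 2$ with a fallback to $k = 1$ when the
silhouette width of the 2-cluster solution is below 0.5 — a documented
heuristic, overridable. A presentation is labelled a short-latency
response when any spike falls within mean $\pm 2$ SD of the shortest
cluster. With overlapping clusters both short and long labels can be 1;
this is surfaced, not resolved. Note the 2 SD window by construction
excludes roughly 5 % of genuine short-latency spikes; this is inherent to
the rule, not an estimation error.

### Subspace identification (`spike_triggered_cov`, `significance_test`)

The covariance $C_s$ of the spike-eliciting stimuli (about their own
mean, $n - 1$ denominator) is compared with the raw ensemble, which is
white with variance $\approx \sigma^2$ in every direction. Eigenvalues of
$C_s$ above (below) that level mark excitatory (suppressive) stimulus
directions. Sorted sample eigenvalues spread substantially even under the
null (for $p$ electrodes and $n_s$ spikes the extremes sit near
$(1 \pm \sqrt{p/n_s})^2 \sigma^2$), so significance is judged against a
null built by circularly shifting the response vector relative to the
stimulus sequence (uniform offset $\geq 1$), which preserves the spike
count and stimulus statistics. Each of the (default) 1000 shuffles
contributes its largest and smallest eigenvalue; the interval is the null
mean $\pm n_{sd}$ SD of the corresponding extreme (default $n_{sd} = 2$,
roughly a 95 % interval — the mean $\pm$ SD form is used rather than
percentiles, with $n_{sd}$ configurable). When an observed extreme falls
outside, its axis is recorded, the data are projected onto the
orthogonal complement (dimension-reducing deflation, so no spurious zero
eigenvalue remains), the null is regenerated on the deflated data, and
the test repeats.

The strength ratio
$G = |e_1 - \bar{e}_{rnd}| \,/\, |e_2 - \bar{e}_{rnd}|$ takes $e_1, e_2$
as the two eigenvalues most separated from the first iteration's null
mean $\bar{e}_{rnd}$ (the mean over all eigenvalues of all first-round
shuffles). $G \gg 1$ means the cell is effectively one-dimensional:
electrode interactions combine linearly.

### Polarity-split receptive fields (`estimate_erfs`, `electrode_significance`)

The first principal axis $\vec{v}_1$ (sign-fixed so its largest component
is positive, which points it toward net anodic-first for cells with
positive weights) divides the spike-eliciting stimuli by the sign of
their projection; zero projections count as positive (measure zero for
continuous stimuli). The two subset means are $\vec{w}^+$ and
$\vec{w}^-$ — polarity-resolved spike-triggered averages. Their Pearson
correlation over operational electrodes is near $-1$ when the same
electrodes drive the cell under both polarities; a side with no spikes
(a cell driven by one polarity only) is flagged absent and contributes 0
at prediction time.

Electrode significance follows the RMS rule: for every first-iteration
shuffle, $\vec{w}^\pm$ is recomputed from that shuffle's spike-triggered
stimuli split on that shuffle's own first eigenvector; an electrode is
significant when its true weight exceeds the per-electrode RMS of these
null fields. Because a null ERF is the mean of a half-space-selected
Gaussian sample ($\approx \sigma\sqrt{2/\pi}$ spread over a random
direction), the bound is far above the estimation noise of genuinely
silent electrodes, and concentrated true supports are recovered exactly.
The flip side, worth knowing: for a cell whose spiking is *independent*
of the stimulus, the observed ERF is itself a draw from the null
distribution, so this rule flags electrodes at its chance level (about a
third of them, scattered); the subspace significance test — which
reports no significant components in that situation — is the gatekeeper,
not the RMS rule.

The spatial extent $D^\pm$ is the weighted mean cell-to-electrode
distance. Signed weights can make the ratio negative or unstable, so the
weights enter in absolute value: $D$ is a spatial spread, by
interpretation.

### The nonlinearity (`bin_projections`, `fit_double_sigmoid`)

All stimuli are projected onto the unit-normalized ERFs, so thresholds
are in $\mu A$ and comparable across cells. One orientation convention
matters: the cathodic projection axis is the *negated* unit $\vec{w}^-$.
Since $\vec{w}^-$ itself points cathodic (negative entries), a literal
projection onto it would give net-cathodic stimuli positive coordinates;
negating the axis puts them at negative values so the fitted cathodic
threshold $c_-$ comes out negative, matching the reported convention
($c_+ > 0 > c_-$, magnitudes typically 50–450 $\mu A$).

Each polarity side is segmented into 15 bins containing equal numbers of
spike-eliciting stimuli (quantile edges of the spike projections), and
the bin probability is spikes / all stimuli in the bin. Equal-spike
binning concentrates bins where the data are, at the cost of wide outer
bins. The sigmoids

$$N^+(x) = \frac{a_+}{1 + e^{-b_+(x - c_+)}}, \qquad
  N^-(x) = a_- - \frac{a_-}{1 + e^{-b_-(x - c_-)}}$$

are fitted per side by Levenberg–Marquardt least squares with bounds
$a \in (0, 1]$, $b > 0$ (which enforces monotonicity), initialization
$a = \max p$, $c$ = bin center nearest $a/2$, $b = 4a/\text{span}$, and a
5-point multi-start over $b$; $r^2$ is computed jointly over all bins.
The two sides never share parameters, so per-side fitting is exact, not
an approximation. At prediction time both terms are evaluated for every
stimulus as the model equation is written (the off-side term sits near
its floor); a `piecewise` mode that zeroes the off-side term is available
for comparison.

### Validation (`split_data`, `validation_error`)

The split is 80/20 at the *distinct stimulus* level so that repeated
presentations of one stimulus never straddle the split (repeats are
statistically dependent). Held-out presentations are binned by predicted
probability into $B = 10$ equal-width bins on $[0, 1]$; the error is the
RMS difference between mean predicted and empirical probability over
non-empty bins (empty bins are omitted and counted). This is a
*calibration* error: it asks whether predicted probabilities are honest,
not whether the model discriminates. Two consequences follow. First, with
moderate test sets the sparsely populated high-probability bins dominate
the error's sampling noise. Second, any model whose nonlinearity is
estimated by binned empirical probabilities on its own projection axis is
self-calibrated in the large-sample limit — so a 2-D model can only beat
a 1-D model on this metric when the 1-D parametric fit is miscalibrated,
which is why mostly "little improvement" is seen from the second
dimension even when genuine suppressive structure exists (the package's
suppressive-axis tests therefore check the recovered 2-D surface
directly).

### The 2-D surface (`fit_2d`)

The joint nonlinearity over two significant axes is a 2-D histogram on an
equal-width grid (default $15 \times 15$) with cells under `min_count`
(default 20) training stimuli flagged unsupported. Predictions
interpolate bilinearly between supported cell centers — bilinear rather
than a global cubic spline because it reproduces the binned value exactly
at grid nodes and degrades gracefully around holes in the support.
Queries outside the supported region return `NA` and are omitted from
validation, mirroring the omission of under-sampled regions. The
estimator carries a small positive bias in calibration error from surface
curvature across a cell's width; it shrinks with grid resolution but at
the price of per-cell noise.

### Efficient stimulation (`make_strategies`, `compare_strategies`)

With identical electrode geometries, fixed power equals fixed Euclidean
norm of the stimulus vector. The threshold of a unit direction $\vec{u}$
is the scale at which $N^+$ reaches half its saturation:
$t = c_+ / (\vec{u} \cdot \hat{w}^+)$ — analytic, with a bisection solver
as cross-check. By Cauchy–Schwarz no unit direction projects onto
$\hat{w}^+$ more than $\hat{w}^+$ itself, so ERF-proportional stimulation
never needs more power than the best naive strategy (equal positive
amplitudes on the $k \leq 3$ electrodes nearest the cell; distance ties
break by electrode index; a signed naive variant matching ERF signs is
not provided since naive means polarity-uninformed). The interesting
quantity is the ratio, typically 0.7–1.0 depending on how concentrated
the ERF is.

### Morphology (`stratification_depth`, `classify_cell`)

Dendritic stratification depth within the inner plexiform layer is
$s(x) = 100\,(L_s - x)/(L_s - L_e)$, with strata found by the same 1-D
k-means/silhouette machinery as the latency clustering. Classification:
OFF if all strata $\leq 40\%$, ON if all $\geq 60\%$, ON-OFF if both
bands are hit, otherwise unclassified.

## The synthetic cell

`make_cell()` builds a ground-truth LN cell on the default 20-electrode
array (staggered grid, 1 mm vertical pitch, 400 µm discs, ~3.5 × 3.5 mm):
positive weight on the 1–3 electrodes nearest the soma with
exponentially distance-decaying magnitudes (space constant 1 mm, 10 %
seed jitter), polarity-symmetric by default
($\vec{w}^- = -\vec{w}^+$), sigmoid $a = 0.9$, $b = 0.03/\mu A$,
$c_+ = 150\,\mu A$, $c_- = -150\,\mu A$ (thresholds mid-range of those
recovered from real cells), short latencies $1.75 \pm 0.35$ ms and long
latencies $11 \pm 2.6$ ms (population means of directly and synaptically
activated responses). `simulate_responses()` draws one Bernoulli response
per presentation from the model probability; long-latency responses are
phenomenological (independent Bernoulli with their own latency
distribution) — enough to exercise latency clustering and re-running the
pipeline on long-latency labels, not a model of retinal network dynamics.
An optional suppressive axis multiplies the probability by
$(1 - s) + s\,e^{-x_2^2/2\tau^2}$, suppressing stimuli far from zero
along a second direction and producing a genuinely 2-D cell with a
low-side eigenvalue. An asymmetric-threshold mode
($c_- \neq -c_+$) exists to probe the estimator under mis-specification.

What the simulator does *not* emulate: temporal interactions between
pulses (presentations are exchangeable; the 10 Hz independence assumption
is baked in), electrode-to-tissue biophysics, spike-history effects,
drifting excitability over hours, and correlated network noise. Passing
recovery tests therefore demonstrates the estimator is correct under its
own assumptions — not that those assumptions hold in tissue.

## Study conditions used by the tests and acceptance script

Chosen once, as the package's canonical synthetic study: 25 cells (50 for
the specificity/sensitivity checks at $n = 5000$), each with 6000
presentations at that cell's calibrated $\sigma$, 1000 shuffles, 80/20
split, $B = 10$, 15 bins per polarity side. Under these conditions the
pipeline recovers $\cos(\hat{w}^+, w^+_{true}) \approx 0.99$, thresholds
within a few percent, the exact significant-electrode set, ERF
correlations near $-0.98$, $G \approx 6$, and held-out calibration errors
with a 95th percentile just under the worst error observed in real
cells (11.7 %). Smaller problem sizes are used in unit tests where only
correctness, not statistical power, is at stake.

## Known limitations

* The additive two-sigmoid predictor evaluates both terms everywhere; far
  along one axis the off-side floor adds up to
  $N^-(0) \approx a_-/(1+e^{-b_- c_-})$, a small constant. The
  `piecewise` mode removes it at the cost of a discontinuity at the
  polarity boundary.
* The time-shift null assumes presentation-exchangeable responses; slow
  drift in excitability would widen the true null beyond it.
* Equal-spike binning needs tens of spikes per side; cells driven by one
  polarity only yield a single-sided model (handled, with the absent side
  contributing zero).
* The RMS electrode rule is conditional on the subspace test having found
  a significant component (see above).
* $G$ is reported as `Inf` for the degenerate case where every remaining
  eigenvalue equals the null mean (never observed off toy inputs).
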