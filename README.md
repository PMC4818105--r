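# elstim

Linear–nonlinear models of single-neuron responses to concurrent
multi-electrode electrical stimulation.

Neural prostheses (retinal, cochlear, cortical) usually stimulate one
electrode at a time because the combinatorics of multi-electrode
stimulation are intractable to explore psychophysically. `elstim` takes
the system-identification route instead: stimulate **all** electrodes
simultaneously with Gaussian white-noise current pulses, record a cell's
spikes, and fit a model that predicts the spike probability for *any*
stimulation pattern. It is aimed at electrophysiologists and
neuroprosthesis engineers characterizing electrical receptive fields, and
ships with a ground-truth simulator so every estimation stage is testable
by parameter recovery.

## The model

A stimulus is a vector **S**ₜ of signed pulse amplitudes in µA, one per
electrode (positive = anodic-first). The spike probability is

    P(spike | Sₜ) = N⁺(w⁺ · Sₜ) + N⁻(w⁻ · Sₜ) + p₀

where **w⁺**, **w⁻** are the *electrical receptive fields* (ERFs) for net
anodic-first and net cathodic-first stimulation — the per-electrode weight
vectors saying which electrodes drive the cell — and N± are saturating
sigmoids with amplitude a±, gain b± (1/µA) and half-saturation thresholds
c± (µA):

    N⁺(x) = a⁺ / (1 + exp(−b⁺ (x − c⁺)))
    N⁻(x) = a⁻ − a⁻ / (1 + exp(−b⁻ (x − c⁻)))

The significant stimulus subspace is found by spike-triggered covariance:
eigenvalues of cov(S_D) (the spike-eliciting stimuli) are tested against a
null built by circularly time-shifting the response vector 1000 times,
with iterative deflation of significant axes. Splitting the
spike-triggered stimuli by the sign of their projection on the first
principal axis gives w⁺ and w⁻; equal-spike binning of the projections
and nonlinear least squares give N±. Model quality is the binned
calibration error (E^RMS, B = 10 equal-width probability bins) on a
held-out 20 % of distinct stimuli. A strength ratio G compares the first
eigenvalue's separation from the shuffle-null mean with the next most
significant one: G ≫ 1 means electrode interactions are effectively
linear. Finally, at fixed stimulation power (fixed vector norm),
stimulating proportionally to w⁺ never needs more current than equal
amplitudes on the 1–3 electrodes nearest the cell — the threshold ratio
quantifies the saving.

## Worked example

Simulate a ground-truth cell on the default 20-electrode array, calibrate
the noise amplitude, record 6000 presentations, and fit the full model:

```r
library(elstim)

cell <- make_cell(seed = 1)                      # truth: 3 electrodes, c+ = 150 uA
cal  <- simulate_calibration(cell, seed = 2)
calib <- calibrate_sigma(cal$sigma_grid, cal$response_prob)
calib
#> Sigma calibration: chosen sigma = 104.0 uA
#>   fitted max = 0.335, gain = 0.0270 /uA, mid = 104.0 uA

ens <- sample_white_noise(6000, 20, calib$chosen_sigma, seed = 3)
rec <- simulate_responses(cell, ens, seed = 4)
res <- run_pipeline(ens, rec$responses, config = list(fit_2d = FALSE))
res
#> Pipeline result
#>   significant components: 1 excitatory, 1 suppressive (G = 5.18)
#>   nonlinearity r2 = 0.969; validation E_RMS = 0.0843
res$erf
#> Electrical receptive field pair
#>   w+: 433 spike-eliciting stimuli, significant electrodes: 11 12 15
#>   w-: 425 spike-eliciting stimuli, significant electrodes: 11 12 15
#>   corr(w+, w-) = -0.977
```

Reading the output: the subspace test found one dominant excitatory
component (G = 5.2, so the cell is essentially one-dimensional — electrode
interactions linear), the RMS electrode test recovered exactly the three
electrodes that truly drive the cell (11, 12, 15), the anodic and cathodic
receptive fields are near-mirror images (corr −0.98), the double-sigmoid
fit explains 97 % of the binned probability variance, and held-out
predictions are calibrated to within 8.4 % RMS.

The fitted model then quantifies stimulation efficiency at fixed power:

```r
st <- make_strategies(res$erf, cell$array$positions, cell$position)
compare_strategies(res$model, st)
#> Fixed-power threshold comparison
#>   naive-1    228.99 uA
#>   naive-2    193.13 uA
#>   naive-3    161.08 uA
#>   erf        157.84 uA
#>   ratio erf / best naive (naive-3) = 0.980
```

ERF-proportional stimulation reaches half-saturation at 158 µA versus
161 µA for the best equal-amplitude strategy — a guaranteed saving
(ratio ≤ 1 always, by Cauchy–Schwarz), small here because this cell's
ERF is close to the three nearest electrodes.

A thin command-line wrapper is installed at `inst/cli/elstim.R`
(`simulate` and `run` subcommands) for shell pipelines; `write_dataset()`
/ `read_dataset()` define the on-disk CSV + JSON format.

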