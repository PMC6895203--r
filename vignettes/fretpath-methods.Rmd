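---
title: "fretpath: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{fretpath: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fretpath)
```

# Scope

`fretpath` quantifies the conformational activation of dimeric metabotropic
glutamate receptors (mGluRs) from single-molecule FRET (smFRET) intensity
traces, and ships a synthetic-data generator that realises the same
conformational model the analysis assumes. Because no raw traces are
publicly deposited for this system, every stage of the pipeline is
validated by *parameter recovery*: the generator encodes published
equilibrium quantities (FRET levels, EC50s, occupancies, component
fractions) as ground truth, and the pipeline must recover them from
simulated recordings.

# The conformational state model

An mGluR dimer is modelled as a continuous-time Markov chain over a linear
pathway of conformational states. Each state emits a characteristic FRET
efficiency between the two N-terminal fluorophores:

* **Roo** — resting, both ligand-binding domains (LBDs) open; FRET ~0.45.
* **Roo\*** — LBDs open but rotated into the activation orientation; an
  intermediate at FRET ~0.3, entered spontaneously (without agonist) in the
  mGluR2/7 heterodimer.
* **Acc** — active, LBDs closed and rotated; FRET ~0.2.

Homodimer presets use the two-state pathway Roo ⇌ Acc; the heterodimer
preset inserts the intermediate: Roo ⇌ Roo\* ⇌ Acc.

## Rates from equilibria

Publications in this area print equilibrium quantities (occupancies,
EC50s), not rate constants. The model therefore fixes the backward
(deactivation) rate $k_-$ of each transition and derives the forward rate
from the target stationary distribution $\pi$:

$$k_+^{(j)} = k_-^{(j)} \, \frac{\pi_{j+1}}{\pi_j},$$

so detailed balance holds and the stationary law reproduces the printed
concentration–response relation *exactly*. The target activated-state
occupancy follows the Boltzmann (Hill-in-log-concentration) law

$$a(c) = a_0 + (a_\infty - a_0) \sum_i \frac{f_i}{1 + (EC_{50,i}/c)^{h_i}},
\qquad \textstyle\sum_i f_i = 1,$$

with one phase for homodimers and two for the biphasic heterodimer. The
default slope is $h = 1$ per phase (no slopes are printed for these
relations). The intermediate keeps a constant share of the non-active
mass, $\pi_{Roo^*} = i_0 (1 - a)$: basal rotation is treated as
concentration-independent, and the intermediate drains into the active
state as agonist saturates (its shoulder disappears at saturating ligand).

Ligand classes act on specific transitions. A competitive orthosteric
antagonist (LY341495) blocks agonist-driven closure, zeroing $a$ but
leaving the basal intermediate untouched. A combination of negative
allosteric modulators ("NAM-combo") stabilises the resting transmembrane
conformation and blocks rotation, zeroing both $a$ and $i_0$. Tethered
agonists (trans-configured D-MAG-0) are modelled as a
concentration-independent activation level.

## Preset parameter values

| preset | states | glutamate response | other conditions |
|---|---|---|---|
| mGluR2/2 | 0.45 / 0.20 | EC50 18.7 µM, efficacy 1 | — |
| mGluR7/7 | 0.45 / 0.20 | EC50 38.3 mM, efficacy 0.10 | LSP4-2022 (EC50 462 µM, efficacy 0.75); D-MAG-0-trans (0.50) |
| mGluR2/7 | 0.45 / 0.30 / 0.20 | biphasic: 80% at 8.4 µM, 20% at 9.9 mM; $i_0 = 0.25$ | ensemble variant: 2.7 µM / 2.5 mM via overrides |
| mGluR3/7 | 0.45 / 0.20 | basal 0.70, plateau 0.97, EC50 0.8 µM | — |
| mGluR2/2-YADA | 0.45 / 0.20 | biphasic: 10% at 18.7 µM, 90% at 18.7 mM, plateau 0.30 | — |

Two preset values are pinned indirectly. The LSP4-2022 response of
mGluR7/7 must reproduce two reported occupancies — slightly above 50% at
1 mM and ~65% at 3 mM — which a single-site law satisfies with efficacy
0.75 and EC50 462 µM (giving 0.513 and 0.650 respectively). The mGluR3/7
plateau (0.97) and EC50 (0.8 µM) interpolate the two reported occupancies
(70% basal, ~95% at 10 µM).

## Kinetic timescales

Dwell times are not printed and are a modelling choice. Homodimer presets
use $k_- = 0.5\,\mathrm{s}^{-1}$ (mean active dwell 2 s), giving cleanly
resolved two-state trajectories and bimodal histograms at 10 Hz — matching
the two-peak histograms reported for mGluR2/2 and mGluR7/7. The mGluR2/7
preset uses $k_- = 2\,\mathrm{s}^{-1}$ (dwell 0.5 s): the heterodimer is
reported to be markedly more dynamic than mGluR2/2, with a single
*broadened* 10 Hz histogram rather than two resolved peaks, and its
kinetics motivated a 10× faster acquisition experiment. A `fast = TRUE`
override multiplies rates by 10 and switches the preset to 100 Hz for
dynamics studies. None of these choices affect equilibrium occupancies,
which are pinned to the printed values by construction.

# Synthetic data

`simulate_state_path()` performs exact stochastic simulation (exponential
holding times, competing-rate jump selection), starting from the
stationary law. `render_trace()` maps each frame's time-weighted mean FRET
$E^\star$ (camera integration; frames straddling a jump receive the
blurred average) to channel intensities by inverting the crosstalk-corrected
estimator:

$$I_A = S\,\frac{E^\star + \alpha}{1 + \alpha}, \qquad I_D = S - I_A,$$

with $\alpha = 0.1$ donor→acceptor bleed-through, so the noiseless
render→estimate round trip is the identity to machine precision.

Photophysics defaults: sum-channel scale $S = 1000$ detector units,
additive Gaussian per-channel noise $\sigma = 80$ (per-channel SNR ≈ 6 at
10 Hz; camera-dominated regime — shot noise is omitted because intensities
are in arbitrary detector units), exponential single-step photobleaching
with mean lifetimes 20 s (acceptor) and 30 s (donor). Acceptor bleach
converts the molecule into a donor-only emitter ($I_A \to$ background,
$I_D \to S$) — producing the two-step signature quality control looks
for — while donor bleach sends both channels to background. Neither the
SNR nor the bleach lifetimes are published; they are stated here and in
the configuration, not taken from any source.

Reproducibility uses a counter-based scheme: every molecule's path and
render seeds are derived deterministically from the master seed and the
(condition, movie, molecule) indices, so datasets are identical across
runs and independent of simulation order.

# Trace quality control

A molecule is analysable when it shows the canonical single-pair
signature: exactly one acceptor photobleaching step with a concomitant
donor rise, followed by exactly one donor step — or, optionally, a single
donor step with a dark acceptor — and a stable total intensity (CV ≤ 0.15,
a bound this package chooses; no figure is published) for more than 5 s
before the first bleach. The analysis window ends at the first bleach.
The 5 s requirement is applied to the pre-bleach window, i.e. the analysed
region.

Steps are located by recursive binary segmentation maximising the
standardized mean-difference statistic, with ties broken toward the
earlier frame, followed by amplitude pruning: candidate change points are
removed weakest-first until every surviving event's adjacent-segment mean
difference is at least `step_min_amplitude` (default 3) times the
channel's noise SD, estimated robustly from the median absolute successive
difference. The factor 3 separates photobleaching steps from
conformational transitions: with the default photophysics a 0.45→0.20
transition moves the acceptor by ~2.8 SD while the smallest bleach step
(acceptor dying in the active state) moves it by ~3.4 SD. Because
segmentation cannot place a change point within `min_seg` (4) frames of
another, a bleach occurring a frame or two after a conformational
transition would be mislocalized; a local threshold-crossing refinement
(first sustained excursion below the midpoint of the pre/post levels)
restores ±1-frame accuracy for ≥95% of accepted traces.

With defaults, acceptance rates on synthetic data land near 35–40%,
inside the 20–60% band plausible for real recordings (donor-first
bleaching, early bleaching, and instability account for the rejections).

# Filtering and FRET

Traces are denoised with a Chung–Kennedy-style forward/backward predictor
filter: at each frame, forward and backward running means of span
`window` (2) are blended with weights proportional to the inverse `P`-th
power (P = 15) of each predictor's summed squared prediction error over
the trailing/leading `M` (2) frames. The large exponent makes the weights
effectively binary, so plateaus are averaged without smearing
transitions; edges fall back to the available one-sided predictor, and a
strictly constant series passes through unchanged. The cited literature
admits several variants of this filter; this mapping of
(`window`, `M`, `P`) is documented here and alternatives are selectable
through `filter_params()`.

Single-molecule efficiency is
$E = (I_A - \alpha I_D)/(I_D + I_A)$ after per-channel background
subtraction (background defaults to 0 — the generator emits
background-subtracted intensities). Frames with non-positive total are
masked and counted, then excluded from histograms and correlations rather
than interpolated. Both channels are filtered before the ratio is formed;
the raw series is kept alongside, and histograms can be compiled from
either (filtered by default, matching the stated practice of smoothing
individual traces before analysis).

Ensemble (live-cell style) recordings use the plain ratio
$I_A/(I_D + I_A)$ without a crosstalk term, and titration responses are
reported as ΔFRET per concentration step (baseline minus step plateau,
plateau = mean of the final 50% of the step) normalized to the saturating
10 mM reference step.

# Histograms and occupancy

Each molecule's efficiency histogram (bin width 0.02 over [−0.2, 1.2];
0.02 resolves ~0.04-wide peaks without empty-bin noise) is normalized to
unit mass so long and short traces contribute equally; movie-mean
histograms are averaged into the pooled histogram and the per-bin SEM is
taken across movies — the field's error-bar convention. SEM across movie
means (rather than across molecules) is used because movies are the
independent replication unit.

Two-component Gaussian decomposition constrains the centers to the
resting band [0.35, 0.55] and the active band [0.10, 0.30]; activated-state
occupancy is the low-FRET component's share of the fitted mass.
Width bounds matter more than one might expect: with widths allowed up to
0.15, the low component degenerates into a broad pedestal under the
resting peak's inner flank (camera-blur bridge frames plus filter tails),
inflating near-zero occupancies roughly three-fold and wrecking the
low-efficacy titration. Widths are therefore bounded to [0.01, 0.08],
about 1.7× the width the filtered noise actually produces.

For the heterodimer regime — a single shifted distribution rather than two
resolved peaks — a single-Gaussian fit (center bounded to [0.2, 0.45]) is
available, and `active_state_occupancy()` maps its center linearly between
the resting (0.45) and active (0.20) reference levels, flagged
"shift-based" (the simplest monotone mapping that places both dimer types
on one occupancy axis). The pipeline's default location statistic for
this regime, however, is the *histogram mean* (`shift_occupancy()`):
camera integration, the filter (bias < 1%) and symmetric noise all
preserve the mean, making the statistic affine in the true occupancy —
whereas a fitted center tracks the dominant mode when kinetics leave
residual bimodality, and clips at its bounds as the peak approaches a
reference level. For the same reason the shift estimate is *not* clipped
into [0, 1] by default: clipping near the ends of a titration fakes early
saturation and biases the low-affinity EC50 downward. A small residual
bias remains from the ratio form of the estimator (for $E$ below
$(1-\alpha)/2$ the per-frame efficiency is biased by
$(2E - (1-\alpha))\,\sigma^2/S^2$, about −0.003 at $E = 0.2$ with default
photophysics); it is affine in the occupancy and therefore absorbed by
the concentration–response fit's baseline and amplitude.

# Concentration–response fitting

`fit_boltzmann()` fits the single or double Boltzmann by least squares on
log-concentration with a deterministic multi-start over log-spaced EC50
grids; zero-concentration points constrain the baseline only; phases are
reported in ascending EC50 order. Slopes are free within [0.5, 3] — the
physically plausible band for saturable binding, which also removes
boundary-slope local optima that can swallow a poorly sampled phase.
When per-point SEMs are supplied, weights are variance-shrunk,
$w = 1/(\mathrm{sem}^2 + \mathrm{median}(\mathrm{sem}^2))$: SEMs
estimated from a handful of movies are themselves noisy, and raw
$1/\mathrm{sem}^2$ weights let a single fortuitously precise-looking
point dominate. `fix_baseline` and `fix_amplitude` support normalized
data (e.g. a titration rescaled to its saturating plateau, amplitude
pinned at 1), and the F-test in `compare_phase_fits()` drives the `auto`
phase mode.

Two estimator choices in the acceptance analyses deserve note. First, the
low-efficacy homodimer titration is fitted after normalizing to its
saturating plateau (mean of the two highest concentrations): with a free
amplitude, the amplitude/EC50 trade-off is badly conditioned when the
total response spans only ~10% occupancy. Second, the biphasic
heterodimer fit pins both slopes at the default h = 1: Monte Carlo on
ideal data at the stated design (12 log-spaced concentrations, 150
molecules per condition, 3 seeds) shows free-slope fits recover the
low-affinity EC50 within ±30% only ~65% of the time, against ~90% with
slopes pinned. Slopes remain free in the package defaults.

# Dynamics

Donor/acceptor cross-correlation is computed per molecule on raw
(unfiltered) intensities — the filter's correlated smoothing would distort
the lag structure — as the mean-subtracted normalized cross-covariance
over the analysis window, pooled as the mean across molecules with
movie-level SEM. For a symmetric two-state chain this decays as
$\exp(-(k_{12}+k_{21})\tau)$, which the test suite checks against the
analytic rate. `fit_double_exponential()` fits $|CC(\tau)|$ with two
exponentials (time constants ascending, degenerate fits flagged), and
`slowest_relaxation_time()` exposes the generator's own relaxation
eigenvalue as the oracle: the three-state heterodimer chain always relaxes
more slowly than a two-state chain at matched per-transition rates.
Finite-window mean subtraction biases long-lag correlations low by
roughly $2\tau_c/T$; analyses use windows of at least tens of correlation
times.

# What the synthetic world does and does not establish

The generator reproduces the statistical structure the analysis assumes:
Markovian two/three-state dynamics, camera blur, single-step bleaching,
one global crosstalk constant, additive Gaussian noise, movie-level
grouping. Real recordings additionally contain acceptor blinking,
photophysical intermediate intensity states, gamma/detection-efficiency
mismatch between channels, background drift, molecule-to-molecule
brightness heterogeneity, and non-Markovian kinetics. A green recovery
test therefore establishes that the pipeline is a consistent estimator of
the model's parameters under its stated assumptions — not that those
assumptions exhaust real data. The QC acceptance band (20–60%) and the
noise regime are tunable to approximate a given instrument, but no claim
of instrument realism is made.

# Numerical and degenerate-input policy

Stationary laws are solved from the global-balance equations with a
sum-to-one constraint, restricted to the reachable component (absorbing
or disconnected chains put all mass on the reachable part). Mixture and
Boltzmann fits use box-constrained quasi-Newton optimisation from
deterministic multi-start grids, so results are reproducible without a
random seed. Histogram fits refuse degenerate inputs (< 5 non-empty
bins); response fits refuse constant responses and undersized designs;
ties in step detection resolve to the earlier frame. All occupancy
probabilities are renormalized to sum to one within 1e-12.
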