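---
title: "Probing seizure resilience and neural excitability with epiprobe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probing seizure resilience and neural excitability with epiprobe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 3.5)
library(epiprobe)
```

## The scientific problem

Seizures can be understood as a critical transition in a bistable neural
circuit: a non-ictal and an ictal regime coexist, separated by a barrier
whose height depends on a slowly varying excitability parameter. As
excitability rises the system approaches a fold (saddle-node) bifurcation;
resilience — the size of the perturbation needed to push the circuit into
the ictal regime — shrinks, recovery from small perturbations slows, and
eventually the barrier vanishes and seizures start unprovoked. `epiprobe`
implements the computational side of this programme: a stochastic Epileptor
neural-mass simulator with stimulation protocols, active probing metrics
(evoked-response line length, input–output curves, rheobase,
time-to-seizure), passive critical-slowing signatures, non-negative matrix
factorization of multi-channel responses into responsive sub-networks,
bootstrap effect-size estimation, and permutation-tested decoding of
excitability levels — together with a synthetic multi-channel iEEG
generator so every stage is testable without recorded data.

## The Epileptor model

The Epileptor couples three subsystems through six state variables. A fast
pair (`x1`, `y1`) produces ictal discharges; a slower pair (`x2`, `y2`)
produces spike-wave activity; a very slow permittivity variable `z`
controls the switch between regimes; and an auxiliary variable `g`
realises the exponentially weighted integral of `x1` that feeds the
spike-wave subsystem,

$$\dot g = x_1 - \gamma g,$$

which is the standard state-space realisation of a convolution with an
exponential kernel (the literature prints the kernel integral with
ambiguous bounds; the filter form is our interpretation and is exact for
the intended exponentially weighted memory). The fast nonlinearity
switches branch at $x_1 = 0$, the spike-wave nonlinearity at
$x_2 = -0.25$. Parameters follow the published setting:
$\tau_0 = 20000$, $\tau_2 = 10$, $I_1 = 3.1$, $I_2 = 0.45$,
$\gamma = 0.01$, with the excitability (epileptogenicity) parameter $x_0$
as the control knob: $-2.25$ is the non-ictal baseline, $-2.20$ a raised
("PTZ-like") and $-2.30$ a lowered ("BZD-like") level, while $-2.0$ is an
epileptogenic state with spontaneous recurrent seizures. The
fast-subsystem offset $y_0$ is not part of the published parameter table;
we use the value 1 from the original Epileptor formulation (configurable).

**Fixed points.** With $x_1 < 0$ the fast subsystem decouples from the
spike-wave pair, so the equilibrium reduces to two cubics that
`find_fixed_point()` solves with `polyroot()`. Two details matter. First,
the non-ictal branch requires $x_1 < -4/3$ (below the knee of the fold);
the knee gives the critical excitability $x_0^{c} \approx -2.06$, which is
why $x_0 = -2.0$ has no stable non-ictal equilibrium and produces
recurrent seizures. Second, the spike-wave cubic has three equilibria — an
unstable focus surrounded by a limit cycle, a saddle, and a stable node
near $x_2 \approx -0.78$. Only the node yields a fully stable fixed point
(all six Jacobian eigenvalues negative); simulations start there, so the
interictal background is quiescent with noise-driven excursions toward the
saddle — interictal-spike-like events whose rate grows with excitability.

```{r bifurcation}
bd <- bifurcation_diagram(epileptor_params(x0 = -2.25))
attr(bd, "fold")
```

**Integration.** Deterministic runs use classical RK4. One model time
unit corresponds to 10 ms of real time; internally the solver steps at
`dt = 0.1` (1 ms of real time) so that a 3 ms stimulation pulse occupies
three internal steps, and trajectories are returned on the 10 ms grid
(100 Hz). RK4 at `dt = 0.1` is comfortably inside the stability region of
the stiffest eigenvalue (about $-16.7$ per time unit); `dt = 1` would not
be. Stochastic runs add white Gaussian increments on `x1`, `x2`, `y2`
with variances 0.005, 1e-4, 1e-4 per unit model time (per-step SD
$\sqrt{\sigma^2\,dt}$). The default scheme applies the additive increment
after an RK4 drift step: for additive noise this is strong order 0.5, and
it collapses *exactly* onto the deterministic RK4 trajectory when the
variances are zero, which we use as a cross-check invariant. Stochastic
Heun (strong order 1.0 for additive noise) and Euler–Maruyama backends are
available for comparison; all three agree in stationary law at the default
step. A blow-up guard aborts if any state exceeds 1e6.

**Seizure detection.** The ictal branch of the fast nonlinearity is the
$x_1 \ge 0$ regime, so a sample is ictal when `x1 > 0`. Ictal discharges
oscillate around that threshold, so above-threshold runs separated by
gaps shorter than 2 s are merged, and the first merged run sustained for
at least 10 s (the experimenters' rule for a seizure) is reported.
Both the dwell and the gap tolerance are arguments, and tests scale them
down where appropriate.

**Stimulation.** Pulses add 2 to $I_1$ and 5 to $I_2$ (times an intensity
scale) for their 3 ms width. Under 20 Hz trains the fast subsystem creeps
along its slow manifold — each pulse leaves a small residue in `y1` — until
the trajectory clears the saddle: the time-to-seizure. The model behaves
as an integrator with a frequency threshold near 18 Hz: below it the
residue decays fully between pulses and trains never provoke, above it
time-to-seizure decreases with both excitability and frequency (the
package asserts the ordering on a 20/30/40 Hz grid).

## Passive critical-slowing signatures

Five statistics are computed on 4 s stimulation-free epochs: line length
(mean absolute first difference scaled to per-ms units), population
variance, adjusted Fisher–Pearson skewness, the width of the normalised
autocorrelation function at half maximum (first downward crossing of 0.5,
linearly interpolated between lags — interpolation is our choice, needed
for resolution when the half-width is a few samples), and the mean
pairwise Pearson correlation across channels. Passive epochs start at
least 4 s after the previous stimulation and end before the next one
("between two pulses"); requiring 4 s clearance on *both* sides would
leave no epochs at the 8–12 s inter-stimulus intervals used throughout,
so the trailing clearance defaults to zero (configurable).

One filtering convention deserves emphasis. The signature pipeline is
shared between 2 kHz in-vivo-like recordings and the 100 Hz simulation
proxy. Variance, skewness and autocorrelation are computed on epochs
band-passed with edges fixed in *normalised* frequency
(0.00025–0.05 cycles/sample — the 0.5–100 Hz band at 2 kHz), so the
filter acts identically per sample at every rate; line length is
deliberately computed on the wide-band signal, as in the evoked-response
pipeline where it is defined. Signals are demeaned before this narrow
band-pass: its lower edge is so low that a DC offset would otherwise leak
into short segments as an edge transient. With this convention the
simulated contrasts between excitability conditions fall in the published
in-silico range for all four univariate signatures; with a literal
0.5–100 Hz band at 100 Hz (a pure high-pass there), the autocorrelation
and skewness contrasts come out an order of magnitude larger than
published, so we regard the normalised-band convention as the faithful
reading of the shared pipeline.

The headline in-silico experiment (`run_insilico_signatures()`) simulates
790 four-second epochs per condition, computes the four univariate
signatures per epoch, and bootstraps the mean percent change of each
against baseline (percentile CI, 5000 resamples, resampling both groups
and normalising to the control mean). Lowered excitability decreases and
raised excitability increases every signature; variance is the most
sensitive, line length the least (sub-percent changes that sit near the
Monte-Carlo floor of the experiment — their sign at n = 790 is not stable
across random seeds, and the package reports whatever the seeded run
produces).

```{r fig4, eval = FALSE}
rs <- run_insilico_signatures(n_epochs = 790, seed = 1)
rs$contrasts
```

## Active probing metrics

The evoked response to a pulse is the line length of the first 250 ms
after onset (the stimulation artifact window having been interpolated).
`input_output_curve()` averages responses per intensity, normalises to a
reference, and integrates trapezoidally over the normalised intensity
axis: the IOC is 0 for no response at any intensity and 1 for maximal
response at minimal intensity. When conditions are compared, the
normalisation reference is shared across the block (the maximum mean
response over all sessions), so the IOC compares amplitudes rather than
curve shapes; a per-session maximum is available but cannot, by
construction, express a uniform amplitude change. The rheobase is the
smallest intensity whose mean response exceeds the baseline mean plus two
baseline SDs (the detectability rule is ours; none is published).
`run_insilico_probing()` also reproduces the ramp experiment: in the
epileptogenic regime, starting from an elevated (post-ictal-like)
permittivity $z = 4.2$, repeated maximal pulses every 8–12 s evoke
growing responses as $z$ decays toward the fold, until a seizure occurs —
the regression slope of response line length on time is positive before
the detected onset.

Condition contrasts are estimated with `bootstrap_difference()`:
percentile 95% CIs from 5000 resamples, paired, unpaired, or expressed as
percent of the control mean (the normalised-to-control convention).

## Network decomposition

Per-stimulation line-length responses of all channels are stacked into a
non-negative matrix `V` (channels x stimulations) and factorised as
`V ~ W H` by Lee–Seung multiplicative updates for the Frobenius
objective (1000 iterations maximum, relative-error tolerance 1e-6, best
of 20 seeded restarts; the per-iteration error is non-increasing, which
the tests assert on random instances). `W` columns are normalised to unit
sum so `H` carries amplitude; dead channels are removed before
factorisation and reinstated as zero weights. The published rank-selection
procedure is a "stability NMF" whose criterion is not spelled out; our
surrogate scores each candidate rank by the mean best-match cosine
similarity of `W` columns across restarts (greedy one-to-one pairing
against the lowest-error run) and returns the largest rank above a 0.95
threshold. The threshold is deliberately high: on planted benchmarks,
overfit ranks still reproduce across restarts with similarity around
0.85–0.92, while the planted rank scores essentially 1. Sub-networks whose
mean activation increases with stimulation intensity (one-sided Spearman
test at 0.05) are the responsive ones; each gets a network IOC by feeding
its mean `H` per intensity through the same IOC machinery. For single-site
mouse-like data a rank of 1 is configured directly.

## Decoding excitability

Three multinomial L2-regularised logistic classifiers (softmax link)
decode the excitability condition: *active* (raw multi-channel voltage of
the 250 ms post-pulse window, no feature extraction), *passive* (the five
signatures per channel on 4 s inter-pulse epochs), and *combined*.
Evaluation is stratified 5-fold cross-validation, grouped by session so
trials of one session never straddle the train/test split (grouping is
our default; a flag gives plain stratified folds). Features are z-scored
with training-fold statistics. The model is fitted with glmnet
(`alpha = 0`, fixed penalty `lambda = 1/(n * l2)` with `l2 = 1` — the
inverse-regularisation convention; the published strength is unstated).
Accuracy is the fraction of correctly labelled held-out trials, the
micro-average of `(TP + TN)/(TP + TN + FP + FN)` over one-vs-rest
confusions. Chance level is established by label permutation — at the
session level by default, respecting the grouping — with
`p = (C + 1)/(n_perm + 1)`; the p-value can never be 0.
`timepoint_decoding()` trains one classifier per peri-stimulus sample
and returns the accuracy trace with a per-timepoint permutation band;
on synthetic data the pre-stimulus baseline decodes at chance and the
evoked window above it.

## The synthetic-recordings generator

`generate_session()` emulates a mouse-like stimulation session: 12 depth
channels at 2 kHz, single pulses (or paired pulses, or trains) at 8–12 s
intervals with intensities on a 12-step grid, and per condition
(low/normal/high excitability) an evoked gain of 0.6/1/1.6 and an AR(1)
background with lag-1 autocorrelation 0.90/0.92/0.94. The AR innovation
SD is fixed (20 µV), so higher-autocorrelation conditions also carry
higher variance — the critical-slowing direction. The evoked template is
a difference-of-exponentials with two negative peaks over ~250 ms (CCEP
morphology), scaled by a saturating logistic map of intensity (anchored
to 0 at intensity 0 and 1 at 1, midpoint 0.4, slope 0.12); channels have
individual amplitude weights and propagation delays. Line noise (50 Hz,
common-mode) and a high-amplitude biphasic artifact exactly in the
−2..10 ms kriging window are added so preprocessing has ground truth to
remove. `generate_epileptor_backend_session()` instead mixes the
stochastic Epileptor proxy to channels (weight, delay, AR noise) at the
proxy's native 100 Hz, with real pulse dynamics and the condition label
derived from `x0`.

What the generator does *not* emulate: 1/f spectral structure, behavioural
state changes, electrode drift, spatially structured noise, and genuine
physiological variability across animals. Passing tests on synthetic data
therefore demonstrate the correctness and sensitivity of the analysis
chain under the stated generative assumptions, not performance on real
recordings.

## Preprocessing

Bipolar derivation subtracts neighbouring contacts of one lead (labels
like `A1-A2`), removing common-mode line noise (the tests assert a >10x
power reduction). Stimulation artifacts are replaced by a straight line
connecting the window edges plus Gaussian noise with the SD of the 50 ms
preceding the window; overlapping windows merge; no sample outside the
declared windows changes. Filtering is a zero-phase 4th-order Butterworth
band-pass (0.5–200 Hz human, 0.5–800 Hz mouse) plus zero-phase biquad
notches at the mains frequency and all harmonics below the band edge. The
notches use a constant absolute bandwidth across harmonics with Q = 60 at
the fundamental: a constant Q would widen to ~25 Hz at 750 Hz, and wider
notches make repeated filtering measurably lossy — with the chosen design
a second pipeline pass changes the RMS of band-limited data by well under
1%, while a pure 50 Hz tone is still attenuated by more than 40 dB.
Human-profile data are finally resampled to 500 Hz by polyphase rational
resampling with exact re-indexing of event onsets.

## Numerical choices and degenerate inputs

* Fixed points are found analytically (cubic roots), with a residual
  check at 1e-8 and a finite-difference Jacobian eigenvalue check.
* Skewness and autocorrelation error on constant epochs (zero variance);
  spatial correlation skips constant channels with a warning.
* The autocorrelation half-width returns `NA` when the function never
  drops below 0.5 within the lag window (long-memory epochs); such epochs
  are excluded from contrast averages.
* `detect_seizure()` is threshold + gap-merge + dwell; a brute-force scan
  oracle in the tests confirms the onset on epileptogenic runs.
* Bootstrap CIs are percentile (not BCa): simplest to verify, matching
  the estimation-statistics convention of reporting a mean difference
  with its resampling interval.
* All randomness flows from explicit seeds; pipeline stages derive their
  seeds from a master seed by a fixed counter scheme (`derive_seed()`),
  so any stage can be re-run in isolation and full runs are bit-identical.

## Problem sizes

The package's own experiments are sized for a desk machine: the
signature-contrast experiment runs the full 790 epochs x 3 conditions
(about 9.5 million internal integration steps) in seconds thanks to the
compiled core; the probing suite uses 12-intensity noise-free
dose-response curves, a 3x3 time-to-seizure grid and a 300–400 s ramp; the
decoding rehearsal defaults to 5 sessions x 3 conditions with 10–12 pulses
each and a reduced permutation count (24–30). The unit-test suite uses
smaller sessions throughout and reserves the full-scale settings for the
acceptance tests.

## Known limitations

* The published in-silico contrasts come with much tighter bootstrap CIs
  than this implementation produces at the same epoch count; our epoch
  statistics are heavy-tailed because rare spike excursions dominate
  them. Point estimates fall in the published range for all eight
  contrasts, but the two line-length contrasts (±0.3–0.8%) are smaller
  than the Monte-Carlo spread and their sign is seed-dependent.
* $y_0$, the exact stochastic integrator, and the stability-NMF criterion
  are unstated in the source material; our choices (documented above) are
  principled but not verifiable against it.
* The single-node Epileptor generates one common source; multi-channel
  structure comes entirely from the synthetic mixing model. No
  network-of-Epileptors coupling is implemented.
* No spectral (PSD/band-power) features are included among the passive
  signatures, by design.
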