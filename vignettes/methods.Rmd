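---
title: "Models and methods behind b2bikit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind b2bikit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

b2bikit implements the computational chain of a brain-to-brain interface
built on ultraflexible stimulating electrode arrays: steady-state visual
evoked potentials (SSVEPs) recorded from a human occipital montage are
decoded into one of eight two-mouse commands, each command is turned into a
charge-balanced biphasic stimulation train delivered to a mouse's secondary
motor cortex (M2), and the evoked turning is quantified from tracked
trajectories. A quasi-static field model compares how much current flexible
and rigid electrode geometries need to activate the same number of neurons.
This vignette documents the models, the tunable parameters, and the design
choices made where the published description leaves the design open.

## The eight-target code and the synthetic SSVEP generator

Targets are coded jointly by flicker frequency and phase: frequencies 8-15 Hz
in 1 Hz steps, phases cycling 0, pi/2, pi, 3*pi/2 twice, mapped in order to
the commands LL, RR, LR, RL, LX, RX, XL, XR (`target_table()`). The first
letter commands mouse 1, the second mouse 2; `L` means a left turn evoked by
stimulating the right M2, `R` a right turn via the left M2, `X` no
stimulation.

No public recordings accompany the study, so `synth_ssvep_trial()` generates
trials with the statistical structure the downstream analyses assume:

* **Harmonic stack.** The clean response at frequency $f$ and stimulus phase
  $\phi$ is $\sum_{k=1}^{K} a_k \sin(2\pi k f t + k\phi)$ with $K = 3$
  harmonics and $a_k = A/k$ by default. The $1/k$ roll-off is a standard
  shape for a periodic non-sinusoidal cortical response; the per-harmonic
  phase $k\phi$ is what a phase-shifted periodic stimulus produces. $A$
  defaults to 5 uV.
* **Channel mixing.** One all-positive gain vector (uniform on 0.5-1.5,
  drawn once per run) scales the waveform per channel: every occipital
  channel sees the SSVEP, at different amplitude. There is no
  volume-conduction head model and no biophysical source model.
* **Noise.** Per-channel independent noise, by default pink (1/f) plus white
  at equal band power, reflecting the approximately 1/f EEG background. The
  signal-to-noise ratio is defined as SSVEP power over noise power within
  4-100 Hz and the noise is rescaled so the realized ratio matches `snr_db`
  exactly per trial; the clean and noise components are stored alongside the
  trial so the calibration is checkable.
* **Determinism.** The seed fully determines a trial; dataset seeds are
  derived per trial from the master seed by a fixed affine map kept below
  $2^{31}$.

No SSVEP amplitudes or SNRs are reported for the real recordings, so
`snr_db` is a difficulty dial, not an estimate of the real recordings; the
default +10 dB makes the 8-class problem clearly learnable but not trivial.
Consequences for interpretation: passing decoder tests show the architecture
and training recipe can recover a joint frequency-phase code from realistic
noise, not that they would reach the published accuracies on real human EEG
(92.5-98.75%), which are irreproducible without the recordings.

## Preprocessing

The acquisition chain's filters are reproduced as second-order Butterworth
designs: band-stops at 48-52 Hz and 98-102 Hz (the union of the two
power-line descriptions in the source pipeline: a 48-52 Hz notch, and
suppression of 50 and 100 Hz; the superset is harmless for 4-100 Hz content)
followed by a 4-100 Hz band-pass. Filters are applied forward-backward by
default, because the decoder consumes waveform shape and the deployed
system's phase handling is unstated; a `causal` flag switches to single-pass
filtering. Edges are handled by odd-reflection padding, at least 250 samples
because narrow band-stops ring far longer than the classic
3 x (filter length) heuristic. `to_tensor()` stacks trials into the
`(batch, 1, channels, time)` tensor the decoder consumes.

## The dual-branch decoder

The decoder has two concurrent branches over each 1-s trial:

* **Time branch** - three blocks of (2-D convolution, batch norm, ReLU, max
  pool) on the raw waveform tensor. The first kernel spans the full channel
  axis (8 x 25, stride 2 in time), so temporal and inter-channel structure
  are processed jointly; later kernels are 1 x 11 over 8 feature maps, each
  block pooling by 4. A linear layer maps the flattened activations to a
  32-dimensional branch feature.
* **Frequency branch** - a Hann-window STFT per channel (window 250
  samples, hop 62: at least two cycles of the lowest 8 Hz target per window
  and 75% overlap; bins kept up to the 100 Hz band edge, giving a 26 x 13
  map), a 1 x 1 stem convolution projecting the 8 channels to 4 feature
  maps, then two residual blocks of dilated convolutions with the broad
  9 x 13 kernel at dilation 2 ("same" padding, identity skips), batch norm
  and ReLU throughout, and a linear layer to another 32 dimensions.
* The 64-dimensional concatenation of both branch features is the embedding
  inspected with t-SNE; dropout (rate 0.5) and a final fully connected layer
  produce the 8-class logits.

Layer counts and widths are not published; these defaults are the smallest
architecture that honors every named component (dual branches, 2-D
convolutions + max pooling + linear layers, STFT maps, residual blocks with
dilated 9 x 13 kernels, batch norm, dropout, one-hot output). With a 4 Hz
STFT bin spacing the frequency branch cannot separate neighboring 1 Hz
targets on its own; the time branch carries that discrimination, which is
the point of the dual design. The stride-2 first convolution and the 4-map
frequency branch keep a 100-epoch training run on one CPU within minutes;
both are exposed in `decoder_config()`.

Training follows the stated recipe: plain SGD, batch size 32, initial
learning rate 0.2, cosine annealing with warm restarts (initial period 50
epochs, period multiplier 2 - the restart schedule itself is unstated), 500
epochs by default (the workflow scripts use 100, which this synthetic task
does not need more of), shuffling every epoch, and additive white Gaussian
noise injected into a random 50% of each batch. The augmentation
perturbation is unstated beyond "random noise"; white noise at 10% of the
per-batch RMS is the default and both knobs are exposed. The loss is
cross-entropy against the one-hot target. All randomness (initialization,
shuffling, dropout, augmentation) derives from explicit seeds, so runs are
bit-reproducible; evaluation mode uses batch-norm running statistics and no
dropout, so prediction is deterministic.

The network and its training loop are implemented in-package (convolution
and pooling kernels in C++ via RcppArmadillo, batch normalization, dropout,
linear algebra and SGD in R) with every layer's backward pass verified
against numerical differentiation in the unit tests.

## Evaluation

`confusion()` builds the true-by-predicted count matrix with attached
accuracy; `behavior_confusion()` adds the observed-only "XX" column for
trials where neither mouse produced a valid turn. `sweep_parameter()`
re-trains from scratch at every grid point (no warm starts, mirroring the
independent optimizations of signal length, trial count and channel count)
and reports per-point dispersion over seeds; single-seed sweeps are flagged.
`tsne_embed()` is an exact (non-Barnes-Hut) t-SNE - perplexity 30 by
default, seeded and deterministic, with early exaggeration - implemented
in-package and adequate for the few hundred embeddings inspected here.

## Stimulation trains and accelerated aging

`make_biphasic_train()` renders the deployed waveform: cathodic-leading
biphasic pulses of 200 us cathodic phase, 100 us interphase gap, and 400 us
anodic phase at half the cathodic amplitude, repeated at 100 Hz. Charge
balance is exact by construction (200 us x I = 400 us x I/2) and the default
1 MHz output rate makes every phase width an integer sample count, so the
rendered train is charge balanced to floating-point precision; incompatible
output rates are rejected rather than rounded. Cathodic current is emitted
as negative by convention.

`accelerated_aging_equivalent()` implements the Q10 soak-test rule:
duration x Q10^((T_test - T_ref)/10), Q10 = 2 by ASTM convention (the
constant is not printed in the source description). Four weeks at 60 C
against 37 C gives 19.7, i.e. about 20 weeks.

## Behavior quantification

Trajectories are timestamped 2-D positions (mm) at 30 samples/s by default -
a video-tracking-like rate; the true rate is unstated. Heading comes from
the velocity direction `atan2(dy, dx)`, unwrapped so no step exceeds 180
degrees. Tracked position is the only observable, so heading is undefined
while the animal is stationary: steps shorter than 1 mm hold the previous
heading, and the stretch before the first movement adopts the first observed
heading retroactively (otherwise the first step out of stillness would count
as a spurious turn of up to 180 degrees). Counterclockwise (leftward)
turning is positive.

Per phase (before, during, after stimulation), `max_angular_change()`
returns the signed cumulative heading change of largest magnitude within the
phase - the peak excursion, matching the "maximum change" wording, with the
endpoint variant available. "Linear displacement" is accumulated path
length, not net displacement: the published near-stationary baselines (tens
of mm over a pre-stimulation phase) are consistent with accumulated path,
and path length better measures how much motion a stimulation evokes. A
valid turn requires |angle| strictly greater than 20 degrees ("exceeded
20"); otherwise the response is X. Phase comparisons use the classic
pooled-variance two-tailed unpaired Student's t-test (Welch by flag), with
the conventional star coding and a flagged p = 1 convention for the
degenerate all-equal case.

The trajectory generator drifts the heading at `turn_rate` (deg/s, sign from
the command letter) while the animal moves at `speed` during stimulation,
and produces a sub-threshold positional wander otherwise; `jitter` scales
heading noise and wander. Defaults (25 deg/s, 40 mm/s, 10 s phases) sit in
the range of the published per-bout angular displacements (~100-460 degrees
over a stimulation bout) and keep per-frame steps above the 1 mm heading
epsilon during locomotion. It emulates command-conditioned turning only - no
wall-following, rearing, grooming or arena geometry - so behavior-recovery
tests validate the displacement operators and the valid-turn rule, not a
behavioral model of real mice.

## Spike metrics

`p2p_amplitude()` is max - min of the waveform. The source reports SNR
values without defining the estimator, so `spike_snr()` uses peak-to-peak
amplitude over k x SD of a spike-free noise trace with k = 2 by default and
k attached to the result; reported numbers are interpretable only together
with k. `firing_rate()` bins counts (conserving the total), and
`rate_velocity_correlation()` is the Pearson correlation against
max-normalized velocity. Spike sorting itself is out of scope; a CSV shim
(`read_spike_csv()`) ingests externally sorted trains.

## The quasi-static field model

The electrode comparison solves $\nabla \cdot (\sigma \nabla V) = 0$ in a
3 mm tissue cube with brain conductivity 0.2 S/m and relative permittivity
88.9 (stored but unused: the solve is DC and the activation criterion is on
conduction current density). Electrodes are surfaces on the cube's floor
injecting constant total current as uniform current density: the flexible
and rigid arrays are eight 16 x 12 um rectangles in a single column at 30 um
pitch (the pitch reading of "30 um apart", consistent with 16 sites spanning
450 um on the fabricated shank); the microwire is a single 100 um disc,
conductive only at the tip. Rigid geometries are wrapped by a 40 um glial
scar at 0.166 S/m covering the electrode footprint dilated laterally by its
own thickness; the flexible array has none. Neurons are counted as
activatable where $|J| > 1000$ A/m^2, multiplying the supra-threshold
tissue volume by the neuron density; scar volume is excluded from tissue.
The density constant is kept as printed (135,801 m^-3) even though its units
produce fractional counts in a 3 mm domain - matched-current comparisons
divide it out entirely, which is why the acceptance quantities are currents,
not counts.

Discretization is a cell-centered finite-volume scheme on a graded
tensor-product grid: uniform 4 um cells (5 um for the microwire) around the
electrodes, geometric coarsening (ratio 1.4) to the boundary. All three
geometries are mirror-symmetric about x = 0 and y = 0, so one quarter of the
domain is solved with natural no-flux symmetry planes and volumes scaled by
4. Face conductances use distance-weighted harmonic means of the cell
conductivities; the far faces are grounded (V = 0), approximating a distant
return electrode, and the rest of the floor is insulating. The sparse SPD
system is factorized with a supernodal Cholesky (CHOLMOD). $|J| = \sigma
|\nabla V|$ is evaluated at cell centers by central differences, and the
threshold comparison is strict.

Choices the source leaves open, decided here: the grounded-far-face boundary
condition (absolute thresholds shift with this choice more than
flexible-vs-rigid ratios do); equal current per array site ("current" is the
per-site output, matching the parametric 1-100 uA electrode-output scan, and
the only reading consistent with the printed 62.5 uA microwire match); and
the single-column site layout. Verification gates the solver before any
comparison: the discrete solution conserves current to round-off globally
and within 2% through interior surfaces, scales linearly with injected
current, matches the closed-form on-axis current density of a uniform-flux
disc source within 10% for a bare microwire, and the matched currents move
by under 10% when the grid is refined by 25%.

Matching exploits linearity: one unit-current solve per geometry yields the
whole activation curve by rescaling the threshold, and
`matching_current()` bisects that monotone curve to 0.1 uA for the smallest
current whose count reaches the flexible array's count at 5 uA per site.
Activation is the threshold-on-|J| criterion only - no cable or
compartmental neuron models.

## Problem sizes and numerical conventions

The workflow scripts and tests run desk-scale configurations chosen as the
package's defaults: 640 training / 320 test trials and 100 training epochs
for the decoder; quarter-domain grids of roughly 100-150 thousand cells for
the field solves, with a 1.25x refinement used for the convergence check.
Ties in the classifier argmax resolve to the lowest class index; batch-norm
running statistics use momentum 0.1 and epsilon 1e-5; He initialization
throughout; the t-SNE layout uses learning rate 200 with early exaggeration
for the first 100 iterations. Degenerate inputs error early and explicitly
(empty windows, non-monotone time stamps, bands outside Nyquist, pool sizes
that empty a branch, unrepresentable stimulation phase widths).

## Known limitations

* Synthetic EEG has no artifacts, eye blinks, alpha background or
  inter-subject variability; decoder bars on it are property checks, not
  accuracy claims about real recordings.
* The field model's absolute activated volumes depend on the open boundary
  and layout choices above; only matched-current ratios are compared against
  the published values, and at the stated 25% tolerance.
* Trajectories idealize turning; displacement magnitudes are not calibrated
  to specific animals.
* Real-time operation (streaming inference, stimulator I/O) is out of
  scope throughout.
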