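---
title: "Estimating lower-limb sagittal joint angles from foot acceleration and angular-velocity norms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating lower-limb sagittal joint angles from foot acceleration and angular-velocity norms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The estimation problem

Hip, knee, and ankle sagittal angles over a gait cycle are the quantities a
gait laboratory reports and a clinician reads. A shoe-mounted inertial
sensor could make them available outside the laboratory, but its three-axis
signals change whenever the sensor tilts in the shoe. The per-sample
Euclidean norms of foot linear acceleration and foot angular velocity do
not: for any fixed rotation Q, ‖Q·v‖ = ‖v‖. `gaitnorms` therefore learns a
mapping from the four norm waveforms of one gait cycle — ipsilateral and
contralateral foot ‖a‖ and ‖ω‖, each time-normalized to 200 points (an
800-value feature row) — to the ipsilateral hip/knee/ankle angle waveforms
(a 600-value target row).

This package provides the complete pipeline in R, exercised end to end on a
synthetic gait generator with known ground truth; the same functions apply
unchanged to real marker and force-plate data supplied in the package's
plain-text trial dialect.

## Kinematics

**Foot frame.** From the five foot landmarks, with M the midpoint of the
first and fifth metatarsal heads: origin = midpoint(heel, M); y (anterior) =
unit(M − heel); z (superior) = unit((MT1 − heel) × y) for the left foot; x =
y × z. The construction is printed for the left side only; the right foot
mirrors it with the cross-product order flipped so that z stays superior and
the frame right-handed — the one free choice a bilateral implementation must
make.

**Joint angles.** For each joint the relative rotation is taken
proximal-to-distal, R = R_proxᵀ·R_dist (the order is a documented
convention; it only fixes signs), and decomposed as Cardan x-y-z:
R = Rx(α)·Ry(β)·Rz(γ), with α the sagittal angle and β constrained to
[−90°, 90°]. Signs are mapped so hip flexion, knee flexion, and ankle
dorsiflexion are positive (the knee α is negated: knee flexion carries the
shank backwards relative to the thigh). Within 1e−8 of gimbal lock
(|R[1,3]| → 1) only α ∓ γ is determined; γ is set to 0, α absorbs the free
rotation, and the sample is flagged. Gimbal lock is ~90° out of the sagittal
working range of these joints, so the flag should never fire on gait data.

**Derived foot signals.** The virtual foot marker is the midpoint of the
metatarsal-head midpoint and the malleoli midpoint, i.e. 0.25·(MT1 + MT5 +
MML + LML). Linear acceleration is the second central difference,
a_i = (p_{i+1} − 2p_i + p_{i−1})·rate², exact for quadratic trajectories
with O(rate⁻²) error otherwise. Frame attitudes are converted to unit
quaternions (sign-continuous: consecutive dot products ≥ 0, required before
differencing) and angular velocity is ω_i = 2·vec(q̇_i ⊗ q_i*), with q̇ by
central differences. The first and last samples of any differenced series
are flagged invalid rather than padded; cycles are only extracted from trial
interiors. Whether ω is read in the body or lab frame changes nothing
downstream because only ‖ω‖ is consumed.

## Gait events and matrix assembly

Markers are low-pass filtered at 10 Hz and vertical GRF at 56 Hz with a
zero-lag Butterworth filter. "Fourth-order with zero lag" is implemented as
a forward–backward pass of a second-order filter, giving a combined
fourth-order magnitude response; the alternative reading (fourth order per
pass, eighth combined) is flagged as an open choice, and the cutoffs are
configurable through `pipeline_params()`. The implementation pads by odd
reflection at both ends so no startup transient reaches the data.

Heel contacts are upward crossings of a 20 N threshold separated by a 0.2 s
refractory period — the threshold and refractory are conventional
force-plate practice, not prescribed values, and both are configurable. A
cycle runs from one heel contact to the next ipsilateral heel contact;
events found at the GRF rate are mapped to the nearest marker-rate sample
(the rates are integer multiples). One cycle per trial — the first fully
interior one — enters the analysis, matching the row arithmetic of a
10-trial protocol (10 rows per subject). Each channel is linearly
interpolated onto 200 points at phases i/199, endpoints included. Feature
channels are ordered [ipsi ‖a‖, ipsi ‖ω‖, contra ‖a‖, contra ‖ω‖]; any
fixed order is information-equivalent, so the order is simply frozen. Rows
are sorted by (subject, trial), making the assembled matrices independent of
processing order.

## The PCA waveform codec

For a t × d waveform matrix (t trials, d points per row) the codec
standardizes each column by its own mean and SD and eigen-decomposes the
correlation matrix — the mean/SD structure of the reconstruction identity

Waveformᵀ = M_mean + M_sd · M_loadings · M_scoresᵀ

forces correlation-matrix (not covariance) PCA. Components with eigenvalue
≥ 1 are retained (Kaiser rule; the threshold is configurable, and `all` /
`fixed-n` retentions exist for testing). Loading signs follow a fixed
convention — the largest-magnitude loading of each component is positive —
so fits are reproducible across linear-algebra backends. A column SD below
1e−12 raises an error naming the column: a flat channel indicates an
upstream bug, not something to rescale silently. The retained component
count is a property of the data, not a constant of the method; on synthetic
data it is typically ~60–110 for the input matrix (noise raises it) and
~5–30 for the output matrix.

## Estimator and tuning

Subjects are randomly assigned to five near-equal groups; every trial of a
subject shares its group, so no subject straddles a train/validation/test
boundary. One group is the test set. Tuning runs 4-fold cross-validation
over the remaining four: each fold in turn is the validation set, the input
and output codecs are fit on the three training groups only, one network is
trained per grid condition, and the pooled mean absolute error between
actual and predicted validation output scores is recorded; per-condition
MAEs are averaged over the four folds and the argmin wins (ties to grid
order). The default grid is 12 layer/node combinations ({1,2,3,4} layers ×
{40,80,120} nodes — the in-body text states only "12", so the axes are
package defaults chosen to include the reported optimum of 1 layer × 80
nodes) × batch {128,256,512} × dropout {0.3,0.4,0.5} × learning rate
{0.01,0.001,0.0001}: 324 conditions, hence 1,296 enumerated fits.

The network is fully connected: input scores → hidden blocks of
dense → Swish → dropout → linear output, trained with Adam on MSE over the
output scores for a fixed number of epochs (default 300; no early
stopping). PC scores enter and leave the network unrescaled. Two trainer
details are deliberate implementation choices: (1) the output layer is
initialized at zero weights with the target-column means as biases, so
optimization starts from the mean-waveform baseline instead of having to
traverse the large dynamic range of raw output scores (without this,
convergence within a fixed epoch budget was seed-dependent); (2) minibatches
are reshuffled every epoch with the run seed and the last short batch is
kept. Dropout after each hidden activation, the linear output layer, and
MSE-on-scores are conventional choices where the method description is
silent. Everything is deterministic given the seed.

The main model refits both codecs on the four training groups, trains one
network with the winning condition, and predicts by encode → forward pass
(dropout off) → decode. A row audit (`train_rows`) records exactly which
matrix rows influenced the codecs and weights; the test suite asserts the
test group is disjoint from it.

## Evaluation

Per trial and joint over the 200 cycle points: RMSE (deg); NRMSE = 100 ×
RMSE / (max − min of the *actual* waveform) — range normalization following
the convention of waveform-accuracy studies, with SD normalization available
as a configuration; Pearson ρ. Each is averaged over trials (a constant
actual waveform has undefined NRMSE/ρ and is excluded with a warning). Six
angle-at-timing errors are reported as mean (SD) of absolute differences:
hip flexion at heel contact, peak hip extension, peak knee flexion, ankle
dorsiflexion at heel contact, peak ankle dorsiflexion, peak ankle plantar
flexion. At-heel-contact is point 1 of the normalized cycle; peaks are
full-cycle extrema (the stance-restricted reading of "peak dorsiflexion"
used in some clinical work is noted but not adopted).

## The synthetic gait generator

The generator exists so that every stage has an exact oracle: it emulates
the *structure* of a 200-subject × 10-trial instrumented-walkway study
(markers at 200 Hz, per-limb vertical GRF at 1,000 Hz, barefoot straight
walking, five trials per leg) while remaining fully self-contained.

**Angle templates.** Normative hip/knee/ankle sagittal curves are stored as
truncated Fourier series (constant term + 5 harmonics, coefficients fixed
package constants fitted once to smooth periodic curves through textbook
landmark values: ~30° hip flexion at heel contact to ~−10° peak extension,
~60° swing knee-flexion peak near 72% cycle, ankle dorsi/plantar excursions
of +11°/−15°). Periodicity is exact by construction.

**Subjects.** Each subject is a pure function of (master seed, subject
index) via a deterministic seed mix, so profiles are reproducible
independently of generation order. A single `subject_effect_sd` (default
0.2) gates *all* between-subject variation: cadence (0.9 strides/s ± 0.1·sd
scale), stride length (1.30 m ± 0.16·sd scale), a common stature scale on
segment lengths, and log-normal per-joint amplitude scales. Mean-posture
offsets are a deterministic function of the amplitude scales
(offset = 10°·(amplitude − 1) per joint, ≈2° SD at the default). The
coupling is a design requirement, not a convenience: a constant angle offset
drawn independently of the movement is invisible to any derivative-based,
tilt-invariant norm feature, which would make the targets partly
unlearnable from the inputs by construction; tying posture to excursion
keeps every degree of freedom of the truth angles expressed in the foot
kinematics. At `subject_effect_sd = 0` all subjects are identical
(amplitudes 1, offsets 0).

**Trials.** Each trial covers three full ipsilateral cycles plus lead-in and
tail margins (so an interior cycle always has valid central differences).
Smooth per-trial noise — white noise low-passed at 3 Hz, rescaled to
`noise_sd_angle` (default 0.75°) — is added to each limb's angle series
*before* forward kinematics, so the stored truth is exactly consistent with
the markers; the 3 Hz band represents slow stride-to-stride drift rather
than jitter (high-band angle noise would be amplified by (2πf)² in the
acceleration features out of proportion to anything seen in gait data). The
default noise and subject-effect values put the between-subject waveform SD
at several times the stride-to-stride SD, the regime adult gait data shows.

**Forward kinematics.** A planar sagittal chain per limb: the pelvis
translates along +y at stride_length × cadence with identity orientation;
thigh, shank, and foot rotate about the lab x axis by hip, hip − knee, and
hip − knee + ankle. Foot markers ride rigidly on the foot frame, so
inverting the chain through the kinematics module recovers the stored truth
to machine precision before filtering (≤0.5° RMS after the 10 Hz filter).
The contralateral limb is the same chain shifted by exactly half a cycle.
The lab convention is fixed and documented: x right, y anterior, z up.

**GRF.** Stance occupies `cycle_fraction_stance` (default 0.6) of each
cycle; the vertical force is a two-peaked template
W·(sin(πu) + 0.25·sin(3πu) + 0.07·(1 − u)) on stance phase u, exactly zero
in swing. The small 0.07·W step at stance onset models the heel-strike
impact transient and makes the threshold crossing of the raw force coincide
with the scheduled contact to within one GRF sample, which is what lets the
generator schedule serve as the event-detection oracle.

**What the generator does not emulate.** Only sagittal-plane motion — no
frontal/transverse kinematics, no soft-tissue artifact, no marker dropout,
no double-support force sharing, and between-subject variation spans a
low-dimensional manifold (amplitude/posture/timing scales) rather than the
full shape variability of real cohorts. Passing tests therefore demonstrate
that the pipeline's machinery is correct and that the estimator recovers
structure the features genuinely carry; they do not certify accuracy levels
on real motion-capture data.

## Numerical choices and degenerate inputs

- Collinear landmarks (zero-length cross products) raise degenerate-geometry
  errors naming the first bad sample.
- Derivative endpoints are NA by contract; `time_normalize` refuses NA
  spans, so a cycle touching a trial endpoint can never slip through.
- The Butterworth wrapper refuses cutoffs at or above Nyquist.
- Quaternion extraction uses the four-case (Shepperd) branch on the largest
  diagonal combination, vectorized over samples.
- Codec `all` retention is capped at min(t − 1, d), the rank of a centered
  t × d matrix.
- Ties in cross-validation resolve to the earliest grid condition, making
  tuning deterministic.
- Seeds are mixed with a fixed integer hash (`master seed × subject × trial`
  and `run seed × fold × condition`) so sub-streams never depend on
  evaluation order, and all RNG use is wrapped to restore the caller's
  RNG state.

## Problem sizes used in the checks

The shipped test-and-reproduction setup runs the full pipeline twice at the
full 200-subject × 10-trial scale — once at the default noise level and once
noise-free (noise-free accuracy is limited by subject-manifold
interpolation, which needs the dense subject sampling) — with an
8-condition reduced grid (1 layer × {40,80} nodes, batch 128, dropout
{0,0.2}, learning rate {0.01,0.003}) and 100 epochs, keeping each run to a
few minutes on one CPU. The structural bookkeeping (324-condition
grid, 1,296-fit enumeration, 2,000/1,600/1,200/400-row and 800/600-column
matrices) is recomputed exactly at the full scale.

## Known limitations

- The proximal (pelvis/thigh/shank) frame recipe of the source database is
  not public; `build_proximal_frame()` implements a documented minimal
  construction (origin, long-axis landmark, plane landmark) and accepts
  precomputed orientations, which is what the generator supplies.
- No C3D reader: motion data enter through the package's documented TSV
  dialect. Positions are in meters throughout.
- The estimator trains a fixed number of epochs (no early stopping) and a
  single network (no ensembling), by design.
- Accuracy numbers produced on synthetic data characterize the pipeline, not
  any real cohort; see the generator's non-goals above.
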