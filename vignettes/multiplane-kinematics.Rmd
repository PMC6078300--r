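---
title: "Multiplane hind limb kinematics: model, conventions, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiplane hind limb kinematics: model, conventions, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hindkin)
```

## The problem

Single-plane (sagittal) gait models measure one angle per joint — the
included angle between three markers — and cannot separate flexion-extension
from internal-external rotation or abduction-adduction. When a limb rotates
about its long axis at constant flexion, the three-marker angle still
changes: the out-of-plane rotation masquerades as flexion. A multiplane
model resolves each joint rotation into three clinically named components
using segment-embedded anatomical coordinate systems and a joint coordinate
system (JCS) decomposition. `hindkin` implements such a model for the
quadruped (feline) pelvis and hind limbs driven by skin-mounted
motion-capture markers, together with everything needed to run and test it:
trajectory I/O, gap filling, stifle virtual-marker prediction, gait-cycle
statistics, a triad-based validation transform, and a forward-kinematics
generator of synthetic trials with known ground truth.

## Anatomical frames

Four segment frames are built per limb from marker positions (mm, lab
frame); all bases are right-handed and orthonormal to 1e-9:

* **Pelvis** — origin at the right iliac crest (RIC); ẑ from the left to the
  right iliac crest (mediolateral); x̂ = unit((RIC − RIT) × ẑ);
  ŷ = ẑ × x̂. A single pelvis frame serves both hips.
* **Femur** — origin at the greater trochanter (GT); ŷ from the predicted
  stifle virtual marker up to GT. The skin over the femoral condyles moves
  too much for condyle markers, so the femoral mediolateral direction is
  borrowed from the tibia: x̂ = unit(malleolus axis × ŷ), ẑ = x̂ × ŷ.
* **Tibia** — origin at the lateral malleolus (LM); ẑ along the malleolus
  axis; x̂ from a proximal reference point via a cross product with ẑ. Two
  variants exist: variant 1 takes the reference from the fibular vector
  marker ("unadjusted tibia axis"), variant 2 from the predicted stifle
  ("adjusted tibia axis"). This is the only place the two analysis
  techniques differ.
* **Tarsus** — origin at the calcaneus (C); ẑ along the metatarsal axis
  (5th to 2nd); x̂ from the calcaneus-to-5MT vector via a cross product.

Left-side formulas flip the differenced marker pairs (e.g. ẑ = unit(LMM −
LLM) for the left tibia) so that every segment's ẑ keeps one mediolateral
sense — toward the animal's right — on both limbs. Mirroring a limb across
the sagittal plane and swapping labels preserves the mediolateral component
of every ẑ exactly, and preserves the full vector for planar poses; the
clinically important consequence, identical signed angle traces for
mirror-symmetric gait, is exact and is asserted in the test suite.

### The femur–tibia coupling

Because the femur borrows the tibial mediolateral axis, the model femur
frame always satisfies x̂_femur ⊥ ẑ_tibia. Two consequences are worth
understanding:

1. The stifle's reported internal-external rotation is not an independent
   degree of freedom of the marker set. Given the raw stifle flexion angle
   *a* and abduction angle *b*, frame consistency forces the raw stifle
   rotation to `atan2(-sin a · sin b, cos a)`. True tibial axial rotation is
   instead absorbed into the femur frame and surfaces at the hip. This is
   intrinsic to any marker set without reliable femoral condyle markers,
   not an implementation artifact.
2. The synthetic-data generator therefore prescribes eight free waveforms
   (hip FE/IE/AbAd, stifle FE/AbAd, tarsus FE/IE/AbAd) and reports the
   induced stifle IE as ground truth; supplying a stifle IE waveform
   triggers a warning.

## Stifle virtual marker

Skin motion across the stifle makes a physical knee marker unreliable. The
virtual marker is predicted per frame from rigid landmarks and two palpated
segment lengths (per-subject configuration inputs, mm):

* tibial endpoint: the fibula-length vector from the lateral malleolus
  through the fibular vector marker (a skin marker ~2.5 cm proximal to the
  malleolus);
* femoral endpoint: the femur-length vector from the greater trochanter
  toward that tibial endpoint;
* virtual marker: the midpoint of the two endpoints.

Both analysis techniques share this prediction; they differ only in the
tibia frame variant used downstream. No frame-to-frame smoothing is applied
— inputs are already gap-filled and the projection is deterministic. Frames
with any occluded input marker propagate as invalid virtual-marker samples.

## Joint coordinate system

For a proximal frame P and distal frame D, with e1 = P's ẑ (flexion axis),
e3 = D's ŷ (long/rotation axis), and floating axis e2 = unit(e3 × e1):

* **flexion-extension** — angle between the proximal and distal long axes
  measured in the plane normal to e1, folded to [0, 180];
* **abduction-adduction** — 90° minus the angle between e1 and e3;
* **internal-external rotation** — signed angle about e3 between the
  floating axis and the distal frame, referenced so coincident frames read
  zero (measured to the distal ẑ and offset by the 90° the two subtend at
  the neutral pose).

This triple is algebraically identical to an intrinsic z-x-y Euler
decomposition of the relative rotation, which is how the test suite checks
it against an independent projection oracle. Raw signed angles mirror
between sides; a per-side sign map (right limb negated) makes positive mean
external rotation and abduction on both limbs.

Two flexion conventions are supported via `angle-convention`: `absolute`
(default; aligned long axes read 0°) and `complement` (the included angle
between segments, 180° minus the former). Published feline tables report
the included segment angle, i.e. the `complement` convention; the exact
fold used by any given lab is rarely printed, so the choice is explicit
here rather than inferred. Angles are reported per frame in principal
ranges; no unwrapping is applied.

Gimbal handling: if the distal long axis is within 1e-9 of ±the flexion
axis, the floating axis is undefined; the series code reuses the previous
frame's floating axis with a warning, and errs if there is none. Hind-limb
gait never approaches this configuration, so failing loudly beats guessing.

## Sagittal comparison model

The three-marker model uses the iliac crest, greater trochanter, stifle
virtual marker, lateral malleolus, and 5th metatarsal: hip = angle at GT,
stifle = angle at the virtual marker, tarsus = angle at LM. Under pure
hinge motion it equals multiplane flexion-extension (complement convention)
up to a constant marker-placement offset; under axial rotation it conflates
rotation with flexion, which the multiplane model separates. Both behaviors
are reproduced quantitatively in the acceptance tests. One subtlety: a pure
rotation about a segment's long axis moves only markers that sit *off* that
axis. With idealized on-axis marker placements no sagittal angle changes at
all, so the conflation demonstration uses a realistic laterodistal 5th
metatarsal placement (15 mm cranial + 15 mm lateral of the tarsus long
axis) and a ±15° tarsal rotation at constant flexion: the multiplane
flexion stays constant to 1e-3° while the sagittal tarsus angle swings by
several degrees.

## Gait processing

* **Events** — contact/liftoff are detected from the distal foot marker:
  stance is where vertical speed < 50 mm/s and height is within 10 mm of
  the 10th height percentile; contacts are falling crossings, liftoffs
  rising ones. These thresholds suit 100 Hz captures of walking; supplied
  event files always take precedence, and events at the very first/last
  frame of a recording are undetectable (no crossing), so trials should
  carry at least one cycle of lead-in/out when detection is used.
* **Normalization** — each stride is linearly resampled onto a 101-point
  0–100% grid (the grid size is a convention; the resampling error of
  linear interpolation at 100 Hz is negligible relative to marker noise).
  Cycles containing invalid samples are dropped and logged. The stance
  fraction is (liftoff − contact)/(next contact − contact).
* **Summary statistics** — mean, SD, max, min, and ROM = max − min are
  computed on the mean (cycle-averaged) waveform, matching the convention
  "over the average step cycle" used in published feline tables; SD pooled
  across cycle samples is available via `sd_mode = "pooled"`. ROM is exact
  arithmetic on the extrema; `reference_rom_summary()` ships a published
  reference table on which the identity holds to one-decimal print
  rounding (±0.1°).

## Gap filling

Short occlusions (≤ 4 frames by default, i.e. gaps strictly shorter than 5)
are bridged per coordinate by exact quintic polynomial interpolation
through up to three valid frames on each side — the short-gap limit of
Woltring-style quintic splines. Full generalized cross-validated smoothing
is deliberately not implemented: over < 5-frame gaps, interpolation and
lightly smoothed splines are indistinguishable, and smoothing parameters
would be arbitrary. Valid samples are never modified (bit-exact), boundary
gaps are left unfilled and logged, and the operation is idempotent.

## Validation transform

For cadaver-style validation, rigid marker triads (origin + 19 mm X and Y
arms, Gram–Schmidt re-orthogonalized with x̂ primary since physical plates
are never perfectly square) define bone-fixed frames. Landmark-derived
joint angles are related to triad-derived ones by R_transform = R3 R2 R1,
where R2 is the per-frame landmark joint rotation and R1, R3 are constant
alignment rotations computed at a single neutral-pose frame (triad-to-bony
distally, bony-to-triad proximally). Frame-to-frame rotations are composed
as (target basis)ᵀ(source basis) with bases as column matrices. On a rigid
limb the transform telescopes to the triad-frame relative rotation, so
transformed landmark angles equal triad angles exactly — the package
asserts ≤ 1e-9° on synthetic rigid trials, the noise-free analogue of
cadaver agreement within a few degrees. Angle extraction from rotation
matrices uses atan2 throughout and refuses gimbal configurations
(|R[3,1]| = 1) by raising an error naming the problem.

## Synthetic data generator

`forward_kinematics()` composes pelvis → femur → tibia → tarsus poses from
prescribed joint waveforms using exactly the frame conventions above, then
places markers at fixed local coordinates chosen so that rebuilding each
frame from the generated markers reproduces it exactly. The true stifle
lies precisely at fibula length from the malleolus along the
malleolus-to-vector-marker line and at femur length from the trochanter, so
prediction is exact on noise-free output. Default dimensions approximate an
adult cat (femur 105 mm, fibula 100 mm, pelvis width 60 mm, malleolus
marker separation 18 mm, metatarsal separation 16 mm); waveform styles are
`multiplane` (sinusoids spanning published feline ranges, for round-trip
recovery), `stance_flat` (raised-cosine swing bumps that hold the limb
still during stance, giving detectable contacts), and `hinge` (pure
sagittal motion). Gaussian marker noise and scheduled occlusion gaps are
reproducible under a seed.

What the generator does *not* emulate: soft-tissue artifact (markers are
rigid in their segments), ground contact mechanics (the "treadmill-style"
default holds the pelvis still rather than solving foot-ground
constraints), inter-cycle variability, and real occlusion statistics.
Passing round-trip tests therefore demonstrates correctness of the
geometry and decomposition pipeline, not robustness to skin motion — the
published validation against bone-mounted triads is the evidence for the
latter, and its mathematics (not its cadaver data, which are not publicly
deposited) is what the validation module reproduces.

### Noise sensitivity

With 0.5 mm isotropic marker noise, pooled RMS angle errors are roughly
1.4–3.4° depending on plane. The error budget is dominated by the short
inter-marker baselines the marker set dictates: the fibular vector marker
sits only ~25 mm from the malleolus (so the tibial reference direction
amplifies noise ~40:1 onto a 100 mm projection), and malleolus/metatarsal
separations of ~16–18 mm set the transverse/frontal axis precision. Error
scales approximately linearly with noise SD. Flexion-extension, driven by
long-baseline axes, is the most robust plane — one reason published work
reports it most confidently.

## Problem sizes used in tests

Synthetic trials in the test and acceptance suites use 1–4 cycles at
25–100 Hz (36–420 frames, 18–30 markers), 1000-draw randomized frame
sweeps, a 161 × 11 × 11 Euler round-trip grid, and 20-trial Monte-Carlo
noise runs — sizes at which every property asserted is already at its
asymptotic (machine-precision or statistically stable) value.

## Known limitations

* The C3D reader/writer supports the common Intel-format subset (3D point
  data, float or scaled-integer, standard POINT parameters); analog
  channels are skipped. CSV round trips are bit-exact; C3D round trips are
  limited by the format's single-precision storage (~1e-5 relative).
* Joint translations, helical-axis decompositions, and 6-DOF least-squares
  bone pose estimation are out of scope.
* Hip angles for the left limb use the single pelvis frame originated at
  the right iliac crest; re-originating at the left crest would change no
  axis directions, only the (unused) origin.
* Event detection assumes walking-like kinematics with a clear stance; run
  it on filled (gap-free) foot trajectories, or supply events from file.
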