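# hindkin

Three-dimensional multiplane kinematic analysis of the quadruped (feline)
hind limb from optical motion-capture marker trajectories.

Single-plane gait models report one angle per joint — the included angle
between three markers — and cannot tell flexion-extension apart from
internal-external rotation or abduction-adduction: rotating a limb about its
long axis at constant flexion still changes the three-marker angle. This
package implements a multiplane model for the cat pelvis and hind limbs that
resolves hip, stifle (knee), and tarsal (ankle) rotations into all three
clinical planes, for researchers quantifying locomotion in health, injury,
and recovery.

## What it computes

Anatomical segment frames are built per limb from skin-marker positions
(Table-style formulas; pelvis origin RIC, femur origin GT, tibia origin LM,
tarsus origin C, with left-side sign flips keeping one mediolateral ẑ sense
on both limbs). Because condyle skin markers are unreliable, the lateral
stifle is a *virtual* marker: with palpated femur length `L_fem` and fibula
length `L_fib`,

    tibia endpoint  t = LM + L_fib * unit(V - LM)
    femur endpoint  f = GT + L_fem * unit(t - GT)
    stifle          S = (t + f) / 2

where `V` is a fibular skin marker ~2.5 cm proximal to the lateral
malleolus. Joint rotations are decomposed with a joint coordinate system:
flexion axis `e1` = proximal ẑ, rotation axis `e3` = distal ŷ, floating axis
`e2 = unit(e3 x e1)`; flexion-extension is the inter-long-axis angle in the
plane normal to `e1`, abduction-adduction is `90° - angle(e1, e3)`, and
internal-external rotation is the signed angle about `e3` referenced so
coincident frames read zero — with a per-side sign map making positive mean
external rotation/abduction on either limb. Strides are resampled to a
101-point percent-cycle grid and summarized as mean, SD, max, min, and
ROM = max − min over the average cycle. A validation module relates
skin-landmark angles to rigid marker-triad angles through the alignment
transform `R_transform = R3 R2 R1`, with `R1`, `R3` fixed at a neutral-pose
frame. A forward-kinematics generator produces synthetic trials (C3D/CSV)
with exact ground truth for all of the above.

## Worked example

Generate a synthetic bilateral walking trial, predict the stifle, compute
multiplane angles, detect gait events, and summarize:

```r
library(hindkin)

spec <- synthetic_limb_spec(sides = c("right", "left"), n_cycles = 3,
                            rate = 100,
                            waveforms = default_gait_waveforms("stance_flat"))
fk <- forward_kinematics(spec)

limb <- limb_definition("right", femur_length = 105, fibula_length = 100)
traj <- stifle_trajectory(fk$traj, limb, technique = 1)
series <- limb_angle_series(traj, limb, technique = 1,
                            convention = "complement")
events <- detect_events(traj, "right")
gait_summary(series, events)
```

```
   joint  side               plane  mean       sd   max    min      rom
1    hip right   flexion_extension 100.0 8.29e+00 105.0  80.09 2.49e+01
2    hip right   internal_external   5.0 3.58e-14   5.0   5.00 2.05e-13
3    hip right abduction_adduction  -7.0 6.75e-15  -7.0  -7.00 1.42e-14
4 stifle right   flexion_extension 129.1 9.95e+00 135.0 105.11 2.99e+01
5 stifle right   internal_external   8.3 4.39e+00  21.2   5.97 1.52e+01
6 stifle right abduction_adduction  -6.0 1.02e-14  -6.0  -6.00 5.42e-14
7 tarsus right   flexion_extension 116.0 6.63e+00 120.0 100.08 1.99e+01
8 tarsus right   internal_external   9.0 4.50e-14   9.0   9.00 2.50e-13
9 tarsus right abduction_adduction   5.0 5.37e-14   5.0   5.00 3.30e-13
```

Flexion-extension (here in the `complement` convention, the included
segment angle) swings through walking-typical arcs — e.g. the stifle moves
between 105° and 135° for a 30° ROM — while the prescribed constant
transverse/frontal waveforms come back constant to machine precision. The
stifle internal-external rotation is *not* constant even though nothing
axial was prescribed there: this marker set derives the femoral
mediolateral axis from the tibia (no reliable condyle markers exist), which
couples the stifle's reported rotation to its flexion and abduction — see
the methods vignette (`vignettes/multiplane-kinematics.Rmd`) for the
closed form and its consequences.

A thin command-line interface wraps the same pipeline:

```sh
inst/cli/hindkin analyze  --config run.yaml --technique 1
inst/cli/hindkin validate --config validate.yaml --neutral-frame 1
inst/cli/hindkin synth    --style stance_flat --seed 5 --out fixtures/
```

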