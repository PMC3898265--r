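# angioflow

Absolute blood volume flow rate quantification from dynamic angiographic
data, for (vessel-encoded) arterial spin labeling MR angiography and related
time-resolved modalities.

Dynamic ASL angiography labels inflowing arterial blood magnetically and
images its passage through the vasculature. The signal in a voxel is
proportional to the *volume* of labeled blood it contains, not to flow, so
quantifying volume flow rates (ml/s) through named vessels — middle cerebral,
internal carotid, and so on — needs a kinetic model, a signal-to-volume
calibration, and a way to convert calibrated volume maps into flow.
`angioflow` implements that chain end to end, together with a flow-phantom
simulator providing full ground truth.

## The model

The measured signal in one voxel at time *t* is

    S(t) = A ∫ c_in(t − t′ − Δt) D(t′) T(t) Ψ(t) dt′

where `c_in` is the labeled input — a rect of duration τ (the labeling
time) — delayed by the transit time Δt and dispersed by a gamma-variate
kernel `D` with sharpness `s` (1/s) and time-to-peak `p` (s); `T = exp(−t/T1)`
is longitudinal decay of the label and `Ψ = cos(α)^n` the attenuation from
the `n` imaging excitations (flip angle α) the blood has experienced. The
scaling factor `A = S0·v` is the product of the labeled blood volume `v` in
the voxel and a calibration factor `S0` (signal per mm³ of blood). Fitting
the four free parameters `(A, Δt, s, p)` per voxel (bounded
Levenberg–Marquardt with a Laplace covariance) turns the image series into
parameter maps.

Calibration is self-contained: across a vessel of circular cross-section
running in the imaging plane, the projected `A_tot` profile follows the
chord of a circle,

    A_tot(d) = S0 Δx Δy √(d̄² − 4(d − d0)²),   |d − d0| ≤ d̄/2,

so a least-squares fit of profiles through a few vessel segments yields `S0`
(and the vessel diameter d̄) from the same data set. For 3D acquisitions,
any voxel entirely inside an artery gives `S0 = A_tot/(Δx Δy Δz)` directly.

Flow follows from conservation of mass: the volume of blood labeled during
τ must pass every downstream vessel once per interval τ. A very short bolus
(τ′ = 1 ms) is *simulated* from the fitted parameters with attenuation
removed,

    S′(t) = A ∫_{t−Δt−τ′}^{t−Δt} D(t′) dt′,

summed over a mask covering the vessel and its downstream branches, and
divided by `S0·τ′`. While the simulated bolus lies entirely inside the mask
this quantity is constant — the plateau — and equals the volume flow rate.
The plateau is located automatically (20%-of-maximum thresholding, then the
median rule) and its mean and SD are the flow estimate and its error, with
fit and calibration uncertainty propagated via sigma points.

## Worked example

Simulate the single-tube flow phantom (4 mm tube, true flow 0.30 ml/s,
20 frames at 55 ms, peak SNR 20) and run the whole pipeline — decode the
tag/control cycles, fit the kinetic model in high-signal voxels,
self-calibrate, quantify:

```r
library(angioflow)

cfg <- tube_phantom_config(flow = 0.30, seed = 1)
phantom <- generate_phantom(cfg)
res <- quantify_phantom(phantom)

res$pipeline$calibration
#> Self-calibration (2d method): S0 = 50.57 +/- 0.17 (SE) from 10 profiles

res$estimate
#> Flow estimate: 0.2968 +/- 0.048 ml/s (plateau 0.04-0.81 s)
#>   model-based SD: 0.036 ml/s (S0 rel. SE 0.0034)
```

The generating calibration factor was `S0 = 50` and the true flow
0.30 ml/s: the pipeline recovers both to within a few percent, and the flow
curve (`plot(res$estimate)`) shows the plateau while the simulated bolus is
fully contained in the mask. Vessel-encoded, multi-artery data work the same
way — `mixing_tree_config()` builds a two-inlet phantom whose outlet mixes
blood from separately labeled arteries, and `quantify_vessel()` then reports
the per-artery flow decomposition.

A command-line interface wraps the same stages for file-based work
(NIfTI images, YAML configs, CSV outputs):

```sh
inst/cli/angioflow simulate --config phantom.yaml --out sim/ --seed 0
inst/cli/angioflow pipeline --config run.yaml --out results/
```

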