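# spheromech

Analysis chain for **force-direction-dependent platelet activation** in
blood-contacting devices: how the direction of mechanical load on integrin
αIIbβ3 — tangential friction from a *sliding* (discoid) platelet versus
normal pulling from a *rolling* (spherical) platelet — decides whether the
receptor unfolds toward its activating extended conformation, and how that
single-molecule anisotropy propagates to device-scale coagulation metrics.
It is written for biophysicists and biomedical engineers working with AFM
force spectroscopy, FRET/FLIM conformational readouts, cell-tracking data
and extracorporeal-circuit (hemodialysis) experiments.

## What it computes

**AFM force spectroscopy** — from a force–displacement curve: a robust
baseline noise model (median / 1.4826·MAD), the terminal rupture event
(largest windowed-median step > 5 SD; magnitude by local linear
extrapolation to the jump), and pre-rupture unfolding peaks on the
detrended ramp with the significance rule

> peak amplitude > 1.96 × SD(noise)  (strict)

A curve with ≥ 1 significant peak is classified *unfolded* (the tangential
signature), otherwise *folded*.

**FRET photophysics** — the Förster chain
J = ∫ f_D(λ) ε_A(λ) λ⁴ dλ, R₀ = 0.02108 (κ² Φ_D n⁻⁴ J)^{1/6} nm,
E = 1/(1 + (r/R₀)⁶) and its inverse, lifetime efficiency E = 1 − τ_DA/τ_D,
and the two-state conformational mixture
f = (E_rest − E_region)/(E_rest − E_active) with pixelwise map support.

**Coarse-grained unfolding mechanics** — a bond-graph surrogate of the
anisotropic unfolding pathways: tangential force breaks PRO381–ARG563
(58 pN, Separation I4) then SER367–SER551 (60 pN, Separation I3) and
extends the receptor (θ: 45°→75°); normal force rotates the head
(φ: 140°→100°), forms three extra calf-contact hydrogen bonds, and the
70-pN integrin–ligand bond detaches before the > 140 pN five-bond network
can dissociate — the receptor stays bent at every normal force. Includes
Bell-model loading-rate rescaling and emission of synthetic curves carrying
each pathway's signature.

**Track kinematics** — rolling index = radius × |total rotation| / path
length (1 = no-slip rolling, 0 = sliding), rolling/sliding classification,
velocity trends, cohort fold ratios with Katz confidence intervals, and
discoid-fraction (spherification/recovery) time courses.

**Device metrics** — pressure-rise clotting time (first sample strictly
above a 50 % / +25 mmHg rule), prolongation percent, fiber occlusion ratio,
ACT change, and ng/mL → nM dose conversion.

**Synthetic data** — seeded generators for every input above (curves,
spectra, tracks, cohorts, pressure/ACT series, shape kinetics, FLIM maps);
same seed ⇒ byte-identical output, no global RNG state touched.

## Worked example

```r
library(spheromech)

## FRET: calibrate spectra to R0 = 5.25 nm and infer the bent-closed distance
spec <- calibrate_spectra_to_R0(spectra_spec(), 5.25)
pair <- gen_spectra(spec)
R0   <- forster_radius(overlap_integral(pair$donor, pair$acceptor))
efficiency_to_distance(0.63, R0)
#> [1] 4.804367
activated_fraction(0.60, 0.20)$percent_rounded
#> [1] 70
molecules_shifted(0.7, 80000)
#> [1] 56000

## AFM: a synthetic tangential curve with 2.2 and 2.15 SD peaks + a 1.0 SD decoy
cv <- gen_force_curve(curve_spec(peak_amplitudes_sd_units = c(2.2, 2.15, 1.0)),
                      seed = 1)
nm <- estimate_noise(cv)
rup <- detect_rupture(cv, nm)
pk  <- detect_prerupture_peaks(cv, rup, nm)
sum(pk$significant)
#> [1] 2
classify_unfolding(pk)
#> [1] "unfolded"

## Unfolding model: the direction dichotomy at 70 pN
g <- build_default_integrin()
simulate_loading(g, loading_protocol("tangential", force = 70))$final_state
#> [1] "extended"
simulate_loading(g, loading_protocol("normal", force = 70))$final_state
#> [1] "bent"

## Device: the control run terminates at 24 min; treated at 42 min
percent_rise(50, 61)          # pressure rise when the control clots
#> [1] 22
prolongation_percent(24, 42)  # clotting-time prolongation
#> [1] 75
```

The distance 4.8 nm is the inferred head-to-membrane separation of the
bent-closed receptor; 70 % / 56,000 molecules is the activated share of the
~80,000 surface copies in a spreading region whose apparent efficiency
dropped from 60 % to 20 %; the two significant peaks are the stepwise
inter-domain separations that only tangential load produces.

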