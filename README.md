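# tpmsense

Quantification of myocardial velocities from SENSE-accelerated tissue
phase mapping (TPM), with a digital cardiac phantom for end-to-end
validation.

TPM is cine phase-contrast MRI of the heart muscle: bipolar gradients make
the image phase proportional to tissue velocity, yielding radial and
longitudinal velocity-time curves of the left ventricle.  Parallel imaging
(SENSE) shortens the long TPM scan by acquiring every R-th phase-encode
line and unfolding the aliased images with coil sensitivity profiles; the
central question this package addresses quantitatively is *how much of the
velocity information survives acceleration*.  It is aimed at MR physicists
and image-analysis developers who need a tested, reproducible reference
implementation of the full chain.

## What it implements

* **Four-point Hadamard velocity encoding/decoding** — encoding phases
  `φ_e = φ_0 + π/(2·venc)·(h_e·v)` with the balanced sign matrix
  `H = [−1,−1,−1; +1,+1,−1; +1,−1,+1; −1,+1,+1]`; decoding by wrap-safe
  signed sums of inter-encoding phase differences
  (`encode_images()`, `hadamard_decode()`).
* **Cartesian SENSE** — per-pixel-group least squares `S·ρ = a` with
  optional noise-covariance pre-whitening, g-factor maps
  `g = sqrt(diag((SᴴΨ⁻¹S)⁻¹)·diag(SᴴΨ⁻¹S))`, and windowed local SNR maps
  (3×3 mean over sample SD) with regional summaries
  (`sense_unfold()`, `gfactor()`, `snr_map()`, `regional_snr()`).
* **Phase-error corrections** — least-squares plane fit to static-tissue
  velocity per phase and component, and the zero-integral shift enforcing
  zero accumulated displacement over the cycle
  (`correct_background()`, `zero_integral_shift()`).
* **Curves and metrics** — radial/longitudinal projection, six-segment
  partition (anteroseptal → anterior), natural-cubic-spline resampling,
  peak metrics, peak factor `PF = Δv₂/Δv₁`, normalised RMSD, curve
  correlation (Pearson on the dense samples), Bland–Altman agreement and
  paired t-tests, assembled into tidy comparison tables
  (`extract_curves()`, `compare_acquisitions()`).
* **Sequence timing** — deterministic protocol arithmetic: phase interval,
  alternating black-blood saturation spacing, cardiac-phase count under
  navigator gating, nominal acceleration ratios (`sequence_timing()`).
* **Digital phantom** — annular short-axis myocardium with prescribed
  zero-net-displacement biphasic waveforms, synthetic phased-array coil
  sensitivities, injected background phase and eddy-current-like velocity
  offset planes, and seeded complex k-space noise (`phantom_spec()`,
  `run_pipeline()`).

## Worked example

```r
library(tpmsense)

print(sequence_timing())
#> Sequence timing: TR 7 ms, 3 k-lines + 1 startup, sat 12 ms
#>   phase interval 40 ms, saturation spacing 80 ms, 21 phases at 1000 ms RR

res <- run_pipeline(tpm_config(recon = list(sense_factors = c(1, 4))))

peak_metrics(res$curves$R1$global.radial)
#> peaks: sys +2.885, dias -5.042, range 7.927 cm/s; t_dias 520.0 ms

subset(res$comparison, region == "global")
#>  sequence region    direction    pf nrmsd_pct     c dt_dias_ms
#>        R4 global       radial 0.982     0.770 0.999       0.08
#>        R4 global longitudinal 0.993     0.692 1.000      -1.81

res$snr
#>   sequence R anatomical_myocardium velocity_myocardium
#> 1       R1 1             31.392015            9.681487
#> 2       R4 4              6.981187            2.295887
```

Reading: the default phantom prescribes radial peaks of +2.90/−5.03 cm/s;
at the default noise level the unaccelerated reconstruction recovers them
to a few hundredths of a cm/s (`sys +2.885, dias −5.042`).  Accelerating
four-fold changes the velocity range by under 2% (`pf 0.982`), leaves the
curves nearly congruent (`nrmsd < 1%`, correlation ≈ 1) and shifts the
diastolic peak time by a fraction of the 40 ms frame — while the
myocardial SNR drops from ≈ 31 to ≈ 7, the expected price of R = 4 with
8 coils.  A command-line front end for simulation, timing reports and full
runs lives in `inst/cli/tpm.R`.

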