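# smfretr

Quantitative analysis for chaperone–client binding studies that combine
three measurement modalities:

* **Diffusion smFRET under PIE/ALEX.** Per-segment background estimation,
  dual-channel sliding-window burst search, raw and corrected FRET
  efficiency/stoichiometry with the consensus corrections
  (`F_DA' = F_DA − lk·F_DD − dir·F_AA`, `E = F_DA'/(F_DA' + γ·F_DD)`,
  `S = (F_DA' + γ·F_DD)/(F_DA' + γ·F_DD + F_AA/β)`), ALEX-2CDE filtering,
  burst variance analysis against the binomial shot-noise line
  `σ = √(E(1−E)/5)`, and mean-microtime donor lifetimes with static
  (`E = 1 − τ/τ_D0`) and two-state dynamic
  (`E = 1 − τ₁τ₂/(τ_D0(τ₁+τ₂−τ̄))`) FRET lines. Defaults are the study
  parameters: lk = 0.14, dir = 0.14, γ = 1.0, β = 1.4, 60-s background
  segments, 3× dual-channel threshold, 50-photon minimum burst size,
  S ∈ [0.3, 0.7], ALEX-2CDE ≤ 95, 5-photon BVA windows, 0.05 E_raw bins.
* **Methyl-TROSY NMR perturbation mapping.** Intensity ratios `R = Y/X`
  with propagated errors, chemical shift perturbations
  `CSP = √(ΔH² + (0.251·ΔC)²)`, Z-scores of the intensity loss `1 − R`
  and of the CSP, the broadened-below-noise substitution rule, and
  per-domain hotspot summaries.
* **Hill binding isotherms.**
  `S_obs = S_U + (S_B − S_U)/(1 + (K_d,app/[L])^n)` fitted by
  Levenberg–Marquardt least squares with positivity-safe
  log-parameterisation.

A first-class synthetic-data module generates PIE photon streams with
two-state FRET interconversion and full instrument crosstalk, NMR
apo/bound peak-table pairs with planted binding sites, and noisy binding
curves — so every stage is testable against known ground truth without any
download. Photon data round-trip through a Photon-HDF5-layout container;
tables are TSV with the run configuration serialised into each header.

## Worked example

```r
library(smfretr)

# --- simulate 30 s of a static E = 0.45 molecule with the study's
#     corrections applied in generation, then analyse it back
m  <- two_state_model(E1 = 0.45, corrections = correction_set(),
                      burst_rate = 30, seed = 7)
ps <- simulate_photon_stream(m, duration = 30)
ps
#> photon_stream: 294264 photons, 30 s, clock 8e+07 Hz
#>   Dex/D 78385  Dex/A 81274  Aex/A 134605  (outside windows: 0)

res <- burst_pipeline(ps)          # background -> bursts -> E/S -> filters
e <- res$accepted$E
mean(e, na.rm = TRUE)              # 0.446  (E_true = 0.45)
mean(res$accepted$S, na.rm = TRUE) # 0.508  (S_true = 0.5)

# --- NMR: 40-residue synthetic protein, 6 binding-site residues planted
#     in core-N/P1 at 0.4 attenuation, 5% noise
tabs <- simulate_nmr_pair(nmr_synth_spec(
  n_residues = 40, hotspot_residues = c(2L, 5L, 8L, 13L, 16L, 19L),
  attenuation = 0.4, conf_residues = c(24L, 33L),
  dH = 0.03, dC = 0.15, seed = 1))
pm <- map_perturbations(tabs$apo, tabs$bound)
pm
#> perturbation_map: 40 residues (0 dropped), mode=as_printed
#>  domain  n n_significant mean_Z_intensity mean_Z_CSP
#>  core-N 10             5        0.5382740 -0.2294157
#>      P1 10             4        0.4330870 -0.2294157
#>      P2 10             1       -0.4485681  0.2294157
#>  core-C 10             2       -0.5227928  0.2294157
sort(pm$records$residue[order(-pm$records$Z_intensity)][1:6])
#> 2  5  8 13 16 19        # all six planted sites top the Z-ranking

# --- Hill fit of a noisy titration (Kd_true = 5, n_true = 1.5)
d <- simulate_binding_curve(100, 900, Kd_app = 5, n = 1.5,
                            concentrations = 10^seq(-2, 2, length.out = 16) * 5,
                            noise_cv = 0.01, seed = 2)
fit_hill(d$concentration_uM, d$signal)
#> Hill fit:
#>   S_U    = 100.746 +/- 4.33
#>   S_B    = 896.526 +/- 4.29
#>   Kd_app = 4.89453 +/- 0.106
#>   n      = 1.53507 +/- 0.0456
#>   rss = 897, converged: TRUE
```

The mean corrected E lands on the planted 0.45 because the generator
composes leakage, direct excitation, γ and β exactly the way the
correction chain inverts them; the planted binding sites top the
intensity-loss Z-ranking; and the Hill fit recovers K_d,app within ~2%
at 1% noise.

A shell entry point wraps the same stages
(`inst/exec/smfret simulate|bursts|bva|lifetime|nmr-map|hillfit`).

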