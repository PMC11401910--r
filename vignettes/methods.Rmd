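---
title: "Models and methods behind smfretr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind smfretr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

smfretr implements the three quantitative layers of a chaperone–client
binding study: diffusion-based single-molecule FRET burst analysis with
dynamics detection, methyl-TROSY NMR perturbation mapping, and Hill-equation
binding fits. This vignette explains the models, the tunable parameters and
their defaults, the numerical choices, and what the synthetic-data
generator does and does not emulate.

## The smFRET burst pipeline

### Measurement model

A doubly labelled protein at low-picomolar concentration diffuses through a
confocal volume, producing photon bursts on a Poisson background. Under
pulsed interleaved excitation (PIE/ns-ALEX) donor and acceptor lasers fire
alternately within one TCSPC period, so a photon's microtime assigns it an
excitation slot (Dex or Aex) while the detection channel (D or A) gives its
colour. Three photon streams matter: Dex/D, Dex/A and Aex/A.

Per burst, background-subtracted counts `F_DD`, `F_DA`, `F_AA` give the raw
proximity ratio `E_raw = F_DA / (F_DD + F_DA)` and raw stoichiometry. The
consensus correction chain

    F_DA' = F_DA - lk * F_DD - dir * F_AA
    E     = F_DA' / (F_DA' + gamma * F_DD)
    S     = (F_DA' + gamma * F_DD) / (F_DA' + gamma * F_DD + F_AA / beta)

removes donor leakage (`lk`), acceptor direct excitation (`dir`), detection
asymmetry (`gamma`) and excitation-rate imbalance (`beta`). The package
defaults are the study's published values: `lk = 0.14`, `dir = 0.14`,
`gamma = 1.0`, `beta = 1.4`, with background estimated per 60-s segment, a
dual-channel burst search at 3x background and a minimum burst size of 50
donor-excitation photons, an `S` filter of `[0.3, 0.7]`, and an ALEX-2CDE
cutoff of 95. All of these live in `run_config()` and are serialised into
every output header.

### Background estimation

Each 60-s segment and stream gets a maximum-likelihood exponential fit to
the inter-photon delays above an iteratively chosen threshold (start at
twice the mean delay, re-fit with the memoryless-excess estimator
`rate = 1/(mean(d[d > T]) - T)`, reset `T = 2/rate`, stop at <1% change).
Long delays are background-dominated, so the tail fit is robust to bursts.
Segments with fewer than 50 photons fall back to the plain mean rate.

### Burst search and the edge problem

A photon stream's local rate is assessed over sliding windows of
`window_m = 10` consecutive photons; a photon is *in burst* when a window
containing it has rate above `3x` the segment background, and bursts are
connected components of the intersection of the Dex/D and Dex/A flagged
intervals (the dual-channel AND construction that selects doubly labelled
molecules; a single-stream search would also select donor-only molecules).

Two properties of this construction are worth knowing:

* **Threshold monotonicity holds for photons, not burst counts.** Raising
  the threshold shrinks the flagged photon set, so the total number of
  accepted burst photons never grows — but one long burst can split into
  two bursts that each clear the minimum size, so the *count* of bursts
  can increase. The property tests assert the photon-count version.
* **Edge recruitment.** Windows straddling a burst boundary still clear the
  threshold, so bursts recruit a few background photons per stream and
  side; because the recruited span is delimited by background photons, the
  background content of a burst slightly exceeds `rate x duration`
  (a boundary-conditioned point-process effect). `search_bursts()`
  therefore trims boundary donor-excitation photons whose gap to the next
  burst photon exceeds `1/(3 * (rate_DexD + rate_DexA))` — background-like
  gaps — which restores `rate x duration` as a usable per-burst
  background expectation. Trimming is on by default (`edge_trim`).

On streams of up to 10^4 photons the search is verified photon-exact
against an independent brute-force scan.

### ALEX-2CDE

The filter score uses exponential-kernel densities
`KDE^X(t) = sum_j exp(-|t - t_j|/tau)` (default `tau = 100` microseconds,
configurable) evaluated across excitation streams:
`ALEX-2CDE = 100 - 50 * (BR_DA + BR_AD)` with
`BR_DA = (1/N_Dex) sum_{i in Aex} KDE^Dex(t_i)/KDE^Aex(t_i)` and the
symmetric term. Well-mixed Dex/Aex photons score near 0; segregation
(acceptor bleaching mid-burst, blinking, multi-molecule events) drives the
score toward 100. The kernel sums are computed with O(n) forward/backward
exponential filters and validated against the literal pairwise sum.

### Burst variance analysis

BVA splits each burst's donor-excitation photons into consecutive 5-photon
windows and compares the *population* standard deviation `s_i` of the
window acceptor fractions with the binomial shot-noise expectation
`sqrt(E(1-E)/5)`. The population (rather than sample) SD matches the
worked definition in which two windows at fractions 0.2 and 0.6 give
`s_i = 0.2`. Remainder photons after the last complete window are
discarded, and bursts with fewer than two windows are excluded with a
reason. Binning along `E_raw` uses half-open 0.05-wide bins, with
`E_raw = 1` joining the last bin.

Three small systematic effects matter when comparing mean `s_i` with the
closed-form line, all quantified in the test suite:

1. a finite number of windows `K` biases any standard-deviation statistic
   low by `O(1/K)` (population-SD factor plus Jensen's inequality);
2. recruited edge background photons (acceptor fraction
   `r_DexA/(r_DexD + r_DexA)`, about 0.375 at the default rates) add
   between-window spread, visible at extreme `E`;
3. conditioning on a single `E_raw` bin skews `s_i` when a static
   population straddles a bin edge (bursts sort into bins partly by their
   own window fluctuations); pooling the two straddling bins cancels this.

The acceptance tests therefore compare pooled per-population means against
a Monte-Carlo binomial null evaluated at the bursts' actual window counts
and measured background loads, and additionally verify the pure
closed-form line on transit-ground-truth photons. `bva_null_mean_si()`
exposes the finite-size null.

### Lifetimes and FRET lines

The apparent donor lifetime of a burst is the mean microtime of its Dex/D
photons minus the IRF mean — the estimator used in the study. Uniform
background microtimes bias it upward by roughly
`w_bg * (T/2 - tau)` for background fraction `w_bg` and Dex window span
`T`; `burst_lifetimes()` optionally removes the expected background
microtime mass using the segment rates, and the donor-only reference
`tau_D0` pools bursts with `S > 0.9`. Static and two-state dynamic FRET
lines are

    E(tau) = 1 - tau/tau_D0
    E(tau_bar) = 1 - tau1*tau2 / (tau_D0 * (tau1 + tau2 - tau_bar))

with the dynamic line passing exactly through both state points; molecules
exchanging within a burst displace toward it because the burst-mean
lifetime is intensity-weighted while E is occupancy-weighted.

## The synthetic photon stream

`simulate_photon_stream()` generates transits as rectangular-rate emission
periods with exponentially distributed duration (default mean 1 ms) at a
default rate of 5 per second — the bursty, one-molecule-at-a-time regime
of a low-picomolar measurement; overlapping transits are dropped.
Within a transit a two-state continuous-time Markov chain (rates `k12`,
`k21`) selects the FRET state photon by photon. Crosstalk is composed so
the correction chain is exactly invertible in expectation: FRET branching
first; leakage as an extra A-channel detection with probability `lk` per
detected D photon (leaving `F_DD` untouched and giving
`E[F_DA_leak] = lk * F_DD` exactly); direct excitation as an independent
Poisson stream at `dir` times the Aex acceptor rate; `gamma` as a
detection thinning of one channel; and the Aex rate set to
`beta * peak_rate * (1 - S_true)/S_true` so corrected `S` recovers
`S_true`. Donor microtimes are exponential with mean
`tau_D0 * (1 - E_state)` plus a fixed IRF offset (delta-function IRF, the
only property the mean-microtime estimator uses), truncated at the PIE
window end by rejection; with the default 20 MHz alternation (25 ns
half-period, 4096 TCSPC bins) the truncation shifts a 4-ns decay by under
0.1 ns, and tests compare against the exact truncated law. Background is
homogeneous Poisson per stream with uniform microtimes; defaults of
1000/600/400 counts/s (Dex/D, Dex/A, Aex/A) are typical filtered-confocal
levels. The laser repetition rate and 50:50 duty cycle are not taken from
the study (it does not state them); they are configurable `pie_scheme()`
parameters.

What the generator does **not** emulate: three-dimensional diffusion
through a Gaussian excitation profile (so burst size and duration
correlations are simpler than in real data), triplet blinking and other
dye photophysics, detector afterpulsing and dead time, and IRF width.
Passing tests therefore certify the statistical machinery of the pipeline,
not instrument-specific artefact handling.

Every stochastic operation takes a seed and uses a single RNG stream, so
identical seeds give bit-identical outputs, including the written
Photon-HDF5-layout files.

## NMR perturbation mapping

For apo intensity `X` with noise floor `dX` and bound intensity `Y` with
noise floor `dY`, the intensity ratio is `R = Y/X` with error, in the
default `"as_printed"` mode, `dR = |R| sqrt(dX/X) + sqrt(dY/Y)` — the
published expression kept verbatim for fidelity. That form is
dimensionally anomalous (it adds a scaled ratio to the square root of a
ratio), so the standard quadrature propagation
`dR = |R| sqrt((dX/X)^2 + (dY/Y)^2)` is available as `"quadrature"`; the
mode used is recorded in every output, and neither is silently preferred.

CSPs combine the two dimensions as `sqrt(dH^2 + (0.251 dC)^2)`, the carbon
axis scaled for the gyromagnetic-ratio difference. Peaks broadened below
the bound spectrum's noise floor take the noise floor as their effective
intensity (an upper bound, hence a lower bound on the attenuation), are
flagged, and appear with an asterisk in outputs; the substitution can only
increase the residue's intensity-loss Z-score. Z-scores use the population
standard deviation over all included peaks, and the intensity statistic is
the loss `1 - R`, so perturbed residues carry positive Z, matching the
red-for-positive colouring convention; significance defaults to `Z > 0`
with no multiple-testing correction, as in the study, and the threshold is
configurable. Overlapped or excluded peaks are dropped only when flagged
in the input tables — exclusions are data provenance, never inferred.

## Hill fits

Titrations are fitted to
`S_obs = S_U + (S_B - S_U)/(1 + (Kd_app/[L])^n)` by unweighted
Levenberg-Marquardt least squares in linear signal space (the study states
no weighting; a weighted option exists). `Kd_app` and `n` are
log-parameterised so positivity needs no constraints, and standard errors
come from the local curvature via the delta method — reported as such,
since the study does not describe its uncertainty estimates. Automatic
initialisation takes the plateaus from the extreme concentrations, the
midpoint crossing for `Kd_app`, and `n = 1`. A `plateau_warning` flags
titrations whose highest concentration is below twice the fitted `Kd_app`
or whose amplitude has a relative SE above 20% — the "no plateau"
pathology in which `S_B` is unconstrained.

## Problem sizes

The test suite and the acceptance script regenerate everything from seeds:
about 5,000 analysed bursts for the corrected-E recovery, 40-s acquisitions
per point of the BVA static grid, 60-s acquisitions for the dynamics
contrasts, 100 fuzzed streams for the burst-search oracle, 100 synthetic
proteins for hotspot recovery and 500 titrations for Hill recovery. These
sizes put Monte-Carlo standard errors comfortably below the tolerances
being asserted while keeping a full run around a minute on one core.

## Known limitations

* Burst-edge background recruitment is mitigated, not eliminated; at the
  default background the mean-microtime lifetime retains a residual of
  roughly +0.01–0.02 `tau_D0` relative to the ideal static line, which is
  why the dynamics conclusion rests on the static-vs-dynamic contrast.
* The simulator's rectangular transits underestimate the burst-size
  dispersion of real diffusion; quantities conditioned on burst brightness
  will differ from real data in detail.
* No photon-by-photon kinetic fitting (dynamic PDA, H2MM) is included;
  BVA and the FRET lines support qualitative dynamics calls only.
* The Photon-HDF5 reader handles the documented field subset and tolerates
  unknown groups, but has not been exercised against vendor conversions.
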