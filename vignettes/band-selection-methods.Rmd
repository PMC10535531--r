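---
title: "Methods: emulated spectra, MLP retrievals and permutation-based band selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: emulated spectra, MLP retrievals and permutation-based band selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Purpose and overall design

`cyanospec` answers a spectral-requirements question: how few, and which,
spectral bands does a visible/near-infrared imager need to retrieve
cyanobacterial pigments — chlorophyll-a (Chl-a), phycocyanin (PC) — and the
cyanobacteria:algae ratio (CAR) over optically complex inland waters?

The workflow is: (1) simulate labeled reflectance spectra over seven optical
water types, at three processing levels — water-leaving remote-sensing
reflectance (RRS, sr⁻¹), top-of-atmosphere reflectance (TOAR) and
bottom-of-Rayleigh reflectance (BRR); (2) resample them through an
overlapping-band imager model (300 Gaussian channels, 500–780 nm, 12 nm
FWHM, decimated to 100 working channels); (3) train a multilayer-perceptron
(MLP) regressor per product; (4) attribute per-channel importance by
permutation; (5) reduce each attribution profile to a nine-band ("P1") and a
three-band ("P2") configuration, and merge these across products into
minimum-viable and optimal syntheses.

Everything is seeded: `generate_dataset()` and `run_experiment()` are pure
functions of their configuration and seed.

## The bio-optical emulator

The generator is a parametric *emulator* of an inland-water radiative
transfer study, not a radiative-transfer code. It aims at the statistical
structure a band-selection analysis depends on — which spectral features
carry information about which label — rather than radiometric fidelity.

**Water states.** Seven water types (oligotrophic, mixed eutrophic,
sediment-dominated, CDOM-dominated, eukaryote bloom, cyanobacterial bloom,
scum) are sampled with log-uniform concentration priors: Chl-a from
0.1 µg/L (oligotrophic) to 10,000 µg/L (scum), NAP up to 200 g/m³
(sediment-dominated), CDOM absorption at 440 nm up to 10 m⁻¹
(CDOM-dominated). CAR is uniform on [0, 1] except in the bloom types
(eukaryote U(0, 0.3), cyanobacterial U(0.7, 1)). CAR is defined as a
*fraction* of phytoplankton biomass, not an unbounded ratio: it enters the
model only as a linear mixing weight, so a fraction is the only reading
under which the mixing formula is well-defined.

**IOPs.** Phytoplankton absorption mixes two chlorophyll-specific bases,
`a_ph = chl · ((1−car)·a*_alg + car·a*_cy)`. Both bases are sums of Gaussian
pigment bands (m²/mg): the algal basis has the chlorophyll Soret (440 nm)
and red (675 nm) bands plus a carotenoid shoulder at 490 nm; the
cyanobacterial basis replaces the carotenoid shoulder with the phycocyanin
band at 620 nm (amplitude `0.0095 · pc_to_chl`) and a weak 650 nm
phycocyanobilin shoulder. Both bases carry a chl-b/c shoulder at 620 nm with
amplitude 0.0029 m²/mg, solved so that `a*(620) ≈ 0.24 · a*(665)` for the
pure algal basis. This matters: the PC label is computed by the standard
chlorophyll correction

PC = (a_ph(620) − 0.24 · a_ph(665)) / a*_pc(620),  a*_pc(620) = 0.0095 · (0.5 + 0.5·CAR),

clamped at zero, and without the shoulder the correction (tuned for real
pigment spectra, which absorb appreciably at 620 nm even without PC) would
overshoot idealized Gaussian bases and clamp PC to zero in most mixed
waters. With it, the correction removes the non-PC contribution almost
exactly, PC > 0 whenever CAR > 0, and PC:Chl spans realistic values. The
PC label is computed from the state's own IOPs at sampling time, so
`phycocyanin_label()` round-trips by construction (relative error < 1e-6,
asserted in tests). The decomposition constants are deliberately
config-exposed (`optical_constants()`): they are standard in form but their
published calibrations vary by study.

CDOM and NAP absorption are exponentials (CDOM slope U(0.010, 0.020) nm⁻¹,
NAP slope 0.011 nm⁻¹, a*_NAP(440) = 0.030 m²/g). Particulate backscattering
is a power law in wavelength (exponent U(0.3, 1.5)) with magnitude
`0.004·chl^0.63 + 0.005·nap` m⁻¹ at 550 nm, multiplied by `(1 + car)`
beyond the red edge (logistic ramp at 700 nm) to mimic the strong
near-infrared scattering of gas-vacuolate cyanobacteria. Pure-water
absorption is a bundled 5 nm literature-style table (it exceeds 2.5 m⁻¹ by
750 nm, which drives the red-edge reflectance features the selection
finds); pure-water backscattering is the standard λ⁻⁴·³² law.

**Reflectance.** The elastic signal uses the Gordon-style quadratic:
`u = bb/(a+bb)`, `rrs = 0.0949·u + 0.0794·u²`, transferred above the
surface as `Rrs = 0.52·rrs/(1 − 1.7·rrs)`. Sun-induced chlorophyll
fluorescence adds two Gaussian emissions at 685 nm (FWHM 25 nm) and 730 nm
(FWHM 50 nm, amplitude ratio 0.2), with amplitude
`5e-4 · chl · yield · (1 − 0.7·car)` sr⁻¹ — the CAR term encodes the
weakly fluorescing photosystem-I pool of cyanobacterial Chl-a, the yield is
sampled U(0, 0.02). Surface scums, where water-column closure fails, are
emulated by blending with a canonical vegetation red-edge spectrum
(`0.05 + 0.45/(1+exp(−(λ−715)/10))`, weight = scum fraction).

**Atmosphere.** Each water gets two randomized atmospheres. TOAR is
analytic single scattering: Rayleigh path reflectance from the standard
optical-thickness closed form with the (3/4)(1+cos²Θ) phase; aerosol path
reflectance from an Ångström-law optical depth (τ_a(550) ~ U(0.02, 0.3),
exponent U(0.5, 2)), Henyey–Greenstein phase (g = 0.7), single-scattering
albedo 0.95; two-way diffuse transmittances `exp(−0.5·τ_r·M)` and
`exp(−0.25·τ_a·M)` with air-mass factor M (the aerosol factor is halved
relative to Rayleigh because forward-peaked scattering removes little light
from the diffuse beam); plus vegetation adjacency stray light (weight
U(0, 0.3)). BRR inverts the Rayleigh terms only:
`BRR = (TOAR − ρ_r)/t_r`, leaving aerosol and adjacency in — exactly
algebraic, so the aerosol-free inversion recovers π·Rrs to machine
precision (asserted at 1e-9).

**What the emulator does not contain** — and hence what passing tests do
not show about real data: no radiative-transfer fidelity (no multiple
scattering, no gaseous absorption lines), no sensor noise, no sun glint, no
bidirectional effects, no AERONET-derived aerosol climatology, and
water-type priors that are plausible rather than fitted to a measured IOP
library. Scum CAR is sampled U(0, 1) although real scums are almost always
cyanobacterial. Conclusions about *which wavelengths matter* transfer to
the extent that the emulator places the right physics at the right
wavelengths; absolute error magnitudes do not transfer.

## Instrument model

300 evenly spaced channel centers span 500–780 nm (spacing 280/299 ≈
0.94 nm — the heavily overlapping regime). Each channel is a Gaussian
response with σ = FWHM/(2√(2 ln 2)), truncated at ±3σ and renormalized to
unit sum on the 1 nm simulation grid, so flat spectra are preserved exactly
and resampling is exactly linear. `decimate(step = 3)` keeps every third
channel (100 working channels ≈ 2.8 nm spacing); `bin_adjacent()` models
on-board SNR binning by group means. The working FWHM is 12 nm, with 8 nm
as the comparison configuration.

## Retrieval protocol

Features are channel reflectances, log10-transformed with a 1e-6 floor,
then standardized per channel with means/scales fitted on training rows
only. Pigment targets are log10-transformed (floor 1e-3 µg/L); CAR is
untransformed. The regressor is a fixed MLP — five hidden layers of 100
rectified-linear units, single linear output — trained with Adam
(batch 256, learning rate 1e-3) on mean-absolute-error loss, with early
stopping on a 10% inner validation split (patience 10, epoch cap 200 by
default; the headline runs cap at 100, which early stopping rarely
reaches). The trainer is a compiled core with a self-contained RNG, so a
seed reproduces training exactly.

Model selection protocol: an outer record-level 80/20 split reserves an
untouched holdout; within the 80%, optional 5-fold cross-validation reports
fold means ± sd as a sampling-bias check; the reported metrics come from a
single model trained on the full 80% and applied to the 20%. That single
model is also the one attributed. Because the split is record-level, the
two atmospheres of one water can straddle the split for TOAR/BRR — a mild
optimistic bias shared by all configurations being compared, so it does not
affect the orderings the analysis rests on.

Metrics: R² (coefficient of determination) computed on the model's target
scale — log10 for pigments, raw for CAR — so that decade-spanning
concentrations are not reduced to a bloom-only statistic; MAPE (percent,
observations ≤ 0.01 excluded, which matters for CAR in purely algal
waters); RMSELE = RMSE of log10(x + 1e-3), with negative inputs clamped to
zero first so the statistic is total even when a ratio regressor
undershoots.

## Attribution and band selection

Permutation importance uses the error measure L = 1 − R², so the baseline
e_orig is near 0 for a good model and importance FI_j = mean(e_perm) −
e_orig is positive-is-important. Each feature column is shuffled 5 times
(without replacement) with independent seeded permutations on the holdout.
A perfectly informative standard-normal feature under a pass-through model
has E[FI] = 2, because a randomly permuted perfect predictor has expected
R² of −1; this closed form anchors the Monte-Carlo oracle test. Constant
columns score exactly zero. Correlated neighboring channels share
importance — the known caveat of permutation attribution on spectra — and
no decorrelation correction is applied; the selection step compensates by
enforcing minimum peak separations.

Peak finding smooths the profile with a 3-channel moving average (edges
truncated), takes strict local maxima (endpoints qualify against their one
neighbor), and greedily accepts peaks in descending attribution subject to
a minimum separation, ties broken toward the lower wavelength. P1 takes the
9 top peaks at ≥ 9 nm separation; P2 takes the 3 top peaks at ≥ 30 nm
separation (one per broad importance region). The separations were chosen
to be consistent with the minimum gaps observed in the published CyanoSat
configuration tables, and both are config-exposed; the procedure itself
(smoothing, strictness, greedy suppression) is otherwise unconstrained by
any published description, so it is deliberately simple and deterministic.
P2 is *not* constrained to be a subset of P1: the published tables do not
respect such a constraint in every cell, and enforcing it would couple the
two selections for no analytical gain.

`merge_configs()` unions selections, collapsing centers within a tolerance
(default 0 nm: exact duplicates) and counting how many input selections
contributed each band — the analogue of bolding repeated bands in a
configuration table. Merging the published per-product three-band sets
reproduces the published minimum-viable synthesis exactly for all three
data types; this is an in-data identity and is asserted exactly.

## Numerical choices and degenerate inputs

- Channel count wins over nominal spacing: "approximately 1 nm sampling"
  and "300 channels over 500–780 nm" conflict slightly; the package fixes
  300 channels. The published P1 tables list two centers (782, 788 nm)
  beyond 780 nm; the instrument model does not extrapolate and the
  selection cannot produce them.
- Standardization guards constant channels (scale < 1e-12 → 1).
- `r_squared()` refuses zero-variance observations; `mape()` refuses
  non-positive observations (callers pre-filter CAR at 0.01).
- SRF truncation beyond ±3σ is renormalized; at FWHM = grid spacing the
  response collapses toward nearest-grid-point sampling (asserted ≤ 1e-3
  deviation on smooth spectra).
- Selection failures (fewer peaks than requested) raise an error naming
  the deficit; the experiment driver logs and continues rather than
  aborting a sweep.

## Problem sizes

The headline emulated experiment uses 10,000 waters (10,000 RRS records;
8,000 training / 2,000 holdout), 100 channels, three products, and Full,
P1 and P2 configurations — chosen as the scale at which holdout metrics
stabilize (orderings are unchanged from 3,000 waters upward). Unit tests
use 250–700 waters with 5–25 epoch caps, enough to exercise every code
path deterministically. The analysis scripts under `analysis/` run at
3,000 waters across all three data types.

## Known limitations

The emulator's band placements follow from its own pigment bases, so
band-selection output validates the *method*, not a specific published
band list; agreement with published configurations (e.g. the PC attribution
peak at 620 nm, the green-peak and red-edge selections) is qualitative.
CAR retrieval from three bands is poor (holdout R² ≈ 0.15 at RRS) — the
expected negative result that cyanobacteria discrimination needs more than
a minimal band set. MAPE values are large in an absolute sense because the
dataset spans four orders of magnitude of concentration including
near-zero PC waters; they are comparable *between* configurations, which
is what the analysis uses.
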