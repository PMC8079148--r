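# transkin

Transient enzyme kinetics and time-resolved fluorescence anisotropy in R.

`transkin` is for biophysicists analyzing the catalytic cycle of
nucleic-acid processing enzymes (the motivating system is an
ATP-dependent dsRNA-specific endoribonuclease of the Dicer family) with
two complementary experiments:

* **stopped-flow fluorescence kinetics** — Cy3 intensity, PIFE and
  Cy3→Cy5 FRET traces recorded under pseudo first-order conditions and
  analyzed with single or double exponential rate equations,
  `RFU = Σ Aᵢ e^(−k_obs,i·t) + offset`, with `k_obs = ln2 / t½`;
* **TCSPC fluorescence lifetimes and anisotropy** — paired polarized
  photon-count histograms processed via channel alignment, background
  subtraction, g-factor tail-matching, `I_tot = g·I_VV + 2·I_VH`,
  `r(t) = (g·I_VV − I_VH)/(g·I_VV + 2·I_VH)`, and exponential decay
  fits yielding rotational correlation times φᵢ, amplitudes Aᵢ,
  limiting anisotropy r∞ and Δr = r₀ − r∞.

Because raw instrument records for such studies are typically not
deposited, the package includes first-class synthetic-data generators
for both instruments: mass-action simulation of the catalytic-cycle
reaction schemes (two-step binding, chase dissociation,
unwinding/rewinding, translocation, cleavage/release) with realistic
noise, and a TCSPC simulator with Gaussian IRF, inter-channel delay,
detection-efficiency mismatch, neutral-density attenuation, dark
background and Poisson counting. Derived quantities — residence times,
Eyring activation free energies `ΔG‡ = −RT·ln(k_off·h/(k_B·T))`,
kinetically determined two-step dissociation constants
`K_d,app = (k₋₁/k₁)·k₋₂/(k₂+k₋₂)`, and catalytic-cycle summary
tables — are computed from the fitted microscopic rates.

## Worked example

Simulate a chase-dissociation experiment (enzyme–RNA complex mixed with
excess unlabeled competitor) with the blunt-terminus off-rates 0.12 and
0.002 s⁻¹, fit it, and derive the residence time and activation energy:

```r
library(transkin)

sch   <- kinetic_scheme("dissociation_chase",
                        rates = c(k_minus1 = 0.12, k_minus2 = 0.002))
trace <- simulate_sf_trace(sch, seed = 1, sigma = 0.02)
fit   <- select_model(trace)
fit
#> 2-phase exponential fit (2000 points)
#>   phase 1: A = 0.0786, k_obs = 0.126 s^-1 (t1/2 = 5.52 s)
#>   phase 2: A = 0.711, k_obs = 0.00201 s^-1 (t1/2 = 344 s)
#>   offset = 0.21, reduced chi^2 = 0.982, runs-test p = 0.374

residence_time(fit$phases$k_obs[2])   # half-life of the bound complex
#> [1] 344.2528
eyring_dg(fit$phases$k_obs[1])        # activation energy, kcal/mol
#> [1] 18.67289
```

The model selector kept two phases and recovered both injected
off-rates (0.126 vs 0.12, 0.00201 vs 0.002 s⁻¹); the slow phase gives a
~345 s residence time and the fast off-rate an ~18.7 kcal/mol barrier.
A reduced χ² near 1 and a non-small runs-test p indicate the residuals
are consistent with the 2% noise model.

The TCSPC side works the same way end to end:

```r
inst <- instrument_model(nd_attenuation = 10, background_rate = 2,
                         total_counts = 1e7)
decay   <- simulate_decay(dsrna_free_model(), inst, seed = 1)
control <- simulate_decay(cy3_nhs_control(), inst, seed = 2)
process_decay(decay, control = control)
```

which calibrates g on the free-dye control, builds r(t), and fits the
two rotational correlation times of the free duplex (≈0.34 and ≈2.6 ns).

## Package tour

| Area | Functions |
| --- | --- |
| Schemes & simulation | `kinetic_scheme`, `simulate_scheme`, `observed_eigenrates`, `to_trace`, `add_noise`, `simulate_sf_trace` |
| Trace fitting | `fit_exponentials`, `select_model`, `average_traces`, `normalize_trace`, `kobs_from_halflife` |
| Derived kinetics | `residence_time`, `eyring_dg`, `delta_delta_g`, `two_step_kd`, `summarize_cycle` |
| TCSPC simulation | `photophysics_model`, `instrument_model`, `simulate_decay`, `ideal_polarized_intensities` |
| TCSPC analysis | `align_channels`, `subtract_background`, `estimate_g`, `total_intensity`, `anisotropy_trace`, `fit_lifetime`, `fit_anisotropy`, `refit_fast_phase`, `process_decay` |
| I/O & workflows | `read_trace_csv`, `write_trace_csv`, `read_tcspc_ascii`, `write_tcspc_ascii`, `run_workflow` |

The methods vignette
(`vignettes/transient-kinetics-and-anisotropy.Rmd`) documents the
models, the numerical choices, and the limits of what the synthetic
generators emulate.
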