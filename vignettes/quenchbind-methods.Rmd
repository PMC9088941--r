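---
title: "Methods: fluorescence-quenching binding analysis with quenchbind"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fluorescence-quenching binding analysis with quenchbind}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quenchbind)
```

# Scope and model

`quenchbind` implements the standard analysis chain for steady-state
fluorescence-quenching studies of ligand–protein binding, the companion
time-resolved, spectral-shape and enzyme-activity experiments, and the
post-simulation trajectory observables used to corroborate the binding
picture. The chain is:

1. **Quenching ratios.** Intrinsic protein fluorescence (Trp/Tyr, excited
   near 280 nm) is titrated with ligand; F₀/F is read per concentration.
2. **Stern–Volmer fit.** F₀/F = 1 + K_SV[Q] by ordinary least squares; with
   the unquenched mean lifetime τ₀, the apparent bimolecular rate constant
   is K_q = K_SV/τ₀.
3. **Mechanism call.** Static vs. dynamic quenching from three independent
   criteria (below).
4. **Binding constants.** lg[(F₀−F)/F] = lg K_a + n lg[Q] over the nonzero
   concentrations.
5. **Thermodynamics.** ln K_a = −ΔH/RT + ΔS/R across temperatures
   (R = 8.314 J mol⁻¹ K⁻¹ exactly), ΔG = ΔH − TΔS, and a sign-rule force
   label.
6. **Structure/function corroboration.** Synchronous-scan shift analysis,
   EEM peak attenuation, CD band descriptors, relative enzyme activity, and
   trajectory metrics (RMSD/RMSF/Rg/distances/H-bonds).

Out of scope by design: docking and its scoring, running any MD engine,
binding-energy estimation from trajectories, CD secondary-structure
deconvolution, inner-filter corrections, and modified (Lehrer) Stern–Volmer
analysis.

# Conventions and assumptions

**[Q] is total added ligand.** The fits use the added ligand concentration,
not free ligand; this matches the near-universal practice for these
double-log plots and means K_a is an apparent constant. No free-ligand
iteration is attempted.

**F is read at a fixed wavelength.** `quench_ratios()` defaults to the
wavelength of the unquenched spectrum's maximum. Because static quenching
attenuates the band without moving it, peak-tracking and fixed-wavelength
readings agree on clean data; integrated band area and user-chosen
wavelengths are available as modes.

**Regression is unweighted OLS** everywhere a line is fit (Stern–Volmer,
double-log, Van't Hoff), matching the linear plots these studies publish. A
weighted Van't Hoff variant exists but is off by default.

**K_a enters ln() unit-bearing** (L mol⁻¹). This reproduces the published
convention; the implied standard state is absorbed in ΔS. It is a
convention, not a thermodynamic claim.

**ΔG is computed from unrounded ΔH and ΔS**, then rounded only for display.
Computing from rounded inputs loses ~0.01 kJ/mol at the highest temperature.

**τ₀ is stored in ns** and converted to seconds only inside the K_q
division, which avoids the classic 10⁹ unit slip.

# The mechanism decision rule

Three criteria each cast a vote:

- **K_SV trend**: strictly decreasing with temperature (at a 1% relative
  tolerance per step, absorbing fit noise) → static; strictly increasing →
  dynamic; otherwise the criterion abstains as inconclusive.
- **K_q ceiling**: K_q above 2 × 10¹⁰ L mol⁻¹ s⁻¹ — the diffusion-controlled
  maximum for collisional quenching of a biopolymer — → static; at or below
  → dynamic.
- **Lifetime invariance**: excited-state lifetime unchanged on ligand
  addition (relative spread ≤ 2% by default) → static; shortening →
  dynamic. Skipped when no lifetime data exist.

The label is `static` or `dynamic` only when at least two criteria agree and
none contradicts; anything else is `inconclusive`. Published analyses apply
these criteria informally; the quorum rule makes the call deterministic and
auditable (the full evidence table is returned).

# Lifetime fitting

Decays are tail-fit: the window runs from the channel of maximum counts to
the last channel with at least 10 counts (the window is user-overridable;
published work rarely states one). The model is a sum of 1–3 exponentials
with Poisson weights w = 1/max(count, 1). Lifetimes are searched by a
profiled objective — for fixed lifetimes the amplitudes are a weighted
linear solve — with deterministic multi-starts from log-spaced initial
lifetimes, so fits are reproducible without touching the RNG. Reduced χ²
uses dof = n_window − 2k; on well-formed simulated data it calibrates to
≈ 1, the acceptance band being [0.8, 1.2].

Amplitudes are reported as fractions summing to 1 and components sorted by
descending amplitude. `mean_lifetime()` computes τ_ave = Σ αᵢτᵢ; percent
amplitudes are detected (sum near 100) and divided by 100 but **not**
renormalized, so published rounded components reproduce published τ_ave
values digit for digit. Model order is user-fixed (3 for the reference
data) or chosen as the smallest order with reduced χ² < 1.3 under
`n_components = "auto"`.

# The synthetic-data module

The generators state a world and keep it fixed:

- **Titrations**: protein 16 µM, ligand 0–24 µM in 4 µM steps (the
  reference design), a single Gaussian emission band at 345 nm (σ = 25 nm)
  on a 300–500 nm grid, and multiplicative Gaussian noise (shot-noise
  proxy) with default σ = 1%. Two exact models are provided — Stern–Volmer
  (F₀/F − 1 linear in [Q], default K_SV = 4.142 × 10⁴ L mol⁻¹) and
  double-log ((F₀−F)/F = K_a[Q]ⁿ, default K_a = 8.978 × 10⁴, n = 1.073) —
  because no single dataset can satisfy both relations exactly unless
  n = 1 and K_a = K_SV. Quenching is uniform across the band (no shift),
  consistent with static complex formation.
- **Decays**: Poisson counts around total_counts · Σ αᵢ e^(−t/τᵢ), channel
  1 at the decay peak, no instrument-response convolution — the same model
  the tail fitter assumes, so recovery tests are meaningful. Default truth
  is the reference tri-exponential (τ = 1.836/5.719/0.474 ns,
  α ≈ 16.7/76.0/7.3%), 1024 channels of 0.05 ns.
- **EEMs**: Gaussian peaks on a 200–400 nm grid (5 nm step) plus a
  first-order Rayleigh ridge along λ_ex = λ_em.
- **Trajectories**: a deterministic helical Cα trace with iid Gaussian
  jitter per frame and optional random rigid motion — a fixture for the
  metric operators, not a physical simulation.

What a green test does *not* establish: real spectra have wavelength-
correlated noise, inner-filter effects, baseline drift and Raman scatter;
real decays have an instrument response; real trajectories have correlated,
anisotropic fluctuations. The generators deliberately omit all of these, so
passing tests certify the *estimators*, not instrument robustness. The raw
intensity scale (`f0_peak`) is arbitrary units throughout; only ratios
matter downstream.

All generators are bit-reproducible under their integer `seed`.

# Numerical choices and degenerate inputs

- Peak positions in scans are located by 3-point parabolic interpolation
  around the grid maximum, resolving sub-grid shifts; the shift verdict
  tolerance is 2 nm (under half the 5 nm EEM step). Flat scans and maxima
  pinned to the grid edge are errors.
- The EEM Rayleigh mask is ±10 nm about the diagonal; second-order scatter
  (λ_em ≈ 2λ_ex) masking exists but is off by default. Candidate peaks
  below 5% of the strongest off-diagonal cell are discarded as ripple.
- Superposition is Kabsch via SVD with the determinant sign correction, so
  reflections are never returned; RMSD of a mirror image is strictly
  positive.
- RMSF superposes frames onto their mean structure (two passes) before
  measuring displacements; for iid jitter σ the per-atom RMSF approaches
  σ√3 with a small downward bias from the 6 rigid degrees of freedom
  absorbed by superposition (≈ 2% at 50 atoms) — inside the 5% acceptance
  band.
- Ligand–residue distance is the closest atom pair by default (a
  centre-of-mass variant is provided) because published "distance between
  ligand and residue" values rarely state the convention.
- H-bond detection attaches hydrogens to donor heavy atoms by a 1.25 Å
  covalent cutoff in the first frame; donors with no hydrogen raise an
  error naming them. Defaults d_max = 3.5 Å (H···A), angle_min = 120°
  are stated package defaults, not a published criterion.
- Unknown elements get mass 12.0 with a warning in mass-weighted Rg.
- Double-log fits drop points with F ≥ F₀ (no net quenching) with a
  warning; fewer than 3 surviving points is an error. Zero or negative
  intensities at the evaluation wavelength name the offending
  concentration.
- An exactly zero ΔH or ΔS makes the force label indeterminate (error from
  `classify_force()`; `vant_hoff()` converts that to an `NA` label rather
  than failing the whole analysis).

# Open design points, resolved

- **Renormalization of printed amplitudes**: published percent amplitudes
  often sum to 99.99 after rounding. We use them as printed (÷100 only):
  renormalizing changes τ_ave in the fourth decimal and breaks agreement
  with published means; the un-renormalized dot product is evidently what
  instrument software reports.
- **Ksv-trend strictness**: strict monotonicity is evaluated with a 1%
  relative tolerance so that fit noise cannot flip a clear trend into an
  abstention.
- **Quorum rule**: two agreeing criteria with no contradiction; a 1–1
  split (e.g. falling K_SV but sub-ceiling K_q and no lifetime data) is
  inconclusive rather than a coin flip.
- **Pipeline determinism**: no stage consumes randomness; rerunning
  `run_pipeline()` on the same config reproduces every number and the same
  config hash.

# Known limitations

- The double-log intercept extrapolates to lg[Q] = 0 across ~4–5 decades,
  so K_a is very noise-sensitive: at 1% multiplicative noise K_SV is
  recoverable to a few percent, but K_a can be off severalfold. This is a
  property of the method, not the implementation; error bars on K_a should
  come from replicate titrations.
- Van't Hoff over three temperatures spanning 12 K assumes constant ΔH;
  no ΔCp term is offered.
- CD analysis is qualitative (band positions and signs only).
- Only multi-model PDB trajectories are read; large MD formats (DCD/XTC)
  are out of scope.
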