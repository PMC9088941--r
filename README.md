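# quenchbind

Characterizing how a small-molecule ligand binds a protein from
fluorescence-quenching titrations and their companion experiments. The
package is aimed at spectroscopists and computational chemists running
drug–protein interaction studies: it takes titration spectra, TCSPC lifetime
histograms, synchronous scans, excitation–emission matrices (EEMs),
enzyme-assay absorbances and MD trajectory snapshots, and turns them into
binding constants, a quenching-mechanism call, binding thermodynamics with a
dominant-force label, and structural/dynamic summaries. A synthetic-data
module generates every input class with known ground truth, so the whole
pipeline is testable without instrument files.

## The models

With F₀ and F the fluorescence intensities before and after adding quencher
at concentration [Q]:

- **Stern–Volmer**: F₀/F = 1 + K_SV·[Q]; the slope K_SV and the bimolecular
  rate constant K_q = K_SV/τ₀ (τ₀ the unquenched lifetime) diagnose the
  quenching mechanism. K_q far above the diffusion limit of
  2 × 10¹⁰ L mol⁻¹ s⁻¹, K_SV falling with temperature, and an unchanged
  lifetime all indicate *static* quenching (ground-state complex formation).
- **Double-log binding**: lg[(F₀ − F)/F] = lg K_a + n·lg[Q] gives the binding
  constant K_a and the apparent number of high-affinity sites n.
- **Van't Hoff / Gibbs–Helmholtz**: ln K_a = −ΔH/RT + ΔS/R and
  ΔG = ΔH − TΔS; the signs of ΔH and ΔS classify the dominant non-covalent
  force (both negative → hydrogen bond / van der Waals; both positive →
  hydrophobic; ΔH<0, ΔS>0 → electrostatic).
- **Mean lifetime**: τ_ave = Σ αᵢτᵢ from a 1–3 exponential tail fit of the
  TCSPC histogram with Poisson weights (reduced χ² ≈ 1 on well-formed data).
- **Trajectory observables**: Kabsch-superposed RMSD, per-residue RMSF,
  radius of gyration, closest-contact ligand–residue distances, and geometric
  hydrogen-bond counts (H···acceptor ≤ 3.5 Å, donor–H···acceptor ≥ 120° by
  default).

## Worked example

Simulate a three-temperature titration study with known binding constants,
fit a synthetic photon-counting decay for τ₀, and run the whole chain:

```r
library(quenchbind)

kas <- c(8.978e4, 4.998e4, 1.782e4)          # ground-truth Ka (L/mol)
series <- mapply(function(T, ka) {
  simulate_titration(quench_sim_spec(ka_true = ka, noise_sd = 0, seed = T),
                     temperature = T, model = "double_log")
}, c(298, 304, 310), kas, SIMPLIFY = FALSE)

decay <- simulate_decay(decay_sim_spec(total_counts = 1e6, seed = 1))
report <- run_pipeline(list(titrations = series, decays = list(decay)))

report$binding
#> # A tibble: 3 × 5
#>   temperature     ka     n r.squared n_points
#>         <dbl>  <dbl> <dbl>     <dbl>    <int>
#> 1         298 89780.  1.07         1        6
#> 2         304 49980.  1.07         1        6
#> 3         310 17820.  1.07         1        6

report$mechanism
#> <mechanism_call> label: static
#> # A tibble: 3 × 2
#>   criterion           verdict
#> 1 ksv_trend           static
#> 2 kq_ceiling          static
#> 3 lifetime_invariance static

report$thermo
#> <thermo_result> dH = -103.30 kJ/mol, dS = -251.16 J/mol/K (R^2 = 0.97166)
#> # A tibble: 3 × 2
#>   temperature delta_g
#> 1         298   -28.4
#> 2         304   -26.9
#> 3         310   -25.4
#> dominant force: hydrogen-bond/van-der-Waals (spontaneous at all temperatures)
```

Reading the output: the binding fits recover the generator's Ka at each
temperature exactly (noiseless data); all three mechanism criteria vote
static — Ksv falls with temperature, K_q ≈ 10¹³ L mol⁻¹ s⁻¹ is far above the
diffusion limit, and the fitted mean lifetime (4.69 ns, reduced χ² = 0.98)
is invariant; the Van't Hoff line over the recovered Ka ladder gives
ΔH = −103.3 kJ/mol and ΔS = −251.2 J/mol/K, i.e. an enthalpy-driven,
spontaneous association dominated by hydrogen bonding / van der Waals
contacts, with ΔG rising from −28.4 to −25.4 kJ/mol as temperature
destabilizes the complex.

Individual stages are plain functions — `quench_ratios()`,
`stern_volmer_fit()`, `double_log_fit()`, `classify_mechanism()`,
`vant_hoff()`, `fit_decay()`, `sync_shift()`, `eem_peaks()`,
`inhibition_rate()`, `rmsd_series()`, `hbond_count()`, … — and plain-text
readers/writers (`read_table()`, multi-model PDB support) cover all the
formats.

## Acceptance script

`scripts/acceptance.R` recomputes the study's headline numbers from scratch
with the installed package — the three amplitude-weighted mean lifetimes
from published decay components, and the Van't Hoff enthalpy and entropy
from the published per-temperature binding constants — and writes them as
JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
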