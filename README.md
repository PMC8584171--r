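# ternafac

Trilinear (CP/PARAFAC) isolation of weak-interaction factors from
ATR-FTIR spectra of ternary solutions: a peptide model
(*N*-methylacetamide, NMA), water, and an osmolyte.

## The problem and the method

Stabilizing osmolytes (TMAO, glycine, betaine) and destabilizing ones
(alkylureas) shift protein stability, but in an FTIR spectrum of a
ternary solution their fingerprints are buried under water's OH
bending band and both solutes' own absorptions. `ternafac` targets
this by measuring spectra over a full two-way concentration design —
both solute molarities varied on a grid — so the series forms a
three-way tensor (wavenumber × c_NMA × c_osmolyte) that can be
decomposed trilinearly:

    X[p, i, j] ≈ Σ_r A[p, r] · B[i, r] · C[j, r]

Unlike two-way factor methods, the trilinear model is unique under
mild conditions, so the factor spectra `A[, r]` have direct physical
meaning. Before decomposition the dominant known contributions are
removed: water is subtracted with composition-dependent coefficients
(volume-additive water molarity), then one solute's per-molar spectrum
(fitted from the binary edge of the design), yielding two *isolated*
series. Factors of each isolated series are classified by Tucker
congruence against the pure component spectra and against the
*derivative spectrum* (the concentration slope of molar absorbance,
the signature of a solute affected by its own concentration). What
matches neither is a **candidate interaction factor** — a factor whose
loadings vary with both concentrations. Negative (difference) bands
are meaningful throughout; non-negative decompositions are
deliberately not offered.

The package includes:

* `scattered_spectra` / `spectra_grid` containers with wide-CSV +
  JSON/YAML sidecar I/O and a minimal JCAMP-DX reader,
* scattered-to-grid interpolation by local plane fits (Delaunay
  barycentric or moving-LS planes) with strict convex-hull safety,
* water/solute subtraction and component estimation,
* derivative spectra and congruence matching,
* unconstrained CP-ALS with restarts, normalization/sign conventions,
  degeneracy resolution, and incremental rank selection
  (redundancy / noise-factor / fit-plateau stopping),
* a synthetic-data generator with closed-form ground truth
  (ideal / stabilizer / denaturant scenarios),
* a pipeline driver (`run_pipeline()`) and a CLI
  (`inst/cli/ternafac`).

## Worked example

Simulate a denaturant-like system (a bilinear NMA–osmolyte interaction
with a wave-like difference band is planted), run the full chain, and
inspect the NMA-isolated series:

```r
library(ternafac)
cfg <- pipeline_config(scenario = "denaturant", seed = 1,
                       noise_sd = 0, jitter_sd = 0,
                       n_restarts = 6, max_iter = 600)
report <- run_pipeline(cfg)
print(report)
#> Pipeline run report (scenario: denaturant)
#>   36 input spectra -> 5x5 grid
#>   nma_isolated: rank 3 (fit_plateau), labels: pure_component, concentration_change, candidate_interaction
#>   osm_isolated: rank 3 (fit_plateau), labels: pure_component, candidate_interaction, concentration_change

print(report$nma_isolated$labels, digits = 3)
#>   factor                 label congruence_pure congruence_derivative matched_reference
#> 1      1        pure_component          1.0000                 0.399               nma
#> 2      2  concentration_change          0.0329                 1.000          d/dc nma
#> 3      3 candidate_interaction          0.3187                 0.459              <NA>

print(report$nma_isolated$scan)
#> Rank scan: chose 3 factors (fit_plateau)
#>   R = 2: rel_error = 0.01862
#>   R = 3: rel_error = 2.191e-05
#>   R = 4: rel_error = 3.006e-09
```

Reading the output: the 36 simulated solutions were interpolated onto
the 5 × 5 grid; the rank scan stepped 2 → 3 → 4 factors and stopped
when the fourth added essentially no fit. Of the three factors, one
reproduces the pure NMA spectrum (congruence 1.00), one the NMA
derivative spectrum (1.00), and the third matches neither reference —
the interaction factor, whose spectral loading recovers the planted
interaction band. Rerunning with `scenario = "stabilizer"` (no
interaction term) yields rank 2 and only
`pure_component` / `concentration_change` labels — the
stabilizer/denaturant contrast in one switch.

The same chain runs from the shell:

```sh
inst/cli/ternafac simulate --scenario denaturant --seed 1 --out sim/
inst/cli/ternafac regrid --in sim/series.csv --out grid.csv
inst/cli/ternafac isolate --grid grid.csv --water sim/water.csv --mode both --out iso/
inst/cli/ternafac decompose --tensor iso/nma_isolated.csv --rank auto --out model.json
```

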