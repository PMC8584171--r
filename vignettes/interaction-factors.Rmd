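---
title: "Isolating interaction factors from FTIR spectra of ternary solutions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Isolating interaction factors from FTIR spectra of ternary solutions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ternafac)
```

## The problem

Osmolytes modulate protein stability: trimethylamine *N*-oxide,
glycine and glycine betaine stabilize the folded state, alkylureas
destabilize it. Whether they act through direct contacts with the
peptide backbone or indirectly through water is hard to read off
ATR-FTIR spectra of ternary solutions (peptide model + water +
osmolyte), because every spectrum superimposes the solvent, both
solutes, and whatever weak interaction signal exists -- all in heavily
overlapping bands (the amide I region, 1700--1600 cm⁻¹, sits right on
water's OH bending band).

`ternafac` implements a decomposition strategy for this situation.
Spectra are measured on a full two-way concentration design: both the
peptide-model concentration $c_1$ (*N*-methylacetamide, NMA) and the
osmolyte concentration $c_2$ are varied over a grid. The series then
has three natural axes -- wavenumber, $c_1$, $c_2$ -- and can be
decomposed *trilinearly*, which (unlike two-way PCA/MCR) yields
factors that are unique under mild conditions, without rotational
post-processing. The trilinear (CP/PARAFAC) model is

$$X_{pij} \approx \sum_{r=1}^{R} A_{pr}\,B_{ir}\,C_{jr},$$

where $A$ holds factor spectra, and $B$, $C$ hold their loadings along
the two concentration axes. Factors whose loadings vary with *both*
concentrations carry the interaction information.

Because the dominant contributions (water, each solute alone) would
swamp the decomposition, they are removed first: the water spectrum is
subtracted with composition-dependent coefficients, then one solute's
per-molar spectrum, giving two "isolated" series (one dominated by NMA
signal, one by osmolyte signal) that are decomposed separately.
Negative bands produced by the subtraction are meaningful -- they
encode band shifts and width changes -- so nothing in the package
clips negatives and non-negative decomposition variants are
deliberately not offered.

## Pipeline stages

`run_pipeline()` executes, with artifacts written between stages:

1. **Input.** A `scattered_spectra` series (wide CSV + sidecar with
   per-column compositions) and a pure-water reference, or one of the
   built-in synthetic scenarios.
2. **Regridding.** Preparation error makes the measured design
   unevenly spaced, which trilinear decomposition cannot tolerate.
   For every wavenumber, local planes are fit through the measured
   $(c_1, c_2)$ points and evaluated on an evenly spaced grid strictly
   inside the convex hull of the design (`interpolate_grid()`). The
   default is barycentric interpolation on a Delaunay triangulation
   built once and reused across wavenumbers; a moving
   least-squares plane through the $k$ nearest design points is
   available as `mls_plane`. A *local* plane fit is essential: a
   single global plane per wavenumber would annihilate exactly the
   curvature in $(c_1, c_2)$ -- the self-association and interaction
   terms -- that the method exists to find.
3. **Water subtraction.** $X' = X - (c_w/c_{w,\mathrm{pure}})
   A_\mathrm{water}(\nu)$ with $c_w$ from volume additivity:
   $c_w = c_{w,\mathrm{pure}} (1 - c_1 \bar V_1 - c_2 \bar V_2)$.
4. **Component estimation.** Each solute's per-molar spectrum
   $\varepsilon(\nu)$ is the through-origin least-squares slope of
   water-subtracted absorbance against concentration over the binary
   edge of the design (the solutions where the other solute is
   absent).
5. **Solute subtraction.** Removing $c_2\,\varepsilon_2(\nu)$ gives
   the NMA-isolated series; removing $c_1\,\varepsilon_1(\nu)$ the
   osmolyte-isolated one.
6. **Derivative spectra.** Over a binary series, the molar absorbance
   $a(\nu, c) = A(\nu, c)/c$ is constant under ideal Beer--Lambert
   mixing; its least-squares slope against $c$ (the "derivative
   spectrum") is the signature of the concentration-change factor and
   must not be mistaken for an interaction factor.
7. **Decomposition and rank selection.** Unconstrained CP-ALS with
   multiple restarts (`cp_als()`), scanned over increasing rank
   (`select_rank()`), then factor classification against the pure and
   derivative references of *all* components (`classify_factors()`) --
   both isolated series can carry the same differential information,
   so comparison only against the series' own component would
   misattribute duplicated changes of the other solute.

## The synthetic scenarios and what they do (not) show

No public archive of the original instrument data exists, so the
package ships a generator (`generate_scenario()`) whose ground truth
makes every stage testable in closed form:

$$A(\nu; c_1, c_2) = c_w \varepsilon_w + c_1 \varepsilon_1 +
  c_2 \varepsilon_2 + k_{s,1} c_1^2 s_1(\nu) + k_{s,2} c_2^2 s_2(\nu)
  + k_\mathrm{int}\, c_1 c_2\, g(\nu) + \mathcal N(0, \sigma_A).$$

Components are sums of Gaussian bands; defaults place the water OH
bend at 1640 cm⁻¹, NMA-like bands at 1625/1580/1420/1330 cm⁻¹ and
stabilizer-like osmolyte bands at 1480/1395 cm⁻¹, with heights giving
realistic ATR absorbances (pure water ≈ 1 AU, solutes 0.1--0.6 AU at
the design maximum). The design is the full 6 × 6 factorial over
0--2 mol dm⁻³ (36 solutions including pure water). Self-association
($\propto c^2$, difference-band shape $s$) makes the derivative
spectrum non-zero with the closed-form value $k_s s(\nu)$; the
interaction is bilinear ($\propto c_1 c_2$) -- the simplest law whose
factor has non-constant loadings on both axes, and the one that keeps
the ground truth exactly trilinear.

Three canonical conditions:

* `ideal_scenario()`: pure Beer--Lambert mixing; everything subtracts
  to zero.
* `stabilizer_scenario()`: no interaction term, NMA self-association
  present; each isolated series is exactly trilinear of rank 2. The
  osmolyte mixes ideally in these two scenarios so the planted ranks
  are unambiguous.
* `denaturant_scenario()`: adds the bilinear term with a wave-like
  $g(\nu)$ (positive/negative pair at 1665/1642 cm⁻¹), making each
  isolated series rank 3.

Preparation jitter (default $\sigma = 0.01$ mol dm⁻³) perturbs only
*nonzero* nominal concentrations -- a solute that was never added has
no weighing error -- which also keeps the $c = 0$ design edge exact, so
the convex hull always contains the 0-anchored target grid. Detector
noise (default $2 \times 10^{-4}$ AU, typical of a 256-scan ATR
measurement) is added last. Both default magnitudes are generator
choices on the scale of real experiments, not literature values.

The generator deliberately omits: Voigt/ATR-dispersed lineshapes,
baseline drift, water-vapor lines, detector nonlinearity, and --
importantly -- the perturbation of the *water* spectrum by solutes.
In real data water subtraction is therefore imperfect and produces
extra difference-band factors; passing tests on synthetic data show
the machinery is correct, not that real systems will yield factors
this clean.

## Identifiability, and how factor identity is fixed

A subtle property of isolated series: when no interaction is present,
*every* factor of (say) the NMA-isolated series is constant along the
osmolyte axis. Two factors sharing a parallel loading in one
concentration mode can be mixed by any invertible 2 × 2 matrix (the
other mode absorbing the inverse) without changing the fitted tensor
-- Kruskal's uniqueness condition fails and CP alone returns an
arbitrary mixture of, e.g., the pure-NMA and derivative-shaped
factors. This is not a numerical artifact but a structural ambiguity
of the model class on exactly these tensors.

The package resolves it the way the method identifies factors in
general -- by comparison with known structure
(`resolve_degeneracy()`):

* the fitted tensor is split exactly into the part constant along the
  other solute's axis (its zero-concentration slab) and the part
  vanishing there (slab differences). Interaction factors and
  duplicated changes of the other solute live entirely in the second
  part, which is trilinear-identifiable on its own; the constant part
  is rotated onto the best-matching reference spectra (pure
  component, derivative);
* the remaining mode is then re-solved by least squares, leaving the
  reconstruction unchanged.

`select_rank()` applies this canonicalization to every scanned model
before judging it, because an arbitrarily rotated factor pair can
masquerade as redundant (or hide real redundancy).

## Rank selection

The scan starts at two factors -- an isolated series carries at least
the unaffected component and the component affected by its own
concentration change -- and adds factors until the larger model brings
nothing new, operationalized as any of:

* **redundancy**: two spectral loadings nearly coincide (absolute
  congruence ≥ 0.98 after a 10 cm⁻¹ boxcar smooth -- the algorithmic
  analogue of comparing shapes by eye, which ignores point noise), or
  a factor pair agrees in *all three* modes with product congruence
  ≥ 0.85 (the classical two-factor-degeneracy flag);
* **noise factor**: a factor's spectral loading is white
  (lag-1 autocorrelation < 0.5). Real vibrational bands are ≥ 4×
  wider than the 2 cm⁻¹ sampling step, so genuine factor spectra
  score near 1 and a factor fitted to detector noise near 0; such a
  factor carries no spectral features;
* **fit plateau**: the relative-error gain drops below $10^{-3}$.

The chosen rank is the last one before the trigger; all scanned models
are kept in the `rank_scan` so the shapes can also be judged visually.

## Numerical choices

* ALS updates solve the Khatri--Rao normal equations with a ridge of
  $10^{-12}$ × the Gram diagonal, escalating ×100 while the system is
  numerically singular -- this survives the collinear concentration
  loadings (e.g. $c$ vs $c^2$, congruence 0.975 on the default grid)
  and collapsed factors of rank-deficient fits. If a sweep would
  increase the loss (possible only when the ridge dominates at the
  numerical floor), the previous iterate is kept and iteration stops,
  so the reported error trace is non-increasing by construction.
* Restarts use seeds `seed`, `seed + 1`, ...; the best (lowest error)
  is returned and the matched spectral congruence between the two
  best restarts is reported -- values well below 1 flag degenerate
  solutions. An SVD-based initialization is available for the first
  restart.
* Scale convention: concentration loadings have unit norm with their
  largest-magnitude entry positive; all magnitude and residual sign
  sit in the spectral loadings, so factor spectra are directly
  comparable with measured $\varepsilon$ and derivative spectra.
* The Delaunay triangulation is built once per design; grid nodes on
  a hull edge that the point locator misses are re-located after an
  inward nudge of at most $10^{-6}$ of the design extent, but their
  barycentric weights are always computed exactly for the original
  node. k-NN ties in `mls_plane` break by input order after a stable
  sort.
* The target grid shrinks from `0.9 ×` the measured maxima by factors
  of 0.95 (at most 20 times) until all 25 nodes are inside the hull;
  nodes outside the hull are always an error, never silently
  extrapolated.

## Open choices the data could not settle

* Whether the original plane fits were local or global is not
  recoverable; both are implemented, defaulting to local
  (`piecewise_linear`), since a global plane cannot represent the
  curvature of interest.
* The exact water-subtraction coefficient formula is not stated
  beyond being based on molar concentrations; volume additivity with
  configurable partial molar volumes is used, with $\bar V = 0$ (the
  explicit constant-water approximation) as the neutral default of
  `water_model()`. The synthetic scenarios use realistic
  $\bar V_1 = 0.077$, $\bar V_2 = 0.072$ dm³ mol⁻¹ and the pipeline
  passes the scenario's model through, so generation and subtraction
  share one code path.
* Whether $\varepsilon$ for subtraction came from one reference
  concentration or a fit across the binary series is not stated; the
  through-origin fit across the series is the default here (it uses
  all points and is exact for ideal mixing).
* Spectral windowing before decomposition is left to configuration
  (`window =` in `pipeline_config()`); no truncation is applied by
  default.
* The interaction band's magnitude relative to the solute bands is
  exposed as `k_int` (default 0.05 AU dm⁶ mol⁻²) rather than asserted
  as a literature value.

## Problem sizes and test design

The test-suite and the acceptance script run the full pipeline on the
6 × 6 → 5 × 5 design with 276-point spectra; CP fits use 3--8 restarts
and up to 600--4000 sweeps depending on whether a test asserts label
correctness (robust to moderate convergence) or near-machine exactness
(swamp-prone collinear fits need the tighter settings). Stochastic
checks use 10--20 consecutive seeds with fixed pass thresholds. All
expected values are either closed-form consequences of the generator's
ground truth or were computed with independent brute-force oracles
(per-wavenumber `lm()` fits, direct normal equations, explicit
outer-product sums) before being frozen into the tests.

## Known limitations

* The structural canonicalization needs a zero level on the other
  solute's axis (the default grids always include one) and assumes
  each true factor is either constant or vanishing there -- true for
  the bilinear interaction law, not necessarily for other laws.
* Under heavy noise the split of the fitted tensor into constant and
  vanishing parts uses a singular-value threshold (1% of the tensor
  norm); interaction terms weaker than that will be folded into the
  constant part and can only be recovered by lowering the threshold.
* No ATR penetration-depth correction, water-vapor compensation or
  proprietary instrument formats; inputs must share one wavenumber
  axis (mismatch is an error, resampling is out of scope).
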