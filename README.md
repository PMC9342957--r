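# tetramem

Quantitative analysis of mitochondria-targeted cationic-aromatic
tetrapeptides interacting with cardiolipin-containing membranes.

Szeto–Schiller (SS) peptides are C-terminally amidated tetrapeptides with
alternating basic (B) and aromatic (φ) residues that concentrate in
mitochondria and bind cardiolipin-rich bilayers. Characterising how
sequence register (B-φ-B-φ vs φ-B-φ-B) and aromatic side-chain composition
shape their membrane interactions requires a stack of quantitative
analyses spanning NMR restraints, molecular-dynamics trajectories,
calorimetry and fluorescence titrations. `tetramem` implements that
analysis layer as a tested, reusable R package:

* **Membrane-trajectory metrics** — per-residue insertion depth
  (unsigned Z-distance of side-chain Cβ atoms to the bilayer centre of
  mass, lower leaflet reflected), bilayer thickness from the phosphate
  planes, area per lipid from the lateral box, component-resolved
  Shrake–Rupley solvent-accessible surface area (headgroup / acyl /
  peptide, acyl = atoms below the ester carbon), lateral (x–y) radial
  distribution functions with minimum-image wrapping, ensemble RMSD /
  radius-of-gyration statistics after Kabsch superposition, and
  block-averaged standard errors for correlated series.
* **NOE restraint compliance** — the ensemble average
  r\*(t) = [(1/N) Σᵢ rᵢ(t)⁻⁶]^(−1/6) over N restrained chains, forward-window
  time averaging r̄\*(t) = [(1/W) Σ r\*(j)⁻³]^(−1/3) with τ = 10 ps and
  Δt = 1 ps, violation scoring against the upper bound + 0.3 Å buffer, and
  the i→i+2 / i→i+3 medium-range restraint filter.
* **ITC single-site thermodynamics** — Wiseman-plot fitting of
  lipid-into-peptide titrations (independent identical sites, quadratic
  closed form, perfusion-cell dilution correction, effective outer-leaflet
  lipid axis), ΔG = RT·ln K_D, TΔS = ΔH − ΔG, the entropy/enthalpy balance
  TΔS/|ΔH|, and the membrane binding footprint
  n × (0.8·A_POPC + 0.2·A_TOCL).
* **Fluorescence titration readouts** — baseline normalization, plateau
  extraction and one-site saturation fits for surface-potential probe
  courses, the 420/520 nm excitation ratio of the dipole-potential probe,
  fractional quench of the transmembrane-potential probe, and the
  PFG-NMR hydration-radius conversion R_h = R_h,ref · D_ref/D_analyte.
* **Sequence space** — enumeration of the alternating B/φ tetrapeptide
  space (|φ|²·|B|²·2 sequences; 72 for Arg/Lys × Phe/Tyr/Trp), register
  classification and net-charge accounting (+3 for the amidated test set).
* **Synthetic-data generators** — seeded, pure-function generators for
  every input: a 150-lipid 20:80 TOCL:POPC pseudo-atom bilayer with 20
  surface-bound tetrapeptides, per-restraint ensemble distance series with
  designed violation fractions, single-site ITC isotherms, and saturable
  titration traces — so the whole pipeline is testable without downloads.

## Worked example

Simulate the calorimetry protocol (20 × 2.5 µl injections of 8 mM lipid
into 170 µl of 150 µM peptide, 1 % heat noise), fit it, and derive the
membrane footprint; then generate a bilayer trajectory and measure it:

```r
library(tetramem)

truth <- syntheticTruth(itcN = 5, itcKd = 30, itcDh = -5, seed = 42)
fit <- wisemanFit(makeItcIsotherm(truth, relativeNoise = 0.01))
fit
#> Single-site binding parameters
#>   n   = 5.01 lipids/peptide (eff.)
#>   Kd  = 29.5 uM
#>   dH  = -4.97 kJ/mol
#>   dG  = -25.9 kJ/mol,  TdS = 20.9 kJ/mol,  TdS/|dH| = 4.21
footprint(fit@n)
#> [1] 410
```

The fit recovers the generating truth (n = 5, K_D = 30 µM, ΔH = −5 kJ/mol)
to within the 1 % noise; the footprint is the fitted stoichiometry times
the 81.8 Å² composition-weighted lipid area. The trajectory metrics
recover the constructed geometry the same way:

```r
tr <- makeBilayerTrajectory(bilayerSpec(), 20, truth, nFrames = 200)
bilayerThickness(tr)$mean
#> [1] 37.99  # truth: 38 A phosphate-to-phosphate
insertionDepth(tr)
#> Insertion depth profile (A from bilayer COM):
#>  residue meanDepth         sd  n
#>        1  15.99732 0.05862705 20
#>        2  13.98061 0.07297543 20
#>        3  15.50071 0.08282737 20
#>        4  14.49630 0.06081459 20
#>   phosphate plane 19.00 A, ester plane 15.00 A
```

The per-residue means sit within jitter of the designed depths
(16, 14, 15.5, 14.5 Å), between the ester-carbon and phosphate reference
planes, as expected for interfacially bound peptides.

## Layout

* `R/` — implementation (S4 classes `Trajectory`, `DistanceSeries`,
  `ITCExperiment`, `TitrationTrace`, `PeptideSpec`, plus analysis
  functions).
* `tests/testthat/` — unit, property and end-to-end suites with
  independent oracles (brute-force distance averaging, grid-quadrature
  SASA, analytic AR(1) errors).
* `vignettes/tetramem-methods.Rmd` — the methods vignette: models,
  assumptions, parameter choices and limitations.
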