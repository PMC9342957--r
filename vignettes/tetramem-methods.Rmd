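---
title: "tetramem: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{tetramem: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tetramem)
```

`tetramem` is an analysis layer for structure–activity work on
mitochondria-targeted cationic-aromatic tetrapeptides (Szeto–Schiller-type
compounds) binding cardiolipin-containing bilayers. This vignette explains
the models the package implements, the assumptions behind them, the
parameters that matter, and what its synthetic-data generators do and do
not emulate.

## The system

The compounds are C-terminally amidated tetrapeptides with alternating
basic (Arg/Lys; "B") and aromatic (Phe/Tyr/Trp, or unnatural residues such
as 2,6-dimethyltyrosine; "φ") residues. They carry a net +3 charge at
physiological pH (+1 per basic side chain, +1 for the free N-terminal
amine; amidation removes the C-terminal acid). They bind the surface of
anionic, cardiolipin-containing membranes, where their conformations,
insertion depths and effects on bilayer packing and electrostatics all
depend on side-chain composition and register. The reference membrane
throughout is an 80:20 molar POPC:TOCL bilayer — 150 lipids, 75 per
leaflet in the simulated systems — with 20 surface-bound peptides (10 per
leaflet), i.e. 7.5 lipids and 1.5 cardiolipins per peptide.

## NOE distance calculus

Restrained ensemble MD enforces NMR distance bounds softly, so compliance
is judged on averaged, not instantaneous, distances. For an ensemble of
$N$ chains, the instantaneous effective distance is the inverse-sixth-power
average

$$r^*(t) = \Big[\tfrac{1}{N}\sum_{i=1}^N r_i(t)^{-6}\Big]^{-1/6},$$

reflecting the $r^{-6}$ distance dependence of NOE intensities: the
average is dominated by the shortest chain distances, and is bounded by
the per-chain minimum and maximum. Time averaging then applies an
inverse-third-power forward window

$$\bar r^*(t) = \Big[\tfrac{1}{W}\sum_{j=t}^{t+\tau/\Delta t}
r^*(j)^{-3}\Big]^{-1/3},$$

with defaults $\tau = 10$ ps and $\Delta t = 1$ ps. The window runs from
$t$ to $t+\tau/\Delta t$ inclusive, i.e. $W = \tau/\Delta t + 1$ samples;
terminal windows are truncated to the frames that exist and renormalized
by the actual count. We chose the literal flat summation window over an
exponential-memory ("decay time") average: the two agree in spirit, the
flat window matches the printed summation bounds exactly, and it makes
the arithmetic verifiable against a brute-force oracle to machine
precision. A window is a violation when $\bar r^*$ exceeds the
experimental upper bound plus a 0.3 Å buffer; the compliance summary is
the share of restraints violated less than 20 % of the time. The ensemble
size is taken from the data rather than fixed at the study's 20 chains.
Restraint tables are expected pre-reduced (degenerate methyl/aromatic
protons already collapsed to pseudo-atom distances); no within-chain
sub-averaging is applied.

## Trajectory metrics

**Insertion depth.** The depth of a residue is the unsigned Z-distance of
its side-chain Cβ atom from the bilayer centre of mass, averaged over
frames; lower-leaflet chains are reflected so depths from both leaflets
pool as positive numbers. The bilayer COM is computed per frame over
lipid atoms only (unit weights) — peptide and solvent positions should
not move the reference the depths are measured against. The phosphate and
ester-carbon planes are reported the same way to situate the peptide in
the interfacial region. Where depth profiles are described as
"normalized" distances elsewhere, we interpret and implement this as the
plain folded distance (no scaling by leaflet thickness); this choice is
deliberate and flagged here because the alternative is not uniquely
defined.

**Thickness and area per lipid.** Thickness is the per-frame distance
between the mean phosphate Z of the two leaflets; leaflets are assigned
once, at frame 1, by the sign of Z relative to the COM (no flip-flop
tracking — interfacially bound systems do not flip lipids on analysis
timescales). Area per lipid is the lateral box area divided by the
lipids per leaflet (75 by default).

**Ensemble statistics.** RMSD to the ensemble-average structure always
follows optimal least-squares (Kabsch) superposition on the scoped atoms,
with the determinant-positive branch enforced so degenerate rotations
never introduce reflections. The average structure is obtained by
superposing all conformers and refining the mean once. The radius of
gyration uses unit weights about each conformer's centre of mass.
Conformational similarity to a reference is summarised as the fraction of
frames with superposed heavy-atom RMSD under a 3 Å threshold, per chain.

**SASA.** Solvent-accessible surface area uses the Shrake–Rupley
sphere-point algorithm with a 1.4 Å probe and 240 points per atom by
default; dot density is a parameter and the error decreases as
O(1/nDots). We use Shrake–Rupley rather than the double-cubic-lattice
method: both approximate the same integral, the sphere-point construction
is simpler to implement and verify, and the implementation is checked
against an independent latitude–longitude quadrature oracle to within
2 %. Components are reported per role — lipid headgroup, lipid acyl
region (the atoms below the ester carbon) and peptide — with each atom's
exposed area credited to its own role; solvent atoms are excluded from
the solute set entirely. Atomic radii come from a bundled element table
(Bondi radii).

**Lateral RDFs.** g(r) in the membrane (x–y) plane, minimum-image wrapped
in x and y only, normalized per frame by annulus area times the mean
target surface density, with self-pairs excluded when reference and
target selections overlap.

**Block averaging.** Correlated series (thickness, area, SASA) get their
uncertainties from non-overlapping block averages: the SE of the mean is
computed from block means over an increasing ladder of block sizes, and
the chosen size is the smallest at which the relative SE change to the
next size falls below 5 % (configurable). White noise plateaus
immediately at σ/√n; correlated series plateau once blocks exceed the
correlation time.

## ITC single-site model

Lipid-into-peptide titrations are fit as Wiseman plots under an
independent-identical-sites model. Because externally added peptide can
only reach the outer leaflet of a vesicle, the lipid axis uses the
effective concentration — total lipid times the outer-leaflet fraction,
default 0.5 (symmetric leaflets of ~100 nm LUVs; configurable, since
vesicle size and lamellarity shift it). Each peptide in the cell presents
$n$ lipid sites with dissociation constant $K_D$; the bound-lipid
concentration after each injection is the root of the single-site
quadratic. Injections dilute the cell contents under a perfusion model —
the cell volume is constant and each injection displaces an equal volume
of mixed contents; displaced bound material releases no heat. The
instrument's true displacement handling is rarely documented, so this
standard model is the default and can be switched off
(`displacement = FALSE`). ΔH is defined per mole of lipid bound (the
injectant convention used by calorimeter software for the Wiseman y-axis).
Heats are accepted pre-integrated and blank-corrected.

Fitting uses Levenberg–Marquardt least squares with starting values read
off the isotherm (ΔH from the first far-from-saturation injection, n from
the half-height molar ratio). A Wiseman c-value ($[\mathrm{peptide}]/K_D$)
outside roughly [1, 1000] yields a warning — the sigmoid is then too
shallow or too sharp to determine all parameters well — but not a
failure. Derived quantities: $\Delta G = RT\ln K_D$ (K_D in molar,
T = 298.15 K by default), $T\Delta S = \Delta H - \Delta G$, and the
entropy/enthalpy balance $T\Delta S/|\Delta H|$, undefined at
$\Delta H = 0$. The identity $\Delta G = \Delta H - T\Delta S$ holds
exactly by construction. Note that a printed ΔG range need not equal
$RT\ln K_D$ of the printed K_D range endpoints when the per-analog
pairing of values is unknown; the package always derives from first
principles.

The membrane **footprint** is $n$ times the composition-weighted lipid
cross-sectional area — for 80:20 POPC:TOCL with literature areas 70 and
129 Å², the mean area is 81.8 Å². Values are rounded to the nearest Å²
per the reporting convention.

## Titration readouts

Fluorescence time courses are normalized to the mean of a baseline
window (the membrane-only segment). Per-addition plateaus are read as
the mean over the last 50 % of each inter-event interval — a published
trace is read "by eye" at steady state; a deterministic rule is needed
here, and the settle fraction is exposed because the true settling time
of a given probe/instrument is not knowable from the trace format. The
saturation model is a one-site hyperbola
$\Delta F = R_{max} D/(K_{1/2}+D)$ (the simplest saturable form; nothing
in the data format identifies a more specific mechanism), and flat traces
are flagged unidentifiable rather than fitted. The dipole-potential
readout is the ratio R of emission under 420 nm vs 520 nm excitation,
each read over a ±2 nm window; the transmembrane-potential readout is the
fractional change of the normalized signal after an addition event. No
conversion of probe responses to millivolts is attempted — calibration of
ψ_s/ψ_d in physical units needs information outside these traces. The
hydration-radius conversion $R_h = R_{h,\mathrm{ref}} D_\mathrm{ref}/D$
uses the DSS internal standard ($R_h$ = 3.34 Å) so solvent viscosity
cancels.

## Sequence space

The design space alternates basic and aromatic residues in two registers,
giving $|\varphi|^2|B|^2 \times 2$ sequences — 72 for {Arg, Lys} ×
{Phe, Tyr, Trp}. Enumeration is over L-residues only; D-stereochemistry
and unnatural residues (e.g. Dmt, representable through the extensible
aromatic alphabet) multiply the space without changing its structure, so
they are carried as metadata rather than enumerated. Net charge counts
+1 per basic side chain, +1 for the N-terminal amine, −1 for a free-acid
C-terminus (0 when amidated).

## Synthetic data: what it emulates, and what it does not

All generators are pure functions of their parameters and a master seed
(sub-streams are derived deterministically per artifact, and every
artifact records its seed and truth in provenance). The bilayer builder
places minimal pseudo-atom lipids — phosphate, ester carbon, terminal
acyl bead, plus a choline bead for PC — on jittered leaflet grids at
±19 Å, with peptides as 4-residue Cα/Cβ backbones whose Cβ depths
fluctuate about prescribed truths (defaults 16/14/15.5/14.5 Å, placed in
the interfacial region between the ester and phosphate planes, with 1 Å
Gaussian jitter). The default area per lipid is the composition-weighted
81.8 Å². The NOE generator lays out block-wise violation patterns whose
window-violation fraction is designed (exactly 0 or 1 for deterministic
fixtures, binomial about f otherwise). The ITC generator simulates the
study protocol (20 × 2.5 µl of 8 mM lipid into 170 µl of 150 µM peptide
at 25 °C) under the same single-site model the fitter uses. Trace
generators produce instant-settling plateaus with hyperbolic dose
response (half-saturation 20 nmol, fold-change 1.8 by default) and a
−0.35 fractional quench for the potentiometric course.

These fixtures validate the *estimators*: geometry recovery, averaging
arithmetic, fit inversion, counting statistics. They deliberately do not
emulate real membrane physics — there is no force field, no correlated
lipid dynamics, no undulations, no realistic SASA texture, and the ITC
recovery study is a self-inversion of the model, not a test of model
adequacy on a real instrument. Passing tests therefore demonstrate
correctness of the computations, not that the one-site model or the
pseudo-atom bilayer describes any particular experiment.

## Numerical choices and problem sizes

Tolerances and sizes used by the test suites, chosen as the smallest
configurations that make the statistics sharp: distance-averaging
oracles run on 20 × 1000 matrices (agreement to 1e-10); SASA oracle
comparisons use 960 dots against a 90 × 180 quadrature grid (2 % band);
block-averaging theory checks use 10⁴ white-noise and 5 × 10⁴ AR(1)
samples (5 % and 20 % bands); ITC recovery uses 50 seeded replicates at
1 % noise (5 % median-bias band); trajectory recovery uses 300–500
frames. Degenerate inputs are rejected with explanatory errors (odd
peptide counts, empty selections, non-increasing bin edges, non-positive
distances, overlapping settle windows, leaflets without phosphates).

## Limitations

* Depth profiles assume the Cβ atom as stated, for all residues.
* Leaflet assignment is frozen at frame 1; systems with lipid flip-flop
  need explicit tracking.
* The RDF target density uses N/A including the reference when the
  selections coincide, a 1/N bias that is negligible at the system sizes
  analysed here.
* No membrane curvature spectra, order parameters, electron-density
  profiles or hydrogen-bond analyses are provided.
* The ITC module fits a single-site model only; surface-partitioning and
  cooperative models are out of scope.
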