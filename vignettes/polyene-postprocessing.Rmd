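---
title: "Methods: post-processing conjugated-dye quantum-chemistry results"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: post-processing conjugated-dye quantum-chemistry results}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyeneQC)
```

`polyeneQC` reduces electronic-structure output for conjugated polyene
chromophores — the achiote dyes bixin, isobixin, norbixin, isonorbixin and
synthetic analogues — to desk-checkable scalars, validates their internal
consistency, and benchmarks them across functionals and media.  This
vignette records the models, the conventions chosen where the underlying
definitions are ambiguous, the defaults and their units, what the
synthetic-data generators do and do not emulate, and the package's known
limitations.  No quantum-chemistry engine is involved anywhere: raw DFT and
TDDFT computation, geometry optimization and solvation models are out of
scope; the chloroform medium is carried as metadata (dielectric 4.71 vs
1.00 for gas) and never evaluated.

## Units and constants

All conversions route through one constant table (`unit_constants()`):
`hc = 1239.84193` eV·nm, `1 hartree = 27.211386` eV, `1 a.u. dipole =
2.5417464` Debye, polarizability `1 a.u. = 0.1481847 × 10⁻²⁴` esu, first
hyperpolarizability `1 a.u. = 8.639418 × 10⁻³³` esu (reported on the
`10⁻³⁰` esu scale), `1 eV = 8065.544` cm⁻¹.  These CODATA-derived factors
reproduce the packaged reference wavelengths from the tabulated energies to
within the tables' printed precision.  Internally, all energies are stored
in eV, NLO tensors in atomic units and transition dipoles in Debye;
conversions happen only at the I/O boundary and in the reporting functions.

A note on the broadening width: the conventional literature value is quoted
as "0.37 eV (3000 cm⁻¹)", but those two numbers disagree by about 0.5 %
(0.37 eV is 2984.3 cm⁻¹).  The package treats **0.37 eV** as the
authoritative default everywhere; the wavenumber variant is not offered.

## Bond-length alternation

For a conjugation path of declared single/double bonds,
`BLA = (R_single − R_double)/N`, where `N` is the number of single–double
bond pairs, `min(#single, #double)`.  Two readings of this formula coexist:

* **mean-difference** (default): `mean(single lengths) − mean(double
  lengths)`.  For the canonical polyene backbone with 9 double and 8 single
  bonds and lengths 1.44/1.36 Å this gives `+0.08` Å, the magnitude of
  per-pair alternation and the scale of the published totals (0.072–0.101
  Å);
* **strict-sum** (`strict_sum = TRUE`): the literal
  `(Σ single − Σ double)/N`, which for the same backbone gives
  `(8×1.44 − 9×1.36)/8 = −0.09` Å — dominated by the count imbalance, not
  by alternation.

The mean-difference convention is the default because only it matches the
magnitude of the published per-pair totals under unequal class counts; the
strict-sum variant is kept for sensitivity analysis.  Relatedly, whether
`N` should count 8 or 9 pairs for a 9-double-bond chain cannot be settled
from the published totals alone; under the mean-difference convention the
question is moot, which is a further argument for it.

Bond classes are **declared**, never perceived from distances: distance
thresholds would inject a heuristic the analysis does not need, since the
examined bond set is part of the study design.  Paths are supplied as
plain-text files (`i j single|double` per line) or built by the generator;
the packaged `reference_backbone_path()` is the 17-bond backbone of the
18-carbon synthetic analogue.  Atom indices are **1-based** throughout the
package, the natural convention in R; path files written by 0-based tools
are read with `zero_based = TRUE`.

### Torsions

`torsion_angle()` returns the raw signed dihedral in `(−180°, 180°]`, 0 for
cis and 180 for trans.  `max_backbone_torsion()` instead reports the
largest *deviation from planarity* along the path's consecutive 4-atom
windows, `min(|τ|, 180° − |τ|)`: an ideal all-trans zig-zag (raw dihedrals
of 180°) scores 0, matching how "small torsion angles of 1–2 degrees" are
spoken of for near-planar chromophores.  Collinear atom triples are a hard
error — the dihedral is undefined there, and for these backbones collinear
triples indicate corrupt input rather than chemistry.

## Frontier orbitals

The gap is `E_LUMO − E_HOMO`; Koopmans estimates are `IP = −E_HOMO`,
`EA = −E_LUMO`.  A record with `HOMO ≥ LUMO` is flagged (constructor
attribute, warning attribute on the gap) but never silently repaired or
rejected: inverted levels in a summary table are evidence of a transcription
problem upstream, and hiding them would defeat the package's purpose.

The packaged orbital-energy table contains one such case: the
isonorbixin/CAM-B3LYP row's LUMO is printed `+1.911` eV while the printed
gap (4.465 eV) requires `−1.911`.  The fixture keeps the printed value
verbatim, adds a `lumo_corrected` column and an `erratum` flag, and every
computation uses the corrected field.  Printed values are never mutated.

Comparisons against printed tables use ±0.005 eV (tables print three
decimals, and gaps recomputed from the rounded HOMO/LUMO columns can be off
by one unit in the last digit).  Ordering checks (`B3LYP < M06 <
CAM-B3LYP`, rising with the Hartree–Fock exchange fraction) use strict
inequalities with a 0.001 eV tie tolerance; ties fail with an explicit tie
report rather than passing by accident.

## Nonlinear-optical scalars

From a tensor set in atomic units: `μ = |μ⃗|`, `ᾱ = tr(α)/3`, and the
beta-vector `β_vec = Σᵢ βᵢ μᵢ/|μ⃗|`, `βᵢ = Σₖ β_ikk` — the projection of the
contracted first-hyperpolarizability vector onto the dipole direction,
undefined (hard error) for a zero dipole.  All three are invariant under
rigid rotation of the tensor set, which the test suite verifies with random
rotations.

β input is accepted as a full 3×3×3 array or as named Kleinman-unique
components (`xxx`, `xyy`, `xyz`, ..., expanded over index permutations;
engines report either form).  Kleinman symmetry is *not* enforced: the
formula only consumes the `i-kk` contractions, so it is evaluated as
written, and a full array violating permutation symmetry beyond a relative
`1e-6` triggers a warning only.  The polarizability must be symmetric to a
relative `1e-8` — an asymmetric α has no physical reading and is rejected.

Reported scales follow the conventional table headers: Debye, `10⁻²⁴` esu,
`10⁻³⁰` esu; `units = "au"` is available everywhere.  Because the published
benchmark prints only the derived scalars, not the underlying tensors,
those values enter the package as fixtures and trend targets
(`nlo_trend_report()`), not as recomputable outputs: the expected pattern
is CAM-B3LYP minimal for every quantity, with exactly one exception pair
(isonorbixin in gas phase, where B3LYP gives the smallest μ and β_vec), and
chloroform enhancing all three quantities everywhere.

## Spectra

Vertical transitions carry an energy (eV), an oscillator strength, an
optional transition-dipole vector (Debye) and an optional stored
wavelength.  Consistency checks use the length-gauge relation
`f = (2/3) ΔE[a.u.] μ₀₁²[a.u.]`; across all 24 packaged transition rows the
printed `f` agrees with this relation to better than 0.2 %, and
`λ₀₁ = hc/E₀₁` to better than 0.03 %, which is what
`validate_transition()`'s default 1 % tolerance is calibrated against.

`broaden_spectrum()` convolves the transition energies with Gaussians of
FWHM 0.37 eV (default), weighted by oscillator strength:
`I(E) = Σₙ fₙ exp(−(E−Eₙ)²/2σ²)`, `σ = FWHM/(2√(2 ln 2))`.  Design choices:

* **Energy-domain broadening, pointwise wavelength mapping.**  The
  convolution is always performed on the energy axis; a wavelength-axis
  curve maps the grid through `E = hc/λ` *without* Jacobian reweighting, so
  a single transition peaks exactly at `λ₀₁ = hc/E₀₁` and the curve matches
  the usual presentation of TDDFT stick spectra next to tabulated `λ₀₁`
  values.  The photophysically rigorous `dE/dλ = hc/λ²` weight is available
  via `jacobian = TRUE`.  A wavelength-domain convolution variant is
  deliberately not implemented.
* **f-weighting.**  Unweighted convolution would erase the band-intensity
  differences between functionals that the oscillator strengths encode.
* **Grid policy.**  Default 300–800 nm with 2000 points, normalized to a
  maximum of 1.  A transition energy outside the grid is a hard error; a
  grid that merely truncates a transition's ±3·FWHM wing warns, because any
  realistic visible-range window clips the far wing of a ~2 eV band
  (2.0 eV − 3×0.37 eV = 0.89 eV ≈ 1390 nm) and rejecting that would make
  the default window unusable.
* **Peak ties.**  `peak_wavelength()` breaks exact intensity ties toward
  the lower energy / longer wavelength, with a warning.

`solvent_shift()` is `λ₀₁(solvated) − λ₀₁(gas)` (positive = red shift) for
matching functional/basis, preferring stored wavelengths when both records
carry them so that printed tables reproduce their own differences exactly.

## Synthetic data

The generators produce every input the pipeline consumes, with prescribed
ground truth:

* `gen_polyene()` — a planar zig-zag all-carbon chain, `n_double` C=C plus
  the `n_double − 1` intervening C–C (default 9/8, mirroring the dyes'
  conjugation length), exact bond lengths, 120° in-plane angles, optional
  bond-indexed out-of-plane twists and Gaussian coordinate jitter.
  Hydrogens, methyls and the acid/ester termini are deliberately absent:
  the BLA and torsion operations only touch the declared backbone path, so
  a backbone-only abstraction exercises them fully.  What it does *not*
  emulate: realistic force-field geometry relaxation, conformer ensembles,
  end-group effects on bond lengths — so generator-based tests demonstrate
  algorithmic correctness (exact parameter recovery), not chemical realism.
* `gen_transition()` — oscillator strength computed from the length-gauge
  relation and wavelength from `hc/E`, so validation passes at machine
  precision.
* `gen_nlo_tensors()` — dipole along a random unit vector with the target
  magnitude; α as the isotropic trace-matching part plus random traceless
  symmetric noise; β as a random Kleinman-symmetric tensor whose
  fully-symmetric `{i,1,1}` components are shifted so the contraction
  vector hits the target projection exactly, plus a random component
  orthogonal to the dipole in the projection sense.  All three scalars are
  recovered exactly (to floating point) by the NLO module, for any seed.

All generators accept a seed, restore the caller's RNG state, and are
deterministic given the seed.  Prescribed-value recovery is tested at
`1e-9` or tighter.

## Numerical choices and degenerate inputs

* Printed-table comparisons: ±0.005 eV (energies), ±0.002 D (dipole norms),
  0.1 % (wavelengths), 1 % (oscillator strengths) — each set by the printed
  precision of the corresponding column.
* Trend orderings: strict inequality, 0.001 tie tolerance.
* Rotation-invariance tests: relative `1e-9` over 1000 random rotations;
  brute-force β_vec oracle equality at `1e-12`.
* Degenerate inputs with a defined answer return it flagged (non-positive
  gap, tied orderings); inputs with no defined answer error (zero-dipole
  β_vec, collinear dihedral, BLA without both bond classes, flat zero
  spectrum).
* Problem sizes in the shipped tests: 18-atom backbones, 24-row tables,
  grids of 2000–20001 points, 1000-draw property loops — the whole suite
  runs in well under a minute on a single core.

## Coverage and limitations

* The packaged orbital-energy table covers the chloroform medium at
  6-31+G(d,p) only, and BLA the same single basis set — that is the extent
  of the transcribed reference data.  `trend_suite()` therefore reports
  gas-phase gap
  ordering and gas-phase cis/trans comparisons as `not_evaluable` rather
  than guessing; BLA, λ₀₁ and NLO trends are evaluable in both media.
* Only S0→S1 rows are packaged; `broaden_spectrum()` accepts any number of
  states, so full TDDFT records can be consumed when available.
* Frequency-dependent hyperpolarizabilities, the second hyperpolarizability
  γ, vibronic structure and non-Gaussian lineshapes are out of scope.
* The `qcsum/1` record format is engine-agnostic by design; parsing engine
  log files directly is left to external converters.

## Command line

The `qc_cli()` dispatcher (wrapped by `inst/scripts/polyeneqc.R`) exposes
`bla`, `electronic`, `nlo`, `spectrum`, `validate`, `synth` and `report`
subcommands with `--out`/`--format {csv,json}`; it is a thin layer over the
functions documented above and adds no behaviour of its own.
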