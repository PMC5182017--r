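---
title: "Methods: per-atom density-loss analysis of dose series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: per-atom density-loss analysis of dose series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dlossr)
```

## The model

A damage series is a set of diffraction datasets collected from one
crystal at increasing accumulated dose (MGy), indexed n = 1, 2, …, with a
single coordinate model refined against the first dataset and used
unchanged for all doses. The difference density at dose n is

ρ_n(x) = (1/V) Σ_hkl [ |F_n(h)| − |F_1(h)| ] · cos( φ_1(h) − 2π h·x ),

summed over both Friedel hemispheres, where φ_1 are the phases calculated
from the first-dataset model and V is the cell volume. Because the phase
set is fixed, amplitude-only changes map linearly onto density changes,
and localized chemical damage (decarboxylation, disulfide cleavage)
appears as negative peaks at the damaged atoms. F(000) is excluded, so
every map has exactly zero mean; map "sigma" is the population standard
deviation over all grid points, and contour statements like ±5σ refer to
multiples of it.

D_loss(atom, n) is the maximum of −ρ_n over all grid points within a
vicinity radius of the atom (periodic minimum image). It may legitimately
be negative when an atom's neighbourhood only gains density; no clamping
is applied, because clipped values would hide genuine density-gain
observations. Atoms retain a D_loss value even at zero model occupancy —
the map does not depend on the model beyond its phases.

Key assumptions inherited from the experimental design:

* the model is rigid-body-consistent across the series (no re-refinement
  per dose);
* amplitudes of later datasets are on a consistent relative scale after a
  single overall least-squares factor k = ΣF₁Fₙ/ΣFₙ² (the protocol for
  resolution-dependent scaling is deliberately not guessed; the overall
  scalar is logged on every run);
* alternate conformers other than '' / 'A' are excluded by default to
  avoid double counting; hydrogens are ignored throughout.

## Parameters that matter

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| vicinity radius | 1.5 | Å | covers an atom's own density at typical map spacings without engulfing bonded neighbours entirely; always reported in output. Bonded atoms < 3 Å apart can still share a peak and tie. |
| dose floor | 1.0 | MGy | non-reference datasets below 1 MGy are excluded: specific damage only becomes detectable above this dose; set 0 to disable for low-dose controls. |
| map grid | 1.5 × Nyquist | — | grid spacing ≈ dmin/3 per axis; the Nyquist bound 2·edge/dmin is enforced as a hard error. |
| H-bond cutoff | 4.0 | Å | Tyr OH to carboxylate O distance, strict inequality; purely distance-based (no angular term). |
| SASA probe / points | 1.4 / 960 | Å / — | water probe; golden-spiral sampling gives ≤ 1% error on an isolated sphere (verified analytically in the tests). |
| Bdamage radius / bins | 7.0 / 10 | Å / — | packing density is the heavy-atom count within 7 Å; equal-width bins with < 10-atom bins merged into a neighbour. |

## Ranking and signatures

Atom types are ranked per dataset by descending mean raw D_loss (rank 0 =
most damaged) and across datasets by ranking the product of per-dataset
ranks. Two consequences are accepted as faithful properties of the
scheme rather than patched: a type ranked 0 anywhere has product 0, and
product ties are possible. Ties (in means or products) are broken by the
mean of per-dataset ranks, then lexicographically by key; the policy is
recorded in the result attributes and the run log. Ranking uses *raw*
D_loss (ranks precede normalization conceptually); signatures and KS
comparisons use Cα-normalized values. Raw D_loss values are never
compared across different series — cross-series statements are rank-based
only, because map-scale calibration between independent experiments is
unreliable.

The KS statistic is computed as the exact ECDF supremum over pooled
sample points, which is well defined under ties (D_loss tables contain
exact ties when neighbouring atoms share a peak); the p-value uses the
asymptotic Kolmogorov series with the standard small-sample effective-n
correction. KDE signatures use Gaussian kernels with Scott's-rule
bandwidth on ≥ 256 abscissae spanning the data ± 3 bandwidths.

The hydrogen-bonded versus non-bonded Tyr comparison uses the two-sample
Hotelling T² with pooled covariance (one coordinate per retained dose)
and the exact F transform. In power assessments the damaged subset's mean
shift grows linearly with dose index (0.5σ per dose step), reflecting the
cumulative nature of specific damage; a dose-constant shift of 0.5σ at
n = 15 per group has analytic power of only ≈ 0.43 and is not the regime
the method is meant to detect.

## The synthetic generator

`make_toy_structure()` places idealized residues (standard bond lengths;
no torsional or Ramachandran realism) on a 15 Å lattice in a cubic P1
cell sized to the residue count: Tyr–Glu pairs engineered with OH···OE1 =
2.9 Å, disulfide-bonded Cys pairs (S–S 2.05 Å), at least two isolated
Tyr, and singles of Phe, Asp, Asn, Gln, Ser, Thr, Leu, Ile, each with its
Cα. Occupancies are 1; B-factors are uniform on [10, 25] Å². Structure
factors use a single-Gaussian atom model — electron count weight with the
B-factor envelope exp(−B s²/4) — rather than Cromer–Mann scattering: the
pipeline's contracts concern relative density bookkeeping, not absolute
scattering physics.

`make_damage_series()` injects damage in two mechanistically distinct
ways so the cleavage and disorder hypotheses are separable in tests:
occupancy loss accumulating linearly per dose step (cleavage-like), and
rigid displacement of Tyr/Phe ring atoms along a fixed random
per-residue direction (disorder-like). Gaussian noise with sd =
noise_sigma × mean first-dataset amplitude is applied to amplitudes (not
map values), since the pipeline ingests amplitudes; amplitudes are
clipped at zero. The default dose ladder is 0.5, 2, 4, 8 MGy: a
sub-1-MGy reference plus three datasets spanning the range where
decarboxylation is reported.

What passing tests on these fixtures show — and do not show. They show
the chain amplitude-difference → map → D_loss → statistics is correct and
well calibrated: injected losses are recovered as rank patterns, FFT maps
agree with direct summation to rounding, and the tests' null statistics
reject at close to nominal rates. They do not show robustness to the
things real data add: space-group symmetry (everything here is P1; real
inputs must be pre-expanded), bulk solvent, resolution-dependent scaling
errors, non-isomorphism, model-phase bias, or realistic Wilson-statistics
noise.

## Numerical choices

* FFT convention: coefficients ΔF·e^{iφ} are placed at wrapped indices h
  mod N with Friedel mates conjugated; the forward FFT then evaluates the
  crystallographic sum Σ F(h) e^{−2πi h·x}, divided by V.
* The direct-summation evaluator is retained as a first-class exported
  function (`difference_map_direct`) — it is the module's oracle and is
  implemented without the FFT path.
* Vicinity search: candidate voxels come from a fractional-space bounding
  box sized by per-axis perpendicular cell widths, then filtered by
  minimum-image Euclidean distance; the nearest grid node is always
  included so the voxel set is never empty. A radius exceeding half the
  smallest perpendicular cell width is a hard error.
* Cα normalization divides by the per-dose mean Cα D_loss; a zero mean
  (exactly zero damage) is an error at the operation level, and
  `run_series()` degrades gracefully by reporting NA normalized values
  with a message.
* Degenerate inputs: all-equal KDE samples error (suggesting a
  histogram); constant x errors in regression, constant y returns R² = 0
  with a warning; a singular pooled covariance in T² errors with advice
  to drop doses.

## Design choices where the protocol was open

* Vicinity construction: a fixed sphere was chosen over a nearest-atom
  voxel partition; the partition variant is a possible extension and
  would remove peak-sharing ties between bonded atoms.
* Solvent atoms: HETATM records are excluded from the ranking universe by
  default (polymer residues only), configurable at selection level.
* Disulfide distances are measured to the bond midpoint; the nearest-S
  alternative is exposed as a flag.
* Tyr "ring" solvent accessibility includes the OH oxygen by default
  (flag to exclude), since the correlate of interest is the OH oxygen's
  density loss.
* Carboxylate removal for the SASA experiment deletes the full CO2
  moiety including its carbon (Glu CD/OE1/OE2, Asp CG/OD1/OD2), matching
  decarboxylation chemistry.
* Crystal-contact accounting in SASA is approximated (P1 translates
  only, off by default); a full symmetry treatment is out of scope.

## Problem sizes

The test suite and the acceptance script run entirely on synthetic
series: toy structures with 1–2 residues per type (~90–140 atoms, 45 Å
cubic P1 cell, dmin 2.8 Å, ~10⁴ reflections, 52³ map grids), 20-seed
recovery loops, and 1000–2000-replicate calibration loops. These sizes
were chosen to make every oracle comparison (direct summation, exhaustive
voxel scans, O(n²) distance counts) exact and fast while leaving the
statistical assertions well-powered.

## Known limitations

* P1 only; no space-group symmetry in map synthesis or SASA contacts.
* Single-Gaussian scattering model; no bulk-solvent correction.
* A single overall inter-dataset scale factor; no resolution-binned or
  anisotropic scaling.
* Distance-only hydrogen-bond criterion; no donor–H–acceptor angles.
* The KS test's size at small equal samples is granular: at n = 50 + 50
  the achievable sizes near 5% are 0.039 and 0.068, so "rejects at 5%"
  means the conservative side of that pair.
* mmCIF/MTZ are not parsed; adapters must convert to the columnar text
  format (`H K L F1 … PHI1`).
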