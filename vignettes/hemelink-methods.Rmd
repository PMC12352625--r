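---
title: "Methods: haem-site descriptors, spectral shifts and water statistics in hemelink"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: haem-site descriptors, spectral shifts and water statistics in hemelink}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemelink)
```

# The scientific problem

Cytochrome P460 oxidises hydroxylamine at a c-type haem whose porphyrin
is covalently tethered to a lysine side chain. The tether can be a
single bond (Lys NZ to the gamma-meso carbon CHA, "SC"), or a double
crosslink with an additional Lys CD to haem C2A bond ("DC"), which in
turn forces the C2A–C3A ring bond to become single and leaves an
exocyclic C3A=CMA double bond; an unsaturated variant of the lysine
chain ("DCu") is also chemically plausible. The crosslink state
co-varies with observable quantities: the iron's displacement from the
porphyrin plane, the coordination of a distal water, the Soret
absorption maximum in each redox state, and the statistics of water
near Fe in dynamics. `hemelink` implements those observables as
reusable, tested operations. It deliberately contains **no** quantum
chemistry, crystallographic refinement, or molecular dynamics: its
inputs are coordinates, excitation stick spectra, trajectories and ESP
grids produced elsewhere.

# Structure input and site mapping

PDB input is parsed by fixed columns (ATOM/HETATM/MODEL/ENDMDL), mmCIF
through its `_atom_site` loop, and XYZ as stacked frames. No
pre-installed R package in the target environment parses macromolecular
coordinate files, so the readers are part of the package and are
guarded by round-trip and malformed-input tests; they do not attempt
symmetry expansion, assembly building or hydrogen placement.

Alternate conformations are resolved by the convention used when
crystal structures are prepared for simulation: keep the copy with the
greater fractional occupancy, break ties by the lower B-factor, then by
altloc label. The operation is idempotent and the identity on
altloc-free input.

Site mapping resolves atom handles by role rather than hard-coded
serial numbers. Two choices deserve note:

* the **proximal His nitrogen** is the His side-chain N nearest Fe,
  selected by distance rather than by the name NE2, because deposited
  naming dialects vary;
* the **distal water** is the water oxygen nearest Fe if within a
  cutoff, default 4.0 Å — wide enough to capture both a coordinated
  ferric water (~2.1 Å) and the displaced ferrous water (~3.3 Å), while
  excluding bulk solvent. Both the cutoff and the whole naming table are
  user-overridable (`read_site_config()`), since the exact haem atom
  naming of any given deposition cannot be assumed.

XYZ files carry no residue metadata, so haem mapping from XYZ requires
an explicit index table in the configuration.

# Geometric descriptors

All descriptors are Euclidean distances between mapped atoms except:

* **Fe-OOP**: the distance between Fe and the centroid of the four
  pyrrole nitrogens. The four atoms are identical, so the unweighted
  centroid equals the centre of mass. The signed variant projects
  Fe onto the normal of the N4 least-squares plane and is positive when
  Fe lies opposite the proximal His — i.e. displaced toward the distal
  (water) side, the direction expected on reduction to the
  five-coordinate ferrous state.
* **ring_rms_dev**: the RMS deviation of the 24 macrocycle core atoms
  from their own least-squares plane (SVD fit). This is a scalar
  planarity summary only; no decomposition into ruffling/saddling
  normal modes is attempted.

A collinear N4 set has no defined plane and raises an error rather than
returning a junk normal.

## Classification thresholds

Crosslink state is a rule on two distances. Any crosslink requires a
covalent NZ–CHA bond, taken as ≤ 1.80 Å — comfortably above covalent
C–N lengths (~1.45–1.55 Å) and far below any non-bonded contact. Given
that, CD–C2A ≤ 1.80 Å is `DC`, ≥ 2.80 Å is `SC`, and the band between
is `AMBIGUOUS`. The cut points are chosen so that the reference
exemplars classify correctly: 1.58 Å (bonded, DC), 1.94 and 2.11 Å
(the ambiguous serial-crystallography conformations), 3.7 Å (clearly
single-crosslinked). C–C bond character uses ≤ 1.40 Å double / ≥ 1.48 Å
single, bracketing the printed exemplars 1.33 Å (double-bond
restraints), 1.43 Å (intermediate) and 1.52 Å (single). All four
thresholds are configurable; classification is monotone in the distance
by construction, which a property test enforces.

# Spectral analysis

A stick spectrum is an ordered list of (excitation energy, oscillator
strength) pairs. Order matters: truncation to the first *n* states is
by upstream state index, not by energy, mirroring how excited-state
codes emit transitions. Defaults are 30 states for ferrous and 50 for
ferric spectra.

Convolution assigns each included transition a **unit-area** Gaussian
weighted by its oscillator strength, so the integral of the curve
equals the summed oscillator strength — a conservation property tested
to 0.1 % by trapezoidal quadrature. The broadening parameter, default
0.15 eV, is interpreted as the Gaussian standard deviation; whether a
given upstream plot used σ or FWHM is generally unstated, so a
`sigma_is_fwhm` toggle is provided and neither interpretation is
asserted. The default grid is 1.5–6.0 eV in 0.002 eV steps; a grid not
covering every included transition ± 5σ sets a coverage flag on the
result rather than silently clipping intensity.

Soret assignment defaults to the transition with the largest oscillator
strength inside a 300–550 nm window (ties to lower energy), matching
the practice of comparing the strongest computed states; the argmax of
the convolved curve is available as a sensitivity check, and a test
constructs a spectrum where the two methods legitimately disagree
(two near-degenerate moderate sticks outweighing one strong stick after
broadening).

Shift arithmetic uses `E = hc/λ` with `hc = 1239.84193` eV·nm and, by
default, rounds each energy half-away-from-zero to two decimals before
differencing. That policy reproduces shift values quoted from energies
printed at two decimals. One published exemplar is *not* reproducible
this way: a ferrous solution maximum quoted as 460 nm alongside
2.69 eV. hc/460 nm = 2.6953 eV rounds to 2.70, so the printed 0.27 eV
difference can only come from the printed energies (2.96 − 2.69), whose
2.69 corresponds to ~461 nm. The package computes 0.26 eV from the
wavelengths and the corresponding acceptance test is intentionally left
failing rather than special-cased. The model-to-model comparisons
(368/387 → 0.17 eV, 368/411 → 0.35 eV, 392/415 → 0.17 eV) all reproduce
exactly under the same policy. A positive shift (ferric minus ferrous)
is labelled `red_shift_on_reduction`.

# Trajectory statistics

Water residence takes, per frame, the minimum Fe to water-oxygen
distance; occupancy is the fraction of frames with that minimum within
the cutoff (default 3.5 Å, the conventional first-shell criterion for
water "near" a metal). Mean and sd (sample, n−1) are computed over
contributing frames only, because residence statistics for a
coordination site are conventionally quoted for the frames in which the
site is occupied; an `all_frames` flag exposes the unconditioned
statistic. Histograms default to 0.05 Å bins.

H-bond occupancy applies standard geometric criteria — donor–acceptor
heavy-atom distance ≤ 3.5 Å, and, when hydrogens are available,
D–H···A angle ≥ 120° — because upstream reports of "H-bond fraction"
rarely state their criteria; both cutoffs are parameters, and the
occupancy is by definition the exhaustive per-frame count. Where an
upstream quantity like "interaction with Asp102" is reproduced, it is
implemented and labelled as H-bond occupancy.

Mode detection box-smooths the histogram (default 3 bins), finds local
maxima, discards peaks below 10 % of the global maximum, and merges
peaks closer than 0.15 Å, keeping the taller. With 0.05 Å bins these
defaults resolve the reference bimodal mixture (means 2.6 and 2.9 Å,
σ = 0.1 Å) into exactly two modes while collapsing a 0.05 Å separation
into one — both ends are tested. A flat histogram returns its weighted
centre; this degenerate case is defined rather than an error.

No periodic-boundary imaging is performed: inputs are assumed whole and
centred, which holds for protein-site analyses exported from any
mainstream MD package. This is a documented limitation, not a silent
assumption.

# Constrained ESP charge fitting

The fit minimises the sum of squared deviations between the point-charge
Coulomb potential `V(r) = Σ q_i/|r − r_i|` (k = 1 in e/Å units; the fit
is invariant to any consistent unit system, and `esp_unit_factor()`
converts to atomic units) and the supplied grid potential, subject to
**hard** equality constraints: the total charge, group sums (e.g.
neutral chemical groups, as CHARMM charge derivation requires) and
equal-charge equivalence classes. Hard constraints are imposed through
the KKT augmented system and solved exactly — not as penalty terms —
because group neutrality is a requirement of the forcefield convention,
not a preference. Redundant constraints are tolerated after a
consistency check; inconsistent targets and rank-deficient designs are
rejected with named errors. An optional harmonic restraint toward zero
charge is available (weight default 0); hyperbolic RESP-style restraints
are deliberately not implemented since nothing in the emulated workflow
specifies them.

Boundary-charge redistribution (`split_transferable_charges`) brings
each declared group exactly to its target by shifting the deficit
uniformly over the group's non-boundary atoms; any change to the grand
total is absorbed uniformly by ungrouped atoms, and it is an error if
none exist. The exact group definitions for the P460 haem live in
supplementary material not reproduced here, so the module ships the
generic constraint language instead of hard-coding them.

# The synthetic-data generators

Each generator returns data **plus the ground truth used to build it**,
so downstream operations are tested against what was constructed, not
against themselves. All randomness flows from the spec seed through an
isolated RNG scope (the global stream is saved and restored), and
identical specs are bit-identical.

* `make_porphyrin` builds an idealized, perfectly planar D4h-like
  porphine core (pyrrole N at 2.05 Å circumradius; alpha, beta and meso
  carbons at proportional radii) and places Fe, His N, water O, Lys
  NZ/CD/CE and CMA so that every requested distance is realized exactly
  before optional isotropic Gaussian noise. Defaults follow the
  damage-free ferric serial-crystallography parameter set (Fe–His 2.14,
  Fe–water 2.11, NZ–CHA 1.46, CD–C2A 1.94, C3A–CMA 1.43, Fe-OOP
  0.06 Å). A requested absent CD–C2A places the CD atom at the
  non-bonded 3.7 Å separation observed for the single-crosslinked
  ferrous structure. What it does **not** emulate: real bond-length
  distributions within the macrocycle, side chains beyond the mapped
  atoms, thermal anisotropy, or any crystal-lattice context — so a green
  geometry test establishes correctness of the descriptor arithmetic
  and mapping, not realism of the scaffold.
* `make_trajectory` redraws the water oxygen each frame at a distance
  sampled from a stated Gaussian mixture (defaults: a single 3.3 ±
  0.1 Å component; the bimodal reference case is 2.6/2.9 ± 0.1 Å at
  equal weight) along a random direction, steered so that the
  water→pyrrole-N_D H-bond distance criterion holds in exactly
  `round(fraction × n_frames)` frames. Protein atoms do not move; the
  generator emulates the *statistics* the analyses consume, not
  dynamics.
* `make_stick_spectrum` plants one dominant transition at `hc/soret_nm`
  above a seeded background whose oscillator strengths are bounded
  strictly below the dominant one (enforced by a spec guard), so the
  max-oscillator assignment provably recovers the requested maximum.
* `make_esp_problem` draws Merz–Kollman-style grid shells at 1.4–2.0 ×
  a 1.7 Å van-der-Waals-like radius around each atom, discards points
  inside any atom's innermost shell, and evaluates the exact
  point-charge potential of the (optionally constrained-consistent)
  true charges plus optional noise. The actual grid scheme of any
  particular quantum-chemistry code is not reproduced; only its role
  (well-conditioned sampling outside the molecular surface) is.

# Numerical choices

* Plane fits use SVD; collinearity is detected on the second singular
  value (< 1e-9) and raised as an error.
* Rounding for shift arithmetic is half-away-from-zero, not banker's
  rounding, because quoted spectroscopic energies are rounded that way.
* Crosslink classification ties: the boundary values themselves are
  assigned to the bonded/SC sides (≤ and ≥), so the AMBIGUOUS band is
  open.
* Soret ties in oscillator strength go to the lower energy.
* The KKT system is solved by QR; rank is checked on the full
  augmented matrix so that either data degeneracy or constraint
  degeneracy is caught before `solve`.
* Residence sd uses the sample (n−1) convention; a single contributing
  frame reports sd 0, no contributing frames report NA.

# Known limitations

* The regression against the deposited crystal structures requires
  downloading them; offline, the corresponding acceptance test fails
  with an explanatory message by design. Whether published
  experimental descriptor rows are chain-A or chain-averaged values is
  not always stated; the regression reads chain A, major conformation.
* mmCIF support covers the `_atom_site` loop (the part needed for
  coordinates), not the full CIF grammar.
* H-bond analysis is geometric only; no energetic or
  information-theoretic criteria.
* The ESP module fits charges to a *given* grid; it neither generates
  quantum-mechanical potentials nor selects spin states.
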