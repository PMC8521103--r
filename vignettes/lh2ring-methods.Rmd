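---
title: "Methods: descriptors, exciton spectra and the synthetic C9 generator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: descriptors, exciton spectra and the synthetic C9 generator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lh2ring)
```

`lh2ring` analyses trajectories of nine-fold symmetric light-harvesting
complex 2 (LH2)-like assemblies: ring geometry, conformational
descriptors of the αβ-polypeptide subunits, heavy-atom contact
occupancies, and point-dipole Frenkel exciton absorption spectra. This
vignette explains the models, the choices behind the defaults, and what
the synthetic test bed does and does not establish.

## Ring fitting

Rings (helix rings, pigment rings, the carotenoid tail ring) are
summarized by a circle fitted to per-subunit mass centers. The objective
is the radial variance ΔR² = Σᵢ(rᵢ − r̄)², minimized over the center;
the mean distance r̄ at the optimum is the radius. Two choices are worth
noting:

* **Dimensionality.** The objective is agnostic to dimension; because
  the assembly is a membrane-embedded ring, points are first projected
  onto the plane perpendicular to a declared symmetry axis (default z,
  i.e. the membrane normal). Descriptors are rigid-body invariant once
  the axis is transformed along with the coordinates.
* **Optimization.** This radial-variance objective is not the algebraic
  (Kåsa) circle fit, but the Kåsa solution is an excellent start; a
  BFGS descent with the analytic gradient 2Σ(rᵢ − r̄)(c − pᵢ)/rᵢ
  converges to machine precision in a few steps (relative tolerance
  1e-15, ≤ 500 iterations). Collinear point sets (second singular value
  < 1e-9 of the first after projection) raise a degenerate-geometry
  error. The test suite certifies optimality against a brute-force grid
  search (0.25 Å coarse grid refined to 1e-4 Å).

"Mass centers" are unweighted heavy-atom centroids: residue composition
is not part of the frame model, and for 3–7-residue backbone windows the
unweighted centroid differs from the mass-weighted one by far less than
the conformational spread the descriptors are meant to resolve.

## Conformational descriptors

* **L-angle** — the kink between the α-polypeptide N-terminal segment
  and the main helix: the angle between (centroid of residues 7–9 −
  centroid of residues 1–3) and (centroid of 34–36 − centroid of
  12–14). Both vectors run N→C, a convention that makes an unkinked
  helix read ≈ 0°. Residue indices are 1-based per chain; PDB author
  numbering is remapped to this convention on load.
* **N-terminal length** — distance between the residue 1–3 and 7–9
  centroids, in Å.
* **Helicity count** — the number of residues among 1–9 whose (φ, ψ)
  fall in an α-helical window, default φ ∈ [−100°, −30°], ψ ∈ [−67°,
  −7°]. A dihedral-window detector was chosen over an i→i+4
  hydrogen-bond detector because the synthetic backbone proxies
  guarantee correct dihedrals but not carbonyl geometry fidelity; both
  the window and the residue range are arguments. Terminal residues
  lacking a neighbour for φ or ψ are never counted, so an isolated
  ideal 9-residue helix scores 7 and residues 1–9 of a longer chain
  score 8.
* **ω angle** — the carotenoid bend: the angle at the centroid of
  carbons C18–C22 formed with the centroids of C9–C13 and C26–C30;
  collinear centroids give 180°.
* **Ring radii** — six standard rings: α-helix residues 26–32 (r_up)
  and 17–23 (r_down), β-helix residues 77–82 (R_up) and 66–71 (R_down),
  the carotenoid C21–C30 tail ring (t), and the B850 porphyrin-center
  ring (T). The source literature labels the 26–32/77–82 rings
  inconsistently (cytoplasmic vs periplasmic); the package keys radii to
  residue ranges, never to surface names. T uses all 18 pigment centers
  by default; a 9-point per-subunit-pair mode is available
  (`T_mode = "per_subunit"`) since either reading is defensible.
* **Closest contact** — the minimum heavy-atom distance between the
  carotenoid tail (C21–C30) of a subunit and all B850 atoms of the
  complex; overlapping selections return 0 with a warning.
* **Superposition/RMSD** — Kabsch least-squares superposition via SVD
  with the determinant corrected to +1 (proper rotations only). The
  representative frame of a trajectory is the argmin of RMSD to the
  average of first-frame-superposed coordinates, ties broken by lowest
  index for determinism.

## Contact ("hydrogen bond") occupancies

Occupancy is 100 × (frames with donor–acceptor heavy-atom distance
strictly < cutoff)/frames, cutoff 3.5 Å by default, averaged over the
nine subunits (per-subunit output available; whether published tables
average over subunits is typically unstated, so the averaging choice is
explicit here). The criterion is distance-only by design — occupancy
tables defined on non-hydrogen distances carry no angle term — and the
strict inequality follows the usual "less than" phrasing. The six
canonical αβ-interface pairs ship as `table_pairs()`, with side-chain
atoms mapped to backbone proxies (Nε → N, Oγ/Oδ → O) so they resolve on
synthetic assemblies.

## Exciton model

Site energies εₙ (eV) and transition dipoles μₙ (Debye) enter the
Frenkel Hamiltonian with point-dipole couplings
V = C|μᵢ||μⱼ|κ/R³. Unit conventions: μ in Debye, R in Å, and
C = 5034.12 cm⁻¹·Å³·D⁻² — the vacuum dipole–dipole constant
(10⁻¹² erg expressed in cm⁻¹ through hc), with no dielectric screening,
converted to eV via 1 cm⁻¹ = 1.239841984 × 10⁻⁴ eV. κ is computed from
unit vectors and is bounded in [−2, 2].

Diagonalization uses the symmetric eigensolver; eigenvalues are
ascending, and eigenstate dipole strengths Mᵢ = ‖Σₙ cᵢₙμₙ‖ conserve
ΣMᵢ² = Σ|μₙ|². Within a degenerate pair (C9 symmetry produces four
degenerate pairs plus a singlet per 9-ring) individual Mᵢ are
basis-dependent; only pair sums should be consumed downstream, and the
broadened spectrum depends only on those sums.

The spectrum A(v) = v/(√(2π)σ)ΣᵢMᵢ²exp[−(Eᵢ−v)²/2σ²] is evaluated on a
uniform energy grid (default 1.2–1.9 eV, 1 meV step, σ = 0.022 eV). The
frequency prefactor is evaluated at the grid energy v rather than at
Eᵢ — the formula is ambiguous on this point — which shifts a single-state
peak by ≈ σ²/E ≈ 0.3 meV, below one grid step. Wavelengths are
λ(nm) = 1239.841984/E(eV).

Ensembles are averaged pointwise and the averaged spectrum is fitted
with a two-Gaussian model ("mean-then-fit"); a fit-each-then-average
workflow is possible by calling `bimodal_fit()` per snapshot — "bimodal
fitting of an ensemble of spectra" is commonly described in ways that
admit either reading. The fit is Levenberg–Marquardt
least squares; initial centers are the two highest local maxima of a
lightly smoothed copy of the curve separated by at least max(3 grid
steps, 2σ) — smoothing prevents shot noise from splitting one band into
two adjacent starts. A component carrying < 1% of the total fitted area
flags the result degenerate (single-peak input). Non-convergence raises
an error naming the initial centers.

Carotenoid (RG1) rows are accepted in pigment tables but excluded from
the BChl Hamiltonian by default; they feed the pairwise RG1–B850
coupling report, which emits every pair plus the per-carotenoid maximum
|V| rather than asserting that any single pair is *the* reported
coupling.

## The synthetic generator

`generate_assembly()` builds one subunit and replicates it by rotations
of 360°/9 about z: an α pseudo-helix (36 residues of N/CA/C/O backbone
on ideal helix geometry, φ/ψ = −57°/−47°, with its first 9 residues
stretched or compressed to the requested N-terminal length and oriented
at the requested kink angle), an 82-residue β pseudo-helix (so residue
ranges 66–71/77–82 resolve), one B800 and two B850 porphyrin proxies
(MG plus eight ring carbons placed symmetrically, so the heavy-atom
centroid is exactly the configured ring point), and a 30-carbon
carotenoid chain whose constrained group centroids realize the bend
angle and tail radius exactly. Helix placement solves a two-unknown
Newton problem (radial offset and tilt) so the constrained residue-range
centroids sit exactly on the configured radii; every geometric config
parameter therefore closes the loop to 1e-6 through the geometry module
at zero noise, which is the backbone of the test suite.

The "temperature knob" is explicit: linear per-parameter drifts across a
trajectory plus i.i.d. Gaussian positional noise, all seeded from a
single integer (no hidden RNG state; identical seeds give bitwise
identical trajectories). This is a test harness for the *analysis*, not
physics: it contains no membrane, solvent, force field, or correlated
thermal motion, and it does not reproduce any crystal structure's
coordinates. Passing tests therefore establish that the descriptors
measure what they claim and that trends imposed on the geometry are
recovered — not that any particular biological system behaves this way.

Ring radii defaults are free parameters (no reference geometry is
reproduced); they follow canonical LH2 dimensions — B850 centers at
23.5 Å (18 pigments ⇒ ≈ 8.2 Å neighbour spacing), B800 at 29 Å
(≈ 20 Å spacing), α ring ≈ 17–18 Å, β ring ≈ 26.5–27.5 Å, carotenoid
tail at 19 Å — and the descriptor defaults are a
physiological-temperature condition (kink 67.8°, N-terminal length
12.1 Å, ω 151°). Default positional noise is 0.1 Å, a deliberately
small stand-in for thermal disorder that keeps zero-noise closed-loop
checks meaningful.

B850 dipoles are ring tangents with an alternating ±10° out-of-plane
tilt, mimicking the two-pigments-per-subunit arrangement; neighbouring
dipoles are then nearly head-to-tail (κ ≈ −1.9), the nearest-neighbour
coupling is negative, and the bright states sit at the bottom of the
band — a strong, red-shifted B850 band, qualitatively as in LH2. B800
dipoles are purely tangential. The BChl site energy is one free scalar:
the shared default 1.628 eV was calibrated once so that, on the default
geometry, the −0.07 eV-shifted B800 sites give a band at ≈ 800 nm and
the excitonically red-shifted B850 band lands at ≈ 859 nm. The
carotenoid dipole (13 D along the C21–C30 tail, centered on the tail
centroid — the segment in contact with B850) makes the RG1–B850
coupling decrease monotonically as the tail–B850 contact opens, the
mechanistic behaviour the coupling report is meant to expose; its
absolute magnitude is a point-dipole estimate at short range and should
be read qualitatively.

## Pipeline and reporting

`run_comparison()` runs geometry, occupancy and spectra over labeled
ensembles (in-memory frames or PDB/DCD paths), with an equilibration
window expressed as a skip fraction (synthetic trajectories have
arbitrary timestep) and a stride. Selections are label-based, so all
atom indices are resolved once per ensemble and per-frame work is pure
arithmetic; a test asserts the fast path equals the public per-frame
functions. Distribution centers are reported as sample mean ± sd
(a fitted density mode would be an alternative reading of
"distribution center"; the mean is deterministic), with
Freedman–Diaconis histograms. A trend is claimed only when per-label
means are strictly monotone *and* the pooled Spearman correlation
against condition rank exceeds a threshold (default 0.5; the acceptance
workflow uses 0.3 with its small ensembles) — either check alone
over-claims from noise. Reruns with the same config write byte-identical
artefacts.

Problem sizes: the shipped workflows use 3 conditions × 15–20 frames ×
9 subunits with 5–10 spectra snapshots, which the package analyses in
seconds; the pipeline comfortably handles hundreds of frames per
condition on one CPU.

## Known limitations

* Backbone proxies carry four atoms per residue and no side chains;
  descriptors needing side-chain atoms must map them to proxies (as the
  shipped contact pairs do).
* The point-dipole approximation overestimates couplings at contact
  distances; no transition-density or screened variants are provided.
* The helicity detector is a dihedral window, not a full
  secondary-structure assignment.
* Spectra model static (inhomogeneous) disorder only: no lifetime
  broadening, vibronic structure, or exciton dynamics.
* The generator's drift-plus-noise trajectories have no correlated
  dynamics, so time-correlation analyses are out of scope.
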