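---
title: "Multiscale hybrid theories and theory-agnostic jobs: models, conventions, numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiscale hybrid theories and theory-agnostic jobs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mschem)
```

This vignette is the package's own account of the models it implements,
the conventions it fixes where the literature leaves freedom, and what its
test systems do and do not show about real molecular systems.

## The evaluation contract

Every job in the package — optimization, scans, saddle searches, NEB,
Hessians, MD — consumes only a `fragment` (elements, Cartesian coordinates
in Å, masses in amu, charge, multiplicity, optional connectivity) and a
theory object answering `evaluate(theory, frag, pointcharges, gradient)`.
The result carries the energy in Hartree, the 3N gradient in Hartree/Bohr,
and optionally a dipole (a.u., origin at the Cartesian origin) and a
gradient on external point charges. Internal units are the
quantum-chemistry convention (Hartree, Bohr for derivatives) with
coordinates kept in Å so file I/O stays natural; conversions happen once at
the theory boundary. Non-finite energies or gradients raise immediately
rather than propagating NaN into an optimizer.

## Built-in analytic potentials

Three potential families stand in for external programs, each with exact
analytic gradients:

* a **harmonic force field**: `½k(r−r₀)²` stretches, `½k(θ−θ₀)²` bends,
  `V(1+cos(nφ−φ₀))` torsions, and Coulomb plus Lennard-Jones over
  non-excluded pairs. Exclusions are 1-2 and 1-3 only, with no 1-4
  scaling and no cutoffs: the systems are tiny, and exactness matters
  more than speed here.
* a **mock QM theory**: Morse pairs plus, under embedding, the exact
  Coulomb interaction between its fixed atom charges and external point
  charges, differentiated with respect to both atom and charge positions
  (the action–reaction sum vanishes to 1e-9). Its dipole is the
  point-charge sum, which is what makes IR intensities testable in closed
  form.
* the standard **2D test surfaces** (Müller–Brown with the literature
  constants; a LEPS-type two-bond model), evaluated on a single
  pseudo-atom whose (x, y) are the surface coordinates. Their stationary
  points are never quoted as external truths in the tests; they are
  located by an in-repo dense-grid + Newton oracle built on energy finite
  differences alone.

A limitation worth stating plainly: the mock QM potential has *no angular
stiffness*. A covalently cut QM region therefore has soft bending modes
that a real QM Hamiltonian would stiffen, and an unconstrained
minimization of such a region can drive three centres collinear — where a
retained MM torsion is mathematically singular. The QM/MM gradient
assembly is exact at any non-singular geometry (the finite-difference
checks run on chains with cut bonds), but minimization fixtures for QM/MM
use the solute-in-solvent system, where the boundary is non-covalent and
the physics is well-posed.

## Additive QM/MM

The energy is assembled as `E = E_QM' + E_MM'`. The MM side deletes every
bonded term fully inside the QM region, the boundary angle pattern
QM2–QM1–MM1 and dihedral pattern QM3–QM2–QM1–MM (terminal MM), keeps the
QM1–MM1 stretch, and excludes QM–QM nonbonded pairs. Under electrostatic
embedding the QM atom charges are zeroed in the MM evaluation — the
QM-environment electrostatics live entirely in the QM calculation — while
under mechanical embedding they are retained so that the classical
QM–MM Coulomb coupling survives. Cut bonds are capped with hydrogen link
atoms at a fixed 1.09 Å from QM1 along the bond (a typical C–H length), or
at a scaled fraction 0.723 of the actual bond length (≈ C–H over C–C); the
partitioner refuses boundaries that are not carbon–carbon unless told
otherwise, since cutting polar bonds is the classic way to ruin a QM/MM
model.

Boundary charges follow either the charge-shift scheme or RCD. For
charge shifting, the MM1 charge is zeroed and split equally over its n MM
neighbours; the dipole error this introduces is repaired by a ± pair per
MM2 site. The pair is placed at `r_MM2 ± f·(r_MM2 − r_MM1)` with a fixed
*fractional* offset `f = 0.1` and magnitudes `∓ q₀/(2nf)`. This differs
from the fixed-0.1-Å offset sometimes described: with a fractional offset
the auxiliary charge *values* are geometry-independent and the dipole
restoration is exact at every geometry, so the only geometry dependence is
through the positions, whose Jacobians (`(1±f)·I` on MM2, `∓f·I` on MM1)
are constant. That is what makes the assembled gradient exactly
consistent with the energy — with a geometry-dependent charge value, the
missing `∂E/∂q · ∂q/∂r` term would break the finite-difference identity
the tests enforce. RCD removes the MM1 charge, places `2q₀/n` at each
MM1–MM2 midpoint and subtracts `q₀/n` from each MM2, which preserves
charge and dipole identically.

Link-atom forces are projected onto the hosts by the exact chain rule of
the placement map `L(r_QM1, r_MM1)` (the fixed-distance Jacobian
`∂L/∂r_MM1 = (d/R)(I − ûûᵀ)`), or by the simpler lever rule. Chain-rule
projection preserves both the total force and the total torque, and is the
default.

## ONIOM and WrapTheory

ONIOM is implemented subtractively, `E = E_full^LL + Σ (E_region^high −
E_region^low)`, for two and three layers, with the *same* partition/link
machinery as QM/MM (one boundary code path). Under electrostatic embedding
the environment charges — boundary-shifted exactly as in QM/MM — enter
*both* members of each correction pair, and both pair theories must accept
point charges. For the 3-layer scheme each pair sees the charges of all
atoms outside its own region (region-1 calculations see middle + outer
charges; region-12 calculations see outer charges); link atoms are applied
identically at the region-2/region-3 boundary as at the inner one.
`wrap_theory` composes theories on the same fragment with arbitrary
weights — the Δ-correction pattern — and is itself a full citizen of the
contract.

## Optimizers

Minimization is Cartesian L-BFGS (memory 12) with an Armijo backtracking
line search, which guarantees monotone energies. Internal-coordinate
machinery (TRIC/HDLC/DLC) is deliberately not implemented; for the small
systems this package targets, Cartesian steps with projection-based
constraints are robust and much simpler. Convergence demands all five
criteria simultaneously: gradient max 4.5e-4 and rms 3.0e-4 Hartree/Bohr,
step max 1.8e-3 and rms 1.2e-3 Å, energy change 1e-6 Hartree — the common
quasi-Newton convention. Frozen atoms are removed from the optimization
vector entirely, so their coordinates are bit-identical on output.
Constraints (distance, angle, dihedral) are enforced by projecting
gradient and step onto the constraint tangent space and restoring the
constraint values after each step by Newton iterations (tolerance 1e-8;
for distances this is the SHAKE idea). Relaxed scans are sequences of
constrained minimizations, each warm-started from the previous grid
point; unrelaxed scans move only the last atom of the coordinate
definition, leaving every other degree of freedom untouched.

P-RFO takes the partitioned rational-function step: uphill along one
Hessian eigenmode (initially the lowest; thereafter the mode of maximal
overlap with the previously followed one — a deterministic tie-break),
downhill along the rest via the augmented-Hessian shift. The Hessian is
carried by Bofill's SR1/PSB interpolated update; the trust radius starts
at 0.1 Å and adapts within [0.01, 0.3] Å by the actual-to-predicted
energy-change ratio. On convergence a fresh numerical Hessian verifies
exactly one negative eigenvalue. The MECP search minimizes the Harvey-type
effective gradient `2(E_A−E_B)(g_A−g_B) + P⊥ ḡ` — the exact gradient of
the squared gap plus the mean gradient projected orthogonal to the gap
direction — with L-BFGS directions and a step cap instead of a line search
(there is no scalar objective); convergence requires the gap below 1e-6
Hartree and the seam-projected gradient below the usual thresholds.

## NEB

The initial path comes from IDPP: linear interpolation refined per image
by minimizing `Σ w(d_t)(d_t − d)²` over atom pairs, with targets `d_t`
interpolated linearly between the endpoint distance matrices and weights
`d_t⁻⁴`. Tangents are the improved energy-ordered scheme. Springs are
energy-weighted: with `E_ref = max(E_reactant, E_product)` and `E_max` the
band maximum, segment constants interpolate linearly in segment energy
between `k_min = 0.01` and `k_max = 0.1` Hartree/Å² (segments below
`E_ref` get `k_min`). This exact formula is re-derived independently in
the test suite and both implementations must agree to 1e-12. The climbing
image feels the full true force with inverted parallel component and no
springs, and converges under a tighter threshold (half of `conv_fmax` by
default). The band is driven by L-BFGS on the stacked interior
coordinates with a 0.1 Å per-atom step cap and a memory reset when the
maximum force overshoots — NEB forces are not the gradient of any scalar
function, so no line search is possible. Rigid-body alignment of each
image to its predecessor uses the quaternion (Horn) best-fit rotation; it
is skipped for systems with fewer than three atoms (a single pseudo-atom
on a 2D surface has no meaningful rigid-body fit — aligning would simply
translate images onto each other) and when frozen atoms are present.
NEB-TS runs the band to a loose threshold only, then builds a numerical
Hessian at the climbing image and refines with P-RFO; on the bundled 2D
surface this reaches the same saddle at roughly 3 % of the gradient calls
of a tight CI-NEB.

## Hessians, thermochemistry, Wigner sampling

Numerical Hessians are finite differences of analytic gradients, central
(default) or forward, with a default displacement of 0.005 Bohr expressed
in Å, symmetrized as `(H+Hᵀ)/2`. Partial Hessians restrict displacement
and response rows to a chosen atom subset. The displacement-parallel run
mode evaluates displacements out of order but assembles strictly by
displacement index, so it is bit-identical to serial — results must never
depend on completion order. Hessians are written to disk as plain text
with a small metadata header.

Harmonic analysis mass-weights (amu → electron masses), optionally
projects out the 3 translations and 2/3 rotations (linear molecules
detected by the smallest principal moment falling below 1e-8 amu·Å²),
diagonalizes in the orthogonal complement, and reports negative force
constants as negative wavenumbers. IR intensities use central-difference
dipole derivatives transformed to normal coordinates, `I = 974.88 ·
|∂μ/∂Q|²` km/mol with `∂μ/∂Q` in e·amu^−1/2; the point-charge dipole of
the mock QM theory makes the diatomic case exactly `C q²/μ`.

Thermochemistry is ideal-gas RRHO: Sackur–Tetrode translation, classical
rigid-rotor rotation with a symmetry number, harmonic vibrations with
`ZPE = ½Σhν`. Two quasi-RRHO variants treat low frequencies: the Grimme
damped free-rotor interpolation (`w = 1/(1+(ν₀/ν)⁴)`, free-rotor moment
capped by B_av = 10⁻⁴⁴ kg·m², default cutoff ν₀ = 100 cm⁻¹) and the
Truhlar floor (frequencies below the cutoff raised to it, entropy only).
A cutoff of zero recovers pure RRHO identically, and `G = H − TS` holds to
1e-10 Hartree by construction — the tests verify the identity rather than
assert tabulated values, except for the monoatomic gas where the
closed-form Sackur–Tetrode value is checked exactly.

Wigner sampling draws each mass-weighted normal coordinate from the
harmonic-oscillator Wigner distribution, a Gaussian of variance
`(1/2ω)·coth(ω/2k_BT)` in atomic units (the T → 0 limit is the pure
zero-point width), transforms back to Cartesians, and optionally supplies
conjugate velocities. The seed is mandatory: ensembles must be exactly
reproducible.

## Molecular dynamics

NVE uses velocity Verlet; NVT uses the BAOAB splitting of Langevin
dynamics, chosen for its configurational accuracy at practical time
steps. With friction zero BAOAB reduces exactly to velocity Verlet, which
the tests exploit as a consistency check. Time steps are given in fs and
converted internally to atomic time units (1 a.t.u. = 2.4188843×10⁻² fs);
friction is given in ps⁻¹. Frozen atoms are excluded from drift, noise,
kick and kinetic-energy bookkeeping entirely. Same seed ⇒ bit-identical
trajectories. Constraints (SHAKE/RATTLE) are not implemented in MD;
frozen atoms are the only restraint mechanism.

## Synthetic fixtures and problem sizes

All tests and the acceptance script build their inputs from the seeded
fixture generator: a pseudo-alkane `chain(n)` (zigzag carbons, alternating
charges summing to zero, matching Morse mock-QM terms so a boundary can be
cut anywhere), a `solvated_diatomic(m)` (polar ±0.3 e Morse diatomic among
m neutral three-site solvent molecules — the boundary-free QM/MM case),
and an argon `cluster(n)`. These emulate the *coupling topology* of real
multiscale systems — cut bonds, redistributed charges, solvent shells —
but not their chemistry: there is no electronic polarization, no angular
QM stiffness, and the energy scales are arbitrary. Passing tests
demonstrate that the coupling algebra, projections and integrators are
exact and deterministic, not that any real system is described well.

Problem sizes were chosen so the whole suite runs in well under a minute:
6–8-atom chains and an 11-atom solvated system for gradient checks
(finite-difference oracles scale as 6N energy evaluations per theory),
10-image bands on the 2D surface, 10⁴-step NVE and 50 ps / 25 000-step
Langevin runs on a 5-atom cluster, and 10⁵ Wigner samples. The Langevin
friction in the acceptance run is 20 ps⁻¹ so that the kinetic-temperature
estimator decorrelates quickly enough for its time average to sit within
a small fraction of the target at these run lengths; NVE amplitude
(0.05 Å on the model diatomic) keeps the velocity-Verlet energy ripple,
which scales as (ωΔt)² times the oscillation energy, below 10⁻⁶ Hartree
at Δt = period/100.

## Known limitations

No internal-coordinate optimization, no periodic boundary conditions, no
polarizable embedding, no Raman activities (polarizabilities are absent
from the theory contract), no SHAKE/RATTLE, no barostats. The mock QM
theory's missing angular stiffness limits which optimization problems are
well-posed for covalently cut regions, as discussed above. Boundary
treatments beyond link atoms (frozen orbitals, pseudopotential caps) are
out of scope.
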