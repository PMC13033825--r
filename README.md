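# mschem — a multiscale, theory-agnostic molecular modelling driver

Computational-chemistry job types — geometry optimization, surface scans,
transition-state and crossing-point searches, nudged-elastic-band paths,
numerical Hessians with thermochemistry, Wigner sampling, and
Born–Oppenheimer molecular dynamics — need nothing from the Hamiltonian
beyond an energy and a 3N gradient. `mschem` takes that separation
seriously: every job in the package is written against a single evaluation
contract,

```r
evaluate(theory, fragment, pointcharges = NULL, gradient = TRUE)
```

and every Hamiltonian is an S3 *theory* object honouring it. The package is
aimed at people developing or teaching hybrid-method machinery (QM/MM,
ONIOM, Δ-corrections) who want the full coupling algebra exercised against
fast, exactly differentiable analytic potentials rather than external
electronic-structure codes.

## What is implemented

**Built-in potentials.** A harmonic force field (bonds, angle bends,
periodic torsions, Coulomb + Lennard-Jones with 1-2/1-3 exclusions), an
embedding-capable Morse/Coulomb surrogate for a QM program (point-charge
energies, `pc_gradient`, dipoles), and the standard 2D test surfaces
(Müller–Brown, a LEPS-type two-bond model).

**Additive QM/MM** with mechanical and electrostatic embedding:

```
E_QM/MM = E_QM + E_MM + E_coupling ,   E_coupling = E_elstat + E_vdW + E_covalent
```

assembled in practice as a modified `E_QM'` (link-atom-capped QM region,
plus the interaction with the redistributed MM charges under electrostatic
embedding) and a modified `E_MM'` (QM-internal terms and the boundary
angle/dihedral patterns removed). Boundary machinery: hydrogen link atoms
at a fixed 1.09 Å (or scaled) along the cut bond, the charge-shift scheme
(MM1 → 0, equal redistribution to its MM neighbours, dipole-restoring ±
charge pairs) and the redistributed-charge-and-dipole (RCD) scheme,
chain-rule (or lever-rule) projection of link-atom forces onto the QM1/MM1
hosts, and exact mapping of point-charge forces — including those on the
auxiliary dipole charges — back onto real atoms. The assembled gradient
matches a pure finite-difference gradient of the composite energy to
better than 1e-6 Hartree/Bohr on every bundled fixture.

**Subtractive ONIOM**, 2- and 3-layer:

```
E = E_full^LL + E_1^HL − E_1^LL
E = E_full^LL + E_1^HL − E_1^ML + E_2^ML − E_2^LL
```

with the same link-atom code path for covalent region boundaries, and
optional electrostatic embedding of the environment charges in each
high/low correction pair. **WrapTheory** composes arbitrary theories as a
weighted sum (Δ-correction style), and the result is a first-class theory
usable by every job.

**Jobs.** Cartesian L-BFGS minimization with Armijo backtracking, exact
frozen-atom active regions, and distance/angle/dihedral constraints by
tangent-space projection; relaxed and unrelaxed 1D/2D scans; P-RFO saddle
refinement (Bofill updates, adaptive trust radius, eigenmode following)
with a final one-negative-eigenvalue check; Harvey-style minimum-energy
crossing point search; CI-NEB with IDPP interpolation, improved tangents,
energy-weighted springs and quaternion alignment, plus the NEB-TS
shortcut (loose NEB → numerical Hessian → P-RFO); numerical Hessians
(1-/2-point, partial, order-independent displacement-parallel assembly),
harmonic analysis with translation/rotation projection, IR intensities
from dipole derivatives, RRHO and quasi-RRHO (Grimme damping or Truhlar
frequency-raising) thermochemistry, Wigner ensembles; velocity-Verlet NVE
and BAOAB Langevin MD.

## A worked example

A six-centre pseudo-alkane chain with a QM/MM boundary through the middle
C–C bond, electrostatic embedding with the default charge-shift + dipole
correction:

```r
library(mschem)

fx <- generate_fixture("chain", n = 6, seed = 4)
th <- qmmm_theory(fx$qm_spec, fx$ff_spec, fx$fragment, qm_atoms = 1:3,
                  embedding = "electrostatic",
                  link_morse = c(D = 0.12, a = 1.7, r0 = 1.05))

r <- evaluate(th, fx$fragment)
r$extra$breakdown
#> $e_total
#> [1] 0.05736776
#> $e_qm_mod
#> [1] 0.002050839
#> $e_mm_mod
#> [1] 0.05531692
#> $embedding
#> [1] "electrostatic"

ng <- evaluate(numgrad_theory(th, step = 1e-4), fx$fragment)
max(abs(r$gradient - ng$gradient))
#> [1] 5.391047e-09
```

`e_total = e_qm_mod + e_mm_mod` holds to machine precision, and the
assembled analytic gradient — link-force projection, embedding forces and
dipole-correction Jacobians included — agrees with the numerical gradient
of the composite energy to ~5e-9 Hartree/Bohr.

The same theory object drives any job, e.g. dynamics:

```r
st <- md_settings(dt_fs = 0.5, n_steps = 200, ensemble = "nvt_langevin",
                  temperature_K = 300, friction_ps = 10, seed = 1)
traj <- run_md(th, fx$fragment, st)
```

Configured runs go through `run_job()` (YAML or list; atom indices are
0-based in configs), with a thin CLI wrapper in `inst/cli/mschem.R`:

```yaml
job: opt
seed: 1
fragment:
  fixture: {kind: chain, size: 6, seed: 4}
theory:
  type: qmmm
  qm_atoms: [0, 1, 2]
  embedding: electrostatic
```

```sh
Rscript inst/cli/mschem.R --config job.yaml --output-dir out/
```

Results are written as `results.json`, geometries as XYZ, scan tables and
energy logs as TSV.

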