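# Additive QM/MM: partitioning, link atoms, boundary charge redistribution,
# bonded-term deletion, force projection, and the headline composite
# gradient-vs-numerical-gradient checks.

test_that("partition_system finds boundaries and guards unusual ones", {
  fx <- generate_fixture("chain", n = 4, seed = 1)
  part <- partition_system(fx$fragment, 1:2)
  expect_equal(part$boundaries$qm1, 2)
  expect_equal(part$boundaries$mm1, 3)
  # O at the MM1 position makes the boundary unusual
  f2 <- fx$fragment
  f2$elements[3] <- "O"
  expect_error(partition_system(f2, 1:2), "unusual boundary")
  expect_silent(partition_system(f2, 1:2, allow_unusual = TRUE))
  # solute-in-solvent: no crossing bonds
  sv <- generate_fixture("solvated_diatomic", n = 2, seed = 2)
  expect_equal(nrow(partition_system(sv$fragment, 1:2)$boundaries), 0)
  expect_error(partition_system(fx$fragment, 1:4), "proper subset")
  expect_error(partition_system(fx$fragment, integer(0)), "nonempty")
})

test_that("link atoms: fixed 1.09 A default, custom element/distance, scaled mode", {
  f <- fragment(c("C", "C"), rbind(c(0, 0, 0), c(1.5, 0, 0)),
                connectivity = cbind(1, 2))
  bd <- data.frame(qm1 = 1, mm1 = 2)
  expect_equal(place_link_atoms(f, bd), matrix(c(1.09, 0, 0), 1, 3),
               tolerance = 1e-12)
  expect_equal(place_link_atoms(f, bd, link_distance = 1.35),
               matrix(c(1.35, 0, 0), 1, 3), tolerance = 1e-12)
  # fixed mode: moving MM1 leaves the link distance unchanged
  f2 <- f; f2$coords[2, ] <- c(1.9, 0.4, -0.2)
  lp <- place_link_atoms(f2, bd)
  expect_equal(sqrt(sum(lp^2)), 1.09, tolerance = 1e-12)
  # scaled mode tracks the bond length
  lp_s <- place_link_atoms(f2, bd, mode = "scaled", scale_ratio = 0.723)
  expect_equal(sqrt(sum(lp_s^2)), 0.723 * sqrt(sum(f2$coords[2, ]^2)),
               tolerance = 1e-12)
  f3 <- f; f3$coords[2, ] <- f3$coords[1, ]
  expect_error(place_link_atoms(f3, bd), "coincident")
})

test_that("charge shifting: MM1 zeroed, equal split, charge and dipole conserved", {
  fx <- generate_fixture("chain", n = 6, seed = 4)
  frag <- fx$fragment
  charges <- c(0.05, -0.05, 0.05, -0.30, 0.10, 0.15)
  part <- partition_system(frag, 1:3)
  bd <- part$boundaries[1, ]          # mm1 = 4, single MM2 neighbour (5)
  cr <- shift_charges(frag, charges, bd, part$connectivity, part$qm_atoms)
  expect_identical(cr$charges[4], 0)
  expect_equal(cr$charges[5], 0.10 - 0.30)       # the full q0 onto the single MM2
  expect_equal(sum(cr$charges[4:6]) + sum(cr$extra$q), sum(charges[4:6]),
               tolerance = 1e-12)
  # q_MM1 = 0 is a no-op
  cr0 <- shift_charges(frag, replace(charges, 4, 0), bd, part$connectivity,
                       part$qm_atoms)
  expect_equal(cr0$charges, replace(charges, 4, 0))
  expect_equal(nrow(cr0$extra), 0)
  # dipole of (modified + extra) MM set equals the original MM set
  mm <- part$mm_atoms
  dip <- function(pos, q) colSums(pos * q)
  d0 <- dip(frag$coords[mm, ], charges[mm])
  d1 <- dip(rbind(frag$coords[mm, ], as.matrix(cr$extra[, c("x", "y", "z")])),
            c(cr$charges[mm], cr$extra$q))
  expect_lt(max(abs(d0 - d1)), 1e-10)
  # branched MM1: two MM2 neighbours get q0/2 each (forced arithmetic)
  fb <- fragment(rep("C", 5),
                 rbind(c(0, 0, 0), c(1.5, 0, 0), c(3, 0, 0),
                       c(3.8, 1.2, 0), c(3.8, -1.2, 0)),
                 connectivity = rbind(c(1, 2), c(2, 3), c(3, 4), c(3, 5)))
  qb <- c(0, 0, -0.30, 0.10, 0.10)
  pb <- partition_system(fb, 1:2)
  crb <- shift_charges(fb, qb, pb$boundaries[1, ], pb$connectivity, pb$qm_atoms)
  expect_identical(crb$charges[3], 0)
  expect_equal(crb$charges[4:5], c(-0.05, -0.05))
  expect_equal(sum(crb$charges[3:5]) + sum(crb$extra$q), -0.10, tolerance = 1e-12)
})

test_that("RCD scheme preserves total charge and dipole; n=1 gives one midpoint", {
  fx <- generate_fixture("chain", n = 6, seed = 4)
  frag <- fx$fragment
  charges <- fx$ff_spec$charges
  part <- partition_system(frag, 1:3)
  cr <- rcd_charges(frag, charges, part$boundaries[1, ], part$connectivity,
                    part$qm_atoms)
  mm <- part$mm_atoms
  expect_equal(sum(cr$charges[mm]) + sum(cr$extra$q), sum(charges[mm]),
               tolerance = 1e-12)
  dip <- function(pos, q) colSums(pos * q)
  d0 <- dip(frag$coords[mm, ], charges[mm])
  d1 <- dip(rbind(frag$coords[mm, ], as.matrix(cr$extra[, c("x", "y", "z")])),
            c(cr$charges[mm], cr$extra$q))
  expect_lt(max(abs(d0 - d1)), 1e-10)
  # single MM2 neighbour: exactly one midpoint charge, one modified MM2
  expect_equal(nrow(cr$extra), 1)
  expect_equal(cr$extra$q, 2 * charges[4])
  expect_equal(cr$charges[5], charges[5] - charges[4])
})

test_that("boundary bonded-term deletion matches exhaustive pattern enumeration", {
  fx <- generate_fixture("chain", n = 5, seed = 2)
  spec <- fx$ff_spec
  qm <- 1:3
  mod <- delete_boundary_terms(spec, qm)
  # chain C1..C5, QM={1,2,3}: angle (2,3,4) deleted, dihedral (1,2,3,4) deleted,
  # bond (3,4) kept, QM-internal bond (1,2),(2,3) and angle (1,2,3) deleted
  expect_true(all(apply(mod$bonds[, c("i", "j")], 1, function(r) !all(r %in% qm))))
  expect_equal(nrow(mod$bonds), 2)        # (3,4) kept + (4,5)
  expect_equal(nrow(mod$angles), 1)       # only (3,4,5)
  expect_equal(unname(unlist(mod$angles[1, c("i", "j", "k")])), c(3, 4, 5))
  expect_equal(nrow(mod$dihedrals), 1)    # only (2,3,4,5)
  expect_equal(unname(unlist(mod$dihedrals[1, c("i", "j", "k", "l")])), c(2, 3, 4, 5))
  expect_true(all(mod$charges[qm] == 0))
  # brute-force enumeration over random QM subsets
  set.seed(7)
  fx8 <- generate_fixture("chain", n = 8, seed = 3)
  for (rep in 1:4) {
    qm <- sort(sample(1:8, sample(2:6, 1)))
    mod <- delete_boundary_terms(fx8$ff_spec, qm)
    keep_angle <- function(a) {
      nq <- sum(c(a[1], a[2], a[3]) %in% qm)
      !(nq == 3 || (nq == 2 && a[2] %in% qm && (!(a[1] %in% qm) || !(a[3] %in% qm))))
    }
    keep_dih <- function(d) {
      nq <- sum(d %in% qm)
      !(nq == 4 || (nq == 3 && d[2] %in% qm && d[3] %in% qm &&
                      (!(d[1] %in% qm) || !(d[4] %in% qm))))
    }
    want_a <- sum(apply(as.matrix(fx8$ff_spec$angles[, c("i", "j", "k")]), 1, keep_angle))
    want_d <- sum(apply(as.matrix(fx8$ff_spec$dihedrals[, c("i", "j", "k", "l")]), 1, keep_dih))
    expect_equal(nrow(mod$angles), want_a)
    expect_equal(nrow(mod$dihedrals), want_d)
  }
})

test_that("link-force projection: zero force, fd oracle, sum/torque conservation", {
  fx <- generate_fixture("chain", n = 4, seed = 6)
  frag <- fx$fragment
  part <- partition_system(frag, 1:2)
  qm <- part$qm_atoms
  # zero link force -> zero boundary contributions
  gz <- matrix(0.0, 3, 3)
  pz <- project_link_forces(gz, part$boundaries, frag, qm)
  expect_true(all(pz == 0))
  # random link force: force sum and torque preserved by chain projection
  set.seed(3)
  g <- matrix(stats::rnorm(9), 3, 3)
  lpos <- place_link_atoms(frag, part$boundaries)
  proj <- project_link_forces(g, part$boundaries, frag, qm, mode = "chain")
  sum_before <- colSums(g)
  expect_lt(max(abs(colSums(proj) - sum_before)), 1e-12)
  torque <- function(pos, gg) {
    t <- c(0, 0, 0)
    for (i in seq_len(nrow(pos))) t <- t + mschem:::.cross3(pos[i, ], gg[i, ])
    t
  }
  t_before <- torque(rbind(frag$coords[qm, ], lpos), g)
  t_after <- torque(frag$coords, proj)
  expect_lt(max(abs(t_before - t_after)), 1e-9)
  # lever mode conserves the force sum as well
  projl <- project_link_forces(g, part$boundaries, frag, qm, mode = "lever")
  expect_lt(max(abs(colSums(projl) - sum_before)), 1e-12)
  expect_error(project_link_forces(g, part$boundaries, frag, qm, mode = "nope"))
})

test_that("QM/MM assembly: breakdown identity, degenerate limit, gradient oracle", {
  fx <- generate_fixture("chain", n = 6, seed = 4)
  frag <- fx$fragment
  qm <- 1:3
  # headline: composite analytic gradient vs central differences, all variants
  for (variant in list(
    list(embedding = "electrostatic", charge_scheme = "shift", dipole_correction = TRUE),
    list(embedding = "electrostatic", charge_scheme = "shift", dipole_correction = FALSE),
    list(embedding = "electrostatic", charge_scheme = "rcd"),
    list(embedding = "mechanical", charge_scheme = "shift"))) {
    th <- do.call(qmmm_theory, c(list(qm_spec = fx$qm_spec, mm_spec = fx$ff_spec,
                                      frag = frag, qm_atoms = qm,
                                      link_morse = c(D = 0.12, a = 1.7, r0 = 1.05)),
                                 variant))
    r <- evaluate(th, frag)
    bd <- r$extra$breakdown
    expect_equal(bd$e_total, bd$e_qm_mod + bd$e_mm_mod, tolerance = 1e-12)
    ng <- evaluate(numgrad_theory(th, step = 1e-4), frag)
    expect_lt(max(abs(r$gradient - ng$gradient)), 1e-6)
    expect_lt(max(abs(colSums(r$gradient))), 1e-9)   # translational invariance
  }
  # lever projection also passes the conservation-level check
  thl <- qmmm_theory(fx$qm_spec, fx$ff_spec, frag, qm, projection = "lever",
                     link_morse = c(D = 0.12, a = 1.7, r0 = 1.05))
  expect_lt(max(abs(colSums(evaluate(thl, frag)$gradient))), 1e-9)
  # degenerate limit: Morse D = 0, no embedding charges -> plain modified-MM energy
  qm0 <- fx$qm_spec
  qm0$morse_pairs$D <- 0
  thd <- qmmm_theory(qm0, fx$ff_spec, frag, qm, embedding = "mechanical")
  rd <- evaluate(thd, frag)
  mm_only <- evaluate(forcefield_theory(delete_boundary_terms(fx$ff_spec, qm,
                                                              zero_qm_charges = FALSE)),
                      frag, gradient = FALSE)
  expect_equal(rd$energy, mm_only$energy, tolerance = 1e-12)
})

test_that("solute-in-solvent electrostatic embedding and energy extensivity", {
  sv <- generate_fixture("solvated_diatomic", n = 3, seed = 5)
  th <- qmmm_theory(sv$qm_spec, sv$ff_spec, sv$fragment, sv$qm_atoms,
                    embedding = "electrostatic")
  r <- evaluate(th, sv$fragment)
  bd <- r$extra$breakdown
  expect_identical(bd$e_total, bd$e_qm_mod + bd$e_mm_mod)
  ng <- evaluate(numgrad_theory(th, step = 1e-4), sv$fragment)
  expect_lt(max(abs(r$gradient - ng$gradient)), 1e-6)
  # extensivity: two far-separated copies give the sum of the parts
  f1 <- sv$fragment
  n1 <- n_atoms(f1)
  f2 <- f1
  f2$coords <- f1$coords + 5000      # far enough that residual dipole-dipole
                                     # coupling is below the tolerance
  joint <- fragment(c(f1$elements, f2$elements), rbind(f1$coords, f2$coords),
                    atom_charges = c(f1$atom_charges, f2$atom_charges),
                    connectivity = rbind(f1$connectivity, f1$connectivity + n1))
  ff2 <- forcefield_spec(
    bonds = rbind(sv$ff_spec$bonds,
                  transform(sv$ff_spec$bonds, i = i + n1, j = j + n1)),
    angles = rbind(sv$ff_spec$angles,
                   transform(sv$ff_spec$angles, i = i + n1, j = j + n1, k = k + n1)),
    charges = c(sv$ff_spec$charges, sv$ff_spec$charges),
    lj = rbind(sv$ff_spec$lj, sv$ff_spec$lj))
  qm2 <- mockqm_spec(rbind(sv$qm_spec$morse_pairs,
                           transform(sv$qm_spec$morse_pairs, i = i + n1, j = j + n1)),
                     atom_charges = c(sv$qm_spec$atom_charges, sv$qm_spec$atom_charges))
  thj <- qmmm_theory(qm2, ff2, joint, c(sv$qm_atoms, sv$qm_atoms + n1),
                     embedding = "electrostatic")
  ej <- evaluate(thj, joint, gradient = FALSE)$energy
  expect_lt(abs(ej - 2 * r$energy), 1e-10)
})
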