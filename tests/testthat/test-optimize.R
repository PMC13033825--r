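# Geometry optimization, scans, P-RFO saddle search, MECP.

test_that("L-BFGS: unique minimum, monotone energies, freeze contract", {
  hd <- harmonic_diatomic(k = 1, r0 = 1.0, r_start = 1.3)
  o <- lbfgs_minimize(hd$theory, hd$fragment)
  expect_true(o$converged)
  expect_lt(abs(mschem:::.dist(o$fragment$coords, 1, 2) - 1.0), 1e-5)
  expect_true(all(diff(o$energies) <= 1e-14))
  # frozen atom bit-identical
  o2 <- lbfgs_minimize(hd$theory, hd$fragment, active_atoms = 2)
  expect_identical(o2$fragment$coords[1, ], hd$fragment$coords[1, ])
  expect_true(o2$converged)
  # started at the minimum: immediate convergence
  o3 <- lbfgs_minimize(hd$theory, o$fragment)
  expect_true(o3$converged)
  expect_equal(o3$iterations, 0)
  # max_iter exceeded returns converged = FALSE, no exception
  o4 <- lbfgs_minimize(hd$theory, hd$fragment, opt_settings(max_iter = 1))
  expect_false(o4$converged)
})

test_that("L-BFGS finds the Muller-Brown minima located by the grid oracle", {
  mb <- surface2d_theory("muller_brown")
  oracle <- mb_oracle()
  expect_gte(length(oracle$minima), 3)
  starts <- list(c(-0.5, 1.3), c(0.5, 0.1), c(-0.1, 0.45))
  for (st in starts) {
    o <- lbfgs_minimize(mb, surface_point(st[1], st[2]), tight_opt())
    expect_true(o$converged)
    e <- utils::tail(o$energies, 1)
    devs <- vapply(oracle$minima, function(m) abs(m$energy - e), 0)
    expect_lt(min(devs), 1e-6)
  }
})

test_that("optimizer is theory-agnostic across all hybrid theory kinds", {
  fx <- generate_fixture("chain", n = 5, seed = 12)
  frag <- fx$fragment
  sv <- generate_fixture("solvated_diatomic", n = 2, seed = 3)
  s <- opt_settings(max_iter = 600)
  # the QM/MM case runs on the solute/solvent fixture: the Morse-only QM
  # surrogate has no angular stiffness, so optimizing a covalently-cut
  # chain is not a well-posed minimization for it
  cases <- list(
    FF = list(forcefield_theory(fx$ff_spec), frag),
    mockQM = list(mockqm_theory(fx$qm_spec), frag),
    QMMM = list(qmmm_theory(sv$qm_spec, sv$ff_spec, sv$fragment, sv$qm_atoms,
                            embedding = "electrostatic"), sv$fragment),
    ONIOM = list(oniom_theory(frag, list(1:2), list(fx$qm_spec, fx$ff_spec),
                              link_morse = c(D = 0.12, a = 1.7, r0 = 1.05)), frag),
    Wrap = list(wrap_theory(list(forcefield_theory(fx$ff_spec),
                                 mockqm_theory(fx$qm_spec)), c(1, 0.2)), frag))
  for (nm in names(cases)) {
    o <- lbfgs_minimize(cases[[nm]][[1]], cases[[nm]][[2]], s)
    expect_true(o$converged, label = paste("converged with", nm))
    expect_lt(max(abs(o$final$gradient)), 5e-4)
  }
})

test_that("unrelaxed scans: closed-form energies and 2D shape contract", {
  hd <- harmonic_diatomic(k = 0.8, r0 = 1.0, r_start = 1.0)
  tab <- scan_surface(hd$theory, hd$fragment,
                      list(type = "distance", atoms = c(1, 2)),
                      list(c(0.9, 1.0, 1.1)), relaxed = FALSE)
  expect_equal(tab$energy, c(0.005, 0, 0.005) * 0.8, tolerance = 1e-12)
  # 2D scan over bond + angle of a triatomic: |g1| x |g2| rows, coord1-major
  spec <- forcefield_spec(bonds = data.frame(i = c(1, 2), j = c(2, 3),
                                             k = c(1, 0.5), r0 = c(1, 1.2)),
                          angles = data.frame(i = 1, j = 2, k = 3,
                                              kth = 0.2, theta0 = 1.9),
                          charges = rep(0, 3))
  f3 <- fragment(rep("C", 3), rbind(c(0, 0, 0), c(1, 0, 0), c(1.4, 1.1, 0)))
  g1 <- c(0.9, 1.0, 1.1); g2 <- c(1.8, 1.9)
  tab2 <- scan_surface(forcefield_theory(spec), f3,
                       list(list(type = "distance", atoms = c(1, 2)),
                            list(type = "angle", atoms = c(1, 2, 3))),
                       list(g1, g2), relaxed = FALSE)
  expect_equal(nrow(tab2), 6)
  expect_equal(tab2$coord1, rep(g1, each = 2))
  expect_equal(tab2$coord2, rep(g2, 3))
  expect_error(scan_surface(forcefield_theory(spec), f3,
                            list(type = "angle", atoms = c(1, 2, 3)),
                            list(c(3.5)), relaxed = FALSE),
               "unreachable")
})

test_that("relaxed scans bound and bracket the unconstrained minimum", {
  spec <- forcefield_spec(bonds = data.frame(i = c(1, 2), j = c(2, 3),
                                             k = c(1, 0.5), r0 = c(1, 1.2)),
                          angles = data.frame(i = 1, j = 2, k = 3,
                                              kth = 0.2, theta0 = 1.9),
                          charges = rep(0, 3))
  th <- forcefield_theory(spec)
  f3 <- fragment(rep("C", 3), rbind(c(0, 0, 0), c(1.1, 0, 0), c(1.6, 1.0, 0.2)))
  s <- tight_opt()
  grid <- seq(0.9, 1.1, by = 0.05)
  tab <- scan_surface(th, f3, list(type = "distance", atoms = c(1, 2)),
                      list(grid), relaxed = TRUE, settings = s)
  e_min <- utils::tail(lbfgs_minimize(th, f3, s)$energies, 1)
  # upper bound at every grid point; equality where the grid hits r0
  expect_true(all(tab$energy >= e_min - 1e-12))
  expect_lt(min(tab$energy) - e_min, 1e-8)
  # constrained value is actually held
  frs <- attr(tab, "fragments")
  for (i in seq_along(grid)) {
    expect_lt(abs(mschem:::.dist(frs[[i]]$coords, 1, 2) - grid[i]), 1e-7)
  }
})

test_that("P-RFO: double-well barrier, oracle saddle, zero-step start", {
  # 1D double well: barrier top at x = 0 is the root of the known derivative
  dw <- poly_dw_theory(a = 0.05, b = 1.0)
  f <- fragment("X", matrix(c(0.31, 0, 0), 1, 3))
  H0 <- numerical_hessian(dw, f)
  o <- prfo_ts_opt(dw, f, H0, tight_opt(), verify_hessian = FALSE)
  expect_true(o$converged)
  expect_lt(abs(o$fragment$coords[1, 1]), 1e-5)
  expect_lt(abs(evaluate(dw, o$fragment)$gradient[1, 1]), 1e-7)
  # Muller-Brown: converges to the oracle saddle from a nearby start
  mb <- surface2d_theory("muller_brown")
  saddle_energies <- vapply(mb_oracle()$saddles, `[[`, 0, "energy")
  f0 <- surface_point(-0.7, 0.6)
  ts <- prfo_ts_opt(mb, f0, numerical_hessian(mb, f0), tight_opt())
  expect_true(ts$converged)
  expect_true(ts$saddle_ok)
  expect_lt(min(abs(utils::tail(ts$energies, 1) - saddle_energies)), 1e-6)
  # started exactly at the saddle: zero steps
  ts2 <- prfo_ts_opt(mb, ts$fragment, numerical_hessian(mb, ts$fragment),
                     tight_opt(), verify_hessian = FALSE)
  expect_true(ts2$converged)
  expect_equal(ts2$iterations, 0)
})

test_that("MECP: parabola intersection, degenerate surfaces, 2D seam oracle", {
  # 1D: E_A = (x-1)^2/2, E_B = (x-1.8)^2/2 + 0.05 cross where gap = 0
  thA <- quad1d_theory(k = 1, x0 = 1.0)
  thB <- quad1d_theory(k = 1, x0 = 1.8, c0 = 0.05)
  # closed form: 0.5(x-1)^2 = 0.5(x-1.8)^2 + 0.05 -> x = (1.8^2-1+0.1)/(2*0.8)
  x_cross <- (1.8^2 - 1 + 0.1) / (2 * 0.8)
  f <- fragment("X", matrix(c(1.2, 0, 0), 1, 3))
  o <- mecp_optimize(thA, thB, f, opt_settings(max_iter = 600))
  expect_true(o$converged)
  expect_lt(abs(o$fragment$coords[1, 1] - x_cross), 1e-4)
  expect_lt(abs(diff(o$energies_AB)), 1e-6)
  # identical surfaces: falls back to plain minimization, zero gap
  o2 <- mecp_optimize(thA, thA, f, opt_settings(max_iter = 600))
  expect_true(o2$converged)
  expect_lt(abs(o2$fragment$coords[1, 1] - 1.0), 1e-3)
  expect_equal(abs(diff(o2$energies_AB)), 0)
  # 2D displaced paraboloids (as harmonic diatomic surfaces in x,y):
  # seam minimum cross-checked against a brute-force seam scan
  sA <- forcefield_theory(forcefield_spec(
    bonds = data.frame(i = 1, j = 2, k = 1.0, r0 = 1.0), charges = c(0, 0)))
  sB <- forcefield_theory(forcefield_spec(
    bonds = data.frame(i = 1, j = 2, k = 2.0, r0 = 1.5), charges = c(0, 0)))
  f2 <- fragment(c("H", "H"), rbind(c(0, 0, 0), c(1.2, 0.1, 0)))
  om <- mecp_optimize(sA, sB, f2, opt_settings(max_iter = 800))
  expect_true(om$converged)
  r_mecp <- mschem:::.dist(om$fragment$coords, 1, 2)
  # brute force on the seam (1D family parametrized by bond length)
  rs <- seq(0.5, 2.5, by = 1e-4)
  gap <- 0.5 * 1 * (rs - 1)^2 - (0.5 * 2 * (rs - 1.5)^2)
  seam <- rs[which(abs(gap) < 2e-4)]
  e_seam <- 0.5 * (rs[which(abs(gap) < 2e-4)] - 1)^2 / 1
  r_best <- seam[which.min(e_seam)]
  expect_lt(abs(r_mecp - r_best), 5e-3)
})
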