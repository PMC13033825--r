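# NEB: IDPP interpolation, quaternion alignment, effective forces (with an
# independent re-derivation of the energy-weighted spring formula), CI-NEB
# on the 2D surface against the grid+Newton oracle, NEB-TS handoff.

test_that("IDPP: identical endpoints, exact 1D pairwise target, monotone objective", {
  fa <- fragment(c("H", "H"), rbind(c(0, 0, 0), c(1.0, 0, 0)))
  b0 <- idpp_interpolate(fa, fa, 3)
  for (im in 2:3) expect_equal(b0$images[[im]]$coords, fa$coords, tolerance = 1e-12)
  fb <- fragment(c("H", "H"), rbind(c(0, 0, 0), c(2.0, 0, 0)))
  b <- idpp_interpolate(fa, fb, 5)
  expect_lt(abs(mschem:::.dist(b$images[[3]]$coords, 1, 2) - 1.5), 1e-3)
  # refinement objective decreases monotonically (4-atom case)
  set.seed(8)
  f1 <- fragment(rep("C", 4), matrix(stats::rnorm(12, sd = 1.5), 4, 3))
  f2 <- fragment(rep("C", 4), f1$coords + matrix(stats::rnorm(12, sd = 0.8), 4, 3))
  bi <- idpp_interpolate(f1, f2, 6)
  traces <- attr(bi, "idpp_traces")
  for (tr in traces[!vapply(traces, is.null, TRUE)]) {
    expect_true(all(diff(tr) <= 1e-12))
  }
  expect_error(idpp_interpolate(fa, fragment("H", matrix(0, 1, 3)), 5),
               "identical atoms")
})

test_that("quaternion alignment removes rigid transforms; idempotent; matches grid search", {
  set.seed(5)
  P <- matrix(stats::rnorm(12), 4, 3)
  R <- random_rotation()
  moved <- P %*% t(R) + matrix(rep(c(1, -2, 0.5), each = 4), 4, 3)
  b <- neb_band(list(fragment(rep("C", 4), P),
                     fragment(rep("C", 4), moved),
                     fragment(rep("C", 4), P)))
  b2 <- align_images(b)
  expect_lt(sqrt(mean((b2$images[[2]]$coords - P)^2)), 1e-9)
  # idempotence
  b3 <- align_images(b2)
  expect_equal(b3$images[[2]]$coords, b2$images[[2]]$coords, tolerance = 1e-12)
  # rotation-grid oracle on a z-rotated copy: best grid angle matches
  ang_true <- 0.9
  rotated <- rotate_z(P, ang_true)
  b4 <- align_images(neb_band(list(fragment(rep("C", 4), P),
                                   fragment(rep("C", 4), rotated),
                                   fragment(rep("C", 4), P))))
  rmsd_aligned <- sqrt(mean((b4$images[[2]]$coords - P)^2))
  grid_rmsd <- min(vapply(seq(0, 2 * pi, length.out = 5000), function(a) {
    sqrt(mean((rotate_z(rotated, a) - P)^2))
  }, 0))
  # the quaternion fit must be at least as good as the best grid rotation,
  # and the two must agree to the grid resolution
  expect_lte(rmsd_aligned, grid_rmsd + 1e-9)
  expect_lt(grid_rmsd - rmsd_aligned, 1e-3)
})

test_that("NEB effective forces equal an independent re-derivation", {
  # independent oracle: same documented formula coded from scratch on flat vectors
  oracle_forces <- function(X, E, G, k_min, k_max, climb) {
    ni <- length(X)
    E_ref <- max(E[1], E[ni]); E_max <- max(E)
    kseg <- vapply(seq_len(ni - 1), function(j) {
      Es <- max(E[j], E[j + 1])
      if (E_max > E_ref && Es > E_ref)
        k_max - (k_max - k_min) * (E_max - Es) / (E_max - E_ref) else k_min
    }, 0)
    ci <- if (climb) which.max(E[2:(ni - 1)]) + 1L else NA
    out <- vector("list", ni)
    for (i in 2:(ni - 1)) {
      tp <- X[[i + 1]] - X[[i]]; tm <- X[[i]] - X[[i - 1]]
      if (E[i + 1] > E[i] && E[i] > E[i - 1]) tau <- tp
      else if (E[i + 1] < E[i] && E[i] < E[i - 1]) tau <- tm
      else {
        dmax <- max(abs(E[i + 1] - E[i]), abs(E[i - 1] - E[i]))
        dmin <- min(abs(E[i + 1] - E[i]), abs(E[i - 1] - E[i]))
        tau <- if (E[i + 1] > E[i - 1]) tp * dmax + tm * dmin else tp * dmin + tm * dmax
      }
      tau <- tau / sqrt(sum(tau^2))
      ft <- -G[[i]]
      fpar <- sum(ft * tau) * tau
      out[[i]] <- if (!is.na(ci) && i == ci) ft - 2 * fpar
      else (ft - fpar) + (kseg[i] * sqrt(sum(tp^2)) - kseg[i - 1] * sqrt(sum(tm^2))) * tau
    }
    out
  }
  set.seed(13)
  ni <- 6; nat <- 3
  imgs <- lapply(1:ni, function(i) fragment(rep("C", nat), matrix(stats::rnorm(9), nat, 3)))
  band <- neb_band(imgs)
  band$energies <- c(0, 0.4, 0.9, 1.2, 0.7, 0.1)
  grads <- lapply(1:ni, function(i) matrix(stats::rnorm(9), nat, 3))
  for (climb in c(FALSE, TRUE)) {
    got <- neb_forces(band, grads, k_min = 0.02, k_max = 0.15, climb = climb)
    want <- oracle_forces(lapply(imgs, function(f) as.numeric(t(f$coords))),
                          band$energies,
                          lapply(grads, function(g) as.numeric(t(g)) / units_au$bohr_to_ang),
                          0.02, 0.15, climb)
    for (i in 2:(ni - 1)) {
      expect_lt(max(abs(as.numeric(t(got[[i]])) - want[[i]])), 1e-12)
    }
    # endpoints feel nothing
    expect_true(all(got[[1]] == 0) && all(got[[ni]] == 0))
  }
  expect_error(neb_band(imgs[1:2]), "at least 3")
})

test_that("CI-NEB on the 2D surface reproduces the oracle saddle; endpoints fixed", {
  mb <- surface2d_theory("muller_brown")
  oracle <- mb_oracle()
  mA <- lbfgs_minimize(mb, surface_point(-0.5, 1.5), tight_opt())$fragment
  mB <- lbfgs_minimize(mb, surface_point(0.6, 0.0), tight_opt())$fragment
  r <- neb_optimize(mb, mA, mB, n_images = 10, climb = TRUE,
                    conv_fmax = 5e-4, max_iter = 2000)
  expect_true(r$converged)
  saddle_e <- vapply(oracle$saddles, `[[`, 0, "energy")
  expect_lt(min(abs(max(r$energies) - saddle_e)), 1e-4)
  # endpoints bit-identical through the optimization
  expect_identical(r$band$images[[1]]$coords, mA$coords)
  expect_identical(r$band$images[[10]]$coords, mB$coords)
  # with climb off, interior images have small perpendicular true force
  r0 <- neb_optimize(mb, mA, mB, n_images = 8, climb = FALSE,
                     conv_fmax = 1e-3, max_iter = 2000)
  expect_true(r0$converged)
  # path length stayed bounded
  plen <- function(band) sum(vapply(2:length(band$images), function(i) {
    sqrt(mean((band$images[[i]]$coords - band$images[[i - 1]]$coords)^2))
  }, 0))
  expect_lt(plen(r$band), 10 * plen(idpp_interpolate(mA, mB, 10)))
  # identical endpoints: immediate convergence, zero barrier
  rid <- neb_optimize(mb, mA, mA, n_images = 5, climb = FALSE, conv_fmax = 1e-3)
  expect_true(rid$converged)
  expect_equal(rid$iterations, 0)
  expect_lt(max(rid$energies) - rid$energies[1], 1e-12)
})

test_that("NEB-TS reaches the same saddle as tight CI-NEB with fewer gradient calls", {
  mb <- surface2d_theory("muller_brown")
  mA <- lbfgs_minimize(mb, surface_point(-0.5, 1.5), tight_opt())$fragment
  mB <- lbfgs_minimize(mb, surface_point(0.6, 0.0), tight_opt())$fragment
  cth <- counting_theory(mb)
  tight <- neb_optimize(cth, mA, mB, n_images = 10, climb = TRUE,
                        conv_fmax = 5e-4, max_iter = 2000)
  calls_tight <- evaluation_count(cth)
  ts <- neb_ts(mb, mA, mB, n_images = 10, loose_fmax = 0.05,
               settings = tight_opt())
  expect_true(ts$saddle$converged)
  expect_true(ts$saddle$saddle_ok)
  expect_lt(abs(utils::tail(ts$saddle$energies, 1) - max(tight$energies)), 1e-4)
  expect_lt(ts$n_gradient_calls, calls_tight)
  # double-well toy: saddle at the closed-form barrier top x = 0
  dw <- poly_dw_theory(a = 0.05, b = 1.0)
  fa <- fragment("X", matrix(c(-1, 0, 0), 1, 3))
  fb <- fragment("X", matrix(c(1, 0, 0), 1, 3))
  tsd <- neb_ts(dw, fa, fb, n_images = 7, loose_fmax = 0.01,
                settings = tight_opt())
  expect_true(tsd$saddle$converged)
  expect_lt(abs(tsd$saddle$fragment$coords[1, 1]), 1e-5)
  expect_lt(abs(utils::tail(tsd$saddle$energies, 1) - 0.05), 1e-8)  # a b^4
})
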