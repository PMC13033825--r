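# Numerical Hessian, harmonic analysis, IR intensities, thermochemistry,
# Wigner sampling.

test_that("numerical Hessian: quadratic exactness, determinism, partial block", {
  hd <- harmonic_diatomic(k = 0.6, r0 = 1.1)
  H <- numerical_hessian(hd$theory, hd$fragment)
  # symmetric by construction
  expect_lt(max(abs(H - t(H))), 1e-12)
  # xx element along the bond equals k (exact for a quadratic), in Hartree/Bohr^2
  k_bohr <- 0.6 * units_au$bohr_to_ang^2
  expect_lt(abs(H[1, 1] - k_bohr), 1e-8 * k_bohr)
  # displacement-parallel assembly is bit-identical to serial
  fx <- generate_fixture("solvated_diatomic", n = 1, seed = 2)
  th <- mockqm_theory(fx$qm_spec)
  Hs <- numerical_hessian(th, fx$fragment, hess_atoms = 1:2)
  Hp <- numerical_hessian(th, fx$fragment, hess_atoms = 1:2, runmode = "parallel")
  expect_identical(Hs, Hp)
  # partial Hessian equals the corresponding full-Hessian block
  Hfull <- numerical_hessian(hd$theory, hd$fragment)
  Hpart <- numerical_hessian(hd$theory, hd$fragment, hess_atoms = 1)
  expect_equal(Hpart, Hfull[1:3, 1:3], tolerance = 1e-12)
  # one-point formula agrees with two-point to O(step)
  H1 <- numerical_hessian(hd$theory, hd$fragment, formula = "one-point")
  expect_lt(max(abs(H1 - Hfull)), 1e-3)
  # halving the step shrinks the two-point error ~4x vs the analytic assembly
  f_anh <- fragment(c("H", "H"), rbind(c(0, 0, 0), c(1.2, 0, 0)))
  th_anh <- mockqm_theory(mockqm_spec(data.frame(i = 1, j = 2, D = 0.2, a = 1.5, r0 = 1.1),
                                      atom_charges = c(0, 0)))
  href <- numerical_hessian(th_anh, f_anh, step = 1e-5)
  e1 <- max(abs(numerical_hessian(th_anh, f_anh, step = 8e-3) - href))
  e2 <- max(abs(numerical_hessian(th_anh, f_anh, step = 4e-3) - href))
  expect_equal(e1 / e2, 4, tolerance = 0.3)
})

test_that("hessian text file round-trips", {
  hd <- harmonic_diatomic()
  H <- numerical_hessian(hd$theory, hd$fragment)
  p <- withr::local_tempfile(fileext = ".txt")
  write_hessian(H, hd$fragment, p, step = 0.0026)
  expect_equal(read_hessian(p), unname(H), tolerance = 1e-14)
})

test_that("harmonic analysis: closed-form diatomic frequency and isotope shift", {
  k <- 0.6
  hd <- harmonic_diatomic(k = k, r0 = 1.1)
  va <- harmonic_analysis(numerical_hessian(hd$theory, hd$fragment),
                          hd$fragment, project = TRUE)
  mu_me <- prod(hd$fragment$masses) / sum(hd$fragment$masses) * units_au$amu_to_me
  nu_expect <- units_au$hartree_to_cm1 * sqrt(k * units_au$bohr_to_ang^2 / mu_me)
  expect_lt(abs(max(va$frequencies) - nu_expect), 0.1)
  expect_true(va$linear)
  # unprojected Hessian of a translation-invariant theory: >= 3 near-zero modes
  va0 <- harmonic_analysis(numerical_hessian(hd$theory, hd$fragment),
                           hd$fragment, project = FALSE)
  expect_gte(sum(abs(va0$frequencies) < 5), 3)
  # isotope substitution scales by sqrt(mu1/mu2)
  fD <- fragment(c("D", "Cl"), hd$fragment$coords)
  vaD <- harmonic_analysis(numerical_hessian(hd$theory, fD), fD, project = TRUE)
  muH <- prod(hd$fragment$masses) / sum(hd$fragment$masses)
  muD <- prod(fD$masses) / sum(fD$masses)
  expect_lt(abs(max(vaD$frequencies) / max(va$frequencies) - sqrt(muH / muD)), 1e-4)
  # nonlinear triatomic at its minimum: exactly 3 nonzero modes after projection
  spec3 <- forcefield_spec(bonds = data.frame(i = c(1, 1), j = c(2, 3),
                                              k = 0.5, r0 = 0.96),
                           angles = data.frame(i = 2, j = 1, k = 3,
                                               kth = 0.12, theta0 = 1.824),
                           charges = rep(0, 3))
  th3 <- forcefield_theory(spec3)
  f3 <- fragment(c("O", "H", "H"),
                 rbind(c(0, 0, 0), c(0.96, 0, 0), c(-0.24, 0.93, 0)))
  f3 <- lbfgs_minimize(th3, f3, tight_opt())$fragment
  va3 <- harmonic_analysis(numerical_hessian(th3, f3), f3, project = TRUE)
  expect_equal(length(va3$frequencies), 3)
  expect_true(all(va3$frequencies > 5))
  expect_false(va3$linear)
})

test_that("IR intensities: closed form, symmetry zero, rotation invariance", {
  q <- 0.25
  f <- fragment(c("H", "Cl"), rbind(c(0, 0, 0), c(1.1, 0, 0)))
  th <- mockqm_theory(mockqm_spec(data.frame(i = 1, j = 2, D = 0.2, a = 1.5, r0 = 1.1),
                                  atom_charges = c(q, -q)))
  va <- harmonic_analysis(numerical_hessian(th, f), f, project = TRUE)
  ir <- ir_intensities(th, f, va)
  # point-charge dipole derivative: dmu/dQ = q/sqrt(mu) -> I = C q^2/mu
  mu_amu <- prod(f$masses) / sum(f$masses)
  expect_equal(max(ir), units_au$ir_kmmol * q^2 / mu_amu, tolerance = 1e-6)
  expect_true(all(ir >= 0))
  # equal charges on a homonuclear diatomic: stretch is IR-silent
  f2 <- fragment(c("H", "H"), rbind(c(0, 0, 0), c(1.1, 0, 0)))
  th2 <- mockqm_theory(mockqm_spec(data.frame(i = 1, j = 2, D = 0.2, a = 1.5, r0 = 1.1),
                                   atom_charges = c(0.2, 0.2)))
  va2 <- harmonic_analysis(numerical_hessian(th2, f2), f2, project = TRUE)
  expect_lt(max(ir_intensities(th2, f2, va2)), 1e-10)
  # intensities invariant under rigid rotation of the input
  set.seed(4)
  R <- random_rotation()
  fr <- f
  fr$coords <- f$coords %*% t(R)
  var <- harmonic_analysis(numerical_hessian(th, fr), fr, project = TRUE)
  expect_equal(sort(ir_intensities(th, fr, var)), sort(ir),
               tolerance = 1e-6)
  # dipole-free theory refuses
  hd <- harmonic_diatomic()
  expect_error(ir_intensities(hd$theory, hd$fragment, va), "dipole")
})

test_that("thermochemistry: Sackur-Tetrode, limits, quasi-RRHO switches", {
  u <- units_au
  fa <- fragment("Ar", matrix(0, 1, 3))
  tr <- thermochemistry(NULL, fa, T = 298.15, P = 101325)
  # closed-form Sackur-Tetrode (SI), converted
  m_kg <- fa$masses * u$amu_to_kg
  S_st <- u$kB_SI * (log((2 * pi * m_kg * u$kB_SI * 298.15 / u$h_SI^2)^1.5 *
                           u$kB_SI * 298.15 / 101325) + 2.5) / u$hartree_to_J
  expect_lt(abs(tr$S_total - S_st), 1e-10)
  expect_equal(tr$S_rot, 0)
  expect_equal(tr$zpe, 0)
  # G = H - T S identity across temperatures and systems
  hd <- harmonic_diatomic(k = 0.6, r0 = 1.1)
  va <- harmonic_analysis(numerical_hessian(hd$theory, hd$fragment),
                          hd$fragment, project = TRUE)
  for (T in c(50, 298.15, 1000)) {
    t2 <- thermochemistry(va, hd$fragment, T = T)
    expect_lt(abs(t2$G - (t2$H - T * t2$S_total)), 1e-10)
  }
  # T -> 0: vibrational entropy and thermal energy vanish, U -> ZPE (+ trans/rot)
  t0 <- thermochemistry(va, hd$fragment, T = 1e-4)
  expect_lt(t0$S_vib, 1e-12)
  expect_lt(abs(t0$U - t0$zpe), 1e-6)
  # quasi-RRHO with cutoff 0 is exactly RRHO, both variants
  tg0 <- thermochemistry(va, hd$fragment, quasi_rrho = "grimme", cutoff = 0)
  tt0 <- thermochemistry(va, hd$fragment, quasi_rrho = "truhlar", cutoff = 0)
  tr0 <- thermochemistry(va, hd$fragment)
  expect_identical(tg0$S_vib, tr0$S_vib)
  expect_identical(tt0$S_vib, tr0$S_vib)
  # a low-frequency mode gains less entropy under the damped free-rotor
  soft <- harmonic_diatomic(k = 0.0005, r0 = 3)
  va_s <- harmonic_analysis(numerical_hessian(soft$theory, soft$fragment),
                            soft$fragment, project = TRUE)
  s_rrho <- thermochemistry(va_s, soft$fragment)$S_vib
  s_q <- thermochemistry(va_s, soft$fragment, quasi_rrho = "grimme",
                         cutoff = 100)$S_vib
  expect_lt(s_q, s_rrho)
  expect_error(thermochemistry(va, hd$fragment, T = -10), "temperature")
  expect_warning(
    thermochemistry(structure(list(frequencies = c(-50, 1000)), class = "vibrational_analysis"),
                    hd$fragment), "imaginary")
})

test_that("Wigner sampling: closed-form width, determinism, zero mean", {
  q <- 0.25
  f <- fragment(c("H", "Cl"), rbind(c(0, 0, 0), c(1.1, 0, 0)))
  th <- mockqm_theory(mockqm_spec(data.frame(i = 1, j = 2, D = 0.2, a = 1.5, r0 = 1.1),
                                  atom_charges = c(q, -q)))
  va <- harmonic_analysis(numerical_hessian(th, f), f, project = TRUE)
  omega <- max(va$frequencies) / units_au$hartree_to_cm1
  mode <- va$modes_mw[, which.max(va$frequencies)]
  m_me <- rep(f$masses * units_au$amu_to_me, each = 3)
  proj_q <- function(w) {
    sum(ang_to_bohr(as.numeric(t(w$coords - f$coords))) * sqrt(m_me) * mode)
  }
  for (T in c(0, 300)) {
    n <- 20000
    ws <- wigner_sample(va, f, n = n, T = T, seed = 31)
    qs <- vapply(ws, proj_q, 0)
    kB <- units_au$kB_hartree
    coth <- if (T > 0) 1 / tanh(omega / (2 * kB * T)) else 1
    sd_expect <- sqrt(coth / (2 * omega))
    expect_lt(abs(stats::sd(qs) / sd_expect - 1), 0.02)
    expect_lt(abs(mean(qs)), 3 * sd_expect / sqrt(n))
  }
  # determinism under the seed
  expect_identical(wigner_sample(va, f, 5, T = 300, seed = 7),
                   wigner_sample(va, f, 5, T = 300, seed = 7))
  expect_error(wigner_sample(va, f, 5, T = 300), "seed")
  # imaginary modes refuse
  va_bad <- va
  va_bad$frequencies[1] <- -100
  expect_error(wigner_sample(va_bad, f, 5, T = 300, seed = 1), "imaginary")
})
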