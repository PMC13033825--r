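# Numerical Hessian, harmonic analysis with translation/rotation
# projection, IR intensities from finite-difference dipole derivatives,
# RRHO / quasi-RRHO thermochemistry and Wigner sampling.

#' Numerical Hessian by finite differences of analytic gradients
#'
#' Column blocks from displaced-gradient differences: the two-point
#' (central) formula uses +/- step (2 * 3h gradient calls for h displaced
#' atoms), the one-point (forward) formula uses +step and the reference
#' (3h + 1 calls). The result is symmetrized as (H + H^T)/2. A partial
#' Hessian over \code{hess_atoms} returns the 3h x 3h block. The
#' displacement-parallel run mode evaluates displacements out of order and
#' assembles strictly by displacement index, so it is bit-identical to the
#' serial mode.
#'
#' @param theory gradient-capable theory.
#' @param frag the \code{fragment} (usually a stationary point).
#' @param step displacement in Angstrom; default 0.005 Bohr expressed in
#'   Angstrom.
#' @param formula "two-point" (default) or "one-point".
#' @param hess_atoms optional atom subset for a partial Hessian.
#' @param runmode "serial" or "parallel" (displacement-parallel assembly).
#' @return 3h x 3h symmetric matrix, Hartree/Bohr^2.
#' @export
numerical_hessian <- function(theory, frag,
                              step = 0.005 * units_au$bohr_to_ang,
                              formula = c("two-point", "one-point"),
                              hess_atoms = NULL,
                              runmode = c("serial", "parallel")) {
  formula <- match.arg(formula)
  runmode <- match.arg(runmode)
  stopifnot(step > 0)
  n <- n_atoms(frag)
  atoms <- if (is.null(hess_atoms)) seq_len(n) else sort(unique(as.integer(hess_atoms)))
  if (any(atoms < 1 | atoms > n)) stop("hess_atoms index out of range")
  h <- length(atoms)
  rows <- as.vector(t(outer(atoms, 1:3, function(a, k) 3 * (a - 1) + k)))
  step_bohr <- ang_to_bohr(step)

  grad_at <- function(cc) {
    f <- frag; f$coords <- cc
    g <- evaluate(theory, f, gradient = TRUE)$gradient
    if (any(!is.finite(g))) stop("non-finite displaced gradient in numerical Hessian")
    as.numeric(t(g))[rows]
  }

  disp <- vector("list", 3 * h)
  d <- 0
  for (a in atoms) for (k in 1:3) {
    d <- d + 1
    disp[[d]] <- c(a, k)
  }
  order_idx <- if (runmode == "parallel") rev(seq_len(3 * h)) else seq_len(3 * h)

  g0 <- if (formula == "one-point") grad_at(frag$coords) else NULL
  cols <- vector("list", 3 * h)
  for (d in order_idx) {
    a <- disp[[d]][1]; k <- disp[[d]][2]
    cp <- frag$coords; cp[a, k] <- cp[a, k] + step
    gp <- grad_at(cp)
    if (formula == "two-point") {
      cm <- frag$coords; cm[a, k] <- cm[a, k] - step
      gm <- grad_at(cm)
      cols[[d]] <- (gp - gm) / (2 * step_bohr)
    } else {
      cols[[d]] <- (gp - g0) / step_bohr
    }
  }
  H <- do.call(cbind, cols)
  (H + t(H)) / 2
}

#' Write / read a Hessian as plain text
#'
#' Plain-text symmetric matrix with a small metadata header (atom count,
#' elements, displacement step).
#'
#' @param hessian matrix, Hartree/Bohr^2.
#' @param frag the fragment it belongs to.
#' @param path file path.
#' @param step displacement used (metadata only).
#' @return path (write) or matrix (read), invisibly / directly.
#' @export
write_hessian <- function(hessian, frag, path, step = NA) {
  hdr <- c(sprintf("# mschem hessian  natoms %d  dim %d  step_ang %s",
                   n_atoms(frag), nrow(hessian), format(step)),
           paste("#", paste(frag$elements, collapse = " ")))
  body <- apply(hessian, 1, function(r) paste(sprintf("%.15e", r), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_hessian
#' @export
read_hessian <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  do.call(rbind, lapply(strsplit(trimws(body), "[[:space:]]+"), as.numeric))
}

# Orthonormal basis of global translations and rotations in mass-weighted
# coordinates; rank 5 for linear molecules, 6 otherwise (3 for an atom).
.transrot_basis <- function(coords, masses) {
  n <- nrow(coords)
  sm <- sqrt(masses)
  com <- colSums(coords * masses) / sum(masses)
  rc <- sweep(coords, 2, com)
  B <- matrix(0.0, 3 * n, 0)
  for (k in 1:3) {
    v <- rep(0, 3 * n)
    v[seq(k, 3 * n, by = 3)] <- sm
    B <- cbind(B, v)
  }
  for (k in 1:3) {
    e <- c(0, 0, 0); e[k] <- 1
    v <- numeric(3 * n)
    for (i in seq_len(n)) {
      v[(3 * i - 2):(3 * i)] <- sm[i] * .cross3(e, rc[i, ])
    }
    B <- cbind(B, v)
  }
  qrB <- qr(B)
  qr.Q(qrB)[, seq_len(qrB$rank), drop = FALSE]
}

# Principal moments of inertia, amu * Angstrom^2.
.inertia_moments <- function(coords, masses) {
  com <- colSums(coords * masses) / sum(masses)
  rc <- sweep(coords, 2, com)
  I <- matrix(0.0, 3, 3)
  for (i in seq_len(nrow(coords))) {
    r <- rc[i, ]
    I <- I + masses[i] * (sum(r^2) * diag(3) - tcrossprod(r))
  }
  sort(eigen(I, symmetric = TRUE, only.values = TRUE)$values)
}

#' Harmonic (normal-mode) analysis
#'
#' Mass-weights the Hessian, optionally projects out the global
#' translations and rotations (2 rotations for a linear molecule, detected
#' by the smallest principal moment of inertia being below 1e-8
#' amu Angstrom^2), and diagonalizes in the complement. Negative force
#' constants are reported as negative wavenumbers.
#'
#' @param hessian 3h x 3h matrix, Hartree/Bohr^2.
#' @param frag the fragment (masses, geometry).
#' @param project project out translations/rotations (default TRUE).
#' @param atoms atom subset matching a partial Hessian.
#' @return object of class \code{vibrational_analysis}: \code{frequencies}
#'   (cm^-1, ascending), \code{modes_mw} (orthonormal mass-weighted
#'   modes, columns), \code{modes_cart} (Cartesian displacement modes),
#'   \code{hessian}, \code{masses}, \code{linear}, \code{n_projected}.
#' @export
harmonic_analysis <- function(hessian, frag, project = TRUE, atoms = NULL) {
  atoms <- if (is.null(atoms)) seq_len(n_atoms(frag)) else sort(as.integer(atoms))
  masses <- frag$masses[atoms]
  if (any(!is.finite(masses)) || any(masses <= 0)) stop("invalid masses")
  coords <- frag$coords[atoms, , drop = FALSE]
  nd <- 3 * length(atoms)
  if (nrow(hessian) != nd) stop("hessian dimension does not match atom selection")
  H <- (hessian + t(hessian)) / 2
  m_me <- rep(masses * units_au$amu_to_me, each = 3)
  Hmw <- H / sqrt(outer(m_me, m_me))

  linear <- FALSE
  if (project && length(atoms) > 1) {
    mom <- .inertia_moments(coords, masses)
    linear <- mom[1] < 1e-8
    B <- .transrot_basis(coords, masses)
    Qfull <- qr.Q(qr(cbind(B, diag(nd))))
    C <- Qfull[, (ncol(B) + 1):nd, drop = FALSE]
    sub <- t(C) %*% Hmw %*% C
    eg <- eigen((sub + t(sub)) / 2, symmetric = TRUE)
    vals <- rev(eg$values)
    modes_mw <- C %*% eg$vectors[, rev(seq_len(ncol(sub))), drop = FALSE]
    n_proj <- ncol(B)
  } else {
    eg <- eigen(Hmw, symmetric = TRUE)
    vals <- rev(eg$values)
    modes_mw <- eg$vectors[, rev(seq_len(nd)), drop = FALSE]
    n_proj <- 0L
  }
  freqs <- sign(vals) * units_au$hartree_to_cm1 * sqrt(abs(vals))
  modes_cart <- modes_mw / sqrt(m_me)
  structure(list(frequencies = freqs, modes_mw = modes_mw,
                 modes_cart = modes_cart, hessian = H,
                 masses = masses, coords = coords, atoms = atoms,
                 linear = linear, n_projected = n_proj),
            class = "vibrational_analysis")
}

#' @export
print.vibrational_analysis <- function(x, ...) {
  cat(sprintf("<vibrational_analysis: %d modes, %d projected%s>\n",
              length(x$frequencies), x$n_projected,
              if (x$linear) ", linear" else ""))
  cat("frequencies (cm^-1):", paste(sprintf("%.2f", x$frequencies), collapse = " "), "\n")
  invisible(x)
}

#' IR intensities from finite-difference dipole derivatives
#'
#' Central-difference dipole derivatives along Cartesian displacements,
#' transformed to normal coordinates; intensity per mode is
#' \code{974.88 |dmu/dQ|^2} km/mol with dmu/dQ in e/sqrt(amu).
#'
#' @param theory dipole-capable theory.
#' @param frag the fragment.
#' @param analysis a \code{\link{harmonic_analysis}} result.
#' @param step displacement in Angstrom.
#' @return numeric vector of intensities (km/mol), one per mode.
#' @export
ir_intensities <- function(theory, frag, analysis,
                           step = 0.005 * units_au$bohr_to_ang) {
  probe <- evaluate(theory, frag, gradient = FALSE)
  if (is.null(probe$dipole)) stop("theory does not provide dipole moments")
  atoms <- analysis$atoms
  nd <- 3 * length(atoms)
  dmu <- matrix(0.0, nd, 3)
  step_bohr <- ang_to_bohr(step)
  d <- 0
  for (a in atoms) for (k in 1:3) {
    d <- d + 1
    cp <- frag$coords; cp[a, k] <- cp[a, k] + step
    cm <- frag$coords; cm[a, k] <- cm[a, k] - step
    fp <- frag; fp$coords <- cp
    fm <- frag; fm$coords <- cm
    mup <- evaluate(theory, fp, gradient = FALSE)$dipole
    mum <- evaluate(theory, fm, gradient = FALSE)$dipole
    dmu[d, ] <- (mup - mum) / (2 * step_bohr)        # e (a.u. dipole per Bohr)
  }
  m_amu <- rep(analysis$masses, each = 3)
  dmudQ <- t(analysis$modes_mw / sqrt(m_amu)) %*% dmu   # e / sqrt(amu)
  pmax(units_au$ir_kmmol * rowSums(dmudQ^2), 0)
}

#' RRHO / quasi-RRHO thermochemistry
#'
#' Ideal-gas rigid-rotor harmonic-oscillator partition functions:
#' Sackur-Tetrode translational entropy, classical rigid-rotor rotation
#' (linear/nonlinear), harmonic vibrations (ZPE = 1/2 sum h nu). The
#' quasi-RRHO options damp low-frequency vibrational entropy:
#' \code{"grimme"} interpolates each mode toward a free-rotor entropy with
#' the damping function \code{w = 1/(1 + (nu0/nu)^4)}; \code{"truhlar"}
#' raises frequencies below the cutoff to the cutoff (entropy only). A
#' cutoff of 0 recovers pure RRHO. Imaginary modes are excluded with a
#' warning. All energies in Hartree; \code{G = H - T S} holds by
#' construction and is verified in the returned record.
#'
#' @param analysis a \code{\link{harmonic_analysis}} result (or NULL for a
#'   single atom).
#' @param frag the fragment (masses, multiplicity).
#' @param T temperature, K.
#' @param P pressure, Pa.
#' @param sigma rotational symmetry number.
#' @param quasi_rrho "none", "grimme" or "truhlar".
#' @param cutoff quasi-RRHO frequency parameter nu0, cm^-1 (default 100).
#' @return list of class \code{thermo_record} with components (Hartree or
#'   Hartree/K): \code{zpe, U_vib, S_trans, S_rot, S_vib, S_elec, S_total,
#'   U, H, G, T, P}.
#' @export
thermochemistry <- function(analysis, frag, T = 298.15, P = 101325,
                            sigma = 1,
                            quasi_rrho = c("none", "grimme", "truhlar"),
                            cutoff = 100) {
  quasi_rrho <- match.arg(quasi_rrho)
  if (T <= 0) stop("temperature must be > 0")
  kB <- units_au$kB_hartree
  u <- units_au
  n <- n_atoms(frag)

  freqs <- if (is.null(analysis)) numeric(0) else analysis$frequencies
  if (any(freqs < 0)) {
    warning(sprintf("%d imaginary mode(s) excluded from thermochemistry",
                    sum(freqs < 0)))
    freqs <- freqs[freqs >= 0]
  }
  freqs <- freqs[freqs > 1e-3]          # drop numerically-zero modes

  # translation (Sackur-Tetrode), SI then converted
  m_kg <- sum(frag$masses) * u$amu_to_kg
  q_t <- (2 * pi * m_kg * u$kB_SI * T / u$h_SI^2)^1.5 * (u$kB_SI * T / P)
  S_trans <- u$kB_SI * (log(q_t) + 2.5) / u$hartree_to_J       # Hartree/K
  U_trans <- 1.5 * kB * T

  # rotation
  S_rot <- 0; U_rot <- 0
  linear <- FALSE
  if (n > 1) {
    mom <- .inertia_moments(frag$coords, frag$masses) * u$amu_to_kg * 1e-20  # kg m^2
    linear <- mom[1] / (u$amu_to_kg * 1e-20) < 1e-8
    if (linear) {
      I1 <- mom[3]
      q_r <- 8 * pi^2 * I1 * u$kB_SI * T / (sigma * u$h_SI^2)
      S_rot <- u$kB_SI * (log(q_r) + 1) / u$hartree_to_J
      U_rot <- kB * T
    } else {
      q_r <- sqrt(pi) / sigma *
        (8 * pi^2 * u$kB_SI * T / u$h_SI^2)^1.5 * sqrt(prod(mom))
      S_rot <- u$kB_SI * (log(q_r) + 1.5) / u$hartree_to_J
      U_rot <- 1.5 * kB * T
    }
  }

  # vibrations
  nu_h <- freqs / u$hartree_to_cm1      # Hartree per quantum
  x <- nu_h / (kB * T)
  zpe <- 0.5 * sum(nu_h)
  U_vib <- sum(nu_h / (exp(x) - 1))
  s_ho <- function(xv) kB * (xv / (exp(xv) - 1) - log1p(-exp(-xv)))
  S_modes <- if (length(x)) s_ho(x) else numeric(0)
  if (quasi_rrho == "grimme" && length(freqs) && cutoff > 0) {
    # damped free-rotor interpolation
    mu_m <- u$h_SI / (8 * pi^2 * u$c_SI * freqs)          # kg m^2 (h/(8 pi^2 c nu~))
    Bav <- 1e-44
    mu_eff <- mu_m * Bav / (mu_m + Bav)
    s_fr <- u$kB_SI * (0.5 + log(sqrt(8 * pi^3 * mu_eff * u$kB_SI * T) / u$h_SI)) /
      u$hartree_to_J
    w <- 1 / (1 + (cutoff / freqs)^4)
    S_modes <- w * S_modes + (1 - w) * s_fr
  } else if (quasi_rrho == "truhlar" && length(freqs) && cutoff > 0) {
    nu_eff <- pmax(freqs, cutoff) / u$hartree_to_cm1
    S_modes <- s_ho(nu_eff / (kB * T))
  }
  S_vib <- sum(S_modes)

  S_elec <- kB * log(frag$mult)
  S_total <- S_trans + S_rot + S_vib + S_elec
  U <- zpe + U_vib + U_trans + U_rot
  H <- U + kB * T
  G <- H - T * S_total
  structure(list(zpe = zpe, U_vib = U_vib, S_trans = S_trans, S_rot = S_rot,
                 S_vib = S_vib, S_elec = S_elec, S_total = S_total,
                 U = U, H = H, G = G, T = T, P = P, sigma = sigma,
                 linear = linear, quasi_rrho = quasi_rrho, cutoff = cutoff),
            class = "thermo_record")
}

#' @export
print.thermo_record <- function(x, ...) {
  cat(sprintf("<thermo @ %.2f K, %.0f Pa: ZPE %.6f, H %.6f, S %.9f Ha/K, G %.6f Ha>\n",
              x$T, x$P, x$zpe, x$H, x$S_total, x$G))
  invisible(x)
}

#' Wigner ensemble sampling
#'
#' Draws geometries (and conjugate velocities) from the harmonic-oscillator
#' Wigner distribution at temperature T: each mass-weighted normal
#' coordinate is Gaussian with variance \code{(1/(2 omega)) coth(omega /
#' (2 kB T))} in atomic units (\code{coth -> 1} as T -> 0).
#'
#' @param analysis a \code{\link{harmonic_analysis}} result with all-real
#'   frequencies.
#' @param frag the reference fragment.
#' @param n number of samples.
#' @param T temperature, K (0 allowed: zero-point distribution).
#' @param seed integer seed (mandatory; reproducibility).
#' @param velocities also sample momenta and return velocities (Angstrom/fs).
#' @return list of \code{fragment}s; when \code{velocities = TRUE}, each
#'   carries a \code{velocity} attribute.
#' @export
wigner_sample <- function(analysis, frag, n, T = 300, seed, velocities = FALSE) {
  if (missing(seed)) stop("seed is mandatory for wigner_sample")
  keep <- analysis$frequencies > 1e-3
  if (any(analysis$frequencies < -1e-3)) stop("imaginary modes present; not a minimum")
  freqs <- analysis$frequencies[keep]
  modes <- analysis$modes_mw[, keep, drop = FALSE]
  omega <- freqs / units_au$hartree_to_cm1             # a.u. (hbar = 1)
  kB <- units_au$kB_hartree
  coth <- if (T > 0) 1 / tanh(omega / (2 * kB * T)) else rep(1, length(omega))
  sd_q <- sqrt(coth / (2 * omega))
  sd_p <- sqrt(omega * coth / 2)
  m_me <- rep(analysis$masses * units_au$amu_to_me, each = 3)

  set.seed(seed)
  nm <- length(omega)
  Q <- matrix(stats::rnorm(n * nm), n, nm) %*% diag(sd_q, nm)
  P <- if (velocities) matrix(stats::rnorm(n * nm), n, nm) %*% diag(sd_p, nm) else NULL
  out <- vector("list", n)
  for (s in seq_len(n)) {
    dx_mw <- drop(modes %*% Q[s, ])
    dx <- bohr_to_ang(dx_mw / sqrt(m_me))
    f <- frag
    f$coords <- frag$coords + matrix(dx, ncol = 3, byrow = TRUE)
    if (velocities) {
      p_mw <- drop(modes %*% P[s, ])
      v_au <- p_mw / sqrt(m_me)   # q = sqrt(m) x, p = dq/dt => dx/dt = p/sqrt(m)
      v <- matrix(v_au, ncol = 3, byrow = TRUE) *
        units_au$bohr_to_ang / units_au$au_time_fs
      attr(f, "velocity") <- v
    }
    out[[s]] <- f
  }
  out
}
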