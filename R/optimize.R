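# Theory-agnostic Cartesian geometry optimization: L-BFGS minimization with
# backtracking line search, frozen-atom active regions, projection-enforced
# constraints (distance / angle / dihedral), relaxed and unrelaxed surface
# scans, P-RFO saddle refinement (Bofill Hessian update, adaptive trust
# radius) and Harvey-style minimum-energy crossing point search.
#
# Internal coordinates are intentionally not implemented: the package uses
# Cartesian L-BFGS with projection-based constraints throughout.

#' Optimization settings
#'
#' Default convergence thresholds follow the common quasi-Newton
#' convention: gradient max 4.5e-4 / rms 3.0e-4 Hartree/Bohr, step max
#' 1.8e-3 / rms 1.2e-3 Angstrom, energy change 1e-6 Hartree. Convergence
#' requires all five criteria simultaneously.
#'
#' @param max_iter iteration cap.
#' @param conv_grad_max,conv_grad_rms gradient thresholds, Hartree/Bohr.
#' @param conv_step_max,conv_step_rms step thresholds, Angstrom.
#' @param conv_e_change energy-change threshold, Hartree.
#' @param history_size L-BFGS memory.
#' @param max_step largest allowed step norm per iteration, Angstrom.
#' @return list of class \code{opt_settings}.
#' @export
opt_settings <- function(max_iter = 300,
                         conv_grad_max = 4.5e-4, conv_grad_rms = 3.0e-4,
                         conv_step_max = 1.8e-3, conv_step_rms = 1.2e-3,
                         conv_e_change = 1e-6,
                         history_size = 12, max_step = 0.3) {
  stopifnot(conv_grad_max > 0, conv_grad_rms > 0, conv_step_max > 0,
            conv_step_rms > 0, conv_e_change > 0, max_step > 0)
  structure(list(max_iter = max_iter, conv_grad_max = conv_grad_max,
                 conv_grad_rms = conv_grad_rms, conv_step_max = conv_step_max,
                 conv_step_rms = conv_step_rms, conv_e_change = conv_e_change,
                 history_size = history_size, max_step = max_step),
            class = "opt_settings")
}

#' Define a geometric constraint
#'
#' @param type "distance" (Angstrom), "angle" or "dihedral" (radians).
#' @param atoms the 2, 3 or 4 atom indices (1-based).
#' @param value target value.
#' @return constraint definition list.
#' @export
geom_constraint <- function(type = c("distance", "angle", "dihedral"),
                            atoms, value) {
  type <- match.arg(type)
  need <- c(distance = 2, angle = 3, dihedral = 4)[[type]]
  if (length(atoms) != need) stop(type, " constraint needs ", need, " atoms")
  list(type = type, atoms = as.integer(atoms), value = as.numeric(value))
}

# Value and d(value)/d(coords of involved atoms) for a geometric coordinate.
.coord_value_grad <- function(coords, type, atoms) {
  if (type == "distance") {
    i <- atoms[1]; j <- atoms[2]
    dv <- coords[j, ] - coords[i, ]; r <- sqrt(sum(dv^2)); u <- dv / r
    list(value = r, grad = rbind(-u, u))
  } else if (type == "angle") {
    i <- atoms[1]; j <- atoms[2]; k <- atoms[3]
    u <- coords[i, ] - coords[j, ]; v <- coords[k, ] - coords[j, ]
    lu <- sqrt(sum(u^2)); lv <- sqrt(sum(v^2))
    cth <- pmin(1 - 1e-12, pmax(-1 + 1e-12, sum(u * v) / (lu * lv)))
    sth <- sqrt(1 - cth^2)
    di <- (cth * u / lu - v / lv) / (lu * sth)
    dk <- (cth * v / lv - u / lu) / (lv * sth)
    list(value = acos(cth), grad = rbind(di, -(di + dk), dk))
  } else {
    i <- atoms[1]; j <- atoms[2]; k <- atoms[3]; l <- atoms[4]
    b1 <- coords[j, ] - coords[i, ]; b2 <- coords[k, ] - coords[j, ]
    b3 <- coords[l, ] - coords[k, ]
    m <- .cross3(b1, b2); nn <- .cross3(b2, b3)
    lb2 <- sqrt(sum(b2^2))
    phi <- atan2(sum(.cross3(nn, m) * b2) / lb2, sum(m * nn))
    d1 <- lb2 / sum(m^2) * m
    d4 <- -lb2 / sum(nn^2) * nn
    s <- sum(b1 * b2) / lb2^2; t <- sum(b3 * b2) / lb2^2
    d2 <- -(1 + s) * d1 + t * d4
    d3 <- s * d1 - (1 + t) * d4
    list(value = phi, grad = rbind(d1, d2, d3, d4))
  }
}

# Constraint Jacobian (n_con x 3n_active) and residuals on the active
# coordinate vector. Active atoms must contain all constrained atoms.
.constraint_system <- function(coords, constraints, active) {
  ncon <- length(constraints)
  J <- matrix(0.0, ncon, 3 * length(active))
  res <- numeric(ncon)
  pos_of <- match(seq_len(nrow(coords)), active)
  for (c in seq_len(ncon)) {
    cn <- constraints[[c]]
    vg <- .coord_value_grad(coords, cn$type, cn$atoms)
    diff <- vg$value - cn$value
    if (cn$type == "dihedral") diff <- atan2(sin(diff), cos(diff))
    res[c] <- diff
    for (a in seq_along(cn$atoms)) {
      p <- pos_of[cn$atoms[a]]
      if (is.na(p)) stop("constrained atom ", cn$atoms[a], " is not in the active region")
      J[c, (3 * p - 2):(3 * p)] <- vg$grad[a, ]
    }
  }
  list(J = J, res = res)
}

# Project a vector onto the tangent space of the constraints.
.project_constraints <- function(v, J) {
  if (is.null(J) || nrow(J) == 0) return(v)
  JJt <- J %*% t(J)
  v - drop(t(J) %*% solve(JJt, J %*% v))
}

# Newton restoration of constraint values (SHAKE-like), tolerance 1e-8.
.restore_constraints <- function(coords, constraints, active, tol = 1e-8, max_it = 50) {
  if (length(constraints) == 0) return(coords)
  for (it in seq_len(max_it)) {
    cs <- .constraint_system(coords, constraints, active)
    if (max(abs(cs$res)) < tol) break
    dx <- -drop(t(cs$J) %*% solve(cs$J %*% t(cs$J), cs$res))
    coords[active, ] <- coords[active, ] +
      matrix(dx, ncol = 3, byrow = TRUE)
  }
  coords
}

# Two-loop L-BFGS direction from memory lists of s and y vectors.
.lbfgs_direction <- function(g, S, Y) {
  q <- g
  k <- length(S)
  if (k == 0) return(-g)
  alpha <- numeric(k)
  rho <- vapply(seq_len(k), function(i) 1 / sum(Y[[i]] * S[[i]]), 0)
  for (i in k:1) {
    alpha[i] <- rho[i] * sum(S[[i]] * q)
    q <- q - alpha[i] * Y[[i]]
  }
  gamma <- sum(S[[k]] * Y[[k]]) / sum(Y[[k]] * Y[[k]])
  z <- gamma * q
  for (i in 1:k) {
    beta <- rho[i] * sum(Y[[i]] * z)
    z <- z + S[[i]] * (alpha[i] - beta)
  }
  -z
}

.grad_measures <- function(g_bohr_rows) {
  gnorm <- sqrt(rowSums(g_bohr_rows^2))
  list(max = max(abs(g_bohr_rows)), rms = sqrt(mean(g_bohr_rows^2)),
       atom_max = if (length(gnorm)) max(gnorm) else 0)
}

#' L-BFGS geometry minimization
#'
#' Cartesian quasi-Newton minimization with an Armijo backtracking line
#' search (energies are monotone non-increasing over accepted steps).
#' Non-active atoms are exactly frozen (coordinates bit-identical on
#' output); constraints are enforced by projecting gradient and step onto
#' the constraint tangent space plus Newton restoration of the constraint
#' values after each step.
#'
#' @param theory any theory yielding gradients (wrap energy-only theories
#'   in \code{\link{numgrad_theory}}).
#' @param frag starting \code{fragment}.
#' @param settings an \code{\link{opt_settings}}.
#' @param active_atoms optional index set of atoms allowed to move.
#' @param constraints list of \code{\link{geom_constraint}}.
#' @return an \code{opt_result}: \code{fragment} (final), \code{energies},
#'   \code{grad_max} traces, \code{converged}, \code{iterations},
#'   \code{final} (last evaluation result).
#' @export
lbfgs_minimize <- function(theory, frag, settings = opt_settings(),
                           active_atoms = NULL, constraints = list()) {
  n <- n_atoms(frag)
  active <- if (is.null(active_atoms)) seq_len(n) else sort(unique(as.integer(active_atoms)))
  coords <- frag$coords
  coords <- .restore_constraints(coords, constraints, active)
  frag_at <- function(cc) { f <- frag; f$coords <- cc; f }
  ev <- function(cc) evaluate(theory, frag_at(cc), gradient = TRUE)

  res <- ev(coords)
  e <- res$energy
  e_trace <- e
  g_trace <- numeric(0)
  S <- list(); Y <- list()
  conv <- FALSE
  it <- 0
  g_prev <- NULL; x_prev <- NULL

  repeat {
    g_bohr <- res$gradient[active, , drop = FALSE]
    cs <- if (length(constraints)) .constraint_system(coords, constraints, active) else NULL
    gvec_bohr <- as.numeric(t(g_bohr))
    if (!is.null(cs)) gvec_bohr <- .project_constraints(gvec_bohr, cs$J)
    gm <- .grad_measures(matrix(gvec_bohr, ncol = 3, byrow = TRUE))
    g_trace <- c(g_trace, gm$max)
    if (gm$max < settings$conv_grad_max && gm$rms < settings$conv_grad_rms && it == 0) {
      conv <- TRUE   # started at a (constrained) stationary point
      break
    }
    if (it >= settings$max_iter) break

    g_ang <- gvec_bohr / units_au$bohr_to_ang   # Hartree/Angstrom
    x <- as.numeric(t(coords[active, , drop = FALSE]))
    if (!is.null(g_prev)) {
      s <- x - x_prev; y <- g_ang - g_prev
      if (sum(s * y) > 1e-14) {
        S <- c(S, list(s)); Y <- c(Y, list(y))
        if (length(S) > settings$history_size) { S <- S[-1]; Y <- Y[-1] }
      }
    }
    dir <- .lbfgs_direction(g_ang, S, Y)
    if (!is.null(cs)) dir <- .project_constraints(dir, cs$J)
    if (sum(dir * g_ang) >= 0) dir <- -g_ang      # enforce descent
    dn <- sqrt(sum(dir^2))
    if (dn > settings$max_step) dir <- dir * settings$max_step / dn

    # Armijo backtracking
    step <- 1.0
    accepted <- FALSE
    slope <- sum(dir * g_ang)
    for (ls in 1:25) {
      x_new <- x + step * dir
      cc <- coords
      cc[active, ] <- matrix(x_new, ncol = 3, byrow = TRUE)
      cc <- .restore_constraints(cc, constraints, active)
      res_new <- tryCatch(ev(cc), error = function(e) NULL)
      if (!is.null(res_new) && res_new$energy <= e + 1e-4 * step * slope) {
        accepted <- TRUE
        break
      }
      step <- step / 2
    }
    if (!accepted) {
      if (length(S) > 0) { S <- list(); Y <- list(); next }   # reset memory, retry
      break
    }
    x_prev <- x; g_prev <- g_ang
    dstep <- as.numeric(t(cc[active, , drop = FALSE])) - x
    step_rows <- matrix(dstep, ncol = 3, byrow = TRUE)
    step_max <- max(abs(step_rows)); step_rms <- sqrt(mean(step_rows^2))
    de <- res_new$energy - e
    coords <- cc; res <- res_new; e <- res$energy
    e_trace <- c(e_trace, e)
    it <- it + 1

    g_bohr2 <- res$gradient[active, , drop = FALSE]
    gv2 <- as.numeric(t(g_bohr2))
    if (!is.null(cs)) {
      cs2 <- .constraint_system(coords, constraints, active)
      gv2 <- .project_constraints(gv2, cs2$J)
    }
    gm2 <- .grad_measures(matrix(gv2, ncol = 3, byrow = TRUE))
    if (gm2$max < settings$conv_grad_max && gm2$rms < settings$conv_grad_rms &&
        abs(de) < settings$conv_e_change &&
        step_max < settings$conv_step_max && step_rms < settings$conv_step_rms) {
      g_trace <- c(g_trace, gm2$max)
      conv <- TRUE
      break
    }
  }

  out_frag <- frag
  out_frag$coords <- coords
  structure(list(fragment = out_frag, energies = e_trace, grad_max = g_trace,
                 converged = conv, iterations = it, final = res),
            class = "opt_result")
}

#' @export
print.opt_result <- function(x, ...) {
  cat(sprintf("<opt_result: %s in %d iterations, E = %.10f Hartree>\n",
              if (x$converged) "converged" else "NOT converged",
              x$iterations, utils::tail(x$energies, 1)))
  invisible(x)
}

# Set a geometric coordinate by moving the last atom of the definition
# (all other degrees of freedom untouched) - used by unrelaxed scans.
.set_coordinate <- function(coords, def, value) {
  a <- def$atoms
  if (def$type == "distance") {
    u <- coords[a[2], ] - coords[a[1], ]
    u <- u / sqrt(sum(u^2))
    coords[a[2], ] <- coords[a[1], ] + value * u
  } else if (def$type == "angle") {
    if (value < 0 || value > pi) stop("unreachable angle value")
    cur <- .angle(coords, a[1], a[2], a[3])
    axis <- .cross3(coords[a[1], ] - coords[a[2], ], coords[a[3], ] - coords[a[2], ])
    if (sqrt(sum(axis^2)) < 1e-10) axis <- c(0, 0, 1)
    coords[a[3], ] <- .rotate_point(coords[a[3], ], coords[a[2], ], axis, value - cur)
  } else {
    cur <- .dihedral(coords, a[1], a[2], a[3], a[4])
    axis <- coords[a[3], ] - coords[a[2], ]
    coords[a[4], ] <- .rotate_point(coords[a[4], ], coords[a[3], ], axis, value - cur)
  }
  coords
}

.rotate_point <- function(p, origin, axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  v <- p - origin
  ct <- cos(angle); st <- sin(angle)
  origin + v * ct + .cross3(u, v) * st + u * sum(u * v) * (1 - ct)
}

#' Relaxed / unrelaxed surface scan (1D or 2D)
#'
#' For each grid point: unrelaxed scans set the coordinate(s) by moving the
#' last atom of each definition (all other degrees of freedom untouched);
#' relaxed scans run a constrained minimization at the fixed coordinate
#' value(s), each point warm-started from the previous point's geometry.
#' For 2D scans the first coordinate is the slow (outer) loop; rows are
#' ordered coord1-major.
#'
#' @param theory the theory.
#' @param frag starting \code{fragment}.
#' @param coords list of 1 or 2 coordinate definitions
#'   (\code{list(type =, atoms =)}).
#' @param grid list of 1 or 2 numeric value vectors.
#' @param relaxed logical.
#' @param settings \code{\link{opt_settings}} for relaxed points.
#' @param active_atoms optional active region for relaxed points.
#' @return data frame: \code{coord1[, coord2]}, \code{energy},
#'   \code{converged}; the final geometries in attribute
#'   \code{"fragments"}.
#' @export
scan_surface <- function(theory, frag, coords, grid, relaxed = TRUE,
                         settings = opt_settings(), active_atoms = NULL) {
  if (!is.list(coords[[1]])) coords <- list(coords)
  if (!is.list(grid)) grid <- list(grid)
  stopifnot(length(coords) %in% c(1, 2), length(grid) == length(coords))
  pts <- if (length(grid) == 1) {
    data.frame(coord1 = grid[[1]])
  } else {
    expand.grid(coord2 = grid[[2]], coord1 = grid[[1]])[, c("coord1", "coord2")]
  }
  energies <- numeric(nrow(pts))
  convs <- logical(nrow(pts))
  frags <- vector("list", nrow(pts))
  cur <- frag
  for (r in seq_len(nrow(pts))) {
    vals <- as.numeric(pts[r, ])
    cc <- if (relaxed) cur$coords else frag$coords
    for (ci in seq_along(coords)) cc <- .set_coordinate(cc, coords[[ci]], vals[ci])
    f <- frag; f$coords <- cc
    if (relaxed) {
      cons <- lapply(seq_along(coords), function(ci) {
        geom_constraint(coords[[ci]]$type, coords[[ci]]$atoms, vals[ci])
      })
      opt <- lbfgs_minimize(theory, f, settings, active_atoms = active_atoms,
                            constraints = cons)
      energies[r] <- utils::tail(opt$energies, 1)
      convs[r] <- opt$converged
      frags[[r]] <- opt$fragment
      cur <- opt$fragment
    } else {
      energies[r] <- evaluate(theory, f, gradient = FALSE)$energy
      convs[r] <- TRUE
      frags[[r]] <- f
    }
  }
  out <- cbind(pts, energy = energies, converged = convs)
  attr(out, "fragments") <- frags
  out
}

# Bofill-mixed Hessian update (SR1 / PSB interpolation).
.bofill_update <- function(H, s, y) {
  r <- y - drop(H %*% s)
  rs <- sum(r * s)
  s2 <- sum(s * s); r2 <- sum(r * r)
  if (s2 < 1e-20 || r2 < 1e-20) return(H)
  phi <- rs^2 / (r2 * s2)
  dH_sr1 <- if (abs(rs) > 1e-12) tcrossprod(r) / rs else matrix(0, length(s), length(s))
  dH_psb <- (tcrossprod(r, s) + tcrossprod(s, r)) / s2 - rs * tcrossprod(s) / s2^2
  H + phi * dH_sr1 + (1 - phi) * dH_psb
}

#' P-RFO transition-state optimization
#'
#' Partitioned rational-function optimization: the step maximizes the
#' energy along one Hessian eigenmode (the lowest, or the mode of maximal
#' overlap with the previously followed mode) and minimizes along all
#' others. The Hessian is carried with Bofill updates; the trust radius
#' starts at 0.1 Angstrom and adapts within [0.01, 0.3] by the ratio of
#' actual to predicted energy change. On convergence the structure is
#' optionally verified to have exactly one negative Hessian eigenvalue by
#' a fresh numerical Hessian.
#'
#' @param theory the theory.
#' @param frag starting \code{fragment}.
#' @param hessian initial Hessian, 3N x 3N Hartree/Bohr^2 (e.g. from
#'   \code{\link{numerical_hessian}}).
#' @param settings \code{\link{opt_settings}}.
#' @param verify_hessian recompute a numerical Hessian at the end and count
#'   negative eigenvalues (default TRUE).
#' @return an \code{opt_result}; fields \code{neg_eigenvalues} (when
#'   verified) and \code{saddle_ok}.
#' @export
prfo_ts_opt <- function(theory, frag, hessian, settings = opt_settings(),
                        verify_hessian = TRUE) {
  n <- n_atoms(frag)
  b2a <- units_au$bohr_to_ang
  H <- (hessian + t(hessian)) / 2 / b2a^2       # -> Hartree/Angstrom^2
  frag_at <- function(cc) { f <- frag; f$coords <- cc; f }
  coords <- frag$coords
  res <- evaluate(theory, frag_at(coords), gradient = TRUE)
  e <- res$energy
  e_trace <- e; g_trace <- numeric(0)
  trust <- 0.1
  conv <- FALSE
  it <- 0
  mode_prev <- NULL

  repeat {
    g_bohr <- res$gradient
    gm <- .grad_measures(g_bohr)
    g_trace <- c(g_trace, gm$max)
    if (gm$max < settings$conv_grad_max && gm$rms < settings$conv_grad_rms && it == 0) {
      conv <- TRUE; break
    }
    if (it >= settings$max_iter) break
    g <- as.numeric(t(g_bohr)) / b2a           # Hartree/Angstrom

    eg <- eigen(H, symmetric = TRUE)
    vals <- rev(eg$values)                      # ascending
    vecs <- eg$vectors[, rev(seq_along(eg$values)), drop = FALSE]
    k <- if (is.null(mode_prev)) 1 else which.max(abs(drop(t(vecs) %*% mode_prev)))
    mode_prev <- vecs[, k]
    gbar <- drop(t(vecs) %*% g)

    # uphill along mode k
    hk <- vals[k]; gk <- gbar[k]
    lam_p <- 0.5 * hk + 0.5 * sqrt(hk^2 + 4 * gk^2)
    step_k <- if (abs(lam_p - hk) > 1e-14) gk / (lam_p - hk) else 0
    # downhill along the rest (augmented-Hessian lowest eigenvalue)
    rest <- setdiff(seq_along(vals), k)
    steps <- numeric(length(vals))
    steps[k] <- step_k
    if (length(rest) > 0) {
      Ab <- rbind(cbind(diag(vals[rest], length(rest)), gbar[rest]),
                  c(gbar[rest], 0))
      lam_n <- min(eigen(Ab, symmetric = TRUE, only.values = TRUE)$values)
      lam_n <- min(lam_n, 0)
      denom <- lam_n - vals[rest]
      denom[abs(denom) < 1e-12] <- -1e-12
      steps[rest] <- gbar[rest] / denom
    }
    s <- drop(vecs %*% steps)
    sn <- sqrt(sum(s^2))
    if (sn > trust) s <- s * trust / sn
    e_pred <- sum(g * s) + 0.5 * sum(s * drop(H %*% s))

    cc <- coords + matrix(s, ncol = 3, byrow = TRUE)
    res_new <- evaluate(theory, frag_at(cc), gradient = TRUE)
    de <- res_new$energy - e
    ratio <- if (abs(e_pred) > 1e-16) de / e_pred else 1
    if (ratio < 0.25 || ratio > 4) {
      trust <- max(trust / 2, 0.01)
    } else if (ratio > 0.75 && ratio < 1.25 && sqrt(sum(s^2)) > 0.9 * trust) {
      trust <- min(trust * 1.5, 0.3)
    }
    g_new <- as.numeric(t(res_new$gradient)) / b2a
    H <- .bofill_update(H, s, g_new - g)
    coords <- cc; res <- res_new; e <- res$energy
    e_trace <- c(e_trace, e)
    it <- it + 1

    gm2 <- .grad_measures(res$gradient)
    step_rows <- matrix(s, ncol = 3, byrow = TRUE)
    if (gm2$max < settings$conv_grad_max && gm2$rms < settings$conv_grad_rms &&
        abs(de) < settings$conv_e_change &&
        max(abs(step_rows)) < settings$conv_step_max &&
        sqrt(mean(step_rows^2)) < settings$conv_step_rms) {
      g_trace <- c(g_trace, gm2$max)
      conv <- TRUE
      break
    }
  }

  out_frag <- frag
  out_frag$coords <- coords
  neg <- NA_integer_
  saddle_ok <- NA
  if (conv && verify_hessian) {
    Hnum <- numerical_hessian(theory, out_frag)
    if (n == 1) {
      ev <- eigen((Hnum + t(Hnum)) / 2, symmetric = TRUE, only.values = TRUE)$values
      # single pseudo-atom (2D surface): ignore the flat z direction
      ev <- ev[abs(ev) > 1e-10]
      neg <- sum(ev < 0)
    } else {
      va <- harmonic_analysis(Hnum, out_frag, project = TRUE)
      neg <- sum(va$frequencies < -5)
    }
    saddle_ok <- neg == 1L
  }
  structure(list(fragment = out_frag, energies = e_trace, grad_max = g_trace,
                 converged = conv, iterations = it, final = res,
                 neg_eigenvalues = neg, saddle_ok = saddle_ok),
            class = "opt_result")
}

#' Minimum-energy crossing point search (Harvey-type)
#'
#' Minimizes on the seam between two energy surfaces using the effective
#' gradient \code{2 (E_A - E_B) (g_A - g_B)} (the exact gradient of the
#' squared gap) plus the component of the mean gradient orthogonal to the
#' gap-gradient direction. Converged when the energy gap is below
#' \code{gap_tol} and the seam-projected mean gradient satisfies the
#' gradient thresholds.
#'
#' @param theoryA,theoryB the two surfaces (same fragment dimension).
#' @param frag starting \code{fragment}.
#' @param settings \code{\link{opt_settings}}.
#' @param gap_tol convergence threshold on |E_A - E_B|, Hartree.
#' @return an \code{opt_result} with per-surface energies in
#'   \code{$energies_AB} and gap trace in \code{$gap}.
#' @export
mecp_optimize <- function(theoryA, theoryB, frag, settings = opt_settings(),
                          gap_tol = 1e-6) {
  coords <- frag$coords
  frag_at <- function(cc) { f <- frag; f$coords <- cc; f }
  b2a <- units_au$bohr_to_ang
  S <- list(); Y <- list()
  g_prev <- NULL; x_prev <- NULL
  conv <- FALSE; it <- 0
  e_trace <- numeric(0); gap_trace <- numeric(0)
  eA <- NA; eB <- NA

  repeat {
    rA <- evaluate(theoryA, frag_at(coords), gradient = TRUE)
    rB <- evaluate(theoryB, frag_at(coords), gradient = TRUE)
    eA <- rA$energy; eB <- rB$energy
    gap <- eA - eB
    gA <- as.numeric(t(rA$gradient)) / b2a
    gB <- as.numeric(t(rB$gradient)) / b2a
    dg <- gA - gB
    ndg <- sqrt(sum(dg^2))
    gmean <- (gA + gB) / 2
    if (ndg > 1e-10) {
      x1 <- dg / ndg
      gperp <- gmean - sum(gmean * x1) * x1
      geff <- 2 * gap * dg + gperp
    } else {
      gperp <- gmean           # degenerate surfaces: plain minimization
      geff <- gmean
    }
    gm <- .grad_measures(matrix(gperp * b2a, ncol = 3, byrow = TRUE))
    e_trace <- c(e_trace, (eA + eB) / 2)
    gap_trace <- c(gap_trace, gap)
    if ((ndg < 1e-10 || abs(gap) < gap_tol) &&
        gm$max < settings$conv_grad_max && gm$rms < settings$conv_grad_rms) {
      conv <- TRUE; break
    }
    if (it >= settings$max_iter) break

    x <- as.numeric(t(coords))
    if (!is.null(g_prev)) {
      s <- x - x_prev; y <- geff - g_prev
      if (sum(s * y) > 1e-14) {
        S <- c(S, list(s)); Y <- c(Y, list(y))
        if (length(S) > settings$history_size) { S <- S[-1]; Y <- Y[-1] }
      }
    }
    dir <- .lbfgs_direction(geff, S, Y)
    if (sum(dir * geff) >= 0) dir <- -geff
    dn <- sqrt(sum(dir^2))
    cap <- min(settings$max_step, 0.1)
    if (dn > cap) dir <- dir * cap / dn
    x_prev <- x; g_prev <- geff
    coords <- coords + matrix(dir, ncol = 3, byrow = TRUE)
    it <- it + 1
  }

  out_frag <- frag
  out_frag$coords <- coords
  structure(list(fragment = out_frag, energies = e_trace, gap = gap_trace,
                 energies_AB = c(eA, eB), grad_max = NA,
                 converged = conv, iterations = it,
                 final = NULL),
            class = "opt_result")
}
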