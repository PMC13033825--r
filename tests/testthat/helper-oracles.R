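# Independent oracles used across the suite: central-difference gradients
# computed from energies only, a dense-grid + Newton stationary-point
# finder for the 2D surfaces, and small polynomial theories with closed
# forms. These never call the analytic-gradient / optimizer code paths
# they are used to check.

# Finite-difference gradient from energy evaluations only (Hartree/Bohr).
fd_gradient <- function(theory, frag, h = 1e-5, pointcharges = NULL) {
  n <- n_atoms(frag)
  g <- matrix(0.0, n, 3)
  for (i in seq_len(n)) {
    for (k in 1:3) {
      cp <- frag$coords; cp[i, k] <- cp[i, k] + h
      cm <- frag$coords; cm[i, k] <- cm[i, k] - h
      fp <- frag; fp$coords <- cp
      fm <- frag; fm$coords <- cm
      g[i, k] <- (evaluate(theory, fp, pointcharges, gradient = FALSE)$energy -
                    evaluate(theory, fm, pointcharges, gradient = FALSE)$energy) / (2 * h)
    }
  }
  g * units_au$bohr_to_ang
}

# 2D surface helpers working purely from energies.
surf_e <- function(theory, x, y) {
  evaluate(theory, surface_point(x, y), gradient = FALSE)$energy
}
surf_g <- function(theory, p, h = 1e-6) {
  c((surf_e(theory, p[1] + h, p[2]) - surf_e(theory, p[1] - h, p[2])) / (2 * h),
    (surf_e(theory, p[1], p[2] + h) - surf_e(theory, p[1], p[2] - h)) / (2 * h))
}
surf_h <- function(theory, p, h = 1e-4) {
  H <- matrix(0, 2, 2)
  for (a in 1:2) for (b in 1:2) {
    pp <- p; pp[a] <- pp[a] + h; pp[b] <- pp[b] + h; epp <- surf_e(theory, pp[1], pp[2])
    pm <- p; pm[a] <- pm[a] + h; pm[b] <- pm[b] - h; epm <- surf_e(theory, pm[1], pm[2])
    mp <- p; mp[a] <- mp[a] - h; mp[b] <- mp[b] + h; emp <- surf_e(theory, mp[1], mp[2])
    mm <- p; mm[a] <- mm[a] - h; mm[b] <- mm[b] - h; emm <- surf_e(theory, mm[1], mm[2])
    H[a, b] <- (epp - epm - emp + emm) / (4 * h^2)
  }
  (H + t(H)) / 2
}

# Newton refinement of a stationary point from a starting guess.
surf_newton <- function(theory, p, max_it = 80) {
  for (i in seq_len(max_it)) {
    g <- surf_g(theory, p)
    if (max(abs(g)) < 5e-9) break
    step <- solve(surf_h(theory, p), g)
    sn <- sqrt(sum(step^2))
    if (sn > 0.2) step <- step * 0.2 / sn
    p <- p - step
  }
  ev <- eigen(surf_h(theory, p), symmetric = TRUE, only.values = TRUE)$values
  list(xy = p, energy = surf_e(theory, p[1], p[2]),
       neg = sum(ev < 0), grad_norm = sqrt(sum(surf_g(theory, p)^2)))
}

# Dense grid + Newton: all stationary points of a 2D surface in a window.
# Candidates are grid points whose gradient norm is a local minimum over
# the 8-neighbourhood; each is refined by Newton and classified by the
# Hessian eigenvalue signs.
surf_stationary_points <- function(theory, xlim, ylim, n = 60) {
  xs <- seq(xlim[1], xlim[2], length.out = n)
  ys <- seq(ylim[1], ylim[2], length.out = n)
  gn <- matrix(0.0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    gn[i, j] <- sqrt(sum(surf_g(theory, c(xs[i], ys[j]))^2))
  }
  found <- list()
  for (i in 2:(n - 1)) for (j in 2:(n - 1)) {
    nb <- gn[(i - 1):(i + 1), (j - 1):(j + 1)]
    if (gn[i, j] <= min(nb)) {
      st <- tryCatch(surf_newton(theory, c(xs[i], ys[j])), error = function(e) NULL)
      if (is.null(st) || st$grad_norm > 1e-6) next
      if (st$xy[1] < xlim[1] - 0.3 || st$xy[1] > xlim[2] + 0.3 ||
          st$xy[2] < ylim[1] - 0.3 || st$xy[2] > ylim[2] + 0.3) next
      dup <- any(vapply(found, function(f) sum((f$xy - st$xy)^2) < 1e-6, TRUE))
      if (!dup) found[[length(found) + 1]] <- st
    }
  }
  found
}

# Cached Muller-Brown stationary points (minima and the upper saddle).
mb_oracle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      th <- surface2d_theory("muller_brown")
      pts <- surf_stationary_points(th, c(-1.6, 1.2), c(-0.3, 2.0), n = 60)
      minima <- Filter(function(p) p$neg == 0, pts)
      saddles <- Filter(function(p) p$neg == 1, pts)
      minima <- minima[order(vapply(minima, `[[`, 0, "energy"))]
      saddles <- saddles[order(vapply(saddles, `[[`, 0, "energy"))]
      cache <<- list(minima = minima, saddles = saddles)
    }
    cache
  }
})

# --- tiny closed-form 1D theories (act on the x coordinate of atom 1) ---

# double well  E = a (x^2 - b^2)^2 : minima at +/-b, barrier top at x = 0
poly_dw_theory <- function(a = 0.05, b = 1.0) {
  structure(list(a = a, b = b, label = "double_well"),
            class = c("poly_dw_theory", "mschem_theory"))
}
evaluate.poly_dw_theory <- function(theory, frag, pointcharges = NULL,
                                    gradient = TRUE, ...) {
  x <- frag$coords[1, 1]
  e <- theory$a * (x^2 - theory$b^2)^2
  g <- matrix(c(4 * theory$a * x * (x^2 - theory$b^2), 0, 0), 1, 3) *
    units_au$bohr_to_ang
  theory_result(e, gradient = if (gradient) g else NULL, label = theory$label)
}

# shifted parabola  E = 0.5 k (x - x0)^2 + c
quad1d_theory <- function(k = 1, x0 = 0, c0 = 0) {
  structure(list(k = k, x0 = x0, c0 = c0, label = "quad1d"),
            class = c("quad1d_theory", "mschem_theory"))
}
evaluate.quad1d_theory <- function(theory, frag, pointcharges = NULL,
                                   gradient = TRUE, ...) {
  x <- frag$coords[1, 1]
  e <- 0.5 * theory$k * (x - theory$x0)^2 + theory$c0
  g <- matrix(c(theory$k * (x - theory$x0), 0, 0), 1, 3) * units_au$bohr_to_ang
  theory_result(e, gradient = if (gradient) g else NULL, label = theory$label)
}

registerS3method("evaluate", "poly_dw_theory", evaluate.poly_dw_theory,
                 envir = asNamespace("mschem"))
registerS3method("evaluate", "quad1d_theory", evaluate.quad1d_theory,
                 envir = asNamespace("mschem"))

rotate_z <- function(coords, ang) {
  R <- matrix(c(cos(ang), -sin(ang), 0, sin(ang), cos(ang), 0, 0, 0, 1),
              3, 3, byrow = TRUE)
  coords %*% t(R)
}

random_rotation <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(w^2 + x^2 - y^2 - z^2, 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), w^2 - x^2 + y^2 - z^2, 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), w^2 - x^2 - y^2 + z^2),
         3, 3, byrow = TRUE)
}

tight_opt <- function(max_iter = 500) {
  opt_settings(max_iter = max_iter, conv_grad_max = 1e-6, conv_grad_rms = 1e-6,
               conv_step_max = 1e-3, conv_step_rms = 1e-3, conv_e_change = 1e-10)
}

harmonic_diatomic <- function(k = 0.6, r0 = 1.1, r_start = r0,
                              elements = c("H", "Cl")) {
  list(theory = forcefield_theory(
         forcefield_spec(bonds = data.frame(i = 1, j = 2, k = k, r0 = r0),
                         charges = c(0, 0))),
       fragment = fragment(elements, rbind(c(0, 0, 0), c(r_start, 0, 0))),
       k = k, r0 = r0)
}
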