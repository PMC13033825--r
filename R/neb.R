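# Nudged elastic band with IDPP interpolation, improved (energy-ordered)
# tangents, energy-weighted springs, climbing image, quaternion rigid-body
# alignment, and the NEB-TS handoff (loose NEB -> numerical Hessian ->
# P-RFO refinement).
#
# Energy-weighted springs: with E_ref = max(E_reactant, E_product) and
# E_max the band maximum, the spring constant of segment j (images j,j+1,
# segment energy E_seg = max(E_j, E_j+1)) is
#     k_j = k_max - (k_max - k_min) (E_max - E_seg)/(E_max - E_ref)   if E_seg > E_ref
#     k_j = k_min                                                    otherwise.

#' Build a band of images
#'
#' @param images list of \code{fragment}s (fixed endpoints first/last).
#' @param energies optional per-image energies (Hartree).
#' @return object of class \code{neb_band}.
#' @export
neb_band <- function(images, energies = NULL) {
  if (length(images) < 3) stop("a band needs at least 3 images")
  n <- n_atoms(images[[1]])
  if (!all(vapply(images, n_atoms, 0L) == n)) stop("images differ in atom count")
  structure(list(images = images, energies = energies,
                 climbing_index = NA_integer_),
            class = "neb_band")
}

#' @export
print.neb_band <- function(x, ...) {
  cat(sprintf("<neb_band: %d images x %d atoms%s>\n", length(x$images),
              n_atoms(x$images[[1]]),
              if (!is.null(x$energies))
                sprintf(", barrier %.6f", max(x$energies) - x$energies[1]) else ""))
  invisible(x)
}

# Small internal L-BFGS on a plain objective fg(x) -> list(e, g); Armijo
# backtracking, monotone decrease. Used by the IDPP refinement.
.fmin_lbfgs <- function(x0, fg, max_iter = 200, gtol = 1e-6, max_step = 0.2,
                        memory = 10) {
  x <- x0
  r <- fg(x)
  S <- list(); Y <- list()
  g_prev <- NULL; x_prev <- NULL
  trace <- r$e
  for (it in seq_len(max_iter)) {
    if (max(abs(r$g)) < gtol) break
    if (!is.null(g_prev)) {
      s <- x - x_prev; y <- r$g - g_prev
      if (sum(s * y) > 1e-14) {
        S <- c(S, list(s)); Y <- c(Y, list(y))
        if (length(S) > memory) { S <- S[-1]; Y <- Y[-1] }
      }
    }
    dir <- .lbfgs_direction(r$g, S, Y)
    if (sum(dir * r$g) >= 0) dir <- -r$g
    dn <- sqrt(sum(dir^2))
    if (dn > max_step) dir <- dir * max_step / dn
    slope <- sum(dir * r$g)
    step <- 1.0; ok <- FALSE
    for (ls in 1:20) {
      r_new <- fg(x + step * dir)
      if (r_new$e <= r$e + 1e-4 * step * slope) { ok <- TRUE; break }
      step <- step / 2
    }
    if (!ok) {
      if (length(S)) { S <- list(); Y <- list(); next } else break
    }
    x_prev <- x; g_prev <- r$g
    x <- x + step * dir
    r <- r_new
    trace <- c(trace, r$e)
  }
  list(x = x, value = r$e, trace = trace)
}

#' IDPP interpolation between two endpoints
#'
#' Starts from linear interpolation and refines each interior image by
#' minimizing the image-dependent pair-potential objective
#' \code{sum_pairs w(d_t) (d_t - d)^2} with pairwise target distances
#' \code{d_t} linearly interpolated between the endpoint distances and
#' weights \code{w = d_t^-4}. Endpoints are untouched.
#'
#' @param reactant,product endpoint \code{fragment}s (same atoms/order).
#' @param n_images total number of images including the endpoints.
#' @param max_iter refinement iterations per image.
#' @return a \code{neb_band}; attribute \code{"idpp_traces"} holds the
#'   per-image objective traces (monotone non-increasing).
#' @export
idpp_interpolate <- function(reactant, product, n_images, max_iter = 200) {
  if (n_images < 3) stop("need at least 3 images")
  n <- n_atoms(reactant)
  if (n_atoms(product) != n ||
      !identical(reactant$elements, product$elements)) {
    stop("endpoints must have identical atoms and ordering")
  }
  dR <- as.matrix(stats::dist(reactant$coords))
  dP <- as.matrix(stats::dist(product$coords))
  pairs <- which(upper.tri(dR), arr.ind = TRUE)
  images <- vector("list", n_images)
  images[[1]] <- reactant
  images[[n_images]] <- product
  traces <- vector("list", n_images)
  for (im in 2:(n_images - 1)) {
    t_frac <- (im - 1) / (n_images - 1)
    x0 <- (1 - t_frac) * reactant$coords + t_frac * product$coords
    if (n < 2) {
      f <- reactant; f$coords <- x0
      images[[im]] <- f
      next
    }
    d_t <- (1 - t_frac) * dR[pairs] + t_frac * dP[pairs]
    w <- 1 / pmax(d_t, 1e-3)^4
    fg <- function(xv) {
      cc <- matrix(xv, ncol = 3, byrow = TRUE)
      dv <- cc[pairs[, 2], , drop = FALSE] - cc[pairs[, 1], , drop = FALSE]
      dd <- sqrt(rowSums(dv^2))
      diff <- d_t - dd
      e <- sum(w * diff^2)
      coef <- 2 * w * diff / pmax(dd, 1e-12)       # dS/dd * dd/dx factor
      fp <- dv * coef                               # contribution to atom j
      g <- matrix(0.0, n, 3)
      acc <- rowsum(rbind(fp, -fp), group = c(pairs[, 1], pairs[, 2]))
      rows <- as.integer(rownames(acc))
      g[rows, ] <- g[rows, ] + acc
      list(e = e, g = as.numeric(t(g)))
    }
    sol <- .fmin_lbfgs(as.numeric(t(x0)), fg, max_iter = max_iter,
                       gtol = 1e-6, max_step = 0.1)
    f <- reactant
    f$coords <- matrix(sol$x, ncol = 3, byrow = TRUE)
    images[[im]] <- f
    traces[[im]] <- sol$trace
  }
  band <- neb_band(images)
  attr(band, "idpp_traces") <- traces
  band
}

# Best-fit rotation (Horn quaternion method): rotate P onto Q, both centered.
.quaternion_rotation <- function(P, Q) {
  S <- t(P) %*% Q
  K <- matrix(0, 4, 4)
  K[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  K[1, 2] <- K[2, 1] <- S[2, 3] - S[3, 2]
  K[1, 3] <- K[3, 1] <- S[3, 1] - S[1, 3]
  K[1, 4] <- K[4, 1] <- S[1, 2] - S[2, 1]
  K[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  K[2, 3] <- K[3, 2] <- S[1, 2] + S[2, 1]
  K[2, 4] <- K[4, 2] <- S[3, 1] + S[1, 3]
  K[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  K[3, 4] <- K[4, 3] <- S[2, 3] + S[3, 2]
  K[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  eg <- eigen(K, symmetric = TRUE)
  q <- eg$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(w^2 + x^2 - y^2 - z^2, 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), w^2 - x^2 + y^2 - z^2, 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), w^2 - x^2 - y^2 + z^2),
         3, 3, byrow = TRUE)
}

#' Rigid-body align band images to their predecessors
#'
#' Each image is aligned (quaternion best-fit rotation plus centroid
#' translation) to its already-aligned predecessor; the first image is the
#' reference. Energies are unchanged.
#'
#' @param band a \code{neb_band}.
#' @return the aligned band.
#' @export
align_images <- function(band) {
  for (i in 2:length(band$images)) {
    ref <- band$images[[i - 1]]$coords
    mov <- band$images[[i]]$coords
    cr <- colMeans(ref); cm <- colMeans(mov)
    P <- sweep(mov, 2, cm); Q <- sweep(ref, 2, cr)
    R <- .quaternion_rotation(P, Q)
    band$images[[i]]$coords <- sweep(P %*% t(R), 2, cr, `+`)
  }
  band
}

#' NEB effective forces
#'
#' Improved (energy-ordered) tangents, perpendicular true force plus
#' parallel energy-weighted spring force; the climbing image (highest
#' interior image) feels the full true force with inverted parallel
#' component and no springs. Endpoint forces are zero. Forces are returned
#' in Hartree/Angstrom.
#'
#' @param band a \code{neb_band} with current \code{energies}.
#' @param gradients list of per-image gradients (Hartree/Bohr).
#' @param k_min,k_max spring-constant bounds, Hartree/Angstrom^2.
#' @param climb activate the climbing image.
#' @return list of per-image force matrices; attribute
#'   \code{"climbing_index"}.
#' @export
neb_forces <- function(band, gradients, k_min = 0.01, k_max = 0.1,
                       climb = FALSE) {
  ni <- length(band$images)
  if (ni < 3) stop("fewer than 3 images")
  E <- band$energies
  X <- lapply(band$images, function(f) as.numeric(t(f$coords)))
  E_ref <- max(E[1], E[ni])
  E_max <- max(E)
  seg_k <- vapply(seq_len(ni - 1), function(j) {
    E_seg <- max(E[j], E[j + 1])
    if (E_max > E_ref && E_seg > E_ref) {
      k_max - (k_max - k_min) * (E_max - E_seg) / (E_max - E_ref)
    } else k_min
  }, 0)
  ci <- if (climb) which.max(E[2:(ni - 1)]) + 1L else NA_integer_

  forces <- vector("list", ni)
  forces[[1]] <- matrix(0.0, n_atoms(band$images[[1]]), 3)
  forces[[ni]] <- forces[[1]]
  for (i in 2:(ni - 1)) {
    tp <- X[[i + 1]] - X[[i]]
    tm <- X[[i]] - X[[i - 1]]
    if (E[i + 1] > E[i] && E[i] > E[i - 1]) {
      tau <- tp
    } else if (E[i + 1] < E[i] && E[i] < E[i - 1]) {
      tau <- tm
    } else {
      dmax <- max(abs(E[i + 1] - E[i]), abs(E[i - 1] - E[i]))
      dmin <- min(abs(E[i + 1] - E[i]), abs(E[i - 1] - E[i]))
      tau <- if (E[i + 1] > E[i - 1]) tp * dmax + tm * dmin else tp * dmin + tm * dmax
    }
    tn <- sqrt(sum(tau^2))
    tau <- if (tn > 1e-14) tau / tn else tp / max(sqrt(sum(tp^2)), 1e-14)
    g <- as.numeric(t(gradients[[i]])) / units_au$bohr_to_ang   # Hartree/Ang
    f_true <- -g
    f_par <- sum(f_true * tau) * tau
    if (!is.na(ci) && i == ci) {
      f <- f_true - 2 * f_par
    } else {
      f_perp <- f_true - f_par
      f_spring <- (seg_k[i] * sqrt(sum(tp^2)) - seg_k[i - 1] * sqrt(sum(tm^2))) * tau
      f <- f_perp + f_spring
    }
    forces[[i]] <- matrix(f, ncol = 3, byrow = TRUE)
  }
  attr(forces, "climbing_index") <- ci
  attr(forces, "spring_k") <- seg_k
  forces
}

#' Nudged-elastic-band optimization
#'
#' IDPP-interpolated initial path (unless a band is supplied), optional
#' rigid-body alignment (skipped for < 3 atoms or with frozen atoms),
#' L-BFGS on the stacked interior-image coordinates driven by the NEB
#' effective forces. Convergence when the maximum per-atom effective force
#' is below \code{conv_fmax} (climbing image: \code{ci_fmax}).
#'
#' @param theory the theory.
#' @param reactant,product endpoint minima (warned if their gradient is
#'   large) or a prebuilt \code{neb_band} via \code{band}.
#' @param n_images total images, default 10.
#' @param k_min,k_max spring bounds, Hartree/Angstrom^2.
#' @param climb climbing image on (default TRUE).
#' @param conv_fmax force threshold, Hartree/Bohr (per-atom norm).
#' @param ci_fmax climbing-image threshold (default \code{conv_fmax/2}).
#' @param max_iter iteration cap.
#' @param band optional starting band.
#' @param frozen_atoms indices whose coordinates stay fixed in every image.
#' @param align rigid-body align the initial path.
#' @return list of class \code{neb_result}: \code{band}, \code{ci_fragment}
#'   (highest image), \code{converged}, \code{iterations},
#'   \code{n_gradient_calls}, \code{energies}.
#' @export
neb_optimize <- function(theory, reactant, product, n_images = 10,
                         k_min = 0.01, k_max = 0.1, climb = TRUE,
                         conv_fmax = 1e-3, ci_fmax = conv_fmax / 2,
                         max_iter = 500, band = NULL,
                         frozen_atoms = NULL, align = TRUE) {
  if (is.null(band)) {
    band <- idpp_interpolate(reactant, product, n_images)
  }
  ni <- length(band$images)
  nat <- n_atoms(band$images[[1]])
  if (align && nat >= 3 && is.null(frozen_atoms)) band <- align_images(band)
  active_rows <- setdiff(seq_len(nat), frozen_atoms)

  n_calls <- 0L
  eval_band <- function(bd, interior_only = TRUE) {
    idx <- if (interior_only) 2:(ni - 1) else seq_len(ni)
    grads <- vector("list", ni)
    for (i in idx) {
      r <- evaluate(theory, bd$images[[i]], gradient = TRUE)
      n_calls <<- n_calls + 1L
      bd$energies[i] <- r$energy
      grads[[i]] <- r$gradient
    }
    list(band = bd, grads = grads)
  }
  # endpoints once
  for (i in c(1, ni)) {
    r <- evaluate(theory, band$images[[i]], gradient = TRUE)
    n_calls <- n_calls + 1L
    band$energies[i] <- r$energy
    if (max(sqrt(rowSums(r$gradient^2))) > 0.01) {
      warning("band endpoint ", i, " does not look like a minimum (large gradient)")
    }
  }

  pack <- function(bd) {
    unlist(lapply(2:(ni - 1), function(i)
      as.numeric(t(bd$images[[i]]$coords[active_rows, , drop = FALSE]))))
  }
  unpack <- function(bd, x) {
    len <- 3 * length(active_rows)
    for (i in 2:(ni - 1)) {
      seg <- x[((i - 2) * len + 1):((i - 1) * len)]
      bd$images[[i]]$coords[active_rows, ] <- matrix(seg, ncol = 3, byrow = TRUE)
    }
    bd
  }
  force_vec <- function(forces) {
    unlist(lapply(2:(ni - 1), function(i)
      as.numeric(t(forces[[i]][active_rows, , drop = FALSE]))))
  }
  fmax_of <- function(forces, which_imgs) {
    m <- 0
    for (i in which_imgs) {
      fr <- forces[[i]][active_rows, , drop = FALSE]
      m <- max(m, sqrt(max(rowSums(fr^2))))
    }
    m * units_au$bohr_to_ang          # Hartree/Ang -> Hartree/Bohr scale
  }

  S <- list(); Y <- list()
  x_prev <- NULL; g_prev <- NULL
  conv <- FALSE
  it <- 0
  fmax_last <- Inf
  repeat {
    eb <- eval_band(band)
    band <- eb$band
    forces <- neb_forces(band, eb$grads, k_min, k_max, climb = climb)
    ci <- attr(forces, "climbing_index")
    interior <- 2:(ni - 1)
    fmax_all <- fmax_of(forces, setdiff(interior, ci))
    fmax_ci <- if (!is.na(ci)) fmax_of(forces, ci) else 0
    if (fmax_all < conv_fmax && fmax_ci < (if (!is.na(ci)) ci_fmax else conv_fmax)) {
      conv <- TRUE
      band$climbing_index <- if (!is.na(ci)) ci else which.max(band$energies)
      break
    }
    if (it >= max_iter) break
    g <- -force_vec(forces)          # treat negative force as gradient
    x <- pack(band)
    fmax_now <- max(fmax_all, fmax_ci)
    if (fmax_now > 2 * fmax_last) { S <- list(); Y <- list() }  # overshoot: reset
    fmax_last <- fmax_now
    if (!is.null(g_prev)) {
      s <- x - x_prev; y <- g - g_prev
      if (sum(s * y) > 1e-14) {
        S <- c(S, list(s)); Y <- c(Y, list(y))
        if (length(S) > 12) { S <- S[-1]; Y <- Y[-1] }
      }
    }
    dir <- .lbfgs_direction(g, S, Y)
    if (sum(dir * g) >= 0) dir <- -g
    # cap the largest per-atom displacement
    dmat <- matrix(dir, ncol = 3, byrow = TRUE)
    dmax <- sqrt(max(rowSums(dmat^2)))
    cap <- 0.1
    if (dmax > cap) dir <- dir * cap / dmax
    x_prev <- x; g_prev <- g
    band <- unpack(band, x + dir)
    it <- it + 1
  }
  band$climbing_index <- if (!is.null(band$climbing_index) && !is.na(band$climbing_index))
    band$climbing_index else which.max(band$energies)
  ci_frag <- band$images[[which.max(band$energies)]]
  structure(list(band = band, ci_fragment = ci_frag, converged = conv,
                 iterations = it, n_gradient_calls = n_calls,
                 energies = band$energies),
            class = "neb_result")
}

#' @export
print.neb_result <- function(x, ...) {
  cat(sprintf("<neb_result: %s, %d iterations, %d gradient calls, barrier %.6f>\n",
              if (x$converged) "converged" else "NOT converged",
              x$iterations, x$n_gradient_calls,
              max(x$energies) - x$energies[1]))
  invisible(x)
}

#' NEB-TS: loose NEB, then Hessian-based P-RFO saddle refinement
#'
#' Runs NEB to a loose force threshold, takes the climbing-image geometry,
#' builds a numerical Hessian there and hands off to
#' \code{\link{prfo_ts_opt}}; the final saddle is verified to have exactly
#' one negative eigenvalue.
#'
#' @param theory the theory.
#' @param reactant,product endpoint minima.
#' @param n_images total images.
#' @param loose_fmax NEB force threshold (Hartree/Bohr), looser than a
#'   production NEB.
#' @param settings \code{\link{opt_settings}} for the refinement.
#' @param ... passed to \code{\link{neb_optimize}}.
#' @return list of class \code{nebts_result}: \code{saddle} (an
#'   \code{opt_result}), \code{neb} (the loose \code{neb_result}),
#'   \code{n_gradient_calls} (total including the Hessian).
#' @export
neb_ts <- function(theory, reactant, product, n_images = 10,
                   loose_fmax = 5e-3, settings = opt_settings(), ...) {
  cth <- counting_theory(theory)
  neb <- neb_optimize(cth, reactant, product, n_images = n_images,
                      conv_fmax = loose_fmax, ci_fmax = loose_fmax, ...)
  H <- numerical_hessian(cth, neb$ci_fragment)
  saddle <- prfo_ts_opt(cth, neb$ci_fragment, H, settings = settings)
  structure(list(saddle = saddle, neb = neb,
                 n_gradient_calls = evaluation_count(cth)),
            class = "nebts_result")
}
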