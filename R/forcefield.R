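# Harmonic force field: the built-in analytic MM potential.  Plays the role
# of the external MM program in hybrid schemes: bonds, angles, periodic
# dihedrals, Coulomb and Lennard-Jones nonbonded terms with 1-2/1-3
# exclusions.  No cutoffs or switching (exactness over speed; systems are
# tiny), no 1-4 scaling.

#' Harmonic force-field specification
#'
#' @param bonds data frame / matrix with columns \code{i, j, k, r0}:
#'   harmonic stretches, \code{k} in Hartree/Angstrom^2, \code{r0} Angstrom.
#' @param angles columns \code{i, j, k, kth, theta0}: harmonic bends,
#'   \code{kth} in Hartree/rad^2, \code{theta0} rad (central atom j).
#' @param dihedrals columns \code{i, j, k, l, V, n, phi0}: periodic
#'   torsions \code{V (1 + cos(n phi - phi0))}, \code{V} Hartree.
#' @param charges per-atom partial charges (e); defines the atom count.
#' @param lj per-atom Lennard-Jones parameters, columns \code{eps}
#'   (Hartree) and \code{sigma} (Angstrom); Lorentz-Berthelot combination.
#' @param exclusions optional extra nonbonded exclusion pairs (2-column,
#'   1-based) beyond the automatic 1-2 and 1-3 exclusions.
#' @return object of class \code{forcefield_spec}.
#' @export
forcefield_spec <- function(bonds = NULL, angles = NULL, dihedrals = NULL,
                            charges, lj = NULL, exclusions = NULL) {
  n <- length(charges)
  as_df <- function(x, cols) {
    if (is.null(x) || NROW(x) == 0) {
      return(as.data.frame(matrix(numeric(0), ncol = length(cols),
                                  dimnames = list(NULL, cols))))
    }
    x <- as.data.frame(x)
    names(x) <- cols
    x
  }
  bonds <- as_df(bonds, c("i", "j", "k", "r0"))
  angles <- as_df(angles, c("i", "j", "k", "kth", "theta0"))
  dihedrals <- as_df(dihedrals, c("i", "j", "k", "l", "V", "n", "phi0"))
  if (is.null(lj)) lj <- data.frame(eps = rep(0, n), sigma = rep(1, n))
  lj <- as.data.frame(lj); names(lj) <- c("eps", "sigma")
  idx <- c(bonds$i, bonds$j, angles$i, angles$j, angles$k,
           dihedrals$i, dihedrals$j, dihedrals$k, dihedrals$l)
  if (length(idx) && (min(idx) < 1 || max(idx) > n)) {
    stop("force-field term index out of range")
  }
  if (any(bonds$k < 0) || any(angles$kth < 0)) stop("force constants must be >= 0")
  if (any(lj$eps < 0) || any(lj$sigma <= 0)) stop("lj: eps >= 0 and sigma > 0 required")
  if (nrow(lj) != n) stop("lj must have one row per atom")
  if (!is.null(exclusions)) exclusions <- normalize_bonds(exclusions, n)
  structure(list(bonds = bonds, angles = angles, dihedrals = dihedrals,
                 charges = as.numeric(charges), lj = lj,
                 exclusions = exclusions, n_atoms = n),
            class = "forcefield_spec")
}

# Non-excluded nonbonded pair list: all pairs minus 1-2 (bond terms),
# 1-3 (pairs sharing a bonded neighbour) and explicit exclusions.
.ff_pairlist <- function(spec) {
  n <- spec$n_atoms
  if (n < 2) return(matrix(integer(0), ncol = 2))
  excl <- matrix(integer(0), ncol = 2)
  b <- cbind(spec$bonds$i, spec$bonds$j)
  if (nrow(b) > 0) {
    excl <- rbind(excl, b)
    adj <- vector("list", n)
    for (r in seq_len(nrow(b))) {
      adj[[b[r, 1]]] <- c(adj[[b[r, 1]]], b[r, 2])
      adj[[b[r, 2]]] <- c(adj[[b[r, 2]]], b[r, 1])
    }
    for (jc in seq_len(n)) {
      nb <- unique(adj[[jc]])
      if (length(nb) >= 2) excl <- rbind(excl, t(utils::combn(nb, 2)))
    }
  }
  if (!is.null(spec$exclusions) && nrow(spec$exclusions) > 0) {
    excl <- rbind(excl, spec$exclusions)
  }
  all_pairs <- t(utils::combn(n, 2))
  if (nrow(excl) > 0) {
    excl <- unique(t(apply(excl, 1, sort)))
    key <- function(m) m[, 1] * (n + 1L) + m[, 2]
    all_pairs <- all_pairs[!(key(all_pairs) %in% key(excl)), , drop = FALSE]
  }
  all_pairs
}

#' Harmonic force-field theory
#'
#' @param spec a \code{\link{forcefield_spec}}.
#' @param label provenance label.
#' @return theory object of class \code{forcefield_theory}.
#' @export
forcefield_theory <- function(spec, label = "harmonicFF") {
  stopifnot(inherits(spec, "forcefield_spec"))
  pairs <- .ff_pairlist(spec)
  structure(list(spec = spec, pairs = pairs, label = label),
            class = c("forcefield_theory", "mschem_theory"))
}

#' @export
evaluate.forcefield_theory <- function(theory, frag, pointcharges = NULL,
                                       gradient = TRUE, ...) {
  spec <- theory$spec
  if (n_atoms(frag) != spec$n_atoms) stop("fragment size does not match force-field spec")
  x <- frag$coords
  e <- 0.0
  g <- matrix(0.0, nrow(x), 3)       # Hartree/Angstrom while assembling

  if (nrow(spec$bonds) > 0) {
    for (r in seq_len(nrow(spec$bonds))) {
      b <- spec$bonds[r, ]
      dvec <- x[b$j, ] - x[b$i, ]
      rr <- sqrt(sum(dvec^2))
      if (rr < 1e-12) stop("zero interatomic distance in bond term")
      e <- e + 0.5 * b$k * (rr - b$r0)^2
      f <- b$k * (rr - b$r0) * dvec / rr
      g[b$i, ] <- g[b$i, ] - f
      g[b$j, ] <- g[b$j, ] + f
    }
  }

  if (nrow(spec$angles) > 0) {
    for (r in seq_len(nrow(spec$angles))) {
      a <- spec$angles[r, ]
      u <- x[a$i, ] - x[a$j, ]; v <- x[a$k, ] - x[a$j, ]
      lu <- sqrt(sum(u^2)); lv <- sqrt(sum(v^2))
      cth <- sum(u * v) / (lu * lv)
      cth <- pmin(1 - 1e-12, pmax(-1 + 1e-12, cth))
      th <- acos(cth); sth <- sqrt(1 - cth^2)
      e <- e + 0.5 * a$kth * (th - a$theta0)^2
      dEdth <- a$kth * (th - a$theta0)
      dth_di <- (cth * u / lu - v / lv) / (lu * sth)
      dth_dk <- (cth * v / lv - u / lu) / (lv * sth)
      g[a$i, ] <- g[a$i, ] + dEdth * dth_di
      g[a$k, ] <- g[a$k, ] + dEdth * dth_dk
      g[a$j, ] <- g[a$j, ] - dEdth * (dth_di + dth_dk)
    }
  }

  if (nrow(spec$dihedrals) > 0) {
    for (r in seq_len(nrow(spec$dihedrals))) {
      d <- spec$dihedrals[r, ]
      b1 <- x[d$j, ] - x[d$i, ]; b2 <- x[d$k, ] - x[d$j, ]; b3 <- x[d$l, ] - x[d$k, ]
      m <- .cross3(b1, b2); nn <- .cross3(b2, b3)
      lb2 <- sqrt(sum(b2^2))
      phi <- atan2(sum(.cross3(nn, m) * b2) / lb2, sum(m * nn))
      e <- e + d$V * (1 + cos(d$n * phi - d$phi0))
      dEdphi <- -d$V * d$n * sin(d$n * phi - d$phi0)
      dphi_d1 <- lb2 / sum(m^2) * m
      dphi_d4 <- -lb2 / sum(nn^2) * nn
      s <- sum(b1 * b2) / lb2^2; t <- sum(b3 * b2) / lb2^2
      dphi_d2 <- -(1 + s) * dphi_d1 + t * dphi_d4
      dphi_d3 <- s * dphi_d1 - (1 + t) * dphi_d4
      g[d$i, ] <- g[d$i, ] + dEdphi * dphi_d1
      g[d$j, ] <- g[d$j, ] + dEdphi * dphi_d2
      g[d$k, ] <- g[d$k, ] + dEdphi * dphi_d3
      g[d$l, ] <- g[d$l, ] + dEdphi * dphi_d4
    }
  }

  p <- theory$pairs
  if (nrow(p) > 0) {
    dv <- x[p[, 2], , drop = FALSE] - x[p[, 1], , drop = FALSE]
    rr <- sqrt(rowSums(dv^2))
    if (any(rr < 1e-12)) stop("zero interatomic distance in nonbonded pair")
    qq <- spec$charges[p[, 1]] * spec$charges[p[, 2]]
    rb <- ang_to_bohr(rr)
    e_c <- qq / rb
    eps <- sqrt(spec$lj$eps[p[, 1]] * spec$lj$eps[p[, 2]])
    sig <- 0.5 * (spec$lj$sigma[p[, 1]] + spec$lj$sigma[p[, 2]])
    sr6 <- (sig / rr)^6
    e <- e + sum(e_c) + sum(4 * eps * (sr6^2 - sr6))
    dEdr <- -e_c / rr + 4 * eps * (-12 * sr6^2 + 6 * sr6) / rr   # Hartree/Angstrom
    fpair <- dv * (dEdr / rr)                                    # force on atom j of pair
    acc <- rowsum(rbind(-fpair, fpair), group = c(p[, 1], p[, 2]))
    rows <- as.integer(rownames(acc))
    g[rows, ] <- g[rows, ] + acc
  }

  theory_result(e,
                gradient = if (gradient) g * units_au$bohr_to_ang else NULL,
                label = theory$label)
}
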