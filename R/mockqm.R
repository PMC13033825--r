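# Morse/Coulomb surrogate for an external QM program.  Implements the parts
# of the theory contract a point-charge-embeddable QM code exposes: energy,
# analytic nuclear gradient, gradient on external point charges, and a
# dipole moment (from its fixed per-atom charges, origin at the Cartesian
# origin).

#' Mock-QM specification
#'
#' @param morse_pairs data frame / matrix with columns \code{i, j, D, a, r0}:
#'   Morse bonds \code{D (1 - exp(-a (r - r0)))^2}; \code{D} Hartree,
#'   \code{a} 1/Angstrom, \code{r0} Angstrom. All three must be > 0
#'   (\code{D = 0} is allowed to switch a pair off).
#' @param atom_charges fixed per-atom charges (e) used for the embedding
#'   interaction and the dipole; defines the atom count.
#' @return object of class \code{mockqm_spec}.
#' @export
mockqm_spec <- function(morse_pairs = NULL, atom_charges) {
  n <- length(atom_charges)
  if (is.null(morse_pairs) || NROW(morse_pairs) == 0) {
    morse_pairs <- data.frame(i = integer(0), j = integer(0),
                              D = numeric(0), a = numeric(0), r0 = numeric(0))
  } else {
    morse_pairs <- as.data.frame(morse_pairs)
    names(morse_pairs) <- c("i", "j", "D", "a", "r0")
  }
  if (nrow(morse_pairs) > 0) {
    if (min(morse_pairs$i, morse_pairs$j) < 1 || max(morse_pairs$i, morse_pairs$j) > n) {
      stop("morse pair index out of range")
    }
    if (any(morse_pairs$D < 0) || any(morse_pairs$a <= 0) || any(morse_pairs$r0 <= 0)) {
      stop("morse parameters require D >= 0, a > 0, r0 > 0")
    }
  }
  structure(list(morse_pairs = morse_pairs, atom_charges = as.numeric(atom_charges),
                 n_atoms = n),
            class = "mockqm_spec")
}

#' Mock-QM theory (embedding-capable Morse/Coulomb potential)
#'
#' Energy: sum of Morse pair terms plus, when external point charges are
#' supplied, the Coulomb interaction between the fixed atom charges and the
#' point charges (computed in atomic units). Provides the nuclear gradient,
#' the gradient on the point charges (action-reaction pair), and the dipole
#' of the atom charges.
#'
#' @param spec a \code{\link{mockqm_spec}}.
#' @param label provenance label.
#' @return theory object of class \code{mockqm_theory}.
#' @export
mockqm_theory <- function(spec, label = "mockQM") {
  stopifnot(inherits(spec, "mockqm_spec"))
  structure(list(spec = spec, label = label),
            class = c("mockqm_theory", "mschem_theory"))
}

#' @export
supports_pointcharges.mockqm_theory <- function(theory) TRUE

#' @export
evaluate.mockqm_theory <- function(theory, frag, pointcharges = NULL,
                                   gradient = TRUE, ...) {
  spec <- theory$spec
  if (n_atoms(frag) != spec$n_atoms) stop("fragment size does not match mock-QM spec")
  x <- frag$coords
  e <- 0.0
  g <- matrix(0.0, nrow(x), 3)    # Hartree/Angstrom

  mp <- spec$morse_pairs
  for (r in seq_len(nrow(mp))) {
    dvec <- x[mp$j[r], ] - x[mp$i[r], ]
    rr <- sqrt(sum(dvec^2))
    if (rr < 1e-12) stop("zero interatomic distance in Morse pair")
    ex <- exp(-mp$a[r] * (rr - mp$r0[r]))
    e <- e + mp$D[r] * (1 - ex)^2
    dEdr <- 2 * mp$D[r] * (1 - ex) * mp$a[r] * ex
    f <- dEdr * dvec / rr
    g[mp$i[r], ] <- g[mp$i[r], ] - f
    g[mp$j[r], ] <- g[mp$j[r], ] + f
  }

  pcg <- NULL
  if (!is.null(pointcharges) && length(pointcharges$charges) > 0) {
    qp <- pointcharges$charges
    xp <- pointcharges$positions
    pcg_ang <- matrix(0.0, nrow(xp), 3)
    for (i in seq_len(nrow(x))) {
      qi <- spec$atom_charges[i]
      dv <- sweep(xp, 2, x[i, ])          # atom -> charge vectors
      rr <- sqrt(rowSums(dv^2))
      if (any(rr < 1e-8)) stop("point charge coincident with an atom")
      rb <- ang_to_bohr(rr)
      e <- e + sum(qi * qp / rb)
      dEdr <- -qi * qp / (rb * rr)        # Hartree/Angstrom (d/dr of q/r_bohr)
      fvec <- dv * (dEdr / rr)
      g[i, ] <- g[i, ] - colSums(fvec)
      pcg_ang <- pcg_ang + fvec
    }
    pcg <- pcg_ang * units_au$bohr_to_ang
  }

  dip <- colSums(spec$atom_charges * ang_to_bohr(x))   # e * Bohr, origin 0
  theory_result(e,
                gradient = if (gradient) g * units_au$bohr_to_ang else NULL,
                dipole = dip,
                pc_gradient = if (gradient) pcg else NULL,
                label = theory$label)
}
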