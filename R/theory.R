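# The uniform theory contract.  Every Hamiltonian — analytic toy potential
# or hybrid composition — is an S3 object answering evaluate(); every job
# type in the package is written against this contract alone.

#' Evaluate a theory on a fragment
#'
#' The uniform evaluation contract all job types use: one theory, one
#' fragment, optional external point charges, a gradient flag. Evaluation
#' is pure (the fragment is never mutated).
#'
#' @param theory a theory object.
#' @param frag a \code{\link{fragment}}.
#' @param pointcharges optional \code{\link{point_charges}}; only accepted
#'   by embedding-capable theories.
#' @param gradient logical; compute the nuclear gradient?
#' @param ... passed to methods.
#' @return a \code{theory_result}: energy (Hartree), gradient (N x 3,
#'   Hartree/Bohr, or NULL when not requested), optional dipole (a.u.),
#'   optional \code{pc_gradient} (M x 3, Hartree/Bohr) on the point
#'   charges, and a provenance label.
#' @export
evaluate <- function(theory, frag, pointcharges = NULL, gradient = TRUE, ...) {
  if (!is.null(pointcharges) && !supports_pointcharges(theory)) {
    stop("theory '", class(theory)[1], "' does not support point-charge embedding")
  }
  UseMethod("evaluate")
}

#' Does a theory support external point charges?
#'
#' @param theory a theory object.
#' @return logical.
#' @export
supports_pointcharges <- function(theory) UseMethod("supports_pointcharges")

#' @export
supports_pointcharges.default <- function(theory) FALSE

#' Construct a theory result
#'
#' @param energy scalar energy in Hartree.
#' @param gradient N x 3 gradient in Hartree/Bohr or NULL.
#' @param dipole optional length-3 dipole in a.u.
#' @param pc_gradient optional M x 3 gradient on external point charges.
#' @param label provenance string.
#' @param extra optional named list (energy breakdowns etc.).
#' @return object of class \code{theory_result}.
#' @export
theory_result <- function(energy, gradient = NULL, dipole = NULL,
                          pc_gradient = NULL, label = "", extra = NULL) {
  if (!is.finite(energy)) stop("non-finite energy from theory '", label, "'")
  if (!is.null(gradient) && any(!is.finite(gradient))) {
    stop("non-finite gradient from theory '", label, "'")
  }
  structure(list(energy = energy, gradient = gradient, dipole = dipole,
                 pc_gradient = pc_gradient, label = label, extra = extra),
            class = "theory_result")
}

#' @export
print.theory_result <- function(x, ...) {
  cat(sprintf("<theory_result [%s]: E = %.10f Hartree%s>\n", x$label, x$energy,
              if (!is.null(x$gradient)) sprintf(", |grad|max = %.3e", max(abs(x$gradient))) else ""))
  invisible(x)
}

# internal: evaluate and return only what is asked, with shape checks
.check_result <- function(res, frag, gradient) {
  if (gradient && (is.null(res$gradient) || nrow(res$gradient) != n_atoms(frag))) {
    stop("theory returned a gradient of the wrong shape")
  }
  res
}

#' Numerical-gradient wrapper theory
#'
#' Wraps any energy-capable theory and supplies a finite-difference
#' gradient: \code{two-point} central differences (2 * 3N evaluations) or
#' \code{one-point} forward differences (3N + 1 evaluations). The energy
#' reported is the undisplaced evaluation.
#'
#' @param theory the wrapped theory.
#' @param step displacement in Angstrom (default 1e-3).
#' @param formula "two-point" (central) or "one-point" (forward).
#' @return a theory object of class \code{numgrad_theory}.
#' @export
numgrad_theory <- function(theory, step = 1e-3, formula = c("two-point", "one-point")) {
  formula <- match.arg(formula)
  stopifnot(step > 0)
  structure(list(theory = theory, step = step, formula = formula),
            class = c("numgrad_theory", "mschem_theory"))
}

#' @export
supports_pointcharges.numgrad_theory <- function(theory) {
  supports_pointcharges(theory$theory)
}

#' @export
evaluate.numgrad_theory <- function(theory, frag, pointcharges = NULL,
                                    gradient = TRUE, ...) {
  base <- evaluate(theory$theory, frag, pointcharges, gradient = FALSE)
  if (!gradient) {
    return(theory_result(base$energy, dipole = base$dipole,
                         label = paste0("numgrad(", base$label, ")")))
  }
  n <- n_atoms(frag)
  h <- theory$step
  g_ang <- matrix(0.0, n, 3)
  e_at <- function(coords) {
    f2 <- frag
    f2$coords <- coords
    e <- evaluate(theory$theory, f2, pointcharges, gradient = FALSE)$energy
    if (!is.finite(e)) stop("non-finite displaced energy in numerical gradient")
    e
  }
  for (i in seq_len(n)) {
    for (k in 1:3) {
      cp <- frag$coords; cp[i, k] <- cp[i, k] + h
      ep <- e_at(cp)
      if (theory$formula == "two-point") {
        cm <- frag$coords; cm[i, k] <- cm[i, k] - h
        em <- e_at(cm)
        g_ang[i, k] <- (ep - em) / (2 * h)
      } else {
        g_ang[i, k] <- (ep - base$energy) / h
      }
    }
  }
  theory_result(base$energy, gradient = g_ang * units_au$bohr_to_ang,
                dipole = base$dipole,
                label = paste0("numgrad(", base$label, ")"))
}

#' Count gradient/energy evaluations of a theory
#'
#' Wraps a theory and counts \code{evaluate()} calls (used e.g. to compare
#' the cost of NEB against NEB-TS).
#'
#' @param theory the wrapped theory.
#' @return a \code{counting_theory}; read the tally with
#'   \code{\link{evaluation_count}}.
#' @export
counting_theory <- function(theory) {
  env <- new.env(parent = emptyenv())
  env$n <- 0L
  structure(list(theory = theory, env = env),
            class = c("counting_theory", "mschem_theory"))
}

#' @rdname counting_theory
#' @param x a \code{counting_theory}.
#' @export
evaluation_count <- function(x) x$env$n

#' @export
supports_pointcharges.counting_theory <- function(theory) {
  supports_pointcharges(theory$theory)
}

#' @export
evaluate.counting_theory <- function(theory, frag, pointcharges = NULL,
                                     gradient = TRUE, ...) {
  theory$env$n <- theory$env$n + 1L
  evaluate(theory$theory, frag, pointcharges, gradient, ...)
}
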