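# Standard analytic 2D test surfaces for path methods and saddle searches.
# The fragment is a single pseudo-atom whose (x, y) coordinates are the
# surface coordinates; z is ignored and its gradient is 0.
#
# muller_brown: the four-Gaussian surface of Muller & Brown (1979), the
#   standard benchmark for minimum-energy-path algorithms; constants below
#   are the literature definition.
# leps_like: a LEPS-type two-bond model surface V(rAB, rBC) with the
#   standard parameter set (a=0.05, b=0.30, c=0.05, dAB=dBC=4.746,
#   dAC=3.445, r0=0.742, alpha=1.942), x = rAB, y = rBC.

.mb_const <- list(
  A  = c(-200, -100, -170, 15),
  a  = c(-1, -1, -6.5, 0.7),
  b  = c(0, 0, 11, 0.6),
  cc = c(-10, -10, -6.5, 0.7),
  x0 = c(1, 0, -0.5, -1),
  y0 = c(0, 0.5, 1.5, 1)
)

.mb_eval <- function(x, y) {
  k <- .mb_const
  dx <- x - k$x0; dy <- y - k$y0
  ex <- k$A * exp(k$a * dx^2 + k$b * dx * dy + k$cc * dy^2)
  list(e = sum(ex),
       gx = sum(ex * (2 * k$a * dx + k$b * dy)),
       gy = sum(ex * (k$b * dx + 2 * k$cc * dy)))
}

.leps_const <- list(a = 0.05, b = 0.30, c = 0.05,
                    dAB = 4.746, dBC = 4.746, dAC = 3.445,
                    r0 = 0.742, alpha = 1.942)

.leps_Q <- function(d, r, k) {
  e1 <- exp(-2 * k$alpha * (r - k$r0)); e2 <- exp(-k$alpha * (r - k$r0))
  q <- d / 2 * (1.5 * e1 - e2)
  dq <- d / 2 * (-3 * k$alpha * e1 + k$alpha * e2)
  list(v = q, d = dq)
}

.leps_J <- function(d, r, k) {
  e1 <- exp(-2 * k$alpha * (r - k$r0)); e2 <- exp(-k$alpha * (r - k$r0))
  j <- d / 4 * (e1 - 6 * e2)
  dj <- d / 4 * (-2 * k$alpha * e1 + 6 * k$alpha * e2)
  list(v = j, d = dj)
}

.leps_eval <- function(x, y) {
  k <- .leps_const
  rAB <- x; rBC <- y; rAC <- x + y
  sa <- 1 + k$a; sb <- 1 + k$b; sc <- 1 + k$c
  QA <- .leps_Q(k$dAB, rAB, k); QB <- .leps_Q(k$dBC, rBC, k); QC <- .leps_Q(k$dAC, rAC, k)
  JA <- .leps_J(k$dAB, rAB, k); JB <- .leps_J(k$dBC, rBC, k); JC <- .leps_J(k$dAC, rAC, k)
  S <- JA$v^2 / sa^2 + JB$v^2 / sb^2 + JC$v^2 / sc^2 -
       JA$v * JB$v / (sa * sb) - JB$v * JC$v / (sb * sc) - JA$v * JC$v / (sa * sc)
  rootS <- sqrt(max(S, 1e-300))
  e <- QA$v / sa + QB$v / sb + QC$v / sc - rootS
  # dS/dJA etc.
  dS_dJA <- 2 * JA$v / sa^2 - JB$v / (sa * sb) - JC$v / (sa * sc)
  dS_dJB <- 2 * JB$v / sb^2 - JA$v / (sa * sb) - JC$v / (sb * sc)
  dS_dJC <- 2 * JC$v / sc^2 - JB$v / (sb * sc) - JA$v / (sa * sc)
  dE_drAB <- QA$d / sa - (dS_dJA * JA$d) / (2 * rootS)
  dE_drBC <- QB$d / sb - (dS_dJB * JB$d) / (2 * rootS)
  dE_drAC <- QC$d / sc - (dS_dJC * JC$d) / (2 * rootS)
  list(e = e, gx = dE_drAB + dE_drAC, gy = dE_drBC + dE_drAC)
}

#' 2D analytic test-surface theory
#'
#' @param name \code{"muller_brown"} or \code{"leps_like"}.
#' @return theory object of class \code{surface2d_theory}. Evaluate on a
#'   single-pseudo-atom fragment; the atom's (x, y) are the surface
#'   coordinates.
#' @export
surface2d_theory <- function(name = c("muller_brown", "leps_like")) {
  name <- match.arg(name)
  structure(list(name = name, label = paste0("surface2d:", name)),
            class = c("surface2d_theory", "mschem_theory"))
}

#' @export
evaluate.surface2d_theory <- function(theory, frag, pointcharges = NULL,
                                      gradient = TRUE, ...) {
  if (n_atoms(frag) != 1) stop("2D surface theories take a single pseudo-atom fragment")
  x <- frag$coords[1, 1]; y <- frag$coords[1, 2]
  v <- switch(theory$name,
              muller_brown = .mb_eval(x, y),
              leps_like = .leps_eval(x, y))
  g <- matrix(c(v$gx, v$gy, 0), 1, 3) * units_au$bohr_to_ang
  theory_result(v$e, gradient = if (gradient) g else NULL, label = theory$label)
}

#' Single pseudo-atom fragment for 2D surfaces
#'
#' @param x,y surface coordinates.
#' @return a one-atom \code{fragment} with element \code{X}.
#' @export
surface_point <- function(x, y) fragment("X", matrix(c(x, y, 0), 1, 3))
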