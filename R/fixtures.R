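# Seedable fixture generator: builds the small, internally-consistent test
# systems every example and test in the package runs on (no external data).

.zigzag_chain <- function(n, bond = 1.5, theta = 1.911) {
  coords <- matrix(0.0, n, 3)
  if (n >= 2) coords[2, ] <- c(bond, 0, 0)
  for (i in seq_len(n)[-(1:2)]) {
    prev <- coords[i - 1, ]; prev2 <- coords[i - 2, ]
    u <- prev - prev2; u <- u / sqrt(sum(u^2))
    # alternate direction in the xy plane at the set angle
    ang <- pi - theta
    rot <- if (i %% 2 == 0) ang else -ang
    R <- matrix(c(cos(rot), -sin(rot), 0, sin(rot), cos(rot), 0, 0, 0, 1),
                3, 3, byrow = TRUE)
    coords[i, ] <- prev + bond * drop(R %*% u)
  }
  coords
}

#' Generate a deterministic test fixture
#'
#' Kinds:
#' \describe{
#' \item{chain}{pseudo-alkane of \code{n} carbon-like centres with bonds,
#'   angles, dihedrals, alternating charges (sum 0) and LJ terms; carries a
#'   matching Morse mock-QM spec so a QM/MM boundary can be drawn anywhere.}
#' \item{solvated_diatomic}{a polar Morse diatomic (+0.3/-0.3 e) plus
#'   \code{n} rigid-charge three-site solvent molecules (each neutral);
#'   no covalent solute-solvent boundary.}
#' \item{cluster}{an \code{n}-atom argon Lennard-Jones cluster.}
#' }
#'
#' @param kind "chain", "solvated_diatomic" or "cluster".
#' @param n size parameter (atoms for chain/cluster; solvent molecules for
#'   solvated_diatomic).
#' @param seed integer seed; identical seeds give identical fixtures.
#' @param jitter coordinate jitter amplitude, Angstrom.
#' @return list with \code{fragment}, \code{ff_spec}, \code{qm_spec}
#'   (where applicable) and \code{qm_atoms} (a natural QM region).
#' @export
generate_fixture <- function(kind = c("chain", "solvated_diatomic", "cluster"),
                             n = 4, seed = 1, jitter = 0.05) {
  kind <- match.arg(kind)
  set.seed(seed)
  if (kind == "chain") {
    stopifnot(n >= 2)
    coords <- .zigzag_chain(n) + matrix(stats::rnorm(3 * n, sd = jitter), n, 3)
    q <- 0.1 * (-1)^(seq_len(n))
    q <- q - mean(q)
    bonds <- if (n >= 2) data.frame(i = 1:(n - 1), j = 2:n, k = 0.3, r0 = 1.5) else NULL
    angles <- if (n >= 3) data.frame(i = 1:(n - 2), j = 2:(n - 1), k = 3:n,
                                     kth = 0.15, theta0 = 1.911) else NULL
    dihedrals <- if (n >= 4) data.frame(i = 1:(n - 3), j = 2:(n - 2),
                                        k = 3:(n - 1), l = 4:n,
                                        V = 0.005, n = 3, phi0 = 0) else NULL
    ff <- forcefield_spec(bonds, angles, dihedrals, charges = q,
                          lj = data.frame(eps = rep(3e-4, n), sigma = rep(3.4, n)))
    qm <- mockqm_spec(if (n >= 2) data.frame(i = 1:(n - 1), j = 2:n,
                                             D = 0.15, a = 1.8, r0 = 1.5) else NULL,
                      atom_charges = q)
    frag <- fragment(rep("C", n), coords, atom_charges = q,
                     connectivity = cbind(1:(n - 1), 2:n))
    list(fragment = frag, ff_spec = ff, qm_spec = qm,
         qm_atoms = seq_len(max(1, floor(n / 2))))
  } else if (kind == "solvated_diatomic") {
    m <- n
    el <- c("N", "O")
    coords <- rbind(c(0, 0, 0), c(1.1, 0, 0))
    q <- c(0.3, -0.3)
    # place solvent oxygens on shells, rejecting close contacts
    placed <- coords
    for (s in seq_len(m)) {
      repeat {
        u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
        r <- 3.2 + 1.3 * stats::runif(1) + 0.55 * s
        p <- r * u
        if (min(sqrt(rowSums(sweep(placed, 2, p)^2))) > 2.6) break
      }
      # three-site solvent: O at p, two H-like sites
      d1 <- stats::rnorm(3); d1 <- d1 / sqrt(sum(d1^2))
      d2 <- stats::rnorm(3); d2 <- d2 - sum(d2 * d1) * d1; d2 <- d2 / sqrt(sum(d2^2))
      h1 <- p + 0.96 * d1
      h2 <- p + 0.96 * (cos(1.824) * d1 + sin(1.824) * d2)
      coords <- rbind(coords, p, h1, h2)
      placed <- rbind(placed, p)
      el <- c(el, "O", "H", "H")
      q <- c(q, -0.4, 0.2, 0.2)
    }
    nat <- nrow(coords)
    sol_idx <- 3:nat
    o_idx <- sol_idx[(seq_along(sol_idx) - 1) %% 3 == 0]
    bonds <- rbind(data.frame(i = 1, j = 2, k = 0.4, r0 = 1.1),
                   do.call(rbind, lapply(o_idx, function(o)
                     data.frame(i = c(o, o), j = c(o + 1, o + 2), k = 0.5, r0 = 0.96))))
    angles <- do.call(rbind, lapply(o_idx, function(o)
      data.frame(i = o + 1, j = o, k = o + 2, kth = 0.1, theta0 = 1.824)))
    lj <- data.frame(eps = c(2e-4, 2e-4, rep(c(2.5e-4, 0, 0), m)),
                     sigma = c(3.2, 3.2, rep(c(3.15, 1.0, 1.0), m)))
    ff <- forcefield_spec(bonds, angles, NULL, charges = q, lj = lj)
    qm <- mockqm_spec(data.frame(i = 1, j = 2, D = 0.2, a = 2.0, r0 = 1.1),
                      atom_charges = c(0.3, -0.3, rep(0, nat - 2)))
    conn <- as.matrix(bonds[, c("i", "j")])
    frag <- fragment(el, coords, atom_charges = q, connectivity = conn)
    list(fragment = frag, ff_spec = ff, qm_spec = qm, qm_atoms = c(1, 2))
  } else {
    stopifnot(n >= 2)
    coords <- matrix(0.0, n, 3)
    box <- 3.8 * n^(1 / 3) + 1.5     # leaves room for the 3.2 A contact cutoff
    for (i in seq_len(n)) {
      repeat {
        p <- (stats::runif(3) - 0.5) * box
        if (i == 1 ||
            min(sqrt(rowSums(sweep(coords[seq_len(i - 1), , drop = FALSE], 2, p)^2))) > 3.2) break
      }
      coords[i, ] <- p
    }
    ff <- forcefield_spec(charges = rep(0, n),
                          lj = data.frame(eps = rep(3.794e-4, n),
                                          sigma = rep(3.4, n)))
    frag <- fragment(rep("Ar", n), coords)
    list(fragment = frag, ff_spec = ff, qm_spec = NULL, qm_atoms = NULL)
  }
}
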