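# Additive QM/MM with electrostatic or mechanical embedding:
#
#   E_QM/MM = E_QM + E_MM + E_coupling,   E_coupling = E_elstat + E_vdW + E_covalent
#
# In practice the energy is assembled as a modified E_QM' (QM region capped
# with link atoms, plus the embedding interaction with the redistributed MM
# charges under electrostatic embedding) plus a modified E_MM' (MM terms with
# QM-internal contributions and the boundary angle/dihedral patterns removed).
# Link-atom forces are projected onto the QM1/MM1 host atoms by the exact
# chain rule (or the approximate lever rule).

#' Partition a system into QM and MM regions
#'
#' Boundary bonds are the connectivity pairs crossing the partition. By
#' default the partitioner rejects boundaries whose QM1/MM1 elements are not
#' both carbon (an "unusual boundary"), unless \code{allow_unusual = TRUE}.
#'
#' @param frag a \code{fragment} with connectivity (detected if absent).
#' @param qm_atoms integer vector of QM atom indices (1-based), a nonempty
#'   proper subset of the atoms.
#' @param allow_unusual allow non carbon-carbon boundary bonds.
#' @return a \code{qmmm_partition}: sorted \code{qm_atoms}, \code{mm_atoms},
#'   \code{boundaries} (data frame with columns \code{qm1, mm1}),
#'   and the \code{connectivity} used.
#' @export
partition_system <- function(frag, qm_atoms, allow_unusual = FALSE) {
  frag <- with_connectivity(frag)
  n <- n_atoms(frag)
  qm_atoms <- sort(unique(as.integer(qm_atoms)))
  if (length(qm_atoms) == 0) stop("qm_atoms must be nonempty")
  if (any(qm_atoms < 1 | qm_atoms > n)) stop("qm_atoms index out of range")
  if (length(qm_atoms) == n) stop("qm_atoms must be a proper subset of the system")
  conn <- frag$connectivity
  in_qm <- seq_len(n) %in% qm_atoms
  crosses <- xor(in_qm[conn[, 1]], in_qm[conn[, 2]])
  bd <- conn[crosses, , drop = FALSE]
  boundaries <- data.frame(qm1 = integer(0), mm1 = integer(0))
  if (nrow(bd) > 0) {
    qm1 <- ifelse(in_qm[bd[, 1]], bd[, 1], bd[, 2])
    mm1 <- ifelse(in_qm[bd[, 1]], bd[, 2], bd[, 1])
    boundaries <- data.frame(qm1 = qm1, mm1 = mm1)
    unusual <- frag$elements[qm1] != "C" | frag$elements[mm1] != "C"
    if (any(unusual) && !allow_unusual) {
      stop(sprintf("unusual boundary detected (%s-%s); set allow_unusual = TRUE to proceed",
                   frag$elements[qm1[which(unusual)[1]]],
                   frag$elements[mm1[which(unusual)[1]]]))
    }
    if (anyDuplicated(qm1)) {
      warning("multiple link atoms on one QM boundary atom (allowed, not recommended)")
    }
  }
  structure(list(qm_atoms = qm_atoms,
                 mm_atoms = setdiff(seq_len(n), qm_atoms),
                 boundaries = boundaries,
                 connectivity = conn),
            class = "qmmm_partition")
}

#' Place link atoms along cut boundary bonds
#'
#' Fixed mode places the link at distance \code{link_distance} from QM1
#' along the QM1 -> MM1 direction (default 1.09 Angstrom, a typical C-H
#' bond). Scaled mode uses \code{d = scale_ratio * |r_MM1 - r_QM1|}
#' (default ratio 0.723, approximately a C-H over C-C bond-length ratio).
#'
#' @param frag a \code{fragment}.
#' @param boundaries data frame with columns \code{qm1, mm1}.
#' @param mode "fixed" or "scaled".
#' @param link_distance fixed-mode distance, Angstrom.
#' @param scale_ratio scaled-mode ratio.
#' @return L x 3 matrix of link-atom positions (Angstrom).
#' @export
place_link_atoms <- function(frag, boundaries, mode = c("fixed", "scaled"),
                             link_distance = 1.09, scale_ratio = 0.723) {
  mode <- match.arg(mode)
  L <- nrow(boundaries)
  pos <- matrix(0.0, L, 3)
  for (b in seq_len(L)) {
    rq <- frag$coords[boundaries$qm1[b], ]
    rm <- frag$coords[boundaries$mm1[b], ]
    dv <- rm - rq
    R <- sqrt(sum(dv^2))
    if (R < 1e-8) stop("coincident QM1/MM1 atoms at boundary")
    d <- if (mode == "fixed") link_distance else scale_ratio * R
    pos[b, ] <- rq + d / R * dv
  }
  pos
}

# Jacobians of the link placement L(r_q, r_m) for fixed / scaled modes.
# Returns list(Jq, Jm): dL/dr_q and dL/dr_m (3 x 3).
.link_jacobian <- function(rq, rm, mode, link_distance, scale_ratio) {
  dv <- rm - rq
  R <- sqrt(sum(dv^2))
  u <- dv / R
  P <- diag(3) - tcrossprod(u)           # I - u u^T
  if (mode == "fixed") {
    d <- link_distance
    Jm <- (d / R) * P
    Jq <- diag(3) - Jm
  } else {
    Jm <- scale_ratio * diag(3)
    Jq <- (1 - scale_ratio) * diag(3)
  }
  list(Jq = Jq, Jm = Jm)
}

#' Project link-atom forces onto the QM1/MM1 host atoms
#'
#' \code{chain} mode uses the exact Jacobian of the link placement
#' \code{L(r_QM1, r_MM1)} (transpose chain rule); \code{lever} mode splits
#' the link gradient by the lever ratio \code{d/|r_MM1 - r_QM1|}. Link rows
#' are consumed: the result has one row per real atom.
#'
#' @param gradient (n_QM + L) x 3 gradient of the capped QM system,
#'   Hartree/Bohr, QM atoms (ascending index) first, link atoms last in
#'   boundary order.
#' @param boundaries data frame with \code{qm1, mm1} (full-system indices).
#' @param frag the full-system \code{fragment} (for the placement geometry).
#' @param qm_atoms sorted QM atom indices.
#' @param mode "chain" or "lever".
#' @param link_mode,link_distance,scale_ratio placement parameters, see
#'   \code{\link{place_link_atoms}}.
#' @return N x 3 full-system gradient contribution (zero on MM atoms other
#'   than the MM1 hosts).
#' @export
project_link_forces <- function(gradient, boundaries, frag, qm_atoms,
                                mode = c("chain", "lever"),
                                link_mode = "fixed", link_distance = 1.09,
                                scale_ratio = 0.723) {
  mode <- match.arg(mode)
  nqm <- length(qm_atoms)
  L <- nrow(boundaries)
  if (nrow(gradient) != nqm + L) stop("gradient shape does not match QM atoms + link atoms")
  g_full <- matrix(0.0, n_atoms(frag), 3)
  g_full[qm_atoms, ] <- gradient[seq_len(nqm), , drop = FALSE]
  for (b in seq_len(L)) {
    gL <- gradient[nqm + b, ]
    iq <- boundaries$qm1[b]; im <- boundaries$mm1[b]
    rq <- frag$coords[iq, ]; rm <- frag$coords[im, ]
    if (mode == "chain") {
      J <- .link_jacobian(rq, rm, link_mode, link_distance, scale_ratio)
      g_full[iq, ] <- g_full[iq, ] + drop(t(J$Jq) %*% gL)
      g_full[im, ] <- g_full[im, ] + drop(t(J$Jm) %*% gL)
    } else {
      R <- sqrt(sum((rm - rq)^2))
      d <- if (link_mode == "fixed") link_distance else scale_ratio * R
      w <- d / R
      g_full[iq, ] <- g_full[iq, ] + (1 - w) * gL
      g_full[im, ] <- g_full[im, ] + w * gL
    }
  }
  g_full
}

# MM2 neighbours of an MM1 atom: bonded, in the MM region.
.mm2_neighbours <- function(mm1, connectivity, qm_atoms) {
  nb <- c(connectivity[connectivity[, 1] == mm1, 2],
          connectivity[connectivity[, 2] == mm1, 1])
  setdiff(unique(nb), qm_atoms)
}

#' Charge-shift boundary scheme
#'
#' The MM1 charge is set to 0.0 and redistributed equally over the n MM2
#' neighbours. With \code{dipole_correction} (default), a +/- point-charge
#' pair is placed symmetrically about each MM2 along the MM1 -> MM2 axis,
#' at \code{MM2 +/- f (r_MM2 - r_MM1)} with a fixed fractional offset
#' \code{f}, and magnitudes \code{-+ dq/(2f)} (where \code{dq = q0/n} is
#' the shifted charge). This restores the dipole removed by the shift
#' exactly at every geometry while keeping the auxiliary charge values
#' geometry-independent (so all geometry dependence is through the
#' positions, with constant placement Jacobians); total charge is
#' conserved by construction.
#'
#' @param frag full-system \code{fragment} (geometry for the correction pairs).
#' @param charges full-length per-atom charge vector (e).
#' @param boundary one-row data frame / list with \code{qm1, mm1}.
#' @param connectivity bond pair matrix.
#' @param qm_atoms QM region indices.
#' @param dipole_correction logical, default TRUE.
#' @param offset_frac fractional offset f of the correction pair along the
#'   MM1-MM2 vector (default 0.1, i.e. 10 percent of the bond length).
#' @return a \code{charge_redistribution}: \code{scheme}, full-length
#'   \code{charges} after modification, and \code{extra} (data frame
#'   \code{x, y, z, q, mm1, mm2, sgn} of auxiliary charges with their
#'   host atoms and pair sign).
#' @export
shift_charges <- function(frag, charges, boundary, connectivity,
                          qm_atoms, dipole_correction = TRUE, offset_frac = 0.1) {
  mm1 <- boundary$mm1
  q0 <- charges[mm1]
  extra <- .empty_extra()
  mm2 <- .mm2_neighbours(mm1, connectivity, qm_atoms)
  out <- charges
  if (length(mm2) == 0) {
    # no MM neighbour: move the charge to the nearest MM atom
    warning("MM1 atom has no MM neighbours; moving its charge to the nearest MM atom")
    mm_all <- setdiff(seq_len(n_atoms(frag)), c(qm_atoms, mm1))
    d <- sqrt(rowSums((frag$coords[mm_all, , drop = FALSE] -
                         matrix(frag$coords[mm1, ], length(mm_all), 3, byrow = TRUE))^2))
    tgt <- mm_all[which.min(d)]
    out[mm1] <- 0
    out[tgt] <- out[tgt] + q0
    return(structure(list(scheme = "charge_shift", charges = out, extra = extra),
                     class = "charge_redistribution"))
  }
  n2 <- length(mm2)
  out[mm1] <- 0
  out[mm2] <- out[mm2] + q0 / n2
  if (dipole_correction && q0 != 0) {
    f <- offset_frac
    for (a2 in mm2) {
      r1 <- frag$coords[mm1, ]; r2 <- frag$coords[a2, ]
      dv <- r2 - r1
      # shift of dq = q0/n2 from r1 to r2 changed the dipole by dq*(r2-r1);
      # pair +/- qd at r2 +/- f*(r2-r1) adds 2*qd*f*(r2-r1); qd = -dq/(2f)
      qd <- -(q0 / n2) / (2 * f)
      pp <- r2 + f * dv
      pm <- r2 - f * dv
      extra <- rbind(extra,
                     data.frame(x = c(pp[1], pm[1]), y = c(pp[2], pm[2]),
                                z = c(pp[3], pm[3]), q = c(qd, -qd),
                                mm1 = mm1, mm2 = a2, sgn = c(1, -1)))
    }
  }
  structure(list(scheme = "charge_shift", charges = out, extra = extra,
                 offset_frac = offset_frac),
            class = "charge_redistribution")
}

.empty_extra <- function() {
  data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
             q = numeric(0), mm1 = integer(0), mm2 = integer(0),
             sgn = numeric(0))
}

#' Redistributed charge and dipole (RCD) boundary scheme
#'
#' The MM1 charge is removed; charges of \code{2 q0/n} are placed at the
#' MM1-MM2 bond midpoints and each MM2 charge is reduced by \code{q0/n}.
#' Both the total charge and the total dipole of the MM charge set are
#' preserved exactly.
#'
#' @inheritParams shift_charges
#' @return a \code{charge_redistribution}; \code{extra} holds the midpoint
#'   charges (hosts \code{mm1} and \code{mm2}, Jacobian 1/2 each).
#' @export
rcd_charges <- function(frag, charges, boundary, connectivity, qm_atoms) {
  mm1 <- boundary$mm1
  q0 <- charges[mm1]
  mm2 <- .mm2_neighbours(mm1, connectivity, qm_atoms)
  out <- charges
  extra <- .empty_extra()
  if (length(mm2) == 0) {
    warning("MM1 atom has no MM neighbours; moving its charge to the nearest MM atom")
    return(shift_charges(frag, charges, boundary, connectivity, qm_atoms,
                         dipole_correction = FALSE))
  }
  n2 <- length(mm2)
  out[mm1] <- 0
  out[mm2] <- out[mm2] - q0 / n2
  for (a2 in mm2) {
    mid <- 0.5 * (frag$coords[mm1, ] + frag$coords[a2, ])
    extra <- rbind(extra, data.frame(x = mid[1], y = mid[2], z = mid[3],
                                     q = 2 * q0 / n2, mm1 = mm1, mm2 = a2,
                                     sgn = 0))
  }
  structure(list(scheme = "rcd", charges = out, extra = extra),
            class = "charge_redistribution")
}

#' Delete MM bonded terms at and inside the QM region
#'
#' Removes every bonded term fully internal to the QM region, the boundary
#' angle pattern QM2-QM1-MM1 and the boundary dihedral pattern
#' QM3-QM2-QM1-MM (terminal MM atom); the QM1-MM1 bond stretch is retained.
#' QM-QM nonbonded pairs are added to the exclusions. Optionally zeroes the
#' QM atom charges inside the MM evaluation (electrostatic embedding; the
#' QM-environment electrostatics then live entirely in the QM calculation).
#'
#' @param spec a \code{\link{forcefield_spec}} for the full system.
#' @param qm_atoms QM region indices.
#' @param zero_qm_charges zero QM partial charges in the MM evaluation.
#' @return modified \code{forcefield_spec}.
#' @export
delete_boundary_terms <- function(spec, qm_atoms, zero_qm_charges = TRUE) {
  in_qm <- function(ix) ix %in% qm_atoms
  b <- spec$bonds
  keep_b <- !(in_qm(b$i) & in_qm(b$j))
  a <- spec$angles
  nq_a <- in_qm(a$i) + in_qm(a$j) + in_qm(a$k)
  # QM2-QM1-MM1: two QM with the MM atom terminal
  boundary_a <- nq_a == 2 & (!in_qm(a$i) | !in_qm(a$k)) & in_qm(a$j)
  keep_a <- !(nq_a == 3 | boundary_a)
  d <- spec$dihedrals
  nq_d <- in_qm(d$i) + in_qm(d$j) + in_qm(d$k) + in_qm(d$l)
  boundary_d <- nq_d == 3 & (!in_qm(d$i) | !in_qm(d$l)) & in_qm(d$j) & in_qm(d$k)
  keep_d <- !(nq_d == 4 | boundary_d)
  charges <- spec$charges
  if (zero_qm_charges) charges[qm_atoms] <- 0
  qq_excl <- if (length(qm_atoms) >= 2) t(utils::combn(sort(qm_atoms), 2)) else NULL
  forcefield_spec(bonds = b[keep_b, , drop = FALSE],
                  angles = a[keep_a, , drop = FALSE],
                  dihedrals = d[keep_d, , drop = FALSE],
                  charges = charges,
                  lj = spec$lj,
                  exclusions = rbind(spec$exclusions, qq_excl))
}

# Build the embedding point-charge set for a region: the environment
# charges with the boundary redistribution applied, plus auxiliary
# charges, together with the host mapping needed to chain-rule the
# pc_gradient back onto real atoms.
.build_embedding_charges <- function(frag, charges, part, scheme = "shift",
                                     dipole_correction = TRUE, offset_frac = 0.1) {
  q <- charges
  extras <- list()
  for (b in seq_len(nrow(part$boundaries))) {
    bd <- part$boundaries[b, ]
    cr <- if (scheme == "shift") {
      shift_charges(frag, q, bd, part$connectivity, part$qm_atoms,
                    dipole_correction = dipole_correction,
                    offset_frac = offset_frac)
    } else {
      rcd_charges(frag, q, bd, part$connectivity, part$qm_atoms)
    }
    q <- cr$charges
    if (nrow(cr$extra) > 0) extras[[length(extras) + 1]] <- cr$extra
  }
  extra <- if (length(extras)) do.call(rbind, extras) else .empty_extra()
  mm <- part$mm_atoms
  positions <- rbind(frag$coords[mm, , drop = FALSE],
                     as.matrix(extra[, c("x", "y", "z")]))
  values <- c(q[mm], extra$q)
  list(pc = point_charges(positions, values),
       mm_atoms = mm, extra = extra, scheme = scheme,
       dipole_correction = dipole_correction, offset_frac = offset_frac,
       charges_after = q)
}

# Map a pc_gradient (rows: MM sites then extra charges) back onto real atoms.
# Auxiliary-charge rows are chain-ruled onto their host atoms:
#   rcd midpoint p = (r1+r2)/2            => J = I/2 on each host
#   shift pair  p = r2 + sgn*f*(r2-r1)    => J2 = (1+sgn*f) I, J1 = -sgn*f I
.map_pc_gradient <- function(pcg, emb, frag) {
  g <- matrix(0.0, n_atoms(frag), 3)
  nmm <- length(emb$mm_atoms)
  g[emb$mm_atoms, ] <- g[emb$mm_atoms, ] + pcg[seq_len(nmm), , drop = FALSE]
  ex <- emb$extra
  if (nrow(ex) > 0) {
    f <- emb$offset_frac
    for (r in seq_len(nrow(ex))) {
      gE <- pcg[nmm + r, ]
      i1 <- ex$mm1[r]; i2 <- ex$mm2[r]
      if (emb$scheme == "rcd") {
        g[i1, ] <- g[i1, ] + 0.5 * gE
        g[i2, ] <- g[i2, ] + 0.5 * gE
      } else {
        sgn <- ex$sgn[r]
        g[i2, ] <- g[i2, ] + (1 + sgn * f) * gE
        g[i1, ] <- g[i1, ] - sgn * f * gE
      }
    }
  }
  g
}

# Restrict a full-system mock-QM spec to a capped region: Morse pairs fully
# inside the region are kept and remapped; link atoms are appended with
# charge link_charge and optional Morse terms (one per boundary, QM1-link).
.restrict_mockqm <- function(spec, atoms, n_links, boundaries = NULL,
                             link_charge = 0, link_morse = NULL) {
  atoms <- sort(atoms)
  remap <- match(seq_len(spec$n_atoms), atoms)
  mp <- spec$morse_pairs
  keep <- !is.na(remap[mp$i]) & !is.na(remap[mp$j])
  mp <- mp[keep, , drop = FALSE]
  mp$i <- remap[mp$i]; mp$j <- remap[mp$j]
  if (!is.null(link_morse) && n_links > 0) {
    for (b in seq_len(n_links)) {
      mp <- rbind(mp, data.frame(i = remap[boundaries$qm1[b]],
                                 j = length(atoms) + b,
                                 D = link_morse[["D"]], a = link_morse[["a"]],
                                 r0 = link_morse[["r0"]]))
    }
  }
  mockqm_spec(mp, c(spec$atom_charges[atoms], rep(link_charge, n_links)))
}

#' Additive QM/MM hybrid theory
#'
#' Combines an embedding-capable QM surrogate (a \code{\link{mockqm_spec}}
#' in full-system atom indexing) with a full-system MM force field.
#' Electrostatic embedding passes the redistributed MM charges (plus any
#' dipole-correction charges) to the QM calculation as point charges;
#' mechanical embedding keeps the classical QM-MM electrostatics in the MM
#' evaluation. The assembled gradient covers the whole system, with
#' link-atom forces projected onto QM1/MM1 and point-charge forces mapped
#' back onto the MM sites (auxiliary charges via the placement Jacobians).
#'
#' @param qm_spec \code{\link{mockqm_spec}} in full-system indexing (terms
#'   outside the QM region are ignored).
#' @param mm_spec \code{\link{forcefield_spec}} for the full system.
#' @param frag reference \code{fragment} defining the topology.
#' @param qm_atoms QM region (1-based indices).
#' @param embedding "electrostatic" (default) or "mechanical".
#' @param charge_scheme "shift" (charge shifting, default) or "rcd".
#' @param dipole_correction apply the dipole correction in the shift scheme.
#' @param link_element,link_mode,link_distance,scale_ratio link-atom
#'   parameters, see \code{\link{place_link_atoms}}.
#' @param link_charge embedding charge carried by link atoms (default 0).
#' @param link_morse optional named vector \code{c(D=, a=, r0=)} adding a
#'   QM1-link Morse term to the capped QM system.
#' @param projection link-force projection mode, "chain" or "lever".
#' @param allow_unusual allow non C-C boundary bonds.
#' @return theory object of class \code{qmmm_theory}. Evaluation results
#'   carry an energy breakdown in \code{$extra$breakdown} with
#'   \code{e_total = e_qm_mod + e_mm_mod}.
#' @export
qmmm_theory <- function(qm_spec, mm_spec, frag, qm_atoms,
                        embedding = c("electrostatic", "mechanical"),
                        charge_scheme = c("shift", "rcd"),
                        dipole_correction = TRUE,
                        link_element = "H", link_mode = "fixed",
                        link_distance = 1.09, scale_ratio = 0.723,
                        link_charge = 0, link_morse = NULL,
                        projection = c("chain", "lever"),
                        allow_unusual = FALSE) {
  embedding <- match.arg(embedding)
  charge_scheme <- match.arg(charge_scheme)
  projection <- match.arg(projection)
  part <- partition_system(frag, qm_atoms, allow_unusual = allow_unusual)
  L <- nrow(part$boundaries)
  qm_theory <- mockqm_theory(
    .restrict_mockqm(qm_spec, part$qm_atoms, L, part$boundaries,
                     link_charge, link_morse),
    label = "mockQM(region)")
  mm_mod <- delete_boundary_terms(mm_spec, part$qm_atoms,
                                  zero_qm_charges = (embedding == "electrostatic"))
  structure(list(part = part, qm_theory = qm_theory, mm_spec = mm_spec,
                 mm_theory = forcefield_theory(mm_mod, label = "MM(modified)"),
                 embedding = embedding, charge_scheme = charge_scheme,
                 dipole_correction = dipole_correction,
                 link_element = link_element, link_mode = link_mode,
                 link_distance = link_distance, scale_ratio = scale_ratio,
                 projection = projection,
                 label = sprintf("QM/MM(%s,%s)", embedding, charge_scheme)),
            class = c("qmmm_theory", "mschem_theory"))
}

#' @export
evaluate.qmmm_theory <- function(theory, frag, pointcharges = NULL,
                                 gradient = TRUE, ...) {
  if (!is.null(pointcharges)) stop("QM/MM theory does not accept external point charges")
  part <- theory$part
  qm <- part$qm_atoms
  L <- nrow(part$boundaries)
  lpos <- place_link_atoms(frag, part$boundaries, theory$link_mode,
                           theory$link_distance, theory$scale_ratio)
  capped <- fragment(c(frag$elements[qm], rep(theory$link_element, L)),
                     rbind(frag$coords[qm, , drop = FALSE], lpos))
  emb <- NULL
  pc <- NULL
  if (theory$embedding == "electrostatic") {
    emb <- .build_embedding_charges(frag, theory$mm_spec$charges, part,
                                    scheme = theory$charge_scheme,
                                    dipole_correction = theory$dipole_correction)
    pc <- emb$pc
  }
  qm_res <- evaluate(theory$qm_theory, capped, pointcharges = pc, gradient = gradient)
  mm_res <- evaluate(theory$mm_theory, frag, gradient = gradient)
  e_total <- qm_res$energy + mm_res$energy
  g <- NULL
  if (gradient) {
    g <- mm_res$gradient +
      project_link_forces(qm_res$gradient, part$boundaries, frag, qm,
                          mode = theory$projection,
                          link_mode = theory$link_mode,
                          link_distance = theory$link_distance,
                          scale_ratio = theory$scale_ratio)
    if (!is.null(pc) && !is.null(qm_res$pc_gradient)) {
      g <- g + .map_pc_gradient(qm_res$pc_gradient, emb, frag)
    }
  }
  breakdown <- list(e_total = e_total, e_qm_mod = qm_res$energy,
                    e_mm_mod = mm_res$energy, embedding = theory$embedding)
  theory_result(e_total, gradient = g, dipole = qm_res$dipole,
                label = theory$label, extra = list(breakdown = breakdown))
}
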