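# Subtractive ONIOM (2- and 3-layer) and additive WrapTheory composition.
#
# 2-layer:  E = E_full^LL + E_1^HL - E_1^LL
# 3-layer:  E = E_full^LL + E_1^HL - E_1^ML + E_12^ML - E_12^LL
#
# Region subsystems are capped with link atoms exactly as in additive QM/MM
# (one boundary code path); under electrostatic embedding the environment
# charges (boundary-redistributed via the charge-shift machinery) enter both
# members of each high/low correction pair.

# Restrict a full-system force-field spec to a capped region.
.restrict_ff <- function(spec, atoms, n_links, ...) {
  atoms <- sort(atoms)
  remap <- match(seq_len(spec$n_atoms), atoms)
  inr <- function(ix) !is.na(remap[ix])
  b <- spec$bonds[inr(spec$bonds$i) & inr(spec$bonds$j), , drop = FALSE]
  b$i <- remap[b$i]; b$j <- remap[b$j]
  a <- spec$angles[inr(spec$angles$i) & inr(spec$angles$j) & inr(spec$angles$k), , drop = FALSE]
  a$i <- remap[a$i]; a$j <- remap[a$j]; a$k <- remap[a$k]
  d <- spec$dihedrals[inr(spec$dihedrals$i) & inr(spec$dihedrals$j) &
                        inr(spec$dihedrals$k) & inr(spec$dihedrals$l), , drop = FALSE]
  d$i <- remap[d$i]; d$j <- remap[d$j]; d$k <- remap[d$k]; d$l <- remap[d$l]
  excl <- NULL
  if (!is.null(spec$exclusions) && nrow(spec$exclusions) > 0) {
    e <- spec$exclusions
    keep <- inr(e[, 1]) & inr(e[, 2])
    if (any(keep)) excl <- cbind(remap[e[keep, 1]], remap[e[keep, 2]])
  }
  forcefield_spec(bonds = b, angles = a, dihedrals = d,
                  charges = c(spec$charges[atoms], rep(0, n_links)),
                  lj = rbind(spec$lj[atoms, , drop = FALSE],
                             data.frame(eps = rep(0, n_links), sigma = rep(1, n_links))),
                  exclusions = excl)
}

.restrict_spec <- function(spec, atoms, n_links, boundaries = NULL,
                           link_charge = 0, link_morse = NULL) {
  if (inherits(spec, "mockqm_spec")) {
    .restrict_mockqm(spec, atoms, n_links, boundaries, link_charge, link_morse)
  } else if (inherits(spec, "forcefield_spec")) {
    .restrict_ff(spec, atoms, n_links)
  } else {
    stop("cannot restrict a '", class(spec)[1], "' to a region")
  }
}

.theory_from_spec <- function(spec, label) {
  if (inherits(spec, "forcefield_spec")) forcefield_theory(spec, label)
  else if (inherits(spec, "mockqm_spec")) mockqm_theory(spec, label)
  else stop("unsupported theory spec of class '", class(spec)[1], "'")
}

.spec_charges <- function(spec) {
  if (inherits(spec, "forcefield_spec")) spec$charges
  else if (inherits(spec, "mockqm_spec")) spec$atom_charges
  else NULL
}

#' Subtractive ONIOM hybrid theory (2 or 3 layers)
#'
#' Layers are nested region index sets, innermost first; the outermost
#' layer is the whole system and is implicit. Theories are full-system spec
#' objects (\code{\link{mockqm_spec}} or \code{\link{forcefield_spec}}),
#' ordered from the highest level to the lowest:
#' \code{list(HL, LL)} for 2-layer, \code{list(HL, ML, LL)} for 3-layer.
#'
#' Under electrostatic embedding each correction pair (e.g. E_1^HL and
#' E_1^LL) sees the charges of all atoms outside its region, with the
#' charge-shift boundary treatment applied; both theories of the pair must
#' support point charges. Mechanical embedding evaluates the pairs in vacuo.
#'
#' @param frag reference \code{fragment} (topology).
#' @param layers list of integer index vectors: \code{list(region1)} or
#'   \code{list(region1, region12)}, with \code{region1} a subset of
#'   \code{region12}.
#' @param specs list of theory specs, highest level first (length
#'   \code{length(layers) + 1}).
#' @param embedding "mechanical" (default) or "electrostatic".
#' @param env_charges optional full-length per-atom charges for embedding;
#'   defaults to the charges of the lowest-level spec.
#' @param link_element,link_mode,link_distance,scale_ratio,link_charge,link_morse
#'   link-atom parameters as in \code{\link{qmmm_theory}}.
#' @param projection link-force projection mode.
#' @param allow_unusual allow non C-C boundary bonds.
#' @return theory object of class \code{oniom_theory}; results carry the
#'   subtractive energy breakdown in \code{$extra$breakdown}.
#' @export
oniom_theory <- function(frag, layers, specs,
                         embedding = c("mechanical", "electrostatic"),
                         env_charges = NULL,
                         link_element = "H", link_mode = "fixed",
                         link_distance = 1.09, scale_ratio = 0.723,
                         link_charge = 0, link_morse = NULL,
                         projection = c("chain", "lever"),
                         allow_unusual = FALSE) {
  embedding <- match.arg(embedding)
  projection <- match.arg(projection)
  if (!is.list(layers) || !(length(layers) %in% c(1, 2))) {
    stop("layers must be a list of 1 (2-layer) or 2 (3-layer) region index sets")
  }
  if (length(specs) != length(layers) + 1) {
    stop("need one theory spec per level: ", length(layers) + 1)
  }
  n <- n_atoms(frag)
  layers <- lapply(layers, function(l) sort(unique(as.integer(l))))
  if (length(layers) == 2 && !all(layers[[1]] %in% layers[[2]])) {
    stop("regions must be nested: region1 within region12")
  }
  frag <- with_connectivity(frag)
  parts <- lapply(layers, function(l) {
    if (length(l) == n) NULL else partition_system(frag, l, allow_unusual = allow_unusual)
  })
  if (embedding == "electrostatic") {
    if (is.null(env_charges)) env_charges <- .spec_charges(specs[[length(specs)]])
    if (is.null(env_charges)) stop("electrostatic embedding requires per-atom charges")
  }
  structure(list(layers = layers, specs = specs, parts = parts,
                 embedding = embedding, env_charges = env_charges,
                 link_element = link_element, link_mode = link_mode,
                 link_distance = link_distance, scale_ratio = scale_ratio,
                 link_charge = link_charge, link_morse = link_morse,
                 projection = projection, connectivity = frag$connectivity,
                 label = sprintf("ONIOM(%d-layer,%s)", length(layers) + 1, embedding)),
            class = c("oniom_theory", "mschem_theory"))
}

# One subtractive correction pair: E_region^high - E_region^low with link
# atoms and optional embedding charges. Returns energy pair and the
# full-system gradient contribution.
.oniom_pair <- function(theory, frag, region, spec_hi, spec_lo, gradient) {
  n <- n_atoms(frag)
  if (length(region) == n) {
    hi <- evaluate(.theory_from_spec(spec_hi, "ONIOM:high"), frag, gradient = gradient)
    lo <- evaluate(.theory_from_spec(spec_lo, "ONIOM:low"), frag, gradient = gradient)
    g <- if (gradient) hi$gradient - lo$gradient else NULL
    return(list(e_hi = hi$energy, e_lo = lo$energy, g = g))
  }
  part <- partition_system(frag, region, allow_unusual = TRUE)
  L <- nrow(part$boundaries)
  lpos <- place_link_atoms(frag, part$boundaries, theory$link_mode,
                           theory$link_distance, theory$scale_ratio)
  capped <- fragment(c(frag$elements[part$qm_atoms], rep(theory$link_element, L)),
                     rbind(frag$coords[part$qm_atoms, , drop = FALSE], lpos))
  th_hi <- .theory_from_spec(
    .restrict_spec(spec_hi, part$qm_atoms, L, part$boundaries,
                   theory$link_charge, theory$link_morse), "ONIOM:high")
  th_lo <- .theory_from_spec(
    .restrict_spec(spec_lo, part$qm_atoms, L, part$boundaries,
                   theory$link_charge, theory$link_morse), "ONIOM:low")
  pc <- NULL; emb <- NULL
  if (theory$embedding == "electrostatic") {
    if (!supports_pointcharges(th_hi) || !supports_pointcharges(th_lo)) {
      stop("electrostatic ONIOM embedding requires point-charge support in both pair theories")
    }
    emb <- .build_embedding_charges(frag, theory$env_charges, part, scheme = "shift")
    pc <- emb$pc
  }
  hi <- evaluate(th_hi, capped, pointcharges = pc, gradient = gradient)
  lo <- evaluate(th_lo, capped, pointcharges = pc, gradient = gradient)
  g <- NULL
  if (gradient) {
    proj <- function(res) project_link_forces(res$gradient, part$boundaries, frag,
                                              part$qm_atoms, mode = theory$projection,
                                              link_mode = theory$link_mode,
                                              link_distance = theory$link_distance,
                                              scale_ratio = theory$scale_ratio)
    g <- proj(hi) - proj(lo)
    if (!is.null(pc)) {
      if (!is.null(hi$pc_gradient)) g <- g + .map_pc_gradient(hi$pc_gradient, emb, frag)
      if (!is.null(lo$pc_gradient)) g <- g - .map_pc_gradient(lo$pc_gradient, emb, frag)
    }
  }
  list(e_hi = hi$energy, e_lo = lo$energy, g = g)
}

#' @export
evaluate.oniom_theory <- function(theory, frag, pointcharges = NULL,
                                  gradient = TRUE, ...) {
  if (!is.null(pointcharges)) stop("ONIOM theory does not accept external point charges")
  nlev <- length(theory$specs)
  ll_spec <- theory$specs[[nlev]]
  full <- evaluate(.theory_from_spec(ll_spec, "ONIOM:LL(full)"), frag, gradient = gradient)
  e <- full$energy
  g <- if (gradient) full$gradient else NULL
  breakdown <- list(e_full_ll = full$energy, embedding = theory$embedding)
  p1 <- .oniom_pair(theory, frag, theory$layers[[1]],
                    theory$specs[[1]], theory$specs[[2]], gradient)
  e <- e + p1$e_hi - p1$e_lo
  if (gradient) g <- g + p1$g
  breakdown$e_r1_hl <- p1$e_hi
  if (nlev == 2) {
    breakdown$e_r1_ll <- p1$e_lo
  } else {
    breakdown$e_r1_ml <- p1$e_lo
    p2 <- .oniom_pair(theory, frag, theory$layers[[2]],
                      theory$specs[[2]], theory$specs[[3]], gradient)
    e <- e + p2$e_hi - p2$e_lo
    if (gradient) g <- g + p2$g
    breakdown$e_r12_ml <- p2$e_hi
    breakdown$e_r12_ll <- p2$e_lo
  }
  breakdown$e_total <- e
  theory_result(e, gradient = g, label = theory$label,
                extra = list(breakdown = breakdown))
}

#' Additive composition of theories (WrapTheory)
#'
#' Defines an energy expression as a weighted sum of component theories
#' evaluated on the same fragment: \code{E = sum(w_i E_i)},
#' \code{grad = sum(w_i grad_i)}. Negative weights enable
#' delta-correction compositions.
#'
#' @param theories list of theory objects.
#' @param weights numeric weights, default all 1.
#' @return theory object of class \code{wrap_theory}.
#' @export
wrap_theory <- function(theories, weights = rep(1, length(theories))) {
  if (length(theories) < 1) stop("wrap_theory needs at least one component")
  if (length(weights) != length(theories)) stop("one weight per theory required")
  structure(list(theories = theories, weights = as.numeric(weights),
                 label = "WrapTheory"),
            class = c("wrap_theory", "mschem_theory"))
}

#' @export
supports_pointcharges.wrap_theory <- function(theory) {
  all(vapply(theory$theories, supports_pointcharges, logical(1)))
}

#' @export
evaluate.wrap_theory <- function(theory, frag, pointcharges = NULL,
                                 gradient = TRUE, ...) {
  e <- 0.0; g <- NULL; pcg <- NULL
  for (i in seq_along(theory$theories)) {
    w <- theory$weights[i]
    res <- evaluate(theory$theories[[i]], frag, pointcharges, gradient)
    e <- e + w * res$energy
    if (gradient) {
      if (is.null(res$gradient) || nrow(res$gradient) != n_atoms(frag)) {
        stop("component gradient shape mismatch in wrap_theory")
      }
      g <- if (is.null(g)) w * res$gradient else g + w * res$gradient
      if (!is.null(res$pc_gradient)) {
        pcg <- if (is.null(pcg)) w * res$pc_gradient else pcg + w * res$pc_gradient
      }
    }
  }
  theory_result(e, gradient = g, pc_gradient = pcg, label = theory$label)
}
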