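# Fragment: the molecular-system container every job and theory consumes.
# Coordinates are stored in Angstrom; indices are 0-based at the user
# interface of the CLI but 1-based inside R (standard R convention, stated
# in all docs).

#' Create a molecular fragment
#'
#' The central molecular-system container: element symbols, Cartesian
#' coordinates (Angstrom), per-atom masses (amu), total charge, spin
#' multiplicity, optional connectivity and optional per-atom partial
#' charges (used by MM theories and embedding).
#'
#' @param elements character vector of element symbols.
#' @param coords N x 3 numeric matrix of Cartesian coordinates in Angstrom.
#' @param charge integer total charge (e). Default 0.
#' @param mult integer spin multiplicity (2S+1), >= 1. Default 1.
#' @param masses optional numeric vector of per-atom masses in amu;
#'   defaulted from the bundled most-abundant-isotope table. Per-atom
#'   overrides enable isotope frequency shifts.
#' @param connectivity optional 2-column integer matrix of bonded atom
#'   pairs (1-based).
#' @param atom_charges optional per-atom partial charges in e.
#' @return an object of class \code{fragment}.
#' @export
fragment <- function(elements, coords, charge = 0, mult = 1,
                     masses = NULL, connectivity = NULL,
                     atom_charges = NULL) {
  elements <- normalize_element(elements)
  coords <- matrix(as.numeric(coords), ncol = 3)
  n <- length(elements)
  if (nrow(coords) != n) stop("coords row count does not match elements length")
  if (is.null(masses)) masses <- element_mass(elements)
  if (length(masses) != n) stop("masses length must equal atom count")
  if (any(!is.finite(masses)) || any(masses <= 0)) stop("masses must be strictly positive")
  if (mult < 1) stop("spin multiplicity must be >= 1")
  if (!is.null(connectivity)) {
    connectivity <- normalize_bonds(connectivity, n)
  }
  if (!is.null(atom_charges) && length(atom_charges) != n) {
    stop("atom_charges length must equal atom count")
  }
  structure(list(elements = elements, coords = coords,
                 masses = as.numeric(masses), charge = charge, mult = mult,
                 connectivity = connectivity,
                 atom_charges = if (is.null(atom_charges)) NULL else as.numeric(atom_charges)),
            class = "fragment")
}

# Canonical bond list: 2-column matrix, i < j, distinct in-range indices,
# duplicate-free under pair symmetry.
normalize_bonds <- function(bonds, n_atoms) {
  if (is.null(bonds) || length(bonds) == 0) {
    return(matrix(integer(0), ncol = 2, dimnames = list(NULL, c("i", "j"))))
  }
  bonds <- matrix(as.integer(bonds), ncol = 2)
  if (any(bonds < 1) || any(bonds > n_atoms)) stop("connectivity index out of range")
  if (any(bonds[, 1] == bonds[, 2])) stop("connectivity pair with identical indices")
  bonds <- t(apply(bonds, 1, sort))
  bonds <- unique(bonds)
  bonds <- bonds[order(bonds[, 1], bonds[, 2]), , drop = FALSE]
  dimnames(bonds) <- list(NULL, c("i", "j"))
  bonds
}

#' @export
print.fragment <- function(x, ...) {
  cat(sprintf("<fragment: %d atoms, charge %d, mult %d%s>\n",
              nrow(x$coords), x$charge, x$mult,
              if (!is.null(x$connectivity)) sprintf(", %d bonds", nrow(x$connectivity)) else ""))
  invisible(x)
}

#' Number of atoms in a fragment
#' @param frag a \code{fragment}.
#' @return integer atom count.
#' @export
n_atoms <- function(frag) nrow(frag$coords)

#' External point charges
#'
#' A set of external point charges (positions in Angstrom, charges in e)
#' passed to embedding-capable theories.
#'
#' @param positions M x 3 numeric matrix, Angstrom.
#' @param charges numeric vector of length M, elementary charge.
#' @return object of class \code{point_charges}.
#' @export
point_charges <- function(positions, charges) {
  positions <- matrix(as.numeric(positions), ncol = 3)
  if (nrow(positions) != length(charges)) {
    stop("positions row count must equal charges length")
  }
  structure(list(positions = positions, charges = as.numeric(charges)),
            class = "point_charges")
}

#' Read an XYZ file
#'
#' Standard 2-header-line XYZ dialect: atom count, comment, then
#' \code{element x y z} rows (Angstrom).
#'
#' @param path path to the file.
#' @param charge,mult total charge and multiplicity to attach (XYZ carries
#'   neither). Defaults 0 and 1.
#' @return a \code{fragment}.
#' @export
read_xyz <- function(path, charge = 0, mult = 1) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 1) stop("empty XYZ file")
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n) || n < 1) stop("malformed XYZ count line: ", lines[1])
  if (length(lines) < n + 2) stop("XYZ file has fewer atom rows than the count line states")
  rows <- lines[3:(n + 2)]
  toks <- strsplit(trimws(rows), "[[:space:]]+")
  bad <- vapply(toks, length, 0L) < 4
  if (any(bad)) stop("malformed XYZ atom row: ", rows[which(bad)[1]])
  el <- vapply(toks, `[[`, "", 1)
  xyz <- t(vapply(toks, function(t) as.numeric(t[2:4]), numeric(3)))
  if (any(!is.finite(xyz))) stop("unparseable coordinate in XYZ file")
  fragment(el, xyz, charge = charge, mult = mult)
}

#' Write an XYZ file
#'
#' @param frag a \code{fragment} (or bare N x 3 coordinate matrix together
#'   with \code{elements}).
#' @param path output path.
#' @param comment comment line.
#' @param append append as an extra frame (multi-frame XYZ trajectories).
#' @return the path, invisibly.
#' @export
write_xyz <- function(frag, path, comment = "", append = FALSE) {
  n <- n_atoms(frag)
  rows <- sprintf("%-3s %18.10f %18.10f %18.10f", frag$elements,
                  frag$coords[, 1], frag$coords[, 2], frag$coords[, 3])
  cat(c(n, comment, rows), file = path, sep = "\n", append = append)
  invisible(path)
}

# Element from a PDB atom name, used when columns 77-78 are blank.
# Two-letter elements are only accepted when the name starts in column 13
# (PDB convention); otherwise the first alphabetic character wins.
.pdb_name_element <- function(name_raw) {
  name <- gsub("[^A-Za-z]", "", name_raw)
  if (nchar(name) == 0) return(NA_character_)
  two <- normalize_element(substr(name, 1, 2))
  lead <- substr(name_raw, 1, 1) != " "   # starts in col 13 => possibly 2-letter
  if (lead && nchar(name) >= 2 && two %in% .element_table$symbol &&
      !(two %in% c("Ca", "Cd", "Nd", "Ne", "Hg", "He"))) {
    # ambiguous biomolecule names (" CA " = alpha carbon) carry a leading blank,
    # so a name starting at col 13 like "FE" is taken as the element
    return(two)
  }
  one <- normalize_element(substr(name, 1, 1))
  if (one %in% .element_table$symbol) one else NA_character_
}

#' Read a PDB file (ATOM/HETATM/CONECT subset)
#'
#' Fixed-column reading: coordinates from columns 31-54 (Angstrom),
#' element from columns 77-78 when present, else deduced from the atom
#' name. Altloc other than '' or 'A' is skipped; insertion codes are
#' ignored. CONECT records populate the connectivity.
#'
#' @param path path to the PDB file.
#' @param charge,mult total charge and multiplicity to attach.
#' @return a \code{fragment}.
#' @export
read_pdb <- function(path, charge = 0, mult = 1) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  atom_lines <- lines[rec %in% c("ATOM  ", "HETATM")]
  if (length(atom_lines) == 0) stop("no ATOM/HETATM records in ", path)
  altloc <- substr(atom_lines, 17, 17)
  keep <- altloc %in% c(" ", "", "A")
  atom_lines <- atom_lines[keep]
  serial <- suppressWarnings(as.integer(substr(atom_lines, 7, 11)))
  x <- suppressWarnings(as.numeric(substr(atom_lines, 31, 38)))
  y <- suppressWarnings(as.numeric(substr(atom_lines, 39, 46)))
  z <- suppressWarnings(as.numeric(substr(atom_lines, 47, 54)))
  if (any(is.na(x) | is.na(y) | is.na(z))) stop("unparseable coordinate field in PDB file")
  el_col <- trimws(substr(atom_lines, 77, 78))
  name_col <- substr(atom_lines, 13, 16)
  el <- character(length(atom_lines))
  for (k in seq_along(atom_lines)) {
    if (nchar(el_col[k]) > 0 && .is_known_element(el_col[k])) {
      el[k] <- normalize_element(el_col[k])
    } else {
      e <- .pdb_name_element(name_col[k])
      if (is.na(e)) stop("cannot deduce element for PDB atom name '", name_col[k], "'")
      el[k] <- e
    }
  }
  # CONECT: map serials to kept-row indices
  conect <- lines[rec == "CONECT"]
  bonds <- NULL
  if (length(conect) > 0) {
    idx_of_serial <- match(seq_len(max(serial, na.rm = TRUE)), serial)
    pairs <- list()
    for (ln in conect) {
      flds <- suppressWarnings(as.integer(substring(ln,
        seq(7, 27, by = 5), seq(11, 31, by = 5))))
      flds <- flds[!is.na(flds)]
      if (length(flds) >= 2) {
        a <- idx_of_serial[flds[1]]
        for (b_ser in flds[-1]) {
          b <- if (b_ser <= length(idx_of_serial)) idx_of_serial[b_ser] else NA
          if (!is.na(a) && !is.na(b)) pairs[[length(pairs) + 1]] <- c(a, b)
        }
      }
    }
    if (length(pairs) > 0) bonds <- do.call(rbind, pairs)
  }
  fragment(el, cbind(x, y, z), charge = charge, mult = mult, connectivity = bonds)
}

#' Detect covalent connectivity from geometry
#'
#' Pair (i, j) is bonded iff \code{|r_i - r_j| <= scale * (Rcov(i) + Rcov(j))}.
#'
#' @param frag a \code{fragment}.
#' @param scale positive scaling of the covalent-radius sum; default 1.2
#'   (the standard heuristic).
#' @return 2-column matrix of bonded pairs (i < j), duplicate-free.
#' @export
detect_connectivity <- function(frag, scale = 1.2) {
  stopifnot(scale > 0)
  n <- n_atoms(frag)
  r <- covalent_radius(frag$elements)
  if (n < 2) return(normalize_bonds(NULL, n))
  d <- as.matrix(stats::dist(frag$coords))
  thr <- outer(r, r, `+`) * scale
  hit <- which(d <= thr & upper.tri(d), arr.ind = TRUE)
  normalize_bonds(hit, n)
}

#' Attach detected connectivity to a fragment
#'
#' @param frag a \code{fragment}.
#' @param scale covalent-radius scaling, see \code{\link{detect_connectivity}}.
#' @return the fragment with its \code{connectivity} field set.
#' @export
with_connectivity <- function(frag, scale = 1.2) {
  if (is.null(frag$connectivity) || nrow(frag$connectivity) == 0) {
    frag$connectivity <- detect_connectivity(frag, scale)
  }
  frag
}

# --- internal geometry helpers (Angstrom / radians) ---

.dist <- function(coords, i, j) sqrt(sum((coords[i, ] - coords[j, ])^2))

.angle <- function(coords, i, j, k) {
  a <- coords[i, ] - coords[j, ]
  b <- coords[k, ] - coords[j, ]
  cosang <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  acos(pmin(1, pmax(-1, cosang)))
}

.dihedral <- function(coords, i, j, k, l) {
  b1 <- coords[j, ] - coords[i, ]
  b2 <- coords[k, ] - coords[j, ]
  b3 <- coords[l, ] - coords[k, ]
  n1 <- .cross3(b1, b2)
  n2 <- .cross3(b2, b3)
  m1 <- .cross3(n1, b2 / sqrt(sum(b2^2)))
  atan2(sum(m1 * n2), sum(n1 * n2))
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
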