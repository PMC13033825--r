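# Bundled element data: masses of the most abundant isotope (amu) and
# covalent radii (Angstrom, Cordero et al. 2008 compilation).  "D" is
# deuterium, "X" a massless-charge-free pseudo-atom used by the 2D test
# surfaces and point-like fixtures.

.element_table <- data.frame(
  symbol = c("H", "D", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne",
             "Na", "Mg", "Al", "Si", "P", "S", "Cl", "Ar", "K", "Ca",
             "Fe", "Cu", "Zn", "Br", "I", "X"),
  mass = c(1.00782503207, 2.01410177812, 4.002603254, 7.016004548,
           9.012182, 11.009305, 12.0, 14.003074005, 15.994914620,
           18.998403163, 19.992440175, 22.989769282, 23.985041697,
           26.981538530, 27.976926535, 30.973761998, 31.972071174,
           34.968852682, 39.962383124, 38.963706486, 39.962590863,
           55.934937475, 62.929597720, 63.929142220, 78.918337600,
           126.904473000, 1.0),
  covalent_radius = c(0.31, 0.31, 0.28, 1.28, 0.96, 0.84, 0.76, 0.71,
                      0.66, 0.57, 0.58, 1.66, 1.41, 1.21, 1.11, 1.07,
                      1.05, 1.02, 1.06, 2.03, 1.76, 1.32, 1.32, 1.22,
                      1.20, 1.39, 0.76),
  stringsAsFactors = FALSE
)

#' Normalize an element symbol ("FE" -> "Fe")
#'
#' @param sym character vector of element symbols.
#' @return normalized symbols.
#' @export
normalize_element <- function(sym) {
  sym <- trimws(sym)
  paste0(toupper(substr(sym, 1, 1)), tolower(substring(sym, 2)))
}

#' Look up element masses (amu, most abundant isotope)
#'
#' @param elements character vector of element symbols.
#' @return numeric vector of masses.
#' @export
element_mass <- function(elements) {
  elements <- normalize_element(elements)
  i <- match(elements, .element_table$symbol)
  if (anyNA(i)) {
    stop("unknown element symbol(s): ",
         paste(unique(elements[is.na(i)]), collapse = ", "))
  }
  .element_table$mass[i]
}

#' Look up covalent radii (Angstrom)
#'
#' @param elements character vector of element symbols.
#' @return numeric vector of covalent radii.
#' @export
covalent_radius <- function(elements) {
  elements <- normalize_element(elements)
  i <- match(elements, .element_table$symbol)
  if (anyNA(i)) {
    stop("no covalent radius for element(s): ",
         paste(unique(elements[is.na(i)]), collapse = ", "))
  }
  .element_table$covalent_radius[i]
}

.is_known_element <- function(elements) {
  normalize_element(elements) %in% .element_table$symbol
}
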