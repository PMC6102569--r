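# Standard average atomic masses (IUPAC 2021 abridged values, g/mol) and
# Bondi van der Waals radii (A). Both tables are deliberately small: the
# pipeline refuses to guess properties of elements it does not know.

.atomic_masses <- c(
  H = 1.008, He = 4.003, Li = 6.94, B = 10.81, C = 12.011, N = 14.007,
  O = 15.999, F = 18.998, Na = 22.990, Mg = 24.305, Al = 26.982,
  Si = 28.085, P = 30.974, S = 32.06, Cl = 35.45, K = 39.098,
  Ca = 40.078, Mn = 54.938, Fe = 55.845, Co = 58.933, Ni = 58.693,
  Cu = 63.546, Zn = 65.38, Se = 78.971, Br = 79.904, I = 126.904
)

.vdw_radii <- c(
  H = 1.20, C = 1.70, N = 1.55, O = 1.52, F = 1.47, P = 1.80,
  S = 1.80, Cl = 1.75, Br = 1.85, I = 1.98, Se = 1.90
)
.vdw_default <- 1.70

#' Standard average atomic mass of an element
#'
#' @param element Character vector of element symbols (case sensitive,
#'   e.g. `"C"`, `"Cl"`).
#' @return Numeric vector of masses in g/mol.
#' @export
element_mass <- function(element) {
  m <- .atomic_masses[element]
  if (anyNA(m)) {
    stop("unknown element(s): ",
         paste(unique(element[is.na(m)]), collapse = ", "))
  }
  unname(m)
}

#' Van der Waals radius of an element
#'
#' Bondi radii; elements absent from the table fall back to the carbon
#' radius of 1.70 A (pseudo-atoms in synthetic receptors use carbon anyway).
#'
#' @param element Character vector of element symbols.
#' @return Numeric vector of radii in Angstrom.
#' @export
vdw_radius <- function(element) {
  r <- .vdw_radii[element]
  r[is.na(r)] <- .vdw_default
  unname(r)
}

# Normalise an element symbol guessed from an atom name or SYBYL type.
.norm_element <- function(x) {
  x <- sub("\\..*$", "", x)          # strip SYBYL subtype, e.g. "C.ar"
  x <- gsub("[^A-Za-z]", "", x)
  substr(x, 1, 1) <- toupper(substr(x, 1, 1))
  if (any(nchar(x) > 1)) {
    i <- nchar(x) > 1
    x[i] <- paste0(substr(x[i], 1, 1), tolower(substr(x[i], 2, 2)))
  }
  # two-letter symbols that are really one-letter + label (e.g. "CA" calcium
  # vs C-alpha) cannot be disambiguated here; callers pass true symbols.
  x
}
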