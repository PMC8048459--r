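# Physical constants and element tables used across the package.
# Internal unit system: nm, kJ/mol, amu, e; angles in radians internally,
# degrees at I/O boundaries.

#' Unit-conversion and physical constants
#'
#' Single source of truth for every conversion constant the package uses,
#' so emitted parameters are reproducible to the digit.
#'
#' @format A named list with elements:
#' \describe{
#'   \item{hartree_to_kjmol}{1 Hartree in kJ/mol (2625.4996).}
#'   \item{bohr_to_nm}{1 Bohr in nm (0.0529177).}
#'   \item{angstrom_to_nm}{1 Angstrom in nm (0.1).}
#'   \item{c_cm_s}{Speed of light in cm/s.}
#'   \item{avogadro}{Avogadro constant, 1/mol.}
#'   \item{kjmol_nm2_amu_to_s2}{Scale from kJ mol^-1 nm^-2 amu^-1 to s^-2.}
#' }
#' @export
xlf_constants <- list(
  hartree_to_kjmol = 2625.4996,
  bohr_to_nm       = 0.0529177,
  angstrom_to_nm   = 0.1,
  c_cm_s           = 2.99792458e10,
  avogadro         = 6.02214076e23,
  # 1 kJ/mol = 1000/N_A J ; 1 amu = 1e-3/N_A kg ; 1 nm^2 = 1e-18 m^2
  # => (1000/N_A) / (1e-3/N_A) / 1e-18 = 1e24 s^-2
  kjmol_nm2_amu_to_s2 = 1e24
)

# Isotope-averaged atomic masses (amu), keyed by element symbol.
.element_masses <- c(
  H = 1.008, He = 4.0026, Li = 6.94, Be = 9.0122, B = 10.81, C = 12.011,
  N = 14.007, O = 15.999, F = 18.998, Ne = 20.180, Na = 22.990, Mg = 24.305,
  Al = 26.982, Si = 28.085, P = 30.974, S = 32.06, Cl = 35.45, Ar = 39.948,
  K = 39.098, Ca = 40.078, Fe = 55.845, Zn = 65.38, Se = 78.971, Br = 79.904,
  I = 126.90
)

# Covalent radii (nm), Cordero-style values, used for bond-graph inference.
.covalent_radii <- c(
  H = 0.031, He = 0.028, Li = 0.128, Be = 0.096, B = 0.084, C = 0.076,
  N = 0.071, O = 0.066, F = 0.057, Na = 0.166, Mg = 0.141, Al = 0.121,
  Si = 0.111, P = 0.107, S = 0.105, Cl = 0.102, K = 0.203, Ca = 0.176,
  Fe = 0.132, Zn = 0.122, Se = 0.120, Br = 0.120, I = 0.139
)

# Bondi van der Waals radii (nm), used as SASA atomic radii.
.vdw_radii <- c(
  H = 0.120, He = 0.140, C = 0.170, N = 0.155, O = 0.152, F = 0.147,
  Na = 0.227, Mg = 0.173, Si = 0.210, P = 0.180, S = 0.180, Cl = 0.175,
  K = 0.275, Br = 0.185, I = 0.198, Zn = 0.139, Se = 0.190
)

.element_numbers <- c(
  H = 1, He = 2, Li = 3, Be = 4, B = 5, C = 6, N = 7, O = 8, F = 9, Ne = 10,
  Na = 11, Mg = 12, Al = 13, Si = 14, P = 15, S = 16, Cl = 17, Ar = 18,
  K = 19, Ca = 20, Fe = 26, Zn = 30, Se = 34, Br = 35, I = 53
)

#' Look up isotope-averaged atomic masses
#'
#' @param element character vector of element symbols (e.g. \code{"C"}).
#' @return numeric vector of masses in amu.
#' @export
element_mass <- function(element) {
  m <- .element_masses[element]
  if (anyNA(m)) {
    stop("unknown element symbol(s): ",
         paste(unique(element[is.na(m)]), collapse = ", "))
  }
  unname(m)
}

#' Look up covalent radii
#'
#' @param element character vector of element symbols.
#' @return numeric vector of covalent radii in nm.
#' @export
covalent_radius <- function(element) {
  r <- .covalent_radii[element]
  if (anyNA(r)) {
    stop("no covalent radius for element(s): ",
         paste(unique(element[is.na(r)]), collapse = ", "))
  }
  unname(r)
}

#' Look up van der Waals (Bondi) radii
#'
#' @param element character vector of element symbols.
#' @return numeric vector of radii in nm.
#' @export
vdw_radius <- function(element) {
  r <- .vdw_radii[element]
  if (anyNA(r)) {
    stop("no van der Waals radius for element(s): ",
         paste(unique(element[is.na(r)]), collapse = ", "))
  }
  unname(r)
}

# Element symbol from atomic number.
element_from_number <- function(z) {
  sym <- names(.element_numbers)[match(z, .element_numbers)]
  if (anyNA(sym)) {
    stop("unknown atomic number(s): ", paste(unique(z[is.na(sym)]), collapse = ", "))
  }
  sym
}

# Guess an element symbol from an atom name ("OD1" -> "O", "HD12" -> "H").
element_from_name <- function(name) {
  lead <- sub("^[0-9]*", "", name)
  two <- substr(lead, 1, 2)
  two <- paste0(substr(two, 1, 1), tolower(substr(two, 2, 2)))
  ifelse(two %in% names(.element_masses) & nchar(lead) > 1 &
           !substr(lead, 1, 1) %in% c("H", "C", "N", "O", "P", "S") ,
         two, substr(lead, 1, 1))
}
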