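# Bundled periodic-table data: element symbols, single-bond covalent radii
# (Cordero et al. 2008 compilation, high-spin values for Mn/Fe/Co), and the
# AutoDock atom-type -> element map used by the PDBQT reader.

# Covalent radii in Angstrom, H through Rn.
.covalent_radii <- c(
  H = 0.31, He = 0.28, Li = 1.28, Be = 0.96, B = 0.84, C = 0.76, N = 0.71,
  O = 0.66, F = 0.57, Ne = 0.58, Na = 1.66, Mg = 1.41, Al = 1.21, Si = 1.11,
  P = 1.07, S = 1.05, Cl = 1.02, Ar = 1.06, K = 2.03, Ca = 1.76, Sc = 1.70,
  Ti = 1.60, V = 1.53, Cr = 1.39, Mn = 1.61, Fe = 1.52, Co = 1.50, Ni = 1.24,
  Cu = 1.32, Zn = 1.22, Ga = 1.22, Ge = 1.20, As = 1.19, Se = 1.20, Br = 1.20,
  Kr = 1.16, Rb = 2.20, Sr = 1.95, Y = 1.90, Zr = 1.75, Nb = 1.64, Mo = 1.54,
  Tc = 1.47, Ru = 1.46, Rh = 1.42, Pd = 1.39, Ag = 1.45, Cd = 1.44, In = 1.42,
  Sn = 1.39, Sb = 1.39, Te = 1.38, I = 1.39, Xe = 1.40, Cs = 2.44, Ba = 2.15,
  La = 2.07, Ce = 2.04, Pr = 2.03, Nd = 2.01, Pm = 1.99, Sm = 1.98, Eu = 1.98,
  Gd = 1.96, Tb = 1.94, Dy = 1.92, Ho = 1.92, Er = 1.89, Tm = 1.90, Yb = 1.87,
  Lu = 1.87, Hf = 1.75, Ta = 1.70, W = 1.62, Re = 1.51, Os = 1.44, Ir = 1.41,
  Pt = 1.36, Au = 1.36, Hg = 1.32, Tl = 1.45, Pb = 1.46, Bi = 1.48, Po = 1.40,
  At = 1.50, Rn = 1.50
)

# Radius used for elements absent from the table above (classic carbon-like
# fallback); a warning is emitted once per call into bond perception.
.fallback_radius <- 0.77

.known_elements <- names(.covalent_radii)

# AutoDock 4 atom types -> element. Types not listed here keep their verbatim
# string in the `autodock_type` column and fall back to name-based inference.
.autodock_type_to_element <- c(
  C = "C", A = "C", N = "N", "NA" = "N", NS = "N", OA = "O", OS = "O",
  SA = "S", S = "S", H = "H", HD = "H", HS = "H", P = "P", F = "F",
  Cl = "Cl", CL = "Cl", Br = "Br", BR = "Br", I = "I", Fe = "Fe", FE = "Fe",
  Zn = "Zn", ZN = "Zn", Mg = "Mg", MG = "Mg", Mn = "Mn", MN = "Mn",
  Ca = "Ca", CA = "Ca", W = "O"
)

#' Look up single-bond covalent radii for element symbols
#'
#' Unknown or empty symbols receive a 0.77 Angstrom fallback radius and raise
#' a warning, mirroring the permissive behaviour of distance-based bond
#' perception on incompletely annotated structures.
#'
#' @param elements Character vector of element symbols (canonical
#'   capitalization, e.g. `"C"`, `"Fe"`).
#' @return Numeric vector of radii in Angstrom.
#' @export
covalent_radius <- function(elements) {
  r <- unname(.covalent_radii[elements])
  bad <- is.na(r)
  if (any(bad)) {
    moltk_warn(
      "moltk_unknown_element",
      "unknown element(s) %s: using fallback covalent radius %.2f A",
      paste(unique(elements[bad]), collapse = ", "), .fallback_radius
    )
    r[bad] <- .fallback_radius
  }
  r
}

# Canonical capitalization: first letter upper, rest lower ("FE" -> "Fe").
canonical_element <- function(x) {
  x <- trimws(x)
  out <- ifelse(
    nchar(x) == 0L, "",
    paste0(toupper(substr(x, 1L, 1L)), tolower(substr(x, 2L, nchar(x))))
  )
  out
}

# Element inference when the PDB element column (77-78) is blank.
# Rule: strip digits and primes from the atom name; if the raw 4-char name
# field starts flush in its first column AND the first two characters of the
# stripped name form a known element symbol, use that element; otherwise use
# the first alphabetic character. Reproduces the PDB name-justification
# convention (" CA " is a C-alpha carbon, "CA  " is calcium).
infer_element_from_name <- function(raw_name_field) {
  vapply(raw_name_field, function(raw) {
    starts_col13 <- nchar(raw) > 0L && substr(raw, 1L, 1L) != " "
    stripped <- gsub("[0-9'\"*]", "", trimws(raw))
    if (nchar(stripped) == 0L) return("")
    if (starts_col13 && nchar(stripped) >= 2L) {
      two <- canonical_element(substr(stripped, 1L, 2L))
      if (two %in% .known_elements) return(two)
    }
    first_alpha <- regmatches(stripped, regexpr("[A-Za-z]", stripped))
    if (length(first_alpha) == 0L) return("")
    canonical_element(first_alpha)
  }, character(1L), USE.NAMES = FALSE)
}

# Map an AutoDock type string to an element; unmapped -> "".
autodock_element <- function(types) {
  out <- unname(.autodock_type_to_element[trimws(types)])
  out[is.na(out)] <- ""
  out
}
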