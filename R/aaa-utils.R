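# Small numeric and chemistry helpers shared across modules.

vnorm <- function(v) sqrt(sum(v^2))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a zero-length vector")
  v / n
}

#' Angle between two 3-vectors in degrees
#'
#' Returns the arc-cosine of the normalized dot product, reported in
#' \code{[0, 180]} degrees. Undefined (NA) if either vector has zero length.
#'
#' @param a,b numeric 3-vectors.
#' @return angle in degrees, or \code{NA_real_}.
#' @export
angle_between <- function(a, b) {
  na <- vnorm(a); nb <- vnorm(b)
  if (na < 1e-12 || nb < 1e-12) return(NA_real_)
  ct <- sum(a * b) / (na * nb)
  ct <- max(-1, min(1, ct))
  acos(ct) * 180 / pi
}

# Rotation matrix about an arbitrary unit axis (Rodrigues).
rotation_matrix <- function(axis, angle_deg) {
  u <- unitv(axis)
  th <- angle_deg * pi / 180
  c1 <- cos(th); s1 <- sin(th)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  K <- matrix(c(0, -uz, uy, uz, 0, -ux, -uy, ux, 0), 3, 3, byrow = TRUE)
  diag(3) * c1 + s1 * K + (1 - c1) * (u %o% u)
}

# Standard 3-letter -> 1-letter amino acid codes.
AA_THREE_TO_ONE <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V"
)

# Common modified residues mapped to their parent standard residue.
AA_PARENT <- c(
  MSE = "MET", SEC = "CYS", PYL = "LYS", SEP = "SER", TPO = "THR",
  PTR = "TYR", CSO = "CYS", HYP = "PRO", MLY = "LYS", FME = "MET"
)

# Covalent radii (Angstrom) used for bond inference on HET groups.
COVALENT_RADII <- c(
  H = 0.31, C = 0.77, N = 0.71, O = 0.66, P = 1.07, S = 1.05,
  F = 0.57, CL = 1.02, BR = 1.20, I = 1.39, SE = 1.20, B = 0.84,
  "NA" = 1.66, K = 2.03, MG = 1.41, CA = 1.76, ZN = 1.22, MN = 1.39,
  FE = 1.32, CO = 1.26, NI = 1.24, CU = 1.32, MO = 1.54, W = 1.62
)

METAL_ELEMENTS <- c("NA", "K", "MG", "CA", "ZN", "MN", "FE", "CO", "NI",
                    "CU", "MO", "W", "LI", "CD", "HG")

WATER_CODES <- c("HOH", "DOD", "WAT", "H2O")

# Element symbol guessed from a PDB atom name when the element column is
# blank: strip digits/primes, take the leading alphabetic token.
guess_element <- function(atom_name) {
  nm <- toupper(gsub("[^A-Za-z]", "", atom_name))
  if (nchar(nm) == 0) return("")
  two <- substr(nm, 1, 2)
  if (two %in% names(COVALENT_RADII) && two %in% c(METAL_ELEMENTS, "CL", "BR", "SE")) {
    return(two)
  }
  substr(nm, 1, 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
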