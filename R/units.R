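#' Unit conventions and physical constants
#'
#' All lengths handled by the package are in nanometres, all times in
#' picoseconds and all angles in degrees.  PDB files (which use
#' Angstroms) are converted at the I/O boundary.
#'
#' @name memtraj-units
#' @keywords internal
NULL

#' Conversion factor from Angstrom to nanometre
#' @keywords internal
ANGSTROM_PER_NM <- 10

#' Conversion factor from nm^2/ps to cm^2/s
#'
#' 1 nm^2 = 1e-14 cm^2 and 1 ps = 1e-12 s, hence
#' 1 nm^2 ps^-1 = 1e-14 / 1e-12 cm^2 s^-1 = 1e-2 cm^2 s^-1.
#'
#' @export
NM2_PER_PS_TO_CM2_PER_S <- 1e-2

#' Standard atomic masses (u) used for mass-weighted centroids
#' @keywords internal
.atomic_masses <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999,
  P = 30.974, S = 32.06, NA. = 22.990, CL = 35.45
)

#' Look up atomic masses for a vector of element symbols
#'
#' @param element character vector of element symbols (e.g. "C", "N").
#' @return numeric vector of masses in u.
#' @keywords internal
atomic_mass <- function(element) {
  key <- toupper(element)
  key[key == "NA"] <- "NA."
  m <- .atomic_masses[key]
  if (anyNA(m)) {
    stop("no mass tabulated for element(s): ",
         paste(unique(element[is.na(m)]), collapse = ", "))
  }
  unname(m)
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Angle between two vectors in degrees
#'
#' The dot product is clamped to [-1, 1] so that numerically degenerate
#' near-parallel vectors never produce NaN.
#'
#' @param u,v numeric vectors of length 3 (need not be unit length).
#' @return angle in degrees in [0, 180].
#' @keywords internal
vec_angle <- function(u, v) {
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("zero-length vector in angle computation")
  rad2deg(acos(max(-1, min(1, sum(u * v) / (nu * nv)))))
}
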