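#' Physical constants and unit conversions
#'
#' Conversion factors used throughout the package. All energies are carried
#' internally in kcal/mol and all lengths in Angstrom; parameter and energy
#' files declaring atomic units are converted once at the reading boundary.
#'
#' @format A named list with elements:
#' \describe{
#'   \item{hartree_kcal}{kcal/mol per hartree (627.509474)}
#'   \item{bohr_ang}{Angstrom per bohr (0.52917721)}
#' }
#' @export
d4_constants <- list(
  hartree_kcal = 627.509474,
  bohr_ang     = 0.52917721
)

# Standard atomic weights (u) for the symbols the XYZ reader recognizes.
# H and O are the working set; the rest let foreign XYZ files be read and
# re-emitted without claiming water-specific semantics for them.
.atomic_masses <- c(
  H = 1.008, He = 4.0026,
  Li = 6.94, Be = 9.0122, B = 10.81, C = 12.011, N = 14.007, O = 15.999,
  F = 18.998, Ne = 20.180,
  Na = 22.990, Mg = 24.305, Al = 26.982, Si = 28.085, P = 30.974,
  S = 32.06, Cl = 35.45, Ar = 39.948,
  K = 39.098, Ca = 40.078, Br = 79.904, I = 126.90
)

#' Reference gas-phase geometry of the water monomer
#'
#' The internal geometry of the isolated water molecule used as the reference
#' state for one-body (monomer deformation) energies: both O-H bonds at
#' `r_oh` and the H-O-H angle at `theta_hoh`.
#'
#' @param r_oh O-H bond length, Angstrom.
#' @param theta_hoh H-O-H angle, degrees.
#' @return An object of class `ref_geometry`.
#' @examples
#' ref_geometry()
#' @export
ref_geometry <- function(r_oh = 0.95865, theta_hoh = 104.348) {
  if (!is.finite(r_oh) || r_oh <= 0)
    d4_abort("r_oh must be a positive length", "d4tune_domain_error")
  if (!is.finite(theta_hoh) || theta_hoh <= 0 || theta_hoh >= 180)
    d4_abort("theta_hoh must lie in (0, 180) degrees", "d4tune_domain_error")
  structure(list(r_oh = r_oh, theta_hoh = theta_hoh), class = "ref_geometry")
}

#' @export
print.ref_geometry <- function(x, ...) {
  cat(sprintf("Water monomer reference geometry: r(OH) = %.5f A, HOH = %.3f deg\n",
              x$r_oh, x$theta_hoh))
  invisible(x)
}

# Signal a classed condition so callers (and the CLI) can map error kinds to
# exit codes without string matching.
d4_abort <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "d4tune_error", "error", "condition")))
}
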