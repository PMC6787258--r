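# Elastic-theory estimate of the protein surface density required to
# stabilize a membrane tube. Everything is in kBT units: the binding free
# energy comes out of the curvature analysis in kBT, and keeping the bending
# rigidity in the same unit removes temperature as a hidden parameter.

#' Helfrich bending-energy cost per area of a tube
#'
#' The elastic energy per unit area needed to bend a flat membrane into a
#' cylindrical tube of radius `R` (diameter `2R`):
#' \deqn{f_{tube}(R) = \frac{k_c}{2 R^2}}
#' with `k_c` the bending rigidity (about 20 kBT for fluid bilayers).
#'
#' @param kc Bending rigidity, kBT.
#' @param R Tube radius, nm.
#' @return Energy density in kBT / nm^2.
#' @export
#' @examples
#' tube_energy_density(kc = 20, R = 25)  # 0.016 kBT/nm^2
tube_energy_density <- function(kc, R) {
  if (any(!is.finite(kc)) || any(kc <= 0)) {
    rlang::abort("`kc` must be a positive bending rigidity in kBT.")
  }
  if (any(kc > 0 & !(R > 0))) rlang::abort("`R` must be a positive radius in nm.")
  kc / (2 * R^2)
}

#' Protein surface density required to stabilize a membrane tube
#'
#' Balances the Helfrich bending cost of the tube against the
#' curvature-dependent binding free energy gained per bound protein:
#' \deqn{\rho = \frac{f_{tube}(R_{bind})}{|\Delta G_{bind}|}}
#' giving the areal number density of proteins needed so that binding pays
#' for bending, and its reciprocal, the membrane area available per protein.
#'
#' @param kc Bending rigidity, kBT.
#' @param R_bind Radius of curvature at which the binding free energy was
#'   measured, nm.
#' @param dG_bind Binding free energy relative to a flat membrane, kBT;
#'   negative = favourable. May come straight from [binding_free_energy()].
#' @return A `tube_coverage` object: list with `kc`, `R_bind`, `dG_bind`,
#'   `f_tube` (kBT/nm^2), `rho` (1/nm^2) and `area_per_protein` (nm^2).
#' @export
#' @examples
#' required_density(kc = 20, R_bind = 25, dG_bind = -2)
required_density <- function(kc, R_bind, dG_bind) {
  if (dG_bind == 0) {
    rlang::abort(paste0(
      "`dG_bind` = 0: a protein with no curvature preference cannot pay the ",
      "bending cost at any density."
    ))
  }
  if (dG_bind > 0) {
    rlang::warn(paste0(
      "`dG_bind` > 0 (unfavourable binding): the coverage estimate is not ",
      "meaningful for a curvature-avoiding protein."
    ))
  }
  f_tube <- tube_energy_density(kc, R_bind)
  rho <- f_tube / abs(dG_bind)
  structure(
    list(kc = kc, R_bind = R_bind, dG_bind = dG_bind, f_tube = f_tube,
         rho = rho, area_per_protein = 1 / rho),
    class = "tube_coverage"
  )
}

#' @export
print.tube_coverage <- function(x, ...) {
  cat("<tube_coverage>\n")
  cat(sprintf("  k_c      = %g kBT    R_bind = %g nm    dG_bind = %g kBT\n",
              x$kc, x$R_bind, x$dG_bind))
  cat(sprintf("  f_tube   = %g kBT/nm^2\n", x$f_tube))
  cat(sprintf("  rho      = %g proteins/nm^2\n", x$rho))
  cat(sprintf("  area per protein = %g nm^2\n", x$area_per_protein))
  invisible(x)
}

#' @export
tidy.tube_coverage <- function(x, ...) {
  tibble::tibble(kc = x$kc, R_bind = x$R_bind, dG_bind = x$dG_bind,
                 f_tube = x$f_tube, rho = x$rho,
                 area_per_protein = x$area_per_protein)
}

#' @export
glance.tube_coverage <- function(x, ...) tidy.tube_coverage(x, ...)
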