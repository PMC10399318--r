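# Fluidized-bed design: Ergun minimum fluidization velocity and grain bulk
# density.

#' Fluidized-bed specification
#'
#' Grain and fluid properties of an air-fluidized granular bed. Defaults
#' describe the study's poppy-seed bed: 1 mm grains of material density
#' 983 kg/m^3 (bulk density ~570 kg/m^3 at loose packing fraction 0.58),
#' fluidized by 20 C air (density 1.2 kg/m^3, viscosity 1.8e-5 Pa s),
#' operated at a superficial velocity of 0.55 m/s.
#'
#' @param grain_diameter Mean grain diameter (m).
#' @param grain_density Grain material density (kg/m^3).
#' @param packing_fraction Solids volume fraction phi (0-1); the void
#'   fraction is `1 - phi`.
#' @param sphericity Grain sphericity (0-1].
#' @param fluid_density Fluid density (kg/m^3).
#' @param fluid_viscosity Dynamic viscosity (Pa s).
#' @param g Gravitational acceleration (m/s^2).
#' @param superficial_velocity Operating superficial velocity U (m/s).
#' @return A `bed_spec` object.
#' @export
bed_spec <- function(grain_diameter = 1e-3, grain_density = 570 / 0.58,
                     packing_fraction = 0.58, sphericity = 1,
                     fluid_density = 1.2, fluid_viscosity = 1.8e-5,
                     g = 9.81, superficial_velocity = 0.55) {
  stop_if(packing_fraction <= 0 || packing_fraction >= 1,
          "packing_fraction must be in (0, 1)")
  stop_if(sphericity <= 0 || sphericity > 1, "sphericity must be in (0, 1]")
  vals <- c(grain_diameter, grain_density, fluid_density, fluid_viscosity,
            g, superficial_velocity)
  stop_if(any(!is.finite(vals)) || any(vals <= 0),
          "all physical bed quantities must be positive")
  structure(list(grain_diameter = grain_diameter,
                 grain_density = grain_density,
                 packing_fraction = packing_fraction,
                 sphericity = sphericity, fluid_density = fluid_density,
                 fluid_viscosity = fluid_viscosity, g = g,
                 superficial_velocity = superficial_velocity),
            class = "bed_spec")
}

#' Minimum fluidization velocity (Ergun)
#'
#' Solves the Ergun packed-bed pressure-drop relation at minimum
#' fluidization, where drag balances the submerged weight of the bed:
#' \deqn{\frac{150\,\mu\,U\,(1-\varepsilon)^2}{\varepsilon^3 (\phi_s d)^2}
#'       + \frac{1.75\,\rho_f\,U^2\,(1-\varepsilon)}{\varepsilon^3 \phi_s d}
#'       = (\rho - \rho_f)\, g\, (1-\varepsilon)}
#' with void fraction `epsilon = 1 - packing_fraction`. The positive root
#' of this quadratic in U is returned in closed form. For the default
#' poppy-seed bed it comes to about 0.32 m/s. A bed whose grains are no
#' denser than the fluid needs no flow to fluidize: `Uf = 0` with a
#' warning.
#'
#' @param bed A [bed_spec()].
#' @return Minimum fluidization velocity Uf (m/s).
#' @examples
#' ergun_minimum_fluidization(bed_spec())
#' @export
ergun_minimum_fluidization <- function(bed) {
  stopifnot(inherits(bed, "bed_spec"))
  eps <- 1 - bed$packing_fraction
  d <- bed$sphericity * bed$grain_diameter
  drho <- bed$grain_density - bed$fluid_density
  if (drho <= 0) {
    warning("grain density does not exceed fluid density; Uf = 0",
            call. = FALSE)
    return(0)
  }
  A <- 1.75 * bed$fluid_density * (1 - eps) / (eps^3 * d)
  B <- 150 * bed$fluid_viscosity * (1 - eps)^2 / (eps^3 * d^2)
  C <- drho * bed$g * (1 - eps)
  (-B + sqrt(B^2 + 4 * A * C)) / (2 * A)
}

#' Operating-point fluidization ratio
#'
#' Ratio of the operating superficial velocity to the minimum
#' fluidization velocity; above 1 the bed is fluidized.
#'
#' @param bed A [bed_spec()].
#' @return `U / Uf` (dimensionless).
#' @export
fluidization_ratio <- function(bed) {
  bed$superficial_velocity / ergun_minimum_fluidization(bed)
}

#' Grain bulk density
#'
#' Bulk density of the packed grains, `phi * rho`.
#'
#' @param phi Packing fraction (0-1].
#' @param rho Grain material density (kg/m^3).
#' @return Bulk density (kg/m^3).
#' @export
bulk_density <- function(phi, rho) {
  stop_if(phi <= 0 || phi > 1, "phi must be in (0, 1]")
  phi * rho
}
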