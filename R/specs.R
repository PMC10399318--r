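# Parameter objects: bead geometry, chain layout, force constants, forcing.

stop_if <- function(cond, ...) if (isTRUE(cond)) stop(..., call. = FALSE)

#' Resin bead geometry and material
#'
#' Describes one 3D-printed resin bead: a hollow sphere with a cylindrical
#' protrusion, bored through along its axis so it can be strung on thread.
#' All lengths in metres, density in kg/m^3. Defaults are the study bead:
#' a 6 mm sphere with 0.4 mm walls, a 1.5 mm x 1.5 mm protrusion, a 1 mm
#' bore, printed in resin of density 1230 kg/m^3.
#'
#' @param outer_diameter Sphere outer diameter (m).
#' @param wall_thickness Shell wall thickness (m); at `outer_diameter/2` the
#'   sphere is solid.
#' @param protrusion_length,protrusion_diameter Cylindrical protrusion (m).
#' @param bore_diameter Axial threading hole diameter (m).
#' @param material_density Print material density (kg/m^3).
#' @return A `bead_spec` object.
#' @examples
#' bead_spec()
#' effective_bead_density(bead_spec(wall_thickness = 5e-4))
#' @export
bead_spec <- function(outer_diameter = 6e-3, wall_thickness = 4e-4,
                      protrusion_length = 1.5e-3, protrusion_diameter = 1.5e-3,
                      bore_diameter = 1e-3, material_density = 1230) {
  vals <- c(outer_diameter, wall_thickness, protrusion_length,
            protrusion_diameter, bore_diameter, material_density)
  stop_if(any(!is.finite(vals)) || any(vals <= 0),
          "all bead_spec fields must be positive and finite")
  stop_if(wall_thickness > outer_diameter / 2,
          "wall_thickness cannot exceed the sphere radius")
  stop_if(bore_diameter >= protrusion_diameter,
          "bore_diameter must be smaller than protrusion_diameter")
  stop_if(protrusion_diameter >= outer_diameter,
          "protrusion_diameter must be smaller than outer_diameter")
  structure(list(outer_diameter = outer_diameter,
                 wall_thickness = wall_thickness,
                 protrusion_length = protrusion_length,
                 protrusion_diameter = protrusion_diameter,
                 bore_diameter = bore_diameter,
                 material_density = material_density),
            class = "bead_spec")
}

#' Chain layout
#'
#' Describes the alternating crimp/bead chain: `n_beads` resin beads
#' alternating with `n_beads + 1` crimps, strung between two anchors with a
#' length `string_segment_length` of string at each end. Defaults are the
#' full study chain: 14 beads, 2 mm x 1.4 mm crimps, 12 mm string segments,
#' anchors 101 mm apart. `crimp_sim_diameter` is the diameter of the sphere
#' standing in for a crimp in simulation (1.5 mm).
#'
#' @param n_beads Number of resin beads (>= 1).
#' @param crimp_length,crimp_diameter Physical crimp cylinder (m).
#' @param crimp_sim_diameter Simulated crimp sphere diameter (m).
#' @param slack_length Free string length threaded into the chain (m).
#' @param string_segment_length Rest length of each end string segment (m).
#' @param anchor_separation Distance between the two fixed anchors (m).
#' @return A `chain_spec` object.
#' @export
chain_spec <- function(n_beads = 14, crimp_length = 1.4e-3,
                       crimp_diameter = 2e-3, crimp_sim_diameter = 1.5e-3,
                       slack_length = 0, string_segment_length = 1.2e-2,
                       anchor_separation = 0.101) {
  stop_if(!is.numeric(n_beads) || n_beads < 1 || n_beads != round(n_beads),
          "n_beads must be a positive integer")
  lens <- c(crimp_length, crimp_diameter, crimp_sim_diameter,
            slack_length, string_segment_length)
  stop_if(any(!is.finite(lens)) || any(lens < 0),
          "chain lengths must be non-negative and finite")
  stop_if(!is.finite(anchor_separation) || anchor_separation <= 0,
          "anchor_separation must be positive")
  structure(list(n_beads = as.integer(n_beads), crimp_length = crimp_length,
                 crimp_diameter = crimp_diameter,
                 crimp_sim_diameter = crimp_sim_diameter,
                 slack_length = slack_length,
                 string_segment_length = string_segment_length,
                 anchor_separation = anchor_separation),
            class = "chain_spec")
}

#' Force-field constants
#'
#' The five coefficients of the chain force field, all SI: `kl` (N/m) for the
#' harmonic stretch bonds, `ka` (N/rad, i.e. the harmonic angle constant in
#' the bending potential 0.5*ka*(theta - pi)^2) for the bending bonds, `ks`
#' (N/m) for the one-sided anchor strings, `kv` (N s/m) viscous damping, and
#' `kr` (N) the kick-force magnitude.
#'
#' The default damping, 5 N s/m, is the package's calibrated value for the
#' full chain study: it keeps the overdamped position update inside the
#' stability bound set by the stiffest bending mode while leaving velocity
#' relaxation far faster than one timestep, so bead velocities track the
#' kick forces (see the methods vignette for the derivation).
#'
#' @param kl Stretch bond stiffness (N/m).
#' @param ka Bending stiffness (N/rad).
#' @param ks String stiffness (N/m).
#' @param kv Viscous damping coefficient (N s/m).
#' @param kr Kick force scale (N).
#' @return A `force_field` object.
#' @export
force_field <- function(kl = 1, ka = 1e-2, ks = 5, kv = 5, kr = 1e-2) {
  vals <- c(kl = kl, ka = ka, ks = ks, kv = kv, kr = kr)
  stop_if(any(!is.finite(vals)) || any(vals < 0),
          "force-field coefficients must be non-negative and finite")
  structure(as.list(vals), class = "force_field")
}

#' Stochastic forcing model
#'
#' Kick forces applied to the chain every timestep: independent components
#' along x, y, z, drawn from a standard normal (`"gaussian"`) or a standard
#' Laplace distribution (`"laplace"`, built from two uniforms as
#' `-log(U1)` with the sign decided by `U2`), scaled by the force-field
#' coefficient `kr`. Kicks are redrawn once per timestep and held constant
#' within it.
#'
#' @param kind `"gaussian"` or `"laplace"`.
#' @param targets Which particles are kicked: `"all"` mobile particles
#'   (beads and crimps, the default, since both are immersed in the bed) or
#'   `"beads_only"`.
#' @param seed Optional integer seed recorded with the model; simulations
#'   seed the RNG from it when present.
#' @return A `forcing_model` object.
#' @export
forcing_model <- function(kind = c("laplace", "gaussian"),
                          targets = c("all", "beads_only"), seed = NULL) {
  kind <- match.arg(kind)
  targets <- match.arg(targets)
  if (!is.null(seed)) {
    stop_if(!is.numeric(seed) || length(seed) != 1 || !is.finite(seed),
            "seed must be a single integer")
    seed <- as.integer(seed)
  }
  structure(list(kind = kind, targets = targets, seed = seed),
            class = "forcing_model")
}

#' @export
print.bead_spec <- function(x, ...) {
  cat(sprintf("<bead_spec> sphere %.3g mm, wall %.3g mm, protrusion %.3g x %.3g mm, bore %.3g mm, material %.4g kg/m^3\n",
              x$outer_diameter * 1e3, x$wall_thickness * 1e3,
              x$protrusion_length * 1e3, x$protrusion_diameter * 1e3,
              x$bore_diameter * 1e3, x$material_density))
  invisible(x)
}

#' @export
print.chain_spec <- function(x, ...) {
  cat(sprintf("<chain_spec> %d beads / %d crimps, slack %.3g mm, string l0 %.3g mm, anchors %.3g mm apart\n",
              x$n_beads, x$n_beads + 1L, x$slack_length * 1e3,
              x$string_segment_length * 1e3, x$anchor_separation * 1e3))
  invisible(x)
}

#' @export
print.force_field <- function(x, ...) {
  cat(sprintf("<force_field> kl=%g N/m  ka=%g N/rad  ks=%g N/m  kv=%g N.s/m  kr=%g N\n",
              x$kl, x$ka, x$ks, x$kv, x$kr))
  invisible(x)
}

#' @export
print.forcing_model <- function(x, ...) {
  cat(sprintf("<forcing_model> %s kicks on %s%s\n", x$kind, x$targets,
              if (is.null(x$seed)) "" else sprintf(", seed %d", x$seed)))
  invisible(x)
}
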