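# Chain construction: alternating bead/crimp topology, chain geometry,
# hollow-bead density balancing.

#' Effective density of a hollow bead
#'
#' Ratio of the bead's material mass to the volume of its spherical
#' envelope. Material volume = spherical shell + protrusion cylinder - bore
#' cylinder, where the bore removes material along the axis over the length
#' it actually traverses (both shell walls plus the protrusion). With
#' `wall_thickness` equal to the sphere radius the shell term is the full
#' sphere. Setting the bead density is how the chain is made neutrally
#' buoyant in the fluidized bed (around 0.4 g/cm^3 for the study's bed).
#'
#' @param bead A [bead_spec()].
#' @return Effective density (kg/m^3).
#' @examples
#' # study bead: ~0.43 g/cm^3
#' effective_bead_density(bead_spec())
#' @export
effective_bead_density <- function(bead) {
  stopifnot(inherits(bead, "bead_spec"))
  R <- bead$outer_diameter / 2
  w <- bead$wall_thickness
  shell <- 4 / 3 * pi * (R^3 - (R - w)^3)
  protrusion <- pi * (bead$protrusion_diameter / 2)^2 * bead$protrusion_length
  bore <- pi * (bead$bore_diameter / 2)^2 * (2 * w + bead$protrusion_length)
  envelope <- 4 / 3 * pi * R^3
  (shell + protrusion - bore) * bead$material_density / envelope
}

#' Wall thickness achieving a target effective density
#'
#' Inverts [effective_bead_density()] in the wall thickness by root finding.
#' The density is strictly increasing in the wall thickness as long as the
#' sphere's inner cavity outgrows the bore cross-section (wall thickness
#' below `R - bore_radius/sqrt(2)`); beyond that, thicker walls mostly add
#' bore-drilled material and the map turns over, so the search is
#' restricted to the increasing branch. Used to tune the printed bead to
#' the bed's neutral-buoyancy density.
#'
#' @param bead A [bead_spec()]; its `wall_thickness` is ignored.
#' @param target Target effective density (kg/m^3); must lie strictly
#'   between the densities of the thinnest and the thickest feasible wall.
#' @return Wall thickness (m).
#' @examples
#' wall_thickness_for_target_density(bead_spec(), 429)
#' @export
wall_thickness_for_target_density <- function(bead, target) {
  stopifnot(inherits(bead, "bead_spec"))
  stop_if(!is.numeric(target) || length(target) != 1 || !is.finite(target) ||
            target <= 0 || target >= bead$material_density,
          "target density must lie strictly between 0 and the material density")
  R <- bead$outer_diameter / 2
  f <- function(w) {
    b <- bead
    b$wall_thickness <- w
    effective_bead_density(b) - target
  }
  lo <- R * 1e-9
  hi <- min(R, R - bead$bore_diameter / 2 / sqrt(2))
  if (f(lo) > 0) {
    stop("target density is below the minimum achievable for this geometry",
         call. = FALSE)
  }
  if (f(hi) < 0) {
    stop("target density exceeds that of the thickest-walled bead of this ",
         "geometry", call. = FALSE)
  }
  uniroot(f, c(lo, hi), tol = R * 1e-13)$root
}

#' End-to-end contact length of the physical chain
#'
#' The chain length with all elements in contact: each bead contributes its
#' sphere diameter plus protrusion length, each of the `n_beads + 1` crimps
#' its cylinder length, plus any threaded-in slack. The 14-bead study chain
#' comes to 126 mm.
#'
#' @param chain A [chain_spec()].
#' @param bead A [bead_spec()].
#' @return Length (m).
#' @export
chain_contact_length <- function(chain, bead) {
  stopifnot(inherits(chain, "chain_spec"), inherits(bead, "bead_spec"))
  n <- chain$n_beads
  n * (bead$outer_diameter + bead$protrusion_length) +
    (n + 1) * chain$crimp_length + chain$slack_length
}

#' Build the simulated chain topology
#'
#' Lays out the alternating crimp/bead chain (a chain of `N` beads has
#' `N + 1` crimps, starting and ending with a crimp) plus two immobile
#' anchors, and enumerates its bonds: `2N` stretch bonds between adjacent
#' particles with equilibrium length `rb + rt`, `2N - 1` bending bonds on
#' consecutive triples, and one string bond from each anchor to the nearest
#' end crimp. Initial positions place the chain straight along the
#' anchor-anchor axis (x), centred between the anchors.
#'
#' Particle masses default to `particle_density` times the sphere volume at
#' each particle's radius. The default density is the study's printed
#' simulation value; it is physically implausible (it yields sub-nanogram
#' beads) but, combined with the damping, is precisely what puts velocity
#' relaxation far below one timestep so that bead velocities mirror the
#' kick forces. Override per-kind masses with `mass_bead` / `mass_crimp`.
#'
#' @param chain A [chain_spec()].
#' @param bead A [bead_spec()]; its outer radius is the simulated bead
#'   radius `rb`.
#' @param force_params A [force_field()]; bond stiffnesses are copied into
#'   the bond tables.
#' @param particle_density Simulated particle density (kg/m^3).
#' @param mass_bead,mass_crimp Optional explicit masses (kg) overriding the
#'   density-derived values.
#' @return A `chain_topology`: list with `particles` (data frame: kind,
#'   radius, mass, x, y, z, mobile), `linear_bonds`, `angular_bonds`,
#'   `string_bonds` data frames, and the input specs. The attribute
#'   `"taut"` flags anchors farther apart than the chain plus both strings
#'   can span.
#' @examples
#' topo <- build_topology(chain_spec(n_beads = 2), bead_spec(), force_field())
#' topo
#' @export
build_topology <- function(chain, bead, force_params,
                           particle_density = 5e-3,
                           mass_bead = NULL, mass_crimp = NULL) {
  stopifnot(inherits(chain, "chain_spec"), inherits(bead, "bead_spec"),
            inherits(force_params, "force_field"))
  stop_if(!is.finite(particle_density) || particle_density <= 0,
          "particle_density must be positive")
  N <- chain$n_beads
  rb <- bead$outer_diameter / 2
  rt <- chain$crimp_sim_diameter / 2
  n_mobile <- 2L * N + 1L

  kind <- c("anchor", rep(c("crimp", "bead"), N), "crimp", "anchor")
  radius <- ifelse(kind == "bead", rb, ifelse(kind == "crimp", rt, 0))
  mass <- particle_density * 4 / 3 * pi * radius^3
  if (!is.null(mass_bead)) mass[kind == "bead"] <- mass_bead
  if (!is.null(mass_crimp)) mass[kind == "crimp"] <- mass_crimp
  stop_if(any(mass[kind != "anchor"] <= 0),
          "all mobile particle masses must be positive")
  mass[kind == "anchor"] <- Inf

  # straight along x, centred between the anchors
  span <- 2 * N * (rb + rt)
  x <- numeric(length(kind))
  x[1] <- -chain$anchor_separation / 2
  x[length(x)] <- chain$anchor_separation / 2
  x[2:(length(x) - 1)] <- seq(-span / 2, span / 2, length.out = n_mobile)
  particles <- data.frame(kind = kind, radius = radius, mass = mass,
                          x = x, y = 0, z = 0, mobile = kind != "anchor")

  mob <- which(particles$mobile)
  linear_bonds <- data.frame(i = mob[-length(mob)], j = mob[-1],
                             stiffness = force_params$kl, r0 = rb + rt)
  angular_bonds <- if (n_mobile >= 3) {
    data.frame(i = mob[1:(n_mobile - 2)], j = mob[2:(n_mobile - 1)],
               k = mob[3:n_mobile], stiffness = force_params$ka)
  } else {
    data.frame(i = integer(), j = integer(), k = integer(),
               stiffness = numeric())
  }
  string_bonds <- data.frame(anchor = c(1L, length(kind)),
                             particle = c(mob[1], mob[n_mobile]),
                             stiffness = force_params$ks,
                             l0 = chain$string_segment_length)

  taut <- chain$anchor_separation >
    span + 2 * chain$string_segment_length
  if (taut) {
    warning("anchors are farther apart than the chain plus both strings can ",
            "span; the chain starts taut", call. = FALSE)
  }
  structure(list(particles = particles, linear_bonds = linear_bonds,
                 angular_bonds = angular_bonds, string_bonds = string_bonds,
                 chain = chain, bead = bead, force_field = force_params),
            class = "chain_topology", taut = taut)
}

#' @export
print.chain_topology <- function(x, ...) {
  p <- x$particles
  cat(sprintf("<chain_topology> %d beads, %d crimps, %d anchors\n",
              sum(p$kind == "bead"), sum(p$kind == "crimp"),
              sum(p$kind == "anchor")))
  cat(sprintf("  bonds: %d stretch, %d bending, %d string\n",
              nrow(x$linear_bonds), nrow(x$angular_bonds),
              nrow(x$string_bonds)))
  cat(sprintf("  bond span %.1f mm between anchors %.1f mm apart%s\n",
              (max(p$x[p$mobile]) - min(p$x[p$mobile])) * 1e3,
              x$chain$anchor_separation * 1e3,
              if (isTRUE(attr(x, "taut"))) " (taut)" else ""))
  invisible(x)
}

#' Serialize a chain topology to YAML
#'
#' Writes the particle and bond tables (plus specs) as a YAML document, and
#' reads them back. Round trips exactly up to numeric printing precision.
#'
#' @param topology A `chain_topology`.
#' @param path File path.
#' @return `write_topology()` returns `path` invisibly; `read_topology()`
#'   the `chain_topology`.
#' @export
write_topology <- function(topology, path) {
  stopifnot(inherits(topology, "chain_topology"))
  doc <- list(
    chain = unclass(topology$chain),
    bead = unclass(topology$bead),
    force_field = unclass(topology$force_field),
    particles = as.list(topology$particles),
    linear_bonds = as.list(topology$linear_bonds),
    angular_bonds = as.list(topology$angular_bonds),
    string_bonds = as.list(topology$string_bonds),
    taut = isTRUE(attr(topology, "taut")))
  yaml::write_yaml(doc, path, precision = 15)
  invisible(path)
}

#' @rdname write_topology
#' @export
read_topology <- function(path) {
  doc <- yaml::read_yaml(path)
  need <- c("chain", "bead", "force_field", "particles", "linear_bonds",
            "angular_bonds", "string_bonds")
  missing <- setdiff(need, names(doc))
  stop_if(length(missing) > 0,
          "topology document is missing fields: ",
          paste(missing, collapse = ", "))
  topo <- list(
    particles = as.data.frame(doc$particles),
    linear_bonds = as.data.frame(doc$linear_bonds),
    angular_bonds = as.data.frame(lapply(doc$angular_bonds, unlist)),
    string_bonds = as.data.frame(doc$string_bonds),
    chain = structure(doc$chain, class = "chain_spec"),
    bead = structure(doc$bead, class = "bead_spec"),
    force_field = structure(doc$force_field, class = "force_field"))
  # YAML has no Inf literal guarantee across emitters; restore anchor masses
  topo$particles$mass[topo$particles$kind == "anchor"] <- Inf
  structure(topo, class = "chain_topology", taut = isTRUE(doc$taut))
}
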