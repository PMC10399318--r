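# Shared fixtures: small chains, a free kicked particle, quick configs.

# small chain with anchors placed 2 mm beyond each end crimp (strings
# slack at rest, as in the full study geometry)
quick_topology <- function(n_beads = 2, ff = force_field(), ...) {
  sep <- 2 * n_beads * 3.75e-3 + 2 * 2e-3
  build_topology(chain_spec(n_beads = n_beads, anchor_separation = sep, ...),
                 bead_spec(), ff)
}

# a single mobile particle with no bonds: pure kick + damping dynamics
free_particle_topology <- function(mass = 1e-9, ff = force_field()) {
  particles <- data.frame(kind = "bead", radius = 1e-3, mass = mass,
                          x = 0, y = 0, z = 0, mobile = TRUE)
  empty_lin <- data.frame(i = integer(), j = integer(),
                          stiffness = numeric(), r0 = numeric())
  empty_ang <- data.frame(i = integer(), j = integer(), k = integer(),
                          stiffness = numeric())
  empty_str <- data.frame(anchor = integer(), particle = integer(),
                          stiffness = numeric(), l0 = numeric())
  structure(list(particles = particles, linear_bonds = empty_lin,
                 angular_bonds = empty_ang, string_bonds = empty_str,
                 chain = chain_spec(n_beads = 1), bead = bead_spec(),
                 force_field = ff),
            class = "chain_topology", taut = FALSE)
}

# randomly bent copy of a topology (for gradient / energy tests)
perturb_topology <- function(topo, amplitude, seed = 1) {
  set.seed(seed)
  p <- topo$particles
  n <- sum(p$mobile)
  p[p$mobile, c("x", "y", "z")] <- p[p$mobile, c("x", "y", "z")] +
    matrix(rnorm(3 * n, sd = amplitude), n, 3)
  topo$particles <- p
  topo
}

laplace_cdf <- function(q) ifelse(q < 0, 0.5 * exp(q), 1 - 0.5 * exp(-q))
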