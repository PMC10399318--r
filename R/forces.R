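# The chain force laws and the stochastic kick generator, as plain R
# functions. run_simulation() uses a compiled implementation of the same
# laws; these are the reference forms used directly by integrate_step(),
# system_energy() and the tests.

unit_or_stop <- function(u, name) {
  stop_if(length(u) != 3 || any(!is.finite(u)), name, " must be a finite 3-vector")
  n <- sqrt(sum(u^2))
  stop_if(abs(n - 1) > 1e-8, name, " must have unit norm")
  u
}

#' Stretch-bond restoring force
#'
#' Harmonic restoring force on the bond between two adjacent particles:
#' magnitude `kl * |R - (rb + rt)|`, zero at the equilibrium separation
#' `rb + rt`, directed along `rhat` (toward the neighbour) when the bond is
#' stretched and opposite when compressed -- the exact negative gradient of
#' the bond potential `0.5 * kl * (R - rb - rt)^2` with respect to this
#' particle's position. At exactly coincident centers the direction is
#' undefined and a zero force is returned with a warning.
#'
#' @param R Center-to-center distance (m).
#' @param rb,rt Bead and crimp radii (m); their sum is the equilibrium
#'   separation.
#' @param kl Stiffness (N/m).
#' @param rhat Unit vector toward the adjacent particle.
#' @return Force 3-vector (N).
#' @export
linear_bond_force <- function(R, rb, rt, kl, rhat) {
  if (R == 0) {
    warning("coincident bond partners: direction undefined, returning zero force",
            call. = FALSE)
    return(c(0, 0, 0))
  }
  stop_if(R < 0, "distance R must be non-negative")
  rhat <- unit_or_stop(rhat, "rhat")
  kl * (R - (rb + rt)) * rhat
}

#' Bending (angular) bond forces on a particle triple
#'
#' Exact negative gradient of the bending potential
#' `0.5 * ka * (theta - pi)^2`, where `theta` is the angle at the central
#' particle `j` formed with neighbours `i` and `k`. The end particles feel
#' forces of magnitude `ka * |theta - pi| / arm` perpendicular to their
#' arms, in the bending plane, directed so as to straighten the triple; the
#' central particle balances them (the triple's net force is zero). At
#' `theta == pi` the bending plane is undefined and no torque is needed:
#' all three forces are zero.
#'
#' @param xi,xj,xk Positions (3-vectors, m) of the two ends and the center.
#' @param ka Bending stiffness (N/rad).
#' @return List with force 3-vectors `fi`, `fj`, `fk` (N) and `theta` (rad).
#' @export
angular_bond_force <- function(xi, xj, xk, ka) {
  a <- xi - xj
  b <- xk - xj
  la <- sqrt(sum(a^2))
  lb <- sqrt(sum(b^2))
  stop_if(la == 0 || lb == 0, "angle bond with zero-length arm")
  ah <- a / la
  bh <- b / lb
  ct <- max(-1, min(1, sum(ah * bh)))
  st <- sqrt(max(1 - ct^2, 0))
  theta <- acos(ct)
  if (st < 1e-12) {
    z <- c(0, 0, 0)
    return(list(fi = z, fj = z, fk = z, theta = theta))
  }
  dU <- ka * (theta - pi)
  fi <- -dU / (la * st) * (ct * ah - bh)
  fk <- -dU / (lb * st) * (ct * bh - ah)
  list(fi = fi, fj = -(fi + fk), fk = fk, theta = theta)
}

#' One-sided string force from an anchor
#'
#' Zero while the string is slack (`l <= l0`); a linear restoring force
#' `-ks * (l - l0) * lhat` pulling the end particle back toward the anchor
#' once taut. Continuous at `l0`.
#'
#' @param l Anchor-to-particle distance (m).
#' @param l0 String rest length (m).
#' @param ks Stiffness (N/m).
#' @param lhat Unit vector from anchor to particle.
#' @return Force 3-vector (N).
#' @export
string_anchor_force <- function(l, l0, ks, lhat) {
  stop_if(l < 0, "distance l must be non-negative")
  if (l <= l0) return(c(0, 0, 0))
  lhat <- unit_or_stop(lhat, "lhat")
  -ks * (l - l0) * lhat
}

#' Viscous damping force
#'
#' `-kv * v`, applied to every mobile particle (beads and crimps alike).
#'
#' @param v Velocity 3-vector (m/s).
#' @param kv Damping coefficient (N s/m).
#' @return Force 3-vector (N).
#' @export
damping_force <- function(v, kv) -kv * v

#' Kick force from a dimensionless draw
#'
#' Scales a dimensionless random 3-vector `P` by the kick magnitude `kr`,
#' componentwise in the fixed laboratory frame. The draw is held constant
#' within one timestep.
#'
#' @param P Dimensionless 3-vector (one row of [sample_noise()]).
#' @param kr Kick magnitude (N).
#' @return Force 3-vector (N).
#' @export
kick_force <- function(P, kr) kr * P

#' Standard Laplace deviate from two uniforms
#'
#' `-log(u1)` when `u2 <= 0.5`, `+log(u1)` otherwise: an exponential
#' magnitude with a fair sign, i.e. a standard Laplace (double exponential)
#' variate with location 0 and scale 1.
#'
#' @param u1,u2 Uniform(0,1) draws (vectorized).
#' @return Laplace(0,1) deviates.
#' @export
laplace_from_uniform <- function(u1, u2) {
  ifelse(u2 <= 0.5, -log(u1), log(u1))
}

#' Sample dimensionless kick components
#'
#' Draws an `n x 3` matrix of independent dimensionless kick components,
#' one row per kicked particle: standard normal for the Gaussian model,
#' standard Laplace (via [laplace_from_uniform()]) for the Laplace model.
#' Components are drawn particle-by-particle, x then y then z, with the
#' Laplace branch consuming its two uniforms per component in order --
#' the same stream order as the compiled integrator, so R-level and
#' compiled runs are reproducible against each other under one seed.
#'
#' @param model A [forcing_model()].
#' @param n Number of rows (kicked particles).
#' @return `n x 3` numeric matrix.
#' @export
sample_noise <- function(model, n) {
  stopifnot(inherits(model, "forcing_model"))
  if (n == 0) return(matrix(numeric(), 0, 3))
  if (model$kind == "gaussian") {
    P <- rnorm(3 * n)
  } else {
    u <- runif(6 * n)
    u1 <- u[seq(1, 6 * n, by = 2)]
    u2 <- u[seq(2, 6 * n, by = 2)]
    P <- laplace_from_uniform(u1, u2)
  }
  matrix(P, nrow = n, ncol = 3, byrow = TRUE,
         dimnames = list(NULL, c("x", "y", "z")))
}

# --- assembled conservative forces and potentials over a whole topology ---

# positions: n x 3 matrix. Returns n x 3 matrix of bonded (conservative)
# forces: stretch + bending + string. Kicks and damping are not included.
assemble_forces <- function(positions, topology) {
  ff <- topology$force_field
  n <- nrow(positions)
  F <- matrix(0, n, 3)
  lb <- topology$linear_bonds
  for (b in seq_len(nrow(lb))) {
    i <- lb$i[b]; j <- lb$j[b]
    d <- positions[j, ] - positions[i, ]
    R <- sqrt(sum(d^2))
    if (R == 0) next
    f_i <- lb$stiffness[b] * (R - lb$r0[b]) * d / R  # -kl (R - r0) rhat, rhat = d/R
    F[i, ] <- F[i, ] + f_i
    F[j, ] <- F[j, ] - f_i
  }
  ab <- topology$angular_bonds
  for (b in seq_len(nrow(ab))) {
    out <- angular_bond_force(positions[ab$i[b], ], positions[ab$j[b], ],
                              positions[ab$k[b], ], ab$stiffness[b])
    F[ab$i[b], ] <- F[ab$i[b], ] + out$fi
    F[ab$j[b], ] <- F[ab$j[b], ] + out$fj
    F[ab$k[b], ] <- F[ab$k[b], ] + out$fk
  }
  sb <- topology$string_bonds
  for (b in seq_len(nrow(sb))) {
    a <- sb$anchor[b]; p <- sb$particle[b]
    d <- positions[p, ] - positions[a, ]
    l <- sqrt(sum(d^2))
    if (l > sb$l0[b]) {
      F[p, ] <- F[p, ] - sb$stiffness[b] * (l - sb$l0[b]) * d / l
    }
  }
  F
}

# total bonded potential energy at given positions (J)
potential_energy <- function(positions, topology) {
  U <- 0
  lb <- topology$linear_bonds
  for (b in seq_len(nrow(lb))) {
    R <- sqrt(sum((positions[lb$j[b], ] - positions[lb$i[b], ])^2))
    U <- U + 0.5 * lb$stiffness[b] * (R - lb$r0[b])^2
  }
  ab <- topology$angular_bonds
  for (b in seq_len(nrow(ab))) {
    out <- angular_bond_force(positions[ab$i[b], ], positions[ab$j[b], ],
                              positions[ab$k[b], ], 0)
    U <- U + 0.5 * ab$stiffness[b] * (out$theta - pi)^2
  }
  sb <- topology$string_bonds
  for (b in seq_len(nrow(sb))) {
    l <- sqrt(sum((positions[sb$particle[b], ] - positions[sb$anchor[b], ])^2))
    if (l > sb$l0[b]) U <- U + 0.5 * sb$stiffness[b] * (l - sb$l0[b])^2
  }
  U
}
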