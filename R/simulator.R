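# Time integration of the chain under bonds + damping + kicks.

#' Simulation configuration
#'
#' Defaults follow the chain study: 1e-4 s timestep, 4e5 steps with the
#' first 1e5 discarded as equilibration, and every 100th step recorded
#' (3,000 frames over the 30 s production window).
#'
#' @param timestep Integration timestep (s).
#' @param n_steps Total number of steps.
#' @param equilibration_steps Steps discarded before recording begins.
#' @param record_stride Record every `record_stride`-th step.
#' @param seed Integer seed for the kick stream; `NULL` leaves the RNG
#'   state alone.
#' @param integrator `"split_damping"` (velocity Verlet for conservative +
#'   kick forces with an exact exponential damping sub-step per half step;
#'   stable for arbitrarily strong damping, reduces to velocity Verlet as
#'   `kv -> 0`) or `"verlet"` (damping treated as an ordinary semi-explicit
#'   force; only valid when `kv * dt / m` is small).
#' @return A `sim_config` object.
#' @export
sim_config <- function(timestep = 1e-4, n_steps = 4e5,
                       equilibration_steps = 1e5, record_stride = 100,
                       seed = NULL,
                       integrator = c("split_damping", "verlet")) {
  integrator <- match.arg(integrator)
  stop_if(!is.finite(timestep) || timestep <= 0, "timestep must be positive")
  stop_if(n_steps < 1 || n_steps != round(n_steps),
          "n_steps must be a positive integer")
  stop_if(equilibration_steps < 0 || equilibration_steps >= n_steps,
          "equilibration_steps must be in [0, n_steps)")
  stop_if(record_stride < 1 || record_stride != round(record_stride),
          "record_stride must be a positive integer")
  if (!is.null(seed)) seed <- as.integer(seed)
  structure(list(timestep = timestep, n_steps = as.integer(n_steps),
                 equilibration_steps = as.integer(equilibration_steps),
                 record_stride = as.integer(record_stride), seed = seed,
                 integrator = integrator),
            class = "sim_config")
}

kick_targets <- function(topology, forcing) {
  p <- topology$particles
  if (is.null(forcing)) return(rep(FALSE, nrow(p)))
  if (forcing$targets == "beads_only") p$kind == "bead" else p$mobile
}

#' Run a chain simulation
#'
#' Integrates the chain under the bonded, damping and kick forces and
#' returns the post-equilibration trajectory, sampled every
#' `record_stride` steps. Runs are reproducible: the same seed, topology,
#' force field and configuration give bit-identical trajectories. Anchors
#' never move.
#'
#' @param topology A [build_topology()] result.
#' @param forcing A [forcing_model()], or `NULL` for no kicks.
#' @param config A [sim_config()].
#' @return A `trajectory`: list with `times` (s), `positions` and
#'   `velocities` (`frames x particles x 3` arrays, m and m/s), the
#'   `particles` table, and the `config`, `forcing` and `force_field` used.
#' @examples
#' topo <- build_topology(chain_spec(n_beads = 2), bead_spec(), force_field())
#' traj <- run_simulation(topo, forcing_model("laplace"),
#'                        sim_config(n_steps = 2000, equilibration_steps = 500,
#'                                   record_stride = 10, seed = 1))
#' dim(traj$velocities)
#' @export
run_simulation <- function(topology, forcing = forcing_model(),
                           config = sim_config()) {
  stopifnot(inherits(topology, "chain_topology"), inherits(config, "sim_config"))
  if (!is.null(forcing)) stopifnot(inherits(forcing, "forcing_model"))
  p <- topology$particles
  ff <- topology$force_field
  seed <- if (!is.null(config$seed)) config$seed else forcing$seed
  if (!is.null(seed)) set.seed(seed)
  kick_kind <- if (is.null(forcing)) 0L else
    switch(forcing$kind, gaussian = 1L, laplace = 2L)
  x0 <- as.matrix(p[, c("x", "y", "z")])
  v0 <- matrix(0, nrow(p), 3)
  res <- .cpp_run_chain(
    x0, p$mass, p$mobile, kick_targets(topology, forcing),
    as.integer(topology$linear_bonds$i - 1L),
    as.integer(topology$linear_bonds$j - 1L),
    topology$linear_bonds$r0,
    as.integer(topology$angular_bonds$i - 1L),
    as.integer(topology$angular_bonds$j - 1L),
    as.integer(topology$angular_bonds$k - 1L),
    as.integer(topology$string_bonds$anchor - 1L),
    as.integer(topology$string_bonds$particle - 1L),
    topology$string_bonds$l0,
    ff$kl, ff$ka, ff$ks, ff$kv, ff$kr, kick_kind,
    config$timestep, config$n_steps, config$equilibration_steps,
    config$record_stride,
    if (config$integrator == "split_damping") 1L else 0L,
    v0)
  dn <- list(NULL, NULL, c("x", "y", "z"))
  dimnames(res$positions) <- dn
  dimnames(res$velocities) <- dn
  structure(list(times = res$times, positions = res$positions,
                 velocities = res$velocities, particles = p,
                 config = config, forcing = forcing, force_field = ff,
                 topology = topology),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d frames x %d particles, t = %.4g..%.4g s (stride %d x %.3g s)\n",
              length(x$times), dim(x$positions)[2],
              if (length(x$times)) min(x$times) else NA,
              if (length(x$times)) max(x$times) else NA,
              x$config$record_stride, x$config$timestep))
  invisible(x)
}

#' Advance one timestep (reference implementation)
#'
#' A plain-R single step of the same schemes as [run_simulation()]'s
#' compiled core, operating on a state list. Useful for tests and for
#' inspecting the integrator; `run_simulation()` is the fast path.
#'
#' The `split_damping` scheme replaces each velocity-Verlet half update by
#' the exact solution of `m dv/dt = F - kv v` over `dt/2` with the
#' non-damping force `F` held constant, so its fixed point under constant
#' force is exactly `F / kv` and it is stable for arbitrarily strong
#' damping.
#'
#' @param state List with `positions` and `velocities` (`n x 3` matrices).
#' @param topology A `chain_topology`.
#' @param kick Either `NULL` (no kicks), or an `n x 3` matrix of kick
#'   forces (N) held constant across the step.
#' @param dt Timestep (s).
#' @param integrator `"split_damping"` or `"verlet"`.
#' @return Updated state list.
#' @export
integrate_step <- function(state, topology, kick = NULL, dt,
                           integrator = c("split_damping", "verlet")) {
  integrator <- match.arg(integrator)
  p <- topology$particles
  ff <- topology$force_field
  x <- state$positions
  v <- state$velocities
  stop_if(any(!is.finite(x)) || any(!is.finite(v)),
          "non-finite state entering integrate_step")
  n <- nrow(p)
  if (is.null(kick)) kick <- matrix(0, n, 3)
  mob <- p$mobile
  m <- p$mass

  half <- function(v, F) {
    if (integrator == "split_damping") {
      if (ff$kv > 0) {
        gh <- ff$kv * dt / (2 * m)
        dec <- exp(-gh)
        em <- -expm1(-gh)
        v[mob, ] <- v[mob, ] * dec[mob] + (F[mob, ] / ff$kv) * em[mob]
      } else {
        v[mob, ] <- v[mob, ] + F[mob, ] * dt / (2 * m[mob])
      }
    } else {
      v[mob, ] <- v[mob, ] + (F[mob, ] - ff$kv * v[mob, ]) * dt / (2 * m[mob])
    }
    v
  }
  F1 <- assemble_forces(x, topology) + kick
  v <- half(v, F1)
  x[mob, ] <- x[mob, ] + v[mob, ] * dt
  F2 <- assemble_forces(x, topology) + kick
  v <- half(v, F2)
  list(positions = x, velocities = v)
}

#' Kinetic and potential energy of a state
#'
#' Kinetic energy of the mobile particles plus the bonded potential energy
#' (stretch, bending, string terms).
#'
#' @param state List with `positions` and `velocities` (`n x 3` matrices).
#' @param topology A `chain_topology`.
#' @return Named numeric vector `c(kinetic = , potential = )` (J).
#' @export
system_energy <- function(state, topology) {
  p <- topology$particles
  mob <- p$mobile
  ke <- 0.5 * sum(p$mass[mob] * rowSums(state$velocities[mob, , drop = FALSE]^2))
  c(kinetic = ke, potential = potential_energy(state$positions, topology))
}

#' Initial state of a topology
#'
#' Positions from the topology, all velocities zero.
#'
#' @param topology A `chain_topology`.
#' @return State list for [integrate_step()].
#' @export
initial_state <- function(topology) {
  list(positions = as.matrix(topology$particles[, c("x", "y", "z")]),
       velocities = matrix(0, nrow(topology$particles), 3))
}
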