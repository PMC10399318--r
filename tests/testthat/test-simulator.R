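test_that("the equilibrium chain at rest is a fixed point", {
  topo <- quick_topology(n_beads = 2)
  st <- initial_state(topo)
  st2 <- integrate_step(st, topo, kick = NULL, dt = 1e-4)
  expect_equal(st2$positions, st$positions, tolerance = 1e-14)
  expect_equal(st2$velocities, st$velocities, tolerance = 1e-14)
  # and through the compiled path
  traj <- run_simulation(topo, forcing = NULL,
                         sim_config(n_steps = 50, equilibration_steps = 0,
                                    record_stride = 1))
  expect_lt(max(abs(traj$velocities)), 1e-12)
})

test_that("a damped particle under constant force reaches exactly F/kv", {
  ff <- force_field(kv = 0.5, kr = 0)
  topo <- free_particle_topology(mass = 1e-3, ff = ff)
  Fconst <- matrix(c(2e-3, -1e-3, 5e-4), 1, 3)
  st <- initial_state(topo)
  dt <- 1e-3  # relaxation time m/kv = 2 ms; run 100 steps = 50 relaxations
  for (i in 1:100) st <- integrate_step(st, topo, kick = Fconst, dt = dt)
  expect_equal(st$velocities[1, ], Fconst[1, ] / ff$kv, tolerance = 1e-6)
})

test_that("energy is conserved without kicks or damping", {
  # bent chain, conservative dynamics; masses heavy enough that the
  # stiffest bending mode satisfies the Verlet stability criterion
  ff <- force_field(kv = 0, kr = 0)
  topo <- build_topology(chain_spec(n_beads = 2, anchor_separation = 0.02),
                         bead_spec(), ff,
                         mass_bead = 1e-3, mass_crimp = 1e-3)
  topo <- perturb_topology(topo, 3e-4, seed = 5)
  cfg <- sim_config(timestep = 5e-6, n_steps = 1e4, equilibration_steps = 0,
                    record_stride = 100)
  traj <- run_simulation(topo, forcing = NULL, config = cfg)
  E <- vapply(seq_along(traj$times), function(f) {
    st <- list(positions = traj$positions[f, , ],
               velocities = traj$velocities[f, , ])
    sum(system_energy(st, topo))
  }, numeric(1))
  E0 <- sum(system_energy(initial_state(topo), topo))
  expect_gt(E0, 0)
  expect_lt(max(abs(E - E0)) / E0, 1e-4)
})

test_that("pure damping dissipates kinetic energy monotonically to nothing", {
  ff <- force_field(kv = 1e-6, kr = 0, kl = 0, ka = 0, ks = 0)
  topo <- build_topology(chain_spec(n_beads = 1, anchor_separation = 0.01),
                         bead_spec(), ff,
                         mass_bead = 1e-6, mass_crimp = 1e-6)
  st <- initial_state(topo)
  st$velocities[topo$particles$mobile, ] <- 0.1
  ke0 <- system_energy(st, topo)[["kinetic"]]
  ke <- numeric(60)
  for (i in seq_along(ke)) {
    st <- integrate_step(st, topo, kick = NULL, dt = 0.5)
    ke[i] <- system_energy(st, topo)[["kinetic"]]
  }
  expect_true(all(diff(c(ke0, ke)) < 0))
  expect_lt(ke[length(ke)] / ke0, 1e-12)
})

test_that("recorded frame count and times follow the config", {
  topo <- quick_topology(n_beads = 1)
  cfg <- sim_config(n_steps = 4000, equilibration_steps = 1000,
                    record_stride = 10, seed = 3)
  traj <- run_simulation(topo, forcing_model("laplace"), cfg)
  expect_equal(length(traj$times), (4000 - 1000) / 10)
  expect_equal(dim(traj$positions), c(300, 5, 3))
  expect_equal(unique(round(diff(traj$times), 12)), 1e-4 * 10)
  expect_equal(traj$times[1], (1000 + 10) * 1e-4)
})

test_that("simulations are bit-reproducible under a fixed seed", {
  topo <- quick_topology(n_beads = 2)
  cfg <- sim_config(n_steps = 500, equilibration_steps = 100,
                    record_stride = 5, seed = 77)
  t1 <- run_simulation(topo, forcing_model("laplace"), cfg)
  t2 <- run_simulation(topo, forcing_model("laplace"), cfg)
  expect_identical(t1$positions, t2$positions)
  expect_identical(t1$velocities, t2$velocities)
})

test_that("anchors never move and frames stay finite", {
  topo <- quick_topology(n_beads = 2)
  cfg <- sim_config(n_steps = 2000, equilibration_steps = 0,
                    record_stride = 20, seed = 5)
  traj <- run_simulation(topo, forcing_model("gaussian"), cfg)
  anchors <- which(!traj$particles$mobile)
  for (a in anchors) {
    expect_equal(max(abs(sweep(traj$positions[, a, ], 2,
                               unlist(traj$particles[a, c("x", "y", "z")])))),
                 0)
  }
  expect_true(all(is.finite(traj$positions)))
  expect_true(all(is.finite(traj$velocities)))
})

test_that("compiled and R reference integrators agree step for step", {
  topo <- quick_topology(n_beads = 2)
  for (kind in c("laplace", "gaussian")) {
    forcing <- forcing_model(kind)
    cfg <- sim_config(n_steps = 5, equilibration_steps = 0,
                      record_stride = 1, seed = 42)
    traj <- run_simulation(topo, forcing, cfg)
    # replay with the R-level stepper using the same RNG stream
    set.seed(42)
    st <- initial_state(topo)
    kicked <- which(topo$particles$mobile)
    for (s in 1:5) {
      P <- sample_noise(forcing, length(kicked))
      kick <- matrix(0, nrow(topo$particles), 3)
      kick[kicked, ] <- topo$force_field$kr * P
      st <- integrate_step(st, topo, kick = kick, dt = cfg$timestep)
    }
    expect_equal(unname(st$positions), unname(traj$positions[5, , ]),
                 tolerance = 1e-12)
    expect_equal(unname(st$velocities), unname(traj$velocities[5, , ]),
                 tolerance = 1e-12)
  }
})

test_that("beads_only targeting leaves crimps unkicked", {
  ff <- force_field(kv = 1e-4, kl = 0, ka = 0, ks = 0)
  topo <- build_topology(chain_spec(n_beads = 2, anchor_separation = 0.02),
                         bead_spec(), ff)
  cfg <- sim_config(n_steps = 200, equilibration_steps = 0,
                    record_stride = 1, seed = 9)
  traj <- run_simulation(topo, forcing_model("laplace", targets = "beads_only"),
                         cfg)
  crimps <- which(traj$particles$kind == "crimp")
  beads <- which(traj$particles$kind == "bead")
  expect_equal(max(abs(traj$velocities[, crimps, ])), 0)
  expect_gt(max(abs(traj$velocities[, beads, ])), 0)
})

test_that("overdamped stationary velocities mirror the kick distribution", {
  # one free particle with velocity relaxation much faster than the
  # timestep: per-component velocities should be the kick distribution
  # rescaled by kr/kv
  for (kind in c("laplace", "gaussian")) {
    ff <- force_field(kv = 5, kr = 1e-2)
    topo <- free_particle_topology(mass = 5.65e-10, ff = ff)
    cfg <- sim_config(n_steps = 1400, equilibration_steps = 100,
                      record_stride = 1, seed = 31)
    traj <- run_simulation(topo, forcing_model(kind), cfg)
    v <- as.numeric(traj$velocities[, 1, ])
    set.seed(77)
    ref <- ff$kr / ff$kv * as.numeric(sample_noise(forcing_model(kind), 1300))
    expect_gt(stats::ks.test(v, ref)$p.value, 0.01)
  }
})

test_that("a blow-up is reported with its step index", {
  # undamped stiff spring with an enormous timestep explodes
  ff <- force_field(kv = 0, kr = 0)
  topo <- build_topology(chain_spec(n_beads = 1, anchor_separation = 0.01),
                         bead_spec(), ff)
  topo <- perturb_topology(topo, 1e-3, seed = 2)
  expect_error(
    run_simulation(topo, forcing = NULL,
                   sim_config(timestep = 100, n_steps = 2000,
                              equilibration_steps = 0, record_stride = 10)),
    "blow-up at step")
})

test_that("non-finite states are rejected by the stepper", {
  topo <- quick_topology(1)
  st <- initial_state(topo)
  st$positions[2, 1] <- NaN
  expect_error(integrate_step(st, topo, NULL, 1e-4), "non-finite")
})
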