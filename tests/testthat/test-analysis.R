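toy_tracks <- function(df, frame_rate = 30) {
  # build a track_table directly from a data frame (already in metres)
  tracks <- generate_synthetic_tracks(1, 2, seed = 1)
  out <- df[order(df$track_id, df$frame), ]
  rownames(out) <- NULL
  attributes(out) <- c(attributes(out)[c("names", "row.names")],
                       list(class = class(tracks), frame_rate = frame_rate,
                            length_unit = 1e-3))
  out
}

test_that("finite differences are exact for static and linear motion", {
  fr <- 0:9
  static <- toy_tracks(data.frame(track_id = 1, frame = fr, x = 0.5, y = -0.2))
  v <- finite_difference_velocities(static)
  expect_equal(unique(v$x$values), 0)
  expect_equal(unique(v$y$values), 0)
  expect_equal(length(v$x$values), 10)  # 8 central + 2 one-sided
  a <- 0.03
  lin <- toy_tracks(data.frame(track_id = 1, frame = fr,
                               x = a * fr / 30, y = 0))
  vl <- finite_difference_velocities(lin)
  expect_equal(vl$x$values, rep(a, 10), tolerance = 1e-12)
})

test_that("gaps drop exactly the samples a brute-force enumeration drops", {
  # 10 frames, frame 5 missing: frames 4 and 6 lose their central
  # difference, frame 5 contributes nothing; brute force over all frames
  fr <- setdiff(0:9, 5)
  pos <- data.frame(track_id = 1, frame = fr, x = sin(fr), y = 0)
  v <- finite_difference_velocities(toy_tracks(pos))
  brute <- 0
  for (f in fr) {
    has <- function(k) k %in% fr
    if (f == min(fr) || f == max(fr)) {
      if (has(f + 1) || has(f - 1)) brute <- brute + 1
    } else if (has(f - 1) && has(f + 1)) brute <- brute + 1
  }
  expect_equal(length(v$x$values), brute)
  expect_equal(brute, 7)  # frames 0,1,2,3,7,8,9
})

test_that("single-frame tracks yield a warning and no samples", {
  tr <- toy_tracks(data.frame(track_id = c(1, 2, 2, 2),
                              frame = c(0, 0, 1, 2),
                              x = c(0, 0, 1e-3, 2e-3), y = 0))
  expect_warning(v <- finite_difference_velocities(tr), "single frame")
  expect_equal(length(v$x$values), 3)  # only track 2 contributes
})

test_that("middle tracer selection centres on the chain and errors when short", {
  topo <- quick_topology(n_beads = 14)
  idx <- select_middle_tracers(topo, 5)
  crimps <- which(topo$particles$kind == "crimp")
  # crimps 6..10 of the 15, counted along the chain
  expect_equal(match(idx, crimps), 6:10)
  expect_equal(select_middle_tracers(topo, 15), crimps)
  small <- quick_topology(n_beads = 1)  # only 2 crimps
  expect_error(select_middle_tracers(small, 5), "at least 5")
  tr <- generate_synthetic_tracks(7, 5, seed = 1)
  expect_equal(select_middle_tracers(tr, 3), 3:5)
})

test_that("per-sign exponential rates are consistent MLEs", {
  set.seed(21)
  n <- 1e4
  v <- c(stats::rexp(n, rate = 2), -stats::rexp(n, rate = 5))
  fit <- fit_signed_exponential(velocity_sample(v))
  # MLE standard error of an exponential rate is rate/sqrt(n)
  expect_lt(abs(fit$lambda_pos - 2), 3 * 2 / sqrt(n))
  expect_lt(abs(fit$lambda_neg - 5), 3 * 5 / sqrt(n))
  # mirrored sample: equal rates by construction
  sym <- velocity_sample(c(v, -v))
  fs <- fit_signed_exponential(sym)
  expect_equal(fs$lambda_pos, fs$lambda_neg)
  # all-positive sample: negative rate absent
  expect_warning(fp <- fit_signed_exponential(velocity_sample(abs(v))),
                 "below the minimum")
  expect_true(is.na(fp$lambda_neg))
  expect_false(is.na(fp$lambda_pos))
})

test_that("beta recovery: Laplace and Gaussian samples fit near 1 and 2", {
  set.seed(5)
  lap <- laplace_from_uniform(runif(1e4), runif(1e4)) * 0.03
  fit1 <- fit_exponent_beta(velocity_sample(lap), n_boot = 50)
  expect_gt(fit1$beta, 0.9)
  expect_lt(fit1$beta, 1.1)
  expect_true(fit1$ci[1] <= fit1$beta && fit1$beta <= fit1$ci[2])
  gau <- rnorm(1e4, sd = 0.03)
  fit2 <- fit_exponent_beta(velocity_sample(gau), n_boot = 0)
  expect_gt(fit2$beta, 1.85)
  expect_lt(fit2$beta, 2.15)
  expect_null(fit2$ci)
})

test_that("beta is scale invariant and degenerate samples error", {
  set.seed(8)
  v <- laplace_from_uniform(runif(5000), runif(5000))
  b1 <- fit_exponent_beta(velocity_sample(v), n_boot = 0)$beta
  b2 <- fit_exponent_beta(velocity_sample(v * 37.5), n_boot = 0)$beta
  expect_equal(b1, b2, tolerance = 1e-6)
  expect_error(fit_exponent_beta(velocity_sample(rep(1, 1000)), n_boot = 0),
               "degenerate")
  expect_error(fit_exponent_beta(velocity_sample(rnorm(100)), n_boot = 0),
               "at least")
})

test_that("the log-histogram fit agrees roughly with the MLE", {
  set.seed(13)
  v <- rnorm(2e4)
  lh <- fit_beta_loghist(velocity_sample(v))
  expect_gt(lh$beta, 1.6)
  expect_lt(lh$beta, 2.4)
})

test_that("mean speed reduces to |v| for constant motion", {
  topo <- quick_topology(n_beads = 1)
  cfg <- sim_config(n_steps = 100, equilibration_steps = 0,
                    record_stride = 10, seed = 2)
  traj <- run_simulation(topo, forcing = NULL, cfg)  # nothing moves
  expect_equal(mean_speed(traj), 0)
  # paint a constant velocity onto the recorded frames
  traj$velocities[, , ] <- 0
  traj$velocities[, 3, 1] <- 0.3
  traj$velocities[, 3, 2] <- 0.4
  expect_equal(mean_speed(traj, particles = 3), 0.5)
  expect_error(mean_speed(traj, particles = integer()), "empty")
})

test_that("finite-difference velocities approach recorded ones as stride shrinks", {
  # smooth damped relaxation (no kicks): position differences converge to
  # the instantaneous velocities as the recording stride decreases
  ff <- force_field(kv = 0, kr = 0)
  topo <- build_topology(chain_spec(n_beads = 2, anchor_separation = 0.02),
                         bead_spec(), ff,
                         mass_bead = 1e-2, mass_crimp = 1e-2)
  topo <- perturb_topology(topo, 5e-4, seed = 4)
  rms <- vapply(c(8, 4, 2, 1), function(stride) {
    cfg <- sim_config(timestep = 1e-4, n_steps = 800,
                      equilibration_steps = 0, record_stride = stride)
    traj <- run_simulation(topo, forcing = NULL, cfg)
    n_f <- length(traj$times)
    fd <- (traj$positions[3:n_f, 3, 1] - traj$positions[1:(n_f - 2), 3, 1]) /
      (2 * stride * 1e-4)
    sqrt(mean((fd - traj$velocities[2:(n_f - 1), 3, 1])^2))
  }, numeric(1))
  expect_true(all(diff(rms) < 0))
})

test_that("kick symmetry: pooled vx has no significant mean", {
  topo <- quick_topology(n_beads = 2)
  cfg <- sim_config(n_steps = 2e4, equilibration_steps = 2e3,
                    record_stride = 10, seed = 6)
  traj <- run_simulation(topo, forcing_model("laplace"), cfg)
  vx <- as.numeric(traj$velocities[, which(traj$particles$mobile), 1])
  expect_lt(abs(mean(vx)), 3 * sd(vx) / sqrt(length(vx)))
})

test_that("damping calibration selects the kv nearest the target speed", {
  topo <- quick_topology(n_beads = 1)
  cfg <- sim_config(n_steps = 3000, equilibration_steps = 500,
                    record_stride = 5, seed = 10)
  forcing <- forcing_model("laplace")
  kvs <- c(2, 4, 8)
  sweep <- damping_calibration_sweep(topo, forcing, cfg, kvs,
                                     target = 0)  # smallest speed wins
  expect_equal(sweep$kv, 8)
  expect_equal(nrow(sweep$table), 3)
  # overdamped scaling: doubling kv halves the mean speed
  s <- sweep$table$mean_speed
  expect_equal(s[1] / s[2], 2, tolerance = 0.1)
  expect_equal(s[2] / s[3], 2, tolerance = 0.1)
  # self-consistency: targeting a tabulated speed selects its kv
  sw2 <- damping_calibration_sweep(topo, forcing, cfg, kvs,
                                   target = s[2])
  expect_equal(sw2$kv, 4)
  # single-value sweep returns that value
  sw1 <- damping_calibration_sweep(topo, forcing, cfg, 4, target = 99)
  expect_equal(sw1$kv, 4)
})
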