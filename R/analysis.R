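# Velocity-distribution analysis: finite-difference velocities from tracks,
# per-sign exponential tail fits, and the stretched-exponential
# (exponential-power) exponent beta.

#' Velocity sample container
#'
#' A labelled set of per-component velocity observations, carrying the
#' component label, the source (`"simulation"` or `"tracks"`), a free-form
#' selection descriptor and the frame interval.
#'
#' @param values Numeric velocities (m/s); must be finite.
#' @param component Component label (`"x"`, `"y"`, `"z"`, or e.g.
#'   `"pooled:xyz"`).
#' @param source `"simulation"` or `"tracks"`.
#' @param selection Free-form description of the particles included.
#' @param frame_interval Time between consecutive observations (s).
#' @return A `velocity_sample` object.
#' @export
velocity_sample <- function(values, component = "x",
                            source = c("simulation", "tracks"),
                            selection = "", frame_interval = 1 / 30) {
  source <- match.arg(source)
  stop_if(any(!is.finite(values)), "velocity values must be finite")
  stop_if(!is.finite(frame_interval) || frame_interval <= 0,
          "frame_interval must be positive")
  structure(list(values = as.numeric(values), component = component,
                 source = source, selection = selection,
                 frame_interval = frame_interval),
            class = "velocity_sample")
}

#' @export
print.velocity_sample <- function(x, ...) {
  cat(sprintf("<velocity_sample> %s, %d values from %s [%s], sd %.4g m/s\n",
              x$component, length(x$values), x$source, x$selection,
              sd(x$values)))
  invisible(x)
}

#' Middle tracer crimps of a chain
#'
#' The `k` crimps closest to the chain midpoint, mimicking the analysis of
#' the middle five tracer crimps far from the constrained ends. For a
#' `chain_topology` the result is particle indices; for a track table it is
#' the middle `k` track ids in sorted order. Ties (even windows) break
#' toward the lower index.
#'
#' @param x A `chain_topology` or `track_table`.
#' @param k Number of tracers (default 5).
#' @return Integer particle indices (topology) or track ids (track table).
#' @examples
#' topo <- build_topology(chain_spec(), bead_spec(), force_field())
#' select_middle_tracers(topo)  # crimps 6..10 of 15
#' @export
select_middle_tracers <- function(x, k = 5) UseMethod("select_middle_tracers")

middle_window <- function(n, k) {
  stop_if(k < 1, "k must be at least 1")
  stop_if(n < k, sprintf("need at least %d tracers, have %d", k, n))
  start <- floor((n - k) / 2) + 1
  start:(start + k - 1)
}

#' @export
select_middle_tracers.chain_topology <- function(x, k = 5) {
  crimps <- which(x$particles$kind == "crimp")
  crimps[middle_window(length(crimps), k)]
}

#' @export
select_middle_tracers.track_table <- function(x, k = 5) {
  ids <- sort(unique(x$track_id))
  ids[middle_window(length(ids), k)]
}

#' Finite-difference velocities from tracked positions
#'
#' With `method = "central"` (default): central differences on interior
#' frames (both neighbour frames present), one-sided differences at track
#' ends. With `method = "forward"`: one-frame forward differences wherever
#' the next frame is present. In both cases frames adjacent to a gap yield
#' no sample rather than a difference spanning the gap. Returns one
#' [velocity_sample()] per coordinate column present (x, y, and z only if
#' the tracks are 3D -- 2D projected tracks simply have no z column).
#'
#' Central differencing smooths: each sample averages the displacement of
#' two consecutive intervals, which biases distribution-shape estimates
#' toward Gaussian when the underlying velocity decorrelates within one
#' frame. Use `"forward"` when the shape of the per-frame velocity
#' distribution is the quantity of interest.
#'
#' @param tracks A `track_table` (see [read_tracks_csv()]); positions in
#'   metres, frames 0-based.
#' @param frame_interval Time between frames (s); defaults to the table's
#'   `frame_rate` attribute.
#' @param method `"central"` or `"forward"`.
#' @return Named list of `velocity_sample` objects.
#' @export
finite_difference_velocities <- function(tracks,
                                         frame_interval = NULL,
                                         method = c("central", "forward")) {
  method <- match.arg(method)
  stopifnot(inherits(tracks, "track_table"))
  if (is.null(frame_interval)) {
    frame_interval <- 1 / attr(tracks, "frame_rate")
  }
  comps <- intersect(c("x", "y", "z"), names(tracks))
  out <- lapply(comps, function(cc) numeric(0))
  names(out) <- comps
  for (id in unique(tracks$track_id)) {
    tr <- tracks[tracks$track_id == id, , drop = FALSE]
    tr <- tr[order(tr$frame), , drop = FALSE]
    if (nrow(tr) < 2) {
      warning(sprintf("track %s has a single frame; no velocities", id),
              call. = FALSE)
      next
    }
    fr <- tr$frame
    prev_ok <- c(FALSE, diff(fr) == 1)          # frame-1 present
    next_ok <- c(diff(fr) == 1, FALSE)          # frame+1 present
    for (cc in comps) {
      p <- tr[[cc]]
      v <- rep(NA_real_, nrow(tr))
      if (method == "forward") {
        i <- which(next_ok)
        v[i] <- (p[i + 1] - p[i]) / frame_interval
      } else {
        interior <- prev_ok & next_ok
        if (any(interior)) {
          i <- which(interior)
          v[i] <- (p[i + 1] - p[i - 1]) / (2 * frame_interval)
        }
        # one-sided at the track's first and last observed frame
        if (!interior[1] && next_ok[1]) v[1] <- (p[2] - p[1]) / frame_interval
        nlast <- length(v)
        if (!interior[nlast] && prev_ok[nlast]) {
          v[nlast] <- (p[nlast] - p[nlast - 1]) / frame_interval
        }
      }
      out[[cc]] <- c(out[[cc]], v[!is.na(v)])
    }
  }
  lapply(stats::setNames(comps, comps), function(cc) {
    velocity_sample(out[[cc]], component = cc, source = "tracks",
                    selection = sprintf("%d tracks",
                                        length(unique(tracks$track_id))),
                    frame_interval = frame_interval)
  })
}

#' Velocity sample from a simulated trajectory
#'
#' Extracts recorded instantaneous velocities for selected particles and
#' components, pooled into one [velocity_sample()].
#'
#' @param traj A `trajectory`.
#' @param particles Particle indices (e.g. [select_middle_tracers()]).
#' @param components Coordinate labels to pool (default x, y, z; use
#'   `c("x", "y")` for the experiment-comparable 2D projection).
#' @return A `velocity_sample`.
#' @export
trajectory_velocity_sample <- function(traj, particles,
                                       components = c("x", "y", "z")) {
  stopifnot(inherits(traj, "trajectory"))
  components <- match.arg(components, c("x", "y", "z"), several.ok = TRUE)
  vals <- as.numeric(traj$velocities[, particles, components])
  velocity_sample(vals,
                  component = paste0("pooled:", paste(components, collapse = "")),
                  source = "simulation",
                  selection = paste(particles, collapse = ","),
                  frame_interval = traj$config$timestep *
                    traj$config$record_stride)
}

#' Per-sign exponential tail rates
#'
#' Maximum-likelihood exponential rates fitted separately to the positive
#' velocities and to the magnitudes of the negative velocities (the
#' per-sign "best exponential fits" drawn on semi-log velocity
#' histograms). Exact zeros belong to neither sign. A sign with fewer than
#' `min_n` observations gets an `NA` rate.
#'
#' @param sample A [velocity_sample()].
#' @param min_n Minimum per-sign count (default 30).
#' @return Named list: `lambda_pos`, `lambda_neg` (s/m), per-sign counts.
#' @export
fit_signed_exponential <- function(sample, min_n = 30) {
  stopifnot(inherits(sample, "velocity_sample"))
  v <- sample$values
  pos <- v[v > 0]
  neg <- -v[v < 0]
  rate <- function(x) if (length(x) >= min_n) 1 / mean(x) else NA_real_
  if (length(pos) < min_n || length(neg) < min_n) {
    warning("a sign class is below the minimum count; its rate is NA",
            call. = FALSE)
  }
  list(lambda_pos = rate(pos), lambda_neg = rate(neg),
       n_pos = length(pos), n_neg = length(neg))
}

# profile negative log-likelihood machinery for the exponential-power
# (generalized normal) family: f(v) = beta / (2 a Gamma(1/beta))
#                                      * exp(-(|v - mu|/a)^beta)
epd_profile_nll <- function(beta, av, n) {
  # profile MLE of the scale a at fixed beta
  a <- (beta / n * sum(av^beta))^(1 / beta)
  -(n * (log(beta) - log(2 * a) - lgamma(1 / beta)) - n / beta)
}

epd_fit_beta <- function(av, lower = 0.05, upper = 20) {
  n <- length(av)
  opt <- optimize(epd_profile_nll, c(lower, upper), av = av, n = n,
                  tol = 1e-8)
  beta <- opt$minimum
  if (beta < lower * 1.05 || beta > upper * 0.95) {
    stop(sprintf(paste0("exponential-power fit did not converge in the ",
                        "interior: beta_hat = %.3g at bound [%g, %g] ",
                        "(n = %d, sd = %.3g)"),
                 beta, lower, upper, n, sd(av)), call. = FALSE)
  }
  a <- (beta / n * sum(av^beta))^(1 / beta)
  list(beta = beta, a = a, loglik = -opt$objective)
}

#' Fit the stretched-exponential exponent beta
#'
#' Maximum-likelihood fit of the exponential-power (generalized normal)
#' family `P(v) ~ exp(-(|v - mu|/a)^beta)` to a velocity sample, with the
#' location fixed at the sample median. `beta = 2` is Gaussian, `beta = 1`
#' exponential (Laplace); fluidized-bed tracer velocities typically come
#' out near 1. The scale is reported both as `a` and as
#' `alpha = a^(-beta)` (the coefficient in `exp(-alpha |v|^beta)`).
#' A percentile bootstrap (seeded) gives a confidence interval on beta.
#'
#' Estimation maximizes the profile likelihood in `beta` (the scale has a
#' closed-form conditional MLE), which is bin-free, unlike least squares
#' on a log histogram; see [fit_beta_loghist()] for that alternative.
#'
#' @param sample A [velocity_sample()], or a bare numeric vector.
#' @param n_boot Bootstrap resamples for the CI (default 200; 0 disables).
#' @param conf Confidence level (default 0.95).
#' @param boot_seed Seed for the bootstrap resampling.
#' @param min_n Minimum sample size (default 500).
#' @return A `velocity_fit`: list with `beta`, `alpha`, `a`, `loglik`,
#'   `n`, `ci` (bootstrap bounds on beta, or NULL), and the per-sign rates
#'   of [fit_signed_exponential()].
#' @examples
#' set.seed(1)
#' s <- velocity_sample(rnorm(2000), "x")
#' fit_exponent_beta(s, n_boot = 0)$beta  # near 2
#' @export
fit_exponent_beta <- function(sample, n_boot = 200, conf = 0.95,
                              boot_seed = 1, min_n = 500) {
  if (!inherits(sample, "velocity_sample")) {
    sample <- velocity_sample(as.numeric(sample))
  }
  v <- sample$values
  stop_if(length(v) < min_n,
          sprintf("need at least %d samples to fit beta, have %d",
                  min_n, length(v)))
  vc <- v - median(v)
  av <- abs(vc)
  av <- av[av > 0]
  stop_if(length(av) < min_n / 2 || sd(v) == 0,
          "degenerate (near-constant) sample; cannot fit beta")
  fit <- epd_fit_beta(av)
  ci <- NULL
  if (n_boot > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(boot_seed)
    bb <- vapply(seq_len(n_boot), function(i) {
      vb <- v[sample.int(length(v), replace = TRUE)]
      ab <- abs(vb - median(vb))
      ab <- ab[ab > 0]
      tryCatch(epd_fit_beta(ab)$beta, error = function(e) NA_real_)
    }, numeric(1))
    bb <- bb[is.finite(bb)]
    alp <- (1 - conf) / 2
    ci <- quantile(bb, c(alp, 1 - alp), names = FALSE)
  }
  rates <- suppressWarnings(fit_signed_exponential(sample))
  structure(list(beta = fit$beta, alpha = fit$a^(-fit$beta), a = fit$a,
                 loglik = fit$loglik, n = length(v), ci = ci,
                 lambda_pos = rates$lambda_pos,
                 lambda_neg = rates$lambda_neg,
                 component = sample$component, source = sample$source),
            class = "velocity_fit")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' @export
print.velocity_fit <- function(x, ...) {
  cat(sprintf("<velocity_fit> beta = %.3f%s, a = %.4g m/s, n = %d (%s, %s)\n",
              x$beta,
              if (!is.null(x$ci)) sprintf(" [%.3f, %.3f]", x$ci[1], x$ci[2])
              else "",
              x$a, x$n, x$component, x$source))
  if (is.finite(x$lambda_pos) || is.finite(x$lambda_neg)) {
    cat(sprintf("  per-sign exponential rates: %.4g (v>0), %.4g (v<0) s/m\n",
                x$lambda_pos, x$lambda_neg))
  }
  invisible(x)
}

#' Log-histogram least-squares beta (plotting parity)
#'
#' Weighted least squares of `log P(v)` against `|v|^beta` on a
#' Freedman-Diaconis histogram with empty bins dropped. Bin-sensitive;
#' provided for visual parity with semi-log histogram fits, not for
#' estimation (use [fit_exponent_beta()]).
#'
#' @param sample A [velocity_sample()] or numeric vector.
#' @return List with `beta`, `alpha`.
#' @export
fit_beta_loghist <- function(sample) {
  v <- if (inherits(sample, "velocity_sample")) sample$values else
    as.numeric(sample)
  vc <- abs(v - median(v))
  vc <- vc[vc > 0]
  h <- graphics::hist(vc, breaks = "FD", plot = FALSE)
  keep <- h$density > 0
  mids <- h$mids[keep]
  ld <- log(h$density[keep])
  w <- h$counts[keep]
  obj <- function(beta) {
    X <- cbind(1, mids^beta)
    fit <- stats::lm.wfit(X, ld, w)
    sum(w * fit$residuals^2)
  }
  beta <- optimize(obj, c(0.2, 8))$minimum
  X <- cbind(1, mids^beta)
  co <- stats::lm.wfit(X, ld, w)$coefficients
  list(beta = beta, alpha = -co[[2]])
}

#' Mean speed of selected particles
#'
#' Time-and-particle average of the velocity magnitude over the recorded
#' frames; the quantity used to calibrate the damping coefficient against
#' experiment.
#'
#' @param traj A `trajectory`.
#' @param particles Particle indices; defaults to all beads.
#' @param components Components entering the magnitude (default 3D).
#' @return Mean speed (m/s).
#' @export
mean_speed <- function(traj, particles = NULL,
                       components = c("x", "y", "z")) {
  stopifnot(inherits(traj, "trajectory"))
  if (is.null(particles)) particles <- which(traj$particles$kind == "bead")
  stop_if(length(particles) == 0, "empty particle selection")
  v <- traj$velocities[, particles, components, drop = FALSE]
  sp <- sqrt(apply(v^2, c(1, 2), sum))
  mean(sp)
}

#' Damping calibration sweep
#'
#' Runs one seeded simulation per candidate damping coefficient, tabulates
#' the mean bead speed, and selects the damping whose mean speed is
#' nearest the target -- the simulation-side analog of calibrating the
#' drag against the experimentally measured mean speed. Mean speed is
#' expected to decrease with damping; a non-monotone table draws a
#' warning (sampling noise), not an error.
#'
#' @param topology A `chain_topology` (its force field supplies all
#'   coefficients except `kv`).
#' @param forcing A [forcing_model()].
#' @param config A [sim_config()]; the same seed is reused for every run.
#' @param kv_values Candidate damping coefficients (N s/m), at least 2
#'   for a meaningful sweep (a single value is allowed and selected).
#' @param target Target mean speed (m/s).
#' @return List with `table` (data.frame kv, mean_speed) and `kv` (the
#'   selected value).
#' @export
damping_calibration_sweep <- function(topology, forcing, config, kv_values,
                                      target) {
  stop_if(length(kv_values) < 1, "kv_values must be non-empty")
  speeds <- vapply(kv_values, function(kv) {
    topo <- topology
    topo$force_field$kv <- kv
    mean_speed(run_simulation(topo, forcing, config))
  }, numeric(1))
  tab <- data.frame(kv = kv_values, mean_speed = speeds)
  ord <- order(kv_values)
  if (length(kv_values) > 1 && any(diff(speeds[ord]) > 0)) {
    warning("mean speed is not monotone decreasing in kv over this sweep",
            call. = FALSE)
  }
  list(table = tab, kv = kv_values[which.min(abs(speeds - target))])
}
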