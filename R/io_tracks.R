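# Track-table I/O (TrackMate-style CSV), synthetic track generation, and
# trajectory file writers/readers (XYZ, LAMMPS-dump text, RDS container).

new_track_table <- function(df, frame_rate, length_unit) {
  df <- df[order(df$track_id, df$frame), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("track_table", "data.frame"),
            frame_rate = frame_rate, length_unit = length_unit)
}

validate_track_table <- function(df) {
  stop_if(any(df$frame < 0), "frames must be non-negative")
  stop_if(any(!is.finite(df$x)) || any(!is.finite(df$y)),
          "track coordinates must be finite")
  dup <- duplicated(df[, c("track_id", "frame")])
  stop_if(any(dup), "duplicated (track_id, frame) rows: ",
          paste(utils::head(sprintf("(%s,%s)", df$track_id[dup],
                                    df$frame[dup]), 5), collapse = " "))
  df
}

#' Read a tracked-bead CSV
#'
#' Reads tracked tracer positions from CSV in either the TrackMate export
#' dialect (columns `TRACK_ID`, `FRAME`, `POSITION_X`, `POSITION_Y`,
#' optionally `POSITION_Z`) or a simple dialect (`track`, `frame`, `x`,
#' `y`, optionally `z`). Coordinates are converted to metres at read time
#' via `length_unit` (default: millimetres, the usual calibrated TrackMate
#' unit). Rows are sorted by (track, frame); duplicated (track, frame)
#' pairs are an error.
#'
#' @param path CSV file path.
#' @param dialect `"auto"` (default), `"trackmate"`, or `"simple"`.
#' @param frame_rate Frames per second (default 30).
#' @param length_unit Metres per coordinate unit in the file (default
#'   `1e-3`).
#' @return A `track_table`: data frame with `track_id`, `frame`, `x`, `y`
#'   (and `z` if present) in metres, with `frame_rate` and `length_unit`
#'   attributes.
#' @export
read_tracks_csv <- function(path, dialect = c("auto", "trackmate", "simple"),
                            frame_rate = 30, length_unit = 1e-3) {
  dialect <- match.arg(dialect)
  stop_if(!file.exists(path), "file not found: ", path)
  raw <- read.csv(path, check.names = FALSE)
  tm_cols <- c("TRACK_ID", "FRAME", "POSITION_X", "POSITION_Y")
  simple_cols <- c("track", "frame", "x", "y")
  if (dialect == "auto") {
    dialect <- if (all(tm_cols %in% names(raw))) "trackmate"
    else if (all(simple_cols %in% names(raw))) "simple"
    else stop("cannot identify dialect; columns present: ",
              paste(names(raw), collapse = ", "), call. = FALSE)
  }
  need <- if (dialect == "trackmate") tm_cols else simple_cols
  missing <- setdiff(need, names(raw))
  stop_if(length(missing) > 0, "missing required columns: ",
          paste(missing, collapse = ", "))
  if (dialect == "trackmate") {
    df <- data.frame(track_id = as.integer(raw$TRACK_ID),
                     frame = as.integer(raw$FRAME),
                     x = raw$POSITION_X * length_unit,
                     y = raw$POSITION_Y * length_unit)
    if ("POSITION_Z" %in% names(raw)) df$z <- raw$POSITION_Z * length_unit
    if ("QUALITY" %in% names(raw)) df$quality <- raw$QUALITY
  } else {
    df <- data.frame(track_id = as.integer(raw$track),
                     frame = as.integer(raw$frame),
                     x = raw$x * length_unit, y = raw$y * length_unit)
    if ("z" %in% names(raw)) df$z <- raw$z * length_unit
    if ("quality" %in% names(raw)) df$quality <- raw$quality
  }
  new_track_table(validate_track_table(df), frame_rate, length_unit)
}

#' Write a track table to CSV
#'
#' Inverse of [read_tracks_csv()]: writes the simple dialect (`track`,
#' `frame`, `x`, `y` and, when present, `z`), converting metres back to the table's length
#' unit so that a write/read round trip is the identity.
#'
#' @param tracks A `track_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_tracks_csv <- function(tracks, path) {
  stopifnot(inherits(tracks, "track_table"))
  unit <- attr(tracks, "length_unit")
  out <- data.frame(track = tracks$track_id, frame = tracks$frame,
                    x = tracks$x / unit, y = tracks$y / unit)
  if ("z" %in% names(tracks)) out$z <- tracks$z / unit
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Generate synthetic tracer tracks
#'
#' Emulates 2D-projected, fixed-frame-rate tracks of tracer beads whose
#' per-frame displacements follow a chosen per-component velocity
#' distribution, with additive detection noise on positions and i.i.d.
#' frame dropout (emulating motion-blur detection failures). Used to test
#' the analysis stack without experimental data: with no noise and no
#' dropout, finite-difference velocities recover the generating
#' distribution's shape.
#'
#' @param n_tracers Number of tracks.
#' @param n_frames Frames per track before dropout.
#' @param frame_rate Frames per second (default 30).
#' @param kind Per-component velocity distribution: `"laplace"` or
#'   `"gaussian"`.
#' @param scale Velocity scale (m/s): the Laplace scale or Gaussian sd per
#'   component.
#' @param noise_sd Detection noise sd added to positions (m).
#' @param dropout Probability each frame is lost, i.i.d.
#' @param seed Integer seed (reproducible tables).
#' @return A `track_table` with x and y columns (2D projection), metres.
#' @export
generate_synthetic_tracks <- function(n_tracers = 5, n_frames = 1000,
                                      frame_rate = 30,
                                      kind = c("laplace", "gaussian"),
                                      scale = 0.05, noise_sd = 0,
                                      dropout = 0, seed = NULL) {
  kind <- match.arg(kind)
  stop_if(n_tracers < 1 || n_frames < 2, "need >= 1 tracer and >= 2 frames")
  stop_if(dropout < 0 || dropout > 1, "dropout must be a probability")
  if (!is.null(seed)) set.seed(seed)
  dt <- 1 / frame_rate
  draw <- function(n) {
    if (kind == "gaussian") rnorm(n, sd = scale)
    else laplace_from_uniform(runif(n), runif(n)) * scale
  }
  pieces <- lapply(seq_len(n_tracers), function(id) {
    vx <- draw(n_frames - 1)
    vy <- draw(n_frames - 1)
    x <- cumsum(c(0, vx * dt)) + rnorm(n_frames, sd = noise_sd)
    y <- cumsum(c(0, vy * dt)) + rnorm(n_frames, sd = noise_sd)
    keep <- runif(n_frames) >= dropout
    data.frame(track_id = id, frame = (0:(n_frames - 1))[keep],
               x = x[keep], y = y[keep])
  })
  new_track_table(validate_track_table(do.call(rbind, pieces)),
                  frame_rate, 1e-3)
}

#' Convert simulated trajectories to experiment-style tracks
#'
#' Projects recorded particle positions into a `track_table` (one track
#' per selected particle, frames numbered from 0 at the recording rate),
#' optionally dropping the out-of-plane z coordinate the way a 2D X-ray
#' projection does.
#'
#' @param traj A `trajectory`.
#' @param particles Particle indices to export (default: mobile crimps).
#' @param project_2d Keep only x and y (default TRUE).
#' @return A `track_table` in metres.
#' @export
trajectory_to_tracks <- function(traj, particles = NULL, project_2d = TRUE) {
  stopifnot(inherits(traj, "trajectory"))
  if (is.null(particles)) {
    particles <- which(traj$particles$kind == "crimp")
  }
  n_f <- length(traj$times)
  pieces <- lapply(seq_along(particles), function(i) {
    p <- particles[i]
    df <- data.frame(track_id = i, frame = 0:(n_f - 1),
                     x = traj$positions[, p, 1],
                     y = traj$positions[, p, 2])
    if (!project_2d) df$z <- traj$positions[, p, 3]
    df
  })
  frame_rate <- 1 / (traj$config$timestep * traj$config$record_stride)
  new_track_table(do.call(rbind, pieces), frame_rate, 1e-3)
}

#' Write a trajectory to disk
#'
#' Formats: `"xyz"` (one frame per block: atom count, a comment line with
#' the time, then `element x y z` with element B for beads, C for crimps,
#' X for anchors), `"lammps_dump"` (`ITEM: TIMESTEP` blocks with
#' `id type x y z vx vy vz`; type 1 = bead, 2 = crimp, 3 = anchor), or
#' `"rds"` (R serialization; lossless, the full-precision container).
#' Text formats print 9 significant digits; the RDS round trip is
#' bit-identical.
#'
#' @param traj A `trajectory`.
#' @param path Output path.
#' @param format `"xyz"`, `"lammps_dump"` or `"rds"`.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path,
                             format = c("xyz", "lammps_dump", "rds")) {
  stopifnot(inherits(traj, "trajectory"))
  format <- match.arg(format)
  n_frames <- length(traj$times)
  p <- traj$particles
  n <- nrow(p)
  if (format == "rds") {
    saveRDS(traj, path)
    return(invisible(path))
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "xyz") {
    elem <- c(bead = "B", crimp = "C", anchor = "X")[p$kind]
    for (f in seq_len(n_frames)) {
      writeLines(as.character(n), con)
      writeLines(sprintf("t= %.9g", traj$times[f]), con)
      writeLines(sprintf("%s %.9g %.9g %.9g", elem,
                         traj$positions[f, , 1], traj$positions[f, , 2],
                         traj$positions[f, , 3]), con)
    }
  } else {
    type <- c(bead = 1L, crimp = 2L, anchor = 3L)[p$kind]
    step0 <- traj$config$timestep
    for (f in seq_len(n_frames)) {
      writeLines(c("ITEM: TIMESTEP",
                   as.character(round(traj$times[f] / step0)),
                   "ITEM: NUMBER OF ATOMS", as.character(n),
                   "ITEM: BOX BOUNDS ff ff ff",
                   rep("-1 1", 3),
                   "ITEM: ATOMS id type x y z vx vy vz"), con)
      writeLines(sprintf("%d %d %.9g %.9g %.9g %.9g %.9g %.9g",
                         seq_len(n), type,
                         traj$positions[f, , 1], traj$positions[f, , 2],
                         traj$positions[f, , 3],
                         traj$velocities[f, , 1], traj$velocities[f, , 2],
                         traj$velocities[f, , 3]), con)
    }
  }
  invisible(path)
}

#' Read a trajectory written by [write_trajectory()]
#'
#' The RDS container restores the full `trajectory` object. The text
#' formats restore what they store: positions (XYZ) or positions and
#' velocities plus timestep indices (LAMMPS dump), to printed precision,
#' as plain lists.
#'
#' @param path File path.
#' @param format `"xyz"`, `"lammps_dump"` or `"rds"`.
#' @return A `trajectory` (rds) or a list with `positions` (and for
#'   lammps_dump `velocities`, `steps`, `types`).
#' @export
read_trajectory <- function(path, format = c("xyz", "lammps_dump", "rds")) {
  format <- match.arg(format)
  if (format == "rds") return(readRDS(path))
  lines <- readLines(path)
  if (format == "xyz") {
    out <- list()
    times <- numeric()
    i <- 1
    while (i <= length(lines)) {
      n <- as.integer(lines[i])
      times <- c(times, as.numeric(sub("^t= ", "", lines[i + 1])))
      block <- lines[(i + 2):(i + 1 + n)]
      m <- do.call(rbind, lapply(strsplit(block, " "), function(s)
        as.numeric(s[2:4])))
      out[[length(out) + 1]] <- m
      i <- i + 2 + n
    }
    nf <- length(out)
    n <- if (nf) nrow(out[[1]]) else 0
    pos <- array(NA_real_, c(nf, n, 3))
    for (f in seq_len(nf)) pos[f, , ] <- out[[f]]
    return(list(times = times, positions = pos))
  }
  # lammps_dump
  steps <- integer(); frames <- list()
  i <- 1
  while (i <= length(lines)) {
    stopifnot(lines[i] == "ITEM: TIMESTEP")
    steps <- c(steps, as.integer(lines[i + 1]))
    n <- as.integer(lines[i + 3])
    atom_lines <- lines[(i + 9):(i + 8 + n)]
    m <- do.call(rbind, lapply(strsplit(atom_lines, " "), as.numeric))
    frames[[length(frames) + 1]] <- m
    i <- i + 9 + n
  }
  nf <- length(frames)
  n <- if (nf) nrow(frames[[1]]) else 0
  pos <- array(NA_real_, c(nf, n, 3))
  vel <- array(NA_real_, c(nf, n, 3))
  for (f in seq_len(nf)) {
    ord <- order(frames[[f]][, 1])
    pos[f, , ] <- frames[[f]][ord, 3:5]
    vel[f, , ] <- frames[[f]][ord, 6:8]
  }
  types <- if (nf) frames[[1]][order(frames[[1]][, 1]), 2] else integer()
  list(steps = steps, positions = pos, velocities = vel, types = types)
}
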