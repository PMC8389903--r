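#' Construct a trajectory object
#'
#' A trajectory is an ordered set of frames of labeled particle positions in
#' a cubic periodic box. Coordinates are stored exactly as given (wrapped by
#' default); unwrapping for displacement analysis is an explicit operation,
#' see [unwrap()].
#'
#' @param coords Numeric array of dimension (n_frames, n_particles, 3), nm.
#' @param species Character vector of per-particle species labels.
#' @param box_length Cubic box edge length in nm, > 0.
#' @param dt Time between stored frames in ps, > 0.
#' @param charges Optional per-particle charges in e (default 0).
#' @param time0 Time of the first frame in ps. Default 0.
#' @return An object of class `trajectory`.
#' @export
trajectory <- function(coords, species, box_length, dt,
                       charges = NULL, time0 = 0) {
  stopifnot(is.array(coords), length(dim(coords)) == 3L, dim(coords)[3] == 3L)
  if (!all(is.finite(coords))) stop("all coordinates must be finite")
  if (!is.numeric(box_length) || length(box_length) != 1L || box_length <= 0) {
    stop("box_length must be a single positive number (cubic boxes only)")
  }
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0) stop("dt must be > 0")
  n_particles <- dim(coords)[2]
  if (length(species) != n_particles) {
    stop("species labels (", length(species), ") must match particle count (",
         n_particles, ")")
  }
  if (is.null(charges)) charges <- rep(0, n_particles)
  if (length(charges) != n_particles) {
    stop("charges (", length(charges), ") must match particle count (",
         n_particles, ")")
  }
  structure(list(coords = coords, species = as.character(species),
                 charges = as.numeric(charges), box_length = box_length,
                 dt = dt, times = time0 + dt * (seq_len(dim(coords)[1]) - 1)),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("trajectory:", dim(x$coords)[1], "frames x", dim(x$coords)[2],
      "particles; box", x$box_length, "nm; dt", x$dt, "ps\n")
  cat("species:", paste(sprintf("%s(%d)", names(table(x$species)),
                                table(x$species)), collapse = " "), "\n")
  invisible(x)
}

n_frames <- function(traj) dim(traj$coords)[1]
n_particles <- function(traj) dim(traj$coords)[2]

#' Minimum-image displacement
#'
#' @param d Displacement component(s) in nm.
#' @param box_length Cubic box edge in nm.
#' @return Displacements folded into (-L/2, L/2].
#' @export
minimum_image <- function(d, box_length) {
  d - box_length * round(d / box_length)
}

#' Wrap coordinates into the primary box [0, L)
#'
#' @param traj A [trajectory()].
#' @return A trajectory with all coordinates wrapped.
#' @export
wrap <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  traj$coords <- traj$coords %% traj$box_length
  traj
}

#' Unwrap periodic coordinates into continuous tracks
#'
#' Makes particle tracks continuous by removing box jumps: successive frame
#' displacements are folded by the minimum-image convention and accumulated.
#' Valid only when no particle truly moves more than L/2 between stored
#' frames; near-ambiguous jumps (> 0.45 L after folding) raise an error.
#' Re-wrapping the output reproduces the wrapped input exactly (up to the
#' periodic image).
#'
#' @param traj A [trajectory()] with wrapped (or already continuous) coordinates.
#' @return A trajectory with continuous coordinates.
#' @export
unwrap <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  L <- traj$box_length
  x <- traj$coords
  nf <- dim(x)[1]
  if (nf > 1) {
    disp <- x[-1, , , drop = FALSE] - x[-nf, , , drop = FALSE]
    disp <- minimum_image(disp, L)
    if (max(abs(disp)) > 0.45 * L) {
      stop("ambiguous unwrapping: a folded inter-frame jump exceeds 0.45 L; ",
           "store frames more frequently")
    }
    for (k in 2:nf) x[k, , ] <- x[k - 1, , ] + disp[k - 1, , ]
  }
  traj$coords <- x
  traj
}

#' Construct a scalar or vector time series
#'
#' Carrier for per-frame collective observables such as the box dipole moment
#' M(t) (e nm) or the ion current J(t) (e nm/ps).
#'
#' @param values Numeric vector (scalar series) or matrix with 3 columns
#'   (vector series), one row per frame.
#' @param dt Time between frames in ps.
#' @param time0 Time of the first frame in ps.
#' @return An object of class `scalar_series`.
#' @export
scalar_series <- function(values, dt, time0 = 0) {
  if (is.vector(values)) values <- matrix(values, ncol = 1)
  stopifnot(is.matrix(values), ncol(values) %in% c(1L, 3L),
            is.numeric(dt), length(dt) == 1L, dt > 0)
  if (!all(is.finite(values))) stop("all series values must be finite")
  structure(list(values = values, dt = dt,
                 times = time0 + dt * (seq_len(nrow(values)) - 1)),
            class = "scalar_series")
}

# ---- file formats ----------------------------------------------------------

#' Read a trajectory file
#'
#' Supported formats: `"xyz"` (multi-frame XYZ with the box length and time
#' on the comment line as `box=L t=T`, coordinates in nm), `"gro"`
#' (concatenated GROMACS coordinate frames, nm), and `"csv"` (long table with
#' columns `frame, particle, species, x, y, z`). Coordinates are returned
#' exactly as stored — no silent re-imaging.
#'
#' @param path File path.
#' @param format One of "xyz", "gro", "csv". Default guesses from extension.
#' @param dt Frame spacing in ps; required for csv, read from time stamps for
#'   xyz/gro when present (fallback 1 ps).
#' @param forcefield Optional named list of [species_params()]; when given,
#'   per-particle charges are resolved from species labels and unknown labels
#'   raise an error.
#' @param box_length Box edge in nm; required for csv.
#' @return A [trajectory()].
#' @export
read_trajectory <- function(path, format = c("auto", "xyz", "gro", "csv"),
                            dt = NULL, forcefield = NULL, box_length = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     xyz = "xyz", gro = "gro", csv = "csv",
                     stop("cannot guess trajectory format from extension: ", path))
  }
  traj <- switch(format,
                 xyz = .read_xyz(path, dt),
                 gro = .read_gro(path, dt),
                 csv = .read_traj_csv(path, dt, box_length))
  if (!is.null(forcefield)) {
    unknown <- setdiff(unique(traj$species), names(forcefield))
    if (length(unknown) > 0) {
      stop("unknown species label(s) not in force field: ",
           paste(unknown, collapse = ", "))
    }
    traj$charges <- unname(vapply(traj$species,
                                  function(s) forcefield[[s]]$charge,
                                  numeric(1)))
  }
  traj
}

#' Write a trajectory file
#'
#' @param traj A [trajectory()].
#' @param path Output path.
#' @param format One of "xyz", "gro", "csv"; default guesses from extension.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, format = c("auto", "xyz", "gro", "csv")) {
  stopifnot(inherits(traj, "trajectory"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     xyz = "xyz", gro = "gro", csv = "csv",
                     stop("cannot guess trajectory format from extension: ", path))
  }
  switch(format,
         xyz = .write_xyz(traj, path),
         gro = .write_gro(traj, path),
         csv = .write_traj_csv(traj, path))
  invisible(path)
}

.write_xyz <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  np <- n_particles(traj)
  for (k in seq_len(n_frames(traj))) {
    writeLines(as.character(np), con)
    writeLines(sprintf("box=%.10g t=%.10g", traj$box_length, traj$times[k]), con)
    writeLines(sprintf("%s %.10g %.10g %.10g", traj$species,
                       traj$coords[k, , 1], traj$coords[k, , 2],
                       traj$coords[k, , 3]), con)
  }
}

.read_xyz <- function(path, dt = NULL) {
  lines <- readLines(path)
  i <- 1L
  frames <- list(); times <- c(); box <- NA_real_; species <- NULL
  frame_idx <- 0L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    np <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(np)) stop("malformed XYZ count line at line ", i)
    frame_idx <- frame_idx + 1L
    comment <- lines[i + 1L]
    bm <- regmatches(comment, regexec("box=([0-9.eE+-]+)", comment))[[1]]
    tm <- regmatches(comment, regexec("t=([0-9.eE+-]+)", comment))[[1]]
    if (length(bm) == 2) box <- as.numeric(bm[2])
    times <- c(times, if (length(tm) == 2) as.numeric(tm[2]) else NA_real_)
    body <- lines[(i + 2L):(i + 1L + np)]
    if (length(body) < np || any(!nzchar(trimws(body)))) {
      stop("frame ", frame_idx, ": expected ", np, " particle lines")
    }
    parts <- strsplit(trimws(body), "\\s+")
    if (any(lengths(parts) < 4)) stop("frame ", frame_idx, ": malformed particle line")
    sp <- vapply(parts, `[`, character(1), 1)
    xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    if (is.null(species)) {
      species <- sp
    } else if (length(sp) != length(species)) {
      stop("frame ", frame_idx, ": particle count ", length(sp),
           " differs from first frame (", length(species), ")")
    }
    frames[[frame_idx]] <- xyz
    i <- i + 2L + np
  }
  if (frame_idx == 0L) stop("no frames found in ", path)
  if (is.na(box)) stop("XYZ comment lines must carry box=<L>")
  .assemble_traj(frames, species, box, times, dt)
}

.assemble_traj <- function(frames, species, box, times, dt) {
  nf <- length(frames); np <- length(species)
  coords <- array(0, dim = c(nf, np, 3))
  for (k in seq_len(nf)) coords[k, , ] <- frames[[k]]
  if (is.null(dt)) {
    dt <- if (nf > 1 && !anyNA(times)) {
      d <- diff(times)
      if (any(d <= 0) || diff(range(d)) > 1e-9 * max(abs(d)))
        stop("frame times must be strictly increasing with constant spacing")
      d[1]
    } else 1
  }
  t0 <- if (!is.na(times[1])) times[1] else 0
  trajectory(coords, species, box, dt, time0 = t0)
}

.write_gro <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  np <- n_particles(traj)
  resname <- substr(sprintf("%-5s", gsub("[+-]", "", traj$species)), 1, 5)
  atomname <- substr(sprintf("%5s", gsub("[+-]", "", traj$species)), 1, 5)
  for (k in seq_len(n_frames(traj))) {
    writeLines(sprintf("kbff frame t= %.6f", traj$times[k]), con)
    writeLines(sprintf("%5d", np), con)
    writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                       seq_len(np) %% 100000, resname, atomname,
                       seq_len(np) %% 100000,
                       traj$coords[k, , 1], traj$coords[k, , 2],
                       traj$coords[k, , 3]), con)
    writeLines(sprintf("%10.5f%10.5f%10.5f", traj$box_length,
                       traj$box_length, traj$box_length), con)
  }
}

.read_gro <- function(path, dt = NULL) {
  lines <- readLines(path)
  i <- 1L
  frames <- list(); times <- c(); box <- NA_real_; species <- NULL
  frame_idx <- 0L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    frame_idx <- frame_idx + 1L
    title <- lines[i]
    tm <- regmatches(title, regexec("t= *([0-9.eE+-]+)", title))[[1]]
    times <- c(times, if (length(tm) == 2) as.numeric(tm[2]) else NA_real_)
    np <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
    if (is.na(np)) stop("frame ", frame_idx, ": malformed GRO atom-count line")
    body <- lines[(i + 2L):(i + 1L + np)]
    if (length(body) < np) stop("frame ", frame_idx, ": truncated GRO frame")
    sp <- trimws(substr(body, 11, 15))
    x <- as.numeric(substr(body, 21, 28))
    y <- as.numeric(substr(body, 29, 36))
    z <- as.numeric(substr(body, 37, 44))
    if (anyNA(x) || anyNA(y) || anyNA(z)) {
      stop("frame ", frame_idx, ": malformed GRO coordinate field")
    }
    boxline <- strsplit(trimws(lines[i + 2L + np]), "\\s+")[[1]]
    bv <- as.numeric(boxline)
    if (length(bv) > 3 && any(abs(bv[4:length(bv)]) > 0)) {
      stop("triclinic boxes are not supported (cubic only)")
    }
    if (length(bv) < 3 || diff(range(bv[1:3])) > 1e-6) {
      stop("frame ", frame_idx, ": box must be cubic")
    }
    box <- bv[1]
    if (is.null(species)) {
      species <- sp
    } else if (length(sp) != length(species)) {
      stop("frame ", frame_idx, ": particle count ", length(sp),
           " differs from first frame (", length(species), ")")
    }
    frames[[frame_idx]] <- cbind(x, y, z)
    i <- i + 3L + np
  }
  if (frame_idx == 0L) stop("no frames found in ", path)
  .assemble_traj(frames, species, box, times, dt)
}

.write_traj_csv <- function(traj, path) {
  nf <- n_frames(traj); np <- n_particles(traj)
  df <- data.frame(
    frame = rep(seq_len(nf), each = np),
    particle = rep(seq_len(np), times = nf),
    species = rep(traj$species, times = nf),
    x = as.vector(t(traj$coords[, , 1])),
    y = as.vector(t(traj$coords[, , 2])),
    z = as.vector(t(traj$coords[, , 3]))
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

.read_traj_csv <- function(path, dt = NULL, box_length = NULL) {
  if (is.null(box_length)) stop("box_length is required for csv trajectories")
  if (is.null(dt)) dt <- 1
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame", "particle", "species", "x", "y", "z")
  if (!all(need %in% names(df))) {
    stop("csv trajectory must have columns: ", paste(need, collapse = ", "))
  }
  frames_id <- sort(unique(df$frame))
  counts <- table(df$frame)
  if (length(unique(counts)) != 1) {
    bad <- names(counts)[counts != counts[1]][1]
    stop("frame ", bad, ": particle count ", counts[[bad]],
         " differs from frame ", names(counts)[1], " (", counts[[1]], ")")
  }
  df <- df[order(df$frame, df$particle), ]
  np <- counts[[1]]
  species <- df$species[df$frame == frames_id[1]]
  frames <- lapply(frames_id, function(f) {
    sub <- df[df$frame == f, ]
    as.matrix(sub[, c("x", "y", "z")])
  })
  .assemble_traj(frames, species, box_length, rep(NA_real_, length(frames)), dt)
}

#' Read a scalar/vector time series from CSV
#'
#' Accepts two-column (`time, value`) or four-column (`time, vx, vy, vz`)
#' tables with a header.
#'
#' @param path CSV path.
#' @return A [scalar_series()].
#' @export
read_scalar_series <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (ncol(df) == 2) {
    vals <- matrix(df[[2]], ncol = 1)
  } else if (ncol(df) == 4) {
    vals <- as.matrix(df[, 2:4])
  } else {
    stop("series CSV must have 2 (time,value) or 4 (time,vx,vy,vz) columns")
  }
  tt <- df[[1]]
  d <- diff(tt)
  if (length(d) == 0 || any(d <= 0) || diff(range(d)) > 1e-9 * max(abs(d))) {
    stop("series times must be strictly increasing with constant spacing")
  }
  scalar_series(vals, dt = d[1], time0 = tt[1])
}

#' Write a scalar/vector time series to CSV
#'
#' @param series A [scalar_series()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scalar_series <- function(series, path) {
  stopifnot(inherits(series, "scalar_series"))
  v <- series$values
  df <- if (ncol(v) == 1) {
    data.frame(time = series$times, value = v[, 1])
  } else {
    data.frame(time = series$times, vx = v[, 1], vy = v[, 2], vz = v[, 3])
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
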