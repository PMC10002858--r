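# Trajectory container: frames of coordinates + periodic box + timestamps.

#' Construct a trajectory
#'
#' @param system An `md_system`.
#' @param coords Numeric array `n_atoms x 3 x n_frames` (Angstrom).
#' @param box `n_frames x 3` matrix (or length-3 vector, recycled) of
#'   orthorhombic box lengths (Angstrom), all > 0.
#' @param time Numeric vector of frame times (ns), strictly increasing.
#'   Defaults to `0, dt, 2 dt, ...`.
#' @param dt Nominal frame spacing (ns); inferred from `time` when uniform.
#' @return Object of class `md_trajectory`.
#' @export
md_trajectory <- function(system, coords, box, time = NULL, dt = NULL) {
  stopifnot(inherits(system, "md_system"))
  if (length(dim(coords)) != 3 || dim(coords)[2] != 3) {
    stop("coords must be an n_atoms x 3 x n_frames array")
  }
  nf <- dim(coords)[3]
  if (nf < 1) stop("trajectory needs >= 1 frame")
  if (dim(coords)[1] != n_atoms(system)) {
    stop("coordinate count (", dim(coords)[1],
         ") does not match system atom count (", n_atoms(system), ")")
  }
  box <- .mat3(box, nf)
  if (nrow(box) != nf) stop("box must have one row per frame")
  if (any(box <= 0)) stop("box lengths must be > 0")
  if (is.null(time)) {
    if (is.null(dt)) dt <- 1
    time <- (seq_len(nf) - 1) * dt
  }
  if (length(time) != nf) stop("time must have one entry per frame")
  if (nf > 1 && any(diff(time) <= 0)) {
    stop("frame times must be strictly increasing")
  }
  if (is.null(dt)) {
    dt <- if (nf > 1) {
      steps <- diff(time)
      if (max(steps) - min(steps) < 1e-9 * max(steps)) steps[1] else mean(steps)
    } else 1
  }
  structure(list(system = system, coords = coords, box = box,
                 time = as.numeric(time), dt = dt),
            class = "md_trajectory")
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat("<md_trajectory> ", x$system$name, ": ", n_frames(x), " frames x ",
      n_atoms(x$system), " atoms, t = ", format(x$time[1]), "..",
      format(x$time[n_frames(x)]), " ns (dt ", format(x$dt), " ns)\n",
      sep = "")
  cat("  box: ", paste(format(x$box[1, ], digits = 4), collapse = " x "),
      " A\n", sep = "")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj An `md_trajectory`.
#' @return Integer frame count.
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' Coordinates of one frame
#' @param traj An `md_trajectory`.
#' @param i Frame index.
#' @return `n_atoms x 3` matrix (Angstrom).
#' @export
frame_coords <- function(traj, i) {
  m <- traj$coords[, , i, drop = FALSE]
  dim(m) <- dim(m)[1:2]
  m
}

#' Subset a trajectory by frame stride or range
#' @param traj An `md_trajectory`.
#' @param frames Integer vector of frame indices to keep (in order).
#' @return An `md_trajectory`.
#' @export
subset_frames <- function(traj, frames) {
  md_trajectory(traj$system, traj$coords[, , frames, drop = FALSE],
                traj$box[frames, , drop = FALSE], traj$time[frames])
}
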