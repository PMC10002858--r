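# Membrane insertion depth, tilt angle, 2D topology histograms and QC.

#' Membrane insertion depth time series
#'
#' Depth of a reference protein atom (conventionally the Cα of a
#' binding-loop glycine) relative to the mean z of the PS phosphate
#' atoms of the protein-containing leaflet. The sign is chosen so that
#' positive depth means displaced from the phosphate plane toward the
#' membrane midplane (deeper insertion), where the midplane is the mean z
#' of all lipid headgroup atoms. Leaflet membership is re-evaluated per
#' frame.
#'
#' @param traj An `md_trajectory`.
#' @param ref_idx Atom indices of the reference atom(s); their mean z is
#'   used.
#' @param phosphate_idx Atom indices of the phosphate atoms defining the
#'   reference plane (typically the PS phosphates).
#' @param headgroup_idx Lipid headgroup atom indices used for leaflet
#'   assignment and the midplane.
#' @param leaflet Leaflet whose phosphates define the plane (default
#'   `"lower"`, the protein-containing leaflet).
#' @return data.frame with `time` (ns), `depth` (Angstrom) and
#'   `plane_z` (Angstrom, the per-frame phosphate-plane position).
#' @export
insertion_depth <- function(traj, ref_idx, phosphate_idx, headgroup_idx,
                            leaflet = c("lower", "upper")) {
  leaflet <- match.arg(leaflet)
  if (!length(phosphate_idx)) stop("empty phosphate selection")
  if (!length(ref_idx)) stop("empty reference selection")
  atoms <- traj$system$atoms
  ph_mol <- atoms$molecule_id[phosphate_idx]
  nf <- n_frames(traj)
  depth <- numeric(nf)
  plane <- numeric(nf)
  for (i in seq_len(nf)) {
    xyz <- frame_coords(traj, i)
    leaf <- leaflet_assign(traj$system, xyz, headgroup_idx)
    keep <- leaf[as.character(ph_mol)] == leaflet
    if (!any(keep)) {
      stop("frame ", i, ": no phosphate atoms in the ", leaflet, " leaflet")
    }
    plane[i] <- mean(xyz[phosphate_idx[keep], 3])
    midplane <- mean(xyz[headgroup_idx, 3])
    s <- if (midplane >= plane[i]) 1 else -1
    depth[i] <- s * (mean(xyz[ref_idx, 3]) - plane[i])
  }
  data.frame(time = traj$time, depth = depth, plane_z = plane)
}

#' Tilt-angle time series
#'
#' Angle between the protein long axis and the membrane normal (z). The
#' long axis runs from the centroid of the lower-third residue Cα atoms to
#' the centroid of the upper-third residue Cα atoms; the angle is folded to
#' [0, 90] degrees. With `convention = "in_plane"` the complementary angle
#' (relative to the membrane plane) is returned instead.
#'
#' @param traj An `md_trajectory`.
#' @param upper_residues,lower_residues Residue numbers whose Cα atoms
#'   define the two centroids. Defaults are the upper-third /
#'   bottom-third marker residues of the C1b domain construct.
#' @param atom_name Atom name used per residue (default `"CA"`).
#' @param convention `"normal"` (0 = upright) or `"in_plane"` (90 =
#'   upright).
#' @return data.frame with `time` (ns) and `tilt` (degrees).
#' @export
tilt_angle <- function(traj,
                       upper_residues = c(239, 241, 253, 255),
                       lower_residues = c(233, 246, 263, 276),
                       atom_name = "CA",
                       convention = c("normal", "in_plane")) {
  convention <- match.arg(convention)
  atoms <- traj$system$atoms
  find_ca <- function(res) {
    idx <- vapply(res, function(r) {
      hit <- which(atoms$segment_kind == "protein" &
                     atoms$residue_seq == r & atoms$atom_name == atom_name)
      if (!length(hit)) {
        stop("residue ", r, " (atom ", atom_name, ") not found in system")
      }
      hit[1]
    }, 0L)
    idx
  }
  up <- find_ca(upper_residues)
  lo <- find_ca(lower_residues)
  nf <- n_frames(traj)
  tilt <- vapply(seq_len(nf), function(i) {
    xyz <- frame_coords(traj, i)
    v <- centroid(xyz[up, , drop = FALSE]) - centroid(xyz[lo, , drop = FALSE])
    nv <- sqrt(sum(v^2))
    if (nv < 1e-12) stop("frame ", i, ": degenerate axis (coincident centroids)")
    acos(min(1, abs(v[3]) / nv)) * 180 / pi
  }, 0)
  if (convention == "in_plane") tilt <- 90 - tilt
  data.frame(time = traj$time, tilt = tilt)
}

#' Pooled 2D depth-tilt topology histogram
#'
#' Pools one or more (depth, tilt) series into a 2D histogram. Values
#' outside the bin range are clamped into the edge bins (with a message).
#'
#' @param depth Numeric vector or list of vectors (Angstrom).
#' @param tilt Numeric vector or list of vectors (degrees), matching
#'   lengths.
#' @param depth_edges,tilt_edges Bin edges; defaults 0.5 Angstrom bins over
#'   [-5, 15] and 2 degree bins over [0, 90].
#' @return Object of class `topology_histogram`: list with `counts`
#'   (depth bins x tilt bins), the edges, `n` (frames pooled) and the
#'   pooled `depth_mean` / `tilt_mean`.
#' @export
topology_histogram <- function(depth, tilt,
                               depth_edges = seq(-5, 15, by = 0.5),
                               tilt_edges = seq(0, 90, by = 2)) {
  if (!is.list(depth)) depth <- list(depth)
  if (!is.list(tilt)) tilt <- list(tilt)
  if (length(depth) != length(tilt)) stop("depth/tilt series count mismatch")
  d <- unlist(depth); t_ <- unlist(tilt)
  if (length(d) != length(t_)) stop("depth/tilt lengths differ")
  if (!length(d)) stop("no frames to histogram")
  clamp <- function(x, edges) pmin(pmax(x, edges[1]), edges[length(edges)])
  n_out <- sum(d < depth_edges[1] | d > depth_edges[length(depth_edges)] |
                 t_ < tilt_edges[1] | t_ > tilt_edges[length(tilt_edges)])
  if (n_out) {
    message(n_out, " frame(s) outside bin range; clamped into edge bins")
  }
  di <- findInterval(clamp(d, depth_edges), depth_edges,
                     rightmost.closed = TRUE, all.inside = TRUE)
  ti <- findInterval(clamp(t_, tilt_edges), tilt_edges,
                     rightmost.closed = TRUE, all.inside = TRUE)
  counts <- matrix(0L, length(depth_edges) - 1, length(tilt_edges) - 1)
  for (k in seq_along(di)) counts[di[k], ti[k]] <- counts[di[k], ti[k]] + 1L
  structure(list(counts = counts, depth_edges = depth_edges,
                 tilt_edges = tilt_edges, n = length(d),
                 depth_mean = mean(d), tilt_mean = mean(t_)),
            class = "topology_histogram")
}

#' @export
print.topology_histogram <- function(x, ...) {
  cat("<topology_histogram> ", x$n, " frames pooled; mean depth ",
      format(x$depth_mean, digits = 4), " A, mean tilt ",
      format(x$tilt_mean, digits = 4), " deg\n", sep = "")
  invisible(x)
}

#' Area per lipid time series
#'
#' Lateral box area divided by the per-leaflet lipid count; a standard
#' membrane equilibration check (a stable APL indicates an equilibrated
#' bilayer).
#'
#' @param traj An `md_trajectory`.
#' @param composition A `membrane_composition` giving per-leaflet counts.
#' @return data.frame with `time` (ns), `upper` and `lower` (Angstrom^2).
#' @export
area_per_lipid <- function(traj, composition) {
  stopifnot(inherits(composition, "membrane_composition"))
  n_up <- sum(composition$upper); n_lo <- sum(composition$lower)
  if (n_up <= 0 || n_lo <= 0) stop("leaflet lipid counts must be > 0")
  area <- traj$box[, 1] * traj$box[, 2]
  data.frame(time = traj$time, upper = area / n_up, lower = area / n_lo)
}

#' Drift check on a scalar QC series
#'
#' Fits a linear trend to the trailing window of the series and compares
#' the absolute slope to a tolerance.
#'
#' @param series Numeric vector (e.g. depth or APL).
#' @param time Frame times in ns, same length.
#' @param window_ns Trailing window length (default 100 ns); the series
#'   must extend beyond it.
#' @param tolerance Maximum absolute slope considered stable, in series
#'   units per ns (default 0.01).
#' @return List with `verdict` (`"stable"`/`"drifting"`), `slope` (units
#'   per ns) and `window_frames`.
#' @export
stability_check <- function(series, time, window_ns = 100,
                            tolerance = 0.01) {
  if (length(series) != length(time)) stop("series/time length mismatch")
  span <- time[length(time)] - time[1]
  if (span <= window_ns) {
    stop("series (", format(span), " ns) not longer than window (",
         window_ns, " ns)")
  }
  keep <- time >= time[length(time)] - window_ns
  fit <- stats::lm.fit(cbind(1, time[keep]), series[keep])
  slope <- unname(fit$coefficients[2])
  list(verdict = if (abs(slope) <= tolerance) "stable" else "drifting",
       slope = slope, window_frames = sum(keep))
}
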