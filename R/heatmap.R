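# Lateral (x, y) localization heatmaps of tracked lipid atoms per leaflet,
# with mean protein Cα overlay points.

#' Construct a heatmap grid
#'
#' @param counts Numeric matrix (x bins x y bins), all >= 0.
#' @param x_edges,y_edges Bin edges (Angstrom), lengths `nrow(counts)+1` /
#'   `ncol(counts)+1`.
#' @param normalization `"counts"` or `"frequency"` (sums to 1).
#' @param overlay Optional data.frame of labeled points: `label`, `x`, `y`.
#' @return Object of class `heatmap_grid`.
#' @export
heatmap_grid <- function(counts, x_edges, y_edges,
                         normalization = c("counts", "frequency"),
                         overlay = NULL) {
  normalization <- match.arg(normalization)
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be >= 0")
  if (length(x_edges) != nrow(counts) + 1 ||
      length(y_edges) != ncol(counts) + 1) {
    stop("bin edges do not match counts dimensions")
  }
  structure(list(counts = counts, x_edges = x_edges, y_edges = y_edges,
                 normalization = normalization, overlay = overlay),
            class = "heatmap_grid")
}

#' @export
print.heatmap_grid <- function(x, ...) {
  cat("<heatmap_grid> ", nrow(x$counts), " x ", ncol(x$counts),
      " bins (", x$normalization, "), total ",
      format(sum(x$counts)), "\n", sep = "")
  if (!is.null(x$overlay)) {
    cat("  overlay: ", nrow(x$overlay), " point(s)\n", sep = "")
  }
  invisible(x)
}

#' Convert a counts grid to frequencies
#' @param grid A `heatmap_grid` with counts.
#' @return A `heatmap_grid` whose cells sum to 1 (unchanged if empty).
#' @export
normalize_grid <- function(grid) {
  tot <- sum(grid$counts)
  heatmap_grid(if (tot > 0) grid$counts / tot else grid$counts,
               grid$x_edges, grid$y_edges, "frequency", grid$overlay)
}

# Wrap values into [0, L) by the minimum image relative to the box center.
.wrap_into_box <- function(v, L) v - L * floor(v / L)

#' Lateral localization heatmap of tracked lipid atoms
#'
#' Per frame, every tracked atom whose parent lipid is assigned to the
#' chosen leaflet increments the bin containing its (x, y) position after
#' wrapping into the primary box image. With `recenter = TRUE` positions
#' are taken relative to the protein's lateral centroid (wrapped into
#' [-Lx/2, Lx/2) x [-Ly/2, Ly/2)), which removes lateral protein drift.
#'
#' @param traj An `md_trajectory`.
#' @param lipid_idx Atom indices of the tracked lipid atoms.
#' @param headgroup_idx Lipid headgroup atom indices for leaflet
#'   assignment (defaults to `lipid_idx`).
#' @param leaflet `"lower"` (default; the protein-containing leaflet) or
#'   `"upper"`.
#' @param bin_width Bin width in Angstrom (default 1).
#' @param recenter Recenter laterally on the protein centroid (default
#'   FALSE).
#' @param protein_idx Atoms defining the protein centroid when
#'   `recenter = TRUE` (default: protein Cα atoms).
#' @return A [heatmap_grid()] of counts.
#' @export
lipid_heatmap <- function(traj, lipid_idx, headgroup_idx = lipid_idx,
                          leaflet = c("lower", "upper"), bin_width = 1,
                          recenter = FALSE, protein_idx = NULL) {
  leaflet <- match.arg(leaflet)
  if (!length(lipid_idx)) stop("empty lipid selection")
  atoms <- traj$system$atoms
  if (any(atoms$segment_kind[lipid_idx] != "lipid")) {
    stop("lipid selection contains non-lipid atoms")
  }
  if (recenter && is.null(protein_idx)) {
    protein_idx <- which(atoms$segment_kind == "protein" &
                           atoms$atom_name == "CA")
    if (!length(protein_idx)) stop("no protein CA atoms for recentering")
  }
  Lx <- mean(traj$box[, 1]); Ly <- mean(traj$box[, 2])
  x_edges <- if (recenter) seq(-Lx / 2, Lx / 2 + bin_width, by = bin_width)
             else seq(0, Lx + bin_width, by = bin_width)
  y_edges <- if (recenter) seq(-Ly / 2, Ly / 2 + bin_width, by = bin_width)
             else seq(0, Ly + bin_width, by = bin_width)
  counts <- matrix(0L, length(x_edges) - 1, length(y_edges) - 1)
  mol <- atoms$molecule_id[lipid_idx]
  for (i in seq_len(n_frames(traj))) {
    xyz <- frame_coords(traj, i)
    leaf <- leaflet_assign(traj$system, xyz, headgroup_idx)
    keep <- leaf[as.character(mol)] == leaflet
    if (!any(keep)) next
    x <- xyz[lipid_idx[keep], 1]; y <- xyz[lipid_idx[keep], 2]
    bx <- traj$box[i, 1]; by <- traj$box[i, 2]
    if (recenter) {
      cen <- centroid(xyz[protein_idx, , drop = FALSE])
      x <- .wrap_into_box(x - cen[1] + bx / 2, bx) - bx / 2
      y <- .wrap_into_box(y - cen[2] + by / 2, by) - by / 2
    } else {
      x <- .wrap_into_box(x, bx)
      y <- .wrap_into_box(y, by)
    }
    xi <- findInterval(pmin(pmax(x, x_edges[1]), x_edges[length(x_edges)]),
                       x_edges, rightmost.closed = TRUE, all.inside = TRUE)
    yi <- findInterval(pmin(pmax(y, y_edges[1]), y_edges[length(y_edges)]),
                       y_edges, rightmost.closed = TRUE, all.inside = TRUE)
    for (k in seq_along(xi)) counts[xi[k], yi[k]] <- counts[xi[k], yi[k]] + 1L
  }
  heatmap_grid(counts, x_edges, y_edges, "counts")
}

#' Mean lateral protein positions
#'
#' Per-residue mean (x, y) over frames of the selected atoms (Cα by
#' default), under the same wrapping/recentering convention as
#' [lipid_heatmap()]; used as overlay points on lipid heatmaps.
#'
#' @param traj An `md_trajectory`.
#' @param ca_idx Atom indices (default: protein Cα atoms).
#' @param recenter Use protein-centroid-relative coordinates.
#' @return data.frame with `residue_seq`, `label`, `x`, `y` (Angstrom).
#' @export
mean_protein_positions <- function(traj, ca_idx = NULL, recenter = FALSE) {
  atoms <- traj$system$atoms
  if (is.null(ca_idx)) {
    ca_idx <- which(atoms$segment_kind == "protein" & atoms$atom_name == "CA")
  }
  if (!length(ca_idx)) stop("no atoms selected")
  nf <- n_frames(traj)
  acc_x <- numeric(length(ca_idx)); acc_y <- numeric(length(ca_idx))
  for (i in seq_len(nf)) {
    xyz <- frame_coords(traj, i)
    x <- xyz[ca_idx, 1]; y <- xyz[ca_idx, 2]
    bx <- traj$box[i, 1]; by <- traj$box[i, 2]
    if (recenter) {
      cen <- centroid(xyz[ca_idx, , drop = FALSE])
      x <- .wrap_into_box(x - cen[1] + bx / 2, bx) - bx / 2
      y <- .wrap_into_box(y - cen[2] + by / 2, by) - by / 2
    } else {
      x <- .wrap_into_box(x, bx)
      y <- .wrap_into_box(y, by)
    }
    acc_x <- acc_x + x; acc_y <- acc_y + y
  }
  res <- atoms$residue_seq[ca_idx]
  data.frame(residue_seq = res,
             label = paste0(atoms$residue_name[ca_idx], res),
             x = acc_x / nf, y = acc_y / nf)
}
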