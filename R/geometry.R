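# Periodic-boundary geometry and Kabsch superposition.

# Coerce to n x 3 and recycle single rows up to n.
.mat3 <- function(x, n = NULL) {
  m <- if (is.matrix(x)) x else matrix(x, ncol = 3, byrow = TRUE)
  if (!is.null(n) && nrow(m) == 1 && n > 1) m <- m[rep(1, n), , drop = FALSE]
  m
}

#' Minimum-image displacement under an orthorhombic box
#'
#' @param p1,p2 Numeric 3-vectors or n x 3 matrices (Angstrom).
#' @param box Length-3 box vector `(Lx, Ly, Lz)` or n x 3 matrix, all > 0.
#' @return n x 3 matrix of componentwise minimum-image displacements
#'   `p1 - p2`.
#' @export
min_image_displacement <- function(p1, p2, box) {
  n <- max(NROW(.mat3(p1)), NROW(.mat3(p2)))
  p1 <- .mat3(p1, n); p2 <- .mat3(p2, n); b <- .mat3(box, n)
  if (any(b <= 0)) stop("box lengths must be > 0")
  d <- p1 - p2
  d - b * round(d / b)
}

#' Minimum-image distance under an orthorhombic box
#'
#' Euclidean norm of the componentwise minimum-image displacement; the
#' standard convention for distances under periodic boundary conditions.
#'
#' @inheritParams min_image_displacement
#' @param periodic If `FALSE`, the plain (non-wrapped) distance is returned.
#' @return Numeric vector of distances (Angstrom).
#' @export
min_image_distance <- function(p1, p2, box, periodic = TRUE) {
  if (!periodic) {
    n <- max(NROW(.mat3(p1)), NROW(.mat3(p2)))
    d <- .mat3(p1, n) - .mat3(p2, n)
    return(sqrt(rowSums(d^2)))
  }
  d <- min_image_displacement(p1, p2, box)
  sqrt(rowSums(d^2))
}

#' Centroid of a point set
#'
#' @param points n x 3 matrix (or length-3 vector) of coordinates.
#' @return Length-3 numeric vector, the arithmetic mean.
#' @export
centroid <- function(points) {
  points <- if (is.matrix(points)) points else matrix(points, ncol = 3, byrow = TRUE)
  if (!nrow(points)) stop("centroid of an empty point set")
  colMeans(points)
}

#' Optimal rigid superposition (Kabsch algorithm)
#'
#' Finds the proper rotation `R` and translation `t` minimizing the RMSD of
#' `R %*% mobile + t` onto `reference`, via SVD of the covariance matrix
#' with reflection correction.
#'
#' @param mobile,reference N x 3 coordinate matrices, N >= 3, matching rows.
#' @return Object of class `rigid_transform`: list with `rotation` (3 x 3,
#'   det +1), `translation` (length 3) and `rmsd` (Angstrom) after
#'   superposition.
#' @export
kabsch_superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!all(dim(mobile) == dim(reference)) || ncol(mobile) != 3) {
    stop("mobile and reference must be matching N x 3 matrices")
  }
  n <- nrow(mobile)
  if (n < 3) stop("need at least 3 points for superposition")
  cm <- colMeans(mobile); cr <- colMeans(reference)
  P <- sweep(mobile, 2, cm); Q <- sweep(reference, 2, cr)
  sv_p <- svd(P)$d
  if (sv_p[2] < 1e-8 * max(sv_p[1], 1)) {
    stop("degenerate (collinear) point set: superposition not unique")
  }
  H <- crossprod(P, Q)  # 3x3 covariance
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  rotated <- P %*% t(R)
  rmsd <- sqrt(mean(rowSums((rotated - Q)^2)))
  structure(list(rotation = R,
                 translation = as.numeric(cr - R %*% cm),
                 rmsd = rmsd),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("<rigid_transform> rmsd after superposition: ",
      format(x$rmsd, digits = 6), " A\n", sep = "")
  invisible(x)
}

#' Apply a rigid transform to coordinates
#' @param transform A `rigid_transform`.
#' @param coords N x 3 matrix.
#' @return Transformed N x 3 matrix.
#' @export
apply_transform <- function(transform, coords) {
  coords <- as.matrix(coords)
  sweep(coords %*% t(transform$rotation), 2, transform$translation, `+`)
}

#' RMSD time series against a reference frame
#'
#' Each frame's selected atoms are optimally superposed (Kabsch) on the
#' reference frame's and the post-fit RMSD reported; the standard
#' equilibration QC trace. C-alpha atoms are the conventional selection.
#'
#' @param traj An `md_trajectory`.
#' @param atom_idx Atom indices used for fitting (default: all protein
#'   atoms named `CA`).
#' @param reference_frame Frame index of the reference (default 1).
#' @return data.frame with `time` (ns) and `rmsd` (Angstrom).
#' @export
rmsd_series <- function(traj, atom_idx = NULL, reference_frame = 1) {
  if (is.null(atom_idx)) {
    a <- traj$system$atoms
    atom_idx <- which(a$segment_kind == "protein" & a$atom_name == "CA")
  }
  if (length(atom_idx) < 3) stop("need >= 3 atoms for RMSD fitting")
  ref <- frame_coords(traj, reference_frame)[atom_idx, , drop = FALSE]
  vals <- vapply(seq_len(n_frames(traj)), function(i) {
    kabsch_superpose(frame_coords(traj, i)[atom_idx, , drop = FALSE], ref)$rmsd
  }, 0)
  data.frame(time = traj$time, rmsd = vals)
}
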