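# Independent oracles and small builders shared across tests.

# Minimum-image distance by brute force over all 27 periodic images.
brute_min_image <- function(p1, p2, box) {
  shifts <- expand.grid(x = -1:1, y = -1:1, z = -1:1)
  min(apply(shifts, 1, function(s) {
    sqrt(sum((p1 - (p2 + s * box))^2))
  }))
}

# Best-fit RMSD by direct numeric minimization over rotations (Euler
# angles, multi-start Nelder-Mead) after centering both point sets.
rmsd_numeric_oracle <- function(mobile, reference) {
  P <- sweep(mobile, 2, colMeans(mobile))
  Q <- sweep(reference, 2, colMeans(reference))
  rot <- function(ang) {
    ca <- cos(ang); sa <- sin(ang)
    Rz1 <- matrix(c(ca[1], sa[1], 0, -sa[1], ca[1], 0, 0, 0, 1), 3, 3)
    Ry <- matrix(c(ca[2], 0, -sa[2], 0, 1, 0, sa[2], 0, ca[2]), 3, 3)
    Rz2 <- matrix(c(ca[3], sa[3], 0, -sa[3], ca[3], 0, 0, 0, 1), 3, 3)
    Rz1 %*% Ry %*% Rz2
  }
  obj <- function(ang) sqrt(mean(rowSums((P %*% t(rot(ang)) - Q)^2)))
  best <- Inf
  for (s in seq_len(24)) {
    start <- c(s %% 4, (s %/% 4) %% 3, s %/% 12) * pi / 2 + 0.1
    fit <- stats::optim(start, obj, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-14))
    fit <- stats::optim(fit$par, obj, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-14))
    best <- min(best, fit$value)
  }
  best
}

# Standard error of the time-average of a stationary two-state chain with
# stationary occupancy p, using the effective sample size implied by the
# chain's lag-1 autocorrelation rho = 1 - q_on - q_off.
two_state_se <- function(p, mean_lifetime_ns, dt, n_total) {
  q_off <- dt / mean_lifetime_ns
  q_on <- q_off * p / (1 - p)
  rho <- 1 - q_on - q_off
  n_eff <- n_total * (1 - rho) / (1 + rho)
  sqrt(p * (1 - p) / n_eff)
}

# Minimal trajectory builder: atoms data.frame + list of n x 3 frames.
make_traj <- function(atoms, frames, box = c(60, 60, 90), dt = 1,
                      name = "test") {
  sys <- md_system(atoms, name = name)
  arr <- array(0, c(nrow(atoms), 3, length(frames)))
  for (i in seq_along(frames)) arr[, , i] <- frames[[i]]
  md_trajectory(sys, arr, box, time = (seq_along(frames) - 1) * dt)
}

# A lifetime_set with prescribed longest-segment and total durations.
lifetime_set_with <- function(max_ns, total_ns) {
  if (total_ns < max_ns) stop("total must be >= max")
  rest <- total_ns - max_ns
  segs <- max_ns
  while (rest > 1e-9) {
    s <- min(max_ns, rest)
    # avoid a second segment equal to max when it would change nothing
    segs <- c(segs, s)
    rest <- rest - s
  }
  lifetime_set(segs)
}

synthetic_selections <- function() {
  read_selection_spec(default_selection_path("synthetic"))
}

# Minimal protein whose long-axis direction is prescribed: the four upper
# and four lower marker residues sit around the +/- axis endpoints with
# perpendicular offsets that cancel within each quartet.
tilt_toy <- function(axis) {
  axis <- axis / sqrt(sum(axis^2))
  up_res <- c(239, 241, 253, 255)
  lo_res <- c(233, 246, 263, 276)
  names <- c("MET", "PRO", "GLY", "VAL", "PRO", "HIS", "ASP", "VAL")
  atoms <- data.frame(
    atom_name = "CA", residue_name = names,
    residue_seq = c(up_res, lo_res))
  perp <- if (abs(axis[3]) < 0.9) {
    v <- c(-axis[2], axis[1], 0)
    v / sqrt(sum(v^2))
  } else c(1, 0, 0)
  offs <- rbind(perp, -perp, 2 * perp, -2 * perp)
  up <- sweep(offs, 2, 10 * axis, `+`)
  lo <- sweep(offs, 2, -10 * axis, `+`)
  frames <- list(sweep(rbind(up, lo), 2, c(30, 30, 45), `+`))
  make_traj(atoms, frames, box = c(90, 90, 90))
}

# Minimal selection spec covering only what a (fixture) system contains:
# one NZ probe group per lysine present, one lipid probe group per lipid
# class present, and a headgroups reference over all lipid atoms.
mini_selections <- function(sys) {
  a <- sys$atoms
  groups <- list()
  for (r in unique(a$residue_seq[a$residue_name == "LYS" &
                                 a$atom_name == "NZ"])) {
    groups[[length(groups) + 1]] <- list(
      name = paste0("K", r, "_NZ"), role = "protein_probe",
      atoms = list(list(residue_seq = r, atom_name = "NZ")))
  }
  lip <- a[a$segment_kind == "lipid", ]
  for (cls in unique(lip$lipid_class)) {
    nm <- unique(lip$atom_name[lip$lipid_class == cls])
    groups[[length(groups) + 1]] <- list(
      name = cls, role = "lipid_probe",
      atoms = lapply(nm, function(x) list(lipid_class = cls, atom_name = x)))
  }
  groups[[length(groups) + 1]] <- list(
    name = "headgroups", role = "reference",
    atoms = lapply(unique(lip$atom_name), function(x) list(atom_name = x)))
  selection_spec(groups)
}
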