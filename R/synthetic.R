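# Synthetic membrane-protein trajectories with known ground truth:
# bilayer composition, lateral lipid diffusion, planted two-state binding
# kinetics, planted insertion depth and tilt.

# Synthetic residue naming per lipid class, and the single headgroup
# pseudo-atom carried by each lipid.
.synthetic_lipid_residue <- c(CHOL = "CHL1", PC = "POPC", PE = "POPE",
                              PS = "SOPS", PA = "POPA", PIP = "PLPI",
                              CER = "CER1")
.synthetic_headgroup_atom <- c(CHOL = "O3", PC = "P", PE = "P", PS = "P",
                               PA = "P", PIP = "P", CER = "O1")

# Rigid pseudo-Calpha scaffold of the C1b-like construct in body frame
# (z = long axis). The upper-third marker residues (239, 241, 253, 255)
# have their Calpha centroid exactly on the axis at +10, the bottom-third
# markers (233, 246, 263, 276) at -10, so the planted tilt is recovered
# exactly by the centroid construction. Probe pseudo-atoms (lysine NZ,
# backbone N/O, SER OG, TRP NE1) sit 1.5 A radially outside their Calpha.
.protein_scaffold <- function() {
  res_names <- c(
    "233" = "PRO", "239" = "MET", "240" = "SER", "241" = "PRO",
    "242" = "THR", "246" = "HIS", "250" = "LEU", "252" = "TRP",
    "253" = "GLY", "255" = "VAL", "256" = "LYS", "260" = "LYS",
    "263" = "ASP", "271" = "LYS", "275" = "LYS", "276" = "VAL"
  )
  seqs <- 231:280
  name_of <- function(r) {
    n <- res_names[as.character(r)]
    if (is.na(n)) "ALA" else n
  }
  upper <- c(239, 241, 253, 255); lower <- c(233, 246, 263, 276)
  special_axial <- c("256" = -2, "260" = 0, "271" = -4, "275" = -5)
  special_az <- c("256" = 0, "260" = 180, "271" = 20, "275" = 350)
  probes <- list(
    "250" = "N", "252" = "NE1", "240" = c("OG", "N"), "241" = c("O", "N"),
    "253" = "N", "256" = "NZ", "260" = "NZ", "271" = "NZ", "275" = "NZ"
  )
  rows <- list()
  r_ca <- 3
  for (k in seq_along(seqs)) {
    r <- seqs[k]
    key <- as.character(r)
    if (r %in% upper) {
      a <- 10; az <- (match(r, upper) - 1) * 90
    } else if (r %in% lower) {
      a <- -10; az <- 45 + (match(r, lower) - 1) * 90
    } else if (key %in% names(special_axial)) {
      a <- special_axial[key]; az <- special_az[key]
    } else {
      a <- -12 + 24 * (k - 1) / (length(seqs) - 1); az <- (100 * k) %% 360
    }
    azr <- az * pi / 180
    rows[[length(rows) + 1]] <- data.frame(
      residue_seq = r, residue_name = name_of(r), atom_name = "CA",
      bx = r_ca * cos(azr), by = r_ca * sin(azr), bz = a)
    pr <- probes[[key]]
    if (!is.null(pr)) {
      for (pi_ in seq_along(pr)) {
        paz <- azr + (pi_ - 1) * 15 * pi / 180
        rows[[length(rows) + 1]] <- data.frame(
          residue_seq = r, residue_name = name_of(r), atom_name = pr[pi_],
          bx = (r_ca + 1.5) * cos(paz), by = (r_ca + 1.5) * sin(paz), bz = a)
      }
    }
  }
  do.call(rbind, rows)
}

#' Parameters for the synthetic trajectory generator
#'
#' Defaults emulate the simulated study systems at desk scale: the
#' phorbol-system bilayer composition (66/59 lipids per leaflet), a
#' 60 x 60 x 90 Angstrom orthorhombic box, 500 ns of frames at 0.1 ns
#' spacing, phosphate planes at +/-20 Angstrom, and a planted insertion
#' depth of 8 +/- 1 Angstrom with a 48 +/- 5 degree tilt.
#'
#' @param composition A `membrane_composition` (default: the
#'   phorbol-system bilayer, [reference_composition()]).
#' @param box Box lengths `(Lx, Ly, Lz)` in Angstrom.
#' @param n_frames Number of frames.
#' @param dt Frame spacing (ns).
#' @param lipid_step_sd Lateral Gaussian step of the lipid random walk
#'   (Angstrom per frame).
#' @param lipid_z_sd Per-frame Gaussian jitter of headgroup z about the
#'   leaflet plane (Angstrom).
#' @param half_thickness Distance of each headgroup plane from the
#'   midplane (Angstrom).
#' @param depth_mean,depth_sd Planted insertion depth of the reference
#'   residue (G253 Calpha), Angstrom.
#' @param tilt_mean,tilt_sd Planted tilt angle, degrees.
#' @param contact_plan data.frame of planted binding episodes with columns
#'   `groups` (probe group name, or several joined by `+` for a bridged
#'   multivalent contact), `lipid_class`, `occupancy` (stationary
#'   probability p, in (0,1)), `mean_lifetime_ns` (> dt; `Inf` gives the
#'   absorbing always-bound limit) and optional `lipid_index` (which
#'   lower-leaflet molecule of the class is planted; default: entries get
#'   distinct molecules in order).
#' @param contact_cutoff When bound, the lipid is placed uniformly in a
#'   2 to `contact_cutoff - 0.5` Angstrom shell of the probe; when
#'   unbound, at least `unbound_min` away from every probe atom.
#' @param unbound_min Minimum probe distance of an unbound planted lipid.
#' @param seed RNG seed (integer).
#' @return Object of class `synthetic_params` (validated list).
#' @export
synthetic_params <- function(composition = reference_composition("phorbol"),
                             box = c(60, 60, 90),
                             n_frames = 5000, dt = 0.1,
                             lipid_step_sd = 1, lipid_z_sd = 0.3,
                             half_thickness = 20,
                             depth_mean = 8, depth_sd = 1,
                             tilt_mean = 48, tilt_sd = 5,
                             contact_plan = NULL,
                             contact_cutoff = 6, unbound_min = 8,
                             seed = 1) {
  stopifnot(inherits(composition, "membrane_composition"))
  if (length(box) != 3 || any(box <= 0)) stop("box must be 3 positive lengths")
  if (n_frames < 1) stop("n_frames must be >= 1")
  if (dt <= 0) stop("dt must be > 0")
  # feasibility: each leaflet must fit its lipids at >= 5 A spacing
  max_leaf <- max(sum(composition$upper), sum(composition$lower))
  if (box[1] * box[2] < max_leaf * 25) {
    stop("box too small for composition at >= 5 A lipid spacing")
  }
  if (is.null(contact_plan)) {
    contact_plan <- data.frame(groups = character(), lipid_class = character(),
                               occupancy = numeric(),
                               mean_lifetime_ns = numeric(),
                               lipid_index = integer())
  }
  if (nrow(contact_plan)) {
    if (is.null(contact_plan$lipid_index)) {
      contact_plan$lipid_index <- NA_integer_
    }
    for (cls in unique(contact_plan$lipid_class)) {
      rows <- which(contact_plan$lipid_class == cls)
      free <- setdiff(seq_len(1e6), contact_plan$lipid_index[rows])
      na_rows <- rows[is.na(contact_plan$lipid_index[rows])]
      contact_plan$lipid_index[na_rows] <- free[seq_along(na_rows)]
      if (anyDuplicated(contact_plan$lipid_index[rows])) {
        stop("contact_plan assigns one lipid molecule to several entries")
      }
    }
    ok_p <- contact_plan$occupancy > 0 & contact_plan$occupancy < 1
    ok_p <- ok_p | (is.infinite(contact_plan$mean_lifetime_ns) &
                      contact_plan$occupancy > 0 & contact_plan$occupancy <= 1)
    if (!all(ok_p)) stop("planted occupancy must be in (0, 1)")
    if (any(contact_plan$mean_lifetime_ns <= dt)) {
      stop("mean_lifetime_ns must exceed dt")
    }
    lower_counts <- stats::setNames(composition$lower, composition$lipid_class)
    for (i in seq_len(nrow(contact_plan))) {
      cls <- contact_plan$lipid_class[i]
      if (!(cls %in% names(lower_counts)) ||
          contact_plan$lipid_index[i] > lower_counts[cls]) {
        stop("contact_plan row ", i, ": no lower-leaflet ", cls,
             " molecule with index ", contact_plan$lipid_index[i])
      }
    }
  }
  structure(list(composition = composition, box = box, n_frames = n_frames,
                 dt = dt, lipid_step_sd = lipid_step_sd,
                 lipid_z_sd = lipid_z_sd, half_thickness = half_thickness,
                 depth_mean = depth_mean, depth_sd = depth_sd,
                 tilt_mean = tilt_mean, tilt_sd = tilt_sd,
                 contact_plan = contact_plan,
                 contact_cutoff = contact_cutoff, unbound_min = unbound_min,
                 seed = as.integer(seed)),
            class = "synthetic_params")
}

#' Build the static synthetic system for a composition
#'
#' Protein first (rigid pseudo-Calpha scaffold, residues 231-280 with
#' probe pseudo-atoms), then upper-leaflet lipids, then lower-leaflet
#' lipids, each lipid a single headgroup pseudo-atom. Residue/atom naming
#' matches the shipped `selections_synthetic.yaml`.
#'
#' @param composition A `membrane_composition`.
#' @param name System name.
#' @return An [md_system()]; lipid rows are ordered upper leaflet first,
#'   then lower, class order as in `composition`.
#' @export
synthetic_system <- function(composition, name = "synthetic") {
  scaf <- .protein_scaffold()
  prot <- data.frame(atom_name = scaf$atom_name,
                     residue_name = scaf$residue_name,
                     residue_seq = scaf$residue_seq)
  lip_rows <- list()
  next_seq <- 1000L
  for (leaf in c("upper", "lower")) {
    for (i in seq_len(nrow(composition))) {
      cls <- composition$lipid_class[i]
      n <- composition[[leaf]][i]
      if (n < 1) next
      lip_rows[[length(lip_rows) + 1]] <- data.frame(
        atom_name = unname(.synthetic_headgroup_atom[cls]),
        residue_name = unname(.synthetic_lipid_residue[cls]),
        residue_seq = next_seq + seq_len(n) - 1L)
      next_seq <- next_seq + n
    }
  }
  md_system(rbind(prot, do.call(rbind, lip_rows)), name = name)
}

# Two-state chain: per-frame switch probabilities q_off = dt/mean_lifetime,
# q_on = q_off * p / (1 - p); stationary occupancy p. mean_lifetime = Inf
# gives q_off = 0 with a bound start (absorbing limit).
.simulate_chain <- function(n, p, mean_lifetime, dt) {
  if (is.infinite(mean_lifetime)) return(rep(TRUE, n))
  q_off <- dt / mean_lifetime
  q_on <- q_off * p / (1 - p)
  if (q_on > 1 || q_off > 1) {
    stop("infeasible chain: switch probability exceeds 1 ",
         "(increase mean_lifetime or dt resolution)")
  }
  s <- logical(n)
  s[1] <- stats::runif(1) < p
  u <- stats::runif(n - 1)
  for (i in seq_len(n - 1)) {
    s[i + 1] <- if (s[i]) u[i] >= q_off else u[i] < q_on
  }
  s
}

.unit_vector <- function() {
  repeat {
    v <- stats::rnorm(3)
    n <- sqrt(sum(v^2))
    if (n > 1e-8) return(v / n)
  }
}

#' Simulate a synthetic membrane-protein trajectory
#'
#' Deterministic given `params$seed`. Lipids carry one headgroup
#' pseudo-atom on two z-planes at +/- `half_thickness` with a lateral
#' Gaussian random walk (periodic wrap) and per-frame z jitter. The rigid
#' protein scaffold is placed at the planted depth and tilt with per-frame
#' Gaussian jitter. Each contact-plan entry drives a two-state Markov
#' chain; on bound frames the designated lower-leaflet lipid is placed
#' within the contact shell of its probe group(s), on unbound frames it is
#' kept at least `unbound_min` away from every probe atom.
#'
#' @param params A [synthetic_params()].
#' @param out_dir Optional directory: writes `structure.pdb`, `frames.pdb`,
#'   `frames.gro` and `ground_truth.json` there.
#' @return List with `trajectory` (an [md_trajectory()]) and `truth`
#'   (chain states, realized occupancy and lifetimes per planted pair,
#'   planted depth/tilt series, planted molecule ids, leaflet of every
#'   lipid molecule).
#' @export
simulate_trajectory <- function(params, out_dir = NULL) {
  stopifnot(inherits(params, "synthetic_params"))
  set.seed(params$seed)
  comp <- params$composition
  nf <- params$n_frames
  sys <- synthetic_system(comp)
  atoms <- sys$atoms
  box <- params$box
  coords <- array(0, c(nrow(atoms), 3, nf))

  # --- lipids: lateral random walk + z jitter -------------------------
  lip_idx <- which(atoms$segment_kind == "lipid")
  n_up <- sum(comp$upper)
  leaflet_of <- c(rep("upper", n_up), rep("lower", sum(comp$lower)))
  plane_of <- ifelse(leaflet_of == "upper",
                     params$half_thickness, -params$half_thickness)
  n_lip <- length(lip_idx)
  for (ax in 1:2) {
    x0 <- stats::runif(n_lip, 0, box[ax])
    steps <- matrix(stats::rnorm((nf - 1) * n_lip, 0, params$lipid_step_sd),
                    nrow = nf - 1, ncol = n_lip)
    pos <- apply(rbind(matrix(x0, nrow = 1), steps), 2, cumsum)
    if (nf == 1) pos <- matrix(pos, nrow = 1)  # apply drops to a vector
    pos <- .wrap_into_box(pos, box[ax])        # nf x n_lip
    coords[lip_idx, ax, ] <- t(pos)
  }
  zjit <- matrix(stats::rnorm(nf * n_lip, 0, params$lipid_z_sd), nrow = nf)
  coords[lip_idx, 3, ] <- t(sweep(zjit, 2, plane_of, `+`))

  # --- protein: rigid scaffold at planted depth/tilt ------------------
  scaf <- .protein_scaffold()
  body <- as.matrix(scaf[, c("bx", "by", "bz")])
  prot_idx <- which(atoms$segment_kind == "protein")
  g253 <- which(scaf$residue_seq == 253 & scaf$atom_name == "CA")
  depth_t <- params$depth_mean + stats::rnorm(nf, 0, params$depth_sd)
  tilt_t <- params$tilt_mean + stats::rnorm(nf, 0, params$tilt_sd)
  tilt_t <- pmin(pmax(tilt_t, 0), 180)
  phi <- stats::runif(1, 0, 2 * pi)
  cen_xy <- box[1:2] / 2
  for (i in seq_len(nf)) {
    th <- tilt_t[i] * pi / 180
    Ry <- matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)), 3, 3)
    Rz <- matrix(c(cos(phi), sin(phi), 0, -sin(phi), cos(phi), 0, 0, 0, 1),
                 3, 3)
    R <- Rz %*% Ry
    rot <- body %*% t(R)
    target_z <- -params$half_thickness + depth_t[i]
    shift <- c(cen_xy[1] - mean(rot[, 1]), cen_xy[2] - mean(rot[, 2]),
               target_z - rot[g253, 3])
    coords[prot_idx, , i] <- sweep(rot, 2, shift, `+`)
  }

  # --- planted contacts ----------------------------------------------
  plan <- params$contact_plan
  sel <- selection_by_role(
    read_selection_spec(default_selection_path("synthetic")),
    "protein_probe")
  resolved <- resolve_selection(sys, sel)
  probe_atoms_all <- unique(unlist(resolved))
  chains <- matrix(FALSE, nf, nrow(plan))
  planted_mol <- integer(nrow(plan))
  lip_mol <- atoms$molecule_id[lip_idx]
  for (e in seq_len(nrow(plan))) {
    cls <- plan$lipid_class[e]
    cls_lower <- which(leaflet_of == "lower" &
                         atoms$lipid_class[lip_idx] == cls)
    tgt <- cls_lower[plan$lipid_index[e]]  # position within lip_idx
    planted_mol[e] <- lip_mol[tgt]
    grps <- strsplit(plan$groups[e], "+", fixed = TRUE)[[1]]
    miss <- setdiff(grps, names(resolved))
    if (length(miss)) {
      stop("contact_plan group(s) not in synthetic selections: ",
           paste(miss, collapse = ", "))
    }
    probe_idx <- lapply(grps, function(g) resolved[[g]])
    chains[, e] <- .simulate_chain(nf, plan$occupancy[e],
                                   plan$mean_lifetime_ns[e], params$dt)
    tgt_atom <- lip_idx[tgt]
    for (i in seq_len(nf)) {
      probes <- matrix(coords[unlist(probe_idx), , i], ncol = 3)
      anchor <- colMeans(probes)
      if (chains[i, e]) {
        if (length(grps) == 1) {
          pos <- anchor + .unit_vector() *
            stats::runif(1, 2, params$contact_cutoff - 0.5)
        } else {
          pos <- anchor + .unit_vector() * stats::runif(1, 0, 0.5)
        }
        coords[tgt_atom, , i] <- pos
      } else {
        pos <- coords[tgt_atom, , i]
        push <- 0
        while (push < 20) {
          dmin <- min(min_image_distance(
            matrix(coords[probe_atoms_all, , i], ncol = 3), pos, box))
          if (dmin >= params$unbound_min) break
          dir_xy <- pos[1:2] - cen_xy
          nrm <- sqrt(sum(dir_xy^2))
          if (nrm < 1e-6) { dir_xy <- c(1, 0); nrm <- 1 }
          pos[1:2] <- pos[1:2] + dir_xy / nrm * 2
          push <- push + 1
        }
        if (push >= 20) stop("could not place unbound planted lipid")
        coords[tgt_atom, , i] <- pos
      }
    }
  }

  traj <- md_trajectory(sys, coords, box,
                        time = (seq_len(nf) - 1) * params$dt)
  realized_lt <- lapply(seq_len(ncol(chains)), function(e) {
    r <- rle(chains[, e])
    r$lengths[r$values] * params$dt
  })
  truth <- list(
    chains = chains,
    plan = plan,
    planted_molecule_id = planted_mol,
    realized_occupancy = if (ncol(chains)) colMeans(chains) else numeric(0),
    realized_lifetimes = realized_lt,
    depth = depth_t, tilt = tilt_t,
    leaflet = stats::setNames(leaflet_of,
                              atoms$molecule_id[lip_idx][!duplicated(lip_mol)])
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_trajectory(subset_frames(traj, 1), file.path(out_dir, "structure.pdb"))
    write_trajectory(traj, file.path(out_dir, "frames.pdb"))
    write_trajectory(traj, file.path(out_dir, "frames.gro"))
    jsonlite::write_json(
      list(plan = plan, planted_molecule_id = planted_mol,
           realized_occupancy = truth$realized_occupancy,
           realized_lifetimes = realized_lt,
           depth_mean_realized = mean(depth_t),
           tilt_mean_realized = mean(tilt_t)),
      file.path(out_dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  }
  list(trajectory = traj, truth = truth)
}
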