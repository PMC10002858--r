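# Tiny hand-built fixture trajectories, generated in code (no stored data).

#' Write the worked-example fixture files
#'
#' Builds four miniature trajectories used in documentation and tests:
#'
#' * `three_atoms.pdb` — one frame, a single glycine (N, CA, C);
#' * `occupancy10.pdb` — 10 frames of one lysine NZ probe and one PS
#'   lipid at probe distances 5,5,7,5,7,7,5,5,7,7 Angstrom, so the 6
#'   Angstrom-cutoff occupancy is exactly 0.5;
#' * `bridge.pdb` — one frame in which a single PS lipid sits within the
#'   cutoff of both K271 and K275 probes (a multivalent contact);
#' * `empty.pdb` — 5 frames in which the lipid never approaches the probe
#'   (all-zero contact tables).
#'
#' @param dir Output directory (created if needed).
#' @return Named character vector of file paths.
#' @export
worked_fixtures <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  box <- c(60, 60, 90)
  mk <- function(atoms, coords_list, name) {
    sys <- md_system(atoms, name = name)
    arr <- array(0, c(nrow(atoms), 3, length(coords_list)))
    for (i in seq_along(coords_list)) arr[, , i] <- coords_list[[i]]
    md_trajectory(sys, arr, box, time = (seq_along(coords_list) - 1) * 1)
  }
  paths <- character(0)

  gly <- data.frame(atom_name = c("N", "CA", "C"),
                    residue_name = "GLY", residue_seq = 1)
  tr <- mk(gly, list(rbind(c(10, 10, 10), c(11.2, 10.4, 10),
                           c(12.1, 11.3, 10.5))), "three_atoms")
  paths["three_atoms"] <- file.path(dir, "three_atoms.pdb")
  write_trajectory(tr, paths["three_atoms"])

  probe_lip <- data.frame(
    atom_name = c("NZ", "P"),
    residue_name = c("LYS", "SOPS"),
    residue_seq = c(256, 1001))
  d10 <- c(5, 5, 7, 5, 7, 7, 5, 5, 7, 7)
  frames <- lapply(d10, function(d) {
    rbind(c(30, 30, -12), c(30 + d, 30, -12))
  })
  paths["occupancy10"] <- file.path(dir, "occupancy10.pdb")
  write_trajectory(mk(probe_lip, frames, "occupancy10"), paths["occupancy10"])

  bridge <- data.frame(
    atom_name = c("NZ", "NZ", "P"),
    residue_name = c("LYS", "LYS", "SOPS"),
    residue_seq = c(271, 275, 1001))
  paths["bridge"] <- file.path(dir, "bridge.pdb")
  write_trajectory(mk(bridge, list(rbind(c(30, 30, -15), c(33, 30, -15),
                                         c(31.5, 30, -12))), "bridge"),
                   paths["bridge"])

  frames_empty <- lapply(1:5, function(i) {
    rbind(c(30, 30, -12), c(10, 10, -20))
  })
  paths["empty"] <- file.path(dir, "empty.pdb")
  write_trajectory(mk(probe_lip, frames_empty, "empty"), paths["empty"])

  paths
}
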