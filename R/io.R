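# File I/O: PDB (via bio3d) and GRO structures and frame sequences,
# CSV tables, plain-text heatmap grid container.

.guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("pdb", "ent")) return("pdb")
  if (ext == "gro") return("gro")
  stop("cannot guess format of '", path, "'; pass format explicitly")
}

#' Read a structure file into a molecular system
#'
#' Supports PDB (parsed with bio3d) and GRO. For multi-frame files the atom
#' table of the first frame defines the system. GRO coordinates are in nm in
#' the file and are converted to Angstrom.
#'
#' @param path Path to a `.pdb` or `.gro` file.
#' @param format `"auto"` (by extension), `"pdb"` or `"gro"`.
#' @param name System name (defaults to the file name).
#' @param lipid_table Residue-name to lipid-class mapping, see
#'   [default_lipid_table()].
#' @param ligand_residues Residue names classified as ligand.
#' @return An [md_system()].
#' @export
read_structure <- function(path, format = c("auto", "pdb", "gro"),
                           name = NULL,
                           lipid_table = default_lipid_table(),
                           ligand_residues = character()) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") format <- .guess_format(path)
  if (is.null(name)) name <- basename(path)
  atoms <- if (format == "pdb") {
    pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
    data.frame(atom_name = pdb$atom$elety,
               residue_name = pdb$atom$resid,
               residue_seq = pdb$atom$resno)
  } else {
    g <- .parse_gro(path, first_only = TRUE)
    g$atoms
  }
  md_system(atoms, name = name, lipid_table = lipid_table,
            ligand_residues = ligand_residues)
}

#' Read trajectory frames
#'
#' Reads a multi-model PDB (MODEL/ENDMDL blocks) or a concatenated GRO file
#' into an [md_trajectory()]. Frame times are taken from `REMARK ... TIME=`
#' lines (PDB) or `t=` tokens on GRO title lines when present (a bare `t=`
#' value is interpreted as ps, the GROMACS convention, and converted to ns;
#' an explicit `ns` unit is honoured); otherwise times are `0, dt, ...`.
#'
#' @param path Path to the frames file.
#' @param system Optional `md_system`; derived from the file if `NULL`.
#'   Frame atom counts are validated against it.
#' @param format `"auto"`, `"pdb"` or `"gro"`.
#' @param dt Frame spacing in ns used when the file carries no times.
#' @inheritParams read_structure
#' @return An [md_trajectory()].
#' @export
read_frames <- function(path, system = NULL, format = c("auto", "pdb", "gro"),
                        dt = 1,
                        lipid_table = default_lipid_table(),
                        ligand_residues = character()) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") format <- .guess_format(path)
  if (is.null(system)) {
    system <- read_structure(path, format, lipid_table = lipid_table,
                             ligand_residues = ligand_residues)
  }
  nat <- n_atoms(system)
  if (format == "pdb") {
    lines <- readLines(path)
    pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
    xyz <- pdb$xyz
    if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
    nf <- nrow(xyz)
    if (ncol(xyz) != 3 * nat) {
      stop("frame 1: atom count ", ncol(xyz) / 3,
           " does not match system atom count ", nat)
    }
    coords <- aperm(array(t(xyz), c(3, nat, nf)), c(2, 1, 3))
    cryst <- lines[startsWith(lines, "CRYST1")]
    box <- if (length(cryst)) {
      b <- t(vapply(cryst, function(l) {
        as.numeric(c(substr(l, 7, 15), substr(l, 16, 24), substr(l, 25, 33)))
      }, numeric(3)))
      rownames(b) <- NULL
      if (nrow(b) == 1) b[rep(1, nf), , drop = FALSE]
      else if (nrow(b) == nf) b
      else stop("found ", nrow(b), " CRYST1 records for ", nf, " frames")
    } else {
      warning("no CRYST1 record; using a nominal 1e6 A box (no wrapping)")
      matrix(1e6, nf, 3)
    }
    tl <- lines[grepl("^REMARK .*TIME=", lines)]
    time <- if (length(tl) == nf) {
      as.numeric(sub(".*TIME= *([-0-9.eE+]+).*", "\\1", tl))
    } else NULL
    md_trajectory(system, coords, box, time = time,
                  dt = if (is.null(time)) dt else NULL)
  } else {
    g <- .parse_gro(path, first_only = FALSE)
    nf <- length(g$frames)
    for (i in seq_len(nf)) {
      if (nrow(g$frames[[i]]) != nat) {
        stop("frame ", i, ": atom count ", nrow(g$frames[[i]]),
             " does not match system atom count ", nat)
      }
    }
    coords <- array(0, c(nat, 3, nf))
    for (i in seq_len(nf)) coords[, , i] <- as.matrix(g$frames[[i]])
    time <- g$times
    if (anyNA(time)) time <- NULL
    md_trajectory(system, coords, do.call(rbind, g$boxes), time = time,
                  dt = if (is.null(time)) dt else NULL)
  }
}

# Fixed-column GRO parser. Returns atom table of the first frame plus, unless
# first_only, per-frame coordinate matrices (A), boxes (A) and times (ns).
.parse_gro <- function(path, first_only = FALSE) {
  lines <- readLines(path)
  pos <- 1L
  frames <- list(); boxes <- list(); times <- numeric(0); atoms <- NULL
  frame_i <- 0L
  while (pos <= length(lines)) {
    if (!nzchar(trimws(lines[pos]))) { pos <- pos + 1L; next }
    frame_i <- frame_i + 1L
    title <- lines[pos]
    nat <- suppressWarnings(as.integer(trimws(lines[pos + 1L])))
    if (is.na(nat)) {
      stop("malformed GRO atom-count line at line ", pos + 1L)
    }
    if (pos + 1L + nat + 1L > length(lines)) {
      stop("truncated GRO frame ", frame_i, " starting at line ", pos)
    }
    al <- lines[(pos + 2L):(pos + 1L + nat)]
    x <- suppressWarnings(as.numeric(substr(al, 21, 28)))
    y <- suppressWarnings(as.numeric(substr(al, 29, 36)))
    z <- suppressWarnings(as.numeric(substr(al, 37, 44)))
    if (anyNA(x) || anyNA(y) || anyNA(z)) {
      bad <- pos + 1L + which(is.na(x) | is.na(y) | is.na(z))[1]
      stop("malformed GRO atom record at line ", bad)
    }
    if (is.null(atoms)) {
      atoms <- data.frame(
        residue_seq = as.integer(substr(al, 1, 5)),
        residue_name = trimws(substr(al, 6, 10)),
        atom_name = trimws(substr(al, 11, 15))
      )[, c("atom_name", "residue_name", "residue_seq")]
    }
    bl <- as.numeric(strsplit(trimws(lines[pos + 2L + nat]), "\\s+")[[1]])
    if (length(bl) < 3 || anyNA(bl[1:3])) {
      stop("malformed GRO box line at line ", pos + 2L + nat)
    }
    # nm -> Angstrom
    frames[[frame_i]] <- cbind(x, y, z) * 10
    boxes[[frame_i]] <- bl[1:3] * 10
    t_ns <- NA_real_
    m <- regmatches(title, regexec("t= *([-0-9.eE+]+) *(ns|ps)?", title))[[1]]
    if (length(m) >= 2 && nzchar(m[2])) {
      t_ns <- as.numeric(m[2])
      if (!identical(m[3], "ns")) t_ns <- t_ns / 1000  # ps -> ns
    }
    times[frame_i] <- t_ns
    if (first_only) break
    pos <- pos + 2L + nat + 1L
  }
  if (!frame_i) stop("no frames found in ", path)
  list(atoms = atoms, frames = frames, boxes = boxes, times = times)
}

#' Write a trajectory to a multi-model PDB or concatenated GRO file
#'
#' The PDB writer emits one CRYST1 record per frame, a
#' `REMARK   6 TIME= ... NS` line and MODEL/ENDMDL blocks; the GRO writer
#' emits `t= <ns> ns` on each title line and converts Angstrom to nm. Both
#' round-trip through [read_frames()].
#'
#' @param traj An `md_trajectory`.
#' @param path Output path.
#' @param format `"auto"` (by extension), `"pdb"` or `"gro"`.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, format = c("auto", "pdb", "gro")) {
  format <- match.arg(format)
  if (format == "auto") format <- .guess_format(path)
  a <- traj$system$atoms
  nf <- n_frames(traj)
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "pdb") {
    name4 <- ifelse(nchar(a$atom_name) < 4,
                    sprintf(" %-3s", a$atom_name), a$atom_name)
    for (i in seq_len(nf)) {
      writeLines(sprintf(
        "CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
        traj$box[i, 1], traj$box[i, 2], traj$box[i, 3], 90, 90, 90), con)
      writeLines(sprintf("REMARK   6 TIME=%14.6f NS", traj$time[i]), con)
      writeLines(sprintf("MODEL     %4d", i), con)
      xyz <- frame_coords(traj, i)
      # name cols 13-16, resName 18-21, resSeq right-justified into 22-26
      writeLines(sprintf(
        "ATOM  %5d %-4s %-4s%5d    %8.3f%8.3f%8.3f%6.2f%6.2f",
        a$atom_index %% 100000, name4, a$residue_name,
        a$residue_seq %% 10000, xyz[, 1], xyz[, 2], xyz[, 3], 1, 0), con)
      writeLines("ENDMDL", con)
    }
    writeLines("END", con)
  } else {
    for (i in seq_len(nf)) {
      writeLines(sprintf("%s frame %d t= %.6f ns",
                         traj$system$name, i, traj$time[i]), con)
      writeLines(sprintf("%5d", n_atoms(traj$system)), con)
      xyz <- frame_coords(traj, i) / 10  # Angstrom -> nm
      writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                         a$residue_seq %% 100000, a$residue_name,
                         substr(a$atom_name, 1, 5), a$atom_index %% 100000,
                         xyz[, 1], xyz[, 2], xyz[, 3]), con)
      writeLines(sprintf("%10.5f%10.5f%10.5f", traj$box[i, 1] / 10,
                         traj$box[i, 2] / 10, traj$box[i, 3] / 10), con)
    }
  }
  invisible(path)
}

#' Write a tabular result as CSV
#'
#' @param records A data.frame (may have zero rows; the header is still
#'   written).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path) {
  stopifnot(is.data.frame(records))
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' Write / read a heatmap grid as a plain-text container
#'
#' Header comment lines carry the normalization, the bin edges (Angstrom)
#' and any overlay points; the body is the dense count matrix (rows = x
#' bins, columns = y bins), tab-separated.
#'
#' @param grid A `heatmap_grid` (see [lipid_heatmap()]).
#' @param path Output path.
#' @return `path` invisibly (`write_grid`); a `heatmap_grid` (`read_grid`).
#' @export
write_grid <- function(grid, path) {
  stopifnot(inherits(grid, "heatmap_grid"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# heatmap_grid v1", con)
  writeLines(paste0("# normalization: ", grid$normalization), con)
  writeLines(paste0("# x_edges: ",
                    paste(sprintf("%.17g", grid$x_edges), collapse = " ")), con)
  writeLines(paste0("# y_edges: ",
                    paste(sprintf("%.17g", grid$y_edges), collapse = " ")), con)
  if (!is.null(grid$overlay) && nrow(grid$overlay)) {
    for (i in seq_len(nrow(grid$overlay))) {
      writeLines(sprintf("# overlay: %s %.17g %.17g",
                         grid$overlay$label[i], grid$overlay$x[i],
                         grid$overlay$y[i]), con)
    }
  }
  utils::write.table(grid$counts, con, row.names = FALSE, col.names = FALSE,
                     sep = "\t")
  invisible(path)
}

#' @rdname write_grid
#' @export
read_grid <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  body <- body[nzchar(body)]
  get1 <- function(key) {
    l <- hdr[startsWith(hdr, paste0("# ", key, ":"))]
    if (!length(l)) stop("grid file lacks header '", key, "'")
    trimws(sub(paste0("# ", key, ":"), "", l[1], fixed = TRUE))
  }
  counts <- do.call(rbind, lapply(strsplit(body, "\t"), as.numeric))
  overlay_lines <- hdr[startsWith(hdr, "# overlay:")]
  overlay <- NULL
  if (length(overlay_lines)) {
    parts <- strsplit(sub("# overlay: ", "", overlay_lines, fixed = TRUE), " ")
    overlay <- data.frame(
      label = vapply(parts, `[`, "", 1),
      x = as.numeric(vapply(parts, `[`, "", 2)),
      y = as.numeric(vapply(parts, `[`, "", 3))
    )
  }
  heatmap_grid(counts,
               x_edges = as.numeric(strsplit(get1("x_edges"), " ")[[1]]),
               y_edges = as.numeric(strsplit(get1("y_edges"), " ")[[1]]),
               normalization = get1("normalization"),
               overlay = overlay)
}
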