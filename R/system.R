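# Static molecular topology: atoms, residues, lipid classification, leaflets.

#' Known lipid classes
#'
#' The seven lipid classes of the heterogeneous plasma-membrane mimic:
#' cholesterol, phosphatidylcholine, -ethanolamine, -serine, phosphatidic
#' acid, phosphatidylinositol phosphate and ceramide.
#'
#' @return Character vector of class codes.
#' @export
lipid_classes <- function() {
  c("CHOL", "PC", "PE", "PS", "PA", "PIP", "CER")
}

#' Default residue-name to lipid-class mapping
#'
#' Covers CHARMM36 residue tokens and the synthetic generator's residue
#' names. Entirely user-overridable: pass a modified table to
#' [md_system()] / [read_structure()].
#'
#' @return Named character vector mapping residue name to lipid class.
#' @export
default_lipid_table <- function() {
  c(
    CHL1 = "CHOL", CHOL = "CHOL",
    POPC = "PC", DOPC = "PC", DPPC = "PC",
    POPE = "PE", DOPE = "PE",
    SOPS = "PS", POPS = "PS", DOPS = "PS",
    POPA = "PA",
    PLPI = "PIP", SAPI = "PIP", PIPX = "PIP",
    CER1 = "CER", CER2 = "CER"
  )
}

# Standard amino-acid three-letter codes (incl. common protonation variants).
.amino_acids <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "HSD",
  "HSE", "HSP", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR",
  "TRP", "TYR", "VAL"
)

.solvent_residues <- c("TIP3", "HOH", "SOL", "WAT", "SPC")
.ion_residues <- c("SOD", "CLA", "POT", "NA", "CL", "K", "MG", "CAL", "ZN")

#' Classify residue names into segment kinds
#'
#' @param residue_name Character vector of residue names.
#' @param lipid_table Named vector mapping residue names to lipid classes.
#' @param ligand_residues Residue names to classify as ligand.
#' @return List with `segment_kind` and `lipid_class` character vectors
#'   (`lipid_class` is `NA` for non-lipids).
#' @export
classify_residues <- function(residue_name,
                              lipid_table = default_lipid_table(),
                              ligand_residues = character()) {
  kind <- rep("other", length(residue_name))
  lipid_class <- rep(NA_character_, length(residue_name))
  kind[residue_name %in% .amino_acids] <- "protein"
  is_lip <- residue_name %in% names(lipid_table)
  kind[is_lip] <- "lipid"
  lipid_class[is_lip] <- unname(lipid_table[residue_name[is_lip]])
  kind[residue_name %in% .solvent_residues] <- "solvent"
  kind[residue_name %in% .ion_residues] <- "ion"
  kind[residue_name %in% ligand_residues] <- "ligand"
  unknown <- unique(residue_name[kind == "other"])
  if (length(unknown)) {
    warning("unknown residue name(s) classified as 'other': ",
            paste(unknown, collapse = ", "), call. = FALSE)
  }
  list(segment_kind = kind, lipid_class = lipid_class)
}

#' Construct a molecular system
#'
#' A static atom table describing one simulation system. Each row is one
#' atom; lipid molecules are single residues, protein "molecules" are grouped
#' per residue so that every `molecule_id` is homogeneous in residue name.
#'
#' @param atoms data.frame with columns `atom_name`, `residue_name`,
#'   `residue_seq` and optionally `segment_kind`, `lipid_class`,
#'   `molecule_id`. Missing classification columns are filled via
#'   [classify_residues()]; missing `molecule_id` is derived from runs of
#'   constant (`residue_seq`, `residue_name`).
#' @param name System name.
#' @param lipid_table Residue-name to lipid-class mapping.
#' @param ligand_residues Residue names treated as ligand.
#' @return Object of class `md_system`: list with `name` and the validated
#'   `atoms` data.frame (gains a 1-based `atom_index` column).
#' @export
md_system <- function(atoms, name = "system",
                      lipid_table = default_lipid_table(),
                      ligand_residues = character()) {
  stopifnot(is.data.frame(atoms), nrow(atoms) >= 1)
  need <- c("atom_name", "residue_name", "residue_seq")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) {
    stop("atoms table lacks column(s): ", paste(miss, collapse = ", "))
  }
  atoms$atom_name <- as.character(atoms$atom_name)
  atoms$residue_name <- as.character(atoms$residue_name)
  atoms$residue_seq <- as.integer(atoms$residue_seq)
  if (is.null(atoms$segment_kind) || is.null(atoms$lipid_class)) {
    cls <- classify_residues(atoms$residue_name, lipid_table, ligand_residues)
    if (is.null(atoms$segment_kind)) atoms$segment_kind <- cls$segment_kind
    if (is.null(atoms$lipid_class)) atoms$lipid_class <- cls$lipid_class
  }
  if (is.null(atoms$molecule_id)) {
    key <- paste(atoms$residue_seq, atoms$residue_name)
    new_mol <- c(TRUE, key[-1] != key[-length(key)])
    atoms$molecule_id <- cumsum(new_mol)
  }
  atoms$atom_index <- seq_len(nrow(atoms))
  bad <- atoms$segment_kind == "lipid" & is.na(atoms$lipid_class)
  if (any(bad)) {
    stop("lipid atoms without lipid_class: rows ",
         paste(utils::head(which(bad), 5), collapse = ", "))
  }
  for (m in unique(atoms$molecule_id[duplicated(atoms$molecule_id)])) {
    sub <- atoms[atoms$molecule_id == m, ]
    if (length(unique(sub$residue_name)) > 1 ||
        length(unique(sub$segment_kind)) > 1) {
      stop("molecule_id ", m, " mixes residue names or segment kinds")
    }
  }
  structure(list(name = name, atoms = atoms), class = "md_system")
}

#' @export
print.md_system <- function(x, ...) {
  a <- x$atoms
  cat("<md_system> ", x$name, ": ", nrow(a), " atoms, ",
      length(unique(a$molecule_id)), " molecules\n", sep = "")
  kinds <- table(a$segment_kind)
  cat("  kinds: ", paste(names(kinds), kinds, sep = "=", collapse = ", "),
      "\n", sep = "")
  lip <- a[a$segment_kind == "lipid", ]
  if (nrow(lip)) {
    ncls <- table(lip$lipid_class[!duplicated(lip$molecule_id)])
    cat("  lipid molecules: ",
        paste(names(ncls), ncls, sep = "=", collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Number of atoms in a system
#' @param system An `md_system`.
#' @return Integer atom count.
#' @export
n_atoms <- function(system) nrow(system$atoms)

#' Assign lipid molecules to leaflets for one frame
#'
#' A lipid is assigned to the lower leaflet iff the mean z of its headgroup
#' atoms lies below the membrane midplane, taken as the mean z of all lipid
#' headgroup atoms in the frame. Assignment is per-frame (lipids may flip).
#'
#' @param system An `md_system`.
#' @param coords n_atoms x 3 coordinate matrix (Angstrom) for one frame.
#' @param headgroup_idx Integer atom indices of lipid headgroup atoms
#'   (e.g. from [resolve_selection()]); must cover every lipid molecule.
#' @return Named character vector, `"upper"`/`"lower"`, names = lipid
#'   `molecule_id`.
#' @export
leaflet_assign <- function(system, coords, headgroup_idx) {
  atoms <- system$atoms
  if (!length(headgroup_idx)) stop("empty headgroup selection")
  lipid_mols <- unique(atoms$molecule_id[atoms$segment_kind == "lipid"])
  hg <- atoms[headgroup_idx, ]
  if (any(hg$segment_kind != "lipid")) {
    stop("headgroup selection contains non-lipid atoms")
  }
  z <- coords[headgroup_idx, 3]
  mol_z <- tapply(z, hg$molecule_id, mean)
  missing <- setdiff(lipid_mols, as.integer(names(mol_z)))
  if (length(missing)) {
    stop("lipid molecule(s) with no headgroup atom in selection: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  midplane <- mean(z)
  out <- stats::setNames(ifelse(as.vector(mol_z) < midplane,
                                "lower", "upper"),
                         names(mol_z))
  out[as.character(lipid_mols)]
}

#' Per-leaflet lipid class counts realized in a frame
#'
#' @inheritParams leaflet_assign
#' @return data.frame with columns `lipid_class`, `upper`, `lower`.
#' @export
leaflet_class_counts <- function(system, coords, headgroup_idx) {
  leaf <- leaflet_assign(system, coords, headgroup_idx)
  atoms <- system$atoms
  lip <- atoms[atoms$segment_kind == "lipid" & !duplicated(atoms$molecule_id), ]
  lip <- lip[lip$molecule_id %in% as.integer(names(leaf)), ]
  cls <- lipid_classes()
  tab <- table(factor(lip$lipid_class, levels = cls),
               factor(leaf[as.character(lip$molecule_id)],
                      levels = c("upper", "lower")))
  data.frame(lipid_class = cls,
             upper = as.integer(tab[, "upper"]),
             lower = as.integer(tab[, "lower"]))
}
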