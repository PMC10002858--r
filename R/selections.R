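# Named atom selections: tracked atoms per protein residue and lipid class.

#' Construct a selection specification
#'
#' A selection spec is a list of named groups. Each group has a `role`
#' (`protein_probe`, `lipid_probe` or `reference`) and a predicate table;
#' an atom matches a predicate row when every non-missing field of the row
#' matches (`residue_name`, `residue_seq`, `atom_name`, `lipid_class`).
#' A group's atoms are the union over its predicate rows.
#'
#' @param groups List of group definitions: each a list with `name`, `role`
#'   and `atoms` (list of predicate lists or a data.frame).
#' @return Object of class `selection_spec`.
#' @export
selection_spec <- function(groups) {
  roles <- c("protein_probe", "lipid_probe", "reference")
  out <- lapply(groups, function(g) {
    if (is.null(g$name) || !nzchar(g$name)) stop("selection group without name")
    if (is.null(g$role) || !(g$role %in% roles)) {
      stop("selection group '", g$name, "': role must be one of ",
           paste(roles, collapse = ", "))
    }
    preds <- g$atoms
    if (is.null(preds) || !length(preds)) {
      stop("selection group '", g$name, "' has no atom predicates")
    }
    if (!is.data.frame(preds)) {
      preds <- do.call(rbind, lapply(preds, function(p) {
        data.frame(
          residue_name = if (is.null(p$residue_name)) NA_character_ else as.character(p$residue_name),
          residue_seq = if (is.null(p$residue_seq)) NA_integer_ else as.integer(p$residue_seq),
          atom_name = if (is.null(p$atom_name)) NA_character_ else as.character(p$atom_name),
          lipid_class = if (is.null(p$lipid_class)) NA_character_ else as.character(p$lipid_class)
        )
      }))
    } else {
      for (col in c("residue_name", "atom_name", "lipid_class")) {
        if (is.null(preds[[col]])) preds[[col]] <- NA_character_
      }
      if (is.null(preds$residue_seq)) preds$residue_seq <- NA_integer_
    }
    empty <- is.na(preds$residue_name) & is.na(preds$residue_seq) &
      is.na(preds$atom_name) & is.na(preds$lipid_class)
    if (any(empty)) {
      stop("selection group '", g$name, "': predicate with no fields")
    }
    list(name = g$name, role = g$role, atoms = preds)
  })
  names(out) <- vapply(out, `[[`, "", "name")
  if (anyDuplicated(names(out))) stop("duplicate selection group names")
  structure(out, class = "selection_spec")
}

#' @export
print.selection_spec <- function(x, ...) {
  cat("<selection_spec> ", length(x), " groups\n", sep = "")
  for (g in x) {
    cat("  ", g$name, " [", g$role, "]: ", nrow(g$atoms),
        " predicate(s)\n", sep = "")
  }
  invisible(x)
}

#' Read a selection specification from YAML or JSON
#'
#' The file holds a top-level `groups` list; each entry has `name`, `role`
#' and `atoms` (list of predicate maps with any of `residue_name`,
#' `residue_seq`, `atom_name`, `lipid_class`). See the files shipped under
#' `system.file("extdata", package = "membcontacts")`.
#'
#' @param path File path (`.yaml`/`.yml` or `.json`).
#' @return A `selection_spec`.
#' @export
read_selection_spec <- function(path) {
  if (!file.exists(path)) stop("selection file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw$groups)) stop("selection file lacks top-level 'groups'")
  selection_spec(raw$groups)
}

#' Path to a shipped default selection file
#'
#' `"synthetic"` matches the pseudo-atom naming of [simulate_trajectory()];
#' `"charmm36"` encodes the tracked-atom lists for a CHARMM36 all-atom system
#' (lysine NZ probes, backbone amides, lipid phosphate/hydroxyl oxygens).
#'
#' @param which `"synthetic"` or `"charmm36"`.
#' @return File path.
#' @export
default_selection_path <- function(which = c("synthetic", "charmm36")) {
  which <- match.arg(which)
  system.file("extdata", paste0("selections_", which, ".yaml"),
              package = "membcontacts", mustWork = TRUE)
}

#' Resolve a selection against a system
#'
#' @param system An `md_system`.
#' @param spec A `selection_spec`.
#' @return Named list mapping group name to a sorted integer vector of
#'   1-based atom indices. Errors (naming group and predicate) if any
#'   predicate matches no atom.
#' @export
resolve_selection <- function(system, spec) {
  stopifnot(inherits(spec, "selection_spec"))
  atoms <- system$atoms
  out <- lapply(spec, function(g) {
    idx <- integer(0)
    for (i in seq_len(nrow(g$atoms))) {
      p <- g$atoms[i, ]
      keep <- rep(TRUE, nrow(atoms))
      if (!is.na(p$residue_name)) keep <- keep & atoms$residue_name == p$residue_name
      if (!is.na(p$residue_seq)) keep <- keep & atoms$residue_seq == p$residue_seq
      if (!is.na(p$atom_name)) keep <- keep & atoms$atom_name == p$atom_name
      if (!is.na(p$lipid_class)) {
        keep <- keep & !is.na(atoms$lipid_class) & atoms$lipid_class == p$lipid_class
      }
      hit <- which(keep)
      if (!length(hit)) {
        stop("selection group '", g$name, "': predicate (",
             paste(stats::na.omit(c(
               if (!is.na(p$residue_name)) paste0("residue_name=", p$residue_name),
               if (!is.na(p$residue_seq)) paste0("residue_seq=", p$residue_seq),
               if (!is.na(p$atom_name)) paste0("atom_name=", p$atom_name),
               if (!is.na(p$lipid_class)) paste0("lipid_class=", p$lipid_class)
             )), collapse = ", "),
             ") matched no atoms", call. = FALSE)
      }
      idx <- c(idx, hit)
    }
    sort(unique(idx))
  })
  names(out) <- names(spec)
  out
}

#' Selection groups filtered by role
#' @param spec A `selection_spec`.
#' @param role Role to keep.
#' @return A `selection_spec` with only the matching groups.
#' @export
selection_by_role <- function(spec, role) {
  keep <- vapply(spec, function(g) g$role == role, TRUE)
  structure(unclass(spec)[keep], class = "selection_spec")
}
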