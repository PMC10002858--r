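# Protein-lipid contacts: distance series, occupancy, lifetimes,
# transient/stable classification, multivalency.

#' Per-frame minimum distance between two atom sets
#'
#' For every frame, the minimum over all atom pairs of the minimum-image
#' distance between the two sets.
#'
#' @param traj An `md_trajectory`.
#' @param atoms_a,atoms_b Non-empty integer vectors of atom indices.
#' @param periodic Apply the minimum-image convention (default TRUE).
#' @return Numeric vector, one distance (Angstrom) per frame.
#' @export
distance_series <- function(traj, atoms_a, atoms_b, periodic = TRUE) {
  if (!length(atoms_a) || !length(atoms_b)) {
    stop("atom sets must be non-empty")
  }
  nf <- n_frames(traj)
  boxt <- t(traj$box)  # 3 x nf
  best <- rep(Inf, nf)
  for (i in atoms_a) {
    ci <- matrix(traj$coords[i, , ], nrow = 3)
    for (j in atoms_b) {
      d <- ci - matrix(traj$coords[j, , ], nrow = 3)
      if (periodic) d <- d - boxt * round(d / boxt)
      best <- pmin(best, sqrt(colSums(d^2)))
    }
  }
  best
}

#' Build contact records for protein probes against lipid molecules
#'
#' One record per (protein probe group, lipid molecule) pair: the per-frame
#' minimum distance between the probe's tracked atoms and the lipid's
#' tracked atoms, and the boolean bound series `distance <= cutoff`.
#' Lipid molecules are those covered by the spec's `lipid_probe` groups.
#'
#' @param traj An `md_trajectory`.
#' @param selections A `selection_spec` (or path to one); must contain at
#'   least one `protein_probe` and one `lipid_probe` group.
#' @param cutoff Contact cutoff in Angstrom (default 6; bound when
#'   `distance <= cutoff`, inclusive).
#' @param lipid_classes Optional subset of lipid classes to keep.
#' @param molecule_ids Optional subset of lipid molecule ids to keep.
#' @param periodic Apply the minimum-image convention.
#' @return Object of class `contact_set`: list of `contact_record`s, each
#'   with `protein_group`, `lipid_class`, `lipid_molecule_id`, `distance`,
#'   `bound`, `cutoff`; attributes carry `time` and `dt`.
#' @export
contact_records <- function(traj, selections, cutoff = 6,
                            lipid_classes = NULL, molecule_ids = NULL,
                            periodic = TRUE) {
  if (is.character(selections)) selections <- read_selection_spec(selections)
  if (cutoff <= 0) stop("cutoff must be > 0")
  resolved <- resolve_selection(traj$system, selections)
  prot <- names(selection_by_role(selections, "protein_probe"))
  lip <- names(selection_by_role(selections, "lipid_probe"))
  if (!length(prot)) stop("no protein_probe group in selections")
  if (!length(lip)) stop("no lipid_probe group in selections")
  atoms <- traj$system$atoms
  records <- list()
  for (pg in prot) {
    for (lg in lip) {
      lat <- atoms[resolved[[lg]], ]
      if (any(lat$segment_kind != "lipid")) {
        stop("lipid_probe group '", lg, "' selects non-lipid atoms")
      }
      for (mol in unique(lat$molecule_id)) {
        cls <- lat$lipid_class[lat$molecule_id == mol][1]
        if (!is.null(lipid_classes) && !(cls %in% lipid_classes)) next
        if (!is.null(molecule_ids) && !(mol %in% molecule_ids)) next
        d <- distance_series(traj, resolved[[pg]],
                             lat$atom_index[lat$molecule_id == mol],
                             periodic = periodic)
        records[[length(records) + 1]] <- structure(
          list(protein_group = pg, lipid_class = cls,
               lipid_molecule_id = mol, distance = d,
               bound = d <= cutoff, cutoff = cutoff),
          class = "contact_record")
      }
    }
  }
  structure(records, class = "contact_set",
            time = traj$time, dt = traj$dt)
}

#' @export
print.contact_set <- function(x, ...) {
  nb <- vapply(x, function(r) sum(r$bound), 0)
  cat("<contact_set> ", length(x), " records x ",
      length(attr(x, "time")), " frames; ", sum(nb > 0),
      " record(s) with any contact\n", sep = "")
  invisible(x)
}

#' Occupancy of protein probes by lipid class
#'
#' Union semantics: a probe is occupied by a class in a frame when *any*
#' molecule of that class is bound. The occupancy fraction is the share of
#' frames occupied.
#'
#' @param records A `contact_set` (all records share one trajectory).
#' @param replicate_id Optional replicate label attached to each row.
#' @return data.frame with `protein_group`, `lipid_class`,
#'   `occupancy_fraction`, `n_frames`, `replicate_id`.
#' @export
occupancy <- function(records, replicate_id = 1L) {
  stopifnot(inherits(records, "contact_set"))
  lens <- vapply(records, function(r) length(r$bound), 0L)
  if (length(unique(lens)) > 1) {
    stop("records have differing trajectory lengths")
  }
  if (!length(records)) {
    return(data.frame(protein_group = character(), lipid_class = character(),
                      occupancy_fraction = numeric(), n_frames = integer(),
                      replicate_id = replicate_id[0]))
  }
  keys <- vapply(records, function(r) paste(r$protein_group, r$lipid_class,
                                            sep = "\r"), "")
  out <- lapply(unique(keys), function(k) {
    sub <- records[keys == k]
    any_bound <- Reduce(`|`, lapply(sub, `[[`, "bound"))
    data.frame(protein_group = sub[[1]]$protein_group,
               lipid_class = sub[[1]]$lipid_class,
               occupancy_fraction = mean(any_bound),
               n_frames = length(any_bound),
               replicate_id = replicate_id)
  })
  do.call(rbind, out)
}

#' Per-molecule occupancy table
#'
#' @inheritParams occupancy
#' @return data.frame with one row per (probe, lipid molecule).
#' @export
occupancy_by_molecule <- function(records, replicate_id = 1L) {
  stopifnot(inherits(records, "contact_set"))
  if (!length(records)) {
    return(data.frame(protein_group = character(), lipid_class = character(),
                      lipid_molecule_id = integer(),
                      occupancy_fraction = numeric(), n_frames = integer(),
                      replicate_id = replicate_id[0]))
  }
  do.call(rbind, lapply(records, function(r) {
    data.frame(protein_group = r$protein_group, lipid_class = r$lipid_class,
               lipid_molecule_id = r$lipid_molecule_id,
               occupancy_fraction = mean(r$bound),
               n_frames = length(r$bound), replicate_id = replicate_id)
  }))
}

#' Construct a lifetime set
#'
#' @param segments Numeric vector of bound-segment durations (ns).
#' @return Object of class `lifetime_set` with `segments`, `total_bound`
#'   (= sum) and `max_continuous` (= max, 0 when empty).
#' @export
lifetime_set <- function(segments = numeric(0)) {
  if (any(segments <= 0)) stop("segment durations must be > 0")
  structure(list(segments = as.numeric(segments),
                 total_bound = sum(segments),
                 max_continuous = if (length(segments)) max(segments) else 0),
            class = "lifetime_set")
}

#' @export
print.lifetime_set <- function(x, ...) {
  cat("<lifetime_set> ", length(x$segments), " segment(s), total ",
      format(x$total_bound), " ns, longest ", format(x$max_continuous),
      " ns\n", sep = "")
  invisible(x)
}

#' Interaction lifetimes of one contact record
#'
#' Maximal runs of bound frames; unbound gaps of at most
#' `gap_tolerance_frames` frames flanked by bound frames are bridged into
#' one segment. A segment's duration is its frame count (including bridged
#' gaps) times `dt`.
#'
#' @param record A `contact_record`, or a logical bound vector.
#' @param dt Frame spacing (ns); required when `record` is a plain vector,
#'   otherwise taken from the parent `contact_set` via the `dt` argument.
#' @param gap_tolerance_frames Non-negative integer (default 0: no
#'   bridging).
#' @return A [lifetime_set()], segments in trajectory order.
#' @export
lifetimes <- function(record, dt, gap_tolerance_frames = 0) {
  bound <- if (inherits(record, "contact_record")) record$bound else record
  stopifnot(is.logical(bound))
  if (gap_tolerance_frames < 0) stop("gap_tolerance_frames must be >= 0")
  if (!any(bound)) return(lifetime_set())
  r <- rle(bound)
  if (gap_tolerance_frames > 0 && length(r$lengths) > 2) {
    inner <- seq_along(r$values)[-c(1, length(r$values))]
    bridge <- inner[!r$values[inner] &
                      r$lengths[inner] <= gap_tolerance_frames]
    r$values[bridge] <- TRUE
    r <- rle(inverse.rle(r))
  }
  lifetime_set(r$lengths[r$values] * dt)
}

#' Lifetime table for a contact set
#'
#' @param records A `contact_set`.
#' @param gap_tolerance_frames Passed to [lifetimes()].
#' @param replicate_id Optional replicate label.
#' @return data.frame with one row per bound segment: `protein_group`,
#'   `lipid_class`, `lipid_molecule_id`, `segment`, `duration_ns`, plus the
#'   per-record `total_bound_ns`, `max_continuous_ns` and `classification`.
#' @export
lifetime_table <- function(records, gap_tolerance_frames = 0,
                           replicate_id = 1L) {
  stopifnot(inherits(records, "contact_set"))
  dt <- attr(records, "dt")
  rows <- lapply(records, function(r) {
    ls <- lifetimes(r, dt = dt, gap_tolerance_frames = gap_tolerance_frames)
    if (!length(ls$segments)) return(NULL)
    data.frame(protein_group = r$protein_group, lipid_class = r$lipid_class,
               lipid_molecule_id = r$lipid_molecule_id,
               segment = seq_along(ls$segments),
               duration_ns = ls$segments,
               total_bound_ns = ls$total_bound,
               max_continuous_ns = ls$max_continuous,
               classification = classify_interaction(ls),
               replicate_id = replicate_id)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) {
    return(data.frame(protein_group = character(), lipid_class = character(),
                      lipid_molecule_id = integer(), segment = integer(),
                      duration_ns = numeric(), total_bound_ns = numeric(),
                      max_continuous_ns = numeric(),
                      classification = character(),
                      replicate_id = replicate_id[0]))
  }
  do.call(rbind, rows)
}

#' Classify an interaction as transient or stable
#'
#' Transient when the longest continuous bound segment is shorter than
#' `continuous_min_ns` *or* the total bound time is shorter than
#' `total_min_ns`; stable otherwise.
#'
#' @param ls A [lifetime_set()].
#' @param continuous_min_ns Continuous-time threshold (default 10 ns).
#' @param total_min_ns Total-time threshold (default 50 ns).
#' @return `"transient"` or `"stable"`.
#' @export
classify_interaction <- function(ls, continuous_min_ns = 10,
                                 total_min_ns = 50) {
  stopifnot(inherits(ls, "lifetime_set"))
  if (ls$max_continuous < continuous_min_ns ||
      ls$total_bound < total_min_ns) "transient" else "stable"
}

#' Multivalency of protein-lipid engagement
#'
#' Per frame: how many probe groups each lipid molecule binds, and how many
#' lipid molecules each probe group binds. A frame is multivalent for an
#' entity when its count is >= 2.
#'
#' @param records A `contact_set` from one trajectory.
#' @return List with `lipid_counts` (frames x molecules matrix),
#'   `group_counts` (frames x groups matrix) and `summary`, a data.frame of
#'   per-entity bound-frame counts, multivalent-frame counts and the
#'   fraction of bound frames that are multivalent.
#' @export
multivalency <- function(records) {
  stopifnot(inherits(records, "contact_set"))
  if (!length(records)) stop("empty contact set")
  nf <- length(records[[1]]$bound)
  mols <- sort(unique(vapply(records, `[[`, 0, "lipid_molecule_id")))
  grps <- unique(vapply(records, `[[`, "", "protein_group"))
  lipid_counts <- matrix(0L, nf, length(mols),
                         dimnames = list(NULL, as.character(mols)))
  group_counts <- matrix(0L, nf, length(grps),
                         dimnames = list(NULL, grps))
  for (r in records) {
    m <- as.character(r$lipid_molecule_id)
    lipid_counts[, m] <- lipid_counts[, m] + r$bound
    group_counts[, r$protein_group] <- group_counts[, r$protein_group] + r$bound
  }
  summarize <- function(counts, kind) {
    data.frame(
      entity = colnames(counts), kind = kind,
      bound_frames = colSums(counts >= 1),
      multivalent_frames = colSums(counts >= 2),
      multivalent_fraction = ifelse(colSums(counts >= 1) > 0,
                                    colSums(counts >= 2) / colSums(counts >= 1),
                                    0),
      row.names = NULL)
  }
  list(lipid_counts = lipid_counts, group_counts = group_counts,
       summary = rbind(summarize(lipid_counts, "lipid_molecule"),
                       summarize(group_counts, "protein_group")))
}
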