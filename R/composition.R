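# Membrane composition: per-leaflet lipid class counts and percentages.

#' Construct a membrane composition
#'
#' Per-leaflet counts of lipid molecules by class.
#'
#' @param upper,lower Named integer vectors (names = lipid classes,
#'   values = molecule counts, all >= 0).
#' @return Object of class `membrane_composition`: data.frame with columns
#'   `lipid_class`, `upper`, `lower`.
#' @export
membrane_composition <- function(upper, lower) {
  cls <- union(names(upper), names(lower))
  if (!length(cls) || is.null(names(upper)) || is.null(names(lower))) {
    stop("upper and lower must be named count vectors")
  }
  up <- ifelse(cls %in% names(upper), upper[cls], 0L)
  lo <- ifelse(cls %in% names(lower), lower[cls], 0L)
  if (any(up < 0) || any(lo < 0)) stop("counts must be >= 0")
  out <- data.frame(lipid_class = cls,
                    upper = as.integer(up), lower = as.integer(lo))
  class(out) <- c("membrane_composition", "data.frame")
  out
}

#' @export
print.membrane_composition <- function(x, ...) {
  cat("<membrane_composition> upper total ", sum(x$upper),
      ", lower total ", sum(x$lower), "\n", sep = "")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Per-leaflet mole percentages of a composition
#'
#' Percentages are `100 * count / leaflet_total` rounded to the nearest
#' integer (`round()`).
#'
#' @param composition A `membrane_composition`.
#' @return data.frame with `lipid_class`, `upper_count`, `upper_pct`,
#'   `lower_count`, `lower_pct`.
#' @export
composition_percentages <- function(composition) {
  stopifnot(inherits(composition, "membrane_composition"))
  data.frame(
    lipid_class = composition$lipid_class,
    upper_count = composition$upper,
    upper_pct = as.integer(round(100 * composition$upper / sum(composition$upper))),
    lower_count = composition$lower,
    lower_pct = as.integer(round(100 * composition$lower / sum(composition$lower)))
  )
}

# Largest-remainder allocation of `total` seats to `fractions` (named,
# summing to 1). Ties broken deterministically by position in `fractions`.
.largest_remainder <- function(fractions, total) {
  quota <- fractions * total
  base <- floor(quota)
  left <- total - sum(base)
  if (left > 0) {
    rem <- quota - base
    ord <- order(-rem, seq_along(rem))
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  stats::setNames(as.integer(base), names(fractions))
}

#' Build a composition from target fractions and leaflet totals
#'
#' Counts are allocated by largest-remainder rounding so each leaflet sums
#' exactly to its total; ties break deterministically by the order of
#' `fractions`.
#'
#' @param fractions Named numeric vector of class proportions summing to 1
#'   (within 1e-6).
#' @param leaflet_totals Integer vector `c(upper, lower)`, both > 0.
#' @return A `membrane_composition`.
#' @export
build_composition <- function(fractions, leaflet_totals) {
  if (is.null(names(fractions))) stop("fractions must be named by lipid class")
  if (abs(sum(fractions) - 1) > 1e-6) stop("fractions must sum to 1")
  if (any(fractions < 0)) stop("fractions must be >= 0")
  if (length(leaflet_totals) != 2 || any(leaflet_totals <= 0)) {
    stop("leaflet_totals must be two positive counts (upper, lower)")
  }
  membrane_composition(
    upper = .largest_remainder(fractions, as.integer(leaflet_totals[1])),
    lower = .largest_remainder(fractions, as.integer(leaflet_totals[2]))
  )
}

#' Published heterogeneous plasma-membrane mimic compositions
#'
#' Per-leaflet lipid counts of the two simulated bilayer systems: the
#' phorbol-complex membrane (66 upper / 59 lower lipids) and the
#' bryostatin/Merle27-complex membrane (73 upper / 67 lower). Lower-leaflet
#' totals are smaller because the protein-ligand complex is inserted there.
#'
#' @param system `"phorbol"` or `"bryostatin"`.
#' @return A `membrane_composition`.
#' @export
reference_composition <- function(system = c("phorbol", "bryostatin")) {
  system <- match.arg(system)
  if (system == "phorbol") {
    membrane_composition(
      upper = c(CHOL = 14, PC = 13, PE = 18, PS = 8, PA = 2, PIP = 4, CER = 7),
      lower = c(CHOL = 13, PC = 12, PE = 17, PS = 7, PA = 1, PIP = 3, CER = 6)
    )
  } else {
    membrane_composition(
      upper = c(CHOL = 16, PC = 15, PE = 19, PS = 8, PA = 3, PIP = 5, CER = 7),
      lower = c(CHOL = 16, PC = 13, PE = 18, PS = 8, PA = 2, PIP = 4, CER = 6)
    )
  }
}
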