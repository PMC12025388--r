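#' Molecular structure objects
#'
#' A `structure3d` holds one conformer geometry: element symbols and
#' Cartesian coordinates in angstrom, with an optional energy (and its
#' declared unit) and a free-text label. A `conformer_ensemble` is an
#' ordered list of such structures sharing element sequence and
#' provenance (ligand id, substrate kind, coordination mode, pipeline
#' stage) plus a designated baseline structure (the conformer-search
#' input geometry, whose energy anchors relative-energy reporting).
#'
#' @name structure3d
NULL

# element symbols accepted for geometry input (periodic table, Z <= 103)
PERIODIC_SYMBOLS <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne", "Na", "Mg", "Al",
  "Si", "P", "S", "Cl", "Ar", "K", "Ca", "Sc", "Ti", "V", "Cr", "Mn",
  "Fe", "Co", "Ni", "Cu", "Zn", "Ga", "Ge", "As", "Se", "Br", "Kr",
  "Rb", "Sr", "Y", "Zr", "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd",
  "In", "Sn", "Sb", "Te", "I", "Xe", "Cs", "Ba", "La", "Ce", "Pr", "Nd",
  "Pm", "Sm", "Eu", "Gd", "Tb", "Dy", "Ho", "Er", "Tm", "Yb", "Lu",
  "Hf", "Ta", "W", "Re", "Os", "Ir", "Pt", "Au", "Hg", "Tl", "Pb", "Bi",
  "Po", "At", "Rn", "Fr", "Ra", "Ac", "Th", "Pa", "U", "Np", "Pu", "Am",
  "Cm", "Bk", "Cf", "Es", "Fm", "Md", "No", "Lr"
)

#' Normalize an element symbol to periodic-table capitalization
#'
#' First letter upper case, any second letter lower case ("RH" -> "Rh").
#' @param symbol character vector of element symbols.
#' @return normalized character vector.
#' @export
normalize_element <- function(symbol) {
  s <- paste0(toupper(substr(symbol, 1L, 1L)),
              tolower(substr(symbol, 2L, nchar(symbol))))
  bad <- !(s %in% PERIODIC_SYMBOLS)
  if (any(bad)) {
    stop("invalid element symbol(s): ",
         paste(unique(symbol[bad]), collapse = ", "), call. = FALSE)
  }
  s
}

#' Create a structure object
#'
#' @param elements character vector of element symbols (case-normalized).
#' @param coords numeric matrix, n x 3, Cartesian coordinates in angstrom.
#' @param energy optional scalar energy.
#' @param energy_unit unit of `energy` (see [convert_energy()]); required
#'   when `energy` is given.
#' @param label free-text label.
#' @return an object of class `structure3d`.
#' @export
structure3d <- function(elements, coords, energy = NULL,
                        energy_unit = "hartree", label = "") {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L) stop("coords must be an n x 3 matrix", call. = FALSE)
  if (length(elements) != nrow(coords)) {
    stop("elements and coords disagree on atom count", call. = FALSE)
  }
  if (!all(is.finite(coords))) stop("coordinates must be finite", call. = FALSE)
  elements <- normalize_element(as.character(elements))
  if (!is.null(energy)) {
    stopifnot(is.numeric(energy), length(energy) == 1L, is.finite(energy))
    match_energy_unit(energy_unit)
  }
  storage.mode(coords) <- "double"
  dimnames(coords) <- NULL
  obj <- list(elements = elements, coords = coords, energy = energy,
              energy_unit = if (is.null(energy)) NULL else energy_unit,
              label = as.character(label))
  class(obj) <- "structure3d"
  obj
}

#' @export
print.structure3d <- function(x, ...) {
  cat("<structure3d> ", n_atoms(x), " atoms", sep = "")
  if (!is.null(x$energy)) {
    cat(sprintf(", E = %.6f %s", x$energy, x$energy_unit))
  }
  if (nzchar(x$label)) cat(" [", x$label, "]", sep = "")
  cat("\n")
  invisible(x)
}

#' Number of atoms in a structure
#' @param s a `structure3d`.
#' @return integer atom count.
#' @export
n_atoms <- function(s) nrow(s$coords)

#' Structure energy in a requested unit
#' @param s a `structure3d`.
#' @param unit target unit.
#' @return scalar energy, or `NULL` when the structure carries none.
#' @export
structure_energy <- function(s, unit = "hartree") {
  # [[ with exact matching: `$energy` would partial-match energy_unit
  # on structures whose energy field was removed
  if (is.null(s[["energy"]])) return(NULL)
  convert_energy(s[["energy"]], s[["energy_unit"]], unit)
}

#' Subset a structure by atom indices
#'
#' Atom order in the result follows the original index order.
#' @param s a `structure3d`.
#' @param idx integer atom indices (1-based).
#' @return a `structure3d` with the selected atoms; energy and label kept.
#' @export
subset_atoms <- function(s, idx) {
  idx <- sort(unique(as.integer(idx)))
  if (any(idx < 1L | idx > n_atoms(s))) {
    stop("atom index out of range", call. = FALSE)
  }
  structure3d(s$elements[idx], s$coords[idx, , drop = FALSE],
              energy = s$energy,
              energy_unit = if (is.null(s$energy)) "hartree" else s$energy_unit,
              label = s$label)
}

#' Create a conformer ensemble
#'
#' @param members list of `structure3d`, all with identical element
#'   sequences.
#' @param ligand_id ligand identifier.
#' @param substrate_kind `"S"` (prochiral substrate) or `"NBD"`
#'   (norbornadiene placeholder).
#' @param coordination_mode one of `"major1"`, `"major2"`, `"minor1"`,
#'   `"minor2"`, `"nbd"`.
#' @param baseline optional `structure3d`: the conformer-search input
#'   geometry. Must carry an energy when `stage = "dft"`.
#' @param stage `"crest"` or `"dft"`.
#' @return an object of class `conformer_ensemble`.
#' @export
conformer_ensemble <- function(members, ligand_id = "L?",
                               substrate_kind = c("S", "NBD"),
                               coordination_mode = c("major1", "major2",
                                                     "minor1", "minor2",
                                                     "nbd"),
                               baseline = NULL,
                               stage = c("crest", "dft")) {
  substrate_kind <- match.arg(substrate_kind)
  coordination_mode <- match.arg(coordination_mode)
  stage <- match.arg(stage)
  if (!length(members)) stop("ensemble needs at least one member", call. = FALSE)
  if (!all(vapply(members, inherits, logical(1), "structure3d"))) {
    stop("all members must be structure3d objects", call. = FALSE)
  }
  ref_elems <- members[[1L]]$elements
  same <- vapply(members, function(m) identical(m$elements, ref_elems),
                 logical(1))
  if (!all(same)) {
    stop("inconsistent element sequence across ensemble members (first at member ",
         which(!same)[1L], ")", call. = FALSE)
  }
  if (!is.null(baseline)) {
    stopifnot(inherits(baseline, "structure3d"))
    if (!identical(baseline$elements, ref_elems)) {
      stop("baseline element sequence differs from members", call. = FALSE)
    }
    if (stage == "dft" && is.null(baseline$energy)) {
      stop("baseline must carry an energy when stage = \"dft\"", call. = FALSE)
    }
  }
  obj <- list(members = members, ligand_id = ligand_id,
              substrate_kind = substrate_kind,
              coordination_mode = coordination_mode,
              baseline = baseline, stage = stage)
  class(obj) <- "conformer_ensemble"
  obj
}

#' @export
print.conformer_ensemble <- function(x, ...) {
  cat(sprintf("<conformer_ensemble> %d members x %d atoms | %s-Rh-%s %s (%s)\n",
              length(x$members), n_atoms(x$members[[1L]]), x$ligand_id,
              x$substrate_kind, x$coordination_mode, x$stage))
  invisible(x)
}

#' @export
length.conformer_ensemble <- function(x) length(x$members)

#' Member energies of an ensemble
#' @param ensemble a `conformer_ensemble`.
#' @param unit target unit.
#' @return numeric vector, one energy per member.
#' @export
ensemble_energies <- function(ensemble, unit = "hartree") {
  e <- vapply(ensemble[["members"]], function(m) {
    v <- structure_energy(m, unit)
    if (is.null(v)) NA_real_ else v
  }, numeric(1))
  if (anyNA(e)) {
    stop("ensemble member(s) without energy: ",
         paste(which(is.na(e)), collapse = ", "), call. = FALSE)
  }
  e
}

#' Replace ensemble members, keeping provenance
#' @keywords internal
replace_members <- function(ensemble, members) {
  out <- ensemble
  out$members <- members
  out
}

#' Index of the minimum-energy member (ties by lowest index)
#' @param ensemble a `conformer_ensemble`.
#' @return integer member index.
#' @export
lowest_energy_member <- function(ensemble) {
  e <- ensemble_energies(ensemble, "hartree")
  which.min(e)  # which.min takes the first minimum: documented tie-break
}
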