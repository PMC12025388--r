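#' Fragment specification for a catalyst-substrate complex
#'
#' Assigns every atom of a complex a role: the metal center, the
#' bidentate ligand (including its two phosphorus donor atoms) or the
#' substrate. The split into a ligand part and a substrate part double
#' counts the metal (both parts) and the donors (ligand by role,
#' substrate part for orientation reference), mirroring how fragment
#' RMSD profiles are defined for these complexes.
#'
#' @param metal_index atom index of the metal center (1-based).
#' @param donor_indices exactly two atom indices: the P donors. Must be
#'   ligand atoms.
#' @param ligand_indices atom indices of the bidentate ligand.
#' @param substrate_indices atom indices of the substrate.
#' @param n_atoms optional total atom count; when given, coverage of all
#'   atoms is checked at construction.
#' @return an object of class `fragment_spec`.
#' @export
fragment_spec <- function(metal_index, donor_indices, ligand_indices,
                          substrate_indices, n_atoms = NULL) {
  metal_index <- as.integer(metal_index)
  donor_indices <- as.integer(donor_indices)
  ligand_indices <- sort(unique(as.integer(ligand_indices)))
  substrate_indices <- sort(unique(as.integer(substrate_indices)))
  if (length(metal_index) != 1L) stop("need exactly one metal index", call. = FALSE)
  if (length(donor_indices) != 2L || donor_indices[1] == donor_indices[2]) {
    stop("need exactly two distinct donor indices", call. = FALSE)
  }
  if (length(intersect(ligand_indices, substrate_indices))) {
    stop("ligand and substrate indices must be disjoint", call. = FALSE)
  }
  if (metal_index %in% c(ligand_indices, substrate_indices)) {
    stop("metal index must not be a ligand or substrate atom", call. = FALSE)
  }
  if (!all(donor_indices %in% ligand_indices)) {
    stop("donor indices must be ligand atoms", call. = FALSE)
  }
  if (!length(substrate_indices)) {
    stop("substrate_indices must be nonempty", call. = FALSE)
  }
  spec <- list(metal_index = metal_index, donor_indices = donor_indices,
               ligand_indices = ligand_indices,
               substrate_indices = substrate_indices)
  class(spec) <- "fragment_spec"
  if (!is.null(n_atoms)) validate_fragment_spec(spec, n_atoms)
  spec
}

#' Validate a fragment spec against an atom count
#' @param spec a `fragment_spec`.
#' @param n_atoms total atom count of the structure.
#' @return `spec`, invisibly; errors if indices are out of range or do
#'   not cover all atoms.
#' @export
validate_fragment_spec <- function(spec, n_atoms) {
  all_idx <- c(spec$metal_index, spec$ligand_indices, spec$substrate_indices)
  if (any(all_idx < 1L | all_idx > n_atoms)) {
    stop("fragment spec index out of range for ", n_atoms, " atoms",
         call. = FALSE)
  }
  if (!setequal(all_idx, seq_len(n_atoms))) {
    stop("fragment spec must cover all ", n_atoms, " atoms", call. = FALSE)
  }
  invisible(spec)
}

#' Serialize / deserialize fragment specs
#'
#' Round-trips through a YAML mapping with 0-based index lists, the
#' interchange convention used by upstream structure-building tools.
#' @param spec a `fragment_spec`.
#' @param path file path.
#' @return `read_fragment_spec` returns a `fragment_spec`;
#'   `write_fragment_spec` returns `path` invisibly.
#' @export
write_fragment_spec <- function(spec, path) {
  yaml::write_yaml(list(
    metal_index = spec$metal_index - 1L,
    donor_indices = spec$donor_indices - 1L,
    ligand_indices = spec$ligand_indices - 1L,
    substrate_indices = spec$substrate_indices - 1L
  ), path)
  invisible(path)
}

#' @rdname write_fragment_spec
#' @export
read_fragment_spec <- function(path) {
  y <- yaml::read_yaml(path)
  fragment_spec(y$metal_index + 1L, y$donor_indices + 1L,
                y$ligand_indices + 1L, y$substrate_indices + 1L)
}

COORDINATION_MODES_S <- c("major1", "major2", "minor1", "minor2")

#' Complex template: one ligand x coordination mode combination
#'
#' @param ligand_id ligand identifier.
#' @param substrate_kind `"S"` or `"NBD"`; `"NBD"` if and only if
#'   `coordination_mode = "nbd"`.
#' @param coordination_mode one of `"major1"`, `"major2"`, `"minor1"`,
#'   `"minor2"`, `"nbd"`.
#' @param chiral_reference ordered 4-tuple of atom indices defining the
#'   ligand's axial-chirality dihedral (optional until retention checks
#'   are run).
#' @return an object of class `complex_template`.
#' @export
complex_template <- function(ligand_id, substrate_kind, coordination_mode,
                             chiral_reference = NULL) {
  substrate_kind <- match.arg(substrate_kind, c("S", "NBD"))
  coordination_mode <- match.arg(coordination_mode,
                                 c(COORDINATION_MODES_S, "nbd"))
  if ((substrate_kind == "NBD") != (coordination_mode == "nbd")) {
    stop("substrate_kind NBD requires coordination_mode \"nbd\" and vice versa",
         call. = FALSE)
  }
  if (!is.null(chiral_reference) && length(chiral_reference) != 4L) {
    stop("chiral_reference must be 4 atom indices", call. = FALSE)
  }
  obj <- list(ligand_id = ligand_id, substrate_kind = substrate_kind,
              coordination_mode = coordination_mode,
              chiral_reference = as.integer(chiral_reference))
  class(obj) <- "complex_template"
  obj
}

#' Enumerate catalyst-substrate complex templates
#'
#' For each ligand, the prochiral substrate S binds through its alkene
#' and amide oxygen in four orientations (two "major", two "minor" in
#' the quadrant picture of a C2-chiral bisphosphine pocket), while the
#' norbornadiene (NBD) placeholder has a single mode. Eleven ligands
#' therefore give 44 substrate-bound templates and 55 in total with the
#' precatalysts.
#'
#' @param ligand_ids character vector of distinct ligand identifiers.
#' @param substrate_kinds subset of `c("S", "NBD")`.
#' @return list of [complex_template()] in deterministic order (ligand,
#'   then mode: major1, major2, minor1, minor2, nbd).
#' @examples
#' length(enumerate_complexes(paste0("L", 1:11), "S"))            # 44
#' length(enumerate_complexes(paste0("L", 1:11), c("S", "NBD")))  # 55
#' @export
enumerate_complexes <- function(ligand_ids, substrate_kinds = c("S", "NBD")) {
  if (!length(ligand_ids)) stop("ligand_ids must be nonempty", call. = FALSE)
  if (anyDuplicated(ligand_ids)) {
    stop("duplicate ligand ids: ",
         paste(unique(ligand_ids[duplicated(ligand_ids)]), collapse = ", "),
         call. = FALSE)
  }
  substrate_kinds <- match.arg(substrate_kinds, c("S", "NBD"),
                               several.ok = TRUE)
  out <- list()
  for (lig in ligand_ids) {
    if ("S" %in% substrate_kinds) {
      for (mode in COORDINATION_MODES_S) {
        out[[length(out) + 1L]] <- complex_template(lig, "S", mode)
      }
    }
    if ("NBD" %in% substrate_kinds) {
      out[[length(out) + 1L]] <- complex_template(lig, "NBD", "nbd")
    }
  }
  out
}

#' Split a complex into ligand and substrate parts
#'
#' The ligand part comprises the bidentate ligand atoms plus the metal
#' center; the substrate part comprises the substrate atoms, the metal
#' center and the two P donor atoms (the donors give the substrate part
#' an orientation reference). Atom order within each part follows the
#' original index order.
#'
#' @param structure a `structure3d`.
#' @param spec a `fragment_spec` valid for the structure's atom count.
#' @return list with elements `ligand_part` and `substrate_part`, each a
#'   `structure3d`, plus the index vectors `ligand_idx`, `substrate_idx`
#'   used for each part.
#' @export
split_fragments <- function(structure, spec) {
  validate_fragment_spec(spec, n_atoms(structure))
  lig_idx <- sort(c(spec$ligand_indices, spec$metal_index))
  sub_idx <- sort(c(spec$substrate_indices, spec$metal_index,
                    spec$donor_indices))
  list(ligand_part = subset_atoms(structure, lig_idx),
       substrate_part = subset_atoms(structure, sub_idx),
       ligand_idx = lig_idx, substrate_idx = sub_idx)
}

#' Dihedral angle over four points
#'
#' Signed angle in degrees, IUPAC sign convention (positive = clockwise
#' rotation of the far bond looking down the central bond).
#' @param p 4 x 3 coordinate matrix.
#' @return dihedral angle in degrees, in (-180, 180].
#' @export
dihedral_angle <- function(p) {
  stopifnot(is.matrix(p), nrow(p) == 4L, ncol(p) == 3L)
  b1 <- p[2, ] - p[1, ]
  b2 <- p[3, ] - p[2, ]
  b3 <- p[4, ] - p[3, ]
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  if (vnorm(n1) < 1e-10 || vnorm(n2) < 1e-10) {
    stop("collinear atom triple: dihedral undefined", call. = FALSE)
  }
  x <- sum(n1 * n2)
  y <- sum(cross3(n1, n2) * b2) / vnorm(b2)
  atan2(y, x) * 180 / pi
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

vnorm <- function(v) sqrt(sum(v * v))

#' Check retention of axial chirality
#'
#' Evaluates the sign of the dihedral over the four reference atoms that
#' define the ligand's chiral axis and compares it to the expected sign.
#' A reflection of the structure flips the dihedral sign, so this test
#' catches conformers whose chirality was inverted during sampling.
#'
#' @param structure a `structure3d`.
#' @param chiral_reference ordered 4-tuple of atom indices.
#' @param expected_sign `+1` or `-1`.
#' @return `TRUE` iff the dihedral sign matches `expected_sign`.
#' @export
check_chirality <- function(structure, chiral_reference, expected_sign) {
  stopifnot(length(chiral_reference) == 4L, expected_sign %in% c(-1, 1))
  idx <- as.integer(chiral_reference)
  if (any(idx < 1L | idx > n_atoms(structure))) {
    stop("chiral_reference index out of range", call. = FALSE)
  }
  ang <- dihedral_angle(structure$coords[idx, , drop = FALSE])
  sign(ang) == expected_sign
}

#' Classify the substrate coordination mode of a conformer
#'
#' Builds a right-handed local frame at the metal center from the two
#' metal-to-donor vectors: x along their bisector, z along their cross
#' product (normal to the donor-metal-donor plane), y completing the
#' frame. The out-of-plane reference atom of the substrate's directing
#' group (the amide/carbonyl oxygen, third entry of `anchor_indices`) is
#' projected onto this frame; the quadrant labels follow from the signs
#' of its (x, y) projection. By the package's documented convention,
#' y > 0 maps to "major" (flip with `major_y_positive = FALSE`) and
#' x > 0 maps to mode 1.
#'
#' @param structure a `structure3d`.
#' @param spec a `fragment_spec` (provides metal and donor indices).
#' @param anchor_indices integer vector of three substrate atom indices:
#'   the two metal-coordinated alkene carbons (in-plane orientation
#'   anchors) and the out-of-plane reference atom, in that order.
#' @param major_y_positive convention flag: `TRUE` (default) labels the
#'   y > 0 half-space "major".
#' @param boundary_tol reference-atom projections within this distance
#'   (angstrom) of a quadrant boundary plane raise an ambiguity error
#'   instead of a silent assignment.
#' @return one of `"major1"`, `"major2"`, `"minor1"`, `"minor2"`.
#' @export
classify_coordination <- function(structure, spec, anchor_indices,
                                  major_y_positive = TRUE,
                                  boundary_tol = 1e-3) {
  stopifnot(length(anchor_indices) == 3L)
  anchor_indices <- as.integer(anchor_indices)
  if (any(anchor_indices < 1L | anchor_indices > n_atoms(structure))) {
    stop("anchor index out of range", call. = FALSE)
  }
  if (!all(anchor_indices %in% spec$substrate_indices)) {
    stop("anchor indices must be substrate atoms", call. = FALSE)
  }
  fr <- metal_frame(structure, spec)
  ref <- structure$coords[anchor_indices[3L], ] - fr$origin
  px <- sum(ref * fr$x)
  py <- sum(ref * fr$y)
  if (abs(px) < boundary_tol || abs(py) < boundary_tol) {
    stop(sprintf(
      "coordination ambiguous: reference atom projection (%.4f, %.4f) lies within %g angstrom of a quadrant boundary",
      px, py, boundary_tol), call. = FALSE)
  }
  major <- if (major_y_positive) py > 0 else py < 0
  one <- px > 0
  paste0(if (major) "major" else "minor", if (one) "1" else "2")
}

#' Local right-handed frame at the metal center
#'
#' x = bisector of the two unit metal-to-donor vectors, z = their cross
#' product normalized, y = z cross x.
#' @keywords internal
metal_frame <- function(structure, spec) {
  m <- structure$coords[spec$metal_index, ]
  u1 <- structure$coords[spec$donor_indices[1L], ] - m
  u2 <- structure$coords[spec$donor_indices[2L], ] - m
  u1 <- u1 / vnorm(u1)
  u2 <- u2 / vnorm(u2)
  bis <- u1 + u2
  if (vnorm(bis) < 1e-8) {
    stop("degenerate donor geometry: donors are antiparallel at the metal",
         call. = FALSE)
  }
  x <- bis / vnorm(bis)
  z <- cross3(u1, u2)
  if (vnorm(z) < 1e-8) {
    stop("degenerate donor geometry: donors are collinear with the metal",
         call. = FALSE)
  }
  z <- z / vnorm(z)
  y <- cross3(z, x)
  list(origin = m, x = x, y = y, z = z)
}
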