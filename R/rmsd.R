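#' Kabsch superposition of two coordinate sets
#'
#' Least-squares rigid superposition of `Q` onto `P` after centroid
#' removal, solved in closed form by singular value decomposition of the
#' covariance matrix. Only proper rotations are allowed: if the optimal
#' orthogonal transform is a reflection, the smallest singular direction
#' is flipped. Reflections would silently invert stereochemistry, which
#' is unacceptable for chiral catalyst complexes.
#'
#' @param P,Q numeric n x 3 coordinate matrices with identical atom
#'   ordering, n >= 3.
#' @return an object of class `rmsd_result`: list with `rmsd` (angstrom),
#'   `rotation` (3 x 3 proper orthogonal matrix mapping centered Q onto
#'   centered P), `translation` (3-vector such that the aligned Q is
#'   `Q %*% t(rotation) + translation`), `atoms_used`.
#' @export
kabsch_superpose <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  if (!identical(dim(P), dim(Q))) {
    stop("coordinate sets differ in size", call. = FALSE)
  }
  if (ncol(P) != 3L) stop("coordinates must be n x 3", call. = FALSE)
  n <- nrow(P)
  if (n < 3L) stop("need at least 3 atoms for superposition", call. = FALSE)
  cP <- colMeans(P)
  cQ <- colMeans(Q)
  P0 <- sweep(P, 2L, cP)
  Q0 <- sweep(Q, 2L, cQ)
  H <- crossprod(Q0, P0)        # 3x3 covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)   # proper rotation, det +1
  Qr <- Q0 %*% t(R)
  rmsd <- sqrt(sum((P0 - Qr)^2) / n)
  res <- list(rmsd = rmsd, rotation = R,
              translation = as.numeric(cP - R %*% cQ),
              atoms_used = n)
  class(res) <- "rmsd_result"
  res
}

#' @export
print.rmsd_result <- function(x, ...) {
  cat(sprintf("<rmsd_result> rmsd = %.6f angstrom over %d atoms\n",
              x$rmsd, x$atoms_used))
  invisible(x)
}

#' Minimal RMSD between two structures
#'
#' Applies an optional atom mask, drops hydrogen atoms by default
#' (structural-difference analysis of these complexes ignores H), then
#' computes the Kabsch minimal RMSD. Atom correspondence is positional:
#' conformers of one complex share the atom ordering of their common
#' input structure.
#'
#' @param a,b `structure3d` objects with identical element sequences.
#' @param exclude_hydrogens drop H atoms before superposing (default
#'   `TRUE`).
#' @param mask optional integer index set applied before hydrogen
#'   filtering (e.g. a fragment's atom indices).
#' @return an `rmsd_result` (see [kabsch_superpose()]).
#' @export
minimal_rmsd <- function(a, b, exclude_hydrogens = TRUE, mask = NULL) {
  if (!identical(a$elements, b$elements)) {
    stop("structures differ in element sequence", call. = FALSE)
  }
  idx <- seq_len(n_atoms(a))
  if (!is.null(mask)) {
    mask <- sort(unique(as.integer(mask)))
    if (any(mask < 1L | mask > n_atoms(a))) {
      stop("mask index out of range", call. = FALSE)
    }
    idx <- mask
  }
  if (exclude_hydrogens) idx <- idx[a$elements[idx] != "H"]
  if (length(idx) < 3L) {
    stop("fewer than 3 atoms survive masking/hydrogen filtering",
         call. = FALSE)
  }
  res <- kabsch_superpose(a$coords[idx, , drop = FALSE],
                          b$coords[idx, , drop = FALSE])
  res
}

#' Fragment-resolved RMSD profile of an ensemble
#'
#' For every ensemble member, computes the minimal heavy-atom RMSD of the
#' whole complex, the ligand part and the substrate part (see
#' [split_fragments()]) relative to a reference conformer, each part
#' superposed independently. The reference defaults to the member with
#' the lowest energy (ties broken by lowest member index), matching how
#' structural variability within a conformer set is usually reported.
#'
#' @param ensemble an energy-annotated `conformer_ensemble`.
#' @param spec a `fragment_spec` for the complex.
#' @param reference member index of the reference conformer; default the
#'   lowest-energy member.
#' @param exclude_hydrogens drop H atoms (default `TRUE`).
#' @return a `data.frame` with columns `member`, `delta_E_kj` (energy
#'   relative to the reference conformer, kJ/mol), `rmsd_whole`,
#'   `rmsd_ligand`, `rmsd_substrate` (angstrom). The reference row is
#'   all-zero.
#' @export
rmsd_profile <- function(ensemble, spec, reference = NULL,
                         exclude_hydrogens = TRUE) {
  e_kj <- ensemble_energies(ensemble, "kJ/mol")
  if (is.null(reference)) reference <- lowest_energy_member(ensemble)
  reference <- as.integer(reference)
  stopifnot(reference >= 1L, reference <= length(ensemble))
  ref <- ensemble$members[[reference]]
  validate_fragment_spec(spec, n_atoms(ref))
  lig_idx <- sort(c(spec$ligand_indices, spec$metal_index))
  sub_idx <- sort(c(spec$substrate_indices, spec$metal_index,
                    spec$donor_indices))
  n <- length(ensemble)
  out <- data.frame(member = seq_len(n),
                    delta_E_kj = e_kj - e_kj[reference],
                    rmsd_whole = numeric(n),
                    rmsd_ligand = numeric(n),
                    rmsd_substrate = numeric(n))
  for (i in seq_len(n)) {
    if (i == reference) next
    m <- ensemble$members[[i]]
    out$rmsd_whole[i] <- minimal_rmsd(ref, m, exclude_hydrogens)$rmsd
    out$rmsd_ligand[i] <- minimal_rmsd(ref, m, exclude_hydrogens,
                                       mask = lig_idx)$rmsd
    out$rmsd_substrate[i] <- minimal_rmsd(ref, m, exclude_hydrogens,
                                          mask = sub_idx)$rmsd
  }
  attr(out, "reference") <- reference
  out
}

#' Apply a proper rigid motion to coordinates
#'
#' @param coords n x 3 matrix.
#' @param rotation 3 x 3 proper rotation matrix.
#' @param translation 3-vector.
#' @return transformed n x 3 matrix.
#' @export
apply_rigid_motion <- function(coords, rotation, translation = c(0, 0, 0)) {
  sweep(as.matrix(coords) %*% t(rotation), 2L, -translation)
}

#' Random proper rotation matrix
#'
#' Uniform over SO(3), built from a random unit quaternion.
#' @return 3 x 3 rotation matrix with determinant +1.
#' @export
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3L, 3L, byrow = TRUE)
}
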