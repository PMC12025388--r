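#' Van der Waals radii (Bondi) used for buried volume
#'
#' Bondi's tabulated radii in angstrom, supplemented with 2.00 angstrom
#' for the platinum-group metals the original table omits (the sphere
#' center atom is excluded from the buried-volume integration by
#' default, so the metal radius rarely enters).
#'
#' @param element character vector of element symbols.
#' @return numeric vector of radii (angstrom); errors on elements with
#'   no tabulated radius.
#' @export
vdw_radius <- function(element) {
  element <- normalize_element(element)
  r <- .bondi_radii[element]
  if (anyNA(r)) {
    stop("no tabulated van der Waals radius for element(s): ",
         paste(unique(element[is.na(r)]), collapse = ", "), call. = FALSE)
  }
  unname(r)
}

.bondi_radii <- c(
  H = 1.20, He = 1.40, Li = 1.82, B = 1.92, C = 1.70, N = 1.55, O = 1.52,
  F = 1.47, Ne = 1.54, Na = 2.27, Mg = 1.73, Al = 1.84, Si = 2.10,
  P = 1.80, S = 1.80, Cl = 1.75, Ar = 1.88, K = 2.75, Ca = 2.31,
  Ni = 1.63, Cu = 1.40, Zn = 1.39, Ga = 1.87, Ge = 2.11, As = 1.85,
  Se = 1.90, Br = 1.85, Kr = 2.02, Rb = 3.03, Sr = 2.49, Pd = 1.63,
  Ag = 1.72, Cd = 1.58, In = 1.93, Sn = 2.17, Sb = 2.06, Te = 2.06,
  I = 1.98, Xe = 2.16, Cs = 3.43, Ba = 2.68, Pt = 1.75, Au = 1.66,
  Hg = 1.55, Tl = 1.96, Pb = 2.02, U = 1.86,
  # platinum-group supplements (not in Bondi's table)
  Ru = 2.00, Rh = 2.00, Ir = 2.00, Os = 2.00, Fe = 2.00, Co = 2.00
)

#' Percent buried volume at an atom
#'
#' Fraction (in percent) of a probe sphere centered on one atom that is
#' occupied by the van der Waals spheres of the surrounding atoms — the
#' standard steric descriptor for the pocket around a metal center or a
#' donor atom. Defaults follow the de-facto convention of the
#' buried-volume literature: probe sphere radius 3.5 angstrom, Bondi
#' radii scaled by 1.17, hydrogens excluded, the center atom itself
#' excluded. The integral is evaluated deterministically on a cubic grid
#' (spacing <= 0.05 angstrom by default), which is stable to about 0.05
#' percentage points under grid refinement.
#'
#' @param structure a `structure3d`.
#' @param center_index atom index of the sphere center.
#' @param sphere_radius probe sphere radius, angstrom.
#' @param radii_scale multiplier on the tabulated Bondi radii.
#' @param exclude_hydrogens drop H atoms (default `TRUE`).
#' @param exclude_indices atom indices excluded from the occupying set;
#'   default the center atom.
#' @param grid_spacing integration grid cell size, angstrom.
#' @return buried volume in percent (0-100).
#' @export
buried_volume <- function(structure, center_index, sphere_radius = 3.5,
                          radii_scale = 1.17, exclude_hydrogens = TRUE,
                          exclude_indices = center_index,
                          grid_spacing = 0.05) {
  stopifnot(sphere_radius > 0, grid_spacing > 0, radii_scale > 0)
  center_index <- as.integer(center_index)
  if (center_index < 1L || center_index > n_atoms(structure)) {
    stop("center_index out of range", call. = FALSE)
  }
  keep <- setdiff(seq_len(n_atoms(structure)), as.integer(exclude_indices))
  if (exclude_hydrogens) keep <- keep[structure$elements[keep] != "H"]
  if (!length(keep)) return(0)
  radii <- vdw_radius(structure$elements[keep]) * radii_scale
  center <- structure$coords[center_index, ]
  rel <- sweep(structure$coords[keep, , drop = FALSE], 2L, center)
  # atoms that cannot intersect the probe sphere contribute nothing
  dist <- sqrt(rowSums(rel^2))
  near <- dist < sphere_radius + radii
  if (!any(near)) return(0)
  counts <- buried_volume_grid_cpp(rel[near, , drop = FALSE], radii[near],
                                   sphere_radius, grid_spacing)
  100 * counts[1L] / counts[2L]
}

#' Per-conformer electronic descriptors from a property table
#'
#' Extracts, for every ensemble member, the natural-population charge on
#' the metal, the mean charge of the two donor atoms, and the HOMO-LUMO
#' gap converted from hartree to eV. Electronic quantities are ingested
#' from upstream quantum-chemistry output, never recomputed here.
#'
#' @param table a `property_table` (see [ingest_property_table()]).
#' @param spec a `fragment_spec` identifying metal and donor atoms.
#' @return `data.frame` with columns `member`, `q_metal`, `q_donor`
#'   (au) and `homo_lumo_gap` (eV).
#' @export
electronic_descriptors <- function(table, spec) {
  qcol <- function(i) paste0("q_", i)
  need <- qcol(c(spec$metal_index, spec$donor_indices))
  missing_cols <- setdiff(need, names(table))
  if (length(missing_cols)) {
    stop("property table lacks per-atom charge column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  gap_hartree <- table$lumo_hartree - table$homo_hartree
  data.frame(
    member = as.integer(table$member),
    q_metal = table[[qcol(spec$metal_index)]],
    q_donor = (table[[qcol(spec$donor_indices[1L])]] +
               table[[qcol(spec$donor_indices[2L])]]) / 2,
    homo_lumo_gap = convert_energy(gap_hartree, "hartree", "eV")
  )
}

#' Five-descriptor table for a conformer ensemble
#'
#' Per member: percent buried volume at the metal and at the donors
#' (computed per donor, then averaged over the two P atoms), the metal
#' and donor-averaged natural-population charges, and the HOMO-LUMO gap.
#'
#' @param ensemble a `conformer_ensemble`.
#' @param spec a `fragment_spec`.
#' @param table a `property_table` aligned to the ensemble.
#' @param ... buried-volume parameters passed to [buried_volume()].
#' @return `data.frame` with one row per member and columns `member`,
#'   `V_bur_metal`, `V_bur_donor` (percent), `q_metal`, `q_donor` (au),
#'   `homo_lumo_gap` (eV).
#' @export
descriptor_table <- function(ensemble, spec, table, ...) {
  validate_fragment_spec(spec, n_atoms(ensemble$members[[1L]]))
  el <- electronic_descriptors(table, spec)
  if (nrow(el) != length(ensemble)) {
    stop("property table and ensemble sizes differ", call. = FALSE)
  }
  n <- length(ensemble)
  vb_m <- numeric(n)
  vb_d <- numeric(n)
  for (i in seq_len(n)) {
    m <- ensemble$members[[i]]
    vb_m[i] <- buried_volume(m, spec$metal_index, ...)
    vb_d[i] <- (buried_volume(m, spec$donor_indices[1L], ...) +
                buried_volume(m, spec$donor_indices[2L], ...)) / 2
  }
  data.frame(member = el$member, V_bur_metal = vb_m, V_bur_donor = vb_d,
             q_metal = el$q_metal, q_donor = el$q_donor,
             homo_lumo_gap = el$homo_lumo_gap)
}
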