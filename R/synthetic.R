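#' Configuration for the synthetic-ensemble generator
#'
#' The generator emulates the statistical structure of conformer
#' ensembles of bisphosphine-Rh catalyst complexes: a rigid substrate
#' fragment (heavy-atom RMSD well under 1 angstrom across conformers), a
#' flexible ligand fragment (RMSD up to several angstrom), energies
#' spread over tens of kJ/mol above the minimum with a right-skewed,
#' minimum-anchored distribution, and electronic descriptors that drift
#' with ligand distortion. Defaults: per-coordinate displacement scales
#' `sigma_ligand` = 0.8 and `sigma_substrate` = 0.05 angstrom (giving
#' ligand-part RMSDs of roughly 1-3 angstrom and substrate-part RMSDs
#' near 0.1 angstrom), exponential energy spread with mean 10 kJ/mol,
#' and 20 conformers per group.
#'
#' @param n_ligand_atoms ligand atom count, including the two P donors
#'   (minimum 5).
#' @param n_substrate_atoms substrate atom count, including the two
#'   alkene-carbon anchors and the carbonyl-oxygen reference (minimum 3).
#' @param sigma_ligand,sigma_substrate per-atom, per-coordinate Gaussian
#'   displacement scales (angstrom).
#' @param n_conformers conformers per ensemble.
#' @param n_wells,well_separation,jitter_sd dedup-fixture geometry: well
#'   count, minimum heavy-atom RMSD between well centers (angstrom) and
#'   within-well jitter scale (angstrom).
#' @param energy_scale mean of the exponential energy spread above the
#'   minimum (kJ/mol).
#' @param descriptor_model list with per-descriptor `intercept`, `slope`
#'   (per angstrom of ligand-part RMSD) and `noise_sd`, for the
#'   electronic descriptors `q_metal` (au), `q_donor` (au) and
#'   `homo_lumo_gap` (eV).
#' @param seed integer seed; a fixed seed makes every generator output
#'   reproducible.
#' @return a list of class `generator_config`.
#' @export
generator_config <- function(n_ligand_atoms = 24, n_substrate_atoms = 10,
                             sigma_ligand = 0.8, sigma_substrate = 0.05,
                             n_conformers = 20, n_wells = 5,
                             well_separation = 3.0, jitter_sd = 0.01,
                             energy_scale = 10,
                             descriptor_model = list(
                               q_metal = list(intercept = -0.20,
                                              slope = 0.02,
                                              noise_sd = 0.005),
                               q_donor = list(intercept = 1.10,
                                              slope = 0.01,
                                              noise_sd = 0.002),
                               homo_lumo_gap = list(intercept = 3.5,
                                                    slope = -0.10,
                                                    noise_sd = 0.02)),
                             seed = 1L) {
  stopifnot(n_ligand_atoms >= 5L, n_substrate_atoms >= 3L,
            sigma_ligand >= 0, sigma_substrate >= 0, n_conformers >= 1L,
            n_wells >= 1L, well_separation > 0, jitter_sd >= 0,
            energy_scale >= 0)
  cfg <- list(n_ligand_atoms = as.integer(n_ligand_atoms),
              n_substrate_atoms = as.integer(n_substrate_atoms),
              sigma_ligand = sigma_ligand,
              sigma_substrate = sigma_substrate,
              n_conformers = as.integer(n_conformers),
              n_wells = as.integer(n_wells),
              well_separation = well_separation, jitter_sd = jitter_sd,
              energy_scale = energy_scale,
              descriptor_model = descriptor_model,
              seed = as.integer(seed))
  class(cfg) <- "generator_config"
  cfg
}

#' Build a synthetic base complex with known fragment roles
#'
#' Constructs a geometrically valid catalyst-substrate complex: metal at
#' the origin, the two P donors symmetric about the donor-bisector axis,
#' two ligand arms grown from the donors with a well-defined axial
#' dihedral, and the substrate (two in-plane anchor carbons, one
#' out-of-plane oxygen reference, plus a chain) trans to the donors. The
#' reference atom is placed in the quadrant matching the requested
#' coordination mode, so [classify_coordination()] recovers it by
#' construction. No two atoms lie closer than 0.8 angstrom.
#'
#' @param config a [generator_config()].
#' @param coordination_mode requested mode (default `"major1"`;
#'   `"nbd"` builds the same skeleton with a symmetric placeholder
#'   label).
#' @param ligand_id ligand identifier stored on the template.
#' @return list with `structure` (a `structure3d`), `spec`
#'   (a `fragment_spec`), `template` (a `complex_template` with
#'   `chiral_reference` set), `anchor_indices` and `expected_sign` (sign
#'   of the built chiral dihedral).
#' @export
make_complex_template <- function(config, coordination_mode = "major1",
                                  ligand_id = "Lsyn") {
  nl <- config$n_ligand_atoms
  ns <- config$n_substrate_atoms
  substrate_kind <- if (coordination_mode == "nbd") "NBD" else "S"

  # lab placement: metal at origin, donors with a common -y component so
  # the donor bisector is well defined
  metal <- c(0, 0, 0)
  d1 <- c(1.55, -0.90, 0)
  d2 <- c(-1.55, -0.90, 0)
  fr <- local({  # frame implied by this placement
    u1 <- d1 / vnorm(d1); u2 <- d2 / vnorm(d2)
    x <- (u1 + u2) / vnorm(u1 + u2)
    z <- cross3(u1, u2); z <- z / vnorm(z)
    list(x = x, y = cross3(z, x) , z = z)
  })

  # two ligand arms; the first atom of each arm is lifted out of plane in
  # opposite directions, defining a nonzero axial dihedral
  n_arm <- nl - 2L
  n_arm1 <- ceiling(n_arm / 2)
  n_arm2 <- n_arm - n_arm1
  arm <- function(donor, side, n) {
    if (!n) return(NULL)
    out <- matrix(0, n, 3L)
    for (j in seq_len(n)) {
      out[j, ] <- donor + c(side * (0.9 + 0.9 * j),
                            -0.4 * j,
                            side * 0.8 * ((j - 1) %% 3 + 1) / 2)
    }
    out
  }
  arm1 <- arm(d1, +1, n_arm1)
  arm2 <- arm(d2, -1, n_arm2)

  # substrate trans to the donors (+y lab half-space)
  sx <- if (coordination_mode %in% c("major1", "minor1")) 1 else -1
  sy <- if (coordination_mode %in% c("major1", "major2", "nbd")) 1 else -1
  c1 <- -2.1 * fr$x + 0.7 * fr$y
  c2 <- -2.1 * fr$x - 0.7 * fr$y
  ref <- 0.9 * sx * fr$x + 0.9 * sy * fr$y + 1.1 * fr$z
  n_chain <- ns - 3L
  chain <- if (n_chain) {
    out <- matrix(0, n_chain, 3L)
    for (j in seq_len(n_chain)) {
      out[j, ] <- -(2.6 + 0.9 * j) * fr$x +
        0.9 * sin(1.7 * j) * fr$y + 0.6 * cos(1.3 * j) * fr$z
    }
    out
  } else NULL

  coords <- rbind(metal, d1, d2, arm1, arm2, c1, c2, ref, chain)
  rownames(coords) <- NULL
  # roles by construction order
  metal_index <- 1L
  donor_indices <- c(2L, 3L)
  ligand_indices <- seq_len(2L + n_arm) + 1L       # donors + arms
  substrate_indices <- (2L + n_arm + 2L):(nrow(coords))

  # elements: sprinkle hydrogens into arm/chain interiors so the
  # hydrogen-exclusion paths are exercised; anchors/donors/ref stay heavy
  elements <- character(nrow(coords))
  elements[metal_index] <- "Rh"
  elements[donor_indices] <- "P"
  arm_idx <- setdiff(ligand_indices, donor_indices)
  elements[arm_idx] <- ifelse(seq_along(arm_idx) %% 4L == 0L, "H", "C")
  anchor_indices <- substrate_indices[1:3]
  elements[substrate_indices] <- "C"
  elements[anchor_indices[3L]] <- "O"
  if (n_chain >= 4L) {
    chain_idx <- substrate_indices[-(1:3)]
    elements[chain_idx[seq_along(chain_idx) %% 4L == 0L]] <- "H"
  }

  if (min(stats::dist(coords)) < 0.8) {
    stop("infeasible atom counts: generated atoms closer than 0.8 angstrom",
         call. = FALSE)
  }
  s <- structure3d(elements, coords,
                   label = paste0(ligand_id, "-Rh-", substrate_kind))
  spec <- fragment_spec(metal_index, donor_indices, ligand_indices,
                        substrate_indices, n_atoms = nrow(coords))
  chiral_reference <- c(ligand_indices[3L], donor_indices[1L],
                        donor_indices[2L], ligand_indices[3L + n_arm1])
  expected_sign <- sign(dihedral_angle(coords[chiral_reference, ]))
  template <- complex_template(ligand_id, substrate_kind,
                               coordination_mode,
                               chiral_reference = chiral_reference)
  list(structure = s, spec = spec, template = template,
       anchor_indices = anchor_indices, expected_sign = expected_sign)
}

#' Generate a synthetic conformer ensemble with ground truth
#'
#' Conformer i is the base complex plus independent Gaussian
#' displacements (`sigma_ligand` on ligand atoms, `sigma_substrate` on
#' substrate atoms, the metal and the metal-anchored P donors), followed
#' by a random proper rigid
#' motion of the whole frame so downstream superposition cannot pass by
#' coordinate coincidence. Energies are `E_min` plus exponential draws
#' (mean `energy_scale` kJ/mol, member 1 pinned at the minimum).
#' Electronic descriptor values follow the configured linear model in
#' the conformer's ligand-part RMSD plus Gaussian noise, and are emitted
#' both in the property table and in the truth record.
#'
#' @param config a [generator_config()].
#' @param template_bundle output of [make_complex_template()].
#' @param stage ensemble stage label.
#' @return list with `ensemble` (a `conformer_ensemble`, baseline = the
#'   undistorted base structure), `property_table`, and `truth` (list:
#'   per-member `delta_E_kj`, `ligand_rmsd`, `descriptors` data.frame of
#'   noiseless-plus-noise values actually emitted).
#' @export
make_ensemble <- function(config, template_bundle, stage = "dft") {
  set.seed(config$seed)
  base <- template_bundle$structure
  spec <- template_bundle$spec
  n <- config$n_conformers
  nat <- n_atoms(base)
  e_base <- -5000  # hartree-scale electronic energy of the base complex

  delta_kj <- c(0, stats::rexp(n - 1L, rate = 1 / max(config$energy_scale,
                                                      1e-12)))
  if (config$energy_scale == 0) delta_kj[] <- 0
  sig <- rep(config$sigma_substrate, nat)
  sig[spec$ligand_indices] <- config$sigma_ligand
  # donors are metal-anchored in real complexes: the substrate part that
  # includes them is rigid, so they take the substrate displacement scale
  sig[spec$donor_indices] <- config$sigma_substrate
  members <- vector("list", n)
  for (i in seq_len(n)) {
    disp <- matrix(stats::rnorm(nat * 3L, sd = sig), nat, 3L)
    xyz <- base$coords + disp
    xyz <- apply_rigid_motion(xyz, random_rotation(),
                              stats::rnorm(3L, sd = 5))
    members[[i]] <- structure3d(
      base$elements, xyz,
      energy = e_base + convert_energy(delta_kj[i], "kJ/mol", "hartree"),
      energy_unit = "hartree",
      label = sprintf("conf%03d", i))
  }
  baseline <- structure3d(base$elements, base$coords,
                          energy = e_base + convert_energy(
                            2, "kJ/mol", "hartree"),  # search input sits above the best conformer
                          energy_unit = "hartree", label = "crest-input")
  ens <- conformer_ensemble(members,
                            ligand_id = template_bundle$template$ligand_id,
                            substrate_kind =
                              template_bundle$template$substrate_kind,
                            coordination_mode =
                              template_bundle$template$coordination_mode,
                            baseline = baseline, stage = stage)

  # descriptor ground truth from realized ligand-part flexibility
  ref <- which.min(delta_kj)
  lig_mask <- sort(c(spec$ligand_indices, spec$metal_index))
  lig_rmsd <- vapply(seq_len(n), function(i) {
    if (i == ref) return(0)
    minimal_rmsd(members[[ref]], members[[i]], mask = lig_mask)$rmsd
  }, numeric(1))
  dm <- config$descriptor_model
  val <- function(d) dm[[d]]$intercept + dm[[d]]$slope * lig_rmsd +
    stats::rnorm(n, sd = dm[[d]]$noise_sd)
  q_metal <- val("q_metal")
  q_donor <- val("q_donor")
  gap_ev <- pmax(val("homo_lumo_gap"), 0.5)

  gap_hartree <- convert_energy(gap_ev, "eV", "hartree")
  homo <- rep(-0.30, n)
  tab <- data.frame(member = seq_len(n),
                    energy_hartree = ensemble_energies(ens, "hartree"),
                    homo_hartree = homo,
                    lumo_hartree = homo + gap_hartree)
  tab[[paste0("q_", spec$metal_index)]] <- q_metal
  tab[[paste0("q_", spec$donor_indices[1L])]] <- q_donor + 0.01
  tab[[paste0("q_", spec$donor_indices[2L])]] <- q_donor - 0.01
  tab <- ingest_property_table(tab, ens)

  list(ensemble = ens, property_table = tab,
       truth = list(delta_E_kj = delta_kj, ligand_rmsd = lig_rmsd,
                    descriptors = data.frame(member = seq_len(n),
                                             q_metal = q_metal,
                                             q_donor = q_donor,
                                             homo_lumo_gap = gap_ev)))
}

#' Generate a deduplication fixture with a known well count
#'
#' Builds `n_wells` well centers (base complex plus well-specific ligand
#' displacements, redrawn until every pair of centers is at least
#' `well_separation` apart in heavy-atom minimal RMSD) and replicates
#' each with Gaussian jitter far below typical dedup tolerances, plus a
#' random rigid motion per member. Replicate energies stay within 0.2
#' kJ/mol of their well's energy, while wells get distinct energies.
#'
#' @param config a [generator_config()]; `jitter_sd` must be well below
#'   `well_separation`.
#' @param n_total total member count; replicates are spread as evenly as
#'   possible over wells (e.g. 151 members over 35 wells gives wells of
#'   4-5). Default `n_wells * 4`.
#' @return list with `ensemble` (members in generation order) and
#'   `truth` (per-member well id).
#' @export
make_dedup_fixture <- function(config, n_total = config$n_wells * 4L) {
  if (config$well_separation <= 10 * config$jitter_sd) {
    stop("well_separation must clearly exceed the jitter scale",
         call. = FALSE)
  }
  set.seed(config$seed + 1L)
  tb <- make_complex_template(config)
  base <- tb$structure
  spec <- tb$spec
  nat <- n_atoms(base)
  n_wells <- config$n_wells
  if (n_total < n_wells) stop("n_total < n_wells", call. = FALSE)

  lig_idx <- spec$ligand_indices
  well_structs <- vector("list", n_wells)
  for (k in seq_len(n_wells)) {
    for (attempt in 1:200) {
      xyz <- base$coords
      xyz[lig_idx, ] <- xyz[lig_idx, ] +
        matrix(stats::rnorm(length(lig_idx) * 3L,
                            sd = config$well_separation), ncol = 3L)
      cand <- structure3d(base$elements, xyz)
      ok <- TRUE
      for (m in seq_len(k - 1L)) {
        if (minimal_rmsd(well_structs[[m]], cand)$rmsd <
            config$well_separation) { ok <- FALSE; break }
      }
      if (ok) { well_structs[[k]] <- cand; break }
      if (attempt == 200) {
        stop("could not separate well centers; increase well_separation",
             call. = FALSE)
      }
    }
  }
  # replicate counts as even as possible; well energies 3 kJ/mol apart
  reps <- rep(n_total %/% n_wells, n_wells)
  extra <- n_total %% n_wells
  if (extra) reps[seq_len(extra)] <- reps[seq_len(extra)] + 1L
  e_base <- -5000
  members <- list()
  well_of <- integer(0)
  for (k in seq_len(n_wells)) {
    e_well_kj <- 3 * (k - 1L)
    for (r in seq_len(reps[k])) {
      xyz <- well_structs[[k]]$coords +
        matrix(stats::rnorm(nat * 3L, sd = config$jitter_sd), nat, 3L)
      xyz <- apply_rigid_motion(xyz, random_rotation(),
                                stats::rnorm(3L, sd = 5))
      e_kj <- e_well_kj + stats::runif(1, 0, 0.2)
      members[[length(members) + 1L]] <- structure3d(
        base$elements, xyz,
        energy = e_base + convert_energy(e_kj, "kJ/mol", "hartree"),
        energy_unit = "hartree",
        label = sprintf("well%02d_rep%02d", k, r))
      well_of <- c(well_of, k)
    }
  }
  ens <- conformer_ensemble(members, ligand_id = tb$template$ligand_id,
                            substrate_kind = tb$template$substrate_kind,
                            coordination_mode =
                              tb$template$coordination_mode,
                            baseline = base, stage = "crest")
  list(ensemble = ens, truth = list(well = well_of), spec = spec)
}

#' Write a synthetic dataset to disk in pipeline input formats
#'
#' Emits, under `dir`: `ensemble.xyz` (CREST-dialect multi-frame XYZ),
#' `baseline.xyz`, `properties.tsv` and `fragments.yml`, i.e. exactly
#' the formats the analysis pipeline reads.
#'
#' @param config a [generator_config()].
#' @param dir output directory (created if needed).
#' @param coordination_mode passed to [make_complex_template()].
#' @return the generation output of [make_ensemble()], invisibly, with
#'   `$paths` added.
#' @export
write_synthetic_dataset <- function(config, dir,
                                    coordination_mode = "major1") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tb <- make_complex_template(config, coordination_mode)
  gen <- make_ensemble(config, tb)
  paths <- list(ensemble = file.path(dir, "ensemble.xyz"),
                baseline = file.path(dir, "baseline.xyz"),
                properties = file.path(dir, "properties.tsv"),
                fragments = file.path(dir, "fragments.yml"))
  write_xyz(gen$ensemble, paths$ensemble)
  write_xyz(gen$ensemble$baseline, paths$baseline)
  write_property_table(gen$property_table, paths$properties)
  write_fragment_spec(tb$spec, paths$fragments)
  yaml::write_yaml(list(ligand_id = tb$template$ligand_id,
                        substrate_kind = tb$template$substrate_kind,
                        coordination_mode = tb$template$coordination_mode,
                        chiral_reference = tb$template$chiral_reference - 1L,
                        anchor_indices = tb$anchor_indices - 1L,
                        expected_sign = tb$expected_sign),
                   file.path(dir, "template.yml"))
  gen$paths <- paths
  gen$template_bundle <- tb
  invisible(gen)
}
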