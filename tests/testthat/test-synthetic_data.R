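test_that("generated base complexes satisfy every structural contract", {
  cfg <- generator_config(seed = 19)
  tb <- make_complex_template(cfg)
  spec <- tb$spec
  n <- n_atoms(tb$structure)
  expect_silent(validate_fragment_spec(spec, n))
  expect_identical(length(intersect(spec$ligand_indices,
                                    spec$substrate_indices)), 0L)
  expect_true(all(spec$donor_indices %in% spec$ligand_indices))
  expect_false(spec$metal_index %in% c(spec$ligand_indices,
                                       spec$substrate_indices))
  expect_gte(min(dist(tb$structure$coords)), 0.8)
  expect_identical(tb$structure$elements[spec$metal_index], "Rh")
  expect_identical(tb$structure$elements[spec$donor_indices], c("P", "P"))
  # classifier closure and chirality
  expect_identical(
    classify_coordination(tb$structure, spec, tb$anchor_indices), "major1")
  expect_true(check_chirality(tb$structure, tb$template$chiral_reference,
                              tb$expected_sign))
  mirrored <- tb$structure
  mirrored$coords <- mirrored$coords %*% diag(c(1, 1, -1))
  expect_false(check_chirality(mirrored, tb$template$chiral_reference,
                               tb$expected_sign))
  expect_error(generator_config(n_ligand_atoms = 3))
})

test_that("ensembles are seed-deterministic with exact truth records", {
  cfg <- generator_config(seed = 20, n_conformers = 9)
  tb <- make_complex_template(cfg)
  g1 <- make_ensemble(cfg, tb)
  g2 <- make_ensemble(cfg, tb)
  expect_identical(g1$ensemble$members[[5]]$coords,
                   g2$ensemble$members[[5]]$coords)
  expect_identical(g1$truth, g2$truth)
  g3 <- make_ensemble(generator_config(seed = 21, n_conformers = 9), tb)
  expect_false(identical(g1$ensemble$members[[5]]$coords,
                         g3$ensemble$members[[5]]$coords))
  # energies: minimum-anchored, first member at the minimum
  expect_equal(g1$truth$delta_E_kj[1], 0)
  expect_true(all(g1$truth$delta_E_kj >= 0))
})

test_that("zero displacement scales give all-zero rmsd profiles", {
  cfg <- generator_config(seed = 22, sigma_ligand = 0, sigma_substrate = 0,
                          n_conformers = 5)
  tb <- make_complex_template(cfg)
  gen <- make_ensemble(cfg, tb)
  prof <- rmsd_profile(gen$ensemble, tb$spec)
  expect_lt(max(prof$rmsd_whole, prof$rmsd_ligand, prof$rmsd_substrate),
            1e-7)
})

test_that("part rmsd magnitudes track the displacement scales", {
  cfg <- generator_config(seed = 23, sigma_ligand = 0.8,
                          sigma_substrate = 0.05, n_conformers = 100)
  tb <- make_complex_template(cfg)
  gen <- make_ensemble(cfg, tb)
  prof <- rmsd_profile(gen$ensemble, tb$spec)
  sub_med <- median(prof$rmsd_substrate[-attr(prof, "reference")])
  lig_med <- median(prof$rmsd_ligand[-attr(prof, "reference")])
  expect_lt(sub_med, 0.2)
  expect_gt(lig_med, 0.5)
  # chi-square expectation for two independently displaced copies after
  # removing the 6 rigid-body degrees of freedom: squared residuals sum
  # to ~ 6 sum(sigma_i^2) and the fit absorbs ~ 12 mean(sigma_i^2), so
  # E[rmsd^2] ~= (6 sum(sigma_i^2) - 12 mean(sigma_i^2)) / n; with equal
  # sigmas this is the textbook 2 sigma^2 (3n - 6) / n
  expected_rmsd <- function(sig_vec) {
    n <- length(sig_vec)
    sqrt((6 * sum(sig_vec^2) - 12 * mean(sig_vec^2)) / n)
  }
  part_sigmas <- function(idx) {
    idx <- idx[tb$structure$elements[idx] != "H"]
    sig <- rep(0.05, n_atoms(tb$structure))
    arm <- setdiff(tb$spec$ligand_indices, tb$spec$donor_indices)
    sig[arm] <- 0.8
    sig[idx]
  }
  lig_idx <- sort(c(tb$spec$ligand_indices, tb$spec$metal_index))
  sub_idx <- sort(c(tb$spec$substrate_indices, tb$spec$metal_index,
                    tb$spec$donor_indices))
  expect_equal(mean(prof$rmsd_ligand[-attr(prof, "reference")]),
               expected_rmsd(part_sigmas(lig_idx)), tolerance = 0.15)
  expect_equal(mean(prof$rmsd_substrate[-attr(prof, "reference")]),
               expected_rmsd(part_sigmas(sub_idx)), tolerance = 0.15)
})

test_that("dedup fixtures plant well-separated wells with tight replicates", {
  cfg <- generator_config(seed = 24, n_wells = 4, well_separation = 3,
                          jitter_sd = 0.01)
  fix <- make_dedup_fixture(cfg, n_total = 17L)
  expect_length(fix$ensemble, 17L)
  expect_identical(sort(unique(fix$truth$well)), 1:4)
  # within-well rmsd far below tolerance; across-well far above
  mem <- fix$ensemble$members
  w <- fix$truth$well
  same <- minimal_rmsd(mem[[which(w == 1)[1]]], mem[[which(w == 1)[2]]])
  diff_w <- minimal_rmsd(mem[[which(w == 1)[1]]], mem[[which(w == 2)[1]]])
  expect_lt(same$rmsd, 0.1)
  expect_gt(diff_w$rmsd, 1.0)
  # single well / single replicate degenerate cases
  fix1 <- make_dedup_fixture(generator_config(seed = 25, n_wells = 1),
                             n_total = 6L)
  expect_length(deduplicate(fix1$ensemble), 1L)
  fixr1 <- make_dedup_fixture(generator_config(seed = 26, n_wells = 5),
                              n_total = 5L)
  expect_length(deduplicate(fixr1$ensemble), 5L)
  expect_error(make_dedup_fixture(generator_config(seed = 1,
                                                   well_separation = 0.05,
                                                   jitter_sd = 0.01)),
               "exceed")
})

test_that("written synthetic datasets round-trip through the readers", {
  dir <- withr::local_tempdir()
  cfg <- generator_config(seed = 27, n_conformers = 6)
  gen <- write_synthetic_dataset(cfg, dir, coordination_mode = "minor2")
  entry <- dataset_entry(dir)
  ens <- read_ensemble_xyz(entry$ensemble, "crest")
  expect_length(ens, 6L)
  expect_equal(ensemble_energies(ens),
               ensemble_energies(gen$ensemble), tolerance = 1e-9)
  spec <- read_fragment_spec(entry$fragments)
  expect_identical(spec$donor_indices, gen$template_bundle$spec$donor_indices)
  tab <- ingest_property_table(entry$properties, ens)
  expect_equal(tab$lumo_hartree, gen$property_table$lumo_hartree,
               tolerance = 1e-10)
  tpl <- yaml::read_yaml(file.path(dir, "template.yml"))
  expect_identical(tpl$coordination_mode, "minor2")
})
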