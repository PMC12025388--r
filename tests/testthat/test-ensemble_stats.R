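mk_ens <- function(delta_kj, base = -5000, baseline_kj = 0) {
  # tiny rigid triangle complex; energies offset from the baseline in kJ/mol
  els <- c("Rh", "P", "P", "C", "C", "O")
  xyz <- rbind(c(0, 0, 0), c(1.6, -0.9, 0), c(-1.6, -0.9, 0),
               c(0, 2.1, 0.4), c(0.9, 2.4, -0.3), c(-0.8, 2.8, 0.9))
  members <- lapply(delta_kj, function(d) {
    structure3d(els, xyz,
                energy = base + convert_energy(d, "kJ/mol", "hartree"),
                energy_unit = "hartree")
  })
  baseline <- structure3d(els, xyz,
                          energy = base + convert_energy(baseline_kj,
                                                         "kJ/mol",
                                                         "hartree"),
                          energy_unit = "hartree")
  conformer_ensemble(members, substrate_kind = "S",
                     coordination_mode = "major1", baseline = baseline,
                     stage = "dft")
}

test_that("baseline-relative energies convert to kJ/mol correctly", {
  ens <- mk_ens(c(0, -26.25499639, 5))
  # -0.01 hartree relative to baseline is -26.255 kJ/mol
  expect_equal(relative_energies(ens), c(0, -26.25499639, 5),
               tolerance = 1e-9)
  ens$baseline$energy <- NULL
  expect_error(relative_energies(ens), "baseline")

  cfg <- generator_config(seed = 12, n_conformers = 8)
  gen <- make_ensemble(cfg, make_complex_template(cfg))
  # generator pins the search-input baseline 2 kJ/mol above the minimum
  expect_equal(relative_energies(gen$ensemble),
               gen$truth$delta_E_kj - 2, tolerance = 1e-9)
})

test_that("energy window filter retains members within the window", {
  kc <- function(x) convert_energy(x, "kcal/mol", "kJ/mol")
  ens <- mk_ens(kc(c(0, 3, 7)))
  expect_length(energy_window_filter(ens, 6, "kcal/mol"), 2L)
  expect_length(energy_window_filter(ens, 8, "kcal/mol"), 3L)
  expect_length(energy_window_filter(ens, 0, "kcal/mol"), 1L)
  # filter at w1 then w2 equals filter at min(w1, w2)
  a <- energy_window_filter(energy_window_filter(ens, 8), 4)
  b <- energy_window_filter(ens, 4)
  expect_equal(ensemble_energies(a), ensemble_energies(b))
})

test_that("deduplication recovers planted wells and is idempotent", {
  cfg <- generator_config(seed = 13, n_wells = 6, well_separation = 3,
                          jitter_sd = 0.01)
  fix <- make_dedup_fixture(cfg, n_total = 27L)
  dd <- deduplicate(fix$ensemble, rmsd_tol = 0.25, energy_tol = 1.0)
  expect_length(dd, 6L)
  # representatives are cluster energy minima, output sorted by energy
  expect_true(!is.unsorted(ensemble_energies(dd)))
  cl <- attr(dd, "cluster")
  expect_identical(length(unique(cl)), 6L)
  # cluster assignment matches the planted wells up to relabeling
  expect_equal(length(unique(paste(cl, fix$truth$well))), 6L)
  # idempotence
  dd2 <- deduplicate(dd, rmsd_tol = 0.25, energy_tol = 1.0)
  expect_length(dd2, length(dd))
  expect_equal(ensemble_energies(dd2), ensemble_energies(dd))

  expect_error(deduplicate(fix$ensemble, rmsd_tol = -1), "positive")
})

test_that("exact copies collapse to one; distant members stay distinct", {
  ens <- mk_ens(c(0, 0.05, 0.1))
  expect_length(deduplicate(ens), 1L)
  # two members 1.0 angstrom apart at tolerance 0.25 stay distinct
  a <- mk_ens(0)$members[[1]]
  b <- a
  b$coords[4:6, ] <- b$coords[4:6, ] +
    matrix(c(1.5, 0, 0, -1.2, 0.8, 0, 0, -1.4, 0.9), 3, 3, byrow = TRUE)
  two <- conformer_ensemble(list(a, b), substrate_kind = "S",
                            coordination_mode = "major1")
  expect_gt(minimal_rmsd(a, b)$rmsd, 0.5)
  expect_length(deduplicate(two, rmsd_tol = 0.25, energy_tol = 1.0), 2L)
})

test_that("retention filters remove flipped-chirality and rotated members", {
  cfg <- generator_config(seed = 14, sigma_ligand = 0.1,
                          sigma_substrate = 0.02, n_conformers = 10)
  tb <- make_complex_template(cfg, "major1")
  gen <- make_ensemble(cfg, tb)
  ens <- gen$ensemble

  # clean ensemble: identity, empty log
  clean <- apply_retention_filters(ens, tb$template, tb$spec,
                                   anchor_indices = tb$anchor_indices,
                                   expected_sign = tb$expected_sign)
  expect_length(clean$ensemble, 10L)
  expect_identical(nrow(clean$log), 0L)

  # mirror member 3 (chirality flip); rotate the substrate of members 5
  # and 8 into the opposite quadrant
  fr <- rhconf:::metal_frame(tb$structure, tb$spec)
  tamper <- ens
  m3 <- tamper$members[[3]]
  m3$coords <- m3$coords %*% diag(c(1, 1, -1))
  tamper$members[[3]] <- m3
  for (i in c(5, 8)) {
    m <- tamper$members[[i]]
    frm <- rhconf:::metal_frame(m, tb$spec)
    for (j in tb$spec$substrate_indices) {
      rel <- m$coords[j, ] - frm$origin
      m$coords[j, ] <- frm$origin + rel - 2 * sum(rel * frm$y) * frm$y
    }
    tamper$members[[i]] <- m
  }
  res <- apply_retention_filters(tamper, tb$template, tb$spec,
                                 anchor_indices = tb$anchor_indices,
                                 expected_sign = tb$expected_sign)
  expect_length(res$ensemble, 7L)
  expect_identical(res$log$member, c(3L, 5L, 8L))
  expect_identical(sort(unique(res$log$reason[res$log$member == 3])),
                   "chirality")
  expect_identical(res$log$reason[res$log$member %in% c(5, 8)],
                   c("coordination", "coordination"))
})

test_that("ensemble summaries respect count and energy invariants", {
  cfg <- generator_config(seed = 15, n_conformers = 15)
  tb <- make_complex_template(cfg)
  gen <- make_ensemble(cfg, tb)
  dd <- deduplicate(gen$ensemble, 0.25, 1.0)
  summ <- ensemble_summary(gen$ensemble, dd, spec = tb$spec)
  expect_lte(summ$n_distinct_dft, summ$n_crest)
  expect_lte(summ$delta_E_min, summ$delta_E_max)
  expect_gte(summ$rmsd_ligand_max, summ$rmsd_substrate_max)
  crest_small <- conformer_ensemble(gen$ensemble$members[1:3],
                                    substrate_kind = "S",
                                    coordination_mode = "major1")
  expect_error(ensemble_summary(crest_small, gen$ensemble),
               "cannot exceed")
})
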