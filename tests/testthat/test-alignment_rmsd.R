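test_that("Kabsch superposition recovers exact rigid motions", {
  with_seed(41, {
    P <- matrix(rnorm(24, sd = 2), 8, 3)
    res <- kabsch_superpose(P, P)
    expect_equal(res$rmsd, 0, tolerance = 1e-12)
    expect_equal(res$rotation, diag(3), tolerance = 1e-8)

    Rz90 <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE)
    Q <- apply_rigid_motion(P, Rz90, c(5, -2, 1))
    res <- kabsch_superpose(P, Q)
    expect_lt(res$rmsd, 1e-10)
    expect_equal(det(res$rotation), 1, tolerance = 1e-8)
    # returned transform maps Q onto P
    back <- apply_rigid_motion(Q, res$rotation, res$translation)
    expect_lt(max(abs(back - P)), 1e-8)
  })
  expect_error(kabsch_superpose(diag(3)[1:2, ], diag(3)[1:2, ]), "3 atoms")
  expect_error(kabsch_superpose(matrix(0, 4, 3), matrix(0, 5, 3)),
               "differ in size")
})

test_that("Kabsch rmsd matches the rotation-grid-search oracle", {
  # planar triangle with one displaced vertex
  P <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  Q <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1.2, 0))
  expect_lt(abs(kabsch_superpose(P, Q)$rmsd - grid_search_rmsd(P, Q)),
            1e-3)
  with_seed(43, {
    for (i in 1:4) {
      n <- sample(4:6, 1)
      P <- matrix(rnorm(3 * n, sd = 1.5), n, 3)
      Q <- P + matrix(rnorm(3 * n, sd = 0.3), n, 3)
      oracle <- grid_search_rmsd(P, Q)
      got <- kabsch_superpose(P, Q)$rmsd
      expect_lt(abs(got - oracle), 1e-3)
      expect_lte(got, oracle + 1e-12)  # closed form is the true minimum
    }
  })
})

test_that("rmsd is symmetric, rigid-motion invariant and bounded by the max displacement", {
  with_seed(47, {
    P <- matrix(rnorm(30, sd = 2), 10, 3)
    Q <- P + matrix(rnorm(30, sd = 0.5), 10, 3)
    expect_equal(kabsch_superpose(P, Q)$rmsd, kabsch_superpose(Q, P)$rmsd,
                 tolerance = 1e-9)
    base <- kabsch_superpose(P, Q)
    for (i in 1:100) {
      Qm <- apply_rigid_motion(Q, random_rotation(), rnorm(3, sd = 10))
      expect_equal(kabsch_superpose(P, Qm)$rmsd, base$rmsd,
                   tolerance = 1e-8)
    }
    # rmsd <= max per-atom displacement after optimal superposition
    aligned <- apply_rigid_motion(Q, base$rotation, base$translation)
    max_disp <- max(sqrt(rowSums((P - aligned)^2)))
    expect_lte(base$rmsd, max_disp + 1e-12)
  })
})

test_that("hydrogen exclusion and masks behave per contract", {
  eth <- ethanol_fixture()
  pert <- eth
  h_idx <- which(eth$elements == "H")
  with_seed(53, {
    pert$coords[h_idx, ] <- pert$coords[h_idx, ] +
      matrix(rnorm(length(h_idx) * 3, sd = 0.3), ncol = 3)
  })
  expect_equal(minimal_rmsd(eth, pert, exclude_hydrogens = TRUE)$rmsd, 0,
               tolerance = 1e-12)
  expect_gt(minimal_rmsd(eth, pert, exclude_hydrogens = FALSE)$rmsd, 0.05)

  methane <- structure3d(c("C", "H", "H", "H", "H"),
                         rbind(c(0, 0, 0), c(0.63, 0.63, 0.63),
                               c(-0.63, -0.63, 0.63), c(-0.63, 0.63, -0.63),
                               c(0.63, -0.63, -0.63)))
  expect_error(minimal_rmsd(methane, methane), "fewer than 3")
  expect_error(minimal_rmsd(eth, eth, mask = c(1, 99)), "out of range")
  other <- structure3d(rev(eth$elements), eth$coords)
  expect_error(minimal_rmsd(eth, other), "element sequence")
})

test_that("masked fragment rmsd agrees with the grid-search oracle on a torsioned pair", {
  # ligand-part pair differing by a known torsion of one arm
  cfg <- generator_config(seed = 6, n_ligand_atoms = 5,
                          n_substrate_atoms = 3)
  tb <- make_complex_template(cfg)
  a <- tb$structure
  b <- a
  # rotate the first arm atom about the donor-donor axis by 25 degrees
  d1 <- a$coords[tb$spec$donor_indices[1], ]
  d2 <- a$coords[tb$spec$donor_indices[2], ]
  axis <- (d2 - d1) / sqrt(sum((d2 - d1)^2))
  th <- 25 * pi / 180
  K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  Rax <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
  arm_idx <- setdiff(tb$spec$ligand_indices, tb$spec$donor_indices)
  for (i in arm_idx) {
    b$coords[i, ] <- d1 + as.numeric(Rax %*% (b$coords[i, ] - d1))
  }
  mask <- sort(c(tb$spec$ligand_indices, tb$spec$metal_index))
  got <- minimal_rmsd(a, b, mask = mask)$rmsd
  heavy <- mask[a$elements[mask] != "H"]
  want <- grid_search_rmsd(a$coords[heavy, ], b$coords[heavy, ])
  expect_gt(got, 0.05)
  expect_lt(abs(got - want), 1e-3)
})

test_that("rmsd agrees with an independent superposition implementation", {
  skip_if_not_installed("bio3d")
  with_seed(59, {
    P <- matrix(rnorm(36, sd = 2), 12, 3)
    Q <- P + matrix(rnorm(36, sd = 0.4), 12, 3)
    ref <- bio3d::rmsd(as.numeric(t(P)), as.numeric(t(Q)),
                       fit = TRUE)
    expect_equal(kabsch_superpose(P, Q)$rmsd, as.numeric(ref),
                 tolerance = 1e-3)
  })
})

test_that("rmsd profiles are referenced to the lowest-energy member", {
  cfg <- generator_config(seed = 9, n_conformers = 12)
  tb <- make_complex_template(cfg)
  gen <- make_ensemble(cfg, tb)
  prof <- rmsd_profile(gen$ensemble, tb$spec)
  ref <- attr(prof, "reference")
  expect_identical(ref, lowest_energy_member(gen$ensemble))
  expect_equal(unlist(prof[ref, c("delta_E_kj", "rmsd_whole",
                                  "rmsd_ligand", "rmsd_substrate")]),
               c(delta_E_kj = 0, rmsd_whole = 0, rmsd_ligand = 0,
                 rmsd_substrate = 0), tolerance = 1e-12)
  expect_true(all(prof$delta_E_kj >= 0))

  # identical copies with distinct energies: all rmsd zero, ref = member 2
  s <- tb$structure
  mk <- function(e) structure3d(s$elements, s$coords, energy = e,
                                energy_unit = "hartree")
  ens2 <- conformer_ensemble(list(mk(-4999.99), mk(-5000.00)),
                             substrate_kind = "S",
                             coordination_mode = "major1")
  prof2 <- rmsd_profile(ens2, tb$spec)
  expect_identical(attr(prof2, "reference"), 2L)
  expect_equal(max(prof2[c("rmsd_whole", "rmsd_ligand",
                           "rmsd_substrate")]), 0, tolerance = 1e-12)

  noE <- conformer_ensemble(list(structure3d(s$elements, s$coords)),
                            substrate_kind = "S",
                            coordination_mode = "major1")
  expect_error(rmsd_profile(noE, tb$spec), "without energy")
})

test_that("flexible ligand and rigid substrate separate in the profile", {
  cfg <- generator_config(seed = 10, sigma_ligand = 0.8,
                          sigma_substrate = 0.05, n_conformers = 30)
  tb <- make_complex_template(cfg)
  gen <- make_ensemble(cfg, tb)
  prof <- rmsd_profile(gen$ensemble, tb$spec)
  expect_gt(median(prof$rmsd_ligand), median(prof$rmsd_substrate))
  expect_gt(median(prof$rmsd_ligand), 0.5)
  expect_lt(median(prof$rmsd_substrate), 0.2)
})
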