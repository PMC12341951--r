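test_that("membrane patches conserve composition and core slab thickness", {
  p <- build_membrane_patch("bilayer", builtin_composition("jojoba"),
                            patch_dims = c(60, 60),
                            n_lipids_per_leaflet = 100, seed = 2L)
  top <- p$topology
  geom0 <- p$frame$coords[, 3L]
  for (leaf in c(1, -1)) {
    heads <- which(top$role == "lipid_head" & sign(geom0) == leaf)
    counts <- table(top$residue_name[heads])
    expect_equal(counts[["PC"]], 45L)
    expect_equal(counts[["PE"]], 38L)
    expect_equal(counts[["PI"]], 10L)
    expect_equal(counts[["PG"]], 7L)
  }
  expect_equal(sum(top$role == "core_neutral"), 0L)

  we <- build_membrane_patch("we_monolayer", core_gap = 30, seed = 2L)
  core_z <- we$frame$coords[we$topology$role == "core_neutral", 3L]
  expect_equal(max(core_z) - min(core_z), 30, tolerance = 2)

  expect_error(build_membrane_patch("bilayer", n_lipids_per_leaflet = 2),
               "too small")
})

test_that("patch generation is deterministic under a fixed seed", {
  a <- build_membrane_patch("we_monolayer", seed = 5L)
  b <- build_membrane_patch("we_monolayer", seed = 5L)
  expect_identical(a$frame$coords, b$frame$coords)
  c_ <- build_membrane_patch("we_monolayer", seed = 6L)
  expect_false(identical(a$frame$coords, c_$frame$coords))
})

test_that("protein placement honors height and the six orientations", {
  prot <- make_pseudo_protein(30L, seed = 3L)
  box <- c(60, 60, 100)
  placed <- place_protein(prot, 1L, 50, 0, box)
  expect_equal(mean(placed$coords[, 3L]), 50, tolerance = 1e-9)
  expect_equal(mean(placed$coords[, 1L]), 30, tolerance = 1e-9)

  # orientations 1 and 3 differ by a 180-degree x rotation: z mirrors
  p1 <- place_protein(prot, 1L, 50, 0, box)
  p3 <- place_protein(prot, 3L, 50, 0, box)
  expect_equal(p1$coords[, 3L] - 50, -(p3$coords[, 3L] - 50),
               tolerance = 1e-9)

  # all six orientations of an asymmetric body are pairwise distinct
  placed_all <- lapply(1:6, function(o)
    sweep(place_protein(prot, o, 50, 0, box)$coords, 2L,
          c(30, 30, 50)))
  for (i in 1:5) for (j in (i + 1):6) {
    rmsd <- sqrt(mean(rowSums((placed_all[[i]] - placed_all[[j]])^2)))
    expect_gt(rmsd, 0.5)
  }
  expect_error(place_protein(prot, 7L, 50, 0, box), "orientation")
  expect_warning(place_protein(prot, 1L, 5, 0, box), "overlap")
})

test_that("trajectories are reproducible and binding residues validated", {
  cfg <- scenario_config(n_frames = 10L, n_lipids_per_leaflet = 20L,
                         patch_dims = c(30, 30), n_residues = 20L,
                         binding_residues = 8:10, seed = 4L)
  a <- generate_trajectory(cfg)
  b <- generate_trajectory(cfg)
  expect_identical(a$frames[[10L]]$coords, b$frames[[10L]]$coords)
  cfg2 <- scenario_config(n_frames = 10L, n_lipids_per_leaflet = 20L,
                          patch_dims = c(30, 30), n_residues = 20L,
                          binding_residues = 8:10, seed = 5L)
  expect_false(identical(generate_trajectory(cfg2)$frames[[10L]]$coords,
                         a$frames[[10L]]$coords))
  expect_error(scenario_config(n_residues = 20L, binding_residues = 40:45),
               "binding_residues")
})

test_that("a bounce scenario associates and then releases", {
  cfg <- scenario_config(membrane_kind = "we_monolayer", n_frames = 80L,
                         bounce = TRUE, bind_time = 20, seed = 5L)
  traj <- generate_trajectory(cfg)
  s <- residue_contact_series(traj, 42L)
  expect_gt(max(s), 0.5)             # initial association
  expect_equal(tail(s, 3L), c(0, 0, 0))  # contacts return to zero
})

test_that("zero surfacing rate keeps the core below the glycerol plane", {
  cfg <- scenario_config(membrane_kind = "we_monolayer", n_frames = 30L,
                         surfacing_rate = 0, jitter_sigma = 0, seed = 9L)
  traj <- generate_trajectory(cfg)
  glyc <- attr(traj, "glycerol_plane")
  core_idx <- select_atoms(traj$topology, role = "core_neutral")
  top_core <- max(vapply(traj$frames, function(f)
    max(f$coords[core_idx, 3L]), numeric(1L)))
  expect_lt(top_core, glyc)
})

test_that("ideal helices have canonical dihedrals, rise and wheel period", {
  h <- generate_ideal_helix(strrep("ALSKFGEVTM", 2L))
  dh <- backbone_dihedrals(h)
  interior <- dh[2:19, ]
  expect_true(all(abs(interior$phi[-1L] - (-57)) < 1, na.rm = TRUE))
  expect_true(all(abs(interior$psi - (-47)) < 1, na.rm = TRUE))

  # rise per residue from a least-squares axis fit on CA positions
  ca <- h$frame$coords[h$topology$atom_name == "CA", ]
  cc <- sweep(ca, 2L, colMeans(ca))
  axis <- svd(cc)$v[, 1L]
  rise <- abs(mean(diff(cc %*% axis)))
  expect_equal(rise, 1.5, tolerance = 0.1)

  # 18 residues span exactly 5 turns: residue 19 returns to residue 1
  ang <- wheel_angles(19L)
  expect_equal(ang[19L], ang[1L])
  expect_error(generate_ideal_helix("ALX"), "at least 4|unknown")
  expect_error(generate_ideal_helix("ALXKK"), "unknown")
})
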