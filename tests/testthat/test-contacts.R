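test_that("contact kernel matches its closed form and is monotone", {
  expect_equal(contact_kernel(4), 0.5)
  expect_lt(abs(contact_kernel(0) - 1), 1e-8)
  expect_equal(contact_kernel(5), 1 / (1 + exp(5)), tolerance = 1e-12)
  expect_equal(contact_kernel(5), 0.006693, tolerance = 1e-4)
  d <- seq(0, 10, by = 0.05)
  expect_true(all(diff(contact_kernel(d)) < 0))
  expect_error(contact_kernel(-1), "nonnegative")
})

test_that("single-pair geometry gives the kernel value; the 5 A prefilter
           zeroes distant pairs", {
  sys <- toy_bilayer(n_side = 1L, spacing = 40)  # one lipid per leaflet
  # protein atom exactly 4 A above the upper head bead
  head_z <- max(sys$frame$coords[, 3L])
  head_xy <- sys$frame$coords[which.max(sys$frame$coords[, 3L]), 1:2]
  sys2 <- with_protein(sys, matrix(c(head_xy, head_z + 4), 1L))
  traj <- one_frame_traj(sys2)
  # only the head bead is within 5 A (glycerol is 2 A further)
  s <- residue_contact_series(traj, 1L,
                              membrane_selection = select_atoms(
                                sys2$topology, role = "lipid_head"))
  expect_equal(s, 0.5, tolerance = 1e-12)

  sys3 <- with_protein(sys, matrix(c(head_xy, head_z + 6), 1L))
  s3 <- residue_contact_series(one_frame_traj(sys3), 1L)
  expect_identical(s3, 0)
  expect_error(residue_contact_series(traj, 1L,
                                      membrane_selection = integer(0)),
               "empty")
})

test_that("prefiltered contacts equal the brute-force all-pairs oracle", {
  set.seed(42)
  sys <- toy_bilayer(n_side = 3L)  # 54 membrane atoms
  for (rep in 1:5) {
    prot <- cbind(runif(4, 0, 15), runif(4, 0, 15), runif(4, 8, 20))
    sys2 <- with_protein(sys, prot)
    traj <- one_frame_traj(sys2)
    mem_idx <- select_atoms(sys2$topology, role = lipid_roles(TRUE),
                            heavy_only = TRUE)
    got <- residue_contact_series(traj, 1L)
    prot_idx <- select_atoms(sys2$topology, role = "protein")
    want <- brute_contact_sum(sys2$frame$coords, sys2$frame$box,
                              prot_idx, mem_idx)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("contacts are invariant under in-plane translation and periodic
           wrapping, and monotone in membrane additions", {
  sys <- toy_bilayer(n_side = 3L)
  prot <- matrix(c(7.5, 7.5, 18), 1L)
  base <- with_protein(sys, prot)
  s0 <- residue_contact_series(one_frame_traj(base), 1L)

  shift <- base
  shifted_coords <- base$frame$coords
  shifted_coords[, 1L] <- shifted_coords[, 1L] + 3.3
  shift$frame <- ld_frame(shifted_coords, box = base$frame$box)
  expect_equal(residue_contact_series(one_frame_traj(shift), 1L), s0,
               tolerance = 1e-9)

  wrap <- base
  wc <- base$frame$coords
  wc[1L, 1L] <- wc[1L, 1L] + base$frame$box[1L]  # wrap one atom by a period
  wrap$frame <- ld_frame(wc, box = base$frame$box)
  expect_equal(residue_contact_series(one_frame_traj(wrap), 1L), s0,
               tolerance = 1e-9)

  # adding a membrane atom within the cutoff never decreases C
  extra_df <- rbind(as.data.frame(unclass(base$topology)),
                    data.frame(atom_id = max(base$topology$atom_id) + 1L,
                               atom_name = "HD", element = "C",
                               is_heavy = TRUE, residue_index = 1L,
                               residue_name = "PC",
                               molecule_id = max(base$topology$molecule_id)
                                 + 1L,
                               role = "lipid_head"))
  top2 <- ld_topology(extra_df$atom_id, extra_df$atom_name,
                      extra_df$element, extra_df$residue_index,
                      extra_df$residue_name, extra_df$molecule_id,
                      extra_df$role)
  coords2 <- rbind(base$frame$coords, c(7.5, 7.5, 15))
  traj2 <- one_frame_traj(list(topology = top2,
                               frame = ld_frame(coords2, base$frame$box)))
  expect_gte(residue_contact_series(traj2, 1L), s0)
})

test_that("bound-state detection uses a strict threshold", {
  expect_identical(bound_frames(c(30, 10, 26)), c(TRUE, FALSE, TRUE))
  expect_identical(bound_frames(c(25, 25.0001)), c(FALSE, TRUE))
  expect_identical(bound_frames(rep(0, 4L)), rep(FALSE, 4L))
})

test_that("cumulative profiles sum bound averages in sequence order", {
  expect_equal(cumulative_profile(c(1, 2, 3)), c(1, 3, 6))
  expect_equal(cumulative_profile(c(5, 0, 5)), c(5, 5, 10))
  v <- runif(20, 0, 40)
  expect_equal(cumulative_profile(v)[20L], sum(v))
  expect_true(all(diff(cumulative_profile(v)) >= 0))
})

test_that("avg_bound is above threshold or exactly zero", {
  traj <- generate_trajectory(scenario_config(
    n_frames = 40L, n_lipids_per_leaflet = 40L, patch_dims = c(42, 42),
    n_residues = 20L, binding_residues = 8:10, bind_time = 8, seed = 21L))
  prof <- contact_profile(traj)
  expect_true(all(prof$avg_bound > prof$threshold | prof$avg_bound == 0))
  expect_true(all(prof$per_frame >= 0))
  expect_true(all(diff(prof$cumulative) >= 0))
  expect_identical(unname(prof$bound_mask),
                   unname(prof$per_frame > prof$threshold))
})
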