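test_that("PDB write/read round-trips a small synthetic patch", {
  sys <- toy_bilayer(n_side = 2L)
  tf <- tempfile(fileext = ".pdb")
  write_structure(sys$topology, sys$frame, tf)
  back <- read_structure(tf)
  expect_equal(nrow(back$topology), nrow(sys$topology))
  expect_equal(back$topology$atom_name, sys$topology$atom_name)
  expect_equal(back$frame$coords, sys$frame$coords, tolerance = 1e-3)
  # role recovery through the default map + atom-name refinement
  expect_equal(back$topology$role, sys$topology$role)
})

test_that("hydrogen atoms are read as light; unknown residues warn", {
  tf <- tempfile(fileext = ".pdb")
  top <- ld_topology(1:2, c("CA", "H1"), c("C", "H"), c(1L, 1L),
                     c("ALA", "ALA"), c(1L, 1L), rep("protein", 2L))
  write_structure(top, ld_frame(rbind(c(0, 0, 0), c(1, 0, 0)),
                                box = c(10, 10, 10)), tf)
  back <- read_structure(tf)
  expect_identical(back$topology$is_heavy, c(TRUE, FALSE))

  top2 <- ld_topology(1L, "X1", "C", 1L, "ZZZ", 1L, "solvent")
  write_structure(top2, ld_frame(matrix(0, 1L, 3L), box = c(10, 10, 10)), tf)
  expect_warning(back2 <- read_structure(tf), "ZZZ")
  expect_identical(back2$topology$role, "solvent")
})

test_that("empty or missing structure files raise parse errors", {
  tf <- tempfile(fileext = ".pdb")
  writeLines(character(0), tf)
  expect_error(read_structure(tf))
  expect_error(read_structure(tempfile()), "not found")
})

test_that("XYZ trajectory round-trips and flags truncation", {
  sys <- toy_bilayer(n_side = 2L)
  traj <- one_frame_traj(sys, times = c(0, 1, 2))
  tf <- tempfile(fileext = ".xyz")
  write_trajectory_xyz(traj, tf)
  top <- read_topology_json(paste0(tf, ".top.json"))
  back <- read_trajectory(top, tf)
  expect_equal(length(back$frames), 3L)
  # static structure: all frames identical, coordinates kept to 3 decimals
  expect_equal(back$frames[[1L]]$coords, back$frames[[3L]]$coords)
  expect_equal(back$frames[[2L]]$coords, traj$frames[[2L]]$coords,
               tolerance = 1e-3)
  expect_equal(vapply(back$frames, `[[`, numeric(1L), "time"), c(0, 1, 2))

  # drop the tail of the last frame -> error identifying frame 2
  lines <- readLines(tf)
  writeLines(lines[seq_len(length(lines) - 5L)], tf)
  expect_error(read_trajectory(top, tf), "frame 2")

  # a frame with the wrong atom count is named
  writeLines(c("2", "frame=0 t=0", "A 0 0 0", "B 1 0 0"), tf)
  expect_error(read_trajectory(top, tf), "frame 0")
})

test_that("atom selection is deterministic, idempotent and complementary", {
  sys <- toy_bilayer(n_side = 2L)
  top <- sys$topology
  expect_identical(select_atoms(top, role = "protein"), integer(0))
  heads <- select_atoms(top, role = "lipid_head")
  expect_identical(select_atoms(top, role = "lipid_head"), heads)
  expect_false(is.unsorted(heads))
  others <- select_atoms(top, role = setdiff(
    c("protein", "lipid_head", "lipid_glycerol", "lipid_chain",
      "core_neutral", "solvent"), "lipid_head"))
  expect_identical(sort(union(heads, others)), seq_len(nrow(top)))

  mixed <- ld_topology(1:8, c(paste0("H", 1:3), paste0("C", 1:5)),
                       c(rep("H", 3L), rep("C", 5L)), rep(1L, 8L),
                       rep("ALA", 8L), rep(1L, 8L), rep("protein", 8L))
  expect_length(select_atoms(mixed, heavy_only = TRUE), 5L)
})

test_that("membrane geometry is symmetric, translation-equivariant and
           consistent with direct plane averaging", {
  sys <- toy_bilayer(n_side = 3L)
  traj <- one_frame_traj(sys)
  geom <- membrane_geometry(traj)
  expect_equal(geom$center_z[1L], 0, tolerance = 1e-9)
  expect_gt(geom$head_plane_upper[1L], geom$center_z[1L])
  expect_lt(geom$head_plane_lower[1L], geom$center_z[1L])
  # mirror-symmetric patch: mean of head planes is the center
  expect_equal((geom$head_plane_upper[1L] + geom$head_plane_lower[1L]) / 2,
               geom$center_z[1L], tolerance = 1e-9)

  shifted <- sys
  shifted$frame <- ld_frame(sweep(sys$frame$coords, 2L, c(0, 0, 7)),
                            box = sys$frame$box)
  gs <- membrane_geometry(one_frame_traj(shifted))
  expect_equal(gs$center_z[1L], geom$center_z[1L] - 7, tolerance = 1e-9)
  expect_equal(gs$head_plane_upper[1L], geom$head_plane_upper[1L] - 7,
               tolerance = 1e-9)

  inplane <- sys
  inplane$frame <- ld_frame(sweep(sys$frame$coords, 2L, c(-3, 4, 0)),
                            box = sys$frame$box)
  gi <- membrane_geometry(one_frame_traj(inplane))
  expect_equal(gi$center_z[1L], geom$center_z[1L], tolerance = 1e-9)
})

test_that("degenerate membranes are rejected", {
  # single leaflet only: all heads on one side
  sys <- toy_bilayer(n_side = 2L)
  top <- sys$topology
  coords <- sys$frame$coords
  coords[, 3L] <- abs(coords[, 3L]) + 1  # push everything to the upper side
  expect_error(membrane_geometry(one_frame_traj(
    list(topology = top, frame = ld_frame(coords, sys$frame$box)))),
    "leaflet")
})
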