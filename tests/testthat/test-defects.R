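test_that("a fully tiled leaflet has no defect cells", {
  sys <- tiled_monolayer()
  dm <- classify_surface(sys$frame, sys$topology, "upper",
                         sys$glycerol_plane)
  expect_equal(sum(dm$defect), 0L)
  expect_equal(nrow(dm$components), 0L)
  expect_equal(dm$area_fraction, 0)
})

test_that("a 3x3 uncovered window over exposed core is one 9 A^2 component", {
  win <- as.matrix(expand.grid(3:5, 3:5))
  sys <- tiled_monolayer(drop_cells = win,
                         core_at = matrix(c(4.5, 4.5), 1L), z_core = 10)
  dm <- classify_surface(sys$frame, sys$topology, "upper",
                         sys$glycerol_plane)
  expect_equal(nrow(dm$components), 1L)
  expect_equal(dm$components$area, 9)
  # component bookkeeping: total area equals defect cells x cell area
  expect_equal(sum(dm$components$area), sum(dm$defect) * dm$cell_size^2)
})

test_that("two separated windows give two components; leaflets are
           symmetric", {
  win <- rbind(as.matrix(expand.grid(1:3, 1:3)),
               as.matrix(expand.grid(7:9, 7:9)))
  sys <- tiled_monolayer(drop_cells = win)
  dm <- classify_surface(sys$frame, sys$topology, "upper",
                         sys$glycerol_plane)
  expect_equal(nrow(dm$components), 2L)
  expect_equal(sort(dm$components$area), c(9, 9))
  # the untouched lower leaflet stays fully covered
  dl <- classify_surface(sys$frame, sys$topology, "lower",
                         -sys$glycerol_plane)
  expect_equal(sum(dl$defect), 0L)
  expect_error(classify_surface(sys$frame,
                                toy_topology(rep("protein", 3L)),
                                "upper", 15), "lipid")
})

test_that("half-cell shifts change component areas by at most a cell ring", {
  win <- as.matrix(expand.grid(3:6, 3:6))  # 4x4 window, area 16
  sys <- tiled_monolayer(drop_cells = win)
  base <- classify_surface(sys$frame, sys$topology, "upper",
                           sys$glycerol_plane)
  shifted <- sys
  sc <- sys$frame$coords
  sc[, 1L] <- sc[, 1L] + 0.5
  shifted$frame <- ld_frame(sc, box = sys$frame$box)
  dm <- classify_surface(shifted$frame, sys$topology, "upper",
                         sys$glycerol_plane)
  expect_equal(nrow(dm$components), 1L)
  ring <- 4 * 4 + 4  # one ring of cells around a 4x4 component
  expect_lte(abs(dm$components$area - base$components$area), ring)
})

test_that("the exponential size constant recovers simulated draws", {
  set.seed(101)
  areas <- 5 + rexp(2000, 1 / 12)
  lam <- defect_size_constant(areas, a_min = 5)
  expect_equal(lam, 12, tolerance = 0.6 / 12)
  expect_equal(defect_size_constant(rep(5, 30), a_min = 5), 0)
  expect_error(defect_size_constant(rexp(10) + 5), "more frames")
})

test_that("defect area grows with the surfacing footprint", {
  lam <- function(disc, rate, seed) {
    cfg <- scenario_config(membrane_kind = "we_monolayer", n_frames = 60L,
                           surfacing_rate = rate, surfacing_disc = disc,
                           seed = seed)
    traj <- generate_trajectory(cfg)
    geom <- membrane_geometry(traj)
    ds <- defect_series(traj, geom, radius = 4)
    c(lambda = tryCatch(defect_size_constant(ds$areas$area),
                        error = function(e) 0),
      frac = mean(ds$area_fraction))
  }
  lo <- (lam(8, 0.2, 31L) + lam(8, 0.2, 32L)) / 2
  hi <- (lam(12, 0.5, 31L) + lam(12, 0.5, 32L)) / 2
  expect_gt(hi[["lambda"]], lo[["lambda"]])
  expect_gt(hi[["frac"]], lo[["frac"]])
})
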