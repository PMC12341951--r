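test_that("Wimley-White sums are additive and match scale entries", {
  expect_equal(ww_sum("IM"), -0.31 + -0.23)
  expect_equal(ww_sum(""), 0)
  s1 <- "ALSKF"; s2 <- "GEVTM"
  expect_equal(ww_sum(paste0(s1, s2)), ww_sum(s1) + ww_sum(s2))
  expect_error(ww_sum("ALX"), "X")
  expect_length(ww_interface_scale(), 20L)
})

test_that("mutations apply by position with wild-type checking", {
  seqwin <- "AAIKKMAA"  # I at 3, M at 6
  mut <- apply_mutations(seqwin, c("I3F", "M6L"))
  expect_identical(mut, "AAFKKLAA")
  # order independence and involution
  expect_identical(apply_mutations(seqwin, c("M6L", "I3F")), mut)
  expect_identical(apply_mutations(mut, c("F3I", "L6M")), seqwin)
  expect_error(apply_mutations(seqwin, "A3F"), "expected A, found I")
  expect_error(apply_mutations(seqwin, "I99F"), "outside")
  # window offset: full-protein numbering into a window
  expect_identical(apply_mutations(seqwin, c("I158F", "M161L"),
                                   offset = 155L), "AAFKKLAA")
})

test_that("the mutation delta is sequence-independent", {
  delta <- ww_mutation_delta(c("I158F", "M161L"))
  sc <- ww_interface_scale()
  expect_equal(delta, (sc[["F"]] - sc[["I"]]) + (sc[["L"]] - sc[["M"]]))
  expect_equal(delta, -1.15)
  # same delta realized in two different contexts
  ctx1 <- "GGIGGMGG"; ctx2 <- "WWIEEMKK"
  expect_equal(ww_sum(apply_mutations(ctx1, c("I3F", "M6L"))) - ww_sum(ctx1),
               delta)
  expect_equal(ww_sum(apply_mutations(ctx2, c("I3F", "M6L"))) - ww_sum(ctx2),
               delta)
})

test_that("hydrophobic moments cancel, point at the hydrophobic face and
           are phase-invariant", {
  # homopolymer over exact turns: symmetric cancellation
  expect_lt(hydrophobic_moment(strrep("L", 18L))$magnitude, 1e-9)

  # perfect amphipathic toy: hydrophobic (+1) at wheel angles 0..180,
  # hydrophilic (-1) elsewhere, via a custom scale over 36 residues
  # (angles k*100 mod 360 cover all decades)
  ang <- wheel_angles(36L)
  h <- ifelse(ang <= 180, 1, -1)
  # direct vector-summation oracle
  mx <- sum(h * cos(ang * pi / 180)); my <- sum(h * sin(ang * pi / 180))
  want_dir <- (atan2(my, mx) * 180 / pi) %% 360
  # feed the same per-residue values through a two-letter alternating
  # sequence whose scale is chosen to reproduce h
  seq2 <- paste(ifelse(ang <= 180, "L", "K"), collapse = "")
  got <- hydrophobic_moment(seq2, scale = c(L = 1, K = -1))
  expect_equal(got$direction, want_dir, tolerance = 1e-6)
  expect_equal(got$direction, 90, tolerance = 10)

  m0 <- hydrophobic_moment("ALSKFGEVTMAL")
  m1 <- hydrophobic_moment("ALSKFGEVTMAL", phase = 100)
  expect_equal(m0$magnitude, m1$magnitude, tolerance = 1e-9)
  expect_equal((m1$direction - m0$direction) %% 360, 100,
               tolerance = 1e-6)
})

test_that("dihedrals follow the IUPAC convention on planar cases", {
  trans <- rbind(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, -1, 0))
  expect_equal(abs(ldbind:::dihedral_angle(trans)), 180)
  cis <- rbind(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0))
  expect_equal(ldbind:::dihedral_angle(cis), 0)
})

test_that("dihedral computation round-trips the ideal-helix builder and
           agrees with an independent reference", {
  h <- generate_ideal_helix("ALSKFGEVTMAL")
  dh <- backbone_dihedrals(h)
  inner <- dh[3:10, ]
  expect_true(all(abs(inner$phi - (-57)) < 1))
  expect_true(all(abs(inner$psi - (-47)) < 1))
  expect_true(is.na(dh$phi[1L]))   # no preceding C for the first residue

  tf <- tempfile(fileext = ".pdb")
  write_structure(h$topology, h$frame, tf)
  tor <- bio3d::torsion.pdb(bio3d::read.pdb(tf, verbose = FALSE))
  expect_equal(dh$phi[3:10], tor$phi[3:10], tolerance = 0.1)
  expect_equal(dh$psi[3:10], tor$psi[3:10], tolerance = 0.1)
})

test_that("helicity classification is inclusive at the tolerance boundary", {
  expect_true(helicity_classify(-57, -47)$helical)
  expect_identical(helicity_classify(-57, -47)$region, "allowed")
  expect_false(helicity_classify(-57, 120)$helical)
  expect_true(helicity_classify(-87, -47, tolerance = 30)$helical)
  expect_false(helicity_classify(-88, -47, tolerance = 30)$helical)
  expect_identical(helicity_classify(-110, -90)$region, "marginal")
  expect_identical(helicity_classify(60, 40)$region, "outside")
})

test_that("helix annotation bundles wheel, scores and structure calls", {
  seqfull <- strrep("ALSKFGEVTM", 3L)
  ann <- helix_annotation(seqfull, start = 11L, end = 28L)
  expect_equal(ann$table$wheel_angle,
               (seq(0, by = 100, length.out = 18L)) %% 360)
  expect_equal(ann$ww_sum, ww_sum(substr(seqfull, 11L, 28L)))
  expect_identical(ann$table$residue, 11:28)

  h <- generate_ideal_helix(substr(seqfull, 1L, 12L))
  ann2 <- helix_annotation(substr(seqfull, 1L, 12L), structure = h)
  expect_true(all(ann2$table$helical[3:10]))
  expect_error(helix_annotation(seqfull, start = 20L, end = 99L), "outside")
})

test_that("FASTA sequences round-trip", {
  tf <- tempfile(fileext = ".fasta")
  writeLines(c(">helix6 test", "ALSKFGEVTM", "ALSKF", ">b", "IMIM"), tf)
  seqs <- read_fasta_sequences(tf)
  expect_identical(unname(seqs["helix6"]), "ALSKFGEVTMALSKF")
  expect_identical(unname(seqs["b"]), "IMIM")
})
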