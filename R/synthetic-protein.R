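#' @title Pseudo-proteins, placement and ideal helices
#' @name synthetic-protein
NULL

#' Build a rigid pseudo-protein of bead residues
#'
#' Residues are laid along a planar serpentine chain (3.8 Angstrom between
#' consecutive residues, rows of 10); each residue is a compact blob of
#' beads around its center. Eight beads per residue is the default, matching
#' the mean heavy-atom count of an amino acid, so contact numbers computed
#' downstream are on the scale of all-atom systems.
#'
#' @param n_residues number of residues.
#' @param beads_per_residue heavy beads per residue.
#' @param sequence optional one-letter sequence (length `n_residues`) used
#'   for residue names; defaults to a repeating pattern.
#' @param seed integer seed for bead placement.
#' @return list with `topology` and `frame` (protein centered at origin).
#' @export
make_pseudo_protein <- function(n_residues = 60L, beads_per_residue = 8L,
                                sequence = NULL, seed = 1L) {
  stopifnot(n_residues >= 1L, beads_per_residue >= 1L)
  if (is.null(sequence)) {
    pat <- c("A", "L", "S", "K", "F", "G", "E", "V", "T", "M")
    sequence <- paste(rep(pat, length.out = n_residues), collapse = "")
  }
  letters1 <- strsplit(sequence, "")[[1L]]
  if (length(letters1) != n_residues)
    stop("sequence length must equal n_residues")
  res3 <- aa_three_letter(letters1)

  per_row <- 10L
  rx <- ((seq_len(n_residues) - 1L) %% per_row)
  ry <- ((seq_len(n_residues) - 1L) %/% per_row)
  # serpentine: reverse x in odd rows so consecutive residues stay adjacent
  rx <- ifelse(ry %% 2L == 1L, per_row - 1L - rx, rx)
  cx <- rx * 3.8
  cy <- ry * 3.8

  with_seed(seed, {
    n_atoms <- n_residues * beads_per_residue
    off <- matrix(stats::rnorm(3L * n_atoms, 0, 1.0), ncol = 3L)
    r <- sqrt(rowSums(off^2))
    off <- off * pmin(r, 1.8) / pmax(r, 1e-9)
    off[seq(1L, n_atoms, by = beads_per_residue), ] <- 0  # first bead = center
    resi <- rep(seq_len(n_residues), each = beads_per_residue)
    coords <- cbind(cx[resi] + off[, 1L], cy[resi] + off[, 2L], off[, 3L])
    coords <- sweep(coords, 2L, colMeans(coords))  # center at origin
    bead_names <- if (beads_per_residue == 1L) "CA"
                  else c("CA", paste0("B", seq_len(beads_per_residue - 1L)))
    top <- ld_topology(
      atom_id = seq_len(n_atoms),
      atom_name = rep(bead_names, n_residues),
      element = rep("C", n_atoms),
      residue_index = resi,
      residue_name = res3[resi],
      molecule_id = rep(1L, n_atoms),
      role = rep("protein", n_atoms)
    )
    out <- list(topology = top,
                frame = ld_frame(coords, box = c(100, 100, 100)))
    attr(out, "residue_center_xy") <- cbind(cx, cy)
    out
  })
}

# canonical rotations of the six-orientation protocol: four 90-degree steps
# about the x axis, then +90 / -90 about the y axis, so each face of the
# protein "cube" starts proximal to the membrane once
orientation_rotation <- function(orientation_index) {
  if (!orientation_index %in% 1:6) stop("orientation_index must be in 1..6")
  if (orientation_index <= 4L)
    rotation_matrix("x", 90 * (orientation_index - 1L))
  else
    rotation_matrix("y", c(90, -90)[orientation_index - 4L])
}

#' Place a rigid protein above the membrane center
#'
#' Applies the canonical rotation for one of six starting orientations
#' (x-axis 0/90/180/270 degrees for indices 1-4; y-axis +90/-90 for 5-6),
#' then translates the protein so its centroid sits `placement_height`
#' above the membrane center, centered in the patch plane.
#'
#' @param structure list with `topology` and `frame` (protein only).
#' @param orientation_index integer 1..6.
#' @param placement_height centroid height above the membrane center
#'   (Angstrom); droplet-mimic setups use 50 above a monolayer center and
#'   40 above a bilayer center.
#' @param geometry a [membrane_geometry()] (frame-1 center used) or a single
#'   center-z value.
#' @param box patch box lengths c(x, y, z) used to center the protein in
#'   the plane.
#' @return [ld_frame()] of placed protein coordinates.
#' @export
place_protein <- function(structure, orientation_index, placement_height,
                          geometry, box) {
  stopifnot(placement_height > 0)
  center_z <- if (inherits(geometry, "membrane_geometry"))
    geometry$center_z[1L] else as.numeric(geometry)[1L]
  coords <- structure$frame$coords
  cen <- colMeans(coords)
  rot <- orientation_rotation(orientation_index)
  rc <- sweep(coords, 2L, cen) %*% t(rot)
  radius <- max(sqrt(rowSums(rc^2)))
  if (radius > placement_height)
    warning("protein radius exceeds placement height; overlap possible")
  target <- c(box[1L] / 2, box[2L] / 2, center_z + placement_height)
  placed <- sweep(rc, 2L, target, "+")
  ld_frame(placed, box = box, frame_index = 0L, time = 0)
}

aa_one_to_three <- c(
  A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
  E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
  M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
  Y = "TYR", V = "VAL")

aa_three_letter <- function(letters1) {
  out <- aa_one_to_three[letters1]
  if (anyNA(out))
    stop("unknown amino-acid letter(s): ",
         paste(unique(letters1[is.na(out)]), collapse = ", "))
  unname(out)
}

# NeRF internal-coordinate placement: position D given A, B, C, the C-D
# bond length, the B-C-D angle and the A-B-C-D torsion (degrees).
place_internal <- function(a, b, c_, length, angle, torsion) {
  th <- angle * pi / 180
  chi <- torsion * pi / 180
  d2 <- c(-length * cos(th),
          length * sin(th) * cos(chi),
          length * sin(th) * sin(chi))
  bc <- c_ - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- cross3(ab, bc)
  n <- n / sqrt(sum(n^2))
  m <- cross3(n, bc)
  c_ + d2[1L] * bc + d2[2L] * m + d2[3L] * n
}

#' Build an ideal alpha-helix backbone from a sequence
#'
#' Backbone atoms (N, CA, C, O) placed by sequential internal coordinates
#' with phi = -57, psi = -47, omega = 180 degrees and standard bond
#' lengths/angles, i.e. the canonical alpha-helical dihedrals.
#'
#' @param sequence one-letter amino-acid string, length >= 4.
#' @param phi,psi,omega backbone dihedrals in degrees.
#' @return list with `topology` and `frame`.
#' @export
generate_ideal_helix <- function(sequence, phi = -57, psi = -47,
                                 omega = 180) {
  letters1 <- strsplit(sequence, "")[[1L]]
  n <- length(letters1)
  if (n < 4L) stop("sequence must have at least 4 residues")
  res3 <- aa_three_letter(letters1)

  # bond lengths / angles (Angstrom, degrees): Engh-Huber-type standards
  b_NCA <- 1.458; b_CAC <- 1.525; b_CN <- 1.329; b_CO <- 1.231
  a_NCAC <- 111.2; a_CACN <- 116.2; a_CNCA <- 121.7; a_CACO <- 120.8

  N <- matrix(0, n, 3L); CA <- matrix(0, n, 3L)
  C <- matrix(0, n, 3L); O <- matrix(0, n, 3L)
  N[1L, ] <- c(0, 0, 0)
  CA[1L, ] <- c(b_NCA, 0, 0)
  ang <- (180 - a_NCAC) * pi / 180
  C[1L, ] <- CA[1L, ] + b_CAC * c(cos(ang), sin(ang), 0)
  for (i in 2:n) {
    N[i, ] <- place_internal(N[i - 1L, ], CA[i - 1L, ], C[i - 1L, ],
                             b_CN, a_CACN, psi)
    CA[i, ] <- place_internal(CA[i - 1L, ], C[i - 1L, ], N[i, ],
                              b_NCA, a_CNCA, omega)
    C[i, ] <- place_internal(C[i - 1L, ], N[i, ], CA[i, ],
                             b_CAC, a_NCAC, phi)
  }
  for (i in seq_len(n)) O[i, ] <- place_internal(N[i, ], CA[i, ], C[i, ],
                                                 b_CO, a_CACO, psi + 180)

  coords <- matrix(0, 4L * n, 3L)
  for (i in seq_len(n))
    coords[(4L * i - 3L):(4L * i), ] <- rbind(N[i, ], CA[i, ], C[i, ],
                                              O[i, ])
  top <- ld_topology(
    atom_id = seq_len(4L * n),
    atom_name = rep(c("N", "CA", "C", "O"), n),
    element = rep(c("N", "C", "C", "O"), n),
    residue_index = rep(seq_len(n), each = 4L),
    residue_name = rep(res3, each = 4L),
    molecule_id = rep(1L, 4L * n),
    role = rep("protein", 4L * n)
  )
  span <- apply(coords, 2L, function(v) diff(range(v)))
  list(topology = top, frame = ld_frame(coords, box = pmax(span + 20, 20)))
}
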