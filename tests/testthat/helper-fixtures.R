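# Small in-code fixtures shared across tests.

# Minimal topology builder: one row per atom from parallel vectors.
toy_topology <- function(role, residue_index = rep(1L, length(role)),
                         molecule_id = seq_along(role),
                         element = rep("C", length(role)),
                         atom_name = NULL) {
  n <- length(role)
  if (is.null(atom_name)) {
    atom_name <- ifelse(role == "lipid_head", "HD",
                        ifelse(role == "lipid_glycerol", "GL",
                               ifelse(role == "lipid_chain", "C1", "CA")))
  }
  ld_topology(seq_len(n), atom_name, element, residue_index,
              ifelse(role == "protein", "ALA", "PC"),
              molecule_id, role)
}

# Symmetric toy bilayer: n x n lattice of 3-bead lipids mirrored about z = 0.
toy_bilayer <- function(n_side = 4L, spacing = 5, z_head = 17, z_glyc = 15,
                        z_chain = 10) {
  xy <- expand.grid(x = (seq_len(n_side) - 0.5) * spacing,
                    y = (seq_len(n_side) - 0.5) * spacing)
  rows <- list()
  mol <- 0L
  for (s in c(1, -1)) {
    for (i in seq_len(nrow(xy))) {
      mol <- mol + 1L
      rows[[mol]] <- data.frame(
        atom_name = c("HD", "GL", "C1"), element = "C",
        residue_index = 1L, residue_name = "PC", molecule_id = mol,
        role = c("lipid_head", "lipid_glycerol", "lipid_chain"),
        x = xy$x[i], y = xy$y[i], z = s * c(z_head, z_glyc, z_chain))
    }
  }
  df <- do.call(rbind, rows)
  top <- ld_topology(seq_len(nrow(df)), df$atom_name, df$element,
                     df$residue_index, df$residue_name, df$molecule_id,
                     df$role)
  box <- c(n_side * spacing, n_side * spacing, 60)
  list(topology = top, frame = ld_frame(cbind(df$x, df$y, df$z), box = box))
}

# Append protein atoms to a membrane system at given coordinates.
with_protein <- function(system, prot_coords,
                         residue_index = rep(1L, nrow(prot_coords))) {
  np <- nrow(prot_coords)
  top <- system$topology
  ptop <- ld_topology(max(top$atom_id) + seq_len(np),
                      rep("CA", np), rep("C", np), residue_index,
                      rep("ALA", np), rep(max(top$molecule_id) + 1L, np),
                      rep("protein", np))
  all_df <- rbind(as.data.frame(unclass(top)), as.data.frame(unclass(ptop)))
  top2 <- ld_topology(all_df$atom_id, all_df$atom_name, all_df$element,
                      all_df$residue_index, all_df$residue_name,
                      all_df$molecule_id, all_df$role)
  coords <- rbind(system$frame$coords, prot_coords)
  list(topology = top2,
       frame = ld_frame(coords, box = system$frame$box))
}

one_frame_traj <- function(system, times = 0) {
  frames <- lapply(seq_along(times), function(k)
    ld_frame(system$frame$coords, box = system$frame$box,
             frame_index = k - 1L, time = times[k]))
  ld_trajectory(system$topology, frames)
}

# Brute-force contact oracle: all-pairs loop, kernel hard-zeroed beyond the
# cutoff, minimum image in x,y. Independent of the package's vectorized path.
brute_contact_sum <- function(coords, box, prot_idx, mem_idx, cutoff = 5) {
  total <- 0
  for (i in prot_idx) {
    for (j in mem_idx) {
      dx <- coords[i, 1] - coords[j, 1]
      dx <- dx - box[1] * round(dx / box[1])
      dy <- coords[i, 2] - coords[j, 2]
      dy <- dy - box[2] * round(dy / box[2])
      dz <- coords[i, 3] - coords[j, 3]
      d <- sqrt(dx^2 + dy^2 + dz^2)
      if (d <= cutoff) total <- total + 1 / (1 + exp(5 * (d - 4)))
    }
  }
  total
}

# Flat fully-tiled headgroup lattice for defect tests: one head bead per
# 1-Angstrom cell at z_head, plus per-cell glycerol beads at z_glyc.
tiled_monolayer <- function(nx = 12L, ny = 12L, z_head = 17, z_glyc = 15,
                            drop_cells = NULL, core_at = NULL,
                            z_core = 10) {
  all_cells <- expand.grid(ix = seq_len(nx) - 1L, iy = seq_len(ny) - 1L)
  keep <- rep(TRUE, nrow(all_cells))
  if (!is.null(drop_cells))
    keep <- !(paste(all_cells$ix, all_cells$iy) %in%
                paste(drop_cells[, 1], drop_cells[, 2]))
  cells <- all_cells[keep, ]
  n <- nrow(cells)
  df <- data.frame(
    atom_name = rep(c("HD", "GL"), each = n), element = "C",
    residue_index = 1L, residue_name = "PC",
    molecule_id = rep(seq_len(n), 2L),
    role = rep(c("lipid_head", "lipid_glycerol"), each = n),
    x = rep(cells$ix + 0.5, 2L), y = rep(cells$iy + 0.5, 2L),
    z = rep(c(z_head, z_glyc), each = n))
  # a full (hole-free) mirrored lower leaflet, so holes affect only the
  # upper surface and leaflet assignment is well defined
  nl <- nrow(all_cells)
  low <- data.frame(
    atom_name = rep(c("HD", "GL"), each = nl), element = "C",
    residue_index = 1L, residue_name = "PC",
    molecule_id = n + rep(seq_len(nl), 2L),
    role = rep(c("lipid_head", "lipid_glycerol"), each = nl),
    x = rep(all_cells$ix + 0.5, 2L), y = rep(all_cells$iy + 0.5, 2L),
    z = rep(-c(z_head, z_glyc), each = nl))
  df <- rbind(df, low)
  if (!is.null(core_at)) {
    nc <- nrow(core_at)
    df <- rbind(df, data.frame(
      atom_name = "ES", element = "C", residue_index = 1L,
      residue_name = "WEX", molecule_id = max(df$molecule_id) + seq_len(nc),
      role = "core_neutral",
      x = core_at[, 1], y = core_at[, 2], z = rep(z_core, nc)))
  }
  top <- ld_topology(seq_len(nrow(df)), df$atom_name, df$element,
                     df$residue_index, df$residue_name, df$molecule_id,
                     df$role)
  list(topology = top,
       frame = ld_frame(cbind(df$x, df$y, df$z), box = c(nx, ny, 60)),
       glycerol_plane = z_glyc)
}

# Small, fast binding scenario reused by recovery tests.
recovery_scenario <- function(seed = 7L, n_frames = 100L) {
  scenario_config(membrane_kind = "we_monolayer", n_frames = n_frames,
                  seed = seed, binding_residues = 40:45, bind_time = 20)
}
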