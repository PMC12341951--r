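#' @title Topology, frames and trajectories
#' @description Core containers for membrane-protein systems: a topology is a
#'   data frame of atom records with role tags, a frame carries one set of
#'   coordinates plus the orthorhombic box, and a trajectory is an ordered
#'   list of frames sharing one topology. All coordinates are Angstrom, all
#'   times nanoseconds, and the membrane normal is the z axis.
#' @name core-model
NULL

ATOM_ROLES <- c("protein", "lipid_head", "lipid_glycerol", "lipid_chain",
                "core_neutral", "solvent")

#' Construct a topology of atom records
#'
#' @param atom_id positive integer atom identifiers.
#' @param atom_name short atom names (e.g. "CA", "P", "C12").
#' @param element element symbols; hydrogens ("H") are the only light atoms.
#' @param residue_index 1-based residue index within the molecule's chain.
#' @param residue_name 3-letter (or headgroup-code) residue names.
#' @param molecule_id integer molecule identifiers.
#' @param role one of `"protein"`, `"lipid_head"`, `"lipid_glycerol"`,
#'   `"lipid_chain"`, `"core_neutral"`, `"solvent"`.
#' @return A data frame of class `ld_topology` with an `is_heavy` column
#'   derived from `element`.
#' @export
ld_topology <- function(atom_id, atom_name, element, residue_index,
                        residue_name, molecule_id, role) {
  n <- length(atom_id)
  stopifnot(
    n > 0L,
    length(atom_name) == n, length(element) == n,
    length(residue_index) == n, length(residue_name) == n,
    length(molecule_id) == n, length(role) == n
  )
  if (any(atom_id <= 0L)) stop("atom_id must be positive")
  if (any(residue_index < 1L)) stop("residue_index must be >= 1")
  bad <- setdiff(unique(role), ATOM_ROLES)
  if (length(bad) > 0L)
    stop("unknown role(s): ", paste(bad, collapse = ", "))
  top <- data.frame(
    atom_id = as.integer(atom_id),
    atom_name = as.character(atom_name),
    element = as.character(element),
    is_heavy = toupper(element) != "H",
    residue_index = as.integer(residue_index),
    residue_name = as.character(residue_name),
    molecule_id = as.integer(molecule_id),
    role = as.character(role),
    stringsAsFactors = FALSE
  )
  class(top) <- c("ld_topology", "data.frame")
  top
}

#' Construct a single coordinate frame
#'
#' @param coords numeric n x 3 matrix of coordinates (Angstrom), rows ordered
#'   as in the topology.
#' @param box orthorhombic box lengths c(x, y, z) in Angstrom.
#' @param frame_index 0-based frame index.
#' @param time frame time in nanoseconds.
#' @return An object of class `ld_frame`.
#' @export
ld_frame <- function(coords, box, frame_index = 0L, time = 0) {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 3L, nrow(coords) > 0L)
  if (length(box) != 3L || any(box <= 0))
    stop("box must be three positive lengths")
  structure(
    list(frame_index = as.integer(frame_index), time = as.numeric(time),
         box = as.numeric(box), coords = unname(coords)),
    class = "ld_frame"
  )
}

#' Construct a trajectory from a topology and frames
#'
#' @param topology an [ld_topology()].
#' @param frames list of [ld_frame()] objects, ordered in time.
#' @return An object of class `ld_trajectory`.
#' @export
ld_trajectory <- function(topology, frames) {
  stopifnot(inherits(topology, "ld_topology"), length(frames) >= 1L)
  n_atoms <- nrow(topology)
  for (k in seq_along(frames)) {
    f <- frames[[k]]
    if (!inherits(f, "ld_frame")) stop("frames must be ld_frame objects")
    if (nrow(f$coords) != n_atoms)
      stop(sprintf("frame %d has %d atoms; topology has %d",
                   k - 1L, nrow(f$coords), n_atoms))
  }
  times <- vapply(frames, `[[`, numeric(1L), "time")
  if (length(times) > 1L && any(diff(times) <= 0))
    stop("frame times must be strictly increasing")
  structure(list(topology = topology, frames = frames),
            class = "ld_trajectory")
}

#' @export
print.ld_trajectory <- function(x, ...) {
  cat(sprintf("ld_trajectory: %d atoms, %d frames (%.3g - %.3g ns)\n",
              nrow(x$topology), length(x$frames),
              x$frames[[1L]]$time, x$frames[[length(x$frames)]]$time))
  cat("roles:", paste(sprintf("%s=%d", names(table(x$topology$role)),
                              table(x$topology$role)), collapse = " "), "\n")
  invisible(x)
}

n_frames <- function(traj) length(traj$frames)

#' Default residue-name to role mapping
#'
#' Table-driven role assignment used when reading structures. The defaults
#' cover the synthetic naming scheme of this package plus common CHARMM
#' lipid/solvent residue names; extend by passing additional rows with the
#' same column names (`residue_name`, `role`) to [read_structure()].
#'
#' @return data frame with columns `residue_name`, `role`.
#' @export
default_role_map <- function() {
  aa3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
           "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
           "TYR", "VAL")
  data.frame(
    residue_name = c(aa3, "PC", "PE", "PI", "PG", "PA", "PS",
                     "POPC", "POPE", "POPG", "POPS", "POPA", "POPI",
                     "WEX", "TAG", "TRIO",
                     "HOH", "TIP3", "SOL", "WAT"),
    role = c(rep("protein", length(aa3)), rep("lipid_head", 12L),
             rep("core_neutral", 3L), rep("solvent", 4L)),
    stringsAsFactors = FALSE
  )
}

# Refine lipid roles by atom name: role maps give molecule-level class;
# within a phospholipid the head bead, glycerol bead and chain beads are
# distinguished by atom-name prefix (synthetic scheme: "P"/"HD" head,
# "GL" glycerol, "C<k>" chain).
refine_lipid_roles <- function(role, atom_name) {
  lip <- role == "lipid_head"
  refined <- role
  refined[lip & grepl("^(GL)", atom_name)] <- "lipid_glycerol"
  refined[lip & grepl("^C[0-9]", atom_name)] <- "lipid_chain"
  refined
}

#' Select atom indices by predicate on topology fields
#'
#' @param topology an [ld_topology()].
#' @param role optional character vector of roles to keep.
#' @param residue_index optional integer vector of residue indices to keep.
#' @param heavy_only if `TRUE`, keep only non-hydrogen atoms.
#' @param predicate optional function taking the topology data frame and
#'   returning a logical vector.
#' @return Sorted integer vector of row indices (possibly empty).
#' @export
select_atoms <- function(topology, role = NULL, residue_index = NULL,
                         heavy_only = FALSE, predicate = NULL) {
  keep <- rep(TRUE, nrow(topology))
  if (!is.null(role)) keep <- keep & topology$role %in% role
  if (!is.null(residue_index))
    keep <- keep & topology$residue_index %in% residue_index
  if (heavy_only) keep <- keep & topology$is_heavy
  if (!is.null(predicate)) keep <- keep & predicate(topology)
  sort(which(keep))
}

lipid_roles <- function(include_core = TRUE) {
  r <- c("lipid_head", "lipid_glycerol", "lipid_chain")
  if (include_core) r <- c(r, "core_neutral")
  r
}

#' Membrane reference geometry per frame
#'
#' Computes, for every frame, the membrane center (mean z of all lipid heavy
#' atoms, core neutral lipids included for filled-monolayer systems) and the
#' mean headgroup and glycerol plane heights per leaflet. Leaflets are
#' assigned per lipid molecule from the sign of its head-bead z relative to
#' the lipid centroid. Solvent atoms are excluded throughout.
#'
#' @param traj an [ld_trajectory()].
#' @param include_core include `core_neutral` atoms in the center-of-membrane
#'   average (default `TRUE`).
#' @return Object of class `membrane_geometry`: list of per-frame numeric
#'   vectors `center_z`, `head_plane_upper`, `head_plane_lower`,
#'   `glycerol_plane_upper`, `glycerol_plane_lower`.
#' @export
membrane_geometry <- function(traj, include_core = TRUE) {
  top <- traj$topology
  lip_idx <- select_atoms(top, role = lipid_roles(include_core),
                          heavy_only = TRUE)
  if (length(lip_idx) == 0L) stop("no lipid atoms in topology")
  head_idx <- select_atoms(top, role = "lipid_head", heavy_only = TRUE)
  glyc_idx <- select_atoms(top, role = "lipid_glycerol", heavy_only = TRUE)
  if (length(head_idx) == 0L) stop("no lipid headgroup atoms in topology")

  # leaflet assignment from frame 1: sign of head z relative to the lipid
  # phase centroid (leaflets do not flip in the systems this models)
  z0 <- traj$frames[[1L]]$coords[, 3L]
  centroid_z <- mean(z0[lip_idx])
  head_upper <- head_idx[z0[head_idx] > centroid_z]
  head_lower <- head_idx[z0[head_idx] <= centroid_z]
  if (length(head_upper) == 0L || length(head_lower) == 0L)
    stop("a leaflet has zero lipids")
  mol_upper <- unique(top$molecule_id[head_upper])
  glyc_upper <- glyc_idx[top$molecule_id[glyc_idx] %in% mol_upper]
  glyc_lower <- setdiff(glyc_idx, glyc_upper)

  nf <- n_frames(traj)
  out <- list(center_z = numeric(nf),
              head_plane_upper = numeric(nf), head_plane_lower = numeric(nf),
              glycerol_plane_upper = numeric(nf),
              glycerol_plane_lower = numeric(nf))
  for (k in seq_len(nf)) {
    z <- traj$frames[[k]]$coords[, 3L]
    out$center_z[k] <- mean(z[lip_idx])
    out$head_plane_upper[k] <- mean(z[head_upper])
    out$head_plane_lower[k] <- mean(z[head_lower])
    out$glycerol_plane_upper[k] <-
      if (length(glyc_upper)) mean(z[glyc_upper]) else NA_real_
    out$glycerol_plane_lower[k] <-
      if (length(glyc_lower)) mean(z[glyc_lower]) else NA_real_
  }
  structure(out, class = "membrane_geometry")
}
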