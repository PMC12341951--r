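#' @title Structure and trajectory I/O
#' @description PDB structures are read and written through `bio3d`;
#'   multi-frame XYZ (with a JSON topology sidecar) is the native trajectory
#'   format, and multi-model PDB is accepted as an alternative.
#' @name io
NULL

guess_element <- function(atom_name) {
  sym <- sub("^[0-9]*", "", atom_name)
  sym <- substr(sym, 1L, 1L)
  toupper(sym)
}

#' Read a PDB structure into a topology and frame
#'
#' One atom record per ATOM/HETATM line; roles are assigned from
#' `residue_name` through a mapping table (see [default_role_map()]), with
#' lipid atoms refined into head/glycerol/chain by atom name. Residue names
#' absent from the map become `solvent` with a warning.
#'
#' @param path path to a PDB file.
#' @param role_map data frame with columns `residue_name`, `role`;
#'   rbind extra rows onto [default_role_map()] for custom naming schemes.
#' @param box orthorhombic box lengths (Angstrom) to attach to the frame;
#'   defaults to the coordinate extent plus a margin when absent.
#' @return list with elements `topology` ([ld_topology()]) and `frame`
#'   ([ld_frame()]).
#' @export
read_structure <- function(path, role_map = default_role_map(), box = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e) stop("PDB parse error in ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0L) stop("no ATOM/HETATM records in ", path)
  bad <- which(!is.finite(at$x) | !is.finite(at$y) | !is.finite(at$z))
  if (length(bad) > 0L)
    stop("garbled coordinate columns at atom line(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  element <- at$elesy
  if (is.null(element)) element <- rep("", nrow(at))
  element[is.na(element) | element == ""] <-
    guess_element(at$elety[is.na(element) | element == ""])

  role <- role_map$role[match(at$resid, role_map$residue_name)]
  if (anyNA(role)) {
    unknown <- unique(at$resid[is.na(role)])
    warning("unmapped residue name(s) assigned role 'solvent': ",
            paste(unknown, collapse = ", "))
    role[is.na(role)] <- "solvent"
  }
  role <- refine_lipid_roles(role, at$elety)

  # molecule id: new molecule whenever resno resets or chain changes
  chain <- at$chain
  chain[is.na(chain)] <- " "
  mol_break <- c(TRUE, diff(at$resno) < 0 |
                   chain[-1L] != chain[-length(chain)])
  # lipids/solvent: one molecule per residue; protein: one molecule per chain
  per_res <- role != "protein"
  res_break <- c(TRUE, diff(at$resno) != 0 |
                   chain[-1L] != chain[-length(chain)])
  molecule_id <- cumsum(ifelse(per_res, res_break, mol_break))

  top <- ld_topology(
    atom_id = at$eleno, atom_name = at$elety, element = element,
    residue_index = at$resno, residue_name = at$resid,
    molecule_id = molecule_id, role = role
  )
  coords <- cbind(at$x, at$y, at$z)
  if (is.null(box)) {
    span <- apply(coords, 2L, function(v) diff(range(v)))
    box <- pmax(span + 10, 10)
  }
  list(topology = top, frame = ld_frame(coords, box = box))
}

#' Write a topology + frame as a PDB file
#'
#' @param topology an [ld_topology()].
#' @param frame an [ld_frame()] (or a list of frames for a multi-model PDB).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(topology, frame, path) {
  frames <- if (inherits(frame, "ld_frame")) list(frame) else frame
  xyz <- do.call(rbind, lapply(frames, function(f) as.vector(t(f$coords))))
  bio3d::write.pdb(
    file = path,
    xyz = xyz,
    resno = topology$residue_index,
    resid = topology$residue_name,
    eleno = topology$atom_id,
    elety = topology$atom_name,
    elesy = topology$element
  )
  invisible(path)
}

#' Write a trajectory in the native multi-frame XYZ format
#'
#' Each frame is an atom-count line, a comment line `frame=<k> t=<ns>`, then
#' one `name x y z` line per atom (Angstrom, 3 decimals). The topology is
#' written alongside as a JSON sidecar (`<path>.top.json`) carrying atom
#' records and the box.
#'
#' @param traj an [ld_trajectory()].
#' @param path output `.xyz` path.
#' @param sidecar write the JSON topology sidecar (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_trajectory_xyz <- function(traj, path, sidecar = TRUE) {
  top <- traj$topology
  con <- file(path, "w")
  on.exit(close(con))
  for (f in traj$frames) {
    writeLines(as.character(nrow(top)), con)
    writeLines(sprintf("frame=%d t=%.6f", f$frame_index, f$time), con)
    writeLines(sprintf("%-6s %12.3f %12.3f %12.3f", top$atom_name,
                       f$coords[, 1L], f$coords[, 2L], f$coords[, 3L]), con)
  }
  if (sidecar) write_topology_json(top, traj$frames[[1L]]$box,
                                   paste0(path, ".top.json"))
  invisible(path)
}

#' @rdname write_trajectory_xyz
#' @param box box lengths stored with the topology sidecar.
#' @export
write_topology_json <- function(topology, box, path) {
  jsonlite::write_json(
    list(box = box,
         atoms = as.data.frame(unclass(topology), stringsAsFactors = FALSE)),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_trajectory_xyz
#' @export
read_topology_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  at <- obj$atoms
  top <- ld_topology(at$atom_id, at$atom_name, at$element, at$residue_index,
                     at$residue_name, at$molecule_id, at$role)
  attr(top, "box") <- as.numeric(obj$box)
  top
}

#' Read a trajectory from multi-frame XYZ or multi-model PDB
#'
#' @param topology an [ld_topology()] describing every frame's atoms.
#' @param path `.xyz` (native) or `.pdb` (multi-model) file.
#' @param box orthorhombic box lengths; defaults to the box stored in the
#'   XYZ sidecar if present, else the frame-0 coordinate extent.
#' @param stride frame spacing in ns used when the file carries no times.
#' @return An [ld_trajectory()]. Frame times come from `t=` comments when
#'   present, else `frame_index * stride`.
#' @export
read_trajectory <- function(topology, path, box = NULL, stride = 1) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "xyz") read_trajectory_xyz(topology, path, box, stride)
  else read_trajectory_pdb(topology, path, box, stride)
}

read_trajectory_xyz <- function(topology, path, box = NULL, stride = 1) {
  if (is.null(box)) {
    sidecar <- paste0(path, ".top.json")
    if (file.exists(sidecar))
      box <- attr(read_topology_json(sidecar), "box")
  }
  lines <- readLines(path)
  if (length(lines) == 0L) stop("empty trajectory file: ", path)
  n_atoms <- nrow(topology)
  frames <- list()
  pos <- 1L
  k <- 0L
  while (pos <= length(lines)) {
    if (!grepl("^\\s*[0-9]+\\s*$", lines[pos]))
      stop(sprintf("frame %d: expected atom-count line at line %d", k, pos))
    n <- as.integer(trimws(lines[pos]))
    if (n != n_atoms)
      stop(sprintf("frame %d has %d atoms; topology has %d", k, n, n_atoms))
    if (pos + 1L + n > length(lines))
      stop(sprintf("truncated trajectory: frame %d incomplete", k))
    comment <- lines[pos + 1L]
    tm <- regmatches(comment, regexec("t=([-0-9.eE+]+)", comment))[[1L]]
    time <- if (length(tm) == 2L) as.numeric(tm[2L]) else k * stride
    body <- lines[(pos + 2L):(pos + 1L + n)]
    fields <- strsplit(trimws(body), "\\s+")
    bad <- which(lengths(fields) < 4L)
    if (length(bad) > 0L)
      stop(sprintf("frame %d: malformed atom line %d", k, bad[1L]))
    coords <- matrix(as.numeric(unlist(lapply(fields, `[`, 2:4))),
                     ncol = 3L, byrow = TRUE)
    if (anyNA(coords))
      stop(sprintf("frame %d: non-numeric coordinates", k))
    b <- box
    if (is.null(b)) {
      span <- apply(coords, 2L, function(v) diff(range(v)))
      b <- pmax(span + 10, 10)
    }
    frames[[k + 1L]] <- ld_frame(coords, box = b, frame_index = k, time = time)
    pos <- pos + 2L + n
    k <- k + 1L
  }
  ld_trajectory(topology, frames)
}

read_trajectory_pdb <- function(topology, path, box = NULL, stride = 1) {
  pdb <- tryCatch(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
                  error = function(e) stop("PDB parse error in ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  if (ncol(xyz) != 3L * nrow(topology))
    stop(sprintf("model atom count %d does not match topology (%d atoms)",
                 ncol(xyz) / 3L, nrow(topology)))
  frames <- lapply(seq_len(nrow(xyz)), function(k) {
    coords <- matrix(xyz[k, ], ncol = 3L, byrow = TRUE)
    b <- box
    if (is.null(b)) {
      span <- apply(coords, 2L, function(v) diff(range(v)))
      b <- pmax(span + 10, 10)
    }
    ld_frame(coords, box = b, frame_index = k - 1L, time = (k - 1L) * stride)
  })
  ld_trajectory(topology, frames)
}
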