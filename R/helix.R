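#' @title Amphipathic-helix analytics
#' @description Helical-wheel projection (100 degrees per residue),
#'   Wimley-White interfacial hydrophobicity sums (negative = hydrophobic,
#'   i.e. lower free energy of partitioning into the membrane interface),
#'   hydrophobic moment in the Eisenberg sense, point mutations, backbone
#'   dihedrals and Ramachandran helicity classification.
#' @name helix
NULL

#' Wimley-White interfacial hydrophobicity scale
#'
#' Per-residue free energies (kcal/mol) of partitioning from water into the
#' POPC bilayer interface (Wimley & White 1996), with charged side chains in
#' their standard protonation states. Negative values are hydrophobic
#' (favorable interface partitioning).
#'
#' @return named numeric vector over the 20 standard one-letter codes.
#' @export
ww_interface_scale <- function() {
  c(A =  0.17, R =  0.81, N =  0.42, D =  1.23, C = -0.24,
    Q =  0.58, E =  2.02, G =  0.01, H =  0.17, I = -0.31,
    L = -0.56, K =  0.99, M = -0.23, F = -1.13, P =  0.45,
    S =  0.13, T =  0.14, W = -1.85, Y = -0.94, V =  0.07)
}

check_sequence <- function(sequence) {
  letters1 <- strsplit(toupper(sequence), "")[[1L]]
  bad <- setdiff(unique(letters1), names(ww_interface_scale()))
  if (length(bad) > 0L)
    stop("nonstandard amino-acid letter(s): ", paste(bad, collapse = ", "))
  letters1
}

#' Wimley-White sum over a sequence window
#'
#' Arithmetic sum of interfacial-scale values; additive, so the change from
#' a set of mutations is independent of the surrounding sequence.
#'
#' @param sequence one-letter amino-acid string (may be empty).
#' @return sum in kcal/mol (0 for an empty window).
#' @export
ww_sum <- function(sequence) {
  if (nchar(sequence) == 0L) return(0)
  sum(ww_interface_scale()[check_sequence(sequence)])
}

#' Parse a mutation string of the form `XnY`
#'
#' @param spec e.g. `"F159I"`: wild-type letter, 1-based position in
#'   full-protein numbering, replacement letter.
#' @return list with `wt`, `position`, `new`.
#' @export
mutation_spec <- function(spec) {
  m <- regexec("^([A-Za-z])([0-9]+)([A-Za-z])$", spec)[[1L]]
  if (m[1L] == -1L) stop("cannot parse mutation '", spec,
                         "' (expected form like F159I)")
  parts <- regmatches(spec, regexec("^([A-Za-z])([0-9]+)([A-Za-z])$",
                                    spec))[[1L]]
  list(wt = toupper(parts[2L]), position = as.integer(parts[3L]),
       new = toupper(parts[4L]))
}

#' Apply point mutations to a sequence
#'
#' @param sequence one-letter string, positions numbered 1..nchar.
#' @param mutations character vector of `XnY` strings (or list of
#'   [mutation_spec()] results). Order-independent for non-overlapping
#'   positions; each wild-type letter must match the sequence.
#' @param offset value subtracted from mutation positions when `sequence`
#'   is a window out of a longer protein (e.g. `offset = 155` maps
#'   position 156 to window index 1).
#' @return mutated sequence.
#' @export
apply_mutations <- function(sequence, mutations, offset = 0L) {
  letters1 <- check_sequence(sequence)
  for (mu in mutations) {
    if (is.character(mu)) mu <- mutation_spec(mu)
    pos <- mu$position - offset
    if (pos < 1L || pos > length(letters1))
      stop("mutation position ", mu$position, " outside sequence")
    if (letters1[pos] != mu$wt)
      stop(sprintf("wild-type mismatch at position %d: expected %s, found %s",
                   mu$position, mu$wt, letters1[pos]))
    letters1[pos] <- mu$new
  }
  paste(letters1, collapse = "")
}

#' Wimley-White sum change caused by mutations
#'
#' By additivity of the scale the delta depends only on the swapped
#' residues: `sum(WW[new] - WW[wt])`. Adjusting a known wild-type regional
#' sum by this delta gives the mutant regional sum without needing the
#' full sequence.
#'
#' @inheritParams apply_mutations
#' @return delta in kcal/mol.
#' @export
ww_mutation_delta <- function(mutations) {
  scale <- ww_interface_scale()
  sum(vapply(mutations, function(mu) {
    if (is.character(mu)) mu <- mutation_spec(mu)
    unname(scale[mu$new] - scale[mu$wt])
  }, numeric(1L)))
}

#' Helical-wheel angles for a residue window
#'
#' @param n window length (or a sequence, whose length is used).
#' @param period wheel periodicity in degrees per residue (100 for an
#'   ideal alpha helix).
#' @param phase angle of the first residue in degrees.
#' @return numeric vector of angles in [0, 360).
#' @export
wheel_angles <- function(n, period = 100, phase = 0) {
  if (is.character(n)) n <- nchar(n)
  ((seq_len(n) - 1L) * period + phase) %% 360
}

#' Hydrophobic moment of a sequence window
#'
#' Vector sum of per-residue hydrophobicities placed at helical-wheel
#' angles. With the default scale the Wimley-White interfacial values are
#' negated so that the hydrophobic face carries a positive resultant and
#' the moment direction points at it.
#'
#' @param sequence one-letter window, length >= 3.
#' @param scale named per-residue hydrophobicity vector; default
#'   `-ww_interface_scale()`.
#' @param period degrees per residue on the wheel (default 100).
#' @param phase wheel angle of the first residue (degrees).
#' @return list with `magnitude`, `per_residue` (magnitude / length) and
#'   `direction` (degrees in [0, 360), angle of the resultant).
#' @export
hydrophobic_moment <- function(sequence, scale = NULL, period = 100,
                               phase = 0) {
  letters1 <- check_sequence(sequence)
  if (length(letters1) < 3L) stop("window must have at least 3 residues")
  if (is.null(scale)) scale <- -ww_interface_scale()
  h <- scale[letters1]
  ang <- wheel_angles(length(letters1), period, phase) * pi / 180
  mx <- sum(h * cos(ang))
  my <- sum(h * sin(ang))
  list(magnitude = sqrt(mx^2 + my^2),
       per_residue = sqrt(mx^2 + my^2) / length(letters1),
       direction = (atan2(my, mx) * 180 / pi) %% 360)
}

#' Partition a window into hydrophobic and hydrophilic faces
#'
#' A residue is on the hydrophobic face when its wheel angle lies within
#' 90 degrees of the hydrophobic-moment direction.
#'
#' @inheritParams hydrophobic_moment
#' @return character vector (`"hydrophobic"` / `"hydrophilic"`) per residue.
#' @export
helix_faces <- function(sequence, scale = NULL, period = 100, phase = 0) {
  mom <- hydrophobic_moment(sequence, scale, period, phase)
  ang <- wheel_angles(nchar(sequence), period, phase)
  ifelse(circ_diff(ang, mom$direction) <= 90, "hydrophobic", "hydrophilic")
}

#' Backbone phi/psi dihedrals from a structure
#'
#' Standard IUPAC convention, degrees in (-180, 180]:
#' phi = C(i-1)-N-CA-C, psi = N-CA-C-N(i+1). Residues missing a backbone
#' atom (or a required neighbor) get `NA`.
#'
#' @param structure list with `topology` and `frame` (as returned by
#'   [read_structure()] or [generate_ideal_helix()]).
#' @param residue_range optional integer vector of residue indices.
#' @return data frame with columns `residue`, `phi`, `psi`.
#' @export
backbone_dihedrals <- function(structure, residue_range = NULL) {
  top <- structure$topology
  coords <- structure$frame$coords
  resis <- sort(unique(top$residue_index[top$role == "protein"]))
  if (!is.null(residue_range)) resis <- intersect(resis, residue_range)
  get_atom <- function(resi, name) {
    i <- which(top$residue_index == resi & top$atom_name == name &
                 top$role == "protein")
    if (length(i) == 0L) NULL else coords[i[1L], ]
  }
  out <- data.frame(residue = resis, phi = NA_real_, psi = NA_real_)
  for (r in seq_along(resis)) {
    resi <- resis[r]
    N <- get_atom(resi, "N"); CA <- get_atom(resi, "CA")
    C <- get_atom(resi, "C")
    Cp <- get_atom(resi - 1L, "C")
    Nn <- get_atom(resi + 1L, "N")
    if (!is.null(Cp) && !is.null(N) && !is.null(CA) && !is.null(C))
      out$phi[r] <- dihedral_angle(rbind(Cp, N, CA, C))
    if (!is.null(N) && !is.null(CA) && !is.null(C) && !is.null(Nn))
      out$psi[r] <- dihedral_angle(rbind(N, CA, C, Nn))
  }
  out
}

#' Classify phi/psi angles as alpha-helical
#'
#' Helical iff both circular differences from the canonical alpha-helix
#' dihedrals (-57, -47) are within `tolerance` (boundary inclusive).
#' The region label uses a declared rectangle set: allowed alpha for
#' phi in [-100, -30] and psi in [-80, -5]; marginal after dilating both
#' intervals by 20 degrees; `"outside"` otherwise.
#'
#' @param phi,psi angles in degrees (vectorized).
#' @param tolerance circular tolerance in degrees (default 30).
#' @return data frame with columns `phi`, `psi`, `helical`, `region`.
#' @export
helicity_classify <- function(phi, psi, tolerance = 30) {
  helical <- circ_diff(phi, -57) <= tolerance &
    circ_diff(psi, -47) <= tolerance
  allowed <- phi >= -100 & phi <= -30 & psi >= -80 & psi <= -5
  marginal <- phi >= -120 & phi <= -10 & psi >= -100 & psi <= 15
  region <- ifelse(allowed, "allowed",
                   ifelse(marginal, "marginal", "outside"))
  region[is.na(phi) | is.na(psi)] <- NA_character_
  helical[is.na(phi) | is.na(psi)] <- NA
  data.frame(phi = phi, psi = psi, helical = helical, region = region)
}

#' Annotate an amphipathic-helix window
#'
#' Bundles the wheel projection, Wimley-White scores, hydrophobic moment,
#' face partition and (when a structure is given) phi/psi plus helicity
#' calls for a residue window in full-protein numbering.
#'
#' @param sequence full-protein one-letter sequence, or the window itself
#'   when `start = 1` and `end = nchar(sequence)`.
#' @param start,end 1-based window bounds in full-protein numbering.
#' @param mutations optional `XnY` mutation strings (full-protein
#'   numbering), applied before scoring.
#' @param structure optional structure covering the window, for dihedrals.
#' @param tolerance helicity tolerance in degrees.
#' @return object of class `helix_annotation`: list with `start`, `end`,
#'   `sequence`, `table` (per-residue data frame), `ww_sum`, `moment`.
#' @export
helix_annotation <- function(sequence, start = 1L,
                             end = nchar(sequence) + start - 1L,
                             mutations = NULL, structure = NULL,
                             tolerance = 30) {
  if (end > nchar(sequence) || start < 1L || end < start)
    stop("window ", start, ":", end, " outside sequence")
  full <- sequence
  if (!is.null(mutations)) full <- apply_mutations(full, mutations)
  window <- substr(full, start, end)
  letters1 <- check_sequence(window)
  scale <- ww_interface_scale()
  ww <- unname(scale[letters1])
  ang <- wheel_angles(length(letters1))
  mom <- hydrophobic_moment(window)
  faces <- helix_faces(window)
  tab <- data.frame(residue = seq(start, length.out = length(letters1)),
                    aa = letters1, wheel_angle = ang, ww = ww,
                    face = faces, phi = NA_real_, psi = NA_real_,
                    helical = NA, region = NA_character_)
  if (!is.null(structure)) {
    dh <- backbone_dihedrals(structure, tab$residue)
    m <- match(tab$residue, dh$residue)
    tab$phi <- dh$phi[m]
    tab$psi <- dh$psi[m]
    hc <- helicity_classify(tab$phi, tab$psi, tolerance)
    tab$helical <- hc$helical
    tab$region <- hc$region
  }
  structure(list(start = start, end = start + length(letters1) - 1L,
                 sequence = window, table = tab, ww_sum = sum(ww),
                 moment = mom),
            class = "helix_annotation")
}

#' @export
print.helix_annotation <- function(x, ...) {
  cat(sprintf("helix_annotation %d-%d: %s\n", x$start, x$end, x$sequence))
  cat(sprintf("WW sum %.2f kcal/mol; moment %.2f (%.2f/res) at %.0f deg\n",
              x$ww_sum, x$moment$magnitude, x$moment$per_residue,
              x$moment$direction))
  invisible(x)
}

#' Read sequences from a FASTA file
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta_sequences <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stop("no FASTA headers in ", path)
  id <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], id[!hdr]), paste, character(1L),
                 collapse = "")
  names(seqs) <- sub("^>\\s*(\\S+).*$", "\\1", lines[hdr])
  gsub("\\s", "", seqs)
}
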