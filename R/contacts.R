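#' @title Per-residue protein-membrane contact analysis
#' @description Contacts are scored with the sigmoid distance-weighted
#'   contact function C = sum 1 / (1 + exp(5 (d - 4))) over protein-membrane
#'   heavy-atom pairs, after a 5 Angstrom pair prefilter (the kernel is
#'   below 0.007 there, so truncation changes each pair by < 0.7%). A
#'   residue is in a bound conformation in a frame when its contact number
#'   exceeds 25 (strict).
#' @name contacts
NULL

#' Sigmoid distance-weighted contact kernel
#'
#' `1 / (1 + exp(5 * (d - 4)))` with `d` in Angstrom: 0.5 at 4 Angstrom,
#' saturating to 1 at contact and decaying steeply beyond.
#'
#' @param d distances in Angstrom (vectorized), `d >= 0`.
#' @return values in (0, 1).
#' @export
contact_kernel <- function(d) {
  if (any(d < 0)) stop("distances must be nonnegative")
  1 / (1 + exp(5 * (d - 4)))
}

# per-frame contact numbers for a set of protein atoms against a membrane
# selection; returns per-atom sums
frame_atom_contacts <- function(coords, box, prot_idx, mem_idx, cutoff) {
  # exact z prefilter: z is not periodic, so atoms farther than the cutoff
  # in z alone cannot form a pair
  pz <- coords[prot_idx, 3L]
  mz <- coords[mem_idx, 3L]
  keep <- mz >= min(pz) - cutoff & mz <= max(pz) + cutoff
  out <- numeric(length(prot_idx))
  if (!any(keep)) return(out)
  d <- pair_distances_xy_periodic(coords[prot_idx, , drop = FALSE],
                                  coords[mem_idx[keep], , drop = FALSE],
                                  box)
  w <- contact_kernel(d)
  w[d > cutoff] <- 0
  rowSums(w)
}

#' Contact-number series for one residue
#'
#' `C_i(t)`: for each frame, all heavy-atom pairs between the residue and
#' the membrane selection within `cutoff` (minimum image in x,y) are summed
#' through [contact_kernel()]; pairs beyond the cutoff contribute exactly 0.
#'
#' @param traj an [ld_trajectory()].
#' @param residue_index protein residue index.
#' @param membrane_selection integer atom indices of membrane heavy atoms;
#'   defaults to all lipid and core heavy atoms.
#' @param cutoff pair prefilter distance in Angstrom (default 5).
#' @return numeric vector, one contact number per frame.
#' @export
residue_contact_series <- function(traj, residue_index,
                                   membrane_selection = NULL, cutoff = 5) {
  top <- traj$topology
  if (is.null(membrane_selection))
    membrane_selection <- select_atoms(top, role = lipid_roles(TRUE),
                                       heavy_only = TRUE)
  if (length(membrane_selection) == 0L) stop("empty membrane selection")
  prot_idx <- select_atoms(top, role = "protein",
                           residue_index = residue_index, heavy_only = TRUE)
  if (length(prot_idx) == 0L)
    stop("residue ", residue_index, " has no heavy atoms")
  vapply(traj$frames, function(f)
    sum(frame_atom_contacts(f$coords, f$box, prot_idx, membrane_selection,
                            cutoff)),
    numeric(1L))
}

#' Per-residue contact profile over a trajectory
#'
#' Computes `C_i(t)` for every protein residue, the bound mask
#' (`C_i(t) > threshold`, strict), the per-residue average contact number
#' over bound frames only (0 for residues never bound), and its cumulative
#' sum over residue index.
#'
#' @inheritParams residue_contact_series
#' @param threshold bound-conformation threshold (default 25, strict).
#' @return object of class `contact_profile`: list with `residue_ids`,
#'   `per_frame` (residue x frame matrix), `bound_mask`, `avg_bound`,
#'   `cumulative`, `threshold`, `first_bound_frame` (1-based index of the
#'   first frame in which any residue is bound, `NA` if none).
#' @export
contact_profile <- function(traj, membrane_selection = NULL, cutoff = 5,
                            threshold = 25) {
  stopifnot(threshold > 0)
  top <- traj$topology
  if (is.null(membrane_selection))
    membrane_selection <- select_atoms(top, role = lipid_roles(TRUE),
                                       heavy_only = TRUE)
  if (length(membrane_selection) == 0L) stop("empty membrane selection")
  prot_idx <- select_atoms(top, role = "protein", heavy_only = TRUE)
  if (length(prot_idx) == 0L) stop("no protein heavy atoms")
  resi <- top$residue_index[prot_idx]
  residue_ids <- sort(unique(resi))
  grp <- match(resi, residue_ids)

  nf <- n_frames(traj)
  per_frame <- matrix(0, length(residue_ids), nf,
                      dimnames = list(residue_ids, NULL))
  for (k in seq_len(nf)) {
    f <- traj$frames[[k]]
    ac <- frame_atom_contacts(f$coords, f$box, prot_idx,
                              membrane_selection, cutoff)
    per_frame[, k] <- as.vector(rowsum(ac, grp))
  }
  bound <- per_frame > threshold
  avg_bound <- vapply(seq_along(residue_ids), function(i) {
    b <- bound[i, ]
    if (any(b)) mean(per_frame[i, b]) else 0
  }, numeric(1L))
  any_bound <- which(colSums(bound) > 0)
  structure(
    list(residue_ids = residue_ids, per_frame = per_frame,
         bound_mask = bound, avg_bound = avg_bound,
         cumulative = cumsum(avg_bound), threshold = threshold,
         first_bound_frame = if (length(any_bound)) min(any_bound)
                             else NA_integer_),
    class = "contact_profile")
}

#' @export
print.contact_profile <- function(x, ...) {
  nb <- sum(x$avg_bound > 0)
  cat(sprintf(
    "contact_profile: %d residues x %d frames; %d residue(s) bound (C > %g)\n",
    length(x$residue_ids), ncol(x$per_frame), nb, x$threshold))
  if (nb > 0)
    cat("bound residues:",
        paste(x$residue_ids[x$avg_bound > 0], collapse = " "), "\n")
  invisible(x)
}

#' Bound-conformation mask for a contact series
#'
#' @param series numeric contact-number series.
#' @param threshold strict threshold (default 25); a frame is bound iff
#'   `C > threshold`.
#' @return logical vector.
#' @export
bound_frames <- function(series, threshold = 25) {
  stopifnot(threshold > 0)
  series > threshold
}

#' Cumulative per-residue contact profile
#'
#' Running sum of the bound-conformation average contact number over
#' residue index (sequence order); residues never bound contribute 0.
#'
#' @param profile a [contact_profile()] or a numeric `avg_bound` vector.
#' @return numeric nondecreasing vector.
#' @export
cumulative_profile <- function(profile) {
  v <- if (inherits(profile, "contact_profile")) profile$avg_bound
       else as.numeric(profile)
  cumsum(v)
}

#' Write contact outputs as TSV
#'
#' @param profile a [contact_profile()].
#' @param dir output directory (created if needed).
#' @return paths of `contacts_per_frame.tsv` and `contact_profile.tsv`,
#'   invisibly.
#' @export
write_contact_tables <- function(profile, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pf <- data.frame(
    frame = rep(seq_len(ncol(profile$per_frame)) - 1L,
                each = length(profile$residue_ids)),
    residue = rep(profile$residue_ids, ncol(profile$per_frame)),
    contact = as.vector(profile$per_frame))
  p1 <- file.path(dir, "contacts_per_frame.tsv")
  utils::write.table(pf, p1, sep = "\t", row.names = FALSE, quote = FALSE)
  pr <- data.frame(residue = profile$residue_ids,
                   avg_bound = profile$avg_bound,
                   cumulative = profile$cumulative)
  p2 <- file.path(dir, "contact_profile.tsv")
  utils::write.table(pr, p2, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(c(p1, p2))
}
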