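#' @title Residue penetration-depth probability maps
#' @description Depth of a residue is the absolute z-distance of its
#'   heavy-atom center of geometry from the membrane center; because the
#'   membrane is compositionally symmetric and the protein can reach either
#'   face through the periodic images, the two leaflets are folded together
#'   by the absolute value. Per-residue depth occupancies are normalized by
#'   each residue's maximum (P_i(z) / P_i(max)), which makes rows
#'   comparable across residues.
#' @name depth
NULL

#' Per-frame depth series for one residue
#'
#' `depth(t) = | z_cog,i(t) - center_z(t) |` with `z_cog` the heavy-atom
#' center of geometry (or the CA bead when `method = "ca"`).
#'
#' @param traj an [ld_trajectory()].
#' @param residue_index protein residue index.
#' @param geometry a [membrane_geometry()] for the trajectory.
#' @param method `"cog"` (heavy-atom center of geometry, default) or
#'   `"ca"` (CA atom only).
#' @return numeric vector of depths (Angstrom, >= 0), one per frame.
#' @export
residue_depth_series <- function(traj, residue_index, geometry,
                                 method = c("cog", "ca")) {
  method <- match.arg(method)
  top <- traj$topology
  idx <- select_atoms(top, role = "protein", residue_index = residue_index,
                      heavy_only = TRUE)
  if (method == "ca") idx <- idx[top$atom_name[idx] == "CA"]
  if (length(idx) == 0L)
    stop("residue ", residue_index, " has no heavy atoms")
  nf <- n_frames(traj)
  if (length(geometry$center_z) != nf)
    stop("geometry does not cover every frame")
  vapply(seq_len(nf), function(k)
    abs(mean(traj$frames[[k]]$coords[idx, 3L]) - geometry$center_z[k]),
    numeric(1L))
}

#' Histogram of a depth series
#'
#' Half-open 1-Angstrom bins `[k w, (k+1) w)` from 0 to `z_max`; depths at
#' or beyond `z_max` are clipped into the last bin with a warning.
#'
#' @param series numeric depth series (Angstrom).
#' @param bin_width bin width in Angstrom (default 1).
#' @param z_max histogram range upper limit (default 60, covering the
#'   50-Angstrom initial placement).
#' @return integer vector of counts, one per bin, summing to the number of
#'   frames.
#' @export
depth_histogram <- function(series, bin_width = 1, z_max = 60) {
  stopifnot(bin_width > 0, z_max > bin_width)
  if (length(series) == 0L) stop("empty depth series")
  n_bins <- ceiling(z_max / bin_width)
  idx <- floor(series / bin_width) + 1L
  if (any(idx > n_bins)) {
    warning(sum(idx > n_bins), " depth value(s) beyond z_max clipped into ",
            "the last bin")
    idx[idx > n_bins] <- n_bins
  }
  counts <- tabulate(idx, nbins = n_bins)
  names(counts) <- sprintf("%.1f", (seq_len(n_bins) - 0.5) * bin_width)
  counts
}

#' Max-normalized relative probability of a histogram row
#'
#' Each entry divided by the row maximum, so the modal bin is exactly 1.
#'
#' @param counts numeric vector (or matrix, normalized row-wise) with at
#'   least one nonzero entry per row.
#' @return same shape as `counts`, values in [0, 1].
#' @export
relative_probability <- function(counts) {
  if (is.matrix(counts)) {
    return(t(apply(counts, 1L, relative_probability)))
  }
  m <- max(counts)
  if (m <= 0) stop("all-zero counts row")
  counts / m
}

#' Residue-by-residue depth map over a trajectory
#'
#' @inheritParams residue_depth_series
#' @inheritParams depth_histogram
#' @param residue_ids residues to map; default all protein residues.
#' @return object of class `depth_map`: list with `residue_ids`,
#'   `bin_edges`, `counts` (residue x bin), `relative` (row-max-normalized),
#'   `modal_depth` (bin center of each residue's modal bin).
#' @export
depth_map <- function(traj, geometry, residue_ids = NULL, bin_width = 1,
                      z_max = 60, method = "cog") {
  top <- traj$topology
  if (is.null(residue_ids))
    residue_ids <- sort(unique(top$residue_index[top$role == "protein"]))
  counts <- t(vapply(residue_ids, function(r)
    depth_histogram(residue_depth_series(traj, r, geometry, method),
                    bin_width, z_max),
    numeric(ceiling(z_max / bin_width))))
  rownames(counts) <- residue_ids
  rel <- relative_probability(counts)
  centers <- (seq_len(ncol(counts)) - 0.5) * bin_width
  structure(
    list(residue_ids = residue_ids,
         bin_edges = seq(0, by = bin_width, length.out = ncol(counts) + 1L),
         counts = counts, relative = rel,
         modal_depth = centers[apply(counts, 1L, which.max)]),
    class = "depth_map")
}

#' Write a depth map as a TSV matrix
#'
#' @param map a [depth_map()].
#' @param path output path (`depth_relative.tsv` convention).
#' @return `path`, invisibly.
#' @export
write_depth_table <- function(map, path) {
  centers <- (map$bin_edges[-1L] + map$bin_edges[-length(map$bin_edges)]) / 2
  df <- data.frame(residue = map$residue_ids, map$relative,
                   check.names = FALSE)
  colnames(df) <- c("residue", sprintf("%.1f", centers))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
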