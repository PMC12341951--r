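#' @title Synthetic membrane patches
#' @description Coarse pseudo-atom (bead) membrane builders. Each
#'   phospholipid is one headgroup bead, one glycerol bead and two tails of
#'   8-12 chain beads on a jittered lattice; filled monolayers add wax-ester
#'   (two acyl arms joined by an ester bead) or triacylglycerol (three arms
#'   on a glycerol bead) chains in a core slab between the leaflets. Bead
#'   resolution is deliberate: every analysis in this package consumes only
#'   heavy-atom positions and role tags, not chemistry.
#' @name synthetic-membrane
NULL

# Geometry constants of the bead lipid model (Angstrom).
BEAD_SPACING <- 1.4      # z spacing between consecutive chain beads
HEAD_ABOVE_GLYC <- 2.0   # head bead height above the glycerol bead
MEAN_TAIL_BEADS <- 10L   # mean beads per acyl tail (sampled 8..12)

#' Build a bilayer or core-filled monolayer patch
#'
#' Lipids are laid on a jittered square lattice, two leaflets mirrored about
#' z = 0. For `we_monolayer` / `tag_monolayer` the leaflets are separated so
#' the neutral-lipid core fills a slab of thickness `core_gap` centered at
#' z = 0, mimicking the lipid-droplet surface as a planar monolayer over a
#' neutral-lipid layer. Per-leaflet headgroup counts come from
#' [allocate_counts()] and are conserved exactly.
#'
#' @param kind `"bilayer"`, `"we_monolayer"` or `"tag_monolayer"`.
#' @param composition a [composition_table()].
#' @param patch_dims in-plane patch dimensions c(x, y) in Angstrom.
#' @param n_lipids_per_leaflet lipids per leaflet.
#' @param core_gap slab thickness (Angstrom) between leaflets for filled
#'   monolayers (published droplet-mimic setups use 30).
#' @param n_core number of core neutral-lipid molecules; default scales
#'   with the leaflet lipid count.
#' @param seed integer seed; same seed gives bit-identical coordinates.
#' @return list with `topology`, `frame` and bookkeeping attributes
#'   (`counts` per leaflet, `head_plane`, `glycerol_plane`).
#' @export
build_membrane_patch <- function(kind = c("bilayer", "we_monolayer",
                                          "tag_monolayer"),
                                 composition = builtin_composition("jojoba"),
                                 patch_dims = c(60, 60),
                                 n_lipids_per_leaflet = 100,
                                 core_gap = 30,
                                 n_core = NULL,
                                 seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(length(patch_dims) == 2L, all(patch_dims > 0))
  counts <- allocate_counts(composition, n_lipids_per_leaflet)
  filled <- kind != "bilayer"
  if (is.null(n_core)) n_core <- round(n_lipids_per_leaflet * 1.2)

  # leaflet vertical placement: in a bilayer the tails of the two leaflets
  # meet near z = 0; in a filled monolayer the mean tail terminus sits at
  # the core slab surface (z = core_gap / 2)
  slab_half <- if (filled) core_gap / 2 else 0
  z_glyc <- slab_half + BEAD_SPACING * MEAN_TAIL_BEADS

  with_seed(seed, {
    species <- rep(names(counts), counts)
    nl <- length(species)
    side <- ceiling(sqrt(nl))
    sx <- patch_dims[1L] / side
    sy <- patch_dims[2L] / side
    cells <- expand.grid(ix = seq_len(side) - 1L, iy = seq_len(side) - 1L)

    rows <- list()
    mol <- 0L
    for (leaflet in c(1, -1)) {
      # independent shuffles of lattice site and species per leaflet
      site <- cells[sample.int(nrow(cells), nl), ]
      sp <- sample(species)
      x <- (site$ix + 0.5) * sx + stats::rnorm(nl, 0, 0.6)
      y <- (site$iy + 0.5) * sy + stats::rnorm(nl, 0, 0.6)
      for (i in seq_len(nl)) {
        mol <- mol + 1L
        n_t1 <- sample(8:12, 1L)
        n_t2 <- sample(8:12, 1L)
        zs <- leaflet * c(z_glyc + HEAD_ABOVE_GLYC, z_glyc,
                          z_glyc - BEAD_SPACING * seq_len(n_t1),
                          z_glyc - BEAD_SPACING * seq_len(n_t2))
        nb <- length(zs)
        dx <- c(0, 0, stats::rnorm(n_t1, 0, 0.3) + 0.7,
                stats::rnorm(n_t2, 0, 0.3) - 0.7)
        dy <- c(0, 0, stats::rnorm(nb - 2L, 0, 0.3))
        rows[[mol]] <- data.frame(
          atom_name = c("HD", "GL", paste0("C", seq_len(n_t1)),
                        paste0("C", 100L + seq_len(n_t2))),
          element = "C",
          residue_index = 1L,
          residue_name = sp[i],
          molecule_id = mol,
          role = c("lipid_head", "lipid_glycerol",
                   rep("lipid_chain", nb - 2L)),
          x = x[i] + dx, y = y[i] + dy, z = zs,
          stringsAsFactors = FALSE
        )
      }
    }

    if (filled) {
      n_arms <- if (kind == "we_monolayer") 2L else 3L
      core_res <- if (kind == "we_monolayer") "WEX" else "TAG"
      for (i in seq_len(n_core)) {
        mol <- mol + 1L
        cx <- stats::runif(1, 0, patch_dims[1L])
        cy <- stats::runif(1, 0, patch_dims[2L])
        cz <- stats::runif(1, -slab_half + 1.5, slab_half - 1.5)
        ax <- cx; ay <- cy; az <- cz
        for (a in seq_len(n_arms)) {
          n_beads <- sample(7:9, 1L)
          theta <- stats::runif(1, 0, 2 * pi)
          tilt <- stats::rnorm(1, 0, 0.25)
          step <- c(cos(theta), sin(theta), tilt)
          step <- 1.4 * step / sqrt(sum(step^2))
          bz <- pmin(pmax(cz + seq_len(n_beads) * step[3L],
                          -slab_half + 0.5), slab_half - 0.5)
          ax <- c(ax, cx + seq_len(n_beads) * step[1L])
          ay <- c(ay, cy + seq_len(n_beads) * step[2L])
          az <- c(az, bz)
        }
        rows[[mol]] <- data.frame(
          atom_name = c("ES", paste0("K", seq_along(ax)[-1L])),
          element = "C", residue_index = 1L, residue_name = core_res,
          molecule_id = mol, role = "core_neutral",
          x = ax, y = ay, z = az, stringsAsFactors = FALSE
        )
      }
    }

    df <- do.call(rbind, rows)
    top <- ld_topology(seq_len(nrow(df)), df$atom_name, df$element,
                       df$residue_index, df$residue_name, df$molecule_id,
                       df$role)
    coords <- wrap_xy(cbind(df$x, df$y, df$z),
                      c(patch_dims, 2 * (z_glyc + HEAD_ABOVE_GLYC) + 40))
    frame <- ld_frame(coords,
                      box = c(patch_dims, 2 * (z_glyc + HEAD_ABOVE_GLYC) + 40))
    out <- list(topology = top, frame = frame)
    attr(out, "counts") <- counts
    attr(out, "head_plane") <- z_glyc + HEAD_ABOVE_GLYC
    attr(out, "glycerol_plane") <- z_glyc
    out
  })
}
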