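#' @title Scripted binding trajectories
#' @description Deterministic, seed-reproducible trajectory generator that
#'   stands in for molecular-dynamics runs: a rigid pseudo-protein starts
#'   high above a membrane patch in one of six canonical orientations,
#'   approaches the surface by a mean-reverting height process, and either
#'   inserts a scripted set of binding residues below the head plane or
#'   bounces off; lipid beads carry Gaussian thermal jitter and core
#'   neutral lipids surface stochastically, opening packing defects.
#' @name synthetic-trajectory
NULL

#' Scenario configuration for the trajectory generator
#'
#' @param membrane_kind `"bilayer"`, `"we_monolayer"` or `"tag_monolayer"`.
#' @param composition a [composition_table()].
#' @param patch_dims in-plane patch size c(x, y), Angstrom.
#' @param n_lipids_per_leaflet lipids per leaflet (default 100).
#' @param core_gap core slab thickness for filled monolayers, Angstrom.
#' @param orientation_index starting orientation, 1..6.
#' @param placement_height initial protein centroid height above the
#'   membrane center, Angstrom; defaults to 50 for monolayers and 40 for
#'   bilayers, matching droplet-mimic placement protocols.
#' @param n_residues,beads_per_residue pseudo-protein size.
#' @param binding_residues residue indices scripted to insert.
#' @param bind_time time (ns) at which insertion (or surface contact, for
#'   bounce scenarios) begins.
#' @param insertion_depth target depth of binding residues below the head
#'   plane, Angstrom.
#' @param bounce if `TRUE`, the protein contacts the surface then retreats
#'   at least 20 Angstrom (reversible association; no residues insert).
#' @param surfacing_rate Poisson rate (events/ns) of core molecules
#'   transiently surfacing.
#' @param surfacing_disc radius (Angstrom) of the lipid-free disc opened
#'   around a surfacing event.
#' @param surfacing_dwell mean dwell (ns) of a surfaced core molecule.
#' @param jitter_sigma lipid bead thermal jitter (Angstrom, per frame).
#' @param n_frames,dt number of frames and frame spacing (ns).
#' @param seed integer master seed; sub-streams (membrane build, protein
#'   build, kinematics, per-frame jitter, surfacing) are derived by fixed
#'   offsets.
#' @param protein_label free-text label carried into summaries.
#' @return object of class `scenario_config` (a validated list).
#' @export
scenario_config <- function(membrane_kind = "we_monolayer",
                            composition = builtin_composition("jojoba"),
                            patch_dims = c(60, 60),
                            n_lipids_per_leaflet = 100L,
                            core_gap = 30,
                            orientation_index = 1L,
                            placement_height = NULL,
                            n_residues = 60L,
                            beads_per_residue = 8L,
                            binding_residues = 40:45,
                            bind_time = NULL,
                            insertion_depth = 2,
                            bounce = FALSE,
                            surfacing_rate = 0.2,
                            surfacing_disc = 8,
                            surfacing_dwell = 2,
                            jitter_sigma = 0.3,
                            n_frames = 200L,
                            dt = 1,
                            seed = 1L,
                            protein_label = "pseudo") {
  membrane_kind <- match.arg(membrane_kind,
                             c("bilayer", "we_monolayer", "tag_monolayer"))
  if (is.null(placement_height))
    placement_height <- if (membrane_kind == "bilayer") 40 else 50
  if (is.null(bind_time)) bind_time <- 0.2 * n_frames * dt
  cfg <- list(
    membrane_kind = membrane_kind, composition = composition,
    patch_dims = patch_dims,
    n_lipids_per_leaflet = as.integer(n_lipids_per_leaflet),
    core_gap = core_gap, orientation_index = as.integer(orientation_index),
    placement_height = placement_height,
    n_residues = as.integer(n_residues),
    beads_per_residue = as.integer(beads_per_residue),
    binding_residues = as.integer(binding_residues),
    bind_time = bind_time, insertion_depth = insertion_depth,
    bounce = isTRUE(bounce), surfacing_rate = surfacing_rate,
    surfacing_disc = surfacing_disc, surfacing_dwell = surfacing_dwell,
    jitter_sigma = jitter_sigma, n_frames = as.integer(n_frames), dt = dt,
    seed = as.integer(seed), protein_label = protein_label
  )
  validate_scenario_config(cfg)
  class(cfg) <- "scenario_config"
  cfg
}

validate_scenario_config <- function(cfg) {
  stopifnot(cfg$placement_height > 0,
            cfg$orientation_index >= 1L, cfg$orientation_index <= 6L,
            cfg$n_frames >= 2L, cfg$surfacing_rate >= 0,
            cfg$dt > 0, cfg$jitter_sigma >= 0)
  if (any(cfg$binding_residues < 1L |
          cfg$binding_residues > cfg$n_residues))
    stop("binding_residues outside the protein (1..",
         cfg$n_residues, ")")
  invisible(cfg)
}

#' Generate a scripted binding trajectory
#'
#' See [scenario_config()] for the scenario parameters. Kinematics:
#' (i) before `bind_time` the rigid protein descends by a mean-reverting
#' height process toward a contact height just above the head plane;
#' (ii) at `bind_time`, binding residues are steered over a 5-frame ramp to
#' `insertion_depth` below the upper head plane and held there with jitter,
#' while non-binding residues remain above the head plane at a standoff that
#' grows with sequence distance from the binding set; (iii) in a bounce
#' scenario the protein touches the contact height and then retreats at
#' least 20 Angstrom; (iv) lipid beads receive Gaussian jitter each frame;
#' (v) core surfacing events arrive as a Poisson process, each raising one
#' core molecule's top bead to the head plane for an exponential dwell and
#' clearing lipids from a disc around it.
#'
#' @param config a [scenario_config()].
#' @return an [ld_trajectory()]; the scenario and membrane bookkeeping are
#'   attached as attributes `"config"`, `"head_plane"`, `"glycerol_plane"`.
#' @export
generate_trajectory <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  cfg <- config
  patch <- build_membrane_patch(
    kind = cfg$membrane_kind, composition = cfg$composition,
    patch_dims = cfg$patch_dims,
    n_lipids_per_leaflet = cfg$n_lipids_per_leaflet,
    core_gap = cfg$core_gap, seed = derive_seed(cfg$seed, 1L))
  prot <- make_pseudo_protein(cfg$n_residues, cfg$beads_per_residue,
                              seed = derive_seed(cfg$seed, 2L))

  box <- patch$frame$box
  head_plane <- attr(patch, "head_plane")
  glyc_plane <- attr(patch, "glycerol_plane")
  center_z <- 0

  placed0 <- place_protein(prot, cfg$orientation_index,
                           cfg$placement_height, center_z, box)

  n_mem <- nrow(patch$topology)
  n_prot <- nrow(prot$topology)
  top <- rbind_topologies(patch$topology, prot$topology)

  # target (inserted) protein coordinates: unrotated serpentine centered in
  # the plane; z per residue scripted from the binding set
  res_xy <- attr(prot, "residue_center_xy")
  res_xy <- sweep(res_xy, 2L, colMeans(res_xy))
  res_xy[, 1L] <- res_xy[, 1L] + box[1L] / 2
  res_xy[, 2L] <- res_xy[, 2L] + box[2L] / 2
  resi <- prot$topology$residue_index
  seqdist <- vapply(seq_len(cfg$n_residues), function(i)
    min(abs(i - cfg$binding_residues)), numeric(1L))
  standoff <- 2 + 1.5 * pmin(seqdist, 8)
  z_target_res <- ifelse(seqdist == 0,
                         head_plane - cfg$insertion_depth,
                         head_plane + standoff)
  prot_local <- prot$frame$coords  # centered blob offsets
  intra_z <- prot_local[, 3L] * 0.3
  target_coords <- cbind(res_xy[resi, 1L] + prot_local[, 1L],
                         res_xy[resi, 2L] + prot_local[, 2L],
                         z_target_res[resi] + intra_z)

  # kinematics streams
  nf <- cfg$n_frames
  times <- (seq_len(nf) - 1L) * cfg$dt
  k_bind <- min(nf, max(2L, round(cfg$bind_time / cfg$dt) + 1L))
  ramp <- 5L
  contact_height <- head_plane + 3

  kin <- with_seed(derive_seed(cfg$seed, 3L), {
    h <- numeric(nf)
    h[1L] <- center_z + cfg$placement_height
    tau <- max(cfg$bind_time / 3, cfg$dt)
    noise <- stats::rnorm(nf, 0, 0.6)
    for (k in 2:nf) {
      drift <- (contact_height - h[k - 1L]) * min(1, cfg$dt / tau)
      h[k] <- h[k - 1L] + drift + noise[k] * sqrt(cfg$dt)
    }
    h
  })

  # surfacing events (Poisson arrivals, exponential dwells)
  events <- NULL
  core_mols <- unique(top$molecule_id[top$role == "core_neutral"])
  if (cfg$surfacing_rate > 0 && length(core_mols) > 0L) {
    events <- with_seed(derive_seed(cfg$seed, 4L), {
      total_t <- nf * cfg$dt
      n_ev <- stats::rpois(1L, cfg$surfacing_rate * total_t)
      if (n_ev == 0L) NULL else {
        t0 <- sort(stats::runif(n_ev, 0, total_t))
        data.frame(
          t0 = t0,
          t1 = t0 + stats::rexp(n_ev, 1 / cfg$surfacing_dwell),
          mol = sample(core_mols, n_ev, replace = TRUE)
        )
      }
    })
  }

  mem_coords0 <- patch$frame$coords
  core_top_bead <- integer(0)
  if (length(core_mols) > 0L) {
    core_top_bead <- vapply(core_mols, function(m) {
      idx <- which(top$molecule_id == m)
      idx[which.max(mem_coords0[idx, 3L])]
    }, integer(1L))
    names(core_top_bead) <- as.character(core_mols)
  }
  # reference xy of each upper-leaflet lipid head bead (for disc clearing)
  mem_role <- top$role[seq_len(n_mem)]
  head_idx <- which(mem_role == "lipid_head" & mem_coords0[, 3L] > 0)
  lipid_of_head <- top$molecule_id[head_idx]
  atoms_of_mol <- split(seq_len(n_mem), top$molecule_id[seq_len(n_mem)])

  bounce_hold <- 5L
  frames <- vector("list", nf)
  jitter_roles <- top$role %in% lipid_roles(TRUE)
  jit_idx <- which(jitter_roles)

  for (k in seq_len(nf)) {
    mem <- mem_coords0
    # (iv) thermal jitter: per-frame derived stream, so frame k's jitter
    # does not depend on how many frames the scenario has
    if (cfg$jitter_sigma > 0) {
      jit <- with_seed(derive_seed(cfg$seed, 100L + k),
                       stats::rnorm(length(jit_idx) * 3L, 0,
                                    cfg$jitter_sigma))
      mem[jit_idx, ] <- mem[jit_idx, ] + matrix(jit, ncol = 3L)
    }
    # (v) surfacing events active at this time
    if (!is.null(events)) {
      act <- which(events$t0 <= times[k] & times[k] < events$t1)
      for (e in act) {
        bead <- core_top_bead[[as.character(events$mol[e])]]
        cx <- mem_coords0[bead, 1L]; cy <- mem_coords0[bead, 2L]
        mem[bead, 3L] <- head_plane
        dx <- mem_coords0[head_idx, 1L] - cx
        dx <- dx - box[1L] * round(dx / box[1L])
        dy <- mem_coords0[head_idx, 2L] - cy
        dy <- dy - box[2L] * round(dy / box[2L])
        rr <- sqrt(dx^2 + dy^2)
        hit <- which(rr < cfg$surfacing_disc)
        for (hh in hit) {
          mols <- atoms_of_mol[[as.character(lipid_of_head[hh])]]
          push <- (cfg$surfacing_disc - rr[hh] + 1) / max(rr[hh], 0.5)
          mem[mols, 1L] <- mem[mols, 1L] + dx[hh] * push
          mem[mols, 2L] <- mem[mols, 2L] + dy[hh] * push
        }
      }
    }

    # protein coordinates
    if (cfg$bounce) {
      if (k < k_bind) {
        pz <- kin[k]
      } else if (k < k_bind + bounce_hold) {
        pz <- contact_height
      } else {
        pz <- min(contact_height + 4 * (k - k_bind - bounce_hold + 1L),
                  contact_height + 30)
      }
      pc <- placed0$coords
      pc[, 3L] <- pc[, 3L] - mean(pc[, 3L]) + pz
    } else if (k < k_bind) {
      pc <- placed0$coords
      pc[, 3L] <- pc[, 3L] - mean(pc[, 3L]) + kin[k]
    } else {
      lam <- min(1, (k - k_bind + 1L) / ramp)
      pre <- placed0$coords
      pre[, 3L] <- pre[, 3L] - mean(pre[, 3L]) + kin[k]
      pc <- (1 - lam) * pre + lam * target_coords
      if (lam >= 1 && cfg$jitter_sigma > 0) {
        pj <- with_seed(derive_seed(cfg$seed, 5000L + k),
                        stats::rnorm(length(pc), 0, 0.15))
        pc <- pc + matrix(pj, ncol = 3L)
      }
    }

    frames[[k]] <- ld_frame(rbind(mem, pc), box = box,
                            frame_index = k - 1L, time = times[k])
  }

  traj <- ld_trajectory(top, frames)
  attr(traj, "config") <- cfg
  attr(traj, "head_plane") <- head_plane
  attr(traj, "glycerol_plane") <- glyc_plane
  traj
}

# stack two topologies, renumbering atom and molecule ids of the second
rbind_topologies <- function(a, b) {
  b2 <- b
  b2$atom_id <- b$atom_id + max(a$atom_id)
  b2$molecule_id <- b$molecule_id + max(a$molecule_id)
  out <- rbind(as.data.frame(unclass(a), stringsAsFactors = FALSE),
               as.data.frame(unclass(b2), stringsAsFactors = FALSE))
  ld_topology(out$atom_id, out$atom_name, out$element, out$residue_index,
              out$residue_name, out$molecule_id, out$role)
}
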