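#' Synthetic-system configuration
#'
#' Ground-truth parameters for the synthetic generator.  The defaults
#' are the study conditions the analyses are meant to recover at desk
#' scale: area per lipid 0.61 nm^2 and headgroup tilt 90(36) degrees
#' (pure-POPC bilayer values), phosphate leaflets at +/-1.9 nm,
#' lateral diffusion 5e-8 (protein-proximal) and 8e-8 (free) cm^2/s,
#' a dominant ligand pose at 92.4% with two minor poses at 3.8%, and
#' 16 cavity waters; frames are spaced 20 ps apart.  The seed is
#' mandatory: the generator has no implicit randomness, and each
#' generator operation derives its own RNG stream from the master seed
#' plus an operation tag, so adding one operation never perturbs
#' another.
#'
#' @param seed master integer seed (required).
#' @param n_lipids named integer vector of lipid counts per type
#'   (split equally between leaflets; counts must be even).
#' @param apl_true true area per lipid in nm^2.
#' @param leaflet_z leaflet phosphate plane at +/-`leaflet_z` nm.
#' @param lattice_jitter in-plane placement jitter (nm).
#' @param tilt_mean,tilt_sd named per-type tilt mean/sd in degrees
#'   (wrapped-normal about the leaflet normal).
#' @param d_true named diffusion coefficients (cm^2/s) for the
#'   `proximal` and `free` groups.
#' @param n_frames,dt trajectory length and frame spacing (ps).
#' @param pose_weights mixture weights of the ligand pose library
#'   (must sum to 1).
#' @param pose_jitter isotropic Gaussian jitter of ligand atoms (nm).
#' @param pose_dwell mean dwell time in frames for Markov pose
#'   switching; `NULL` for independent draws (the stationary
#'   distribution equals `pose_weights` either way).
#' @param n_cavity_waters,n_outside_waters water counts inside/outside
#'   the cavity box.
#' @param helix_n_residues length of the helical C-alpha trace.
#' @param helix_noise per-frame coordinate noise on the trace (nm).
#' @param unfold_frame frame from which the unfolding residue range is
#'   extended; `NULL` for no unfolding event.
#' @param unfold_range residue indices that unfold (default: second
#'   half of the trace).
#' @return a `synth_config` list.
#' @export
synth_config <- function(seed,
                         n_lipids = c(POPC = 128),
                         apl_true = 0.61,
                         leaflet_z = 1.9,
                         lattice_jitter = 0.03,
                         tilt_mean = c(POPC = 90, POPE = 90),
                         tilt_sd = c(POPC = 36, POPE = 28),
                         d_true = c(proximal = 5e-8, free = 8e-8),
                         n_frames = 200,
                         dt = 20,
                         pose_weights = c(0.924, 0.038, 0.038),
                         pose_jitter = 0.02,
                         pose_dwell = NULL,
                         n_cavity_waters = 16,
                         n_outside_waters = 50,
                         helix_n_residues = 40,
                         helix_noise = 0.01,
                         unfold_frame = NULL,
                         unfold_range = NULL) {
  if (missing(seed)) stop("seed is mandatory (no implicit randomness)")
  if (abs(sum(pose_weights) - 1) > 1e-9) stop("pose weights must sum to 1")
  stopifnot(apl_true > 0, leaflet_z > 0, dt > 0, n_frames >= 1,
            pose_jitter > 0, all(d_true >= 0))
  if (any(n_lipids %% 2 != 0)) stop("per-type lipid counts must be even")
  structure(list(seed = as.integer(seed), n_lipids = n_lipids,
                 apl_true = apl_true, leaflet_z = leaflet_z,
                 lattice_jitter = lattice_jitter, tilt_mean = tilt_mean,
                 tilt_sd = tilt_sd, d_true = d_true,
                 n_frames = as.integer(n_frames), dt = dt,
                 pose_weights = pose_weights, pose_jitter = pose_jitter,
                 pose_dwell = pose_dwell,
                 n_cavity_waters = as.integer(n_cavity_waters),
                 n_outside_waters = as.integer(n_outside_waters),
                 helix_n_residues = as.integer(helix_n_residues),
                 helix_noise = helix_noise, unfold_frame = unfold_frame,
                 unfold_range = unfold_range),
            class = "synth_config")
}

#' Read a synthetic-system config from YAML
#' @param path YAML file whose keys match [synth_config()] arguments.
#' @return a `synth_config`.
#' @export
read_synth_config <- function(path) {
  raw <- yaml::read_yaml(path)
  for (nm in c("n_lipids", "tilt_mean", "tilt_sd", "d_true")) {
    if (!is.null(raw[[nm]])) raw[[nm]] <- unlist(raw[[nm]])
  }
  if (!is.null(raw$pose_weights)) raw$pose_weights <- unlist(raw$pose_weights)
  do.call(synth_config, raw)
}

# per-operation RNG stream: master seed + op tag
.op_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * (seq_along(utf8ToInt(tag)) + 13L))
  (as.integer(seed) %% 1000003L) * 1009L + h %% 1000003L
}

# sample tilt angles (degrees in [0, 180]) from a wrapped normal
.sample_tilt <- function(n, mean, sd) {
  x <- stats::rnorm(n, mean, sd) %% 360
  ifelse(x > 180, 360 - x, x)
}

#' Generate a synthetic bilayer
#'
#' Two leaflets of pseudo-lipids on a jittered square lattice with
#' lattice constant `sqrt(apl_true)`, so that the box area divided by
#' the per-leaflet lipid count equals `apl_true` exactly.  Each
#' POPC/POPE pseudo-lipid carries a phosphorus bead (P), a headgroup
#' nitrogen (N) placed 0.4 nm from P along a direction drawn from a
#' wrapped-normal tilt about the leaflet's outward normal with uniform
#' azimuth, an acceptor oxygen (OP), two tail beads, and (POPE only)
#' an amine hydrogen (HN); cholesterol is a hydroxyl bead plus tails.
#' Requested counts are padded up to fill a perfect-square lattice.
#'
#' @param cfg a [synth_config()].
#' @param include_protein add a transmembrane pseudo-protein column at
#'   the box centre (displacing the nearest lattice sites).
#' @return list with `topology`, `frame` and `n_per_leaflet`.
#' @export
make_bilayer <- function(cfg, include_protein = FALSE) {
  set.seed(.op_seed(cfg$seed, "make_bilayer"))
  types_leaf <- rep(names(cfg$n_lipids), cfg$n_lipids / 2)
  a <- sqrt(cfg$apl_true)
  m <- ceiling(sqrt(length(types_leaf)))
  n_sites <- m * m
  if (n_sites > length(types_leaf)) {
    types_leaf <- c(types_leaf,
                    rep(names(cfg$n_lipids)[1], n_sites - length(types_leaf)))
  }
  box <- c(m * a, m * a, 2 * (cfg$leaflet_z + 1.2))
  centre <- box[1:2] / 2
  sites <- cbind(x = (rep(seq_len(m), m) - 0.5) * a,
                 y = (rep(seq_len(m), each = m) - 0.5) * a)
  excl <- rep(FALSE, n_sites)
  prot <- NULL
  if (include_protein) {
    r_site <- sqrt((sites[, 1] - centre[1])^2 + (sites[, 2] - centre[2])^2)
    excl <- r_site < 0.9
    zs <- seq(-cfg$leaflet_z - 0.3, cfg$leaflet_z + 0.3, by = 0.3)
    ring <- cbind(cos(seq(0, 2 * pi, length.out = 7)[-7]),
                  sin(seq(0, 2 * pi, length.out = 7)[-7])) * 0.6
    prot_xyz <- do.call(rbind, lapply(seq_along(zs), function(k) {
      cbind(centre[1] + ring[, 1], centre[2] + ring[, 2],
            box[3] / 2 + zs[k])
    }))
    # one acceptor bead per ring for protein-lipid hydrogen bonding
    ob <- cbind(centre[1] + 0.62, centre[2], box[3] / 2 + zs)
    prot <- list(
      xyz = rbind(prot_xyz, ob),
      name = c(rep("CA", nrow(prot_xyz)), rep("OB", length(zs))),
      resid = c(rep(seq_along(zs), each = 6), seq_along(zs)),
      elem = c(rep("C", nrow(prot_xyz)), rep("O", length(zs))))
  }
  bead <- list()
  resid0 <- 100L
  for (leaf in c(1, -1)) {
    use <- which(!excl)
    for (k in seq_along(use)) {
      tp <- types_leaf[(k - 1) %% length(types_leaf) + 1]
      p_xy <- sites[use[k], ] + stats::runif(2, -cfg$lattice_jitter,
                                             cfg$lattice_jitter)
      p <- c(p_xy, box[3] / 2 + leaf * cfg$leaflet_z)
      resid0 <- resid0 + 1L
      if (tp %in% c("POPC", "POPE")) {
        tilt <- deg2rad(.sample_tilt(1, cfg$tilt_mean[[tp]],
                                     cfg$tilt_sd[[tp]]))
        az <- stats::runif(1, 0, 2 * pi)
        dir <- c(sin(tilt) * cos(az), sin(tilt) * sin(az),
                 leaf * cos(tilt))
        nn <- p + 0.4 * dir
        atoms <- list(
          list("P", p, "P"), list("N", nn, "N"),
          list("OP", p + c(0.08, 0, 0), "O"),
          list("T1", p - c(0, 0, leaf * 0.5), "C"),
          list("T2", p - c(0, 0, leaf * 1.0), "C"))
        if (tp == "POPE") {
          atoms <- c(atoms, list(list("HN", nn + 0.1 * dir, "H")))
        }
      } else { # CHOL
        atoms <- list(
          list("O3", p, "O"),
          list("C1", p - c(0, 0, leaf * 0.45), "C"),
          list("C2", p - c(0, 0, leaf * 0.9), "C"))
      }
      for (at in atoms) {
        bead[[length(bead) + 1]] <- list(name = at[[1]], xyz = at[[2]],
                                         resid = resid0, resname = tp,
                                         elem = at[[3]])
      }
    }
  }
  aname <- vapply(bead, `[[`, character(1), "name")
  resname <- vapply(bead, `[[`, character(1), "resname")
  resid <- vapply(bead, `[[`, integer(1), "resid")
  elem <- vapply(bead, `[[`, character(1), "elem")
  xyz <- do.call(rbind, lapply(bead, `[[`, "xyz"))
  if (!is.null(prot)) {
    aname <- c(prot$name, aname)
    resname <- c(rep("ALA", length(prot$name)), resname)
    resid <- c(prot$resid, resid)
    elem <- c(prot$elem, elem)
    xyz <- rbind(prot$xyz, xyz)
  }
  top <- topology(aname, resname, resid, element = elem)
  list(topology = top, frame = mdframe(xyz, box, 0),
       n_per_leaflet = sum(!excl))
}

#' Generate 2-D Brownian motion of the bilayer molecules
#'
#' Each lipid/cholesterol molecule performs a rigid lateral random
#' walk with per-axis increments `Normal(0, 2 D dt)` wrapped into the
#' box; z is held at the leaflet plane and protein/water atoms stay
#' static.  When a pseudo-protein is present, molecules starting near
#' it are assigned the `proximal` diffusion coefficient and are pulled
#' to within contact distance of the protein at the first frame (so
#' the proximal/free classification has its ground truth); all others
#' diffuse with the `free` coefficient.
#'
#' @param cfg a [synth_config()] (uses `d_true`, `n_frames`, `dt`).
#' @param sys a system from [make_bilayer()].
#' @return an [mdtrajectory()] with attribute `"groups"`: the
#'   ground-truth group (`proximal`/`free`) per residue id.
#' @export
make_brownian <- function(cfg, sys) {
  set.seed(.op_seed(cfg$seed, "make_brownian"))
  top <- sys$topology
  box <- sys$frame$box
  d_nm2ps <- cfg$d_true / NM2_PER_PS_TO_CM2_PER_S
  sdstep <- sqrt(2 * d_nm2ps * cfg$dt)
  if (any(4 * sdstep > min(box[1:2]) / 2)) {
    stop("Brownian step size exceeds half the box; reduce D or dt")
  }
  mobile_roles <- c("POPC", "POPE", "CHOL")
  mol_idx <- split(which(top$chain_role %in% mobile_roles),
                   top$residue_id[top$chain_role %in% mobile_roles])
  prot_idx <- which(top$chain_role == "protein")
  xyz0 <- sys$frame$coords
  groups <- stats::setNames(rep("free", length(mol_idx)), names(mol_idx))
  if (length(prot_idx)) {
    prot <- xyz0[prot_idx, , drop = FALSE]
    for (mth in seq_along(mol_idx)) {
      g <- xyz0[mol_idx[[mth]], , drop = FALSE]
      dmin <- Inf; pair <- NULL
      for (k in seq_len(nrow(g))) {
        dv <- min_image_displacement(prot, g[k, ], box)
        dk <- sqrt(rowSums(dv^2))
        if (min(dk) < dmin) {
          dmin <- min(dk)
          pair <- list(at = k, dv = dv[which.min(dk), ])
        }
      }
      if (dmin < 1.6) {
        groups[mth] <- "proximal"
        if (dmin > 0.3) { # pull into contact at frame 1 (xy only)
          shift <- (dmin - 0.3) / dmin * pair$dv[1:2]
          xyz0[mol_idx[[mth]], 1] <- g[, 1] + shift[1]
          xyz0[mol_idx[[mth]], 2] <- g[, 2] + shift[2]
        }
      }
    }
  }
  nf <- cfg$n_frames
  frames <- vector("list", nf)
  cur <- xyz0
  frames[[1]] <- mdframe(cur, box, 0)
  for (f in 2:max(nf, 2)) {
    if (nf < 2) break
    for (mth in seq_along(mol_idx)) {
      s <- sdstep[[groups[mth]]]
      step <- stats::rnorm(2, 0, s)
      idx <- mol_idx[[mth]]
      cur[idx, 1] <- (cur[idx, 1] + step[1]) %% box[1]
      cur[idx, 2] <- (cur[idx, 2] + step[2]) %% box[2]
    }
    frames[[f]] <- mdframe(cur, box, (f - 1) * cfg$dt)
  }
  traj <- mdtrajectory(top, frames[seq_len(max(nf, 1))])
  attr(traj, "groups") <- groups
  traj
}

# xanthine-like planar bicyclic template (nm, ring plane = xy)
.ligand_template <- function() {
  hex <- cbind(0.14 * cos(seq(0, 2 * pi, length.out = 7)[-7]),
               0.14 * sin(seq(0, 2 * pi, length.out = 7)[-7]), 0)
  rownames(hex) <- c("N1", "C2", "N3", "C4", "C5", "C6")
  five <- rbind(N7 = c(-0.25, 0.10, 0), C8 = c(-0.33, 0.0, 0),
                N9 = c(-0.25, -0.10, 0))
  methyl <- rbind(C10 = c(0.28, 0.05, 0), C11 = c(0.10, 0.28, 0),
                  O2 = c(0.12, -0.26, 0))
  xyz <- rbind(hex, five, methyl)
  list(xyz = xyz, name = rownames(xyz),
       elem = toupper(substr(rownames(xyz), 1, 1)))
}

.rot3 <- function(axis, angle_deg) {
  a <- deg2rad(angle_deg)
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K)
}

#' Generate a ligand-in-receptor trajectory from a pose mixture
#'
#' Per frame a pose index is drawn from the categorical mixture (or a
#' Markov chain with the same stationary distribution when
#' `pose_dwell` is set), ligand coordinates are the reference pose
#' plus isotropic Gaussian jitter, and a small random rigid-body
#' wobble is applied to the whole system so that backbone alignment
#' is genuinely exercised.  Reference poses are rigid transforms of a
#' planar xanthine-like bicyclic template, mutually separated by far
#' more than the jitter scale (an error is raised if the jitter
#' reaches half the minimum inter-pose RMSD, since clusters would
#' merge by construction).
#'
#' @param cfg a [synth_config()].
#' @param receptor optional list(topology, frame) to embed the ligand
#'   in; default is a rigid C-alpha cage around the binding site.
#' @return an [mdtrajectory()] with attribute `"pose_truth"`: the
#'   generated per-frame pose index.
#' @export
make_ligand_traj <- function(cfg, receptor = NULL) {
  set.seed(.op_seed(cfg$seed, "make_ligand_traj"))
  box <- c(10, 10, 10)
  centre <- box / 2
  if (is.null(receptor)) {
    g <- expand.grid(x = -1:1, y = -1:1, z = -1:1)
    rxyz <- sweep(as.matrix(g) * 0.8, 2, centre, "+")
    rtop <- topology(rep("CA", 27), rep("GLY", 27), 1:27,
                     element = rep("C", 27))
    receptor <- list(topology = rtop, frame = mdframe(rxyz, box, 0))
  }
  tmpl <- .ligand_template()
  k <- length(cfg$pose_weights)
  pose_tf <- list(list(R = diag(3), t = c(0, 0, 0)),
                  list(R = .rot3(c(1, 0, 0), 180), t = c(0, 0, 0)),
                  list(R = .rot3(c(0, 0, 1), 90), t = c(0.15, 0, 0)),
                  list(R = .rot3(c(0, 0, 1), 180), t = c(0, 0.15, 0)))
  if (k > length(pose_tf)) stop("pose library supports up to 4 poses")
  poses <- lapply(pose_tf[seq_len(k)], function(tf) {
    sweep(tmpl$xyz %*% tf$R, 2, centre + tf$t, "+")
  })
  if (k > 1) {
    dmin <- min(utils::combn(k, 2, function(ij) {
      rmsd(poses[[ij[1]]], poses[[ij[2]]])
    }))
    if (cfg$pose_jitter >= dmin / 2) {
      stop("pose_jitter >= half the minimum inter-pose RMSD (",
           signif(dmin, 3), " nm); clusters would merge by construction")
    }
  }
  lig_n <- nrow(tmpl$xyz)
  top <- topology(c(receptor$topology$atom_name, tmpl$name),
                  c(receptor$topology$residue_name, rep("CFF", lig_n)),
                  c(receptor$topology$residue_id, rep(500L, lig_n)),
                  element = c(receptor$topology$element, tmpl$elem))
  nf <- cfg$n_frames
  pose_idx <- integer(nf)
  if (is.null(cfg$pose_dwell)) {
    pose_idx <- sample.int(k, nf, replace = TRUE, prob = cfg$pose_weights)
  } else {
    a <- 1 / cfg$pose_dwell
    pose_idx[1] <- sample.int(k, 1, prob = cfg$pose_weights)
    for (f in seq_len(nf - 1)) {
      pose_idx[f + 1] <- if (stats::runif(1) < a) {
        sample.int(k, 1, prob = cfg$pose_weights)
      } else pose_idx[f]
    }
  }
  frames <- vector("list", nf)
  for (f in seq_len(nf)) {
    lig <- poses[[pose_idx[f]]] +
      matrix(stats::rnorm(3 * lig_n, 0, cfg$pose_jitter), lig_n, 3)
    xyz <- rbind(receptor$frame$coords, lig)
    # joint rigid wobble of receptor + ligand
    R <- .rot3(stats::rnorm(3), abs(stats::rnorm(1, 0, 2)))
    t <- stats::rnorm(3, 0, 0.03)
    xyz <- sweep(sweep(xyz, 2, centre) %*% R, 2, centre + t, "+")
    frames[[f]] <- mdframe(xyz, box, (f - 1) * cfg$dt)
  }
  traj <- mdtrajectory(top, frames)
  attr(traj, "pose_truth") <- pose_idx
  traj
}

#' Generate a helical C-alpha trace with an optional unfolding event
#'
#' An ideal alpha-helix trace (rise 0.15 nm, 100 degrees per residue,
#' radius 0.23 nm) with small per-frame noise.  From `unfold_frame`
#' onward the residues in `unfold_range` (default: the second half)
#' are replaced by an extended continuation along the helix axis with
#' 0.36 nm spacing, reproducing a programmed helix-to-coil transition.
#'
#' @param cfg a [synth_config()] (uses `helix_n_residues`,
#'   `helix_noise`, `unfold_frame`, `unfold_range`, `n_frames`, `dt`).
#' @return an [mdtrajectory()] of CA beads.
#' @export
make_helix_trace <- function(cfg) {
  set.seed(.op_seed(cfg$seed, "make_helix_trace"))
  n <- cfg$helix_n_residues
  i <- seq_len(n)
  helix <- cbind(0.23 * cos(deg2rad(100 * i)),
                 0.23 * sin(deg2rad(100 * i)), 0.15 * i)
  helix <- sweep(helix, 2, c(3, 3, 1), "+")
  range_u <- if (is.null(cfg$unfold_range)) (n %/% 2 + 1):n else
    cfg$unfold_range
  unfolded <- helix
  anchor <- min(range_u) - 1
  if (anchor < 1) stop("unfold_range must leave at least one anchor residue")
  for (j in range_u) {
    unfolded[j, ] <- helix[anchor, ] + c(0, 0, 0.36 * (j - anchor))
  }
  box <- c(8, 8, max(8, 0.36 * n + 2))
  top <- topology(rep("CA", n), rep("GLY", n), i, element = rep("C", n))
  nf <- cfg$n_frames
  frames <- vector("list", nf)
  for (f in seq_len(nf)) {
    base <- if (!is.null(cfg$unfold_frame) && f >= cfg$unfold_frame)
      unfolded else helix
    xyz <- base + matrix(stats::rnorm(3 * n, 0, cfg$helix_noise), n, 3)
    frames[[f]] <- mdframe(xyz, box, (f - 1) * cfg$dt)
  }
  mdtrajectory(top, frames)
}

#' Place water oxygens inside and outside a cavity box
#'
#' Exactly `n_cavity_waters` water molecules (oxygen plus one
#' hydrogen bead) uniformly inside the box and `n_outside_waters`
#' uniformly in the surrounding shell, rejected from the box interior.
#'
#' @param cfg a [synth_config()].
#' @param box a `cavity_box` (see [cavity_box_from_residues()]).
#' @param shell half-width added around the box for the outside
#'   placement region (nm, default 2).
#' @param res_id_start first residue id for the waters (default 1000).
#' @return list with `topology` and `coords` (static positions, nm).
#' @export
place_waters <- function(cfg, box, shell = 2, res_id_start = 1000L) {
  set.seed(.op_seed(cfg$seed, "place_waters"))
  lo <- box$center - box$half_extents
  hi <- box$center + box$half_extents
  n_in <- cfg$n_cavity_waters
  n_out <- cfg$n_outside_waters
  inside <- cbind(stats::runif(n_in, lo[1], hi[1]),
                  stats::runif(n_in, lo[2], hi[2]),
                  stats::runif(n_in, lo[3], hi[3]))
  outside <- matrix(0, 0, 3)
  lo2 <- lo - shell; hi2 <- hi + shell
  while (nrow(outside) < n_out) {
    cand <- cbind(stats::runif(n_out, lo2[1], hi2[1]),
                  stats::runif(n_out, lo2[2], hi2[2]),
                  stats::runif(n_out, lo2[3], hi2[3]))
    in_box <- cand[, 1] >= lo[1] & cand[, 1] <= hi[1] &
      cand[, 2] >= lo[2] & cand[, 2] <= hi[2] &
      cand[, 3] >= lo[3] & cand[, 3] <= hi[3]
    outside <- rbind(outside, cand[!in_box, , drop = FALSE])
  }
  outside <- outside[seq_len(n_out), , drop = FALSE]
  ow <- rbind(inside, outside)
  nw <- nrow(ow)
  dirm <- matrix(stats::rnorm(3 * nw), nw, 3)
  hw <- ow + 0.1 * dirm / sqrt(rowSums(dirm^2))
  xyz <- matrix(0, 2 * nw, 3)
  xyz[seq(1, 2 * nw, 2), ] <- ow
  xyz[seq(2, 2 * nw, 2), ] <- hw
  top <- topology(rep(c("OW", "HW1"), nw), rep("SOL", 2 * nw),
                  rep(res_id_start + seq_len(nw) - 1L, each = 2),
                  element = rep(c("O", "H"), nw))
  list(topology = top, coords = xyz)
}

#' Append static atoms to every frame of a trajectory
#'
#' @param traj an [mdtrajectory()].
#' @param extra list with `topology` and `coords` (e.g. from
#'   [place_waters()]).
#' @return the extended [mdtrajectory()].
#' @export
add_static_atoms <- function(traj, extra) {
  top <- rbind(traj$topology, extra$topology)
  class(top) <- c("topology", "data.frame")
  frames <- lapply(seq_len(n_frames(traj)), function(f) {
    mdframe(rbind(traj$coords[, , f], extra$coords), traj$box[f, ],
            traj$times[f])
  })
  out <- mdtrajectory(top, frames)
  for (a in setdiff(names(attributes(traj)), c("names", "class"))) {
    attr(out, a) <- attr(traj, a)
  }
  out
}
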