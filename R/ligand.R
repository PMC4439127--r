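#' Gromos conformational clustering of ligand poses
#'
#' For every frame pair the two frames are superposed on `align_spec`
#' (typically the protein backbone) and the RMSD of `cluster_spec`
#' (typically the ligand heavy atoms) under that fit is taken.  The
#' Gromos algorithm then repeatedly promotes the frame with the most
#' neighbours within `cutoff` to a cluster centre, removes the cluster,
#' and iterates until all frames are assigned.  Clusters are numbered
#' by decreasing size; neighbour-count ties promote the lower frame
#' index (reproducibility).
#'
#' @param traj an [mdtrajectory()].
#' @param align_spec selection used for the pairwise superposition.
#' @param cluster_spec selection whose RMSD is clustered.
#' @param cutoff RMSD cutoff in nm (0.2 nm is the conventional ligand
#'   pose cutoff).
#' @return a `pose_clustering`: `cluster_labels` (per frame, 1 =
#'   largest), `populations` (percent of frames per cluster, summing
#'   to 100), `representatives` (frame index whose mean RMSD to its
#'   cluster members is minimal), `cutoff`, `rmsd` (the pairwise
#'   matrix used).
#' @export
gromos_cluster <- function(traj, align_spec, cluster_spec, cutoff = 0.2) {
  if (cutoff <= 0) stop("cutoff must be > 0")
  nf <- n_frames(traj)
  if (nf < 1) stop("empty trajectory")
  ai <- select_atoms(traj$topology, align_spec, warn_empty = FALSE)
  ci <- select_atoms(traj$topology, cluster_spec, warn_empty = FALSE)
  if (!length(ai) || !length(ci)) stop("empty selection")
  m <- matrix(0, nf, nf)
  for (i in seq_len(max(nf - 1, 0))) {
    ref_a <- frame_coords(traj, ai, i)
    ref_c <- frame_coords(traj, ci, i)
    for (j in (i + 1):nf) {
      if (j > nf) break
      fit <- kabsch_superpose(frame_coords(traj, ai, j), ref_a)
      moved <- sweep(frame_coords(traj, ci, j) %*% fit$rotation,
                     2, fit$translation, "+")
      m[i, j] <- m[j, i] <- rmsd(moved, ref_c)
    }
  }
  neigh <- m <= cutoff            # includes self on the diagonal
  remaining <- rep(TRUE, nf)
  labels <- integer(nf)
  centers <- integer(0)
  k <- 0L
  while (any(remaining)) {
    counts <- colSums(neigh[remaining, , drop = FALSE]) * remaining
    center <- which.max(counts)   # ties: lowest frame index
    members <- which(neigh[, center] & remaining)
    k <- k + 1L
    labels[members] <- k
    centers[k] <- center
    remaining[members] <- FALSE
  }
  sizes <- tabulate(labels, k)
  ord <- order(-sizes, centers)   # renumber by decreasing size
  relab <- integer(k); relab[ord] <- seq_len(k)
  labels <- relab[labels]
  centers <- centers[ord]
  sizes <- sizes[ord]
  reps <- vapply(seq_len(k), function(cl) {
    members <- which(labels == cl)
    if (length(members) == 1) return(members)
    mean_r <- colMeans(m[members, members, drop = FALSE])
    members[which.min(mean_r)]
  }, integer(1))
  structure(list(cluster_labels = labels,
                 populations = 100 * sizes / nf,
                 representatives = reps,
                 sizes = sizes, cutoff = cutoff, rmsd = m),
            class = "pose_clustering")
}

#' @export
print.pose_clustering <- function(x, ...) {
  cat(sprintf("pose_clustering: %d clusters over %d frames (cutoff %.2f nm)\n",
              length(x$populations), length(x$cluster_labels), x$cutoff))
  for (i in seq_along(x$populations)) {
    cat(sprintf("  cluster %d: %5.1f%%  (representative frame %d)\n",
                i, x$populations[i], x$representatives[i]))
  }
  invisible(x)
}

#' Write cluster assignments (TSV) and populations (JSON)
#'
#' @param clustering a `pose_clustering`.
#' @param traj the clustered trajectory (for frame times).
#' @param tsv_path,json_path output paths (either may be `NULL`).
#' @export
write_pose_clustering <- function(clustering, traj, tsv_path = NULL,
                                  json_path = NULL) {
  if (!is.null(tsv_path)) {
    df <- data.frame(frame = seq_along(clustering$cluster_labels),
                     time_ps = traj$times,
                     cluster = clustering$cluster_labels)
    utils::write.table(df, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(list(cutoff_nm = clustering$cutoff,
                              populations_percent = clustering$populations,
                              representatives = clustering$representatives),
                         json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(clustering)
}

#' Map clusters to named reference poses by RMSD
#'
#' Pose populations are reported over all clusters; when reference
#' pose structures are supplied (e.g. crystallographic or previously
#' published poses), each cluster representative is mapped to the
#' nearest reference within `cutoff`, unmatched clusters remaining
#' unnamed.
#'
#' @param clustering a `pose_clustering`.
#' @param traj the clustered trajectory.
#' @param cluster_spec the selection that was clustered.
#' @param references named list of reference coordinate matrices for
#'   the same selection.
#' @param cutoff maximum RMSD (nm) for a match.
#' @return character vector of reference names (or `NA`) per cluster.
#' @export
map_poses_to_references <- function(clustering, traj, cluster_spec,
                                    references, cutoff = 0.2) {
  ci <- select_atoms(traj$topology, cluster_spec, warn_empty = FALSE)
  vapply(clustering$representatives, function(f) {
    x <- frame_coords(traj, ci, f)
    d <- vapply(references, function(r) rmsd(x, r, superpose = TRUE),
                numeric(1))
    if (min(d) <= cutoff) names(references)[which.min(d)] else NA_character_
  }, character(1))
}

#' Orientational flipping angle of a ligand
#'
#' The ligand orientation at each frame is the unit vector from the
#' centroid of its six-membered-ring atoms to the centroid of its
#' five-membered-ring atoms (a deterministic in-plane vector for a
#' xanthine-like bicyclic core; atom names configurable).  The
#' flipping angle at frame tau is `arccos(mu_tau . mu_ref)` in degrees,
#' zero at the reference frame by construction.
#'
#' @param traj an [mdtrajectory()].
#' @param ligand_spec selection containing the ligand.
#' @param reference_frame frame index defining the reference
#'   orientation (default 1).
#' @param ring6_atoms,ring5_atoms atom names of the two rings (defaults
#'   follow xanthine numbering).
#' @return a `flipping_series`: `angle` (degrees, per frame, in
#'   [0, 180]), `reference_frame`, `reference_vector`.
#' @export
flipping_angle <- function(traj, ligand_spec, reference_frame = 1,
                           ring6_atoms = c("N1", "C2", "N3", "C4", "C5", "C6"),
                           ring5_atoms = c("N7", "C8", "N9")) {
  li <- select_atoms(traj$topology, ligand_spec, warn_empty = FALSE)
  if (!length(li)) stop("empty ligand selection")
  sub <- traj$topology[li, ]
  i6 <- li[sub$atom_name %in% ring6_atoms]
  i5 <- li[sub$atom_name %in% ring5_atoms]
  if (!length(i6) || !length(i5)) {
    stop("ligand lacks the ring atoms needed to define the orientation vector")
  }
  mu <- function(f) {
    v <- colMeans(frame_coords(traj, i5, f)) -
      colMeans(frame_coords(traj, i6, f))
    nv <- sqrt(sum(v^2))
    if (nv < 1e-12) stop("degenerate (zero-length) orientation vector")
    v / nv
  }
  mu_ref <- mu(reference_frame)
  ang <- vapply(seq_len(n_frames(traj)), function(f) {
    rad2deg(acos(max(-1, min(1, sum(mu(f) * mu_ref)))))
  }, numeric(1))
  ang[reference_frame] <- 0
  structure(list(angle = ang, reference_frame = reference_frame,
                 reference_vector = mu_ref),
            class = "flipping_series")
}

#' Ligand centre-of-mass cloud in the receptor-aligned frame
#'
#' Each frame is superposed on the reference frame using `align_spec`
#' (protein backbone); the mass-weighted ligand centroid is recorded in
#' that common frame.  The spread of the resulting point cloud
#' measures ligand translational mobility.  Per-axis spreads are
#' population standard deviations (divide by n), so a symmetric
#' two-point distribution at +/-d has spread exactly d.
#'
#' @param traj an [mdtrajectory()].
#' @param align_spec alignment selection.
#' @param ligand_spec ligand selection (masses from element symbols).
#' @param reference_frame frame defining the common frame (default 1).
#' @return a `com_cloud`: `com` (F x 3 matrix, nm), `mean`, `sd`
#'   (per-axis population SD), `rg` (radius of gyration of the cloud).
#' @export
com_cloud <- function(traj, align_spec, ligand_spec, reference_frame = 1) {
  ai <- select_atoms(traj$topology, align_spec, warn_empty = FALSE)
  li <- select_atoms(traj$topology, ligand_spec, warn_empty = FALSE)
  if (!length(ai) || !length(li)) stop("empty selection")
  mass <- atomic_mass(traj$topology$element[li])
  ref <- frame_coords(traj, ai, reference_frame)
  nf <- n_frames(traj)
  com <- matrix(0, nf, 3)
  for (f in seq_len(nf)) {
    fit <- kabsch_superpose(frame_coords(traj, ai, f), ref)
    lig <- sweep(frame_coords(traj, li, f) %*% fit$rotation,
                 2, fit$translation, "+")
    com[f, ] <- colSums(lig * mass) / sum(mass)
  }
  mu <- colMeans(com)
  sdv <- sqrt(colMeans(sweep(com, 2, mu)^2))
  rg <- sqrt(mean(rowSums(sweep(com, 2, mu)^2)))
  structure(list(com = com, mean = mu, sd = sdv, rg = rg),
            class = "com_cloud")
}

#' Define a rectangular cavity box from binding-site residues
#'
#' Axis-aligned bounding box of the atoms of the given residues, grown
#' by a symmetric padding.  The box is typically computed once on an
#' averaged or reference structure and then held fixed, so hydration
#' counts are comparable across frames.
#'
#' @param top a [topology()].
#' @param frame an [mdframe()].
#' @param residues selection of the cavity-defining residues.
#' @param padding symmetric padding in nm (default 0.15).
#' @return a `cavity_box`: `center`, `half_extents` (nm).
#' @export
cavity_box_from_residues <- function(top, frame, residues, padding = 0.15) {
  idx <- select_atoms(top, residues, warn_empty = FALSE)
  if (!length(idx)) stop("empty cavity residue selection")
  xyz <- frame$coords[idx, , drop = FALSE]
  lo <- apply(xyz, 2, min) - padding
  hi <- apply(xyz, 2, max) + padding
  structure(list(center = (lo + hi) / 2, half_extents = (hi - lo) / 2),
            class = "cavity_box")
}

#' Count water molecules inside a cavity box
#'
#' A water molecule counts if its oxygen atom lies inside the box
#' (inclusive bounds).  Returns the per-frame counts and their mean —
#' the standard binding-cavity hydration measure.
#'
#' @param traj an [mdtrajectory()].
#' @param box a `cavity_box`.
#' @param water_spec selection of the water oxygen atoms; defaults to
#'   oxygen atoms of water residues.
#' @return list with `counts` (per frame) and `mean`.
#' @export
count_cavity_waters <- function(traj, box,
                                water_spec = sel(role = "water")) {
  wi <- select_atoms(traj$topology, water_spec, warn_empty = FALSE)
  wi <- wi[traj$topology$element[wi] == "O"]
  lo <- box$center - box$half_extents
  hi <- box$center + box$half_extents
  counts <- vapply(seq_len(n_frames(traj)), function(f) {
    xyz <- frame_coords(traj, wi, f)
    sum(xyz[, 1] >= lo[1] & xyz[, 1] <= hi[1] &
        xyz[, 2] >= lo[2] & xyz[, 2] <= hi[2] &
        xyz[, 3] >= lo[3] & xyz[, 3] <= hi[3])
  }, numeric(1))
  list(counts = counts, mean = mean(counts))
}

#' Per-frame minimum distance between two selections
#'
#' Minimum over all atom pairs of the periodic minimum-image distance.
#'
#' @param traj an [mdtrajectory()].
#' @param spec_a,spec_b non-empty selections.
#' @return numeric vector, one minimum distance (nm) per frame.
#' @export
min_distance_series <- function(traj, spec_a, spec_b) {
  ia <- select_atoms(traj$topology, spec_a, warn_empty = FALSE)
  ib <- select_atoms(traj$topology, spec_b, warn_empty = FALSE)
  if (!length(ia) || !length(ib)) stop("empty selection")
  vapply(seq_len(n_frames(traj)), function(f) {
    a <- frame_coords(traj, ia, f)
    b <- frame_coords(traj, ib, f)
    box <- traj$box[f, ]
    d2 <- matrix(0, length(ia), length(ib))
    for (k in 1:3) {
      dk <- outer(a[, k], b[, k], "-")
      dk <- dk - box[k] * round(dk / box[k])
      d2 <- d2 + dk^2
    }
    sqrt(min(d2))
  }, numeric(1))
}

#' Fraction of frames with a contact
#'
#' @param series per-frame minimum distances (nm).
#' @param threshold contact threshold in nm (> 0).
#' @return fraction of frames with `series <= threshold`.
#' @export
contact_occupancy <- function(series, threshold) {
  if (threshold <= 0) stop("threshold must be > 0")
  mean(series <= threshold)
}
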