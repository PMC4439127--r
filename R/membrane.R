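#' Number-density profile along the bilayer normal
#'
#' Histograms the selected atoms' z coordinates, measured from the
#' instantaneous bilayer midplane (mean z of all lipid phosphorus
#' atoms by default), averages over frames and normalises to number
#' density (nm^-3).  The integral of the profile over z times the
#' lateral box area recovers the mean selected-atom count.
#'
#' @param traj an [mdtrajectory()].
#' @param spec selection to profile (e.g. lipid phosphate P atoms).
#' @param bin_width bin width in nm (> 0, default 0.1).
#' @param midplane_spec selection defining the midplane; default: P
#'   atoms of POPC/POPE lipids.
#' @return a `density_profile`: `bin_centers` (nm, midplane-relative),
#'   `density` (nm^-3), `bin_width`, `area` (mean lateral area, nm^2),
#'   `n_mean` (mean selected-atom count).
#' @export
density_profile <- function(traj, spec, bin_width = 0.1,
                            midplane_spec = sel(role = c("POPC", "POPE"),
                                                atom_name = "P")) {
  if (bin_width <= 0) stop("bin_width must be > 0")
  idx <- select_atoms(traj$topology, spec, warn_empty = FALSE)
  if (!length(idx)) stop("empty selection")
  mi <- select_atoms(traj$topology, midplane_spec, warn_empty = FALSE)
  if (!length(mi)) mi <- idx
  nf <- n_frames(traj)
  half_z <- max(traj$box[, 3]) / 2
  breaks <- seq(-half_z - bin_width, half_z + bin_width, by = bin_width)
  counts <- numeric(length(breaks) - 1)
  for (f in seq_len(nf)) {
    z <- traj$coords[idx, 3, f] - mean(traj$coords[mi, 3, f])
    z <- pmin(pmax(z, breaks[1] + 1e-12), breaks[length(breaks)] - 1e-12)
    counts <- counts + graphics::hist(z, breaks = breaks, plot = FALSE)$counts
  }
  counts <- counts / nf
  area <- mean(traj$box[, 1] * traj$box[, 2])
  structure(list(bin_centers = (breaks[-1] + breaks[-length(breaks)]) / 2,
                 density = counts / (bin_width * area),
                 bin_width = bin_width, area = area,
                 n_mean = sum(counts)),
            class = "density_profile")
}

#' Write a density profile as TSV
#' @param profile a `density_profile`.
#' @param path output path.
#' @export
write_density_profile <- function(profile, path) {
  utils::write.table(data.frame(z_nm = profile$bin_centers,
                                density_nm3 = profile$density),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Bilayer thickness from a phosphate density profile
#'
#' The leaflets are the two sides of the midplane (z = 0).  Thickness
#' is the distance between the density-weighted mean z of the upper
#' and lower leaflets; the peak-to-peak distance is also reported.
#'
#' @param profile a `density_profile` of the phosphate groups.
#' @return list with `thickness` (nm) and `peak_to_peak` (nm).
#' @export
bilayer_thickness <- function(profile) {
  z <- profile$bin_centers
  d <- profile$density
  up <- z > 0 & d > 0
  lo <- z < 0 & d > 0
  if (!any(up) || !any(lo)) stop("no bilayer detected")
  mean_up <- sum(z[up] * d[up]) / sum(d[up])
  mean_lo <- sum(z[lo] * d[lo]) / sum(d[lo])
  peak_up <- z[up][which.max(d[up])]
  peak_lo <- z[lo][which.max(d[lo])]
  list(thickness = mean_up - mean_lo, peak_to_peak = peak_up - peak_lo)
}

#' Grid-based area per lipid for one frame
#'
#' Re-implementation of the grid method for membrane-protein systems:
#' each leaflet's lateral plane is covered by an n x n grid; every
#' grid cell is assigned to the laterally nearest reference atom (one
#' phosphorus per lipid, competing with protein heavy atoms lying in
#' the leaflet's phosphate slab), using the xy minimum-image metric.
#' A lipid's area is its number of cells times the cell area, so the
#' per-leaflet areas sum to the lateral box area exactly by
#' construction.
#'
#' @param top a [topology()].
#' @param frame an [mdframe()].
#' @param lipid_spec selection with exactly one reference atom (P) per
#'   lipid.
#' @param protein_spec optional selection of protein heavy atoms that
#'   compete for grid cells.
#' @param grid_n grid dimension per leaflet (>= 10, default 100).
#' @param slab_half_width protein atoms within this distance (nm) of a
#'   leaflet's mean phosphate z compete in that leaflet (default 0.5).
#' @return an `apl_result`: `per_lipid` (named nm^2 vector),
#'   `apl_mean`, `protein_area` (per leaflet), `leaflet` (per lipid),
#'   `grid_n`, `cell_area`, `box_area`.
#' @export
area_per_lipid_grid <- function(top, frame, lipid_spec,
                                protein_spec = NULL, grid_n = 100,
                                slab_half_width = 0.5) {
  if (grid_n < 10) stop("grid_n must be >= 10")
  li <- select_atoms(top, lipid_spec, warn_empty = FALSE)
  if (!length(li)) stop("empty lipid selection")
  pi_ <- if (is.null(protein_spec)) integer(0) else
    select_atoms(top, protein_spec, warn_empty = FALSE)
  pi_ <- pi_[top$element[pi_] != "H"]
  box <- frame$box
  midplane <- mean(frame$coords[li, 3])
  leaflet <- ifelse(frame$coords[li, 3] >= midplane, "upper", "lower")
  cell <- c(box[1] / grid_n, box[2] / grid_n)
  gx <- (seq_len(grid_n) - 0.5) * cell[1]
  gy <- (seq_len(grid_n) - 0.5) * cell[2]
  per_lipid <- numeric(length(li))
  names(per_lipid) <- paste0("res", top$residue_id[li], "_", leaflet)
  protein_area <- c(upper = 0, lower = 0)
  for (side in c("upper", "lower")) {
    sel_l <- which(leaflet == side)
    if (!length(sel_l)) next
    leaf_z <- mean(frame$coords[li[sel_l], 3])
    prot <- pi_[abs(frame$coords[pi_, 3] - leaf_z) <= slab_half_width]
    refs <- rbind(frame$coords[li[sel_l], 1:2, drop = FALSE],
                  frame$coords[prot, 1:2, drop = FALSE])
    # nearest reference for every cell centre, xy minimum image
    dx <- outer(gx, refs[, 1], "-")
    dx <- dx - box[1] * round(dx / box[1])
    dy <- outer(gy, refs[, 2], "-")
    dy <- dy - box[2] * round(dy / box[2])
    best <- matrix(0L, grid_n, grid_n)
    bestd <- matrix(Inf, grid_n, grid_n)
    for (r in seq_len(nrow(refs))) {
      d2 <- outer(dx[, r]^2, dy[, r]^2, "+")
      upd <- d2 < bestd
      best[upd] <- r
      bestd[upd] <- d2[upd]
    }
    tab <- tabulate(best, nbins = nrow(refs))
    areas <- tab * cell[1] * cell[2]
    per_lipid[sel_l] <- areas[seq_along(sel_l)]
    protein_area[side] <- sum(areas[-seq_along(sel_l)])
  }
  zero <- which(per_lipid == 0)
  if (length(zero)) {
    warning(length(zero), " lipid(s) received 0 grid cells")
  }
  structure(list(per_lipid = per_lipid, apl_mean = mean(per_lipid),
                 protein_area = protein_area, leaflet = leaflet,
                 grid_n = grid_n, cell_area = cell[1] * cell[2],
                 box_area = box[1] * box[2]),
            class = "apl_result")
}

#' Trajectory-averaged area per lipid
#'
#' Runs [area_per_lipid_grid()] on each analysed frame and averages
#' the per-frame mean APL.
#'
#' @inheritParams area_per_lipid_grid
#' @param traj an [mdtrajectory()].
#' @param stride analyse every `stride`-th frame (default 1).
#' @return list with `apl_mean` (nm^2) and `per_frame` means.
#' @export
area_per_lipid_traj <- function(traj, lipid_spec, protein_spec = NULL,
                                grid_n = 100, stride = 1) {
  fidx <- seq(1, n_frames(traj), by = stride)
  per_frame <- vapply(fidx, function(f) {
    area_per_lipid_grid(traj$topology, get_frame(traj, f), lipid_spec,
                        protein_spec, grid_n)$apl_mean
  }, numeric(1))
  list(apl_mean = mean(per_frame), per_frame = per_frame, frames = fidx)
}

#' Headgroup PN tilt angles
#'
#' For each lipid the PN vector runs from its phosphorus to its
#' headgroup nitrogen; the tilt is the angle between that vector and
#' the bilayer normal.  Lower-leaflet lipids are measured against the
#' inward normal (-z), so the distribution is leaflet-symmetric.
#' P and N atoms must pair one-to-one by residue id.
#'
#' @param traj an [mdtrajectory()].
#' @param p_spec selection of the phosphorus atoms (one per lipid).
#' @param n_spec selection of the headgroup nitrogen atoms.
#' @return a `tilt_record`: `phi` (frames x lipids matrix, degrees in
#'   [0, 180]), `lipid_type` (per lipid), `residue_id`.
#' @export
pn_tilt <- function(traj, p_spec = sel(role = c("POPC", "POPE"),
                                       atom_name = "P"),
                    n_spec = sel(role = c("POPC", "POPE"),
                                 atom_name = "N")) {
  pidx <- select_atoms(traj$topology, p_spec, warn_empty = FALSE)
  nidx <- select_atoms(traj$topology, n_spec, warn_empty = FALSE)
  pres <- traj$topology$residue_id[pidx]
  nres <- traj$topology$residue_id[nidx]
  if (length(pidx) != length(nidx) || anyDuplicated(pres) ||
      anyDuplicated(nres) || !setequal(pres, nres)) {
    stop("P and N atoms do not pair 1:1 per lipid")
  }
  nidx <- nidx[match(pres, nres)]
  nf <- n_frames(traj)
  nl <- length(pidx)
  phi <- matrix(0, nf, nl)
  for (f in seq_len(nf)) {
    midplane <- mean(traj$coords[pidx, 3, f])
    s <- ifelse(traj$coords[pidx, 3, f] >= midplane, 1, -1)
    v <- frame_coords(traj, nidx, f) -
      frame_coords(traj, pidx, f)
    cosphi <- (v[, 3] * s) / sqrt(rowSums(v^2))
    phi[f, ] <- rad2deg(acos(pmin(1, pmax(-1, cosphi))))
  }
  structure(list(phi = phi,
                 lipid_type = traj$topology$chain_role[pidx],
                 residue_id = pres),
            class = "tilt_record")
}

#' Normalised tilt distribution per lipid type
#'
#' @param record a `tilt_record`.
#' @param breaks histogram breaks in degrees (default 2-degree bins).
#' @return data.frame with `lipid_type`, `phi_mid`, `density`.
#' @export
tilt_distribution <- function(record, breaks = seq(0, 180, by = 2)) {
  out <- lapply(unique(record$lipid_type), function(tp) {
    x <- as.vector(record$phi[, record$lipid_type == tp, drop = FALSE])
    h <- graphics::hist(x, breaks = breaks, plot = FALSE)
    data.frame(lipid_type = tp, phi_mid = h$mids, density = h$density)
  })
  do.call(rbind, out)
}
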