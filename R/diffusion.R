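#' Classify molecules as protein-proximal or free
#'
#' A molecule (grouped by residue id within `group_spec`) is
#' `proximal` if, in at least one analysed frame, any of its atoms
#' lies within `cutoff` of any protein atom ("ever" semantics); the
#' rest are `free`.  A `per_frame` mode returning the frame-wise label
#' matrix is also available.
#'
#' @param traj an [mdtrajectory()].
#' @param group_spec selection of the molecules to classify (e.g.
#'   cholesterol).
#' @param protein_spec selection of the protein atoms.
#' @param cutoff proximity cutoff in nm (default 0.35).
#' @param mode `"ever"` (default) or `"per_frame"`.
#' @return named character vector `proximal`/`free` per residue id;
#'   for `per_frame`, a frames x molecules logical matrix of
#'   within-cutoff status with the summary vector as attribute
#'   `"ever"`.
#' @export
classify_proximal <- function(traj, group_spec, protein_spec,
                              cutoff = 0.35, mode = c("ever", "per_frame")) {
  mode <- match.arg(mode)
  if (cutoff <= 0) stop("cutoff must be > 0")
  gi <- select_atoms(traj$topology, group_spec, warn_empty = FALSE)
  pi_ <- select_atoms(traj$topology, protein_spec, warn_empty = FALSE)
  if (!length(gi) || !length(pi_)) stop("empty selection")
  mol <- split(gi, traj$topology$residue_id[gi])
  nf <- n_frames(traj)
  near <- matrix(FALSE, nf, length(mol),
                 dimnames = list(NULL, names(mol)))
  for (f in seq_len(nf)) {
    prot <- frame_coords(traj, pi_, f)
    box <- traj$box[f, ]
    for (mth in seq_along(mol)) {
      g <- frame_coords(traj, mol[[mth]], f)
      d2min <- Inf
      for (k in seq_len(nrow(g))) {
        dv <- min_image_displacement(prot, g[k, ], box)
        d2min <- min(d2min, min(rowSums(dv^2)))
        if (d2min <= cutoff^2) break
      }
      near[f, mth] <- d2min <= cutoff^2
    }
  }
  ever <- ifelse(apply(near, 2, any), "proximal", "free")
  if (mode == "per_frame") {
    attr(near, "ever") <- ever
    return(near)
  }
  ever
}

#' Lateral (xy) mean-square displacement
#'
#' MSD(lag) averaged over all molecules and all time origins, in the
#' membrane plane only.  Periodic wrapping is removed by mapping each
#' consecutive displacement to its minimum image (valid while
#' per-frame motion stays below half the box).
#'
#' @param traj an [mdtrajectory()] with >= 10 frames.
#' @param ref_spec selection with one reference atom per molecule.
#' @param unwrap remove periodic jumps (default `TRUE`).
#' @param max_lag_frac largest lag as a fraction of the trajectory
#'   length (default 0.5; long lags have few origins).
#' @return an `msd_curve`: `lag_ps`, `msd` (nm^2, `msd[1] = 0` at lag
#'   0), `n_molecules`.
#' @export
lateral_msd <- function(traj, ref_spec, unwrap = TRUE,
                        max_lag_frac = 0.5) {
  idx <- select_atoms(traj$topology, ref_spec, warn_empty = FALSE)
  if (!length(idx)) stop("empty selection")
  nf <- n_frames(traj)
  if (nf < 10) stop("need at least 10 frames for an MSD")
  xy <- traj$coords[idx, 1:2, , drop = FALSE]     # mol x 2 x frames
  if (unwrap) {
    for (f in 2:nf) {
      box <- traj$box[f, ]
      for (k in 1:2) {
        d <- xy[, k, f] - xy[, k, f - 1]
        d <- d - box[k] * round(d / box[k])
        xy[, k, f] <- xy[, k, f - 1] + d
      }
    }
  }
  max_lag <- max(1L, as.integer(floor(nf * max_lag_frac)))
  msd <- numeric(max_lag + 1)
  for (lag in seq_len(max_lag)) {
    d1 <- xy[, 1, (1 + lag):nf, drop = FALSE] - xy[, 1, 1:(nf - lag), drop = FALSE]
    d2 <- xy[, 2, (1 + lag):nf, drop = FALSE] - xy[, 2, 1:(nf - lag), drop = FALSE]
    msd[lag + 1] <- mean(d1^2 + d2^2)
  }
  dt <- if (nf > 1) (traj$times[nf] - traj$times[1]) / (nf - 1) else 1
  structure(list(lag_ps = (0:max_lag) * dt, msd = msd,
                 n_molecules = length(idx)),
            class = "msd_curve")
}

#' Write an MSD curve as TSV
#' @param msd an `msd_curve`.
#' @param path output path.
#' @export
write_msd_curve <- function(msd, path) {
  utils::write.table(data.frame(lag_ps = msd$lag_ps, msd_nm2 = msd$msd),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Fit a lateral diffusion coefficient (2-D Einstein relation)
#'
#' Least-squares line through the MSD curve over the fit window; the
#' diffusion coefficient is `slope / 4` (two lateral dimensions),
#' converted from nm^2/ps to cm^2/s via [NM2_PER_PS_TO_CM2_PER_S].
#' The default window, 10--50% of the maximum lag, excludes the
#' short-lag ballistic/noise regime and the poorly sampled long-lag
#' tail.
#'
#' @param msd an `msd_curve`.
#' @param window fit window as fractions of the maximum lag
#'   (default `c(0.1, 0.5)`).
#' @return a `diffusion_estimate`: `D` (cm^2 s^-1), `slope`
#'   (nm^2 ps^-1), `r2`, `window_ps`, `negative_slope` flag.
#' @export
fit_diffusion <- function(msd, window = c(0.1, 0.5)) {
  stopifnot(length(window) == 2, window[1] < window[2], window[1] >= 0)
  lag <- msd$lag_ps
  lo <- window[1] * max(lag); hi <- window[2] * max(lag)
  keep <- lag >= lo & lag <= hi
  if (sum(keep) < 2) stop("fit window contains fewer than 2 lags")
  fit <- stats::lm(y ~ x, data = data.frame(x = lag[keep],
                                            y = msd$msd[keep]))
  slope <- unname(stats::coef(fit)[2])
  ss_tot <- sum((msd$msd[keep] - mean(msd$msd[keep]))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - sum(stats::residuals(fit)^2) / ss_tot
  neg <- slope < 0
  if (neg) warning("negative MSD slope; diffusion estimate is unreliable")
  structure(list(D = slope / 4 * NM2_PER_PS_TO_CM2_PER_S, slope = slope,
                 r2 = r2, window_ps = c(lo, hi), negative_slope = neg),
            class = "diffusion_estimate")
}

#' @export
print.diffusion_estimate <- function(x, ...) {
  cat(sprintf("diffusion_estimate: D = %.3g cm^2/s (r^2 = %.3f%s)\n",
              x$D, x$r2,
              if (x$negative_slope) ", negative slope" else ""))
  invisible(x)
}
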