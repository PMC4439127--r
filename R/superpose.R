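#' Kabsch superposition of two point sets
#'
#' Finds the proper rotation and translation minimising the (optionally
#' weighted) RMSD between `mobile` and `reference`.  The rotation is
#' obtained from the SVD of the weighted cross-covariance matrix with
#' the usual determinant correction, so reflections are never returned.
#'
#' @param mobile,reference N x 3 matrices (N >= 3, not all collinear).
#' @param weights optional non-negative per-point weights (default
#'   uniform; superposition of trajectory frames uses uniform weights).
#' @return list with `rotation` (3 x 3, det +1), `translation`
#'   (length 3), `transformed` (mobile after the fit, closest to
#'   reference) and `rmsd` (post-fit weighted RMSD, nm).  The transform
#'   acts on row vectors: `y = x %*% rotation + translation`.
#' @export
kabsch_superpose <- function(mobile, reference, weights = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  n <- nrow(mobile)
  if (n != nrow(reference)) stop("point counts differ")
  if (n < 3) stop("need at least 3 points for superposition")
  w <- if (is.null(weights)) rep(1, n) else as.numeric(weights)
  if (length(w) != n || any(w < 0) || sum(w) == 0) {
    stop("invalid weights")
  }
  w <- w / sum(w)
  cm_m <- colSums(mobile * w)
  cm_r <- colSums(reference * w)
  P <- sweep(mobile, 2, cm_m)
  Q <- sweep(reference, 2, cm_r)
  # degenerate (collinear) sets leave the rotation about the line free
  sv_p <- svd(P * sqrt(w))$d
  if (sv_p[2] < 1e-10 * max(sv_p[1], 1e-300)) {
    stop("degenerate (collinear) point configuration")
  }
  H <- crossprod(P * w, Q)          # 3 x 3 cross-covariance
  s <- svd(H)
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  transformed <- P %*% R
  transformed <- sweep(transformed, 2, cm_r, "+")
  dev2 <- rowSums((transformed - reference)^2)
  list(rotation = R, translation = as.numeric(cm_r - cm_m %*% R),
       transformed = transformed, rmsd = sqrt(sum(w * dev2)))
}

#' Root-mean-square deviation between two point sets
#'
#' @param a,b N x 3 coordinate matrices, nm.
#' @param superpose if `TRUE`, fit `a` onto `b` by [kabsch_superpose()]
#'   first.
#' @param weights optional per-point weights.
#' @return RMSD in nm.
#' @export
rmsd <- function(a, b, superpose = FALSE, weights = NULL) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (nrow(a) != nrow(b)) stop("point counts differ")
  if (superpose) return(kabsch_superpose(a, b, weights)$rmsd)
  w <- if (is.null(weights)) rep(1, nrow(a)) else weights
  w <- w / sum(w)
  sqrt(sum(w * rowSums((a - b)^2)))
}

#' All-to-all RMSD matrix over a trajectory
#'
#' Entry (i, j) is the superposed RMSD between the selected atoms of
#' frames i and j; the diagonal is exactly zero and the matrix exactly
#' symmetric.  The block structure of this matrix is the basis of the
#' convergence diagnosis (see [diagnose_convergence()]).
#'
#' @param traj an [mdtrajectory()].
#' @param spec atom selection (e.g. C-alpha atoms); must be non-empty.
#' @param stride analyse every `stride`-th stored frame (default 10,
#'   bounding the quadratic cost; recorded in the result).
#' @return an `rmsd_matrix` object: `values` (symmetric matrix, nm),
#'   `frame_times` (ps), `frame_index`, `stride`, `selection`.
#' @export
pairwise_rmsd_matrix <- function(traj, spec, stride = 10) {
  idx <- select_atoms(traj$topology, spec, warn_empty = FALSE)
  if (!length(idx)) stop("selection resolved to 0 atoms")
  fidx <- seq(1, n_frames(traj), by = max(1L, as.integer(stride)))
  nf <- length(fidx)
  sets <- lapply(fidx, function(i) frame_coords(traj, idx, i))
  m <- matrix(0, nf, nf)
  for (i in seq_len(nf - 1)) {
    for (j in (i + 1):nf) {
      m[i, j] <- m[j, i] <- kabsch_superpose(sets[[j]], sets[[i]])$rmsd
    }
  }
  structure(list(values = m, frame_times = traj$times[fidx],
                 frame_index = fidx, stride = stride, selection = spec),
            class = "rmsd_matrix")
}

#' Export an RMSD matrix as TSV
#'
#' One-line header carries the frame times (ps); values are in nm.
#'
#' @param m an `rmsd_matrix`.
#' @param path output path.
#' @export
write_rmsd_matrix <- function(m, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("time_ps", sprintf("%g", m$frame_times)),
                   collapse = "\t"), con)
  for (i in seq_len(nrow(m$values))) {
    writeLines(paste(c(sprintf("%g", m$frame_times[i]),
                       sprintf("%.6f", m$values[i, ])), collapse = "\t"), con)
  }
  invisible(path)
}

#' Diagnose trajectory convergence from an all-to-all RMSD matrix
#'
#' Frames are binarised as mutually "similar" (RMSD <= `cutoff`) and
#' the frame range split at the boundary that maximises within-block
#' similarity.  The verdicts follow the block-structure reading of such
#' matrices: an early->late transition with essentially no cross-block
#' similarity and no late frame ever returning near the early block is
#' an `irreversible_transition`; at least one frame that leaves the
#' early conformational neighbourhood and later returns to it is a
#' `leave_and_return` (the converged-alike signature); anything else —
#' including the degenerate all-similar matrix, where nothing was ever
#' left — is `undetermined`.
#'
#' @param m an `rmsd_matrix` with at least 10 frames.
#' @param cutoff similarity cutoff in nm (default 0.2 nm for C-alpha
#'   RMSD; a declared convention of this package).
#' @param overlap_max cross-block similarity fraction below which a
#'   clean two-block split counts as a transition (default 0.05).
#' @return a `convergence_report`: `verdict`, `block_boundaries`
#'   (index of the last early-block frame), `block_overlap_score`
#'   (fraction of cross-block pairs within cutoff).
#' @export
diagnose_convergence <- function(m, cutoff = 0.2, overlap_max = 0.05) {
  stopifnot(inherits(m, "rmsd_matrix"))
  if (cutoff <= 0) stop("cutoff must be > 0")
  S <- m$values <= cutoff
  nf <- nrow(S)
  if (nf < 10) stop("need at least 10 frames to diagnose convergence")
  # optimal 2-segmentation: maximise the fraction of similar pairs
  # within the two contiguous blocks; ties resolved to the earliest
  # boundary so that an A..B..A excursion keeps block A minimal
  within_frac <- function(b) {
    i1 <- 1:b; i2 <- (b + 1):nf
    p1 <- sum(S[i1, i1, drop = FALSE]) - b          # off-diagonal trues
    p2 <- sum(S[i2, i2, drop = FALSE]) - (nf - b)
    n1 <- b * (b - 1); n2 <- (nf - b) * (nf - b - 1)
    if (n1 + n2 == 0) return(0)
    (p1 + p2) / (n1 + n2)
  }
  scores <- vapply(1:(nf - 1), within_frac, numeric(1))
  b <- which.max(scores)                            # first maximum
  early <- 1:b; late <- (b + 1):nf
  cross <- S[early, late, drop = FALSE]
  overlap <- mean(cross)
  # per-frame: is the frame within cutoff of any early-block frame?
  near_early <- apply(S[, early, drop = FALSE], 1, any)
  excursion <- which(!near_early)
  returns <- if (length(excursion)) {
    which(near_early & seq_len(nf) > min(excursion))
  } else integer(0)
  verdict <- if (!length(excursion)) {
    "undetermined"                                  # nothing was left
  } else if (length(returns) >= 1) {
    "leave_and_return"
  } else if (overlap < overlap_max) {
    "irreversible_transition"
  } else "undetermined"
  structure(list(verdict = verdict, block_boundaries = b,
                 block_overlap_score = overlap, cutoff = cutoff,
                 n_frames = nf),
            class = "convergence_report")
}

#' @export
print.convergence_report <- function(x, ...) {
  cat(sprintf(paste0("convergence_report: %s (boundary after frame %d,",
                     " cross-block overlap %.3f, cutoff %.2f nm)\n"),
              x$verdict, x$block_boundaries, x$block_overlap_score,
              x$cutoff))
  invisible(x)
}

#' Write a convergence report as JSON
#' @param report a `convergence_report`.
#' @param path output path.
#' @export
write_convergence_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Per-atom root-mean-square fluctuation
#'
#' All frames are superposed on the running mean structure of the
#' alignment selection (two fixed-point iterations, which converges to
#' numerical noise for equilibrated ensembles); the per-atom RMS
#' deviation of the measured selection about its mean in that common
#' frame is returned.  By default the measured atoms also define the
#' alignment; passing a rigid `align_spec` (e.g. a stable core)
#' measures fluctuation relative to that core.
#'
#' @param traj an [mdtrajectory()] with >= 2 frames.
#' @param spec atom selection whose fluctuations are measured.
#' @param align_spec selection the frames are superposed on (default:
#'   `spec`).
#' @return numeric vector of per-atom RMSF values (nm), one per
#'   selected atom.
#' @export
rmsf <- function(traj, spec, align_spec = spec) {
  idx <- select_atoms(traj$topology, spec, warn_empty = FALSE)
  aidx <- select_atoms(traj$topology, align_spec, warn_empty = FALSE)
  if (!length(idx) || !length(aidx)) stop("selection resolved to 0 atoms")
  nf <- n_frames(traj)
  if (nf < 2) stop("need at least 2 frames for RMSF")
  asets <- lapply(seq_len(nf), function(i) frame_coords(traj, aidx, i))
  ref <- asets[[1]]
  fits <- NULL
  for (iter in 1:2) {
    fits <- lapply(asets, function(x) kabsch_superpose(x, ref))
    ref <- Reduce(`+`, lapply(fits, `[[`, "transformed")) / nf
  }
  moved <- lapply(seq_len(nf), function(i) {
    sweep(frame_coords(traj, idx, i) %*% fits[[i]]$rotation, 2,
          fits[[i]]$translation, "+")
  })
  xbar <- Reduce(`+`, moved) / nf
  dev2 <- Reduce(`+`, lapply(moved, function(x) rowSums((x - xbar)^2))) / nf
  sqrt(dev2)
}
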