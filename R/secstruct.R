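#' Simplified per-residue helicity timeline
#'
#' A geometric stand-in for secondary-structure assignment on
#' C-alpha-only models: residue i satisfies the alpha-helix signature
#' when the Calpha(i) -- Calpha(i+4) distance lies in [0.50, 0.65] nm;
#' residues covered by a run of at least 3 consecutive satisfying
#' windows are labelled helix, all others coil.  States are defined
#' for residues 3..N-2 only (window edges are coil).  Consecutive
#' C-alpha distances above 0.45 nm are treated as chain breaks: the
#' flanking residues are forced coil and a warning is raised.
#'
#' @param traj an [mdtrajectory()] of C-alpha positions.
#' @param ca_spec selection of the consecutive C-alpha atoms.
#' @return a `helicity_timeline`: `states` (frames x residues
#'   character matrix, `"helix"`/`"coil"`), `helix_fraction` (per
#'   frame, over the defined residues 3..N-2), `defined` (logical per
#'   residue).
#' @export
assign_helicity <- function(traj, ca_spec) {
  idx <- select_atoms(traj$topology, ca_spec, warn_empty = FALSE)
  n <- length(idx)
  if (n < 7) stop("need at least 7 consecutive C-alpha atoms")
  nf <- n_frames(traj)
  states <- matrix("coil", nf, n)
  broke <- FALSE
  for (f in seq_len(nf)) {
    xyz <- frame_coords(traj, idx, f)
    d1 <- sqrt(rowSums((xyz[-1, , drop = FALSE] -
                        xyz[-n, , drop = FALSE])^2))
    breaks <- which(d1 > 0.45)
    d4 <- sqrt(rowSums((xyz[5:n, , drop = FALSE] -
                        xyz[1:(n - 4), , drop = FALSE])^2))
    crit <- d4 >= 0.50 & d4 <= 0.65
    # windows spanning a chain break are invalid
    for (b in breaks) crit[max(1, b - 3):min(length(crit), b)] <- FALSE
    r <- rle(crit)
    pos <- 1L
    for (seg in seq_along(r$lengths)) {
      if (r$values[seg] && r$lengths[seg] >= 3) {
        states[f, pos:(pos + r$lengths[seg] - 1 + 4)] <- "helix"
      }
      pos <- pos + r$lengths[seg]
    }
    if (length(breaks)) {
      broke <- TRUE
      states[f, unique(c(breaks, breaks + 1))] <- "coil"
    }
    states[f, c(1, 2, n - 1, n)] <- "coil"
  }
  if (broke) warning("chain break(s) detected; flanking residues set to coil")
  defined <- seq_len(n) %in% 3:(n - 2)
  helix_fraction <- rowMeans(states[, defined, drop = FALSE] == "helix")
  structure(list(states = states, helix_fraction = helix_fraction,
                 defined = defined),
            class = "helicity_timeline")
}

#' Write a helicity timeline as TSV
#'
#' Long-format per-residue states plus a per-frame helix-fraction
#' table.
#'
#' @param timeline a `helicity_timeline`.
#' @param states_path,fraction_path output paths (either may be
#'   `NULL`).
#' @export
write_helicity_timeline <- function(timeline, states_path = NULL,
                                    fraction_path = NULL) {
  if (!is.null(states_path)) {
    nf <- nrow(timeline$states); n <- ncol(timeline$states)
    df <- data.frame(frame = rep(seq_len(nf), each = n),
                     residue = rep(seq_len(n), nf),
                     state = as.vector(t(timeline$states)))
    utils::write.table(df, states_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(fraction_path)) {
    utils::write.table(
      data.frame(frame = seq_along(timeline$helix_fraction),
                 helix_fraction = timeline$helix_fraction),
      fraction_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(timeline)
}
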