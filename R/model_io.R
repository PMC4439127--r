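#' Chain-role mapping from residue names
#'
#' Every atom in a topology is assigned a chain role (protein, POPC,
#' POPE, CHOL, water, ligand or ion) from its residue name through an
#' editable mapping table.  Unknown residue names are an error: silent
#' misclassification would corrupt every downstream metric, so the map
#' must be extended explicitly via the `extra` argument.
#'
#' @param extra named character vector of additional residue-name ->
#'   role entries, e.g. `c(DPPC = "POPC")`.
#' @return named character vector mapping residue names to roles.
#' @export
default_role_map <- function(extra = NULL) {
  aa <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL")
  map <- c(
    stats::setNames(rep("protein", length(aa)), aa),
    POPC = "POPC", POPE = "POPE",
    CHL1 = "CHOL", CHOL = "CHOL",
    SOL = "water", HOH = "water", TIP3 = "water", WAT = "water",
    CFF = "ligand", LIG = "ligand",
    "NA" = "ion", CL = "ion", "NA+" = "ion", "CL-" = "ion", ION = "ion"
  )
  if (!is.null(extra)) map[names(extra)] <- extra
  map
}

CHAIN_ROLES <- c("protein", "POPC", "POPE", "CHOL", "water", "ligand", "ion")

#' Construct a molecular topology
#'
#' A topology is an ordered table of atom records: atom name, residue
#' name, 1-based residue id (as in the source file), chain role and
#' element symbol.  Atom order is significant and preserved by all I/O.
#'
#' @param atom_name character vector of atom names.
#' @param residue_name character vector of residue names.
#' @param residue_id integer vector of residue ids (>= 1).
#' @param element element symbols; if `NULL`, guessed as the first
#'   alphabetic character of the atom name.
#' @param role_map residue-name -> chain-role map
#'   (see [default_role_map()]).
#' @return a `topology` object (a data.frame).
#' @export
topology <- function(atom_name, residue_name, residue_id, element = NULL,
                     role_map = default_role_map()) {
  n <- length(atom_name)
  stopifnot(length(residue_name) == n, length(residue_id) == n)
  residue_id <- as.integer(residue_id)
  if (any(residue_id < 1L)) stop("residue_id must be >= 1")
  if (is.null(element)) {
    element <- toupper(substr(gsub("[^A-Za-z].*$", "", atom_name), 1, 1))
  }
  role <- unname(role_map[residue_name])
  if (anyNA(role)) {
    bad <- unique(residue_name[is.na(role)])
    stop("unknown residue name(s) with no chain-role mapping: ",
         paste(bad, collapse = ", "),
         "; extend the role map via default_role_map(extra = ...)")
  }
  top <- data.frame(
    atom_name = as.character(atom_name),
    residue_name = as.character(residue_name),
    residue_id = residue_id,
    chain_role = role,
    element = as.character(element),
    stringsAsFactors = FALSE
  )
  class(top) <- c("topology", "data.frame")
  top
}

#' @export
print.topology <- function(x, ...) {
  cat(sprintf("topology: %d atoms, %d residues, roles: %s\n",
              nrow(x), length(unique(x$residue_id)),
              paste(sort(unique(x$chain_role)), collapse = ", ")))
  invisible(x)
}

#' Construct a single coordinate frame
#'
#' @param coords N x 3 numeric matrix of coordinates in nm.
#' @param box numeric length-3 orthorhombic box vector in nm
#'   (z is the bilayer normal by convention).
#' @param time frame time in ps.
#' @return an `mdframe` object.
#' @export
mdframe <- function(coords, box, time = 0) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3) stop("coords must be an N x 3 matrix")
  box <- as.numeric(box)
  if (length(box) != 3 || any(!is.finite(box)) || any(box <= 0)) {
    stop("box must be 3 positive lengths (orthorhombic, nm)")
  }
  structure(list(coords = unname(coords), box = box, time = as.numeric(time)),
            class = "mdframe")
}

#' Construct a trajectory
#'
#' A trajectory is one topology shared by an ordered series of frames.
#' Coordinates are stored as an N x 3 x F array; each frame carries its
#' own box and time stamp; times must be strictly increasing.
#'
#' @param top a [topology()].
#' @param frames list of [mdframe()] objects with matching atom counts.
#' @return an `mdtrajectory` object.
#' @export
mdtrajectory <- function(top, frames) {
  stopifnot(inherits(top, "topology"), length(frames) >= 1)
  n <- nrow(top)
  for (i in seq_along(frames)) {
    if (nrow(frames[[i]]$coords) != n) {
      stop("frame ", i, " has ", nrow(frames[[i]]$coords),
           " atoms; topology has ", n)
    }
  }
  times <- vapply(frames, function(f) f$time, numeric(1))
  if (length(times) > 1 && any(diff(times) <= 0)) {
    stop("frame times must be strictly increasing")
  }
  coords <- array(0, dim = c(n, 3, length(frames)))
  boxes <- matrix(0, length(frames), 3)
  for (i in seq_along(frames)) {
    coords[, , i] <- frames[[i]]$coords
    boxes[i, ] <- frames[[i]]$box
  }
  structure(list(topology = top, coords = coords, box = boxes, times = times),
            class = "mdtrajectory")
}

#' Number of frames in a trajectory
#' @param traj an `mdtrajectory`.
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' Extract one frame from a trajectory
#' @param traj an `mdtrajectory`.
#' @param i frame index.
#' @return an [mdframe()].
#' @export
get_frame <- function(traj, i) {
  mdframe(matrix(traj$coords[, , i], ncol = 3), traj$box[i, ],
          traj$times[i])
}

#' Extract selected atom coordinates of one frame as an N x 3 matrix
#'
#' @param traj an `mdtrajectory`.
#' @param idx atom indices.
#' @param f frame index.
#' @return N x 3 coordinate matrix (nm).
#' @export
frame_coords <- function(traj, idx, f) {
  matrix(traj$coords[idx, , f], ncol = 3)
}

#' Restrict a trajectory to a subset of frames
#' @param traj an `mdtrajectory`.
#' @param idx increasing frame indices to keep.
#' @export
subset_frames <- function(traj, idx) {
  idx <- as.integer(idx)
  stopifnot(all(idx >= 1), all(idx <= n_frames(traj)), !is.unsorted(idx, strictly = TRUE))
  structure(list(topology = traj$topology,
                 coords = traj$coords[, , idx, drop = FALSE],
                 box = traj$box[idx, , drop = FALSE],
                 times = traj$times[idx]),
            class = "mdtrajectory")
}

#' Keep only the trailing fraction of a trajectory
#'
#' Analyses of equilibrated properties are routinely restricted to the
#' tail of a run (e.g. the last half); this returns the last
#' `fraction` of the frames.
#'
#' @param traj an `mdtrajectory`.
#' @param fraction fraction of frames to keep, in (0, 1].
#' @export
last_fraction_window <- function(traj, fraction = 0.5) {
  stopifnot(fraction > 0, fraction <= 1)
  f <- n_frames(traj)
  start <- f - max(1L, as.integer(ceiling(f * fraction))) + 1L
  subset_frames(traj, start:f)
}

#' @export
print.mdtrajectory <- function(x, ...) {
  cat(sprintf("mdtrajectory: %d atoms x %d frames, t = %g..%g ps\n",
              dim(x$coords)[1], n_frames(x), x$times[1],
              x$times[n_frames(x)]))
  invisible(x)
}

## ---------------------------------------------------------------------
## Fixed-column structure formats (PDB Angstrom / GRO nm)
## ---------------------------------------------------------------------

.fmt_from_path <- function(path) {
  ext <- toupper(tools::file_ext(path))
  if (ext %in% c("PDB", "GRO")) ext else
    stop("cannot guess format from extension: ", path)
}

.parse_gro_block <- function(lines, offset, role_map) {
  # lines: title, natoms, atom lines, box line; offset = absolute line
  # number of the title line (for error messages)
  if (length(lines) < 3) stop("truncated GRO block at line ", offset)
  natoms <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(natoms)) stop("malformed GRO atom count at line ", offset + 1)
  if (length(lines) < natoms + 3) {
    stop("GRO block starting at line ", offset, " declares ", natoms,
         " atoms but the file is truncated")
  }
  al <- lines[3:(natoms + 2)]
  resid <- suppressWarnings(as.integer(substr(al, 1, 5)))
  resname <- trimws(substr(al, 6, 10))
  aname <- trimws(substr(al, 11, 15))
  x <- suppressWarnings(as.numeric(substr(al, 21, 28)))
  y <- suppressWarnings(as.numeric(substr(al, 29, 36)))
  z <- suppressWarnings(as.numeric(substr(al, 37, 44)))
  bad <- which(is.na(resid) | is.na(x) | is.na(y) | is.na(z))
  if (length(bad)) {
    stop("malformed GRO atom record at line ", offset + 2 + bad[1] - 1)
  }
  box <- suppressWarnings(as.numeric(strsplit(trimws(lines[natoms + 3]),
                                              "\\s+")[[1]]))
  if (length(box) < 3 || anyNA(box[1:3])) {
    stop("missing or malformed GRO box line at line ", offset + natoms + 2)
  }
  tm <- regmatches(lines[1], regexpr("t=\\s*[-0-9.eE+]+", lines[1]))
  time <- if (length(tm)) as.numeric(sub("t=\\s*", "", tm)) else NA_real_
  list(top = topology(aname, resname, resid, role_map = role_map),
       frame = mdframe(cbind(x, y, z), box[1:3],
                       time = if (is.na(time)) 0 else time),
       time_present = !is.na(time),
       nlines = natoms + 3)
}

.parse_pdb_atoms <- function(lines, lineno, role_map) {
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  al <- lines[is_atom]
  ln <- lineno[is_atom]
  if (!length(al)) stop("no ATOM/HETATM records found")
  aname <- trimws(substr(al, 13, 16))
  resname <- trimws(substr(al, 18, 21))
  resid <- suppressWarnings(as.integer(substr(al, 23, 26)))
  x <- suppressWarnings(as.numeric(substr(al, 31, 38)))
  y <- suppressWarnings(as.numeric(substr(al, 39, 46)))
  z <- suppressWarnings(as.numeric(substr(al, 47, 54)))
  elem <- trimws(substr(al, 77, 78))
  bad <- which(is.na(resid) | is.na(x) | is.na(y) | is.na(z))
  if (length(bad)) stop("malformed PDB record at line ", ln[bad[1]])
  elem[elem == ""] <- NA
  element <- ifelse(is.na(elem),
                    toupper(substr(gsub("[^A-Za-z].*$", "", aname), 1, 1)),
                    toupper(elem))
  list(top = topology(aname, resname, resid, element = element,
                      role_map = role_map),
       coords = cbind(x, y, z) / ANGSTROM_PER_NM)
}

.parse_cryst1 <- function(lines) {
  i <- grep("^CRYST1", lines)
  if (!length(i)) stop("missing box: no CRYST1 record (box is required)")
  l <- lines[i[1]]
  box <- suppressWarnings(as.numeric(c(substr(l, 7, 15), substr(l, 16, 24),
                                       substr(l, 25, 33))))
  if (anyNA(box)) stop("malformed CRYST1 record at line ", i[1])
  box / ANGSTROM_PER_NM
}

#' Read a single-frame structure file
#'
#' Supports standard PDB (`ATOM`/`HETATM`/`CRYST1`; coordinates in
#' Angstrom, converted to nm) and GRO (fixed-column, nm, trailing box
#' line).  The box is required in both formats; atom order is
#' preserved.
#'
#' @param path path to a `.pdb` or `.gro` file.
#' @param format `"PDB"`, `"GRO"`, or `NULL` to guess from the
#'   extension.
#' @param role_map residue-name -> chain-role map.
#' @return `list(topology = , frame = )`.
#' @export
read_structure <- function(path, format = NULL,
                           role_map = default_role_map()) {
  if (!file.exists(path)) stop("file not found: ", path)
  format <- if (is.null(format)) .fmt_from_path(path) else toupper(format)
  lines <- readLines(path, warn = FALSE)
  if (format == "GRO") {
    b <- .parse_gro_block(lines, 1L, role_map)
    return(list(topology = b$top, frame = b$frame))
  }
  if (format == "PDB") {
    box <- .parse_cryst1(lines)
    p <- .parse_pdb_atoms(lines, seq_along(lines), role_map)
    return(list(topology = p$top, frame = mdframe(p$coords, box)))
  }
  stop("unsupported format: ", format)
}

#' Write a single-frame structure file
#'
#' @param top a [topology()].
#' @param frame an [mdframe()].
#' @param path output path.
#' @param format `"PDB"`, `"GRO"`, or `NULL` to guess from extension.
#' @export
write_structure <- function(top, frame, path, format = NULL) {
  format <- if (is.null(format)) .fmt_from_path(path) else toupper(format)
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "GRO") {
    .write_gro_block(con, top, frame)
  } else if (format == "PDB") {
    writeLines(.fmt_cryst1(frame$box), con)
    writeLines(.fmt_pdb_atoms(top, frame$coords), con)
    writeLines("END", con)
  } else stop("unsupported format: ", format)
  invisible(path)
}

.write_gro_block <- function(con, top, frame) {
  writeLines(sprintf("memtraj frame t= %.3f", frame$time), con)
  writeLines(sprintf("%5d", nrow(top)), con)
  writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                     top$residue_id %% 100000L,
                     substr(top$residue_name, 1, 5),
                     substr(top$atom_name, 1, 5),
                     seq_len(nrow(top)) %% 100000L,
                     frame$coords[, 1], frame$coords[, 2],
                     frame$coords[, 3]), con)
  writeLines(sprintf("%10.5f%10.5f%10.5f", frame$box[1], frame$box[2],
                     frame$box[3]), con)
}

.fmt_cryst1 <- function(box) {
  sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
          box[1] * ANGSTROM_PER_NM, box[2] * ANGSTROM_PER_NM,
          box[3] * ANGSTROM_PER_NM, 90, 90, 90)
}

.fmt_pdb_atoms <- function(top, coords) {
  ang <- coords * ANGSTROM_PER_NM
  name4 <- ifelse(nchar(top$atom_name) < 4, paste0(" ", top$atom_name),
                  top$atom_name)
  sprintf("ATOM  %5d %-4s %-4s %4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
          seq_len(nrow(top)) %% 100000L, substr(name4, 1, 4),
          substr(top$residue_name, 1, 4), top$residue_id %% 10000L,
          ang[, 1], ang[, 2], ang[, 3], substr(top$element, 1, 2))
}

#' Read a multi-frame trajectory file
#'
#' Multi-model PDB (frames delimited by `MODEL`/`ENDMDL`) and
#' concatenated GRO blocks are supported natively; additional formats
#' can be plugged in with [register_trajectory_reader()].  Every model
#' must have the same atom count and order.  Frame times are taken from
#' the file when present (GRO `t=` title field), otherwise assigned as
#' `(index - 1) * frame_stride`.
#'
#' @param path trajectory file.
#' @param format `"PDB"`, `"GRO"`, a registered format name, or `NULL`
#'   to guess from the extension.
#' @param frame_stride time between frames in ps, used when the file
#'   carries no times (default 20 ps).
#' @param role_map residue-name -> chain-role map.
#' @return an [mdtrajectory()].
#' @export
read_trajectory <- function(path, format = NULL, frame_stride = 20,
                            role_map = default_role_map()) {
  if (!file.exists(path)) stop("file not found: ", path)
  format <- if (is.null(format)) .fmt_from_path(path) else toupper(format)
  if (!format %in% c("PDB", "GRO")) {
    reader <- .traj_readers[[format]]
    if (is.null(reader)) stop("no reader registered for format: ", format)
    return(reader(path, frame_stride = frame_stride, role_map = role_map))
  }
  lines <- readLines(path, warn = FALSE)
  frames <- list()
  top <- NULL
  if (format == "GRO") {
    off <- 1L
    any_time <- FALSE
    while (off <= length(lines) && nzchar(trimws(paste(lines[off], "")))) {
      b <- .parse_gro_block(lines[off:length(lines)], off, role_map)
      if (is.null(top)) top <- b$top
      else if (nrow(b$top) != nrow(top)) {
        stop("atom-count mismatch in model ", length(frames) + 1L,
             ": ", nrow(b$top), " vs ", nrow(top))
      }
      any_time <- any_time || b$time_present
      frames[[length(frames) + 1L]] <- b$frame
      off <- off + b$nlines
      while (off <= length(lines) && !nzchar(trimws(lines[off]))) off <- off + 1L
    }
    if (!any_time) {
      for (i in seq_along(frames)) frames[[i]]$time <- (i - 1) * frame_stride
    }
  } else {
    box <- .parse_cryst1(lines)
    starts <- grep("^MODEL", lines)
    ends <- grep("^ENDMDL", lines)
    if (!length(starts)) { # single implicit model
      p <- .parse_pdb_atoms(lines, seq_along(lines), role_map)
      top <- p$top
      frames[[1]] <- mdframe(p$coords, box, 0)
    } else {
      if (length(starts) != length(ends)) {
        stop("unbalanced MODEL/ENDMDL records")
      }
      for (m in seq_along(starts)) {
        idx <- (starts[m] + 1L):(ends[m] - 1L)
        p <- .parse_pdb_atoms(lines[idx], idx, role_map)
        if (is.null(top)) top <- p$top
        else if (nrow(p$top) != nrow(top)) {
          stop("atom-count mismatch in model ", m, ": ", nrow(p$top),
               " vs ", nrow(top))
        }
        frames[[m]] <- mdframe(p$coords, box, (m - 1) * frame_stride)
      }
    }
  }
  if (!length(frames)) stop("no frames found in ", path)
  mdtrajectory(top, frames)
}

#' Write a trajectory file
#'
#' @param traj an [mdtrajectory()].
#' @param path output path.
#' @param format `"PDB"` (multi-model) or `"GRO"` (concatenated
#'   blocks); `NULL` guesses from the extension.
#' @export
write_trajectory <- function(traj, path, format = NULL) {
  format <- if (is.null(format)) .fmt_from_path(path) else toupper(format)
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "GRO") {
    for (i in seq_len(n_frames(traj))) {
      .write_gro_block(con, traj$topology, get_frame(traj, i))
    }
  } else if (format == "PDB") {
    writeLines(.fmt_cryst1(traj$box[1, ]), con)
    for (i in seq_len(n_frames(traj))) {
      writeLines(sprintf("MODEL     %4d", i), con)
      writeLines(.fmt_pdb_atoms(traj$topology, traj$coords[, , i]), con)
      writeLines("ENDMDL", con)
    }
    writeLines("END", con)
  } else stop("unsupported format: ", format)
  invisible(path)
}

## plug-in point for external trajectory backends (e.g. an XTC reader)
.traj_readers <- new.env(parent = emptyenv())

#' Register an external trajectory reader
#'
#' Plug-in point for compressed-trajectory backends.  The reader must
#' accept `(path, frame_stride, role_map)` and return an
#' [mdtrajectory()].  For example, a reader for the XTC format backed
#' by an external parser can be registered under `"XTC"` without making
#' it a package dependency.
#'
#' @param format format name (case-insensitive).
#' @param reader function `(path, frame_stride, role_map) -> mdtrajectory`.
#' @export
register_trajectory_reader <- function(format, reader) {
  stopifnot(is.function(reader))
  assign(toupper(format), reader, envir = .traj_readers)
  invisible(format)
}
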