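#' Build an atom-selection specification
#'
#' A selection spec is a conjunction of predicates over atom records:
#' chain role(s), residue-id range(s), residue name(s) and atom
#' name(s).  `sel(role = "protein", atom_name = "CA", residue_id = 5:34)`
#' reads "C-alpha atoms of protein residues 5-34".  Specs resolve to a
#' deterministic, source-order index list.
#'
#' @param role chain role(s) to keep (see [default_role_map()]).
#' @param residue_id residue ids to keep (vector; ranges via `a:b`).
#' @param residue_name residue name(s) to keep.
#' @param atom_name atom name(s) to keep.
#' @param invert if `TRUE`, select the complement.
#' @return a `selection_spec` object.
#' @export
sel <- function(role = NULL, residue_id = NULL, residue_name = NULL,
                atom_name = NULL, invert = FALSE) {
  structure(list(role = role, residue_id = residue_id,
                 residue_name = residue_name, atom_name = atom_name,
                 invert = isTRUE(invert)),
            class = "selection_spec")
}

#' @export
print.selection_spec <- function(x, ...) {
  parts <- c(
    if (!is.null(x$role)) paste0("role=", paste(x$role, collapse = "|")),
    if (!is.null(x$residue_id)) paste0("resid=", length(x$residue_id), " ids"),
    if (!is.null(x$residue_name)) paste0("resname=",
                                         paste(x$residue_name, collapse = "|")),
    if (!is.null(x$atom_name)) paste0("name=",
                                      paste(x$atom_name, collapse = "|"))
  )
  cat("selection_spec:", if (x$invert) "NOT" else "",
      paste(parts, collapse = " & "), "\n")
  invisible(x)
}

#' Resolve a selection against a topology
#'
#' @param top a [topology()].
#' @param spec a [sel()] spec or an integer index vector (returned
#'   as-is after validation).
#' @param warn_empty warn when the selection resolves to no atoms
#'   (an empty selection is legal).
#' @return sorted integer vector of atom indices (source order).
#' @export
select_atoms <- function(top, spec, warn_empty = TRUE) {
  stopifnot(inherits(top, "topology"))
  if (is.numeric(spec)) {
    idx <- as.integer(spec)
    if (any(idx < 1L | idx > nrow(top))) stop("atom index out of range")
    return(sort(unique(idx)))
  }
  stopifnot(inherits(spec, "selection_spec"))
  keep <- rep(TRUE, nrow(top))
  if (!is.null(spec$role)) {
    unknown <- setdiff(spec$role, CHAIN_ROLES)
    if (length(unknown)) stop("unknown chain role(s): ",
                              paste(unknown, collapse = ", "))
    keep <- keep & top$chain_role %in% spec$role
  }
  if (!is.null(spec$residue_id)) {
    missing_ids <- setdiff(spec$residue_id, top$residue_id)
    if (length(missing_ids)) {
      stop("selection references unknown residue id(s): ",
           paste(utils::head(missing_ids, 5), collapse = ", "))
    }
    keep <- keep & top$residue_id %in% spec$residue_id
  }
  if (!is.null(spec$residue_name)) {
    keep <- keep & top$residue_name %in% spec$residue_name
  }
  if (!is.null(spec$atom_name)) {
    keep <- keep & top$atom_name %in% spec$atom_name
  }
  if (spec$invert) keep <- !keep
  idx <- which(keep)
  if (!length(idx) && warn_empty) warning("selection resolved to 0 atoms")
  idx
}

#' Minimum-image distance under an orthorhombic box
#'
#' Computes the periodic minimum-image Euclidean distance between
#' points `a` and `b`.  Vectorised: `a` and `b` may be N x 3 matrices
#' (recycled against each other row-wise if one is a single point).
#'
#' @param a,b points (length-3 vectors or N x 3 matrices), nm.
#' @param box orthorhombic box lengths, nm.
#' @return distance(s) in nm.
#' @export
minimum_image_distance <- function(a, b, box) {
  d <- min_image_displacement(a, b, box)
  if (is.matrix(d)) sqrt(rowSums(d^2)) else sqrt(sum(d^2))
}

#' Minimum-image displacement vector(s) b -> a
#'
#' @inheritParams minimum_image_distance
#' @return displacement(s) wrapped into `[-box/2, box/2)` per axis.
#' @export
min_image_displacement <- function(a, b, box) {
  if (is.matrix(a) || is.matrix(b)) {
    a <- if (is.matrix(a)) a else matrix(a, nrow(b), 3, byrow = TRUE)
    b <- if (is.matrix(b)) b else matrix(b, nrow(a), 3, byrow = TRUE)
    d <- a - b
    for (k in 1:3) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
    d
  } else {
    d <- a - b
    d - box * round(d / box)
  }
}
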