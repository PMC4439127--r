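#' Default donor/acceptor rules per residue type
#'
#' Hydrogen-bond donors and acceptors are declared per residue name,
#' never perceived from geometry: each rule lists donor pairs (heavy
#' donor atom name, attached hydrogen name) and acceptor oxygen atom
#' names.  The defaults cover the pseudo-residues produced by the
#' synthetic generator plus water; real systems supply their own rules
#' (see [read_hbond_rules()]).
#'
#' @return named list: per residue name, `donors` (list of
#'   `c(D = , H = )`) and `acceptors` (character vector).
#' @export
default_hbond_rules <- function() {
  list(
    SOL = list(donors = list(c(D = "OW", H = "HW1")), acceptors = "OW"),
    POPC = list(donors = list(), acceptors = "OP"),
    POPE = list(donors = list(c(D = "N", H = "HN")), acceptors = "OP"),
    ALA = list(donors = list(), acceptors = "OB")
  )
}

#' Read donor/acceptor rules from a YAML config
#'
#' Expected layout, keyed by residue name:
#' ```yaml
#' POPE:
#'   donors: [{D: N, H: HN}]
#'   acceptors: [OP]
#' ```
#'
#' @param path YAML file.
#' @return rules list as in [default_hbond_rules()].
#' @export
read_hbond_rules <- function(path) {
  raw <- yaml::read_yaml(path)
  lapply(raw, function(r) {
    list(donors = lapply(r$donors, function(d) c(D = d$D, H = d$H)),
         acceptors = as.character(r$acceptors))
  })
}

#' Build concrete donor/acceptor tables for a topology
#'
#' @param top a [topology()].
#' @param rules rules list (see [default_hbond_rules()]); residues with
#'   no rule contribute nothing.
#' @return list with `donors` (data.frame `d`, `h` atom indices) and
#'   `acceptors` (atom index vector).
#' @export
hbond_tables <- function(top, rules = default_hbond_rules()) {
  donors_d <- integer(0); donors_h <- integer(0); acc <- integer(0)
  split_idx <- split(seq_len(nrow(top)),
                     paste(top$residue_id, top$residue_name))
  for (idx in split_idx) {
    rn <- top$residue_name[idx[1]]
    rule <- rules[[rn]]
    if (is.null(rule)) next
    for (dp in rule$donors) {
      di <- idx[top$atom_name[idx] == dp[["D"]]]
      hi <- idx[top$atom_name[idx] == dp[["H"]]]
      if (length(di) == 1 && length(hi) == 1) {
        donors_d <- c(donors_d, di); donors_h <- c(donors_h, hi)
      }
    }
    acc <- c(acc, idx[top$atom_name[idx] %in% rule$acceptors])
  }
  ord <- order(donors_d)
  list(donors = data.frame(d = donors_d[ord], h = donors_h[ord]),
       acceptors = sort(acc))
}

#' Detect hydrogen bonds in one frame
#'
#' Geometric criterion: donor--acceptor minimum-image distance
#' `<= d_cut` and H--donor--acceptor angle `<= angle_cut` (the angle at
#' the donor between its hydrogen and the acceptor).
#'
#' @param frame an [mdframe()].
#' @param donors data.frame with columns `d` (donor heavy atom index)
#'   and `h` (hydrogen index).
#' @param acceptors vector of acceptor oxygen atom indices.
#' @param d_cut distance cutoff in nm (default 0.35).
#' @param angle_cut angle cutoff in degrees (default 30).
#' @return data.frame with one row per bond: `donor`, `hydrogen`,
#'   `acceptor`, `dist`, `angle`.
#' @export
detect_hbonds <- function(frame, donors, acceptors, d_cut = 0.35,
                          angle_cut = 30) {
  out <- list()
  box <- frame$box
  axyz <- frame$coords[acceptors, , drop = FALSE]
  for (i in seq_len(nrow(donors))) {
    di <- donors$d[i]; hi <- donors$h[i]
    dvec <- min_image_displacement(axyz, frame$coords[di, ], box)
    dist <- sqrt(rowSums(dvec^2))
    cand <- which(dist <= d_cut & acceptors != di)
    if (!length(cand)) next
    hvec <- min_image_displacement(frame$coords[hi, ], frame$coords[di, ],
                                   box)
    ang <- vapply(cand, function(j) vec_angle(hvec, dvec[j, ]), numeric(1))
    keep <- cand[ang <= angle_cut]
    if (length(keep)) {
      out[[length(out) + 1]] <- data.frame(
        donor = di, hydrogen = hi, acceptor = acceptors[keep],
        dist = dist[keep], angle = ang[keep])
    }
  }
  if (!length(out)) {
    return(data.frame(donor = integer(0), hydrogen = integer(0),
                      acceptor = integer(0), dist = numeric(0),
                      angle = numeric(0)))
  }
  do.call(rbind, out)
}

#' Hydrogen-bond occupancies per role-pair class
#'
#' For each class (protein--lipid, lipid--lipid, lipid--solvent) the
#' mean bond count over frames is divided by the total acceptor-oxygen
#' count of the class's lipid side, giving a dimensionless occupancy
#' per acceptor oxygen.
#'
#' @param traj an [mdtrajectory()].
#' @param donors,acceptors tables from [hbond_tables()].
#' @param d_cut,angle_cut geometric criterion (see [detect_hbonds()]).
#' @return an `hbond_occupancy`: `rho` (named vector with entries
#'   `prt_lip`, `lip_lip`, `lip_sol`), `mean_counts`, `n_acceptors`.
#' @export
hbond_occupancies <- function(traj, donors, acceptors, d_cut = 0.35,
                              angle_cut = 30) {
  role <- traj$topology$chain_role
  lipid_roles <- c("POPC", "POPE", "CHOL")
  pair_class <- function(r1, r2) {
    rr <- c(r1, r2)
    if (any(rr == "protein") && any(rr %in% lipid_roles)) return("prt_lip")
    if (all(rr %in% lipid_roles)) return("lip_lip")
    if (any(rr %in% lipid_roles) && any(rr == "water")) return("lip_sol")
    NA_character_
  }
  n_acc_lip <- sum(role[acceptors] %in% lipid_roles)
  n_acc <- c(prt_lip = n_acc_lip, lip_lip = n_acc_lip,
             lip_sol = n_acc_lip)
  if (any(n_acc == 0)) stop("zero acceptor oxygens in a class")
  counts <- matrix(0, n_frames(traj), 3,
                   dimnames = list(NULL, names(n_acc)))
  for (f in seq_len(n_frames(traj))) {
    b <- detect_hbonds(get_frame(traj, f), donors, acceptors, d_cut,
                       angle_cut)
    if (!nrow(b)) next
    cls <- mapply(pair_class, role[b$donor], role[b$acceptor])
    tab <- table(factor(cls, levels = names(n_acc)))
    counts[f, ] <- as.numeric(tab)
  }
  mean_counts <- colMeans(counts)
  structure(list(rho = mean_counts / n_acc, mean_counts = mean_counts,
                 n_acceptors = n_acc),
            class = "hbond_occupancy")
}
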