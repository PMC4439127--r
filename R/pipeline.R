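#' Pipeline run configuration
#'
#' Bundles the synthetic-system config (or input file paths), the
#' analysis thresholds and the tail window.  Every threshold is echoed
#' into the report for full provenance.
#'
#' @param synth a [synth_config()]; mutually exclusive with file
#'   inputs.
#' @param membrane_file,ligand_file,helix_file optional trajectory
#'   paths analysed instead of generated systems (GRO or multi-model
#'   PDB).
#' @param last_fraction tail window analysed for equilibrium
#'   properties (default 0.5, the last half of the run).
#' @param cluster_cutoff Gromos pose-cluster RMSD cutoff, nm.
#' @param convergence_cutoff RMSD-matrix similarity cutoff, nm.
#' @param proximity_cutoff protein-proximity cutoff, nm.
#' @param hbond_d_cut,hbond_angle_cut geometric hydrogen-bond
#'   criterion (nm, degrees).
#' @param grid_n APL grid dimension per leaflet.
#' @param bin_width density-profile bin width, nm.
#' @param msd_window diffusion fit window as fractions of the maximum
#'   lag.
#' @param matrix_stride frame stride of the all-to-all RMSD matrix.
#' @return a `run_config` list.
#' @export
run_config <- function(synth = NULL, membrane_file = NULL,
                       ligand_file = NULL, helix_file = NULL,
                       last_fraction = 0.5, cluster_cutoff = 0.2,
                       convergence_cutoff = 0.2, proximity_cutoff = 0.35,
                       hbond_d_cut = 0.35, hbond_angle_cut = 30,
                       grid_n = 100, bin_width = 0.1,
                       msd_window = c(0.1, 0.5), matrix_stride = 2) {
  if (is.null(synth) &&
      (is.null(membrane_file) || is.null(ligand_file) ||
       is.null(helix_file))) {
    stop("either a synth config or all three input trajectories required")
  }
  structure(list(synth = synth, membrane_file = membrane_file,
                 ligand_file = ligand_file, helix_file = helix_file,
                 last_fraction = last_fraction,
                 cluster_cutoff = cluster_cutoff,
                 convergence_cutoff = convergence_cutoff,
                 proximity_cutoff = proximity_cutoff,
                 hbond_d_cut = hbond_d_cut,
                 hbond_angle_cut = hbond_angle_cut, grid_n = grid_n,
                 bin_width = bin_width, msd_window = msd_window,
                 matrix_stride = matrix_stride),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Executes the complete battery on a synthetic or supplied system:
#' convergence diagnosis on the helical trace, tail-window
#' restriction, ligand analyses (pose clustering and populations,
#' flipping angle, centre-of-mass cloud, cavity hydration,
#' minimum-distance/contact series), membrane analyses (phosphate
#' density profile and thickness, grid area per lipid, PN tilt,
#' hydrogen-bond occupancies, proximity classification, lateral MSD
#' and diffusion fits) and the helicity timeline.  A machine-readable
#' JSON summary plus TSV artifacts are written under `out_dir`; the
#' returned report is fully reproducible from the config (identical
#' config, identical report).
#'
#' @param cfg a [run_config()].
#' @param out_dir output directory (created if missing); `NULL` skips
#'   file artifacts.
#' @param verbose log stage progress to stderr.
#' @return the report, invisibly (a nested list, also written as
#'   `report.json`).
#' @export
run_pipeline <- function(cfg, out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  log_stage <- function(...) if (verbose) message("[memtraj] ", ...)
  t0 <- proc.time()[["elapsed"]]
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  art <- function(name) if (is.null(out_dir)) NULL else
    file.path(out_dir, name)

  ## inputs -------------------------------------------------------------
  if (!is.null(cfg$synth)) {
    log_stage("generating synthetic systems")
    bil <- make_bilayer(cfg$synth, include_protein = TRUE)
    mem_traj <- make_brownian(cfg$synth, bil)
    lig_traj <- make_ligand_traj(cfg$synth)
    cav <- cavity_box_from_residues(lig_traj$topology,
                                    get_frame(lig_traj, 1),
                                    sel(residue_id = 11:17),
                                    padding = 0.15)
    lig_traj <- add_static_atoms(lig_traj,
                                 place_waters(cfg$synth, cav))
    helix_traj <- make_helix_trace(cfg$synth)
  } else {
    log_stage("reading input trajectories")
    mem_traj <- read_trajectory(cfg$membrane_file)
    lig_traj <- read_trajectory(cfg$ligand_file)
    helix_traj <- read_trajectory(cfg$helix_file)
    cav <- cavity_box_from_residues(lig_traj$topology,
                                    get_frame(lig_traj, 1),
                                    sel(role = "protein"),
                                    padding = 0.15)
  }

  ## convergence --------------------------------------------------------
  log_stage("convergence analysis")
  mat <- pairwise_rmsd_matrix(helix_traj, sel(atom_name = "CA"),
                              stride = cfg$matrix_stride)
  conv <- diagnose_convergence(mat, cutoff = cfg$convergence_cutoff)
  if (!is.null(out_dir)) {
    write_rmsd_matrix(mat, art("rmsd_matrix.tsv"))
    write_convergence_report(conv, art("convergence.json"))
  }

  ## tail window --------------------------------------------------------
  lig_w <- last_fraction_window(lig_traj, cfg$last_fraction)
  mem_w <- last_fraction_window(mem_traj, cfg$last_fraction)

  ## ligand battery -----------------------------------------------------
  log_stage("ligand analyses")
  backbone <- sel(role = "protein", atom_name = "CA")
  ligand <- sel(role = "ligand")
  clus <- gromos_cluster(lig_w, backbone, ligand,
                         cutoff = cfg$cluster_cutoff)
  flip <- flipping_angle(lig_traj, ligand)
  cloud <- com_cloud(lig_w, backbone, ligand)
  waters <- count_cavity_waters(lig_w, cav)
  min_d <- min_distance_series(lig_w, ligand, backbone)
  occ <- contact_occupancy(min_d, 0.5)
  if (!is.null(out_dir)) {
    write_pose_clustering(clus, lig_w, art("clusters.tsv"),
                          art("populations.json"))
    rep_frame <- clus$representatives[1]
    write_structure(lig_w$topology, get_frame(lig_w, rep_frame),
                    art("representative_pose.pdb"))
    utils::write.table(
      data.frame(frame = seq_along(min_d), min_dist_nm = min_d),
      art("min_distance.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    utils::write.table(
      data.frame(frame = seq_along(flip$angle),
                 flip_deg = flip$angle),
      art("flipping_angle.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
  }

  ## membrane battery ---------------------------------------------------
  log_stage("membrane analyses")
  phosphates <- sel(role = c("POPC", "POPE"), atom_name = "P")
  prof <- density_profile(mem_w, phosphates, bin_width = cfg$bin_width)
  thick <- bilayer_thickness(prof)
  apl <- area_per_lipid_traj(mem_w, phosphates,
                             protein_spec = sel(role = "protein"),
                             grid_n = cfg$grid_n,
                             stride = max(1L, n_frames(mem_w) %/% 5L))
  tilt <- pn_tilt(mem_w)
  tilt_summary <- vapply(unique(tilt$lipid_type), function(tp) {
    mean(tilt$phi[, tilt$lipid_type == tp])
  }, numeric(1))
  tabs <- hbond_tables(mem_w$topology)
  hb <- hbond_occupancies(mem_w, tabs$donors, tabs$acceptors,
                          d_cut = cfg$hbond_d_cut,
                          angle_cut = cfg$hbond_angle_cut)
  chol_present <- any(mem_w$topology$chain_role == "CHOL")
  diff_group_spec <- if (chol_present) sel(role = "CHOL") else
    sel(role = c("POPC", "POPE"))
  prox <- classify_proximal(mem_traj, diff_group_spec,
                            sel(role = "protein"),
                            cutoff = cfg$proximity_cutoff)
  diff_est <- lapply(c(proximal = "proximal", free = "free"), function(g) {
    ids <- as.integer(names(prox)[prox == g])
    if (!length(ids)) return(NULL)
    refs <- sel(residue_id = ids,
                atom_name = if (chol_present) "O3" else "P")
    est <- fit_diffusion(lateral_msd(mem_traj, refs),
                         window = cfg$msd_window)
    list(D_cm2_s = est$D, r2 = est$r2, n_molecules = length(ids))
  })
  if (!is.null(out_dir)) {
    write_density_profile(prof, art("density_profile.tsv"))
    utils::write.table(tilt_distribution(tilt), art("tilt_distribution.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  ## secondary structure ------------------------------------------------
  log_stage("helicity timeline")
  helicity <- assign_helicity(helix_traj, sel(atom_name = "CA"))
  if (!is.null(out_dir)) {
    write_helicity_timeline(helicity,
                            fraction_path = art("helix_fraction.tsv"))
  }

  report <- list(
    schema_version = "1.0",
    config = list(
      last_fraction = cfg$last_fraction,
      cluster_cutoff_nm = cfg$cluster_cutoff,
      convergence_cutoff_nm = cfg$convergence_cutoff,
      proximity_cutoff_nm = cfg$proximity_cutoff,
      hbond_d_cut_nm = cfg$hbond_d_cut,
      hbond_angle_cut_deg = cfg$hbond_angle_cut,
      grid_n = cfg$grid_n, bin_width_nm = cfg$bin_width,
      msd_window = cfg$msd_window,
      matrix_stride = cfg$matrix_stride,
      seed = if (!is.null(cfg$synth)) cfg$synth$seed else NULL),
    convergence = list(verdict = conv$verdict,
                       boundary = conv$block_boundaries,
                       overlap = conv$block_overlap_score),
    poses = list(populations_percent = clus$populations,
                 n_clusters = length(clus$populations),
                 representatives = clus$representatives),
    flipping = list(mean_deg = mean(flip$angle),
                    sd_deg = stats::sd(flip$angle)),
    com_cloud = list(sd_nm = cloud$sd, rg_nm = cloud$rg),
    cavity_hydration = list(mean_waters = waters$mean),
    contacts = list(min_dist_mean_nm = mean(min_d),
                    occupancy = occ),
    membrane = list(thickness_nm = thick$thickness,
                    apl_nm2 = apl$apl_mean,
                    tilt_mean_deg = as.list(tilt_summary),
                    hbond_occupancy = as.list(hb$rho)),
    diffusion = diff_est,
    helicity = list(mean_fraction = mean(helicity$helix_fraction),
                    final_fraction = helicity$helix_fraction[
                      length(helicity$helix_fraction)]))
  # no timestamps or timings in the report: reruns are byte-identical
  if (!is.null(out_dir)) {
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  log_stage(sprintf("done in %.1f s", proc.time()[["elapsed"]] - t0))
  invisible(report)
}
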