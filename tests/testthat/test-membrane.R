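# minimal bilayer-like fixture: phosphates at given z values
phosphate_traj <- function(z_values, box = c(6, 6, 10), n_frames = 1) {
  n <- length(z_values)
  top <- topology(rep("P", n), rep("POPC", n), seq_len(n))
  xy <- cbind(runif(n, 0, box[1]), runif(n, 0, box[2]))
  frames <- lapply(seq_len(n_frames), function(f) {
    mdframe(cbind(xy, z_values + box[3] / 2), box, (f - 1) * 10)
  })
  mdtrajectory(top, frames)
}

test_that("density profile: delta peaks, normalisation, flat-profile statistics", {
  set.seed(51)
  tr <- phosphate_traj(c(rep(2, 20), rep(-2, 20)))
  prof <- density_profile(tr, sel(atom_name = "P"), bin_width = 0.1)
  expect_equal(prof$n_mean, 40, tolerance = 1e-9)
  # integral x area recovers the atom count
  expect_equal(sum(prof$density) * prof$bin_width * prof$area, 40,
               tolerance = 1e-6)
  pk <- prof$bin_centers[prof$density > 0]
  expect_equal(max(pk) - min(pk), 4, tolerance = 0.11)  # peak separation

  # uniform z: flat within 3-sigma Poisson bands per bin
  nz <- 400
  trU <- phosphate_traj(runif(nz, -5, 5), box = c(6, 6, 10),
                        n_frames = 1)
  # uniform cloud has no leaflet structure; profile about its own mean
  profU <- density_profile(trU, sel(atom_name = "P"), bin_width = 1)
  occ <- profU$density * profU$bin_width * profU$area
  expected <- nz / 10
  inner <- abs(profU$bin_centers) < 4.5   # avoid edge bins
  expect_true(all(abs(occ[inner] - expected) <=
                    3 * sqrt(expected) + 1e-9))
})

test_that("bilayer thickness: delta leaflets exact, Gaussian leaflets, z-shift invariance", {
  tr <- phosphate_traj(c(rep(2, 10), rep(-2, 10)))
  th <- bilayer_thickness(density_profile(tr, sel(atom_name = "P"),
                                          bin_width = 0.05))
  expect_equal(th$thickness, 4, tolerance = 0.03)

  set.seed(52)
  z <- c(rnorm(5000, 1.9, 0.2), rnorm(5000, -1.9, 0.2))
  trg <- phosphate_traj(z, box = c(40, 40, 10))
  thg <- bilayer_thickness(density_profile(trg, sel(atom_name = "P"),
                                           bin_width = 0.05))
  expect_equal(thg$thickness, 3.8, tolerance = 0.02 / 3.8)

  # rigid z-translation leaves thickness unchanged (midplane centering)
  trs <- trg
  trs$coords[, 3, ] <- trs$coords[, 3, ] + 1.3
  ths <- bilayer_thickness(density_profile(trs, sel(atom_name = "P"),
                                           bin_width = 0.05))
  expect_equal(ths$thickness, thg$thickness, tolerance = 1e-9)

  # single mode (all mass at the midplane) -> no bilayer
  tr1 <- phosphate_traj(rep(0, 100), box = c(20, 20, 10))
  prof1 <- density_profile(tr1, sel(atom_name = "P"), bin_width = 0.5)
  expect_error(bilayer_thickness(prof1), "no bilayer")
})

test_that("grid APL: exact lattice closed form, scaling, conservation, protein monotonicity", {
  lattice_frame <- function(a, m = 4, z = 2) {
    n <- m * m
    top <- topology(rep("P", 2 * n), rep("POPC", 2 * n),
                    seq_len(2 * n))
    xy <- cbind((rep(seq_len(m), m) - 0.5) * a,
                (rep(seq_len(m), each = m) - 0.5) * a)
    xyz <- rbind(cbind(xy, 5 + z), cbind(xy, 5 - z))
    list(top = top, frame = mdframe(xyz, c(m * a, m * a, 10)))
  }
  for (a in c(0.8, 1.6, 2.5)) {
    lf <- lattice_frame(a)
    apl <- area_per_lipid_grid(lf$top, lf$frame, sel(atom_name = "P"),
                               grid_n = 100)
    expect_equal(apl$apl_mean, a^2, tolerance = 1e-9)
    expect_equal(unname(apl$per_lipid), rep(a^2, 32), tolerance = 1e-9)
    # cell-area conservation, exact by construction
    for (side in c("upper", "lower")) {
      expect_equal(sum(apl$per_lipid[apl$leaflet == side]) +
                     apl$protein_area[[side]],
                   apl$box_area, tolerance = 1e-12)
    }
  }

  # a protein column strictly decreases the mean APL
  lf <- lattice_frame(0.8)
  prot <- topology(rep("CA", 10), rep("ALA", 10), rep(100L, 10))
  top2 <- rbind(lf$top, prot)
  class(top2) <- c("topology", "data.frame")
  pxyz <- cbind(1.6, 1.6, seq(3.2, 6.8, length.out = 10))
  fr2 <- mdframe(rbind(lf$frame$coords, pxyz), lf$frame$box)
  apl2 <- area_per_lipid_grid(top2, fr2, sel(atom_name = "P"),
                              protein_spec = sel(role = "protein"),
                              grid_n = 100)
  expect_lt(apl2$apl_mean, 0.8^2)
  expect_gt(sum(apl2$protein_area), 0)
  for (side in c("upper", "lower")) {
    expect_equal(sum(apl2$per_lipid[apl2$leaflet == side]) +
                   apl2$protein_area[[side]],
                 apl2$box_area, tolerance = 1e-12)
  }
})

test_that("PN tilt: axis-aligned exact cases, leaflet symmetry, rotation invariance", {
  mk_pn <- function(offsets_upper, offsets_lower) {
    nl <- nrow(offsets_upper) + nrow(offsets_lower)
    names_ <- rep(c("P", "N"), nl)
    res <- rep(seq_len(nl), each = 2)
    xyz <- matrix(0, 2 * nl, 3)
    k <- 0
    for (i in seq_len(nrow(offsets_upper))) {
      p <- c(i, 1, 7); k <- k + 1
      xyz[2 * k - 1, ] <- p; xyz[2 * k, ] <- p + offsets_upper[i, ]
    }
    for (i in seq_len(nrow(offsets_lower))) {
      p <- c(i, 2, 3); k <- k + 1
      xyz[2 * k - 1, ] <- p; xyz[2 * k, ] <- p + offsets_lower[i, ]
    }
    top <- topology(names_, rep("POPC", 2 * nl), res)
    mdtrajectory(top, list(mdframe(xyz, c(10, 10, 10))))
  }
  up <- rbind(c(0, 0, 0.4),   # along outward normal: 0 deg
              c(0.4, 0, 0))   # in-plane: 90 deg
  lo <- rbind(c(0, 0, -0.4),  # outward for the lower leaflet: 0 deg
              c(0, 0.4, 0))   # in-plane: 90 deg
  tr <- mk_pn(up, lo)
  rec <- pn_tilt(tr)
  expect_equal(as.vector(rec$phi), c(0, 90, 0, 90), tolerance = 1e-9)

  # invariant under rotation about z
  th <- 67 * pi / 180
  Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1),
               3, 3)
  tr2 <- tr
  tr2$coords[, , 1] <- tr$coords[, , 1] %*% Rz
  expect_equal(pn_tilt(tr2)$phi, rec$phi, tolerance = 1e-9)

  # unpaired P/N is an error
  bad <- topology(c("P", "N", "P"), rep("POPC", 3), c(1L, 1L, 2L))
  btr <- mdtrajectory(bad, list(mdframe(matrix(runif(9), 3, 3),
                                        c(5, 5, 5))))
  expect_error(pn_tilt(btr), "1:1")
})

test_that("tilt generator round-trip: mean recovered within a degree at n = 1e4", {
  cfg <- synth_config(seed = 61, n_lipids = c(POPC = 20000),
                      tilt_mean = c(POPC = 65), tilt_sd = c(POPC = 10))
  bil <- make_bilayer(cfg)
  tr <- mdtrajectory(bil$topology, list(bil$frame))
  rec <- pn_tilt(tr)
  expect_gte(ncol(rec$phi), 1e4)
  expect_equal(mean(rec$phi), 65, tolerance = 1 / 65)
})

test_that("hydrogen-bond detection: criterion cases and O(N^2) oracle equivalence", {
  # D-A at 0.29 nm, H 10 degrees off the D->A axis: bonded
  mk_frame <- function(a_pos, h_dir_deg) {
    h <- 0.1 * c(cos(h_dir_deg * pi / 180), sin(h_dir_deg * pi / 180), 0)
    top <- topology(c("N", "HN", "OP"), c("POPE", "POPE", "POPC"),
                    c(1L, 1L, 2L))
    fr <- mdframe(rbind(c(1, 1, 1), c(1, 1, 1) + h, a_pos), c(5, 5, 5))
    list(top = top, frame = fr)
  }
  f1 <- mk_frame(c(1.29, 1, 1), 10)
  tabs1 <- hbond_tables(f1$top)
  expect_equal(nrow(detect_hbonds(f1$frame, tabs1$donors,
                                  tabs1$acceptors)), 1)
  f2 <- mk_frame(c(1.40, 1, 1), 10)          # too far
  expect_equal(nrow(detect_hbonds(f2$frame, tabs1$donors,
                                  tabs1$acceptors)), 0)
  f3 <- mk_frame(c(1.29, 1, 1), 40)          # angle too large
  expect_equal(nrow(detect_hbonds(f3$frame, tabs1$donors,
                                  tabs1$acceptors)), 0)

  # random ~100-atom systems vs the exhaustive scan
  set.seed(71)
  for (r in 1:5) {
    n_pe <- 15; n_pc <- 20
    top <- topology(
      c(rep(c("N", "HN"), n_pe), rep("OP", n_pc)),
      c(rep("POPE", 2 * n_pe), rep("POPC", n_pc)),
      c(rep(seq_len(n_pe), each = 2), n_pe + seq_len(n_pc)))
    box <- c(3, 3, 3)
    xyz <- cbind(runif(2 * n_pe + n_pc, 0, 3),
                 runif(2 * n_pe + n_pc, 0, 3),
                 runif(2 * n_pe + n_pc, 0, 3))
    # keep H near its donor
    for (i in seq_len(n_pe)) {
      v <- rnorm(3)
      xyz[2 * i, ] <- xyz[2 * i - 1, ] + 0.1 * v / sqrt(sum(v^2))
    }
    fr <- mdframe(xyz, box)
    tabs <- hbond_tables(top)
    got <- nrow(detect_hbonds(fr, tabs$donors, tabs$acceptors,
                              d_cut = 0.35, angle_cut = 30))
    want <- hbond_scan_oracle(fr, tabs$donors, tabs$acceptors,
                              0.35, 30)
    expect_equal(got, want)
  }
})

test_that("hydrogen-bond occupancies: arithmetic and frame-duplication invariance", {
  # constructed frame: 5 POPE->POPC bonds, 20 lipid acceptor oxygens
  n_d <- 5; n_a <- 20
  top <- topology(
    c(rep(c("N", "HN"), n_d), rep("OP", n_a)),
    c(rep("POPE", 2 * n_d), rep("POPC", n_a)),
    c(rep(seq_len(n_d), each = 2), n_d + seq_len(n_a)))
  xyz <- matrix(0, 2 * n_d + n_a, 3)
  for (i in seq_len(n_d)) {
    xyz[2 * i - 1, ] <- c(i, 1, 1)              # N
    xyz[2 * i, ] <- c(i + 0.1, 1, 1)            # HN toward acceptor
  }
  for (j in seq_len(n_a)) {
    xyz[2 * n_d + j, ] <- if (j <= n_d) c(j + 0.3, 1, 1) else
      c(j %% 7 + 0.5, 4, 4)                     # far away
  }
  fr <- mdframe(xyz, c(20, 20, 20))
  tr <- mdtrajectory(top, list(fr))
  tabs <- hbond_tables(top)
  occ <- hbond_occupancies(tr, tabs$donors, tabs$acceptors)
  expect_equal(unname(occ$rho[["lip_lip"]]), 5 / 20)
  expect_equal(unname(occ$rho[["prt_lip"]]), 0)

  # duplication of all frames leaves occupancies unchanged
  tr2 <- mdtrajectory(top, list(fr, mdframe(xyz, c(20, 20, 20), 10)))
  occ2 <- hbond_occupancies(tr2, tabs$donors, tabs$acceptors)
  expect_equal(occ2$rho, occ$rho)

  # no geometric bonds anywhere -> all zero
  far <- mdframe(xyz + rep(c(0, 0, 0), each = nrow(xyz)), c(20, 20, 20))
  far$coords[seq(2 * n_d + 1, 2 * n_d + n_a), ] <-
    far$coords[seq(2 * n_d + 1, 2 * n_d + n_a), ] + 5
  tr3 <- mdtrajectory(top, list(far))
  expect_true(all(hbond_occupancies(tr3, tabs$donors,
                                    tabs$acceptors)$rho == 0))
})

test_that("APL/thickness anti-correlation on synthetic bilayers", {
  # growing APL with fixed leaflet z never increases computed thickness
  th <- vapply(c(0.50, 0.56, 0.61), function(apl) {
    cfg <- synth_config(seed = 81, apl_true = apl, n_lipids = c(POPC = 72))
    bil <- make_bilayer(cfg)
    tr <- mdtrajectory(bil$topology, list(bil$frame))
    bilayer_thickness(density_profile(tr, sel(atom_name = "P"),
                                      bin_width = 0.1))$thickness
  }, numeric(1))
  expect_true(all(diff(th) <= 1e-9))
})
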