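test_that("Gromos clustering: trivial, constructed 70/30 and oracle equivalence", {
  all_same <- make_pose_fixture(rep("X", 8))
  c1 <- gromos_cluster(all_same, sel(role = "protein"), sel(role = "ligand"),
                       cutoff = 0.2)
  expect_length(c1$populations, 1)
  expect_equal(c1$populations, 100)

  mix <- make_pose_fixture(c(rep("X", 7), rep("Y", 3)), jitter = 0.01,
                           seed = 4)
  c2 <- gromos_cluster(mix, sel(role = "protein"), sel(role = "ligand"),
                       cutoff = 0.2)
  expect_equal(c2$sizes, c(7, 3))
  expect_equal(c2$populations, c(70, 30))
  expect_equal(c2$cluster_labels[1:7], rep(1, 7))

  # equivalence with the exhaustive greedy oracle on <= 30-frame fixtures
  set.seed(9)
  for (r in 1:5) {
    n <- sample(10:30, 1)
    pat <- sample(c("X", "Y"), n, replace = TRUE)
    tr <- make_pose_fixture(pat, jitter = 0.02, seed = 100 + r)
    got <- gromos_cluster(tr, sel(role = "protein"), sel(role = "ligand"),
                          cutoff = 0.2)
    want <- greedy_cluster_oracle(got$rmsd, 0.2)
    expect_equal(got$sizes, want$sizes)
    # same partition (labels may only differ by size-tie ordering)
    expect_equal(got$cluster_labels, want$labels)
  }
})

test_that("clustering invariants: partition, within-cutoff membership, rigid invariance", {
  tr <- make_pose_fixture(sample(c("X", "Y"), 20, replace = TRUE),
                          jitter = 0.02, seed = 7)
  cl <- gromos_cluster(tr, sel(role = "protein"), sel(role = "ligand"),
                       cutoff = 0.2)
  expect_true(all(cl$cluster_labels >= 1))
  expect_equal(sum(cl$sizes), 20)
  expect_equal(sum(cl$populations), 100, tolerance = 1e-9)
  for (k in seq_along(cl$sizes)) {
    members <- which(cl$cluster_labels == k)
    center <- members[which.max(colSums(
      cl$rmsd[members, members, drop = FALSE] <= cl$cutoff))]
    expect_true(all(cl$rmsd[center, members] <= cl$cutoff))
  }

  # populations invariant under a global rigid transform of every frame
  R <- random_rotation(); t <- c(1, -2, 3)
  moved <- tr
  for (f in seq_len(n_frames(tr))) {
    moved$coords[, , f] <- sweep(tr$coords[, , f] %*% R, 2, t, "+")
  }
  cl2 <- gromos_cluster(moved, sel(role = "protein"), sel(role = "ligand"),
                        cutoff = 0.2)
  expect_equal(cl2$populations, cl$populations)
  expect_equal(cl2$cluster_labels, cl$cluster_labels)
})

test_that("flipping angle: exact 0/90/180 cases and joint-rotation invariance", {
  lig_names <- c("N1", "C2", "N3", "C4", "C5", "C6", "N7", "C8", "N9")
  hex <- cbind(0.14 * cos(seq(0, 2 * pi, length.out = 7)[-7]),
               0.14 * sin(seq(0, 2 * pi, length.out = 7)[-7]), 0)
  five <- rbind(c(0.4, 0, 0), c(0.5, 0.05, 0), c(0.5, -0.05, 0))
  lig0 <- rbind(hex, five)                       # mu along +x
  rot_about <- function(x, axis, deg) {
    a <- deg * pi / 180
    u <- axis / sqrt(sum(axis^2))
    K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
    x %*% t(diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K))
  }
  top <- topology(lig_names, rep("CFF", 9), rep(1L, 9))
  mk <- function(rots) {
    frames <- lapply(seq_along(rots), function(f) {
      mdframe(rots[[f]] + 5, c(10, 10, 10), (f - 1) * 10)
    })
    mdtrajectory(top, frames)
  }
  tr <- mk(list(lig0, rot_about(lig0, c(0, 0, 1), 90),
                rot_about(lig0, c(0, 0, 1), 180),
                rot_about(lig0, c(0, 1, 0), 180)))
  fs <- flipping_angle(tr, sel(role = "ligand"))
  expect_equal(fs$angle, c(0, 90, 180, 180), tolerance = 1e-9)

  # invariant under a joint rigid rotation of ligand and reference
  R <- random_rotation()
  tr2 <- tr
  for (f in 1:4) tr2$coords[, , f] <- tr$coords[, , f] %*% R
  expect_equal(flipping_angle(tr2, sel(role = "ligand"))$angle, fs$angle,
               tolerance = 1e-9)
})

test_that("COM cloud collapses for rigid co-motion and is exact for a 2-point oscillation", {
  base <- make_pose_fixture(rep("X", 6))
  # rigidly co-moving receptor+ligand: random rigid transform per frame
  set.seed(15)
  rigid <- base
  for (f in 1:6) {
    R <- random_rotation()
    rigid$coords[, , f] <- sweep(base$coords[, , 1] %*% R, 2, rnorm(3), "+")
  }
  cc <- com_cloud(rigid, sel(role = "protein"), sel(role = "ligand"))
  expect_lt(max(cc$sd), 1e-9)
  expect_lt(cc$rg, 1e-9)

  # ligand oscillating +/-0.2 nm along x in a fixed receptor
  osc <- base
  for (f in 1:6) {
    osc$coords[5:13, 1, f] <- base$coords[5:13, 1, f] +
      ifelse(f %% 2 == 0, 0.2, -0.2)
  }
  cc2 <- com_cloud(osc, sel(role = "protein"), sel(role = "ligand"))
  expect_equal(unname(cc2$sd), c(0.2, 0, 0), tolerance = 1e-9)
})

test_that("COM cloud spread ranks generator jitter scales", {
  spreads <- vapply(c(small = 0.01, mid = 0.04, large = 0.08),
                    function(j) {
    cfg <- synth_config(seed = 42, n_frames = 40, pose_weights = 1,
                        pose_jitter = j)
    tr <- make_ligand_traj(cfg)
    com_cloud(tr, sel(role = "protein"), sel(role = "ligand"))$rg
  }, numeric(1))
  expect_true(spreads[["small"]] < spreads[["mid"]])
  expect_true(spreads[["mid"]] < spreads[["large"]])
})

test_that("cavity box construction and water counting", {
  top <- topology(c("CA", "CA"), c("GLY", "GLY"), 1:2)
  fr <- mdframe(rbind(c(0, 0, 0), c(1, 0, 0)), c(10, 10, 10))
  b1 <- cavity_box_from_residues(top, fr, sel(residue_id = 1),
                                 padding = 0.2)
  expect_equal(b1$center, c(0, 0, 0))
  expect_equal(b1$half_extents, c(0.2, 0.2, 0.2))
  b2 <- cavity_box_from_residues(top, fr, sel(residue_id = 1:2),
                                 padding = 0)
  expect_equal(b2$center, c(0.5, 0, 0))
  expect_equal(b2$half_extents, c(0.5, 0, 0))

  # containment of defining atoms for random selections
  set.seed(33)
  for (r in 1:10) {
    sys <- random_system(40, 200 + r)
    ids <- sample(unique(sys$topology$residue_id), 3)
    bb <- cavity_box_from_residues(sys$topology, sys$frame,
                                   sel(residue_id = ids), padding = 0.05)
    idx <- select_atoms(sys$topology, sel(residue_id = ids))
    xyz <- sys$frame$coords[idx, , drop = FALSE]
    inside <- sweep(abs(sweep(xyz, 2, bb$center)), 2,
                    bb$half_extents + 1e-12) <= 0
    expect_true(all(inside))
  }

  # constructed count: exactly 16 inside, 50 outside
  cfg <- synth_config(seed = 2, n_frames = 1, n_cavity_waters = 16,
                      n_outside_waters = 50)
  box <- structure(list(center = c(5, 5, 5),
                        half_extents = c(1, 1.2, 0.8)),
                   class = "cavity_box")
  w <- place_waters(cfg, box)
  wtraj <- mdtrajectory(w$topology, list(mdframe(w$coords, c(20, 20, 20))))
  got <- count_cavity_waters(wtraj, box)
  expect_equal(got$counts, 16)
  expect_equal(got$mean, 16)

  cfg0 <- synth_config(seed = 2, n_frames = 1, n_cavity_waters = 0)
  w0 <- place_waters(cfg0, box)
  tr0 <- mdtrajectory(w0$topology, list(mdframe(w0$coords, c(20, 20, 20))))
  expect_equal(count_cavity_waters(tr0, box)$mean, 0)

  # counting is monotone non-decreasing in padding
  grow <- function(b, pad) structure(
    list(center = b$center, half_extents = b$half_extents + pad),
    class = "cavity_box")
  counts <- vapply(c(0, 0.2, 0.5, 1),
                   function(p) count_cavity_waters(wtraj, grow(box, p))$mean,
                   numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("minimum-distance series and contact occupancy", {
  top <- topology(c("CA", "CA", "P"), c("GLY", "GLY", "POPC"),
                  c(1L, 2L, 3L))
  mk <- function(xb) mdtrajectory(top, list(
    mdframe(rbind(c(1, 1, 1), c(1.7, 1, 1), xb), c(5, 5, 5))))
  tr <- mk(c(1, 1, 1))   # overlapping selections
  expect_equal(min_distance_series(tr, sel(residue_id = 1),
                                   sel(residue_id = c(1, 3))), 0)
  tr2 <- mk(c(1.7, 1, 1))
  expect_equal(min_distance_series(tr2, sel(residue_id = 1),
                                   sel(residue_id = 3)), 0.7,
               tolerance = 1e-12)

  # equals brute-force pair enumeration with the 27-image oracle
  set.seed(41)
  sys <- random_system(60, 77)
  tr3 <- mdtrajectory(sys$topology, list(sys$frame))
  ia <- select_atoms(sys$topology, sel(role = "protein"),
                     warn_empty = FALSE)
  ib <- select_atoms(sys$topology, sel(role = "protein", invert = TRUE),
                     warn_empty = FALSE)
  got <- min_distance_series(tr3, sel(role = "protein"),
                             sel(role = "protein", invert = TRUE))
  want <- min(outer(ia, ib, Vectorize(function(i, j) {
    image27_distance(sys$frame$coords[i, ], sys$frame$coords[j, ],
                     sys$frame$box)
  })))
  expect_equal(got, want, tolerance = 1e-12)

  s <- c(0.2, 0.4, 0.2, 0.4)
  expect_equal(contact_occupancy(s, 0.5), 1)
  expect_equal(contact_occupancy(s, 0.1), 0)
  expect_equal(contact_occupancy(s, 0.3), 0.5)
  expect_error(contact_occupancy(s, 0), "threshold")
})
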