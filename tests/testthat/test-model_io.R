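test_that("GRO identity read-back and PDB unit conversion", {
  p <- withr::local_tempfile(fileext = ".gro")
  writeLines(c(
    "hand-written 3-atom system",
    "    3",
    "    1POPC    P    1   1.000   2.000   3.000",
    "    1POPC    N    2   1.500   2.000   3.100",
    "    2SOL    OW    3   0.200   0.300   0.400",
    "   5.00000   5.00000   5.00000"), p)
  s <- read_structure(p)
  expect_equal(nrow(s$topology), 3)
  expect_equal(s$frame$box, c(5, 5, 5))
  expect_equal(s$topology$chain_role, c("POPC", "POPC", "water"))
  expect_equal(s$frame$coords[1, ], c(1, 2, 3))

  pp <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "CRYST1   50.000   50.000   50.000  90.00  90.00  90.00 P 1",
    "ATOM      1  CA  ALA     1      10.000   0.000   0.000  1.00  0.00           C",
    "END"), pp)
  s2 <- read_structure(pp)
  expect_equal(s2$frame$coords[1, 1], 1.0)    # 10 A -> 1 nm
  expect_equal(s2$frame$box, c(5, 5, 5))
})

test_that("structure write/read round trips are lossless to format precision", {
  for (seed in 1:5) {
    sys <- random_system(50, seed)
    for (ext in c(".gro", ".pdb")) {
      f <- withr::local_tempfile(fileext = ext)
      write_structure(sys$topology, sys$frame, f)
      back <- read_structure(f)
      expect_equal(back$topology$atom_name, sys$topology$atom_name)
      expect_equal(back$topology$residue_id, sys$topology$residue_id)
      expect_equal(back$frame$coords, sys$frame$coords,
                   tolerance = 2e-3, ignore_attr = TRUE)
      expect_equal(back$frame$box, sys$frame$box, tolerance = 1e-3)
    }
  }
})

test_that("our PDB writer agrees with an independent PDB parser", {
  skip_if_not_installed("bio3d")
  sys <- random_system(40, 99)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(sys$topology, sys$frame, f)
  ref <- bio3d::read.pdb(f)
  xyz <- matrix(ref$xyz, ncol = 3, byrow = TRUE) / 10
  expect_equal(xyz, sys$frame$coords, tolerance = 2e-3,
               ignore_attr = TRUE)
  expect_equal(ref$atom$resid, sys$topology$residue_name)
})

test_that("trajectory read: frame counts, times and mismatch errors", {
  cfg <- synth_config(seed = 3, n_frames = 5, helix_n_residues = 12)
  traj <- make_helix_trace(cfg)

  g <- withr::local_tempfile(fileext = ".gro")
  write_trajectory(traj, g)
  back <- read_trajectory(g)
  expect_equal(n_frames(back), 5)
  expect_equal(back$times, traj$times)
  expect_equal(back$coords, traj$coords, tolerance = 2e-3)

  p <- withr::local_tempfile(fileext = ".pdb")
  write_trajectory(traj, p)
  backp <- read_trajectory(p, frame_stride = 20)
  expect_equal(n_frames(backp), 5)
  expect_equal(backp$times, (0:4) * 20)

  # single-model file is a 1-frame trajectory
  one <- withr::local_tempfile(fileext = ".gro")
  write_structure(traj$topology, get_frame(traj, 1), one)
  expect_equal(n_frames(read_trajectory(one)), 1)

  # atom-count mismatch names the offending model
  bad <- withr::local_tempfile(fileext = ".gro")
  l <- readLines(g)
  block <- 12 + 3                      # 12 atoms + title + count + box
  truncated <- l[seq_len(2 * block)]
  truncated[block + 2] <- "   11"
  truncated <- truncated[-(block + 3)] # drop one atom from model 2
  writeLines(truncated, bad)
  expect_error(read_trajectory(bad), "model 2")
})

test_that("malformed records and missing boxes are loud", {
  p <- withr::local_tempfile(fileext = ".gro")
  writeLines(c("title", "    2",
               "    1POPC    P    1   1.000   2.000   3.000",
               "    1POPC    N    2   xxxxx   2.000   3.100",
               "   5.0   5.0   5.0"), p)
  expect_error(read_structure(p), "line 4")

  nb <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA     1      10.000   0.000   0.000  1.00  0.00           C",
    "END"), nb)
  expect_error(read_structure(nb), "box")

  expect_error(topology("CA", "XYZ", 1), "unknown residue")
})

test_that("selection specs resolve deterministically and partition atoms", {
  n <- 30
  top <- topology(rep(c("CA", "CB", "P"), 10),
                  rep(c("ALA", "GLY", "POPC"), 10),
                  rep(1:10, each = 3))
  ca <- select_atoms(top, sel(atom_name = "CA", residue_id = 5:8))
  expect_equal(top$atom_name[ca], rep("CA", length(ca)))
  expect_true(all(top$residue_id[ca] %in% 5:8))
  expect_false(is.unsorted(ca, strictly = TRUE))

  expect_warning(w <- select_atoms(top, sel(role = "water")), "0 atoms")
  expect_length(w, 0)
  expect_error(select_atoms(top, sel(residue_id = 99)),
               "unknown residue id")

  spec <- sel(role = "protein", atom_name = "CA")
  comp <- sel(role = "protein", atom_name = "CA", invert = TRUE)
  expect_equal(sort(c(select_atoms(top, spec),
                      select_atoms(top, comp))), seq_len(n))
})

test_that("minimum-image distance matches 27-image enumeration and is a metric", {
  box <- c(5, 5, 5)
  expect_equal(minimum_image_distance(c(1, 2, 3), c(1, 2, 3), box), 0)
  expect_equal(minimum_image_distance(c(0.1, 0, 0), c(4.9, 0, 0), box),
               0.2, tolerance = 1e-12)
  set.seed(11)
  for (r in 1:50) {
    bx <- runif(3, 2, 9)
    a <- runif(3, 0, bx); b <- runif(3, 0, bx); c_ <- runif(3, 0, bx)
    dab <- minimum_image_distance(a, b, bx)
    expect_equal(dab, image27_distance(a, b, bx), tolerance = 1e-12)
    expect_equal(dab, minimum_image_distance(b, a, bx), tolerance = 1e-12)
    # triangle inequality within the fundamental cell
    expect_lte(dab, minimum_image_distance(a, c_, bx) +
                 minimum_image_distance(c_, b, bx) + 1e-12)
    expect_lte(dab, sqrt(sum((bx / 2)^2)) + 1e-12)
  }
})

test_that("external trajectory readers can be plugged in", {
  register_trajectory_reader("FAKEFMT", function(path, frame_stride,
                                                 role_map) {
    cfg <- synth_config(seed = 1, n_frames = 2, helix_n_residues = 8)
    make_helix_trace(cfg)
  })
  f <- withr::local_tempfile(fileext = ".xyz")
  file.create(f)
  tr <- read_trajectory(f, format = "FAKEFMT")
  expect_s3_class(tr, "mdtrajectory")
  expect_equal(n_frames(tr), 2)
})
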