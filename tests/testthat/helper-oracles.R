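# Independent oracles used across the suite.  Each deliberately takes a
# different computational route from the implementation it checks.

# Quaternion characteristic-polynomial RMSD (Theobald key matrix):
# minimum RMSD between two point sets via the largest eigenvalue of the
# 4x4 quaternion matrix -- no SVD, no rotation construction.
quaternion_rmsd <- function(A, B) {
  A <- sweep(A, 2, colMeans(A))
  B <- sweep(B, 2, colMeans(B))
  G <- sum(A^2) + sum(B^2)
  M <- crossprod(A, B)
  K <- matrix(c(
    M[1, 1] + M[2, 2] + M[3, 3], M[2, 3] - M[3, 2],
    M[3, 1] - M[1, 3], M[1, 2] - M[2, 1],
    M[2, 3] - M[3, 2], M[1, 1] - M[2, 2] - M[3, 3],
    M[1, 2] + M[2, 1], M[1, 3] + M[3, 1],
    M[3, 1] - M[1, 3], M[1, 2] + M[2, 1],
    -M[1, 1] + M[2, 2] - M[3, 3], M[2, 3] + M[3, 2],
    M[1, 2] - M[2, 1], M[1, 3] + M[3, 1],
    M[2, 3] + M[3, 2], -M[1, 1] - M[2, 2] + M[3, 3]), 4, 4)
  lam <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  sqrt(max(0, (G - 2 * lam) / nrow(A)))
}

# Periodic distance by explicit enumeration of the 27 images.
image27_distance <- function(a, b, box) {
  best <- Inf
  for (i in -1:1) for (j in -1:1) for (k in -1:1) {
    d <- a - (b + c(i, j, k) * box)
    best <- min(best, sqrt(sum(d^2)))
  }
  best
}

# Naive greedy max-neighbour clustering from a precomputed distance
# matrix (the Gromos scheme, written independently of gromos_cluster).
greedy_cluster_oracle <- function(m, cutoff) {
  nf <- nrow(m)
  remaining <- seq_len(nf)
  labels <- integer(nf)
  k <- 0
  sizes <- integer(0)
  while (length(remaining)) {
    best_c <- NA; best_n <- -1
    for (f in remaining) {
      nn <- sum(m[f, remaining] <= cutoff)
      if (nn > best_n) { best_n <- nn; best_c <- f }
    }
    members <- remaining[m[best_c, remaining] <= cutoff]
    k <- k + 1
    labels[members] <- k
    sizes[k] <- length(members)
    remaining <- setdiff(remaining, members)
  }
  ord <- order(-sizes)
  relab <- integer(k); relab[ord] <- seq_len(k)
  list(labels = relab[labels], sizes = sort(sizes, decreasing = TRUE))
}

# Exhaustive donor x acceptor hydrogen-bond scan (27-image distances,
# explicit angle at the donor).
hbond_scan_oracle <- function(frame, donors, acceptors, d_cut, angle_cut) {
  hits <- 0
  for (i in seq_len(nrow(donors))) {
    D <- frame$coords[donors$d[i], ]
    H <- frame$coords[donors$h[i], ]
    for (a in acceptors) {
      if (a == donors$d[i]) next
      dd <- image27_distance(D, frame$coords[a, ], frame$box)
      if (dd > d_cut) next
      # acceptor image closest to the donor
      best <- NULL; bd <- Inf
      for (ii in -1:1) for (jj in -1:1) for (kk in -1:1) {
        av <- frame$coords[a, ] + c(ii, jj, kk) * frame$box
        d2 <- sum((av - D)^2)
        if (d2 < bd) { bd <- d2; best <- av }
      }
      u <- H - D; v <- best - D
      ang <- acos(max(-1, min(1, sum(u * v) /
                                sqrt(sum(u^2) * sum(v^2))))) * 180 / pi
      if (ang <= angle_cut) hits <- hits + 1
    }
  }
  hits
}

# Random small molecular system for I/O round trips.
random_system <- function(n_atoms, seed) {
  set.seed(seed)
  resnames <- c("ALA", "GLY", "POPC", "SOL", "CFF")
  rn <- sample(resnames, n_atoms, replace = TRUE)
  top <- topology(
    atom_name = sample(c("CA", "P", "N", "OW", "C1"), n_atoms,
                       replace = TRUE),
    residue_name = rn,
    residue_id = sort(sample.int(max(2L, n_atoms %/% 2L), n_atoms,
                                 replace = TRUE)))
  box <- runif(3, 4, 12)
  coords <- cbind(runif(n_atoms, 0, box[1]), runif(n_atoms, 0, box[2]),
                  runif(n_atoms, 0, box[3]))
  list(topology = top, frame = mdframe(coords, box, 0))
}

# Uniformly random rotation matrix (QR of a Gaussian matrix, sign-fixed).
random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# Two-conformation trajectory: anchor atoms fixed (so superposition is
# exercised but trivial) and one atom switching between two positions.
two_state_traj <- function(pattern, d = 1) {
  anchors <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                   c(1, 1, 0))
  top <- topology(rep("CA", 6), rep("GLY", 6), 1:6)
  frames <- lapply(seq_along(pattern), function(f) {
    extra <- if (pattern[f] == "A") c(2, 0, 0) else c(2 + d, 0, 0)
    mdframe(rbind(anchors, extra), c(20, 20, 20), (f - 1) * 10)
  })
  mdtrajectory(top, frames)
}

# Ligand-pose fixture: static anchor "receptor" + a ligand switching
# between constructed poses, so pairwise ligand RMSDs can be verified
# directly.
make_pose_fixture <- function(pattern, jitter = 0, seed = 1) {
  set.seed(seed)
  recept <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  lig_names <- c("N1", "C2", "N3", "C4", "C5", "C6", "N7", "C8", "N9")
  ligA <- cbind(0.14 * cos(seq(0, 2 * pi, length.out = 10)[-10]),
                0.14 * sin(seq(0, 2 * pi, length.out = 10)[-10]), 0) +
    matrix(rep(c(3, 3, 3), each = 9), 9, 3)
  ligB <- ligA; ligB[, 3] <- ligB[, 3] + 1.5   # far beyond any cutoff
  top <- topology(c(rep("CA", 4), lig_names),
                  c(rep("GLY", 4), rep("CFF", 9)),
                  c(1:4, rep(10L, 9)))
  frames <- lapply(seq_along(pattern), function(f) {
    lig <- (if (pattern[f] == "X") ligA else ligB) +
      matrix(rnorm(27, 0, jitter), 9, 3)
    mdframe(rbind(recept, lig), c(30, 30, 30), (f - 1) * 10)
  })
  mdtrajectory(top, frames)
}
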