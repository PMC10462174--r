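flat_marker_traj <- function(n = 60, R = 4, z = 0, noise = 0, seed = 1) {
  set.seed(seed)
  a <- seq(0, 2 * pi, length.out = n + 1)[-1]
  r <- R * sqrt(runif(n))
  xyz <- cbind(r * cos(a), r * sin(a), z + rnorm(n, 0, noise))
  atoms <- data.frame(atom_name = "P", element = "P", resname = "DMPC",
                      resseq = seq_len(n), chain = "L",
                      stringsAsFactors = FALSE)
  trajectory(atoms, xyz)
}

test_that("the bilayer normal is recovered for flat, rotated and noisy discs", {
  x <- flat_marker_traj()
  expect_equal(bilayer_normal(x), c(0, 0, 1), tolerance = 1e-9)
  # rotate 90 degrees about x: normal becomes +y
  Rx <- matrix(c(1, 0, 0, 0, 0, -1, 0, 1, 0), 3, 3, byrow = TRUE)
  y <- trajectory(x$atoms, frame_coords(x) %*% t(Rx))
  expect_gt(abs(sum(bilayer_normal(y) * c(0, 1, 0))), 0.999)
  nz <- flat_marker_traj(n = 200, noise = 0.1, seed = 7)
  expect_gt(abs(sum(bilayer_normal(nz) * c(0, 0, 1))), 0.99)
  # degenerate: collinear points
  bad <- trajectory(x$atoms[1:5, ], cbind(1:5, 0, 0))
  expect_error(bilayer_normal(bad, 1:5), "degenerate")
})

test_that("reorient centres the disc, aligns the normal and the major axis", {
  d <- small_disc()
  ro <- reorient(d$traj)
  x <- ro$traj
  lip <- select_atoms(x, resname = "DMPC")
  p <- intersect(lip, select_atoms(x, atom_name = "P"))
  for (f in c(1, n_frames(x))) {
    com <- discbelt:::centre_of_mass(x, lip, f)
    expect_equal(com, c(0, 0, 0), tolerance = 1e-9)
    sds <- apply(frame_coords(x, f)[lip, ], 2, sd)
    expect_gte(sds[1] + 1e-9, sds[2])  # major axis on x
  }
  # idempotence up to axis-sign flips
  ro2 <- reorient(x)
  expect_equal(abs(frame_coords(ro2$traj, 1)),
               abs(frame_coords(x, 1)), tolerance = 1e-6)
  # an arbitrarily rotated disc reorients to the same geometry
  th <- 0.9
  Rm <- matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)), 3, 3,
               byrow = TRUE)
  rot <- trajectory(d$traj$atoms, frame_coords(d$traj, 1) %*% t(Rm))
  rr <- reorient(rot)$traj
  # the recovered bilayer normal of the reoriented frame is +z, and the
  # phosphate planes sit symmetrically about the origin
  expect_gt(abs(sum(bilayer_normal(rr, p) * c(0, 0, 1))), 0.999)
  expect_equal(mean(frame_coords(rr, 1)[p, 3]), 0, tolerance = 0.05)
})

test_that("radius of gyration matches closed forms and is rigid-invariant", {
  two <- trajectory(
    data.frame(atom_name = "X", element = "C", resname = "UNK",
               resseq = 1:2, chain = "A", mass = 1),
    matrix(c(0, 0, 0, 2, 0, 0), ncol = 3, byrow = TRUE))
  expect_equal(radius_of_gyration(two), 1.0, tolerance = 1e-12)
  disc <- thin_disc_traj(n = 6000, R = 5)
  expect_equal(radius_of_gyration(disc), 5 / sqrt(2), tolerance = 0.02)
  th <- 1.1
  Rm <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3,
               byrow = TRUE)
  moved <- trajectory(disc$atoms,
                      sweep(frame_coords(disc) %*% t(Rm), 2, c(3, -2, 7), "+"))
  expect_equal(radius_of_gyration(moved), radius_of_gyration(disc),
               tolerance = 1e-12)
  expect_error(radius_of_gyration(disc, integer(0)), "empty")
})

test_that("Kabsch superposition agrees with the quaternion oracle", {
  set.seed(9)
  A <- matrix(rnorm(45), ncol = 3)
  th <- 0.6
  Rm <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3,
               byrow = TRUE)
  B <- A %*% t(Rm) + matrix(rep(c(1, -2, 0.5), each = 15), ncol = 3)
  expect_lt(kabsch_superpose(A, B)$rmsd, 1e-6)
  for (i in 1:5) {
    M <- matrix(rnorm(60), ncol = 3)
    N <- M + matrix(rnorm(60, 0, 0.3), ncol = 3)
    k <- kabsch_superpose(M, N)
    expect_equal(k$rmsd, quaternion_rmsd(M, N), tolerance = 1e-8)
    expect_equal(det(k$rotation), 1, tolerance = 1e-8)
    # superposed rmsd never exceeds the unsuperposed one
    expect_lte(k$rmsd, sqrt(mean(rowSums((M - N)^2))) + 1e-12)
  }
  # a reflected copy cannot reach rmsd 0 with a proper rotation
  C <- A; C[, 3] <- -C[, 3]
  expect_gt(kabsch_superpose(A, C)$rmsd, 0.1)
  expect_error(kabsch_superpose(A[1:2, ], C[1:2, ]), "at least 3")
  expect_error(kabsch_superpose(A, C[1:5, ]), "same number")
})

test_that("backbone RMSD series has the expected noise statistics and format", {
  d <- quiet_disc()
  base <- subset_frames(d$traj, 1)
  frozen <- perturb_frames(base, 0, 5, seed = 1)
  rs0 <- backbone_rmsd_series(frozen)
  expect_equal(rs0$mean, 0, tolerance = 1e-12)
  expect_equal(rs0$sd, 0, tolerance = 1e-12)
  # jittered frames vs the unjittered reference: per-atom displacement
  # sd*sqrt(3); the fitted reference removes a negligible 6/N dof share
  pf <- perturb_frames(base, 0.05, 100, seed = 4)
  comb <- trajectory(base$atoms,
                     array(c(base$coords, pf$coords),
                           dim = c(n_atoms(base), 3, 101)))
  rs <- backbone_rmsd_series(comb)
  per_frame_expect <- 0.05 * sqrt(3)
  expect_equal(mean(rs$rmsd[-1]), per_frame_expect, tolerance = 0.1)
  expect_match(format_rmsd(rs), "^[0-9]+\\.[0-9]{2} ± [0-9]+\\.[0-9]{2}$")
})

test_that("escaped lipids are exactly the displaced ones", {
  d <- quiet_disc()
  x <- subset_frames(d$traj, 1)
  expect_length(detect_escaped_lipids(x), 0)
  lip <- select_atoms(x, resname = "DMPC")
  ids <- unique(x$atoms$resseq[lip])
  move <- function(x, ids, shift) {
    xyz <- frame_coords(x)
    sel <- which(x$atoms$resseq %in% ids & x$atoms$resname == "DMPC")
    xyz[sel, 1] <- xyz[sel, 1] + shift
    trajectory(x$atoms, xyz)
  }
  one <- move(x, ids[5], 10)
  expect_identical(detect_escaped_lipids(one), ids[5])
  # two lipids displaced together: both reported, matching a brute-force
  # check that they are farther than max_gap from every remaining lipid
  pair <- sort(c(ids[5], ids[6]))
  two <- move(x, pair, 15)
  got <- detect_escaped_lipids(two)
  expect_identical(got, pair)
  cen <- discbelt:::residue_centroids(two, select_atoms(two, resname = "DMPC"))
  rid <- as.integer(sub(".*\\|", "", rownames(cen)))
  dmat <- as.matrix(dist(cen))
  cross <- dmat[rid %in% pair, !(rid %in% pair)]
  expect_gt(min(cross), 2.0)
})
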