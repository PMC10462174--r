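test_that("linearisation keeps every helix internally rigid and extends
           the chain", {
  b <- bundle_fix()
  ext <- linearize_bundle(b$traj, b$segments)
  xin <- frame_coords(b$traj, 1); xout <- frame_coords(ext$traj, 1)
  for (s in seq_len(nrow(b$segments))) {
    idx <- which(b$traj$atoms$resseq >= b$segments$start[s] &
                   b$traj$atoms$resseq <= b$segments$end[s])
    expect_lt(kabsch_superpose(xin[idx, ], xout[idx, ])$rmsd, 1e-9)
  }
  e2e <- function(xyz, atoms) {
    cas <- which(atoms$atom_name == "CA")
    sqrt(sum((xyz[cas[length(cas)], ] - xyz[cas[1], ])^2))
  }
  expect_gt(e2e(xout, ext$traj$atoms), e2e(xin, b$traj$atoms))
  # an already-extended chain is (nearly) a fixed point
  ext2 <- linearize_bundle(ext$traj, ext$segments)
  n <- n_atoms(ext$traj)
  rmsd <- sqrt(mean(rowSums((frame_coords(ext2$traj, 1) -
                               frame_coords(ext$traj, 1))^2)))
  expect_lt(rmsd, 0.1)
  expect_error(linearize_bundle(b$traj,
                                data.frame(start = 1, end = 9999)),
               "outside")
})

test_that("double-belt assembly honours the tandem gap and ring geometry", {
  b <- bundle_fix()
  ext <- linearize_bundle(b$traj, b$segments)
  for (mode in c("parallel", "antiparallel")) {
    belt <- assemble_double_belt(ext, mode)
    tb <- belt$traj
    expect_setequal(unique(tb$atoms$chain), c("A", "B", "C", "D"))
    ca_of <- function(ch, which_end) {
      idx <- select_atoms(tb, chain = ch, atom_name = "CA")
      r <- tb$atoms$resseq[idx]
      idx[if (which_end == "first") which.min(r) else which.max(r)]
    }
    xyz <- frame_coords(tb, 1)
    gaps <- c(
      sqrt(sum((xyz[ca_of("A", "last"), ] - xyz[ca_of("B", "first"), ])^2)),
      sqrt(sum((xyz[ca_of("B", "last"), ] - xyz[ca_of("A", "first"), ])^2)),
      sqrt(sum((xyz[ca_of("C", "last"), ] - xyz[ca_of("D", "first"), ])^2)),
      sqrt(sum((xyz[ca_of("D", "last"), ] - xyz[ca_of("C", "first"), ])^2)))
    expect_true(all(abs(gaps - 0.5) < 0.05))
    # each helix stays internally rigid through linearise + bend
    for (s in seq_len(nrow(b$segments))) {
      idx <- which(tb$atoms$chain == "A" &
                     tb$atoms$resseq >= b$segments$start[s] &
                     tb$atoms$resseq <= b$segments$end[s])
      ref <- which(b$traj$atoms$resseq >= b$segments$start[s] &
                     b$traj$atoms$resseq <= b$segments$end[s])
      expect_lt(kabsch_superpose(frame_coords(b$traj, 1)[ref, ],
                                 xyz[idx, ])$rmsd, 1e-9)
    }
  }
})

test_that("parallel and antiparallel builds differ only in the lower ring's
           angular sense", {
  b <- bundle_fix()
  ext <- linearize_bundle(b$traj, b$segments)
  par <- assemble_double_belt(ext, "parallel")
  anti <- assemble_double_belt(ext, "antiparallel")
  expect_equal(par$ring_radius, anti$ring_radius)
  expect_equal(n_atoms(par$traj), n_atoms(anti$traj))
  up <- select_atoms(par$traj, chain = c("A", "B"))
  expect_equal(frame_coords(par$traj, 1)[up, ],
               frame_coords(anti$traj, 1)[up, ])
  sense <- function(belt, ch) {
    idx <- select_atoms(belt$traj, chain = ch, atom_name = "CA")
    idx <- idx[order(belt$traj$atoms$resseq[idx])]
    xyz <- frame_coords(belt$traj, 1)[idx, ]
    ang <- atan2(xyz[, 2], xyz[, 1])
    sign(sum(sign(diff(unwrap_angles(ang)))))
  }
  unwrap_angles <- function(a) {
    d <- diff(a); d <- ifelse(d > pi, d - 2 * pi, ifelse(d < -pi, d + 2 * pi, d))
    cumsum(c(a[1], d))
  }
  expect_equal(sense(par, "A"), sense(par, "C"))
  expect_equal(sense(anti, "A"), -sense(anti, "C"))
})

test_that("lipid packing fills both leaflets inside the belt without clashes", {
  b <- bundle_fix()
  ext <- linearize_bundle(b$traj, b$segments)
  belt <- assemble_double_belt(ext, "antiparallel")
  lip <- pack_lipid_disc(240, belt)
  p <- select_atoms(lip, atom_name = "P")
  z <- frame_coords(lip, 1)[p, 3]
  expect_equal(sum(z > 0), 120)
  expect_equal(sum(z < 0), 120)
  heavy <- which(lip$atoms$element != "H")
  mind <- discbelt:::min_cross_distance(frame_coords(lip, 1)[heavy, ],
                                        frame_coords(belt$traj, 1))
  expect_gt(mind, 0.2)
  expect_error(pack_lipid_disc(241, belt), "even")
  expect_error(pack_lipid_disc(5000, belt), "ring radius")
})

test_that("built systems are labelled, intact, and warn outside the stable
           size range", {
  b <- bundle_fix()
  sys <- build_system(b, 240, "antiparallel")
  expect_equal(sys$label, "240-A")
  expect_length(detect_escaped_lipids(sys$traj), 0)
  expect_warning(build_system(b, 230, "parallel"), "stable")
  # analysed with the density suite, the belt lies outside the lipids
  ro <- reorient(sys$traj)$traj
  lip <- select_atoms(ro, resname = "DMPC")
  prot <- setdiff(seq_len(n_atoms(ro)), lip)
  dp <- diameter_from_protein(symmetrize_profile(
    mass_density_profile(ro, prot, "x")))
  dl <- diameter_from_lipid(symmetrize_profile(
    mass_density_profile(ro, lip, "x")))
  expect_gt(dp, dl)
})
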