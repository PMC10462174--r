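#' Specification of a synthetic nanodisc
#'
#' Collects every parameter of the synthetic-nanodisc generator. The
#' generator emits an idealised discoidal DMPC-like bilayer (two leaflets of
#' a minimal explicit-hydrogen lipid surrogate, phosphate planes at
#' +/- separation/2) encircled by four helical poly-alanine belt chains, and
#' records the exact ground truth so analysis results can be checked.
#'
#' @param n_lipids_per_leaflet Lipids per leaflet (>= 1).
#' @param area_per_lipid Area per lipid in nm^2 (default 0.60, a typical
#'   fluid-phase DMPC value). The disc radius is
#'   `sqrt(n_lipids_per_leaflet * area_per_lipid / pi)`.
#' @param phosphate_plane_separation Distance between the two phosphate
#'   planes in nm (default 3.4, the measured all-atom DMPC disc thickness).
#' @param tail_tilt Tail-director statistics about the disc normal: a list
#'   `list(kind = "fixed", theta = radians)`, `list(kind = "gaussian",
#'   mu =, sigma = )` or `list(kind = "isotropic")`.
#' @param belt List with `radius_offset` (belt ring radius minus disc radius,
#'   nm), `ring_separation` (z distance between the two rings, nm), `mode`
#'   ("parallel"/"antiparallel") and `n_chains` (fixed at 4).
#' @param rim_tilt_sd Extra Gaussian tilt (sd, radians) applied to lipids
#'   within `rim_width` of the disc edge; models rim-localised disorder.
#' @param rim_width Width of the disordered rim annulus, nm.
#' @param noise_sigma Per-frame isotropic Gaussian positional noise, nm (default 0.05, a realistic thermal displacement amplitude).
#' @param n_frames Number of frames to emit.
#' @param seed RNG seed; recorded in the ground truth.
#' @return A `disc_spec` list.
#' @export
disc_spec <- function(n_lipids_per_leaflet = 120,
                      area_per_lipid = 0.60,
                      phosphate_plane_separation = 3.4,
                      tail_tilt = list(kind = "fixed", theta = 0),
                      belt = list(n_chains = 4L, radius_offset = 0.8,
                                  ring_separation = 1.8,
                                  mode = "antiparallel"),
                      rim_tilt_sd = 0, rim_width = 1.0,
                      noise_sigma = 0.05, n_frames = 1L, seed = 1L) {
  stopifnot(n_lipids_per_leaflet >= 1, area_per_lipid > 0,
            phosphate_plane_separation > 0, noise_sigma >= 0, n_frames >= 1)
  belt_def <- list(n_chains = 4L, radius_offset = 0.8, ring_separation = 1.8,
                   mode = "antiparallel")
  belt <- utils::modifyList(belt_def, belt)
  belt$mode <- match.arg(belt$mode, c("parallel", "antiparallel"))
  structure(list(n_lipids_per_leaflet = as.integer(n_lipids_per_leaflet),
                 area_per_lipid = area_per_lipid,
                 phosphate_plane_separation = phosphate_plane_separation,
                 tail_tilt = tail_tilt, belt = belt,
                 rim_tilt_sd = rim_tilt_sd, rim_width = rim_width,
                 noise_sigma = noise_sigma, n_frames = as.integer(n_frames),
                 seed = as.integer(seed)),
            class = "disc_spec")
}

# Run `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Tail geometry constants of the lipid surrogate (nm).
.tail <- list(n_carbon = 13L,          # carbons 2..14 of a myristoyl chain
              first_z = -0.35,         # first tail carbon below the P atom
              dz = 0.125,              # rise per carbon along the chain
              ch = 0.109,              # C-H bond length
              sn_offset = 0.22)        # lateral sn1/sn2 separation from axis

# Minimal all-atom DMPC surrogate in local coordinates: P at the origin,
# tails descending along -z. Atom names follow CHARMM36 DMPC conventions
# (sn2: C2k with H(k)R/H(k)S; sn1: C3k with H(k)X/H(k)Y) so name-based
# selection works unchanged on real force-field output.
lipid_template <- function() {
  ks <- seq_len(.tail$n_carbon) + 1L   # carbon indices 2..14
  zc <- .tail$first_z - (ks - 2L) * .tail$dz
  nm <- "P"; xyz <- matrix(c(0, 0, 0), ncol = 3)
  for (sn in c(3L, 2L)) {              # sn1 chain first, then sn2
    xoff <- if (sn == 3L) -.tail$sn_offset else .tail$sn_offset
    hsuf <- if (sn == 3L) c("X", "Y") else c("R", "S")
    for (j in seq_along(ks)) {
      k <- ks[j]
      nm <- c(nm, sprintf("C%d%d", sn, k),
              sprintf("H%d%s", k, hsuf[1]), sprintf("H%d%s", k, hsuf[2]))
      # both hydrogens perpendicular to the (local) chain axis
      xyz <- rbind(xyz,
                   c(xoff, 0, zc[j]),
                   c(xoff, .tail$ch, zc[j]),
                   c(xoff, -.tail$ch, zc[j]))
    }
  }
  list(atom_name = nm, xyz = xyz)
}

# Rotation taking +z to the unit vector d.
rotation_z_to <- function(d) {
  d <- d / sqrt(sum(d^2))
  z <- c(0, 0, 1)
  v <- c(z[2] * d[3] - z[3] * d[2], z[3] * d[1] - z[1] * d[3],
         z[1] * d[2] - z[2] * d[1])
  c_ <- sum(z * d)
  if (abs(c_ - 1) < 1e-12) return(diag(3))
  if (abs(c_ + 1) < 1e-12) return(diag(c(1, -1, -1)))
  vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3,
               byrow = TRUE)
  diag(3) + vx + vx %*% vx / (1 + c_)
}

rot_z <- function(phi) {
  matrix(c(cos(phi), -sin(phi), 0, sin(phi), cos(phi), 0, 0, 0, 1),
         3, 3, byrow = TRUE)
}

# Maximum lateral distance of any template atom from the lipid axis: the
# molecular footprint radius, used so the packed disc's atomic edge sits at
# the ground-truth radius.
lipid_footprint <- function() {
  tpl <- lipid_template()
  sqrt(max(tpl$xyz[, 1]^2 + tpl$xyz[, 2]^2))
}

# Uniform packing of n lipid sites in a disc via the Vogel (sunflower /
# golden-angle) spiral: r_k = R*sqrt((k-1/2)/n) gives exactly
# area_per_lipid per site with an isotropic, circular boundary. (A plain
# hexagonal cut-out has a hexagonal edge whose circumradius and apothem
# differ by 13%, which would bias per-axis diameter estimates.) The
# outermost sites sit at R - edge_margin; with edge_margin the molecular
# footprint, the outermost atoms then reach the ground-truth radius.
disc_packing_sites <- function(n, area_per_lipid, edge_margin = 0) {
  R <- sqrt(n * area_per_lipid / pi) - edge_margin
  k <- seq_len(n)
  r <- R * sqrt((k - 0.5) / n)
  theta <- k * pi * (3 - sqrt(5))
  cbind(r * cos(theta), r * sin(theta))
}

# Sample one tail-director unit vector for the given tilt model; `down`
# flips the director for the lower leaflet.
sample_director <- function(tilt, extra_sd = 0) {
  theta <- switch(tilt$kind,
    fixed = tilt$theta,
    gaussian = abs(stats::rnorm(1, tilt$mu, tilt$sigma)),
    isotropic = acos(stats::runif(1, -1, 1)),
    stop("unknown tail_tilt kind: ", tilt$kind))
  if (extra_sd > 0) theta <- theta + abs(stats::rnorm(1, 0, extra_sd))
  phi <- stats::runif(1, 0, 2 * pi)
  c(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))
}

# Build all lipids of one disc/patch. `sites` nx2 lateral positions; returns
# atoms data.frame + coords + per-carbon C-H bond vectors for ground truth.
build_lipids <- function(sites, spec, resseq_start = 1L) {
  tpl <- lipid_template()
  n_at <- length(tpl$atom_name)
  n <- nrow(sites)
  R_edge <- sqrt(max(sites[, 1]^2 + sites[, 2]^2))
  coords <- matrix(0, nrow = 2L * n * n_at, ncol = 3)
  atom_name <- character(2L * n * n_at)
  resseq <- integer(2L * n * n_at)
  row <- 0L; res <- resseq_start - 1L
  for (leaf in c(1, -1)) {
    zP <- leaf * spec$phosphate_plane_separation / 2
    for (i in seq_len(n)) {
      res <- res + 1L
      r_site <- sqrt(sum(sites[i, ]^2))
      extra <- if (r_site > R_edge - spec$rim_width) spec$rim_tilt_sd else 0
      d <- sample_director(spec$tail_tilt, extra)
      Rt <- rotation_z_to(d)
      Rphi <- rot_z(stats::runif(1, 0, 2 * pi))
      loc <- tpl$xyz
      if (leaf < 0) loc[, 3] <- -loc[, 3]
      xyz <- loc %*% t(Rphi) %*% t(Rt)
      xyz[, 1] <- xyz[, 1] + sites[i, 1]
      xyz[, 2] <- xyz[, 2] + sites[i, 2]
      xyz[, 3] <- xyz[, 3] + zP
      idx <- row + seq_len(n_at)
      coords[idx, ] <- xyz
      atom_name[idx] <- tpl$atom_name
      resseq[idx] <- res
      row <- row + n_at
    }
  }
  atoms <- data.frame(atom_name = atom_name,
                      element = element_from_name(atom_name),
                      resname = "DMPC", resseq = resseq, chain = "L",
                      stringsAsFactors = FALSE)
  list(atoms = atoms, coords = coords)
}

# Ideal alpha-helical poly-alanine ribbon wound along a circular arc of
# radius R at height z0, spanning angles [phi0, phi1] (sense given by their
# order). Backbone N/CA/C/O/CB per residue; 1.5 A rise per residue along
# the arc, 100 deg/residue winding of radius 0.23 nm about the arc tangent.
belt_chain <- function(R, z0, phi0, phi1, chain_id, resseq_start = 1L) {
  rise <- 0.15; twist <- 100 * pi / 180; rh <- 0.23
  arc <- abs(phi1 - phi0) * R
  nres <- max(4L, floor(arc / rise))
  phis <- seq(phi0, phi1, length.out = nres)
  # local frame at angle phi: tangent t, radial u, vertical w
  offs <- list(N  = c(-0.05, 0.12, 0), CA = c(0, 0, 0),
               C  = c(0.05, -0.10, 0.05), O = c(0.05, -0.22, 0.10),
               CB = c(0, 0.15, -0.10))
  nm <- character(0); xyz <- NULL; rs <- integer(0)
  for (i in seq_len(nres)) {
    phi <- phis[i]
    u <- c(cos(phi), sin(phi), 0)
    t <- c(-sin(phi), cos(phi), 0) * sign(phi1 - phi0)
    w <- c(0, 0, 1)
    ang <- (i - 1) * twist
    # CA on a helix of radius rh about the arc axis
    ca <- R * u + z0 * w + rh * (cos(ang) * u + sin(ang) * w)
    for (an in names(offs)) {
      o <- offs[[an]]
      p <- ca + o[1] * t +
        o[2] * (cos(ang) * u + sin(ang) * w) +
        o[3] * (-sin(ang) * u + cos(ang) * w)
      xyz <- rbind(xyz, p)
      nm <- c(nm, an)
      rs <- c(rs, resseq_start + i - 1L)
    }
  }
  list(atoms = data.frame(atom_name = nm, element = element_from_name(nm),
                          resname = "ALA", resseq = rs, chain = chain_id,
                          stringsAsFactors = FALSE),
       coords = unname(xyz))
}

# Four-chain double belt around radius R_belt: chains A,B upper ring, C,D
# lower; antiparallel mode reverses the angular sense of the lower ring.
build_belt <- function(R_belt, ring_separation, mode) {
  gap_ang <- 0.5 / R_belt  # ~0.5 nm angular gap between tandem chains
  zu <- ring_separation / 2; zl <- -ring_separation / 2
  up1 <- belt_chain(R_belt, zu, gap_ang / 2, pi - gap_ang / 2, "A")
  up2 <- belt_chain(R_belt, zu, pi + gap_ang / 2, 2 * pi - gap_ang / 2, "B")
  if (mode == "parallel") {
    lo1 <- belt_chain(R_belt, zl, gap_ang / 2, pi - gap_ang / 2, "C")
    lo2 <- belt_chain(R_belt, zl, pi + gap_ang / 2, 2 * pi - gap_ang / 2, "D")
  } else {
    lo1 <- belt_chain(R_belt, zl, pi - gap_ang / 2, gap_ang / 2, "C")
    lo2 <- belt_chain(R_belt, zl, 2 * pi - gap_ang / 2, pi + gap_ang / 2, "D")
  }
  list(atoms = rbind(up1$atoms, up2$atoms, lo1$atoms, lo2$atoms),
       coords = rbind(up1$coords, up2$coords, lo1$coords, lo2$coords))
}

# Per-carbon |S_CD| implied by the constructed C-H bond directions of the
# noise-free base frame (closed-form ground truth for the analysis stage).
analytic_scd <- function(traj) {
  prof <- scd_profile(traj, reoriented = TRUE)
  prof$abs_scd
}

#' Generate a synthetic nanodisc trajectory with known ground truth
#'
#' Two leaflets of an explicit-hydrogen DMPC surrogate are uniformly packed
#' (golden-angle spiral) within the disc radius
#' `sqrt(n * area_per_lipid / pi)`, phosphate planes at
#' +/- separation/2, encircled by four helical poly-alanine belt chains
#' (A/B upper ring, C/D lower; antiparallel mode reverses the lower ring's
#' angular sense). Per-frame isotropic Gaussian noise emulates thermal
#' motion. Deterministic under a fixed seed.
#'
#' @param spec A [disc_spec()].
#' @return List with `traj` (a [trajectory()]) and `truth` (ground-truth
#'   list: `disc_radius`, `thickness`, `belt_radius`, `expected_scd`,
#'   `label`, `seed`).
#' @export
generate_nanodisc <- function(spec = disc_spec()) {
  stopifnot(inherits(spec, "disc_spec"))
  R_disc <- sqrt(spec$n_lipids_per_leaflet * spec$area_per_lipid / pi)
  R_belt <- R_disc + spec$belt$radius_offset
  if (R_belt < R_disc)
    stop("belt radius (", round(R_belt, 2), " nm) smaller than disc radius (",
         round(R_disc, 2), " nm)")
  with_seed(spec$seed, {
    # place the outermost ring one molecular footprint inside the
    # ground-truth radius: the atomic density edge, which is what a
    # density-threshold diameter measures, then sits at the radius itself
    sites <- disc_packing_sites(spec$n_lipids_per_leaflet, spec$area_per_lipid,
                            edge_margin = lipid_footprint())
    lip <- build_lipids(sites, spec)
    belt <- build_belt(R_belt, spec$belt$ring_separation, spec$belt$mode)
    atoms <- rbind(lip$atoms, belt$atoms)
    base <- rbind(lip$coords, belt$coords)
    traj0 <- trajectory(atoms, base)
    expected <- analytic_scd(traj0)
    traj <- jitter_frames(atoms, base, spec$noise_sigma, spec$n_frames)
    label <- system_label(2L * spec$n_lipids_per_leaflet, spec$belt$mode)
    list(traj = traj,
         truth = list(disc_radius = R_disc,
                      thickness = spec$phosphate_plane_separation,
                      belt_radius = R_belt, expected_scd = expected,
                      label = label, seed = spec$seed,
                      n_lipids = 2L * spec$n_lipids_per_leaflet,
                      mode = spec$belt$mode))
  })
}

#' Generate a rectangular bilayer patch (no belt)
#'
#' Reference system emulating a pure DMPC membrane: by default 75 lipids per
#' leaflet (150 total), hexagonally packed on a rectangle, same surrogate as
#' the disc, with a periodic box recorded.
#'
#' @param n_per_leaflet Lipids per leaflet (default 75).
#' @param spec A [disc_spec()] supplying everything but the lipid count and
#'   belt (which a patch does not have).
#' @return List with `traj` and `truth` (thickness, label "patch", seed).
#' @export
generate_bilayer_patch <- function(n_per_leaflet = 75, spec = disc_spec()) {
  stopifnot(n_per_leaflet >= 1)
  a <- sqrt(2 * spec$area_per_lipid / sqrt(3))
  nx <- ceiling(sqrt(n_per_leaflet))
  ny <- ceiling(n_per_leaflet / nx)
  ij <- expand.grid(i = seq_len(nx) - 1L, j = seq_len(ny) - 1L)
  xs <- (ij$i + 0.5 * (ij$j %% 2)) * a
  ys <- ij$j * a * sqrt(3) / 2
  sites <- cbind(xs, ys)[seq_len(n_per_leaflet), , drop = FALSE]
  sites <- sweep(sites, 2, colMeans(sites))
  spec2 <- spec; spec2$rim_tilt_sd <- 0
  with_seed(spec$seed, {
    lip <- build_lipids(sites, spec2)
    box <- c(nx * a, ny * a * sqrt(3) / 2,
             spec$phosphate_plane_separation + 4)
    traj <- jitter_frames(lip$atoms, lip$coords, spec$noise_sigma,
                          spec$n_frames, box = box)
    list(traj = traj,
         truth = list(thickness = spec$phosphate_plane_separation,
                      label = "patch", seed = spec$seed,
                      n_lipids = 2L * n_per_leaflet))
  })
}

# n_frames Gaussian-jittered copies of the base coordinates (assumes the
# caller has already seeded the RNG stream). Thermal noise is applied as a
# rigid per-residue displacement: real dynamics never decorrelates bonded
# atoms, and independent per-atom jitter would randomise C-H bond
# directions (destroying the order-parameter ground truth).
jitter_frames <- function(atoms, base, sigma, n_frames, box = NULL) {
  na <- nrow(base)
  rkey <- paste(atoms$chain, atoms$resseq)
  ridx <- match(rkey, unique(rkey))
  nres <- max(ridx)
  coords <- array(0, dim = c(na, 3, n_frames))
  for (f in seq_len(n_frames)) {
    coords[, , f] <- if (sigma > 0)
      base + matrix(stats::rnorm(3 * nres, 0, sigma), ncol = 3)[ridx, ]
    else base
  }
  trajectory(atoms, coords, box = box)
}

#' Gaussian-perturbed copies of a trajectory's first frame
#'
#' Emulates snapshot averaging: returns `n_frames` independent isotropic
#' Gaussian jitters of frame 1. `sigma = 0` returns identical frames.
#'
#' @param x A `trajectory`.
#' @param sigma Positional noise sd, nm (>= 0).
#' @param n_frames Number of frames to emit.
#' @param seed RNG seed.
#' @return A `trajectory` with `n_frames` frames.
#' @export
perturb_frames <- function(x, sigma, n_frames, seed = 1L) {
  stopifnot(sigma >= 0, n_frames >= 1)
  base <- frame_coords(x, 1)
  with_seed(seed, jitter_frames(x$atoms, base, sigma, n_frames, box = x$box))
}
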