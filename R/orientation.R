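#' Bilayer normal from phosphate positions
#'
#' The normal is taken from the eigenbasis of the positional covariance
#' matrix of the selected atoms (conventionally the lipid phosphates).
#' For a wide flat disc it is the eigenvector with the smallest eigenvalue
#' (minimal out-of-plane variance); because the two phosphate planes of a
#' small disc can contribute as much variance along the normal as the disc
#' radius does in plane, the axis is chosen as the eigenvector along which
#' the phosphate coordinates collapse onto one or two tight planes,
#' which coincides with the smallest-eigenvalue axis whenever the disc is
#' wide. The sign is fixed so the z-component is non-negative.
#'
#' @param x A `trajectory`.
#' @param lipid_sel Atom indices of the in-plane marker atoms (default: all
#'   atoms named "P").
#' @param frame Frame index.
#' @return Unit length-3 vector.
#' @export
bilayer_normal <- function(x, lipid_sel = select_atoms(x, atom_name = "P"),
                           frame = 1L) {
  if (length(lipid_sel) < 3) stop("need at least 3 atoms to fit a plane")
  xyz <- x$coords[lipid_sel, , frame]
  cv <- stats::cov(xyz)
  ev <- eigen(cv, symmetric = TRUE)
  if (ev$values[2] < 1e-12)
    stop("degenerate atom arrangement: cannot determine a bilayer normal")
  centred <- sweep(xyz, 2, colMeans(xyz))
  # per candidate axis, the mean spread within each side of the centre:
  # along the normal the phosphates collapse onto one or two tight planes
  # (spread ~ thermal noise), while along any in-plane axis they spread
  # over a sizeable fraction of the disc radius
  score <- vapply(1:3, function(k) {
    v <- centred %*% ev$vectors[, k]
    up <- v[v >= 0]; dn <- v[v < 0]
    w <- c(if (length(up) > 1) stats::sd(up) else 0,
           if (length(dn) > 1) stats::sd(dn) else 0)
    mean(w)
  }, numeric(1))
  n <- ev$vectors[, which.min(score)]
  if (n[3] < 0) n <- -n
  n / sqrt(sum(n^2))
}

#' Reorient a trajectory so the bilayer normal is the z-axis
#'
#' Every frame is translated so the lipid centre of mass sits at the origin
#' and rotated so the bilayer normal (from [bilayer_normal()]) points along
#' +z. The in-plane principal axes are aligned so the larger in-plane
#' variance lies along x (major axis = x), resolving the x/y choice when
#' reporting per-axis diameters of elliptical discs.
#'
#' @param x A `trajectory`.
#' @param lipid_sel Atom indices defining the bilayer (default: lipid
#'   residues "DMPC", falling back to all atoms).
#' @return List with `traj` (reoriented trajectory) and `transforms` (per
#'   frame: list(rotation = 3x3, translation = length-3)). Applying
#'   `rotation %*% (p - translation)` maps original to reoriented
#'   coordinates.
#' @export
reorient <- function(x, lipid_sel = NULL) {
  if (is.null(lipid_sel)) {
    lipid_sel <- select_atoms(x, resname = "DMPC")
    if (length(lipid_sel) == 0) lipid_sel <- seq_len(n_atoms(x))
  }
  p_sel <- intersect(lipid_sel, select_atoms(x, atom_name = "P"))
  if (length(p_sel) < 3) p_sel <- lipid_sel
  out <- x$coords
  transforms <- vector("list", n_frames(x))
  for (f in seq_len(n_frames(x))) {
    com <- centre_of_mass(x, lipid_sel, f)
    nrm <- bilayer_normal(x, p_sel, f)
    R1 <- rotation_z_to(nrm)      # maps +z to the normal
    R <- t(R1)                    # so R maps the normal to +z
    xyz <- sweep(frame_coords(x, f), 2, com) %*% t(R)
    # in-plane principal axes of the lipid selection: major axis -> x
    lp <- xyz[lipid_sel, 1:2, drop = FALSE]
    cv <- stats::cov(lp)
    ev <- eigen(cv, symmetric = TRUE)
    a1 <- ev$vectors[, 1]
    ang <- atan2(a1[2], a1[1])
    R2 <- rot_z(-ang)
    xyz <- xyz %*% t(R2)
    out[, , f] <- xyz
    transforms[[f]] <- list(rotation = R2 %*% R, translation = com)
  }
  list(traj = trajectory(x$atoms, out, times = x$times, box = x$box),
       transforms = transforms)
}

#' Radius of gyration
#'
#' Mass-weighted root-mean-square distance of the selected atoms from their
#' centre of mass. Averaged over frames when `frames` has length > 1.
#'
#' @param x A `trajectory`.
#' @param sel Atom indices (default all).
#' @param frames Frame indices (default all).
#' @return Rg in nm (mean over the requested frames).
#' @export
radius_of_gyration <- function(x, sel = seq_len(n_atoms(x)),
                               frames = seq_len(n_frames(x))) {
  if (length(sel) == 0) stop("empty selection has no radius of gyration")
  m <- x$atoms$mass[sel]
  vals <- vapply(frames, function(f) {
    xyz <- x$coords[sel, , f, drop = FALSE]
    dim(xyz) <- c(length(sel), 3)
    com <- colSums(xyz * m) / sum(m)
    d2 <- rowSums(sweep(xyz, 2, com)^2)
    sqrt(sum(m * d2) / sum(m))
  }, numeric(1))
  mean(vals)
}

#' Optimal (Kabsch) superposition of two coordinate sets
#'
#' Least-squares rigid superposition of `mobile` onto `reference` with a
#' proper rotation enforced (det = +1), returning the transform and the
#' minimised RMSD.
#'
#' @param reference,mobile `n x 3` coordinate matrices (equal n >= 3), nm.
#' @return List with `rotation` (3x3), `translation` (length 3; the fitted
#'   mobile is `(mobile - centroid_mobile) %*% t(rotation) +
#'   centroid_reference`) and `rmsd` (nm).
#' @export
kabsch_superpose <- function(reference, mobile) {
  reference <- as.matrix(reference); mobile <- as.matrix(mobile)
  if (nrow(reference) != nrow(mobile))
    stop("reference and mobile must have the same number of atoms")
  if (nrow(reference) < 3) stop("need at least 3 atoms to superpose")
  cr <- colMeans(reference); cm <- colMeans(mobile)
  A <- sweep(reference, 2, cr); B <- sweep(mobile, 2, cm)
  H <- t(B) %*% A
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  fitted <- B %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - A)^2)))
  list(rotation = R, translation = cr, rmsd = rmsd)
}

#' Per-frame backbone RMSD against a reference frame
#'
#' Each frame is Kabsch-superposed onto the reference before the RMSD is
#' taken, using the backbone heavy atoms N, CA, C, O by default.
#'
#' @param x A `trajectory`.
#' @param reference_frame Index of the reference frame (default 1).
#' @param sel Atom indices to fit and measure (default backbone N/CA/C/O).
#' @return An `rmsd_series`: list with `rmsd` (per frame, nm), `times`,
#'   `mean`, `sd`.
#' @export
backbone_rmsd_series <- function(x, reference_frame = 1L,
                                 sel = select_backbone(x)) {
  if (length(sel) < 3) stop("backbone selection too small")
  ref <- x$coords[sel, , reference_frame]
  vals <- vapply(seq_len(n_frames(x)), function(f)
    kabsch_superpose(ref, x$coords[sel, , f])$rmsd, numeric(1))
  structure(list(rmsd = vals, times = x$times, mean = mean(vals),
                 sd = stats::sd(vals)),
            class = "rmsd_series")
}

#' @export
print.rmsd_series <- function(x, ...) {
  cat("backbone RMSD over", length(x$rmsd), "frames:",
      format_rmsd(x), "nm\n")
  invisible(x)
}

#' Format an RMSD series as "mean ± sd"
#' @param x An `rmsd_series`.
#' @param digits Decimal places (default 2).
#' @return Character scalar like "0.48 ± 0.10".
#' @export
format_rmsd <- function(x, digits = 2) {
  sprintf(paste0("%.", digits, "f ± %.", digits, "f"),
          x$mean, if (is.na(x$sd)) 0 else x$sd)
}

#' Detect lipids that escaped the nanodisc cluster
#'
#' Single-linkage clustering of lipid residue centroids at linkage distance
#' `max_gap`; every lipid outside the largest cluster is reported escaped.
#'
#' @param x A `trajectory`.
#' @param lipid_sel Atom indices of the lipids (default residues "DMPC").
#' @param max_gap Linkage distance in nm (default 2.0: it must exceed both
#'   the in-plane nearest-neighbour spacing, about 0.9 nm at 0.60 nm^2 per
#'   lipid, and the inter-leaflet centroid separation, about 1.7 nm, or an
#'   intact bilayer splits into two clusters).
#' @param frame Frame index.
#' @return Integer vector of escaped lipid residue ids (possibly empty).
#' @export
detect_escaped_lipids <- function(x, lipid_sel = select_atoms(x, resname = "DMPC"),
                                  max_gap = 2.0, frame = 1L) {
  if (length(lipid_sel) == 0) return(integer(0))
  cen <- residue_centroids(x, lipid_sel, frame)
  ids <- as.integer(sub(".*\\|", "", rownames(cen)))
  if (nrow(cen) == 1) return(integer(0))
  hc <- stats::hclust(stats::dist(cen), method = "single")
  cl <- stats::cutree(hc, h = max_gap)
  main <- as.integer(names(which.max(table(cl))))
  sort(ids[cl != main])
}
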