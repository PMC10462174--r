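# amu per nm^3 -> kg per m^3
.amu_nm3_to_kg_m3 <- 1.66053906660

#' Binned mass density profile along one axis
#'
#' Time-averaged mass histogram of a selection along x, y or z, converted to
#' kg/m^3 using a per-bin slab volume of bin width times the cross-section
#' of the full system's bounding box in the orthogonal plane (fixed per
#' trajectory and recorded in the result). Frames should be reoriented (see
#' [reorient()]) before profiling a nanodisc.
#'
#' @param x A `trajectory`.
#' @param sel Atom indices to profile (non-empty).
#' @param axis "x", "y" or "z".
#' @param n_bins Number of bins (default 100).
#' @param extent Length-2 numeric `c(lo, hi)` in nm; default the full-system
#'   bounding box along `axis` plus a 1 nm margin each side.
#' @param frames Frame indices to average over (default all).
#' @return A `density_profile`: list with `axis`, `bin_edges` (length
#'   `n_bins + 1`), `density` (kg/m^3 per bin), `cross_section` (nm^2),
#'   `n_frames`, `selection_mass` (amu, per frame).
#' @export
mass_density_profile <- function(x, sel, axis = c("z", "x", "y"),
                                 n_bins = 100, extent = NULL,
                                 frames = seq_len(n_frames(x))) {
  axis <- match.arg(axis)
  if (length(sel) == 0) stop("cannot profile an empty selection")
  ax <- match(axis, c("x", "y", "z"))
  others <- setdiff(1:3, ax)
  all_xyz <- x$coords[, , frames, drop = FALSE]
  if (is.null(extent))
    extent <- range(all_xyz[, ax, ]) + c(-1, 1)
  cross <- prod(vapply(others, function(d)
    max(diff(range(all_xyz[, d, ])), 1e-6), numeric(1)))
  edges <- seq(extent[1], extent[2], length.out = n_bins + 1)
  bw <- diff(edges)[1]
  m <- x$atoms$mass[sel]
  acc <- numeric(n_bins)
  for (f in seq_along(frames)) {
    v <- all_xyz[sel, ax, f]
    idx <- findInterval(v, edges, rightmost.closed = TRUE)
    ok <- idx >= 1 & idx <= n_bins
    acc <- acc + as.numeric(tapply(m[ok], factor(idx[ok], levels = 1:n_bins),
                                   sum, default = 0))
  }
  mass_per_bin <- acc / length(frames)
  density <- mass_per_bin / (bw * cross) * .amu_nm3_to_kg_m3
  structure(list(axis = axis, bin_edges = edges, density = density,
                 cross_section = cross, n_frames = length(frames),
                 selection_mass = sum(m)),
            class = "density_profile")
}

bin_centres <- function(p) (head(p$bin_edges, -1) + tail(p$bin_edges, -1)) / 2

#' @export
print.density_profile <- function(x, ...) {
  cat(sprintf("density profile along %s: %d bins over [%.2f, %.2f] nm, peak %.1f kg/m^3\n",
              x$axis, length(x$density), min(x$bin_edges), max(x$bin_edges),
              max(x$density)))
  invisible(x)
}

#' Write a density profile to CSV
#' @param p A `density_profile`.
#' @param path Output CSV path ("bin_center_nm,density_kg_m3").
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(p, path) {
  utils::write.csv(data.frame(bin_center_nm = bin_centres(p),
                              density_kg_m3 = p$density),
                   path, row.names = FALSE)
  invisible(path)
}

#' Symmetrise a density profile about a centre
#'
#' Replaces density(c + d) and density(c - d) by their mean. The centre is
#' snapped to the nearest half-bin grid point so that the reflection maps
#' bins onto bins exactly, making the operation idempotent.
#'
#' @param p A `density_profile`.
#' @param center Centre position in nm (default: the profile's mass-weighted
#'   mean position).
#' @return A symmetrised `density_profile`.
#' @export
symmetrize_profile <- function(p, center = NULL) {
  ctr <- bin_centres(p)
  if (is.null(center)) {
    if (sum(p$density) == 0) stop("cannot centre an all-zero profile")
    center <- sum(ctr * p$density) / sum(p$density)
  }
  if (center < min(p$bin_edges) || center > max(p$bin_edges))
    stop("centre lies outside the profile extent")
  bw <- diff(p$bin_edges)[1]
  # snap so 2*center falls on the bin-centre lattice
  k <- round(2 * (center - ctr[1]) / bw)
  mirror_idx <- k - seq_along(ctr) + 2L  # index of the bin mirrored onto i
  d <- p$density
  out <- d
  valid <- mirror_idx >= 1 & mirror_idx <= length(d)
  out[valid] <- (d[valid] + d[mirror_idx[valid]]) / 2
  p$density <- out
  p$symmetrized_about <- ctr[1] + k * bw / 2
  p
}

# Indices of strict local maxima of v (plateaus take their first bin).
local_maxima <- function(v) {
  n <- length(v)
  if (n < 3) return(integer(0))
  which(vapply(2:(n - 1), function(i)
    v[i] > v[i - 1] && v[i] >= v[i + 1] && v[i] > 0, logical(1))) + 1L
}

# Parabolic (3-point) refinement of a peak position at bin j.
refine_peak <- function(p, j) {
  ctr <- bin_centres(p)
  d <- p$density
  if (j <= 1 || j >= length(d)) return(ctr[j])
  denom <- d[j - 1] - 2 * d[j] + d[j + 1]
  if (abs(denom) < 1e-300) return(ctr[j])
  delta <- 0.5 * (d[j - 1] - d[j + 1]) / denom
  ctr[j] + delta * diff(p$bin_edges)[1]
}

#' Bilayer thickness from a phosphate density profile
#'
#' Peak-to-peak distance of the (symmetrised) phosphate mass density along
#' the bilayer normal: the strongest local maximum on each side of the
#' centre, refined by 3-point parabolic interpolation.
#'
#' @param p A `density_profile` along z of the phosphate atoms.
#' @param symmetrize Symmetrise about the profile centre of mass first
#'   (default TRUE).
#' @return Thickness in nm.
#' @export
bilayer_thickness <- function(p, symmetrize = TRUE) {
  if (symmetrize) p <- symmetrize_profile(p)
  ctr <- bin_centres(p)
  center <- sum(ctr * p$density) / sum(p$density)
  pk <- local_maxima(p$density)
  left <- pk[ctr[pk] < center]; right <- pk[ctr[pk] > center]
  if (length(left) == 0 || length(right) == 0)
    stop("not a bilayer: need a density peak on each side of the centre")
  jl <- left[which.max(p$density[left])]
  jr <- right[which.max(p$density[right])]
  # genuine leaflet peaks are separated by a depleted midplane; a noisy
  # unimodal profile (e.g. a monolayer) has no such valley
  valley <- min(p$density[jl:jr])
  if (valley > 0.5 * min(p$density[jl], p$density[jr]))
    stop("not a bilayer: no density valley between the two candidate peaks")
  refine_peak(p, jr) - refine_peak(p, jl)
}

#' Disc diameter from the protein density profile
#'
#' Distance between the outermost left and right local maxima of the
#' (belt) protein mass density along an in-plane axis, parabolic-refined.
#'
#' @param p A `density_profile` of the protein atoms along x or y.
#' @return Diameter in nm.
#' @export
diameter_from_protein <- function(p) {
  pk <- local_maxima(p$density)
  if (length(pk) < 2)
    stop("protein profile has fewer than two local maxima")
  refine_peak(p, max(pk)) - refine_peak(p, min(pk))
}

#' Disc diameter from the lipid density decay threshold
#'
#' Distance between the leftmost and rightmost positions where the lipid
#' mass density crosses `threshold` (default 1 kg/m^3), linearly
#' interpolated between neighbouring bin centres.
#'
#' @param p A `density_profile` of the lipid atoms along x or y.
#' @param threshold Density threshold in kg/m^3.
#' @return Diameter in nm.
#' @export
diameter_from_lipid <- function(p, threshold = 1) {
  d <- p$density
  ctr <- bin_centres(p)
  above <- which(d >= threshold)
  if (length(above) == 0)
    stop("lipid profile never exceeds the threshold of ", threshold,
         " kg/m^3")
  il <- above[1]; ir <- above[length(above)]
  left <- if (il == 1) ctr[1] else
    ctr[il - 1] + (threshold - d[il - 1]) / (d[il] - d[il - 1]) *
      (ctr[il] - ctr[il - 1])
  right <- if (ir == length(d)) ctr[length(d)] else
    ctr[ir] + (d[ir] - threshold) / (d[ir] - d[ir + 1]) *
      (ctr[ir + 1] - ctr[ir])
  right - left
}

#' Combine per-axis diameters into an average estimate
#'
#' Nanodiscs are treated as elliptical; the reported diameter is the mean of
#' the major (x) and minor (y) axis values, both of which are retained.
#'
#' @param d_x,d_y Diameters along x and y, nm (positive).
#' @param method Label: "protein_maxima" or "lipid_threshold".
#' @return A `diameter_estimate`: list(d_x, d_y, mean, major, minor, method).
#' @export
average_diameter <- function(d_x, d_y, method = c("protein_maxima",
                                                  "lipid_threshold")) {
  method <- match.arg(method)
  stopifnot(d_x > 0, d_y > 0)
  structure(list(d_x = d_x, d_y = d_y, mean = (d_x + d_y) / 2,
                 major = max(d_x, d_y), minor = min(d_x, d_y),
                 method = method),
            class = "diameter_estimate")
}

#' Ordinary least-squares trend of a metric versus lipid count
#'
#' @param n_lipids Numeric vector (>= 2 distinct values).
#' @param metric Numeric vector of the same length.
#' @return List with `slope`, `intercept`, `r_squared`.
#' @export
linear_trend <- function(n_lipids, metric) {
  stopifnot(length(n_lipids) == length(metric), length(n_lipids) >= 2)
  if (length(unique(n_lipids)) < 2)
    stop("degenerate x values: need at least two distinct lipid counts")
  fit <- stats::lm(metric ~ n_lipids)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((metric - mean(metric))^2)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = if (ss_tot == 0) 1 else 1 - ss_res / ss_tot)
}
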