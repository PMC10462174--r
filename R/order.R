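# Map tail carbons to their bonded hydrogens by CHARMM-style names within
# one residue: sn2 carbon C2k pairs with HkR/HkS (HkT on the terminal
# methyl), sn1 carbon C3k with HkX/HkY/HkZ. Returns a data.frame of
# (carbon_atom, hydrogen_atom, carbon_number, lipid_resseq) atom indices.
tail_ch_bonds <- function(x, lipid_sel) {
  nm <- x$atoms$atom_name
  grp <- residue_groups(x, lipid_sel)
  rows <- list()
  for (g in grp) {
    gnm <- nm[g]
    cidx <- grep("^C[23][0-9]+$", gnm)
    for (ci in cidx) {
      sn <- substr(gnm[ci], 2, 2)
      k <- as.integer(substring(gnm[ci], 3))
      hsuf <- if (sn == "2") c("R", "S", "T") else c("X", "Y", "Z")
      hn <- paste0("H", k, hsuf)
      hi <- which(gnm %in% hn)
      for (h in hi)
        rows[[length(rows) + 1L]] <- c(g[ci], g[h], k,
                                       x$atoms$resseq[g[ci]])
    }
  }
  if (length(rows) == 0)
    stop("no tail C-H bonds found: lipids carry no explicit hydrogens ",
         "with recognised names")
  m <- do.call(rbind, rows)
  data.frame(carbon = m[, 1], hydrogen = m[, 2], carbon_number = m[, 3],
             resseq = m[, 4])
}

# Sum of (3cos^2(theta)-1)/2 and bond count per carbon number for the given
# bonds in one frame (theta against +z).
scd_accumulate <- function(coords, bonds) {
  b <- coords[bonds$hydrogen, , drop = FALSE] -
       coords[bonds$carbon, , drop = FALSE]
  cz2 <- b[, 3]^2 / rowSums(b^2)
  s <- (3 * cz2 - 1) / 2
  list(sum = tapply(s, bonds$carbon_number, sum),
       n = tapply(s, bonds$carbon_number, length))
}

#' Deuterium (C-H) order parameter profile |S_CD| per tail carbon
#'
#' For each tail carbon i the order parameter is
#' S_i = <(3 cos^2(theta_i) - 1)/2>, with theta_i the angle between each
#' C-H bond of that carbon and the bilayer normal (+z after reorientation);
#' the average runs over both acyl chains (sn1 and sn2), all selected
#' lipids and all frames, and the magnitude |S_i| is reported. Carbons 2-14
#' of the myristoyl chains map to plot indices 1-13 (terminal methyl
#' included).
#'
#' @param x A `trajectory` with explicit tail hydrogens.
#' @param lipid_sel Atom indices of the lipids (default residues "DMPC").
#' @param lipid_ids Optional restriction to these lipid residue ids.
#' @param frames Frame indices (default all).
#' @param reoriented Set TRUE if frames already have the bilayer normal on
#'   z; otherwise [reorient()] is applied first.
#' @param region Label stored in the result ("full"/"core"/"rim").
#' @return data.frame with `carbon_index` (1-13), `carbon_number` (2-14),
#'   `abs_scd`, `region`, `n_lipids`.
#' @export
scd_profile <- function(x, lipid_sel = NULL, lipid_ids = NULL,
                        frames = seq_len(n_frames(x)), reoriented = FALSE,
                        region = "full") {
  if (is.null(lipid_sel)) {
    lipid_sel <- select_atoms(x, resname = "DMPC")
    if (length(lipid_sel) == 0) lipid_sel <- seq_len(n_atoms(x))
  }
  if (!reoriented) x <- reorient(x)$traj
  if (!is.null(lipid_ids))
    lipid_sel <- lipid_sel[x$atoms$resseq[lipid_sel] %in% lipid_ids]
  if (length(lipid_sel) == 0)
    return(data.frame(carbon_index = integer(0), carbon_number = integer(0),
                      abs_scd = numeric(0), region = character(0),
                      n_lipids = integer(0)))
  bonds <- tail_ch_bonds(x, lipid_sel)
  ks <- sort(unique(bonds$carbon_number))
  ssum <- setNames(numeric(length(ks)), ks)
  sn <- setNames(numeric(length(ks)), ks)
  for (f in frames) {
    acc <- scd_accumulate(frame_coords(x, f), bonds)
    ssum[names(acc$sum)] <- ssum[names(acc$sum)] + acc$sum
    sn[names(acc$n)] <- sn[names(acc$n)] + acc$n
  }
  data.frame(carbon_index = ks - 1L, carbon_number = ks,
             abs_scd = abs(unname(ssum / sn)), region = region,
             n_lipids = length(unique(bonds$resseq)))
}

#' Partition lipids into full / core / rim regions
#'
#' The core holds every lipid whose centroid lies within `core_radius`
#' (in-plane distance) of the lipid centre of mass; the rim holds every
#' lipid whose centroid lies within `rim_distance` of any protein atom.
#' Frames must be reoriented.
#'
#' @param x A reoriented `trajectory`.
#' @param lipid_sel Atom indices of the lipids (default residues "DMPC").
#' @param protein_sel Atom indices of the belt protein (default: every
#'   chain other than "L").
#' @param core_radius Core radius in nm (default 3.0).
#' @param rim_distance Lipid-to-protein distance bounding the rim, nm
#'   (default 1.4).
#' @param frame Frame index.
#' @return List of lipid residue id vectors: `full`, `core`, `rim`.
#' @export
partition_regions <- function(x, lipid_sel = select_atoms(x, resname = "DMPC"),
                              protein_sel = NULL, core_radius = 3.0,
                              rim_distance = 1.4, frame = 1L) {
  if (is.null(protein_sel))
    protein_sel <- which(x$atoms$chain != "L" &
                           x$atoms$resname != "DMPC")
  cen <- residue_centroids(x, lipid_sel, frame)
  ids <- as.integer(sub(".*\\|", "", rownames(cen)))
  com <- centre_of_mass(x, lipid_sel, frame)
  rin <- sqrt((cen[, 1] - com[1])^2 + (cen[, 2] - com[2])^2)
  core <- ids[rin <= core_radius]
  rim <- integer(0)
  if (length(protein_sel) > 0) {
    pp <- x$coords[protein_sel, , frame, drop = FALSE]
    dim(pp) <- c(length(protein_sel), 3)
    d2 <- outer(rowSums(cen^2), rowSums(pp^2), "+") - 2 * cen %*% t(pp)
    rim <- ids[sqrt(pmax(apply(d2, 1, min), 0)) <= rim_distance]
  }
  list(full = ids, core = core, rim = rim)
}

#' Order parameter profiles for the full disc, core and rim
#'
#' Region membership is evaluated per frame (a lipid contributes to
#' whichever region it occupies in each frame), then |S_CD| is computed per
#' region.
#'
#' @inheritParams scd_profile
#' @inheritParams partition_regions
#' @return data.frame stacking the three region profiles.
#' @export
scd_region_profiles <- function(x, lipid_sel = NULL, protein_sel = NULL,
                                core_radius = 3.0, rim_distance = 1.4,
                                frames = seq_len(n_frames(x)),
                                reoriented = FALSE) {
  if (is.null(lipid_sel)) lipid_sel <- select_atoms(x, resname = "DMPC")
  if (!reoriented) x <- reorient(x)$traj
  bonds <- tail_ch_bonds(x, lipid_sel)
  ks <- sort(unique(bonds$carbon_number))
  acc <- lapply(c(full = 1, core = 1, rim = 1), function(.)
    list(sum = setNames(numeric(length(ks)), ks),
         n = setNames(numeric(length(ks)), ks), lip = integer(0)))
  for (f in frames) {
    part <- partition_regions(x, lipid_sel, protein_sel, core_radius,
                              rim_distance, frame = f)
    co <- frame_coords(x, f)
    for (rg in names(acc)) {
      bsub <- bonds[bonds$resseq %in% part[[rg]], , drop = FALSE]
      if (nrow(bsub) == 0) next
      a <- scd_accumulate(co, bsub)
      acc[[rg]]$sum[names(a$sum)] <- acc[[rg]]$sum[names(a$sum)] + a$sum
      acc[[rg]]$n[names(a$n)] <- acc[[rg]]$n[names(a$n)] + a$n
      acc[[rg]]$lip <- union(acc[[rg]]$lip, part[[rg]])
    }
  }
  do.call(rbind, lapply(names(acc), function(rg) {
    ok <- acc[[rg]]$n > 0
    data.frame(carbon_index = ks[ok] - 1L, carbon_number = ks[ok],
               abs_scd = abs(unname(acc[[rg]]$sum[ok] / acc[[rg]]$n[ok])),
               region = rg, n_lipids = length(acc[[rg]]$lip))
  }))
}

#' Per-carbon order parameter difference between belt configurations
#'
#' Delta S_CD = |S_CD(parallel)| - |S_CD(antiparallel)| per carbon index;
#' negative values mean the antiparallel disc is more ordered.
#'
#' @param profile_parallel,profile_antiparallel data.frames from
#'   [scd_profile()] with matching carbon indices and region.
#' @return data.frame with `carbon_index`, `delta_scd`.
#' @export
delta_scd <- function(profile_parallel, profile_antiparallel) {
  if (!identical(profile_parallel$carbon_index,
                 profile_antiparallel$carbon_index))
    stop("carbon index mismatch between the two profiles")
  data.frame(carbon_index = profile_parallel$carbon_index,
             delta_scd = profile_parallel$abs_scd -
               profile_antiparallel$abs_scd)
}
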