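# Side-chain polarity classes. The classification is a package decision
# (recorded in output metadata and overridable): polar residues carry
# charged or hydrogen-bonding side chains, nonpolar residues aliphatic or
# purely hydrophobic ones; a mixed pair is "nonspecific".
default_polarity <- function() {
  c(ASP = "polar", GLU = "polar", LYS = "polar", ARG = "polar", HIS = "polar",
    ASN = "polar", GLN = "polar", SER = "polar", THR = "polar", TYR = "polar",
    CYS = "polar", TRP = "polar",
    ALA = "nonpolar", VAL = "nonpolar", LEU = "nonpolar", ILE = "nonpolar",
    PRO = "nonpolar", PHE = "nonpolar", MET = "nonpolar", GLY = "nonpolar")
}

basic_res <- function() c("ARG", "LYS", "HIS")
acidic_res <- function() c("ASP", "GLU")

#' Classify an inter-chain residue contact
#'
#' A contact is polar if both residues are polar-class, nonpolar if both are
#' nonpolar-class, and nonspecific for a mixed pair. Polar contacts pairing
#' a basic residue (Arg/Lys/His) with an acidic one (Asp/Glu) are flagged
#' ionic (salt bridges).
#'
#' @param resname_i,resname_j Standard 3-letter residue codes.
#' @param polarity Named vector residue -> "polar"/"nonpolar"; extend it to
#'   admit nonstandard residues.
#' @return List with `category` ("polar"/"nonpolar"/"nonspecific") and
#'   `ionic` (logical).
#' @export
#' @examples
#' classify_contact("ARG", "GLU")  # polar, ionic
#' classify_contact("SER", "LEU")  # nonspecific
classify_contact <- function(resname_i, resname_j,
                             polarity = default_polarity()) {
  pi_ <- polarity[resname_i]; pj <- polarity[resname_j]
  if (is.na(pi_)) stop("residue not in the polarity table: ", resname_i)
  if (is.na(pj)) stop("residue not in the polarity table: ", resname_j)
  category <- if (pi_ == "polar" && pj == "polar") "polar"
    else if (pi_ == "nonpolar" && pj == "nonpolar") "nonpolar"
    else "nonspecific"
  ionic <- category == "polar" &&
    ((resname_i %in% basic_res() && resname_j %in% acidic_res()) ||
     (resname_j %in% basic_res() && resname_i %in% acidic_res()))
  list(category = category, ionic = ionic)
}

# Side-chain heavy atom indices of one residue (Gly falls back to CA).
sidechain_atoms <- function(x, res_idx) {
  nm <- x$atoms$atom_name[res_idx]
  el <- x$atoms$element[res_idx]
  sc <- res_idx[!(nm %in% backbone_names()) & el != "H"]
  if (length(sc) == 0) sc <- res_idx[nm == "CA"]
  if (length(sc) == 0)
    stop("residue ", x$atoms$chain[res_idx[1]], ":",
         x$atoms$resseq[res_idx[1]], " has no side-chain heavy atoms")
  sc
}

#' Minimum side-chain heavy-atom distance between two residues
#'
#' @param x A `trajectory`.
#' @param chain_i,resseq_i,chain_j,resseq_j Residue identifiers.
#' @param frame Frame index.
#' @return Distance in nm.
#' @export
residue_min_distance <- function(x, chain_i, resseq_i, chain_j, resseq_j,
                                 frame = 1L) {
  ri <- select_atoms(x, chain = chain_i, resseq = resseq_i)
  rj <- select_atoms(x, chain = chain_j, resseq = resseq_j)
  if (length(ri) == 0 || length(rj) == 0)
    stop("residue not found: ",
         if (length(ri) == 0) paste0(chain_i, ":", resseq_i)
         else paste0(chain_j, ":", resseq_j))
  si <- sidechain_atoms(x, ri); sj <- sidechain_atoms(x, rj)
  a <- x$coords[si, , frame, drop = FALSE]; dim(a) <- c(length(si), 3)
  b <- x$coords[sj, , frame, drop = FALSE]; dim(b) <- c(length(sj), 3)
  sqrt(min(outer(rowSums(a^2), rowSums(b^2), "+") - 2 * (a %*% t(b))))
}

# All pairwise min side-chain distances between the residues of two chains
# for one frame: matrix n_i x n_j. sc_i/sc_j are lists of side-chain heavy
# atom index vectors per residue.
chain_pair_distances <- function(coords, sc_i, sc_j) {
  fi <- rep(seq_along(sc_i), lengths(sc_i))
  fj <- rep(seq_along(sc_j), lengths(sc_j))
  pi_ <- coords[unlist(sc_i), , drop = FALSE]
  pj <- coords[unlist(sc_j), , drop = FALSE]
  d2 <- outer(rowSums(pi_^2), rowSums(pj^2), "+") - 2 * (pi_ %*% t(pj))
  d2[d2 < 0] <- 0
  # min-pool atom rows into residues, then atom columns into residues
  m1 <- do.call(rbind, lapply(split(seq_along(fi), fi), function(r)
    if (length(r) == 1) d2[r, ] else apply(d2[r, , drop = FALSE], 2, min)))
  m2 <- do.call(cbind, lapply(split(seq_along(fj), fj), function(cc)
    if (length(cc) == 1) m1[, cc] else apply(m1[, cc, drop = FALSE], 1, min)))
  sqrt(matrix(m2, nrow = length(sc_i)))
}

#' Extract and classify inter-chain residue contacts
#'
#' Residue pairs from different chains are prefiltered at `prefilter`
#' (minimum side-chain distance in any analysed frame), then evaluated per
#' frame at the contact `cutoff`; a pair is reported when it is in contact
#' in at least `occupancy_min` of the frames. Distances are side-chain
#' heavy-atom minima (Gly uses CA).
#'
#' @param x A `trajectory` (protein chains labelled A-D).
#' @param chain_pairs List of length-2 chain id vectors; default
#'   `list(c("A","C"), c("B","D"))`, the rings that stack on each other.
#' @param prefilter Extraction radius, nm (default 1.0).
#' @param cutoff Contact distance, nm (default 0.4).
#' @param occupancy_min Minimum fraction of frames (default 0.5).
#' @param frames Frame indices to analyse (default all).
#' @param polarity Polarity table for [classify_contact()].
#' @return data.frame with one row per contact: chain/resseq/resname of both
#'   residues, `mean_distance_nm` (mean of the per-frame minima over frames
#'   in contact), `occupancy`, `category`, `ionic`.
#' @export
interchain_contacts <- function(x, chain_pairs = list(c("A", "C"),
                                                      c("B", "D")),
                                prefilter = 1.0, cutoff = 0.4,
                                occupancy_min = 0.5,
                                frames = seq_len(n_frames(x)),
                                polarity = default_polarity()) {
  out <- list()
  for (cp in chain_pairs) {
    for (ch in cp)
      if (!ch %in% x$atoms$chain) stop("unknown chain id: ", ch)
    gi <- residue_groups(x, select_atoms(x, chain = cp[1]))
    gj <- residue_groups(x, select_atoms(x, chain = cp[2]))
    sc_i <- lapply(gi, function(idx) sidechain_atoms(x, idx))
    sc_j <- lapply(gj, function(idx) sidechain_atoms(x, idx))
    nfr <- length(frames)
    dmin <- array(Inf, dim = c(length(sc_i), length(sc_j), nfr))
    for (f in seq_along(frames))
      dmin[, , f] <- chain_pair_distances(frame_coords(x, frames[f]),
                                          sc_i, sc_j)
    pass_pre <- apply(dmin, c(1, 2), min) <= prefilter
    in_contact <- dmin <= cutoff
    occ <- apply(in_contact, c(1, 2), mean)
    hits <- which(pass_pre & occ >= max(occupancy_min, 1e-12), arr.ind = TRUE)
    if (occupancy_min <= 0)
      hits <- which(pass_pre & occ > 0, arr.ind = TRUE)
    for (h in seq_len(nrow(hits))) {
      i <- hits[h, 1]; j <- hits[h, 2]
      ri <- gi[[i]][1]; rj <- gj[[j]][1]
      cls <- classify_contact(x$atoms$resname[ri], x$atoms$resname[rj],
                              polarity)
      dd <- dmin[i, j, ]
      out[[length(out) + 1L]] <- data.frame(
        chain_i = x$atoms$chain[ri], resseq_i = x$atoms$resseq[ri],
        resname_i = x$atoms$resname[ri],
        chain_j = x$atoms$chain[rj], resseq_j = x$atoms$resseq[rj],
        resname_j = x$atoms$resname[rj],
        mean_distance_nm = mean(dd[dd <= cutoff]),
        occupancy = occ[i, j],
        category = cls$category, ionic = cls$ionic,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(chain_i = character(0), resseq_i = integer(0),
                      resname_i = character(0), chain_j = character(0),
                      resseq_j = integer(0), resname_j = character(0),
                      mean_distance_nm = numeric(0), occupancy = numeric(0),
                      category = character(0), ionic = logical(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Summarise classified contacts into category counts
#'
#' @param records data.frame as from [interchain_contacts()].
#' @param label Optional system label to attach.
#' @return A `contact_summary`: list with `polar_total`, `ionic`,
#'   `nonspecific`, `nonpolar`, `total` and `label`.
#' @export
summarize_contacts <- function(records, label = NA_character_) {
  polar <- sum(records$category == "polar")
  structure(list(label = label,
                 polar_total = polar,
                 ionic = sum(records$ionic),
                 nonspecific = sum(records$category == "nonspecific"),
                 nonpolar = sum(records$category == "nonpolar"),
                 total = nrow(records)),
            class = "contact_summary")
}

#' @export
print.contact_summary <- function(x, ...) {
  cat(sprintf("%s: polar %d (ionic %d), nonspecific %d, nonpolar %d, total %d\n",
              if (is.na(x$label)) "contacts" else x$label,
              x$polar_total, x$ionic, x$nonspecific, x$nonpolar, x$total))
  invisible(x)
}

#' Compare contact counts between parallel and antiparallel configurations
#'
#' For each category the ratio of the mean antiparallel count to the mean
#' parallel count is computed over the lipid counts present in both
#' configurations, rounded to one decimal; per-configuration min-max ranges
#' are reported alongside.
#'
#' @param parallel,antiparallel data.frames with columns `n_lipids`,
#'   `polar_total`, `ionic`, `nonspecific`, `nonpolar`, `total` (one row per
#'   system), e.g. from [apoe_contact_counts()] or stacks of
#'   [summarize_contacts()] results.
#' @return List with `ratios` (named, one decimal), `common_n` and
#'   per-configuration `range` tables.
#' @export
configuration_comparison <- function(parallel, antiparallel) {
  common <- intersect(parallel$n_lipids, antiparallel$n_lipids)
  if (length(common) == 0)
    stop("no lipid count is present in both configurations")
  cats <- c("polar_total", "ionic", "nonspecific", "nonpolar", "total")
  p <- parallel[parallel$n_lipids %in% common, ]
  a <- antiparallel[antiparallel$n_lipids %in% common, ]
  ratios <- vapply(cats, function(cc)
    round(mean(a[[cc]]) / mean(p[[cc]]), 1), numeric(1))
  ranges <- list(
    parallel = vapply(cats, function(cc) range(parallel[[cc]]), numeric(2)),
    antiparallel = vapply(cats, function(cc) range(antiparallel[[cc]]),
                          numeric(2)))
  list(ratios = ratios, common_n = sort(common), range = ranges)
}
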