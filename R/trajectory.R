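#' Trajectory container
#'
#' A `trajectory` bundles an atom table with one or more coordinate frames.
#' Coordinates are always stored in nanometres. Atom order is the identity
#' key across frames: every frame holds the same atoms in the same order.
#'
#' @param atoms data.frame with columns `atom_name`, `element`, `resname`,
#'   `resseq`, `chain`, `mass` (amu). Missing `element`/`mass` are inferred
#'   from atom names via [element_from_name()] and [atomic_masses()].
#' @param coords Either an `natoms x 3` matrix (single frame) or an
#'   `natoms x 3 x nframes` array, in nm.
#' @param times Numeric vector of frame times in ns (default `0:(nframes-1)`).
#' @param box Optional length-3 box vector in nm.
#' @param bead_masses Optional named vector of per-bead masses (amu) for
#'   coarse-grained atom names that are not chemical elements.
#' @return An object of class `trajectory`.
#' @export
trajectory <- function(atoms, coords, times = NULL, box = NULL,
                       bead_masses = NULL) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  req <- c("atom_name", "resname", "resseq", "chain")
  missing_cols <- setdiff(req, names(atoms))
  if (length(missing_cols))
    stop("atom table lacks columns: ", paste(missing_cols, collapse = ", "))
  if (is.null(atoms$element) || all(!nzchar(atoms$element)))
    atoms$element <- element_from_name(atoms$atom_name)
  if (is.null(atoms$mass))
    atoms$mass <- lookup_masses(atoms$element, atoms$atom_name, bead_masses)
  if (any(!is.finite(atoms$mass)) || any(atoms$mass <= 0))
    stop("all atom masses must be positive and finite")
  if (is.matrix(coords)) coords <- array(coords, dim = c(nrow(coords), 3, 1))
  stopifnot(length(dim(coords)) == 3, dim(coords)[2] == 3)
  if (dim(coords)[1] != nrow(atoms))
    stop("coordinate rows (", dim(coords)[1], ") do not match atom table (",
         nrow(atoms), ")")
  if (any(!is.finite(coords))) stop("coordinates must be finite")
  nf <- dim(coords)[3]
  if (is.null(times)) times <- as.numeric(seq_len(nf) - 1L)
  if (length(times) != nf) stop("times must have one entry per frame")
  if (nf > 1 && any(diff(times) <= 0))
    stop("frame times must be strictly increasing")
  structure(list(atoms = atoms, coords = coords, times = times, box = box),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d atoms, %d frame(s), %d residues, chains: %s\n",
              n_atoms(x), n_frames(x),
              length(unique(paste(x$atoms$chain, x$atoms$resseq))),
              paste(sort(unique(x$atoms$chain)), collapse = "")))
  invisible(x)
}

#' Number of atoms / frames in a trajectory
#' @param x A `trajectory`.
#' @return Integer count.
#' @export
n_atoms <- function(x) nrow(x$atoms)

#' @rdname n_atoms
#' @export
n_frames <- function(x) dim(x$coords)[3]

#' Extract one frame's coordinate matrix
#' @param x A `trajectory`.
#' @param i Frame index.
#' @return `natoms x 3` matrix in nm.
#' @export
frame_coords <- function(x, i = 1L) {
  stopifnot(i >= 1, i <= n_frames(x))
  m <- x$coords[, , i, drop = FALSE]
  dim(m) <- dim(x$coords)[1:2]
  m
}

#' Keep a subset of frames
#' @param x A `trajectory`.
#' @param idx Frame indices to keep, in increasing order.
#' @return A `trajectory`.
#' @export
subset_frames <- function(x, idx) {
  stopifnot(all(idx >= 1), all(idx <= n_frames(x)))
  trajectory(x$atoms, x$coords[, , idx, drop = FALSE], times = x$times[idx],
             box = x$box)
}

#' Keep a subset of atoms
#' @param x A `trajectory`.
#' @param sel Integer atom indices (as from [select_atoms()]).
#' @return A `trajectory` restricted to the selected atoms.
#' @export
subset_atoms <- function(x, sel) {
  stopifnot(length(sel) > 0)
  trajectory(x$atoms[sel, , drop = FALSE],
             x$coords[sel, , , drop = FALSE], times = x$times, box = x$box)
}

#' System label for a nanodisc ("n-P" / "n-A")
#'
#' Nanodisc systems are conventionally labelled by their total DMPC count
#' hyphenated with P (parallel) or A (antiparallel) for the double-belt
#' ring sense, e.g. "240-A".
#'
#' @param n_lipids Total lipid count.
#' @param mode "parallel" or "antiparallel".
#' @return Character label.
#' @export
#' @examples
#' system_label(240, "antiparallel")  # "240-A"
system_label <- function(n_lipids, mode = c("parallel", "antiparallel")) {
  mode <- match.arg(mode)
  paste0(n_lipids, "-", if (mode == "parallel") "P" else "A")
}
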