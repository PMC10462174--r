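#' Select atoms by simple predicates
#'
#' Returns the indices of atoms matching every supplied predicate (logical
#' AND across fields; each field accepts a vector of allowed values, i.e. OR
#' within a field). An empty selection is a value, not an error.
#'
#' @param x A `trajectory`.
#' @param chain,resname,atom_name,element,resseq Allowed values, or NULL to
#'   leave the field unconstrained.
#' @return Integer vector of atom indices (possibly empty).
#' @export
#' @examples
#' \dontrun{
#' p <- select_atoms(disc, atom_name = "P")       # one per lipid
#' ac <- select_atoms(disc, chain = c("A", "C"))
#' }
select_atoms <- function(x, chain = NULL, resname = NULL, atom_name = NULL,
                         element = NULL, resseq = NULL) {
  a <- x$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(chain))     keep <- keep & a$chain %in% chain
  if (!is.null(resname))   keep <- keep & a$resname %in% resname
  if (!is.null(atom_name)) keep <- keep & a$atom_name %in% atom_name
  if (!is.null(element))   keep <- keep & a$element %in% element
  if (!is.null(resseq))    keep <- keep & a$resseq %in% resseq
  which(keep)
}

# Standard protein backbone heavy atoms.
backbone_names <- function() c("N", "CA", "C", "O")

#' Select protein backbone atoms (N, CA, C, O)
#' @inheritParams select_atoms
#' @return Integer vector of atom indices.
#' @export
select_backbone <- function(x, chain = NULL) {
  select_atoms(x, chain = chain, atom_name = backbone_names())
}

#' Total mass of a selection
#'
#' Sums the tabulated atomic (or per-bead) masses of the selected atoms.
#' Additive over disjoint selections; an empty selection weighs 0.
#'
#' @param x A `trajectory`.
#' @param sel Integer atom indices; default all atoms.
#' @return Mass in amu.
#' @export
subset_mass <- function(x, sel = seq_len(n_atoms(x))) {
  if (length(sel) == 0) return(0)
  sum(x$atoms$mass[sel])
}

# Per-residue grouping: returns a list of atom index vectors keyed by
# "chain|resseq", in order of first appearance.
residue_groups <- function(x, sel = seq_len(n_atoms(x))) {
  key <- paste(x$atoms$chain[sel], x$atoms$resseq[sel], sep = "|")
  split(sel, factor(key, levels = unique(key)))
}

# Centre of mass of a selection for one frame (length-3 vector, nm).
centre_of_mass <- function(x, sel, frame = 1L) {
  m <- x$atoms$mass[sel]
  xyz <- x$coords[sel, , frame, drop = FALSE]
  dim(xyz) <- c(length(sel), 3)
  colSums(xyz * m) / sum(m)
}

# Per-residue centroids (unweighted) for one frame: matrix nres x 3.
residue_centroids <- function(x, sel, frame = 1L) {
  grp <- residue_groups(x, sel)
  t(vapply(grp, function(idx) {
    xyz <- x$coords[idx, , frame, drop = FALSE]
    dim(xyz) <- c(length(idx), 3)
    colMeans(xyz)
  }, numeric(3)))
}
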