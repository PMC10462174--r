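#' Standard atomic masses
#'
#' Returns the table of standard atomic masses (amu) used throughout the
#' package. Values follow the conventional IUPAC standard atomic weights
#' (e.g. C 12.0107, H 1.00794), under which one all-atom DMPC molecule
#' (C36H72NO8P) weighs 677.93 amu.
#'
#' @return Named numeric vector, element symbol -> mass in amu.
#' @export
#' @examples
#' atomic_masses()[["C"]]
atomic_masses <- function() {
  c(H = 1.00794, D = 2.014102, C = 12.0107, N = 14.0067, O = 15.9994,
    P = 30.973762, S = 32.065, NA. = 22.98977, CL = 35.453, K = 39.0983,
    MG = 24.305, CA = 40.078, FE = 55.845, ZN = 65.38, F = 18.9984032,
    BR = 79.904, I = 126.90447, SE = 78.96)
}

#' Molecular mass from a chemical formula
#'
#' @param formula Character, e.g. "C36H72NO8P".
#' @return Mass in amu.
#' @export
#' @examples
#' formula_mass("C36H72NO8P")  # DMPC, 677.93
formula_mass <- function(formula) {
  parts <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  tab <- atomic_masses()
  total <- 0
  for (p in parts) {
    el <- toupper(gsub("[0-9]", "", p))
    n <- gsub("[^0-9]", "", p)
    n <- if (nzchar(n)) as.integer(n) else 1L
    if (el == "NA") el <- "NA."
    if (!el %in% names(tab)) stop("unknown element in formula: ", el)
    total <- total + n * tab[[el]]
  }
  total
}

# Mass of one all-atom DMPC molecule (amu).
dmpc_mass <- function() formula_mass("C36H72NO8P")

#' Infer element symbols from atom names
#'
#' Uses PDB-style conventions: leading digits stripped, two-letter elements
#' recognised only where unambiguous (NA, CL, MG, ...), hydrogen recognised
#' from names beginning with H or a digit followed by H.
#'
#' @param atom_name Character vector of atom names (e.g. "CA", "H2R", "OD1").
#' @return Character vector of element symbols.
#' @export
element_from_name <- function(atom_name) {
  nm <- toupper(gsub("^[0-9']+", "", trimws(atom_name)))
  two <- substr(nm, 1, 2)
  one <- substr(nm, 1, 1)
  el <- one
  special <- c("NA", "CL", "MG", "FE", "ZN", "BR", "SE")
  el[two %in% special] <- two[two %in% special]
  el[one == "H"] <- "H"
  el
}

# Look up per-atom masses. Elements with empty/unknown symbols fall back to
# the bead table (for coarse-grained inputs) keyed by atom name.
lookup_masses <- function(element, atom_name, bead_masses = NULL) {
  tab <- atomic_masses()
  key <- ifelse(element == "NA", "NA.", element)
  m <- unname(tab[key])
  if (any(is.na(m))) {
    miss <- which(is.na(m))
    if (!is.null(bead_masses)) {
      bm <- unname(bead_masses[atom_name[miss]])
      m[miss] <- bm
      miss <- miss[is.na(bm)]
    }
    if (length(miss))
      stop("no tabulated mass for element/bead: ",
           paste(unique(element[miss]), collapse = ", "))
  }
  m
}

#' Total mass of an assembled protein/lipid system
#'
#' Mass accounting for a nanodisc built from `n_chains` scaffold chains and
#' `n_lipids` lipid molecules. The result is reported as an integer number of
#' daltons with any fractional remainder discarded, matching the convention
#' used for published nanodisc system masses (e.g. four 34,000 Da apoE3-NT
#' chains with 240 DMPC at 677.93 Da give 298,703 Da).
#'
#' @param n_chains Number of scaffold protein chains.
#' @param chain_mass Mass of one chain in Da (default 34,000, the apoE3 figure).
#' @param n_lipids Number of lipid molecules.
#' @param lipid_mass Mass of one lipid in Da (default 677.93, the
#'   conventional two-decimal DMPC molecular weight).
#' @return Integer-valued system mass in Da.
#' @export
#' @examples
#' system_mass(4, 34000, 240)  # 298703
#' system_mass(4, 34000, 420)  # 420730
system_mass <- function(n_chains, chain_mass = 34000, n_lipids = 0,
                        lipid_mass = round(dmpc_mass(), 2)) {
  stopifnot(n_chains >= 0, chain_mass >= 0, n_lipids >= 0, lipid_mass >= 0)
  trunc(n_chains * chain_mass + n_lipids * lipid_mass)
}
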