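#' Read a structure or trajectory from a standard coordinate format
#'
#' Supported formats: PDB (single or multi-MODEL, \enc{Å}{Angstrom} converted
#' to nm), GRO (already nm; the format carries no chain identifiers, so chains
#' default to "A"), and DCD (multi-frame binary, \enc{Å}{Angstrom} converted
#' to nm; requires `topology`, a PDB/GRO file naming the atoms). XTC is not
#' supported: no installed reader decodes its coordinate compression --
#' convert to DCD or multi-model PDB first.
#'
#' @param path File to read.
#' @param format One of "pdb", "gro", "dcd"; default inferred from extension.
#' @param topology For DCD input, a PDB or GRO file providing the atom table.
#' @param bead_masses Optional named per-bead mass table (amu) for
#'   coarse-grained atom names.
#' @return A [trajectory()].
#' @export
read_structure <- function(path, format = NULL, topology = NULL,
                           bead_masses = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(format)) format <- tolower(tools::file_ext(path))
  format <- tolower(format)
  switch(format,
    pdb = read_pdb_nm(path, bead_masses),
    gro = read_gro_nm(path, bead_masses),
    dcd = read_dcd_nm(path, topology, bead_masses),
    xtc = stop("XTC input is not supported (compressed xdrfile format); ",
               "convert the trajectory to DCD or multi-model PDB"),
    stop("unknown structure format: ", format)
  )
}

#' Write a trajectory to PDB, GRO or DCD
#'
#' PDB output is multi-MODEL for multi-frame trajectories and stores
#' coordinates in \enc{Å}{Angstrom}; GRO stores nm (single frame only; GRO
#' has no chain field); DCD stores all frames in \enc{Å}{Angstrom}.
#'
#' @param x A `trajectory`.
#' @param path Output file.
#' @param format One of "pdb", "gro", "dcd"; default from extension.
#' @return `path`, invisibly.
#' @export
write_structure <- function(x, path, format = NULL) {
  if (is.null(format)) format <- tolower(tools::file_ext(path))
  format <- tolower(format)
  switch(format,
    pdb = write_pdb_nm(x, path),
    gro = write_gro_nm(x, path),
    dcd = write_dcd_nm(x, path),
    stop("unsupported output format: ", format)
  )
  invisible(path)
}

read_pdb_nm <- function(path, bead_masses = NULL) {
  pdb <- tryCatch(
    bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
    error = function(e) stop("failed to parse PDB file ", path, ": ",
                             conditionMessage(e)))
  a <- pdb$atom
  nf <- nrow(pdb$xyz)
  na <- nrow(a)
  coords <- array(0, dim = c(na, 3, nf))
  for (i in seq_len(nf))
    coords[, , i] <- matrix(pdb$xyz[i, ], ncol = 3, byrow = TRUE) / 10
  chain <- a$chain
  chain[is.na(chain) | !nzchar(chain)] <- "A"
  elesy <- a$elesy
  if (is.null(elesy)) elesy <- rep(NA_character_, na)
  elesy <- toupper(trimws(elesy))
  bad <- is.na(elesy) | !nzchar(elesy)
  elesy[bad] <- element_from_name(a$elety[bad])
  trajectory(data.frame(atom_name = trimws(a$elety), element = elesy,
                        resname = trimws(a$resid), resseq = a$resno,
                        chain = chain, stringsAsFactors = FALSE),
             coords, bead_masses = bead_masses)
}

# Hand-rolled fixed-width ATOM records: 4-character residue names (DMPC)
# occupy columns 18-21 with the chain id kept at column 22, which
# bio3d::write.pdb does not get right.
write_pdb_nm <- function(x, path) {
  a <- x$atoms
  nf <- n_frames(x)
  name_fmt <- ifelse(nchar(a$atom_name) < 4,
                     sprintf(" %-3s", a$atom_name),
                     sprintf("%-4s", a$atom_name))
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(nf)) {
    if (nf > 1) writeLines(sprintf("MODEL     %4d", f), con)
    xyz <- frame_coords(x, f) * 10
    writeLines(sprintf(
      "ATOM  %5d %s %-4s%1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      seq_len(n_atoms(x)) %% 100000L, name_fmt, a$resname, a$chain,
      a$resseq %% 10000L, xyz[, 1], xyz[, 2], xyz[, 3], 1, 0,
      a$element), con)
    writeLines(if (nf > 1) "ENDMDL" else "TER", con)
  }
  writeLines("END", con)
  invisible(path)
}

read_gro_nm <- function(path, bead_masses = NULL) {
  lines <- readLines(path)
  if (length(lines) < 3) stop("GRO file too short: ", path)
  na <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(na)) stop("GRO parse error at line 2 of ", path,
                      ": expected atom count, got '", lines[2], "'")
  if (length(lines) < 2 + na)
    stop("GRO file ", path, " truncated: header promises ", na, " atoms")
  al <- lines[3:(2 + na)]
  resseq <- suppressWarnings(as.integer(substr(al, 1, 5)))
  resname <- trimws(substr(al, 6, 10))
  atom_name <- trimws(substr(al, 11, 15))
  xs <- suppressWarnings(as.numeric(substr(al, 21, 28)))
  ys <- suppressWarnings(as.numeric(substr(al, 29, 36)))
  zs <- suppressWarnings(as.numeric(substr(al, 37, 44)))
  bad <- which(is.na(resseq) | is.na(xs) | is.na(ys) | is.na(zs))
  if (length(bad))
    stop("GRO parse error at line ", bad[1] + 2, " of ", path)
  box <- suppressWarnings(as.numeric(strsplit(trimws(lines[3 + na]),
                                              "\\s+")[[1]]))[1:3]
  if (any(is.na(box))) box <- NULL
  trajectory(data.frame(atom_name = atom_name,
                        element = element_from_name(atom_name),
                        resname = resname, resseq = resseq,
                        chain = "A", stringsAsFactors = FALSE),
             cbind(xs, ys, zs), box = box, bead_masses = bead_masses)
}

write_gro_nm <- function(x, path) {
  if (n_frames(x) > 1)
    stop("GRO output holds a single frame; subset the trajectory first")
  a <- x$atoms
  xyz <- frame_coords(x, 1)
  lines <- c("written by discbelt", sprintf("%5d", n_atoms(x)),
             sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                     a$resseq %% 100000L, a$resname, a$atom_name,
                     seq_len(n_atoms(x)) %% 100000L,
                     xyz[, 1], xyz[, 2], xyz[, 3]))
  box <- if (is.null(x$box)) apply(xyz, 2, function(v) diff(range(v)) + 2)
         else x$box
  lines <- c(lines, sprintf("%10.5f%10.5f%10.5f", box[1], box[2], box[3]))
  writeLines(lines, path)
  invisible(path)
}

read_dcd_nm <- function(path, topology, bead_masses = NULL) {
  if (is.null(topology))
    stop("DCD input needs a `topology` PDB or GRO file naming the atoms")
  top <- read_structure(topology, bead_masses = bead_masses)
  xyz <- bio3d::read.dcd(path, verbose = FALSE)
  nf <- nrow(xyz)
  na <- ncol(xyz) / 3
  if (na != n_atoms(top))
    stop("DCD atom count (", na, ") does not match topology (",
         n_atoms(top), ")")
  coords <- array(0, dim = c(na, 3, nf))
  for (i in seq_len(nf))
    coords[, , i] <- matrix(xyz[i, ], ncol = 3, byrow = TRUE) / 10
  trajectory(top$atoms, coords, box = top$box)
}

# Minimal CHARMM-style DCD writer (x/y/z float records per frame, no unit
# cell). Enough for round trips through bio3d::read.dcd; coordinates written
# in Angstrom per the format convention.
write_dcd_nm <- function(x, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  nf <- n_frames(x); na <- n_atoms(x)
  icntrl <- integer(20)
  icntrl[1] <- nf; icntrl[2] <- 1L; icntrl[3] <- 1L; icntrl[4] <- nf
  icntrl[20] <- 24L  # CHARMM version stamp so readers take the modern layout
  writeBin(84L, con, size = 4)
  writeChar("CORD", con, nchars = 4, eos = NULL)
  writeBin(icntrl[1:9], con, size = 4)
  writeBin(1, con, size = 4)  # DELTA as 32-bit float slot
  writeBin(icntrl[11:20], con, size = 4)
  writeBin(84L, con, size = 4)
  title <- formatC("written by discbelt", width = -80)
  writeBin(84L, con, size = 4)
  writeBin(1L, con, size = 4)
  writeChar(title, con, nchars = 80, eos = NULL)
  writeBin(84L, con, size = 4)
  writeBin(4L, con, size = 4); writeBin(na, con, size = 4)
  writeBin(4L, con, size = 4)
  nb <- na * 4L
  for (i in seq_len(nf)) {
    xyz <- frame_coords(x, i) * 10
    for (d in 1:3) {
      writeBin(nb, con, size = 4)
      writeBin(as.numeric(xyz[, d]), con, size = 4)
      writeBin(nb, con, size = 4)
    }
  }
  invisible(path)
}


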