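# Shared fixtures, built once per test run.
.fix <- new.env()

fixture <- function(key, builder) {
  if (is.null(.fix[[key]])) .fix[[key]] <- builder()
  .fix[[key]]
}

small_disc <- function() fixture("small_disc", function()
  generate_nanodisc(disc_spec(n_lipids_per_leaflet = 60, n_frames = 5,
                              seed = 11)))

quiet_disc <- function() fixture("quiet_disc", function()
  generate_nanodisc(disc_spec(n_lipids_per_leaflet = 40, noise_sigma = 0,
                              seed = 2)))

bundle_fix <- function() fixture("bundle", function() generate_helix_bundle())

# Independent quaternion (Horn) superposition oracle: the optimal rotation
# is the eigenvector of the 4x4 key matrix with the largest eigenvalue.
quaternion_rmsd <- function(reference, mobile) {
  A <- sweep(reference, 2, colMeans(reference))
  B <- sweep(mobile, 2, colMeans(mobile))
  M <- t(B) %*% A
  Sxx <- M[1,1]; Sxy <- M[1,2]; Sxz <- M[1,3]
  Syx <- M[2,1]; Syy <- M[2,2]; Syz <- M[2,3]
  Szx <- M[3,1]; Szy <- M[3,2]; Szz <- M[3,3]
  K <- matrix(c(
    Sxx+Syy+Szz, Syz-Szy,      Szx-Sxz,      Sxy-Syx,
    Syz-Szy,     Sxx-Syy-Szz,  Sxy+Syx,      Szx+Sxz,
    Szx-Sxz,     Sxy+Syx,     -Sxx+Syy-Szz,  Syz+Szy,
    Sxy-Syx,     Szx+Sxz,      Syz+Szy,     -Sxx-Syy+Szz), 4, 4,
    byrow = TRUE)
  lam <- max(eigen(K, symmetric = TRUE)$values)
  msd <- (sum(A^2) + sum(B^2) - 2 * lam) / nrow(A)
  sqrt(max(0, msd))
}

# Minimal protein residue for contact fixtures: backbone + one named
# side-chain atom at `sc_pos`.
contact_residue <- function(chain, resseq, resname, base, sc_name, sc_pos) {
  atoms <- data.frame(
    atom_name = c("N", "CA", "C", "O", sc_name),
    element = c("N", "C", "C", "O", element_from_name(sc_name)),
    resname = resname, resseq = resseq, chain = chain,
    stringsAsFactors = FALSE)
  xyz <- rbind(base + c(0, 0.1, 0), base, base + c(0.1, 0, 0),
               base + c(0.2, 0, 0), sc_pos)
  list(atoms = atoms, xyz = xyz)
}

bind_residues <- function(...) {
  parts <- list(...)
  trajectory(do.call(rbind, lapply(parts, `[[`, "atoms")),
             do.call(rbind, lapply(parts, `[[`, "xyz")))
}

# Salt-bridge fixture: ARG(A1)-GLU(C1) side chains `d_close` apart,
# LEU(A2)-VAL(C2) side chains `d_far` apart, chains otherwise distant.
salt_bridge_traj <- function(d_close = 0.35, d_far = 0.45) {
  bind_residues(
    contact_residue("A", 1, "ARG", c(0, 0, 1), "NH1", c(0, 0, d_close / 2)),
    contact_residue("A", 2, "LEU", c(3, 0, 1), "CD1", c(3, 0, d_far / 2)),
    contact_residue("C", 1, "GLU", c(0, 0, -1), "OE1", c(0, 0, -d_close / 2)),
    contact_residue("C", 2, "VAL", c(3, 0, -1), "CG1", c(3, 0, -d_far / 2)))
}

# Uniform-density thin disc of unit point masses (for the Rg closed form).
thin_disc_traj <- function(n = 4000, R = 5, seed = 1) {
  set.seed(seed)
  r <- R * sqrt(runif(n)); a <- runif(n, 0, 2 * pi)
  atoms <- data.frame(atom_name = "X", element = "C", resname = "UNK",
                      resseq = seq_len(n), chain = "A", mass = 1,
                      stringsAsFactors = FALSE)
  trajectory(atoms, cbind(r * cos(a), r * sin(a), 0))
}

# n independent isotropically oriented C-H bonds on a single tail carbon,
# one bond per residue (direct Monte-Carlo fixture for |S_CD| -> 0).
isotropic_bond_traj <- function(n, seed = 1) {
  set.seed(seed)
  z <- runif(n, -1, 1); phi <- runif(n, 0, 2 * pi)
  s <- sqrt(1 - z^2)
  b <- 0.109 * cbind(s * cos(phi), s * sin(phi), z)
  cpos <- cbind(seq_len(n) * 0.5, 0, 0)
  atoms <- data.frame(
    atom_name = rep(c("C22", "H2R"), n), element = rep(c("C", "H"), n),
    resname = "DMPC", resseq = rep(seq_len(n), each = 2), chain = "L",
    stringsAsFactors = FALSE)
  xyz <- matrix(0, 2 * n, 3)
  xyz[seq(1, 2 * n, 2), ] <- cpos
  xyz[seq(2, 2 * n, 2), ] <- cpos + b
  trajectory(atoms, xyz)
}
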