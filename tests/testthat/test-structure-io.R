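test_that("a minimal PDB file parses into atoms with chain assignments", {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   ALA A   1       1.000   2.000   3.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       2.000   2.000   3.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       3.000   2.000   3.000  1.00  0.00           C",
    "END"), f)
  x <- read_structure(f)
  expect_equal(n_atoms(x), 3)
  expect_equal(unique(x$atoms$chain), "A")
  expect_equal(unique(x$atoms$resname), "ALA")
  # Angstrom converted to nm
  expect_equal(frame_coords(x)[1, ], c(0.1, 0.2, 0.3))
})

test_that("coordinates, names and chains round-trip through PDB", {
  set.seed(4)
  n <- 100
  atoms <- data.frame(atom_name = sample(c("CA", "CB", "P", "O"), n, TRUE),
                      element = NA, resname = "DMPC",
                      resseq = rep(1:20, each = 5),
                      chain = rep(c("A", "L"), length.out = n))
  atoms$element <- element_from_name(atoms$atom_name)
  x <- trajectory(atoms, matrix(rnorm(3 * n), ncol = 3))
  f <- tempfile(fileext = ".pdb")
  write_structure(x, f)
  y <- read_structure(f)
  expect_identical(y$atoms$atom_name, x$atoms$atom_name)
  expect_identical(y$atoms$chain, x$atoms$chain)
  expect_identical(y$atoms$resseq, x$atoms$resseq)
  # PDB stores 3 decimals in Angstrom: 5e-5 nm precision
  expect_lt(max(abs(y$coords - x$coords)), 1e-4)
})

test_that("the synthetic bilayer patch round-trips through GRO with 150 lipids", {
  p <- generate_bilayer_patch(75, disc_spec(n_frames = 1, seed = 5))
  f <- tempfile(fileext = ".gro")
  write_structure(p$traj, f)
  y <- read_structure(f)
  expect_equal(length(unique(y$atoms$resseq[y$atoms$resname == "DMPC"])), 150)
  expect_lt(max(abs(y$coords - p$traj$coords)), 1e-3)  # GRO: 3 decimals in nm
})

test_that("multi-frame trajectories survive PDB and DCD round trips", {
  d <- small_disc()
  x <- subset_frames(d$traj, 1:3)
  fp <- tempfile(fileext = ".pdb")
  write_structure(x, fp)
  y <- read_structure(fp)
  expect_equal(n_frames(y), 3)
  expect_lt(max(abs(y$coords - x$coords)), 1e-4)
  fd <- tempfile(fileext = ".dcd")
  write_structure(x, fd)
  z <- read_structure(fd, topology = fp)
  expect_equal(n_frames(z), 3)
  expect_lt(max(abs(z$coords - x$coords)), 1e-5)
})

test_that("XTC input and malformed files raise informative errors", {
  expect_error(read_structure(tempfile(), format = "xtc"), "not found")
  f <- tempfile(fileext = ".xtc"); writeLines("x", f)
  expect_error(read_structure(f), "XTC")
  g <- tempfile(fileext = ".gro")
  writeLines(c("title", "not_a_number", "junk"), g)
  expect_error(read_structure(g), "line 2")
  g2 <- tempfile(fileext = ".gro")
  writeLines(c("title", "    2",
               "    1DMPC    P    1   bad.000   0.000   0.000",
               "    1DMPC   C2    2   0.000   0.000   0.000",
               "   5.0 5.0 5.0"), g2)
  expect_error(read_structure(g2), "line 3")
})

test_that("atom selection composes by intersection and unions are disjoint", {
  d <- small_disc()
  x <- d$traj
  p <- select_atoms(x, atom_name = "P")
  expect_equal(length(p), d$truth$n_lipids)  # one phosphorus per lipid
  a <- select_atoms(x, chain = "A"); cc <- select_atoms(x, chain = "C")
  both <- select_atoms(x, chain = c("A", "C"))
  expect_equal(sort(both), sort(c(a, cc)))
  expect_length(intersect(a, cc), 0)
  expect_length(select_atoms(x, resname = "NOPE"), 0)
})

test_that("subset_mass is additive and matches tabulated element masses", {
  d <- small_disc()
  x <- d$traj
  expect_equal(subset_mass(x, integer(0)), 0)
  i <- select_atoms(x, element = "C")[1]
  expect_equal(subset_mass(x, i), 12.0107)
  a <- select_atoms(x, chain = "A"); b <- select_atoms(x, chain = "B")
  expect_equal(subset_mass(x, c(a, b)),
               subset_mass(x, a) + subset_mass(x, b))
  # an all-atom DMPC molecule weighs 677.93 amu
  expect_equal(formula_mass("C36H72NO8P"), 677.93, tolerance = 1e-5)
  expect_error(formula_mass("C2Xx3"), "unknown element")
})

test_that("system mass accounting is linear in lipid count and integer-valued", {
  expect_identical(system_mass(4, 34000, 0), 136000)
  m1 <- system_mass(4, 34000, 100)
  m2 <- system_mass(4, 34000, 200)
  expect_equal(m2 - m1, trunc(100 * 677.93), tolerance = 1)
  # linearity property at full precision
  lm_ <- 677.93
  for (n in c(0, 10, 240, 420))
    expect_equal(system_mass(4, 34000, n, lm_),
                 trunc(4 * 34000 + n * lm_))
})
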