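test_that("residue minimum distances use side-chain heavy atoms only", {
  x <- salt_bridge_traj()
  expect_equal(residue_min_distance(x, "A", 1, "C", 1), 0.35,
               tolerance = 1e-12)
  expect_equal(residue_min_distance(x, "A", 2, "C", 2), 0.45,
               tolerance = 1e-12)
  # residues sharing the side-chain position: distance 0
  y <- salt_bridge_traj(d_close = 0)
  expect_equal(residue_min_distance(y, "A", 1, "C", 1), 0, tolerance = 1e-12)
  expect_error(residue_min_distance(x, "A", 9, "C", 1), "not found")
  # brute force over every side-chain atom pair agrees
  d <- small_disc()
  z <- subset_frames(d$traj, 1)
  got <- residue_min_distance(z, "A", 3, "C", 3)
  si <- discbelt:::sidechain_atoms(z, select_atoms(z, chain = "A", resseq = 3))
  sj <- discbelt:::sidechain_atoms(z, select_atoms(z, chain = "C", resseq = 3))
  brute <- min(sqrt(outer(rowSums(frame_coords(z)[si, , drop = FALSE]^2),
                          rowSums(frame_coords(z)[sj, , drop = FALSE]^2), "+") -
                    2 * frame_coords(z)[si, , drop = FALSE] %*%
                      t(frame_coords(z)[sj, , drop = FALSE])))
  expect_equal(got, brute, tolerance = 1e-9)
})

test_that("contact extraction applies the 0.4 nm cutoff after the 1 nm
           prefilter and tracks occupancy", {
  x <- salt_bridge_traj()          # ARG-GLU at 0.35, LEU-VAL at 0.45
  multi <- perturb_frames(x, 0, 4, seed = 1)
  rec <- interchain_contacts(multi, chain_pairs = list(c("A", "C")))
  expect_equal(nrow(rec), 1)
  expect_equal(rec$resname_i, "ARG")
  expect_equal(rec$occupancy, 1)
  expect_equal(rec$category, "polar")
  expect_true(rec$ionic)
  # the 0.45 nm pair passed the prefilter but fails the cutoff
  wide <- interchain_contacts(multi, chain_pairs = list(c("A", "C")),
                              cutoff = 0.5)
  expect_equal(nrow(wide), 2)       # raising the cutoff never removes contacts
  far <- salt_bridge_traj(d_close = 5, d_far = 6)
  expect_equal(nrow(interchain_contacts(far,
                                        chain_pairs = list(c("A", "C")))), 0)
  expect_error(interchain_contacts(x, chain_pairs = list(c("A", "Z"))),
               "unknown chain")
})

test_that("single-frame extraction at occupancy 0 equals a brute-force scan", {
  d <- quiet_disc()
  x <- subset_frames(d$traj, 1)
  rec <- interchain_contacts(x, chain_pairs = list(c("A", "C")),
                             occupancy_min = 0, cutoff = 0.8)
  rs <- unique(x$atoms$resseq[x$atoms$chain == "A"])
  rs2 <- unique(x$atoms$resseq[x$atoms$chain == "C"])
  brute <- 0
  for (i in rs) for (j in rs2)
    if (residue_min_distance(x, "A", i, "C", j) <= 0.8) brute <- brute + 1
  expect_equal(nrow(rec), brute)
})

test_that("the contact classifier follows the polarity decision table", {
  cases <- list(
    list("ARG", "GLU", "polar", TRUE), list("LYS", "ASP", "polar", TRUE),
    list("HIS", "GLU", "polar", TRUE), list("ASP", "LYS", "polar", TRUE),
    list("SER", "THR", "polar", FALSE), list("ARG", "LYS", "polar", FALSE),
    list("LEU", "VAL", "nonpolar", FALSE),
    list("SER", "LEU", "nonspecific", FALSE),
    list("GLU", "ALA", "nonspecific", FALSE))
  for (cs in cases) {
    got <- classify_contact(cs[[1]], cs[[2]])
    expect_equal(got$category, cs[[3]], label = paste(cs[[1]], cs[[2]]))
    expect_equal(got$ionic, cs[[4]], label = paste(cs[[1]], cs[[2]]))
  }
  expect_error(classify_contact("XYZ", "GLU"), "polarity table")
  ext <- c(default_polarity <- discbelt:::default_polarity(), XYZ = "polar")
  expect_equal(classify_contact("XYZ", "GLU", polarity = ext)$category,
               "polar")
})

test_that("contact summaries count categories and ignore record order", {
  empty <- interchain_contacts(salt_bridge_traj(5, 6),
                               chain_pairs = list(c("A", "C")))
  s0 <- summarize_contacts(empty)
  expect_equal(s0$total, 0)
  expect_equal(s0$polar_total + s0$nonspecific + s0$nonpolar, 0)
  rec <- data.frame(category = c(rep("polar", 3), rep("nonpolar", 2),
                                 rep("nonspecific", 5)),
                    ionic = c(TRUE, FALSE, FALSE, rep(FALSE, 7)))
  s <- summarize_contacts(rec)
  expect_equal(unlist(s[c("polar_total", "ionic", "nonspecific",
                          "nonpolar", "total")]),
               c(polar_total = 3, ionic = 1, nonspecific = 5, nonpolar = 2,
                 total = 10))
  set.seed(1)
  s2 <- summarize_contacts(rec[sample(nrow(rec)), ])
  expect_equal(unclass(s)[-1], unclass(s2)[-1])
})

test_that("configuration comparison reproduces published contact ratios", {
  tab <- apoe_contact_counts()
  p <- tab[tab$mode == "parallel", ]
  a <- tab[tab$mode == "antiparallel", ]
  cmp <- configuration_comparison(p, a)
  expect_equal(unname(cmp$ratios["nonpolar"]), 2.3)
  expect_equal(unname(cmp$ratios["ionic"]), 3.2)
  expect_equal(cmp$common_n, seq(260, 400, 20))
  expect_equal(unname(cmp$range$antiparallel[, "total"]), c(140, 205))
  same <- configuration_comparison(p, p)
  expect_true(all(same$ratios == 1.0))
  expect_error(configuration_comparison(p[p$n_lipids < 300, ],
                                        a[a$n_lipids > 350, ]),
               "no lipid count")
})
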