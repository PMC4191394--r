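test_that("ideal helices have A-form pitch and zero bonded energy", {
  geom <- aform_geometry()
  # one full turn in 360 / 32.7 ~ 11 bp, within 5%
  expect_equal(360 / geom$twist, 11, tolerance = 0.05)
  co <- build_ideal_helix(11)
  # pair 12 would be one turn up; pair 11 center is twisted 10 * 32.7 deg
  m1 <- co[nrow(co) - 10, ]
  m11 <- co[nrow(co), ]
  expect_equal(m11[3] - m1[3], 10 * geom$rise, tolerance = 1e-9)
  top <- duplex_topology(11)
  ef <- energy_forces(co, top)
  expect_lt(sum(abs(ef$breakdown[c("bond", "angle", "improper",
                                   "dihedral")])), 1e-8)
  expect_error(build_ideal_helix(1), "at least 2")
})

test_that("the idealized tRNA reference is native-like by construction", {
  ref <- wt_reference()
  top <- ref$topology
  co <- ref$coords
  expect_true(all(ref$restraint_check$satisfied))
  expect_true(group_contact(co, top, "D-loop", "T-loop"))
  # zero native-inconsistent contacts
  for (pr in toprna:::native_inconsistent_pairs()) {
    ra <- toprna:::resolve_element(top$ss, pr[1])
    rb <- toprna:::resolve_element(top$ss, pr[2])
    if (is.null(ra) || is.null(rb)) next
    expect_false(group_contact(co, top, ra, rb),
                 info = paste(pr, collapse = "-"))
  }
  # both native interhelical stacks present
  expect_true(coaxial_stack(co, top, c("D-stem", "AC-stem")))
  expect_true(coaxial_stack(co, top, c("T-stem", "A-stem")))
  # the build is deterministic: seeds give identical structures
  ref2 <- build_reference_trna(seed = 99)
  expect_lt(kabsch_rmsd(ref$coords, ref2$coords, bead_P(1:76)), 3)
  # every supplied tertiary pair passes the residue-contact rule
  for (q in seq_len(nrow(trna_conserved_pairs()))) {
    pr <- trna_conserved_pairs()[q, ]
    expect_true(residue_contact(co, pr[1], pr[2]) || abs(pr[1] - pr[2]) < 5,
                info = paste(pr, collapse = "-"))
  }
})

test_that("native contact tables are reproducible from coordinates", {
  ref <- wt_reference()
  nc <- ref$native_contacts
  expect_true(all(nc$j - nc$i >= 5))
  expect_true(all(nc$ss_distance < 14))
  redo <- toprna:::native_contact_table(ref$coords, ref$topology)
  expect_identical(nc, redo)
})

test_that("coarse-graining a synthetic all-atom helix recovers the beads", {
  skip_if_not_installed("bio3d")
  # fabricate an all-atom PDB whose moiety centroids sit exactly on the
  # ideal bead positions
  n_bp <- 4
  ss <- duplex_ss(n_bp)
  ideal <- build_ideal_helix(n_bp)
  dir <- withr::local_tempdir()
  pdb <- file.path(dir, "synthetic_helix.pdb")
  con <- file(pdb, "w")
  atomno <- 0
  sugar <- c("C1'", "C2'", "C3'", "C4'", "O4'")
  offs <- rbind(c(0.5, 0, 0), c(-0.5, 0, 0), c(0, 0.5, 0), c(0, -0.5, 0),
                c(0, 0, 0))
  for (r in seq_len(2 * n_bp)) {
    at <- function(name, xyz) {
      atomno <<- atomno + 1
      writeLines(sprintf(
        "ATOM  %5d %-4s   G A%4d    %8.3f%8.3f%8.3f  1.00  0.00",
        atomno, name, r, xyz[1], xyz[2], xyz[3]), con)
    }
    at("P", ideal[bead_P(r), ])
    for (q in 1:5) at(sugar[q], ideal[bead_S(r), ] + offs[q, ])
    # base: N9/C8/N7 symmetric about the centroid
    at("N9", ideal[bead_B(r), ] + c(0.7, 0, 0))
    at("C8", ideal[bead_B(r), ] + c(-0.7, 0, 0))
    at("N7", ideal[bead_B(r), ])
  }
  writeLines("END", con)
  close(con)
  ref <- coarse_grain_pdb(pdb, ss)
  expect_equal(ref$provenance, "pdb-derived")
  res_beads <- seq_len(3 * 2 * n_bp)
  expect_lt(max(abs(ref$coords[res_beads, ] - ideal[res_beads, ])), 0.1)
  expect_length(ref$flagged_residues, 0)
  # residue count mismatch is an error
  expect_error(coarse_grain_pdb(pdb, duplex_ss(6)), "residues")
})

test_that("synthetic generators hit their planted statistics", {
  # Bernoulli stream: measured P within 3 binomial sigma
  s <- make_synthetic_ensembles(list(generator = "correlated_contacts",
                                     n = 1e5, p = 0.2, C = 1), seed = 12)
  sigma <- sqrt(0.2 * 0.8 / 1e5)
  expect_lt(abs(mean(s[, "X"]) - 0.2), 3 * sigma)
  expect_lt(abs(mean(s[, "Y"]) - 0.2), 3 * sigma)
  # infeasible joint law is refused
  expect_error(make_synthetic_ensembles(
    list(generator = "correlated_contacts", n = 10, p = 0.5, C = 10)),
    "infeasible")
  expect_error(make_synthetic_ensembles(list(generator = "nope")),
               "unknown generator")
  # generators are seed-reproducible
  a <- make_synthetic_ensembles(list(generator = "independent_angles",
                                     n = 50), seed = 4)
  b <- make_synthetic_ensembles(list(generator = "independent_angles",
                                     n = 50), seed = 4)
  expect_identical(a, b)
})

test_that("generic start coordinates respect the topology", {
  top <- build_topology(bulge_ss())
  co <- build_start_coords(top)
  expect_equal(nrow(co), top$n_beads)
  expect_false(anyNA(co))
  # bonds are near their equilibria after relaxation
  d <- sqrt(rowSums((co[top$bonds$i, ] - co[top$bonds$j, ])^2))
  expect_lt(max(abs(d - top$bonds$r0)), 2)
})
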