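test_that("bead and term counts follow the bonding rules", {
  # 10-nt two-strand duplex (5 pairs): 30 moiety beads + 5 M beads
  top <- build_topology(duplex_ss(5))
  expect_equal(top$n_beads, 30 + 5)
  expect_equal(sum(top$beads$kind == "M"), 5)
  # dihedrals on all backbone quadruples within the helix: per strand,
  # 4 P-S-P-S steps and 3 S-P-S-P steps
  expect_equal(nrow(top$dihedrals), 2 * (4 + 3))

  # 10-nt unpaired strand: 30 beads, no M, no dihedrals
  top0 <- build_topology(
    parse_secondary_structure(c("AAAAAAAAAA", "..........")))
  expect_equal(top0$n_beads, 30)
  expect_equal(nrow(top0$dihedrals), 0)

  # WT tRNA: 3*76 + 21 beads
  expect_equal(wt_topology()$n_beads, 3 * 76 + 21)
})

test_that("single strands carry no dihedrals and every pair has one M bead", {
  top <- wt_topology()
  ss <- top$ss
  loops <- unlist(ss$elements[!grepl("stem", names(ss$elements))])
  loop_beads <- c(bead_P(loops), bead_S(loops), bead_B(loops))
  dih_beads <- unique(unlist(top$dihedrals[, c("i", "j", "k", "l")]))
  expect_length(intersect(dih_beads, loop_beads), 0)
  expect_equal(nrow(top$m_beads), nrow(ss$pairs))
  # LJ: every bead has eps 0.01; only paired-B (and M) carry the attraction
  expect_true(all(top$beads$eps == 0.01))
  attract_b <- which(top$beads$attract & top$beads$kind == "B")
  expect_setequal(top$beads$residue[attract_b],
                  sort(c(ss$pairs[, 1], ss$pairs[, 2])))
})

test_that("term topology is a pure function of the pair table", {
  ss1 <- trna_fixture("wt")
  seqc <- strsplit(ss1$sequence, "")[[1]]
  set.seed(9)
  shuffled <- paste(sample(seqc), collapse = "")
  ss2 <- parse_secondary_structure(pairs = ss1$pairs, sequence = shuffled)
  t1 <- build_topology(ss1)
  t2 <- build_topology(ss2)
  for (part in c("bonds", "angles", "impropers", "dihedrals")) {
    expect_identical(t1[[part]], t2[[part]], info = part)
  }
})

test_that("a cut removes exactly one backbone bond and its adjacent terms", {
  wt <- wt_topology()
  cut <- build_topology(trna_fixture("cut_ad"))
  b1 <- with(wt$bonds, paste(i, j, type))
  b2 <- with(cut$bonds, paste(i, j, type))
  gone <- setdiff(b1, b2)
  expect_length(gone, 1)
  expect_equal(gone, paste(bead_S(8), bead_P(9), "SP"))
  expect_length(setdiff(b2, b1), 0)
  # cutting directly on the topology object matches the rebuilt version
  cut2 <- apply_variant(wt, "cut", at = 8)
  expect_setequal(with(cut2$bonds, paste(i, j, type)), b2)
})

test_that("restraint tables carry the documented windows and constants", {
  r <- make_restraints("tertiary_pair", c(8, 14))
  expect_equal(nrow(r), 2)
  bb <- r[r$kind == "BB", ]
  ssr <- r[r$kind == "SS", ]
  expect_equal(c(bb$rmin, bb$rmax), c(5.5, 7.5))
  expect_equal(c(ssr$rmin, ssr$rmax), c(11, 14))
  expect_true(all(r$k == 2.0) && all(r$fcap == 2.0))
  expect_equal(bb$bi, bead_B(8))
  expect_equal(ssr$bj, bead_S(14))

  # base triple windows are +/- 1 (B-B) and +/- 1.5 (S-S) around reference
  tr <- make_restraints("base_triple", c(20, 10, 25),
                        reference_distances = list(BB = c(6, 7),
                                                   SS = c(12, 13)))
  expect_equal(tr$rmin[tr$kind == "BB"], c(5, 6))
  expect_equal(tr$rmax[tr$kind == "BB"], c(7, 8))
  expect_equal(tr$rmin[tr$kind == "SS"], c(10.5, 11.5))
  expect_error(make_restraints("base_triple", c(20, 10, 25)), "reference")

  # g26 variant flags force-field modifications
  g <- make_restraints("g26_pair", c(26, 44))
  expect_false(is.null(attr(g, "mods")))
  top <- attach_restraints(wt_topology(), g)
  expect_true(all(top$beads$attract[bead_B(c(26, 44))]))
})

test_that("restraint energy is zero inside the window and the force caps", {
  spec <- make_restraints("tertiary_pair", c(1, 10))[1, ]  # B-B 5.5-7.5
  mid <- restraint_energy_force((5.5 + 7.5) / 2, spec)
  expect_equal(mid$energy, 0)
  expect_equal(mid$force, 0)
  # harmonic regime just outside: F = k * delta
  just <- restraint_energy_force(7.6, spec)
  expect_equal(just$force, 2.0 * 0.1, tolerance = 1e-10)
  # capped far outside
  far <- restraint_energy_force(17.5, spec)
  expect_equal(far$force, 2.0)
  below <- restraint_energy_force(5.0, spec)
  expect_equal(below$force, 2.0 * 0.5, tolerance = 1e-10)
})

test_that("topology text format round-trips", {
  dir <- withr::local_tempdir()
  top <- attach_restraints(build_topology(trna_fixture("cut_ad")),
                           make_restraints("tertiary_pair",
                                           trna_conserved_pairs()))
  f <- file.path(dir, "cut_ad.top")
  write_topology(top, f)
  top2 <- read_topology(f)
  expect_equal(top2$n_beads, top$n_beads)
  expect_identical(top2$bonds, top$bonds)
  expect_identical(top2$dihedrals, top$dihedrals)
  expect_equal(top2$restraints$rmin, top$restraints$rmin)
  expect_equal(top2$strand_breaks, top$strand_breaks)
})
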