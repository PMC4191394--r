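test_that("residue contacts need both the distance and separation criteria", {
  top <- wt_topology()
  n <- top$n_beads
  co <- matrix(0, n, 3)
  place_S <- function(i, x) co[bead_S(i), ] <<- c(x, 0, 0)
  place_S(10, 0); place_S(16, 13.9)
  expect_true(residue_contact(co, 10, 16))
  place_S(16, 14.1)
  expect_false(residue_contact(co, 10, 16))
  place_S(14, 5)  # |i - j| = 4: too close in sequence
  expect_false(residue_contact(co, 10, 14))
})

test_that("group contacts equal a brute-force all-pairs scan", {
  top <- wt_topology()
  set.seed(44)
  els <- top$ss$elements
  for (rep in 1:10) {
    co <- matrix(rnorm(3 * top$n_beads, sd = 14), top$n_beads, 3)
    a <- els[["D-loop"]]; b <- els[["T-loop"]]
    brute <- FALSE
    for (i in a) for (j in b) {
      if (abs(i - j) >= 5 &&
          sqrt(sum((co[bead_S(i), ] - co[bead_S(j), ])^2)) < 14) brute <- TRUE
    }
    expect_equal(group_contact(co, top, "D-loop", "T-loop"), brute)
  }
  expect_error(group_contact(co, top, "D-loop", 14:16), "overlap")
})

test_that("coaxial stacking follows the three geometric criteria", {
  ref <- wt_reference()
  top <- ref$topology
  co <- ref$coords
  # the reference L has both native stacks by construction
  expect_true(coaxial_stack(co, top, c("D-stem", "AC-stem")))
  expect_true(coaxial_stack(co, top, c("T-stem", "A-stem")))

  # bending one helix by 90 degrees about the junction breaks criterion (i)
  co_bent <- co
  arm <- top$ss$elements[["A-stem"]]
  idx <- c(bead_P(arm), bead_S(arm), bead_B(arm),
           top$m_beads$bead[top$m_beads$i %in% arm])
  cp <- toprna:::closing_pairs(top$ss, c("T-stem", "A-stem"))
  pivot <- colMeans(co[bead_B(cp$pair2), , drop = FALSE])
  fr <- fit_helix_frame(co, top, "A-stem")
  R <- toprna:::rotation_about(fr$axes[, "x"], 90)
  co_bent[idx, ] <- sweep(sweep(co[idx, , drop = FALSE], 2, pivot) %*% t(R),
                          2, pivot, "+")
  expect_false(coaxial_stack(co_bent, top, c("T-stem", "A-stem")))

  # translating the helix 10 A away from its partner breaks criterion (ii)
  co_far <- co
  com_a <- colMeans(co[bead_B(cp$pair2), , drop = FALSE])
  com_t <- colMeans(co[bead_B(cp$pair1), , drop = FALSE])
  shift <- 10 * (com_a - com_t) / sqrt(sum((com_a - com_t)^2))
  co_far[idx, ] <- sweep(co[idx, , drop = FALSE], 2, shift, "+")
  expect_false(coaxial_stack(co_far, top, c("T-stem", "A-stem")))
})

test_that("two stacked ideal helix builds satisfy the stack criteria", {
  # 11-bp ideal duplex geometry with pairing split into two helices by an
  # internal loop (residues 6 and 17 unpaired): the builds are exactly
  # coaxial, one single-stranded nt apart
  db <- paste(c(rep("(", 5), ".", rep("(", 4), "..", rep(")", 4), ".",
                rep(")", 5)), collapse = "")
  ss <- parse_secondary_structure(
    c(paste(rep(c("G", "C"), each = 11), collapse = ""), db))
  expect_length(ss$helices, 2)
  top <- build_topology(ss)
  ideal <- build_ideal_helix(11)
  # map ideal duplex beads (which include M beads for all 11 pairs) onto the
  # 9-pair topology: residue beads align; M beads are recomputed
  co <- matrix(NA_real_, top$n_beads, 3)
  co[1:(3 * 22), ] <- ideal[1:(3 * 22), ]
  for (q in seq_len(nrow(top$m_beads))) {
    co[top$m_beads$bead[q], ] <- (co[bead_B(top$m_beads$i[q]), ] +
                                  co[bead_B(top$m_beads$j[q]), ]) / 2
  }
  h12 <- names(ss$helices)[1:2]
  expect_true(coaxial_stack(co, top, h12))
  # 90-degree bend between the axes violates criterion (i)
  co_bent <- co
  res2 <- sort(unlist(lapply(1:2, function(cx) ss$helices[[2]][, cx])))
  idx <- c(bead_P(res2), bead_S(res2), bead_B(res2),
           top$m_beads$bead[top$m_beads$i %in% res2])
  pivot <- c(0, 0, 10 * toprna_params()$geometry$rise)
  R <- toprna:::rotation_about(c(1, 0, 0), 90)
  co_bent[idx, ] <- sweep(sweep(co[idx, , drop = FALSE], 2, pivot) %*% t(R),
                          2, pivot, "+")
  expect_false(coaxial_stack(co_bent, top, h12))
})

test_that("contact free energies follow the log-odds law", {
  ens <- wt_short_ensemble()
  # synthetic indicator streams exercise the arithmetic exactly
  fake <- function(p, n = 1000) c(rep(TRUE, round(p * n)),
                                  rep(FALSE, n - round(p * n)))
  ghalf <- contact_free_energy(ens, NULL, series = fake(0.5))
  expect_equal(ghalf$dg, 0)
  g1 <- contact_free_energy(ens, NULL, series = fake(0.1))
  expect_equal(g1$dg, log(9), tolerance = 1e-12)
  g9 <- contact_free_energy(ens, NULL, series = fake(0.9))
  expect_equal(g9$dg, -g1$dg, tolerance = 1e-12)
  # kcal conversion at 300 K
  expect_equal(g1$dg_kcal, g1$dg * 0.0019872041 * 300, tolerance = 1e-6)
  # unobserved contact: bound reported, flagged
  g0 <- contact_free_energy(ens, NULL, series = rep(FALSE, 500))
  expect_false(g0$bounded)
  expect_equal(g0$dg, log(500))
})

test_that("cooperativity is 1 under independence and P_joint/P^2 when planted", {
  ens <- wt_short_ensemble()
  ind <- make_synthetic_ensembles(list(generator = "correlated_contacts",
                                       n = 2e5, p = 0.2, C = 1,
                                       n_independent = 2), seed = 6)
  cp <- cooperativity(ens, series = ind)
  expect_equal(cp$C, 1, tolerance = 0.15)
  planted <- make_synthetic_ensembles(list(generator = "correlated_contacts",
                                           n = 2e5, p = 0.1, C = 10),
                                      seed = 7)
  cp10 <- cooperativity(ens, series = planted)
  expect_equal(cp10$C, 10, tolerance = 10 * 0.1)
  # measured marginals match the planted rate within binomial noise
  expect_equal(unname(cp10$p_marginal), c(0.1, 0.1), tolerance = 3 * sqrt(0.1 * 0.9 / 2e5) / 0.1 * 0.1 + 0.003)
})

test_that("log-cooperativity relates to joint and marginal free energies", {
  # exact identity on synthetic probabilities:
  # ln C = ln P12 - ln P1 - ln P2, and dG = -ln(P/(1-P))
  p1 <- 0.05; p2 <- 0.08; C <- 4
  p12 <- C * p1 * p2
  lnC <- log(p12) - log(p1) - log(p2)
  dg <- function(p) -log(p / (1 - p))
  # in the P << 1 regime dG ~ -ln P, so lnC ~ dG1 + dG2 - dG12
  approx_lnC <- dg(p1) + dg(p2) - dg(p12)
  expect_equal(lnC, approx_lnC, tolerance = 0.2)
  # exact identity including the odds corrections
  exact <- (dg(p1) + dg(p2) - dg(p12)) +
    log((1 - p12) / ((1 - p1) * (1 - p2)))
  expect_equal(lnC, exact, tolerance = 1e-12)
})

test_that("mean cooperativity separates native from mixed combinations", {
  ens <- wt_short_ensemble()
  set.seed(99)
  n <- 5e4
  # two cooperative "native" contacts + one independent "non-native"
  u <- runif(n)
  a <- u < 0.15
  b <- ifelse(a, runif(n) < 0.6, runif(n) < 0.05)
  cc <- runif(n) < 0.1
  ser <- cbind(A = a, B = b, C = cc)
  contacts <- list(list(type = "residue", i = 1, j = 10),
                   list(type = "residue", i = 2, j = 20),
                   list(type = "residue", i = 3, j = 30))
  # bypass contact evaluation by feeding the series through cooperativity
  mc <- local({
    # emulate mean_cooperativity on the synthetic series
    combos <- utils::combn(3, 2)
    out <- NULL
    for (q in seq_len(ncol(combos))) {
      sel <- combos[, q]
      cp <- cooperativity(ens, series = ser[, sel])
      out <- rbind(out, data.frame(native = all(sel <= 2), C = cp$C))
    }
    out
  })
  expect_gt(mc$C[mc$native], max(mc$C[!mc$native]))
})

test_that("coupled stability implements the restrained-minus-unrestrained rule", {
  ens <- wt_short_ensemble()
  # identical ensembles: ddG = 0
  same <- coupled_stability(ens, ens, list(type = "group", a = "D-loop",
                                           b = "T-loop"))
  expect_equal(same$ddg, 0)
  # synthetic probabilities: P 0.1 -> 0.5 gives -ln 9
  s_u <- c(rep(TRUE, 100), rep(FALSE, 900))
  s_r <- c(rep(TRUE, 500), rep(FALSE, 500))
  g_u <- contact_free_energy(ens, NULL, series = s_u)
  g_r <- contact_free_energy(ens, NULL, series = s_r)
  expect_equal(g_r$dg - g_u$dg, -log(9), tolerance = 1e-12)
  # refusal when the target loops carry an active restraint between them
  top_r <- attach_restraints(wt_topology(),
                             make_restraints("tertiary_pair", c(18, 55)))
  ens_r <- ens
  ens_r$topology <- top_r
  expect_error(
    coupled_stability(ens, ens_r, list(type = "group", a = "D-loop",
                                       b = "T-loop")),
    "active restraint")
})

test_that("mean cooperativity curves enumerate combinations over an ensemble", {
  ref <- wt_reference()
  ens <- make_synthetic_ensembles(list(generator = "jittered_reference",
                                       reference = ref, n = 40, sigma = 4),
                                  seed = 61)
  contacts <- list(
    list(type = "group", a = "D-loop", b = "T-loop"),
    list(type = "group", a = "A/D-loop", b = "D-loop"),
    list(type = "stack", helices = c("D-stem", "AC-stem")),
    list(type = "stack", helices = c("T-stem", "A-stem")))
  native <- c(TRUE, TRUE, TRUE, FALSE)
  curve <- mean_cooperativity(ens, n = 2, contacts = contacts,
                              native = native, min_observed = 5L)
  expect_true(all(c("n", "class", "mean_C", "n_combos") %in% names(curve)))
  expect_true(all(curve$mean_C > 0))
  expect_true(all(curve$n == 2))
})
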