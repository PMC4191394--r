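test_that("forces are the exact negative gradient of the energy", {
  set.seed(7)
  top <- duplex_topology(6)
  co <- build_ideal_helix(6) + matrix(rnorm(3 * (6 * 7)), 6 * 7, 3) * 0.3
  ef <- energy_forces(co, top)
  expect_true(all(c("bond", "angle", "improper", "dihedral", "lj",
                    "restraint") %in% names(ef$breakdown)))
  expect_equal(sum(ef$breakdown), ef$energy)
  h <- 1e-5
  worst <- 0
  for (q in sample(nrow(co), 15)) {
    for (d in 1:3) {
      cp <- co; cm <- co
      cp[q, d] <- cp[q, d] + h
      cm[q, d] <- cm[q, d] - h
      num <- -(energy_forces(cp, top)$energy -
               energy_forces(cm, top)$energy) / (2 * h)
      worst <- max(worst, abs(num - ef$forces[q, d]) / max(abs(num), 1e-3))
    }
  }
  expect_lt(worst, 1e-5)
})

test_that("restrained configurations see zero energy and force in-window", {
  top <- dimer_topology(k = 0)  # no bond force, restraint only
  r <- make_restraints("tertiary_pair", c(1, 2))[1, ]  # B-B window 5.5-7.5
  r$bi <- 1L; r$bj <- 2L
  top <- attach_restraints(top, r)
  for (d in c(5.6, 6.5, 7.4)) {
    co <- rbind(c(0, 0, 0), c(d, 0, 0))
    ef <- energy_forces(co, top)
    expect_equal(ef$breakdown[["restraint"]], 0)
    expect_equal(max(abs(ef$forces)), 0)
  }
  co <- rbind(c(0, 0, 0), c(17.5, 0, 0))
  ef <- energy_forces(co, top)
  expect_equal(abs(ef$forces[2, 1]), 2.0, tolerance = 1e-10)
})

test_that("the ideal A-form helix is the zero of the bonded potential", {
  top <- duplex_topology(8)
  ef <- energy_forces(build_ideal_helix(8), top)
  for (term in c("bond", "angle", "improper", "dihedral")) {
    expect_lt(abs(ef$breakdown[[term]]), 1e-8)
  }
})

test_that("frictionless integration conserves energy (symplectic check)", {
  top <- dimer_topology(k = 2)
  co <- rbind(c(0, 0, 0), c(5.3, 0, 0))  # slightly stretched bond
  v0 <- matrix(0, 2, 3)
  ff <- toprna:::ff_list(top)
  e0 <- toprna:::cpp_run_segment(co, v0, ff, 1, 0.02, 0, 0.6, 1)
  start <- e0$epot + e0$ekin
  out <- toprna:::cpp_run_segment(co, v0, ff, 1e5, 0.02, 0, 0.6, 1)
  drift <- abs((out$epot + out$ekin) - start) / abs(start)
  expect_lt(drift, 0.001)
})

test_that("a thermostatted bond reproduces the Boltzmann distance law", {
  k <- 5; r0 <- 5; temp <- 300
  kB <- toprna_params()$kB
  top <- dimer_topology(k, r0)
  proto <- simulation_protocol(total_steps = 4e5, n_replicas = 1,
                               t_low = temp, snapshot_interval = 200,
                               equilibration_steps = 2e4, seed = 11)
  ens <- run_replica_exchange(top, proto,
                              initial = rbind(c(0, 0, 0), c(r0, 0, 0)))
  d <- apply(ens$coords, 1, function(co) sqrt(sum((co[2, ] - co[1, ])^2)))
  # analytic radial law: p(r) ~ r^2 exp(-beta k (r - r0)^2)
  beta <- 1 / (kB * temp)
  rr <- seq(1e-3, r0 + 6, length.out = 4000)
  dens <- rr^2 * exp(-beta * k * (rr - r0)^2)
  cdf <- cumsum(dens); cdf <- cdf / cdf[length(cdf)]
  ks <- stats::ks.test(d, function(q) approx(rr, cdf, q, rule = 2)$y)
  expect_gt(ks$p.value, 0.01)
  # equipartition: measured kinetic temperature within 2%
  expect_lt(abs(ens$kinetic_temperatures[1] - temp) / temp, 0.02)
})

test_that("replica exchange is deterministic and restraint-free runs match", {
  top <- build_topology(bulge_ss())
  proto <- simulation_protocol(total_steps = 2e4, n_replicas = 3,
                               exchange_interval = 2000,
                               snapshot_interval = 2000,
                               equilibration_steps = 2000, seed = 5)
  e1 <- run_replica_exchange(top, proto)
  e2 <- run_replica_exchange(top, proto)
  expect_identical(e1$coords, e2$coords)  # bit-identical snapshot stream
  # empty restraint set: fold_with_restraints equals the plain run
  e3 <- fold_with_restraints(top, list(), proto)
  expect_identical(e3$coords, e1$coords)
})

test_that("a single restrained bead pair matches the 1D Boltzmann law", {
  # two beads with only a flat-bottom restraint: the stationary distance
  # distribution is p(r) ~ r^2 exp(-beta E_restraint(r))
  temp <- 300
  kB <- toprna_params()$kB
  top <- dimer_topology(k = 0)
  spec <- make_restraints("tertiary_pair", c(1, 2))[1, ]  # window 5.5-7.5
  spec$bi <- 1L; spec$bj <- 2L
  top <- attach_restraints(top, spec)
  proto <- simulation_protocol(total_steps = 6e5, n_replicas = 1,
                               t_low = temp, snapshot_interval = 200,
                               equilibration_steps = 4e4, seed = 17)
  ens <- run_replica_exchange(top, proto,
                              initial = rbind(c(0, 0, 0), c(6.5, 0, 0)))
  expect_true("restraint_satisfied" %in% names(ens$meta))
  d <- apply(ens$coords, 1, function(co) sqrt(sum((co[2, ] - co[1, ])^2)))
  # analytic probability of being inside the window
  beta <- 1 / (kB * temp)
  rr <- seq(0.01, 30, by = 0.005)
  e_rest <- restraint_energy_force(rr, spec)$energy
  dens <- rr^2 * exp(-beta * e_rest)
  p_in <- sum(dens[rr >= 5.5 & rr <= 7.5]) / sum(dens)
  expect_equal(mean(d >= 5.5 & d <= 7.5), p_in, tolerance = 0.08)
  expect_equal(mean(ens$meta$restraint_satisfied), p_in, tolerance = 0.08)
  # the distribution is concentrated in and near the window
  expect_gt(mean(d >= 4.5 & d <= 8.5), 0.85)
})

test_that("kinetic temperatures track the replica ladder", {
  ens <- wt_short_ensemble()
  temps <- ens$protocol$temperatures
  expect_equal(ens$kinetic_temperatures, temps, tolerance = 0.02)
  # exchange acceptance is neither stuck nor saturated
  rates <- ens$exchange_accepts / pmax(1, ens$exchange_attempts)
  expect_true(all(rates > 0.05) && all(rates < 0.95))
})
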