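# Engine-facing representation of a topology: plain vectors consumed by the
# compiled force/integrator routines.
ff_list <- function(top) {
  stopifnot(inherits(top, "toprna_topology"))
  df2l <- function(d, cols) {
    out <- lapply(cols, function(cn) {
      v <- d[[cn]]
      if (cn %in% c("i", "j", "k", "l", "bi", "bj")) as.integer(v) else
        as.numeric(v)
    })
    names(out) <- cols
    out
  }
  ang_rad <- function(x) x * pi / 180
  a <- top$angles; a$th0 <- ang_rad(a$th0)
  im <- top$impropers; im$phi0 <- ang_rad(im$phi0)
  d <- top$dihedrals; d$phi0 <- ang_rad(d$phi0)
  r <- top$restraints
  if (is.null(r)) {
    r <- data.frame(bi = integer(), bj = integer(), rmin = numeric(),
                    rmax = numeric(), k = numeric(), fcap = numeric())
  }
  list(
    n = top$n_beads,
    bonds = df2l(top$bonds, c("i", "j", "r0", "k")),
    angles = df2l(a, c("i", "j", "k", "th0", "kth")),
    impropers = df2l(im, c("i", "j", "k", "l", "phi0", "kimp")),
    dihedrals = df2l(d, c("i", "j", "k", "l", "phi0", "kdih")),
    radius = as.numeric(top$beads$radius),
    mass = as.numeric(top$beads$mass),
    attract = as.integer(top$beads$attract),
    eps = top$params$lj_eps,
    eps_stack = top$params$eps_stack,
    cutoff = top$params$cutoff,
    restraints = df2l(r, c("bi", "bj", "rmin", "rmax", "k", "fcap")))
}

#' Potential energy and forces of a configuration
#'
#' Evaluates the full coarse-grained potential (bonds, angles, chirality
#' impropers, helical dihedrals, Lennard-Jones sterics with the paired-B
#' stacking attraction, and any attached flat-bottom restraints).  Forces are
#' the exact negative gradient of the reported energy.
#'
#' @param coords Bead coordinate matrix (n_beads x 3, Angstrom).
#' @param top A `toprna_topology`.
#' @return List with `energy` (kcal/mol), `forces` (n x 3, kcal/mol/A) and a
#'   named per-term `breakdown`.
#' @export
energy_forces <- function(coords, top) {
  if (nrow(coords) != top$n_beads) {
    stop("coordinate rows (", nrow(coords), ") do not match topology beads (",
         top$n_beads, ")")
  }
  cpp_energy_forces(coords, ff_list(top))
}

#' Flat-bottom restraint energy and force at a distance
#'
#' Zero inside `[r_min, r_max]`, harmonic (`0.5 k delta^2`, force `k delta`)
#' just outside, linear with force magnitude `fcap` far outside.  Vectorized
#' over `distance`.
#'
#' @param distance Distance(s) in Angstrom (> 0).
#' @param spec One row of a `toprna_restraints` table (or a list with `rmin`,
#'   `rmax`, `k`, `fcap`).
#' @return Data frame with `energy` (kcal/mol) and `force` (kcal/mol/A;
#'   positive = pushes the distance back toward the window).
#' @export
restraint_energy_force <- function(distance, spec) {
  stopifnot(all(distance > 0))
  rmin <- spec$rmin[1]; rmax <- spec$rmax[1]
  k <- spec$k[1]; fcap <- spec$fcap[1]
  delta <- ifelse(distance < rmin, rmin - distance,
                  ifelse(distance > rmax, distance - rmax, 0))
  dstar <- fcap / k
  energy <- ifelse(delta <= dstar, 0.5 * k * delta^2,
                   0.5 * k * dstar^2 + fcap * (delta - dstar))
  force <- pmin(k * delta, fcap)
  data.frame(energy = energy, force = force)
}

#' Define a replica-exchange Langevin protocol
#'
#' Defaults follow the study protocol: 20 fs timestep, 5 ps^-1 friction,
#' eight temperature replicas exponentially spaced from 300 to 450 K,
#' exchange attempts and snapshots every 2000 steps, and the leading
#' `equilibration_steps` discarded from analysis (default: a tenth of the run,
#' capped at the 2e6 steps used for full-scale runs).
#'
#' @param total_steps Dynamics steps per replica.
#' @param timestep_fs Integration timestep in femtoseconds.
#' @param friction Langevin friction (ps^-1).
#' @param n_replicas Number of temperature replicas.
#' @param t_low,t_high Temperature range (K), exponentially spaced.
#' @param exchange_interval Steps between neighbor exchange attempts.
#' @param snapshot_interval Steps between recorded T_low snapshots.
#' @param equilibration_steps Steps discarded from the snapshot record.
#' @param seed Integer seed controlling every source of randomness.
#' @return A `toprna_protocol` list.
#' @export
simulation_protocol <- function(total_steps = 2e6, timestep_fs = 20,
                                friction = 5, n_replicas = 8,
                                t_low = 300, t_high = 450,
                                exchange_interval = 2000,
                                snapshot_interval = 2000,
                                equilibration_steps = NULL, seed = 1) {
  if (is.null(equilibration_steps)) {
    equilibration_steps <- min(2e6, floor(total_steps / 10))
  }
  if (equilibration_steps >= total_steps) {
    stop("equilibration must be shorter than the run")
  }
  temps <- if (n_replicas == 1) t_low else
    t_low * (t_high / t_low)^((seq_len(n_replicas) - 1) / (n_replicas - 1))
  if (any(diff(temps) <= 0)) stop("temperatures must be strictly increasing")
  structure(list(
    total_steps = as.numeric(total_steps), timestep_fs = timestep_fs,
    friction = friction, n_replicas = as.integer(n_replicas),
    temperatures = temps, exchange_interval = as.integer(exchange_interval),
    snapshot_interval = as.integer(snapshot_interval),
    equilibration_steps = as.numeric(equilibration_steps),
    seed = as.integer(seed)), class = "toprna_protocol")
}

gcd2 <- function(a, b) if (b == 0) a else gcd2(b, a %% b)

#' Run temperature replica-exchange Langevin dynamics
#'
#' Integrates all replicas with BAOAB Langevin dynamics, attempting Metropolis
#' exchanges between alternating neighbor pairs every
#' `protocol$exchange_interval` steps (velocities are rescaled by
#' `sqrt(T_new/T_old)` on accepted swaps).  Snapshots of the configuration
#' currently at the lowest temperature are recorded every
#' `protocol$snapshot_interval` steps; those within the equilibration window
#' are discarded.  Runs are exactly reproducible for a fixed seed.
#'
#' @param top A `toprna_topology` (with or without attached restraints).
#' @param protocol A `toprna_protocol`.
#' @param initial Starting bead coordinates; defaults to the idealized
#'   L-shaped reference for cloverleaf structures and a generic layout
#'   otherwise.
#' @return A `toprna_ensemble`: snapshot array `coords` (n_snap x n_beads x
#'   3), per-snapshot metadata (`step`, `replica`, `epot`, and the fraction of
#'   satisfied restraint windows when restraints are attached), exchange
#'   acceptance statistics and per-replica mean kinetic temperatures.
#' @export
run_replica_exchange <- function(top, protocol, initial = NULL) {
  stopifnot(inherits(top, "toprna_topology"),
            inherits(protocol, "toprna_protocol"))
  if (is.null(initial)) {
    initial <- if (isTRUE(top$ss$is_cloverleaf)) {
      build_reference_trna(top$ss, params = top$params)$coords
    } else {
      build_start_coords(top)
    }
  }
  if (nrow(initial) != top$n_beads) stop("initial coordinates mismatch")
  ff <- ff_list(top)
  p <- protocol
  kB <- top$params$kB
  dt <- p$timestep_fs / 1000  # ps
  nr <- p$n_replicas
  temps <- p$temperatures
  betas <- 1 / (kB * temps)

  oseed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(oseed)) assign(".Random.seed", oseed,
                                      envir = globalenv()), add = TRUE)
  set.seed(p$seed)

  nb <- top$n_beads
  masses <- top$beads$mass
  kfac <- 418.4
  coords <- vector("list", nr)
  vels <- vector("list", nr)
  for (r in seq_len(nr)) {
    coords[[r]] <- initial
    sd_v <- sqrt(kB * temps[r] * kfac / masses)
    vels[[r]] <- matrix(stats::rnorm(3 * nb), nb, 3) * sd_v
  }

  chunk <- gcd2(p$exchange_interval, p$snapshot_interval)
  n_chunks <- floor(p$total_steps / chunk)
  epot <- rep(NA_real_, nr)
  ekin_sum <- numeric(nr); ekin_n <- 0
  att <- acc <- numeric(max(1, nr - 1))
  snaps <- list(); meta <- list()
  has_restr <- !is.null(top$restraints) && nrow(top$restraints) > 0

  for (ch in seq_len(n_chunks)) {
    step_now <- ch * chunk
    for (r in seq_len(nr)) {
      # exact-integer double < 2^53, unique per (seed, chunk, replica)
      seg_seed <- (as.numeric(p$seed) %% 2^20) * 2^24 +
        (ch %% 2^20) * 16 + r
      out <- cpp_run_segment(coords[[r]], vels[[r]], ff, chunk, dt,
                             p$friction, kB * temps[r], seg_seed)
      coords[[r]] <- out$coords
      vels[[r]] <- out$vel
      epot[r] <- out$epot
      # kinetic energy sampled at the thermostat (post-O) point, where the
      # BAOAB velocity distribution is unbiased
      ekin_sum[r] <- ekin_sum[r] + out$ekin_mid
    }
    ekin_n <- ekin_n + 1
    if (nr > 1 && step_now %% p$exchange_interval == 0) {
      n_ex <- step_now / p$exchange_interval
      first <- if (n_ex %% 2 == 1) 1 else 2
      ks <- if (first <= nr - 1) seq(first, nr - 1, by = 2) else integer()
      for (k in ks) {
        att[k] <- att[k] + 1
        logp <- (betas[k] - betas[k + 1]) * (epot[k] - epot[k + 1])
        if (log(stats::runif(1)) < min(0, logp)) {
          acc[k] <- acc[k] + 1
          tmp <- coords[[k]]; coords[[k]] <- coords[[k + 1]]; coords[[k + 1]] <- tmp
          sc_up <- sqrt(temps[k + 1] / temps[k])
          vtmp <- vels[[k]] * sc_up
          vels[[k]] <- vels[[k + 1]] / sc_up
          vels[[k + 1]] <- vtmp
          etmp <- epot[k]; epot[k] <- epot[k + 1]; epot[k + 1] <- etmp
        }
      }
    }
    if (step_now %% p$snapshot_interval == 0 &&
        step_now > p$equilibration_steps) {
      snaps[[length(snaps) + 1]] <- coords[[1]]
      m <- data.frame(step = step_now, replica = 1L, epot = epot[1])
      if (has_restr) {
        d <- sqrt(rowSums((coords[[1]][top$restraints$bi, , drop = FALSE] -
                           coords[[1]][top$restraints$bj, , drop = FALSE])^2))
        m$restraint_satisfied <- mean(d >= top$restraints$rmin &
                                      d <= top$restraints$rmax)
      }
      meta[[length(meta) + 1]] <- m
    }
  }
  if (length(snaps) == 0) stop("no post-equilibration snapshots recorded")
  arr <- array(NA_real_, c(length(snaps), nb, 3))
  for (s in seq_along(snaps)) arr[s, , ] <- snaps[[s]]
  kin_T <- (2 * ekin_sum / ekin_n) / (3 * nb * kB)
  structure(list(
    coords = arr, topology = top, protocol = p,
    meta = do.call(rbind, meta),
    n_snapshots = length(snaps),
    exchange_attempts = att, exchange_accepts = acc,
    kinetic_temperatures = kin_T), class = "toprna_ensemble")
}

#' Run restrained replica exchange
#'
#' Identical machinery to [run_replica_exchange()] with flat-bottom restraint
#' terms active; per-snapshot restraint-window satisfaction is recorded in the
#' ensemble metadata.
#'
#' @param top A `toprna_topology`.
#' @param restraints One `toprna_restraints` table or a list of them.
#' @param protocol A `toprna_protocol`.
#' @param initial Starting coordinates (typically a reference structure).
#' @return A `toprna_ensemble`.
#' @export
fold_with_restraints <- function(top, restraints, protocol, initial = NULL) {
  if (inherits(restraints, "toprna_restraints")) restraints <- list(restraints)
  top <- do.call(attach_restraints, c(list(top), restraints))
  run_replica_exchange(top, protocol, initial)
}

#' @export
print.toprna_ensemble <- function(x, ...) {
  cat(sprintf("<toprna_ensemble> %d snapshots of %d beads (%.0f K)\n",
              x$n_snapshots, dim(x$coords)[2], x$protocol$temperatures[1]))
  if (any(x$exchange_attempts > 0)) {
    cat("  exchange acceptance:",
        paste(sprintf("%.0f%%", 100 * x$exchange_accepts /
                        pmax(1, x$exchange_attempts)), collapse = " "), "\n")
  }
  invisible(x)
}

#' Subset an ensemble's snapshots
#'
#' @param ens A `toprna_ensemble`.
#' @param idx Snapshot indices to keep.
#' @return A `toprna_ensemble` with the selected snapshots.
#' @export
subset_ensemble <- function(ens, idx) {
  ens$coords <- ens$coords[idx, , , drop = FALSE]
  ens$meta <- ens$meta[idx, , drop = FALSE]
  ens$n_snapshots <- length(idx)
  ens
}
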