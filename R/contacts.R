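# Contact definitions: two residues are in contact when their S beads are
# closer than 14 Angstrom and the residues are at least 5 apart in sequence;
# loops (or a loop and a stem) are in contact when at least one such
# residue-residue contact links them.

CONTACT_SS_CUTOFF <- 14
CONTACT_MIN_SEP <- 5L

#' Residue-residue contact test
#'
#' @param coords Bead coordinates.
#' @param i,j Residue indices (1-based).
#' @return `TRUE` iff the S-S distance is below 14 Angstrom and
#'   `|i - j| >= 5`.
#' @export
residue_contact <- function(coords, i, j) {
  if (abs(i - j) < CONTACT_MIN_SEP) return(FALSE)
  bead_distance(coords[bead_S(i), ], coords[bead_S(j), ]) < CONTACT_SS_CUTOFF
}

#' Group (loop-loop or loop-stem) contact test
#'
#' @param coords Bead coordinates.
#' @param top A `toprna_topology`.
#' @param a,b Element names or residue vectors (must be disjoint).
#' @return `TRUE` iff any qualifying residue-residue contact links the
#'   groups.
#' @export
group_contact <- function(coords, top, a, b) {
  ra <- if (is.character(a)) top$ss$elements[[a]] else a
  rb <- if (is.character(b)) top$ss$elements[[b]] else b
  if (length(intersect(ra, rb)) > 0) stop("elements overlap")
  sa <- coords[bead_S(ra), , drop = FALSE]
  sb <- coords[bead_S(rb), , drop = FALSE]
  d2 <- outer(rowSums(sa^2), rowSums(sb^2), "+") - 2 * sa %*% t(sb)
  sep <- abs(outer(ra, rb, "-"))
  any(d2 < CONTACT_SS_CUTOFF^2 & sep >= CONTACT_MIN_SEP)
}

# least-squares plane normal of the beads of a base pair (B, S, P of both
# residues plus the M bead)
pair_plane_normal <- function(coords, top, i, j) {
  idx <- c(bead_P(i), bead_S(i), bead_B(i), bead_P(j), bead_S(j), bead_B(j))
  w <- which(top$m_beads$i == min(i, j) & top$m_beads$j == max(i, j))
  if (length(w)) idx <- c(idx, top$m_beads$bead[w])
  pts <- coords[idx, , drop = FALSE]
  cc <- sweep(pts, 2, colMeans(pts))
  svd(cc)$v[, 3]
}

#' Coaxial stacking test between two helices
#'
#' The junction-facing (closing) base pairs of the two helices must satisfy:
#' (i) the cosine of the angle between their base-pair-plane normals (least
#' squares fit of all beads of the two paired nucleotides) is >= 0.7;
#' (ii) their B-bead centers of mass are within 9 Angstrom for directly
#' linked helices or 14 Angstrom when one single-stranded nucleotide
#' intervenes; (iii) both normals make an angle < 60 degrees with the vector
#' joining the two centers of mass.
#'
#' @param coords Bead coordinates.
#' @param top A `toprna_topology`.
#' @param helices Character vector of the two helix names.
#' @param n_linker 0 (directly linked) or 1 (one intervening nt); inferred
#'   from the topology when `NULL`.
#' @return Logical.
#' @export
coaxial_stack <- function(coords, top, helices, n_linker = NULL) {
  h1 <- top$ss$helices[[helices[1]]]
  h2 <- top$ss$helices[[helices[2]]]
  if (is.null(h1) || is.null(h2)) stop("helix not found")
  cp <- closing_pairs(top$ss, helices)
  if (is.null(n_linker)) n_linker <- cp$n_linker
  p1 <- cp$pair1; p2 <- cp$pair2
  n1 <- pair_plane_normal(coords, top, p1[1], p1[2])
  n2 <- pair_plane_normal(coords, top, p2[1], p2[2])
  cosn <- abs(sum(n1 * n2))
  if (cosn < 0.7) return(FALSE)
  com1 <- colMeans(coords[bead_B(p1), , drop = FALSE])
  com2 <- colMeans(coords[bead_B(p2), , drop = FALSE])
  dmax <- if (n_linker == 0) 9 else 14
  v <- com2 - com1
  dv <- vnorm(v)
  if (dv > dmax) return(FALSE)
  a1 <- acos(min(1, abs(sum(n1 * v)) / dv)) * 180 / pi
  a2 <- acos(min(1, abs(sum(n2 * v)) / dv)) * 180 / pi
  a1 < 60 && a2 < 60
}

# find the closing base pairs of two helices that face each other across the
# junction (the pair combination with the smallest residue-number gap along
# the strand), and the number of single-stranded nts between them
closing_pairs <- function(ss, helices) {
  h1 <- ss$helices[[helices[1]]]
  h2 <- ss$helices[[helices[2]]]
  ends1 <- list(h1[1, ], h1[nrow(h1), ])
  ends2 <- list(h2[1, ], h2[nrow(h2), ])
  best <- NULL
  for (e1 in ends1) for (e2 in ends2) {
    gap <- min(abs(outer(e1, e2, "-"))) - 1L
    if (is.null(best) || gap < best$n_linker) {
      best <- list(pair1 = e1, pair2 = e2, n_linker = gap)
    }
  }
  best
}

# The interhelical stacks tracked for tRNA-like structures: D/AC and T/A
# always, V/AC when a V-stem exists.
trna_stack_set <- function(ss) {
  hs <- names(ss$helices)
  out <- list()
  if (all(c("D-stem", "AC-stem") %in% hs)) {
    out <- c(out, list(c("D-stem", "AC-stem")))
  }
  if (all(c("T-stem", "A-stem") %in% hs)) {
    out <- c(out, list(c("T-stem", "A-stem")))
  }
  if (all(c("V-stem", "AC-stem") %in% hs)) {
    out <- c(out, list(c("V-stem", "AC-stem")))
  }
  out
}

#' Per-snapshot indicator series of a contact
#'
#' A contact is described by a list: `list(type = "residue", i, j)`,
#' `list(type = "group", a, b)` (element names) or `list(type = "stack",
#' helices = c(h1, h2))`.
#'
#' @param ens A `toprna_ensemble`.
#' @param contact Contact description (see above).
#' @return Logical vector over snapshots.
#' @export
contact_series <- function(ens, contact) {
  top <- ens$topology
  n <- ens$n_snapshots
  vapply(seq_len(n), function(s) {
    co <- ens$coords[s, , ]
    switch(contact$type,
      residue = residue_contact(co, contact$i, contact$j),
      group = group_contact(co, top, contact$a, contact$b),
      stack = coaxial_stack(co, top, contact$helices),
      stop("unknown contact type"))
  }, logical(1))
}

#' Topological contact free energy
#'
#' Converts the occurrence probability `P` of a contact (or the joint
#' occurrence of a set of contacts) into the log-odds free energy
#' `dG_topo = -ln(P / (1 - P))` in units of k_B T at the analysis
#' temperature.  With `P = 0` or `P = 1` in a finite ensemble the free energy
#' is unbounded; the one-sided bound `|dG| >= ln(n_snapshots)` is reported
#' and flagged instead.
#'
#' @param ens A `toprna_ensemble`.
#' @param contacts One contact description or a list of them (joint
#'   occurrence).
#' @param series Optional precomputed logical matrix (snapshots x contacts).
#' @return A `toprna_contact_stats` list: `p`, `dg` (k_B T), `dg_kcal`
#'   (kcal/mol at the analysis temperature), `n`, `bounded` flag.
#' @export
contact_free_energy <- function(ens, contacts, series = NULL) {
  if (is.null(series)) {
    if (!is.null(contacts$type)) contacts <- list(contacts)
    series <- vapply(contacts, function(ct) contact_series(ens, ct),
                     logical(ens$n_snapshots))
  }
  series <- as.matrix(series)
  joint <- rowSums(series) == ncol(series)
  n <- length(joint)
  p <- mean(joint)
  kBT_kcal <- ens$topology$params$kB * ens$protocol$temperatures[1]
  if (p %in% c(0, 1)) {
    dg <- if (p == 0) log(n) else -log(n)
    return(structure(list(p = p, dg = dg, dg_kcal = dg * kBT_kcal, n = n,
                          bounded = FALSE), class = "toprna_contact_stats"))
  }
  dg <- -log(p / (1 - p))
  structure(list(p = p, dg = dg, dg_kcal = dg * kBT_kcal, n = n,
                 bounded = TRUE), class = "toprna_contact_stats")
}

#' Cooperativity of a set of contacts
#'
#' `C = P(c1, ..., cn) / prod(P(ci))`: the factor by which the contacts
#' co-occur more (C > 1) or less (C < 1) often than if they were independent.
#'
#' @param ens A `toprna_ensemble`.
#' @param contacts List of contact descriptions.
#' @param series Optional precomputed logical matrix (snapshots x contacts).
#' @return A `toprna_coop` list: `C`, `p_joint`, `p_marginal`, `n_contacts`,
#'   `n_joint_observed`.
#' @export
cooperativity <- function(ens, contacts = NULL, series = NULL) {
  if (is.null(series)) {
    series <- vapply(contacts, function(ct) contact_series(ens, ct),
                     logical(ens$n_snapshots))
  }
  series <- as.matrix(series)
  pm <- colMeans(series)
  if (any(pm == 0)) {
    return(structure(list(C = NA_real_, p_joint = 0, p_marginal = pm,
                          n_contacts = ncol(series), n_joint_observed = 0L,
                          note = "zero marginal probability"),
                     class = "toprna_coop"))
  }
  joint <- rowSums(series) == ncol(series)
  structure(list(C = mean(joint) / prod(pm), p_joint = mean(joint),
                 p_marginal = pm, n_contacts = ncol(series),
                 n_joint_observed = sum(joint)), class = "toprna_coop")
}

#' Mean cooperativity curves over contact combinations
#'
#' Enumerates all size-`n` combinations drawn from a pool of loop-loop and
#' stacking contacts, computes the cooperativity of each, and averages
#' separately over all-native combinations and combinations containing at
#' least one non-native contact.  Combinations jointly observed 10 times or
#' fewer are excluded from the means, as are combinations with a
#' zero-probability marginal.
#'
#' @param ens A `toprna_ensemble`.
#' @param n Combination sizes (vector).
#' @param contacts Pool of contact descriptions.
#' @param native Logical vector marking the native members of the pool.
#' @param min_observed Minimum joint occurrence count for inclusion.
#' @return Data frame: `n`, `class` (native / non-native), `mean_C`,
#'   `n_combos`.
#' @export
mean_cooperativity <- function(ens, n, contacts, native,
                               min_observed = 10L) {
  stopifnot(length(native) == length(contacts))
  series <- vapply(contacts, function(ct) contact_series(ens, ct),
                   logical(ens$n_snapshots))
  out <- list()
  for (sz in n) {
    if (sz > length(contacts)) next
    combos <- utils::combn(length(contacts), sz)
    Cs <- numeric(0); nat <- logical(0)
    for (c_idx in seq_len(ncol(combos))) {
      sel <- combos[, c_idx]
      cp <- cooperativity(ens, series = series[, sel, drop = FALSE])
      if (is.na(cp$C) || cp$n_joint_observed <= min_observed) next
      Cs <- c(Cs, cp$C)
      nat <- c(nat, all(native[sel]))
    }
    for (cls in c(TRUE, FALSE)) {
      if (any(nat == cls)) {
        out[[length(out) + 1]] <- data.frame(
          n = sz, class = if (cls) "native" else "non-native",
          mean_C = mean(Cs[nat == cls]), n_combos = sum(nat == cls))
      }
    }
  }
  do.call(rbind, out)
}

#' Restraint-induced stabilization of a contact set
#'
#' `ddG_coop({TC}, {TI}) = dG_topo({TC})` in a simulation restrained by the
#' tertiary interactions `{TI}` minus `dG_topo({TC})` unrestrained; negative
#' values mean the restraints stabilize the target contacts.  Loop pairs with
#' an active restraint placed between them are refused, since their contact
#' statistics are dictated by the restraint itself.
#'
#' @param ens_unrestrained,ens_restrained `toprna_ensemble`s sharing element
#'   definitions; the restrained one must carry its restraints.
#' @param contacts Target contact set `{TC}` (one description or a list).
#' @return A `toprna_coupled` list: `ddg` (k_B T), the two `dg` values, and
#'   flags when either free energy is only a bound.
#' @export
coupled_stability <- function(ens_unrestrained, ens_restrained, contacts) {
  if (!is.null(contacts$type)) contacts <- list(contacts)
  restr <- ens_restrained$topology$restraints
  if (!is.null(restr) && nrow(restr) > 0) {
    els <- ens_restrained$topology$ss$elements
    for (ct in contacts) {
      if (ct$type != "group") next
      ra <- if (is.character(ct$a)) els[[ct$a]] else ct$a
      rb <- if (is.character(ct$b)) els[[ct$b]] else ct$b
      bridged <- (restr$res_i %in% ra & restr$res_j %in% rb) |
                 (restr$res_i %in% rb & restr$res_j %in% ra)
      if (any(bridged)) {
        stop("refusing ddG_coop for loops with an active restraint ",
             "between them (", ct$a, " - ", ct$b, ")")
      }
    }
  }
  g_u <- contact_free_energy(ens_unrestrained, contacts)
  g_r <- contact_free_energy(ens_restrained, contacts)
  structure(list(ddg = g_r$dg - g_u$dg, dg_restrained = g_r$dg,
                 dg_unrestrained = g_u$dg,
                 bounded = g_u$bounded && g_r$bounded),
            class = "toprna_coupled")
}
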