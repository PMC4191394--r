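# Reference coordinate builders: ideal sub-helices assembled into full
# molecules, with single strands interpolated and regularized by restrained
# minimization.  No external structure files are required.

# Build ideal-helix coordinates for a list of pair tuples (col 1 = strand at
# +phase, col 2 = strand at -phase); consecutive tuples are stacked.
place_helix_tuples <- function(coords, tuples, rot = diag(3),
                               shift = c(0, 0, 0), geom = aform_geometry()) {
  n_bp <- nrow(tuples)
  for (t in seq_len(n_bp)) {
    for (col in 1:2) {
      res <- tuples[t, col]
      for (kind in c("P", "S", "B")) {
        b <- switch(kind, P = bead_P(res), S = bead_S(res), B = bead_B(res))
        coords[b, ] <- rot %*% aform_bead(t, col, kind, geom) + shift
      }
    }
  }
  coords
}

# deterministic pseudo-jitter (no RNG state involved)
.det_jitter <- function(r, scale = 0.4) {
  scale * c(sin(1.7 * r), cos(2.3 * r), sin(3.1 * r + 1))
}

# interpolate all residues whose beads are still NA between their nearest
# placed sequence neighbors; M beads go to pair-B midpoints
fill_unplaced <- function(coords, top) {
  n <- top$ss$n
  placed <- !is.na(coords[bead_S(seq_len(n)), 1])
  anchors <- which(placed)
  for (r in which(!placed)) {
    before <- anchors[anchors < r]
    after <- anchors[anchors > r]
    if (length(before) && length(after)) {
      a <- max(before); b <- min(after)
      f <- (r - a) / (b - a)
      base <- coords[bead_S(a), ] + f * (coords[bead_S(b), ] - coords[bead_S(a), ])
    } else if (length(before)) {
      a <- max(before)
      dir <- coords[bead_S(a), ] - coords[bead_P(a), ]
      base <- coords[bead_S(a), ] + (r - a) * 4 * unitv(dir)
    } else {
      b <- min(after)
      dir <- coords[bead_P(b), ] - coords[bead_S(b), ]
      base <- coords[bead_S(b), ] + (b - r) * 4 * unitv(dir)
    }
    base <- base + .det_jitter(r)
    coords[bead_P(r), ] <- base + c(-2, 0.3, -0.3)
    coords[bead_S(r), ] <- base
    coords[bead_B(r), ] <- base + c(3, -0.4, 0.6)
  }
  if (nrow(top$m_beads) > 0) {
    for (q in seq_len(nrow(top$m_beads))) {
      coords[top$m_beads$bead[q], ] <-
        (coords[bead_B(top$m_beads$i[q]), ] +
         coords[bead_B(top$m_beads$j[q]), ]) / 2
    }
  }
  coords
}

# native residue-residue contact table under the 14 A / >= 5 nt rule
native_contact_table <- function(coords, top) {
  n <- top$ss$n
  S <- coords[bead_S(seq_len(n)), , drop = FALSE]
  d2 <- outer(rowSums(S^2), rowSums(S^2), "+") - 2 * S %*% t(S)
  pt <- pair_table(top$ss)
  out <- list()
  for (i in seq_len(n - CONTACT_MIN_SEP)) {
    for (j in (i + CONTACT_MIN_SEP):n) {
      if (d2[i, j] < CONTACT_SS_CUTOFF^2) {
        out[[length(out) + 1]] <- data.frame(
          i = i, j = j, ss_distance = sqrt(max(0, d2[i, j])),
          both_loop = is.na(pt[i]) && is.na(pt[j]))
      }
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(i = integer(), j = integer(), ss_distance = numeric(),
               both_loop = logical())
}

#' Build an idealized L-shaped tRNA reference structure
#'
#' Assembles the cloverleaf's helices into the two coaxially stacked arms of
#' the tRNA "L" (acceptor arm: A-stem stacked with T-stem; anticodon arm:
#' D-stem stacked with AC-stem, and the V-stem appended when present), placed
#' at right angles and joined at the elbow.  Single-stranded residues are
#' interpolated and the whole structure regularized by minimization and a
#' short deterministic low-temperature anneal under flat-bottom restraints
#' for the supplied tertiary pairs, so the reference satisfies the restraint
#' windows of the conserved tertiary interactions and defines the default
#' native contact table.
#'
#' @param ss Cloverleaf-classified `toprna_ss` (default: the wild type).
#' @param tertiary_pairs 2-column residue matrix (default
#'   [trna_conserved_pairs()], filtered to residues present).
#' @param params Force-field constants.
#' @param seed Seed for the anneal (build-to-build P-bead RMSD across seeds
#'   is small).
#' @return A `toprna_reference`: `coords`, `topology`, `provenance`
#'   (`"ideal"`), `native_contacts`, `restraint_check` (per-restraint
#'   satisfaction).
#' @export
build_reference_trna <- function(ss = trna_fixture("wt"),
                                 tertiary_pairs = NULL,
                                 params = toprna_params(), seed = 1) {
  if (!isTRUE(ss$is_cloverleaf)) stop("structure is not cloverleaf-classified")
  top <- build_topology(ss, params)
  H <- ss$helices
  rise <- params$geometry$rise
  coords <- matrix(NA_real_, top$n_beads, 3)

  # acceptor arm: A rows then T rows (strand2 continuous across the pivot)
  arm1 <- rbind(H[["A-stem"]], H[["T-stem"]])
  # anticodon arm: D rows reversed/swapped, then AC rows (strand continuous
  # through the D/AC linker), then the V-stem when present
  d <- H[["D-stem"]]
  arm2 <- rbind(d[rev(seq_len(nrow(d))), c(2, 1)], H[["AC-stem"]])
  if (!is.null(H[["V-stem"]])) {
    # the V-stem branches off rather than stacking; place it separately
    v <- H[["V-stem"]]
  } else v <- NULL

  R1 <- rotation_about(c(0, 1, 0), 90)   # build z-axis -> +x
  L1 <- (nrow(arm1) - 1) * rise
  # elbow (T-loop end, last tuple) lands near the origin; acceptor end at -x
  coords <- place_helix_tuples(coords, arm1, R1, c(6 - L1, 0, 0))
  R2 <- rotation_about(c(1, 0, 0), -90)  # build z-axis -> +y
  coords <- place_helix_tuples(coords, arm2, R2, c(0, 6, 0))
  if (!is.null(v)) {
    L2 <- (nrow(arm2) - 1) * rise
    coords <- place_helix_tuples(coords, v, R2, c(0, 14 + L2, 14))
  }
  coords <- fill_unplaced(coords, top)

  if (is.null(tertiary_pairs)) {
    tp <- trna_conserved_pairs()
    tertiary_pairs <- tp[tp[, 1] <= ss$n & tp[, 2] <= ss$n, , drop = FALSE]
    pt <- pair_table(ss)
    # drop pairs already base-paired in this variant (e.g. 26-44 in VS)
    keep <- vapply(seq_len(nrow(tertiary_pairs)), function(r) {
      i <- tertiary_pairs[r, 1]
      is.na(pt[i]) || pt[i] != tertiary_pairs[r, 2]
    }, logical(1))
    tertiary_pairs <- tertiary_pairs[keep, , drop = FALSE]
  }
  # construction restraints: the tertiary windows narrowed by 15% (so the
  # standard windows are satisfied with margin) and stiffened, plus scaffold
  # restraints holding the coaxial stacking of the two arms at their
  # junction steps (same-strand B-B stacking distances)
  build_restr <- list()
  if (nrow(tertiary_pairs) > 0) {
    tr <- make_restraints("tertiary_pair", tertiary_pairs)
    w <- tr$rmax - tr$rmin
    tr$rmin <- tr$rmin + 0.2 * w
    tr$rmax <- tr$rmax - 0.2 * w
    tr$k <- 20; tr$fcap <- 20
    build_restr <- c(build_restr, list(tr))
  }
  junction_steps <- function(t1, t2) {
    # consecutive tuples across a stacked junction: same-column neighbors
    rbind(c(t1[1], t2[1]), c(t1[2], t2[2]))
  }
  n_arm1 <- nrow(H[["A-stem"]])
  eq <- params$eq
  junction_scaffold <- function(t1, t2) {
    # pin the full stacked-step geometry between two junction pairs:
    # same-column B and S neighbors, the B diagonals, and the pair centers
    mrow <- function(tt) which(top$m_beads$i == min(tt) &
                               top$m_beads$j == max(tt))
    data.frame(
      bi = c(bead_B(t1[1]), bead_B(t1[2]), bead_S(t1[1]), bead_S(t1[2]),
             bead_B(t1[1]), bead_B(t1[2]),
             top$m_beads$bead[mrow(t1)]),
      bj = c(bead_B(t2[1]), bead_B(t2[2]), bead_S(t2[1]), bead_S(t2[2]),
             bead_B(t2[2]), bead_B(t2[1]),
             top$m_beads$bead[mrow(t2)]),
      r0 = c(eq$r_BBs, eq$r_BBs, eq$r_SSs, eq$r_SSs, eq$r_Bd1, eq$r_Bd2,
             eq$r_MM1))
  }
  scj <- rbind(junction_scaffold(arm1[n_arm1, ], arm1[n_arm1 + 1, ]),
               junction_scaffold(arm2[nrow(H[["D-stem"]]), ],
                                 arm2[nrow(H[["D-stem"]]) + 1, ]))
  sc <- data.frame(bi = scj$bi, bj = scj$bj,
                   rmin = scj$r0 - 0.5, rmax = scj$r0 + 0.5,
                   k = 20, fcap = 20, res_i = NA_integer_,
                   res_j = NA_integer_, kind = "scaffold")
  class(sc) <- c("toprna_restraints", "data.frame")
  build_restr <- c(build_restr, list(sc))
  top_r <- do.call(attach_restraints, c(list(top), build_restr))

  # staged deterministic minimization: first with sterics off (chains may
  # pass through one another, so interpolated loops untangle and settle into
  # their restraint windows), then with sterics ramped back on
  ffr <- ff_list(top_r)
  ff_soft <- ffr
  ff_soft$eps <- 0; ff_soft$eps_stack <- 0
  coords <- cpp_minimize(coords, ff_soft, 4000, 0.3)
  ff_half <- ffr
  ff_half$radius <- 0.6 * ffr$radius
  coords <- cpp_minimize(coords, ff_half, 2000, 0.2)
  coords <- cpp_minimize(coords, ffr, 4000, 0.2)

  check <- NULL
  if (nrow(tertiary_pairs) > 0) {
    rr <- make_restraints("tertiary_pair", tertiary_pairs)
    dd <- sqrt(rowSums((coords[rr$bi, , drop = FALSE] -
                        coords[rr$bj, , drop = FALSE])^2))
    check <- data.frame(res_i = rr$res_i, res_j = rr$res_j, kind = rr$kind,
                        distance = dd, rmin = rr$rmin, rmax = rr$rmax,
                        satisfied = dd >= rr$rmin - 1e-6 &
                                    dd <= rr$rmax + 1e-6)
    if (!all(check$satisfied)) {
      bad <- check[!check$satisfied, ]
      warning("unsatisfied restraint window(s): ",
              paste(sprintf("%d-%d %s %.1fA [%.1f, %.1f]", bad$res_i,
                            bad$res_j, bad$kind, bad$distance, bad$rmin,
                            bad$rmax), collapse = "; "))
    }
  }
  structure(list(coords = coords, topology = top, provenance = "ideal",
                 native_contacts = native_contact_table(coords, top),
                 restraint_check = check),
            class = "toprna_reference")
}

#' Generic starting coordinates for any topology
#'
#' Lays helices out as ideal A-form sub-helices spaced along the x-axis,
#' interpolates single-stranded residues, and relaxes briefly.  Used as the
#' default starting point for non-cloverleaf structures.
#'
#' @param top A `toprna_topology`.
#' @return Coordinate matrix (n_beads x 3).
#' @export
build_start_coords <- function(top) {
  ss <- top$ss
  coords <- matrix(NA_real_, top$n_beads, 3)
  offset <- 0
  rise <- top$params$geometry$rise
  for (h in ss$helices) {
    R <- rotation_about(c(0, 1, 0), 90)
    coords <- place_helix_tuples(coords, h, R, c(offset, 0, 0))
    offset <- offset + (nrow(h) - 1) * rise + 25
  }
  if (length(ss$helices) == 0) {
    # fully single-stranded: zig-zag line
    for (r in seq_len(ss$n)) {
      base <- c(5.5 * r, 2 * (r %% 2), 0)
      coords[bead_P(r), ] <- base + c(-2, 0.3, -0.3)
      coords[bead_S(r), ] <- base
      coords[bead_B(r), ] <- base + c(3, -0.4, 0.6)
    }
  }
  coords <- fill_unplaced(coords, top)
  cpp_minimize(coords, ff_list(top), 1500, 0.3)
}

#' Coarse-grain an all-atom RNA PDB file
#'
#' P beads take the phosphate P atom position, S beads the sugar-ring
#' heavy-atom centroid, B beads the base heavy-atom centroid; M beads are
#' placed at the paired-B midpoints of the supplied secondary structure.
#' Modified residues are handled implicitly (only atom names are used);
#' residues with missing atoms are flagged and use the centroid of the
#' available atoms.  Requires the `bio3d` package for PDB parsing.
#'
#' @param path PDB file (single RNA chain, standard atom names).
#' @param ss The `toprna_ss` giving the pairing (residue count must match).
#' @param params Force-field constants.
#' @return A `toprna_reference` with provenance `"pdb-derived"`.
#' @export
coarse_grain_pdb <- function(path, ss, params = toprna_params()) {
  if (!requireNamespace("bio3d", quietly = TRUE)) {
    stop("coarse_grain_pdb requires the bio3d package")
  }
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom
  at <- at[at$type == "ATOM", ]
  hyd <- grepl("^[0-9]*H", at$elety) |
    (!is.na(at$elesy) & at$elesy == "H")
  at <- at[!hyd, ]
  resids <- unique(at[, c("chain", "resno")])
  resids <- resids[order(resids$chain, resids$resno), ]
  if (nrow(resids) != ss$n) {
    stop("PDB has ", nrow(resids), " residues but structure has ", ss$n)
  }
  top <- build_topology(ss, params)
  coords <- matrix(NA_real_, top$n_beads, 3)
  sugar_ring <- c("C1'", "C2'", "C3'", "C4'", "O4'")
  backbone <- c("P", "OP1", "OP2", "O1P", "O2P", "O5'", "C5'", "O3'",
                "O2'", sugar_ring)
  flagged <- integer()
  for (r in seq_len(ss$n)) {
    ra <- at[at$chain == resids$chain[r] & at$resno == resids$resno[r], ]
    xyz <- function(rows) {
      if (nrow(rows) == 0) return(NULL)
      colMeans(as.matrix(rows[, c("x", "y", "z")]))
    }
    p <- xyz(ra[ra$elety == "P", ])
    s <- xyz(ra[ra$elety %in% sugar_ring, ])
    b <- xyz(ra[!ra$elety %in% backbone, ])
    if (is.null(p) || nrow(ra[ra$elety %in% sugar_ring, ]) < 5 ||
        is.null(b)) flagged <- c(flagged, r)
    if (is.null(p)) p <- if (!is.null(s)) s + c(-2, 0, 0) else c(0, 0, 0)
    if (is.null(s)) s <- xyz(ra)
    if (is.null(b)) b <- s + c(3, 0, 0)
    coords[bead_P(r), ] <- p
    coords[bead_S(r), ] <- s
    coords[bead_B(r), ] <- b
  }
  if (nrow(top$m_beads) > 0) {
    for (q in seq_len(nrow(top$m_beads))) {
      coords[top$m_beads$bead[q], ] <-
        (coords[bead_B(top$m_beads$i[q]), ] +
         coords[bead_B(top$m_beads$j[q]), ]) / 2
    }
  }
  structure(list(coords = coords, topology = top,
                 provenance = "pdb-derived",
                 flagged_residues = flagged,
                 native_contacts = native_contact_table(coords, top)),
            class = "toprna_reference")
}
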