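# Bead index conventions: residue i owns beads P=3(i-1)+1, S=3(i-1)+2,
# B=3(i-1)+3; one M bead per base pair is appended after all residue beads,
# in pair order.  Bead count is therefore 3*N + n_pairs.

bead_P <- function(i) 3L * (i - 1L) + 1L
bead_S <- function(i) 3L * (i - 1L) + 2L
bead_B <- function(i) 3L * (i - 1L) + 3L

#' Build the coarse-grained bead topology for a secondary structure
#'
#' Emits beads and every bonded term of the model: stiff harmonic bonds along
#' the backbone (P-S within a residue, S-P to the next residue unless the
#' backbone is cut), S-B attachment bonds, permanent pair bonds (B-B, the two
#' cross-pair S-B support bonds, and the M-bead anchors), harmonic angles
#' (stiff inside helices, soft on single strands), a chirality improper on
#' every sugar center, and A-form backbone dihedrals restricted to
#' contiguously paired regions.  Single-stranded residues and pivot segments
#' carry no dihedral terms and are freely rotatable.
#'
#' All equilibrium values come from the ideal A-form build of
#' [toprna_params()], so an ideal helix has zero bonded energy.
#'
#' @param ss A `toprna_ss`.
#' @param params Force-field constants from [toprna_params()].
#' @return An object of class `toprna_topology`.
#' @export
build_topology <- function(ss, params = toprna_params()) {
  stopifnot(inherits(ss, "toprna_ss"))
  n <- ss$n
  pt <- pair_table(ss)
  np <- nrow(ss$pairs)
  paired <- !is.na(pt)
  eq <- params$eq

  kind <- rep(c("P", "S", "B"), n)
  residue <- rep(seq_len(n), each = 3L)
  if (np > 0) {
    kind <- c(kind, rep("M", np))
    residue <- c(residue, rep(NA_integer_, np))
  }
  beads <- data.frame(
    kind = kind,
    residue = residue,
    radius = unname(params$lj_radius[kind]),
    eps = params$lj_eps,
    mass = unname(params$mass[kind]),
    attract = FALSE,
    stringsAsFactors = FALSE)
  # paired B beads (and the M gap-fillers) carry the stacking attraction
  if (np > 0) {
    beads$attract[bead_B(which(paired))] <- TRUE
    beads$attract[3L * n + seq_len(np)] <- TRUE
  }
  m_beads <- if (np > 0) {
    data.frame(bead = 3L * n + seq_len(np),
               i = ss$pairs[, 1], j = ss$pairs[, 2])
  } else {
    data.frame(bead = integer(), i = integer(), j = integer())
  }

  # i and i+1 are consecutive stacked pairs of the same helix
  stacked_next <- logical(n)
  for (i in seq_len(n - 1L)) {
    stacked_next[i] <- paired[i] && paired[i + 1L] &&
      pt[i + 1L] == pt[i] - 1L && !(i %in% ss$cuts)
  }
  backbone <- setdiff(seq_len(n - 1L), ss$cuts)  # S_i -> P_{i+1} present

  bonds <- list()
  add_bond <- function(i, j, r0, k, type)
    bonds[[length(bonds) + 1L]] <<- data.frame(i = i, j = j, r0 = r0, k = k,
                                               type = type)
  add_bond(bead_P(1:n), bead_S(1:n), eq$r_PS, params$k_bond, "PS")
  if (length(backbone)) {
    add_bond(bead_S(backbone), bead_P(backbone + 1L), eq$r_SP,
             params$k_bond, "SP")
  }
  add_bond(bead_S(1:n), bead_B(1:n), eq$r_SB, params$k_bond, "SB")
  if (np > 0) {
    pi <- ss$pairs[, 1]; pj <- ss$pairs[, 2]
    add_bond(bead_B(pi), bead_B(pj), eq$r_BB, params$k_bond, "BB")
    add_bond(m_beads$bead, bead_B(pi), eq$r_MB, params$k_bond_m, "MB")
    add_bond(m_beads$bead, bead_B(pj), eq$r_MB, params$k_bond_m, "MB")
    add_bond(bead_S(pi), bead_B(pj), eq$r_SBx, params$k_bond_x, "SBx")
    add_bond(bead_S(pj), bead_B(pi), eq$r_SBx, params$k_bond_x, "SBx")
  }
  # intra-helix elastic network between consecutively stacked pairs: keeps
  # contiguously paired regions semirigid A-form bodies without stiff
  # (high-frequency) local terms
  w <- which(stacked_next)
  if (length(w)) {
    ks <- params$k_stack
    add_bond(bead_B(w), bead_B(w + 1L), eq$r_BBs, ks, "BBs")
    add_bond(bead_S(w), bead_S(w + 1L), eq$r_SSs, ks, "SSs")
    add_bond(bead_P(w), bead_P(w + 1L), eq$r_PPs, ks, "PPs")
  }
  if (np > 0) {
    # anchor the backbone of every paired residue to its pair center
    pi <- ss$pairs[, 1]; pj <- ss$pairs[, 2]
    ks2 <- params$k_stack / 2
    add_bond(bead_S(pi), m_beads$bead, eq$r_SM, ks2, "SM")
    add_bond(bead_S(pj), m_beads$bead, eq$r_SM, ks2, "SM")
    add_bond(bead_P(pi), m_beads$bead, eq$r_PM, ks2, "PM")
    add_bond(bead_P(pj), m_beads$bead, eq$r_PM, ks2, "PM")
  }
  for (h in ss$helices) {
    if (nrow(h) < 2) next
    mb <- vapply(seq_len(nrow(h)), function(t) {
      m_beads$bead[m_beads$i == min(h[t, ]) & m_beads$j == max(h[t, ])]
    }, integer(1))
    intact <- vapply(seq_len(nrow(h) - 1L), function(t)
      stacked_next[h[t, 1]] && stacked_next[h[t + 1L, 2]], logical(1))
    t1 <- which(intact)
    if (length(t1)) {
      add_bond(mb[t1], mb[t1 + 1L], eq$r_MM1, params$k_stack, "MM1")
      add_bond(bead_B(h[t1, 1]), bead_B(h[t1 + 1L, 2]), eq$r_Bd1,
               params$k_stack, "Bd1")
      add_bond(bead_B(h[t1, 2]), bead_B(h[t1 + 1L, 1]), eq$r_Bd2,
               params$k_stack, "Bd2")
    }
    t2 <- which(intact[-length(intact)] & intact[-1])
    if (length(t2)) {
      add_bond(mb[t2], mb[t2 + 2L], eq$r_MM2, params$k_stack / 2, "MM2")
    }
  }
  bonds <- do.call(rbind, bonds)

  angles <- list()
  add_angle <- function(i, j, k, th0, kth) {
    if (length(i)) angles[[length(angles) + 1L]] <<-
      data.frame(i = i, j = j, k = k, th0 = th0, kth = kth)
  }
  kang <- function(helical) ifelse(helical, params$k_angle_helix,
                                   params$k_angle_ss)
  add_angle(bead_P(1:n), bead_S(1:n), bead_B(1:n), eq$a_PSB, kang(paired))
  ii <- backbone
  add_angle(bead_P(ii), bead_S(ii), bead_P(ii + 1L), eq$a_PSP,
            kang(stacked_next[ii]))
  add_angle(bead_S(ii), bead_P(ii + 1L), bead_S(ii + 1L), eq$a_SPS,
            kang(stacked_next[ii]))
  if (np > 0) {
    pi <- ss$pairs[, 1]; pj <- ss$pairs[, 2]
    add_angle(bead_S(pi), bead_B(pi), bead_B(pj), eq$a_SBB,
              rep(params$k_angle_helix, np))
    add_angle(bead_S(pj), bead_B(pj), bead_B(pi), eq$a_SBB,
              rep(params$k_angle_helix, np))
  }
  angles <- do.call(rbind, angles)

  # sugar chirality impropers: P_i - S_i - P_{i+1} - B_i on every residue
  # with an intact downstream backbone bond
  impropers <- if (length(backbone)) {
    data.frame(i = bead_P(backbone), j = bead_S(backbone),
               k = bead_P(backbone + 1L), l = bead_B(backbone),
               phi0 = eq$x_PSPB, kimp = params$k_improper)
  } else {
    data.frame(i = integer(), j = integer(), k = integer(), l = integer(),
               phi0 = numeric(), kimp = numeric())
  }

  dihedrals <- list()
  add_dih <- function(i, j, k, l, phi0, kdih) {
    if (length(i)) dihedrals[[length(dihedrals) + 1L]] <<-
      data.frame(i = i, j = j, k = k, l = l, phi0 = phi0, kdih = kdih)
  }
  w1 <- which(stacked_next)
  add_dih(bead_P(w1), bead_S(w1), bead_P(w1 + 1L), bead_S(w1 + 1L),
          eq$d_PSPS, params$k_dihedral)
  w2 <- which(stacked_next[-1] & stacked_next[-n]) + 1L  # i-1 and i stacked
  if (length(w2)) {
    add_dih(bead_S(w2 - 1L), bead_P(w2), bead_S(w2), bead_P(w2 + 1L),
            eq$d_SPSP, params$k_dihedral)
  }
  dihedrals <- if (length(dihedrals)) do.call(rbind, dihedrals) else
    data.frame(i = integer(), j = integer(), k = integer(), l = integer(),
               phi0 = numeric(), kdih = numeric())

  structure(list(
    ss = ss, params = params, n_beads = nrow(beads), beads = beads,
    m_beads = m_beads, bonds = bonds, angles = angles,
    impropers = impropers, dihedrals = dihedrals,
    strand_breaks = ss$cuts, restraints = NULL), class = "toprna_topology")
}

# remove one backbone S->P bond from an already built topology
cut_topology <- function(top, at) {
  stopifnot(inherits(top, "toprna_topology"))
  w <- which(top$bonds$type == "SP" & top$bonds$i == bead_S(at) &
             top$bonds$j == bead_P(at + 1L))
  if (!length(w)) stop("no backbone bond after residue ", at, " to cut")
  top$bonds <- top$bonds[-w, ]
  top$strand_breaks <- sort(unique(c(top$strand_breaks, as.integer(at))))
  top$ss$cuts <- top$strand_breaks
  top
}

#' @export
print.toprna_topology <- function(x, ...) {
  cat(sprintf(paste0("<toprna_topology> %d beads (%d nt + %d M), ",
                     "%d bonds, %d angles, %d impropers, %d dihedrals\n"),
              x$n_beads, x$ss$n, nrow(x$m_beads), nrow(x$bonds),
              nrow(x$angles), nrow(x$impropers), nrow(x$dihedrals)))
  if (length(x$strand_breaks)) {
    cat("  strand breaks after residue(s):",
        paste(x$strand_breaks, collapse = ", "), "\n")
  }
  if (!is.null(x$restraints)) {
    cat(sprintf("  %d distance restraints\n", nrow(x$restraints)))
  }
  invisible(x)
}

#' Construct flat-bottom distance restraints
#'
#' Flat-bottom (NOE-style) restraints have zero energy and force inside
#' `[r_min, r_max]`, harmonic walls with force constant `k` just outside, and
#' a force magnitude capped at `fcap` (the energy grows linearly far outside
#' the window).
#'
#' * `tertiary_pair`: one B-B restraint (5.5-7.5 Angstrom) plus one S-S
#'   restraint (11-14 Angstrom) per residue pair, k = 2 kcal/mol/A^2, cap 2
#'   kcal/mol/A.
#' * `base_triple`: B-B and S-S restraints from the tertiary nucleotide to
#'   each of two helical nucleotides, windowed +/- 1 Angstrom (B-B) and
#'   +/- 1.5 Angstrom (S-S) around supplied reference distances.
#' * `g26_pair`: the restraints of `tertiary_pair` plus force-field
#'   modifications applied on attachment (quarter-height backbone dihedrals
#'   for the two residues, stacking attraction on their B beads) consistent
#'   with the pair extending a helix.
#'
#' @param kind `"tertiary_pair"`, `"base_triple"` or `"g26_pair"`.
#' @param residues For pairs, `c(i, j)` or a 2-column matrix of pairs; for a
#'   triple, `c(t, h1, h2)` (tertiary residue first).
#' @param reference_distances For triples, `list(BB = c(d1, d2),
#'   SS = c(d1, d2))`: measured B-B and S-S distances from t to h1 and h2.
#' @return A `toprna_restraints` data frame (bead indices, window, constants).
#' @export
make_restraints <- function(kind = c("tertiary_pair", "base_triple",
                                     "g26_pair"),
                            residues, reference_distances = NULL) {
  kind <- match.arg(kind)
  k <- 2.0; fcap <- 2.0
  row <- function(bi, bj, rmin, rmax, ri, rj, what)
    data.frame(bi = bi, bj = bj, rmin = rmin, rmax = rmax, k = k, fcap = fcap,
               res_i = ri, res_j = rj, kind = what)
  if (kind %in% c("tertiary_pair", "g26_pair")) {
    m <- if (is.matrix(residues)) residues else matrix(residues, ncol = 2,
                                                       byrow = TRUE)
    out <- do.call(rbind, lapply(seq_len(nrow(m)), function(r) {
      i <- m[r, 1]; j <- m[r, 2]
      rbind(row(bead_B(i), bead_B(j), 5.5, 7.5, i, j, "BB"),
            row(bead_S(i), bead_S(j), 11, 14, i, j, "SS"))
    }))
    if (kind == "g26_pair") attr(out, "mods") <- list(residues = c(m))
  } else {
    if (is.null(reference_distances) ||
        is.null(reference_distances$BB) || is.null(reference_distances$SS)) {
      stop("base triples need reference B-B and S-S distances")
    }
    t <- residues[1]; h <- residues[2:3]
    dBB <- reference_distances$BB; dSS <- reference_distances$SS
    out <- rbind(
      row(bead_B(t), bead_B(h[1]), dBB[1] - 1, dBB[1] + 1, t, h[1], "BB"),
      row(bead_B(t), bead_B(h[2]), dBB[2] - 1, dBB[2] + 1, t, h[2], "BB"),
      row(bead_S(t), bead_S(h[1]), dSS[1] - 1.5, dSS[1] + 1.5, t, h[1], "SS"),
      row(bead_S(t), bead_S(h[2]), dSS[2] - 1.5, dSS[2] + 1.5, t, h[2], "SS"))
  }
  stopifnot(all(out$rmin < out$rmax))
  class(out) <- c("toprna_restraints", "data.frame")
  out
}

#' Attach restraints to a topology
#'
#' Concatenates restraint tables onto the topology; `g26_pair` tables also
#' trigger their force-field modifications (quarter-height dihedrals on the
#' two residues and the stacking attraction on their B beads).
#'
#' @param top A `toprna_topology`.
#' @param ... One or more `toprna_restraints` tables.
#' @return The topology with `$restraints` populated.
#' @export
attach_restraints <- function(top, ...) {
  stopifnot(inherits(top, "toprna_topology"))
  specs <- list(...)
  for (sp in specs) {
    mods <- attr(sp, "mods")
    if (!is.null(mods)) {
      for (r in mods$residues) {
        top$beads$attract[bead_B(r)] <- TRUE
        touch <- apply(top$dihedrals[, c("i", "j", "k", "l")], 1, function(q)
          any(q %in% c(bead_P(r), bead_S(r), bead_B(r))))
        top$dihedrals$kdih[touch] <- top$dihedrals$kdih[touch] / 4
      }
    }
    sp <- as.data.frame(sp)
    top$restraints <- if (is.null(top$restraints)) sp else
      rbind(top$restraints, sp)
  }
  if (!is.null(top$restraints) && any(top$restraints$bi > top$n_beads |
                                      top$restraints$bj > top$n_beads)) {
    stop("restraint references a bead outside the topology")
  }
  top
}

#' The six conserved tRNA tertiary pairs
#'
#' Residue pairs (1-based cloverleaf numbering) of the six named conserved
#' tertiary interactions: U8-A14, G15-C48, G18-U55, G19-C56, U54-A58 and
#' G26-A44.  Semiconserved base triples are left to the user (see
#' [make_restraints()]).
#'
#' @return Two-column integer matrix of residue pairs.
#' @export
trna_conserved_pairs <- function() {
  m <- rbind(c(8L, 14L), c(15L, 48L), c(18L, 55L), c(19L, 56L),
             c(54L, 58L), c(26L, 44L))
  colnames(m) <- c("i", "j")
  m
}
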