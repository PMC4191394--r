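#' Idealized A-form helix geometry
#'
#' The coarse-grained model places one bead at the centroid of each base (B),
#' sugar (S) and phosphate (P) moiety, plus a fourth bead (M) midway between
#' the B beads of a base pair that fills the steric gap at the pair center.
#' Helical equilibrium geometry is generated from an idealized A-form fiber
#' parameterization: 32.7 degrees of twist and 2.81 Angstrom of rise per base
#' pair, with each bead type at a fixed cylindrical radius, phase offset from
#' the pair dyad, and axial offset.  The two strands of a duplex are related
#' by the pair dyad (a proper 180 degree rotation), so bonded equilibrium
#' values measured along either strand are identical.
#'
#' @return A list of the cylindrical placement constants: `twist` (deg/bp),
#'   `rise` (Angstrom/bp) and per-bead `radius`, `phase` (deg) and `dz`
#'   (Angstrom) for the S, B and P beads of the reference strand.
#' @export
aform_geometry <- function() {
  list(
    twist = 32.7,
    rise  = 2.81,
    S = list(radius = 9.2, phase = 42, dz = 0),
    B = list(radius = 3.4, phase = 55, dz = 0),
    # P sits radially outside the S-S line so backbone angles stay well away
    # from collinearity (a_SPS ~ 121 deg, a_PSP ~ 150 deg)
    P = list(radius = 10.5, phase = 25, dz = -1.405)
  )
}

# position of one bead on an ideal helix whose axis is global z
# pair_index: 1-based index along the helix; strand: 1 or 2
aform_bead <- function(pair_index, strand, kind, geom = aform_geometry()) {
  stopifnot(kind %in% c("S", "B", "P", "M"))
  t <- pair_index - 1
  theta0 <- t * geom$twist
  z0 <- t * geom$rise
  if (kind == "M") {
    b1 <- aform_bead(pair_index, 1, "B", geom)
    b2 <- aform_bead(pair_index, 2, "B", geom)
    return((b1 + b2) / 2)
  }
  g <- geom[[kind]]
  sgn <- if (strand == 1) 1 else -1
  ang <- (theta0 + sgn * g$phase) * pi / 180
  c(g$radius * cos(ang), g$radius * sin(ang), z0 + sgn * g$dz)
}

#' Build an ideal A-form duplex
#'
#' Constructs bead coordinates for a fully paired duplex of `n_bp` base pairs
#' in the standard orientation (helix axis along +z, pair 1 at the origin end,
#' pair index increasing with z).  Residues 1..n_bp form strand 1 (5'->3' with
#' increasing pair index) and residues n_bp+1..2*n_bp form the antiparallel
#' strand 2, so residue i pairs with residue 2*n_bp+1-i.
#'
#' Bead ordering matches [build_topology()]: residues in order, three beads
#' (P, S, B) per residue, followed by one M bead per pair in pair order.
#'
#' @param n_bp Number of base pairs (>= 2).
#' @param geom Geometry constants, see [aform_geometry()].
#' @return Numeric matrix `(3*2*n_bp + n_bp) x 3` of coordinates in Angstrom.
#' @export
build_ideal_helix <- function(n_bp, geom = aform_geometry()) {
  if (n_bp < 2) stop("an ideal helix needs at least 2 base pairs")
  n_res <- 2L * n_bp
  coords <- matrix(NA_real_, 3L * n_res + n_bp, 3L)
  for (i in seq_len(n_res)) {
    if (i <= n_bp) {
      t <- i; s <- 1
    } else {
      t <- n_res + 1L - i; s <- 2
    }
    coords[3L * (i - 1L) + 1L, ] <- aform_bead(t, s, "P", geom)
    coords[3L * (i - 1L) + 2L, ] <- aform_bead(t, s, "S", geom)
    coords[3L * (i - 1L) + 3L, ] <- aform_bead(t, s, "B", geom)
  }
  for (t in seq_len(n_bp)) {
    coords[3L * n_res + t, ] <- aform_bead(t, 1, "M", geom)
  }
  coords
}

.params_cache <- new.env(parent = emptyenv())

#' Coarse-grained force-field parameter table
#'
#' Equilibrium bond lengths, angles, impropers and helical backbone dihedrals
#' are measured once from an ideal A-form duplex built by
#' [build_ideal_helix()], so the zero of the bonded potential is the ideal
#' helix by construction.  Force constants are fixed package constants: stiff
#' bonds everywhere, stiff angles and backbone dihedrals inside contiguously
#' paired regions (tuned once so a free helix stays within ~1 Angstrom RMSD of
#' ideal at 300 K), soft angles on single strands (which carry no dihedrals at
#' all and are therefore freely rotatable), and a chirality improper on every
#' sugar center.
#'
#' Nonbonded terms use a 6-12 Lennard-Jones potential with epsilon = 0.01
#' kcal/mol for every bead (sterics only); the B beads of base-paired residues
#' additionally attract one another with `eps_stack` (default 0.5 kcal/mol),
#' which maintains intra-helix stacking and only marginally favors
#' interhelical stacking across junctions.  Electrostatics are absent.
#'
#' @param eps_stack Lennard-Jones epsilon (kcal/mol) between paired B beads.
#' @return Named list of force-field constants and measured equilibria.
#' @export
toprna_params <- function(eps_stack = 0.5) {
  key <- sprintf("p_%g", eps_stack)
  if (!is.null(.params_cache[[key]])) return(.params_cache[[key]])
  geom <- aform_geometry()
  b <- function(t, s, k) aform_bead(t, s, k, geom)

  eq <- list(
    # backbone bonds (within/between residues, 5'->3': P_i-S_i, S_i-P_{i+1})
    r_PS = bead_distance(b(2, 1, "P"), b(2, 1, "S")),
    r_SP = bead_distance(b(1, 1, "S"), b(2, 1, "P")),
    r_SB = bead_distance(b(1, 1, "S"), b(1, 1, "B")),
    # pair bonds
    r_BB = bead_distance(b(1, 1, "B"), b(1, 2, "B")),
    r_MB = bead_distance(b(1, 1, "M"), b(1, 1, "B")),
    r_SBx = bead_distance(b(1, 1, "S"), b(1, 2, "B")),
    # angles
    a_PSB = bead_angle(b(2, 1, "P"), b(2, 1, "S"), b(2, 1, "B")),
    a_PSP = bead_angle(b(2, 1, "P"), b(2, 1, "S"), b(3, 1, "P")),
    a_SPS = bead_angle(b(1, 1, "S"), b(2, 1, "P"), b(2, 1, "S")),
    a_SBB = bead_angle(b(1, 1, "S"), b(1, 1, "B"), b(1, 2, "B")),
    # sugar chirality improper P_i - S_i - P_{i+1} - B_i
    x_PSPB = bead_dihedral(b(2, 1, "P"), b(2, 1, "S"), b(3, 1, "P"), b(2, 1, "B")),
    # helical backbone dihedrals
    d_PSPS = bead_dihedral(b(2, 1, "P"), b(2, 1, "S"), b(3, 1, "P"), b(3, 1, "S")),
    d_SPSP = bead_dihedral(b(1, 1, "S"), b(2, 1, "P"), b(2, 1, "S"), b(3, 1, "P")),
    # intra-helix elastic network between stacked pairs: same-strand
    # stacking, base-pair center (M) rise and straightness, cross diagonals
    r_BBs = bead_distance(b(1, 1, "B"), b(2, 1, "B")),
    r_SSs = bead_distance(b(1, 1, "S"), b(2, 1, "S")),
    r_MM1 = bead_distance(b(1, 1, "M"), b(2, 1, "M")),
    r_MM2 = bead_distance(b(1, 1, "M"), b(3, 1, "M")),
    r_Bd1 = bead_distance(b(1, 1, "B"), b(2, 2, "B")),
    r_Bd2 = bead_distance(b(1, 2, "B"), b(2, 1, "B")),
    # backbone-to-core anchors within paired regions
    r_PPs = bead_distance(b(1, 1, "P"), b(2, 1, "P")),
    r_SM = bead_distance(b(1, 1, "S"), b(1, 1, "M")),
    r_PM = bead_distance(b(1, 1, "P"), b(1, 1, "M"))
  )

  p <- list(
    geometry = geom,
    eq = eq,
    # force constants (E = k * deviation^2 for bonds/angles/impropers);
    # kept soft enough that the stiffest normal mode is stable at the 20 fs
    # timestep, with helix rigidity supplied collectively by the intra-helix
    # elastic network rather than by stiff local terms
    k_bond = 12,      # kcal/mol/A^2, backbone + pair bonds
    k_bond_m = 12,    # M-bead anchoring bonds
    k_bond_x = 10,    # cross-pair S-B support bonds
    k_stack = 80,     # intra-helix network springs
    k_angle_helix = 12,  # kcal/mol/rad^2
    k_angle_ss = 3,
    k_improper = 6,      # kcal/mol/rad^2
    k_dihedral = 4,      # kcal/mol, E = k*(1 - cos(phi - phi0))
    # nonbonded
    # effective radii ~ the minimum dimension of each moiety (base
    # thickness/2 for B; P fixed at 2.7 A); stacked neighbors in an ideal
    # helix then sit at or beyond their LJ minima
    lj_radius = c(P = 2.7, S = 2.9, B = 1.7, M = 1.5),  # Angstrom
    lj_eps = 0.01,       # kcal/mol, all beads
    eps_stack = eps_stack,  # paired-B attraction
    cutoff = 9.0,        # Angstrom, nonbonded cutoff
    # masses: moiety group masses scaled by 3 (equilibrium observables are
    # mass independent; heavier beads keep the stiffest normal modes well
    # inside the stability region of the 20 fs timestep)
    mass = 3 * c(P = 95, S = 132, B = 112, M = 100),
    kB = 0.0019872041    # kcal/mol/K
  )
  .params_cache[[key]] <- p
  p
}
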