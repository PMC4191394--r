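#' Fit a helix reference frame
#'
#' The frame's z-axis is the least-squares line through the base-pair centers
#' (midpoints of the paired B beads), oriented 5'->3' along the helix's first
#' strand (increasing pair order); the x-axis is the component, perpendicular
#' to z, of the vector from the helix origin to the S-bead midpoint of the
#' helix's first base pair; y completes a right-handed triad.  The convention
#' is deterministic: near-identical coordinates give near-identical frames
#' with no sign flips.
#'
#' @param coords Bead coordinates (n_beads x 3).
#' @param top A `toprna_topology`.
#' @param helix Helix name (e.g. `"A-stem"`) or a 2-column pair matrix.
#' @return A `toprna_frame`: list with `origin` (length-3) and `axes`
#'   (3 x 3 orthonormal, columns x, y, z).
#' @export
fit_helix_frame <- function(coords, top, helix) {
  h <- if (is.character(helix)) top$ss$helices[[helix]] else helix
  if (is.null(h) || nrow(h) < 2) stop("helix needs at least 2 base pairs")
  centers <- (coords[bead_B(h[, 1]), , drop = FALSE] +
              coords[bead_B(h[, 2]), , drop = FALSE]) / 2
  origin <- colMeans(centers)
  span <- centers[nrow(centers), ] - centers[1, ]
  if (vnorm(span) < 1e-8) stop("degenerate helix coordinates")
  # helical axis as the mean rotation axis of successive base-pair steps:
  # superpose the bead set of pair t onto pair t+1 and take the rotation
  # axis (exact for an ideal helix; averaging damps thermal noise)
  step_axis <- function(t) {
    sel <- function(tt) rbind(coords[bead_P(h[tt, 1]), ],
                              coords[bead_S(h[tt, 1]), ],
                              coords[bead_B(h[tt, 1]), ],
                              coords[bead_P(h[tt, 2]), ],
                              coords[bead_S(h[tt, 2]), ],
                              coords[bead_B(h[tt, 2]), ])
    a <- sel(t); b <- sel(t + 1)
    ac <- sweep(a, 2, colMeans(a)); bc <- sweep(b, 2, colMeans(b))
    H <- crossprod(ac, bc)
    sv <- svd(H)
    d <- sign(det(sv$v %*% t(sv$u)))
    R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
    ax <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
    if (vnorm(ax) < 1e-10) return(NULL)  # no twist: direction undefined
    ax <- unitv(ax)
    if (sum(ax * span) < 0) ax <- -ax
    ax
  }
  axes <- Filter(Negate(is.null),
                 lapply(seq_len(nrow(h) - 1L), step_axis))
  z <- if (length(axes)) unitv(colMeans(do.call(rbind, axes)))
       else unitv(span)
  sref <- (coords[bead_S(h[1, 1]), ] + coords[bead_S(h[1, 2]), ]) / 2
  xr <- sref - origin
  xr <- xr - sum(xr * z) * z
  if (vnorm(xr) < 1e-8) stop("degenerate reference pair geometry")
  x <- unitv(xr)
  y <- pracma_cross(z, x)
  structure(list(origin = origin, axes = cbind(x = x, y = y, z = z)),
            class = "toprna_frame")
}

#' Interhelical Euler angles
#'
#' Decomposes the rotation carrying the H1 frame onto the H2 frame as
#' `Rz(alpha) %*% Ry(beta) %*% Rz(gamma)` (z-y-z convention) expressed in the
#' H1 frame: `alpha` and `gamma` are twists about the two helix axes and
#' `beta` is the interhelical bend.  Ranges: alpha and gamma in
#' `[0, 360)` degrees, beta in `[0, 180]`.  At the gimbal degeneracies
#' (beta ~ 0 or 180) gamma is set to 0
#' and the identifiable twist combination is folded into alpha.
#'
#' @param frame1,frame2 `toprna_frame` objects (H1 listed first).
#' @return Named numeric vector `c(alpha, beta, gamma)` in degrees.
#' @export
euler_angles <- function(frame1, frame2) {
  R <- t(frame1$axes) %*% frame2$axes
  euler_from_matrix(R)
}

euler_from_matrix <- function(R, tol = 1e-6) {
  b <- acos(max(-1, min(1, R[3, 3]))) * 180 / pi
  if (b < tol) {
    a <- atan2(R[2, 1], R[1, 1]) * 180 / pi
    g <- 0
  } else if (b > 180 - tol) {
    a <- atan2(-R[2, 1], -R[1, 1]) * 180 / pi
    g <- 0
  } else {
    a <- atan2(R[2, 3], R[1, 3]) * 180 / pi
    g <- atan2(R[3, 2], -R[3, 1]) * 180 / pi
  }
  a <- a %% 360
  g <- g %% 360
  c(alpha = a, beta = b, gamma = g)
}

euler_to_matrix <- function(angles) {
  a <- angles[1] * pi / 180; b <- angles[2] * pi / 180
  g <- angles[3] * pi / 180
  Rz <- function(t) matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0, 0, 0, 1),
                           3, 3)
  Ry <- function(t) matrix(c(cos(t), 0, -sin(t), 0, 1, 0, sin(t), 0, cos(t)),
                           3, 3)
  Rz(a) %*% Ry(b) %*% Rz(g)
}

#' Minimal RMSD under rigid superposition (Kabsch)
#'
#' @param a,b Coordinate matrices of equal dimensions (>= 3 points).
#' @param sel Optional row selection applied to both.
#' @return RMSD in the units of the input (Angstrom), after optimal rotation
#'   and translation of `b` onto `a`.
#' @export
kabsch_rmsd <- function(a, b, sel = NULL) {
  if (!is.null(sel)) {
    a <- a[sel, , drop = FALSE]
    b <- b[sel, , drop = FALSE]
  }
  if (!all(dim(a) == dim(b))) stop("selection size mismatch")
  if (nrow(a) < 3) stop("need at least 3 points")
  ac <- sweep(a, 2, colMeans(a))
  bc <- sweep(b, 2, colMeans(b))
  H <- crossprod(bc, ac)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  br <- bc %*% t(R)
  sqrt(mean(rowSums((ac - br)^2)))
}

#' Mass-weighted center of mass of an element
#'
#' Includes the P, S and B beads of the element's residues plus any M bead
#' whose base pair lies entirely inside the element.
#'
#' @param coords Bead coordinates.
#' @param top A `toprna_topology`.
#' @param element Element name or integer residue vector.
#' @return Length-3 numeric (Angstrom).
#' @export
center_of_mass <- function(coords, top, element) {
  res <- if (is.character(element)) top$ss$elements[[element]] else element
  if (is.null(res) || length(res) == 0) stop("empty element selection")
  idx <- c(bead_P(res), bead_S(res), bead_B(res))
  if (nrow(top$m_beads) > 0) {
    inm <- top$m_beads$i %in% res & top$m_beads$j %in% res
    idx <- c(idx, top$m_beads$bead[inm])
  }
  m <- top$beads$mass[idx]
  colSums(coords[idx, , drop = FALSE] * m) / sum(m)
}

#' Write a coarse-grained snapshot as PDB
#'
#' Beads become pseudo-atoms (P, S, B, M), one residue per nucleotide, so
#' snapshots can be inspected in any molecular viewer.  Numbering is 1-based.
#'
#' @param coords Bead coordinates.
#' @param top A `toprna_topology`.
#' @param path Output file.
#' @export
write_cg_pdb <- function(coords, top, path) {
  sq <- strsplit(top$ss$sequence, "")[[1]]
  con <- file(path, "w")
  on.exit(close(con))
  for (b in seq_len(top$n_beads)) {
    kind <- top$beads$kind[b]
    res <- top$beads$residue[b]
    if (is.na(res)) {
      w <- which(top$m_beads$bead == b)
      res <- top$m_beads$i[w]
    }
    rn <- if (res <= length(sq)) sq[res] else "N"
    writeLines(sprintf(
      "ATOM  %5d %-4s %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00",
      b, kind, rn, res, coords[b, 1], coords[b, 2], coords[b, 3]), con)
  }
  writeLines("END", con)
  invisible(path)
}
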