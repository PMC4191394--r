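#' Per-snapshot interhelical Euler angles
#'
#' @param ens A `toprna_ensemble`.
#' @param h1,h2 Helix names (H1 frame listed first).
#' @return Matrix `n_snapshots x 3` (alpha, beta, gamma in degrees).
#' @export
euler_series <- function(ens, h1, h2) {
  n <- ens$n_snapshots
  out <- matrix(NA_real_, n, 3,
                dimnames = list(NULL, c("alpha", "beta", "gamma")))
  for (s in seq_len(n)) {
    co <- ens$coords[s, , ]
    f1 <- fit_helix_frame(co, ens$topology, h1)
    f2 <- fit_helix_frame(co, ens$topology, h2)
    out[s, ] <- euler_angles(f1, f2)
  }
  out
}

bin_triple <- function(angles, bin) {
  na <- as.integer(360 / bin); nb <- as.integer(180 / bin)
  ia <- pmin(floor(angles[, 1] / bin), na - 1L)
  ib <- pmin(floor(angles[, 2] / bin), nb - 1L)
  ig <- pmin(floor(angles[, 3] / bin), na - 1L)
  list(code = as.integer((ia * nb + ib) * na + ig),
       n_bins = as.integer(na * nb * na))
}

#' Fraction of pairwise orientation space sampled
#'
#' Discretizes the (alpha, beta, gamma) Euler triples of one helix pair on a
#' regular grid (equal-width bins in each angle; a 10 degree grid has
#' 36 x 18 x 36 bins, a 60 degree grid the 108 bins used for joint coverage)
#' and reports the fraction of bins visited.  Coverage is monotone
#' non-decreasing in the number of snapshots and converges from below toward
#' the equilibrium coverage.
#'
#' @param ens A `toprna_ensemble` (ignored when `angles` is supplied).
#' @param h1,h2 Helix names.
#' @param bin Bin width in degrees (must divide 180).
#' @param angles Optional precomputed matrix from [euler_series()].
#' @return A `toprna_coverage` list: `fraction`, `unique_bins`, `denominator`,
#'   `n_snapshots`, `pair`, `bin`.
#' @export
coverage_3d <- function(ens = NULL, h1 = NULL, h2 = NULL, bin = 10,
                        angles = NULL) {
  if (180 %% bin != 0) stop("bin width must divide 180 degrees")
  if (is.null(angles)) {
    if (!h1 %in% names(ens$topology$ss$helices) ||
        !h2 %in% names(ens$topology$ss$helices)) {
      stop("helix not present in the topology")
    }
    angles <- euler_series(ens, h1, h2)
  }
  if (nrow(angles) < 1) stop("need at least one snapshot")
  bt <- bin_triple(angles, bin)
  u <- length(unique(bt$code))
  structure(list(fraction = u / bt$n_bins, unique_bins = u,
                 denominator = bt$n_bins, n_snapshots = nrow(angles),
                 pair = c(h1, h2), bin = bin), class = "toprna_coverage")
}

#' Joint 9D orientation coverage and its independence ratio
#'
#' Measures the three Euler triples of the remaining helices relative to a
#' common reference helix, discretizes them jointly on a 60 degree 9D grid
#' (denominator 108^3, with 108 the number of per-pair bins on that grid) and
#' reports the sampled fraction, together with the ratio of the 9D fraction
#' to the product of the three pairwise 3D fractions on the same grid.  Under
#' exact independence of the three orientations the ratio converges to 1; a
#' ratio below 1 quantifies interhelical coupling (undersampling also keeps
#' the ratio below its converged value).
#'
#' @param ens A `toprna_ensemble` over a structure with at least 4 helices.
#' @param reference Name of the common H1 helix (default AC-stem).
#' @param bin Grid width in degrees.
#' @param helices Optional names of the three helices measured against the
#'   reference; defaults to the A-, D- and T-stems for cloverleafs.
#' @return A `toprna_coverage9` list: `fraction`, `unique_bins`,
#'   `denominator`, `ratio` (r_9D/(3x3D)), and the per-pair 3D fractions.
#' @export
coverage_9d <- function(ens, reference = "AC-stem", bin = 60,
                        helices = NULL) {
  hs <- names(ens$topology$ss$helices)
  if (length(hs) < 4) stop("9D coverage needs at least 4 helices")
  if (is.null(helices)) {
    helices <- if (all(c("A-stem", "D-stem", "T-stem") %in% hs))
      c("A-stem", "D-stem", "T-stem") else setdiff(hs, reference)[1:3]
  }
  stopifnot(length(helices) == 3, reference %in% hs)
  per_bins <- as.integer((360 / bin)^2 * (180 / bin))
  codes <- vector("list", 3)
  f3 <- numeric(3)
  for (k in 1:3) {
    ang <- euler_series(ens, reference, helices[k])
    bt <- bin_triple(ang, bin)
    codes[[k]] <- bt$code
    f3[k] <- length(unique(bt$code)) / bt$n_bins
  }
  key <- (as.numeric(codes[[1]]) * per_bins + codes[[2]]) * per_bins +
    codes[[3]]
  u9 <- length(unique(key))
  denom <- as.numeric(per_bins)^3
  f9 <- u9 / denom
  structure(list(fraction = f9, unique_bins = u9, denominator = denom,
                 ratio = f9 / prod(f3), fractions_3d = stats::setNames(f3, helices),
                 reference = reference, bin = bin,
                 n_snapshots = ens$n_snapshots), class = "toprna_coverage9")
}

#' Mutual information between two helix orientations
#'
#' Both orientations are Euler triples measured against a common H1 helix,
#' histogrammed with 45 degree bins.  MI is the Kullback-Leibler divergence
#' of the joint from the product of marginals, in bits by default, minus the
#' first-order finite-sample bias `(B_xy - B_x - B_y + 1) / (2 N ln 2)`
#' (B = number of populated bins), floored at zero.  MI is 0 for independent
#' orientations and equals the marginal Shannon entropy for a deterministic
#' dependence.
#'
#' @param ens A `toprna_ensemble` (ignored when `x`/`y` are supplied).
#' @param h1 Common reference helix.
#' @param pair Character vector of the two helices being correlated.
#' @param bin Histogram bin width in degrees.
#' @param correct `TRUE` (first-order analytic bias correction), `FALSE`
#'   (raw plug-in), or `"shift"`: subtract the mean MI of circularly
#'   time-shifted surrogates.  The analytic correction assumes effectively
#'   independent samples; the shift surrogate preserves each stream's
#'   autocorrelation while breaking their synchrony, which makes it the
#'   appropriate null for short, strongly autocorrelated trajectories.  The
#'   shift offsets are deterministic (spread over the middle of the series).
#' @param unit `"bits"` (log2) or `"nats"`.
#' @param x,y Optional precomputed Euler matrices (or integer bin codes).
#' @return A `toprna_mi` list: `mi`, `mi_raw`, `correction`, `H_x`, `H_y`,
#'   populated bin counts and settings.
#' @export
mutual_information <- function(ens = NULL, h1 = NULL, pair = NULL, bin = 45,
                               correct = TRUE, unit = c("bits", "nats"),
                               x = NULL, y = NULL) {
  unit <- match.arg(unit)
  tocode <- function(v) {
    if (is.matrix(v)) bin_triple(v, bin)$code else as.integer(v)
  }
  if (is.null(x)) {
    if (ens$n_snapshots < 1) stop("empty ensemble")
    x <- euler_series(ens, h1, pair[1])
    y <- euler_series(ens, h1, pair[2])
  }
  cx <- tocode(x); cy <- tocode(y)
  n <- length(cx)
  stopifnot(length(cy) == n, n > 0)
  base <- if (unit == "bits") 2 else exp(1)
  plug_in <- function(cx, cy) {
    jt <- table(paste(cx, cy))
    tx <- table(cx); ty <- table(cy)
    pj <- as.numeric(jt) / n
    keys <- do.call(rbind, strsplit(names(jt), " "))
    px <- as.numeric(tx[keys[, 1]]) / n
    py <- as.numeric(ty[keys[, 2]]) / n
    list(mi = sum(pj * log(pj / (px * py), base = base)),
         jt = jt, tx = tx, ty = ty)
  }
  pi0 <- plug_in(cx, cy)
  jt <- pi0$jt; tx <- pi0$tx; ty <- pi0$ty
  mi_raw <- pi0$mi
  H <- function(tb) {
    p <- as.numeric(tb) / n
    -sum(p * log(p, base = base))
  }
  corr <- 0
  if (identical(correct, "shift")) {
    offs <- unique(pmax(1, floor(n * seq(0.25, 0.75, length.out = 8))))
    nulls <- vapply(offs, function(o) {
      plug_in(cx, cy[((seq_len(n) + o - 1L) %% n) + 1L])$mi
    }, numeric(1))
    corr <- mean(nulls)
  } else if (isTRUE(correct)) {
    lb <- if (unit == "bits") log(2) else 1
    corr <- (length(jt) - length(tx) - length(ty) + 1) / (2 * n * lb)
  }
  mi_val <- min(max(0, mi_raw - corr), H(tx), H(ty))
  structure(list(mi = mi_val, mi_raw = mi_raw,
                 correction = corr, H_x = H(tx), H_y = H(ty),
                 populated_joint = length(jt),
                 populated_x = length(tx), populated_y = length(ty),
                 n = n, bin = bin, unit = unit, h1 = h1, pair = pair),
            class = "toprna_mi")
}

#' Correlations between element centers of mass
#'
#' Snapshots are first superposed onto the first snapshot (Kabsch over all P
#' beads) to remove global rotation and translation; Pearson correlations are
#' then computed per Cartesian component between the centers of mass of each
#' element pair across snapshots.
#'
#' @param ens A `toprna_ensemble` with at least 3 snapshots.
#' @param element_pairs List of 2-element character vectors.
#' @param align Superpose snapshots before measuring (recommended).
#' @return Data frame: one row per pair with `R_x`, `R_y`, `R_z` and `R_max`
#'   (largest absolute component correlation, signed).  Constant coordinate
#'   series yield `NA` with a warning.
#' @export
com_correlation <- function(ens, element_pairs, align = TRUE) {
  if (ens$n_snapshots < 3) stop("need at least 3 snapshots")
  top <- ens$topology
  psel <- bead_P(seq_len(top$ss$n))
  ref <- ens$coords[1, , ]
  coords <- ens$coords
  if (align) {
    for (s in seq_len(ens$n_snapshots)) {
      co <- coords[s, , ]
      a <- ref[psel, , drop = FALSE]
      b <- co[psel, , drop = FALSE]
      am <- colMeans(a); bm <- colMeans(b)
      H <- crossprod(sweep(b, 2, bm), sweep(a, 2, am))
      sv <- svd(H)
      d <- sign(det(sv$v %*% t(sv$u)))
      R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
      coords[s, , ] <- sweep(sweep(co, 2, bm) %*% t(R), 2, am, "+")
    }
  }
  els <- unique(unlist(element_pairs))
  coms <- lapply(stats::setNames(els, els), function(e) {
    t(vapply(seq_len(ens$n_snapshots),
             function(s) center_of_mass(coords[s, , ], top, e), numeric(3)))
  })
  out <- lapply(element_pairs, function(pr) {
    A <- coms[[pr[1]]]; B <- coms[[pr[2]]]
    r <- vapply(1:3, function(k) {
      if (stats::sd(A[, k]) < 1e-10 || stats::sd(B[, k]) < 1e-10) {
        warning("constant center-of-mass series; correlation undefined")
        return(NA_real_)
      }
      stats::cor(A[, k], B[, k])
    }, numeric(1))
    data.frame(element_a = pr[1], element_b = pr[2],
               R_x = r[1], R_y = r[2], R_z = r[3],
               R_max = r[which.max(abs(r))])
  })
  do.call(rbind, out)
}
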