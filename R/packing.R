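# Best-packed conformer identification and entropy-weighted native
# specificity.

# count interloop residue-residue contacts (both residues single-stranded)
# and native-tracked coaxial stacks for one snapshot
packing_counts <- function(coords, top) {
  ss <- top$ss
  loops <- which(is.na(pair_table(ss)))
  sl <- coords[bead_S(loops), , drop = FALSE]
  d2 <- outer(rowSums(sl^2), rowSums(sl^2), "+") - 2 * sl %*% t(sl)
  sep <- abs(outer(loops, loops, "-"))
  hit <- d2 < CONTACT_SS_CUTOFF^2 & sep >= CONTACT_MIN_SEP
  n_l <- sum(hit[upper.tri(hit)])
  stacks <- trna_stack_set(ss)
  n_s <- sum(vapply(stacks, function(h) coaxial_stack(coords, top, h),
                    logical(1)))
  c(n_l = n_l, n_s = n_s)
}

#' Select the best-packed conformers of an ensemble
#'
#' Ranks snapshots by the packing score `E = n_l * eps_l + n_s * eps_s`
#' (`n_l`: residue-residue contacts between single-stranded loops; `n_s`:
#' coaxial stacks among the tracked interhelical stacks) and returns the `k`
#' lowest-energy snapshots.  Ties are broken by snapshot order.  The default
#' weights (-0.6 and -3.5 k_B T) reflect the relative interaction energy
#' expected from a nonspecific residue contact versus an interhelical stack;
#' the identified set is insensitive to moderate changes in the weights.
#'
#' @param ens A `toprna_ensemble`.
#' @param k Subset size; defaults to `min(500, n_snapshots / 10)` with at
#'   least 10 conformers, so short runs yield proportionally smaller sets.
#' @param eps_l,eps_s Contact and stack weights (k_B T).
#' @return A `toprna_packing` list: `index` (snapshot indices), `table`
#'   (id, E, n_l, n_s), weights, and the parent ensemble reference.
#' @export
select_best_packed <- function(ens, k = NULL, eps_l = -0.6, eps_s = -3.5) {
  n <- ens$n_snapshots
  if (is.null(k)) k <- max(10L, min(500L, floor(n / 10)))
  if (k > n) {
    warning("ensemble smaller than k; returning all snapshots")
    k <- n
  }
  cnt <- t(vapply(seq_len(n),
                  function(s) packing_counts(ens$coords[s, , ], ens$topology),
                  numeric(2)))
  E <- cnt[, 1] * eps_l + cnt[, 2] * eps_s
  ord <- order(E, seq_len(n))  # stable: ties broken by snapshot order
  idx <- ord[seq_len(k)]
  structure(list(
    index = idx,
    table = data.frame(id = idx, E = E[idx], n_l = cnt[idx, 1],
                       n_s = cnt[idx, 2]),
    eps_l = eps_l, eps_s = eps_s, ensemble = ens),
    class = "toprna_packing")
}

# P-bead selection used for conformer RMSDs; A/D-, V- and ACCA-loop residues
# are excluded so RMSDs are comparable across secondary-structure variants
packing_rmsd_selection <- function(top) {
  ss <- top$ss
  excl <- unlist(ss$elements[grep("^(A/D-loop|V-loop|ACCA-tail)",
                                  names(ss$elements))])
  res <- setdiff(seq_len(ss$n), excl)
  bead_P(res)
}

#' Local ensemble entropy of best-packed conformers
#'
#' For each conformer `i` in the subset, `S_i = ln(1 + sum_j exp(-rmsd_ij^3 /
#' (10 A)^3))` (k_B units), a smooth count of the other conformers within a
#' ~10 Angstrom RMSD volume.  RMSDs are pairwise Kabsch superpositions over P
#' beads, excluding the A/D-, V- and ACCA-loop residues so values are
#' comparable across secondary-structure variants.
#'
#' @param packed A `toprna_packing` from [select_best_packed()].
#' @param selection Optional bead index vector overriding the default P-bead
#'   selection.
#' @param radius Kernel radius in Angstrom (10 by default).
#' @return A `toprna_entropy` list: `S` (k_B), `rmsd` (k x k matrix),
#'   `selection`.
#' @export
conformer_entropy <- function(packed, selection = NULL, radius = 10) {
  ens <- packed$ensemble
  idx <- packed$index
  k <- length(idx)
  if (k < 2) stop("need at least 2 conformers")
  if (is.null(selection)) selection <- packing_rmsd_selection(ens$topology)
  if (length(selection) == 0) stop("empty RMSD selection")
  confs <- lapply(idx, function(s) ens$coords[s, selection, , drop = TRUE])
  rmsd <- matrix(0, k, k)
  for (a in seq_len(k - 1)) {
    for (b in (a + 1):k) {
      rmsd[a, b] <- rmsd[b, a] <- kabsch_rmsd(confs[[a]], confs[[b]])
    }
  }
  kern <- exp(-(rmsd / radius)^3)
  diag(kern) <- 0
  S <- log(1 + rowSums(kern))
  structure(list(S = S, rmsd = rmsd, selection = selection, radius = radius),
            class = "toprna_entropy")
}

# loop pairs whose contact precludes a native-like 3D structure
native_inconsistent_pairs <- function() {
  list(c("A/D-loop", "AC-loop"), c("A/D-loop", "ACCA-tail"),
       c("D-loop", "AC-loop"), c("D-loop", "ACCA-tail"),
       c("D/AC-linker", "ACCA-tail"), c("AC-loop", "V-loop"),
       c("AC-loop", "T-loop"), c("AC-loop", "ACCA-tail"),
       c("V-loop", "ACCA-tail"), c("T-loop", "ACCA-tail"))
}

# resolve an element name to residues, pooling split elements (V-loop.1/.2)
resolve_element <- function(ss, name) {
  if (!is.null(ss$elements[[name]])) return(ss$elements[[name]])
  hits <- grep(paste0("^", gsub("([][(){}.*+?^$\\\\|])", "\\\\\\1", name),
                      "\\."), names(ss$elements))
  if (length(hits)) return(sort(unlist(ss$elements[hits], use.names = FALSE)))
  NULL
}

#' Entropy-weighted native specificity of best-packed conformers
#'
#' A conformer is native-like (`N_i = 1`) when it has at least one
#' residue-residue contact between the D- and T-loops and no contact within
#' the native-inconsistent loop-pair list ((A/D, AC), (A/D, ACCA), (D, AC),
#' (D, ACCA), (D/AC, ACCA), (AC, V), (AC, T), (AC, ACCA), (V, ACCA),
#' (T, ACCA)).  The overall specificity is the entropy-weighted mean
#' `<N> = sum_i N_i exp(S_i) / sum_i exp(S_i)`.
#'
#' @param packed A `toprna_packing`.
#' @param entropies A `toprna_entropy` computed on the same subset.
#' @return A `toprna_specificity` list: `N_mean`, per-conformer `N`,
#'   `weights` (normalized, summing to 1), and the inconsistent pair list.
#' @export
native_specificity <- function(packed, entropies) {
  ens <- packed$ensemble
  top <- ens$topology
  ss <- top$ss
  if (length(entropies$S) != length(packed$index)) {
    stop("entropies were not computed on this subset")
  }
  need <- c("D-loop", "T-loop")
  for (nm in need) {
    if (is.null(resolve_element(ss, nm))) stop("missing element label: ", nm)
  }
  incon <- native_inconsistent_pairs()
  N <- vapply(seq_along(packed$index), function(q) {
    co <- ens$coords[packed$index[q], , ]
    dt <- group_contact(co, top, resolve_element(ss, "D-loop"),
                        resolve_element(ss, "T-loop"))
    if (!dt) return(0L)
    for (pr in incon) {
      ra <- resolve_element(ss, pr[1]); rb <- resolve_element(ss, pr[2])
      if (is.null(ra) || is.null(rb)) next  # element absent in this variant
      if (group_contact(co, top, ra, rb)) return(0L)
    }
    1L
  }, integer(1))
  w <- exp(entropies$S)
  w <- w / sum(w)
  structure(list(N_mean = sum(N * w), N = N, weights = w,
                 inconsistent_pairs = incon),
            class = "toprna_specificity")
}
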