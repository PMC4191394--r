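#' Parse an RNA secondary structure
#'
#' Accepts either dot-bracket text (a sequence line followed by a structure
#' line, or just a structure line) or an explicit base-pair list.  Pairs must
#' be disjoint (each residue in at most one pair) and nested (no pseudoknots).
#' Residue numbering is 1-based throughout.
#'
#' Helices are maximal runs of consecutively stacked pairs; every other
#' residue belongs to one maximal single-stranded segment.  When the structure
#' is a four-way cloverleaf (or the five-helix Class II variant with a V-stem)
#' elements receive tRNA names (A-stem, D-stem, AC-stem, V-stem, T-stem,
#' A/D-loop, D-loop, D/AC-linker, AC-loop, V-loop, T-loop, T/A-pivot,
#' ACCA-tail); otherwise generic names H1..Hk / L1..Lm are used.
#'
#' @param text Character vector: `c(sequence, structure)` or a single
#'   dot-bracket string (optionally with an embedded newline separating the
#'   sequence from the structure).  Ignored when `pairs` is given.
#' @param pairs Optional two-column integer matrix of base pairs (i, j).
#' @param sequence Optional nucleotide string, required with `pairs` (or a
#'   poly-N placeholder is generated).
#' @param cuts Optional integer vector of residues i after which the backbone
#'   (S_i -> P_{i+1}) is severed.
#' @return An object of class `toprna_ss`.
#' @export
parse_secondary_structure <- function(text = NULL, pairs = NULL,
                                      sequence = NULL, cuts = integer()) {
  if (is.null(pairs)) {
    if (is.null(text)) stop("supply dot-bracket text or a pair list")
    if (length(text) == 1 && grepl("\n", text)) {
      text <- strsplit(text, "\n")[[1]]
    }
    text <- trimws(text[nzchar(trimws(text))])
    if (length(text) == 1) {
      db <- text
    } else if (length(text) >= 2) {
      sequence <- text[1]
      db <- text[2]
      if (nchar(sequence) != nchar(db)) {
        stop("sequence length does not match structure length")
      }
    }
    chars <- strsplit(db, "")[[1]]
    if (any(!chars %in% c("(", ")", "."))) {
      bad <- setdiff(unique(chars), c("(", ")", "."))
      if (any(bad %in% c("[", "]", "{", "}", "<", ">"))) {
        stop("unsupported pseudoknot brackets in structure: ",
             paste(bad, collapse = ""))
      }
      stop("unrecognized structure characters: ", paste(bad, collapse = ""))
    }
    n <- length(chars)
    stack <- integer(0)
    pr <- matrix(0L, 0, 2)
    for (i in seq_len(n)) {
      if (chars[i] == "(") {
        stack <- c(stack, i)
      } else if (chars[i] == ")") {
        if (length(stack) == 0) stop("unbalanced brackets: unmatched ')' at ", i)
        pr <- rbind(pr, c(stack[length(stack)], i))
        stack <- stack[-length(stack)]
      }
    }
    if (length(stack) > 0) {
      stop("unbalanced brackets: unmatched '(' at ",
           paste(stack, collapse = ", "))
    }
    pairs <- pr
  } else {
    pairs <- as.matrix(pairs)
    storage.mode(pairs) <- "integer"
    if (ncol(pairs) != 2) stop("pair list must have two columns")
    n <- if (!is.null(sequence)) nchar(sequence) else max(pairs, 0L)
  }
  if (is.null(sequence)) sequence <- paste(rep("N", n), collapse = "")
  n <- nchar(sequence)

  if (nrow(pairs) > 0) {
    pairs <- t(apply(pairs, 1, function(p) sort(p)))
    pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
    if (any(pairs < 1L) || any(pairs > n)) stop("pair index out of range")
    if (anyDuplicated(c(pairs))) stop("pairs are not disjoint")
    # crossing check (i1 < i2 < j1 < j2)
    if (nrow(pairs) > 1) {
      for (a in seq_len(nrow(pairs) - 1)) {
        i1 <- pairs[a, 1]; j1 <- pairs[a, 2]
        b <- (a + 1):nrow(pairs)
        crossing <- pairs[b, 1] < j1 & pairs[b, 2] > j1
        if (any(crossing)) stop("crossing pairs (pseudoknot) are unsupported")
      }
    }
  }
  colnames(pairs) <- c("i", "j")
  ss <- structure(
    list(sequence = sequence, n = n, pairs = pairs,
         cuts = sort(unique(as.integer(cuts)))),
    class = "toprna_ss")
  ss <- derive_elements(ss)
  ss
}

# pair partner lookup (NA when unpaired)
pair_table <- function(ss) {
  pt <- rep(NA_integer_, ss$n)
  if (nrow(ss$pairs) > 0) {
    pt[ss$pairs[, 1]] <- ss$pairs[, 2]
    pt[ss$pairs[, 2]] <- ss$pairs[, 1]
  }
  pt
}

# derive helices, single-stranded segments and element names
derive_elements <- function(ss) {
  n <- ss$n
  pt <- pair_table(ss)
  pairs <- ss$pairs
  # helices: maximal runs of stacked pairs (i,j), (i+1,j-1), ...
  helices <- list()
  if (nrow(pairs) > 0) {
    used <- rep(FALSE, nrow(pairs))
    key <- paste(pairs[, 1], pairs[, 2])
    idx <- seq_len(nrow(pairs))
    has_pair <- function(i, j) {
      w <- which(pairs[, 1] == i & pairs[, 2] == j)
      if (length(w)) w else 0L
    }
    for (a in idx) {
      if (used[a]) next
      i <- pairs[a, 1]; j <- pairs[a, 2]
      # walk outward to the start of the run
      while ((w <- has_pair(i - 1L, j + 1L)) && !used[w]) {
        i <- i - 1L; j <- j + 1L
      }
      run <- matrix(0L, 0, 2)
      while ((w <- has_pair(i, j)) > 0L) {
        run <- rbind(run, c(i, j))
        used[w] <- TRUE
        i <- i + 1L; j <- j - 1L
      }
      helices[[length(helices) + 1L]] <- run
    }
    helices <- helices[order(vapply(helices, function(h) h[1, 1], 0L))]
  }
  # single-stranded segments
  segs <- list()
  unp <- which(is.na(pt))
  if (length(unp) > 0) {
    brk <- c(0, which(diff(unp) != 1), length(unp))
    for (k in seq_len(length(brk) - 1)) {
      segs[[k]] <- unp[(brk[k] + 1):brk[k + 1]]
    }
  }
  named <- cloverleaf_names(ss, helices, segs)
  ss$helices <- named$helices
  ss$segments <- named$segments
  ss$is_cloverleaf <- named$is_cloverleaf
  elements <- c(
    lapply(named$helices, function(h) sort(c(h[, 1], h[, 2]))),
    named$segments)
  ss$elements <- elements
  eo <- rep(NA_character_, n)
  for (nm in names(elements)) eo[elements[[nm]]] <- nm
  ss$element_of <- eo
  ss
}

# Assign tRNA cloverleaf names when the helix arrangement matches; otherwise
# generic H*/L* labels.
cloverleaf_names <- function(ss, helices, segs) {
  nh <- length(helices)
  is_hairpin <- function(h) {
    # innermost pair encloses no other pair
    i <- h[nrow(h), 1]; j <- h[nrow(h), 2]
    !any(ss$pairs[, 1] > i & ss$pairs[, 2] < j)
  }
  generic <- function() {
    hn <- if (nh > 0) paste0("H", seq_len(nh)) else character()
    sn <- if (length(segs) > 0) paste0("L", seq_along(segs)) else character()
    names(helices) <- hn
    names(segs) <- sn
    list(helices = helices, segments = segs, is_cloverleaf = FALSE)
  }
  if (!(nh %in% c(4L, 5L))) return(generic())
  h1 <- helices[[1]]
  inner <- helices[-1]
  # closing helix must enclose all others; the rest must be hairpins in order
  encl <- all(vapply(inner, function(h)
    h[1, 1] > h1[nrow(h1), 1] && h[1, 2] < h1[nrow(h1), 2], TRUE))
  if (!encl || !all(vapply(inner, is_hairpin, TRUE))) return(generic())
  hn <- if (nh == 4L) c("A-stem", "D-stem", "AC-stem", "T-stem")
        else c("A-stem", "D-stem", "AC-stem", "V-stem", "T-stem")
  names(helices) <- hn
  # interval boundaries for loop naming
  H <- function(nm) helices[[nm]]
  a5e <- H("A-stem")[nrow(H("A-stem")), 1]       # 3' end of A 5'-strand
  a3s <- H("A-stem")[nrow(H("A-stem")), 2]       # 5' end of A 3'-strand
  rng <- function(h) range(c(h[, 1], h[, 2]))
  seg_names <- character(length(segs))
  for (k in seq_along(segs)) {
    s <- segs[[k]]
    lo <- min(s); hi <- max(s)
    nm <- paste0("L", k)
    if (hi < rng(H("A-stem"))[1]) nm <- "5'-tail"
    else if (lo > a5e && hi < H("D-stem")[1, 1]) nm <- "A/D-loop"
    else if (lo > H("D-stem")[nrow(H("D-stem")), 1] &&
             hi < H("D-stem")[nrow(H("D-stem")), 2]) nm <- "D-loop"
    else if (lo > H("D-stem")[1, 2] && hi < H("AC-stem")[1, 1]) nm <- "D/AC-linker"
    else if (lo > H("AC-stem")[nrow(H("AC-stem")), 1] &&
             hi < H("AC-stem")[nrow(H("AC-stem")), 2]) nm <- "AC-loop"
    else if (nh == 5L && lo > H("V-stem")[nrow(H("V-stem")), 1] &&
             hi < H("V-stem")[nrow(H("V-stem")), 2]) nm <- "V-stem-loop"
    else if (lo > H("AC-stem")[1, 2] && hi < H("T-stem")[1, 1]) nm <- "V-loop"
    else if (lo > H("T-stem")[nrow(H("T-stem")), 1] &&
             hi < H("T-stem")[nrow(H("T-stem")), 2]) nm <- "T-loop"
    else if (lo > H("T-stem")[1, 2] && hi < a3s) nm <- "T/A-pivot"
    else if (lo > rng(H("A-stem"))[2]) nm <- "ACCA-tail"
    seg_names[k] <- nm
  }
  # V-loop may be split in two by an inserted V-stem; disambiguate
  if (anyDuplicated(seg_names[nzchar(seg_names)])) {
    dup <- unique(seg_names[duplicated(seg_names)])
    for (d in dup) {
      w <- which(seg_names == d)
      seg_names[w] <- paste0(d, ".", seq_along(w))
    }
  }
  names(segs) <- seg_names
  list(helices = helices, segments = segs, is_cloverleaf = TRUE)
}

#' Write a secondary structure back to dot-bracket
#'
#' @param ss A `toprna_ss` object.
#' @return Character vector `c(sequence, structure)`.
#' @export
write_dot_bracket <- function(ss) {
  chars <- rep(".", ss$n)
  if (nrow(ss$pairs) > 0) {
    chars[ss$pairs[, 1]] <- "("
    chars[ss$pairs[, 2]] <- ")"
  }
  c(ss$sequence, paste(chars, collapse = ""))
}

#' @export
print.toprna_ss <- function(x, ...) {
  cat(sprintf("<toprna_ss> %d nt, %d pairs, %d helices, %d single-stranded segments%s\n",
              x$n, nrow(x$pairs), length(x$helices), length(x$segments),
              if (x$is_cloverleaf) " (cloverleaf)" else ""))
  if (length(x$cuts)) cat("  backbone cuts after residue(s):",
                          paste(x$cuts, collapse = ", "), "\n")
  for (nm in names(x$helices)) {
    h <- x$helices[[nm]]
    cat(sprintf("  %-12s %d bp (%d-%d / %d-%d)\n", nm, nrow(h),
                h[1, 1], h[nrow(h), 1], h[nrow(h), 2], h[1, 2]))
  }
  for (nm in names(x$segments)) {
    s <- x$segments[[nm]]
    cat(sprintf("  %-12s %d nt (%d-%d)\n", nm, length(s), min(s), max(s)))
  }
  invisible(x)
}

#' Edit a secondary structure or topology
#'
#' Supported edits mirror the variant constructions used for the tRNA study:
#' * `cut`: sever the backbone bond S_i -> P_{i+1} after residue `at`.
#' * `insert_loop_nt` / `delete_loop_nt`: grow or shrink a named
#'   single-stranded element by `n` residues (renumbering downstream residues
#'   and pairs).
#' * `insert_stem`: replace part of a single-stranded element with a hairpin
#'   (`n_bp` base pairs closed by a loop of `loop_len` nt), inserted after the
#'   `offset`-th residue of the element.
#' * `toggle_pair`: add the base pair (`i`, `j`) if absent, remove it (and its
#'   associated M bead and helical dihedrals on rebuild) if present.
#'
#' Edits apply to a `toprna_ss`; topologies are rebuilt from the edited
#' structure.  A `cut` applied directly to a `toprna_topology` removes exactly
#' that one bond and its bookkeeping.
#'
#' @param x A `toprna_ss` or `toprna_topology`.
#' @param edit One of `"cut"`, `"insert_loop_nt"`, `"delete_loop_nt"`,
#'   `"insert_stem"`, `"toggle_pair"`.
#' @param at Residue index (for `cut`) .
#' @param element Element name (loop edits / `insert_stem`).
#' @param n Number of residues to insert or delete.
#' @param i,j Pair indices for `toggle_pair`.
#' @param n_bp,loop_len,offset Hairpin geometry for `insert_stem`.
#' @param nt Fill nucleotide for inserted residues.
#' @return Edited object of the same class as `x`.
#' @export
apply_variant <- function(x, edit, at = NULL, element = NULL, n = 1L,
                          i = NULL, j = NULL, n_bp = 4L, loop_len = 4L,
                          offset = NULL, nt = "A") {
  if (inherits(x, "toprna_topology")) {
    if (edit != "cut") {
      ss <- apply_variant(x$ss, edit, at = at, element = element, n = n,
                          i = i, j = j, n_bp = n_bp, loop_len = loop_len,
                          offset = offset, nt = nt)
      return(build_topology(ss, x$params))
    }
    return(cut_topology(x, at))
  }
  stopifnot(inherits(x, "toprna_ss"))
  ss <- x
  if (edit == "cut") {
    if (is.null(at) || at < 1 || at >= ss$n) stop("invalid cut site")
    ss$cuts <- sort(unique(c(ss$cuts, as.integer(at))))
    return(derive_elements(ss))
  }
  if (edit == "toggle_pair") {
    stopifnot(!is.null(i), !is.null(j))
    w <- which(ss$pairs[, 1] == min(i, j) & ss$pairs[, 2] == max(i, j))
    pairs <- if (length(w)) ss$pairs[-w, , drop = FALSE]
             else rbind(ss$pairs, sort(c(i, j)))
    return(parse_secondary_structure(pairs = pairs, sequence = ss$sequence,
                                     cuts = ss$cuts))
  }
  if (edit %in% c("insert_loop_nt", "delete_loop_nt", "insert_stem")) {
    if (is.null(element) || !element %in% names(ss$segments)) {
      stop("unknown single-stranded element: ", element)
    }
    seg <- ss$segments[[element]]
    seqc <- strsplit(ss$sequence, "")[[1]]
    shift_after <- function(v, pos, by) ifelse(v > pos, v + by, v)
    if (edit == "delete_loop_nt") {
      if (length(seg) < n + 0L) stop("element too short to delete ", n, " nt")
      if (length(seg) == n) stop("refusing to delete an entire element")
      drop <- seg[seq_len(n)]
      keep <- setdiff(seq_len(ss$n), drop)
      seqc <- seqc[keep]
      pairs <- ss$pairs
      for (d in sort(drop, decreasing = TRUE)) {
        pairs <- ifelse(pairs > d, pairs - 1L, pairs)
      }
      dim(pairs) <- dim(ss$pairs)
      cuts <- ss$cuts[!ss$cuts %in% drop]
      for (d in sort(drop, decreasing = TRUE)) cuts <- ifelse(cuts > d, cuts - 1L, cuts)
      return(parse_secondary_structure(pairs = pairs,
                                       sequence = paste(seqc, collapse = ""),
                                       cuts = cuts))
    }
    if (edit == "insert_loop_nt") {
      pos <- seg[1]  # insert right after the first residue of the element
      seqc <- append(seqc, rep(nt, n), after = pos)
      pairs <- shift_after(ss$pairs, pos, n)
      dim(pairs) <- dim(ss$pairs)
      cuts <- shift_after(ss$cuts, pos, n)
      return(parse_secondary_structure(pairs = pairs,
                                       sequence = paste(seqc, collapse = ""),
                                       cuts = cuts))
    }
    # insert_stem
    if (is.null(offset)) offset <- length(seg) %/% 2
    pos <- seg[1] + offset - 1L  # insert after this residue
    stem_len <- 2L * n_bp + loop_len
    ins <- c(rep("G", n_bp), rep(nt, loop_len), rep("C", n_bp))
    seqc <- append(seqc, ins, after = pos)
    pairs <- shift_after(ss$pairs, pos, stem_len)
    dim(pairs) <- dim(ss$pairs)
    newpairs <- cbind(pos + seq_len(n_bp),
                      pos + stem_len + 1L - seq_len(n_bp))
    cuts <- shift_after(ss$cuts, pos, stem_len)
    return(parse_secondary_structure(pairs = rbind(pairs, newpairs),
                                     sequence = paste(seqc, collapse = ""),
                                     cuts = cuts))
  }
  stop("unknown edit: ", edit)
}
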