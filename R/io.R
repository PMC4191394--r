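# Versioned plain-text serialization of topologies and trajectories so the
# engine, the command-line interface and external tools consume identical
# inputs.  All residue and bead numbering is 1-based.

TOPOLOGY_FORMAT_VERSION <- 1L

#' Write / read a topology as text
#'
#' Self-describing tab-separated sections (`[beads]`, `[bonds]`, ...), one
#' header line per section, preceded by the format version and the
#' originating secondary structure, so a topology round-trips exactly.
#'
#' @param top A `toprna_topology`.
#' @param path Output file.
#' @export
write_topology <- function(top, path) {
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("# toprna topology format v%d (1-based numbering)",
    TOPOLOGY_FORMAT_VERSION)
  db <- write_dot_bracket(top$ss)
  w("sequence\t%s", db[1])
  w("structure\t%s", db[2])
  w("cuts\t%s", paste(top$ss$cuts, collapse = " "))
  w("eps_stack\t%g", top$params$eps_stack)
  sec <- function(name, d) {
    w("[%s]\t%d", name, nrow(d))
    if (nrow(d) > 0) {
      writeLines(paste(colnames(d), collapse = "\t"), con)
      utils::write.table(d, con, sep = "\t", row.names = FALSE,
                         col.names = FALSE, quote = FALSE)
    }
  }
  sec("beads", top$beads)
  sec("bonds", top$bonds)
  sec("angles", top$angles)
  sec("impropers", top$impropers)
  sec("dihedrals", top$dihedrals)
  if (!is.null(top$restraints)) sec("restraints", top$restraints)
  invisible(path)
}

#' @rdname write_topology
#' @param path File written by [write_topology()].
#' @return `read_topology` rebuilds the `toprna_topology` (from the embedded
#'   structure) and verifies the stored term counts.
#' @export
read_topology <- function(path) {
  ln <- readLines(path)
  get1 <- function(key) {
    h <- grep(paste0("^", key, "\t"), ln, value = TRUE)[1]
    sub(paste0("^", key, "\t"), "", h)
  }
  seqc <- get1("sequence")
  struct <- get1("structure")
  cuts <- suppressWarnings(as.integer(strsplit(get1("cuts"), " ")[[1]]))
  cuts <- cuts[!is.na(cuts)]
  eps_stack <- as.numeric(get1("eps_stack"))
  ss <- parse_secondary_structure(c(seqc, struct), cuts = cuts)
  top <- build_topology(ss, toprna_params(eps_stack = eps_stack))
  counts <- regmatches(ln, regexec("^\\[(\\w+)\\]\t(\\d+)$", ln))
  counts <- counts[vapply(counts, length, 0L) == 3]
  for (m in counts) {
    nm <- m[2]; k <- as.integer(m[3])
    have <- switch(nm, beads = nrow(top$beads), bonds = nrow(top$bonds),
                   angles = nrow(top$angles),
                   impropers = nrow(top$impropers),
                   dihedrals = nrow(top$dihedrals), restraints = NA_integer_,
                   NA_integer_)
    if (!is.na(have) && have != k) {
      stop("topology file is inconsistent: ", nm, " count ", k,
           " vs rebuilt ", have)
    }
  }
  # restraints are data, not derivable: reread them
  ri <- grep("^\\[restraints\\]", ln)
  if (length(ri) == 1) {
    k <- as.integer(sub("^\\[restraints\\]\t", "", ln[ri]))
    if (k > 0) {
      hdr <- strsplit(ln[ri + 1], "\t")[[1]]
      body <- utils::read.table(text = ln[(ri + 2):(ri + 1 + k)], sep = "\t",
                                col.names = hdr, stringsAsFactors = FALSE)
      class(body) <- c("toprna_restraints", "data.frame")
      top <- attach_restraints(top, body)
    }
  }
  top
}

#' Write / read an ensemble's snapshots as TSV
#'
#' One row per bead per snapshot (`snapshot`, `bead`, `x`, `y`, `z`), plus a
#' companion `<path>.meta.tsv` with per-snapshot step, replica and potential
#' energy.  Coordinates are in Angstrom.
#'
#' @param ens A `toprna_ensemble`.
#' @param path Output TSV path.
#' @export
write_ensemble_tsv <- function(ens, path) {
  n <- ens$n_snapshots; nb <- dim(ens$coords)[2]
  flat <- data.frame(
    snapshot = rep(seq_len(n), each = nb),
    bead = rep(seq_len(nb), n),
    x = round(as.vector(t(ens$coords[, , 1])), 4),
    y = round(as.vector(t(ens$coords[, , 2])), 4),
    z = round(as.vector(t(ens$coords[, , 3])), 4))
  utils::write.table(flat, path, sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(ens$meta, paste0(path, ".meta.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_ensemble_tsv
#' @param top The `toprna_topology` the snapshots belong to.
#' @return `read_ensemble_tsv` returns a `toprna_ensemble` (protocol metadata
#'   reduced to what the files record).
#' @export
read_ensemble_tsv <- function(path, top) {
  flat <- utils::read.table(path, header = TRUE, sep = "\t")
  meta_path <- paste0(path, ".meta.tsv")
  meta <- if (file.exists(meta_path)) {
    utils::read.table(meta_path, header = TRUE, sep = "\t")
  } else NULL
  nb <- max(flat$bead)
  if (nb != top$n_beads) stop("bead count does not match topology")
  snaps <- sort(unique(flat$snapshot))
  arr <- array(NA_real_, c(length(snaps), nb, 3))
  o <- order(flat$snapshot, flat$bead)
  flat <- flat[o, ]
  arr[, , 1] <- matrix(flat$x, length(snaps), nb, byrow = TRUE)
  arr[, , 2] <- matrix(flat$y, length(snaps), nb, byrow = TRUE)
  arr[, , 3] <- matrix(flat$z, length(snaps), nb, byrow = TRUE)
  if (is.null(meta)) {
    meta <- data.frame(step = snaps, replica = 1L, epot = NA_real_)
  }
  proto <- simulation_protocol(total_steps = max(meta$step, 2000),
                               n_replicas = 1, equilibration_steps = 0)
  structure(list(coords = arr, topology = top, protocol = proto, meta = meta,
                 n_snapshots = length(snaps), exchange_attempts = 0,
                 exchange_accepts = 0,
                 kinetic_temperatures = proto$temperatures),
            class = "toprna_ensemble")
}
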