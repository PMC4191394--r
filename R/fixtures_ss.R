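# Canonical tRNA secondary structures used throughout the package.
# Numbering is 1-based and sequential (76 nt for the wild-type cloverleaf).

.trna_wt_seq <- paste0(
  "GCGGAUUUAGCUCAGUUGGGAGAGCGCCAGACUGAAGAUCUGGAGGUCCUGUGUUCGAUCC",
  "ACAGAAUUCGCACCA")
.trna_wt_db <- paste0(
  "(((((((..((((........)))).(((((.......)))))",  # A-stem, A/D, D-arm, AC-arm
  ".....",                                        # V-loop (44-48)
  "(((((.......)))))",                            # T-arm (49-65)
  ")))))))",                                      # A-stem 3' strand (66-72)
  "....")                                         # ACCA tail (73-76)

#' Built-in tRNA secondary-structure fixtures
#'
#' Returns the phenylalanine-tRNA cloverleaf (`"wt"`, 76 nt, 21 pairs) or one
#' of the variants studied with it, all constructed by editing the wild type
#' with [apply_variant()]:
#' \describe{
#'   \item{`wt`}{Class I cloverleaf: 7-bp A-stem, 4-bp D-stem, 5-bp AC-stem,
#'     5-bp T-stem, 2-nt A/D-loop, 5-nt V-loop, ACCA 3' tail.}
#'   \item{`cut_ad`}{backbone severed between U8(S) and A9(P).}
#'   \item{`cut_v`}{backbone severed between G46(S) and U47(P).}
#'   \item{`vl4`, `vl7`, `vl9`, `vl11`}{V-loop resized to 4/7/9/11 nt.}
#'   \item{`adl3`, `adl5`}{A/D-loop lengthened to 3/5 nt.}
#'   \item{`vs`}{Class II variant: a 4-bp V-stem hairpin inserted in the
#'     V-loop plus the G26-U44 pair extending the AC-stem.}
#'   \item{`vs_nogu`}{`vs` without the G26-U44 pair.}
#' }
#'
#' @param name Fixture name (see above).
#' @return A `toprna_ss`.
#' @export
trna_fixture <- function(name = c("wt", "cut_ad", "cut_v", "vl4", "vl7",
                                  "vl9", "vl11", "adl3", "adl5", "vs",
                                  "vs_nogu")) {
  name <- match.arg(name)
  wt <- parse_secondary_structure(c(.trna_wt_seq, .trna_wt_db))
  switch(name,
    wt = wt,
    cut_ad = apply_variant(wt, "cut", at = 8),
    cut_v = apply_variant(wt, "cut", at = 46),
    vl4 = apply_variant(wt, "delete_loop_nt", element = "V-loop", n = 1),
    vl7 = apply_variant(wt, "insert_loop_nt", element = "V-loop", n = 2),
    vl9 = apply_variant(wt, "insert_loop_nt", element = "V-loop", n = 4),
    vl11 = apply_variant(wt, "insert_loop_nt", element = "V-loop", n = 6),
    adl3 = apply_variant(wt, "insert_loop_nt", element = "A/D-loop", n = 1),
    adl5 = apply_variant(wt, "insert_loop_nt", element = "A/D-loop", n = 3),
    vs = {
      x <- apply_variant(wt, "insert_stem", element = "V-loop",
                         n_bp = 4, loop_len = 4, offset = 2)
      apply_variant(x, "toggle_pair", i = 26, j = 44)
    },
    vs_nogu = apply_variant(wt, "insert_stem", element = "V-loop",
                            n_bp = 4, loop_len = 4, offset = 2)
  )
}

#' Read or write dot-bracket fixture files
#'
#' Plain-text format: line 1 sequence, line 2 dot-bracket structure, optional
#' line 3 `cuts: i1 i2 ...` (backbone severed after those residues; 1-based
#' numbering).
#'
#' @param path File path.
#' @param ss A `toprna_ss` (for writing).
#' @return `read_dot_bracket_file` returns a `toprna_ss`.
#' @export
read_dot_bracket_file <- function(path) {
  ln <- readLines(path)
  ln <- ln[!grepl("^#", ln)]
  ln <- trimws(ln[nzchar(trimws(ln))])
  cuts <- integer()
  if (length(ln) >= 3 && grepl("^cuts:", ln[3])) {
    cuts <- as.integer(strsplit(trimws(sub("^cuts:", "", ln[3])), "\\s+")[[1]])
  }
  parse_secondary_structure(ln[1:2], cuts = cuts)
}

#' @rdname read_dot_bracket_file
#' @export
write_dot_bracket_file <- function(ss, path) {
  ln <- write_dot_bracket(ss)
  if (length(ss$cuts)) ln <- c(ln, paste("cuts:", paste(ss$cuts, collapse = " ")))
  writeLines(ln, path)
  invisible(path)
}
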