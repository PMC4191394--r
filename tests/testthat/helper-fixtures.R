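# Shared fixtures for the test suite.  Everything is generated in code;
# heavier objects are built once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- force(expr)
  .fixture_env[[name]]
}

# a two-strand duplex: fully paired chain with a backbone cut between strands
duplex_ss <- function(n_bp = 10) {
  parse_secondary_structure(
    c(paste(rep(c("G", "C"), c(n_bp, n_bp)), collapse = ""),
      paste(c(rep("(", n_bp), rep(")", n_bp)), collapse = "")),
    cuts = n_bp)
}

duplex_topology <- function(n_bp = 10) build_topology(duplex_ss(n_bp))

# the toy two-way junction: two helices separated by a 2-nt bulge on one
# strand ("2-nt bulge" motif)
bulge_ss <- function() {
  #  strand: 5'-((((..((((    ))))))))-3' hairpin closed with a tetraloop
  parse_secondary_structure(c(
    "GGGGAAGGGGUUUUCCCCCCCC",
    "((((..((((....))))))))"))
}

wt_reference <- function() cached("wt_ref", build_reference_trna())

wt_topology <- function() cached("wt_top", build_topology(trna_fixture("wt")))

# a short but real WT replica-exchange ensemble shared across analysis tests
wt_short_ensemble <- function() {
  cached("wt_ens", {
    proto <- simulation_protocol(total_steps = 1e5, snapshot_interval = 500,
                                 equilibration_steps = 1e4, seed = 42)
    run_replica_exchange(wt_topology(), proto,
                         initial = wt_reference()$coords)
  })
}

# minimal hand-built topology: two P beads joined by one harmonic bond
dimer_topology <- function(k = 5, r0 = 5) {
  p <- toprna_params()
  beads <- data.frame(kind = "P", residue = c(1L, 2L), radius = 2.7,
                      eps = 0.01, mass = unname(p$mass["P"]),
                      attract = FALSE)
  structure(list(
    ss = NULL, params = p, n_beads = 2L, beads = beads,
    m_beads = data.frame(bead = integer(), i = integer(), j = integer()),
    bonds = data.frame(i = 1L, j = 2L, r0 = r0, k = k, type = "PS"),
    angles = data.frame(i = integer(), j = integer(), k = integer(),
                        th0 = numeric(), kth = numeric()),
    impropers = data.frame(i = integer(), j = integer(), k = integer(),
                           l = integer(), phi0 = numeric(),
                           kimp = numeric()),
    dihedrals = data.frame(i = integer(), j = integer(), k = integer(),
                           l = integer(), phi0 = numeric(),
                           kdih = numeric()),
    strand_breaks = integer(), restraints = NULL),
    class = "toprna_topology")
}

# paired WT / cut-A/D-loop replica-exchange runs used by the directional
# acceptance checks (matched protocol and seed)
acceptance_paired_runs <- function() {
  cached("paired_runs", {
    one <- function(name) {
      top <- build_topology(trna_fixture(name))
      proto <- simulation_protocol(total_steps = 4e5,
                                   snapshot_interval = 500,
                                   equilibration_steps = 4e4, seed = 7)
      run_replica_exchange(top, proto)
    }
    list(wt = one("wt"), cut = one("cut_ad"))
  })
}
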