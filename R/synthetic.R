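#' Synthetic ensembles with known ground truth
#'
#' Generators used to validate the estimators against planted statistics:
#'
#' * `independent_angles`: `n` Euler triples per stream, each angle uniform
#'   over its range and independent across streams (true MI = 0, 9D/3D
#'   coverage ratio -> 1).
#' * `correlated_contacts`: paired Bernoulli contact streams with marginal
#'   probability `p` and planted cooperativity `C` (joint probability
#'   `C * p^2`), plus `n_independent` extra independent streams at `p`.
#' * `jittered_reference`: a `toprna_ensemble` whose snapshots are a
#'   reference structure with i.i.d. Gaussian noise of width `sigma` added to
#'   every bead coordinate.
#'
#' @param spec A list naming the generator and its parameters:
#'   `list(generator = "independent_angles", n, n_streams = 2)`,
#'   `list(generator = "correlated_contacts", n, p, C, n_independent = 0)`,
#'   or `list(generator = "jittered_reference", reference, n, sigma)`.
#' @param seed Integer seed.
#' @return For `independent_angles`: list of `n x 3` angle matrices.  For
#'   `correlated_contacts`: logical matrix (`n` rows; columns `X`, `Y`, then
#'   the independent streams).  For `jittered_reference`: a
#'   `toprna_ensemble`.
#' @export
make_synthetic_ensembles <- function(spec, seed = 1) {
  oseed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(oseed)) assign(".Random.seed", oseed,
                                      envir = globalenv()), add = TRUE)
  set.seed(seed)
  gen <- spec$generator
  if (is.null(gen)) stop("spec must name a generator")
  if (gen == "independent_angles") {
    n <- spec$n
    k <- if (is.null(spec$n_streams)) 2L else spec$n_streams
    return(lapply(seq_len(k), function(s) {
      cbind(alpha = stats::runif(n, 0, 360),
            beta = stats::runif(n, 0, 180),
            gamma = stats::runif(n, 0, 360))
    }))
  }
  if (gen == "correlated_contacts") {
    n <- spec$n; p <- spec$p
    C <- if (is.null(spec$C)) 1 else spec$C
    p11 <- C * p^2
    if (p11 > min(p, 1) + 1e-9 || p11 < max(0, 2 * p - 1) - 1e-9) {
      stop("infeasible (p, C) combination")
    }
    p11 <- min(p11, p)
    p10 <- max(0, p - p11)
    u <- stats::runif(n)
    x <- u < p11 | (u >= p11 & u < p11 + p10)
    y <- u < p11 | (u >= p11 + p10 & u < p11 + 2 * p10)
    out <- cbind(X = x, Y = y)
    ni <- if (is.null(spec$n_independent)) 0L else spec$n_independent
    if (ni > 0) {
      extra <- matrix(stats::runif(n * ni) < p, n, ni)
      colnames(extra) <- paste0("I", seq_len(ni))
      out <- cbind(out, extra)
    }
    return(out)
  }
  if (gen == "jittered_reference") {
    ref <- spec$reference
    stopifnot(inherits(ref, "toprna_reference"))
    n <- spec$n; sigma <- spec$sigma
    nb <- nrow(ref$coords)
    arr <- array(NA_real_, c(n, nb, 3))
    for (s in seq_len(n)) {
      arr[s, , ] <- ref$coords + matrix(stats::rnorm(3 * nb, sd = sigma),
                                        nb, 3)
    }
    proto <- simulation_protocol(total_steps = n * 2000, n_replicas = 1,
                                 equilibration_steps = 0, seed = seed)
    return(structure(list(
      coords = arr, topology = ref$topology, protocol = proto,
      meta = data.frame(step = seq_len(n) * 2000, replica = 1L,
                        epot = NA_real_),
      n_snapshots = n, exchange_attempts = 0, exchange_accepts = 0,
      kinetic_temperatures = proto$temperatures),
      class = "toprna_ensemble"))
  }
  stop("unknown generator: ", gen)
}
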