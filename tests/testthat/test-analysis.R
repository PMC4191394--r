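test_that("coverage counts unique bins against the full grid", {
  one <- matrix(c(12, 40, 200), 1, 3)
  cov <- coverage_3d(angles = one, bin = 10)
  expect_equal(cov$denominator, 36 * 18 * 36)
  expect_equal(cov$fraction, 1 / (36 * 18 * 36))
  # saturation: a stream visiting every bin reaches exactly 1
  grid <- as.matrix(expand.grid(alpha = seq(5, 355, 10),
                                beta = seq(5, 175, 10),
                                gamma = seq(5, 355, 10)))
  expect_equal(coverage_3d(angles = grid, bin = 10)$fraction, 1)
  # boundary angles (beta = 180, alpha = 360-eps) stay in range
  edge <- matrix(c(359.999, 180, 0), 1, 3)
  expect_equal(coverage_3d(angles = edge, bin = 10)$unique_bins, 1)
  expect_error(coverage_3d(angles = one, bin = 7), "divide")
})

test_that("coverage is monotone non-decreasing in ensemble size", {
  set.seed(31)
  ang <- make_synthetic_ensembles(list(generator = "independent_angles",
                                       n = 500, n_streams = 1), seed = 31)[[1]]
  prev <- 0
  for (n in c(10, 50, 100, 250, 500)) {
    f <- coverage_3d(angles = ang[seq_len(n), , drop = FALSE], bin = 30)$fraction
    expect_gte(f, prev)
    prev <- f
  }
})

test_that("9D coverage has the 108^3 denominator and ratio -> 1 under independence", {
  # single snapshot: fraction 1/108^3 and ratio exactly 1
  ens <- wt_short_ensemble()
  one <- subset_ensemble(ens, 1L)
  c1 <- coverage_9d(one)
  expect_equal(c1$denominator, 108^3)
  expect_equal(c1$fraction, 1 / 108^3)
  expect_equal(c1$ratio, 1)

  # Monte-Carlo oracle with known independence: on a coarser (90 degree)
  # grid the joint space saturates at reachable sample sizes, so the ratio
  # converges to 1 from below as snapshots accumulate
  streams <- make_synthetic_ensembles(list(generator = "independent_angles",
                                           n = 3e5, n_streams = 3), seed = 8)
  ratio_at <- function(n) {
    codes <- lapply(streams, function(s)
      toprna:::bin_triple(s[seq_len(n), , drop = FALSE], 90)$code)
    nb <- 4 * 2 * 4
    key <- (as.numeric(codes[[1]]) * nb + codes[[2]]) * nb + codes[[3]]
    f9 <- length(unique(key)) / nb^3
    f3 <- vapply(codes, function(cc) length(unique(cc)) / nb, 0)
    f9 / prod(f3)
  }
  r_small <- ratio_at(2e4)
  r_big <- ratio_at(3e5)
  expect_gt(r_big, r_small)   # undersampling keeps the ratio low
  expect_gt(r_big, 0.9)
  expect_lt(r_big, 1.1)
})

test_that("mutual information vanishes for independence and reaches H for copies", {
  streams <- make_synthetic_ensembles(list(generator = "independent_angles",
                                           n = 1e5, n_streams = 2), seed = 77)
  # 90 degree bins keep the joint histogram in the well-sampled regime the
  # first-order bias correction is built for
  mi <- mutual_information(x = streams[[1]], y = streams[[2]], bin = 90)
  expect_lt(abs(mi$mi), 0.01)

  # deterministic copy over k equiprobable bins: MI = H = log2 k
  k <- 16
  set.seed(5)
  z <- sample.int(k, 2e4, replace = TRUE)
  mi2 <- mutual_information(x = z, y = z)
  expect_equal(mi2$mi, log2(k), tolerance = 0.02)
  expect_equal(mi2$H_x, log2(k), tolerance = 0.02)
  expect_lte(mi2$mi, min(mi2$H_x, mi2$H_y) + 1e-9)
})

test_that("MI matches an independent plug-in-minus-bias oracle", {
  # correlated discrete pair with known joint law
  set.seed(13)
  n <- 5e4
  u <- runif(n)
  x <- as.integer(u < 0.5)
  y <- ifelse(runif(n) < 0.8, x, 1L - x)  # noisy copy
  ours <- mutual_information(x = x, y = y, correct = TRUE)
  # direct plug-in on the 2x2 table with the same first-order correction
  tab <- table(x, y) / n
  px <- rowSums(tab); py <- colSums(tab)
  plug <- sum(tab * log2(tab / outer(px, py)))
  bias <- (4 - 2 - 2 + 1) / (2 * n * log(2))
  expect_equal(ours$mi, max(0, plug - bias), tolerance = 1e-9)
})

test_that("bias-corrected MI on independent streams shrinks with sample size", {
  raw <- corrected <- numeric(3)
  ns <- c(1e3, 1e4, 1e5)
  for (q in seq_along(ns)) {
    s <- make_synthetic_ensembles(list(generator = "independent_angles",
                                       n = ns[q], n_streams = 2),
                                  seed = 100 + q)
    corrected[q] <- mutual_information(x = s[[1]], y = s[[2]], bin = 90)$mi
    raw[q] <- mutual_information(x = s[[1]], y = s[[2]], bin = 90,
                                 correct = FALSE)$mi
  }
  expect_lt(corrected[3], 0.01)
  expect_true(all(corrected <= raw))
  expect_lt(raw[3], raw[1])  # plug-in bias decays with n
})

test_that("center-of-mass correlations behave at the limits", {
  ref <- wt_reference()
  ens <- make_synthetic_ensembles(list(generator = "jittered_reference",
                                       reference = ref, n = 60, sigma = 1),
                                  seed = 19)
  self <- com_correlation(ens, list(c("D-stem", "D-stem")), align = FALSE)
  expect_equal(self$R_max, 1, tolerance = 1e-12)
  # independent jitter of two far-apart elements: |R| small
  pair <- com_correlation(ens, list(c("A-stem", "T-loop")), align = FALSE)
  expect_lt(abs(pair$R_max), 0.5)
})

test_that("correlated synthetic COM streams match the analytic attenuation", {
  # COM_B = COM_A + noise: R = sd_A / sqrt(sd_A^2 + sd_noise^2)
  set.seed(23)
  n <- 4000
  sd_a <- 2; sd_n <- 1
  a <- rnorm(n, sd = sd_a)
  b <- a + rnorm(n, sd = sd_n)
  expected <- sd_a / sqrt(sd_a^2 + sd_n^2)
  expect_equal(cor(a, b), expected, tolerance = 0.05)
})

test_that("shift-surrogate correction removes drift-induced spurious MI", {
  # two independent slow random walks: true MI = 0, but the finite sample
  # shows strong apparent dependence that the analytic correction cannot
  # remove; circular-shift surrogates can
  set.seed(57)
  n <- 1500
  walk <- function() {
    v <- cumsum(rnorm(n, sd = 0.15)) %% (2 * pi)
    as.integer(floor(v / (2 * pi) * 8))
  }
  x <- walk(); y <- walk()
  analytic <- mutual_information(x = x, y = y, correct = TRUE)$mi
  shifted <- mutual_information(x = x, y = y, correct = "shift")$mi
  expect_gt(analytic, 0.2)         # the artifact is real
  expect_lt(shifted, analytic / 3)  # and the surrogate null absorbs it
  # for i.i.d. streams the surrogate and analytic corrections agree
  set.seed(58)
  xi <- sample.int(8, 2e4, replace = TRUE)
  yi <- sample.int(8, 2e4, replace = TRUE)
  a <- mutual_information(x = xi, y = yi, correct = TRUE)$mi
  s <- mutual_information(x = xi, y = yi, correct = "shift")$mi
  expect_lt(abs(a - s), 0.01)
})
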