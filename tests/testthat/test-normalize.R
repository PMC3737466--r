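toy_spots <- function(M, A, array = "a1", block = 1, bio_rep = 1,
                      orientation = "forward", valid = TRUE) {
  data.frame(probe = sprintf("p%04d", seq_along(M)), array = array,
             block = block, bio_rep = bio_rep, orientation = orientation,
             ch1 = 2^(A + M / 2), ch2 = 2^(A - M / 2), valid = valid,
             stringsAsFactors = FALSE)
}

test_that("badly formed and non-positive spots are excluded", {
  sp <- toy_spots(rep(0.1, 10), rep(10, 10))
  sp$valid[c(3, 7)] <- FALSE
  expect_equal(nrow(filter_spots(sp)), 8)
  sp2 <- toy_spots(rep(0.1, 5), rep(10, 5))
  sp2$ch1[2] <- 0
  expect_equal(nrow(filter_spots(sp2)), 4)
  sp3 <- toy_spots(rep(0, 3), rep(10, 3), valid = FALSE)
  expect_error(filter_spots(sp3), "no usable spots")
})

test_that("filtering matches an exhaustive row count at a 1% flag rate", {
  set.seed(10)
  sp <- toy_spots(rnorm(10000), rnorm(10000, 10))
  sp$valid <- runif(10000) >= 0.01
  kept <- filter_spots(sp)
  expect_equal(nrow(kept), sum(sp$valid & sp$ch1 > 0 & sp$ch2 > 0))
})

test_that("M and A values follow their definitions", {
  sp <- spot_ma(toy_spots(c(1, -2), c(8, 12)))
  expect_equal(sp$M, c(1, -2))
  expect_equal(sp$A, c(8, 12))
})

test_that("loess normalization absorbs a constant log-ratio entirely", {
  sp <- spot_ma(toy_spots(rep(0.7, 200), seq(6, 14, length.out = 200)))
  out <- loess_normalize_array(sp)
  expect_equal(max(abs(out$M)), 0, tolerance = 1e-12)
})

test_that("loess normalization removes a smooth sinusoidal dye bias", {
  A <- seq(8, 12, length.out = 800)
  sp <- spot_ma(toy_spots(0.5 * sin(A), A))
  out <- loess_normalize_array(sp)
  expect_lt(max(abs(out$M)), 0.05)
  # dense brute-force local regression oracle: tricube-weighted local
  # linear fit at every point
  span <- 0.3
  fit_oracle <- vapply(seq_along(A), function(i) {
    d <- abs(A - A[i])
    h <- sort(d)[ceiling(span * length(A))]
    w <- pmax(0, 1 - (d / h)^3)^3
    f <- stats::lm(sp$M ~ A, weights = w)
    unname(stats::predict(f, data.frame(A = A[i])))
  }, numeric(1))
  expect_lt(max(abs((sp$M - out$M) - fit_oracle)), 0.02)
})

test_that("loess normalization refuses unusable input", {
  sp <- spot_ma(toy_spots(rnorm(50), rnorm(50, 10)))
  expect_error(loess_normalize_array(sp), "too few spots")
  sp2 <- spot_ma(toy_spots(rnorm(200), rnorm(200, 10)))
  sp2$M[1] <- NaN
  expect_error(loess_normalize_array(sp2), "non-finite")
})

test_that("block median centering zeroes every block median", {
  sp <- data.frame(M = c(1, 2, 3, 0.7), block = c(1, 1, 1, 2))
  out <- block_median_center(sp)
  expect_equal(out$M, c(-1, 0, 1, 0))
  set.seed(2)
  sp2 <- data.frame(M = rnorm(300), block = sample(1:5, 300, replace = TRUE))
  out2 <- block_median_center(sp2)
  meds <- tapply(out2$M, out2$block, median)
  expect_true(all(abs(meds) < 1e-12))
})

test_that("generator block offsets are visible before centering", {
  cfg <- generator_config(n_probes = 2000, n_blocks = 2, treatments = "t",
                          frac_regulated = 0, noise_sd_log2 = 0.1,
                          dye_bias_coefs = c(0, 0, 0),
                          block_offsets = c(0.3, -0.3), seed = 15)
  sim <- simulate_experiment(cfg)
  sp <- spot_ma(filter_spots(sim$spots$t))
  a1 <- sp[sp$array == sp$array[1], ]
  meds <- tapply(a1$M, a1$block, median)
  expect_equal(as.numeric(meds), c(0.3, -0.3),
               tolerance = 4 * 0.1 / sqrt(1000))
})

test_that("dye-swap averaging flips the swapped sign and averages", {
  sp <- data.frame(probe = c("g1", "g1"), bio_rep = 1,
                   orientation = c("forward", "swapped"),
                   M = c(1.0, -1.0), A = c(10, 10))
  out <- average_dye_swap(sp)
  expect_equal(out$M, 1.0)
  expect_equal(out$n_spots, 2L)
  sp$M <- c(1.2, -0.8)
  expect_equal(average_dye_swap(sp)$M, 1.0)
})

test_that("dye-swap averaging equals a brute-force recomputation", {
  sim <- quick_sim(33, n_probes = 300)
  sp <- spot_ma(filter_spots(sim$spots$t))
  out <- average_dye_swap(sp)
  m_tc <- ifelse(sp$orientation == "swapped", -sp$M, sp$M)
  for (i in sample(nrow(out), 25)) {
    sel <- sp$probe == out$probe[i] & sp$bio_rep == out$bio_rep[i]
    expect_equal(out$M[i], mean(m_tc[sel]))
    expect_equal(out$n_spots[i], sum(sel))
  }
  # probes absent from one member of the pair keep the available spot
  expect_true(any(out$n_spots == 1) || all(sp$valid))
})

test_that("the normalization chain leaves per-block medians at zero", {
  sim <- quick_sim(12, n_probes = 400)
  sp <- spot_ma(filter_spots(sim$spots$t))
  parts <- lapply(split(sp, sp$array), function(a)
    block_median_center(loess_normalize_array(a)))
  for (a in parts) {
    meds <- tapply(a$M, a$block, median)
    expect_true(all(abs(meds) < 1e-9))
  }
})

test_that("normalization is idempotent where the smoother is exact", {
  # constant and exactly linear trends are reproduced exactly by the
  # smoother, so a second pass changes nothing
  A <- seq(6, 14, length.out = 300)
  for (M in list(rep(0.4, 300), 0.1 * A - 1)) {
    sp <- spot_ma(toy_spots(M, A))
    p1 <- block_median_center(loess_normalize_array(sp))
    p2 <- block_median_center(loess_normalize_array(p1))
    expect_lt(max(abs(p2$M - p1$M)), 1e-6)
  }
})

test_that("re-normalizing noisy data moves log-ratios only marginally", {
  sim <- quick_sim(44, n_probes = 500)
  sp <- spot_ma(filter_spots(sim$spots$t))
  a1 <- sp[sp$array == sp$array[1], ]
  p1 <- block_median_center(loess_normalize_array(a1))
  p2 <- block_median_center(loess_normalize_array(p1))
  expect_lt(max(abs(p2$M - p1$M)), 0.05)
})

test_that("the full chain removes the generator's quadratic dye bias", {
  cfg <- generator_config(n_probes = 2000, treatments = "t",
                          frac_regulated = 0.05, effect_size_log2 = 2,
                          noise_sd_log2 = 0.2, seed = 18)
  sim <- simulate_experiment(cfg)
  norm <- normalize_comparison(sim$spots$t)
  nc_probes <- sim$truth$probe[sim$truth$class == "NC"]
  nc <- rownames(norm$M) %in% nc_probes & norm$signal
  expect_lt(abs(mean(norm$M[nc, ])), 0.02)
})

test_that("spot tables survive a TSV round trip", {
  sim <- quick_sim(2, n_probes = 120)
  f <- tempfile(fileext = ".tsv")
  write_spot_table(sim$spots$t, f)
  back <- read_spot_table(f)
  expect_equal(back$ch1, sim$spots$t$ch1)
  expect_identical(back$valid, sim$spots$t$valid)
  expect_identical(back$probe, sim$spots$t$probe)
})
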