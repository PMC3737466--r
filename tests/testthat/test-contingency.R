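rand_classes <- function(n, p_up = 0.05, p_down = 0.05, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  setNames(sample(c("UP", "DOWN", "NC"), n, replace = TRUE,
                  prob = c(p_up, p_down, 1 - p_up - p_down)),
           sprintf("g%05d", seq_len(n)))
}

test_that("observed counts equal to the independence product give a null table", {
  rowm <- c(100, 800, 100)
  colm <- c(50, 900, 50)
  obs <- outer(rowm, colm) / 1000
  dimnames(obs) <- list(c("UP", "NC", "DOWN"), c("UP", "NC", "DOWN"))
  an <- contingency_from_counts(obs)
  expect_true(all(abs(an$ratio - 1) < 1e-12))
  expect_equal(an$chi2, 0)
  expect_equal(an$p, 1)
  expect_equal(sum(an$theoretical), an$n, tolerance = 1e-6)
})

test_that("chi-squared and p match a cell-enumeration and integration oracle", {
  set.seed(17)
  for (rep in 1:5) {
    obs <- matrix(rmultinom(1, 200, runif(9, 0.02, 0.2)), 3, 3,
                  dimnames = list(c("UP", "NC", "DOWN"),
                                  c("UP", "NC", "DOWN")))
    an <- suppressWarnings(contingency_from_counts(obs))
    orc <- oracle_contingency(obs)
    expect_equal(an$chi2, orc$chi2, tolerance = 1e-12)
    expect_equal(an$p, orc$p, tolerance = 1e-8)
    expect_equal(an$df, 4L)
  }
})

test_that("build_contingency restricts to common probes and is symmetric", {
  v1 <- rand_classes(4000, seed = 23)
  v2 <- rand_classes(5000, seed = 24)
  an <- build_contingency(v1, v2)
  expect_equal(an$n, 4000)
  an_t <- build_contingency(v2, v1)
  expect_equal(an$chi2, an_t$chi2, tolerance = 1e-12)
  expect_identical(an$observed, t(an_t$observed))
  expect_error(build_contingency(v1[1:3],
                                 setNames(c("UP", "NC"), c("x1", "x2"))),
               "no common probes")
})

test_that("enrichment ratios are invariant to duplicating every probe", {
  v1 <- rand_classes(2000, seed = 41)
  v2 <- rand_classes(2000, seed = 42)
  an1 <- suppressWarnings(build_contingency(v1, v2))
  an2 <- suppressWarnings(contingency_from_counts(an1$observed * 2))
  expect_equal(an1$ratio, an2$ratio, tolerance = 1e-12)
})

test_that("zero marginals reduce degrees of freedom and mark ratios NA", {
  obs <- matrix(c(10, 0, 5, 20, 0, 5, 5, 0, 5), 3, 3, byrow = TRUE,
                dimnames = list(c("UP", "NC", "DOWN"),
                                c("UP", "NC", "DOWN")))
  an <- suppressWarnings(contingency_from_counts(obs))
  expect_true(an$degenerate)
  expect_equal(an$df, 2L)
  expect_true(all(is.na(an$ratio[, 2])))
})

test_that("permutation of one class vector yields near-uniform p-values", {
  v1 <- rand_classes(5000, seed = 61)
  base <- rand_classes(5000, seed = 62)
  set.seed(63)
  ps <- replicate(500, suppressWarnings(
    build_contingency(v1, setNames(sample(unname(base)), names(base)))$p))
  # ties in p-values are expected for discrete tables; the KS test is
  # used as an approximate uniformity check
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("ratios render at the published display precision", {
  expect_identical(format_ratio(229, 21.827), "10.5")
  expect_identical(format_ratio(154, 26.518), "5.81")
  expect_identical(format_ratio(0, 10.33), "0")
  expect_identical(format_ratio(1249, 1564.77), "0.80")
  expect_identical(format_ratio(5, 0), "NA")
  rep <- enrichment_report(contingency_from_counts(
    matrix(c(20, 5, 5, 70), 2, 2, dimnames = list(c("UP", "NC"),
                                                  c("UP", "NC")))))
  expect_identical(rep["UP|theoretical", "UP"], "(6.25)")
  expect_identical(rep["UP|ratio", "UP"], "3.20")
  expect_identical(rep["Total", "Total"], "100")
})

test_that("p-values below machine tail are reported with the < 2.2e-16 tag", {
  v <- rand_classes(20000, seed = 71)
  an <- build_contingency(v, v)  # perfect dependence
  expect_identical(an$p_string, "< 2.2e-16")
})

test_that("triple overlap of identical vectors matches the closed form", {
  v <- setNames(rep(c("UP", "NC"), c(100, 900)), sprintf("g%04d", 1:1000))
  to <- triple_overlap(v, v, v)
  expect_equal(to$observed, 100L)
  expect_equal(to$expected, 1000 * 0.1^3)
  expect_equal(to$fold, 100)
  expect_equal(sum(to$expected_array), 1000, tolerance = 1e-9)
})

test_that("triple overlap of shuffled vectors stays near independence", {
  v <- setNames(rep(c("UP", "NC", "DOWN"), c(100, 800, 100)),
                sprintf("g%04d", 1:1000))
  set.seed(5)
  devs <- replicate(20, {
    sh <- function() setNames(sample(unname(v)), names(v))
    to <- triple_overlap(sh(), sh(), sh())
    (to$observed - to$expected) / sqrt(to$expected)
  })
  expect_lt(abs(mean(devs)), 3 / sqrt(20) * 2)
  expect_true(all(abs(devs) < 5))
})

test_that("triple overlap agrees with a brute-force joint count", {
  sim <- quick_sim(83, treatments = c("a", "b", "c"), frac_shared = 1,
                   frac_regulated = 0.1)
  va <- truth_classes(sim$truth, "a")
  vb <- truth_classes(sim$truth, "b")
  vc <- truth_classes(sim$truth, "c")
  to <- triple_overlap(va, vb, vc)
  brute <- sum(va == "UP" & vb == "UP" & vc == "UP")
  expect_equal(to$observed, brute)
  expect_gt(to$fold, 10)
})

test_that("venn regions partition the union", {
  vA <- c(g1 = "UP", g2 = "UP")
  vB <- c(g2 = "UP", g3 = "UP")
  expect_equal(venn_counts(list(A = vA, B = vB), "UP"),
               c(A = 1L, B = 1L, AB = 1L))
  vC <- c(g9 = "UP")
  out <- venn_counts(list(A = vA, B = vB, C = vC), "UP")
  expect_equal(out[["C"]], 1L)
  expect_equal(out[["ABC"]], 0L)
  expect_error(venn_counts(list(vA, vB, vC, vA)), "2 or 3")
})

test_that("venn counts equal brute-force set algebra on random sets", {
  set.seed(9)
  mk <- function() setNames(sample(c("UP", "NC"), 200, TRUE, c(0.3, 0.7)),
                            sprintf("g%03d", 1:200))
  vs <- list(A = mk(), B = mk(), C = mk())
  out <- venn_counts(vs, "UP")
  sets <- lapply(vs, function(v) names(v)[v == "UP"])
  in_abc <- length(Reduce(intersect, sets))
  a_only <- length(setdiff(sets$A, union(sets$B, sets$C)))
  ab_only <- length(setdiff(intersect(sets$A, sets$B), sets$C))
  expect_equal(out[["ABC"]], in_abc)
  expect_equal(out[["A"]], a_only)
  expect_equal(out[["AB"]], ab_only)
  expect_equal(sum(out), length(unique(unlist(sets))))
})

test_that("set overlap statistics follow the hypergeometric model", {
  so <- set_overlap(sprintf("g%02d", 1:10), sprintf("g%02d", 1:10), 100)
  expect_equal(so$observed, 10L)
  expect_equal(so$expected, 1)
  expect_lt(so$p, 1e-10)
  # pure counting, whatever the universe claims
  a <- sprintf("g%03d", 1:515)
  b <- c(sprintf("g%03d", 1:281), sprintf("h%03d", 1:300))
  expect_equal(set_overlap(a, b, 25000)$observed, 281L)
  expect_error(set_overlap(sprintf("g%d", 1:50), "g1", 10), "universe")
  # Monte-Carlo mean overlap
  set.seed(11)
  u <- sprintf("u%04d", 1:500)
  obs <- replicate(1000, set_overlap(sample(u, 40), sample(u, 60), 500)$observed)
  expected <- 40 * 60 / 500
  se <- sd(obs) / sqrt(1000)
  expect_lt(abs(mean(obs) - expected), 3 * se + 0.05)
})
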