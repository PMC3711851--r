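test_that("quantile normalization follows the mean-of-order-statistics
           definition including the tie rule", {
  m <- cbind(a = c(1, 2, 3), b = c(4, 5, 6))
  out <- quantile_normalize(m)
  expect_equal(unname(out[, 1]), c(2.5, 3.5, 4.5))
  expect_equal(unname(out[, 2]), c(2.5, 3.5, 4.5))

  ident <- cbind(c(1, 5, 9), c(1, 5, 9))
  expect_equal(quantile_normalize(ident), ident, ignore_attr = TRUE)

  # tie case: sorted-row means are (1.5, 2.5, 4.5); the tied 1s in column a
  # each get the mean of the rank-1 and rank-2 targets = 2
  tied <- cbind(a = c(1, 1, 3), b = c(2, 4, 6))
  out2 <- quantile_normalize(tied)
  expect_equal(unname(out2[, "a"]), c(2, 2, 4.5))
  expect_equal(unname(out2[, "b"]), c(1.5, 2.5, 4.5))

  # columns share an identical multiset afterwards (exact)
  r <- withr::with_seed(3, matrix(rexp(400), ncol = 4))
  nr <- quantile_normalize(r)
  for (j in 2:4) expect_equal(sort(nr[, 1]), sort(nr[, j]))
  expect_error(quantile_normalize(r[, 1, drop = FALSE]), "2 arrays")
})

test_that("percentile background subtraction floors at zero", {
  expect_equal(subtract_background(rep(7, 10)), rep(0, 10))
  x <- 1:100
  out <- subtract_background(x, 5)
  q5 <- quantile(x, 0.05, names = FALSE)
  expect_equal(out, pmax(x - q5, 0))
  expect_gte(mean(out == 0), 0.05)
  expect_equal(subtract_background(c(0, 2, 5), 0), c(0, 2, 5))
  expect_error(subtract_background(numeric(0)), "empty")
  expect_error(subtract_background(c(-1, 2)), ">= 0")
})

test_that("promoter score is the mean per-probe difference", {
  expect_equal(promoter_score(c(10, 20, 30)), 20)
  expect_equal(promoter_score(rep(0, 8)), 0)
})

test_that("enhancement test reproduces the exact signed-rank tail", {
  expect_equal(test_enhancement(1:10)$p, 2^-10)
  expect_equal(test_enhancement(5)$p, 0.5)
  # agreement with the reference implementation on tie-free data
  d <- withr::with_seed(6, rnorm(12, 0.4))
  expect_equal(test_enhancement(d)$p,
               wilcox.test(d, alternative = "greater")$p.value,
               tolerance = 1e-12)
  # symmetric differences give p near one half
  d_sym <- c(-3.5, -2.2, -1.1, 1.15, 2.25, 3.6)
  expect_lt(abs(test_enhancement(d_sym)$p - 0.5), 0.15)
  # zeros are dropped; all-zero input degenerates to p = 1
  expect_equal(test_enhancement(c(0, 0, 1, 2, 3))$p,
               test_enhancement(c(1, 2, 3))$p)
  expect_warning(res <- test_enhancement(rep(0, 4)), "zero")
  expect_equal(res$p, 1); expect_true(res$degenerate)
})

test_that("non-uniformity permutation test hits its bounds", {
  # constant differences: shuffle-invariant statistic, p = 1
  expect_equal(test_nonuniformity(rep(2, 12))$p, 1)
  # a sharp planted peak is essentially never beaten: a permutation matches
  # the observed window only by re-clustering the five peak values, which
  # has probability ~2e-4 per draw in a 30-probe region
  for (s in 1:5) {
    d <- c(rep(0, 12), rep(50, 5), rep(0, 13)) +
      withr::with_seed(s, rnorm(30, 0, 0.1))
    p <- test_nonuniformity(d, window = 5, B = 999, seed = s)$p
    expect_lte(p, 3 / 1000)
    expect_gte(p, 1 / 1000)
  }
  # permutation p always lies in [1/(B+1), 1]
  for (s in 1:10) {
    d <- withr::with_seed(100 + s, rnorm(15))
    p <- test_nonuniformity(d, B = 99, seed = s)$p
    expect_gte(p, 1 / 100); expect_lte(p, 1)
  }
  short <- test_nonuniformity(c(1, 2), window = 5)
  expect_equal(short$p, 1); expect_true(short$short_region)
  expect_error(test_nonuniformity(rnorm(10), B = 0), "B")
})

test_that("BH adjustment matches the brute-force step-up and the bound rule
           applies both gates", {
  res <- data.frame(score = c(20, 20, 20, 20),
                    p_comb = c(0.01, 0.02, 0.03, 0.04))
  out <- call_bound(res)
  expect_equal(out$q, rep(0.04, 4))
  expect_true(all(out$bound))

  set.seed(9)
  for (i in 1:200) {
    p <- runif(sample(3:40, 1))
    expect_equal(p.adjust(p, "BH"), bh_stepup(p), tolerance = 1e-12)
  }

  # score below 15 is never bound, however small q
  res2 <- data.frame(score = c(14.9, 15), p_comb = c(0.001, 0.001))
  out2 <- call_bound(res2)
  expect_false(out2$bound[1]); expect_true(out2$bound[2])

  res3 <- data.frame(score = rep(50, 5), p_comb = rep(1, 5))
  expect_false(any(call_bound(res3)$bound))
})

test_that("the full caller recovers planted binding on a small dataset", {
  # enough promoters that the BH step-up has resolution below q = 0.05
  g <- gen_chip(sim_chip_params(n_promoters = 150, seed = 41))
  res <- call_binding(g$signals, g$map, B = 999, seed = 42)
  expect_equal(res$promoter_id, g$truth$promoter_id)
  expect_equal(res$p_comb, pmax(res$p_enh, res$p_nonunif))
  tp <- sum(res$bound & g$truth$bound)
  expect_gte(tp / max(1, sum(g$truth$bound)), 0.8)
  expect_equal(sum(res$bound & !g$truth$bound), 0)
})

test_that("mismatched probe universes are rejected", {
  g <- gen_chip(sim_chip_params(n_promoters = 5, seed = 2))
  broken <- g$signals[-1, ]   # drop one probe from one array
  expect_error(call_binding(broken, g$map), "probe universe")
})
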