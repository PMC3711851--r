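# build a 2-group, 1-replicate matrix whose group means are given exactly
matrix_from_means <- function(mean_c, mean_hs, genes) {
  mat <- cbind(C.r1 = mean_c, HS.r1 = mean_hs)
  rownames(mat) <- genes
  colnames(mat) <- c("X.C.r1", "X.HS.r1")
  design <- data.frame(sample_id = colnames(mat), cell_type = "X",
                       condition = c("C", "HS"), replicate = 1L,
                       group = c("X.C", "X.HS"))
  list(mat = mat, design = design)
}

test_that("SLR reproduces the published worked-example arithmetic through
           the full compute_slr path", {
  w <- worked_slr_examples()
  for (ct in unique(w$contrast)) {
    sub <- w[w$contrast == ct, ]
    mm <- matrix_from_means(sub$mean_c, sub$mean_hs,
                            make.unique(sub$gene))
    calls <- call_expressed(mm$mat, mm$design, c(X.C = -Inf, X.HS = -Inf))
    tab <- compute_slr(mm$mat, mm$design, calls, c("X.C", "X.HS"))
    expect_equal(round_half_away(tab$slr, 2), sub$slr_published)
  }
})

test_that("genes below noise in both groups are not evaluated; one-sided
           cases keep their SLR with an nl flag", {
  mm <- matrix_from_means(c(9.18, 4.38, 3.1), c(11.65, 6.31, 3.2),
                          c("gHigh", "gNlC", "gNlBoth"))
  calls <- call_expressed(mm$mat, mm$design, c(X.C = 4.5, X.HS = 4.5))
  tab <- compute_slr(mm$mat, mm$design, calls, c("X.C", "X.HS"))
  expect_equal(tab$de_class, c("null", "null", "not_evaluated"))
  expect_true(tab$nl_c[2]); expect_false(tab$nl_hs[2])
  expect_equal(round_half_away(tab$slr[2], 2), 1.93)
  expect_true(is.na(tab$slr[3]))
  expect_error(compute_slr(mm$mat, mm$design, calls, c("X.C", "nope")),
               "unknown group")
})

test_that("classification partitions evaluated genes and finds far-tail
           genes with near-certain posterior", {
  slr <- withr::with_seed(5, c(rnorm(2700, 0, 0.3), rnorm(150, 1.5, 0.4),
                               rnorm(150, -1.5, 0.4), 6))
  res <- classify_slr(slr_table(slr), k_range = c(1, 5), seed = 2,
                      n_init = 3)
  cnt <- res$mixture$counts
  expect_equal(sum(cnt[c("up", "down", "null")]), length(slr))
  last <- nrow(res$table)
  expect_equal(res$table$de_class[last], "up")
  expect_gt(res$table$posterior_up[last], 0.999)
  # significant ranges: induced lower bound positive, equals the smallest
  # SLR among up-classed genes
  up_slr <- res$table$slr[res$table$de_class == "up"]
  expect_gt(res$mixture$range_up[1], 0)
  expect_equal(res$mixture$range_up[1], min(up_slr))
  down_slr <- res$table$slr[res$table$de_class == "down"]
  expect_lt(res$mixture$range_down[2], 0)
  expect_equal(res$mixture$range_down[2], max(down_slr))
})

test_that("degenerate or undersized SLR inputs are rejected", {
  expect_error(classify_slr(slr_table(rep(0.5, 500))), "identical")
  expect_error(classify_slr(slr_table(rnorm(50))), "at least 100")
})

test_that("raising every HS signal by a constant raises every SLR by that
           constant", {
  e <- gen_expression(sim_expr_params(n_genes = 500, seed = 6))
  thr <- setNames(c(-Inf, -Inf), unique(e$design$group))
  calls <- call_expressed(e$matrix, e$design, thr)
  tab1 <- compute_slr(e$matrix, e$design, calls, c("SC.C", "SC.HS"))
  m2 <- e$matrix
  hs_cols <- e$design$sample_id[e$design$condition == "HS"]
  m2[, hs_cols] <- m2[, hs_cols] + 0.7
  calls2 <- call_expressed(m2, e$design, thr)
  tab2 <- compute_slr(m2, e$design, calls2, c("SC.C", "SC.HS"))
  expect_equal(tab2$slr, tab1$slr + 0.7)
})

test_that("planted up/down fractions are recovered within the binomial 99%
           band on generator defaults", {
  e <- gen_expression(sim_expr_params(n_genes = 8000, seed = 27))
  mods <- fit_group_thresholds(e$matrix, e$design, seed = 3, n_init = 3)
  calls <- call_expressed(e$matrix, e$design, mods)
  tab <- compute_slr(e$matrix, e$design, calls, c("SC.C", "SC.HS"))
  res <- classify_slr(tab, seed = 3, n_init = 3)
  n_eval <- sum(res$mixture$counts[c("up", "down", "null")])
  # planted directional genes among evaluated genes
  tr <- e$truth[match(res$table$gene[res$table$de_class != "not_evaluated"],
                      e$truth$gene), ]
  for (cl in c("up", "down")) {
    planted <- sum(tr$de_class == cl)
    band <- qbinom(c(0.005, 0.995), n_eval,
                   planted / n_eval) + c(-1, 1) * 0.2 * planted
    expect_gte(res$mixture$counts[[cl]], band[1])
    expect_lte(res$mixture$counts[[cl]], band[2])
  }
})

test_that("slr_summary reports ranges and counts in report layout", {
  slr <- withr::with_seed(9, c(rnorm(1500, 0, 0.3), rnorm(120, 1.6, 0.3),
                               rnorm(120, -1.6, 0.3)))
  res <- classify_slr(slr_table(slr), seed = 1, n_init = 3)
  s <- slr_summary(res$mixture)
  expect_equal(s$class, c("induction", "repression"))
  expect_equal(s$n_genes,
               unname(as.integer(res$mixture$counts[c("up", "down")])))
  expect_true(s$slr_from[1] > 0 && s$slr_to[2] < 0)
})
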