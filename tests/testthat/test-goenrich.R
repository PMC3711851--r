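test_that("hypergeometric upper tail matches exhaustive enumeration", {
  # the frozen reference case: N = 10, K_term = 5, n = 5, k = 2
  expect_equal(hypergeom_upper(2, 5, 5, 10), 226 / 252, tolerance = 1e-12)
  expect_equal(hyper_upper_enum(2, 5, 5, 10), 226 / 252, tolerance = 1e-12)
  set.seed(4)
  for (i in 1:20) {
    N <- sample(4:11, 1); K <- sample(1:N, 1); n <- sample(1:N, 1)
    k <- sample(0:min(n, K), 1)
    expect_equal(hypergeom_upper(k, n, K, N), hyper_upper_enum(k, n, K, N),
                 tolerance = 1e-12)
  }
})

test_that("boundary cases and impossible counts behave as defined", {
  expect_equal(hypergeom_upper(0, 5, 5, 10), 1)
  expect_equal(hypergeom_upper(4, 4, 4, 4), 1)   # forced draw
  expect_error(hypergeom_upper(6, 5, 5, 10), "impossible")
  expect_error(hypergeom_upper(2, 12, 5, 10), "impossible")
})

flat_annotation <- function(term_genes, universe) {
  list(term_genes = term_genes,
       parents = setNames(rep(list(character(0)), length(term_genes)),
                          names(term_genes)),
       universe = universe)
}

test_that("with no DAG edges the conditional p equals the raw p", {
  uni <- sprintf("g%02d", 1:40)
  ann <- flat_annotation(list(A = uni[1:10], B = uni[5:20], C = uni[30:40]),
                         uni)
  res <- conditional_enrichment(uni[1:12], ann)
  expect_equal(res$p_conditional, res$p_raw)
})

test_that("a parent fully explained by a significant child is conditioned
           away", {
  uni <- sprintf("g%02d", 1:30)
  ann <- list(
    term_genes = list(child = uni[1:8], parent = character(0),
                      other = uni[15:24]),
    parents = list(child = "parent", parent = character(0),
                   other = character(0)),
    universe = uni
  )
  res <- conditional_enrichment(uni[1:8], ann, child_cutoff = 0.05)
  child_row <- res[res$term == "child", ]
  expect_true(child_row$significant)
  expect_equal(child_row$p_conditional, hypergeom_upper(8, 8, 8, 30))
  # parent is reported (raw overlap >= 1) but its conditional test has
  # nothing left once the significant child's genes are removed
  parent_row <- res[res$term == "parent", ]
  expect_equal(parent_row$k, 0)
  expect_equal(parent_row$p_conditional, 1)
  expect_false(parent_row$significant)
})

test_that("p values stay in (0, 1] and match brute-force recomputation on a
           small DAG", {
  set.seed(12)
  uni <- sprintf("g%03d", 1:50)
  for (rep_ in 1:10) {
    tg <- list(A = sample(uni, 12), B = sample(uni, 8), C = sample(uni, 10),
               P = sample(uni, 5), R = character(0))
    ann <- list(term_genes = tg,
                parents = list(A = "P", B = "P", C = "R", P = "R",
                               R = character(0)),
                universe = uni)
    query <- sample(uni, 15)
    res <- conditional_enrichment(query, ann, child_cutoff = 0.05)
    expect_true(all(res$p_raw > 0 & res$p_raw <= 1))
    expect_true(all(res$p_conditional > 0 & res$p_conditional <= 1))
    # brute-force: replay the conditioning by hand in topological order
    effP <- unique(c(tg$P, tg$A, tg$B))
    sigA <- hypergeom_upper(length(intersect(query, tg$A)), length(query),
                            length(tg$A), 50) < 0.05
    sigB <- hypergeom_upper(length(intersect(query, tg$B)), length(query),
                            length(tg$B), 50) < 0.05
    drop <- unique(c(if (sigA) tg$A, if (sigB) tg$B))
    gP <- setdiff(effP, drop); uP <- setdiff(uni, drop)
    qP <- setdiff(query, drop)
    pP <- hypergeom_upper(length(intersect(qP, gP)), length(qP),
                          length(gP), length(uP))
    if ("P" %in% res$term) {
      expect_equal(res$p_conditional[res$term == "P"], pP)
    }
  }
})

test_that("a cyclic term structure is rejected", {
  uni <- sprintf("g%02d", 1:10)
  ann <- list(term_genes = list(A = uni[1:3], B = uni[4:6]),
              parents = list(A = "B", B = "A"),
              universe = uni)
  expect_error(conditional_enrichment(uni[1:3], ann), "cyclic")
})

test_that("queries outside the universe are rejected", {
  uni <- sprintf("g%02d", 1:10)
  ann <- flat_annotation(list(A = uni[1:5]), uni)
  expect_error(conditional_enrichment(c("g01", "nope"), ann), "universe")
})

test_that("BH-adjusted values are added on request", {
  uni <- sprintf("g%02d", 1:40)
  ann <- flat_annotation(list(A = uni[1:10], B = uni[11:20],
                              C = uni[21:30]), uni)
  res <- conditional_enrichment(uni[1:10], ann, bh = TRUE)
  expect_true("q" %in% names(res))
  expect_equal(res$q, bh_stepup(res$p_conditional),
               tolerance = 1e-12)
})
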