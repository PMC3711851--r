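test_that("generators are deterministic under a fixed seed", {
  pe <- sim_expr_params(n_genes = 300, seed = 7)
  e1 <- gen_expression(pe); e2 <- gen_expression(pe)
  expect_identical(e1$matrix, e2$matrix)
  expect_identical(e1$truth, e2$truth)

  pc <- sim_chip_params(n_promoters = 20, seed = 7)
  c1 <- gen_chip(pc); c2 <- gen_chip(pc)
  expect_identical(c1$signals, c2$signals)
  expect_identical(c1$map, c2$map)

  a1 <- gen_annotation(n_genes = 200, n_terms = 5, seed = 7)
  a2 <- gen_annotation(n_genes = 200, n_terms = 5, seed = 7)
  expect_identical(a1, a2)
})

test_that("adding genes or promoters leaves earlier units unchanged", {
  small <- gen_expression(sim_expr_params(n_genes = 100, seed = 3))
  large <- gen_expression(sim_expr_params(n_genes = 150, seed = 3))
  expect_equal(large$matrix[1:100, ], small$matrix)
  expect_equal(large$truth[1:100, ], small$truth)

  cs <- gen_chip(sim_chip_params(n_promoters = 10, seed = 3))
  cl <- gen_chip(sim_chip_params(n_promoters = 15, seed = 3))
  expect_equal(cl$truth[1:10, ], cs$truth)
  n_small <- nrow(cs$map)
  expect_equal(cl$map[seq_len(n_small), ], cs$map)
})

test_that("with no planted effects the HS-C mean difference matches the
           closed-form replicate-noise sd", {
  p <- sim_expr_params(n_genes = 10000, frac_up = 0, frac_down = 0,
                       floor = -Inf, seed = 11)
  e <- gen_expression(p)
  mc <- rowMeans(e$matrix[, e$design$sample_id[e$design$condition == "C"]])
  mh <- rowMeans(e$matrix[, e$design$sample_id[e$design$condition != "C"]])
  d <- mh - mc
  expect_lt(abs(mean(d)), 0.01)
  sd_expected <- p$rep_sd * sqrt(2 / p$n_reps)
  expect_lt(abs(sd(d) - sd_expected) / sd_expected, 0.10)
})

test_that("planted up-gene count lies in the binomial 99% interval", {
  p <- sim_expr_params(seed = 5)   # defaults: 15000 genes, frac_up 0.03
  e <- gen_expression(p)
  n_expr <- sum(e$truth$expressed)
  n_up <- sum(e$truth$de_class == "up")
  band <- qbinom(c(0.005, 0.995), n_expr, p$frac_up)
  expect_gte(n_up, band[1])
  expect_lte(n_up, band[2])
})

test_that("truth bookkeeping is self-consistent and bounds are respected", {
  e <- gen_expression(sim_expr_params(n_genes = 2000, seed = 13))
  expect_true(all(e$matrix >= 3.0))
  expect_true(all(e$truth$effect[e$truth$de_class == "null"] == 0))
  expect_gt(mean(e$truth$effect[e$truth$de_class == "up"]), 0)
  expect_lt(mean(e$truth$effect[e$truth$de_class == "down"]), 0)
  expect_false(any(e$truth$de_class != "null" & !e$truth$expressed))
  expect_equal(sum(table(e$truth$de_class)), 2000)

  ch <- gen_chip(sim_chip_params(n_promoters = 50, seed = 13))
  expect_true(all(ch$signals$intensity >= 0))
  expect_true(all(ch$truth$amplitude[!ch$truth$bound] == 0))
  expect_true(all(is.na(ch$truth$peak_index[!ch$truth$bound])))
  expect_true(all(table(ch$map$promoter_id) == ch$truth$n_probes[
    match(names(table(ch$map$promoter_id)), ch$truth$promoter_id)]))
})

test_that("unbound generator centres the raw AB1-AB0 differences at zero", {
  ch <- gen_chip(sim_chip_params(n_promoters = 150, frac_bound = 0,
                                 seed = 17))
  ab1 <- tapply(ch$signals$intensity[ch$signals$channel == "AB1"],
                ch$signals$probe_id[ch$signals$channel == "AB1"], mean)
  ab0 <- tapply(ch$signals$intensity[ch$signals$channel == "AB0"],
                ch$signals$probe_id[ch$signals$channel == "AB0"], mean)
  d <- ab1 - ab0[names(ab1)]
  expect_lt(abs(mean(d)), 0.5)    # background sd ~3, thousands of probes
})

test_that("planted amplitude equals the kernel-average expected score", {
  # mean-normalized kernel: expected promoter-mean AB1-AB0 is the amplitude
  ch <- gen_chip(sim_chip_params(n_promoters = 200,
                                 probes_per_promoter = c(15, 15),
                                 frac_bound = 1, amplitude = c(100, 100),
                                 peak_sd = 2, seed = 19))
  ab1 <- tapply(ch$signals$intensity[ch$signals$channel == "AB1"],
                ch$signals$probe_id[ch$signals$channel == "AB1"], mean)
  ab0 <- tapply(ch$signals$intensity[ch$signals$channel == "AB0"],
                ch$signals$probe_id[ch$signals$channel == "AB0"], mean)
  d <- ab1 - ab0[names(ab1)]
  scores <- tapply(d[ch$map$probe_id], ch$map$promoter_id, mean)
  expect_lt(abs(mean(scores) - 100) / 100, 0.25)
})

test_that("annotation generator plants a recoverable term and a valid DAG", {
  g <- gen_annotation(n_genes = 400, n_terms = 8,
                      planted_term_overlap = 1, seed = 23)
  res <- conditional_enrichment(g$query, g$annotation)
  expect_equal(res$term[which.min(res$p_conditional)], g$planted_term)

  g2 <- gen_annotation(n_genes = 100, n_terms = 2, term_size = 10, seed = 2)
  leaves <- setdiff(names(g2$annotation$parents),
                    unlist(g2$annotation$parents))
  expect_length(leaves, 2)
})

test_that("invalid generator parameters are rejected with the field named", {
  expect_error(sim_expr_params(n_reps = 1), "n_reps")
  expect_error(sim_expr_params(frac_up = 0.8, frac_down = 0.4), "frac_up")
  expect_error(sim_expr_params(mixture = list(weights = c(0.5, 0.4),
                                              means = c(1, 2),
                                              sds = c(1, 1))), "mixture")
  expect_error(sim_chip_params(probes_per_promoter = c(2, 5)),
               "probes_per_promoter")
  expect_error(sim_chip_params(amplitude = c(0, 10)), "amplitude")
  expect_error(sim_chip_params(frac_bound = 1.2), "frac_bound")
  expect_error(gen_annotation(planted_term_overlap = 1.5),
               "planted_term_overlap")
  expect_error(gen_annotation(n_terms = 1), "n_terms")
})
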