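#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study -- a control vs heat-shock
# expression matrix with planted effects, a linked promoter tiling-ChIP
# dataset whose bound promoters sit on up-shifted genes, and a term
# annotation with one planted enriched term. Writes everything as TSV under
# results/data/ so the later stages run from files alone.

suppressMessages(library(heatshockr))

seed <- 20260101
dir.create("results/data", showWarnings = FALSE, recursive = TRUE)

expr_params <- sim_expr_params(n_genes = 6000, seed = seed)
chip_params <- sim_chip_params(n_promoters = 300, seed = seed + 1)
study <- gen_linked_study(expr_params, chip_params, seed = seed + 2)

write_expression(study$expr$matrix, study$expr$design,
                 "results/data/expression.tsv", "results/data/design.tsv")
write_chip_signals(study$chip$signals, "results/data/chip_signals.tsv")
write_promoter_map(study$chip$map, "results/data/promoter_map.tsv")
write.table(study$expr$truth, "results/data/truth_expression.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(study$chip$truth, "results/data/truth_binding.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

ann <- gen_annotation(n_genes = nrow(study$expr$matrix), n_terms = 20,
                      planted_term_overlap = 0.8, seed = seed + 3)
g2t <- do.call(rbind, lapply(names(ann$annotation$term_genes), function(t) {
  g <- ann$annotation$term_genes[[t]]
  if (length(g) == 0) NULL else data.frame(gene = g, term = t)
}))
dag <- do.call(rbind, lapply(names(ann$annotation$parents), function(t) {
  p <- ann$annotation$parents[[t]]
  if (length(p) == 0) NULL else data.frame(child = t, parent = p)
}))
write.table(g2t, "results/data/annotation_gene2term.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(dag, "results/data/annotation_dag.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(data.frame(gene = ann$query),
            "results/data/annotation_query.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf(
  "simulated %d genes x %d samples (%d planted up, %d down, %.1f%% expressed)\n",
  nrow(study$expr$matrix), ncol(study$expr$matrix),
  sum(study$expr$truth$de_class == "up"),
  sum(study$expr$truth$de_class == "down"),
  100 * mean(study$expr$truth$expressed)))
cat(sprintf("simulated %d promoters (%d bound), %d probes, planted term %s\n",
            nrow(study$chip$truth), sum(study$chip$truth$bound),
            nrow(study$chip$map), ann$planted_term))
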