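#!/usr/bin/env Rscript
# Stage 4: cluster genes by their (control mean, SLR) response profile with
# a multivariate Gaussian mixture, then test the simulated query gene set
# for term over-representation with the conditional hypergeometric test.

suppressMessages(library(heatshockr))

seed <- 20260104
slr_tab <- read.delim("results/slr_table.tsv", na.strings = "-")
evaluated <- slr_tab[slr_tab$de_class != "not_evaluated" &
                       !is.na(slr_tab$slr), ]
profiles <- cbind(mean_c = evaluated$mean_c, slr = evaluated$slr)
rownames(profiles) <- evaluated$gene

clust <- cluster_profiles(profiles, k_range = c(2, 12), seed = seed)
write.table(data.frame(gene = names(clust$cluster),
                       cluster = clust$cluster),
            "results/clusters.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(data.frame(cluster = seq_len(clust$K), size = clust$sizes,
                       round(clust$centroids, 3)),
            "results/cluster_summary.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("clustered %d genes into %d profile clusters (BIC %.1f)\n",
            length(clust$cluster), clust$K, clust$bic))

g2t <- read.delim("results/data/annotation_gene2term.tsv")
dag <- read.delim("results/data/annotation_dag.tsv")
query <- read.delim("results/data/annotation_query.tsv")$gene
universe <- read.delim("results/data/truth_expression.tsv")$gene
terms <- union(union(dag$child, dag$parent), unique(g2t$term))
annotation <- list(
  term_genes = c(
    split(g2t$gene, g2t$term),
    setNames(rep(list(character(0)), length(setdiff(terms, g2t$term))),
             setdiff(terms, g2t$term))
  ),
  parents = c(
    split(dag$parent, dag$child),
    setNames(rep(list(character(0)),
                 length(setdiff(terms, dag$child))),
             setdiff(terms, dag$child))
  ),
  universe = universe
)
enr <- conditional_enrichment(query, annotation, bh = TRUE)
write.table(enr, "results/enrichment.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
top <- enr[1, ]
cat(sprintf(
  "top enriched term: %s (k = %d of n = %d, p_conditional = %.3g)\n",
  top$term, top$k, top$n, top$p_conditional))
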