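#!/usr/bin/env Rscript
# Stage 6: join the binding calls with the differential-expression classes:
# crosstab with percentage cells, overlap counts of the induced / repressed
# / bound gene sets, and direction-stratified Spearman correlations between
# promoter binding score and SLR.

suppressMessages(library(heatshockr))

slr_tab <- read.delim("results/slr_table.tsv", na.strings = "-")
class(slr_tab) <- c("contrast_table", class(slr_tab))
binding <- read.delim("results/binding.tsv")

bound_genes <- binding$promoter_id[binding$bound]
xt <- crosstab(bound_genes, slr_tab)
write.table(as.data.frame(xt), "results/integration_crosstab.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

sets <- list(induced = slr_tab$gene[slr_tab$de_class == "up"],
             repressed = slr_tab$gene[slr_tab$de_class == "down"],
             bound = bound_genes)
ov <- overlap_sets(sets)
write.table(ov, "results/integration_overlaps.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

sp_up <- spearman_binding_expression(slr_tab, binding, "up")
sp_down <- spearman_binding_expression(slr_tab, binding, "down")
write.table(
  data.frame(direction = c("up", "down"),
             n = c(sp_up$n, sp_down$n),
             rho = c(sp_up$rho, sp_down$rho),
             p = c(sp_up$p, sp_down$p)),
  "results/integration_spearman.tsv", sep = "\t", quote = FALSE,
  row.names = FALSE)

cat(sprintf(
  "bound & induced: %d (%.2f%% of induced, %.2f%% of bound)\n",
  xt$n_bound_induced, xt$pct_of_induced, xt$pct_of_bound_up))
cat(sprintf(
  "bound & repressed: %d (%.2f%% of repressed, %.2f%% of bound)\n",
  xt$n_bound_repressed, xt$pct_of_repressed, xt$pct_of_bound_down))
cat(sprintf("Spearman rho (induced genes): %.3f (n = %d, p = %.3g)\n",
            sp_up$rho, sp_up$n, sp_up$p))
if (!sp_down$insufficient) {
  cat(sprintf("Spearman rho (repressed genes): %.3f (n = %d, p = %.3g)\n",
              sp_down$rho, sp_down$n, sp_down$p))
} else {
  cat(sprintf("repressed direction: %d usable genes (too few for rho)\n",
              sp_down$n))
}
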