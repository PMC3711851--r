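#!/usr/bin/env Rscript
# Stage 5: promoter binding calls from the probe-level AB1/AB0 tiling
# signals -- per-channel quantile normalization, 5th-percentile background
# subtraction, promoter-mean AB1-AB0 scoring, signed-rank enhancement and
# max-window permutation non-uniformity tests, BH FDR, bound calls
# (score >= 15 and q < 0.05).

suppressMessages(library(heatshockr))

seed <- 20260105
signals <- read_chip_signals("results/data/chip_signals.tsv")
map <- read_promoter_map("results/data/promoter_map.tsv")

binding <- call_binding(signals, map, seed = seed)
write.table(binding, "results/binding.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

truth <- read.delim("results/data/truth_binding.tsv")
tr <- truth[match(binding$promoter_id, truth$promoter_id), ]
tp <- sum(binding$bound & tr$bound); fp <- sum(binding$bound & !tr$bound)
fn <- sum(!binding$bound & tr$bound); tn <- sum(!binding$bound & !tr$bound)
cat(sprintf("%d of %d promoters called bound (planted: %d)\n",
            sum(binding$bound), nrow(binding), sum(tr$bound)))
cat(sprintf("sensitivity %.3f, specificity %.3f\n",
            tp / (tp + fn), tn / (tn + fp)))
cat(sprintf("bound-promoter scores span %.1f .. %.1f arbitrary units\n",
            min(binding$score[binding$bound]),
            max(binding$score[binding$bound])))
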