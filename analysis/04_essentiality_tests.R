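#!/usr/bin/env Rscript
# Stage 4: gene-level one-sided significance. Alpha-RRA over per-guide
# percentile ranks with a guide-count-matched permutation null, run
# separately per (line, condition) arm and direction.

suppressPackageStartupMessages(library(oncodep))

guide_scores <- read_scores("results/guide_scores.tsv")
arms <- unique(guide_scores[, c("cell_line", "condition")])

res <- list()
for (i in seq_len(nrow(arms))) {
  gs <- guide_scores[guide_scores$cell_line == arms$cell_line[i] &
                     guide_scores$condition == arms$condition[i], ]
  rra <- rra_test(gs, n_permutations = 2000L, seed = 7L + i)
  rra$cell_line <- arms$cell_line[i]
  rra$condition <- arms$condition[i]
  res[[i]] <- rra
  cat(sprintf("%s/%s: %d genes with depletion p < 0.05, %d with enrichment p < 0.05\n",
              arms$cell_line[i], arms$condition[i],
              sum(rra$p_depletion < 0.05), sum(rra$p_enrichment < 0.05)))
}
write_scores(do.call(rbind, res), "results/rra_results.tsv")
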