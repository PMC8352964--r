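#!/usr/bin/env Rscript
# Stage 5: dependency classification. Joins gene scores with permutation
# p-values, applies the |CS| > 0.5 & p < 0.05 rule per arm, partitions
# essential calls across the three oncogene lines (Venn), and assigns
# the cross-line dependency classes. Finishes by checking recovery of
# the planted truth from stage 1.

suppressPackageStartupMessages(library(oncodep))

gene_scores <- read_scores("results/gene_scores.tsv")
rra <- read_scores("results/rra_results.tsv")

calls <- merge(gene_scores,
               rra[, c("gene", "cell_line", "condition",
                       "p_depletion", "p_enrichment")],
               by = c("gene", "cell_line", "condition"))
calls <- call_genes(calls)
write_scores(calls, "results/gene_calls.tsv")

lines <- c("EGFR", "KRAS", "RIT1")
ess_sets <- lapply(lines, function(l) {
  x <- calls[calls$cell_line == l & calls$condition == "erlotinib", ]
  x$gene[x$essential]
})
names(ess_sets) <- lines
venn <- venn_partition(ess_sets)
write.table(data.frame(region = names(venn), n_genes = as.integer(venn)),
            "results/venn_partition.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("essential-call Venn partition (erlotinib arms):\n")
print(venn)

deps <- classify_dependencies(calls)
write_scores(deps$labels, "results/dependency_calls.tsv")
print(deps)

# recovery of the planted truth
planted <- read.delim("results/data/planted_effects.tsv")
dep_lab <- deps$labels[deps$labels$class == "oncogene_dependency", ]
coop_lab <- deps$labels[deps$labels$class == "cooperating_knockout", ]
dep_truth <- planted[planted$effect < 0, ]
coop_truth <- planted[planted$effect > 0, ]
hit <- mapply(function(g, l) any(dep_lab$gene == g & dep_lab$cell_line == l),
              dep_truth$gene, dep_truth$cell_line)
coop_hit <- mapply(function(g, l) any(coop_lab$gene == g & coop_lab$cell_line == l),
                   coop_truth$gene, coop_truth$cell_line)
cat(sprintf("planted dependencies labelled in the correct line: %d/%d\n",
            sum(hit), nrow(dep_truth)))
cat(sprintf("planted cooperating knockouts recovered: %d/%d\n",
            sum(coop_hit), nrow(coop_truth)))
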