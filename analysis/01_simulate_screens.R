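#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study — an isogenic pooled CRISPR
# knockout screen design with a control line plus EGFR/KRAS/RIT1
# oncogene lines, line-specific planted dependencies and planted
# cooperating (positively selected) knockouts — and write every artifact
# in the pipeline's exchange formats.

suppressPackageStartupMessages(library(oncodep))

out_dir <- "results/data"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

lines <- c("EGFR", "KRAS", "RIT1")
per_line <- 20L

# line-specific essential dependencies under erlotinib, planted at the
# same per-doubling strength used for the essential reference genes
planted_dep <- lapply(seq_along(lines), function(i) {
  sprintf("GENE%05d", 500L - i * per_line + seq_len(per_line))
})
names(planted_dep) <- lines
# a handful of cooperating knockouts in the RIT1 line (positive selection)
planted_coop <- sprintf("GENE%05d", 401:408)

effects <- rbind(
  do.call(rbind, lapply(lines, function(l) {
    data.frame(gene = planted_dep[[l]], cell_line = l,
               condition = "erlotinib", effect = -0.25,
               stringsAsFactors = FALSE)
  })),
  data.frame(gene = planted_coop, cell_line = "RIT1",
             condition = "erlotinib", effect = 0.15,
             stringsAsFactors = FALSE)
)

scenario <- screen_scenario(n_genes = 500L, guides_per_gene = 4L,
                            n_control_guides = 100L, doublings = 12,
                            depth = 500, dispersion = 10,
                            plasmid_spread = 0.5, effects = effects,
                            seed = 101L)
lib <- simulate_library(scenario)
sets <- scenario_gene_sets(scenario)

write.csv(lib[, c("guide_id", "sequence", "gene")],
          file.path(out_dir, "chip.csv"), row.names = FALSE)
for (nm in names(sets)) {
  writeLines(sets[[nm]], file.path(out_dir, paste0(nm, ".txt")))
}

all_lines <- c("control", lines)
for (i in seq_along(all_lines)) {
  line <- all_lines[i]
  conds <- if (line == "control") "DMSO" else c("DMSO", "erlotinib")
  design <- screen_design(
    sample_id = c(paste0(line, "_plasmid"),
                  paste0(line, "_", rep(conds, each = 2), "_r", rep(1:2, length(conds)))),
    cell_line = line,
    condition = c("plasmid", rep(conds, each = 2)),
    replicate = c(1L, rep(1:2, length(conds)))
  )
  arm_scenario <- scenario
  arm_scenario$seed <- scenario$seed + 1000L * i
  counts <- simulate_screen(lib, design, arm_scenario)
  write_count_matrix(counts, file.path(out_dir, paste0("counts_", line, ".tsv")))
  write.table(as.data.frame(design), file.path(out_dir, paste0("design_", line, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("%s: %d guides x %d samples written\n",
              line, nrow(counts$counts), ncol(counts$counts)))
}

write.table(effects, file.path(out_dir, "planted_effects.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("library:", nrow(lib), "guides (", sum(lib$is_control), "non-targeting )\n")
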