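# Shared fixture builders; everything generated in code at test time.

tiny_library <- function(n_genes = 2L, guides_per_gene = 4L, n_controls = 2L) {
  genes <- sprintf("G%02d", seq_len(n_genes))
  gene_col <- rep(genes, each = guides_per_gene)
  ids <- paste0(gene_col, "_sg", rep(seq_len(guides_per_gene), n_genes))
  ctrl <- sprintf("NTC%02d", seq_len(n_controls))
  seqs <- vapply(seq_len(length(ids) + n_controls), function(i) {
    paste(rep(c("A", "C", "G", "T"), 5)[((i + 0:19) %% 20) + 1], collapse = "")
  }, character(1))
  guide_library(c(ids, ctrl), seqs, c(gene_col, rep(NON_TARGETING, n_controls)))
}

tiny_design <- function(n_reps = 2L, line = "RIT1",
                        conditions = c("DMSO", "erlotinib")) {
  screen_design(
    sample_id = c("plasmid",
                  paste0(rep(conditions, each = n_reps), "_r",
                         rep(seq_len(n_reps), length(conditions)))),
    cell_line = line,
    condition = c("plasmid", rep(conditions, each = n_reps)),
    replicate = c(1L, rep(seq_len(n_reps), length(conditions)))
  )
}

# default study-condition scenario with planted RIT1-specific deps
planted_scenario <- function(n_genes = 400L, n_planted = 10L, seed = 3L,
                             effect = -0.25, line = "RIT1",
                             condition = "erlotinib") {
  genes <- sprintf("GENE%05d", seq(n_genes - n_planted + 1L, n_genes))
  screen_scenario(
    n_genes = n_genes, n_control_guides = 100L,
    effects = data.frame(gene = genes, cell_line = line,
                         condition = condition, effect = effect,
                         stringsAsFactors = FALSE),
    seed = seed
  )
}

planted_genes <- function(scenario) {
  unique(scenario$effects$gene)
}

# brute-force one-sided Fisher p by enumerating all tables with fixed margins
enumerate_fisher_p <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  row1 <- a + b; col1 <- a + c; n <- a + b + c + d
  a_min <- max(0, col1 - (n - row1)); a_max <- min(row1, col1)
  probs <- vapply(a_min:a_max, function(x) {
    choose(col1, x) * choose(n - col1, row1 - x) / choose(n, row1)
  }, numeric(1))
  sum(probs[(a_min:a_max) >= a])
}
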