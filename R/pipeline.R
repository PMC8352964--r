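# End-to-end drivers: one screen arm from counts to calls, and the
# multi-line dependency map.

#' Score and test one screen (counts -> QC -> CRISPR scores -> RRA)
#'
#' Runs [qc_report()], [crispr_scores()] and [rra_test()] per
#' (cell_line, condition) arm, then joins gene scores with p-values and
#' applies the threshold calls.
#'
#' @param counts a [screen_counts()] object including the plasmid sample.
#' @param library a [guide_library()].
#' @param gene_sets a [gene_set_registry()] with `essential_ref`,
#'   `nonessential_ref`, `qc_essential`.
#' @param expressed_oncogene oncogene of this screen's line, for the
#'   cross-targeting exclusion.
#' @param n_permutations,alpha,seed RRA settings, see [rra_test()].
#' @param cs_cut,p_cut thresholds for [call_genes()].
#' @return list of class `screen_result`: `qc` (the [qc_report()]),
#'   `scores` (the [crispr_scores()]), `calls` (per-arm gene table with
#'   cs, p-values and flags).
#' @export
analyze_screen <- function(counts, library, gene_sets,
                           expressed_oncogene = "control",
                           n_permutations = 1000L, alpha = 0.25, seed = 1L,
                           cs_cut = 0.5, p_cut = 0.05) {
  qc <- qc_report(counts, library, gene_sets,
                  expressed_oncogene = expressed_oncogene)
  sc <- crispr_scores(qc$counts, qc$library, gene_sets)
  arms <- unique(sc$guide_scores[, c("cell_line", "condition")])
  calls <- do.call(rbind, lapply(seq_len(nrow(arms)), function(i) {
    gs <- sc$guide_scores[sc$guide_scores$cell_line == arms$cell_line[i] &
                          sc$guide_scores$condition == arms$condition[i], ]
    rra <- rra_test(gs, alpha = alpha, n_permutations = n_permutations,
                    seed = seed + i)
    gene_cs <- sc$gene_scores[sc$gene_scores$cell_line == arms$cell_line[i] &
                              sc$gene_scores$condition == arms$condition[i], ]
    merged <- merge(gene_cs, rra[, c("gene", "p_depletion", "p_enrichment",
                                     "fdr_depletion", "fdr_enrichment")],
                    by = "gene")
    call_genes(merged, cs_cut = cs_cut, p_cut = p_cut)
  }))
  rownames(calls) <- NULL
  structure(list(qc = qc, scores = sc, calls = calls),
            class = "screen_result")
}

#' Simulate and analyze a multi-line isogenic screen design
#'
#' Builds one screen per cell line (each with its own plasmid and
#' endpoint replicates), runs [analyze_screen()] on each and classifies
#' dependencies across lines. The control line is screened in vehicle
#' only; oncogene lines in vehicle and drug.
#'
#' @param scenario a [screen_scenario()]; its `effects` table plants
#'   line- and condition-specific dependencies.
#' @param lines oncogene line names (default `c("EGFR","KRAS","RIT1")`).
#' @param n_replicates endpoint replicates per arm (default 2).
#' @param n_permutations,seed,cs_cut,p_cut passed through.
#' @return list of class `dependency_map`: `calls` (all arms),
#'   `dependencies` (a `dependency_calls` object), `venn` (essential-call
#'   partition across oncogene lines in the drug arm), `screens` (per
#'   line `screen_result`s), `library`, `gene_sets`.
#' @export
run_dependency_map <- function(scenario,
                               lines = c("EGFR", "KRAS", "RIT1"),
                               n_replicates = 2L,
                               n_permutations = 1000L, seed = 1L,
                               cs_cut = 0.5, p_cut = 0.05) {
  library <- simulate_library(scenario)
  gene_sets <- scenario_gene_sets(scenario)
  all_lines <- c("control", lines)
  screens <- list()
  for (i in seq_along(all_lines)) {
    line <- all_lines[i]
    conds <- if (line == "control") "DMSO" else c("DMSO", "erlotinib")
    design <- screen_design(
      sample_id = c(paste0(line, "_plasmid"),
                    paste0(line, "_", rep(conds, each = n_replicates), "_r",
                           rep(seq_len(n_replicates), length(conds)))),
      cell_line = line,
      condition = c("plasmid", rep(conds, each = n_replicates)),
      replicate = c(1L, rep(seq_len(n_replicates), length(conds)))
    )
    arm_scenario <- scenario
    arm_scenario$seed <- scenario$seed + 1000L * i
    counts <- simulate_screen(library, design, arm_scenario)
    screens[[line]] <- analyze_screen(
      counts, library, gene_sets, expressed_oncogene = line,
      n_permutations = n_permutations, seed = scenario$seed + 100L * i,
      cs_cut = cs_cut, p_cut = p_cut)
  }
  calls <- do.call(rbind, lapply(screens, function(s) s$calls))
  rownames(calls) <- NULL
  deps <- classify_dependencies(calls)
  ess_sets <- lapply(lines, function(line) {
    x <- calls[calls$cell_line == line & calls$condition == "erlotinib", ]
    x$gene[x$essential]
  })
  names(ess_sets) <- lines
  venn <- if (length(lines) == 3L) venn_partition(ess_sets) else NULL
  structure(list(calls = calls, dependencies = deps,
                 venn = venn,
                 screens = screens, library = library,
                 gene_sets = gene_sets),
            class = "dependency_map")
}
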