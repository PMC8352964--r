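# Threshold calls, cross-line Venn partition, and dependency classes.

#' Flag essential / positively selected genes from scores and p-values
#'
#' A gene is essential in an arm when its CRISPR score is below `-cs_cut`
#' with one-sided depletion p below `p_cut`; positively selected when its
#' score is above `+cs_cut` with enrichment p below `p_cut` (|CS| > 0.5
#' and p < 0.05 at the defaults).
#'
#' @param gene_table data.frame with `cs`, `p_depletion`, `p_enrichment`
#'   columns (any others are carried through).
#' @param cs_cut absolute CRISPR-score threshold (default 0.5).
#' @param p_cut p-value threshold (default 0.05).
#' @return `gene_table` with logical columns `essential` and
#'   `positively_selected` plus attributes `cs_cut`, `p_cut`.
#' @export
call_genes <- function(gene_table, cs_cut = 0.5, p_cut = 0.05) {
  stopifnot(all(c("cs", "p_depletion", "p_enrichment") %in% names(gene_table)))
  gene_table$essential <-
    gene_table$cs < -cs_cut & gene_table$p_depletion < p_cut
  gene_table$positively_selected <-
    gene_table$cs > cs_cut & gene_table$p_enrichment < p_cut
  attr(gene_table, "cs_cut") <- cs_cut
  attr(gene_table, "p_cut") <- p_cut
  gene_table
}

#' Three-set Venn partition of essential-gene calls
#'
#' @param sets named list of exactly three character vectors (gene sets,
#'   e.g. essential calls per line).
#' @return named integer vector over the 7 disjoint regions:
#'   `only_<A>`, `only_<B>`, `only_<C>`, `<A>_and_<B>`, `<A>_and_<C>`,
#'   `<B>_and_<C>` (pairwise, excluding the third) and `all`; the counts
#'   sum to the union size.
#' @export
venn_partition <- function(sets) {
  stopifnot(length(sets) == 3L, !is.null(names(sets)))
  nm <- names(sets)
  a <- unique(sets[[1L]]); b <- unique(sets[[2L]]); c <- unique(sets[[3L]])
  u <- union(union(a, b), c)
  in_a <- u %in% a; in_b <- u %in% b; in_c <- u %in% c
  out <- c(
    sum(in_a & !in_b & !in_c), sum(!in_a & in_b & !in_c),
    sum(!in_a & !in_b & in_c), sum(in_a & in_b & !in_c),
    sum(in_a & !in_b & in_c), sum(!in_a & in_b & in_c),
    sum(in_a & in_b & in_c)
  )
  names(out) <- c(paste0("only_", nm),
                  paste0(nm[1L], "_and_", nm[2L]),
                  paste0(nm[1L], "_and_", nm[3L]),
                  paste0(nm[2L], "_and_", nm[3L]),
                  "all")
  out
}

#' Classify genes into dependency classes across isogenic lines
#'
#' Given per-arm essential / positively-selected flags for a control line
#' (vehicle arm) and oncogene-expressing lines (vehicle and drug arms):
#' \itemize{
#'   \item `oncogene_dependency(line)`: essential in that line's drug arm
#'     and not essential in the control vehicle arm — required
#'     specifically for oncogene-driven survival under EGFR inhibition.
#'   \item `baseline_synthetic_lethal(line)`: essential in that line's
#'     vehicle arm and not in the control vehicle arm.
#'   \item `pan_essential`: essential in every oncogene line's drug arm.
#'   \item `cooperating_knockout(line)`: positively selected in that
#'     line's drug arm (knockout synergizes with the oncogene).
#' }
#' A gene may carry several line-scoped labels; each is a separate row.
#'
#' @param calls data.frame with columns `gene`, `cell_line`, `condition`,
#'   `essential`, `positively_selected` covering the control line's
#'   vehicle arm and both arms of each oncogene line.
#' @param control_line name of the control line (default `"control"`).
#' @param vehicle,drug condition names (defaults `"DMSO"`, `"erlotinib"`).
#' @return list of class `dependency_calls`: `labels`
#'   (`data.frame(gene, class, cell_line)`; `cell_line` is `NA` for
#'   `pan_essential`), and `arms` (the input flags, one row per gene x
#'   arm).
#' @export
classify_dependencies <- function(calls, control_line = "control",
                                  vehicle = "DMSO", drug = "erlotinib") {
  need <- c("gene", "cell_line", "condition", "essential", "positively_selected")
  stopifnot(all(need %in% names(calls)))
  lines <- setdiff(unique(calls$cell_line), control_line)
  arm <- function(line, cond) {
    x <- calls[calls$cell_line == line & calls$condition == cond, , drop = FALSE]
    if (nrow(x) == 0L) stop("missing arm: (", line, ", ", cond, ")")
    x
  }
  ctrl <- arm(control_line, vehicle)
  genes <- unique(calls$gene)
  flag <- function(x, gene, col) {
    v <- x[[col]][match(gene, x$gene)]
    v[is.na(v)] <- FALSE  # genes filtered out of an arm carry no call there
    v
  }
  ctrl_ess <- flag(ctrl, genes, "essential")

  label_rows <- function(g, class, line) {
    data.frame(gene = g, class = rep_len(class, length(g)),
               cell_line = rep_len(line, length(g)), stringsAsFactors = FALSE)
  }
  labels <- list()
  drug_ess <- matrix(FALSE, length(genes), length(lines),
                     dimnames = list(genes, lines))
  for (line in lines) {
    d <- arm(line, drug); v <- arm(line, vehicle)
    d_ess <- flag(d, genes, "essential")
    v_ess <- flag(v, genes, "essential")
    d_sel <- flag(d, genes, "positively_selected")
    drug_ess[, line] <- d_ess
    labels[[paste0("dep_", line)]] <-
      label_rows(genes[d_ess & !ctrl_ess], "oncogene_dependency", line)
    labels[[paste0("bsl_", line)]] <-
      label_rows(genes[v_ess & !ctrl_ess], "baseline_synthetic_lethal", line)
    labels[[paste0("coop_", line)]] <-
      label_rows(genes[d_sel], "cooperating_knockout", line)
  }
  pan <- genes[rowSums(drug_ess) == length(lines)]
  labels$pan <- label_rows(pan, "pan_essential", NA_character_)
  labels <- do.call(rbind, labels)
  rownames(labels) <- NULL
  structure(list(labels = labels, arms = calls), class = "dependency_calls")
}

#' @export
print.dependency_calls <- function(x, ...) {
  cat("dependency_calls:\n")
  print(table(x$labels$class, useNA = "no"))
  invisible(x)
}

#' Per-gene CRISPR-score difference between two arms
#'
#' @param score_a,score_b data.frames with `gene` and `cs` columns on a
#'   common gene universe.
#' @return `data.frame(gene, cs_a, cs_b, delta_cs)` sorted ascending by
#'   `delta_cs = cs_a - cs_b`; antisymmetric under swapping the inputs.
#' @export
differential_cs <- function(score_a, score_b) {
  common <- intersect(score_a$gene, score_b$gene)
  a <- score_a$cs[match(common, score_a$gene)]
  b <- score_b$cs[match(common, score_b$gene)]
  out <- data.frame(gene = common, cs_a = a, cs_b = b, delta_cs = a - b,
                    stringsAsFactors = FALSE)
  out[order(out$delta_cs), , drop = FALSE]
}
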