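# Tumor-cohort co-occurrence of index-gene alteration with pathway low
# expression, plus the IHC H-score.

#' Hippo pathway gene lists used in the co-occurrence analysis
#'
#' `methods` is the 7-gene list (includes NF2); `figure` is the 6-gene
#' display list without NF2.
#'
#' @return named list of two character vectors.
#' @export
hippo_gene_sets <- function() {
  list(
    methods = c("AMOTL1", "NF2", "STK4", "STK38L", "MAP4K5", "TAOK3", "SAV1"),
    figure = c("AMOTL1", "STK4", "STK38L", "MAP4K5", "TAOK3", "SAV1")
  )
}

#' Alteration call and cohort summary
#'
#' A tumor is altered when it carries either a mutation or an
#' amplification of the index gene.
#'
#' @param mutation,amplification logical vectors.
#' @return logical vector of altered flags.
#' @export
call_altered <- function(mutation, amplification) {
  stopifnot(is.logical(mutation), is.logical(amplification),
            length(mutation) == length(amplification))
  mutation | amplification
}

#' Summarize the altered fraction of a cohort
#'
#' @param altered logical vector from [call_altered()].
#' @return `list(n_altered, n_total, percent, percent_rounded)`; the
#'   percent is reported exactly and rounded to the nearest integer.
#' @export
alteration_summary <- function(altered) {
  n <- length(altered)
  k <- sum(altered)
  pct <- 100 * k / n
  list(n_altered = k, n_total = n, percent = pct,
       percent_rounded = round(pct))
}

#' Expression z-score against the diploid reference distribution
#'
#' @param expression numeric vector of index-gene expression per tumor.
#' @param diploid logical vector marking copy-number diploid tumors.
#' @return z per tumor, `(x - mean(diploid)) / sd(diploid)`.
#' @export
zscore_vs_reference <- function(expression, diploid) {
  stopifnot(length(expression) == length(diploid))
  ref <- expression[diploid]
  if (length(ref) < 2L) stop("need >=2 diploid reference tumors")
  s <- sd(ref)
  if (s == 0) stop("diploid reference has zero spread")
  (expression - mean(ref)) / s
}

#' Flag tumors with low expression of a gene
#'
#' Low = strictly more than one standard deviation below the cohort mean
#' (sample sd); a value exactly at mean - sd is not low.
#'
#' @param expression numeric expression vector across the cohort.
#' @return logical vector; all `FALSE` (with a warning) when the column
#'   has zero spread.
#' @export
call_low_expression <- function(expression) {
  stopifnot(length(expression) >= 2L)
  s <- sd(expression)
  if (s == 0) {
    warning("zero expression spread; no tumors called low")
    return(rep(FALSE, length(expression)))
  }
  expression < mean(expression) - s
}

#' Does each tumor have low expression of any listed pathway gene?
#'
#' @param cohort data.frame with one expression column per gene.
#' @param genes pathway gene symbols; every one must be a column.
#' @return logical vector per tumor.
#' @export
any_hippo_low <- function(cohort, genes = hippo_gene_sets()$methods) {
  stopifnot(length(genes) >= 1L)
  missing <- setdiff(genes, names(cohort))
  if (length(missing)) {
    stop("gene(s) absent from the expression table: ",
         paste(missing, collapse = ", "))
  }
  low <- vapply(genes, function(g) call_low_expression(cohort[[g]]),
                logical(nrow(cohort)))
  rowSums(low) > 0
}

#' Cross-tabulate alteration status against pathway-low status
#'
#' @param altered,pathway_low logical vectors of equal length.
#' @return 2x2 integer matrix, rows = altered yes/no, columns =
#'   pathway-low yes/no.
#' @export
build_contingency <- function(altered, pathway_low) {
  stopifnot(length(altered) == length(pathway_low))
  m <- matrix(c(sum(altered & pathway_low), sum(altered & !pathway_low),
                sum(!altered & pathway_low), sum(!altered & !pathway_low)),
              nrow = 2L, byrow = TRUE,
              dimnames = list(altered = c("yes", "no"),
                              pathway_low = c("yes", "no")))
  m
}

#' One-sided Fisher exact test on a 2x2 table
#'
#' Tests whether row 1 (altered tumors) has the greater success (column
#' 1) proportion: the exact hypergeometric probability of tables at
#' least as extreme in that direction, with margins fixed.
#'
#' @param table 2x2 count matrix (rows: altered / non-altered; columns:
#'   pathway-low yes / no).
#' @return one-sided p-value in (0, 1].
#' @export
fisher_one_sided <- function(table) {
  stopifnot(is.matrix(table), all(dim(table) == 2L), all(table >= 0))
  a <- table[1L, 1L]
  m <- sum(table[, 1L])        # column-1 margin (successes)
  n <- sum(table[, 2L])        # column-2 margin (failures)
  k <- sum(table[1L, ])        # row-1 margin (altered draws)
  if (m == 0 || n + m == 0 || k == 0 || k == m + n) {
    warning("degenerate margin; p = 1")
    return(1)
  }
  # P(X >= a), X ~ Hypergeometric(m, n, k)
  phyper(a - 1, m, n, k, lower.tail = FALSE)
}

#' Full cohort co-occurrence analysis
#'
#' Calls alteration from the stored flags, flags low expression per
#' pathway gene, builds the 2x2 table and computes the one-sided Fisher
#' p for the hypothesis that altered tumors are more often pathway-low.
#'
#' @param cohort a `cohort_table` (see [simulate_cohort()]) or any
#'   data.frame with `mutation`, `amplification`, `diploid`, an index
#'   expression column and the pathway expression columns.
#' @param genes pathway gene list (default the 7-gene set).
#' @param index_gene index gene column for the z-score (default "RIT1").
#' @return list of class `cooccurrence_result`: `table` (2x2),
#'   `p` (one-sided Fisher), `prop_low_altered`, `prop_low_nonaltered`,
#'   `summary` (alteration summary), `flags` (per-tumor data.frame with
#'   `altered`, `hippo_low`, `z_index`).
#' @export
cooccurrence_test <- function(cohort, genes = hippo_gene_sets()$methods,
                              index_gene = "RIT1") {
  altered <- call_altered(cohort$mutation, cohort$amplification)
  low <- any_hippo_low(cohort, genes)
  tab <- build_contingency(altered, low)
  z <- zscore_vs_reference(cohort[[index_gene]], cohort$diploid)
  structure(list(
    table = tab,
    p = fisher_one_sided(tab),
    prop_low_altered = tab[1L, 1L] / sum(tab[1L, ]),
    prop_low_nonaltered = tab[2L, 1L] / sum(tab[2L, ]),
    summary = alteration_summary(altered),
    flags = data.frame(tumor_id = cohort$tumor_id, altered = altered,
                       hippo_low = low, z_index = z,
                       stringsAsFactors = FALSE)
  ), class = "cooccurrence_result")
}

#' @export
print.cooccurrence_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("cooccurrence: %d/%d tumors altered (%.0f%%)\n",
              s$n_altered, s$n_total, s$percent))
  cat(sprintf("pathway-low: %.1f%% of altered vs %.1f%% of non-altered; one-sided Fisher p = %.4g\n",
              100 * x$prop_low_altered, 100 * x$prop_low_nonaltered, x$p))
  invisible(x)
}

#' Immunohistochemistry H-score
#'
#' Sum over staining-intensity bins of percent-positive cells times the
#' intensity (1 = weak, 2 = moderate, 3 = strong); range 0-300.
#'
#' @param percent_positive numeric vector of length 3: percent of cells
#'   at intensities 1, 2 and 3; non-negative, summing to at most 100.
#' @return H-score in [0, 300].
#' @export
h_score <- function(percent_positive) {
  stopifnot(length(percent_positive) == 3L, all(percent_positive >= 0))
  if (sum(percent_positive) > 100 + 1e-9) {
    stop("percent positive across intensity bins exceeds 100")
  }
  sum(percent_positive * (1:3))
}
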