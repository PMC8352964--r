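# Per-guide log fold-changes and anchored, normalized CRISPR scores.
#
# Scoring chain per replicate:
#   RPM -> LFC vs plasmid -> median/MAD normalization -> affine anchoring
#   so reference nonessential genes sit at 0 and reference essentials at
#   -1 -> gene-level collapse (mean over guides, then over replicates).

#' Log2 fold-change of guide abundance versus the plasmid library
#'
#' @param rpm reads-per-million matrix (see [to_rpm()]).
#' @param plasmid_sample plasmid column name.
#' @param pseudocount RPM pseudocount added to numerator and denominator
#'   so zero counts stay finite (default 1).
#' @return matrix of LFCs for every non-plasmid column.
#' @export
compute_lfc <- function(rpm, plasmid_sample, pseudocount = 1) {
  rpm <- as.matrix(rpm)
  stopifnot(pseudocount > 0, plasmid_sample %in% colnames(rpm))
  ref <- rpm[, plasmid_sample]
  keep <- setdiff(colnames(rpm), plasmid_sample)
  lfc <- log2(sweep(rpm[, keep, drop = FALSE] + pseudocount, 1,
                    ref + pseudocount, "/"))
  lfc
}

#' Center and scale one replicate's LFC column robustly
#'
#' Subtracts the replicate median and divides by the scaled median
#' absolute deviation (consistency constant 1.4826), so the normalized
#' column has median 0 and MADs 1.
#'
#' @param lfc_column numeric vector of per-guide LFCs for one replicate.
#' @return normalized numeric vector.
#' @export
normalize_replicate <- function(lfc_column) {
  x <- lfc_column[is.finite(lfc_column)]
  if (length(x) < 3L) stop("normalize_replicate needs >=3 finite values")
  m <- median(x)
  s <- mad(x)
  if (s == 0) stop("degenerate replicate: MAD of LFC is zero")
  (lfc_column - m) / s
}

#' Anchor a normalized replicate to reference gene sets
#'
#' Affine map placing the median of the nonessential reference genes at 0
#' and the median of the essential reference genes at -1:
#' `cs = (x - m_non) / (m_non - m_ess)`. Anchor medians are taken
#' gene-first: guide values are averaged per gene, then the median over
#' anchor genes is used, so anchor genes with unequal surviving guide
#' counts contribute equally.
#'
#' @param norm_lfc named numeric vector (names = guide ids) of normalized
#'   LFCs for one replicate.
#' @param library a [guide_library()] mapping guides to genes.
#' @param essential_ref,nonessential_ref anchor gene symbol vectors; each
#'   must be represented by >=10 guides.
#' @return numeric vector of CRISPR scores with attribute `anchors`
#'   (named c(nonessential, essential) medians of the output, 0 and -1 up
#'   to floating point).
#' @export
scale_to_anchors <- function(norm_lfc, library, essential_ref, nonessential_ref) {
  gene <- library$gene[match(names(norm_lfc), library$guide_id)]
  if (anyNA(gene)) stop("norm_lfc contains guides absent from the library")
  ess_idx <- gene %in% essential_ref
  non_idx <- gene %in% nonessential_ref
  if (sum(ess_idx) < 10L || sum(non_idx) < 10L) {
    stop("each anchor set must be represented by >=10 guides (essential: ",
         sum(ess_idx), ", nonessential: ", sum(non_idx), ")")
  }
  gene_median <- function(idx) {
    median(tapply(norm_lfc[idx], gene[idx], mean))
  }
  m_ess <- gene_median(ess_idx)
  m_non <- gene_median(non_idx)
  if (m_non == m_ess) stop("anchor medians are equal; no dynamic range")
  cs <- (norm_lfc - m_non) / (m_non - m_ess)
  attr(cs, "anchors") <- c(
    nonessential = unname(median(tapply(cs[non_idx], gene[non_idx], mean))),
    essential = unname(median(tapply(cs[ess_idx], gene[ess_idx], mean)))
  )
  cs
}

#' Collapse guide-level CRISPR scores to gene level
#'
#' Gene score = mean over the gene's guides within each replicate, then
#' the mean across replicates. Non-targeting guides are excluded; genes
#' with zero surviving guides are absent from the result.
#'
#' @param cs matrix of guide-level CRISPR scores (guides x replicate
#'   samples).
#' @param library a [guide_library()].
#' @param design optional [screen_design()] rows for the columns of `cs`;
#'   when given, `cell_line` and `condition` are carried into the output
#'   and replicates are averaged within each (cell_line, condition) arm.
#' @return `data.frame` with `gene`, (`cell_line`, `condition` when
#'   design given), `cs`, `n_guides`, plus a `replicate_cs` attribute
#'   holding the per-replicate gene-level matrix.
#' @export
collapse_to_genes <- function(cs, library, design = NULL) {
  cs <- as.matrix(cs)
  gene <- library$gene[match(rownames(cs), library$guide_id)]
  if (anyNA(gene)) stop("cs contains guides absent from the library")
  keep <- gene != NON_TARGETING
  cs <- cs[keep, , drop = FALSE]
  gene <- gene[keep]
  genes_u <- sort(unique(gene))
  per_rep <- vapply(seq_len(ncol(cs)),
                    function(j) unname(tapply(cs[, j], gene, mean)[genes_u]),
                    numeric(length(genes_u)))
  per_rep <- matrix(per_rep, nrow = length(genes_u),
                    dimnames = list(genes_u, colnames(cs)))
  n_guides <- as.integer(table(gene)[rownames(per_rep)])

  if (is.null(design)) {
    out <- data.frame(gene = rownames(per_rep), cs = rowMeans(per_rep),
                      n_guides = n_guides, stringsAsFactors = FALSE)
    rownames(out) <- NULL
    attr(out, "replicate_cs") <- per_rep
    return(out)
  }
  design <- design[match(colnames(cs), design$sample_id), , drop = FALSE]
  arm <- paste(design$cell_line, design$condition, sep = "\r")
  arms <- unique(arm)
  out <- do.call(rbind, lapply(arms, function(a) {
    cols <- which(arm == a)
    parts <- strsplit(a, "\r", fixed = TRUE)[[1L]]
    data.frame(gene = rownames(per_rep),
               cell_line = parts[1L], condition = parts[2L],
               cs = rowMeans(per_rep[, cols, drop = FALSE]),
               n_guides = n_guides, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  attr(out, "replicate_cs") <- per_rep
  out
}

#' Full guide-to-gene CRISPR scoring chain for one screen
#'
#' Applies [to_rpm()], [compute_lfc()] vs the plasmid sample,
#' [normalize_replicate()] and [scale_to_anchors()] per replicate, then
#' [collapse_to_genes()]. Anchor medians of every replicate are asserted
#' to be (0, -1) up to floating point on every run.
#'
#' @param counts a (typically QC-filtered) [screen_counts()] object.
#' @param library a [guide_library()].
#' @param gene_sets [gene_set_registry()] with `essential_ref` and
#'   `nonessential_ref`.
#' @param pseudocount RPM pseudocount for the LFC.
#' @param baseline `"plasmid"` (default) or `"ETP"`: the comparison
#'   sample condition.
#' @return list of class `crispr_scores`: `guide_scores` (long
#'   data.frame: guide_id, gene, sample_id, cell_line, condition,
#'   replicate, lfc, norm_lfc, cs), `gene_scores` (see
#'   [collapse_to_genes()]), `anchors` (per-replicate anchor medians).
#' @export
crispr_scores <- function(counts, library, gene_sets, pseudocount = 1,
                          baseline = c("plasmid", "ETP")) {
  baseline <- match.arg(baseline)
  stopifnot(inherits(counts, "screen_counts"),
            all(c("essential_ref", "nonessential_ref") %in% names(gene_sets)))
  base_id <- counts$design$sample_id[counts$design$condition == baseline]
  if (length(base_id) != 1L) {
    stop("need exactly one ", baseline, " sample as baseline; found ",
         length(base_id))
  }
  rpm <- to_rpm(counts)
  lfc <- compute_lfc(rpm, base_id, pseudocount = pseudocount)
  endpoint <- counts$design[!counts$design$condition %in% c("plasmid", "ETP"), ,
                            drop = FALSE]
  lfc <- lfc[, endpoint$sample_id, drop = FALSE]

  norm <- apply(lfc, 2L, normalize_replicate)
  cs <- matrix(NA_real_, nrow(norm), ncol(norm), dimnames = dimnames(norm))
  anchors <- matrix(NA_real_, ncol(norm), 2L,
                    dimnames = list(colnames(norm), c("nonessential", "essential")))
  for (j in seq_len(ncol(norm))) {
    col <- setNames(norm[, j], rownames(norm))
    sc <- scale_to_anchors(col, library, gene_sets$essential_ref,
                           gene_sets$nonessential_ref)
    anchors[j, ] <- attr(sc, "anchors")
    cs[, j] <- sc
  }
  stopifnot(max(abs(anchors[, "nonessential"])) < 1e-9,
            max(abs(anchors[, "essential"] + 1)) < 1e-9)

  gene_scores <- collapse_to_genes(cs, library, design = endpoint)
  guide_scores <- do.call(rbind, lapply(seq_len(ncol(cs)), function(j) {
    sid <- colnames(cs)[j]
    d <- endpoint[endpoint$sample_id == sid, ]
    data.frame(guide_id = rownames(cs),
               gene = library$gene[match(rownames(cs), library$guide_id)],
               sample_id = sid, cell_line = d$cell_line,
               condition = d$condition, replicate = d$replicate,
               lfc = lfc[, j], norm_lfc = norm[, j], cs = cs[, j],
               stringsAsFactors = FALSE)
  }))
  rownames(guide_scores) <- NULL
  structure(list(guide_scores = guide_scores, gene_scores = gene_scores,
                 anchors = anchors),
            class = "crispr_scores")
}

#' @export
print.crispr_scores <- function(x, ...) {
  cat("crispr_scores:", length(unique(x$gene_scores$gene)), "genes,",
      nrow(x$anchors), "replicates; anchor medians (0, -1) asserted\n")
  invisible(x)
}
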