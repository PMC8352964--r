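# Guide-level normalization, exclusion rules, and replicate QC (SSMD,
# correlations).

#' Scale counts to reads per million
#'
#' @param counts a [screen_counts()] object or a numeric matrix with
#'   sample columns.
#' @return numeric matrix; every column sums to 1e6.
#' @export
to_rpm <- function(counts) {
  m <- if (inherits(counts, "screen_counts")) counts$counts else as.matrix(counts)
  cs <- colSums(m)
  if (any(cs == 0)) {
    stop("all-zero counts for sample(s): ",
         paste(colnames(m)[cs == 0], collapse = ", "))
  }
  sweep(m, 2, cs, "/") * 1e6
}

#' Remove guides under-represented in the plasmid library
#'
#' Guides with plasmid abundance below `threshold` reads-per-million are
#' dropped from every sample. The removal count and the removed guide ids
#' are attached as attributes for the QC report.
#'
#' @param counts a [screen_counts()] object.
#' @param plasmid_sample sample id of the plasmid library; defaults to
#'   the unique `condition == "plasmid"` sample in the design.
#' @param threshold RPM cutoff (default 1).
#' @return filtered [screen_counts()] with attributes
#'   `n_low_abundance_removed` and `low_abundance_guides`.
#' @export
filter_low_abundance <- function(counts, plasmid_sample = NULL, threshold = 1) {
  stopifnot(inherits(counts, "screen_counts"))
  if (is.null(plasmid_sample)) {
    plasmid_sample <- counts$design$sample_id[counts$design$condition == "plasmid"]
  }
  if (length(plasmid_sample) != 1L || !plasmid_sample %in% colnames(counts$counts)) {
    stop("plasmid sample not found in counts")
  }
  rpm <- to_rpm(counts)
  low <- rpm[, plasmid_sample] < threshold
  out <- screen_counts(counts$counts[!low, , drop = FALSE], counts$design)
  attr(out, "n_low_abundance_removed") <- sum(low)
  attr(out, "low_abundance_guides") <- rownames(counts$counts)[low]
  out
}

#' Guide sequences that miss the introduced oncogene cDNAs
#'
#' Library guides designed against the endogenous locus that do not cut
#' the ectopically expressed cDNA would score the oncogene as
#' dispensable; they are excluded from screens of the matching line.
#'
#' @return named list: oncogene symbol -> character vector of 20-nt guide
#'   sequences.
#' @export
cross_targeting_exclusions <- function() {
  list(
    KRAS = "AGATATTCACCATTATAGGT",
    RIT1 = c("CATGCGGGACCAGTATATGA", "GTGATGATCTGGCTTACCAA"),
    EGFR = "TGTCACCACATAATTACCTG"
  )
}

#' Drop guides that fail to target the line's introduced oncogene
#'
#' @param library a [guide_library()].
#' @param expressed_oncogene the cell line's introduced oncogene symbol
#'   (e.g. `"KRAS"`); `"control"` or any name absent from the table is an
#'   identity operation.
#' @param exclusion_table named list oncogene -> sequences; defaults to
#'   [cross_targeting_exclusions()].
#' @return filtered [guide_library()] with attribute `excluded_guides`.
#' @export
exclude_cross_targeting <- function(library, expressed_oncogene,
                                    exclusion_table = cross_targeting_exclusions()) {
  stopifnot(inherits(library, "guide_library"))
  seqs <- exclusion_table[[expressed_oncogene]]
  if (is.null(seqs)) {
    attr(library, "excluded_guides") <- character()
    return(library)
  }
  drop <- library$sequence %in% seqs
  out <- library[!drop, , drop = FALSE]
  class(out) <- class(library)
  attr(out, "excluded_guides") <- library$guide_id[drop]
  out
}

#' Pairwise replicate correlations of guide-level log fold-changes
#'
#' @param lfc numeric matrix, guides x replicate samples.
#' @return `data.frame(sample_a, sample_b, r, r_squared)` for every
#'   unordered pair; empty (with a warning) when fewer than two columns.
#' @export
replicate_correlation <- function(lfc) {
  lfc <- as.matrix(lfc)
  if (ncol(lfc) < 2L) {
    warning("fewer than 2 replicates; no correlations computed")
    return(data.frame(sample_a = character(), sample_b = character(),
                      r = numeric(), r_squared = numeric()))
  }
  pairs <- combn(colnames(lfc), 2L)
  r <- apply(pairs, 2L, function(p) {
    cor(lfc[, p[1L]], lfc[, p[2L]], use = "complete.obs")
  })
  data.frame(sample_a = pairs[1L, ], sample_b = pairs[2L, ],
             r = r, r_squared = r^2, stringsAsFactors = FALSE)
}

#' Robust strictly standardized mean difference (SSMD)
#'
#' Contrasts the log fold-change distribution of guides targeting known
#' essential genes against non-targeting control guides:
#' `(median(ess) - median(ctrl)) / sqrt(MADs(ess)^2 + MADs(ctrl)^2)`
#' with `MADs` the median absolute deviation scaled by 1.4826. A
#' well-performing replicate has strong essential dropout, so its SSMD is
#' negative; the pass threshold is SSMD < -0.5.
#'
#' @param lfc named numeric vector of per-guide LFCs for one replicate.
#' @param essential_guides guide ids targeting the QC essential set.
#' @param control_guides non-targeting guide ids.
#' @return a single numeric SSMD value. When both MADs are zero the
#'   result is 0 for equal medians, otherwise signed `Inf` with a
#'   warning.
#' @export
ssmd <- function(lfc, essential_guides, control_guides) {
  ess <- lfc[names(lfc) %in% essential_guides]
  ctrl <- lfc[names(lfc) %in% control_guides]
  ess <- ess[is.finite(ess)]; ctrl <- ctrl[is.finite(ctrl)]
  if (length(ess) < 2L || length(ctrl) < 2L) {
    stop("ssmd needs >=2 finite LFC values in each guide set")
  }
  num <- median(ess) - median(ctrl)
  den <- sqrt(mad(ess)^2 + mad(ctrl)^2)
  if (den == 0) {
    if (num == 0) return(0)
    warning("zero MAD in both guide sets with unequal medians; returning signed Inf")
    return(sign(num) * Inf)
  }
  num / den
}

#' Replicate-level quality-control report for a screen
#'
#' Computes per-endpoint-replicate SSMD (essential-targeting vs
#' non-targeting guide LFCs vs plasmid), the pass flag (SSMD < -0.5) and
#' pairwise replicate LFC correlations, after the low-abundance and
#' cross-targeting filters.
#'
#' @param counts a [screen_counts()] object including the plasmid sample.
#' @param library a [guide_library()] covering the count rows.
#' @param gene_sets a [gene_set_registry()] with a `qc_essential` set.
#' @param expressed_oncogene oncogene introduced in this screen's line
#'   (for cross-targeting exclusion); default `"control"` (no exclusion).
#' @param rpm_threshold plasmid RPM cutoff for [filter_low_abundance()].
#' @param pseudocount RPM pseudocount for the LFC.
#' @param ssmd_cut pass threshold (replicates pass when SSMD < `ssmd_cut`).
#' @return list of class `qc_report`: `replicates` (data.frame with
#'   `sample_id`, `cell_line`, `condition`, `replicate`, `ssmd`, `pass`),
#'   `correlations`, `n_low_abundance_removed`, `cross_targeting_removed`,
#'   and the filtered `counts` ready for scoring.
#' @export
qc_report <- function(counts, library, gene_sets,
                      expressed_oncogene = "control",
                      rpm_threshold = 1, pseudocount = 1, ssmd_cut = -0.5) {
  stopifnot(inherits(counts, "screen_counts"),
            inherits(library, "guide_library"),
            "qc_essential" %in% names(gene_sets))
  lib <- exclude_cross_targeting(library, expressed_oncogene)
  cross_removed <- attr(lib, "excluded_guides")
  keep <- rownames(counts$counts) %in% lib$guide_id
  counts <- screen_counts(counts$counts[keep, , drop = FALSE], counts$design)
  counts <- filter_low_abundance(counts, threshold = rpm_threshold)
  n_low <- attr(counts, "n_low_abundance_removed")

  rpm <- to_rpm(counts)
  plasmid_id <- counts$design$sample_id[counts$design$condition == "plasmid"]
  lfc <- compute_lfc(rpm, plasmid_id, pseudocount = pseudocount)
  lib_idx <- lib[match(rownames(lfc), lib$guide_id), ]
  ess_guides <- lib_idx$guide_id[lib_idx$gene %in% gene_sets$qc_essential]
  ctrl_guides <- lib_idx$guide_id[lib_idx$is_control]

  endpoint <- counts$design[!counts$design$condition %in% c("plasmid", "ETP"), ,
                            drop = FALSE]
  ssmd_vals <- vapply(endpoint$sample_id, function(s) {
    ssmd(setNames(lfc[, s], rownames(lfc)), ess_guides, ctrl_guides)
  }, numeric(1))
  replicates <- data.frame(
    sample_id = endpoint$sample_id, cell_line = endpoint$cell_line,
    condition = endpoint$condition, replicate = endpoint$replicate,
    ssmd = unname(ssmd_vals), stringsAsFactors = FALSE
  )
  replicates$pass <- replicates$ssmd < ssmd_cut

  correlations <- if (nrow(endpoint) >= 2L) {
    replicate_correlation(lfc[, endpoint$sample_id, drop = FALSE])
  } else {
    suppressWarnings(replicate_correlation(lfc[, endpoint$sample_id, drop = FALSE]))
  }

  structure(list(replicates = replicates, correlations = correlations,
                 n_low_abundance_removed = n_low,
                 cross_targeting_removed = cross_removed,
                 counts = counts, library = lib),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("qc_report:", nrow(x$replicates), "endpoint replicates;",
      sum(x$replicates$pass), "pass (SSMD < -0.5)\n")
  cat("guides removed: low-abundance", x$n_low_abundance_removed,
      "; cross-targeting", length(x$cross_targeting_removed), "\n")
  invisible(x)
}
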