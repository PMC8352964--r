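# Gene-level one-sided significance: alpha-robust-rank-aggregation over
# guide percentiles with a permutation null matched on guide count.

#' Percentile ranks of a guide statistic
#'
#' Depletion ranks ascending (most-depleted guide gets the smallest
#' percentile); enrichment ranks descending. Percentile = rank / (N + 1),
#' ties broken by average rank, so values lie strictly inside (0, 1).
#'
#' @param stat finite numeric vector of guide statistics (e.g. CRISPR
#'   scores).
#' @param direction `"depletion"` or `"enrichment"`.
#' @return numeric vector of percentiles in (0, 1).
#' @export
percentile_ranks <- function(stat, direction = c("depletion", "enrichment")) {
  direction <- match.arg(direction)
  stopifnot(all(is.finite(stat)))
  x <- if (direction == "depletion") stat else -stat
  rank(x, ties.method = "average") / (length(x) + 1)
}

#' Alpha-RRA gene statistic
#'
#' For a gene's sorted guide percentiles p(1) <= ... <= p(m), restrict to
#' the k percentiles <= `alpha`; rho is the minimum over i <= k of the
#' Beta(i, m - i + 1) CDF at p(i) — the probability that the i-th order
#' statistic of m uniforms is that small. rho = 1 when no percentile
#' clears alpha.
#'
#' @param percentiles the gene's guide percentiles (any order).
#' @param alpha top fraction of the ranking considered informative
#'   (default 0.25).
#' @return rho in (0, 1].
#' @export
rra_rho <- function(percentiles, alpha = 0.25) {
  stopifnot(length(percentiles) >= 1L, alpha > 0, alpha <= 1)
  p <- sort(percentiles)
  m <- length(p)
  k <- sum(p <= alpha)
  if (k == 0L) return(1)
  i <- seq_len(k)
  min(pbeta(p[i], i, m - i + 1))
}

# rho for each row of a percentile matrix (rows = pseudo-genes of equal
# guide count); vectorized for the permutation null
rra_rho_rows <- function(pmat, alpha) {
  m <- ncol(pmat)
  ps <- t(apply(pmat, 1L, sort))
  if (m == 1L) ps <- matrix(ps, ncol = 1L)
  i <- matrix(rep(seq_len(m), each = nrow(ps)), nrow = nrow(ps))
  b <- pbeta(ps, i, m - i + 1)
  b[ps > alpha] <- Inf
  rho <- apply(b, 1L, min)
  rho[is.infinite(rho)] <- 1
  rho
}

#' Permutation p-values for observed alpha-RRA statistics
#'
#' The null reassigns observed guide percentiles at random to
#' pseudo-genes matched on guide count; the one-sided p-value uses the
#' add-one estimator `p = (1 + #\{null rho <= observed\}) / (n_perm + 1)`,
#' so its floor is `1 / (n_perm + 1)`.
#'
#' @param observed_rho named numeric vector of per-gene rho values.
#' @param gene_guide_count named integer vector: guides per gene (same
#'   names as `observed_rho`).
#' @param percentile_pool the full vector of guide percentiles to
#'   resample from.
#' @param alpha alpha-RRA cutoff used for the observed statistics.
#' @param n_permutations pseudo-genes drawn per distinct guide count
#'   (default 10000, minimum 100).
#' @param seed RNG seed; results are deterministic given it.
#' @return `data.frame(gene, rho, p, n_guides)`.
#' @export
permutation_p <- function(observed_rho, gene_guide_count, percentile_pool,
                          alpha = 0.25, n_permutations = 10000L, seed = 1L) {
  stopifnot(n_permutations >= 100L,
            all(names(observed_rho) %in% names(gene_guide_count)))
  set.seed(seed)
  counts_needed <- sort(unique(gene_guide_count[names(observed_rho)]))
  null_by_count <- lapply(counts_needed, function(g) {
    draws <- matrix(sample(percentile_pool, n_permutations * g, replace = TRUE),
                    nrow = n_permutations)
    sort(rra_rho_rows(draws, alpha))
  })
  names(null_by_count) <- as.character(counts_needed)
  p <- vapply(names(observed_rho), function(gene) {
    null <- null_by_count[[as.character(gene_guide_count[[gene]])]]
    (1 + findInterval(observed_rho[[gene]], null)) / (n_permutations + 1)
  }, numeric(1))
  data.frame(gene = names(observed_rho), rho = unname(observed_rho),
             p = unname(p),
             n_guides = unname(gene_guide_count[names(observed_rho)]),
             stringsAsFactors = FALSE)
}

#' One-sided gene essentiality / enrichment test on guide scores
#'
#' Runs the alpha-RRA + permutation machinery in both directions on a
#' guide-level statistic. The statistic is first averaged per guide
#' across replicates, then ranked once across all guides, so each guide
#' contributes a single percentile (replicate-level observations of one
#' guide share its plasmid representation and are not exchangeable with
#' each other; guides are). Non-targeting guides contribute to the
#' percentile pool and to the null but receive no gene-level call.
#'
#' @param guide_scores data.frame with columns `guide_id`, `gene`,
#'   `sample_id`, and the statistic column `cs` (e.g.
#'   `crispr_scores()$guide_scores`, optionally subset to one arm).
#' @param alpha alpha-RRA cutoff.
#' @param n_permutations permutations per guide-count stratum.
#' @param seed RNG seed.
#' @return `data.frame(gene, n_guides, rho_depletion, p_depletion,
#'   rho_enrichment, p_enrichment, fdr_depletion, fdr_enrichment)`.
#'   FDR columns are Benjamini-Hochberg adjusted and reported for
#'   reference; dependency calls use the raw permutation p.
#' @export
rra_test <- function(guide_scores, alpha = 0.25, n_permutations = 10000L,
                     seed = 1L) {
  stopifnot(all(c("guide_id", "gene", "sample_id", "cs") %in% names(guide_scores)))
  stat <- tapply(guide_scores$cs, guide_scores$guide_id, mean)
  gene <- guide_scores$gene[match(names(stat), guide_scores$guide_id)]
  one_direction <- function(direction, dir_seed) {
    pct <- percentile_ranks(as.numeric(stat), direction)
    targeting <- gene != NON_TARGETING
    rho <- vapply(split(pct[targeting], gene[targeting]), rra_rho,
                  numeric(1), alpha = alpha)
    n_g <- vapply(split(pct[targeting], gene[targeting]), length, integer(1))
    permutation_p(rho, n_g, percentile_pool = pct, alpha = alpha,
                  n_permutations = n_permutations, seed = dir_seed)
  }
  dep <- one_direction("depletion", seed)
  enr <- one_direction("enrichment", seed + 1L)
  stopifnot(identical(dep$gene, enr$gene))
  data.frame(
    gene = dep$gene, n_guides = dep$n_guides,
    rho_depletion = dep$rho, p_depletion = dep$p,
    rho_enrichment = enr$rho, p_enrichment = enr$p,
    fdr_depletion = p.adjust(dep$p, method = "BH"),
    fdr_enrichment = p.adjust(enr$p, method = "BH"),
    stringsAsFactors = FALSE
  )
}
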