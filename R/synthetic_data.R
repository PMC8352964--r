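# Synthetic screens, dose-response plates and tumor cohorts with the
# statistical structure the downstream analysis assumes.

#' Describe a synthetic pooled-screen scenario
#'
#' The generative model: each guide gets a plasmid representation drawn
#' log-normally; after `doublings` population doublings under a condition,
#' its expected proportion is the plasmid proportion times
#' `2^(doublings * effect)`, where `effect` is the per-doubling log2
#' fitness effect of the guide's target gene in that (cell_line,
#' condition) arm. Observed counts are negative binomial around
#' depth-scaled expected proportions.
#'
#' The first `round(essential_frac * n_genes)` genes are reference
#' essentials (planted effect `essential_effect` per doubling in every
#' grown arm), the next `round(nonessential_frac * n_genes)` are
#' reference nonessentials (effect 0); both feed the anchored
#' normalization. Remaining genes have effect 0 unless listed in
#' `effects`.
#'
#' @param n_genes number of targeting genes.
#' @param guides_per_gene guides per gene (library design constant).
#' @param n_control_guides number of non-targeting control guides.
#' @param doublings population doublings between infection and endpoint.
#' @param depth mean reads per guide.
#' @param dispersion negative-binomial size parameter (larger = tighter).
#' @param plasmid_spread log-normal sigma of plasmid representation.
#' @param effects `data.frame(gene, cell_line, condition, effect)` of
#'   planted per-doubling log2 fitness effects; default none.
#' @param essential_frac,nonessential_frac fractions of genes used as
#'   reference essential / nonessential anchors.
#' @param essential_effect per-doubling effect planted in reference
#'   essential genes.
#' @param seed integer RNG seed; every generator is deterministic given it.
#' @return list of class `screen_scenario`.
#' @export
screen_scenario <- function(n_genes = 500L,
                            guides_per_gene = 4L,
                            n_control_guides = 100L,
                            doublings = 12,
                            depth = 500,
                            dispersion = 10,
                            plasmid_spread = 0.5,
                            effects = NULL,
                            essential_frac = 0.1,
                            nonessential_frac = 0.2,
                            essential_effect = -0.25,
                            seed = 1L) {
  stopifnot(n_genes > 0, guides_per_gene > 0, n_control_guides > 0,
            dispersion > 0, depth > 0, plasmid_spread >= 0,
            essential_frac >= 0, nonessential_frac >= 0,
            essential_frac + nonessential_frac <= 1)
  if (is.null(effects)) {
    effects <- data.frame(gene = character(), cell_line = character(),
                          condition = character(), effect = numeric(),
                          stringsAsFactors = FALSE)
  }
  stopifnot(all(c("gene", "cell_line", "condition", "effect") %in% names(effects)))
  structure(list(
    n_genes = as.integer(n_genes),
    guides_per_gene = as.integer(guides_per_gene),
    n_control_guides = as.integer(n_control_guides),
    doublings = doublings, depth = depth, dispersion = dispersion,
    plasmid_spread = plasmid_spread, effects = effects,
    essential_frac = essential_frac, nonessential_frac = nonessential_frac,
    essential_effect = essential_effect, seed = as.integer(seed)
  ), class = "screen_scenario")
}

scenario_genes <- function(scenario) {
  sprintf("GENE%05d", seq_len(scenario$n_genes))
}

#' Reference gene sets implied by a screen scenario
#'
#' @param scenario a [screen_scenario()].
#' @return a [gene_set_registry()] with `essential_ref`,
#'   `nonessential_ref` and `qc_essential` (equal to the essential
#'   anchors; in real screens this is the KEGG
#'   spliceosome/ribosome/proteasome union).
#' @export
scenario_gene_sets <- function(scenario) {
  genes <- scenario_genes(scenario)
  n_ess <- round(scenario$essential_frac * scenario$n_genes)
  n_non <- round(scenario$nonessential_frac * scenario$n_genes)
  stopifnot(n_ess >= 1, n_non >= 1)
  ess <- genes[seq_len(n_ess)]
  non <- genes[n_ess + seq_len(n_non)]
  gene_set_registry(essential_ref = ess, nonessential_ref = non,
                    qc_essential = ess)
}

#' Simulate a guide library for a scenario
#'
#' @param scenario a [screen_scenario()].
#' @return a [guide_library()] with `n_genes * guides_per_gene` targeting
#'   guides plus `n_control_guides` non-targeting controls; deterministic
#'   given `scenario$seed`.
#' @export
simulate_library <- function(scenario) {
  stopifnot(inherits(scenario, "screen_scenario"))
  genes <- scenario_genes(scenario)
  g <- scenario$guides_per_gene
  gene_col <- rep(genes, each = g)
  guide_id <- paste0(gene_col, "_sg", rep(seq_len(g), times = length(genes)))
  ctrl_id <- sprintf("NTC%05d", seq_len(scenario$n_control_guides))
  n_total <- length(guide_id) + length(ctrl_id)
  rng <- local_rng(scenario$seed)
  seqs <- random_dna(n_total, width = 20L)
  guide_library(
    guide_id = c(guide_id, ctrl_id),
    sequence = seqs,
    gene = c(gene_col, rep(NON_TARGETING, length(ctrl_id)))
  )
}

local_rng <- function(seed) set.seed(seed)

random_dna <- function(n, width = 20L) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), width, replace = TRUE), collapse = "")
  }, character(1))
}

guide_effects <- function(library, scenario, cell_line, condition) {
  eff <- numeric(nrow(library))
  if (condition %in% c("plasmid", "ETP")) return(eff)
  if (round(scenario$essential_frac * scenario$n_genes) >= 1 &&
      round(scenario$nonessential_frac * scenario$n_genes) >= 1) {
    sets <- scenario_gene_sets(scenario)
    eff[library$gene %in% sets$essential_ref] <- scenario$essential_effect
  }
  tab <- scenario$effects
  tab <- tab[tab$cell_line == cell_line & tab$condition == condition, , drop = FALSE]
  if (nrow(tab)) {
    idx <- match(library$gene, tab$gene)
    hit <- !is.na(idx)
    eff[hit] <- tab$effect[idx[hit]]
  }
  eff[library$is_control] <- 0
  eff
}

#' Simulate a pooled CRISPR screen
#'
#' Draws plasmid guide proportions from a log-normal, propagates each arm
#' through `doublings` population doublings under the planted per-gene
#' effects, and emits negative-binomial counts at the scenario's depth.
#' Non-targeting guides always have effect 0; `plasmid` and `ETP` samples
#' reflect zero doublings of selection.
#'
#' @param library a [guide_library()].
#' @param design a [screen_design()] containing exactly one plasmid sample.
#' @param scenario a [screen_scenario()].
#' @return a [screen_counts()] object; deterministic given
#'   `scenario$seed` and the design row order.
#' @export
simulate_screen <- function(library, design, scenario) {
  stopifnot(inherits(library, "guide_library"),
            inherits(design, "screen_design"),
            inherits(scenario, "screen_scenario"))
  if (!any(design$condition == "plasmid")) {
    stop("design must contain a plasmid sample")
  }
  n <- nrow(library)
  rng <- local_rng(scenario$seed)
  plasmid_prop <- rlnorm(n, meanlog = 0, sdlog = scenario$plasmid_spread)
  plasmid_prop <- plasmid_prop / sum(plasmid_prop)
  total_reads <- scenario$depth * n
  counts <- matrix(0L, nrow = n, ncol = nrow(design),
                   dimnames = list(library$guide_id, design$sample_id))
  for (j in seq_len(nrow(design))) {
    cond <- design$condition[j]
    eff <- guide_effects(library, scenario, design$cell_line[j], cond)
    prop <- plasmid_prop * 2^(scenario$doublings * eff)
    prop <- prop / sum(prop)
    mu <- prop * total_reads
    counts[, j] <- rnbinom(n, mu = mu, size = scenario$dispersion)
  }
  screen_counts(counts, design, library = library)
}

#' Simulate a dose-response plate
#'
#' Viability follows a log-logistic inhibitor-response curve
#' `bottom + (top - bottom) / (1 + 10^((log10(d) - log10_ec50) * hill))`
#' plus Gaussian noise, truncated at 0.
#'
#' @param true_params list or named vector with `top`, `bottom`,
#'   `log10_ec50`, `hill`.
#' @param doses positive dose vector (molar).
#' @param noise_sd Gaussian noise standard deviation on the viability
#'   fraction.
#' @param seed RNG seed.
#' @param n_replicates replicates per dose.
#' @param compound compound label carried through to the output.
#' @return `data.frame(compound, dose, replicate, viability)`.
#' @export
simulate_dose_response <- function(true_params, doses, noise_sd = 0.05,
                                   seed = 1L, n_replicates = 2L,
                                   compound = "compound") {
  stopifnot(all(doses > 0))
  p <- as.list(true_params)
  rng <- local_rng(seed)
  grid <- expand.grid(dose = doses, replicate = seq_len(n_replicates),
                      KEEP.OUT.ATTRS = FALSE)
  mu <- logistic_viability(grid$dose, p$top, p$bottom, p$log10_ec50,
                           if (is.null(p$hill)) 1 else p$hill)
  v <- mu + rnorm(nrow(grid), sd = noise_sd)
  data.frame(compound = compound, dose = grid$dose,
             replicate = grid$replicate,
             viability = pmax(v, 0), stringsAsFactors = FALSE)
}

#' Describe a synthetic tumor-cohort scenario
#'
#' @param n_tumors cohort size.
#' @param alteration_rate probability a tumor carries the index-gene
#'   alteration (mutation or amplification).
#' @param hippo_genes pathway gene symbols whose low expression is
#'   tracked.
#' @param low_rate_altered,low_rate_nonaltered class-conditional
#'   probabilities that a tumor has >=1 low pathway gene.
#' @param expression_sd standard deviation of the generating log2
#'   expression distribution.
#' @param mutation_share fraction of altered tumors that are mutated
#'   rather than amplified.
#' @param seed RNG seed.
#' @return list of class `cohort_scenario`.
#' @export
cohort_scenario <- function(n_tumors = 230L,
                            alteration_rate = 37 / 230,
                            hippo_genes = hippo_gene_sets()$methods,
                            low_rate_altered = 0.757,
                            low_rate_nonaltered = 0.456,
                            expression_sd = 1,
                            mutation_share = 5 / 37,
                            seed = 1L) {
  stopifnot(n_tumors > 0,
            alteration_rate >= 0, alteration_rate <= 1,
            low_rate_altered >= 0, low_rate_altered <= 1,
            low_rate_nonaltered >= 0, low_rate_nonaltered <= 1,
            expression_sd > 0, length(hippo_genes) >= 1)
  structure(list(
    n_tumors = as.integer(n_tumors), alteration_rate = alteration_rate,
    hippo_genes = hippo_genes, low_rate_altered = low_rate_altered,
    low_rate_nonaltered = low_rate_nonaltered,
    expression_sd = expression_sd, mutation_share = mutation_share,
    seed = as.integer(seed)
  ), class = "cohort_scenario")
}

#' Simulate a tumor cohort for the co-occurrence analysis
#'
#' Each tumor draws an alteration flag from `alteration_rate` and a
#' pathway-low indicator from the class-conditional rate. Expression is
#' constructed so that the cohort-level low-expression rule (value below
#' the cohort mean minus one standard deviation, see
#' [call_low_expression()]) reproduces the planted indicator: non-low
#' values are drawn truncated above one generating-sd below the center
#' while each low tumor has one randomly chosen pathway gene planted four
#' generating-sd below it. The index gene (`RIT1`) gets a copy-number
#' driven expression shift in amplified tumors.
#'
#' @param scenario a [cohort_scenario()].
#' @return `data.frame` of class `cohort_table`: `tumor_id`, `mutation`,
#'   `amplification`, `diploid`, plus one log2-expression column per gene
#'   (index gene `RIT1` and every pathway gene).
#' @export
simulate_cohort <- function(scenario) {
  stopifnot(inherits(scenario, "cohort_scenario"))
  n <- scenario$n_tumors
  sdx <- scenario$expression_sd
  center <- 5
  rng <- local_rng(scenario$seed)
  altered <- runif(n) < scenario$alteration_rate
  mutation <- altered & (runif(n) < scenario$mutation_share)
  amplification <- altered & !mutation
  low_rate <- ifelse(altered, scenario$low_rate_altered,
                     scenario$low_rate_nonaltered)
  hippo_low <- runif(n) < low_rate
  genes <- scenario$hippo_genes
  expr <- matrix(truncnorm_above(n * length(genes), center, sdx,
                                 lower = center - sdx),
                 nrow = n, dimnames = list(NULL, genes))
  low_gene <- sample(length(genes), n, replace = TRUE)
  for (i in which(hippo_low)) {
    expr[i, low_gene[i]] <- center - 4 * sdx
  }
  rit1 <- rnorm(n, mean = center, sd = sdx) + ifelse(amplification, 1.5 * sdx, 0)
  out <- data.frame(
    tumor_id = sprintf("T%04d", seq_len(n)),
    mutation = mutation, amplification = amplification,
    diploid = !amplification,
    RIT1 = rit1,
    stringsAsFactors = FALSE
  )
  out <- cbind(out, as.data.frame(expr))
  class(out) <- c("cohort_table", "data.frame")
  out
}

# normal truncated below at `lower` via inverse-CDF sampling
truncnorm_above <- function(n, mean, sd, lower) {
  p_low <- pnorm(lower, mean, sd)
  qnorm(p_low + runif(n) * (1 - p_low), mean, sd)
}
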