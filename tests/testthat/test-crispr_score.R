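test_that("compute_lfc follows the pseudocount closed form and is monotone", {
  rpm <- cbind(plasmid = c(4, 10, 100), s1 = c(9, 10, 100))
  rownames(rpm) <- paste0("g", 1:3)
  lfc <- compute_lfc(rpm, "plasmid", pseudocount = 1)
  expect_equal(unname(lfc[, "s1"]), c(log2(10 / 5), 0, 0))
  # strictly increasing in sample RPM
  rpm2 <- rpm; rpm2[1, "s1"] <- 20
  expect_gt(compute_lfc(rpm2, "plasmid")[1, "s1"], lfc[1, "s1"])
  expect_error(compute_lfc(rpm, "plasmid", pseudocount = 0))
})

test_that("normalize_replicate centers at median 0 with MADs 1", {
  x <- c(-2, 0, 2)
  z <- normalize_replicate(x)
  expect_equal(median(z), 0)
  expect_equal(z[1], -z[3])
  set.seed(5)
  y <- rnorm(200, mean = 3, sd = 2)
  zy <- normalize_replicate(y)
  expect_equal(median(zy), 0)
  expect_equal(mad(zy), 1)
  # independent robust-statistics oracle
  expect_equal(zy, (y - median(y)) / (1.4826 * median(abs(y - median(y)))),
               tolerance = 1e-12)
  expect_error(normalize_replicate(c(1, 1, 1)), "MAD")
  expect_error(normalize_replicate(c(1, 2)), ">=3")
})

test_that("scale_to_anchors applies the affine map with gene-first medians", {
  # 12 guides over 6 genes: 3 essential anchors, 3 nonessential anchors
  lib <- guide_library(paste0("g", 1:12), rep(strrep("A", 20), 12),
                       rep(c("E1", "E2", "E3", "N1", "N2", "N3"), each = 2))
  ess <- c("E1", "E2", "E3"); non <- c("N1", "N2", "N3")
  # per-gene means: essentials 4, nonessentials 2 -> m_ess = 4, m_non = 2
  x <- setNames(c(rep(4, 6), rep(2, 6)), paste0("g", 1:12))
  expect_error(scale_to_anchors(x, lib, ess, non), ">=10")

  lib2 <- guide_library(paste0("g", 1:24), rep(strrep("A", 20), 24),
                        rep(c("E1", "E2", "E3", "N1", "N2", "N3"), each = 4))
  x2 <- setNames(c(rep(4, 12), rep(2, 12)), paste0("g", 1:24))
  cs <- scale_to_anchors(x2, lib2, ess, non)
  # closed form of the affine map with m_non = 2, m_ess = 4:
  # x = 0 -> +1 ; x = 4 -> -1
  expect_equal(unname((0 - 2) / (2 - 4)), 1)
  expect_equal(unname(cs[1]), -1)   # essential guides at m_ess
  expect_equal(unname(cs[13]), 0)   # nonessential guides at m_non
  expect_equal(attr(cs, "anchors"), c(nonessential = 0, essential = -1))

  # already-anchored input is the identity
  x3 <- setNames(c(rep(-1, 12), rep(0, 12)), paste0("g", 1:24))
  expect_equal(as.numeric(scale_to_anchors(x3, lib2, ess, non)),
               as.numeric(x3))
  # equal anchor medians -> no dynamic range
  flat <- setNames(rep(1, 24), paste0("g", 1:24))
  expect_error(scale_to_anchors(flat, lib2, ess, non), "dynamic range")
})

test_that("anchor medians are exactly (0, -1) per replicate across 100 synthetic screens", {
  worst <- 0
  for (s in 1:100) {
    sc <- screen_scenario(n_genes = 60L, n_control_guides = 20L,
                          essential_frac = 0.25, nonessential_frac = 0.25,
                          seed = s)
    lib <- simulate_library(sc)
    counts <- simulate_screen(lib, tiny_design(n_reps = 2L,
                                               conditions = "erlotinib"), sc)
    res <- crispr_scores(counts, lib, scenario_gene_sets(sc))
    dev <- max(abs(res$anchors[, "nonessential"]),
               abs(res$anchors[, "essential"] + 1))
    worst <- max(worst, dev)
  }
  expect_lt(worst, 1e-12)
})

test_that("collapse_to_genes averages guides within replicate then across replicates", {
  lib <- guide_library(paste0("g", 1:5), rep(strrep("A", 20), 5),
                       c(rep("GA", 4), "GB"))
  cs <- cbind(r1 = c(-1, -0.5, 0, 0.5, 2), r2 = c(-1, -1, -1, -1, 1))
  rownames(cs) <- lib$guide_id
  out <- collapse_to_genes(cs, lib)
  expect_equal(out$cs[out$gene == "GA"], mean(c(-0.25, -1)))
  # single-guide gene: gene score equals the guide mean across replicates
  expect_equal(out$cs[out$gene == "GB"], 1.5)
  expect_equal(out$n_guides, c(4L, 1L))
  # non-targeting guides are excluded
  lib_ntc <- guide_library(paste0("g", 1:5), rep(strrep("A", 20), 5),
                           c(rep("GA", 4), NON_TARGETING))
  out2 <- collapse_to_genes(cs, lib_ntc)
  expect_false(NON_TARGETING %in% out2$gene)
})

test_that("the scoring chain is invariant to rescaling any sample's raw counts", {
  sc <- screen_scenario(n_genes = 80L, n_control_guides = 30L,
                        essential_frac = 0.2, nonessential_frac = 0.25,
                        seed = 6L)
  lib <- simulate_library(sc)
  design <- tiny_design(n_reps = 2L, conditions = "erlotinib")
  counts <- simulate_screen(lib, design, sc)
  res1 <- crispr_scores(counts, lib, scenario_gene_sets(sc))
  scaled <- counts$counts
  scaled[, 2] <- scaled[, 2] * 5L
  res2 <- crispr_scores(screen_counts(scaled, design, lib), lib,
                        scenario_gene_sets(sc))
  expect_equal(res2$gene_scores$cs, res1$gene_scores$cs, tolerance = 1e-10)
})

test_that("gene CRISPR score decreases monotonically with planted effect size", {
  effects <- c(0, -0.1, -0.2, -0.3)
  cs_at_effect <- vapply(effects, function(e) {
    sc <- screen_scenario(
      n_genes = 100L, n_control_guides = 30L, seed = 17L, depth = 1000,
      effects = data.frame(gene = "GENE00100", cell_line = "RIT1",
                           condition = "erlotinib", effect = e))
    lib <- simulate_library(sc)
    counts <- simulate_screen(lib, tiny_design(n_reps = 2L,
                                               conditions = "erlotinib"), sc)
    res <- crispr_scores(counts, lib, scenario_gene_sets(sc))
    res$gene_scores$cs[res$gene_scores$gene == "GENE00100"]
  }, numeric(1))
  expect_true(all(diff(cs_at_effect) < 0))
})
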