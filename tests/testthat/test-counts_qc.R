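test_that("to_rpm normalizes every sample to one million, scale-invariantly", {
  lib <- tiny_library()
  design <- tiny_design(n_reps = 1L)
  m <- matrix(10L, nrow = 10, ncol = 3,
              dimnames = list(lib$guide_id, design$sample_id))
  m[, 2] <- c(rep(25L, 4), rep(5L, 6))
  x <- screen_counts(m, design, lib)
  rpm <- to_rpm(x)
  expect_equal(unname(colSums(rpm)), rep(1e6, 3))
  # equal counts split evenly
  expect_equal(unname(rpm[, 1]), rep(1e5, 10))
  # scaling a sample by 7 leaves its RPM unchanged
  m7 <- m; m7[, 2] <- m[, 2] * 7L
  expect_equal(to_rpm(screen_counts(m7, design, lib))[, 2], rpm[, 2])
  # all-zero column is an error naming the sample
  m0 <- m; m0[, 3] <- 0L
  expect_error(to_rpm(m0), colnames(m)[3])
})

test_that("low-abundance filtering removes exactly the sub-threshold guides and is idempotent", {
  lib <- tiny_library(n_genes = 5L, guides_per_gene = 4L, n_controls = 5L)
  design <- tiny_design(n_reps = 1L, conditions = "DMSO")
  n <- nrow(lib)
  set.seed(42)
  m <- matrix(rpois(n * 2, 200) + 10L, nrow = n,
              dimnames = list(lib$guide_id, design$sample_id))
  # plant k guides below 1 RPM in the plasmid column
  k <- 4L
  low_idx <- sample(n, k)
  m[low_idx, "plasmid"] <- 0L
  x <- screen_counts(m, design, lib)
  filt <- filter_low_abundance(x)
  # brute-force count of sub-threshold guides agrees
  rpm_plasmid <- m[, "plasmid"] / sum(m[, "plasmid"]) * 1e6
  expect_equal(attr(filt, "n_low_abundance_removed"), sum(rpm_plasmid < 1))
  expect_setequal(attr(filt, "low_abundance_guides"), rownames(m)[low_idx])
  expect_equal(nrow(filt$counts), n - k)
  # idempotent (threshold recomputed on the filtered pool stays satisfied)
  again <- filter_low_abundance(filt)
  expect_equal(nrow(again$counts), nrow(filt$counts))
  # all guides above threshold -> identity
  ok <- screen_counts(m[-low_idx, ], design, lib)
  expect_equal(nrow(filter_low_abundance(ok)$counts), n - k)
})

test_that("cross-targeting exclusion drops the printed sequences for the matching line only", {
  excl <- cross_targeting_exclusions()
  seqs <- c(excl$KRAS, excl$RIT1, strrep("A", 20), strrep("C", 20))
  lib <- guide_library(paste0("g", 1:5), seqs,
                       c("KRAS", "RIT1", "RIT1", "GENEX", NON_TARGETING))
  # KRAS line drops exactly the KRAS-listed sequence
  kras <- exclude_cross_targeting(lib, "KRAS")
  expect_identical(attr(kras, "excluded_guides"), "g1")
  # RIT1 line with both listed RIT1 sequences present drops exactly 2
  rit1 <- exclude_cross_targeting(lib, "RIT1")
  expect_setequal(attr(rit1, "excluded_guides"), c("g2", "g3"))
  expect_equal(nrow(rit1), 3L)
  # control line is the identity
  ctrl <- exclude_cross_targeting(lib, "control")
  expect_equal(nrow(ctrl), 5L)
  expect_length(attr(ctrl, "excluded_guides"), 0L)
})

test_that("replicate correlations match the direct covariance formula", {
  set.seed(8)
  x <- rnorm(50)
  m <- cbind(r1 = x, r2 = x, r3 = -x, r4 = rnorm(50))
  tab <- replicate_correlation(m)
  expect_equal(tab$r[tab$sample_a == "r1" & tab$sample_b == "r2"], 1)
  expect_equal(tab$r[tab$sample_a == "r1" & tab$sample_b == "r3"], -1)
  # textbook formula on one pair
  y <- m[, "r4"]
  r_direct <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(tab$r[tab$sample_a == "r1" & tab$sample_b == "r4"], r_direct)
  expect_equal(tab$r_squared, tab$r^2)
  expect_warning(replicate_correlation(m[, 1, drop = FALSE]), "fewer than 2")
})

test_that("ssmd matches the independent robust-statistics computation", {
  lfc <- setNames(c(-3, -2, -1, -0.5, 0, 0.5), paste0("g", 1:6))
  ess <- paste0("g", 1:3); ctrl <- paste0("g", 4:6)
  # independent oracle: medians and 1.4826-scaled MADs assembled by hand
  med_e <- median(c(-3, -2, -1)); med_c <- median(c(-0.5, 0, 0.5))
  mad_e <- 1.4826 * median(abs(c(-3, -2, -1) - med_e))
  mad_c <- 1.4826 * median(abs(c(-0.5, 0, 0.5) - med_c))
  oracle <- (med_e - med_c) / sqrt(mad_e^2 + mad_c^2)
  expect_equal(ssmd(lfc, ess, ctrl), oracle)
  expect_equal(ssmd(lfc, ess, ctrl), -1.206566, tolerance = 1e-6)

  # identical distributions give ~0; shift invariance; antisymmetry
  same <- setNames(rep(c(-1, 0, 1), 2), paste0("g", 1:6))
  expect_equal(ssmd(same, ess, ctrl), 0)
  expect_equal(ssmd(lfc + 5, ess, ctrl), ssmd(lfc, ess, ctrl))
  expect_equal(ssmd(lfc, ctrl, ess), -ssmd(lfc, ess, ctrl))

  # degenerate cases
  flat <- setNames(rep(0, 6), paste0("g", 1:6))
  expect_equal(ssmd(flat, ess, ctrl), 0)
  step <- setNames(c(rep(-2, 3), rep(0, 3)), paste0("g", 1:6))
  expect_warning(s <- ssmd(step, ess, ctrl), "Inf")
  expect_identical(s, -Inf)
  expect_error(ssmd(lfc, "g1", ctrl), ">=2")
})

test_that("qc_report flags replicates by SSMD < -0.5 on a planted essential screen", {
  sc <- planted_scenario(n_genes = 300L, seed = 13L)
  lib <- simulate_library(sc)
  design <- tiny_design(n_reps = 2L, conditions = c("DMSO", "erlotinib"))
  counts <- simulate_screen(lib, design, sc)
  rep_qc <- qc_report(counts, lib, scenario_gene_sets(sc),
                      expressed_oncogene = "RIT1")
  expect_true(all(rep_qc$replicates$ssmd < -0.5))
  expect_identical(rep_qc$replicates$pass,
                   rep_qc$replicates$ssmd < -0.5)
  expect_true(all(rep_qc$correlations$r >= -1 & rep_qc$correlations$r <= 1))
})
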