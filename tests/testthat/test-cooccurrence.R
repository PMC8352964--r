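test_that("the printed cohort contingency table reproduces the one-tailed p to 4 decimals", {
  # 28/37 altered tumors pathway-low vs 88/193 non-altered
  tab <- build_contingency(
    altered = rep(c(TRUE, FALSE), c(37, 193)),
    pathway_low = c(rep(c(TRUE, FALSE), c(28, 9)),
                    rep(c(TRUE, FALSE), c(88, 105))))
  expect_equal(unname(tab[1, ]), c(28, 9))
  expect_equal(unname(tab[2, ]), c(88, 105))
  expect_equal(round(fisher_one_sided(tab), 4), 0.0006)
})

test_that("alteration summary reproduces the printed cohort arithmetic", {
  altered <- call_altered(rep(c(TRUE, FALSE), c(5, 225)),
                          rep(c(FALSE, TRUE, FALSE), c(5, 32, 193)))
  s <- alteration_summary(altered)
  expect_equal(s$n_altered, 37L)
  expect_equal(s$n_total, 230L)
  expect_equal(s$percent_rounded, 16)
  expect_equal(s$percent, 100 * 37 / 230)
  expect_equal(alteration_summary(logical(10))$percent, 0)
  # random flag fixture vs brute-force OR count
  set.seed(10)
  m <- runif(100) < 0.3; a <- runif(100) < 0.2
  expect_equal(sum(call_altered(m, a)), sum(m | a))
})

test_that("fisher_one_sided agrees with enumeration and fisher.test for all small tables", {
  set.seed(19)
  for (i in 1:60) {
    n <- sample(4:60, 1)
    cells <- as.vector(stats::rmultinom(1, n, runif(4, 0.05, 1)))
    tab <- matrix(cells, 2, byrow = TRUE)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    p <- fisher_one_sided(tab)
    expect_equal(p, enumerate_fisher_p(tab), tolerance = 1e-12)
    expect_equal(p, stats::fisher.test(tab, alternative = "greater")$p.value,
                 tolerance = 1e-9)
  }
  # most-extreme table: single most-extreme arrangement, closed form
  ext <- matrix(c(3, 0, 0, 5), 2, byrow = TRUE)
  expect_equal(fisher_one_sided(ext), 1 / choose(8, 3))
  expect_warning(p1 <- fisher_one_sided(matrix(c(0, 3, 0, 5), 2)), "degenerate")
  expect_equal(p1, 1)
})

test_that("expression z-scores use the diploid reference distribution", {
  expr <- c(10, 12, 14, 20)
  diploid <- c(TRUE, TRUE, TRUE, FALSE)
  z <- zscore_vs_reference(expr, diploid)
  expect_equal(z[2], 0)                      # at the diploid mean
  expect_equal(z[3], 1)                      # one reference sd above (sd = 2)
  expect_equal(z, (expr - 12) / 2)
  expect_error(zscore_vs_reference(expr, c(TRUE, FALSE, FALSE, FALSE)), ">=2")
  expect_error(zscore_vs_reference(c(1, 1, 2), c(TRUE, TRUE, FALSE)),
               "zero spread")
})

test_that("low-expression calls use a strict mean-minus-sd rule with the expected tail mass", {
  # boundary: exactly at mean - sd is not low
  x <- c(0, 2, 4)  # mean 2, sd 2 -> threshold 0
  expect_equal(call_low_expression(x), c(FALSE, FALSE, FALSE))
  # clearly below the threshold is low
  expect_true(call_low_expression(c(-5, 1, 1, 1, 1))[1])
  # Gaussian cohort flags ~ the normal lower tail below -1 sd
  set.seed(33)
  g <- rnorm(20000)
  expect_equal(mean(call_low_expression(g)), pnorm(-1), tolerance = 0.02)
  # constant column -> none low, with warning
  expect_warning(none <- call_low_expression(rep(3, 5)), "zero")
  expect_false(any(none))
  # invariant to adding a constant; equivariant under positive rescaling
  y <- rnorm(100)
  expect_equal(call_low_expression(y + 7), call_low_expression(y))
  expect_equal(call_low_expression(y * 3), call_low_expression(y))
})

test_that("pathway-low OR and the contingency builder match brute-force counting", {
  set.seed(44)
  n <- 120
  cohort <- data.frame(H1 = rnorm(n), H2 = rnorm(n), H3 = rnorm(n))
  low <- any_hippo_low(cohort, c("H1", "H2", "H3"))
  manual <- call_low_expression(cohort$H1) | call_low_expression(cohort$H2) |
    call_low_expression(cohort$H3)
  expect_equal(low, manual)
  expect_error(any_hippo_low(cohort, c("H1", "NOPE")), "NOPE")
  altered <- runif(n) < 0.3
  tab <- build_contingency(altered, low)
  expect_equal(unname(tab[1, 1]), sum(altered & low))
  expect_equal(unname(tab[2, 2]), sum(!altered & !low))
  expect_equal(sum(tab), n)
})

test_that("cooccurrence_test runs the full cohort analysis on synthetic data", {
  cohort <- simulate_cohort(cohort_scenario(seed = 2L))
  res <- cooccurrence_test(cohort)
  expect_equal(sum(res$table), 230)
  expect_gt(res$prop_low_altered, res$prop_low_nonaltered)
  expect_lt(res$p, 0.05)
  expect_equal(nrow(res$flags), 230)
})

test_that("H-score is the intensity-weighted percent positivity", {
  expect_equal(h_score(c(0, 0, 100)), 300)
  expect_equal(h_score(c(0, 0, 0)), 0)
  expect_equal(h_score(c(0, 50, 0)), 100)
  expect_equal(h_score(c(10, 20, 30)), 10 + 40 + 90)
  expect_error(h_score(c(60, 30, 20)), "100")
  expect_error(h_score(c(-1, 0, 0)))
})

test_that("hippo gene lists match the published 7- and 6-gene sets", {
  sets <- hippo_gene_sets()
  expect_setequal(sets$methods,
                  c("AMOTL1", "NF2", "STK4", "STK38L", "MAP4K5", "TAOK3", "SAV1"))
  expect_setequal(setdiff(sets$methods, sets$figure), "NF2")
})
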