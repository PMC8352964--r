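#!/usr/bin/env Rscript
# Stage 7: tumor-cohort co-occurrence. First reproduces the published
# contingency analysis from its printed counts (28/37 altered tumors
# pathway-low vs 88/193 non-altered; one-tailed Fisher p = 0.0006), then
# runs the same machinery end to end on a synthetic 230-tumor cohort
# with the matching alteration rate and class-conditional pathway-low
# rates.

suppressPackageStartupMessages(library(oncodep))

# printed-table analysis
tab <- matrix(c(28, 9, 88, 105), nrow = 2, byrow = TRUE,
              dimnames = list(altered = c("yes", "no"),
                              hippo_low = c("yes", "no")))
cat(sprintf("printed table: %.0f%% of altered vs %.0f%% of non-altered tumors pathway-low\n",
            100 * tab[1, 1] / sum(tab[1, ]), 100 * tab[2, 1] / sum(tab[2, ])))
cat(sprintf("one-tailed Fisher p = %.4f\n", fisher_one_sided(tab)))

s <- alteration_summary(call_altered(rep(c(TRUE, FALSE), c(5, 225)),
                                     rep(c(FALSE, TRUE, FALSE), c(5, 32, 193))))
cat(sprintf("altered tumors: %d/%d = %d%%\n",
            s$n_altered, s$n_total, s$percent_rounded))

# synthetic cohort at the same design scale
cohort <- simulate_cohort(cohort_scenario(seed = 701L))
res <- cooccurrence_test(cohort)
print(res)
print(res$table)
write_scores(res$flags, "results/cohort_flags.tsv")
write.table(as.data.frame.matrix(res$table), "results/cohort_contingency.tsv",
            sep = "\t", quote = FALSE)

# H-score illustration on the IHC scale
cat(sprintf("example H-scores: strong diffuse %g, moderate half %g, negative %g\n",
            h_score(c(0, 0, 100)), h_score(c(0, 50, 0)), h_score(c(0, 0, 0))))
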