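---
title: "Mapping oncogene dependencies from isogenic pooled CRISPR screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping oncogene dependencies from isogenic pooled CRISPR screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oncodep)
```

## The problem

Isogenic cell-line panels — a parental line plus derivatives each
expressing one oncogene (here: mutant EGFR, KRAS, or RIT1 in an
EGFR-driven lung adenocarcinoma background) — make it possible to ask
which gene knockouts are lethal *because of* a specific oncogene. A
genome-scale pooled CRISPR knockout screen infects each line with a
guide library (~4 guides per gene plus non-targeting controls), grows
the pool for ~12 population doublings under vehicle or an EGFR
inhibitor, and sequences guide abundance at the endpoint. Guides whose
knockouts kill the cells drop out; guides whose knockouts confer a
growth advantage enrich.

`oncodep` implements the full downstream analysis: guide-level quality
control, anchored CRISPR-score normalization, permutation-based gene
significance, cross-line dependency classification, a differential
drug-sensitivity (delta-AUC) analysis, and a tumor-cohort
alteration/low-expression co-occurrence test. A synthetic-data module
generates screens, dose-response plates and cohorts with the
statistical structure the analysis assumes, so every stage is testable
without external data.

## Scoring model

For each endpoint replicate the chain is:

1. **RPM.** Counts are scaled to reads per million within each sample.
2. **LFC.** `lfc = log2((rpm + c) / (rpm_plasmid + c))` with pseudocount
   `c = 1` RPM. The comparison baseline is the plasmid library (early
   time points track plasmid closely; an ETP baseline is available via
   the `baseline` argument). The pseudocount bounds the LFC of guides
   with zero endpoint counts; 1 RPM is small against typical per-guide
   abundance (hundreds of RPM) so it perturbs well-covered guides
   negligibly.
3. **Robust normalization.** Each replicate's LFC column is centered at
   its median and divided by its scaled median absolute deviation
   (consistency constant 1.4826), giving median 0 / MADs 1 per
   replicate.
4. **Anchoring.** An affine map places the median of reference
   *nonessential* genes at 0 and the median of reference *essential*
   genes at −1: `cs = (x − m_non) / (m_non − m_ess)`. Anchor medians are
   computed gene-first (guide values averaged per gene before the median
   over anchor genes) so anchor genes with unequal surviving guide
   counts contribute equally; the alternative guide-level anchoring
   differs only when guide counts are very unbalanced. The (0, −1)
   anchor medians are asserted to floating-point accuracy on every run.
5. **Gene collapse.** Gene score = mean over the gene's guides within a
   replicate, then mean across replicates. Non-targeting guides are
   excluded. Zero-guide genes drop out of the table rather than carrying
   an undefined score.

The chain is invariant to rescaling any sample's raw counts by a
positive constant (RPM removes depth; the tests assert this property).

## Quality control

Guides under-represented in the plasmid library (< 1 RPM) are removed
before scoring; so are guides that fail to cut the introduced oncogene
cDNA in the matching line (a fixed, published sequence list — these
guides would otherwise score the oncogene as dispensable). Replicate
quality is summarized by the robust strictly standardized mean
difference between guides targeting a known-essential set (in real
screens the KEGG spliceosome/ribosome/proteasome union; in synthetic
screens the planted essential references) and non-targeting controls:

`ssmd = (median(ess) − median(ctrl)) / sqrt(MADs(ess)² + MADs(ctrl)²)`

Essential dropout makes this negative; replicates pass at SSMD < −0.5.
The numerator orientation (essential minus control) is chosen so that a
well-performing replicate is negative, consistent with that published
threshold. "Median average deviation" in the source protocol is read as
the median absolute deviation with the 1.4826 consistency constant —
the standard robust scale estimator; the phrase is otherwise
nonstandard.

## Significance: alpha-RRA with a permutation null

Gene-level one-sided significance re-implements the
robust-rank-aggregation approach of MAGeCK-style screen callers:

- The guide statistic (CRISPR score) is averaged per guide across
  replicates, then converted to percentile ranks `rank / (N + 1)` (ties
  averaged), ascending for depletion and descending for enrichment.
  Averaging before ranking matters: the two replicate observations of
  one guide share the guide's plasmid representation, so they are not
  exchangeable with each other, while guides are; ranking replicate
  observations separately and pooling them inflates the type-I error
  (we measured ~9% at nominal 5%), whereas per-guide averaging is
  calibrated.
- For a gene with sorted percentiles `p(1) ≤ … ≤ p(m)`, only
  percentiles ≤ α (default 0.25) count; the gene statistic is
  `rho = min over i ≤ k of BetaCDF(p(i); i, m − i + 1)`, the probability
  that the i-th order statistic of m uniforms is that extreme; `rho = 1`
  when no guide clears α. α = 0.25 encodes "only the top quarter of the
  ranking is evidence"; it is configurable.
- The null reassigns observed percentiles at random to pseudo-genes
  matched on guide count; `p = (1 + #{null rho ≤ observed}) /
  (n_perm + 1)`, an add-one estimator whose floor is `1/(n_perm + 1)`.
  No mid-p correction. Benjamini–Hochberg FDR is reported alongside,
  but calls use the raw permutation p, matching the published
  `|CS| > 0.5 and p < 0.05` rule.

Exact agreement with MAGeCK's own p-values on real data is not expected
(its internal normalization and variance model differ); the published
gene calls are a threshold rule on scores and one-sided p-values, which
this module reproduces structurally.

## Dependency classes

With per-arm essential (`cs < −0.5`, depletion `p < 0.05`) and
positively-selected (`cs > +0.5`, enrichment `p < 0.05`) flags:

- **oncogene dependency (line):** essential in that line's drug arm,
  not essential in the control line's vehicle arm. The control
  comparison uses the vehicle arm because control cells do not grow
  under the drug.
- **baseline synthetic lethal (line):** essential in the line's vehicle
  arm, not in the control vehicle arm.
- **pan-essential:** essential in every oncogene line's drug arm.
- **cooperating knockout (line):** positively selected in the line's
  drug arm.

A gene may carry several line-scoped labels. The "score < 0.5"
phrasing that sometimes accompanies depletion calls is read as
`cs < −0.5`, reconciling it with the `|CS| > 0.5` magnitude rule; each
direction is paired with its matching one-sided p. The three-line Venn
partition of essential calls is computed as an exhaustive, disjoint
7-region partition whose counts sum to the union; both a
common-universe and an all-lines-covered mode are meaningful, and the
partition function takes whatever call sets it is given.

## Drug screen

Plate luminescence is normalized to the mean of reference wells
(anchor-drug-only treatment). Dose-response uses the log-logistic
inhibitor model `v(d) = bottom + (top − bottom) / (1 + 10^((log10 d −
log10 EC50) · hill))`; the default three-parameter mode fixes
`hill = 1`, mirroring large-screen practice, and a four-parameter mode
is available. Fitting is bounded Levenberg–Marquardt (`minpack.lm`),
`top ∈ [0, 1.5]`, `bottom ∈ [0, top]`, EC50 within two decades of the
tested range; replicates are averaged per dose before fitting. A flat
plate returns `top = bottom` with the EC50 flagged undefined.

AUC integrates the fitted curve over log10 dose and divides by the
range width, so constant viability v yields AUC = v and compounds are
comparable on a [0, 1]-like scale regardless of their dilution series
(the exact AUC convention of commercial curve-fitting software is not
published; range normalization makes the choice explicit and testable).
Non-convergent fits fall back to the trapezoid rule on per-dose means.
Delta-AUC subtracts line A from line B per compound and median-centers
across compounds, so the bulk of the library sits at 0 and
line-selective compounds stand out in the tails.

## Cohort co-occurrence

Per tumor: altered = mutation OR amplification of the index gene;
expression z-scores are taken against the copy-number-diploid subset;
a gene is "low" in a tumor when its expression is strictly more than
one sample standard deviation below the cohort mean (log2 scale
assumed); the pathway-low flag is an OR over the Hippo gene list. The
default list is the 7-gene set (AMOTL1, NF2, STK4, STK38L, MAP4K5,
TAOK3, SAV1); a 6-gene variant without NF2 is provided as the named
alternative, since published figure and protocol lists differ. The
"STK38L MAP4K5" run-on in the source list is parsed as two genes. The
2×2 alteration × pathway-low table is tested with a one-sided Fisher
exact test (hypergeometric upper tail; direction fixed as "altered
tumors have the greater pathway-low proportion"). The IHC H-score is
`sum(percent positive × intensity)` over intensity bins 1–3, range
0–300.

## Synthetic data: what it emulates, and what it does not

`simulate_screen` draws plasmid guide representation log-normally
(sigma 0.5), propagates each arm as `proportion ∝ plasmid ×
2^(doublings × effect)` with per-doubling log2 fitness effects, and
emits negative-binomial counts (default dispersion size 10, depth 500
reads/guide). Effects are per doubling so the 12-doubling design maps
linearly to expected LFC (e.g. −0.125/doubling → −1.5 LFC). Reference
essential genes carry −0.25/doubling in every grown arm — strong
dropout comparable to the planted dependencies — and reference
nonessentials carry 0. Non-targeting guides always have effect 0.
Negative-binomial counts and Gaussian plate noise (truncated at zero
rather than resampled, which slightly inflates mass at zero for
near-zero means) are standard noise models; the generator does not
model infection MOI, selection kinetics, guide-efficiency
heterogeneity, copy-number artifacts, or batch effects. Passing tests
on synthetic screens therefore demonstrate the statistical machinery
under its stated assumptions, not robustness to those real-data
complications.

`simulate_cohort` draws the alteration flag and a class-conditional
pathway-low indicator per tumor, then constructs expression so the
cohort-level low-expression rule reproduces the indicator exactly:
non-low values are drawn from a normal truncated at one generating-sd
below center, and each low tumor has one randomly chosen pathway gene
planted four generating-sd below center. Because the rule's threshold
(cohort mean − sd) is estimated from the realized cohort, this
guarantee is by construction of the margins: for moderate low rates
the realized threshold lands strictly between the two groups. Extreme
rates (near 0 or 1 for every gene) would squeeze those margins; the
default rates (75.7% vs 45.6%, the published proportions) are far from
that regime.

## Problem sizes and numerical choices

The packaged experiments use screens of 500–2,000 genes × 4 guides,
2 replicates per arm, 1,000–2,000 permutations — large enough that the
calibration band (fraction of null genes with p < 0.05 within
[0.03, 0.07]) and the ≥95%/≥90% detection targets are meaningful, and
small enough to run in seconds. Anchor-median assertions use 1e-12;
dose-response recovery on noiseless curves is asserted at 1e-6; the
Fisher test is checked against full enumeration for tables with n ≤ 60.
Degenerate inputs fail loudly where a silent answer would be wrong
(zero-MAD replicate, equal anchor medians, zero-spread z-score
reference) and fall back with a warning where a defensible value exists
(zero-spread low-expression column → no calls; degenerate Fisher margin
→ p = 1; flat dose-response → constant AUC).

## Known limitations

- The permutation null is shared per guide-count stratum, so p-values
  of different genes are correlated; fractions of significant genes
  fluctuate slightly more than binomially.
- Anchored scaling requires both anchor sets (≥10 guides each) in every
  replicate; screens without reference-gene coverage cannot be scored
  on the CS scale (the RRA test itself runs on any monotone statistic,
  e.g. the normalized LFC).
- Gene collapse is the simple mean of guide scores; no guide-efficacy
  weighting or copy-number correction.
- The dose-response model assumes monotone inhibitor response; biphasic
  curves will fit poorly and should be caught via the convergence flag
  and residual norm.
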