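---
title: "Models and methods behind pairscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pairscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pairscreen)
library(dplyr)
```

## The screen this package analyses

A dual-crRNA Cas12a array encodes two spacers on one cassette
(DR–spacer1–DR–overlap–DR–spacer2–DR, where DR is the Cas12a direct repeat
and the overlap is the complementary end used to splice the two
half-cassettes during assembly), so a single construct knocks out two genes
at once. A pooled library of such arrays crosses a kinase set with a
metabolism set: every kinase x metabolism pair is a double knockout (DKO),
every targeting gene paired with each non-targeting control (NTC) spacer is
a single knockout (SKO), and NTC–NTC arrays carry no targeting spacer at
all. With 15 kinases, 12 metabolism genes and 5 controls this gives the
canonical composition of 340 arrays: 180 DKO, 135 SKO (27 genes x 5
controls) and 25 NTC–NTC (5 x 5 ordered control pairs). The number of
control spacers is not a free-floating constant in the package: it is a
parameter of `enumerate_arrays()`, with 5 as the default because it is the
only value consistent with that composition. SKO arrays carry the targeting
spacer in position 1 by convention; NTC–NTC pairs are ordered, which is
what makes 5 controls yield exactly 25 control arrays.

Spacer admission rules (`check_spacer_rules()`): 20-nt A/C/G/T guides,
GC fraction within [0.30, 0.70] (inclusive, computed over the spacer only)
and a 5'-TTTV PAM context for targeting spacers. Controls have no genomic
target and therefore no PAM. Rule violations are reported as codes rather
than errors so candidate tables can be screened wholesale.

The DR and complementary-overlap sequences are properties of the construct
actually sequenced. The package defaults (`default_dr_sequence()`, the
19-nt canonical Cas12a direct repeat, and `default_overlap_sequence()`, a
synthetic 15-nt placeholder) are intended for simulation and examples; real
analyses should supply their own.

## From paired reads to abundances

Amplicon read pairs covering the cassette are merged by exact
suffix/prefix overlap of read 1 and the reverse complement of read 2
(`merge_read_pairs()`). The minimum qualifying overlap is 31 bp (strictly
more than 30); no mismatches are tolerated, because the reads cover a fixed
synthetic cassette, and `N` counts as a mismatch even against another `N`.
Pairs without a qualifying overlap are dropped and tallied.

Counting (`count_merged_reads()`) matches each merged read against the
library's *signatures* — the full inter-spacer cassette
`spacer1 + DR + overlap + DR + spacer2` — rather than spacer pairs alone,
which could collide across SKO/NTC arrays sharing spacers. A read
increments exactly one array when exactly one signature matches (with a
reverse-complement retry for unmatched reads); reads matching none or
several are tallied separately in the QC attribute. Matching uses a
Biostrings `PDict`, so counting a full sample is a single pass.

Counts are normalized per sample to reads per million
(`to_rpm()`), and fold-changes between a final and an initial sample are
`FC = (rpm_final + pc) / (rpm_initial + pc)` with a 1-rpm pseudocount by
default (`compute_lfc()`), log2-transformed to LFC. The pseudocount guards
dropouts; it is exposed because the exact ratio (pseudocount 0) is the
cleaner object in noise-free analyses.

One practical warning that shapes the whole package: LFCs of many final
samples computed against the *same* initial sample all inherit that
sample's measurement error. For plotting this is harmless; for tests that
treat per-sample LFCs as independent observations it is pseudo-replication
and badly inflates significance (in our simulations the nominal 5% null
rejection rate of the rank-sum model became ~36%). `compute_lfc(paired =
TRUE)` therefore pairs each final sample with its own reference, and
`screen_lfc()` builds the canonical table for simulated screens: cell
day-14 replicate k against cell day-4 replicate k, and each day-18 tumour
against the day-10 tumour with the same index, so every reference sample is
used exactly once. With this construction the rank-sum null rate is back at
5%.

## Interaction model 1: expected versus observed DKO enrichment

For each DKO pair (A, B) the package collects eight medians on the rpm
scale (`median_abundance_summary()`): the DKO array's median abundance in
the tumour and cell screens (D_t, D_c), each gene's SKO median (A_t, A_c,
B_t, B_c; median over all of that gene's SKO arrays x samples — the
array-then-sample order of operations is not fixed by convention, so the
package documents this pooled-median choice), and the NTC–NTC median (N_t,
N_c). Then, under NTC normalization,

- observed DKO enrichment = (D_t / D_c) x (N_c / N_t)
- expected DKO enrichment = (A_t / A_c) x (N_c / N_t) + (B_t / B_c) x (N_c / N_t)

A DKO that behaves exactly like the controls has observed enrichment 1; two
neutral genes have expected enrichment 2; and additivity means observed
equals the sum of the single-gene terms. `synergy_by_enrichment()`
regresses observed on expected across all pairs and flags outliers by
externally studentized residuals referenced to t(n − 3), with
Benjamini–Hochberg adjustment and alpha = 0.05 on the adjusted p-values.
Negative residuals are depletion beyond additivity — synergy under negative
selection. BH is used (rather than a Bonferroni-style outlier correction)
throughout the package.

The same studentized-residual machinery drives the tumour-versus-cell
regression screen (`regression_cell_vs_tumour()` over
`screen_entity_abundance()`): entities are DKO arrays plus per-gene
collapsed SKOs (`collapse_sko_per_gene()`), summarized as mean
log2(rpm + 1) per condition. The log2 scale is a package choice to
stabilize variance; raw-rpm entities can be supplied instead, since the
regression accepts any entity table.

Numerical edge cases are handled explicitly: a numerically exact fit
yields residuals that are floating-point noise, so all studentized
residuals are set to 0 and all p to 1; a point whose leave-one-out fit is
exact while its own residual is real is an infinite outlier (p = 0).

## Interaction model 2: rank-sum of DKO versus SKO fold-changes

`synergy_by_rank_test()` compares, per pair, the DKO array's per-sample
LFCs against the pooled per-sample LFCs of both genes' SKO arrays with a
two-sided Wilcoxon rank-sum test (exact null distribution when both groups
have at most 8 observations and no ties, otherwise the normal approximation
with tie and continuity corrections), BH-adjusted across pairs. Pooling the
two genes' SKOs is the default reading of "pair versus corresponding single
genes"; a `per_gene_min` strategy (test against each gene's SKOs
separately, keep the smaller p) is exposed for exploration but is
anti-conservative. When every observation is tied the test carries no
information and p = 1 is returned.

## The virtual double-knockdown survival screen

Given an expression-by-sample cohort with survival times and event
indicators, `run_virtual_screen()` emulates joint inhibition of a gene
pair: samples are split into bottom-quartile (low) and top-quartile (high)
groups of the *mean* normalized expression of the two genes
(`percentile_groups()`, linear-interpolation percentiles, boundary-equal
samples included in the group), and the two groups are compared by the
log-rank (Mantel–Cox) test on Kaplan–Meier curves; the same is done for
each gene alone. The survival-difference test is the package's choice of
log-rank, the standard 1-df comparison. Each pair is scored against each of
its genes by `log1p` of a p-value ratio, and classified: both scores above
1 with the low-expression group surviving longer is `favourable`, both
above 1 with the low group surviving worse is `unfavourable`, anything else
`neutral`. Direction comes from comparing KM median survival of the two
groups, falling back to final survival when neither curve reaches 0.5;
pairs with non-finite scores are dropped and logged, and log-rank p-values
are floored at 1e-300 so ratios stay finite.

Two genuinely open choices are worth spelling out:

- **Score orientation.** Read literally, the score is
  `log1p(p_pair / p_single)`, which exceeds the threshold of 1 exactly when
  the pair's p-value is *larger* than the single gene's — the opposite of
  highlighting pairs whose joint stratification is more prognostic. The
  package default is therefore the reciprocal, `log1p(p_single / p_pair)`,
  which selects pairs that beat their single genes; `orientation =
  "literal"` restores the verbatim reading. A score equals 1 exactly at
  ratio e − 1.
- **Pure interactions are invisible to mean-based quartiles.** In the
  cohort generator the log hazard is linear in standardized log expression
  z with an optional product term: `log h = log h0 + sum beta_g z_g +
  beta_int z_A z_B`. Stratifying on the *mean* expression of the pair is
  symmetric: both the low–low and high–high tails have positive z_A z_B, so
  a pure product interaction (all beta_g = 0) shifts both groups' hazards
  equally and produces no log-rank signal. Detectable planted pairs
  therefore combine main effects with the interaction term, which is how
  the package's recovery benchmarks are constructed
  (beta_A = beta_B = 0.3 with beta_int = −0.4 at n = 400).

Cohort exclusions (e.g. removing samples with a particular viral etiology)
are a plain logical column passed as `exclude =`, not hard-coded logic.

## What the simulators emulate — and what they do not

`simulate_screen()` generates the full sample grid of a desk-scale screen:
one plasmid library, cell pools at day 4 and day 14 (3 replicates each) and
tumours at day 10 and day 18 (6 each). Initial abundances are log-normal
(sdlog 0.5, a moderate cloning skew; 0 gives a perfectly uniform library).
Selection is additive on the log2 scale, `s_i = f_gene1 + f_gene2 +
epsilon_i`, applied once per screen interval: day-14 cells carry one round,
day-10 tumours one in vivo round from the injected (selected) pool, and
day-18 tumours a second one — later harvests are more selected, which also
gives the day-18/day-10 fold-change a one-round interpretation. Tumours
additionally pass a per-mouse multinomial transplantation bottleneck
(default 1e5 cells), and sequencing counts are negative binomial with
variance mu + dispersion * mu^2 (dispersion 0.1, a typical pooled-screen
overdispersion; 0 gives Poisson). Default depth is 500 reads per array. In
noise-free mode the expected counts are returned exactly, and the
enrichment formulas reduce to closed form: observed = 2^(f_A + f_B +
epsilon) and expected = 2^f_A + 2^f_B, which the tests assert to 1e-6.

`simulate_fastq()` embeds each cassette in fixed pseudo-random flanks so
mates overlap by a chosen amount (default 100 bp of 150-bp reads) and the
merge–count round trip recovers planted counts exactly.
`simulate_cohort()` draws log-normal expression, exponential survival times
from the log-linear hazard above, and independent uniform censoring whose
upper bound is solved numerically so the expected censored fraction matches
the requested value.

None of this emulates PCR amplification bias, off-target cutting, multiple
lentiviral integrations, clonal growth dynamics within tumours, or
quality-score structure in reads; passing the planted-recovery benchmarks
therefore demonstrates that the statistical pipeline is correct and
calibrated under its stated noise model, not that any particular biological
screen will behave this way.

## Problem sizes and calibration results baked into the tests

The test suite runs entirely on generated data: the 340-array library, 20
planted-interaction screens per recovery benchmark (5 pairs at epsilon =
−2, dispersion 0.1, 3 cell replicates, 6 tumours), 2000 null rank-sum pair
tests, 1000 replicates of the 20-point null outlier screen, 20 planted
cohorts and 40 null cohorts (n = 400 each) for the virtual screen. On a
single core the whole suite completes in under two minutes. The one
published-scale quantity the package reproduces by construction is the
library composition; screen-level biological findings require real data
and are out of scope here.

Known limitations: exact-match merging will discard genuinely erroneous
reads rather than rescue them (no quality-aware merging); the enrichment
model's t-based outlier p-values are approximate under skewed
median-of-ratio noise, so BH control there is nominal rather than exact
(the null flag rate in simulations is well below alpha, but heavy-tailed
screens can still promote a null pair to the top rank); and the rank-sum
model's independence requires the paired-LFC construction described above.
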