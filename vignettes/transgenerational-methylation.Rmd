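---
title: "Detecting inherited sperm methylation change with methylegacy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting inherited sperm methylation change with methylegacy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylegacy)
library(dplyr)
```

## The question and the design

A paternal-line multigeneration design asks whether an exposure received
early in life by F1 males leaves methylation marks in their sperm that
persist in the sperm of unexposed sons (F2) and grandsons (F3). The data are
reduced representation bisulfite sequencing (RRBS) counts: for each sperm
sample and each CpG, a methylated and an unmethylated read count. The default
design has 6 exposed and 6 control animals in each of three generations.

Two questions are separated deliberately:

1. **Per generation** — which 100-bp tiles are differentially methylated
   (DMS) between exposed and control sperm?
2. **Across generations** — is the number of DMS called *with the same
   direction* in F1 and F2 (or F1, F2 and F3) larger than chance would
   allow, given how DMS counts behave when case/control labels are
   permuted?

## Per-generation detection

Processing follows the standard RRBS recipe:

* **Coverage cap.** Per sample, sites with coverage strictly above the
  nearest-rank 99.9th percentile of that sample's coverage vector are
  discarded (a PCR-duplicate guard). Nearest-rank is used because it is
  deterministic — no interpolation ambiguity; a small epsilon guards the
  rank computation against floating-point noise in `q * n / 100`. The cap
  is computed per sample (a global variant is available via
  `percentile_scope = "global"`), and it is applied *before* uniting:
  swapping the two steps changes which sites survive, and a regression test
  pins the order.
* **Uniting.** A site is retained for a generation only if it has at least
  `min_reads_per_sample` (default 10) reads in *every* sample of that
  generation — a per-sample floor, not a mean.
* **Tiling.** Surviving CpGs are summed into non-overlapping 100-bp windows
  anchored at position 0 of each chromosome; windows need at least 1 CpG,
  and the 10-read floor is re-checked on the tile sums (configurable via
  `recheck_tile_coverage`; whether the floor applies to sites, tiles or both
  is genuinely ambiguous in the field, so both gates are on by default and
  each is independently switchable).

The per-tile test (`test_tile()`, `diff_methylation()`) is a binomial
logistic regression of methylated versus unmethylated counts on group
membership, assessed by likelihood ratio. With a group-only covariate the
fitted proportions are the group-pooled proportions, so the LR statistic
reduces to the G-statistic of the pooled 2×2 table — the implementation
exploits this closed form and the test suite cross-checks it against
`glm(cbind(M, U) ~ group, binomial)`. A pooled two-sided Fisher exact test
(`method = "fisher_pooled"`) is provided as an exactly-enumerable
alternative and is verified against brute-force hypergeometric enumeration.
No overdispersion correction is applied by default, matching the classical
logistic tiling analysis; the beta-binomial simulator (below) quantifies
what that costs in false positives.

The methylation difference is reported as the difference of
coverage-weighted pooled group proportions, in percentage points. "Average
difference between groups of replicates" can also be read as the difference
of per-sample means; that variant is available (`diff_method = "mean"`) but
pooled is the default, matching the convention of tiling-window software.

Multiple testing uses Benjamini–Hochberg step-up q-values. Some historical
pipelines used SLIM q-values instead; BH is exactly specified and
reproducible, and the q threshold is configurable, so any divergence is
transparent. Calling uses a stringency preset: `COV10_Met20` (q ≤ 0.01 and
|Δ| ≥ 20 points) or the relaxed `COV10_Met10` (|Δ| ≥ 10). A tile is `hyper`
if Δ ≥ +min_diff, `hypo` if Δ ≤ −min_diff; with `min_diff = 0` a strict
sign requirement keeps the two categories disjoint at Δ = 0.

## Conservation and the permutation test

A tile is *conserved* along a generation chain if it is called with the same
direction in every generation of the chain; coordinates must match exactly,
which fixed tiling guarantees when all generations share one filter
configuration (an error is raised on mixed units). Because each generation
is united on its own samples, `conserved_sites()` also reports the number of
jointly-testable coordinates, so sparsity is visible rather than silent.

Significance comes from `run_permutation_test()`: for each permuted
case/control assignment the *entire* detection procedure — unite, tile,
test, adjust, call, conserve — is re-run, and

\[ p = \frac{\#\{\text{permutations with conserved count} \ge \text{observed}\}}{N} . \]

The k/N estimator is used (not (k+1)/(N+1)) so that reported proportions at
N = 3962 like 7/3962 = 0.00177 are reproduced exactly; the caveat is that p
can be exactly 0, and an `add_one = TRUE` option provides the conservative
estimator. "At least as extreme" is evaluated separately for hyper- and
hypo-conserved counts (two one-sided statistics). Two permutation schemes
are implemented, both preserving the per-cell sample counts: the default
`across_generations` pools all samples and re-deals them into the original
(generation, group) cells; `within_generation` shuffles labels inside each
generation only. Which labels were exchangeable in the original analyses of
this kind is not fully specified in the literature, so neither mode is
claimed to be "the" original — the default follows the broader reading
("between all cases, controls and generations"). The observed assignment is
not counted among the N permutations, duplicate permutations are allowed
(N is far below the group size at 6/6 × 3), and an exhaustive mode
enumerates every distinct within-generation assignment when the group is
small. A permutation on which detection collapses contributes a conserved
count of 0 rather than being dropped. N = 3962 is kept as a plain
configurable default. `convergence()` reports the running p estimate and
flags estimates that still move by more than a tolerance over the last 20%
of permutations; below 100 permutations it declares itself not evaluable.

## The simulator: what it emulates, what it does not

`simulate_dataset()` generates the study design with a known truth table:

* **Bimodal baseline.** Site means are drawn from a Beta(1,10)/Beta(10,1)
  mixture (weights configurable) and clipped to [0.02, 0.98] — a sperm
  methylome is mostly near-0 or near-1, and clipping avoids degenerate
  all-0/all-1 sites that break logistic fitting.
* **Regional coherence.** The baseline level and any injected effect are
  shared by all CpGs of a 100-bp region (`region_width`). Neighbouring CpGs
  co-vary in real methylomes — that is the premise of tiling-window
  analysis — and without this, an injected single-CpG effect would be
  diluted by null sibling CpGs in the same tile, making the generator
  contradict its own truth table at the tile level.
* **Counts.** Coverage is negative binomial (mean 30, size 20 by default:
  overdispersed but rarely below the 10-read floor); methylated counts are
  beta-binomial around the site's group mean with overdispersion
  φ ∈ [0, 1) (`phi = 0` is exactly binomial). φ = 0.05 is the default
  replicate noise.
* **Injected effects.** `n_dms` regions receive a mean shift of
  `effect_delta` (default 0.25; the spec of real effect sizes is unknown,
  so this is a package choice) in the exposed group. If the baseline is too
  close to a boundary for the shift, the direction is forced away from the
  boundary so the truth direction always matches the sign of the realized
  group-mean difference. Half of the F1 effects persist in F2 and a quarter
  in F3 by default, nested (F3-active ⊂ F2-active); a non-nested mode
  exists because real conserved sets need not nest.

The simulator does **not** model read-level artefacts (bisulfite conversion
error, mapping bias), chromosome-scale genome structure, strand effects, or
between-sample coverage normalisation. Passing tests on simulated data
therefore demonstrate the statistical machinery — calibration under the
null, recovery of planted regional effects — not robustness to alignment-
or chemistry-level artefacts in real RRBS.

## Annotation

Gene models (GTF/GFF3/BED12, or the toy generator `random_gene_model()`)
are decomposed into seven categories with a redefined promoter: a
strand-aware window from 2 kb upstream to 100 bp downstream of the TSS. The
TTS window is ±100 bp (no consensus value exists; it is configurable).
Tiles are annotated by their midpoint base so each receives exactly one
category, and overlaps resolve by the fixed precedence promoter > TTS >
5'UTR > 3'UTR > exon > intron (no published precedence exists for this
analysis; the order is documented and verified against brute-force overlap
evaluation). Sites overlapping nothing are intergenic: the nearest gene by
TSS distance is attached for reference but flagged `gene_excluded`, because
nearest-gene assignments in intergenic space are unreliable and should not
enter downstream gene sets.

## Reproductive endpoints

The closed-form endpoints of the companion phenotype analysis are pure,
vectorised functions (`conception_rate()`, `fertility_rate()`,
`preimplantation_loss()`, `neonatal_mortality()`, `postnatal_mortality()`,
`dfi()`, `daily_spermatid_production()`, `relative_weight()`), plus the
table-level wrapper `litter_metrics()`. Integer-percent reporting uses
round-half-away-from-zero (`round_half_up()`), which is how 8 dead of 64
pups (12.5%) is reported as 13%. Note one documented inconsistency in this
literature: a 32% neonatal mortality figure quoted in text alongside a
caption whose numbers (35 live births of 58 implantations) give 39.7% by
the printed formula; both numbers are preserved here as documentation, and
the function implements the formula.

## Numerical choices and check sizes

* Internal coordinates are 0-based half-open everywhere; conversion happens
  only at file boundaries (count dialects are 1-based, BED is 0-based).
* The percent-methylation column of count files is recomputed from counts,
  never trusted (warning past a 0.1-point discrepancy).
* Tiles with zero group coverage get `p = NA` and are excluded from BH
  adjustment (NA does not count toward m).
* The pipeline seed derives per-stage seeds as
  `(seed * 101 + stage) mod (2^31 - 1)` so stages can be re-run alone.
* Null calibration is checked on 200 simulated null datasets of 2,000 sites
  with 99 permutations each; the conserved-count statistic for that check
  is computed at a permissive calling threshold (any q, any non-zero
  difference), because under the stringent preset the null statistic is
  identically zero — every permutation ties the observed zero and p ≡ 1,
  which is conservative but carries no information about calibration. The
  stringent preset's false-call rate is checked separately on the same
  datasets. Parameter recovery is checked on 20 studies of 2,000 sites with
  199 permutations each. These sizes are the package's chosen compromise
  between Monte-Carlo resolution and a test suite that runs in minutes.

## Known limitations

* BH q-values will not numerically match analyses that used SLIM.
* The logistic test ignores replicate overdispersion; with strongly
  overdispersed data the stringent Δ gate absorbs much of the excess, but a
  beta-binomial caller is out of scope.
* Conservation requires exact tile identity; site-unit runs can use an
  overlap-based comparison only by re-tiling.
* The permutation engine is single-process; results are seed-stable by
  construction.
* No CpG-island, CTCF or insulator annotation, and no enrichment analysis:
  those depend on external, version-dependent databases.
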