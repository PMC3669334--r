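---
title: "Ratio-based discovery of tissue-specific genes across two species"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ratio-based discovery of tissue-specific genes across two species}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tissuespec)
```

## The problem

A gene expressed almost exclusively in one tissue is a candidate marker,
drug target, or entry point into that tissue's biology. Given curated
microarray DataSets (GDS) for a panel of tissues in two species — here
kidney, liver, lung, heart, muscle and adipose, profiled with 2 replicate
samples per tissue in human and 3 (4 for muscle) in mouse — tissuespec
ranks every gene by how concentrated its expression is in a chosen target
tissue, and keeps the genes that rank highly in *both* species. Requiring
cross-species agreement is the key noise filter: a ranking artifact on one
platform is unlikely to recur independently on the other.

## The specificity score

Let $m_t$ be a gene's replicate-averaged expression in tissue $t$, and let
$T$ be the target tissue with $k$ other tissues $t_1,\dots,t_k$. The
package computes two formulations:

$$
s_i \;=\; \frac{1}{k}\sum_{j=1}^{k}\frac{m_{t_j}}{m_T}
\qquad\text{(low = specific, sort ascending)}
$$

$$
s_v \;=\; \frac{m_T}{\frac{1}{k}\sum_{j=1}^{k} m_{t_j}}
\qquad\text{(high = specific, sort descending)}
$$

Because every ratio in $s_i$ shares the same denominator $m_T$, the mean of
ratios collapses to a ratio of means and the two scores are exact
reciprocals, $s_v = 1/s_i$. They therefore induce identical rankings; both
are kept so either published ordering convention can be reproduced, and the
reciprocity is asserted in the test suite rather than assumed.

The score operates on the deposited intensities as-is: no log transform and
no pseudocount. Both formulations are scale-free (multiplying a whole
dataset by a constant changes nothing), which also makes the ranking
insensitive to global normalization differences between platforms.

Worked example, from the packaged mouse kidney table: FXYD2 has kidney mean
9786 and other-tissue means 76, 99, 113, 106, 215, so
$s_v = 9786 / 121.8 = 80.34$ and $s_i = 1/80.34 = 0.01245$.

```{r}
kid <- score_specificity(load_printed_table("mouse", "kidney"), "kidney")
kid[kid$gene_symbol == "FXYD2", c("gene_symbol", "score_i", "score_v")]
```

### Edge cases

A score is only computed when the target mean is defined and strictly
positive and every non-target mean is defined. Anything else gets an
`excluded_reason` instead of a number: scoring on fewer tissues would break
the reciprocity between $s_i$ and $s_v$ and make ranks incomparable across
genes. Excluded features sort after all scored features. Ties (rare with
continuous intensities, common in constructed fixtures) break
deterministically by gene symbol, then feature id.

### Probe-to-gene collapsing

Array platforms carry several probes per gene. Collapsing happens at
ranking time and keeps each symbol's best-ranked probe, rather than
averaging probe intensities: probes of one gene can differ in affinity by
orders of magnitude, and best-rank preserves the identity of the winning
probe for reporting. Unannotated probes are kept per probe.

## Cross-species intersection

Gene-level rankings for the same target tissue are intersected within a
rank cutoff `k` (default 100 — the scale of published per-tissue signature
lists; configurable). Symbols are matched case-insensitively, which handles
the human/mouse casing convention (SLC34A1 vs Slc34a1); an explicit
two-column ortholog map overrides name matching when symbol identity is not
a safe proxy for orthology. Genes top-ranked in one species whose symbol is
entirely absent from the other platform's annotation — so they could never
intersect — are flagged `only_in_*_platform` rather than silently lost; a
gene present but lowly ranked in the other species is deliberately *not*
flagged, because there the data argue against specificity.

## The significance layer

Ranking alone cannot give candidates statistical support, and with
thousands of genes the top-`k` lists of two independent noisy rankings
overlap by chance (about $k^2/n$ genes per tissue). The pipeline therefore
confirms each intersected candidate with the classical protected-LSD
protocol, per species:

1. a per-gene one-way fixed-effect ANOVA across the tissue groups must be
   significant at $\alpha = 0.05$;
2. Fisher's protected least significant difference test — pairwise $t$
   statistics on the ANOVA's pooled mean squared error and residual degrees
   of freedom — must find the target tissue significantly *higher* than
   every other tissue.

A candidate is `confirmed` when both species pass. The per-gene ANOVA is
fixed-effect by design: each tissue group consists of distinct subjects,
with no subject identifiers shared across tissues in the GDS design, so no
random (subject) effect is estimable from the deposited data; the method
label in the results records exactly what was fitted. No multiple-testing
correction is applied by default (each gene is reported with its raw p;
the cross-species requirement, not the p-value, carries the main burden of
false-positive control), and `stats::p.adjust` is one call away for users
who want it.

### ANOVA from printed summaries

Published tables report each tissue as mean ± SEM with a known replicate
count. Since $\mathrm{SEM} = s/\sqrt{n}$, the within-group sum of squares
is $\sum_i (n_i - 1)\, n_i\, \mathrm{SEM}_i^2$ and the between-group sum of
squares follows from the means — so `anova_from_summary()` reproduces the
raw-data F test *exactly* when the summary was computed from the raw
replicates (asserted to 1e-9 relative in the tests). This makes printed
tables first-class, testable inputs. With $n = 2$ the raw replicates are
even recoverable as mean ± SEM.

Tukey's studentized-range test is provided alongside LSD for multi-group
GEO-profile comparisons; for two groups both collapse to the pooled t test
($F = t^2$, $q = \sqrt{2}\,|t|$). `normalize_to_reference()` implements the
housekeeping (cyclophilin-style) transform — every sample's column divided
by that sample's reference value — for relative-expression analyses; it is
idempotent and errors if the reference is missing or non-positive anywhere.

## What the synthetic generator emulates

`generate_pair()` produces a two-species pair with known ground truth so
the whole pipeline is testable without downloads. Defaults mirror the study
design and array-like data:

| parameter | default | why |
|---|---|---|
| `n_genes` | 5000 | large enough for realistic chance-overlap behaviour, small enough to run in seconds |
| `replicates_a` | 2 per tissue | the human roster |
| `replicates_b` | 3, muscle 4 | the mouse roster |
| `baseline_meanlog`, `baseline_sdlog` | log(100), 1 | log-normal baselines spanning roughly 10–10000, like deposited intensities |
| `species_sdlog` | 0.25 | baselines conserved between species only up to an independent factor |
| `noise_cv` | 0.1 | multiplicative replicate noise, CV 10%, typical array replicate scatter |
| `spikes_per_tissue` | 5 | spiked tissue-specific genes per tissue |
| `spike_fold` | 100 | a strong, clearly tissue-specific signal (scalar or log-uniform range) |
| `conservation_prob` | 1 | spikes present in both species unless relaxed |
| `platform_dropout_prob` | 0 | optional one-platform-only genes |

Noise is multiplicative log-normal with mean exactly 1 at the configured
CV ($\sigma^2_{\log} = \log(1+\mathrm{CV}^2)$, $\mu_{\log} =
-\sigma^2_{\log}/2$), so a spiked gene's expected target/other ratio equals
its fold-change — values stay positive and the scale-free ratio statistic
sees signal undistorted by the noise model. Species A symbols are
uppercase, species B title-case, deliberately exercising the cross-species
normalization. The seed is an explicit, required config field; generation
restores the caller's RNG state.

What the generator does **not** emulate: probe-level cross-hybridization,
spatial array artifacts, correlated (batch) noise between tissues,
heavy-tailed outliers, and genes specific to more than one tissue. Passing
the spike-in tests therefore demonstrates the pipeline's correctness and
its behaviour under idealized noise, not performance on any real platform's
artifact spectrum.

`emit_soft_files()` writes the GDS SOFT dialect (header metadata, then an
`ID_REF`/`IDENTIFIER`/GSM table between `!dataset_table_begin` and
`!dataset_table_end`) with full double precision (`%.17g`) and `null` for
missing cells, so parse ∘ emit is the identity — a round-trip oracle the
tests use on a 5000 × 19 dataset.

## Parsing choices

Only the dataset-table block is required of a SOFT file; all other header
lines are retained as opaque metadata, which is sufficient for full GDS
dumps and keeps the parser small. The tokens `null`, `--`, `NA` and the
empty string (case-insensitive) are missing values. Negative parsed values
are clamped to missing with a warning count: the ratio statistic assumes
positive intensities, and a negative deposited intensity is a processing
artifact, not a measurement usable here. Tissue means average the
non-missing replicates and record how many entered each mean; a tissue with
no surviving replicate yields an undefined mean, which excludes the feature
from scoring for every target.

## Problem sizes and determinism

The shipped tests run the full pipeline on 5000-gene pairs (the
spike-recovery and round-trip checks), 100 × 1000-feature random matrices
for the reciprocity property, and 20 independent null-fold simulations for
the chance-level control; the whole suite completes in well under a minute
on one CPU. All TSV output rounds numerics to 6 significant digits with
stable sorts, so identical inputs give byte-identical files; the JSON
report excludes timestamps for the same reason.

## Known limitations

- Symbol-based orthology is a heuristic; genes renamed between annotation
  releases or without one-to-one orthologs need an explicit map.
- The score uses only means; a gene with huge replicate variance can rank
  highly from one lucky replicate. The protected-LSD confirmation is the
  guard, but it needs ≥2 replicates per tissue — in means-only fixture mode
  confirmation is reported as `NA`, not silently passed.
- Deposited GDS values are consumed as-is (the value type — MAS5, gcRMA,
  etc. — is whatever the curators deposited); no renormalization is
  attempted, and rankings from differently processed datasets should not be
  mixed.
- With two replicates per tissue (the human design), the pooled error has
  few degrees of freedom and the per-gene F test is underpowered; the
  cross-species intersection is doing most of the work there, which is
  precisely the method's premise.
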