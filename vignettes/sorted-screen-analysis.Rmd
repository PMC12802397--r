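---
title: "Statistics of sort-based CRISPRi activity screens"
author: "sortscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistics of sort-based CRISPRi activity screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sortscreen)
```

## The experiment this package models

A pooled CRISPRi activity screen couples a per-cell fluorescent readout of a
transient cellular response to cell sorting. Cells expressing dCas9 and a
calcium-integrating reporter (CaMPARI: green fluorescence converts to red
under UV only while intracellular calcium is high) are infected at low MOI
with an sgRNA library, stimulated, photoconverted, and sorted into the top
and bottom tails of the per-cell red/green ratio. Knockdowns that blunt the
response shift a gene's cells toward the low-ratio (non-responder) tail;
sequencing the sgRNA cassettes from each sorted bin turns that shift into a
count-based enrichment statistic. A parallel dropout arm (day 0 versus
endpoint, unsorted) controls for knockdowns that are simply toxic.

`sortscreen` implements the full path from reads to calls:

1. library manifests and sample sheets (`load_manifest()`,
   `load_sample_sheet()`),
2. protospacer counting from FASTQ (`count_sample()`, `merge_columns()`),
3. enrichment statistics and hit calling (`normalize_counts()`,
   `sgrna_log2fc()`, `gene_stats()`, `classify_hits()`,
   `rank_by_phenotype()`),
4. cross-screen comparison (`phenotype_correlation()`,
   `recall_at_threshold()`, `hitset_overlap()`, `geneset_enrichment()`),
5. the secondary assays around a screen (`gate_tails()`,
   `integrated_activity()`, `dff_traces()`, `fit_4pl()`,
   `ddct_knockdown()`, `relative_secretion()`),

together with a generative simulator (`simulate_screen()` and friends) so
every stage can be exercised, calibrated, and power-tested without any
external data.

## The hit-calling model

**Per-sgRNA enrichment.** Counts are normalized to counts-per-million after
adding a pseudocount (default 1), and each element's log2 fold change is

\[ \mathrm{log2FC}_i \;=\; \log_2 \frac{f_i(\text{low bin})}{f_i(\text{high bin})} \]

for the FACS arm (endpoint over day 0 for the dropout arm). The orientation
is chosen so that *positive regulators* — genes whose knockdown suppresses
the response, depleting their sgRNAs from the responder (high-ratio) bin —
receive positive log2FC and therefore appear at the top of rank plots.
When both roles carry matching replicate numbers the log2 ratio is computed
per replicate pair and then averaged; otherwise frequencies are averaged
within role first.

**Gene effect and significance.** A gene's effect is the mean log2FC of its
sgRNAs (optionally the mean of the top *k* by magnitude), centered on the
median of the non-targeting controls (NTCs). Its significance is a
two-sided Mann–Whitney rank-sum test of the gene's sgRNA log2FCs against
the pooled NTC log2FCs — exact (`pwilcox`) when there are no ties, a
tie-corrected normal approximation with continuity correction otherwise.
The implementation is vectorized over genes (U statistics by
`findInterval` against the sorted pool, the exact null reused across genes
of the same size) and is verified against `stats::wilcox.test` in the test
suite. The ranking statistic is the **phenotype score**

\[ S_g \;=\; \text{effect}_g \times \bigl(-\log_{10} p_g\bigr), \]

the product of the two volcano-plot axes.

**Quasi-gene empirical FDR.** Because NTC sgRNAs went through every
experimental step, they calibrate the null at the *gene* level: quasi-genes
are groups of NTC sgRNAs (group size = the modal per-gene sgRNA count,
drawn without replacement within a group, with replacement across groups;
default 10x the number of real genes) scored exactly like real genes, each
tested against the NTC pool minus its own members. The FDR at a gene's
score t (per sign direction) is

\[ \widehat{\mathrm{FDR}}(t) \;=\;
   \frac{\#\{\text{quasi} \ge t\}\cdot N_{\text{real}}/N_{\text{quasi}} + 1}
        {\#\{\text{real} \ge t\}} \]

capped at 1. The add-one in the numerator is the standard finite-sample
correction (as in permutation p-values and knockoff filters): without it
the estimator is mean-unbiased, so calling at an estimated FDR below a
threshold leaves the realized false-discovery proportion fluctuating
*around* that threshold; the +1 buys strict control at negligible cost in
sensitivity. A side effect worth knowing: the estimate cannot fall below
1/(number of real genes at least as extreme), so no gene can be called at
FDR < 0.05 unless at least 20 genes beat the quasi null — screens with
only a handful of true hits are called conservatively (the knockoff-filter
behavior). Reported FDRs are then monotonized q-value-style — each gene
takes the minimum raw FDR over its own and all less extreme thresholds —
so FDR is non-increasing in |phenotype score| within a direction. Strong
hits have FDR < 0.05, weak hits FDR < 0.1, with direction from the sign of
the effect.

## The simulator

`simulate_screen()` generates the statistical structure of the experiment
from the causal chain forward:

* **Knockdown.** Each sgRNA draws an efficacy `kd` uniform on `kd_range`
  (default 0.5–1; CRISPRi-v2-style "top 5 per gene" libraries are mostly
  effective). A gene's planted effect is an odds multiplier `m` on the
  responder state, applied on the log-odds scale so efficacy composes
  multiplicatively:
  `p = plogis(qlogis(base) + kd * log(m))`.
  NTCs and neutral genes sit exactly at the base responder probability —
  the null is exact by construction.
* **Infection and coverage.** MOI (default 0.4) enters as a Poisson
  single-integration filter (cells with more than one integration are
  discarded; the retained fraction is recorded in provenance); cells are
  multinomially distributed over elements at `coverage` (default 1000)
  cells per element.
* **Sorting.** Per-cell log red/green ratios form a two-component Gaussian
  mixture (non-responder mean 0, responder mean 1, common sd 0.5 — about
  two sds of separation, a realistic photoconversion contrast). The gate
  cuts the top and bottom `gate_quantile` (default 0.35) of the *pooled*
  ratio distribution, mirroring the physical order of operations: the
  sorter sees one mixed population. The default mode splits each element's
  cell mass binomially between responder states and bins (exact sampling
  distribution, desk-scale runtime at 20k x 1000 cells); `mode = "percell"`
  simulates every cell and ratio explicitly and is used as the brute-force
  oracle in the tests.
* **Dropout arm.** Endpoint abundance scales with
  `fitness^doublings` (default 6 doublings); neutral growth cancels in the
  relative abundances.
* **Sequencing.** Reads are multinomial at `reads_per_sample`
  (default 1000x the element count, within-bin depth being a free
  parameter of the real protocol) or gamma-mixed multinomial
  (negative-binomial-like) when `dispersion > 0`.

All randomness flows from `sim_config(seed=)`; identical configurations
give byte-identical output.

What the generator deliberately does **not** model: PCR chimeras and
amplification jackpots, sample-barcode demultiplexing, UV-dose
photoconversion kinetics, puromycin-selection dynamics, double-infection
genetics, or correlated off-target effects. Passing calibration and
recovery tests on simulated screens therefore demonstrates that the
statistics behave as designed under the stated noise model — not that any
particular real screen is free of those artifacts.

## Readout quantifications

* `gate_tails()` uses the order-statistic (type-1) quantile; bins hold
  `floor(q*n)` events when boundary ratios are distinct, and a tied group
  spanning a cut is kept together outside the bin (a threshold sorter
  cannot split identical ratios — with all ratios equal both bins are
  empty, with a warning).
* `integrated_activity()` is the per-sample *median* red/green ratio,
  summarized per condition as mean ± SEM over biological samples (never
  over cells), relative to a reference condition.
* `dff_traces()` computes dF/F0 = (F − F0)/F0 with F0 the mean over the
  pre-stimulus baseline, and extracts the peak from a lightly smoothed
  series (5-frame centered moving average by default). The smoothing
  matters: the maximum of a raw noisy trace is biased upward by the
  extreme-value selection over frames (about +7% at a signal-to-noise
  ratio of 10, measured on simulated transients), while a 5-frame average
  over transients at least that wide removes most of the bias (about +2%)
  and leaves noiseless peaks exact. Pass `smooth_frames = 1` for the raw
  maximum.
* `fit_4pl()` fits `r(x) = bottom + (top - bottom)/(1 + (ec50/x)^hill)`
  by Levenberg–Marquardt least squares (via `minpack.lm`), EC50
  parameterized on the log scale, from five deterministic EC50 starts
  spanning the dose range with both Hill-slope signs; `bottom` is bounded
  at 0 by default (fluorescence and secretion are non-negative).
  Non-convergence and negative Hill slopes are flagged, never hidden.
  Note the 4PL symmetry (bottom, top, hill) -> (top, bottom, -hill): a
  flagged negative slope on monotone-increasing data is the same curve
  relabeled. For EC50 estimation, dose series should anchor both
  asymptotes and sample the transition densely — a Cramér–Rao computation
  across candidate 8-dose layouts shows such designs beat plain two-fold
  dilution series by ~20% in EC50 precision at equal replication.
* `ddct_knockdown()` is the closed form `2^(-ddCt)` against a reference
  gene (default *Gapdh*) and control condition; technical-replicate SD
  above 0.5 cycles is flagged. `relative_secretion()` anchors fold
  changes at the reference-condition mean.

## Numerical and design choices

| Parameter | Default | Why |
|---|---|---|
| pseudocount | 1 count | keeps log ratios finite at zero counts |
| gate_quantile | 0.35 | top/bottom-35% sorting |
| coverage | 1000 cells/element | low-MOI screen practice |
| base_responder_fraction | 0.3 | a strong but non-saturating stimulus |
| ratio mixture | N(0, 0.5) vs N(1, 0.5) | ~2 sd photoconversion contrast |
| kd_range | 0.5–1 | "top predicted sgRNAs" libraries |
| reads_per_sample | 1000x elements | typical within-bin depth |
| quasi-gene multiplier | 10x genes | smooth null tail at modest cost |
| strong / weak FDR | 0.05 / 0.1 | conventional hit tiers |

Ties in log2FC (possible: counts are integers) route the rank-sum test to
the tie-corrected normal approximation, exactly as `wilcox.test` does.
Genes with phenotype score exactly 0 take FDR 1. Degenerate inputs error
loudly: all-zero count columns, empty manifests, missing bins, zero NTCs,
all-tied flow ratios.

The test suite runs the calibration suites at fixed sizes: 20 null screens
of 500 genes x 5 sgRNAs + 50 NTCs for calibration; three screens of 2,000
genes (250 NTCs, 50 planted positive regulators at odds multiplier 0.1,
efficacy 0.8–1, coverage 1,000, depth 1,000x) for recovery and
concordance; 10,000 reads for the counting oracle. These sizes keep each
property suite to a few minutes while leaving Monte-Carlo error well below
the tested margins.

## Known limitations

* **Dependence through a small NTC pool.** The rank-sum test is
  conditionally exact, so each gene's p-value is (discretely) uniform under
  the null regardless of the realized NTC pool. But with only ~50 NTC
  sgRNAs all gene p-values share one pool: a pool whose realized spread is
  atypical shifts every p-value in the same direction. The *ensemble* of
  p-values from one screen then wobbles around uniformity far more than an
  iid sample would (the pool's scale error alone is ~10% sd at 50 NTCs),
  so distribution-level uniformity checks (e.g. a Kolmogorov–Smirnov test
  across the genes of a single screen) fail intermittently even though
  per-gene calibration — and, more importantly, the quasi-gene FDR, which
  inherits the same pool — remains sound. This is an information limit of
  small control sets, not an implementation artifact; libraries with a few
  hundred NTCs (2.5% of 20k elements) make it negligible.
* The FDR is calibrated against the *resampled-NTC* null; real screens can
  harbor NTC-specific artifacts (e.g. growth effects of the cassette) that
  resampling cannot expose.
* Effects are modeled per gene with independent sgRNA efficacies; real
  libraries have correlated guide failures (chromatin, TSS annotation).
* The per-sgRNA enrichment assumes a single sorted pair per replicate; it
  does not model partial sorts or re-sorts.
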