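---
title: "Coexpression-anchored promoter motif enrichment: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coexpression-anchored promoter motif enrichment: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coexmotif)
library(dplyr)
```

coexmotif nominates candidate transcriptional regulators of a *seed gene*
from two data sources a lab typically already has: a bulk RNA-Seq count
matrix across many samples, and promoter sequence. The reasoning is
guilt-by-coexpression: genes whose expression tracks the seed gene across
samples plausibly share regulatory input with it, so consensus binding sites
over-represented in their promoters — relative to all other expressed genes —
point at the factors doing the regulating. This vignette explains each stage's
model, the tunable parameters that matter, the synthetic data the tests run
on, and the choices we made where the design was genuinely open.

## Stage 1: which genes count as expressed

Noise genes dilute every later stage, so the screen first keeps only genes
with convincing evidence of expression. A gene is kept when, in at least
`ceiling(min_sample_fraction * n_samples)` samples (default 5% — five samples
in a 99-sample cohort), both

* its CPM exceeds `cpm_threshold` (default 0.25), and
* the lower bound of an exact Poisson confidence interval on its count,
  rescaled to FPKM units, is greater than zero (level `ci_level`,
  default 0.95).

The second condition uses the Garwood chi-square-quantile form of the exact
Poisson interval: the lower bound is `qchisq(alpha/2, 2k)/2` for count `k > 0`
and exactly 0 at `k = 0`. Its operative effect is that a single mapped read
suffices for a positive bound, while a zero count never does: it is a
principled "was anything observed at all" test that does not depend on an
arbitrary pseudo-count. The interval treats the count as Poisson, i.e. it
ignores overdispersion; that is deliberate, since its role is detection, not
inference on the mean.

Counts then become `log2((count + 0.5) / (library_size + 1) * 1e6)` — the
log2-CPM offset transform. We do not compute observation-level precision
weights: the next stage is rank-based and would ignore them. Library size is
the raw column sum; no between-sample scaling factors are applied, because
scaling factors are monotone per sample and Spearman correlation is invariant
to them.

## Stage 2: the seed-gene correlation screen

Every remaining gene is correlated with the seed gene by Spearman's rank
correlation (average ranks on ties), with a two-sided p-value from the
t approximation `t = rho * sqrt((n-2)/(1-rho^2))` and Benjamini–Hochberg
adjustment across all tested genes. The seed gene is excluded from its own
FDR family. For very small cohorts (n below ~10) a seeded permutation
p-value is available via `p_method = "permutation"`.

The correlated *set* is a policy, not a statistic, and the policy applied is
always recorded on the result object. The default — `fdr <= 0.05` and
`rho >= 0.5` — requires both statistical confidence and a practically large
association; `top_n` and plain `rho_min` policies are provided (with
`rho_min = 0` meaning strictly positive, the "rs > 0" convention). A
repressor seed would be screened with the sign flipped or a `top_n` policy on
`-rho`; the enrichment model downstream never sees the sign, only the set.

## Stage 3: promoters

Windows are anchored at the annotated TSS, 1-based and inclusive at both
ends: `[tss - upstream, tss + downstream]` on the `+` strand and the mirror
image on `-`. A 10 kb-up / 1 kb-down window therefore spans
`upstream + downstream + 1` positions and always contains the TSS; anchored
at position 88,638,571 of chromosome 16 it reproduces the interval
88,628,571–88,639,571 exactly, which is what fixes the convention. Windows
are clipped at contig ends with a flag rather than an error, so genome-scale
runs survive telomeric genes. Where a gene has several transcripts the
annotation is expected to carry one designated (canonical, typically
longest) transcript per gene.

Extracted sequences are always *promoter-oriented*: position 1 is the most
distal upstream base, which requires reverse-complementing `-`-strand
windows. Composition covariates (GC fraction with N excluded from the
denominator, usable length) are computed per window.

## Stage 4: IUPAC scanning

Motifs are named sets of IUPAC consensus strings (e.g. the E-box pair
`CAGGTG`/`CACCTG`). A window of the consensus length is an occurrence if any
variant matches it forward, or if the reverse complement of the window
matches a variant. Three semantics are worth stating precisely:

* **Collapse.** Occurrences at the same `(start, length)` arising from both
  orientations or from different variants are one occurrence. `CAGGTG` and
  `CACCTG` are reverse complements, so a single physical E-box would
  otherwise be counted twice — once per variant, or once per strand.
* **Overlaps.** Occurrences at different starts all count; no greedy
  masking. This is the simplest deterministic definition; masking is a
  plausible alternative we did not adopt because it makes counts dependent
  on scan order.
* **N.** An N in the sequence never matches anything, including the N code:
  assembly gaps cannot create sites.

The scanner is a vectorised byte-table implementation verified exactly
against a naive window-by-window enumerator on a thousand random cases in
the test suite.

A reporting gate mirrors figure practice: motifs with fewer than `min_sites`
(default 5) occurrences in the seed gene's own window are dropped from the
reported screen. The gate is tied to the seed's window size — a 2 kb window
of background sequence rarely holds 5 sites of a specific 6-mer, so
experiments on 2 kb synthetic promoters disable it (`min_sites = 0`) and the
gate is exercised separately.

## Stage 5: enrichment

For one motif, with `member` the indicator of correlated-set membership,

```
logit P(member = 1) = b0 + b1 * f(count) + s(gc) + s(length)
```

where `f` is `log(1 + count)` by default (bounded influence of repeat-rich
promoters; raw count and presence are selectable), and `s(.)` are penalized
cubic regression splines with basis dimension 5 fit by mgcv with REML. The
smooths are there because promoter composition confounds any sequence
screen: GC-rich and long promoters carry more of almost every motif, and
coexpression sets are not composition-neutral. The test suite contains a
constructed confound (membership driven by GC, counts independent of
membership given GC) where the unadjusted logistic fit reports significance
and this model correctly does not.

`b1` is tested by a likelihood-ratio test of the full model against the
model with the motif term dropped, on 1 df. When a covariate is
(near-)constant its smooth is dropped and the model degenerates to ordinary
logistic regression — in that case `b1` and the LR statistic agree with the
closed-form 2x2 results to numerical precision, which the tests assert.
Complete separation is detected (runaway coefficient) and the reported
effect falls back to a weakly ridge-penalized fit, flagged
`separation_ridge`; a constant predictor short-circuits to effect 0, p 1,
flagged. P-values are BH-adjusted within one window-size family, because
enrichment at 1 kb and at 10 kb are reported as separate questions.

The smooth basis, predictor transform and the LR test are our choices; the
cited methodology for this family of screens does not pin them down. All
three are exposed in the configuration so alternates can be swapped in.

## Stage 6: target ranking

Per motif, each gene gets two strict empirical quantiles within the
screened universe — fraction of genes strictly below it in motif count, and
in seed correlation — combined by geometric mean. The geometric mean makes
a zero on either axis annihilate the score (a gene with no sites cannot be
a target, however correlated), and quantiles make the ranking invariant to
any monotone rescaling of either input. The top 12 are reported by default,
matching the usual figure-panel size. No formula for this ranking is
standard in the field; ours is a rank-product chosen for those two
invariances, and the scoring function is deliberately small and replaceable.

## The synthetic data, and what passing tests do not show

`simulate_dataset()` generates the full input bundle from one integer seed:

* **Counts.** Per sample, a latent regulator activity `r ~ N(0,1)`. The seed
  gene's log-mean is `baseline + 1.0 r`, each of `n_targets` target genes'
  is `baseline + beta r` (`beta` negative emulates repression), all other
  genes ignore `r`. Counts are negative binomial with dispersion 0.16 — a
  biological CV of 0.4, the usual rule of thumb for human bulk RNA-Seq —
  around log-normal library factors; per-gene baselines are uniform on
  `log(5)`–`log(500)` expected counts.
* **Promoters.** 2 kb of i.i.d. background at GC 0.45 per gene, on
  alternating strands of multi-gene contigs with more than a window of
  spacing. Planted motif instances (default the E-box pair) are inserted at
  Poisson-many non-overlapping random positions — expected 3 per target
  promoter vs 1 per background promoter — each instance realizing degenerate
  positions uniformly, in a random orientation. `gc_confounding` can shift
  target-promoter GC to stress the covariate adjustment. The library is the
  planted motif plus 29 random decoys of length 5–8 with at most two
  degenerate positions, matching the degeneracy of printed literature
  consensi.

The default conditions (1,000 genes x 99 samples, 150 targets, effect 1.5,
3x planting) are the scale at which the recovery experiments in the test
suite run: 20 seeded replicates for signal recovery, 200 label-permutation
replicates (on a 240-gene, 8-motif universe scanned once) for calibration.
These sizes keep the whole suite in the minutes range on one core and give
Monte-Carlo standard errors small enough for the stated bounds.

What the generator does **not** emulate: real promoter sequence composition
(CpG islands, repeats), positional clustering of sites near the TSS,
correlated gene modules beyond the single latent factor, batch effects, and
any connection between a motif's sites and actual binding. Passing the
recovery tests therefore shows the pipeline's statistics behave as designed
under its own assumptions — it does not validate biological discovery on
real data, where the unmodelled structure above is exactly what the GC/length
smooths and the FDR control have to work hardest against.

## Numerical and degenerate-input choices

* Spearman on ties uses average ranks; the vectorised screen reproduces
  `cor.test` to 1e-12 and constant genes report rho 0, p 1 rather than NA.
* A constant seed vector is an error (the screen is meaningless), as are
  all-N sequences, non-ACGTN characters (reported with their position), and
  windows on contigs the genome lacks.
* An empty correlated set or an empty post-filter motif list is a warning
  plus an empty result, not an error: both are legitimate outcomes of strict
  policies.
* Ranking ties break deterministically (by motif count then gene id for
  targets; by |effect| then motif id in the screen), so reruns are
  byte-identical.
* One integer seed drives expression and promoter generation through
  derived seeds, so a dataset is regenerable byte-for-byte; pipeline result
  TSVs carry a provenance hash of the analysis parameters (not file paths),
  so reruns from different directories produce identical bytes.

## Known limitations

Consensus-string matching is binary: a position either satisfies the IUPAC
code or not, with no affinity gradation — a position-weight-matrix scorer
would rank sites a consensus treats as equal. The enrichment model treats
genes as independent, ignoring promoter sequence similarity between
paralogs. The correlated-set policy is a hard threshold, and the set size
can be sensitive to it near the boundary; the recorded selection rule makes
this auditable but not less sharp. Finally, the screen nominates factors
whose *known site vocabulary* is enriched — factors without a curated
consensus are invisible to it.
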