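# coexmotif

Nominating candidate transcriptional regulators of a gene from bulk RNA-Seq
and promoter sequence.

## The problem

The transcriptional control of many genes — the epithelial cytokine *IL17C*
is the motivating example — is unknown, and chromatin-IP experiments for
every candidate factor are expensive. A cheaper first pass is
guilt-by-coexpression: across a large cohort of RNA-Seq samples, find the
genes whose expression tracks the gene of interest (the *seed gene*), then
ask which transcription-factor binding motifs are over-represented in the
promoters of that correlated set relative to all other expressed genes.
Factors whose motifs enrich — and for which the seed gene itself ranks high
as a predicted target — are candidates for follow-up knockdown experiments.
This is the screen that nominated TCF4 (via its E-box site,
5'-CAGGTG/CACCTG-3') as a repressor of *IL17C* in psoriatic skin.

coexmotif implements that screen end to end, for users with a count matrix,
a genome FASTA, a TSS annotation and a library of IUPAC consensus motifs:

1. **Detection filter** — keep genes with CPM > 0.25 and a positive lower
   95% bound of the exact Poisson FPKM interval in ≥ 5% of samples
   (`detection_filter()`), then log2-CPM transform (`log_cpm_transform()`).
2. **Correlation screen** — Spearman *r*ₛ of every gene against the seed
   gene with BH-FDR (`spearman_screen()`), and a recorded selection policy
   for the correlated set (`select_correlated_set()`).
3. **Promoters** — strand-aware TSS-anchored windows, 1-based inclusive
   (`upstream_window()`), promoter-oriented sequence and GC/length
   composition (`extract_sequence()`, `promoter_composition()`).
4. **Motif scanning** — double-stranded IUPAC consensus matching with
   same-window collapse, so a palindromic pair like CAGGTG/CACCTG counts
   once per physical site (`scan_sequence()`, `count_motif_sites()`).
5. **Enrichment** — per motif, a semiparametric logistic GAM
   `logit P(member) = b0 + b1·log1p(count) + s(GC) + s(length)` with a
   likelihood-ratio test on `b1` and BH-FDR within each window family
   (`fit_enrichment()`, `run_motif_screen()`).
6. **Target ranking** — per motif, genes ranked by the geometric mean of
   their motif-count and seed-correlation quantiles (`predict_targets()`).

A fully deterministic synthetic-data generator (`simulate_dataset()`)
produces counts driven by a latent regulator plus promoters with planted
motif instances, so the whole pipeline is testable without downloads; and
`run_screen()` orchestrates every stage from one (YAML-able) config with
TSV outputs and a run manifest.

## Worked example

Simulate a 300-gene x 99-sample cohort in which a latent regulator drives
the seed gene and 50 targets, whose 2 kb promoters carry ~3x more planted
E-box instances than background promoters, then run the screen:

```r
library(coexmotif)
library(dplyr)

cfg <- simulation_config(n_genes = 300, n_samples = 99, n_targets = 50,
                         rng_seed = 1)
ds  <- simulate_dataset(cfg)

expr <- ds$counts |>
  detection_filter(ds$gene_lengths) |>
  log_cpm_transform()
cors <- spearman_screen(expr, "SEED")
head(cors, 3)
#> # A tibble: 3 × 5
#>   gene_id   rho  p_value      fdr n_samples
#>   <chr>   <dbl>    <dbl>    <dbl>     <int>
#> 1 G0022   0.681 8.35e-15 1.63e-12        99
#> 2 G0013   0.676 1.63e-14 1.63e-12        99
#> 3 G0270   0.675 1.87e-14 1.63e-12        99

gene_set <- select_correlated_set(cors)   # fdr <= 0.05 and rho >= 0.5

prom <- upstream_window(ds$annotation, 2000, 0,
                        contig_lengths = ds$contig_lengths) |>
  extract_sequence(ds$genome, windows = _) |>
  promoter_composition()
counts <- count_motif_sites(prom, ds$motif_library)

screen <- run_motif_screen(counts,
                           membership_from_set(prom$gene_id, gene_set),
                           prom |> select(gene_id, gc, seq_length),
                           window_bp = 2000, seed_gene_id = "SEED",
                           min_sites = 0)
head(as_tibble(screen) |> select(motif_id, effect, p_value, fdr, n_member), 4)
#> # A tibble: 4 × 5
#>   motif_id effect  p_value      fdr n_member
#>   <chr>     <dbl>    <dbl>    <dbl>    <int>
#> 1 planted   2.51  1.06e-13 3.17e-12       50
#> 2 decoy18   0.902 6.36e- 3 9.54e- 2       50
#> 3 decoy02  -0.574 9.19e- 2 6.36e- 1       50
#> 4 decoy10  -0.730 1.04e- 1 6.36e- 1       50
```

The planted motif tops the screen with a log-odds effect of 2.5 per unit of
`log1p(count)` and FDR ≈ 3e-12; all 29 decoy motifs are non-significant
after adjustment. Target ranking and truth scoring:

```r
predict_targets(counts, cors, "planted") |>
  select(gene_id, motif_count, rho, combined_score, rank) |> head(5)
#> # A tibble: 5 × 5
#>   gene_id motif_count   rho combined_score  rank
#>   <chr>         <int> <dbl>          <dbl> <int>
#> 1 G0040             7 0.639          0.967     1
#> 2 G0129             7 0.636          0.958     2
#> 3 G0039             7 0.631          0.955     3
#> 4 G0029             9 0.603          0.949     4
#> 5 G0206             9 0.587          0.938     5

evaluate_recovery(gene_set, screen, ds$truth_genes) |>
  select(precision, recall, planted_rank, planted_fdr)
#> # A tibble: 1 × 4
#>   precision recall planted_rank planted_fdr
#>       <dbl>  <dbl>        <int>       <dbl>
#> 1         1      1            1    3.17e-12
```

The correlated set recovered exactly the 50 true targets, and the planted
motif ranked first. `ggplot2::autoplot()` has methods for the correlation
screen, the enrichment screen (volcano) and the target ranking;
`tidy()`/`glance()` summarize a single `fit_enrichment()` object.

A thin command-line wrapper with `simulate` / `screen` / `evaluate`
subcommands lives at `inst/cli/coexmotif.R`.

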