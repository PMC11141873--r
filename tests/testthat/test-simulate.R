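test_that("one seed regenerates the dataset byte-identically", {
  cfg <- simulation_config(n_genes = 60, n_samples = 20, n_targets = 10,
                           rng_seed = 42)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a$counts, b$counts)
  expect_identical(a$genome, b$genome)
  expect_identical(a$annotation, b$annotation)
  expect_identical(a$motif_library$consensus, b$motif_library$consensus)
  expect_identical(a$truth_sites, b$truth_sites)
  # a different seed gives a different dataset
  c <- simulate_dataset(simulation_config(n_genes = 60, n_samples = 20,
                                          n_targets = 10, rng_seed = 43))
  expect_false(identical(a$counts, c$counts))
})

test_that("a zero regulator effect leaves targets indistinguishable", {
  cfg <- simulation_config(n_genes = 300, n_samples = 60, n_targets = 60,
                           seed_gene_effect = 0, rng_seed = 7)
  expr <- simulate_expression(cfg)
  cors <- spearman_screen(log_cpm_transform(expr$counts), cfg$seed_gene_id)
  d <- dplyr::inner_join(cors, expr$target_flags, by = "gene_id")
  ks <- suppressWarnings(
    ks.test(d$rho[d$is_target], d$rho[!d$is_target]))
  expect_gt(ks$p.value, 0.01)
})

test_that("a strong regulator effect separates target correlations", {
  cfg <- simulation_config(n_genes = 300, n_samples = 99, n_targets = 60,
                           seed_gene_effect = 1.5, rng_seed = 8)
  expr <- simulate_expression(cfg)
  cors <- spearman_screen(log_cpm_transform(expr$counts), cfg$seed_gene_id)
  d <- dplyr::inner_join(cors, expr$target_flags, by = "gene_id")
  expect_gt(mean(abs(d$rho[d$is_target])), mean(abs(d$rho[!d$is_target])))
  expect_gt(mean(d$rho[d$is_target]), 0.5)
})

test_that("repression (negative effect) yields negative target correlations", {
  cfg <- simulation_config(n_genes = 200, n_samples = 99, n_targets = 40,
                           seed_gene_effect = -1.5, rng_seed = 9)
  expr <- simulate_expression(cfg)
  cors <- spearman_screen(log_cpm_transform(expr$counts), cfg$seed_gene_id)
  d <- dplyr::inner_join(cors, expr$target_flags, by = "gene_id")
  expect_lt(mean(d$rho[d$is_target]), -0.5)
})

test_that("every planted site is recovered by the scanner on its promoter", {
  cfg <- simulation_config(n_genes = 40, n_samples = 10, n_targets = 10,
                           rng_seed = 12)
  ds <- simulate_dataset(cfg)
  win <- upstream_window(ds$annotation, cfg$promoter_len_bp, 0,
                         contig_lengths = ds$contig_lengths)
  prom <- extract_sequence(ds$genome, win)
  for (g in unique(ds$truth_sites$gene_id)) {
    hits <- scan_sequence(prom$sequence[prom$gene_id == g],
                          cfg$planted_motif)
    truth <- ds$truth_sites[ds$truth_sites$gene_id == g, ]
    # planted sites are a subset of scan hits (background can add more)
    expect_true(all(truth$start %in% hits$start))
  }
})

test_that("promoters alternate strand and keep window-size spacing", {
  cfg <- simulation_config(n_genes = 120, n_samples = 5, n_targets = 20,
                           rng_seed = 3)
  ds <- simulate_dataset(cfg)
  ann <- ds$annotation
  expect_setequal(unique(ann$strand), c("+", "-"))
  win <- upstream_window(ann, cfg$promoter_len_bp, 0,
                         contig_lengths = ds$contig_lengths)
  expect_false(any(win$clipped))
  by_chrom <- split(win, win$chrom)
  for (w in by_chrom) {
    w <- w[order(w$start), ]
    if (nrow(w) > 1) expect_true(all(diff(w$start) > cfg$promoter_len_bp))
  }
})

test_that("recovery report handles perfect, empty and mismatched inputs", {
  truth <- tibble::tibble(gene_id = c("a", "b", "c", "d"),
                          is_target = c(TRUE, TRUE, FALSE, FALSE))
  screen <- tibble::tibble(motif_id = c("planted", "x"), fdr = c(0.001, 0.9),
                           effect = c(2, 0))
  perfect <- tibble::tibble(gene_id = c("a", "b"))
  rep <- evaluate_recovery(perfect, screen, truth)
  expect_equal(rep$precision, 1)
  expect_equal(rep$recall, 1)
  expect_equal(rep$planted_rank, 1)

  empty <- tibble::tibble(gene_id = character(0))
  rep0 <- evaluate_recovery(empty, screen, truth)
  expect_true(is.na(rep0$precision))
  expect_equal(rep0$recall, 0)

  alien <- tibble::tibble(gene_id = "zz")
  expect_error(evaluate_recovery(alien, screen, truth),
               class = "coexmotif_universe_mismatch")
})

test_that("a promoter that cannot hold its instances raises a named error", {
  expect_error(
    coexmotif:::plant_instances(strrep("A", 10), "CAGGTGCAGGTG", 1),
    class = "coexmotif_promoter_too_short"
  )
})
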