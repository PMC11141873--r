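test_that("BH adjustment equals the step-up definition", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(rep(0.07, 6)), rep(0.07, 6))
  set.seed(11)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_fdr(p), oracle_bh(p), tolerance = 1e-15)
  }
  expect_error(bh_fdr(c(0.5, 1.2)))
})

test_that("presence-predictor fit with constant covariates matches the 2x2 LR oracle", {
  inputs <- table_2x2_inputs(mem_present = 30, mem_absent = 20,
                             bg_present = 10, bg_absent = 40)
  fit <- fit_enrichment(inputs, predictor = "presence")
  oracle <- oracle_2x2_lr(inputs$member, inputs$motif_count)
  expect_true("no_smooths" %in% fit$flags)
  expect_equal(fit$effect, oracle$beta, tolerance = 1e-6)
  expect_lt(abs(fit$p_value - oracle$p) / oracle$p, 0.10)
  expect_lt(fit$p_value, 0.01)

  td <- tidy(fit)
  expect_equal(td$estimate, fit$effect)
  gl <- glance(fit)
  expect_equal(gl$n_member, 50)
  expect_equal(gl$n_background, 50)
})

test_that("a constant motif predictor yields a flagged null result", {
  inputs <- tibble::tibble(member = rep(c(1, 0), each = 25),
                           motif_count = 2, gc = runif(50, 0.3, 0.6),
                           seq_length = 2000)
  fit <- fit_enrichment(inputs)
  expect_equal(fit$effect, 0)
  expect_equal(fit$p_value, 1)
  expect_true("constant_predictor" %in% fit$flags)
})

test_that("null counts give near-zero effects and non-extreme p-values", {
  set.seed(808)
  pvals <- replicate(25, {
    inputs <- tibble::tibble(
      member = rep(c(1, 0), c(40, 160)),
      motif_count = rpois(200, 2),
      gc = runif(200, 0.35, 0.55),
      seq_length = sample(1500:2500, 200, replace = TRUE)
    )
    fit_enrichment(inputs)$p_value
  })
  # under the null the LR p-values should look uniform: no pile-up at 0
  expect_lte(sum(pvals < 0.05), 4)
  expect_gt(mean(pvals), 0.25)
})

test_that("smooth composition terms absorb a GC confound a plain fit falls for", {
  set.seed(4242)
  n <- 200
  gc <- runif(n, 0.30, 0.60)
  member <- rbinom(n, 1, plogis(12 * (gc - 0.45)))
  # motif counts depend on gc only, never on membership given gc
  motif_count <- rpois(n, exp(1 + 4 * (gc - 0.45)))
  inputs <- tibble::tibble(member = member, motif_count = motif_count,
                           gc = gc, seq_length = 2000)
  gam_fit <- fit_enrichment(inputs)
  naive <- glm(member ~ log1p(motif_count), family = binomial())
  naive_p <- summary(naive)$coefficients[2, 4]
  expect_lt(naive_p, 0.05)        # the unadjusted fit is fooled
  expect_gt(gam_fit$p_value, 0.05) # the adjusted fit is not
})

test_that("the screen ranks a planted enriched motif first and gates on seed sites", {
  set.seed(31)
  n_mem <- 60; n_bg <- 140
  genes <- c("seed", paste0("g", seq_len(n_mem + n_bg)))
  member <- c(FALSE, rep(c(TRUE, FALSE), c(n_mem, n_bg)))
  counts <- dplyr::bind_rows(lapply(c("planted", paste0("null", 1:9)), function(m) {
    lam <- if (m == "planted") ifelse(member, 2, 0.5) else rep(1, length(genes))
    lam[1] <- 6 # seed promoter carries plenty of sites for every motif
    tibble::tibble(gene_id = genes, motif_id = m,
                   count = rpois(length(genes), lam))
  })) |> dplyr::mutate(present = count >= 1)
  membership <- tibble::tibble(gene_id = genes, member = member)
  covars <- tibble::tibble(gene_id = genes,
                           gc = runif(length(genes), 0.4, 0.5),
                           seq_length = sample(1900:2100, length(genes), TRUE))
  scr <- run_motif_screen(counts, membership, covars, window_bp = 2000,
                          seed_gene_id = "seed", min_sites = 1)
  expect_s3_class(scr, "coexmotif_screen")
  expect_equal(scr$motif_id[1], "planted")
  expect_lt(scr$fdr[1], 0.05)
  expect_equal(scr$window_bp[1], 2000)
  # the seed gene is excluded from the fitted universe
  expect_equal(scr$n_member[1] + scr$n_background[1], n_mem + n_bg)

  expect_warning(
    empty <- run_motif_screen(counts, membership, covars,
                              seed_gene_id = "seed", min_sites = 100),
    class = "coexmotif_empty_screen"
  )
  expect_equal(nrow(empty), 0)
})

test_that("permuted membership leaves the screen without discoveries", {
  set.seed(99)
  genes <- paste0("g", 1:150)
  counts <- dplyr::bind_rows(lapply(paste0("m", 1:5), function(m) {
    tibble::tibble(gene_id = genes, motif_id = m, count = rpois(150, 1.5))
  })) |> dplyr::mutate(present = count >= 1)
  covars <- tibble::tibble(gene_id = genes, gc = runif(150, 0.4, 0.5),
                           seq_length = 2000)
  hits <- replicate(10, {
    membership <- tibble::tibble(gene_id = genes,
                                 member = sample(rep(c(TRUE, FALSE), c(30, 120))))
    scr <- run_motif_screen(counts, membership, covars, seed_gene_id = NULL)
    sum(scr$fdr < 0.05)
  })
  expect_lte(sum(hits > 0), 2)
})
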