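test_that("CPM is closed-form library scaling and columns sum to a million", {
  counts <- tibble::tibble(gene_id = c("g1", "g2"), s1 = c(10, 90))
  cpm <- compute_cpm(counts)
  expect_equal(cpm$s1, c(100000, 900000))

  counts2 <- tibble::tibble(gene_id = paste0("g", 1:4),
                            s1 = c(1, 1, 1, 1), s2 = c(5, 0, 3, 2))
  cpm2 <- compute_cpm(counts2)
  expect_equal(cpm2$s1, rep(250000, 4))
  expect_equal(colSums(cpm2[-1]), c(s1 = 1e6, s2 = 1e6))
  # all-zero gene stays zero in every sample
  expect_equal(unlist(cpm2[cpm2$gene_id == "g2", -1]),
               c(s1 = 250000, s2 = 0))

  zero_lib <- tibble::tibble(gene_id = "g1", s1 = 10, s2 = 0)
  expect_error(compute_cpm(zero_lib), class = "coexmotif_zero_library")
})

test_that("FPKM divides by length-kb and library-millions", {
  counts <- tibble::tibble(gene_id = c("pad", "g"), s1 = c(1e6 - 10, 10))
  lens <- tibble::tibble(gene_id = c("pad", "g"), length_bp = c(1000, 1000))
  expect_equal(compute_fpkm(counts, lens)$s1[2], 10)

  counts2 <- tibble::tibble(gene_id = c("pad", "g"), s1 = c(2e6 - 5, 5))
  lens2 <- tibble::tibble(gene_id = c("pad", "g"), length_bp = c(1000, 500))
  expect_equal(compute_fpkm(counts2, lens2)$s1[2], 5)
  expect_equal(compute_fpkm(counts2, lens2)$s1 * 0,
               c(0, 0)) # zero count -> zero FPKM holds trivially for count 0

  expect_error(
    compute_fpkm(counts, tibble::tibble(gene_id = "pad", length_bp = 1000)),
    class = "coexmotif_missing_length"
  )
})

test_that("FPKM lower confidence bound is the exact Poisson interval, rescaled", {
  expect_identical(fpkm_lower_ci(0, 1000, 1e6), 0)
  expect_gt(fpkm_lower_ci(1, 1000, 1e6), 0)
  # count 10, level 0.95, 1 kb gene in a 1e6 library: the scale factor is 1
  # so the bound equals the chi-square-quantile Poisson bound itself
  expect_equal(fpkm_lower_ci(10, 1000, 1e6), qchisq(0.025, 20) / 2,
               tolerance = 1e-12)
  expect_equal(fpkm_lower_ci(10, 1000, 1e6), 4.795389, tolerance = 1e-6)

  # lower bound never exceeds the point estimate at level >= 0.5, and is
  # zero iff the count is zero
  for (k in c(0, 1, 3, 10, 100)) {
    point <- k / ((2000 / 1000) * (3e6 / 1e6))
    low <- fpkm_lower_ci(k, 2000, 3e6, level = 0.9)
    expect_lte(low, point)
    expect_identical(low == 0, k == 0)
  }
})

test_that("detection filter keeps genes qualifying in >= ceil(fraction * n) samples", {
  # gene qualifying in exactly 5 of 99 samples is kept; 4 of 99 dropped
  n <- 99
  mk <- function(q) {
    m <- matrix(0, 3, n, dimnames = list(c("pad", "gene5", "gene4"),
                                         paste0("s", seq_len(n))))
    m["pad", ] <- 1000               # keeps every library size positive
    m["gene5", seq_len(q[1])] <- 50
    m["gene4", seq_len(q[2])] <- 50
    tibble::as_tibble(m, rownames = "gene_id")
  }
  counts <- mk(c(5, 4))
  lens <- tibble::tibble(gene_id = c("pad", "gene5", "gene4"),
                         length_bp = 1000)
  kept <- detection_filter(counts, lens)
  expect_true("gene5" %in% kept$gene_id)
  expect_false("gene4" %in% kept$gene_id)
  rep <- detection_report(kept)
  expect_equal(rep$n_required[1], 5)
  expect_equal(rep$n_qualifying[rep$gene_id == "gene5"], 5)

  # all-zero gene always dropped
  expect_false(any(rep$kept[rep$gene_id == "gene4"]))

  # monotone in the CPM threshold: lowering it never removes a kept gene
  kept_strict <- detection_filter(counts, lens, cpm_threshold = 10)
  kept_loose <- detection_filter(counts, lens, cpm_threshold = 0.01)
  expect_true(all(kept_strict$gene_id %in% kept_loose$gene_id))
})

test_that("log2-CPM transform uses the half-count offset and is monotone", {
  counts <- tibble::tibble(gene_id = c("g0", "gbig"), s1 = c(0, 1e6))
  v <- log_cpm_transform(counts)
  expect_equal(v$s1[1], log2(0.5 / (1e6 + 1) * 1e6), tolerance = 1e-12)
  expect_equal(v$s1[1], -1.0000014, tolerance = 1e-6)

  counts2 <- tibble::tibble(gene_id = c("a", "b"), s1 = c(499500, 500500))
  v2 <- log_cpm_transform(counts2)
  expect_equal(v2$s1[1], 18.9301252, tolerance = 1e-6)

  # strictly increasing in count at fixed library size
  cnt <- c(0, 1, 5, 50, 1000)
  m <- tibble::tibble(gene_id = paste0("g", seq_along(cnt)),
                      s1 = cnt, s2 = rev(cnt))
  out <- log_cpm_transform(m)
  expect_true(all(diff(out$s1) > 0))
  expect_true(all(is.finite(as.matrix(out[-1]))))
})

test_that("qPCR relative expression is 2^(CT_housekeeping - CT_gene)", {
  expect_equal(qpcr_relative_expression(20, 20), 1)
  expect_equal(qpcr_relative_expression(20, 25), 0.03125)
  expect_equal(qpcr_relative_expression(25, 20), 32)
  expect_equal(qpcr_relative_expression(c(20, 25), c(25, 20)), c(0.03125, 32))
})
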