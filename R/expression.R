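#' Counts per million
#'
#' Library-size normalisation of a raw count matrix. Each sample (column) is
#' scaled so that its values sum to one million; no between-sample scaling
#' factors are applied.
#'
#' @param counts Wide tibble of raw counts: a `gene_id` column followed by one
#'   numeric column per sample.
#' @return A tibble of the same shape holding CPM values. Column sums of the
#'   sample columns are 1e6.
#' @examples
#' counts <- tibble::tibble(gene_id = c("g1", "g2"), s1 = c(10, 90))
#' compute_cpm(counts)
#' @export
compute_cpm <- function(counts) {
  m <- counts_to_matrix(counts)
  ls <- library_sizes(m)
  matrix_to_tibble(sweep(m, 2, ls, "/") * 1e6)
}

#' Fragments per kilobase per million mapped reads
#'
#' @inheritParams compute_cpm
#' @param gene_lengths Tibble with columns `gene_id`, `length_bp` covering
#'   every gene in `counts`; missing genes raise an error naming them.
#' @return Tibble of FPKM values, same shape as `counts`.
#' @examples
#' counts <- tibble::tibble(gene_id = "g1", s1 = 10)
#' lens <- tibble::tibble(gene_id = "g1", length_bp = 1000)
#' compute_fpkm(counts, lens) # 10 at a library size of 10 reads... see details
#' @details
#' `fpkm = count / (length_kb * library_size_in_millions)`, with the library
#' size taken as the raw column sum of `counts`.
#' @export
compute_fpkm <- function(counts, gene_lengths) {
  m <- counts_to_matrix(counts)
  ls <- library_sizes(m)
  len_kb <- align_gene_lengths(gene_lengths, rownames(m)) / 1000
  fpkm <- sweep(sweep(m, 2, ls / 1e6, "/"), 1, len_kb, "/")
  matrix_to_tibble(fpkm)
}

#' Lower confidence bound of FPKM from an exact Poisson interval
#'
#' Treats the raw count as a Poisson observation, takes the lower bound of the
#' exact (Garwood, chi-square quantile form) two-sided confidence interval on
#' the Poisson mean, and rescales it to FPKM units. The bound is exactly 0
#' when the count is 0 and strictly positive for any count of at least 1,
#' which is what makes it usable as a "detected at all" criterion.
#'
#' @param count Non-negative integer vector of raw counts.
#' @param length_bp Positive gene length(s) in bp.
#' @param library_size Positive library size(s) (total mapped reads).
#' @param level Two-sided confidence level, default 0.95.
#' @return Numeric vector of lower FPKM bounds.
#' @examples
#' fpkm_lower_ci(10, 1000, 1e6)       # qchisq(0.025, 20)/2 = 4.795, rescaled
#' fpkm_lower_ci(0, 1000, 1e6)        # exactly 0
#' @export
fpkm_lower_ci <- function(count, length_bp, library_size, level = 0.95) {
  stopifnot(level > 0, level < 1, all(count >= 0))
  alpha <- 1 - level
  lower_count <- ifelse(count == 0, 0, qchisq(alpha / 2, 2 * count) / 2)
  lower_count / ((length_bp / 1000) * (library_size / 1e6))
}

#' Detection filter for expressed genes
#'
#' Keeps a gene when, in at least `ceiling(min_sample_fraction * n_samples)`
#' samples, its CPM exceeds `cpm_threshold` and the lower bound of the exact
#' Poisson confidence interval on its FPKM is greater than zero. With the
#' defaults and 99 samples this is the "at least 5 of 99 samples with
#' CPM > 0.25 and a positive FPKM lower 95% bound" rule.
#'
#' @inheritParams compute_fpkm
#' @param cpm_threshold CPM a sample must exceed to qualify (default 0.25).
#' @param min_sample_fraction Fraction of samples that must qualify
#'   (default 0.05); converted to a count with `ceiling()`.
#' @param ci_level Confidence level of the FPKM lower bound (default 0.95).
#' @return The filtered counts tibble. The per-gene report (gene id,
#'   qualifying-sample count, required count, kept flag) is attached as
#'   attribute `"report"`; retrieve it with [detection_report()].
#' @export
detection_filter <- function(counts, gene_lengths,
                             cpm_threshold = 0.25,
                             min_sample_fraction = 0.05,
                             ci_level = 0.95) {
  stopifnot(cpm_threshold > 0,
            min_sample_fraction > 0, min_sample_fraction <= 1,
            ci_level > 0, ci_level < 1)
  m <- counts_to_matrix(counts)
  ls <- library_sizes(m)
  len <- align_gene_lengths(gene_lengths, rownames(m))

  cpm <- sweep(m, 2, ls, "/") * 1e6
  low <- fpkm_lower_ci(m,
                       length_bp = matrix(len, nrow(m), ncol(m)),
                       library_size = matrix(ls, nrow(m), ncol(m), byrow = TRUE),
                       level = ci_level)
  qualifying <- rowSums(cpm > cpm_threshold & low > 0)
  required <- ceiling(min_sample_fraction * ncol(m))
  keep <- qualifying >= required

  report <- tibble(
    gene_id = rownames(m),
    n_qualifying = as.integer(qualifying),
    n_required = as.integer(required),
    kept = keep
  )
  if (!any(keep)) {
    warn("detection_filter removed every gene.", class = "coexmotif_empty_filter")
  }
  out <- counts[keep, , drop = FALSE]
  attr(out, "report") <- report
  attr(out, "filter_config") <- list(cpm_threshold = cpm_threshold,
                                     min_sample_fraction = min_sample_fraction,
                                     ci_level = ci_level)
  out
}

#' @rdname detection_filter
#' @param filtered A tibble returned by [detection_filter()].
#' @export
detection_report <- function(filtered) {
  rep <- attr(filtered, "report")
  if (is.null(rep)) {
    abort("no detection report attached; was this produced by detection_filter()?",
          class = "coexmotif_bad_input")
  }
  rep
}

#' Log2-CPM transform
#'
#' Converts counts to log2 counts-per-million with the half-count offset used
#' by the voom family of transforms:
#' `log2((count + 0.5) / (library_size + 1) * 1e6)`. The result is finite for
#' zero counts and strictly increasing in the count at fixed library size.
#' Precision weights are not computed; the downstream correlation screen is
#' rank-based and would ignore them.
#'
#' @inheritParams compute_cpm
#' @return Tibble of log2-CPM values (same shape as `counts`) with attribute
#'   `transform_tag = "log2_cpm_offset0.5"`.
#' @export
log_cpm_transform <- function(counts) {
  m <- counts_to_matrix(counts)
  ls <- library_sizes(m)
  v <- log2(sweep(m + 0.5, 2, ls + 1, "/") * 1e6)
  out <- matrix_to_tibble(v)
  attr(out, "transform_tag") <- "log2_cpm_offset0.5"
  out
}

#' Relative expression from qPCR cycle thresholds
#'
#' Normalises a gene of interest to a housekeeping gene:
#' `2^CT(housekeeping) / 2^CT(gene)`, i.e. `2^(ct_housekeeping - ct_gene)`.
#' Values above 1 mean the gene of interest amplifies earlier (is more
#' abundant) than the housekeeping gene.
#'
#' @param ct_housekeeping,ct_gene Finite CT values (vectors recycle).
#' @return Numeric vector of relative expression values.
#' @examples
#' qpcr_relative_expression(20, 25) # 2^-5
#' @export
qpcr_relative_expression <- function(ct_housekeeping, ct_gene) {
  stopifnot(all(is.finite(ct_housekeeping)), all(is.finite(ct_gene)))
  2^(ct_housekeeping - ct_gene)
}
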