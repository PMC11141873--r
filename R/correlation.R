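# Seed-gene correlation screen.
#
# Spearman rho is computed as Pearson correlation of average ranks
# (midranks for ties), vectorised across all genes at once via centred
# cross-products; per-gene p-values use the t approximation
# t = rho * sqrt((n - 2) / (1 - rho^2)) on n - 2 df, two-sided, the same
# formula cor.test() uses when ties are present.

rank_rows <- function(m) {
  t(apply(m, 1, rank, ties.method = "average"))
}

#' Spearman correlation screen against a seed gene
#'
#' Correlates every gene in an expression matrix with a designated seed gene
#' using Spearman rank correlation (average ranks for ties), and adjusts the
#' two-sided p-values with Benjamini-Hochberg across all tested genes. The
#' seed gene itself is excluded from the result and from the FDR family.
#'
#' @param expr Wide tibble of expression values (`gene_id` column + one
#'   column per sample), e.g. from [log_cpm_transform()]. Spearman is
#'   invariant to any strictly monotone transform, so raw CPM works too.
#' @param seed_gene_id Gene id of the seed gene; must be present in `expr`.
#' @param p_method `"t"` (default) for the t approximation, or
#'   `"permutation"` for a seeded permutation p-value (intended for very
#'   small sample counts where the t approximation is poor).
#' @param n_perm Number of permutations when `p_method = "permutation"`.
#' @return A tibble of class `coexmotif_correlations` with columns
#'   `gene_id`, `rho`, `p_value`, `fdr`, `n_samples`, sorted by decreasing
#'   `rho`.
#' @export
spearman_screen <- function(expr, seed_gene_id, p_method = c("t", "permutation"),
                            n_perm = 10000) {
  p_method <- match.arg(p_method)
  m <- counts_to_matrix_loose(expr)
  if (!seed_gene_id %in% rownames(m)) {
    abort(paste0("seed gene not present in expression matrix: ", seed_gene_id),
          class = "coexmotif_missing_seed")
  }
  n <- ncol(m)
  if (n < 5) abort("need at least 5 samples.", class = "coexmotif_bad_input")

  seed <- m[seed_gene_id, ]
  if (length(unique(seed)) == 1L) {
    abort("seed gene expression is constant; Spearman correlation undefined.",
          class = "coexmotif_constant_vector")
  }
  others <- m[setdiff(rownames(m), seed_gene_id), , drop = FALSE]

  rho <- spearman_vec(others, seed)

  if (p_method == "t") {
    p <- spearman_t_pvalue(rho, n)
  } else {
    p <- spearman_perm_pvalue(others, seed, rho, n_perm)
  }
  # constant genes: rho is NA; report rho 0, p 1 (no evidence either way)
  flat <- is.na(rho)
  rho[flat] <- 0
  p[flat] <- 1

  out <- tibble(
    gene_id = rownames(others),
    rho = unname(rho),
    p_value = unname(p),
    fdr = bh_fdr(unname(p)),
    n_samples = n
  ) |>
    arrange(desc(.data$rho), .data$gene_id)
  new_screen_tbl(out, "coexmotif_correlations", seed_gene_id = seed_gene_id)
}

# rows of `m` vs vector `y`, Spearman via Pearson-on-ranks; NA for constant rows
spearman_vec <- function(m, y) {
  rm <- rank_rows(m)
  ry <- rank(y, ties.method = "average")
  rm_c <- rm - rowMeans(rm)
  ry_c <- ry - mean(ry)
  num <- as.vector(rm_c %*% ry_c)
  den <- sqrt(rowSums(rm_c^2) * sum(ry_c^2))
  out <- num / den
  out[den == 0] <- NA_real_
  out
}

spearman_t_pvalue <- function(rho, n) {
  r <- pmin(pmax(rho, -1), 1)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  p[abs(r) >= 1] <- 0
  pmin(p, 1)
}

spearman_perm_pvalue <- function(m, y, rho_obs, n_perm) {
  n <- length(y)
  hits <- rep(1L, nrow(m)) # count observed as one of the permutations
  for (b in seq_len(n_perm)) {
    rb <- spearman_vec(m, y[sample.int(n)])
    hits <- hits + (abs(rb) >= abs(rho_obs) - 1e-12)
  }
  as.numeric(hits) / (n_perm + 1)
}

# like counts_to_matrix but allows negative values (log scale)
counts_to_matrix_loose <- function(x) {
  stopifnot(is.data.frame(x), "gene_id" %in% names(x))
  m <- as.matrix(x[setdiff(names(x), "gene_id")])
  storage.mode(m) <- "double"
  if (any(!is.finite(m))) abort("expression values must be finite.",
                                class = "coexmotif_bad_input")
  rownames(m) <- as.character(x$gene_id)
  if (anyDuplicated(rownames(m))) abort("duplicate gene ids.",
                                        class = "coexmotif_bad_input")
  m
}

#' Select the correlated gene set
#'
#' Applies one of three selection policies to a correlation screen result:
#' `rho_min` (keep genes with `rho >= value`; `rho_min = 0` keeps strictly
#' positive correlations, matching the "positively correlated, rho > 0"
#' convention), `top_n` (the n largest rho), or `fdr_rho` (the default:
#' `fdr <= fdr_max` and `rho >= rho_min` jointly). Members are ordered by
#' decreasing rho with ties broken lexicographically by gene id, and the
#' policy actually applied is recorded on the result for provenance.
#'
#' @param results A `coexmotif_correlations` tibble from [spearman_screen()].
#' @param policy One of `"fdr_rho"`, `"rho_min"`, `"top_n"`.
#' @param rho_min,fdr_max,top_n Policy parameters; defaults `rho_min = 0.5`,
#'   `fdr_max = 0.05`, `top_n = 100`.
#' @return Tibble of class `coexmotif_gene_set` (columns of `results`
#'   restricted to members) with attributes `seed_gene_id` and
#'   `selection_rule`.
#' @export
select_correlated_set <- function(results,
                                  policy = c("fdr_rho", "rho_min", "top_n"),
                                  rho_min = 0.5, fdr_max = 0.05, top_n = 100) {
  policy <- match.arg(policy)
  stopifnot(is.data.frame(results), nrow(results) > 0)
  ordered <- results |> arrange(desc(.data$rho), .data$gene_id)
  sel <- switch(policy,
    rho_min = if (rho_min == 0) ordered$rho > 0 else ordered$rho >= rho_min,
    top_n = seq_len(nrow(ordered)) <= top_n,
    fdr_rho = ordered$fdr <= fdr_max & ordered$rho >= rho_min
  )
  rule <- switch(policy,
    rho_min = list(policy = "rho_min", rho_min = rho_min),
    top_n = list(policy = "top_n", top_n = top_n),
    fdr_rho = list(policy = "fdr_rho", fdr_max = fdr_max, rho_min = rho_min)
  )
  members <- ordered[sel, , drop = FALSE]
  if (nrow(members) == 0) {
    warn("selection policy produced an empty gene set.",
         class = "coexmotif_empty_set")
  }
  new_screen_tbl(members, "coexmotif_gene_set",
                 seed_gene_id = attr(results, "seed_gene_id"),
                 selection_rule = rule)
}

#' Pairwise gene-gene correlation
#'
#' Correlation between two named genes of an expression matrix with a
#' two-sided p-value; positive r means the genes co-increase.
#'
#' @inheritParams spearman_screen
#' @param gene_a,gene_b Gene ids present in `expr`.
#' @param method `"pearson"` or `"spearman"`.
#' @return One-row tibble: `gene_a`, `gene_b`, `method`, `r`, `p_value`, `n`.
#' @export
pairwise_gene_correlation <- function(expr, gene_a, gene_b,
                                      method = c("pearson", "spearman")) {
  method <- match.arg(method)
  m <- counts_to_matrix_loose(expr)
  for (g in c(gene_a, gene_b)) {
    if (!g %in% rownames(m)) {
      abort(paste0("gene not present: ", g), class = "coexmotif_missing_gene")
    }
  }
  x <- m[gene_a, ]; y <- m[gene_b, ]
  n <- length(x)
  if (n < 3) abort("need at least 3 samples.", class = "coexmotif_bad_input")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    abort("constant expression vector; correlation undefined.",
          class = "coexmotif_constant_vector")
  }
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = method, exact = FALSE)
  )
  tibble(gene_a = gene_a, gene_b = gene_b, method = method,
         r = unname(ct$estimate), p_value = ct$p.value, n = n)
}
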