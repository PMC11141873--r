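# Motif-based target-gene ranking.
#
# A gene is a plausible target of a motif's factor when its promoter carries
# many sites for the motif AND its expression tracks the seed gene. Both
# axes are reduced to strict empirical quantiles within the gene universe
# (fraction of genes strictly below), and combined by geometric mean -- a
# rank-product-style score that is invariant to any monotone rescaling of
# counts or correlations and is annihilated by a zero on either axis.

#' Rank predicted target genes for one motif
#'
#' @param motif_counts Long tibble from [count_motif_sites()].
#' @param correlations Correlation screen result ([spearman_screen()]):
#'   columns `gene_id`, `rho`.
#' @param motif_id Motif to rank targets for; must appear in `motif_counts`.
#' @param top_n Number of top-ranked genes to return (default 12).
#' @return Tibble of class `coexmotif_targets`: `motif_id`, `gene_id`,
#'   `motif_count`, `rho`, `motif_component`, `correlation_component`,
#'   `combined_score`, `rank`. Ties in `combined_score` break by larger
#'   motif count, then lexicographic gene id.
#' @export
predict_targets <- function(motif_counts, correlations, motif_id, top_n = 12) {
  stopifnot(top_n >= 1)
  mid <- motif_id
  counts <- motif_counts |> filter(.data$motif_id == mid)
  if (nrow(counts) == 0) {
    abort(paste0("motif absent from counts: ", mid), class = "coexmotif_missing_motif")
  }
  d <- counts |>
    select("gene_id", motif_count = "count") |>
    inner_join(correlations |> select("gene_id", "rho"), by = "gene_id")
  if (nrow(d) == 0) {
    abort("no genes shared between motif counts and correlations.",
          class = "coexmotif_bad_input")
  }
  n <- nrow(d)
  strict_quantile <- function(v) (rank(v, ties.method = "min") - 1) / n
  d <- d |>
    mutate(
      motif_component = strict_quantile(.data$motif_count),
      correlation_component = strict_quantile(.data$rho),
      combined_score = sqrt(.data$motif_component * .data$correlation_component)
    ) |>
    arrange(desc(.data$combined_score), desc(.data$motif_count), .data$gene_id) |>
    mutate(motif_id = mid, rank = dplyr::row_number()) |>
    select("motif_id", "gene_id", "motif_count", "rho", "motif_component",
           "correlation_component", "combined_score", "rank")
  new_screen_tbl(head(d, top_n), "coexmotif_targets", n_universe = n)
}
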