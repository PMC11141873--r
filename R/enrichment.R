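# Semiparametric logistic enrichment model.
#
# For one motif the model is
#   logit P(member = 1) = b0 + b1 * motif_predictor + s(gc) + s(seq_length)
# with penalized cubic regression spline smooths (basis dimension 5). The
# smooths absorb promoter composition: GC-rich or long promoters carry more
# of almost any motif, and membership in a coexpression set is itself not
# composition-neutral, so a naive logistic fit confounds composition with
# enrichment. The motif term is tested with a likelihood-ratio test of the
# full model against the model with the motif term dropped (1 df).

#' Fit the motif-enrichment model for one motif
#'
#' @param inputs Tibble with one row per gene and columns `member` (0/1 or
#'   logical), `motif_count` (non-negative integer), `gc` (fraction in
#'   `[0,1]`) and `seq_length` (bp). Rows with `NA` covariates are dropped.
#' @param predictor How motif occurrence enters the model: `"log1p_count"`
#'   (default, `log(1 + count)`), `"count"`, or `"presence"` (indicator of
#'   at least one site).
#' @param basis_dim Basis dimension of each smooth (default 5).
#' @return An object of class `coexmotif_fit` with elements `effect` (the
#'   motif coefficient, log-odds per unit of predictor), `p_value`
#'   (likelihood-ratio), `n_member`, `n_background`, `flags` (character:
#'   may contain `"constant_predictor"`, `"separation_ridge"`,
#'   `"no_smooths"`), and the underlying `full` / `null` model fits.
#'   Use [tidy()] / [glance()] for tabular summaries.
#' @export
fit_enrichment <- function(inputs,
                           predictor = c("log1p_count", "count", "presence"),
                           basis_dim = 5) {
  predictor <- match.arg(predictor)
  stopifnot(all(c("member", "motif_count", "gc", "seq_length") %in% names(inputs)))
  d <- tibble(
    member = as.integer(as.logical(inputs$member)),
    motif_count = as.numeric(inputs$motif_count),
    gc = as.numeric(inputs$gc),
    seq_length = as.numeric(inputs$seq_length)
  ) |>
    filter(!is.na(.data$gc), !is.na(.data$seq_length))
  if (nrow(d) < 20) {
    abort("need at least 20 genes to fit the enrichment model.",
          class = "coexmotif_bad_input")
  }
  if (length(unique(d$member)) < 2) {
    abort("both member and background classes must be non-empty.",
          class = "coexmotif_bad_input")
  }
  d$x <- switch(predictor,
    log1p_count = log1p(d$motif_count),
    count = d$motif_count,
    presence = as.numeric(d$motif_count >= 1)
  )

  flags <- character(0)
  if (length(unique(d$x)) == 1L) {
    return(new_coexmotif_fit(effect = 0, p_value = 1, d = d,
                             predictor = predictor,
                             flags = "constant_predictor",
                             full = NULL, null = NULL))
  }

  # a smooth needs more distinct covariate values than its basis dimension;
  # when composition is (near-)constant the term drops and the model
  # degenerates to ordinary logistic regression
  smooth_terms <- character(0)
  if (length(unique(d$gc)) > basis_dim) {
    smooth_terms <- c(smooth_terms, sprintf("s(gc, k = %d, bs = 'cr')", basis_dim))
  }
  if (length(unique(d$seq_length)) > basis_dim) {
    smooth_terms <- c(smooth_terms,
                      sprintf("s(seq_length, k = %d, bs = 'cr')", basis_dim))
  }
  if (length(smooth_terms) == 0) flags <- c(flags, "no_smooths")

  rhs_full <- paste(c("x", smooth_terms), collapse = " + ")
  rhs_null <- if (length(smooth_terms)) paste(smooth_terms, collapse = " + ") else "1"

  # convergence chatter from degenerate fits (e.g. near-separable tiny
  # universes) is recorded as a flag rather than escaping as warnings
  gam_warned <- FALSE
  quiet_gam <- function(formula) {
    withCallingHandlers(
      mgcv::gam(formula, family = binomial(), data = d, method = "REML"),
      warning = function(w) {
        gam_warned <<- TRUE
        invokeRestart("muffleWarning")
      }
    )
  }
  full <- quiet_gam(stats::as.formula(paste("member ~", rhs_full)))
  null <- quiet_gam(stats::as.formula(paste("member ~", rhs_null)))
  if (gam_warned) flags <- c(flags, "gam_warning")

  effect <- unname(coef(full)["x"])
  if (!is.finite(effect) || abs(effect) > 15) {
    # complete/quasi-separation: coefficient runs away; report a ridge-
    # penalized estimate, keep the (still well-defined) deviance-based LRT
    flags <- c(flags, "separation_ridge")
    xm <- stats::model.matrix(full)
    rf <- glmnet::glmnet(xm[, -1, drop = FALSE], d$member, family = "binomial",
                         alpha = 0, lambda = 1e-3)
    effect <- unname(coef(rf)["x", 1])
  }

  lrt <- max(deviance(null) - deviance(full), 0)
  p_value <- pchisq(lrt, df = 1, lower.tail = FALSE)

  new_coexmotif_fit(effect = effect, p_value = p_value, d = d,
                    predictor = predictor, flags = flags,
                    full = full, null = null)
}

new_coexmotif_fit <- function(effect, p_value, d, predictor, flags, full, null) {
  structure(
    list(effect = effect, p_value = p_value,
         n_member = sum(d$member == 1), n_background = sum(d$member == 0),
         predictor = predictor, flags = flags, full = full, null = null),
    class = "coexmotif_fit"
  )
}

#' @export
print.coexmotif_fit <- function(x, ...) {
  cat("<coexmotif enrichment fit>\n")
  cat(sprintf("  predictor: %s | effect (log-odds): %.4g | LR p: %.3g\n",
              x$predictor, x$effect, x$p_value))
  cat(sprintf("  members: %d | background: %d%s\n", x$n_member, x$n_background,
              if (length(x$flags)) paste0(" | flags: ", paste(x$flags, collapse = ","))
              else ""))
  invisible(x)
}

#' @rdname fit_enrichment
#' @param x A `coexmotif_fit` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.coexmotif_fit <- function(x, ...) {
  tibble(term = "motif", estimate = x$effect, p.value = x$p_value,
         predictor = x$predictor,
         flags = paste(x$flags, collapse = ","))
}

#' @rdname fit_enrichment
#' @exportS3Method generics::glance
glance.coexmotif_fit <- function(x, ...) {
  tibble(
    n_member = x$n_member, n_background = x$n_background,
    deviance = if (!is.null(x$full)) deviance(x$full) else NA_real_,
    null_deviance = if (!is.null(x$null)) deviance(x$null) else NA_real_,
    logLik = if (!is.null(x$full)) as.numeric(logLik(x$full)) else NA_real_
  )
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: the adjusted value of the i-th smallest p among m
#' is `min_j>=i (m * p_(j) / j)`, capped at 1, order-preserving.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of BH-adjusted values, same order as the input.
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.04)) # 0.03 0.03 0.04
#' @export
bh_fdr <- function(p_values) {
  stopifnot(all(p_values >= 0 & p_values <= 1, na.rm = TRUE))
  p.adjust(p_values, method = "BH")
}

#' Run the motif-enrichment screen over a library
#'
#' Applies the seed-gene minimum-site filter, fits the enrichment model for
#' every surviving motif, adjusts p-values by Benjamini-Hochberg within this
#' window family, and ranks by ascending p (ties: larger `|effect|` first,
#' then motif id).
#'
#' @param motif_counts Long tibble from [count_motif_sites()] over the gene
#'   universe (members and background), for one window size.
#' @param membership Tibble `gene_id`, `member` (logical) covering the same
#'   universe, e.g. from [membership_from_set()].
#' @param covariates Tibble `gene_id`, `gc`, `seq_length` (from
#'   [promoter_composition()]).
#' @param window_bp Window size label recorded in the output (bp upstream).
#' @param seed_gene_id Seed gene whose promoter drives the min-site filter;
#'   `NULL` skips the filter. The seed gene itself is excluded from the
#'   fitted universe.
#' @param min_sites Minimum seed-promoter site count (default 5).
#' @inheritParams fit_enrichment
#' @return Tibble of class `coexmotif_screen`: `motif_id`, `window_bp`,
#'   `effect`, `p_value`, `fdr`, `n_member`, `n_background`, `seed_count`,
#'   `passed_min_sites`, `flags`, sorted as described.
#' @export
run_motif_screen <- function(motif_counts, membership, covariates,
                             window_bp = NA_integer_,
                             seed_gene_id = NULL, min_sites = 5,
                             predictor = c("log1p_count", "count", "presence"),
                             basis_dim = 5) {
  predictor <- match.arg(predictor)

  if (!is.null(seed_gene_id)) {
    gate <- filter_min_sites(motif_counts, seed_gene_id, min_sites)
  } else {
    gate <- motif_counts |> distinct(.data$motif_id) |>
      mutate(seed_count = NA_integer_, passed_min_sites = TRUE)
  }
  surviving <- gate$motif_id[gate$passed_min_sites]
  if (length(surviving) == 0) {
    warn("no motif passed the minimum-site filter.", class = "coexmotif_empty_screen")
    return(new_screen_tbl(
      tibble(motif_id = character(0), window_bp = integer(0), effect = double(0),
             p_value = double(0), fdr = double(0), n_member = integer(0),
             n_background = integer(0), seed_count = integer(0),
             passed_min_sites = logical(0), flags = character(0)),
      "coexmotif_screen"))
  }

  universe <- membership |>
    filter(if (is.null(seed_gene_id)) TRUE else .data$gene_id != seed_gene_id) |>
    inner_join(covariates, by = "gene_id")

  fits <- purrr::map(surviving, function(mid) {
    inputs <- universe |>
      inner_join(motif_counts |> filter(.data$motif_id == mid) |>
                   select("gene_id", motif_count = "count"),
                 by = "gene_id")
    f <- fit_enrichment(inputs, predictor = predictor, basis_dim = basis_dim)
    tibble(motif_id = mid, effect = f$effect, p_value = f$p_value,
           n_member = f$n_member, n_background = f$n_background,
           flags = paste(f$flags, collapse = ","))
  })

  out <- bind_rows(fits) |>
    mutate(fdr = bh_fdr(.data$p_value), window_bp = window_bp) |>
    left_join(gate |> select("motif_id", "seed_count", "passed_min_sites"),
              by = "motif_id") |>
    arrange(.data$p_value, desc(abs(.data$effect)), .data$motif_id) |>
    select("motif_id", "window_bp", "effect", "p_value", "fdr",
           "n_member", "n_background", "seed_count", "passed_min_sites", "flags")
  new_screen_tbl(out, "coexmotif_screen",
                 predictor = predictor, min_sites = min_sites,
                 seed_gene_id = seed_gene_id)
}

#' Membership indicator from a correlated gene set
#'
#' @param gene_ids Character vector: the full gene universe.
#' @param gene_set A `coexmotif_gene_set` (or anything with a `gene_id`
#'   column, or a character vector of member ids).
#' @return Tibble `gene_id`, `member` over `gene_ids`.
#' @export
membership_from_set <- function(gene_ids, gene_set) {
  members <- if (is.character(gene_set)) gene_set else gene_set$gene_id
  tibble(gene_id = gene_ids, member = gene_ids %in% members)
}
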