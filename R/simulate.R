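# Synthetic datasets with the statistical structure the screen assumes:
# a latent regulator drives a target-gene set in a negative-binomial count
# matrix, and the same target genes carry extra planted motif instances in
# their promoters. Everything is regenerable byte-identically from one
# integer seed.

#' Simulation configuration
#'
#' Defaults emulate a bulk RNA-Seq regulator screen at desk scale: 99
#' samples (the cohort size of a typical lesional-skin compendium), 1,000
#' genes of which 150 respond to the latent regulator with coefficient 1.5
#' on the log scale, negative-binomial dispersion 0.16 (a biological
#' coefficient of variation of 0.4, the usual rule of thumb for human bulk
#' RNA-Seq), 2 kb promoters,
#' and a three-fold excess of planted motif instances in target promoters
#' (3 vs 1 expected occurrences).
#'
#' @param n_genes,n_samples,n_targets Universe sizes; `n_targets < n_genes`.
#' @param seed_gene_effect Log-scale coefficient linking target genes to the
#'   latent regulator activity. Negative values emulate repression (the
#'   screen is sign-agnostic through its selection policy).
#' @param nb_dispersion Negative-binomial dispersion (variance
#'   `mu + dispersion * mu^2`); must be > 0.
#' @param baseline_log_mean_range Range (natural log of expected counts at
#'   unit library factor) from which per-gene baselines are drawn.
#' @param library_size_sdlog Log-normal sd of per-sample library factors.
#' @param promoter_len_bp Promoter length upstream of the TSS.
#' @param planted_motif One-row motif tibble ([motif_consensus()]); default
#'   the E-box pair `CAGGTG`/`CACCTG`.
#' @param plant_rate_target,plant_rate_background Expected planted
#'   occurrences per promoter in target / background genes
#'   (`target >= background >= 0`).
#' @param background_gc Background base composition of promoters.
#' @param gc_confounding Added to target-promoter GC to create a composition
#'   confound (0 = none); used to exercise the covariate adjustment.
#' @param n_decoys Number of random decoy motifs in the generated library.
#' @param seed_gene_id Identifier of the seed gene.
#' @param rng_seed Integer seed; one seed reproduces every file.
#' @return A validated config list of class `coexmotif_sim_config`.
#' @export
simulation_config <- function(n_genes = 1000, n_samples = 99, n_targets = 150,
                              seed_gene_effect = 1.5, nb_dispersion = 0.16,
                              baseline_log_mean_range = log(c(5, 500)),
                              library_size_sdlog = 0.3,
                              promoter_len_bp = 2000,
                              planted_motif = NULL,
                              plant_rate_target = 3, plant_rate_background = 1,
                              background_gc = 0.45, gc_confounding = 0,
                              n_decoys = 29,
                              seed_gene_id = "SEED",
                              rng_seed = 1L) {
  planted_motif <- planted_motif %||%
    motif_consensus("planted", "PLANTED", c("CAGGTG", "CACCTG"))
  stopifnot(n_targets < n_genes, nb_dispersion > 0,
            plant_rate_target >= plant_rate_background,
            plant_rate_background >= 0,
            background_gc > 0, background_gc < 1, gc_confounding >= 0,
            promoter_len_bp >= 50)
  structure(
    list(n_genes = n_genes, n_samples = n_samples, n_targets = n_targets,
         seed_gene_effect = seed_gene_effect, nb_dispersion = nb_dispersion,
         baseline_log_mean_range = baseline_log_mean_range,
         library_size_sdlog = library_size_sdlog,
         promoter_len_bp = promoter_len_bp, planted_motif = planted_motif,
         plant_rate_target = plant_rate_target,
         plant_rate_background = plant_rate_background,
         background_gc = background_gc, gc_confounding = gc_confounding,
         n_decoys = n_decoys, seed_gene_id = seed_gene_id,
         rng_seed = as.integer(rng_seed)),
    class = "coexmotif_sim_config"
  )
}

sim_gene_ids <- function(cfg) {
  c(cfg$seed_gene_id,
    sprintf("G%04d", seq_len(cfg$n_genes - 1)))
}

#' Simulate the count matrix driven by a latent regulator
#'
#' Per sample, a latent regulator activity `r_s ~ N(0, 1)` is drawn. The
#' seed gene's log-mean is `baseline + 1.0 * r_s`; each target gene's is
#' `baseline + seed_gene_effect * r_s`; all other genes are independent of
#' the regulator. Counts are negative binomial around
#' `exp(log-mean) * library_factor`, with log-normal library factors.
#'
#' @param cfg A [simulation_config()].
#' @return List: `counts` (wide tibble, first row block includes the seed
#'   gene), `gene_lengths` (tibble), `activity` (latent vector, one value
#'   per sample), `target_flags` (tibble `gene_id`, `is_target`).
#' @export
simulate_expression <- function(cfg) {
  stopifnot(inherits(cfg, "coexmotif_sim_config"))
  set.seed(cfg$rng_seed)
  ids <- sim_gene_ids(cfg)
  non_seed <- ids[-1]
  targets <- sort(sample(non_seed, cfg$n_targets))

  activity <- rnorm(cfg$n_samples)
  baseline <- runif(cfg$n_genes, cfg$baseline_log_mean_range[1],
                    cfg$baseline_log_mean_range[2])
  effect <- numeric(cfg$n_genes)
  names(effect) <- ids
  effect[cfg$seed_gene_id] <- 1.0
  effect[targets] <- cfg$seed_gene_effect

  lib_factor <- rlnorm(cfg$n_samples, 0, cfg$library_size_sdlog)
  log_mu <- outer(baseline, rep(1, cfg$n_samples)) +
    outer(effect, activity) +
    outer(rep(1, cfg$n_genes), log(lib_factor))
  mu <- exp(log_mu)
  counts <- matrix(
    rnbinom(length(mu), mu = mu, size = 1 / cfg$nb_dispersion),
    nrow = cfg$n_genes,
    dimnames = list(ids, sprintf("S%03d", seq_len(cfg$n_samples)))
  )
  lengths <- tibble(gene_id = ids,
                    length_bp = sample(500:5000, cfg$n_genes, replace = TRUE))
  list(
    counts = matrix_to_tibble(counts),
    gene_lengths = lengths,
    activity = activity,
    target_flags = tibble(gene_id = ids,
                          is_target = ids %in% targets)
  )
}

random_seq <- function(n, gc) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  codes <- c(65L, 67L, 71L, 84L) # A C G T
  intToUtf8(codes[sample.int(4, n, replace = TRUE, prob = p)])
}

realize_consensus <- function(consensus) {
  codes <- strsplit(consensus, "")[[1]]
  paste(vapply(codes, function(cd) sample(IUPAC_SETS[[cd]], 1), character(1)),
        collapse = "")
}

# plant `k` non-overlapping instances of the motif into `seq`; returns
# list(seq, sites tibble). Errors if the promoter cannot hold them.
plant_instances <- function(seq, variants, k) {
  empty <- tibble(start = integer(0), length = integer(0),
                  orientation = character(0))
  if (k == 0) return(list(seq = seq, sites = empty))
  S <- nchar(seq)
  occupied <- rep(FALSE, S)
  starts <- integer(k); lens <- integer(k); orients <- character(k)
  for (i in seq_len(k)) {
    cons <- if (length(variants) == 1) variants else sample(variants, 1)
    L <- nchar(cons)
    if (S < L) abort("promoter too short for a planted motif instance.",
                     class = "coexmotif_promoter_too_short")
    placed <- FALSE
    for (try in 1:200) {
      st <- sample.int(S - L + 1, 1)
      if (any(occupied[st:(st + L - 1)])) next
      inst <- realize_consensus(cons)
      orientation <- sample(c("+", "-"), 1)
      if (orientation == "-") inst <- revcomp_iupac(inst)
      substr(seq, st, st + L - 1) <- inst
      occupied[st:(st + L - 1)] <- TRUE
      starts[i] <- st; lens[i] <- L; orients[i] <- orientation
      placed <- TRUE
      break
    }
    if (!placed) abort("promoter too crowded to place a planted motif instance.",
                       class = "coexmotif_promoter_too_short")
  }
  ord <- order(starts)
  list(seq = seq,
       sites = tibble(start = starts[ord], length = lens[ord],
                      orientation = orients[ord]))
}

random_decoy_library <- function(n_decoys, planted_variants) {
  forbidden <- unique(c(planted_variants, revcomp_iupac(planted_variants)))
  degenerate <- setdiff(names(IUPAC_SETS), c("A", "C", "G", "T"))
  out <- list()
  i <- 0
  while (i < n_decoys) {
    L <- sample(5:8, 1)
    n_deg <- sample(0:2, 1)
    codes <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    if (n_deg > 0) {
      pos <- sample.int(L, n_deg)
      codes[pos] <- sample(degenerate, n_deg, replace = TRUE)
    }
    cons <- paste(codes, collapse = "")
    if (cons %in% forbidden) next
    i <- i + 1
    out[[i]] <- motif_consensus(sprintf("decoy%02d", i), sprintf("DECOY%02d", i), cons)
  }
  bind_rows(out)
}

#' Generate promoters with planted motif instances
#'
#' Builds a synthetic genome in which every gene owns a promoter of
#' `promoter_len_bp` random background sequence (at the configured GC, with
#' an optional GC shift in target genes) into which planted-motif instances
#' are inserted at non-overlapping random positions, `Poisson(rate)` many
#' per promoter with the rate set by the gene's target/background class.
#' Each instance realizes every degenerate position uniformly and is
#' inserted in a random orientation. Genes sit on multi-gene contigs on
#' alternating strands with at least a window of spacing.
#'
#' @param cfg A [simulation_config()].
#' @param target_flags Tibble `gene_id`, `is_target` (from
#'   [simulate_expression()]).
#' @return List: `genome` (named character vector of contigs),
#'   `contig_lengths`, `annotation` (tibble `gene_id`, `chrom`, `strand`,
#'   `tss`), `motif_library` (planted motif first, then decoys),
#'   `truth_sites` (tibble `gene_id`, `start`, `length`, `orientation`,
#'   promoter-oriented coordinates).
#' @export
generate_promoters <- function(cfg, target_flags) {
  stopifnot(inherits(cfg, "coexmotif_sim_config"),
            all(c("gene_id", "is_target") %in% names(target_flags)))
  set.seed(cfg$rng_seed + 1L)

  L <- cfg$promoter_len_bp
  variants <- cfg$planted_motif$consensus[[1]]
  genes_per_contig <- 50L
  gap <- L + 1L          # >= window-size spacing between gene slots
  slot <- (L + 1L) + gap

  n <- nrow(target_flags)
  contig_of <- (seq_len(n) - 1L) %/% genes_per_contig + 1L
  pos_in_contig <- (seq_len(n) - 1L) %% genes_per_contig

  annotation <- tibble(
    gene_id = target_flags$gene_id,
    chrom = sprintf("ctg%02d", contig_of),
    strand = ifelse(seq_len(n) %% 2 == 1, "+", "-"),
    tss = NA_real_
  )

  contigs <- character(0)
  truth <- list()
  for (ct in unique(annotation$chrom)) {
    rows <- which(annotation$chrom == ct)
    pieces <- character(length(rows))
    for (j in seq_along(rows)) {
      r <- rows[j]
      off <- pos_in_contig[r] * slot
      gc <- cfg$background_gc +
        if (target_flags$is_target[r]) cfg$gc_confounding else 0
      gc <- min(max(gc, 0.05), 0.95)
      promoter <- random_seq(L + 1L, gc)
      rate <- if (target_flags$is_target[r]) cfg$plant_rate_target
              else cfg$plant_rate_background
      k <- rpois(1, rate)
      planted <- plant_instances(promoter, variants, k)
      if (nrow(planted$sites)) {
        truth[[length(truth) + 1]] <-
          planted$sites |> mutate(gene_id = annotation$gene_id[r], .before = 1)
      }
      # promoter-oriented sequence occupies the slot head; on '-' the stored
      # genomic segment is its reverse complement so extraction returns it
      if (annotation$strand[r] == "+") {
        annotation$tss[r] <- off + L + 1L
        seg <- planted$seq
      } else {
        annotation$tss[r] <- off + 1L
        seg <- revcomp_iupac(planted$seq)
      }
      pieces[j] <- paste0(seg, random_seq(gap, cfg$background_gc))
    }
    contigs[ct] <- paste0(paste(pieces, collapse = ""),
                          random_seq(gap, cfg$background_gc))
  }

  lib <- bind_rows(cfg$planted_motif, random_decoy_library(cfg$n_decoys, variants))
  truth_sites <- if (length(truth)) bind_rows(truth) else
    tibble(gene_id = character(0), start = integer(0), length = integer(0),
           orientation = character(0))
  list(
    genome = contigs,
    contig_lengths = setNames(nchar(contigs), names(contigs)),
    annotation = annotation,
    motif_library = lib,
    truth_sites = truth_sites
  )
}

#' Generate a complete synthetic dataset
#'
#' Couples [simulate_expression()] and [generate_promoters()] under one
#' seed: the genes that respond to the latent regulator are the same genes
#' whose promoters receive extra planted motif instances.
#'
#' @param cfg A [simulation_config()].
#' @return List of class `coexmotif_dataset` with elements `counts`,
#'   `gene_lengths`, `activity`, `genome`, `contig_lengths`, `annotation`,
#'   `motif_library`, `truth_genes`, `truth_sites`, `config`.
#' @export
simulate_dataset <- function(cfg = simulation_config()) {
  expr <- simulate_expression(cfg)
  prom <- generate_promoters(cfg, expr$target_flags)
  structure(
    list(counts = expr$counts, gene_lengths = expr$gene_lengths,
         activity = expr$activity,
         genome = prom$genome, contig_lengths = prom$contig_lengths,
         annotation = prom$annotation, motif_library = prom$motif_library,
         truth_genes = expr$target_flags, truth_sites = prom$truth_sites,
         config = cfg),
    class = "coexmotif_dataset"
  )
}

#' @export
print.coexmotif_dataset <- function(x, ...) {
  cat("<coexmotif synthetic dataset>\n")
  cat(sprintf("  %d genes x %d samples | %d targets | seed gene %s | rng_seed %d\n",
              x$config$n_genes, x$config$n_samples, x$config$n_targets,
              x$config$seed_gene_id, x$config$rng_seed))
  cat(sprintf("  %d contigs | %d motifs (1 planted) | %d planted sites\n",
              length(x$genome), nrow(x$motif_library), nrow(x$truth_sites)))
  invisible(x)
}

#' Score pipeline recovery against simulation truth
#'
#' @param gene_set Selected correlated set ([select_correlated_set()]).
#' @param screen Enrichment screen result ([run_motif_screen()]).
#' @param truth_genes Tibble `gene_id`, `is_target` from the dataset.
#' @param planted_motif_id Motif id of the planted motif (default
#'   `"planted"`).
#' @return One-row tibble: `n_selected`, `n_true_targets`, `precision`
#'   (`NA` when nothing selected), `recall`, `planted_rank`, `planted_fdr`,
#'   `planted_effect`.
#' @export
evaluate_recovery <- function(gene_set, screen, truth_genes,
                              planted_motif_id = "planted") {
  if (!all(gene_set$gene_id %in% truth_genes$gene_id)) {
    abort("selected genes not covered by truth table: mismatched universes.",
          class = "coexmotif_universe_mismatch")
  }
  true_ids <- truth_genes$gene_id[truth_genes$is_target]
  sel <- gene_set$gene_id
  tp <- sum(sel %in% true_ids)
  planted <- screen |> filter(.data$motif_id == planted_motif_id)
  rank_of <- if (nrow(planted)) match(planted_motif_id, screen$motif_id)
             else NA_integer_
  tibble(
    n_selected = length(sel),
    n_true_targets = length(true_ids),
    precision = if (length(sel)) tp / length(sel) else NA_real_,
    recall = if (length(true_ids)) tp / length(true_ids) else NA_real_,
    planted_rank = rank_of,
    planted_fdr = if (nrow(planted)) planted$fdr[1] else NA_real_,
    planted_effect = if (nrow(planted)) planted$effect[1] else NA_real_
  )
}
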