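# End-to-end orchestration: filter -> transform -> correlate -> select ->
# extract -> scan -> enrich -> predict, from one config.

#' Pipeline configuration
#'
#' Assembles and validates the configuration for [run_screen()]. Every
#' element can also be supplied from a YAML file via `config_file`, with
#' arguments overriding file values.
#'
#' @param counts,gene_lengths,genome,annotation,motifs Input file paths
#'   (TSV / FASTA / BED6 or GFF3 / motif TSV), or in-memory objects of the
#'   corresponding types.
#' @param outdir Output directory for result TSVs and the manifest.
#' @param seed_gene_id Seed gene id.
#' @param windows List of `c(upstream, downstream)` pairs in bp. Default:
#'   1 kb, 2 kb and 5 kb upstream, plus 10 kb upstream with 1 kb downstream.
#' @param filter,correlation,enrichment,target Named lists of stage
#'   parameters; see [detection_filter()], [spearman_screen()] /
#'   [select_correlated_set()], [run_motif_screen()], [predict_targets()].
#' @param rng_seed Seed for any stochastic step (permutation p-values).
#' @param config_file Optional YAML file of the same structure.
#' @return Config list of class `coexmotif_config`.
#' @export
pipeline_config <- function(counts, gene_lengths, genome, annotation, motifs,
                            outdir = NULL, seed_gene_id,
                            windows = list(c(1000, 0), c(2000, 0),
                                           c(5000, 0), c(10000, 1000)),
                            filter = list(), correlation = list(),
                            enrichment = list(), target = list(),
                            rng_seed = 1L, config_file = NULL) {
  base <- list(
    counts = counts, gene_lengths = gene_lengths, genome = genome,
    annotation = annotation, motifs = motifs, outdir = outdir,
    seed_gene_id = seed_gene_id, windows = windows,
    filter = filter, correlation = correlation,
    enrichment = enrichment, target = target, rng_seed = as.integer(rng_seed)
  )
  if (!is.null(config_file)) {
    # file values fill in anything not explicitly passed as an argument;
    # defaulted arguments do not clobber the file
    explicit <- c(
      names(base)[!vapply(base, is.null, logical(1)) &
                    !names(base) %in% c("windows", "filter", "correlation",
                                        "enrichment", "target", "rng_seed")],
      if (!missing(windows)) "windows", if (!missing(filter)) "filter",
      if (!missing(correlation)) "correlation",
      if (!missing(enrichment)) "enrichment", if (!missing(target)) "target",
      if (!missing(rng_seed)) "rng_seed"
    )
    file_cfg <- yaml::read_yaml(config_file)
    defaults <- base[setdiff(names(base), c(names(file_cfg), explicit))]
    base <- modifyList(modifyList(base[explicit], file_cfg), base[explicit])
    base <- modifyList(base, defaults)
    if (is.list(base$windows)) base$windows <- lapply(base$windows, unlist)
  }
  if (length(base$windows) == 0) {
    abort("config error: `windows` must be non-empty.", class = "coexmotif_bad_config")
  }
  for (key in c("counts", "gene_lengths", "genome", "annotation", "motifs")) {
    v <- base[[key]]
    if (is.null(v)) {
      abort(paste0("config error: missing required key `", key, "`."),
            class = "coexmotif_bad_config")
    }
    if (is.character(v) && length(v) == 1 && !file.exists(v) &&
        !(key == "genome" && !is.null(names(v)))) {
      abort(paste0("config error: `", key, "` path does not exist: ", v),
            class = "coexmotif_bad_config")
    }
  }
  structure(base, class = "coexmotif_config")
}

resolve_input <- function(x, reader) {
  if (is.character(x) && length(x) == 1 && file.exists(x)) reader(x) else x
}

# hash of the analysis parameters only: file locations and output directory
# do not change what is computed, so they are excluded and a rerun from a
# different directory stays byte-identical
config_fingerprint <- function(config) {
  keep <- unclass(config)
  keep <- keep[setdiff(names(keep),
                       c("counts", "gene_lengths", "genome", "annotation",
                         "motifs", "outdir"))]
  rlang::hash(keep)
}

#' Run the full regulator-nomination screen
#'
#' Executes every stage in order: detection filter, log2-CPM transform,
#' seed-gene Spearman screen, correlated-set selection, promoter window
#' construction and sequence extraction per window size, IUPAC motif
#' scanning, GAM enrichment with per-window BH-FDR, and per-motif target
#' ranking. When `outdir` is set, every intermediate is materialized as TSV
#' and a run manifest (config hash, seed, package version, per-stage row
#' counts) is written even if a later stage fails.
#'
#' @param config A [pipeline_config()].
#' @return List of class `coexmotif_result`: `correlations`, `gene_set`,
#'   `promoters` (per window), `motif_counts` (per window), `enrichment`
#'   (one combined tibble, per-window FDR families), `targets` (per motif of
#'   the largest window), `manifest`.
#' @export
run_screen <- function(config) {
  stopifnot(inherits(config, "coexmotif_config"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("coexmotif")),
    config_hash = config_fingerprint(config),
    rng_seed = config$rng_seed,
    seed_gene_id = config$seed_gene_id,
    started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    stages = list()
  )
  outdir <- config$outdir
  if (!is.null(outdir)) dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  emit <- function(x, name) {
    if (!is.null(outdir)) {
      write_tsv_provenance(x, file.path(outdir, paste0(name, ".tsv")),
                           config_hash = config_fingerprint(config))
    }
    x
  }
  finish_manifest <- function() {
    if (!is.null(outdir)) {
      yaml::write_yaml(manifest, file.path(outdir, "manifest.yaml"))
    }
  }
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      manifest$stages[[name]] <<- list(status = "error",
                                       message = conditionMessage(e))
      finish_manifest()
      abort(paste0("stage `", name, "` failed: ", conditionMessage(e)),
            class = "coexmotif_stage_error", parent = e)
    })
    n <- if (is.data.frame(res)) nrow(res) else NA_integer_
    manifest$stages[[name]] <<- list(status = "ok", n_rows = n)
    res
  }

  counts <- resolve_input(config$counts, read_counts)
  gene_lengths <- resolve_input(config$gene_lengths, read_gene_lengths)
  genome <- if (is.character(config$genome) && length(config$genome) == 1 &&
                file.exists(config$genome)) config$genome else config$genome
  annotation <- resolve_input(config$annotation, read_gene_annotation)
  motifs <- resolve_input(config$motifs, read_motif_library)
  set.seed(config$rng_seed)

  filtered <- stage("detection_filter", do.call(detection_filter,
    c(list(counts = counts, gene_lengths = gene_lengths), config$filter)))
  expr <- stage("log_cpm_transform", log_cpm_transform(filtered))

  cor_args <- config$correlation
  screen_args <- cor_args[intersect(names(cor_args), c("p_method", "n_perm"))]
  select_args <- cor_args[intersect(names(cor_args),
                                    c("policy", "rho_min", "fdr_max", "top_n"))]
  correlations <- stage("spearman_screen", do.call(spearman_screen,
    c(list(expr = expr, seed_gene_id = config$seed_gene_id), screen_args)))
  emit(correlations, "correlations")
  gene_set <- stage("select_correlated_set",
                    do.call(select_correlated_set,
                            c(list(results = correlations), select_args)))
  emit(as_tibble(gene_set), "gene_set")

  contigs <- as_contig_strings(genome)
  contig_lengths <- setNames(nchar(contigs), names(contigs))
  ann <- annotation |> filter(.data$gene_id %in% c(filtered$gene_id))

  enr_args <- config$enrichment
  min_sites <- enr_args$min_sites %||% 5
  predictor <- enr_args$predictor %||% "log1p_count"
  basis_dim <- enr_args$basis_dim %||% 5

  promoters <- list(); motif_counts <- list(); enrichments <- list()
  membership <- membership_from_set(ann$gene_id, gene_set)
  for (w in config$windows) {
    up <- w[[1]]; down <- if (length(w) > 1) w[[2]] else 0
    wname <- paste0("w", up, "u", down, "d")
    prom <- stage(paste0("extract_", wname), {
      win <- upstream_window(ann, up, down, contig_lengths = contig_lengths)
      promoter_composition(extract_sequence(contigs, win))
    })
    promoters[[wname]] <- prom
    mc <- stage(paste0("scan_", wname),
                count_motif_sites(prom, motifs))
    motif_counts[[wname]] <- mc
    enr <- stage(paste0("enrich_", wname),
                 run_motif_screen(mc, membership,
                                  prom |> select("gene_id", "gc", "seq_length"),
                                  window_bp = up,
                                  seed_gene_id = config$seed_gene_id,
                                  min_sites = min_sites,
                                  predictor = predictor,
                                  basis_dim = basis_dim))
    enrichments[[wname]] <- enr
    emit(enr, paste0("enrichment_", wname))
  }
  enrichment <- bind_rows(enrichments)

  top_n <- config$target$top_n %||% 12
  last_counts <- motif_counts[[length(motif_counts)]]
  target_motifs <- enrichment |>
    filter(.data$window_bp == config$windows[[length(config$windows)]][[1]]) |>
    pull(.data$motif_id)
  targets <- purrr::map(target_motifs, function(mid) {
    predict_targets(last_counts, correlations, mid, top_n = top_n)
  }) |> bind_rows()
  emit(targets, "targets")

  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  finish_manifest()

  structure(
    list(correlations = correlations, gene_set = gene_set,
         promoters = promoters, motif_counts = motif_counts,
         enrichment = enrichment, targets = targets, manifest = manifest),
    class = "coexmotif_result"
  )
}

#' @export
print.coexmotif_result <- function(x, ...) {
  cat("<coexmotif screen result>\n")
  cat(sprintf("  correlated set: %d genes | windows: %d | motifs tested: %d\n",
              nrow(x$gene_set), length(x$promoters),
              length(unique(x$enrichment$motif_id))))
  top <- head(x$enrichment, 3)
  if (nrow(top)) {
    cat("  top enrichment:\n")
    for (i in seq_len(nrow(top))) {
      cat(sprintf("    %s (window %d bp): effect %.3f, p %.2e, fdr %.2e\n",
                  top$motif_id[i], top$window_bp[i], top$effect[i],
                  top$p_value[i], top$fdr[i]))
    }
  }
  invisible(x)
}
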