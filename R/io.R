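# Readers and writers for the pipeline's plain-text interchange formats.

#' Read a gene x sample count matrix from TSV
#'
#' First column gene ids (any header name is accepted and renamed to
#' `gene_id`), remaining columns one per sample. Lines starting with `#` are
#' treated as comments.
#'
#' @param path TSV path.
#' @return Wide counts tibble.
#' @export
read_counts <- function(path) {
  x <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  names(x)[1] <- "gene_id"
  x$gene_id <- as.character(x$gene_id)
  x
}

#' Read per-gene lengths from a two-column TSV
#'
#' @param path TSV with columns gene id, length in bp (header optional but
#'   recommended).
#' @return Tibble `gene_id`, `length_bp`.
#' @export
read_gene_lengths <- function(path) {
  x <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  names(x)[1:2] <- c("gene_id", "length_bp")
  x$gene_id <- as.character(x$gene_id)
  x[c("gene_id", "length_bp")]
}

#' Read a TSS annotation from BED6 or GFF3
#'
#' BED input follows the BED standard (0-based, half-open): the feature is
#' taken as the TSS position, i.e. `tss = chromStart + 1`, with the strand
#' from column 6 and the gene id from column 4. GFF3 input (1-based,
#' inclusive) takes the TSS as `start` on `+` features and `end` on `-`
#' features, and the gene id from the `ID` attribute.
#'
#' @param path Annotation file path.
#' @param format `"bed"` or `"gff3"`; guessed from the extension by default.
#' @return Tibble `gene_id`, `chrom`, `strand`, `tss`.
#' @export
read_gene_annotation <- function(path, format = c("auto", "bed", "gff3")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gff3?$", path, ignore.case = TRUE)) "gff3" else "bed"
  }
  if (format == "bed") {
    x <- readr::read_tsv(path, comment = "#", col_names = FALSE,
                         show_col_types = FALSE)
    if (ncol(x) < 6) abort("BED6 required: need a strand column.",
                           class = "coexmotif_bad_input")
    tibble(gene_id = as.character(x[[4]]), chrom = as.character(x[[1]]),
           strand = as.character(x[[6]]), tss = as.numeric(x[[2]]) + 1)
  } else {
    gr <- rtracklayer::import(path, format = "gff3")
    md <- as.data.frame(gr)
    ids <- md$ID %||% md$Name %||% as.character(seq_len(nrow(md)))
    tibble(gene_id = as.character(ids), chrom = as.character(md$seqnames),
           strand = as.character(md$strand),
           tss = ifelse(md$strand == "-", md$end, md$start))
  }
}

#' Read / write a motif library TSV
#'
#' Three tab-separated columns: `motif_id`, `name`, comma-separated IUPAC
#' consensus strings.
#'
#' @param path TSV path.
#' @return Motif library tibble with a `consensus` list-column.
#' @export
read_motif_library <- function(path) {
  x <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  stopifnot(all(c("motif_id", "name", "consensus") %in% names(x)))
  lib <- purrr::pmap(x[c("motif_id", "name", "consensus")],
                     function(motif_id, name, consensus) {
                       motif_consensus(motif_id, name,
                                       strsplit(consensus, ",")[[1]])
                     })
  bind_rows(lib)
}

#' @rdname read_motif_library
#' @param motif_library Motif library tibble.
#' @export
write_motif_library <- function(motif_library, path) {
  flat <- motif_library |>
    mutate(consensus = vapply(.data$consensus, paste, character(1),
                              collapse = ","))
  readr::write_tsv(flat, path)
  invisible(path)
}

#' Bundled demonstration motif library
#'
#' A small library of literature consensus binding sites (E-box/bHLH,
#' homeobox, forkhead, NF-kB, AP-1, IRF, CEBP families and others) for
#' demonstrations and tests. It is not the full binding-site vocabulary a
#' production screen would use.
#'
#' @return Motif library tibble.
#' @export
demo_motif_library <- function() {
  read_motif_library(system.file("extdata", "motifs_demo.tsv",
                                 package = "coexmotif", mustWork = TRUE))
}

#' Write a TSV with a one-line provenance header
#'
#' @param x Data frame.
#' @param path Output path.
#' @param config Optional list hashed into the header for provenance;
#'   alternatively pass a precomputed `config_hash` string.
#' @param config_hash Optional hash string used verbatim.
#' @export
write_tsv_provenance <- function(x, path, config = NULL, config_hash = NULL) {
  hash <- config_hash %||%
    (if (is.null(config)) "none" else rlang::hash(config))
  header <- sprintf("# coexmotif %s | config_hash=%s",
                    as.character(utils::packageVersion("coexmotif")), hash)
  writeLines(header, path)
  readr::write_tsv(x, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Write a synthetic dataset to disk as standard formats
#'
#' Emits `counts.tsv`, `gene_lengths.tsv`, `genome.fa`, `genes.bed` (BED6,
#' one 1 bp TSS feature per gene), `motifs.tsv`, `truth_genes.tsv`,
#' `truth_sites.tsv` and `config.yaml` into `dir`.
#'
#' @param dataset A `coexmotif_dataset` from [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @param force Overwrite an existing non-empty directory (default FALSE).
#' @return `dir`, invisibly.
#' @export
write_synthetic_dataset <- function(dataset, dir, force = FALSE) {
  stopifnot(inherits(dataset, "coexmotif_dataset"))
  if (dir.exists(dir) && length(dir(dir)) > 0 && !force) {
    abort(paste0("output directory not empty (use force = TRUE): ", dir),
          class = "coexmotif_refuse_overwrite")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(dataset$counts, file.path(dir, "counts.tsv"))
  readr::write_tsv(dataset$gene_lengths, file.path(dir, "gene_lengths.tsv"))

  fa <- Biostrings::DNAStringSet(dataset$genome)
  Biostrings::writeXStringSet(fa, file.path(dir, "genome.fa"))

  bed <- dataset$annotation |>
    transmute(chrom = .data$chrom,
              chromStart = as.integer(.data$tss - 1),
              chromEnd = as.integer(.data$tss),
              name = .data$gene_id, score = 0L, strand = .data$strand)
  readr::write_tsv(bed, file.path(dir, "genes.bed"), col_names = FALSE)

  write_motif_library(dataset$motif_library, file.path(dir, "motifs.tsv"))
  readr::write_tsv(dataset$truth_genes, file.path(dir, "truth_genes.tsv"))
  readr::write_tsv(dataset$truth_sites, file.path(dir, "truth_sites.tsv"))

  cfg <- dataset$config
  cfg_out <- cfg[setdiff(names(cfg), "planted_motif")]
  cfg_out$planted_motif_consensus <- cfg$planted_motif$consensus[[1]]
  yaml::write_yaml(cfg_out, file.path(dir, "config.yaml"))
  invisible(dir)
}
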