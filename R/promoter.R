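# Strand-aware promoter windows and sequence extraction.
#
# Coordinate convention: 1-based, inclusive at both ends, so a window of
# `upstream_bp` upstream and `downstream_bp` downstream spans
# upstream_bp + downstream_bp + 1 positions and always contains the TSS.

#' TSS-anchored promoter windows
#'
#' Builds, for each annotated gene, the genomic interval covering
#' `upstream_bp` bases upstream and `downstream_bp` bases downstream of the
#' TSS, respecting strand: upstream means lower coordinates on `+` and higher
#' coordinates on `-`. Windows are clipped at position 1 and, when contig
#' lengths are supplied, at the contig end; clipping is flagged, not an error.
#'
#' @param annotation Tibble with columns `gene_id`, `chrom`, `strand`
#'   (`"+"`/`"-"`) and `tss` (1-based coordinate), e.g. from
#'   [read_gene_annotation()].
#' @param upstream_bp,downstream_bp Non-negative window extents in bp.
#' @param contig_lengths Optional named vector of contig lengths used for
#'   right-clipping and to reject unknown contigs.
#' @return Tibble with columns `gene_id`, `chrom`, `start`, `end`, `strand`,
#'   `upstream_bp`, `downstream_bp`, `clipped`.
#' @examples
#' ann <- tibble::tibble(gene_id = "IL17C", chrom = "chr16",
#'                       strand = "+", tss = 88638571)
#' upstream_window(ann, upstream_bp = 10000, downstream_bp = 1000)
#' @export
upstream_window <- function(annotation, upstream_bp, downstream_bp = 0,
                            contig_lengths = NULL) {
  stopifnot(is.data.frame(annotation),
            all(c("gene_id", "chrom", "strand", "tss") %in% names(annotation)),
            upstream_bp >= 0, downstream_bp >= 0)
  if (upstream_bp == 0 && downstream_bp == 0) {
    abort("window has zero extent on both sides.", class = "coexmotif_bad_input")
  }
  if (!all(annotation$strand %in% c("+", "-"))) {
    abort("strand must be '+' or '-'.", class = "coexmotif_bad_input")
  }
  if (any(annotation$tss < 1)) {
    abort("tss coordinates must be >= 1.", class = "coexmotif_bad_input")
  }
  if (!is.null(contig_lengths)) {
    unknown <- setdiff(unique(annotation$chrom), names(contig_lengths))
    if (length(unknown)) {
      abort(paste0("contig(s) absent from genome: ", paste(unknown, collapse = ", ")),
            class = "coexmotif_missing_contig")
    }
  }
  plus <- annotation$strand == "+"
  start <- ifelse(plus, annotation$tss - upstream_bp, annotation$tss - downstream_bp)
  end <- ifelse(plus, annotation$tss + downstream_bp, annotation$tss + upstream_bp)

  clip_lo <- start < 1
  start <- pmax(start, 1)
  clip_hi <- rep(FALSE, length(end))
  if (!is.null(contig_lengths)) {
    lim <- unname(contig_lengths[annotation$chrom])
    clip_hi <- end > lim
    end <- pmin(end, lim)
  }
  tibble(
    gene_id = annotation$gene_id,
    chrom = annotation$chrom,
    start = as.numeric(start),
    end = as.numeric(end),
    strand = annotation$strand,
    upstream_bp = upstream_bp,
    downstream_bp = downstream_bp,
    clipped = clip_lo | clip_hi
  )
}

#' Extract promoter-oriented sequence for windows
#'
#' Pulls the window sequence out of a genome and orients it so that position
#' 1 is always the most-distal upstream base: `+`-strand windows are returned
#' as-is, `-`-strand windows are reverse-complemented. Sequences are
#' uppercased; `N` is allowed, any other character is an error reporting its
#' position.
#'
#' @param genome A named character vector of contig sequences, a
#'   `Biostrings::DNAStringSet`, or a path to a FASTA file.
#' @param windows Tibble from [upstream_window()].
#' @return `windows` with an added character column `sequence`.
#' @export
extract_sequence <- function(genome, windows) {
  contigs <- as_contig_strings(genome)
  unknown <- setdiff(unique(windows$chrom), names(contigs))
  if (length(unknown)) {
    abort(paste0("contig(s) absent from genome: ", paste(unknown, collapse = ", ")),
          class = "coexmotif_missing_contig")
  }
  lens <- nchar(contigs)
  seqs <- character(nrow(windows))
  for (i in seq_len(nrow(windows))) {
    chrom <- windows$chrom[i]
    s <- windows$start[i]; e <- windows$end[i]
    if (s < 1 || e > lens[[chrom]]) {
      abort(sprintf("window [%d, %d] outside contig %s (length %d)",
                    s, e, chrom, lens[[chrom]]),
            class = "coexmotif_out_of_bounds")
    }
    sq <- toupper(substr(contigs[[chrom]], s, e))
    bad <- regexpr("[^ACGTN]", sq)
    if (bad > 0) {
      abort(sprintf("non-ACGTN character '%s' at window position %d (gene %s)",
                    substr(sq, bad, bad), bad, windows$gene_id[i]),
            class = "coexmotif_bad_alphabet")
    }
    if (windows$strand[i] == "-") sq <- revcomp(sq)
    seqs[i] <- sq
  }
  out <- windows
  out$sequence <- seqs
  out
}

as_contig_strings <- function(genome) {
  if (inherits(genome, "DNAStringSet")) {
    setNames(as.character(genome), names(genome))
  } else if (is.character(genome) && length(genome) == 1 && file.exists(genome)) {
    x <- Biostrings::readDNAStringSet(genome)
    # FASTA headers may carry descriptions; keep the first token as the name
    setNames(as.character(x), sub("\\s.*$", "", names(x)))
  } else if (is.character(genome) && !is.null(names(genome))) {
    genome
  } else {
    abort("genome must be a named character vector, DNAStringSet, or FASTA path.",
          class = "coexmotif_bad_input")
  }
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' GC content of a nucleotide sequence
#'
#' Fraction (G + C) / (A + C + G + T); `N` is excluded from the denominator.
#' Sequences that are more than half `N` get `NA` with a warning (too little
#' sequence to call composition); an all-`N` sequence is an error.
#'
#' @param seq Character vector of sequences over `A,C,G,T,N`.
#' @return Numeric vector in `[0, 1]` (or `NA` for mostly-N sequences).
#' @examples
#' gc_content(c("GGCC", "ACGT", "ATAT"))
#' @export
gc_content <- function(seq) {
  stopifnot(is.character(seq), all(nchar(seq) > 0))
  seq <- toupper(seq)
  counts <- vapply(c("A", "C", "G", "T", "N"), function(b) {
    stringr::str_count(seq, stringr::fixed(b))
  }, numeric(length(seq)))
  if (length(seq) == 1) counts <- matrix(counts, nrow = 1,
                                         dimnames = list(NULL, c("A","C","G","T","N")))
  acgt <- rowSums(counts[, c("A", "C", "G", "T"), drop = FALSE])
  if (any(acgt == 0)) {
    abort("all-N sequence: GC content undefined.", class = "coexmotif_all_n")
  }
  out <- (counts[, "G"] + counts[, "C"]) / acgt
  mostly_n <- counts[, "N"] / nchar(seq) > 0.5
  if (any(mostly_n)) {
    warn(sprintf("%d sequence(s) are >50%% N; GC set to NA.", sum(mostly_n)),
         class = "coexmotif_mostly_n")
    out[mostly_n] <- NA_real_
  }
  unname(out)
}

#' Promoter composition covariates
#'
#' Adds the covariates the enrichment model adjusts for: GC fraction and
#' usable sequence length.
#'
#' @param promoters Tibble with `gene_id` and `sequence` columns
#'   (from [extract_sequence()]).
#' @return `promoters` with added `gc` and `seq_length` columns.
#' @export
promoter_composition <- function(promoters) {
  promoters |>
    mutate(gc = gc_content(.data$sequence),
           seq_length = nchar(.data$sequence))
}
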