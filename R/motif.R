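# IUPAC consensus scanning.
#
# Matching semantics: a consensus code matches a sequence base iff the base
# is one of the code's concrete nucleotides (R = A/G, Y = C/T, ...). N in the
# *sequence* is never a match for any code except when the consensus position
# is itself outside the alphabet check -- i.e. assembly gaps cannot create
# hits. Scanning is double-stranded: a window is an occurrence if any
# consensus string matches the forward window, or the reverse complement of
# the window (equivalently, the reverse complement of the consensus matches
# the forward window). Occurrences arising at the same (start, length) from
# both orientations or from different consensus variants are collapsed into
# one, so a palindromic pair like CAGGTG/CACCTG contributes a single site per
# physical element.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("G", "C"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

check_iupac <- function(x) {
  bad <- regexpr(paste0("[^", paste(names(IUPAC_SETS), collapse = ""), "]"),
                 toupper(x))
  if (any(bad > 0)) {
    i <- which(bad > 0)[1]
    abort(sprintf("invalid IUPAC character '%s' in consensus '%s'",
                  substr(toupper(x[i]), bad[i], bad[i]), x[i]),
          class = "coexmotif_bad_iupac")
  }
  invisible(toupper(x))
}

# 256-slot lookup per consensus code: byte of sequence char -> matches?
iupac_byte_table <- function(code) {
  tab <- rep(FALSE, 256)
  tab[as.integer(charToRaw(paste(IUPAC_SETS[[code]], collapse = ""))) + 1L] <- TRUE
  tab
}

#' Match one IUPAC consensus against an equal-length window
#'
#' @param consensus IUPAC consensus string.
#' @param window Sequence window over `A,C,G,T,N` of the same length.
#' @return `TRUE` iff every window base lies in the degeneracy set of the
#'   corresponding consensus code. `N` in the window never matches.
#' @examples
#' iupac_match("TGTTTRCW", "TGTTTACA") # TRUE
#' iupac_match("TGTTTRCW", "TGTTTCCA") # FALSE: R does not cover C
#' @export
iupac_match <- function(consensus, window) {
  consensus <- check_iupac(consensus)
  window <- toupper(window)
  if (nchar(consensus) != nchar(window)) {
    abort("consensus and window lengths differ.", class = "coexmotif_length_mismatch")
  }
  cs <- strsplit(consensus, "")[[1]]
  ws <- strsplit(window, "")[[1]]
  all(mapply(function(code, base) base %in% IUPAC_SETS[[code]], cs, ws))
}

#' Construct a motif from named IUPAC consensus strings
#'
#' @param motif_id Unique identifier.
#' @param name Display name (transcription factor name).
#' @param consensus Character vector of one or more IUPAC strings, written
#'   5'->3'. Variants may differ in length.
#' @return A one-row tibble with a `consensus` list-column (the in-package
#'   representation of a motif; a motif library is several such rows).
#' @export
motif_consensus <- function(motif_id, name, consensus) {
  stopifnot(length(consensus) >= 1, all(nchar(consensus) > 0))
  consensus <- vapply(consensus, check_iupac, character(1), USE.NAMES = FALSE)
  tibble(motif_id = motif_id, name = name, consensus = list(consensus))
}

# Vectorised single-orientation matcher: starts (1-based) where `consensus`
# matches forward. Byte-table lookups, one AND per consensus position.
match_starts_forward <- function(seq, consensus) {
  match_starts_bytes(as.integer(charToRaw(seq)) + 1L, consensus)
}

match_starts_bytes <- function(bytes, consensus) {
  L <- nchar(consensus)
  n <- length(bytes)
  if (n < L) return(integer(0))
  codes <- strsplit(consensus, "")[[1]]
  # keep only candidate starts after each position; survivors shrink fast
  cand <- which(iupac_byte_table(codes[1])[bytes[seq_len(n - L + 1L)]])
  j <- 2L
  while (j <= L && length(cand)) {
    cand <- cand[iupac_byte_table(codes[j])[bytes[cand + (j - 1L)]]]
    j <- j + 1L
  }
  cand
}

#' Scan a sequence for a motif on both strands
#'
#' Slides every window of each consensus length over the sequence. A window
#' is an occurrence if any consensus variant matches it forward (`+`) or if
#' the reverse complement of the window matches a variant (`-`). Occurrences
#' at the same `(start, length)` are collapsed to one, with strand recorded
#' as `"+"`, `"-"`, or `"+/-"` when both orientations match.
#'
#' @param seq Sequence over `A,C,G,T,N` (promoter-oriented).
#' @param motif One-row motif tibble from [motif_consensus()] (or a plain
#'   character vector of consensus strings).
#' @return Tibble of hits: `start`, `length`, `strand`, `matched_substring`,
#'   sorted by `start` then `length`.
#' @examples
#' tcf4 <- motif_consensus("tcf4", "TCF4", c("CAGGTG", "CACCTG"))
#' scan_sequence("ACAGGTGA", tcf4) # one collapsed occurrence at start 2
#' @export
scan_sequence <- function(seq, motif) {
  seq <- toupper(seq)
  variants <- motif_variants(motif)
  hits <- list()
  k <- 0
  for (cons in variants) {
    L <- nchar(cons)
    fw <- match_starts_forward(seq, cons)
    rv <- match_starts_forward(seq, revcomp_iupac(cons))
    if (length(fw)) {
      k <- k + 1
      hits[[k]] <- tibble(start = fw, length = L, fwd = TRUE, rev = FALSE)
    }
    if (length(rv)) {
      k <- k + 1
      hits[[k]] <- tibble(start = rv, length = L, fwd = FALSE, rev = TRUE)
    }
  }
  if (k == 0) {
    return(tibble(start = integer(0), length = integer(0),
                  strand = character(0), matched_substring = character(0)))
  }
  bind_rows(hits) |>
    group_by(.data$start, .data$length) |>
    summarise(fwd = any(.data$fwd), rev = any(.data$rev), .groups = "drop") |>
    mutate(strand = case_when(.data$fwd & .data$rev ~ "+/-",
                              .data$fwd ~ "+",
                              TRUE ~ "-"),
           matched_substring = substr(rep(seq, dplyr::n()),
                                      .data$start, .data$start + .data$length - 1L)) |>
    select("start", "length", "strand", "matched_substring") |>
    arrange(.data$start, .data$length)
}

motif_variants <- function(motif) {
  if (is.character(motif)) {
    vapply(motif, check_iupac, character(1), USE.NAMES = FALSE)
  } else if (is.data.frame(motif) && "consensus" %in% names(motif)) {
    stopifnot(nrow(motif) == 1)
    motif$consensus[[1]]
  } else {
    abort("motif must be a consensus character vector or a one-row motif tibble.",
          class = "coexmotif_bad_input")
  }
}

# reverse complement that understands degenerate codes
revcomp_iupac <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", D = "H", H = "D", V = "B",
            N = "N")
  vapply(x, function(s) {
    paste(rev(comp[strsplit(toupper(s), "")[[1]]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Count motif occurrences per gene and motif
#'
#' Runs [scan_sequence()] for every (promoter, motif) pair and tallies the
#' collapsed occurrences.
#'
#' @param promoters Tibble with `gene_id` and `sequence` columns (sequences
#'   promoter-oriented, from [extract_sequence()]).
#' @param motif_library Motif library tibble (`motif_id`, `name`,
#'   `consensus` list-column), e.g. from [read_motif_library()] or
#'   [demo_motif_library()].
#' @return Long tibble: `gene_id`, `motif_id`, `count`, `present`.
#' @export
count_motif_sites <- function(promoters, motif_library) {
  stopifnot(all(c("gene_id", "sequence") %in% names(promoters)),
            all(c("motif_id", "consensus") %in% names(motif_library)))
  if (anyDuplicated(motif_library$motif_id)) {
    abort("duplicate motif ids in library.", class = "coexmotif_bad_input")
  }
  seqs <- toupper(promoters$sequence)
  # concatenate once; every (motif, orientation) is then one vectorised pass
  max_len <- max(vapply(motif_library$consensus, function(v) max(nchar(v)), 1))
  sep <- strrep("X", max_len)
  big_bytes <- as.integer(charToRaw(paste(seqs, collapse = sep))) + 1L
  offsets <- cumsum(c(0, head(nchar(seqs), -1) + nchar(sep)))
  res <- purrr::map(seq_len(nrow(motif_library)), function(i) {
    counts <- count_collapsed_occurrences(seqs, motif_library$consensus[[i]],
                                          big_bytes, offsets)
    tibble(gene_id = promoters$gene_id,
           motif_id = motif_library$motif_id[i],
           count = counts)
  })
  bind_rows(res) |>
    mutate(present = .data$count >= 1L)
}

# Fast path used by count_motif_sites: count distinct (sequence, start,
# length) windows across variants/orientations on the concatenated bytes.
count_collapsed_occurrences <- function(seqs, variants,
                                        big_bytes = NULL, offsets = NULL) {
  n <- length(seqs)
  if (n == 0) return(integer(0))
  if (is.null(big_bytes)) {
    sep <- strrep("X", max(nchar(variants)))
    big_bytes <- as.integer(charToRaw(paste(seqs, collapse = sep))) + 1L
    offsets <- cumsum(c(0, head(nchar(seqs), -1) + nchar(sep)))
  }
  seq_lens <- nchar(seqs)
  keys <- numeric(0)
  for (cons in unique(variants)) {
    L <- nchar(cons)
    for (pat in unique(c(cons, revcomp_iupac(cons)))) {
      st <- match_starts_bytes(big_bytes, pat)
      if (!length(st)) next
      idx <- findInterval(st, offsets + 1)
      local <- st - offsets[idx]
      valid <- local + L - 1 <= seq_lens[idx]
      # encode (seq index, local start, length) as one number for dedup
      keys <- c(keys, (idx[valid] * 2^30 + local[valid]) * 64 + L)
    }
  }
  keys <- unique(keys)
  if (!length(keys)) return(integer(n))
  idx <- as.integer(keys %/% 64 %/% 2^30)
  as.integer(tabulate(idx, nbins = n))
}

#' Keep motifs with enough sites in the seed gene's promoter
#'
#' Mirrors the reporting filter "only motifs with at least `min_sites` sites
#' in the seed-gene window": a motif stays in the screen only if its
#' collapsed occurrence count in the seed gene's promoter reaches
#' `min_sites`.
#'
#' @param motif_counts Long count tibble from [count_motif_sites()].
#' @param seed_gene_id Seed gene id; must appear in `motif_counts`.
#' @param min_sites Minimum site count (default 5); 0 keeps everything.
#' @return Tibble `motif_id`, `seed_count`, `passed_min_sites` for every
#'   motif in `motif_counts`.
#' @export
filter_min_sites <- function(motif_counts, seed_gene_id, min_sites = 5) {
  stopifnot(min_sites >= 0)
  if (!seed_gene_id %in% motif_counts$gene_id) {
    abort(paste0("seed gene absent from motif counts: ", seed_gene_id),
          class = "coexmotif_missing_seed")
  }
  motif_counts |>
    filter(.data$gene_id == seed_gene_id) |>
    transmute(motif_id = .data$motif_id,
              seed_count = .data$count,
              passed_min_sites = .data$count >= min_sites)
}
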