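# Shared helpers: wide count tibble <-> matrix conversion and input checks.
#
# The package's tabular convention: a "counts" tibble is wide, first column
# `gene_id`, remaining columns one per sample.  Internally most arithmetic
# happens on plain numeric matrices with gene ids as rownames.

counts_to_matrix <- function(counts) {
  stopifnot(is.data.frame(counts))
  if (!"gene_id" %in% names(counts)) {
    abort("`counts` must have a `gene_id` first column.", class = "coexmotif_bad_input")
  }
  gene_id <- as.character(counts$gene_id)
  if (anyDuplicated(gene_id)) {
    abort("duplicate gene ids in `counts`.", class = "coexmotif_bad_input")
  }
  m <- as.matrix(counts[setdiff(names(counts), "gene_id")])
  if (anyDuplicated(colnames(m))) {
    abort("duplicate sample ids in `counts`.", class = "coexmotif_bad_input")
  }
  storage.mode(m) <- "double"
  if (any(!is.finite(m)) || any(m < 0)) {
    abort("counts must be finite and non-negative.", class = "coexmotif_bad_input")
  }
  rownames(m) <- gene_id
  m
}

matrix_to_tibble <- function(m) {
  out <- as_tibble(m, rownames = "gene_id")
  out
}

# Gene lengths come as tibble(gene_id, length_bp); returns a vector aligned
# to `gene_ids`, erroring with the offending ids if any are missing.
align_gene_lengths <- function(gene_lengths, gene_ids) {
  stopifnot(is.data.frame(gene_lengths))
  if (!all(c("gene_id", "length_bp") %in% names(gene_lengths))) {
    abort("`gene_lengths` must have columns `gene_id` and `length_bp`.",
          class = "coexmotif_bad_input")
  }
  idx <- match(gene_ids, gene_lengths$gene_id)
  if (anyNA(idx)) {
    missing <- gene_ids[is.na(idx)]
    abort(
      paste0("missing gene length for: ", paste(head(missing, 10), collapse = ", "),
             if (length(missing) > 10) sprintf(" (and %d more)", length(missing) - 10)),
      class = "coexmotif_missing_length"
    )
  }
  len <- as.numeric(gene_lengths$length_bp[idx])
  if (any(!is.finite(len)) || any(len <= 0)) {
    abort("gene lengths must be positive.", class = "coexmotif_bad_input")
  }
  names(len) <- gene_ids
  len
}

library_sizes <- function(m) {
  ls <- colSums(m)
  if (any(ls <= 0)) {
    bad <- colnames(m)[ls <= 0]
    abort(
      paste0("zero library size for sample(s): ", paste(bad, collapse = ", ")),
      class = "coexmotif_zero_library"
    )
  }
  ls
}

new_screen_tbl <- function(x, subclass, ...) {
  extra <- list(...)
  out <- as_tibble(x)
  class(out) <- c(subclass, class(out))
  for (nm in names(extra)) attr(out, nm) <- extra[[nm]]
  out
}
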