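# Small fixtures built in code.

tiny_counts <- function() {
  tibble::tibble(
    gene_id = c("g1", "g2", "g3"),
    s1 = c(10, 90, 0),
    s2 = c(1, 3, 0)
  )
}

tiny_lengths <- function(counts = tiny_counts()) {
  tibble::tibble(gene_id = counts$gene_id,
                 length_bp = rep(1000, nrow(counts)))
}

# expression tibble from a plain matrix
expr_tbl <- function(m) {
  if (is.null(colnames(m))) colnames(m) <- paste0("s", seq_len(ncol(m)))
  tibble::as_tibble(m, rownames = "gene_id")
}

# enrichment inputs with a given member/present 2x2 structure and constant
# composition (so the model degenerates to plain logistic regression)
table_2x2_inputs <- function(mem_present, mem_absent, bg_present, bg_absent) {
  tibble::tibble(
    member = c(rep(1, mem_present + mem_absent), rep(0, bg_present + bg_absent)),
    motif_count = c(rep(1, mem_present), rep(0, mem_absent),
                    rep(1, bg_present), rep(0, bg_absent)),
    gc = 0.5,
    seq_length = 2000
  )
}
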