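test_that("IUPAC single-window matching follows the degeneracy sets", {
  expect_true(iupac_match("TGTTTRCW", "TGTTTACA"))
  expect_false(iupac_match("TGTTTRCW", "TGTTTCCA"))
  expect_true(iupac_match("NNNN", "GTCA"))
  # N in the sequence never creates a match, even against the N code:
  # assembly gaps cannot produce hits
  expect_false(iupac_match("ACGT", "ACGN"))
  expect_false(iupac_match("ACGN", "ACGN"))
  expect_true(iupac_match("ACGN", "ACGA"))
  expect_error(iupac_match("ACG", "ACGT"), class = "coexmotif_length_mismatch")
  expect_error(iupac_match("ACGZ", "ACGT"), class = "coexmotif_bad_iupac")
})

test_that("scanning collapses palindromic variant pairs to one site", {
  tcf4 <- motif_consensus("tcf4", "TCF4", c("CAGGTG", "CACCTG"))
  h1 <- scan_sequence("ACAGGTGA", tcf4)
  expect_equal(nrow(h1), 1)
  expect_equal(h1$start, 2)
  expect_equal(h1$strand, "+/-") # CACCTG is the reverse complement of CAGGTG
  expect_equal(h1$matched_substring, "CAGGTG")

  h2 <- scan_sequence("CACCTGCAGGTG", tcf4)
  expect_equal(h2$start, c(1, 7))
  expect_equal(nrow(h2), 2)

  expect_equal(nrow(scan_sequence("CAGG", tcf4)), 0)
})

test_that("scanner equals the brute-force enumerator on random cases", {
  set.seed(1234)
  for (i in 1:300) {
    seq <- random_dna(sample(20:200, 1),
                      alphabet = c("A", "C", "G", "T", if (i %% 5 == 0) "N"))
    variants <- unique(replicate(
      sample(1:2, 1),
      random_iupac_consensus(sample(4:8, 1), sample(0:2, 1))
    ))
    got <- scan_sequence(seq, variants)
    want <- oracle_scan(seq, variants)
    expect_equal(got$start, want$start)
    expect_equal(got$length, want$length)
    expect_equal(got$strand, want$strand)
  }
})

test_that("occurrence totals are invariant under reverse complementation", {
  set.seed(55)
  for (i in 1:25) {
    seq <- random_dna(300)
    variants <- random_iupac_consensus(6, sample(0:2, 1))
    expect_equal(nrow(scan_sequence(seq, variants)),
                 nrow(scan_sequence(oracle_revcomp(seq), variants)))
  }
})

test_that("variant-pair scanning equals double-strand scanning of one member", {
  set.seed(20)
  for (i in 1:20) {
    seq <- random_dna(500)
    both <- scan_sequence(seq, c("CAGGTG", "CACCTG"))
    one <- scan_sequence(seq, "CAGGTG")
    expect_equal(both$start, one$start)
    expect_equal(nrow(both), nrow(one))
  }
})

test_that("per-gene count grids match brute force and respect strand symmetry", {
  set.seed(77)
  proms <- tibble::tibble(
    gene_id = c("g1", "g2", "g3"),
    sequence = c(random_dna(2000), random_dna(2000), strrep("A", 50))
  )
  lib <- dplyr::bind_rows(
    motif_consensus("m6", "M6", "CAGGTG"),
    motif_consensus("pair", "PAIR", c("CAGGTG", "CACCTG")),
    motif_consensus("deg", "DEG", "TGTTTRCW")
  )
  counts <- count_motif_sites(proms, lib)
  for (g in proms$gene_id) {
    for (m in lib$motif_id) {
      want <- nrow(oracle_scan(proms$sequence[proms$gene_id == g],
                               lib$consensus[[match(m, lib$motif_id)]]))
      got <- counts$count[counts$gene_id == g & counts$motif_id == m]
      expect_equal(got, want)
    }
  }
  # all-A promoter: zero row for motifs with G/C content
  expect_true(all(counts$count[counts$gene_id == "g3"] == 0))
  # reverse-complementing any input sequence leaves all counts unchanged
  proms_rc <- proms
  proms_rc$sequence[1] <- oracle_revcomp(proms$sequence[1])
  counts_rc <- count_motif_sites(proms_rc, lib)
  expect_equal(counts$count, counts_rc$count)
})

test_that("seed-promoter minimum-site filter uses an inclusive boundary", {
  counts <- tibble::tibble(
    gene_id = rep(c("seed", "other"), each = 3),
    motif_id = rep(c("m5", "m4", "m0"), 2),
    count = c(5L, 4L, 0L, 9L, 9L, 9L),
    present = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE)
  )
  gate <- filter_min_sites(counts, "seed", min_sites = 5)
  expect_true(gate$passed_min_sites[gate$motif_id == "m5"])
  expect_false(gate$passed_min_sites[gate$motif_id == "m4"])
  expect_true(all(filter_min_sites(counts, "seed", min_sites = 0)$passed_min_sites))
  expect_error(filter_min_sites(counts, "absent"),
               class = "coexmotif_missing_seed")
})

test_that("motif library round-trips through its TSV format", {
  lib <- dplyr::bind_rows(
    motif_consensus("tcf4", "TCF4", c("CAGGTG", "CACCTG")),
    motif_consensus("foxo1", "FOXO1", "WTGTTTAC")
  )
  path <- withr::local_tempfile(fileext = ".tsv")
  write_motif_library(lib, path)
  back <- read_motif_library(path)
  expect_equal(back$motif_id, lib$motif_id)
  expect_equal(back$consensus, lib$consensus)

  demo <- demo_motif_library()
  expect_gte(nrow(demo), 30)
  expect_true(all(c("tcf4", "prrx1", "tcf12", "foxo1", "nfib") %in% demo$motif_id))
  expect_equal(demo$consensus[[match("tcf4", demo$motif_id)]],
               c("CAGGTG", "CACCTG"))
})
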