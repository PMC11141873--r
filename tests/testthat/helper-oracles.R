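# Independent brute-force oracles. These deliberately share no code with the
# package internals: naive window enumeration with set membership for the
# scanner, the literal step-up definition for BH, closed-form 2x2 binomial
# log-likelihoods for the logistic LR test.

oracle_iupac <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("G", "C"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

oracle_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N",
            R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
            B = "V", D = "H", H = "D", V = "B")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

oracle_window_matches <- function(consensus, window) {
  cs <- strsplit(consensus, "")[[1]]
  ws <- strsplit(window, "")[[1]]
  if (length(cs) != length(ws)) return(FALSE)
  for (i in seq_along(cs)) {
    if (!(ws[i] %in% oracle_iupac[[cs[i]]])) return(FALSE)
  }
  TRUE
}

# enumerate every window of every variant length on both strands, collapse
# per (start, length); returns data.frame(start, length, strand)
oracle_scan <- function(seq, variants) {
  out <- list()
  for (cons in variants) {
    L <- nchar(cons)
    if (nchar(seq) < L) next
    for (st in seq_len(nchar(seq) - L + 1)) {
      win <- substr(seq, st, st + L - 1)
      fwd <- oracle_window_matches(cons, win)
      rev <- oracle_window_matches(cons, oracle_revcomp(win))
      if (fwd || rev) {
        out[[length(out) + 1]] <- data.frame(start = st, length = L,
                                             fwd = fwd, rev = rev)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(start = integer(0), length = integer(0),
                      strand = character(0)))
  }
  d <- do.call(rbind, out)
  agg <- aggregate(cbind(fwd, rev) ~ start + length, data = d, FUN = any)
  agg$strand <- ifelse(agg$fwd & agg$rev, "+/-", ifelse(agg$fwd, "+", "-"))
  agg <- agg[order(agg$start, agg$length), c("start", "length", "strand")]
  rownames(agg) <- NULL
  agg
}

# literal BH step-up: adj_(i) = min_{j >= i} m p_(j) / j, capped at 1
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[i] <- min(1, min(m * ps[i:m] / (i:m)))
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# closed-form LR test for a 2x2 membership-vs-presence table:
# full model: separate member rate per presence class; null: pooled rate
oracle_2x2_lr <- function(member, present) {
  ll_binom <- function(k, n) {
    if (n == 0) return(0)
    p <- k / n
    (if (k > 0) k * log(p) else 0) +
      (if (n - k > 0) (n - k) * log(1 - p) else 0)
  }
  n1 <- sum(present == 1); a1 <- sum(member[present == 1])
  n0 <- sum(present == 0); a0 <- sum(member[present == 0])
  ll_full <- ll_binom(a1, n1) + ll_binom(a0, n0)
  ll_null <- ll_binom(a1 + a0, n1 + n0)
  lr <- 2 * (ll_full - ll_null)
  beta <- log((a1 / (n1 - a1)) / (a0 / (n0 - a0)))
  list(beta = beta, lr = lr,
       p = pchisq(lr, df = 1, lower.tail = FALSE))
}

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

random_iupac_consensus <- function(len, n_degenerate) {
  codes <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  if (n_degenerate > 0) {
    pos <- sample.int(len, n_degenerate)
    codes[pos] <- sample(c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "N"),
                         n_degenerate, replace = TRUE)
  }
  paste(codes, collapse = "")
}
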