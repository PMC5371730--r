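# Independent oracles, deliberately naive: they enumerate or follow the
# textbook definition literally and never share code with the implementation.

# P(X >= k) for X ~ Hypergeometric(N, K, n), by enumerating every possible
# sample of size n from a population whose first K members are successes.
hypergeom_enum_oracle <- function(N, K, n, k) {
  if (n == 0) return(as.numeric(k <= 0))
  samples <- utils::combn(N, n)
  successes <- colSums(samples <= K)
  mean(successes >= k)
}

# Exact combinatorial tail sum for populations too large to enumerate:
# sum_{j >= k} C(K,j) C(N-K,n-j) / C(N,n), via choose() only.
hypergeom_enum_oracle_large <- function(N, K, n, k) {
  js <- k:min(n, K)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# Literal Benjamini-Hochberg step-up: sort ascending, adj_(i) =
# min_{j >= i}(p_(j) * m / j) capped at 1, back to input order.
bh_oracle <- function(p) {
  m <- length(p)
  if (m == 0) return(numeric())
  ord <- order(p)
  ps <- p[ord]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[i] <- min(1, min(ps[i:m] * m / (i:m)))
  }
  out <- numeric(m)
  out[ord] <- adj
  out
}

# small random annotation fixture: n_prot proteins, vocab domains, each
# protein gets 0..3 random domains
random_annotation_fixture <- function(n_prot, vocab = 6) {
  prots <- sprintf("P%02d", seq_len(n_prot))
  doms <- sprintf("D%02d", seq_len(vocab))
  rows <- lapply(prots, function(p) {
    k <- sample(0:3, 1)
    if (k == 0) return(NULL)
    data.frame(protein_id = p, term_id = sample(doms, k))
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) df <- data.frame(protein_id = character(), term_id = character())
  list(annotations = annotation_table(df$protein_id, df$term_id),
       universe = prots)
}

write_fixture <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
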