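# independent brute-force oracles, deliberately naive

# ratio-scale average of signed fold-regulations via hand-rolled reciprocals
oracle_avg_signed <- function(values) {
  ratios <- numeric(length(values))
  for (i in seq_along(values)) {
    v <- values[i]
    ratios[i] <- if (v > 0) v else -1 / v
  }
  m <- sum(ratios) / length(ratios)
  if (m >= 1) m else -1 / m
}

# P(X >= k) by enumerating every size-n draw from an N-gene universe of
# which the first K genes are pathway members
oracle_hypergeom <- function(k, K, n, N) {
  draws <- utils::combn(N, n)
  mean(apply(draws, 2, function(d) sum(d <= K) >= k))
}

# BH step-up written out longhand
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  for (i in (n - 1):1) adj[i] <- min(adj[i], adj[i + 1])
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# per-pair source counting with table()
oracle_votes <- function(assertions, mirnas, min_votes) {
  sub <- assertions[assertions$mirna %in% mirnas, ]
  key <- paste(sub$mirna, sub$gene, sep = "|")
  counts <- table(key[!duplicated(paste(key, sub$source))])
  sort(names(counts)[counts >= min_votes])
}

# tiny wide expression tibble from a named matrix
toy_expr <- function(m) {
  dplyr::bind_cols(tibble::tibble(mirna = rownames(m)), tibble::as_tibble(m))
}
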