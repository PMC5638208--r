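# Small fixture builders shared across test files. Everything is generated
# in code; no binary fixtures.

# A tiny fully signed network: n regulators, k targets each, disjoint.
tiny_network <- function(n = 5, k = 12, n_genes = 200, seed = 42,
                         mode_mix = c(0.5, 0.5, 0)) {
  make_network(n, k, n_genes, mode_mix = mode_mix, seed = seed)
}

# A transformed-signature mock with prescribed t2/t1 values.
mock_transformed <- function(t2, t1 = abs(t2)) {
  structure(list(t2 = t2, t1 = t1, label = "mock"),
            class = "netact_transformed")
}

# Random named signature.
random_signature <- function(n = 500, seed = 1, prefix = "G") {
  set.seed(seed)
  stats::setNames(rnorm(n), sprintf("%s%05d", prefix, seq_len(n)))
}

# Brute-force three-tail ES oracle: plain loop over targets, no shared
# code with regulon_es / .es_matrix.
oracle_es <- function(t2, t1, targets, mode, weight) {
  present <- targets %in% names(t2)
  tg <- targets[present]
  w <- weight[present] / sum(weight[present])
  m <- mode[present]
  total <- 0
  for (i in seq_along(tg))
    total <- total + w[i] * (m[i] * t2[[tg[i]]] + (1 - abs(m[i])) * t1[[tg[i]]])
  total
}

# Brute-force BH step-up oracle.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  out <- numeric(n)
  out[o] <- pmin(q, 1)
  out
}

# Brute-force AUROC by pair counting.
oracle_auroc <- function(score, positive) {
  pos <- score[positive]; neg <- score[!positive]
  total <- 0
  for (a in pos) for (b in neg)
    total <- total + (a > b) + 0.5 * (a == b)
  total / (length(pos) * length(neg))
}

write_tmp <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}
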