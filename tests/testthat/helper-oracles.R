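# Independent brute-force oracles used across tests. These deliberately
# avoid the package's own code paths.

# Exhaustive hypergeometric upper tail by enumerating every size-n draw.
enum_hyper_tail <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)      # treat items 1..K as successes
  mean(hits >= k)
}

# Direct-summation hypergeometric upper tail (term-by-term, no tail call).
sum_hyper_tail <- function(N, K, n, k) {
  if (k <= 0) return(1)
  sum(stats::dhyper(k:min(K, n), K, N - K, n))
}

# Brute-force RRHO: recompute every grid cell of a stratified map by
# looping over prefix intersections, mirroring only the map layout.
brute_rrho_cell <- function(sig_a, sig_b, quadrant, len_a, len_b) {
  N <- nrow(sig_a)
  take <- function(sig, from_up, len) {
    g <- sig$gene
    if (from_up) rev(g)[seq_len(len)] else g[seq_len(len)]
  }
  ua <- quadrant %in% c("up-up", "up-down")
  ub <- quadrant %in% c("up-up", "down-up")
  pa <- take(sig_a, ua, len_a)
  pb <- take(sig_b, ub, len_b)
  k <- length(intersect(pa, pb))
  list(k = k, K = len_a, n = len_b, N = N)
}

# Naive AUCell area for one ranking (loop over window positions).
brute_aucell <- function(ranks_of_module, W, M) {
  hits <- vapply(seq_len(W), function(i) sum(ranks_of_module <= i), numeric(1))
  sum(hits) / sum(pmin(seq_len(W), M))
}

# Small paired design used by several tests.
tiny_pair_design <- function(n_genes = 300, seed = 1, ...) {
  synth_design(n_genes = n_genes, groups = c("control", "withdrawal"),
               n_per_group = 8, sexes = c("F", "M"), noise_sd = 0.5,
               seed = seed, ...)
}
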