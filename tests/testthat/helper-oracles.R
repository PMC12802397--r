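# Independent oracles used to cross-check the fast implementations.

# Exhaustive all-pairs Hamming scan: assigns each read to the library
# element whose protospacer (at `offset`) matches exactly (policy "exact")
# or is the unique element at Hamming distance <= 1 (policy "one_mismatch").
# Returns element indices, NA = unmapped.  Deliberately brute force.
hamming_scan_oracle <- function(reads, protospacers, offset,
                                policy = c("exact", "one_mismatch")) {
  policy <- match.arg(policy)
  L <- nchar(protospacers[1])
  sub <- substr(reads, offset, offset + L - 1L)
  read_mat <- matrix(unlist(strsplit(sub, "")), nrow = L)
  ps_mat <- matrix(unlist(strsplit(protospacers, "")), nrow = L)
  vapply(seq_along(sub), function(i) {
    d <- colSums(ps_mat != read_mat[, i])
    if (policy == "exact") {
      hit <- which(d == 0)
      if (length(hit) == 1) hit else NA_integer_
    } else {
      dmin <- min(d)
      if (dmin > 1) return(NA_integer_)
      best <- which(d == dmin)
      if (length(best) == 1) best else NA_integer_
    }
  }, integer(1))
}

# Exhaustive hypergeometric upper tail: enumerate every n-subset of the
# universe and count how often the overlap with the set reaches k.
hyper_enum_oracle <- function(k, set_idx, N, n) {
  subsets <- utils::combn(N, n)
  hits <- colSums(matrix(subsets %in% set_idx, nrow = n))
  mean(hits >= k)
}

# small helper: simulated screen at unit-test scale
tiny_screen <- function(n_genes = 40, n_ntc = 10, seed = 5, ...) {
  man <- make_manifest(n_genes, 5, n_ntc)
  sim <- simulate_screen(man, sim_config(seed = seed, ...))
  list(man = man, sim = sim)
}
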