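# Shared test fixtures: random admissible pairwise states and graph oracles.

# A random state satisfying the stub-count constraints of a regular network of
# degree n, with non-negative implied R-pairs: SS + SI <= n*S, II + SI <= n*I.
random_admissible_state <- function(params) {
  N <- params$N; n <- params$n
  fS <- runif(1, 0.3, 0.85)
  fI <- runif(1, 0.02, min(0.3, 0.98 - fS))
  S <- fS * N; I <- fI * N
  SI <- runif(1, 0.05, 0.6) * n * min(S, I)
  SS <- runif(1, 0.1, 0.95) * (n * S - SI)
  II <- runif(1, 0.1, 0.95) * (n * I - SI)
  pairwise_state(S = S, I = I, SI = SI, SS = SS, II = II)
}

# Implied R-type pair counts of a state (stub-count complements).
implied_R_pairs <- function(state, params) {
  s <- unclass(state)
  list(RS = params$n * s[["S"]] - s[["SS"]] - s[["SI"]],
       IR = params$n * s[["I"]] - s[["SI"]] - s[["II"]])
}

# Brute-force global clustering coefficient by enumerating ordered paths of
# length two: 6 x triangles over 2 x triples.
brute_force_phi <- function(G) {
  nv <- nrow(G)
  closed <- 0; total <- 0
  for (i in seq_len(nv)) for (j in seq_len(nv)) for (k in seq_len(nv)) {
    if (i != j && j != k && i != k && G[i, j] == 1 && G[j, k] == 1) {
      total <- total + 1
      if (G[i, k] == 1) closed <- closed + 1
    }
  }
  if (total == 0) return(NA_real_)
  closed / total
}

# Erdos-Renyi-style random simple graph as an adjacency matrix.
random_graph <- function(nv, p = 0.5) {
  G <- matrix(0, nv, nv)
  for (i in seq_len(nv - 1)) for (j in (i + 1):nv) {
    if (runif(1) < p) G[i, j] <- G[j, i] <- 1
  }
  G
}
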