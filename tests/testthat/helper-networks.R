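# Small systems used across the tests; everything is built in code.

pure_death_network <- function(k1 = 0.3) {
  reaction_network("A", list(
    list(name = "R1", reactants = c(A = 1), products = c(), theta = k1)
  ))
}

# observed species A, hidden species B: B is produced/degraded and
# catalyses production of A; used to exercise the partially observed
# sampler against the exact smoother
toy_hidden_network <- function(th = c(0.5, 0.4, 0.6, 0.5)) {
  reaction_network(
    species = c("A", "B"),
    reactions = list(
      list(name = "R1", reactants = c(), products = c(B = 1), theta = th[1]),
      list(name = "R2", reactants = c(B = 1), products = c(), theta = th[2]),
      list(name = "R3", reactants = c(B = 1), products = c(A = 1, B = 1),
           theta = th[3]),
      list(name = "R4", reactants = c(A = 1), products = c(), theta = th[4])
    ))
}

empty_path <- function(x0, t0, t1) {
  reaction_path(x0, numeric(0), integer(0), t0, t1)
}

# total-variation distance between two samples of non-negative integers
tv_counts <- function(a, b) {
  k <- max(a, b) + 1L
  pa <- tabulate(a + 1L, k) / length(a)
  pb <- tabulate(b + 1L, k) / length(b)
  sum(abs(pa - pb)) / 2
}

# independent brute-force elementary-mode enumeration (direct translation
# of the definition, no shared code with null_set())
brute_force_modes <- function(network, observed, cap = 4L) {
  A_obs <- network$A[, observed, drop = FALSE]
  M <- nrow(A_obs)
  grid <- as.matrix(do.call(expand.grid, rep(list(0:cap), M)))
  ok <- apply(grid, 1, function(q) all(colSums(q * A_obs) == 0) && sum(q) > 0)
  cand <- grid[ok, , drop = FALSE]
  keep <- rep(TRUE, nrow(cand))
  for (i in seq_len(nrow(cand))) {
    si <- cand[i, ] > 0
    for (j in seq_len(nrow(cand))) {
      if (i == j) next
      sj <- cand[j, ] > 0
      strictly_smaller_support <- all(sj <= si) && any(si & !sj)
      same_support_smaller <- all(sj == si) && sum(cand[j, ]) < sum(cand[i, ])
      if ((strictly_smaller_support || same_support_smaller) && keep[j]) {
        keep[i] <- FALSE
        break
      }
    }
  }
  out <- cand[keep, , drop = FALSE]
  out[do.call(order, c(list(rowSums(out)),
                       lapply(seq_len(ncol(out)), function(c) out[, c]))), ,
      drop = FALSE]
}
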