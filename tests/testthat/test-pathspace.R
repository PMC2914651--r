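test_that("null sets match the known elementary modes", {
  bd <- birth_death_network()
  ns <- null_set(bd)
  expect_equal(unname(ns$modes), matrix(c(1L, 1L), 1, 2))

  ar <- autoregulatory_network()
  full <- null_set(ar)
  expect_equal(nrow(full$modes), 4)
  # the four reversible pairs, in canonical order
  pairs <- matrix(0L, 4, 8)
  pairs[1, 7:8] <- 1L
  pairs[2, 5:6] <- 1L
  pairs[3, 3:4] <- 1L
  pairs[4, 1:2] <- 1L
  expect_equal(unname(full$modes), pairs)

  part <- null_set(ar, observed = c("mRNA", "P", "P2"))
  expect_gt(nrow(part$modes), 4)
  # every fully observed mode stays a mode; R1 + R5 + 2 R7 appears
  pm <- unname(part$modes)
  for (k in seq_len(4))
    expect_true(any(apply(pm, 1, function(q)
      all(q == unname(full$modes[k, ])))))
  expect_true(any(apply(pm, 1, function(q)
    all(q == c(1L, 0L, 0L, 0L, 1L, 0L, 2L, 0L)))))
})

test_that("null_set agrees with brute-force enumeration", {
  nets <- list(
    list(net = birth_death_network(), obs = "A"),
    list(net = toy_hidden_network(), obs = "A"),
    list(net = toy_hidden_network(), obs = c("A", "B")),
    list(net = autoregulatory_network(), obs = c("mRNA", "P", "P2"))
  )
  for (case in nets) {
    got <- null_set(case$net, observed = case$obs)$modes
    want <- brute_force_modes(case$net, case$obs)
    expect_equal(unname(got), unname(want))
  }
})

test_that("an observability pattern with no modes is an error", {
  pd <- pure_death_network()
  expect_error(null_set(pd), "empty null set")
})

test_that("minimal reaction counts solve the endpoint constraint", {
  bd <- birth_death_network()
  expect_equal(unname(find_reaction_counts(bd, c(A = 2))), c(0L, 2L))
  expect_equal(unname(find_reaction_counts(bd, c(A = -3))), c(3L, 0L))
  expect_equal(unname(find_reaction_counts(bd, c(A = 0))), c(0L, 0L))

  # infeasible observed change is reported distinctly
  pd <- pure_death_network()
  expect_error(find_reaction_counts(pd, c(A = 1)), "incompatible")

  # random instances: exact constraint satisfied, total is minimal vs a
  # direct search over small totals
  ar <- autoregulatory_network()
  set.seed(5)
  for (i in 1:10) {
    delta <- drop(t(ar$A) %*% sample(0:2, 8, replace = TRUE))
    r <- find_reaction_counts(ar, delta)
    expect_equal(drop(t(ar$A) %*% r), delta)
    if (sum(r) > 0) {
      grid <- as.matrix(do.call(expand.grid, rep(list(0:3), 8)))
      feas <- grid[apply(grid, 1, function(q)
        all(colSums(q * ar$A) == delta)), , drop = FALSE]
      expect_equal(sum(r), min(rowSums(feas)))
    }
  }
})

test_that("initial paths honour the counts and non-negativity", {
  bd <- birth_death_network()
  p0 <- initial_path(bd, c(A = 4), c(0L, 0L), 0, 2)
  expect_length(p0$times, 0)

  # from an empty system, death before birth is impossible: the repair
  # search must order the single birth first
  set.seed(2)
  for (i in 1:10) {
    p <- initial_path(bd, c(A = 0), c(1L, 1L), 0, 2)
    expect_equal(p$types, c(2L, 1L))
    expect_true(is.finite(path_log_likelihood(bd, p)))
  }

  # one transcription event carries an mRNA +1 change
  ar <- autoregulatory_network()
  x <- c(DNA = 10, DNA.P2 = 0, mRNA = 3, P = 5, P2 = 1)
  r <- find_reaction_counts(ar, c(DNA = 0, DNA.P2 = 0, mRNA = 1, P = 0,
                                  P2 = 0))
  expect_equal(unname(r), c(0L, 0L, 1L, 0L, 0L, 0L, 0L, 0L))
  p <- initial_path(ar, x, r, 0, 0.5)
  expect_equal(p$types, 3L)

  # random endpoint changes on the auto-regulatory system give valid paths
  set.seed(9)
  tr <- simulate_ssa(ar, c(DNA = 10, DNA.P2 = 0, mRNA = 0, P = 0, P2 = 0),
                     t_end = 30, seed = 31)
  obs <- make_observations(tr, ar, times = seq(0, 30, by = 2))
  sts <- as.matrix(obs[, ar$species])
  for (i in seq_len(nrow(sts) - 1)) {
    r <- find_reaction_counts(ar, sts[i + 1, ] - sts[i, ])
    p <- initial_path(ar, sts[i, ], r, 0, 2)
    expect_true(is.finite(path_log_likelihood(ar, p)))
    expect_equal(tabulate(p$types, 8), unname(r))
  }
})
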