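test_that("SSA halts when no reaction is possible and respects the seed", {
  pd <- pure_death_network()
  tr <- simulate_ssa(pd, c(A = 0), t_end = 10, seed = 1)
  expect_length(tr$times, 0)

  bd <- birth_death_network()
  t1 <- simulate_ssa(bd, c(A = 5), t_end = 50, seed = 42)
  t2 <- simulate_ssa(bd, c(A = 5), t_end = 50, seed = 42)
  expect_identical(t1$times, t2$times)
  expect_identical(t1$types, t2$types)
})

test_that("the birth-death time average approaches the stationary mean k2/k1", {
  bd <- birth_death_network(0.03, 0.6)
  tr <- simulate_ssa(bd, c(A = 20), t_end = 10000, seed = 7)
  states <- path_states(bd, tr)[, 1]
  times <- c(tr$t0, tr$times, tr$t1)
  keep <- times[-length(times)] >= 1000 # discard the transient
  w <- diff(times)[keep]
  avg <- sum(states[keep] * w) / sum(w)
  # stationary law is Poisson(20); the long-run time average should be close
  expect_gt(avg, 18)
  expect_lt(avg, 22)
})

test_that("inter-event times at constant hazard are exponential", {
  # pure birth process: hazard constant k2, gaps i.i.d. Exp(k2)
  birth <- reaction_network("A", list(
    list(name = "R2", reactants = c(), products = c(A = 1), theta = 0.8)))
  tr <- simulate_ssa(birth, c(A = 0), t_end = 4000, seed = 3)
  gaps <- diff(c(tr$t0, tr$times))
  expect_gt(length(gaps), 2500)
  ks <- suppressWarnings(stats::ks.test(gaps, "pexp", rate = 0.8))
  expect_gt(ks$p.value, 0.01)
})

test_that("auto-regulatory trajectories conserve the promoter copy number", {
  ar <- autoregulatory_network(dna_total = 10)
  tr <- simulate_ssa(ar, c(DNA = 10, DNA.P2 = 0, mRNA = 0, P = 0, P2 = 0),
                     t_end = 50, seed = 2)
  states <- path_states(ar, tr)
  expect_true(all(states[, "DNA"] + states[, "DNA.P2"] == 10))
  expect_true(all(states >= 0))
})

test_that("observation extraction restricts to the requested species", {
  bd <- birth_death_network()
  tr <- simulate_ssa(bd, c(A = 3), t_end = 10, seed = 5)
  # trajectory with no events: every row equals x0
  pd <- simulate_ssa(pure_death_network(), c(A = 0), t_end = 10)
  obs0 <- make_observations(pd, pure_death_network(), times = 0:9)
  expect_true(all(obs0$A == 0))

  ar <- autoregulatory_network()
  tra <- simulate_ssa(ar, c(DNA = 10, DNA.P2 = 0, mRNA = 0, P = 0, P2 = 0),
                      t_end = 20, seed = 2)
  part <- make_observations(tra, ar, times = seq(0, 19, by = 1),
                            observed = c("mRNA", "P", "P2"))
  expect_named(part, c("time", "mRNA", "P", "P2"))
  full <- make_observations(tra, ar, times = seq(0, 19, by = 1))
  expect_named(full, c("time", "DNA", "DNA.P2", "mRNA", "P", "P2"))
  # left limit convention: same grid, restricted columns agree
  expect_equal(part$P, full$P)

  expect_error(make_observations(tra, ar, times = c(0, 25)), "window")
})

test_that("observation CSVs round-trip exactly", {
  b <- generate_benchmark("birth_death", m = 11, dt = 2, seed = 9)
  f <- tempfile(fileext = ".csv")
  write_observations(b$observations, f)
  back <- read_observations(f, b$network)
  expect_equal(as.data.frame(back), as.data.frame(b$observations))
  unlink(f)
})

test_that("benchmark generation is reproducible and well-formed", {
  b1 <- generate_benchmark("autoreg", m = 50, dt = 0.5, seed = 4)
  b2 <- generate_benchmark("autoreg", m = 50, dt = 0.5, seed = 4)
  expect_identical(b1$observations, b2$observations)
  expect_equal(nrow(b1$observations), 50)
  expect_equal(b1$observations$time, seq(0, by = 0.5, length.out = 50))
  expect_true(all(b1$observations$DNA + b1$observations$DNA.P2 == 10))
  counts <- as.matrix(b1$observations[, -1])
  expect_true(all(counts >= 0 & counts == round(counts)))
})
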