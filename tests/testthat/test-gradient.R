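test_that("sufficient statistics match hand calculations and are additive", {
  bd <- birth_death_network(0.03, 0.6)
  st <- sufficient_stats(bd, empty_path(c(A = 5), 0, 2))
  expect_equal(st$n, c(0L, 0L))
  expect_equal(st$G, c(10, 2)) # G1 = n_A * tau, G2 = tau

  # one birth at mid-interval: A = 5 for one unit, 6 for one unit
  p <- reaction_path(c(A = 5), 1, 2L, 0, 2)
  st1 <- sufficient_stats(bd, p)
  expect_equal(st1$n, c(0L, 1L))
  expect_equal(st1$G, c(11, 2))

  # additivity over a list of paths
  q <- reaction_path(c(A = 6), c(2.5), 1L, 2, 4)
  st2 <- sufficient_stats(bd, q)
  both <- sufficient_stats(bd, list(p, q))
  expect_equal(both$n, st1$n + st2$n)
  expect_equal(both$G, st1$G + st2$G)
})

test_that("the complete-data score vanishes exactly at n/G and is monotone", {
  bd <- birth_death_network()
  p <- reaction_path(c(A = 5), c(0.3, 0.8, 1.4), c(2L, 1L, 2L), 0, 2)
  st <- sufficient_stats(bd, p)
  mle <- st$n / st$G
  for (r in 1:2) {
    th <- unname(bd$theta)
    th[r] <- mle[r]
    sc <- path_score(set_theta(bd, th), p)
    expect_equal(unname(sc[r]), 0)
    th[r] <- mle[r] * 1.5
    expect_lt(path_score(set_theta(bd, th), p)[r], 0)
    th[r] <- mle[r] * 0.5
    expect_gt(path_score(set_theta(bd, th), p)[r], 0)
  }
})

test_that("reactions that are never possible contribute an exactly zero score", {
  # a dimerization that can never fire along a path with < 2 proteins
  net <- reaction_network(c("P", "Q"), list(
    list(name = "R1", reactants = c(P = 2), products = c(Q = 1), theta = 0.4),
    list(name = "R2", reactants = c(), products = c(P = 1), theta = 0.5)
  ))
  p <- reaction_path(c(P = 0, Q = 0), 1.0, 2L, 0, 2)
  st <- sufficient_stats(net, p)
  expect_equal(st$n[1], 0L)
  expect_equal(st$G[1], 0)
  expect_equal(unname(path_score(net, p)[1]), 0)
  g <- estimate_gradient(structure(
    list(n = matrix(st$n, 1, 2), G = matrix(st$G, 1, 2), scores = NULL,
         network = net), class = "path_samples"))
  expect_equal(g$estimate[1], 0)
})

test_that("the Monte-Carlo gradient matches exact finite differences", {
  bd <- birth_death_network(0.03, 0.6)
  obs <- tibble::tibble(time = c(0, 2), A = c(20L, 22L))
  set.seed(5)
  s <- sample_paths(bd, obs, mcmc_control(n_samples = 10000, burn_in = 500))
  g <- estimate_gradient(s, ess_correct = TRUE)
  oracle <- cme_log_transition_grad(bd, c(A = 20), c(A = 22), 2,
                                    list(A = c(0, 60)))
  z <- (g$estimate - unname(oracle$gradient)) / g$std_error
  expect_true(all(abs(z) < 3))
})

test_that("gradient error shrinks with the Monte-Carlo sample size", {
  bd <- birth_death_network(0.03, 0.6)
  obs <- tibble::tibble(time = c(0, 2), A = c(20L, 18L))
  oracle <- cme_log_transition_grad(bd, c(A = 20), c(A = 18), 2,
                                    list(A = c(0, 60)))$gradient
  err <- sapply(c(100L, 10000L), function(n) {
    mean(sapply(1:3, function(rep) {
      set.seed(8 + rep)
      s <- sample_paths(bd, obs, mcmc_control(n_samples = n, burn_in = 300))
      g <- estimate_gradient(s)
      sqrt(sum((g$estimate - unname(oracle))^2))
    }))
  })
  # 100x more samples: root-n predicts a 10x error reduction; averaging
  # three chains leaves wide stochastic slack around that
  expect_lt(err[2], err[1] / 2)
})

test_that("the truncated-CME oracle reproduces the linear death process", {
  pd <- pure_death_network(0.3)
  for (k in c(0, 2, 4, 7, 10)) {
    lp <- cme_log_transition(pd, c(A = 10), c(A = k), 1.5, list(A = c(0, 10)))
    exact <- stats::dbinom(k, 10, exp(-0.3 * 1.5), log = TRUE)
    expect_equal(lp, exact, tolerance = 1e-10)
  }
})

test_that("the truncated generator has the correct row structure", {
  bd <- birth_death_network(0.1, 0.5)
  H <- cme_generator(bd, list(A = c(0, 10)))
  rs <- Matrix::rowSums(H)
  # interior rows conserve probability; the top boundary leaks the birth flux
  expect_equal(rs[1:10], rep(0, 10), ignore_attr = TRUE)
  expect_equal(rs[11], -0.5, ignore_attr = TRUE)
  # off-diagonal entries are the hazards
  expect_equal(H[3, 2], 0.1 * 2) # death from A = 2
  expect_equal(H[3, 4], 0.5)
  # too-tight truncation is detected via the leaked mass
  expect_error(cme_log_transition(bd, c(A = 0), c(A = 2), 50,
                                  list(A = c(0, 3))),
               "truncation")
})

test_that("custom-hazard scores agree with mass action on the same path", {
  bd <- birth_death_network(0.03, 0.6)
  mm <- reaction_network("A", list(
    list(name = "R1", reactants = c(A = 1), products = c(), theta = 0.03,
         rate_law = "custom",
         hazard = function(x, theta) theta * x[["A"]],
         dhazard = function(x, theta) x[["A"]]),
    list(name = "R2", reactants = c(), products = c(A = 1), theta = 0.6)))
  p <- reaction_path(c(A = 5), c(0.4, 1.2), c(1L, 2L), 0, 2)
  expect_equal(path_score(mm, p), path_score(bd, p))
  # finite-difference fallback when no analytic derivative is supplied
  mm2 <- reaction_network("A", list(
    list(name = "R1", reactants = c(A = 1), products = c(), theta = 0.03,
         rate_law = "custom",
         hazard = function(x, theta) theta * x[["A"]]),
    list(name = "R2", reactants = c(), products = c(A = 1), theta = 0.6)))
  expect_equal(path_score(mm2, p), path_score(bd, p), tolerance = 1e-6)
})
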