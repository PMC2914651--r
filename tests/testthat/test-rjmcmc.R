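test_that("the path likelihood matches hand calculations and flags invalid paths", {
  bd <- birth_death_network(0.03, 0.6)
  # empty path: only the survival term -(h1 + h2) * tau
  expect_equal(path_log_likelihood(bd, empty_path(c(A = 5), 0, 2)),
               -(0.15 + 0.6) * 2)
  # firing a death from an empty state is impossible
  bad <- reaction_path(c(A = 0), 1, 1L, 0, 2)
  expect_identical(path_log_likelihood(bd, bad), -Inf)
  # one birth at t = 1 from A = 5
  p <- reaction_path(c(A = 5), 1, 2L, 0, 2)
  expect_equal(path_log_likelihood(bd, p),
               log(0.6) - (0.15 + 0.6) * 1 - (0.18 + 0.6) * 1)
  # the R reference path evaluator agrees with the compiled one
  mm <- reaction_network("A", list(
    list(name = "R1", reactants = c(A = 1), products = c(), theta = 0.03,
         rate_law = "custom",
         hazard = function(x, theta) theta * x[["A"]]),
    list(name = "R2", reactants = c(), products = c(A = 1), theta = 0.6)))
  expect_equal(path_log_likelihood(mm, p), path_log_likelihood(bd, p))
})

test_that("summed path densities reproduce the CME transition probability", {
  # integrate exp(log pi) over all paths with J <= 3 events by quadrature
  # and compare with the matrix-exponential transition probability
  bd <- birth_death_network(0.05, 0.3)
  x0 <- 2L
  tau <- 1
  ngrid <- 32
  tgrid <- (seq_len(ngrid) - 0.5) / ngrid * tau
  probs <- new.env()
  tally <- function(xe, p) {
    key <- as.character(xe)
    assign(key, p + (if (exists(key, probs)) get(key, probs) else 0), probs)
  }
  tally(x0, exp(path_log_likelihood(bd, empty_path(c(A = x0), 0, tau))))
  for (J in 1:3) {
    typeseqs <- as.matrix(do.call(expand.grid, rep(list(1:2), J)))
    combs <- as.matrix(do.call(expand.grid, rep(list(tgrid), J)))
    combs <- combs[apply(combs, 1, function(v)
      !is.unsorted(v, strictly = TRUE)), , drop = FALSE]
    for (si in seq_len(nrow(typeseqs))) {
      types <- as.integer(typeseqs[si, ])
      dens <- apply(combs, 1, function(tv) {
        ll <- path_log_likelihood(bd, reaction_path(c(A = x0), tv, types,
                                                    0, tau))
        if (is.finite(ll)) exp(ll) else 0
      })
      # simplex volume element: (tau/ngrid)^J per ordered grid cell
      tally(x0 + sum(ifelse(types == 1L, -1L, 1L)),
            sum(dens) * (tau / ngrid)^J)
    }
  }
  for (xe in 0:4) {
    exact <- exp(cme_log_transition(bd, c(A = x0), c(A = xe), tau,
                                    list(A = c(0, 30))))
    got <- if (exists(as.character(xe), probs)) get(as.character(xe), probs)
           else 0
    # J <= 3 truncation and the time grid limit the attainable accuracy
    expect_lt(abs(got - exact), 0.01)
  }
})

test_that("acceptance corrections satisfy detailed balance on fixed pairs", {
  # forward add and reverse delete corrections must cancel exactly,
  # including modes with repeated reactions (q_j = 2)
  cases <- list(
    list(counts = c(0L, 0L), q = c(1L, 1L), tau = 2),
    list(counts = c(3L, 5L), q = c(1L, 1L), tau = 0.7),
    list(counts = c(2L, 0L, 1L, 4L, 0L, 0L, 3L, 1L),
         q = c(1L, 0L, 0L, 0L, 1L, 0L, 2L, 0L), tau = 0.5),
    list(counts = c(1L, 1L), q = c(2L, 2L), tau = 3)
  )
  for (cs in cases) {
    fwd <- move_log_correction("add", cs$counts, cs$q, cs$tau)
    rev <- move_log_correction("delete", cs$counts + cs$q, cs$q, cs$tau)
    expect_equal(fwd + rev, 0)
  }
  # full acceptance ratios: log AR(forward) + log AR(reverse) = 0
  bd <- birth_death_network()
  ns <- null_set(bd)
  cur <- reaction_path(c(A = 3), c(0.4, 1.1), c(1L, 2L), 0, 2)
  set.seed(1)
  prop <- propose_move(bd, cur, ns, move = "add", mode = 1)
  ar_f <- log_acceptance_ratio(bd, cur, prop)
  back <- list(path = cur, move = "delete", mode = 1, feasible = TRUE,
               log_proposal_ratio = move_log_correction(
                 "delete", tabulate(prop$path$types, 2), ns$modes[1, ], 2))
  ar_b <- log_acceptance_ratio(bd, prop$path, back)
  expect_equal(ar_f + ar_b, 0)
})

test_that("degenerate and infeasible proposals have the right acceptance", {
  bd <- birth_death_network()
  ns <- null_set(bd)
  # deleting a mode from an empty path is infeasible
  p0 <- empty_path(c(A = 3), 0, 2)
  pr <- propose_move(bd, p0, ns, move = "delete", mode = 1)
  expect_false(pr$feasible)
  expect_identical(log_acceptance_ratio(bd, p0, pr), -Inf)
  # a shuffle that reproduces the same path is always accepted
  ident <- list(path = p0, move = "shuffle", mode = 1, feasible = TRUE,
                log_proposal_ratio = 0)
  expect_equal(log_acceptance_ratio(bd, p0, ident), 0)
  # moves preserve type counts as required
  cur <- reaction_path(c(A = 3), c(0.2, 0.9, 1.5), c(2L, 1L, 2L), 0, 2)
  set.seed(3)
  sh <- propose_move(bd, cur, ns, move = "shuffle")
  expect_equal(tabulate(sh$path$types, 2), tabulate(cur$types, 2))
  ad <- propose_move(bd, cur, ns, move = "add", mode = 1)
  expect_equal(tabulate(ad$path$types, 2), tabulate(cur$types, 2) + c(1L, 1L))
})

test_that("endpoint-conditioned reaction counts match the rejection oracle", {
  bd <- birth_death_network(0.03, 0.6)
  obs <- tibble::tibble(time = c(0, 2), A = c(20L, 22L))
  set.seed(11)
  s <- sample_paths(bd, obs, mcmc_control(n_samples = 10000, burn_in = 500))
  rej <- rejection_sampler_counts(bd, c(A = 20), c(A = 22), 2, 10000)
  expect_gte(length(rej), 5000)
  expect_lt(tv_counts(s$J, rej), 0.05)
})

test_that("hidden-state marginals match the exact CME smoother", {
  toy <- toy_hidden_network()
  obs <- tibble::tibble(time = c(0, 1.5, 3), A = c(1L, 2L, 1L))
  set.seed(4)
  s <- sample_paths(toy, obs, mcmc_control(n_samples = 30000, burn_in = 2000,
                                           thin = 4, record_states = TRUE))
  sm <- cme_smoother(toy, obs, list(A = c(0, 14), B = c(0, 15)))
  for (ti in 1:3) {
    bs <- s$state_samples[, (ti - 1) * 2 + 2] # B column at time ti
    emp <- tabulate(bs + 1L, 16) / length(bs)
    ex <- sapply(0:15, function(b) sum(sm[[ti]]$prob[sm[[ti]]$B == b]))
    expect_lt(sum(abs(emp - ex)) / 2, 0.05)
  }
})

test_that("complementary moves keep later states consistent (replay check)", {
  ar <- autoregulatory_network()
  obs_sp <- c("mRNA", "P", "P2")
  b <- generate_benchmark("autoreg", m = 10, dt = 0.5, seed = 21,
                          observed = obs_sp)
  set.seed(22)
  s <- sample_paths(ar, b$observations,
                    mcmc_control(n_samples = 200, burn_in = 100,
                                 record_states = TRUE))
  # final latent state: replaying every interval path from its start state
  # must land exactly on the next state, match observations on the observed
  # species, and keep the conserved total everywhere
  states <- s$final$states
  expect_true(all(states[, "DNA"] + states[, "DNA.P2"] == 10))
  obs <- as.matrix(b$observations[, obs_sp])
  expect_equal(states[, obs_sp], obs, ignore_attr = TRUE)
  for (i in seq_len(nrow(states) - 1)) {
    p <- s$final$paths[[i]]
    pp <- reaction_path(states[i, ], p$times, p$types,
                        b$observations$time[i], b$observations$time[i + 1])
    expect_true(is.finite(path_log_likelihood(ar, pp)))
    final <- states[i, ] + colSums(ar$A[p$types, , drop = FALSE])
    expect_equal(unname(final), unname(states[i + 1, ]))
  }
})

test_that("sampled total reaction counts mix and are diagnosable", {
  bd <- birth_death_network(0.03, 0.6)
  b <- generate_benchmark("birth_death", m = 11, dt = 2, seed = 13)
  set.seed(14)
  s <- sample_paths(bd, b$observations, mcmc_control(2000, 200))
  expect_equal(dim(s$n), c(2000L, 2L))
  expect_true(all(s$J == rowSums(s$n)))
  expect_true(all(s$J_interval >= 0))
  expect_equal(rowSums(s$J_interval), s$J, ignore_attr = TRUE)
  # autocorrelation decays: ESS is well above 1 and the lag-20
  # autocorrelation is below the lag-1 value
  a <- stats::acf(s$J, lag.max = 20, plot = FALSE)$acf
  expect_gt(a[2], a[21])
  expect_gt(ess(s$J), 30)
  p <- autoplot(s)
  expect_s3_class(p, "ggplot")
})
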