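test_that("inference is reproducible and keeps parameters positive", {
  b <- generate_benchmark("birth_death", m = 11, dt = 2, seed = 3)
  cfg <- mcmc_control(n_samples = 200, burn_in = 50)
  f1 <- infer_parameters(b$network, b$observations, seed = 9, mcmc = cfg,
                         sgd = sgd_control(max_iters = 30))
  f2 <- infer_parameters(b$network, b$observations, seed = 9, mcmc = cfg,
                         sgd = sgd_control(max_iters = 30))
  expect_identical(f1$trace, f2$trace)
  expect_identical(f1$theta_hat, f2$theta_hat)
  expect_true(all(f1$trace$theta > 0))
  expect_true(all(f1$theta_hat > 0))
})

test_that("a run that hits the iteration cap is flagged, not fatal", {
  b <- generate_benchmark("birth_death", m = 11, dt = 2, seed = 3)
  f <- infer_parameters(b$network, b$observations, seed = 10,
                        mcmc = mcmc_control(n_samples = 100, burn_in = 20),
                        sgd = sgd_control(max_iters = 3))
  expect_false(f$converged)
  expect_equal(f$iterations, 3L)
  expect_s3_class(glance(f), "tbl_df")
  expect_false(glance(f)$converged)
})

test_that("birth-death rates are recovered across replicate datasets", {
  # ten replicates of the m = 51, dt = 2 design; median relative error of
  # each recovered rate stays well inside the scatter of such designs
  truth <- c(0.03, 0.6)
  est <- matrix(0, 10, 2)
  for (i in 1:10) {
    b <- generate_benchmark("birth_death", theta = truth, m = 51, dt = 2,
                            seed = 300 + i)
    fit <- infer_parameters(b$network, b$observations, seed = 400 + i)
    est[i, ] <- fit$theta_hat
  }
  relerr <- abs(sweep(est, 2, truth, `/`) - 1)
  expect_lt(median(relerr[, 1]), 0.3)
  expect_lt(median(relerr[, 2]), 0.3)
})

test_that("tidy, glance and autoplot expose the fit", {
  b <- generate_benchmark("birth_death", m = 11, dt = 2, seed = 3)
  f <- infer_parameters(b$network, b$observations, seed = 12,
                        mcmc = mcmc_control(n_samples = 200, burn_in = 50))
  td <- tidy(f)
  expect_named(td, c("term", "estimate", "gradient", "std_error"))
  expect_equal(td$term, c("R1", "R2"))
  expect_s3_class(autoplot(f), "ggplot")
  expect_equal(nrow(f$trace), 2 * f$iterations)
})

test_that("random initialization is available and reproducible", {
  b <- generate_benchmark("birth_death", m = 11, dt = 2, seed = 3)
  f <- infer_parameters(b$network, b$observations, theta0 = "random",
                        seed = 77,
                        mcmc = mcmc_control(n_samples = 100, burn_in = 20),
                        sgd = sgd_control(max_iters = 2))
  th0 <- f$trace$theta[f$trace$iteration == 1]
  expect_true(all(th0 >= 0.1 & th0 <= 10))
  f2 <- infer_parameters(b$network, b$observations, theta0 = "random",
                         seed = 77,
                         mcmc = mcmc_control(n_samples = 100, burn_in = 20),
                         sgd = sgd_control(max_iters = 2))
  expect_identical(f$trace$theta, f2$trace$theta)
})
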