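#' Stochastic gradient ascent settings
#'
#' Each iteration takes the preconditioned ascent step
#' `theta <- theta + eta_r * gradient_r` with the per-parameter step size
#' `eta_r = eta * mult_r * theta_r^2 / E[n_r]`, i.e. the gradient is scaled
#' by the inverse complete-data observed information (for mass action
#' `-d2/dtheta2 log pi = n_r / theta_r^2`). With `eta * mult_r = 1` this is
#' the Monte-Carlo EM update `theta_r <- E[n_r] / E[G_r]`; the
#' preconditioning matters because the raw score has wildly different
#' scales across parameters and regions, while the preconditioned step is a
#' precisely estimated ratio even where the likelihood surface is a shallow
#' ridge. Sufficient statistics are smoothed across iterations by an
#' exponential average (weight `beta` on the newest, bias-corrected) to
#' beat down sampling noise. The multiplier `mult_r` adapts within
#' `eta_bounds`: it grows by `grow` after two consecutive same-sign steps
#' (a consistent drift direction, as along a ridge, is worth accelerating)
#' and shrinks by `shrink` when the step direction flips (the iterate has
#' reached the optimum and only noise remains); proposals beyond
#' `max_rel_step` relative change are clipped. Convergence is declared when
#' the largest relative parameter change stays below `rel_tol` for
#' `consec` consecutive iterations, guarding against single lucky draws of
#' the Monte-Carlo noise.
#'
#' @param eta base scale of the preconditioned step (1 = the EM/Newton
#'   step).
#' @param eta_bounds multiplicative adaptation range of the per-parameter
#'   multiplier.
#' @param beta weight of the newest iteration in the exponential average of
#'   the sufficient statistics.
#' @param rel_tol convergence threshold on the relative parameter change.
#' @param consec consecutive sub-threshold iterations required.
#' @param max_iters iteration cap (non-convergence is flagged, not fatal).
#' @param theta_floor positivity floor for the parameters.
#' @param max_rel_step overshoot guard: largest relative change per step.
#' @param grow,shrink multiplier adaptation factors.
#' @return a list of class `sgd_control`.
#' @export
sgd_control <- function(eta = 1, eta_bounds = c(0.05, 10), beta = 0.25,
                        rel_tol = 0.005, consec = 2L, max_iters = 200L,
                        theta_floor = 1e-6, max_rel_step = 0.5, grow = 1.5,
                        shrink = 0.5) {
  stopifnot(eta > 0, rel_tol > 0, rel_tol < 1, theta_floor > 0,
            eta_bounds[1] > 0, eta_bounds[2] >= eta_bounds[1],
            beta > 0, beta <= 1,
            max_rel_step > 0, max_rel_step < 1, grow >= 1, shrink <= 1,
            shrink > 0)
  structure(list(eta = eta, eta_bounds = eta_bounds, beta = beta,
                 rel_tol = rel_tol, consec = as.integer(consec),
                 max_iters = as.integer(max_iters),
                 theta_floor = theta_floor, max_rel_step = max_rel_step,
                 grow = grow, shrink = shrink),
            class = "sgd_control")
}

#' Maximum-likelihood rate-parameter inference by stochastic gradient ascent
#'
#' Iterates: (1) sample latent reaction paths conditioned on the
#' observations at the current parameters with [sample_paths()]; (2)
#' estimate the log-likelihood gradient from the sampled sufficient
#' statistics with [estimate_gradient()]; (3) take an adaptive
#' multiplicative ascent step (see [sgd_control()]). Chains warm-start from
#' the final latent state of the previous iteration (paths stay valid when
#' `theta` changes); burn-in is still applied each iteration.
#'
#' @param network a [reaction_network()] (its `theta` is ignored when
#'   `theta0` is given).
#' @param observations observation tibble (`time` + observed species).
#' @param theta0 initial parameter vector; `NULL` (the default) starts from
#'   the complete-data estimate `n_r / G_r` of the integer-programming
#'   initial path, which places the iterate at the scale the data supports
#'   (the likelihood surfaces of sparsely observed kinetic models carry
#'   long shallow ridges on which runs started at an arbitrary scale stall;
#'   see the package vignette); `"random"` draws i.i.d. uniform on
#'   `[0.1, 10]`.
#' @param sgd an [sgd_control()].
#' @param mcmc an [mcmc_control()] (samples per gradient and burn-in).
#' @param seed optional integer seed (fixed seed implies an identical
#'   trace).
#' @param verbose print per-iteration progress.
#' @return an object of class `sgd_fit` with elements `theta_hat`,
#'   `converged`, `iterations`, `trace` (long tibble: iteration, reaction,
#'   theta, gradient, std_error, step multiplier), `gradient` (final
#'   estimate tibble) and the final network. Methods: [tidy.sgd_fit()],
#'   [glance.sgd_fit()], [autoplot.sgd_fit()].
#' @examples
#' \donttest{
#' bench <- generate_benchmark("birth_death", m = 21, dt = 2, seed = 1)
#' fit <- infer_parameters(bench$network, bench$observations,
#'                         mcmc = mcmc_control(n_samples = 200, burn_in = 50),
#'                         seed = 1)
#' tidy(fit)
#' }
#' @export
infer_parameters <- function(network, observations, theta0 = NULL,
                             sgd = sgd_control(), mcmc = mcmc_control(),
                             seed = NULL, verbose = FALSE) {
  stopifnot(inherits(network, "reaction_network"))
  observations <- as_observation_set(observations, network)
  if (!is.null(seed)) set.seed(seed)
  M <- length(network$reactions)
  nullset <- null_set(network, observed = observed_species(observations))
  warm0 <- NULL
  if (is.null(theta0)) {
    # complete-data estimate of the minimal feasible imputation
    warm0 <- initial_latent(network, observations, nullset, mcmc)
    st0 <- latent_stats(network, warm0, observations$time)
    theta <- pmin(pmax((st0$n + 0.5) / pmax(st0$G, 1e-6), 1e-2), 1e2)
  } else if (identical(theta0, "random")) {
    theta <- runif(M, 0.1, 10)
  } else {
    stopifnot(length(theta0) == M, all(theta0 > 0))
    theta <- as.numeric(theta0)
  }

  mult <- rep(1, M)
  mass_action <- is_mass_action(network)
  last_sign <- integer(M)
  same_sign_run <- integer(M)
  warm <- warm0
  below <- 0L
  converged <- FALSE
  trace <- vector("list", sgd$max_iters)
  iter_used <- 0L
  theta_bar_raw <- numeric(M)
  theta_bar <- theta

  for (iter in seq_len(sgd$max_iters)) {
    iter_used <- iter
    net_i <- set_theta(network, theta)
    samples <- sample_paths(net_i, observations, config = mcmc, init = warm,
                            nullset = nullset)
    warm <- samples$final
    grad <- estimate_gradient(samples)
    g <- grad$estimate
    if (any(!is.finite(g)))
      stop("non-finite gradient estimate at iteration ", iter, call. = FALSE)

    if (mass_action) {
      # preconditioned (inverse complete-data information) score:
      # theta^2/n * (n/theta - G), expressed as a relative change of theta;
      # with eta * mult = 1 this is the Monte-Carlo EM step theta <- n/G
      n_now <- colMeans(samples$n)
      G_now <- colMeans(samples$G)
      proposed <- sgd$eta * mult * (n_now - theta * G_now) / pmax(n_now, 1)
    } else {
      proposed <- sgd$eta * mult * theta * g
    }
    applied <- pmin(pmax(proposed, -sgd$max_rel_step), sgd$max_rel_step)
    theta_new <- pmax(theta * (1 + applied), sgd$theta_floor)

    sgn <- sign(proposed)
    flipped <- sgn != 0 & last_sign != 0 & sgn != last_sign
    same_sign_run <- ifelse(sgn != 0 & sgn == last_sign,
                            same_sign_run + 1L, 0L)
    mult[flipped] <- mult[flipped] * sgd$shrink
    growi <- !flipped & same_sign_run >= 2L
    mult[growi] <- mult[growi] * sgd$grow
    mult <- pmin(pmax(mult, sgd$eta_bounds[1]), sgd$eta_bounds[2])
    last_sign <- sgn

    # convergence is monitored (and the estimate reported) on the
    # exponentially averaged iterate, whose increments damp the
    # Monte-Carlo jitter of the raw iterate
    theta_bar_raw <- (1 - sgd$beta) * theta_bar_raw + sgd$beta * theta_new
    theta_bar_new <- theta_bar_raw / (1 - (1 - sgd$beta)^iter)
    rel_change <- max(abs(theta_bar_new - theta_bar) / theta_bar)
    trace[[iter]] <- tibble(iteration = iter, reaction = network$reactions,
                            theta = theta, theta_bar = theta_bar_new,
                            gradient = g, std_error = grad$std_error,
                            multiplier = mult, rel_change = rel_change)
    if (verbose)
      message(sprintf("iter %3d  max rel change %.4f  theta: %s", iter,
                      rel_change,
                      paste(signif(theta_bar_new, 3), collapse = " ")))
    theta <- theta_new
    theta_bar <- theta_bar_new
    below <- if (rel_change < sgd$rel_tol) below + 1L else 0L
    if (below >= sgd$consec) { converged <- TRUE; break }
  }

  theta <- theta_bar
  grad_final <- estimate_gradient(samples, theta = theta)
  structure(list(theta_hat = setNames(theta, network$reactions),
                 converged = converged, iterations = iter_used,
                 trace = dplyr::bind_rows(trace[seq_len(iter_used)]),
                 gradient = grad_final, accept = samples$accept,
                 network = set_theta(network, theta),
                 observed = observed_species(observations),
                 sgd = sgd, mcmc = mcmc, seed = seed),
            class = "sgd_fit")
}

#' @export
print.sgd_fit <- function(x, ...) {
  cat(sprintf("<sgd_fit> %s after %d gradient evaluation(s)\n",
              if (x$converged) "converged" else "NOT converged",
              x$iterations))
  est <- tidy(x)
  cat(sprintf("  %s = %.4g (grad %.3g +/- %.3g)\n", est$term, est$estimate,
              est$gradient, est$std_error), sep = "")
  invisible(x)
}

#' Tidy method for SGD fits
#'
#' @param x an `sgd_fit`.
#' @param ... unused.
#' @return tibble with one row per rate parameter: `term`, `estimate`, and
#'   the final gradient estimate with its Monte-Carlo `std_error`.
#' @export
tidy.sgd_fit <- function(x, ...) {
  tibble(term = names(x$theta_hat), estimate = unname(x$theta_hat),
         gradient = x$gradient$estimate, std_error = x$gradient$std_error)
}

#' Glance method for SGD fits
#'
#' @param x an `sgd_fit`.
#' @param ... unused.
#' @return one-row tibble: iterations, convergence flag, sampler settings.
#' @export
glance.sgd_fit <- function(x, ...) {
  tibble(iterations = x$iterations, converged = x$converged,
         n_samples = x$mcmc$n_samples, burn_in = x$mcmc$burn_in,
         rel_tol = x$sgd$rel_tol)
}

#' Parameter-trace plot of an SGD run
#'
#' @param object an `sgd_fit`.
#' @param ... unused.
#' @return a ggplot: per-parameter trajectories over iterations (log scale).
#' @export
autoplot.sgd_fit <- function(object, ...) {
  ggplot2::ggplot(object$trace,
                  ggplot2::aes(x = .data$iteration, y = .data$theta,
                               colour = .data$reaction)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "gradient evaluation", y = expression(theta),
                  colour = "reaction") +
    ggplot2::theme_minimal()
}

#' Trace and autocorrelation plot of a path sampler run
#'
#' Total number of reactions per sample (mixing diagnostic) and its
#' autocorrelation.
#'
#' @param object a `path_samples` object.
#' @param lag_max largest autocorrelation lag shown.
#' @param ... unused.
#' @return a ggplot with two panels.
#' @export
autoplot.path_samples <- function(object, lag_max = 50, ...) {
  J <- object$J
  a <- acf(J, lag.max = min(lag_max, length(J) - 1), plot = FALSE)
  df <- dplyr::bind_rows(
    tibble(panel = "total reactions", x = seq_along(J), y = as.numeric(J)),
    tibble(panel = "autocorrelation", x = drop(a$lag), y = drop(a$acf)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~panel, scales = "free", ncol = 1) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
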