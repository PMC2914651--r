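#' Monte-Carlo estimate of the log-likelihood gradient
#'
#' The gradient of the observed-data log-likelihood with respect to the rate
#' parameters equals the conditional expectation of the complete-data score
#' given the observations. For mass-action rate laws the score of a latent
#' path is `n_r / theta_r - G_r` in the sufficient statistics of
#' [sufficient_stats()], so the gradient is estimated by averaging scores
#' over the sampled paths, with a Monte-Carlo standard error per component.
#'
#' @param samples a `path_samples` object from [sample_paths()].
#' @param theta parameter values at which to evaluate the score (default:
#'   the value the paths were sampled at, i.e. the network's `theta`).
#' @param ess_correct inflate standard errors by the autocorrelation of the
#'   score chain (effective-sample-size correction).
#' @return a tibble with columns `reaction`, `estimate`, `std_error`.
#' @export
estimate_gradient <- function(samples, theta = NULL, ess_correct = FALSE) {
  stopifnot(inherits(samples, "path_samples"))
  network <- samples$network
  if (is.null(theta)) theta <- unname(network$theta)
  if (!is.null(samples$scores) && length(samples$scores)) {
    sc <- samples$scores
  } else {
    sc <- sweep(samples$n, 2, theta, `/`) - samples$G
  }
  S <- nrow(sc)
  est <- colMeans(sc)
  se <- apply(sc, 2, sd) / sqrt(S)
  if (ess_correct && S > 2)
    se <- se * sqrt(S / apply(sc, 2, ess))
  tibble(reaction = network$reactions, estimate = unname(est),
         std_error = unname(se))
}

#' Endpoint-conditioned rejection sampler (validation oracle)
#'
#' Draws unconstrained SSA realizations over one interval and keeps those
#' whose final state matches `x_end` exactly; the accepted runs are exact
#' draws from the endpoint-conditioned path law. Exponentially inefficient
#' in the state dimension, so validation-only: the distribution of total
#' reaction counts is the reference the reversible-jump sampler is checked
#' against.
#'
#' @param network a mass-action [reaction_network()].
#' @param x_start,x_end full endpoint states.
#' @param tau interval length.
#' @param n number of accepted samples requested.
#' @param max_tries cap on attempted simulations.
#' @return integer vector of total reaction counts of the accepted runs
#'   (may be shorter than `n` if `max_tries` is exhausted).
#' @export
rejection_sampler_counts <- function(network, x_start, x_end, tau, n,
                                     max_tries = 500 * n) {
  if (!is_mass_action(network))
    stop("the rejection oracle supports mass-action rate laws only",
         call. = FALSE)
  out <- rejection_counts_cpp(check_state(network, x_start),
                              check_state(network, x_end), network$U,
                              network$A, unname(network$theta),
                              convention_code(network), tau, as.integer(n),
                              as.integer(max_tries))
  as.integer(out$counts)
}

# ---------------------------------------------------------------------------
# Truncated chemical-master-equation oracle (validation-scale): transition
# probabilities by matrix exponential of the truncated generator, gradients
# by central finite differences.
# ---------------------------------------------------------------------------

#' Enumerate a truncated state space
#'
#' @param network a [reaction_network()].
#' @param bounds named list (or 2 x K matrix) of per-species `c(lower,
#'   upper)` count bounds.
#' @return list with `states` (N x K integer matrix) and `index(x)` lookup.
#' @keywords internal
cme_state_space <- function(network, bounds) {
  K <- length(network$species)
  lo <- hi <- integer(K)
  for (a in seq_len(K)) {
    b <- bounds[[network$species[a]]]
    if (is.null(b)) stop("bounds missing species ", network$species[a],
                         call. = FALSE)
    lo[a] <- b[1]
    hi[a] <- b[2]
  }
  grids <- lapply(seq_len(K), function(a) lo[a]:hi[a])
  states <- as.matrix(expand.grid(grids))
  colnames(states) <- network$species
  dims <- hi - lo + 1L
  mult <- cumprod(c(1L, dims[-K]))
  index <- function(x) {
    # row index of a state; NA outside the box
    if (any(x < lo) || any(x > hi)) return(NA_integer_)
    as.integer(1L + sum((x - lo) * mult))
  }
  list(states = states, index = index, lo = lo, hi = hi)
}

#' Truncated CME generator
#'
#' Builds the (sparse) generator of the Markov jump process on the truncated
#' box: off-diagonal rate `h_r(x)` from `x` to `x + A_r`, diagonal
#' `-h0(x)` (the full exit rate, so transitions leaving the box leak
#' probability mass; rows away from the boundary sum to zero).
#'
#' @inheritParams cme_state_space
#' @return a sparse `dgCMatrix` generator.
#' @export
cme_generator <- function(network, bounds) {
  ss <- cme_state_space(network, bounds)
  N <- nrow(ss$states)
  M <- length(network$reactions)
  ii <- jj <- integer(0)
  vv <- numeric(0)
  diag_out <- numeric(N)
  for (s in seq_len(N)) {
    x <- ss$states[s, ]
    h <- hazards(network, x)
    diag_out[s] <- -sum(h)
    for (r in seq_len(M)) {
      if (h[r] <= 0) next
      tgt <- ss$index(x + network$A[r, ])
      if (is.na(tgt)) next
      ii <- c(ii, s)
      jj <- c(jj, tgt)
      vv <- c(vv, h[r])
    }
  }
  H <- Matrix::sparseMatrix(i = c(ii, seq_len(N)), j = c(jj, seq_len(N)),
                            x = c(vv, diag_out), dims = c(N, N))
  attr(H, "state_space") <- ss
  H
}

#' Exact (truncated-CME) log transition probability
#'
#' Computes `log P(X(t0 + tau) = x_end | X(t0) = x_start)` by matrix
#' exponential of the truncated generator. The probability mass leaking
#' through the truncation boundary from the start state is checked against
#' `mass_tol`. Validation-scale: state spaces of at most a few thousand
#' states.
#'
#' @param network a [reaction_network()].
#' @param x_start,x_end full states.
#' @param tau interval length.
#' @param bounds per-species truncation bounds (see [cme_generator()]).
#' @param mass_tol maximum tolerated leaked mass.
#' @return log transition probability.
#' @export
cme_log_transition <- function(network, x_start, x_end, tau, bounds,
                               mass_tol = 1e-8) {
  H <- cme_generator(network, bounds)
  ss <- attr(H, "state_space")
  i0 <- ss$index(state_vector(network, x_start))
  i1 <- ss$index(state_vector(network, x_end))
  if (is.na(i0) || is.na(i1))
    stop("start or end state outside the truncation bounds", call. = FALSE)
  P <- as.matrix(Matrix::expm(H * tau))
  leaked <- 1 - sum(P[i0, ])
  if (leaked > mass_tol)
    stop(sprintf(
      "truncation bounds too tight: %.3g probability mass leaked", leaked),
      call. = FALSE)
  log(P[i0, i1])
}

#' Finite-difference gradient of the exact log transition probability
#'
#' Central differences of [cme_log_transition()] in each rate parameter;
#' the independent oracle for [estimate_gradient()] on small systems.
#'
#' @inheritParams cme_log_transition
#' @param rel_step relative step of the central difference.
#' @return list with `loglik` and `gradient` (length `M`).
#' @export
cme_log_transition_grad <- function(network, x_start, x_end, tau, bounds,
                                    rel_step = 1e-4, mass_tol = 1e-8) {
  M <- length(network$reactions)
  th <- unname(network$theta)
  g <- numeric(M)
  for (r in seq_len(M)) {
    h <- rel_step * th[r]
    up <- set_theta(network, replace(th, r, th[r] + h))
    dn <- set_theta(network, replace(th, r, th[r] - h))
    g[r] <- (cme_log_transition(up, x_start, x_end, tau, bounds, mass_tol) -
               cme_log_transition(dn, x_start, x_end, tau, bounds,
                                  mass_tol)) / (2 * h)
  }
  list(loglik = cme_log_transition(network, x_start, x_end, tau, bounds,
                                   mass_tol),
       gradient = setNames(g, network$reactions))
}

#' Exact smoothing distribution over hidden states (truncated CME)
#'
#' Forward-backward recursion over the truncated state space: the forward
#' message is propagated with the matrix exponential of the generator and
#' masked by the indicator of each observation (agreement on the observed
#' species and any conserved totals); the backward message likewise. The
#' smoothed marginal at each observation time is their normalized product.
#' Validation oracle for the partially observed sampler on toy systems.
#'
#' @param network a [reaction_network()].
#' @param observations observation tibble with a strict subset of species.
#' @param bounds truncation bounds.
#' @return list of tibbles, one per observation time, with the full states
#'   and their smoothed probabilities (zero-probability states dropped).
#' @export
cme_smoother <- function(network, observations, bounds) {
  observations <- as_observation_set(observations, network)
  obs_sp <- observed_species(observations)
  obs <- obs_matrix(observations)[, obs_sp, drop = FALSE]
  times <- observations$time
  m <- length(times)
  H <- cme_generator(network, bounds)
  ss <- attr(H, "state_space")
  N <- nrow(ss$states)

  mask <- function(i) {
    ok <- rep(TRUE, N)
    for (s in seq_along(obs_sp))
      ok <- ok & ss$states[, obs_sp[s]] == obs[i, s]
    for (cv in network$conserved %||% list())
      ok <- ok & rowSums(ss$states[, cv$species, drop = FALSE]) == cv$total
    as.numeric(ok)
  }

  Ps <- lapply(seq_len(m - 1), function(i)
    as.matrix(Matrix::expm(H * (times[i + 1] - times[i]))))

  fwd <- matrix(0, m, N)
  fwd[1, ] <- mask(1) # flat prior over states consistent with the first obs
  fwd[1, ] <- fwd[1, ] / sum(fwd[1, ])
  for (i in seq_len(m - 1)) {
    v <- drop(fwd[i, ] %*% Ps[[i]]) * mask(i + 1)
    fwd[i + 1, ] <- v / sum(v)
  }
  bwd <- matrix(0, m, N)
  bwd[m, ] <- 1
  for (i in rev(seq_len(m - 1))) {
    v <- drop(Ps[[i]] %*% (bwd[i + 1, ] * mask(i + 1)))
    bwd[i, ] <- v / max(v)
  }
  lapply(seq_len(m), function(i) {
    p <- fwd[i, ] * bwd[i, ]
    p <- p / sum(p)
    keep <- p > 0
    dplyr::bind_cols(as_tibble(as.data.frame(ss$states[keep, , drop = FALSE])),
                     tibble(prob = p[keep]))
  })
}
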