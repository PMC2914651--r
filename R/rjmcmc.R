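#' MCMC sampler settings
#'
#' @param n_samples post-burn-in samples to record.
#' @param burn_in discarded initial iterations.
#' @param alpha1,alpha2 probabilities of the add and delete moves; the time
#'   shuffle gets the remainder `1 - alpha1 - alpha2`.
#' @param thin keep every `thin`-th post-burn-in iteration.
#' @param record_intervals record per-interval reaction totals (diagnostics).
#' @param record_states record the imputed full states at the observation
#'   times (partially observed sampler only).
#' @param init_cap upper bound of the uniform draw used to initialize hidden
#'   species that are not pinned down by a conserved total.
#' @return a list of class `mcmc_control`.
#' @export
mcmc_control <- function(n_samples = 1000L, burn_in = 100L, alpha1 = 0.25,
                         alpha2 = 0.25, thin = 1L, record_intervals = TRUE,
                         record_states = FALSE, init_cap = 10L) {
  stopifnot(alpha1 > 0, alpha2 > 0, alpha1 + alpha2 < 1, n_samples >= 1,
            burn_in >= 0, thin >= 1)
  structure(list(n_samples = as.integer(n_samples),
                 burn_in = as.integer(burn_in), alpha1 = alpha1,
                 alpha2 = alpha2, thin = as.integer(thin),
                 record_intervals = record_intervals,
                 record_states = record_states,
                 init_cap = as.integer(init_cap)),
            class = "mcmc_control")
}

#' Complete-data log-likelihood of a reaction path
#'
#' For a path with events `(r_j, t_j)`, `j = 1..J`, on `[t0, t1]`:
#' `log pi(path | theta) = sum_j log h_{r_j}(X^{(j-1)}) -
#'  sum_{j=0}^{J} h0(X^{(j)}) (t_{j+1} - t_j)` with `h0` the total hazard,
#' `t_{J+1} = t1`. Returns `-Inf` for an invalid path (a fired reaction with
#' zero hazard, equivalently insufficient reactants, at its firing state).
#'
#' @param network a [reaction_network()].
#' @param path a `reaction_path`.
#' @param theta optional parameter vector overriding the network's.
#' @return a finite log-likelihood, or `-Inf`.
#' @export
path_log_likelihood <- function(network, path, theta = NULL) {
  if (!is.null(theta)) network <- set_theta(network, theta)
  x0 <- check_state(network, path$x0)
  if (is_mass_action(network)) {
    ev <- eval_path_cpp(path$times, path$types, x0, path$t0, path$t1,
                        network$U, network$A, unname(network$theta),
                        convention_code(network))
    return(ev$loglik)
  }
  path_loglik_r(network, path, x0)
}

path_loglik_r <- function(network, path, x0) {
  x <- x0
  ll <- 0
  tprev <- path$t0
  J <- length(path$types)
  for (j in seq_len(J + 1)) {
    tnext <- if (j <= J) path$times[j] else path$t1
    h <- hazards(network, x)
    ll <- ll - sum(h) * (tnext - tprev)
    if (j <= J) {
      r <- path$types[j]
      if (h[r] <= 0) return(-Inf)
      ll <- ll + log(unname(h[r]))
      x <- x + network$A[r, ]
      if (any(x < 0)) return(-Inf)
      tprev <- tnext
    }
  }
  ll
}

#' Per-reaction sufficient statistics of a path
#'
#' Under mass action the complete-data likelihood depends on a path only
#' through the per-reaction event counts `n_r` and the integrated (theta-free)
#' propensities `G_r = int h_r(X(t)) / theta_r dt`; their conditional
#' expectations determine the likelihood gradient. Statistics are additive
#' over intervals, so a list of paths is summed.
#'
#' @param network a mass-action [reaction_network()].
#' @param path a `reaction_path` or a list of them.
#' @return a tibble with columns `reaction`, `n`, `G`.
#' @export
sufficient_stats <- function(network, path) {
  if (!is_mass_action(network))
    stop("sufficient statistics in (n, G) form require mass-action rate laws",
         call. = FALSE)
  paths <- if (inherits(path, "reaction_path")) list(path) else path
  M <- length(network$reactions)
  n <- integer(M)
  G <- numeric(M)
  for (p in paths) {
    ev <- eval_path_cpp(p$times, p$types, check_state(network, p$x0), p$t0,
                        p$t1, network$U, network$A, unname(network$theta),
                        convention_code(network))
    if (!ev$valid) stop("invalid path: replay hits a zero-hazard firing",
                        call. = FALSE)
    n <- n + ev$n
    G <- G + ev$G
  }
  tibble(reaction = network$reactions, n = n, G = G)
}

#' Log proposal-density correction of a reversible-jump move
#'
#' The add move inserts one copy of elementary mode `q` (type counts
#' `q_j`, `Q = sum q_j`) at i.i.d. uniform times; the delete move removes a
#' uniformly chosen matching combination. Detailed balance gives
#' `log AR_add = dloglik + log(alpha2/alpha1) + Q log tau +
#'  sum_j log( c_j! / (c_j + q_j)! )` and the delete move the exact
#' reciprocal, with `c_j` the per-type event counts of the current path.
#' The time shuffle is symmetric (correction 0).
#'
#' @param move `"add"`, `"delete"` or `"shuffle"`.
#' @param counts current per-type event counts on the interval.
#' @param q elementary-mode type counts.
#' @param tau interval length.
#' @param alpha1,alpha2 move probabilities (set `include_alpha = FALSE` to
#'   drop the move-probability ratio, as for the deterministic complementary
#'   move of the partially observed sampler).
#' @param include_alpha include the `alpha` ratio term.
#' @return the log correction added to the log-likelihood ratio.
#' @export
move_log_correction <- function(move, counts, q, tau, alpha1 = 0.25,
                                alpha2 = 0.25, include_alpha = TRUE) {
  Q <- sum(q)
  if (move == "shuffle") return(0)
  if (move == "add") {
    corr <- Q * log(tau) + sum(lgamma(counts + 1) - lgamma(counts + q + 1))
    if (include_alpha) corr <- corr + log(alpha2 / alpha1)
  } else if (move == "delete") {
    if (any(counts < q)) return(-Inf)
    corr <- -Q * log(tau) + sum(lgamma(counts + 1) - lgamma(counts - q + 1))
    if (include_alpha) corr <- corr + log(alpha1 / alpha2)
  } else stop("unknown move: ", move, call. = FALSE)
  corr
}

#' Propose a reversible-jump move on one interval path
#'
#' Reference implementation of the three move types: (1) add one elementary
#' mode with uniform times, (2) delete a uniformly chosen matching
#' combination of events, (3) redraw all event times keeping the type order.
#'
#' @param network a [reaction_network()].
#' @param path current `reaction_path`.
#' @param nullset a [null_set()].
#' @param config an [mcmc_control()] (supplies the move probabilities).
#' @param move,mode optionally force the move type / mode index; drawn at
#'   random when `NULL`.
#' @return list with elements `path` (the proposal; `NULL` when infeasible),
#'   `move`, `mode`, `feasible`, and `log_proposal_ratio` (the correction
#'   term entering the acceptance ratio).
#' @export
propose_move <- function(network, path, nullset, config = mcmc_control(),
                         move = NULL, mode = NULL) {
  M <- length(network$reactions)
  if (is.null(mode)) mode <- sample.int(nrow(nullset$modes), 1)
  q <- nullset$modes[mode, ]
  if (is.null(move)) {
    u <- runif(1)
    move <- if (u < config$alpha1) "add"
    else if (u < config$alpha1 + config$alpha2) "delete" else "shuffle"
  }
  counts <- path_counts(path, M)
  tau <- path$t1 - path$t0
  corr <- move_log_correction(move, counts, q, tau, config$alpha1,
                              config$alpha2)
  if (move == "add") {
    newt <- c(path$times, runif(sum(q), path$t0, path$t1))
    newty <- c(path$types, rep.int(seq_len(M), q))
    o <- order(newt)
    prop <- reaction_path(path$x0, newt[o], newty[o], path$t0, path$t1)
  } else if (move == "delete") {
    if (any(counts < q))
      return(list(path = NULL, move = move, mode = mode, feasible = FALSE,
                  log_proposal_ratio = -Inf))
    drop_idx <- integer(0)
    for (j in which(q > 0)) {
      pos <- which(path$types == j)
      drop_idx <- c(drop_idx, pos[sample.int(length(pos), q[j])])
    }
    prop <- reaction_path(path$x0, path$times[-drop_idx],
                          path$types[-drop_idx], path$t0, path$t1)
  } else {
    newt <- sort(runif(length(path$times), path$t0, path$t1))
    prop <- reaction_path(path$x0, newt, path$types, path$t0, path$t1)
  }
  list(path = prop, move = move, mode = mode, feasible = TRUE,
       log_proposal_ratio = corr)
}

#' Log acceptance ratio of a proposed path
#'
#' `min(1, exp(log_acceptance_ratio(...)))` is the Metropolis-Hastings
#' acceptance probability. An infeasible or invalid proposal has ratio
#' `-Inf` and is always rejected; a degenerate proposal identical to the
#' current path has ratio 0.
#'
#' @param network a [reaction_network()].
#' @param current,proposal the current path and the proposal from
#'   [propose_move()] (the full list, carrying the proposal correction).
#' @return a log acceptance ratio in `[-Inf, Inf)`.
#' @export
log_acceptance_ratio <- function(network, current, proposal) {
  if (!isTRUE(proposal$feasible)) return(-Inf)
  ll_new <- path_log_likelihood(network, proposal$path)
  if (!is.finite(ll_new)) return(-Inf)
  ll_old <- path_log_likelihood(network, current)
  (ll_new - ll_old) + proposal$log_proposal_ratio
}

# ---------------------------------------------------------------------------
# sampler front-end
# ---------------------------------------------------------------------------

#' Sample latent reaction paths conditioned on observations
#'
#' Runs the reversible-jump sampler over the latent reaction paths between
#' consecutive observations. With all species observed, the paths of the
#' `m - 1` intervals are conditionally independent given their endpoint
#' states and are updated independently. With a strict subset observed, the
#' hidden coordinates of the states at the observation times are sampled
#' too: an add/delete move on interval `i` that changes the hidden state at
#' `t_{i+1}` is paired with the complementary move on interval `i + 1`,
#' which restores the state at `t_{i+2}`; an extra move updates the hidden
#' start state at `t_1`, and moves on the last interval update the hidden
#' state at `t_m` freely.
#'
#' @param network a [reaction_network()]; its `theta` is the parameter value
#'   the paths are conditioned on.
#' @param observations an observation tibble (`time` plus observed-species
#'   columns); the observed subset is inferred from the columns.
#' @param config an [mcmc_control()].
#' @param init optional warm start: the `final` element of a previous
#'   `path_samples` object for the same data.
#' @param nullset optionally precomputed [null_set()] for the observed
#'   subset.
#' @return an object of class `path_samples` with per-sample sufficient
#'   statistics (`n`, `G`: matrices of `n_samples` rows), per-sample total
#'   reaction counts `J` (and per-interval counts), acceptance diagnostics,
#'   and the final latent state for warm starts.
#' @export
sample_paths <- function(network, observations, config = mcmc_control(),
                         init = NULL, nullset = NULL) {
  stopifnot(inherits(network, "reaction_network"))
  observations <- as_observation_set(observations, network)
  obs_sp <- observed_species(observations)
  full <- setequal(obs_sp, network$species)
  if (!is_mass_action(network) && !full)
    stop("the partially observed sampler supports mass-action rate laws only",
         call. = FALSE)
  if (is.null(nullset)) nullset <- null_set(network, observed = obs_sp)
  times <- observations$time
  m <- length(times)
  if (m < 2) stop("need at least two observations", call. = FALSE)

  if (full) {
    states <- obs_matrix(observations)[, network$species, drop = FALSE]
    lat <- if (!is.null(init)) init else
      initial_latent(network, observations, nullset, config)
    if (is_mass_action(network)) {
      raw <- rjmcmc_full_cpp(lat$states, times, lat$paths, nullset$modes,
                             unname(network$theta), network$U, network$A,
                             convention_code(network), config$alpha1,
                             config$alpha2, config$n_samples, config$burn_in,
                             config$thin, config$record_intervals)
    } else {
      raw <- rjmcmc_full_r(network, lat$states, times, lat$paths, nullset,
                           config)
    }
  } else {
    lat <- if (!is.null(init)) init else
      initial_latent(network, observations, nullset, config)
    raw <- rjmcmc_partial_cpp(lat$states, times, lat$paths, nullset$modes,
                              unname(network$theta), network$U, network$A,
                              convention_code(network), config$alpha1,
                              config$alpha2, config$n_samples, config$burn_in,
                              config$thin, config$record_intervals,
                              config$record_states)
  }

  n <- raw$n
  G <- raw$G
  colnames(n) <- colnames(G) <- network$reactions
  if (!is.null(raw$states)) colnames(raw$states) <- network$species
  accept <- tibble(move = c("add", "delete", "shuffle"),
                   proposed = as.integer(raw$proposed),
                   accepted = as.integer(raw$accepted))
  structure(list(n = n, G = G, scores = raw$scores, J = as.integer(raw$J),
                 J_interval = raw$J_interval,
                 state_samples = raw$state_samples, accept = accept,
                 final = list(paths = raw$paths, states = raw$states),
                 network = network, observed = obs_sp, times = times,
                 config = config, fully_observed = full),
            class = "path_samples")
}

#' @export
print.path_samples <- function(x, ...) {
  cat(sprintf(
    "<path_samples> %d samples, %d intervals, %s observed\n",
    length(x$J), length(x$times) - 1,
    if (x$fully_observed) "fully" else "partially"))
  acc <- x$accept
  rate <- ifelse(acc$proposed > 0, acc$accepted / acc$proposed, NA)
  cat(sprintf("  acceptance: add %.2f, delete %.2f, shuffle %.2f\n",
              rate[1], rate[2], rate[3]))
  cat(sprintf("  total reactions per sample: mean %.1f, ESS %.0f\n",
              mean(x$J), ess(x$J)))
  invisible(x)
}

#' @export
tidy.path_samples <- function(x, ...) {
  tibble(sample = seq_along(x$J), total_reactions = x$J)
}

#' @export
glance.path_samples <- function(x, ...) {
  acc <- x$accept
  tibble(n_samples = length(x$J),
         accept_add = acc$accepted[1] / max(1L, acc$proposed[1]),
         accept_delete = acc$accepted[2] / max(1L, acc$proposed[2]),
         accept_shuffle = acc$accepted[3] / max(1L, acc$proposed[3]),
         mean_total_reactions = mean(x$J), ess_total_reactions = ess(x$J))
}

#' Effective sample size of a scalar chain
#'
#' Initial positive-sequence estimator based on the empirical
#' autocorrelation.
#'
#' @param x numeric chain.
#' @return effective sample size in `[1, length(x)]`.
#' @export
ess <- function(x) {
  n <- length(x)
  if (n < 3 || sd(x) == 0) return(n)
  rho <- drop(acf(x, lag.max = min(n - 1, 512), plot = FALSE,
                  demean = TRUE)$acf)[-1]
  s <- 0
  for (k in seq_along(rho)) {
    if (rho[k] <= 0) break
    s <- s + rho[k]
  }
  max(1, min(n, n / (1 + 2 * s)))
}

#' Construct the initial latent state for a dataset
#'
#' Builds, for every inter-observation interval, the minimal valid reaction
#' path from [find_reaction_counts()] and [initial_path()]; in the
#' partially observed case the hidden components of the states at the
#' observation times are drawn first (uniformly, respecting known conserved
#' totals) and propagated through the integer-programming solutions.
#'
#' @param network a [reaction_network()].
#' @param observations observation tibble.
#' @param nullset optional precomputed [null_set()] for the observed subset.
#' @param config an [mcmc_control()] (hidden-state initialization cap).
#' @return list with `paths` (per interval: `times`, `types`) and `states`
#'   (full integer state matrix at the observation times).
#' @export
initial_latent <- function(network, observations, nullset = NULL,
                           config = mcmc_control()) {
  observations <- as_observation_set(observations, network)
  obs_sp <- observed_species(observations)
  if (is.null(nullset)) nullset <- null_set(network, observed = obs_sp)
  if (setequal(obs_sp, network$species)) {
    states <- obs_matrix(observations)[, network$species, drop = FALSE]
    list(paths = init_paths_full(network, states, observations$time),
         states = states)
  } else {
    init_latent_partial(network, observations, nullset, config)
  }
}

# summed (n, G) sufficient statistics of a latent state (theta-free)
latent_stats <- function(network, latent, times) {
  M <- length(network$reactions)
  n <- integer(M)
  G <- numeric(M)
  one <- rep(1, M) # G is theta-free, any positive theta works
  for (i in seq_along(latent$paths)) {
    p <- latent$paths[[i]]
    ev <- eval_path_cpp(p$times, p$types, latent$states[i, ], times[i],
                        times[i + 1], network$U, network$A, one,
                        convention_code(network))
    n <- n + ev$n
    G <- G + ev$G
  }
  list(n = n, G = G)
}

init_paths_full <- function(network, states, times, nullset = NULL) {
  m <- nrow(states)
  lapply(seq_len(m - 1), function(i) {
    delta <- states[i + 1, ] - states[i, ]
    r <- tryCatch(find_reaction_counts(network, delta),
                  error = function(e)
                    stop("interval ", i, " [", times[i], ", ", times[i + 1],
                         "]: ", conditionMessage(e), call. = FALSE))
    p <- initial_path(network, states[i, ], r, times[i], times[i + 1],
                      nullset = nullset)
    list(times = p$times, types = p$types)
  })
}

# Draw hidden components of the state at t_1: conserved groups distribute
# the remaining total uniformly over their hidden members; free hidden
# species are uniform on 0..init_cap.
draw_hidden_start <- function(network, obs_row, obs_sp, init_cap) {
  x <- setNames(integer(length(network$species)), network$species)
  x[obs_sp] <- obs_row[obs_sp]
  hidden <- setdiff(network$species, obs_sp)
  assigned <- character(0)
  for (cv in network$conserved %||% list()) {
    hid <- intersect(cv$species, hidden)
    if (!length(hid)) next
    rest <- cv$total - sum(x[intersect(cv$species, obs_sp)])
    if (rest < 0)
      stop("observations exceed the conserved total of {",
           paste(cv$species, collapse = ", "), "}", call. = FALSE)
    # uniform composition of `rest` over the hidden members (stars and bars)
    if (length(hid) == 1) {
      x[hid] <- rest
    } else {
      cuts <- sort(sample.int(rest + length(hid) - 1, length(hid) - 1))
      x[hid] <- as.integer(diff(c(0, cuts, rest + length(hid))) - 1L)
    }
    assigned <- c(assigned, hid)
  }
  free <- setdiff(hidden, assigned)
  if (length(free)) x[free] <- sample.int(init_cap + 1L, length(free),
                                          replace = TRUE) - 1L
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a

init_latent_partial <- function(network, observations, nullset, config,
                                max_restarts = 50L) {
  obs_sp <- observed_species(observations)
  obs <- obs_matrix(observations)[, obs_sp, drop = FALSE]
  times <- observations$time
  m <- length(times)
  K <- length(network$species)
  M <- length(network$reactions)
  mode_effect <- nullset$modes %*% network$A # K' x K net effects

  for (restart in seq_len(max_restarts)) {
    x1 <- draw_hidden_start(network, obs[1, ], obs_sp, config$init_cap)
    states <- matrix(0L, m, K, dimnames = list(NULL, network$species))
    states[1, ] <- x1
    ok <- TRUE
    counts <- vector("list", m - 1)
    for (i in seq_len(m - 1)) {
      delta <- obs[i + 1, ] - obs[i, ]
      r <- tryCatch(find_reaction_counts(network, delta, observed = obs_sp),
                    error = function(e) NULL)
      if (is.null(r)) { ok <- FALSE; break }
      nxt <- states[i, ] + drop(t(network$A) %*% r)
      tries <- 0L
      while (any(nxt < 0) && tries < 50L) {
        deficient <- which(nxt < 0)
        cand <- which(apply(mode_effect[, deficient, drop = FALSE], 1,
                            function(z) any(z > 0)))
        if (!length(cand)) break
        k <- cand[sample.int(length(cand), 1)]
        r <- r + nullset$modes[k, ]
        nxt <- states[i, ] + drop(t(network$A) %*% r)
        tries <- tries + 1L
      }
      if (any(nxt < 0)) { ok <- FALSE; break }
      states[i + 1, ] <- as.integer(nxt)
      counts[[i]] <- r
    }
    if (!ok) next
    paths <- vector("list", m - 1)
    for (i in seq_len(m - 1)) {
      p <- tryCatch(
        initial_path(network, states[i, ], counts[[i]], times[i],
                     times[i + 1],
                     nullset = tryCatch(null_set(network),
                                        error = function(e) NULL)),
        error = function(e) NULL)
      if (is.null(p)) { ok <- FALSE; break }
      # mode escalation inside initial_path only uses all-species modes, so
      # the end state is preserved
      paths[[i]] <- list(times = p$times, types = p$types)
    }
    if (ok) return(list(paths = paths, states = states))
  }
  stop("failed to initialize hidden states and paths after ", max_restarts,
       " restarts", call. = FALSE)
}

# reference fully observed sampler supporting custom hazards (slow)
rjmcmc_full_r <- function(network, states, times, paths0, nullset, config) {
  m <- nrow(states)
  nI <- m - 1
  M <- length(network$reactions)
  paths <- lapply(seq_len(nI), function(i)
    reaction_path(states[i, ], paths0[[i]]$times, paths0[[i]]$types,
                  times[i], times[i + 1]))
  lls <- vapply(paths, function(p) path_log_likelihood(network, p), 0)
  if (any(!is.finite(lls))) stop("invalid initial path", call. = FALSE)
  S <- config$n_samples
  n_iter <- config$burn_in + S * config$thin
  scores <- matrix(0, S, M)
  n_mat <- matrix(0L, S, M)
  G_mat <- matrix(0, S, M)
  J <- integer(S)
  prop_ct <- acc_ct <- integer(3)
  srow <- 0L
  for (iter in seq_len(n_iter)) {
    for (i in seq_len(nI)) {
      pr <- propose_move(network, paths[[i]], nullset, config)
      mv <- match(pr$move, c("add", "delete", "shuffle"))
      prop_ct[mv] <- prop_ct[mv] + 1L
      if (!pr$feasible) next
      ll_new <- path_log_likelihood(network, pr$path)
      logar <- (ll_new - lls[i]) + pr$log_proposal_ratio
      if (is.finite(logar) && log(runif(1)) < logar) {
        acc_ct[mv] <- acc_ct[mv] + 1L
        paths[[i]] <- pr$path
        lls[i] <- ll_new
      }
    }
    if (iter > config$burn_in &&
        (iter - config$burn_in - 1L) %% config$thin == 0L) {
      srow <- srow + 1L
      scores[srow, ] <- Reduce(`+`, lapply(paths, function(p)
        path_score(network, p)))
      if (is_mass_action(network)) {
        st <- sufficient_stats(network, paths)
        n_mat[srow, ] <- st$n
        G_mat[srow, ] <- st$G
      }
      J[srow] <- sum(vapply(paths, function(p) length(p$types), 0L))
      if (srow >= S) break
    }
  }
  list(n = n_mat, G = G_mat, scores = scores, J = J, J_interval = NULL,
       state_samples = NULL, proposed = prop_ct, accepted = acc_ct,
       paths = lapply(paths, function(p) list(times = p$times,
                                              types = p$types)),
       states = states)
}

#' Score (parameter gradient of the complete-data log-likelihood) of a path
#'
#' For mass-action reactions the closed form is
#' `n_r / theta_r - G_r`; custom rate laws use the supplied `dhazard`
#' derivative (or a central finite difference) in
#' `sum_{j: r_j = r} d log h_r / d theta_r - int d h_r / d theta_r dt`.
#'
#' @param network a [reaction_network()].
#' @param path a `reaction_path`.
#' @return named numeric vector of length `M`.
#' @export
path_score <- function(network, path) {
  M <- length(network$reactions)
  if (is_mass_action(network)) {
    st <- sufficient_stats(network, path)
    return(setNames(st$n / unname(network$theta) - st$G, network$reactions))
  }
  x <- check_state(network, path$x0)
  sc <- numeric(M)
  tprev <- path$t0
  J <- length(path$types)
  th <- unname(network$theta)
  dh_at <- function(x) {
    vapply(seq_len(M), function(r) {
      if (network$rate_law[r] == "mass_action")
        return(hazards_mass_action_cpp(x, network$U, th,
                                       convention_code(network))[r] / th[r])
      xs <- setNames(x, network$species)
      if (!is.null(network$dhazard_fns[[r]]))
        return(network$dhazard_fns[[r]](xs, th[r]))
      eps <- 1e-6 * th[r]
      (network$hazard_fns[[r]](xs, th[r] + eps) -
         network$hazard_fns[[r]](xs, th[r] - eps)) / (2 * eps)
    }, 0)
  }
  for (j in seq_len(J + 1)) {
    tnext <- if (j <= J) path$times[j] else path$t1
    sc <- sc - dh_at(x) * (tnext - tprev)
    if (j <= J) {
      r <- path$types[j]
      h <- hazards(network, x)[r]
      if (h <= 0) stop("invalid path in path_score", call. = FALSE)
      sc[r] <- sc[r] + dh_at(x)[r] / h
      x <- x + network$A[r, ]
      tprev <- tnext
    }
  }
  setNames(sc, network$reactions)
}
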