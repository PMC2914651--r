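#' Construct a reaction path
#'
#' A reaction path is the latent record of a Markov jump process on one time
#' interval: the start state at `t0` plus the ordered list of reaction events
#' (firing time, reaction index) up to `t1`. Replaying the events through the
#' rows of the net-effect matrix reconstructs the piecewise-constant state.
#'
#' @param x0 start state (named, or in species order).
#' @param times strictly increasing event times inside `(t0, t1)`.
#' @param types integer reaction indices (1..M), one per event.
#' @param t0,t1 interval endpoints, `t1 > t0`.
#' @param network optional [reaction_network()] used to validate the path.
#' @return an object of class `reaction_path`.
#' @export
reaction_path <- function(x0, times, types, t0, t1, network = NULL) {
  times <- as.numeric(times)
  types <- as.integer(types)
  if (length(times) != length(types))
    stop("times and types must have equal length", call. = FALSE)
  if (t1 <= t0) stop("t1 must exceed t0", call. = FALSE)
  if (length(times) && (is.unsorted(times) || times[1] <= t0 ||
                        times[length(times)] >= t1))
    stop("event times must be increasing and inside (t0, t1)", call. = FALSE)
  if (!is.null(network)) x0 <- check_state(network, x0)
  structure(list(x0 = x0, times = times, types = types, t0 = t0, t1 = t1),
            class = "reaction_path")
}

#' @export
print.reaction_path <- function(x, ...) {
  cat(sprintf("<reaction_path> [%g, %g], %d events\n", x$t0, x$t1,
              length(x$times)))
  invisible(x)
}

path_counts <- function(path, M) {
  tabulate(path$types, nbins = M)
}

#' Exact stochastic simulation (Gillespie direct method)
#'
#' Simulates one exact realization of the Markov jump process defined by the
#' network's hazards, starting from `x0` at time `t0`.
#'
#' @param network a [reaction_network()].
#' @param x0 initial state.
#' @param t_end end of the simulated window.
#' @param t0 start time (default 0).
#' @param seed optional integer seed for reproducibility.
#' @param max_events guard against hazard explosion; the simulation aborts
#'   with an error when more events than this occur.
#' @return a `reaction_path` covering `[t0, t_end]` (also of class
#'   `ssa_trajectory`), with the final state in attribute `x_end`.
#' @examples
#' net <- birth_death_network()
#' tr <- simulate_ssa(net, c(A = 20), t_end = 10, seed = 1)
#' @export
simulate_ssa <- function(network, x0, t_end, t0 = 0, seed = NULL,
                         max_events = 1e6) {
  x <- check_state(network, x0)
  if (!is.null(seed)) set.seed(seed)
  if (is_mass_action(network)) {
    sim <- ssa_cpp(x, network$U, network$A, unname(network$theta),
                   convention_code(network), t0, t_end, as.integer(max_events))
  } else {
    sim <- ssa_r(network, x, t0, t_end, max_events)
  }
  p <- reaction_path(setNames(x, network$species), sim$times, sim$types,
                     t0, t_end)
  attr(p, "x_end") <- setNames(as.integer(sim$x_end), network$species)
  class(p) <- c("ssa_trajectory", class(p))
  p
}

# reference SSA supporting custom hazards
ssa_r <- function(network, x, t0, t_end, max_events) {
  times <- numeric(0)
  types <- integer(0)
  t <- t0
  repeat {
    h <- hazards(network, x)
    h0 <- sum(h)
    if (h0 <= 0) break
    t <- t + stats::rexp(1, h0)
    if (t >= t_end) break
    if (length(times) >= max_events)
      stop("SSA event cap exceeded: hazards may be exploding", call. = FALSE)
    r <- sample.int(length(h), 1, prob = h)
    times <- c(times, t)
    types <- c(types, r)
    x <- x + network$A[r, ]
  }
  list(times = times, types = types, x_end = x)
}

#' States of a path at its event boundaries
#'
#' @param network a [reaction_network()].
#' @param path a `reaction_path`.
#' @return integer matrix with `J + 1` rows: the state after 0, 1, ..., J
#'   events.
#' @export
path_states <- function(network, path) {
  x <- check_state(network, path$x0)
  J <- length(path$types)
  out <- matrix(0L, J + 1, length(network$species),
                dimnames = list(NULL, network$species))
  out[1, ] <- x
  if (J > 0)
    for (j in seq_len(J)) out[j + 1, ] <- out[j, ] + network$A[path$types[j], ]
  out
}

#' @export
as_tibble.ssa_trajectory <- function(x, ..., network = NULL) {
  states <- if (is.null(network)) {
    # reconstruct from stored start state assuming names carry the order
    stop("supply the network to tabulate a trajectory", call. = FALSE)
  } else path_states(network, x)
  tibble(time = c(x$t0, x$times)) |>
    dplyr::bind_cols(as_tibble(as.data.frame(states)))
}

#' Extract discrete observations from a trajectory
#'
#' Records the state of a simulated trajectory at the requested times,
#' restricted to the observed species. The state at an observation time `t`
#' is the value after all events with firing time `<= t`.
#'
#' @param trajectory an `ssa_trajectory` from [simulate_ssa()].
#' @param network the [reaction_network()] that generated it.
#' @param times strictly increasing observation times within the simulated
#'   window.
#' @param observed character vector of observed species (default: all).
#' @return a tibble with a `time` column and one column per observed species;
#'   class `observation_set`.
#' @export
make_observations <- function(trajectory, network, times, observed = NULL) {
  if (is.null(observed)) observed <- network$species
  if (!length(observed) || !all(observed %in% network$species))
    stop("observed must name a non-empty subset of the species", call. = FALSE)
  times <- as.numeric(times)
  if (length(times) < 2 || is.unsorted(times, strictly = TRUE))
    stop("observation times must be strictly increasing (m >= 2)",
         call. = FALSE)
  if (times[1] < trajectory$t0 || times[length(times)] > trajectory$t1)
    stop("requested observation times fall outside the simulated window",
         call. = FALSE)
  states <- path_states(network, trajectory)
  idx <- findInterval(times, trajectory$times) + 1L
  obs <- states[idx, observed, drop = FALSE]
  out <- dplyr::bind_cols(tibble(time = times),
                          as_tibble(as.data.frame(obs)))
  as_observation_set(out, network)
}

as_observation_set <- function(tbl, network = NULL) {
  stopifnot(is.data.frame(tbl), "time" %in% names(tbl))
  tbl <- as_tibble(tbl)
  if (!is.null(network)) {
    sp <- setdiff(names(tbl), "time")
    unknown <- setdiff(sp, network$species)
    if (length(unknown))
      stop("unknown species column(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    # keep species columns in network order
    tbl <- tbl[, c("time", intersect(network$species, sp))]
  }
  if (is.unsorted(tbl$time, strictly = TRUE))
    stop("observation times must be strictly increasing", call. = FALSE)
  counts <- as.matrix(tbl[, -1, drop = FALSE])
  if (any(counts < 0) || any(counts != round(counts)))
    stop("observed counts must be non-negative integers", call. = FALSE)
  class(tbl) <- c("observation_set", class(tbl))
  tbl
}

observed_species <- function(observations) {
  setdiff(names(observations), "time")
}

obs_matrix <- function(observations) {
  m <- as.matrix(observations[, setdiff(names(observations), "time"),
                              drop = FALSE])
  storage.mode(m) <- "integer"
  m
}

#' Write observations to CSV
#'
#' Header `time,<species1>,...`; one row per observation time. The writer and
#' [read_observations()] round-trip exactly.
#'
#' @param observations an observation tibble.
#' @param path output file.
#' @export
write_observations <- function(observations, path) {
  write.csv(as.data.frame(observations), path, row.names = FALSE,
            quote = FALSE)
  invisible(path)
}

#' Read observations from CSV
#'
#' @param path CSV file with a `time` column plus one column per observed
#'   species (a subset of the network's species).
#' @param network a [reaction_network()] used for validation; the observed
#'   subset is inferred from the columns present.
#' @return an observation tibble.
#' @export
read_observations <- function(path, network) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, check.names = FALSE)
  if (!"time" %in% names(df))
    stop(path, ": missing 'time' column", call. = FALSE)
  if (anyDuplicated(df$time))
    stop(path, ": duplicated observation times", call. = FALSE)
  as_observation_set(df, network)
}
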