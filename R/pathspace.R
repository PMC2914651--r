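#' Null set of elementary modes
#'
#' An elementary mode is a non-negative integer combination of reactions
#' whose combined firing leaves every *observed* species count unchanged:
#' `t(A_obs) %*% q = 0`, where `A_obs` is the net-effect matrix restricted to
#' the observed columns. The null set collects all support-minimal such
#' modes; they are the building blocks of the reversible-jump proposals,
#' since adding or deleting a whole mode preserves the endpoint observations
#' of an interval. The null set depends on which species are observed: hiding
#' species can only enlarge it.
#'
#' Modes are found by bounded exhaustive enumeration of coefficient vectors
#' with entries `0..cap`, followed by support-minimality filtering (a mode is
#' dropped when another mode's support is a strict subset of its own, or when
#' it is a multiple of a smaller mode with the same support). This is exact
#' for the small networks this package targets.
#'
#' @param network a [reaction_network()].
#' @param observed character vector of observed species (default: all).
#' @param cap maximum coefficient per reaction in the enumeration.
#' @return an object of class `null_set`: a list with `modes` (a `K' x M`
#'   integer matrix, one row per mode, columns named by reaction) and the
#'   `observed` subset. Rows are in canonical order (increasing total count,
#'   then lexicographic).
#' @examples
#' null_set(birth_death_network()) # single mode: R1 + R2
#' @export
null_set <- function(network, observed = NULL, cap = 4L) {
  stopifnot(inherits(network, "reaction_network"))
  if (is.null(observed)) observed <- network$species
  if (!length(observed) || !all(observed %in% network$species))
    stop("observed must be a non-empty subset of the species", call. = FALSE)
  A_obs <- network$A[, observed, drop = FALSE]
  M <- nrow(A_obs)
  grid <- as.matrix(expand.grid(rep(list(0:cap), M)))
  colnames(grid) <- network$reactions
  keep <- rowSums(abs(grid %*% A_obs)) == 0 & rowSums(grid) > 0
  cand <- grid[keep, , drop = FALSE]
  if (nrow(cand) == 0)
    stop("empty null set for observed = {",
         paste(observed, collapse = ", "),
         "}: no reversible-jump moves exist", call. = FALSE)
  # canonical order: total count, then lexicographic over reaction columns
  ord <- do.call(order, c(list(rowSums(cand)),
                          lapply(seq_len(ncol(cand)), function(j) cand[, j])))
  cand <- cand[ord, , drop = FALSE]
  # support minimality: keep a mode unless an already-kept mode's support is
  # a subset of its support (equal-support multiples are dropped too, since
  # the primitive mode sorts first)
  kept <- matrix(0L, 0, M)
  for (i in seq_len(nrow(cand))) {
    qi <- cand[i, ]
    si <- qi > 0
    dominated <- FALSE
    if (nrow(kept) > 0) {
      for (j in seq_len(nrow(kept))) {
        sj <- kept[j, ] > 0
        if (all(sj <= si)) { dominated <- TRUE; break }
      }
    }
    if (!dominated) kept <- rbind(kept, qi)
  }
  dimnames(kept) <- list(NULL, network$reactions)
  storage.mode(kept) <- "integer"
  structure(list(modes = kept, observed = observed, cap = cap,
                 reactions = network$reactions),
            class = "null_set")
}

#' @export
print.null_set <- function(x, ...) {
  cat(sprintf("<null_set> %d elementary mode(s), observed = {%s}\n",
              nrow(x$modes), paste(x$observed, collapse = ", ")))
  for (k in seq_len(nrow(x$modes))) {
    q <- x$modes[k, ]
    nz <- which(q > 0)
    cat(sprintf("  mode %d: %s\n", k,
                paste(ifelse(q[nz] > 1, paste0(q[nz], "x"), ""),
                      x$reactions[nz], sep = "", collapse = " + ")))
  }
  invisible(x)
}

#' @export
tidy.null_set <- function(x, ...) {
  as_tibble(as.data.frame(x$modes)) |>
    dplyr::mutate(mode = dplyr::row_number(), .before = 1)
}

#' Minimal reaction counts matching an observed change
#'
#' Solves the integer program: find non-negative integer reaction counts `r`
#' with `t(A_obs) %*% r = delta` and minimal total `sum(r)`. This is the
#' smallest multiset of reactions that can carry the system across one
#' inter-observation interval consistently with the observed endpoint
#' change. Solved exactly by iterative-deepening branch and bound.
#'
#' @param network a [reaction_network()].
#' @param delta integer change in the observed species over the interval
#'   (named, or in `observed` order).
#' @param observed character vector of observed species (default: all).
#' @param max_total search cap on `sum(r)`; infeasibility within the cap is
#'   an error.
#' @return named integer vector of reaction counts. The post-condition
#'   `t(A_obs) %*% r == delta` is verified on every call.
#' @export
find_reaction_counts <- function(network, delta, observed = NULL,
                                 max_total = 200L) {
  stopifnot(inherits(network, "reaction_network"))
  if (is.null(observed)) observed <- network$species
  A_obs <- network$A[, observed, drop = FALSE]
  if (!is.null(names(delta))) delta <- delta[observed]
  if (length(delta) != length(observed))
    stop("delta must have one entry per observed species", call. = FALSE)
  delta <- as.integer(delta)
  r <- find_counts_cpp(A_obs, delta, as.integer(max_total))
  if (length(r) == 0)
    stop("no non-negative reaction counts with total <= ", max_total,
         " reproduce the observed change (", paste(delta, collapse = ", "),
         "): observations incompatible with the stoichiometry?",
         call. = FALSE)
  if (!all(drop(t(A_obs) %*% r) == delta))
    stop("internal error: reaction-count solution failed verification")
  setNames(as.integer(r), network$reactions)
}

#' Construct a valid initial path for one interval
#'
#' Given per-reaction event counts `r` (for instance from
#' [find_reaction_counts()]), builds a reaction path on `(t0, t1)` starting
#' at `x_start` whose per-type counts equal `r` and along which no species
#' count goes negative. Event times are drawn i.i.d. uniform and sorted; the
#' event order is found by repair search: when replay hits a state with an
#' insufficient reactant, the violating event is moved after the earliest
#' later event that replenishes the deficient species. After repeated repair
#' failure the times and order are redrawn; after repeated redraws an
#' elementary mode is added to the counts and the search restarts.
#'
#' @param network a [reaction_network()].
#' @param x_start full start state.
#' @param r named per-reaction counts.
#' @param t0,t1 interval endpoints.
#' @param nullset optional [null_set()] used for mode-addition escalation.
#' @param max_repairs,max_resamples,max_modes bounds of the repair search.
#' @return a `reaction_path`.
#' @export
initial_path <- function(network, x_start, r, t0, t1, nullset = NULL,
                         max_repairs = 200L, max_resamples = 50L,
                         max_modes = 20L) {
  x0 <- check_state(network, x_start)
  M <- length(network$reactions)
  r <- as.integer(r)
  stopifnot(length(r) == M, all(r >= 0))
  U <- network$U
  A <- network$A

  try_order <- function(types) {
    # replay with swap repair; returns repaired types or NULL
    for (rep_i in seq_len(max_repairs)) {
      x <- x0
      bad <- 0L
      for (j in seq_along(types)) {
        ty <- types[j]
        if (any(x < U[ty, ])) { bad <- j; break }
        x <- x + A[ty, ]
      }
      if (bad == 0L) return(types)
      deficient <- which(x < U[types[bad], ]) # x = state before event `bad`
      # earliest later event that increases a deficient species
      fix <- 0L
      if (bad < length(types)) {
        for (j in (bad + 1):length(types)) {
          if (any(A[types[j], deficient] > 0)) { fix <- j; break }
        }
      }
      if (fix == 0L) return(NULL)
      types <- append(types[-fix], types[fix], after = bad - 1L)
    }
    NULL
  }

  counts <- r
  for (add_i in 0:max_modes) {
    J <- sum(counts)
    for (res_i in seq_len(max_resamples)) {
      types <- rep.int(seq_len(M), counts)
      if (J > 1) types <- types[sample.int(J)]
      fixed <- try_order(types)
      if (!is.null(fixed)) {
        times <- sort(runif(J, t0, t1))
        return(reaction_path(setNames(x0, network$species), times, fixed,
                             t0, t1))
      }
      if (J == 0) break
    }
    if (add_i == max_modes) break
    if (is.null(nullset)) nullset <- null_set(network)
    k <- sample.int(nrow(nullset$modes), 1)
    counts <- counts + nullset$modes[k, ]
  }
  stop("could not construct a valid initial path on [", t0, ", ", t1,
       "] for the given reaction counts", call. = FALSE)
}
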