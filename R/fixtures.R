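#' Birth-death benchmark network
#'
#' Production and degradation of a single species A: `R1: A -> 0` with
#' first-order hazard `h1 = k1 * n_A`, and `R2: 0 -> A` with zeroth-order
#' hazard `h2 = k2`. The net-effect matrix is `A = (-1, 1)^T` and the null
#' set (all species observed) holds the single mode R1 + R2. The stationary
#' distribution of the count is Poisson with mean `k2 / k1`.
#'
#' @param k1,k2 degradation and production rate constants (positive).
#' @return a [reaction_network()].
#' @export
birth_death_network <- function(k1 = 0.03, k2 = 0.6) {
  stopifnot(k1 > 0, k2 > 0)
  reaction_network(
    species = "A",
    reactions = list(
      list(name = "R1", reactants = c(A = 1), products = c(), theta = k1),
      list(name = "R2", reactants = c(), products = c(A = 1), theta = k2)
    )
  )
}

#' Prokaryotic auto-regulatory gene network
#'
#' A protein dimer represses its own transcription by binding the promoter:
#' \describe{
#'   \item{R1}{`DNA + P2 -> DNA.P2` (repressor binding), `h1 = k1 * DNA * P2`}
#'   \item{R2}{`DNA.P2 -> DNA + P2` (unbinding)}
#'   \item{R3}{`DNA -> DNA + mRNA` (transcription)}
#'   \item{R4}{`mRNA -> 0` (mRNA degradation)}
#'   \item{R5}{`2 P -> P2` (dimerization)}
#'   \item{R6}{`P2 -> 2 P` (dissociation)}
#'   \item{R7}{`mRNA -> mRNA + P` (translation)}
#'   \item{R8}{`P -> 0` (protein degradation)}
#' }
#' `DNA + DNA.P2` is conserved (the promoter copy number `DNA_t`), which is
#' declared on the network so the partially observed sampler can exploit it.
#' With all species observed the null set is the four reversible pairs
#' R1-R2, R3-R4, R5-R6, R7-R8.
#'
#' @param k length-8 positive rate constants `k1..k8`.
#' @param dna_total conserved promoter copy number `DNA_t`.
#' @return a [reaction_network()].
#' @export
autoregulatory_network <- function(k = c(0.1, 0.7, 0.35, 0.3, 0.1, 0.9,
                                         0.2, 0.1),
                                   dna_total = 10L) {
  stopifnot(length(k) == 8, all(k > 0), dna_total >= 1)
  reaction_network(
    species = c("DNA", "DNA.P2", "mRNA", "P", "P2"),
    reactions = list(
      list(name = "R1", reactants = c(DNA = 1, P2 = 1),
           products = c(DNA.P2 = 1), theta = k[1]),
      list(name = "R2", reactants = c(DNA.P2 = 1),
           products = c(DNA = 1, P2 = 1), theta = k[2]),
      list(name = "R3", reactants = c(DNA = 1),
           products = c(DNA = 1, mRNA = 1), theta = k[3]),
      list(name = "R4", reactants = c(mRNA = 1), products = c(),
           theta = k[4]),
      list(name = "R5", reactants = c(P = 2), products = c(P2 = 1),
           theta = k[5]),
      list(name = "R6", reactants = c(P2 = 1), products = c(P = 2),
           theta = k[6]),
      list(name = "R7", reactants = c(mRNA = 1),
           products = c(mRNA = 1, P = 1), theta = k[7]),
      list(name = "R8", reactants = c(P = 1), products = c(), theta = k[8])
    ),
    conserved = list(list(species = c("DNA", "DNA.P2"),
                          total = as.integer(dna_total)))
  )
}

#' Generate a benchmark dataset by exact simulation
#'
#' Simulates the chosen system with the stochastic simulation algorithm and
#' records counts on an arithmetic grid of `m` observation times spaced
#' `dt` apart, restricted to the observed species. A fixed seed reproduces
#' the dataset exactly.
#'
#' @param model `"birth_death"` or `"autoreg"`.
#' @param theta true rate parameters (defaults: `(0.03, 0.6)` for
#'   birth-death; `(0.1, 0.7, 0.35, 0.3, 0.1, 0.9, 0.2, 0.1)` for the
#'   auto-regulatory network).
#' @param m number of observations (`>= 2`).
#' @param dt observation spacing.
#' @param observed observed species subset (default: all).
#' @param dna_total promoter copy number (auto-regulatory model only).
#' @param x0 initial state; defaults: an empty system (`A = 0`, induction at
#'   time zero, so the relaxation transient is observed) for birth-death;
#'   all promoters unbound and no transcripts or protein for the
#'   auto-regulatory network.
#' @param seed optional integer seed.
#' @return list with `observations` (tibble), `trajectory` (the full
#'   simulated path), `network` (with the true `theta`), and the echoed
#'   design.
#' @examples
#' bench <- generate_benchmark("birth_death", m = 21, dt = 2, seed = 1)
#' bench$observations
#' @export
generate_benchmark <- function(model = c("birth_death", "autoreg"),
                               theta = NULL, m = 21L, dt = 2,
                               observed = NULL, dna_total = 10L, x0 = NULL,
                               seed = NULL) {
  model <- match.arg(model)
  stopifnot(m >= 2, dt > 0)
  if (model == "birth_death") {
    if (is.null(theta)) theta <- c(0.03, 0.6)
    network <- birth_death_network(theta[1], theta[2])
    if (is.null(x0)) x0 <- c(A = 0) # induction at t = 0: informative transient
  } else {
    if (is.null(theta)) theta <- c(0.1, 0.7, 0.35, 0.3, 0.1, 0.9, 0.2, 0.1)
    network <- autoregulatory_network(theta, dna_total = dna_total)
    if (is.null(x0)) x0 <- c(DNA = dna_total, DNA.P2 = 0, mRNA = 0, P = 0,
                             P2 = 0)
  }
  times <- seq(0, by = dt, length.out = m)
  trajectory <- simulate_ssa(network, x0, t_end = times[m] + dt, seed = seed)
  observations <- make_observations(trajectory, network, times,
                                    observed = observed)
  list(observations = observations, trajectory = trajectory,
       network = network,
       design = list(model = model, theta = theta, m = as.integer(m),
                     dt = dt, observed = observed %||% network$species,
                     dna_total = if (model == "autoreg") dna_total else NULL,
                     x0 = x0, seed = seed))
}
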