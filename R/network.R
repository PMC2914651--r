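#' Build a stochastic reaction network
#'
#' A reaction network couples `M` reactions over `K` species. Each reaction
#' `r` converts integer multiples of reactant species into product species
#' and carries a rate parameter `theta_r > 0`. The reactant and product
#' stoichiometries form the `M x K` matrices `U` and `V`; their difference
#' `A = V - U` is the net-effect matrix, whose row `r` is the change in the
#' species counts when reaction `r` fires. Under mass-action kinetics the
#' hazard (propensity) of reaction `r` in state `x` is
#' `h_r(x) = theta_r * prod_a C(x_a, u_ra)` (binomial convention, the
#' default) or `theta_r * prod_a x_a (x_a - 1) ... (x_a - u_ra + 1)`
#' (falling-factorial convention). The two conventions differ only for
#' reactions consuming two or more copies of a species, e.g. dimerization.
#'
#' @param species character vector of unique species names.
#' @param reactions list of reactions. Each reaction is a list with elements
#'   `name` (optional), `reactants` and `products` (named integer vectors of
#'   stoichiometries; species not mentioned get 0), `theta` (positive rate
#'   parameter), `rate_law` (`"mass_action"`, the default, or `"custom"`),
#'   and for custom rate laws `hazard = function(x, theta)` returning the
#'   propensity at the named integer state `x`, plus optionally
#'   `dhazard = function(x, theta)` giving its partial derivative in `theta`
#'   (finite differences are used when absent).
#' @param conserved optional list of known conserved totals, each a list with
#'   `species` (character vector) and `total` (non-negative integer). Used by
#'   the partially observed sampler to pin down hidden states.
#' @param convention mass-action combinatorial convention, `"binomial"` or
#'   `"falling"`.
#'
#' @return An object of class `reaction_network` with fields `species`,
#'   `reactions` (names), `U`, `V`, `A`, `theta`, `rate_law`, `conserved`,
#'   `convention`.
#' @examples
#' net <- reaction_network(
#'   species = "A",
#'   reactions = list(
#'     list(name = "R1", reactants = c(A = 1), products = c(), theta = 0.03),
#'     list(name = "R2", reactants = c(), products = c(A = 1), theta = 0.6)
#'   )
#' )
#' net$A # matrix(c(-1, 1))
#' hazards(net, c(A = 10)) # c(0.3, 0.6)
#' @export
reaction_network <- function(species, reactions,
                             conserved = NULL,
                             convention = c("binomial", "falling")) {
  convention <- match.arg(convention)
  species <- as.character(species)
  if (length(species) == 0 || anyDuplicated(species) || any(!nzchar(species)))
    stop("species names must be unique and non-empty", call. = FALSE)
  if (length(reactions) == 0)
    stop("at least one reaction is required", call. = FALSE)
  K <- length(species)
  M <- length(reactions)

  stoich_row <- function(x, what, r) {
    out <- integer(K)
    names(out) <- species
    if (is.null(x) || length(x) == 0) return(out)
    x <- unlist(x)
    if (is.null(names(x)) || any(!nzchar(names(x))))
      stop(sprintf("reaction %d: %s must be a named vector", r, what),
           call. = FALSE)
    unknown <- setdiff(names(x), species)
    if (length(unknown))
      stop(sprintf("reaction %d: unknown species in %s: %s", r, what,
                   paste(unknown, collapse = ", ")), call. = FALSE)
    if (any(x < 0) || any(x != round(x)))
      stop(sprintf("reaction %d: %s stoichiometries must be non-negative integers",
                   r, what), call. = FALSE)
    out[names(x)] <- as.integer(x)
    out
  }

  U <- matrix(0L, M, K, dimnames = list(NULL, species))
  V <- matrix(0L, M, K, dimnames = list(NULL, species))
  theta <- numeric(M)
  rate_law <- character(M)
  rnames <- character(M)
  hazard_fns <- vector("list", M)
  dhazard_fns <- vector("list", M)
  for (r in seq_len(M)) {
    rx <- reactions[[r]]
    U[r, ] <- stoich_row(rx$reactants, "reactants", r)
    V[r, ] <- stoich_row(rx$products, "products", r)
    th <- rx$theta
    if (is.null(th) || !is.numeric(th) || length(th) != 1 || !is.finite(th) ||
        th <= 0)
      stop(sprintf("reaction %d: theta must be a single positive number", r),
           call. = FALSE)
    theta[r] <- th
    rl <- if (is.null(rx$rate_law)) "mass_action" else rx$rate_law
    if (!rl %in% c("mass_action", "custom"))
      stop(sprintf("reaction %d: unknown rate law '%s'", r, rl), call. = FALSE)
    rate_law[r] <- rl
    if (rl == "custom") {
      if (!is.function(rx$hazard))
        stop(sprintf("reaction %d: custom rate law needs a hazard function", r),
             call. = FALSE)
      hazard_fns[[r]] <- rx$hazard
      dhazard_fns[[r]] <- rx$dhazard
    }
    rnames[r] <- if (is.null(rx$name)) paste0("R", r) else rx$name
  }
  if (anyDuplicated(rnames))
    stop("reaction names must be unique", call. = FALSE)
  rownames(U) <- rownames(V) <- rnames

  if (!is.null(conserved)) {
    for (cv in conserved) {
      if (!all(cv$species %in% species))
        stop("conserved group names unknown species", call. = FALSE)
      if (!is.numeric(cv$total) || cv$total < 0 || cv$total != round(cv$total))
        stop("conserved total must be a non-negative integer", call. = FALSE)
    }
  }

  structure(
    list(species = species, reactions = rnames, U = U, V = V,
         A = V - U, theta = setNames(theta, rnames),
         rate_law = setNames(rate_law, rnames),
         hazard_fns = hazard_fns, dhazard_fns = dhazard_fns,
         conserved = conserved, convention = convention),
    class = "reaction_network"
  )
}

#' @export
print.reaction_network <- function(x, ...) {
  cat(sprintf("<reaction_network> %d species, %d reactions (%s convention)\n",
              length(x$species), length(x$reactions), x$convention))
  for (r in seq_along(x$reactions)) {
    lhs <- format_side(x$U[r, ], x$species)
    rhs <- format_side(x$V[r, ], x$species)
    cat(sprintf("  %s: %s -> %s   [%s, theta = %g]\n", x$reactions[r], lhs,
                rhs, x$rate_law[r], x$theta[r]))
  }
  if (!is.null(x$conserved))
    for (cv in x$conserved)
      cat(sprintf("  conserved: %s = %d\n",
                  paste(cv$species, collapse = " + "), cv$total))
  invisible(x)
}

format_side <- function(stoich, species) {
  nz <- which(stoich > 0)
  if (!length(nz)) return("0")
  paste(ifelse(stoich[nz] > 1, paste0(stoich[nz], " "), ""), species[nz],
        sep = "", collapse = " + ")
}

#' @export
tidy.reaction_network <- function(x, ...) {
  tibble(reaction = x$reactions, theta = unname(x$theta),
         rate_law = unname(x$rate_law))
}

convention_code <- function(network) {
  if (network$convention == "binomial") 0L else 1L
}

is_mass_action <- function(network) all(network$rate_law == "mass_action")

#' Replace the rate parameters of a network
#'
#' @param network a [reaction_network()].
#' @param theta positive numeric vector of length `M`.
#' @return the network with updated `theta`.
#' @export
set_theta <- function(network, theta) {
  stopifnot(inherits(network, "reaction_network"))
  if (length(theta) != length(network$theta) || any(!is.finite(theta)) ||
      any(theta <= 0))
    stop("theta must be positive and of length ", length(network$theta),
         call. = FALSE)
  network$theta[] <- theta
  network
}

check_state <- function(network, state) {
  x <- state_vector(network, state)
  if (any(x < 0) || any(x != round(x)))
    stop("state must contain non-negative integer counts", call. = FALSE)
  as.integer(round(x))
}

state_vector <- function(network, state) {
  K <- length(network$species)
  if (!is.null(names(state))) {
    miss <- setdiff(network$species, names(state))
    if (length(miss))
      stop("state is missing species: ", paste(miss, collapse = ", "),
           call. = FALSE)
    state <- state[network$species]
  } else if (length(state) != K) {
    stop("state must have one count per species", call. = FALSE)
  }
  as.numeric(state)
}

#' Reaction hazards at a state
#'
#' Evaluates the hazard (propensity) of every reaction at a state. For
#' mass-action reactions `h_r = theta_r * prod_a C(x_a, u_ra)` under the
#' binomial convention; a reaction with an insufficient reactant count has
#' hazard zero.
#'
#' @param network a [reaction_network()].
#' @param state integer state vector (named, or in species order).
#' @return named numeric vector of `M` non-negative hazards.
#' @export
hazards <- function(network, state) {
  x <- check_state(network, state)
  if (is_mass_action(network)) {
    h <- hazards_mass_action_cpp(x, network$U, unname(network$theta),
                                 convention_code(network))
  } else {
    h <- numeric(length(network$reactions))
    xm <- hazards_mass_action_cpp(x, network$U, unname(network$theta),
                                  convention_code(network))
    xs <- setNames(x, network$species)
    for (r in seq_along(h)) {
      h[r] <- if (network$rate_law[r] == "custom")
        network$hazard_fns[[r]](xs, unname(network$theta[r])) else xm[r]
    }
    if (any(!is.finite(h)) || any(h < 0))
      stop("custom hazard returned a negative or non-finite value",
           call. = FALSE)
  }
  setNames(h, network$reactions)
}
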