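test_that("networks are validated and the net-effect matrix is V - U", {
  bd <- birth_death_network(0.03, 0.6)
  expect_equal(unname(bd$A), matrix(c(-1L, 1L), 2, 1))
  expect_identical(bd$A, bd$V - bd$U)

  ar <- autoregulatory_network()
  expect_equal(dim(ar$A), c(8L, 5L))
  # dimerization 2P -> P2 consumes two proteins, produces one dimer
  expect_equal(unname(ar$A["R5", ]), c(0L, 0L, 0L, -2L, 1L))
  # translation is catalytic in mRNA: only P changes
  expect_equal(unname(ar$A["R7", ]), c(0L, 0L, 0L, 1L, 0L))
  expect_identical(ar$A, ar$V - ar$U)

  expect_error(reaction_network(c("A", "A"), list(
    list(reactants = c(A = 1), products = c(), theta = 1))),
    "unique")
  expect_error(reaction_network("A", list(
    list(reactants = c(A = -1), products = c(), theta = 1))),
    "non-negative")
  expect_error(reaction_network("A", list(
    list(reactants = c(A = 1), products = c(), theta = 0))),
    "positive")
  expect_error(reaction_network("A", list(
    list(reactants = c(A = 1), products = c(), theta = 1,
         rate_law = "michaelis"))),
    "rate law")
})

test_that("mass-action hazards follow the combinatorial convention", {
  bd <- birth_death_network(0.03, 0.6)
  expect_equal(unname(hazards(bd, c(A = 10))), c(0.3, 0.6))
  # a required reactant at count zero forces hazard zero
  expect_equal(unname(hazards(bd, c(A = 0))), c(0, 0.6))

  ar <- autoregulatory_network()
  h <- hazards(ar, c(DNA = 2, DNA.P2 = 0, mRNA = 0, P = 4, P2 = 3))
  expect_equal(unname(h["R1"]), 0.1 * 2 * 3) # k1 * DNA * P2
  # dimerization: binomial convention C(4, 2) = 6 pairs
  expect_equal(unname(h["R5"]), 0.1 * choose(4, 2))

  # falling-factorial convention differs only for u >= 2
  dimer <- function(conv) reaction_network(
    "P", list(list(reactants = c(P = 2), products = c(), theta = 0.1)),
    convention = conv)
  expect_equal(unname(hazards(dimer("binomial"), c(P = 4))), 0.6)
  expect_equal(unname(hazards(dimer("falling"), c(P = 4))), 1.2)
})

test_that("hazards are homogeneous of degree one in theta", {
  ar <- autoregulatory_network()
  set.seed(1)
  for (i in 1:20) {
    x <- c(DNA = sample(0:10, 1), DNA.P2 = sample(0:10, 1),
           mRNA = sample(0:20, 1), P = sample(0:20, 1), P2 = sample(0:20, 1))
    cc <- runif(1, 0.1, 5)
    scaled <- set_theta(ar, cc * ar$theta)
    expect_equal(hazards(scaled, x), cc * hazards(ar, x))
  }
})

test_that("custom rate laws evaluate through the supplied hazard function", {
  mm <- reaction_network(
    species = "S",
    reactions = list(
      list(name = "uptake", reactants = c(S = 1), products = c(),
           rate_law = "custom", theta = 2,
           hazard = function(x, theta) theta * x[["S"]] / (5 + x[["S"]]))
    ))
  expect_equal(unname(hazards(mm, c(S = 5))), 2 * 5 / 10)
  expect_equal(unname(hazards(mm, c(S = 0))), 0)
})
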