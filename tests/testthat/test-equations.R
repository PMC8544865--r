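test_that("the stoichiometric matrix reproduces the enzyme and single-reaction examples", {
  st <- build_stoichiometry(enzyme_model())
  expect_identical(st$N[c("E", "C", "S", "P"), c("r1", "r2")],
                   matrix(c(-1L, 1L, -1L, 0L, 1L, -1L, 0L, 1L), 4, 2,
                          dimnames = list(c("E", "C", "S", "P"),
                                          c("r1", "r2"))))
  ab <- bondgraph_model(reaction_network(
    species = c(A = 1, B = 1),
    reactions = list(r = rxn(c(A = 1), c(B = 1), mass_action(1)))))
  expect_identical(unname(build_stoichiometry(ab)$N), matrix(c(-1L, 1L), 2, 1))
})

test_that("the glycolysis network has the expected internal structure", {
  st <- build_stoichiometry(build_glycolysis())
  keep <- setdiff(st$reactions, c("fbp", "pps"))
  expect_length(keep, 9L)
  internal <- glycolysis_network()$internal
  Ni <- st$N[internal, keep]
  ## every internal species participates, and the internal null space of
  ## the 9-reaction pathway is one-dimensional
  expect_true(all(rowSums(Ni != 0) > 0))
  expect_error(steady_state_pathway(st),  # fbp/pps open futile cycles
               "dimension 3")
  w <- steady_state_pathway(st, exclude = c("fbp", "pps"))
  expect_identical(w[c("pgi", "pfk", "fba", "tpi", "gap", "pgk", "gpm",
                       "eno", "pyk")],
                   c(pgi = 1L, pfk = 1L, fba = 1L, tpi = 1L, gap = 2L,
                     pgk = 2L, gpm = 2L, eno = 2L, pyk = 2L))
})

test_that("assembled derivatives match a brute-force mass-action oracle", {
  set.seed(21)
  models <- list(enzyme_model(), chain_model(),
                 enzyme_model(chemostats = c("S", "P")))
  for (model in models) {
    sys <- assemble_odes(model)
    tab <- reaction_table(model)
    for (i in 1:100) {
      x <- random_positive_state(sys$species)
      expect_equal(sys$deriv(x),
                   brute_deriv(tab, sys$K, x,
                               sys$species[sys$chemostats]),
                   tolerance = 1e-12)
    }
  }
})

test_that("the derived ODEs carry the polynomial mass-action structure", {
  ## dxS/dt = -kappa1 KE KS xE xS + kappa1 KC xC, term by term
  K <- c(E = 2, C = 3, S = 1, P = 0.5); kap <- c(r1 = 1.5, r2 = 0.7)
  sys <- assemble_odes(enzyme_model(K, kap))
  x <- c(E = 0.4, C = 0.9, S = 1.7, P = 0.2)
  dx <- sys$deriv(x)
  t1 <- kap[["r1"]] * K[["E"]] * K[["S"]] * x[["E"]] * x[["S"]]
  t2 <- kap[["r1"]] * K[["C"]] * x[["C"]]
  t3 <- kap[["r2"]] * K[["C"]] * x[["C"]]
  t4 <- kap[["r2"]] * K[["E"]] * K[["P"]] * x[["E"]] * x[["P"]]
  expect_equal(dx[["S"]], -t1 + t2)
  expect_equal(dx[["P"]], t3 - t4)
  expect_equal(dx[["E"]], -t1 + t2 + t3 - t4)
  expect_equal(dx[["C"]], t1 - t2 - t3 + t4)
})

test_that("chemostatting zeroes exactly the clamped rows", {
  model <- enzyme_model(chemostats = c("E", "C", "S", "P"))
  sys <- assemble_odes(model)
  x <- c(E = 0.3, C = 1.1, S = 0.8, P = 2)
  expect_identical(unname(sys$deriv(x)), rep(0, 4))
  sys2 <- assemble_odes(enzyme_model(), chemostats = c("S"))
  dx <- sys2$deriv(x)
  expect_identical(dx[["S"]], 0)
  expect_false(dx[["P"]] == 0)
  expect_error(assemble_odes(enzyme_model(), chemostats = "XX"), "unknown")
})

test_that("thermodynamic and kinetic formulations integrate to the same trajectories", {
  model <- enzyme_model()
  sys <- assemble_odes(model)
  kin <- thermo_to_kinetic(sys)
  tab <- reaction_table(model)
  f_kin <- function(t, y, p)
    list(kinetic_deriv(tab, kin$k_plus, kin$k_minus, y))
  times <- seq(0, 5, length.out = 51)
  tr <- simulate_bg(sys, t_end = 5, n_out = 51)
  ref <- deSolve::ode(sys$x0, times, f_kin, NULL, method = "lsoda",
                      rtol = 1e-10, atol = 1e-12)
  expect_equal(unname(tr$x), unname(ref[, -1]), tolerance = 1e-6)
})

test_that("conserved moieties span the expected totals", {
  in_span <- function(G, g) {
    ## is g in the rational column span of G?
    fit <- qr(G)
    resid <- g - G %*% qr.coef(fit, g)
    max(abs(resid)) < 1e-9
  }
  G <- conserved_moieties(enzyme_model())
  expect_equal(ncol(G), 2L)
  expect_true(in_span(G, c(1, 1, 0, 0)))        # E + C
  expect_true(in_span(G, c(0, 1, 1, 1)))        # S + C + P
  Gab <- conserved_moieties(bondgraph_model(reaction_network(
    species = c(A = 1, B = 1),
    reactions = list(r = rxn(c(A = 1), c(B = 1), mass_action(1))))))
  expect_identical(unname(Gab), matrix(c(1, 1), 2, 1))  # A + B
  ## MAPK phosphorylation cycle: one moiety per substrate and per enzyme
  Gc <- conserved_moieties(mapk_cascade())
  sub <- match(c("MAPK", "MAPKP", "MAPKPP",
                 "L3a.kinase.C", "L3b.kinase.C",
                 "L3a.phosphatase.C", "L3b.phosphatase.C"), rownames(Gc))
  g <- numeric(nrow(Gc)); g[sub] <- 1   # total MAPK across all forms
  expect_true(in_span(Gc, g))
})

test_that("pathway extraction handles chains and reports higher-dimensional null spaces", {
  chain <- chain_model(chemostats = c("A", "C"))
  expect_identical(steady_state_pathway(chain), c(r1 = 1L, r2 = 1L))
  ## branched network with a 2-dimensional internal null space
  branched <- bondgraph_model(reaction_network(
    species = c(A = 1, B = 1, C = 1, D = 1),
    reactions = list(
      r1 = rxn(c(A = 1), c(B = 1), mass_action(1)),
      r2 = rxn(c(B = 1), c(C = 1), mass_action(1)),
      r3 = rxn(c(B = 1), c(D = 1), mass_action(1)))),
    chemostats = c("A", "C", "D"))
  expect_error(steady_state_pathway(branched), "dimension 2")
})

test_that("closed mass-action models are exactly at detailed balance at x = 1/K", {
  set.seed(31)
  for (seed in 1:5) {
    model <- generate_fixture(seed, n_species = 5,
                              shape = sample(c("chain", "cycle", "random"), 1))
    sys <- assemble_odes(model)
    xeq <- 1 / sys$K
    ## exact up to one ulp in K * (1/K); the flux form itself is exact at
    ## K x = 1
    kap <- vapply(sys$laws, function(l) l$params$kappa, 0)
    expect_lt(max(abs(sys$v(xeq)) / kap), 1e-14)
    expect_lt(max(abs(sys$deriv(xeq))) / max(kap), 1e-13)
    aff <- reaction_affinities(sys, xeq)
    expect_lt(max(abs(aff$A)), 1e-10)
    ## and where K * x is exactly representable the zero is exact
    sys1 <- assemble_odes(enzyme_model(K = c(E = 2, C = 4, S = 1, P = 0.5)))
    expect_identical(unname(sys1$v(1 / sys1$K)), c(0, 0))
  }
})
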