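test_that("thermo_to_kinetic follows the parameter redefinition", {
  ## all K = kappa = 1 -> all rate constants 1
  m1 <- enzyme_model(K = c(E = 1, C = 1, S = 1, P = 1),
                     kappa = c(r1 = 1, r2 = 1))
  kin1 <- thermo_to_kinetic(assemble_odes(m1))
  expect_equal(kin1$k_plus, c(1, 1))
  expect_equal(kin1$k_minus, c(1, 1))
  ## kappa1 = 2, KE = 3, KS = 5 -> k1+ = 30
  m2 <- enzyme_model(K = c(E = 3, C = 7, S = 5, P = 2),
                     kappa = c(r1 = 2, r2 = 11))
  kin2 <- thermo_to_kinetic(assemble_odes(m2))
  expect_equal(kin2$k_plus[1], 2 * 3 * 5)
  expect_equal(kin2$k_minus[1], 2 * 7)
  ## k1+ k2+ / (k1- k2-) = KS / KP independent of the kappas and KE, KC
  keq <- with(kin2, k_plus[1] * k_plus[2] / (k_minus[1] * k_minus[2]))
  expect_equal(keq, 5 / 2)
})

test_that("kinetic_to_thermo inverts thermo_to_kinetic under a fixed gauge", {
  K <- c(E = 2, C = 3, S = 1.2, P = 0.5)
  model <- enzyme_model(K = K, kappa = c(r1 = 1.5, r2 = 0.7))
  sys <- assemble_odes(model)
  kin <- thermo_to_kinetic(sys)
  ## pin the same gauge as the original parameters: two moieties -> two pins
  tp <- kinetic_to_thermo(kin$k_plus, kin$k_minus, sys,
                          gauge = c(E = 2, S = 1.2))
  expect_equal(tp$K, K[names(tp$K)], tolerance = 1e-10)
  expect_equal(unname(tp$kappa), c(1.5, 0.7), tolerance = 1e-10)
  ## round trip through the forward map is exact regardless of gauge
  tp2 <- kinetic_to_thermo(kin$k_plus, kin$k_minus, sys)
  m2 <- enzyme_model(K = tp2$K[c("E", "C", "S", "P")],
                     kappa = tp2$kappa)
  kin2 <- thermo_to_kinetic(assemble_odes(m2))
  expect_equal(kin2$k_plus, kin$k_plus, tolerance = 1e-10)
  expect_equal(kin2$k_minus, kin$k_minus, tolerance = 1e-10)
})

test_that("Wegscheider-violating kinetics are rejected with the offending cycle", {
  tri <- bondgraph_model(reaction_network(
    species = c(A = 1, B = 1, C = 1),
    reactions = list(
      r1 = rxn(c(A = 1), c(B = 1), mass_action(1)),
      r2 = rxn(c(B = 1), c(C = 1), mass_action(1)),
      r3 = rxn(c(C = 1), c(A = 1), mass_action(1)))))
  sys <- assemble_odes(tri)
  expect_error(kinetic_to_thermo(c(1, 1, 1), c(1, 1, 2), sys),
               "detailed balance")
  expect_error(kinetic_to_thermo(c(1, 1, 1), c(1, 1, 2), sys), "0\\.5")
  ## the consistent assignment passes
  tp <- kinetic_to_thermo(c(1, 1, 1), c(1, 1, 1), sys)
  expect_equal(unname(tp$K), rep(1, 3))
})

test_that("any rate-constant set is feasible for the acyclic enzyme motif", {
  sys <- assemble_odes(enzyme_model())
  set.seed(41)
  for (i in 1:20) {
    kp <- 10^stats::runif(2, -2, 2); km <- 10^stats::runif(2, -2, 2)
    tp <- kinetic_to_thermo(kp, km, sys)
    m <- enzyme_model(K = tp$K[c("E", "C", "S", "P")], kappa = tp$kappa)
    kin <- thermo_to_kinetic(assemble_odes(m))
    expect_equal(kin$k_plus, kp, tolerance = 1e-9)
    expect_equal(kin$k_minus, km, tolerance = 1e-9)
  }
})

test_that("thermo-parameterised fixtures always satisfy detailed balance", {
  for (seed in 1:25) {
    model <- generate_fixture(seed, n_species = 4 + seed %% 3,
                              shape = c("chain", "cycle", "random")[1 + seed %% 3])
    sys <- assemble_odes(model)
    kin <- thermo_to_kinetic(sys)
    expect_silent(kinetic_to_thermo(kin$k_plus, kin$k_minus, sys))
  }
})

test_that("reaction affinities recover potential differences", {
  sys <- assemble_odes(enzyme_model())
  xeq <- 1 / sys$K
  expect_equal(reaction_affinities(sys, xeq)$A, c(0, 0))
  ## A <-> B with KA xA = 2 KB xB gives A = RT log 2
  ab <- bondgraph_model(reaction_network(
    species = c(A = 3, B = 5),
    reactions = list(r = rxn(c(A = 1), c(B = 1), mass_action(1)))))
  sab <- assemble_odes(ab)
  x <- c(A = 2 / 3, B = 1 / 5)   # KA xA = 2, KB xB = 1
  aff <- reaction_affinities(sab, x, units = "kJ")
  expect_equal(aff$A, sab$RT * log(2) / 1000, tolerance = 1e-10)
  expect_equal(aff$A, 1.787, tolerance = 2e-3)
  expect_error(reaction_affinities(sab, c(A = 0, B = 1)), "positive")
})

test_that("the two total-affinity computations agree at steady state", {
  model <- chain_model(K = c(A = 1, B = 2, C = 4),
                       kappa = c(r1 = 1.3, r2 = 0.8),
                       chemostats = c("A", "C"))
  sys <- assemble_odes(model)
  ss <- find_steady_state(sys, c(A = 2, B = 1, C = 0.1))
  pe <- pathway_energetics(sys, ss$x)
  expect_equal(pe$A_total_kJ, pe$A_total_from_potentials_kJ,
               tolerance = 1e-9)
  expect_equal(unname(pe$overall), c(-1, 1))   # A <=> C
  ## zero pathway vector -> zero overall reaction and zero total
  pe0 <- pathway_energetics(sys, ss$x, pathway = c(0L, 0L))
  expect_length(pe0$overall, 0L)
  expect_identical(pe0$A_total_kJ, 0)
  ## off-steady states are refused
  expect_error(pathway_energetics(sys, c(A = 2, B = 10, C = 0.1)),
               "not at steady state")
})

test_that("dissipation is non-negative everywhere and zero only at equilibrium", {
  set.seed(51)
  for (seed in 1:5) {
    sys <- assemble_odes(generate_fixture(seed, n_species = 5, shape = "random"))
    for (i in 1:200) {
      x <- random_positive_state(sys$species, scale = 1 / sys$K)
      expect_gte(dissipation(sys, x), 0)
    }
    expect_equal(dissipation(sys, 1 / sys$K), 0)
  }
  ## single reaction: A v > 0 whenever off equilibrium
  sab <- assemble_odes(bondgraph_model(reaction_network(
    species = c(A = 1, B = 1),
    reactions = list(r = rxn(c(A = 1), c(B = 1), mass_action(2))))))
  expect_gt(dissipation(sab, c(A = 2, B = 1)), 0)
})
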