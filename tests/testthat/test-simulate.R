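test_that("a closed two-state system relaxes mono-exponentially at rate k+ + k-", {
  K <- c(A = 2, B = 0.5); kappa <- 0.8
  model <- bondgraph_model(reaction_network(
    species = K,
    reactions = list(r = rxn(c(A = 1), c(B = 1), mass_action(kappa)))),
    x0 = c(A = 1, B = 0.2))
  sys <- assemble_odes(model)
  kp <- kappa * K[["A"]]; km <- kappa * K[["B"]]
  tr <- simulate_bg(sys, t_end = 3, n_out = 61)
  tot <- 1.2
  a_inf <- km * tot / (kp + km)
  analytic <- a_inf + (1 - a_inf) * exp(-(kp + km) * tr$times)
  expect_equal(unname(tr$x[, "A"]), unname(analytic), tolerance = 1e-7)
})

test_that("an equilibrium initial state yields a constant trajectory", {
  sys <- assemble_odes(enzyme_model(K = c(E = 2, C = 4, S = 1, P = 0.5)))
  tr <- simulate_bg(sys, 1 / sys$K, t_end = 10, n_out = 11)
  for (j in seq_along(sys$species))
    expect_equal(unname(tr$x[, j]), rep(1 / sys$K[[j]], 11), tolerance = 1e-10)
})

test_that("steady states of chemostatted linear chains match the linear-algebra oracle", {
  K <- c(A = 1, B = 2, C = 4); kappa <- c(r1 = 1.3, r2 = 0.8)
  model <- chain_model(K, kappa, chemostats = c("A", "C"),
                       x0 = c(A = 2, B = 0.3, C = 0.1))
  sys <- assemble_odes(model)
  ss <- find_steady_state(sys)
  ## dB/dt = k1+ A - k1- B - k2+ B + k2- C = 0, solved directly
  kin <- thermo_to_kinetic(sys)
  xB <- (kin$k_plus[1] * 2 + kin$k_minus[2] * 0.1) /
        (kin$k_minus[1] + kin$k_plus[2])
  expect_equal(ss$x[["B"]], xB, tolerance = 1e-8)
  expect_equal(ss$x[["A"]], 2)   # chemostats stay clamped
  ## already-steady input returns itself
  ss2 <- find_steady_state(sys, ss$x)
  expect_equal(ss2$x, ss$x, tolerance = 1e-10)
  ## fixed point: integrating from the steady state goes nowhere
  tr <- simulate_bg(sys, ss$x, t_end = 100, n_out = 5)
  expect_lt(max(abs(tr$x[5, ] - ss$x)), 1e-8 * max(ss$x))
})

test_that("closed-model steady states satisfy detailed balance", {
  model <- enzyme_model()
  sys <- assemble_odes(model)
  ss <- find_steady_state(sys)
  aff <- reaction_affinities(sys, ss$x)
  expect_equal(aff$A, c(0, 0), tolerance = 1e-8)
  expect_lt(dissipation(sys, ss$x), 1e-12)
})

test_that("moieties are conserved along trajectories", {
  set.seed(61)
  for (seed in 1:4) {
    ## chains and cycles always conserve total mass
    model <- generate_fixture(seed, n_species = 5,
                              shape = c("chain", "cycle")[1 + seed %% 2])
    sys <- assemble_odes(model)
    G <- conserved_moieties(sys)
    expect_gte(ncol(G), 1L)
    tr <- simulate_bg(sys, t_end = 20, n_out = 31)
    tot <- tr$x %*% G
    drift <- apply(tot, 2, function(g) max(abs(g - g[1])) / max(abs(g[1]), 1e-12))
    expect_lt(max(drift), 1e-6)
  }
})

test_that("the response-time criterion matches its closed form and is scale invariant", {
  tau <- 0.7
  t <- seq(0, 10, length.out = 2001)
  d <- exp(-t / tau)
  expect_equal(response_time(t, d), tau * log(20), tolerance = 1e-4)
  expect_equal(response_time(t, 1e6 * d), response_time(t, d))
  ## non-monotone deviation: the LAST 5% crossing counts
  d2 <- pmax(exp(-t), 0.3 * exp(-(t - 4)^2))
  expect_gt(response_time(t, d2), 4)
  expect_equal(response_time(t, numeric(2001)), 0)
})

test_that("internal perturbations relax back to the reference steady state", {
  model <- chain_model(K = c(A = 1, B = 2, C = 4),
                       kappa = c(r1 = 1.3, r2 = 0.8),
                       chemostats = c("A", "C"),
                       x0 = c(A = 2, B = 0.3, C = 0.1))
  sys <- assemble_odes(model)
  ss <- find_steady_state(sys)
  pr <- perturb_internal(sys, ss, "B", factor = 1.3)
  expect_gt(pr$response_time, 0)
  final <- pr$traj$x[nrow(pr$traj$x), ]
  expect_lt(max(abs(final - ss$x)), 1e-6 * max(ss$x))
  ## unit factor leaves the system in place
  pr0 <- perturb_internal(sys, ss, "B", factor = 1)
  expect_equal(max(pr0$d), 0)
  expect_equal(pr0$response_time, 0)
  ## linear-system relaxation rate: d(t) ~ exp(-(k1- + k2+) t)
  kin <- thermo_to_kinetic(sys)
  rate <- kin$k_minus[1] + kin$k_plus[2]
  expect_equal(pr$response_time, log(20) / rate, tolerance = 1e-3)
  expect_error(perturb_internal(sys, ss, "A"), "chemostat")
  expect_error(perturb_internal(sys, ss, "ZZ"), "unknown species")
})

test_that("chemostat perturbations settle to the analytic new steady state", {
  K <- c(A = 1, B = 2, C = 4); kappa <- c(r1 = 1.3, r2 = 0.8)
  model <- chain_model(K, kappa, chemostats = c("A", "C"),
                       x0 = c(A = 2, B = 0.3, C = 0.1))
  sys <- assemble_odes(model)
  ss <- find_steady_state(sys)
  pr <- perturb_chemostat(sys, ss, "A", factor = 1.3)
  kin <- thermo_to_kinetic(sys)
  xB_new <- (kin$k_plus[1] * 2.6 + kin$k_minus[2] * 0.1) /
            (kin$k_minus[1] + kin$k_plus[2])
  expect_equal(pr$new_steady_state$x[["B"]], xB_new, tolerance = 1e-8)
  expect_equal(pr$steady_state_deviation, abs(xB_new - ss$x[["B"]]),
               tolerance = 1e-6)
  pr0 <- perturb_chemostat(sys, ss, "A", factor = 1)
  expect_equal(pr0$steady_state_deviation, 0, tolerance = 1e-9)
  expect_error(perturb_chemostat(sys, ss, "B"), "internal")
})

test_that("signal-response curves are flat for input-independent systems", {
  model <- chain_model(chemostats = c("A", "C"),
                       x0 = c(A = 1, B = 0.5, C = 1))
  sys <- assemble_odes(model)
  ## the "input" scales a species the output does not depend on at steady
  ## state (chemostats fix the boundary): vary B's start only
  curve <- signal_response_curve(sys, c(0.1, 0.5, 1, 2),
                                 function(u) { x <- sys$x0; x["B"] <- u; x },
                                 outputs = "B")
  expect_equal(diff(range(curve$B)), 0, tolerance = 1e-8)
})
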