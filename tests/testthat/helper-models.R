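## Shared fixtures, all built in code.

## The classic two-step enzyme motif E + S <-> C <-> E + P.
enzyme_model <- function(K = c(E = 2, C = 3, S = 1, P = 0.5),
                         kappa = c(r1 = 1.5, r2 = 0.7),
                         x0 = c(E = 1, C = 0.1, S = 2, P = 0.2),
                         chemostats = character()) {
  root <- reaction_network(
    species = K,
    reactions = list(
      r1 = rxn(c(E = 1, S = 1), c(C = 1), mass_action(kappa[["r1"]])),
      r2 = rxn(c(C = 1), c(E = 1, P = 1), mass_action(kappa[["r2"]]))))
  bondgraph_model(root, chemostats = chemostats, x0 = x0)
}

## Linear chain A <-> B <-> C.
chain_model <- function(K = c(A = 1, B = 1, C = 1),
                        kappa = c(r1 = 1, r2 = 1),
                        x0 = c(A = 2, B = 1, C = 0.5),
                        chemostats = character()) {
  root <- reaction_network(
    species = K,
    reactions = list(
      r1 = rxn(c(A = 1), c(B = 1), mass_action(kappa[["r1"]])),
      r2 = rxn(c(B = 1), c(C = 1), mass_action(kappa[["r2"]]))))
  bondgraph_model(root, chemostats = chemostats, x0 = x0)
}

## Independent mass-action derivative oracle: sums Marcelin-de Donder
## fluxes species by species straight from a reaction table, with no use
## of the bond-graph machinery.
brute_deriv <- function(reactions, K, x, chemostats = character()) {
  dx <- stats::setNames(numeric(length(x)), names(x))
  for (r in reactions) {
    a <- prod((K * x)[rep(names(r$from), r$from)])
    b <- prod((K * x)[rep(names(r$to), r$to)])
    v <- r$kappa * (a - b)
    for (s in names(r$from)) dx[s] <- dx[s] - r$from[[s]] * v
    for (s in names(r$to)) dx[s] <- dx[s] + r$to[[s]] * v
  }
  dx[chemostats] <- 0
  dx
}

## Kinetic-formulation derivative oracle from forward/reverse rate
## constants (no thermodynamic parameters involved).
kinetic_deriv <- function(reactions, kp, km, x, chemostats = character()) {
  dx <- stats::setNames(numeric(length(x)), names(x))
  for (j in seq_along(reactions)) {
    r <- reactions[[j]]
    v <- kp[j] * prod(x[rep(names(r$from), r$from)]) -
         km[j] * prod(x[rep(names(r$to), r$to)])
    for (s in names(r$from)) dx[s] <- dx[s] - r$from[[s]] * v
    for (s in names(r$to)) dx[s] <- dx[s] + r$to[[s]] * v
  }
  dx[chemostats] <- 0
  dx
}

## Reaction table of a model's flat network, for feeding the oracles.
reaction_table <- function(model) {
  st <- build_stoichiometry(model)
  lapply(seq_along(st$reactions), function(j) {
    f <- table(st$species[st$sites_f[[j]]])
    r <- table(st$species[st$sites_r[[j]]])
    list(from = stats::setNames(as.integer(f), names(f)),
         to = stats::setNames(as.integer(r), names(r)),
         kappa = st$laws[[j]]$params$kappa)
  })
}

random_positive_state <- function(species, scale = 1) {
  stats::setNames(scale * 10^stats::runif(length(species), -1, 1), species)
}
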