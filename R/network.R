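#' Build a bond-graph module from a reaction list
#'
#' Convenience constructor that wires species, reaction and junction
#' components into the stereotyped biochemical bond-graph pattern: every
#' species gets a common-potential (0) junction `J_<name>`; every reaction
#' side with more than one binding site gets a common-flow (1) junction
#' summing the affinities.  The result is an ordinary [bg_module()] that
#' can be composed, exposed and flattened like any hand-built module.
#'
#' @param species named numeric vector of thermodynamic constants `K`
#'   (use `NA` to leave unbound).
#' @param reactions named list of reaction specs created with [rxn()].
#' @param expose character vector of species names whose junctions should
#'   be exposed (label = species name) for external wiring.
#' @param name module name.
#' @return a `bg_module`.
#' @examples
#' m <- reaction_network(
#'   species = c(A = 1, B = 2),
#'   reactions = list(r1 = rxn(c(A = 1), c(B = 1), mass_action(1))))
#' @export
reaction_network <- function(species, reactions, expose = character(),
                             name = "network") {
  mod <- bg_module(name)
  for (s in names(species)) {
    mod <- bg_add(mod, bg_species(K = species[[s]]), s)
    mod <- bg_add(mod, bg_junction("0"), paste0("J_", s))
    mod <- bg_connect(mod, s, paste0("J_", s))
  }
  for (rn in names(reactions)) {
    rx <- reactions[[rn]]
    stopifnot(inherits(rx, "bg_rxn"))
    missing <- setdiff(c(names(rx$from), names(rx$to)), names(species))
    if (length(missing))
      stop(sprintf("reaction '%s' references unknown species: %s",
                   rn, paste(missing, collapse = ", ")))
    mod <- bg_add(mod, bg_reaction(rx$law), rn)
    mod <- wire_side(mod, rn, rx$from, side = "f")
    mod <- wire_side(mod, rn, rx$to, side = "r")
  }
  for (s in expose) mod <- bg_expose(mod, s, paste0("J_", s))
  mod
}

wire_side <- function(mod, rn, stoich, side) {
  nsites <- sum(stoich)
  port <- paste0(rn, ":", side)
  if (nsites == 1) {
    j <- paste0("J_", names(stoich))
    if (side == "f") mod <- bg_connect(mod, j, port)
    else             mod <- bg_connect(mod, port, j)
    return(mod)
  }
  v <- paste0("V_", rn, "_", side)
  mod <- bg_add(mod, bg_junction("1"), v)
  if (side == "f") mod <- bg_connect(mod, v, port)
  else             mod <- bg_connect(mod, port, v)
  for (s in names(stoich)) {
    for (k in seq_len(stoich[[s]])) {
      j <- paste0("J_", s)
      if (side == "f") mod <- bg_connect(mod, j, v)
      else             mod <- bg_connect(mod, v, j)
    }
  }
  mod
}

#' @rdname reaction_network
#' @param from,to named integer vectors of reactant/product stoichiometries.
#' @param law a rate law ([mass_action()], [michaelis_menten()] or
#'   [generalised_kinetics()]).
#' @export
rxn <- function(from, to, law) {
  stopifnot(inherits(law, "bg_rate_law"),
            all(from == as.integer(from)), all(from > 0),
            all(to == as.integer(to)), all(to > 0))
  structure(list(from = from, to = to, law = law), class = "bg_rxn")
}
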