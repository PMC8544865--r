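#' Gas constant (J/K/mol)
#' @export
GAS_CONSTANT <- 8.314

#' Chemical potential of a species
#'
#' \eqn{\mu = RT \log(K x)}: the per-mole free energy of a species with
#' thermodynamic constant `K` at amount/concentration `x`, at thermal
#' energy `RT` (J/mol).  Strictly increasing in `x`; undefined at
#' \eqn{x \le 0} (flux evaluation inside ODE systems works in amount space
#' precisely so that zero states never require a potential).
#'
#' @param K thermodynamic constant (> 0).
#' @param x amount or concentration (> 0).
#' @param RT thermal energy in J/mol, e.g. `GAS_CONSTANT * 310.15`.
#' @return chemical potential in J/mol.
#' @export
chemical_potential <- function(K, x, RT = GAS_CONSTANT * 310.15) {
  stopifnot(all(K > 0), RT > 0)
  if (any(x <= 0)) stop("chemical potential undefined at x <= 0")
  RT * log(K * x)
}

#' Thermodynamic constant from a standard potential
#'
#' \eqn{K = \exp(\mu^0/RT) / (c^0 V)}: converts a standard chemical
#' potential \eqn{\mu^0} (J/mol, referenced to concentration `c0`) and a
#' compartment volume `V` into the thermodynamic constant `K` used by
#' [chemical_potential()].
#'
#' @param mu0 standard chemical potential (J/mol).
#' @param RT thermal energy (J/mol).
#' @param V compartment volume (L), default 1.
#' @param c0 reference concentration (M), default 1.
#' @return K.
#' @export
species_K <- function(mu0, RT = GAS_CONSTANT * 310.15, V = 1, c0 = 1) {
  stopifnot(RT > 0, V > 0, c0 > 0)
  exp(mu0 / RT) / (c0 * V)
}

#' Rate-law fluxes from affinities and potentials
#'
#' Direct evaluation of the three rate laws in potential space.
#' `flux_mass_action()` is the Marcelin–de Donder flux
#' \eqn{v = \kappa(e^{A^f/RT} - e^{A^r/RT})};
#' `flux_michaelis_menten()` is the reversible Michaelis–Menten flux for a
#' single substrate/product pair; `flux_generalised_kinetics()` is the
#' generalised (convenience-style) kinetics for arbitrary site sets, which
#' reduces exactly to the Michaelis–Menten form when each side has one
#' site.  All three vanish iff \eqn{A^f = A^r} and dissipate non-negative
#' power \eqn{(A^f - A^r) v \ge 0}.
#'
#' @param law a rate law object of the matching type.
#' @param Af,Ar forward/reverse affinity (J/mol).
#' @param muS,muP substrate/product chemical potential (J/mol).
#' @param mu_f,mu_r numeric vectors of per-site chemical potentials on the
#'   forward and reverse side (a species with stoichiometry n appears n
#'   times).
#' @param RT thermal energy (J/mol).
#' @return flux (same units as `kappa`, mol/s or M/s).
#' @export
flux_mass_action <- function(law, Af, Ar, RT = GAS_CONSTANT * 310.15) {
  stopifnot(law$type == "MA")
  law$params$kappa * (exp(Af / RT) - exp(Ar / RT))
}

#' @rdname flux_mass_action
#' @export
flux_michaelis_menten <- function(law, muS, muP, RT = GAS_CONSTANT * 310.15) {
  stopifnot(law$type == "MM")
  p <- law$params
  a <- exp(muS / RT); b <- exp(muP / RT)
  p$kappa_bar * p$e0 * (a - b) / (1 + a / p$Rb0 + b / p$Rb1)
}

#' @rdname flux_mass_action
#' @export
flux_generalised_kinetics <- function(law, mu_f, mu_r, RT = GAS_CONSTANT * 310.15) {
  stopifnot(law$type == "GK")
  p <- law$params
  if (length(p$Rb_f) != length(mu_f) || length(p$Rb_r) != length(mu_r))
    stop(sprintf("binding-site mismatch: law has %d+%d sites, got %d+%d potentials",
                 length(p$Rb_f), length(p$Rb_r), length(mu_f), length(mu_r)))
  af <- exp(mu_f / RT); ar <- exp(mu_r / RT)
  num <- prod(af) - prod(ar)
  den <- -1 + prod(1 + af / p$Rb_f) + prod(1 + ar / p$Rb_r)
  p$kappa_bar * p$e0 * num / den
}

## ---- amount-space flux evaluation (internal) ------------------------------
##
## exp(mu/RT) = K*x, so fluxes are evaluated from products of K*x without
## taking logs: x = 0 is regular and the derived ODEs are polynomial (for
## mass action) in x.

## One reaction's flux given the vector kx = K * x.
eval_flux <- function(law, kx, sf, sr) {
  a <- prod(kx[sf]); b <- prod(kx[sr])
  if (law$type == "MA") {
    law$params$kappa * (a - b)
  } else if (law$type == "MM") {
    p <- law$params
    p$kappa_bar * p$e0 * (a - b) / (1 + a / p$Rb0 + b / p$Rb1)
  } else {
    p <- law$params
    den <- -1 + prod(1 + kx[sf] / p$Rb_f) + prod(1 + kx[sr] / p$Rb_r)
    p$kappa_bar * p$e0 * (a - b) / den
  }
}

## Flux vector for all reactions of a stoichiometry list.
eval_fluxes <- function(st, x) {
  kx <- st$K * x
  vapply(seq_along(st$reactions), function(j)
    eval_flux(st$laws[[j]], kx, st$sites_f[[j]], st$sites_r[[j]]), 0)
}
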