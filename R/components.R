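#' Bond-graph leaf components
#'
#' A biochemical bond graph is built from three kinds of leaf component:
#' \emph{species} (energy-storing, with chemical potential
#' \eqn{\mu = RT \log(K x)}), \emph{reactions} (power-dissipating, with a
#' thermodynamically consistent rate law relating flux to the forward and
#' reverse affinities carried on their two ports), and \emph{junctions}
#' (power-conserving connection points).  A `"0"` junction imposes a common
#' chemical potential on all attached bonds and conserves molar flow
#' (mass balance, Kirchhoff-current analogue); a `"1"` junction imposes a
#' common flow and conserves potential (affinity summation,
#' Kirchhoff-voltage analogue).
#'
#' Species carry a single port `"p"`.  Reactions carry a forward port `"f"`
#' (receiving the forward affinity \eqn{A^f}) and a reverse port `"r"`
#' (delivering the reverse affinity \eqn{A^r}).  Junction ports are
#' allocated automatically as bonds are attached.
#'
#' @param K thermodynamic constant of the species (units 1/M when state is
#'   stored as concentration).  `NA` leaves the parameter unbound; it must
#'   then be bound before flattening.
#' @param law a rate-law object created by [mass_action()],
#'   [michaelis_menten()] or [generalised_kinetics()].
#' @param kind junction kind, `"0"` (common potential) or `"1"`
#'   (common flow).
#' @return a `bg_component` object.
#' @seealso [bg_module()], [mass_action()]
#' @export
bg_species <- function(K = NA_real_) {
  if (!is.na(K) && K <= 0) stop("species K must be positive")
  structure(list(kind = "species", params = list(K = as.numeric(K))),
            class = "bg_component")
}

#' @rdname bg_species
#' @export
bg_reaction <- function(law) {
  if (!inherits(law, "bg_rate_law")) stop("'law' must be a bg_rate_law")
  structure(list(kind = "reaction", law = law), class = "bg_component")
}

#' @rdname bg_species
#' @export
bg_junction <- function(kind = c("0", "1")) {
  kind <- match.arg(kind)
  structure(list(kind = "junction", jkind = kind), class = "bg_component")
}

#' @export
print.bg_component <- function(x, ...) {
  if (x$kind == "species") {
    cat(sprintf("<species: K = %s>\n", format(x$params$K)))
  } else if (x$kind == "reaction") {
    cat(sprintf("<reaction: %s law>\n", x$law$type))
  } else {
    cat(sprintf("<%s-junction>\n", x$jkind))
  }
  invisible(x)
}

#' Thermodynamically consistent rate laws
#'
#' Constructors for the three interchangeable reaction rate laws.  All three
#' are expressed in terms of the forward and reverse affinities
#' \eqn{A^f, A^r} (sums of reactant/product chemical potentials) and share
#' the consistency property that the flux is zero exactly when
#' \eqn{A^f = A^r}, and has the sign of \eqn{A^f - A^r} otherwise.
#'
#' \describe{
#' \item{mass action (Marcelin–de Donder)}{\eqn{v = \kappa(e^{A^f/RT} -
#'   e^{A^r/RT})}.  With \eqn{\mu = RT\log(Kx)} this reduces to ordinary
#'   reversible mass-action kinetics with \eqn{k^+ = \kappa \prod K_s},
#'   \eqn{k^- = \kappa \prod K_p}.}
#' \item{reversible Michaelis–Menten}{\eqn{v = \bar\kappa e_0 (e^{\mu_S/RT}
#'   - e^{\mu_P/RT}) / (1 + e^{\mu_S/RT}/R_{b0} + e^{\mu_P/RT}/R_{b1})}
#'   for a single (possibly lumped) substrate and product.}
#' \item{generalised kinetics}{\eqn{v = \bar\kappa e_0 (e^{A^f/RT} -
#'   e^{A^r/RT}) / (-1 + \prod_{s\in S}(1 + e^{\mu_s/RT}/R_{b,s}) +
#'   \prod_{p\in P}(1 + e^{\mu_p/RT}/R_{b,p}))}, with one binding constant
#'   per binding \emph{site}: a species entering with stoichiometry n
#'   contributes n sites, each with its own \eqn{R_{b,z}}.  For one
#'   substrate and one product this is algebraically identical to the
#'   reversible Michaelis–Menten law, and for unit stoichiometries it is
#'   convenience kinetics.}
#' }
#'
#' @param kappa mass-action rate constant (flux units).
#' @param kappa_bar turnover-style rate constant (1/s).
#' @param e0 total enzyme amount/concentration.
#' @param Rb0,Rb1 dimensionless binding constants of substrate and product.
#' @param Rb_f,Rb_r numeric vectors of per-site binding constants for the
#'   forward (reactant) and reverse (product) sides; lengths must match the
#'   site counts of the reaction the law is attached to.
#' @return a `bg_rate_law` object.
#' @export
mass_action <- function(kappa = NA_real_) {
  chk_nonneg(kappa, "kappa")   # 0 switches the reaction off
  structure(list(type = "MA", params = list(kappa = as.numeric(kappa))),
            class = "bg_rate_law")
}

#' @rdname mass_action
#' @export
michaelis_menten <- function(kappa_bar = NA_real_, e0 = NA_real_,
                             Rb0 = NA_real_, Rb1 = NA_real_) {
  for (nm in c("kappa_bar", "Rb0", "Rb1")) chk_pos(get(nm), nm)
  chk_nonneg(e0, "e0")         # e0 = 0 switches the enzyme off
  structure(list(type = "MM",
                 params = list(kappa_bar = as.numeric(kappa_bar),
                               e0 = as.numeric(e0),
                               Rb0 = as.numeric(Rb0), Rb1 = as.numeric(Rb1))),
            class = "bg_rate_law")
}

#' @rdname mass_action
#' @export
generalised_kinetics <- function(kappa_bar = NA_real_, e0 = NA_real_,
                                 Rb_f = NA_real_, Rb_r = NA_real_) {
  chk_pos(kappa_bar, "kappa_bar"); chk_nonneg(e0, "e0")
  if (any(!is.na(Rb_f) & Rb_f <= 0) || any(!is.na(Rb_r) & Rb_r <= 0))
    stop("binding constants must be positive")
  structure(list(type = "GK",
                 params = list(kappa_bar = as.numeric(kappa_bar),
                               e0 = as.numeric(e0),
                               Rb_f = as.numeric(Rb_f),
                               Rb_r = as.numeric(Rb_r))),
            class = "bg_rate_law")
}

chk_pos <- function(x, nm) {
  if (length(x) == 1 && !is.na(x) && x <= 0)
    stop(sprintf("'%s' must be positive", nm))
  invisible(TRUE)
}

chk_nonneg <- function(x, nm) {
  if (length(x) == 1 && !is.na(x) && x < 0)
    stop(sprintf("'%s' must be non-negative", nm))
  invisible(TRUE)
}
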