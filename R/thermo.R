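#' Convert thermodynamic parameters to kinetic rate constants
#'
#' For mass-action reactions, the thermodynamic parameterisation
#' \eqn{(K_s, \kappa_j)} maps onto ordinary forward/reverse rate constants
#' as \eqn{k^+_j = \kappa_j \prod_{s \in f(j)} K_s} and
#' \eqn{k^-_j = \kappa_j \prod_{p \in r(j)} K_p} (products over binding
#' sites, so stoichiometry n contributes \eqn{K^n}).  Kinetics produced
#' this way satisfy detailed balance by construction: around any reaction
#' cycle the equilibrium-constant product is exactly one.
#'
#' @param sys an [assemble_odes()] system (or stoichiometry list) whose
#'   reactions use the mass-action law.
#' @return data frame with columns `reaction`, `k_plus`, `k_minus`.
#' @seealso [kinetic_to_thermo()]
#' @export
thermo_to_kinetic <- function(sys) {
  st <- as_stoich(sys)
  types <- vapply(st$laws, function(l) l$type, "")
  if (any(types != "MA"))
    stop("thermo_to_kinetic applies to mass-action reactions only")
  kp <- km <- numeric(length(st$reactions))
  for (j in seq_along(st$reactions)) {
    kap <- st$laws[[j]]$params$kappa
    kp[j] <- kap * prod(st$K[st$sites_f[[j]]])
    km[j] <- kap * prod(st$K[st$sites_r[[j]]])
  }
  data.frame(reaction = st$reactions, k_plus = kp, k_minus = km,
             row.names = NULL)
}

#' Recover thermodynamic parameters from kinetic rate constants
#'
#' Inverts the map of [thermo_to_kinetic()].  The log-linear system
#' \eqn{\log(k^+_j/k^-_j) = -(N^T \log K)_j} is solvable exactly iff the
#' Wegscheider (detailed balance) conditions hold: for every reaction
#' cycle \eqn{c} with \eqn{N c = 0}, the product of equilibrium constants
#' \eqn{\prod_j (k^+_j/k^-_j)^{c_j}} equals one.  Violations are reported
#' with the offending cycle and its mismatch ratio.  The solution has one
#' gauge freedom per conserved moiety; these are fixed by pinning a
#' spanning set of species constants (default \eqn{K = 1}).
#'
#' @param k_plus,k_minus positive numeric vectors of rate constants, in
#'   reaction declaration order.
#' @param sys system or stoichiometry list defining the network.
#' @param gauge optional named numeric vector of species `K` values to pin
#'   (one per conserved moiety); by default an automatically chosen
#'   spanning set is pinned at 1.
#' @param tol detailed-balance tolerance on relative cycle-product
#'   deviation (default 1e-6).
#' @return list with named vectors `K` and `kappa`, reproducing
#'   `k_plus`/`k_minus` exactly under [thermo_to_kinetic()].
#' @export
kinetic_to_thermo <- function(k_plus, k_minus, sys, gauge = NULL, tol = 1e-6) {
  st <- as_stoich(sys)
  nr <- length(st$reactions); ns <- length(st$species)
  stopifnot(length(k_plus) == nr, length(k_minus) == nr,
            all(k_plus > 0), all(k_minus > 0))
  b <- log(k_plus / k_minus)          # = -(N^T log K)_j when consistent

  ## detailed-balance check over an exact cycle basis
  cycles <- null_basis_int(st$N)
  if (ncol(cycles)) {
    viol <- as.vector(t(cycles) %*% b)
    bad <- which(abs(exp(viol) - 1) > tol)
    if (length(bad)) {
      k <- bad[1]
      members <- which(cycles[, k] != 0)
      stop(sprintf(
        "detailed balance violated: cycle [%s] has equilibrium-constant product %.6g (should be 1)",
        paste(sprintf("%+d %s", cycles[members, k], st$reactions[members]),
              collapse = ", "),
        exp(viol[k])))
    }
  }

  ## least-squares solution of N^T logK = -b
  fit <- stats::lm.fit(t(st$N), -b)
  logK <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)

  ## gauge fixing: free directions are the left null space of N
  G <- null_basis_int(t(st$N))
  rownames(G) <- st$species
  if (ncol(G)) {
    if (is.null(gauge)) {
      pins <- vapply(seq_len(ncol(G)), function(k) {
        cand <- which(G[, k] != 0 &
                      apply(G[, -k, drop = FALSE] != 0, 1, sum) == 0)
        if (!length(cand)) stop("cannot choose a gauge pin automatically")
        cand[1]
      }, 0L)
      target <- rep(0, ncol(G))
    } else {
      pins <- match(names(gauge), st$species)
      if (anyNA(pins)) stop("gauge names must be species names")
      if (length(pins) != ncol(G))
        stop(sprintf("gauge must pin %d species (one per conserved moiety)", ncol(G)))
      target <- log(gauge)
    }
    A <- G[pins, , drop = FALSE]
    alpha <- solve(A, logK[pins] - target)
    logK <- logK - as.vector(G %*% alpha)
  }

  K <- stats::setNames(exp(logK), st$species)
  kappa <- vapply(seq_len(nr), function(j)
    k_plus[j] / prod(K[st$sites_f[[j]]]), 0)
  list(K = K, kappa = stats::setNames(kappa, st$reactions))
}

#' Reaction affinities at a state
#'
#' Computes, for every reaction, the forward affinity \eqn{A^f} (sum of
#' reactant chemical potentials over binding sites), the reverse affinity
#' \eqn{A^r}, and the net affinity \eqn{A = A^f - A^r}, the thermodynamic
#' driving force whose sign the flux follows.
#'
#' @param sys an [assemble_odes()] system.
#' @param x strictly positive state vector (named or in species order).
#' @param units `"J"` (J/mol, default) or `"kJ"` (kJ/mol).
#' @return data frame with columns `reaction`, `Af`, `Ar`, `A`.
#' @export
reaction_affinities <- function(sys, x, units = c("J", "kJ")) {
  units <- match.arg(units)
  st <- sys
  x <- full_state(st, x)
  if (any(x <= 0)) stop("affinities require a strictly positive state")
  RT <- if (!is.null(st$RT)) st$RT else GAS_CONSTANT * st$temperature
  mu <- RT * log(st$K * x)
  Af <- vapply(st$sites_f, function(s) sum(mu[s]), 0)
  Ar <- vapply(st$sites_r, function(s) sum(mu[s]), 0)
  scale <- if (units == "kJ") 1e-3 else 1
  data.frame(reaction = st$reactions, Af = Af * scale, Ar = Ar * scale,
             A = (Af - Ar) * scale, row.names = NULL)
}

full_state <- function(st, x) {
  if (!is.null(names(x))) {
    miss <- setdiff(st$species, names(x))
    if (length(miss))
      stop("state is missing species: ", paste(miss, collapse = ", "))
    x <- x[st$species]
  } else stopifnot(length(x) == length(st$species))
  stats::setNames(as.numeric(x), st$species)
}

#' Pathway energetics at steady state
#'
#' Combines a steady state with a pathway weighting \eqn{w} (by default
#' the unique internal null vector from [steady_state_pathway()]): the
#' overall reaction is \eqn{N w} restricted to the chemostatted species,
#' and the total pathway affinity is computed two independent ways —
#' from the chemostat potentials of the overall reaction, and as the
#' weighted sum \eqn{\sum_j w_j A_j} of member reaction affinities — which
#' must agree.
#'
#' @param sys an [assemble_odes()] system.
#' @param state steady state of the chemostatted system.
#' @param pathway optional integer reaction weights (default: computed).
#' @param steady_tol residual tolerance for accepting `state` as steady
#'   (relative, per species); set `Inf` to skip the check.
#' @return a `pathway_energetics` object: per-reaction table (`weight`,
#'   `A_kJ`), `overall` (named chemostat coefficients), `A_total_kJ`, and
#'   the cross-check `A_total_from_potentials_kJ`.
#' @export
pathway_energetics <- function(sys, state, pathway = NULL, steady_tol = 1e-6) {
  st <- sys
  x <- full_state(st, state)
  if (is.null(pathway)) pathway <- steady_state_pathway(st)
  stopifnot(length(pathway) == length(st$reactions))
  if (is.finite(steady_tol)) {
    dx <- as.vector(st$N %*% eval_fluxes(st, x))
    dx[st$chemostats] <- 0
    res <- max(abs(dx) / pmax(x, 1e-12))
    if (res > steady_tol)
      stop(sprintf("state is not at steady state (relative residual %.3g > %.3g)",
                   res, steady_tol))
  }
  aff <- reaction_affinities(st, x, units = "kJ")
  overall <- as.vector(st$N %*% pathway)
  names(overall) <- st$species
  internal_leak <- overall[!st$chemostats]
  if (any(internal_leak != 0))
    warning("pathway vector does not annihilate internal species: ",
            paste(names(internal_leak)[internal_leak != 0], collapse = ", "))
  RT <- st$RT
  mu_kJ <- RT * log(st$K * x) * 1e-3
  total_b <- sum(pathway * aff$A)
  total_a <- -sum(overall * mu_kJ)
  structure(list(
    table = data.frame(reaction = st$reactions, weight = as.integer(pathway),
                       A_kJ = aff$A, weighted_A_kJ = pathway * aff$A,
                       row.names = NULL),
    overall = overall[overall != 0],
    A_total_kJ = total_b,
    A_total_from_potentials_kJ = total_a),
    class = "pathway_energetics")
}

#' @export
print.pathway_energetics <- function(x, ...) {
  cat("Pathway energetics\n")
  cat("  overall reaction: ", format_reaction(x$overall), "\n", sep = "")
  tab <- x$table[x$table$weight != 0, ]
  for (i in seq_len(nrow(tab)))
    cat(sprintf("  %-8s A = %8.1f kJ/mol  (x%d)\n",
                tab$reaction[i], tab$A_kJ[i], tab$weight[i]))
  cat(sprintf("  total: %.1f kJ/mol (weighted sum), %.1f kJ/mol (chemostat potentials)\n",
              x$A_total_kJ, x$A_total_from_potentials_kJ))
  invisible(x)
}

format_reaction <- function(coefs) {
  lhs <- coefs[coefs < 0]; rhs <- coefs[coefs > 0]
  term <- function(v) paste(ifelse(abs(v) == 1, names(v),
                                   paste0(abs(v), " ", names(v))),
                            collapse = " + ")
  paste(term(lhs), "<=>", term(rhs))
}
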