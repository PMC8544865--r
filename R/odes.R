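#' Assemble the ODE system of a model
#'
#' Turns a (hierarchical or flat) bond-graph model into an explicit ODE
#' system \eqn{dx/dt = N v(x)} with chemostat rows forced to zero.  The
#' flux vector \eqn{v(x)} evaluates each reaction's rate law in amount
#' space (products of \eqn{K_s x_s}), so zero states are regular and, for
#' mass-action laws, the right-hand side is polynomial in \eqn{x}.
#'
#' @param x a [bondgraph_model()] (or module / flat model).
#' @param chemostats optional character vector overriding the model's
#'   chemostat set.
#' @return an `ode_system` with elements `species`, `reactions`, `N`,
#'   `K`, `laws`, `chemostats` (logical mask), `x0`, `RT`, a flux function
#'   `v(x)` and a derivative function `deriv(x)`.
#' @export
assemble_odes <- function(x, chemostats = NULL) {
  st <- as_stoich(x)
  if (!is.null(chemostats)) {
    bad <- setdiff(chemostats, st$species)
    if (length(bad)) stop("unknown chemostat species: ", paste(bad, collapse = ", "))
    st$chemostats <- stats::setNames(st$species %in% chemostats, st$species)
  }
  ## site-count validation for generalised kinetics
  for (j in seq_along(st$reactions)) {
    law <- st$laws[[j]]
    if (law$type == "GK") {
      nf <- length(st$sites_f[[j]]); nr <- length(st$sites_r[[j]])
      if (length(law$params$Rb_f) != nf || length(law$params$Rb_r) != nr)
        stop(sprintf(
          "reaction '%s': GK law declares %d+%d binding constants but has %d+%d sites",
          st$reactions[[j]], length(law$params$Rb_f), length(law$params$Rb_r),
          nf, nr))
    }
  }
  sys <- st
  sys$RT <- GAS_CONSTANT * st$temperature
  free <- !st$chemostats
  sys$v <- function(x) eval_fluxes(st, x)
  sys$deriv <- function(x) {
    dx <- as.vector(st$N %*% eval_fluxes(st, x))
    dx[!free] <- 0
    stats::setNames(dx, st$species)
  }
  class(sys) <- "ode_system"
  sys
}

#' @export
print.ode_system <- function(x, ...) {
  cat(sprintf("<ode_system: %d species (%d chemostatted), %d reactions>\n",
              length(x$species), sum(x$chemostats), length(x$reactions)))
  laws <- vapply(x$laws, function(l) l$type, "")
  cat("  rate laws:", paste(sprintf("%d %s", table(laws), names(table(laws))),
                            collapse = ", "), "\n")
  cat(sprintf("  RT = %.1f J/mol (T = %.2f K)\n", x$RT, x$temperature))
  invisible(x)
}

#' Dissipated power at a state
#'
#' \eqn{\sum_j (A^f_j - A^r_j) v_j}: total free energy dissipated per unit
#' time.  Non-negative at every state for all three rate laws (each flux
#' has the sign of its affinity); zero iff every reaction is at
#' equilibrium.
#'
#' @param sys an [assemble_odes()] system.
#' @param x strictly positive state vector.
#' @return dissipation in J/s (or J/L/s when states are concentrations).
#' @export
dissipation <- function(sys, x) {
  aff <- reaction_affinities(sys, x)
  sum(aff$A * sys$v(x))
}
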