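#' Integrate a model in time
#'
#' Solves \eqn{dx/dt = N v(x)} (chemostat rows held at zero) with a
#' stiff-capable adaptive integrator (deSolve's `lsoda`).  Enzyme systems
#' at nM–uM scales are stiff, hence the tight default tolerances.
#'
#' @param sys an [assemble_odes()] system.
#' @param x0 initial state (named or in species order); chemostat entries
#'   define the fixed chemostat values.  Defaults to the model's `x0`.
#' @param t_end end time (s).
#' @param n_out number of output times (default 201, log-spaced never;
#'   linear grid).
#' @param times explicit output times (overrides `t_end`/`n_out`).
#' @param rtol,atol relative/absolute solver tolerances.
#' @param neg_tol largest tolerated negative-state excursion relative to
#'   the state scale before an error is raised.
#' @return a `bg_trajectory`: `times`, state matrix `x` (time by
#'   species), and solver provenance.
#' @export
simulate_bg <- function(sys, x0 = sys$x0, t_end = 1, n_out = 201,
                        times = NULL, rtol = 1e-8, atol = 1e-12,
                        neg_tol = 1e-6) {
  x0 <- full_state(sys, x0)
  if (any(x0 < 0)) stop("initial state must be non-negative")
  if (is.null(times)) times <- seq(0, t_end, length.out = n_out)
  f <- function(t, y, parms) list(sys$deriv(y))
  out <- deSolve::ode(y = x0, times = times, func = f, parms = NULL,
                      method = "lsoda", rtol = rtol, atol = atol)
  if (attr(out, "istate")[1] < 0)
    stop(sprintf("integration failed at t = %.4g of %.4g",
                 max(out[, 1]), max(times)))
  x <- out[, -1, drop = FALSE]
  scale <- max(abs(x), atol)
  if (min(x) < -neg_tol * scale)
    stop(sprintf("negative-state excursion: min x = %.4g", min(x)))
  x[x < 0] <- 0
  structure(list(times = out[, 1], x = x, species = sys$species,
                 provenance = list(method = "lsoda", rtol = rtol, atol = atol)),
            class = "bg_trajectory")
}

#' @export
print.bg_trajectory <- function(x, ...) {
  cat(sprintf("<bg_trajectory: %d species, %d time points on [0, %g] s>\n",
              ncol(x$x), length(x$times), max(x$times)))
  invisible(x)
}

#' @export
as.data.frame.bg_trajectory <- function(x, ...) {
  data.frame(time = x$times, x$x, check.names = FALSE)
}

#' Find a steady state
#'
#' Integrates over an adaptively doubled horizon until the relative
#' residual \eqn{\max_s |dx_s/dt| / \max(x_s, floor)} falls below `tol`,
#' then optionally polishes with a damped Newton iteration (pseudo-inverse
#' step, re-projected onto the conserved-moiety compatibility class of the
#' starting state).
#'
#' @param sys an [assemble_odes()] system.
#' @param x0 starting state (default model `x0`).
#' @param tol residual tolerance (default 1e-9).
#' @param t0 initial integration horizon (s).
#' @param max_horizon give up beyond this horizon (s).
#' @param polish run the Newton polish (default `TRUE`).
#' @param floor state floor used in the relative residual.
#' @return a `steady_state`: `x`, `residual`, `v` (steady fluxes).
#' @export
find_steady_state <- function(sys, x0 = sys$x0, tol = 1e-9, t0 = 10,
                              max_horizon = 1e9, polish = TRUE,
                              floor = 1e-12) {
  x <- full_state(sys, x0)
  resid <- function(x) max(abs(sys$deriv(x)) / pmax(x, floor))
  h <- t0
  r <- resid(x)
  while (r > tol && h <= max_horizon) {
    tr <- simulate_bg(sys, x, t_end = h, n_out = 11)
    x <- stats::setNames(tr$x[nrow(tr$x), ], sys$species)
    r <- resid(x)
    h <- h * 10
  }
  if (polish && r > tol * 1e-3) {
    pol <- newton_polish(sys, x, tol = tol, floor = floor)
    if (pol$residual < r) { x <- pol$x; r <- pol$residual }
  }
  if (r > tol)
    stop(sprintf("steady state not found within horizon %g s (residual %.3g)",
                 max_horizon, r))
  structure(list(x = x, residual = r, v = sys$v(x)), class = "steady_state")
}

#' @export
print.steady_state <- function(x, ...) {
  cat(sprintf("<steady_state: residual %.3g>\n", x$residual))
  print(utils::head(x$x, 12))
  invisible(x)
}

newton_polish <- function(sys, x, tol, floor, max_iter = 40) {
  free <- which(!sys$chemostats)
  G <- conserved_moieties(sys)
  totals0 <- if (ncol(G)) as.vector(t(G) %*% x[free]) else numeric()
  Ffun <- function(x) sys$deriv(x)[free]
  resid <- function(x) max(abs(sys$deriv(x)) / pmax(x, floor))
  r <- resid(x)
  for (it in seq_len(max_iter)) {
    if (r < tol * 1e-3) break
    Fv <- Ffun(x)
    J <- matrix(0, length(free), length(free))
    for (k in seq_along(free)) {
      hstep <- sqrt(.Machine$double.eps) * max(abs(x[free[k]]), floor)
      xp <- x; xp[free[k]] <- xp[free[k]] + hstep
      J[, k] <- (Ffun(xp) - Fv) / hstep
    }
    sv <- svd(J)
    keep <- sv$d > max(sv$d) * 1e-12
    step <- -sv$v[, keep, drop = FALSE] %*%
      ((t(sv$u[, keep, drop = FALSE]) %*% Fv) / sv$d[keep])
    lambda <- 1
    improved <- FALSE
    for (half in 1:20) {
      xf <- x[free] + lambda * as.vector(step)
      if (ncol(G)) {  # re-project onto the moiety compatibility class
        defect <- totals0 - as.vector(t(G) %*% xf)
        xf <- xf + as.vector(G %*% solve(crossprod(G), defect))
      }
      if (all(xf >= 0)) {
        xc <- x; xc[free] <- xf
        rc <- resid(xc)
        if (rc < r) { x <- xc; r <- rc; improved <- TRUE; break }
      }
      lambda <- lambda / 2
    }
    if (!improved) break
  }
  list(x = x, residual = r)
}

#' Response time of a deviation series
#'
#' The time required to return to within a fraction (default 5\%) of the
#' maximum deviation: the \emph{last} time at which the deviation is at or
#' above the threshold, linearly interpolated between samples (so the
#' criterion is a permanent return, not a first crossing).  Invariant
#' under scaling of the deviation series.
#'
#' @param t time grid.
#' @param d non-negative deviation series on `t`.
#' @param frac threshold fraction of the maximum deviation.
#' @return response time (same units as `t`); 0 if `d` is identically 0.
#' @export
response_time <- function(t, d, frac = 0.05) {
  stopifnot(length(t) == length(d), !is.unsorted(t))
  dmax <- max(d)
  if (dmax == 0) return(0)
  thr <- frac * dmax
  above <- which(d >= thr)
  i <- above[length(above)]
  if (i == length(d)) return(t[i])  # not yet settled; caller extends horizon
  t[i] + (d[i] - thr) / (d[i] - d[i + 1]) * (t[i + 1] - t[i])
}

euclid_dev <- function(traj, ref, set) {
  sqrt(rowSums((traj$x[, set, drop = FALSE] -
                matrix(ref[set], nrow(traj$x), length(set), byrow = TRUE))^2))
}

## Integrate from x0 with horizon doubling until the deviation series has
## settled (final deviation < settle_frac of its maximum) or cap reached.
settle_trajectory <- function(sys, x0, ref, set, t0 = 1, cap = 1e7,
                              settle_frac = 0.01, n_out = 400) {
  h <- t0
  repeat {
    tr <- simulate_bg(sys, x0, t_end = h, n_out = n_out)
    d <- euclid_dev(tr, ref, set)
    if (max(d) == 0 || d[length(d)] < settle_frac * max(d) || h >= cap)
      return(list(traj = tr, d = d, horizon = h, capped = h >= cap))
    h <- h * 4
  }
}

#' Perturbation experiments
#'
#' `perturb_internal()` instantaneously scales one internal species'
#' concentration away from a reference steady state (default +30\%),
#' integrates the transient return, and reports the Euclidean deviation
#' series over the internal species set together with its 5\% response
#' time.  `perturb_chemostat()` applies a prolonged perturbation to an
#' external (chemostatted) species, which moves the system to a new steady
#' state; it additionally reports the steady-state shift.
#'
#' @param sys an [assemble_odes()] system.
#' @param ss reference [find_steady_state()] result (or state vector
#'   at steady state).
#' @param species the perturbed species name.
#' @param factor multiplicative perturbation (default 1.3, i.e. +30\%).
#' @param internal_set species names over which the Euclidean deviation
#'   (and response time) is computed; default: all non-chemostat species.
#' @param readout optional species name whose time course is reported.
#' @param t0,cap initial and maximal integration horizon (s).
#' @return a `perturbation_result`: `species`, `factor`, `traj`, `d`,
#'   `response_time`, `readout`, and for chemostat perturbations
#'   `new_steady_state` and `steady_state_deviation`.
#' @export
perturb_internal <- function(sys, ss, species, factor = 1.3,
                             internal_set = NULL, readout = NULL,
                             t0 = 1, cap = 1e7) {
  x_ref <- if (inherits(ss, "steady_state")) ss$x else full_state(sys, ss)
  if (!species %in% sys$species)
    stop(sprintf("unknown species '%s'; valid: %s", species,
                 paste(sys$species, collapse = ", ")))
  if (sys$chemostats[[species]])
    stop(sprintf("'%s' is a chemostat; use perturb_chemostat()", species))
  set <- internal_names(sys, internal_set)
  x0 <- x_ref
  x0[species] <- x0[species] * factor
  s <- settle_trajectory(sys, x0, x_ref, set, t0 = t0, cap = cap)
  rt <- response_time(s$traj$times, s$d)
  structure(list(kind = "internal", species = species, factor = factor,
                 traj = s$traj, d = s$d, response_time = rt,
                 readout = extract_readout(s$traj, readout),
                 horizon = s$horizon, capped = s$capped),
            class = "perturbation_result")
}

#' @rdname perturb_internal
#' @export
perturb_chemostat <- function(sys, ss, species, factor = 1.3,
                              internal_set = NULL, readout = NULL,
                              t0 = 1, cap = 1e7) {
  x_ref <- if (inherits(ss, "steady_state")) ss$x else full_state(sys, ss)
  if (!species %in% sys$species)
    stop(sprintf("unknown species '%s'; valid: %s", species,
                 paste(sys$species, collapse = ", ")))
  if (!sys$chemostats[[species]])
    stop(sprintf("'%s' is internal; use perturb_internal()", species))
  set <- internal_names(sys, internal_set)
  x0 <- x_ref
  x0[species] <- x0[species] * factor
  new_ss <- find_steady_state(sys, x0)
  s <- settle_trajectory(sys, x0, new_ss$x, set, t0 = t0, cap = cap)
  rt <- response_time(s$traj$times, s$d)
  dev <- sqrt(sum((new_ss$x[set] - x_ref[set])^2))
  structure(list(kind = "chemostat", species = species, factor = factor,
                 traj = s$traj, d = s$d, response_time = rt,
                 readout = extract_readout(s$traj, readout),
                 new_steady_state = new_ss, steady_state_deviation = dev,
                 horizon = s$horizon, capped = s$capped),
            class = "perturbation_result")
}

internal_names <- function(sys, internal_set) {
  if (is.null(internal_set)) return(sys$species[!sys$chemostats])
  bad <- setdiff(internal_set, sys$species)
  if (length(bad)) stop("unknown species in internal_set: ",
                        paste(bad, collapse = ", "))
  internal_set
}

extract_readout <- function(traj, readout) {
  if (is.null(readout)) return(NULL)
  data.frame(time = traj$times, value = traj$x[, readout])
}

#' @export
print.perturbation_result <- function(x, ...) {
  cat(sprintf("<perturbation: %s x%.2f (%s), response time %.4g s%s>\n",
              x$species, x$factor, x$kind, x$response_time,
              if (!is.null(x$steady_state_deviation))
                sprintf(", steady-state shift %.3g", x$steady_state_deviation)
              else ""))
  invisible(x)
}

#' Steady-state signal-response curve
#'
#' Sweeps an input over a grid; for each value an initial state is formed
#' by `make_x0(input)`, the steady state is found, and the designated
#' output species are recorded.  Sweeping from differently activated
#' initial conditions (via `make_x0`) exposes bistability as disagreeing
#' branches.
#'
#' @param sys an [assemble_odes()] system.
#' @param inputs positive numeric grid of input values.
#' @param make_x0 function mapping one input value to an initial state.
#' @param outputs character vector of species to record.
#' @param ... passed to [find_steady_state()].
#' @return data frame with `input` and one column per output; failed grid
#'   points carry `NA` (with a warning).
#' @export
signal_response_curve <- function(sys, inputs, make_x0, outputs, ...) {
  stopifnot(all(inputs > 0))
  res <- matrix(NA_real_, length(inputs), length(outputs),
                dimnames = list(NULL, outputs))
  for (i in seq_along(inputs)) {
    ss <- tryCatch(find_steady_state(sys, make_x0(inputs[i]), ...),
                   error = function(e) {
                     warning(sprintf("input %.4g: %s", inputs[i],
                                     conditionMessage(e)), call. = FALSE)
                     NULL
                   })
    if (!is.null(ss)) res[i, ] <- ss$x[outputs]
  }
  data.frame(input = inputs, res, check.names = FALSE)
}
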