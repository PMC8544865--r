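#' Glycolysis network definition
#'
#' The reaction-level topology of the glycolysis pathway used throughout
#' the package: eleven enzymes (including the gluconeogenic fbp and pps
#' legs of the two futile cycles) over eighteen species.  Ten boundary
#' species (G6P, PYR, NAD, NADH, ATP, ADP, AMP, Pi, H, H2O) are
#' chemostatted; the eight internal species are F6P, F16P, DHAP, GAP,
#' 13DPG, 3PG, 2PG and PEP.  This table is the single source of truth for
#' the stoichiometric matrix; rate laws are swappable per enzyme without
#' touching it.  Note the stoichiometry-2 proton site of pps, which
#' exercises the per-site binding constants of the generalised kinetics
#' law.
#'
#' @return list with `reactions` (named list of `from`/`to` stoichiometry
#'   vectors), `species`, `chemostats` and `internal` name vectors.
#' @export
glycolysis_network <- function() {
  reactions <- list(
    pgi = list(from = c(G6P = 1),                  to = c(F6P = 1)),
    pfk = list(from = c(F6P = 1, ATP = 1),         to = c(F16P = 1, ADP = 1, H = 1)),
    fbp = list(from = c(F16P = 1, H2O = 1),        to = c(F6P = 1, Pi = 1)),
    fba = list(from = c(F16P = 1),                 to = c(DHAP = 1, GAP = 1)),
    tpi = list(from = c(DHAP = 1),                 to = c(GAP = 1)),
    gap = list(from = c(GAP = 1, NAD = 1, Pi = 1), to = c(`13DPG` = 1, NADH = 1, H = 1)),
    pgk = list(from = c(`13DPG` = 1, ADP = 1),     to = c(`3PG` = 1, ATP = 1)),
    gpm = list(from = c(`3PG` = 1),                to = c(`2PG` = 1)),
    eno = list(from = c(`2PG` = 1),                to = c(PEP = 1, H2O = 1)),
    pyk = list(from = c(PEP = 1, ADP = 1, H = 1),  to = c(PYR = 1, ATP = 1)),
    pps = list(from = c(PYR = 1, ATP = 1, H2O = 1),
               to = c(PEP = 1, AMP = 1, Pi = 1, H = 2)))
  internal <- c("F6P", "F16P", "DHAP", "GAP", "13DPG", "3PG", "2PG", "PEP")
  chemostats <- c("G6P", "PYR", "NAD", "NADH", "ATP", "ADP", "AMP", "Pi",
                  "H", "H2O")
  list(reactions = reactions, species = c(chemostats[1], internal,
                                          chemostats[-1]),
       chemostats = chemostats, internal = internal)
}

#' Reference free-energy distribution of the glycolysis pathway
#'
#' The reported per-reaction affinities (kJ/mol) of the nine-reaction
#' glycolytic pathway at steady state, with the pathway weight of each
#' reaction.  Used both as a reference for pathway arithmetic and as the
#' anchor of the synthetic parameterisation below.
#'
#' @return data frame with columns `reaction`, `A_kJ`, `weight`.
#' @export
glycolysis_affinity_table <- function() {
  data.frame(
    reaction = c("pgi", "pfk", "fba", "tpi", "gap", "pgk", "gpm", "eno", "pyk"),
    A_kJ = c(43.4, 81.0, 14.6, 8.4, 51.5, 23.9, 13.5, 45.1, 17.0),
    weight = c(1L, 1L, 1L, 1L, 2L, 2L, 2L, 2L, 2L))
}

#' Synthetic parameter set for the glycolysis model
#'
#' A fully worked parameterisation of the glycolysis network, constructed
#' (not measured) so that the generalised-kinetics model has an exactly
#' known reference steady state whose per-reaction affinities equal the
#' reference free-energy distribution of [glycolysis_affinity_table()].
#' Construction: boundary chemical potentials are fixed at plausible
#' physiological values (45 kJ/mol ATP hydrolysis affinity, water and
#' protons at reference), the nine affinity targets are solved exactly
#' for the internal potentials (and the pyruvate potential), species
#' constants follow as \eqn{K_s = e^{\mu_s/RT}/x_{s,ss}} from literature-
#' scale metabolite concentrations, the steady flux is the pathway vector
#' times `v0`, and each enzyme's binding constants are set to
#' half-saturation at the reference state with the rate constant chosen
#' to carry the reference flux.  fbp and pps are present with `e0 = 0`
#' (switched off), mirroring the pathway analysis conditions.
#'
#' @param temperature absolute temperature (K).
#' @param v0 pathway flux scale at the reference state (M/s); default
#'   1e-4 (about 6 mM/min).
#' @param e0 enzyme concentration used for all active enzymes (M).
#' @return list with `K`, `x_ref`, `mu`, `laws` (named GK law list),
#'   `v_ref`, `temperature`, plus the network definition.
#' @export
glycolysis_params_synthetic <- function(temperature = 310.15, v0 = 1e-4,
                                        e0 = 1e-6) {
  net <- glycolysis_network()
  RT <- GAS_CONSTANT * temperature
  tab <- glycolysis_affinity_table()

  ## reference concentrations (M), literature scale
  x_ref <- c(G6P = 8e-4, F6P = 3e-4, F16P = 1.5e-2, DHAP = 4e-4, GAP = 1e-4,
             `13DPG` = 1e-6, `3PG` = 1.5e-3, `2PG` = 4e-4, PEP = 2e-4,
             PYR = 2e-3, NAD = 2.6e-3, NADH = 8e-5, ATP = 9.6e-3,
             ADP = 5.6e-4, AMP = 2.8e-4, Pi = 1e-2, H = 1e-7, H2O = 1)

  ## fixed boundary potentials (J/mol)
  mu <- c(G6P = 0, ATP = 45e3, ADP = 0, Pi = 0, H = 0, H2O = 0,
          NAD = 0, NADH = 0, AMP = -40e3)

  ## solve the nine affinity targets for the remaining potentials
  ## (the eight internal species plus PYR): sum_s N_sj mu_s = -A_j
  st0 <- stoich_from_table(net)
  Np <- st0$N[, tab$reaction]
  unknown <- c(net$internal, "PYR")
  known <- setdiff(rownames(Np), unknown)
  rhs <- -tab$A_kJ * 1e3 - as.vector(t(Np[known, ]) %*% mu[known])
  mu_u <- solve(t(Np[unknown, ]), rhs)
  mu <- c(mu, stats::setNames(mu_u, unknown))[names(x_ref)]

  K <- exp(mu / RT) / x_ref

  ## reference fluxes: pathway vector times v0 (fbp/pps carry none)
  w <- stats::setNames(numeric(length(net$reactions)), names(net$reactions))
  w[tab$reaction] <- tab$weight
  v_ref <- w * v0

  ## generalised-kinetics laws: half-saturating binding constants at the
  ## reference state; kappa_bar carries the reference flux
  kx <- K * x_ref
  laws <- list()
  for (rn in names(net$reactions)) {
    rx <- net$reactions[[rn]]
    sf <- rep(names(rx$from), rx$from)
    sr <- rep(names(rx$to), rx$to)
    Rb_f <- unname(kx[sf]); Rb_r <- unname(kx[sr])
    a <- prod(kx[sf]); b <- prod(kx[sr])
    den <- -1 + 2^length(sf) + 2^length(sr)
    e0_r <- if (rn %in% c("fbp", "pps")) 0 else e0
    kb <- if (v_ref[[rn]] != 0) v_ref[[rn]] * den / (e0 * (a - b))
          else 0.1 * v0 * den / (e0 * abs(a - b))
    laws[[rn]] <- generalised_kinetics(kappa_bar = kb, e0 = e0_r,
                                       Rb_f = Rb_f, Rb_r = Rb_r)
  }

  list(K = K, x_ref = x_ref, mu = mu, laws = laws, v_ref = v_ref,
       pathway = w, temperature = temperature, network = net)
}

## stoichiometric matrix straight from the network table (no bond graph);
## used only inside parameter construction, before a model exists.
stoich_from_table <- function(net) {
  rn <- names(net$reactions)
  N <- matrix(0L, length(net$species), length(rn),
              dimnames = list(net$species, rn))
  for (j in rn) {
    rx <- net$reactions[[j]]
    for (s in names(rx$from)) N[s, j] <- N[s, j] - rx$from[[s]]
    for (s in names(rx$to)) N[s, j] <- N[s, j] + rx$to[[s]]
  }
  list(N = N)
}

#' Build the glycolysis model
#'
#' Constructs the glycolysis bond-graph model with a chosen rate-law
#' assignment per enzyme: `"GK"` (generalised kinetics, the reference),
#' `"MM"` (reversible Michaelis–Menten on the lumped substrate/product
#' exponentials) or `"MA"` (mass action).  All assignments share the
#' species constants, stoichiometric matrix, chemostat set and initial
#' state; only the flux functions differ.  For `"MM"` and `"MA"` the
#' kinetic constants default to the calibrated values that reproduce the
#' generalised-kinetics reference steady state (see
#' [calibrate_mass_action()] / [calibrate_michaelis_menten()]).
#'
#' @param rate_law single string or named per-reaction character vector
#'   over `"GK"`, `"MM"`, `"MA"`.
#' @param params parameter set, see [glycolysis_params_synthetic()].
#' @return a [bondgraph_model()] whose `x0` is the reference steady
#'   state.
#' @export
build_glycolysis <- function(rate_law = "GK",
                             params = glycolysis_params_synthetic()) {
  net <- params$network
  rls <- expand_law_choice(rate_law, names(net$reactions))
  laws <- params$laws
  if (any(rls != "GK")) {
    cal_ma <- if (any(rls == "MA")) glycolysis_ma_laws(params) else NULL
    cal_mm <- if (any(rls == "MM")) glycolysis_mm_laws(params)$laws else NULL
    for (rn in names(net$reactions)) {
      if (rls[[rn]] == "MA") laws[[rn]] <- cal_ma[[rn]]
      if (rls[[rn]] == "MM") laws[[rn]] <- cal_mm[[rn]]
    }
  }
  rxns <- lapply(names(net$reactions), function(rn)
    rxn(net$reactions[[rn]]$from, net$reactions[[rn]]$to, laws[[rn]]))
  names(rxns) <- names(net$reactions)
  root <- reaction_network(species = params$K[net$species], reactions = rxns,
                           name = "glycolysis")
  bondgraph_model(root, chemostats = net$chemostats,
                  x0 = params$x_ref[net$species],
                  temperature = params$temperature)
}

expand_law_choice <- function(rate_law, rn) {
  if (length(rate_law) == 1 && is.null(names(rate_law)))
    rate_law <- stats::setNames(rep(rate_law, length(rn)), rn)
  bad <- setdiff(names(rate_law), rn)
  if (length(bad)) stop("unknown reactions: ", paste(bad, collapse = ", "))
  out <- stats::setNames(rep("GK", length(rn)), rn)
  out[names(rate_law)] <- rate_law
  if (!all(out %in% c("GK", "MM", "MA")))
    stop("rate laws must be GK, MM or MA")
  out
}

## ---- calibration ----------------------------------------------------------

ref_site_products <- function(params, rn) {
  net <- params$network
  rx <- net$reactions[[rn]]
  kx <- params$K * params$x_ref
  sf <- rep(names(rx$from), rx$from); sr <- rep(names(rx$to), rx$to)
  list(sf = sf, sr = sr, a = prod(kx[sf]), b = prod(kx[sr]))
}

glycolysis_ma_laws <- function(params) {
  laws <- list()
  for (rn in names(params$network$reactions)) {
    s <- ref_site_products(params, rn)
    v <- params$v_ref[[rn]]
    gk_off <- params$laws[[rn]]$params$e0 == 0
    if (v == 0 && !gk_off && abs(s$a - s$b) > 0)
      stop(sprintf("reaction '%s': zero reference flux with nonzero affinity", rn))
    kappa <- if (gk_off) 0 else v / (s$a - s$b)
    laws[[rn]] <- mass_action(kappa)
  }
  laws
}

#' Calibrate simplified glycolysis rate laws against the reference model
#'
#' `calibrate_mass_action()` chooses each enzyme's mass-action rate
#' constant so its flux equals the generalised-kinetics flux at the
#' reference steady state (species constants unchanged, so equilibrium
#' constants are preserved); the reference state is then a steady state
#' of the mass-action model by construction.
#' `calibrate_michaelis_menten()` additionally matches the flux
#' derivatives with respect to one internal substrate and one internal
#' product (where the reaction has them), determining the two binding
#' constants and the rate constant; sides without an internal species
#' keep a half-saturating binding constant, and reactions that cannot be
#' matched exactly (e.g. fba, with two internal products) are matched in
#' flux and flagged.
#'
#' @param params parameter set from [glycolysis_params_synthetic()].
#' @return list with `model` (a calibrated [bondgraph_model()]) and
#'   `report` (data frame: reaction, reference flux, match type, residual
#'   flux mismatch at the reference state).
#' @export
calibrate_mass_action <- function(params = glycolysis_params_synthetic()) {
  laws <- glycolysis_ma_laws(params)
  model <- build_glycolysis("MA", params)
  report <- calibration_report(params, laws,
                               match = ifelse(params$v_ref == 0, "off", "flux"))
  list(model = model, report = report)
}

#' @rdname calibrate_mass_action
#' @export
calibrate_michaelis_menten <- function(params = glycolysis_params_synthetic()) {
  cal <- glycolysis_mm_laws(params)
  model <- build_glycolysis("MM", params)
  report <- calibration_report(params, cal$laws, match = cal$match)
  list(model = model, report = report)
}

glycolysis_mm_laws <- function(params) {
  net <- params$network
  internal <- net$internal
  laws <- list(); match <- character()
  for (rn in names(net$reactions)) {
    s <- ref_site_products(params, rn)
    gk <- params$laws[[rn]]
    if (gk$params$e0 == 0) {
      ## enzyme off: keep a valid (inactive) MM law
      laws[[rn]] <- michaelis_menten(kappa_bar = gk$params$kappa_bar,
                                     e0 = 0, Rb0 = s$a, Rb1 = s$b)
      match[rn] <- "off"
      next
    }
    v <- params$v_ref[[rn]]
    int_f <- intersect(s$sf, internal); int_r <- intersect(s$sr, internal)
    ## GK flux partials w.r.t. the designated internal species, numerically
    dgk <- function(sp) {
      x <- params$x_ref
      h <- 1e-6 * x[[sp]]
      st <- list(K = params$K)
      fl <- function(x) {
        kx <- params$K * x
        eval_flux(gk, kx, match(s$sf, names(x)), match(s$sr, names(x)))
      }
      xp <- x; xp[[sp]] <- xp[[sp]] + h
      xm <- x; xm[[sp]] <- xm[[sp]] - h
      (fl(xp) - fl(xm)) / (2 * h)
    }
    q <- s$a - s$b
    gu <- if (length(int_f)) dgk(int_f[1]) * params$x_ref[[int_f[1]]] / s$a else NA
    gw <- if (length(int_r)) dgk(int_r[1]) * params$x_ref[[int_r[1]]] / s$b else NA
    cf <- if (is.na(gu)) NA else (1 - gu * q / v)        # q/R0 = D*cf
    cr <- if (is.na(gw)) NA else (-(1 + gw * q / v))     # q/R1 = D*cr
    ## D = 1 + a/R0 + b/R1 with the available constraints substituted
    if (!is.na(cf) && !is.na(cr)) {
      D <- 1 / (1 - (s$a * cf + s$b * cr) / q)
      typ <- "exact"
    } else if (!is.na(cf)) {        # product side pinned at half-saturation
      D <- (1 + s$b / s$b) / (1 - s$a * cf / q)  # R1 = b
      typ <- "flux+substrate"
    } else if (!is.na(cr)) {        # substrate side pinned
      D <- (1 + s$a / s$a) / (1 - s$b * cr / q)  # R0 = a
      typ <- "flux+product"
    } else {
      D <- 3                                      # both sides half-saturating
      typ <- "flux-only"
    }
    ok <- is.finite(D) && D > 0
    R0 <- if (!is.na(cf) && ok && cf > 0) q / (D * cf) else s$a
    R1 <- if (!is.na(cr) && ok && cr > 0) q / (D * cr) else s$b
    if (!ok) { D <- 1 + s$a / R0 + s$b / R1; typ <- "flux-only" }
    D <- 1 + s$a / R0 + s$b / R1   # recompute from the final constants
    kb <- v * D / (q * gk$params$e0)
    laws[[rn]] <- michaelis_menten(kappa_bar = kb, e0 = gk$params$e0,
                                   Rb0 = R0, Rb1 = R1)
    ## fba cannot match its second internal product; flag it
    if (length(int_f) > 1 || length(int_r) > 1) typ <- "flux+partial"
    match[rn] <- typ
  }
  list(laws = laws, match = match)
}

calibration_report <- function(params, laws, match) {
  rn <- names(params$network$reactions)
  mismatch <- vapply(rn, function(r) {
    s <- ref_site_products(params, r)
    kx <- params$K * params$x_ref
    idx <- stats::setNames(seq_along(kx), names(kx))
    v <- eval_flux(laws[[r]], kx, idx[s$sf], idx[s$sr])
    v - params$v_ref[[r]]
  }, 0)
  data.frame(reaction = rn, v_ref = unname(params$v_ref[rn]),
             match = unname(match[rn]), mismatch = unname(mismatch),
             row.names = NULL)
}

#' Perturbation benchmark across rate-law variants
#'
#' Runs the transient (+30\% internal species) and prolonged (+30\%
#' chemostat) perturbation protocols on a set of calibrated model
#' variants sharing a reference steady state, reporting per perturbation
#' the 5\% response time, the steady-state shift (chemostat
#' perturbations), and the peak deviation of the readout species.
#'
#' @param models named list of [bondgraph_model()]s (e.g. GK, MM, MA).
#' @param kind `"internal"`, `"external"` or both.
#' @param species perturbation targets; defaults to all internal species
#'   for the transient protocol and all chemostats for the prolonged one.
#' @param exclude species to skip (e.g. a chemostat with negligible
#'   effect).
#' @param factor perturbation factor.
#' @param readout species whose peak deviation is recorded.
#' @return tidy data frame: model, kind, species, response_time,
#'   steady_state_deviation, readout_max_dev; failed cells carry NA.
#' @export
run_benchmark <- function(models, kind = c("internal", "external"),
                          species = NULL, exclude = character(),
                          factor = 1.3, readout = "PEP") {
  kind <- match.arg(kind, several.ok = TRUE)
  rows <- list()
  for (mn in names(models)) {
    sys <- assemble_odes(models[[mn]])
    ss <- find_steady_state(sys)
    targets <- list()
    if ("internal" %in% kind)
      targets$internal <- setdiff(sys$species[!sys$chemostats], exclude)
    if ("external" %in% kind)
      targets$external <- setdiff(sys$species[sys$chemostats], exclude)
    if (!is.null(species))
      targets <- lapply(targets, intersect, species)
    for (kd in names(targets)) for (sp in targets[[kd]]) {
      res <- tryCatch({
        pr <- if (kd == "internal")
          perturb_internal(sys, ss, sp, factor = factor, readout = readout)
        else
          perturb_chemostat(sys, ss, sp, factor = factor, readout = readout)
        data.frame(model = mn, kind = kd, species = sp,
                   response_time = pr$response_time,
                   steady_state_deviation =
                     pr$steady_state_deviation %||% NA_real_,
                   readout_max_dev =
                     max(abs(pr$readout$value - ss$x[[readout]])))
      }, error = function(e) {
        warning(sprintf("%s/%s/%s: %s", mn, kd, sp, conditionMessage(e)),
                call. = FALSE)
        data.frame(model = mn, kind = kd, species = sp,
                   response_time = NA_real_,
                   steady_state_deviation = NA_real_,
                   readout_max_dev = NA_real_)
      })
      rows[[length(rows) + 1L]] <- res
    }
  }
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pathway energetics report for the glycolysis model
#'
#' Finds the steady state of the (GK) glycolysis model with the
#' gluconeogenic enzymes off, computes per-reaction affinities, the
#' pathway weights from the internal stoichiometric null space
#' (restricted to active enzymes) and the total pathway affinity both
#' from the weighted affinity sum and from the chemostat potentials of
#' the overall reaction.
#'
#' @param model a glycolysis [bondgraph_model()]; default the GK model.
#' @param ss optional precomputed steady state.
#' @return a `pathway_energetics` object (see [pathway_energetics()]).
#' @export
energetics_report <- function(model = build_glycolysis("GK"), ss = NULL) {
  sys <- assemble_odes(model)
  if (is.null(ss)) ss <- find_steady_state(sys)
  off <- vapply(sys$laws, function(l) {
    p <- l$params
    (!is.null(p$e0) && p$e0 == 0) || (!is.null(p$kappa) && p$kappa == 0)
  }, TRUE)
  w <- steady_state_pathway(sys, exclude = sys$reactions[off])
  pathway_energetics(sys, ss$x, pathway = w)
}
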