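#' Default parameters for the MAPK cascade model
#'
#' The cascade uses a two-state enzyme mechanism for every kinase
#' (E + X + ATP <-> C <-> E + XP + ADP) and phosphatase
#' (E + XP <-> C <-> E + X + Pi).  Rate constants follow the classic
#' Huang–Ferrell regime: association `a` = 1e9 /M/s, dissociation `d` =
#' 150 /s and catalysis `kcat` = 150 /s, giving Km = (d + kcat)/a =
#' 0.3 uM for every enzymatic step.  Thermodynamic constants place about
#' 47 kJ/mol of driving force on ATP hydrolysis at the default chemostat
#' concentrations (1 mM each of ATP, ADP and Pi), split between the
#' kinase and phosphatase legs of each phosphorylation cycle; every
#' reverse rate then follows from detailed balance rather than being an
#' independent knob.
#'
#' Substrate and enzyme totals are 3 nM MAP3K, 1.2 uM MAP2K and MAPK,
#' 0.3 nM MAP3K/MAP2K phosphatases, 0.12 uM MAPK phosphatase and
#' 0.03 nM input MAP4K.  The feedback phosphorylation cycle reuses the
#' level-1 cycle rate parameters with a 3 nM phosphatase — enough
#' deactivating capacity to open a clear hysteresis window under
#' positive feedback; both are package defaults, overridable through
#' this list.
#'
#' @return named list of parameters (concentrations in M, rates in SI).
#' @export
mapk_params_default <- function() {
  list(a = 1e9, d = 150, kcat = 150,
       K_protein = 1, K_ATP = 1e4, K_ADP = 1, K_Pi = 0.1,
       x_ATP = 1e-3, x_ADP = 1e-3, x_Pi = 1e-3,
       conc = c(MAP3K = 3e-9, MAP2K = 1.2e-6, MAPK = 1.2e-6,
                MAP3KPase = 0.3e-9, MAP2KPase = 0.3e-9, MAPKPase = 0.12e-6,
                MAP4K = 0.03e-9),
       feedback_phosphatase = 3e-9)
}

kinase_rates <- function(p) {
  kappa1 <- (p$a / p$x_ATP) / (p$K_protein^2 * p$K_ATP)
  K_C <- p$d / kappa1
  list(K_C = K_C, kappa1 = kappa1, kappa2 = p$kcat / K_C)
}

phosphatase_rates <- function(p) {
  kappa1 <- p$a / p$K_protein^2
  K_C <- p$d / kappa1
  list(K_C = K_C, kappa1 = kappa1, kappa2 = p$kcat / K_C)
}

#' MAPK cascade building blocks
#'
#' `mapk_kinase_module()` builds the generic kinase module: a two-state
#' mechanism E + X + ATP <-> C <-> E + XP + ADP around an internal
#' enzyme-substrate complex C, with the shared quantities E, X, XP, ATP
#' and ADP exposed as ports.  `mapk_phosphatase_module()` is the analogous
#' phosphatase (E + XP <-> C <-> E + X + Pi; ports E, X, XP, Pi).
#' `mapk_cycle_module()` couples one of each through shared X/XP
#' mass-conservation junctions into a generic phosphorylation cycle with
#' ports (X, XP, E1, E2, ATP, ADP, Pi), where E1 is the kinase and E2 the
#' phosphatase.
#'
#' @param rates list with `K_C` (complex thermodynamic constant),
#'   `kappa1`, `kappa2` (binding/catalytic thermodynamic rate constants).
#' @param kin,pho rate lists for the kinase and phosphatase halves.
#' @return a [bg_module()].
#' @export
mapk_kinase_module <- function(rates) {
  m <- bg_module("kinase")
  m <- bg_add(m, bg_species(K = rates$K_C), "C")
  m <- bg_add(m, bg_junction("0"), "J_C")
  m <- bg_connect(m, "C", "J_C")
  for (s in c("E", "X", "XP", "ATP", "ADP"))
    m <- bg_add(m, bg_junction("0"), paste0("J_", s))
  m <- bg_add(m, bg_reaction(mass_action(rates$kappa1)), "r1")
  m <- bg_add(m, bg_reaction(mass_action(rates$kappa2)), "r2")
  m <- bg_add(m, bg_junction("1"), "V1")
  m <- bg_connect(m, "V1", "r1:f")
  for (s in c("E", "X", "ATP")) m <- bg_connect(m, paste0("J_", s), "V1")
  m <- bg_connect(m, "r1:r", "J_C")
  m <- bg_connect(m, "J_C", "r2:f")
  m <- bg_add(m, bg_junction("1"), "V2")
  m <- bg_connect(m, "r2:r", "V2")
  for (s in c("E", "XP", "ADP")) m <- bg_connect(m, "V2", paste0("J_", s))
  for (s in c("E", "X", "XP", "ATP", "ADP"))
    m <- bg_expose(m, s, paste0("J_", s))
  m
}

#' @rdname mapk_kinase_module
#' @export
mapk_phosphatase_module <- function(rates) {
  m <- bg_module("phosphatase")
  m <- bg_add(m, bg_species(K = rates$K_C), "C")
  m <- bg_add(m, bg_junction("0"), "J_C")
  m <- bg_connect(m, "C", "J_C")
  for (s in c("E", "X", "XP", "Pi"))
    m <- bg_add(m, bg_junction("0"), paste0("J_", s))
  m <- bg_add(m, bg_reaction(mass_action(rates$kappa1)), "r1")
  m <- bg_add(m, bg_reaction(mass_action(rates$kappa2)), "r2")
  m <- bg_add(m, bg_junction("1"), "V1")
  m <- bg_connect(m, "V1", "r1:f")
  for (s in c("E", "XP")) m <- bg_connect(m, paste0("J_", s), "V1")
  m <- bg_connect(m, "r1:r", "J_C")
  m <- bg_connect(m, "J_C", "r2:f")
  m <- bg_add(m, bg_junction("1"), "V2")
  m <- bg_connect(m, "r2:r", "V2")
  for (s in c("E", "X", "Pi")) m <- bg_connect(m, "V2", paste0("J_", s))
  for (s in c("E", "X", "XP", "Pi"))
    m <- bg_expose(m, s, paste0("J_", s))
  m
}

#' @rdname mapk_kinase_module
#' @export
mapk_cycle_module <- function(kin, pho) {
  m <- bg_module("cycle")
  m <- bg_add(m, mapk_kinase_module(kin), "kinase")
  m <- bg_add(m, mapk_phosphatase_module(pho), "phosphatase")
  m <- bg_add(m, bg_junction("0"), "J_X")
  m <- bg_add(m, bg_junction("0"), "J_XP")
  m <- bg_connect(m, "J_X", "kinase:X")
  m <- bg_connect(m, "J_X", "phosphatase:X")
  m <- bg_connect(m, "J_XP", "kinase:XP")
  m <- bg_connect(m, "J_XP", "phosphatase:XP")
  m <- bg_expose(m, "X", "J_X")
  m <- bg_expose(m, "XP", "J_XP")
  m <- bg_expose(m, "E1", "kinase:E")
  m <- bg_expose(m, "E2", "phosphatase:E")
  m <- bg_expose(m, "ATP", "kinase:ATP")
  m <- bg_expose(m, "ADP", "kinase:ADP")
  m <- bg_expose(m, "Pi", "phosphatase:Pi")
  m
}

#' Build the MAPK cascade model
#'
#' Assembles the three-level Mos/MAPK cascade from five instances of the
#' phosphorylation-cycle template: one MAP3K cycle driven by the input
#' kinase MAP4K, and two distributive cycles each for the double
#' phosphorylation of MAP2K and MAPK, with the fully phosphorylated
#' substrate of each level acting as the kinase of the next.  ATP, ADP
#' and Pi are shared globally and chemostatted.  Optional feedback adds a
#' sixth cycle converting MAP4K to/from an inactive form MAP4KI with the
#' output MAPKPP as its kinase: for positive feedback the active MAP4K is
#' the phosphorylated form of that cycle, for negative feedback the
#' unphosphorylated form.
#'
#' @param input initial MAP4K concentration (M).
#' @param feedback `"none"`, `"positive"` or `"negative"`.
#' @param params parameter list, see [mapk_params_default()].
#' @param atp_energy_fraction scales the clamped ATP-hydrolysis affinity
#'   \eqn{\mu_{ATP} - \mu_{ADP} - \mu_{Pi}} to this fraction of its
#'   nominal value (by adjusting the ATP chemostat concentration);
#'   1 = nominal, 0 = equilibrium (no drive).
#' @param activated start from the activated state (phosphorylated
#'   substrate pools, as used to trace the upper branch of a bistable
#'   response) instead of the inactive state.
#' @return a [bondgraph_model()].
#' @export
mapk_cascade <- function(input = 0.03e-9,
                         feedback = c("none", "positive", "negative"),
                         params = mapk_params_default(),
                         atp_energy_fraction = 1, activated = FALSE) {
  feedback <- match.arg(feedback)
  p <- params
  stopifnot(atp_energy_fraction >= 0, atp_energy_fraction <= 1)
  kin <- kinase_rates(p)
  pho <- phosphatase_rates(p)
  cycle <- mapk_cycle_module(kin, pho)

  substrates <- c("MAP4K", "MAP3K", "MAP3KP", "MAP2K", "MAP2KP", "MAP2KPP",
                  "MAPK", "MAPKP", "MAPKPP",
                  "MAP3KPase", "MAP2KPase", "MAPKPase")
  cofactors <- c("ATP", "ADP", "Pi")
  if (feedback != "none")
    substrates <- c(substrates, "MAP4KI", "FBPase")

  m <- bg_module("cascade")
  for (s in substrates) {
    m <- bg_add(m, bg_species(K = p$K_protein), s)
    m <- bg_add(m, bg_junction("0"), paste0("J_", s))
    m <- bg_connect(m, s, paste0("J_", s))
  }
  for (s in cofactors) {
    m <- bg_add(m, bg_species(K = p[[paste0("K_", s)]]), s)
    m <- bg_add(m, bg_junction("0"), paste0("J_", s))
    m <- bg_connect(m, s, paste0("J_", s))
  }

  wire_cycle <- function(m, inst, X, XP, E1, E2) {
    m <- bg_add(m, bg_instantiate(cycle, inst), inst)
    m <- bg_connect(m, paste0("J_", X), paste0(inst, ":X"))
    m <- bg_connect(m, paste0("J_", XP), paste0(inst, ":XP"))
    m <- bg_connect(m, paste0("J_", E1), paste0(inst, ":E1"))
    m <- bg_connect(m, paste0("J_", E2), paste0(inst, ":E2"))
    m <- bg_connect(m, "J_ATP", paste0(inst, ":ATP"))
    m <- bg_connect(m, "J_ADP", paste0(inst, ":ADP"))
    m <- bg_connect(m, "J_Pi", paste0(inst, ":Pi"))
    m
  }
  m <- wire_cycle(m, "L1",  "MAP3K",  "MAP3KP",  "MAP4K",   "MAP3KPase")
  m <- wire_cycle(m, "L2a", "MAP2K",  "MAP2KP",  "MAP3KP",  "MAP2KPase")
  m <- wire_cycle(m, "L2b", "MAP2KP", "MAP2KPP", "MAP3KP",  "MAP2KPase")
  m <- wire_cycle(m, "L3a", "MAPK",   "MAPKP",   "MAP2KPP", "MAPKPase")
  m <- wire_cycle(m, "L3b", "MAPKP",  "MAPKPP",  "MAP2KPP", "MAPKPase")
  if (feedback == "positive")
    m <- wire_cycle(m, "LF", "MAP4KI", "MAP4K", "MAPKPP", "FBPase")
  else if (feedback == "negative")
    m <- wire_cycle(m, "LF", "MAP4K", "MAP4KI", "MAPKPP", "FBPase")

  ## ATP chemostat concentration carrying the requested hydrolysis drive
  gamma <- (p$K_ATP * p$x_ATP) / (p$K_ADP * p$x_ADP * p$K_Pi * p$x_Pi)
  x_ATP <- p$x_ATP * gamma^(atp_energy_fraction - 1)

  x0 <- c(MAP4K = input, p$conc[c("MAP3K", "MAP2K", "MAPK",
                                  "MAP3KPase", "MAP2KPase", "MAPKPase")],
          ATP = x_ATP, ADP = p$x_ADP, Pi = p$x_Pi)
  if (activated) {
    x0[c("MAP3KP", "MAP2KPP", "MAPKPP")] <-
      p$conc[c("MAP3K", "MAP2K", "MAPK")]
    x0[c("MAP3K", "MAP2K", "MAPK")] <- 0
  }
  if (feedback != "none") x0["FBPase"] <- p$feedback_phosphatase

  bondgraph_model(m, chemostats = cofactors, x0 = x0)
}

#' Steady-state activation analysis of the cascade
#'
#' Sweeps the input (MAP4K) concentration over a grid; at each value the
#' steady state is found and the activation of each level is recorded as
#' the percentage of the kinase in its active form (MAP3KP and the
#' biphosphorylated MAP2KPP / MAPKPP), relative to the configured total
#' of that substrate.
#'
#' @inheritParams mapk_cascade
#' @param inputs positive grid of MAP4K concentrations (M).
#' @param ... passed to [find_steady_state()].
#' @return data frame with columns `input`, `MAP3K_act`, `MAP2K_act`,
#'   `MAPK_act` (percent).
#' @export
mapk_activation <- function(inputs, feedback = "none",
                            params = mapk_params_default(),
                            atp_energy_fraction = 1, activated = FALSE, ...) {
  stopifnot(all(inputs > 0), atp_energy_fraction > 0)
  model <- mapk_cascade(input = inputs[1], feedback = feedback,
                        params = params,
                        atp_energy_fraction = atp_energy_fraction,
                        activated = activated)
  sys <- assemble_odes(model)
  make_x0 <- function(u) { x0 <- sys$x0; x0["MAP4K"] <- u; x0 }
  curve <- signal_response_curve(sys, inputs, make_x0,
                                 outputs = c("MAP3KP", "MAP2KPP", "MAPKPP"),
                                 ...)
  tot <- params$conc
  data.frame(input = curve$input,
             MAP3K_act = 100 * curve$MAP3KP / tot[["MAP3K"]],
             MAP2K_act = 100 * curve$MAP2KPP / tot[["MAP2K"]],
             MAPK_act = 100 * curve$MAPKPP / tot[["MAPK"]])
}

#' Effective Hill coefficient of a response curve
#'
#' Quantifies ultrasensitivity from a monotone steady-state dose-response
#' curve via the classic ratio criterion
#' \eqn{n_H = \log 81 / \log(EC_{90}/EC_{10})}, with the 10\% and 90\%
#' effective inputs interpolated on a log-input scale.
#'
#' @param input positive input grid (ascending).
#' @param response response values on the grid.
#' @return effective Hill coefficient.
#' @export
effective_hill <- function(input, response) {
  stopifnot(length(input) == length(response), all(input > 0))
  r <- (response - min(response)) / (max(response) - min(response))
  ec <- function(p) {
    i <- which(r >= p)[1]
    if (i == 1) return(input[1])
    exp(log(input[i - 1]) +
        (p - r[i - 1]) / (r[i] - r[i - 1]) *
          (log(input[i]) - log(input[i - 1])))
  }
  log(81) / log(ec(0.9) / ec(0.1))
}
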