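# bondgraphr

Modular, thermodynamically consistent modelling of biochemical reaction
networks in R, using the bond-graph (network thermodynamics) formalism.

## The problem

Kinetic models of signalling and metabolism are usually written directly as
rate equations.  Two chronic problems follow: forward and reverse rate
constants can be chosen in combinations that violate detailed balance
(creating perpetual-motion models), and models built by different groups are
hard to merge because conservation of mass and energy is implicit in the
equations rather than explicit in the structure.  Bond graphs solve both at
once: a model is a graph of energy-conserving components connected by bonds
that each carry a chemical potential μ (J/mol) and a molar flow v (mol/s),
so every connection transports both mass and energy, and the ODEs are
*derived* from the graph instead of written by hand.

`bondgraphr` is for systems/computational biologists who want to build such
models compositionally — species, reactions and junctions assembled into
reusable modules, modules into models — and then simulate, perturb and
energetically audit them.

## The core formalism

* Species store free energy: μ = RT·log(K·x), with one thermodynamic
  constant K per species (derivable from a standard potential μ⁰ via
  K = exp(μ⁰/RT)/(c⁰V)).
* Reactions dissipate: flux depends on the forward/reverse affinities
  A^f, A^r (sums of reactant/product potentials) through one of three
  interchangeable, thermodynamically consistent rate laws —

  - mass action (Marcelin–de Donder): v = κ(e^{A^f/RT} − e^{A^r/RT}),
  - reversible Michaelis–Menten:
    v = κ̄e₀(e^{μ_S/RT} − e^{μ_P/RT}) / (1 + e^{μ_S/RT}/R_{b0} + e^{μ_P/RT}/R_{b1}),
  - generalised (convenience-style) kinetics with one binding constant per
    binding site, for arbitrary stoichiometries.

  Every law satisfies v = 0 ⇔ A^f = A^r and A·v ≥ 0 (non-negative
  dissipation), so any model assembled from them is thermodynamically sound.
* 0-junctions share a potential and conserve flow (mass balance);
  1-junctions share a flow and sum potentials (affinity assembly).
* Flattening a module hierarchy yields a stoichiometric matrix N and flux
  vector v(x), hence dx/dt = N·v(x), with chemostats (clamped boundary
  species) zeroed row-wise.  Conserved moieties and steady-state pathway
  vectors are computed from the integer null spaces of N in exact rational
  arithmetic.

Two literature systems ship as built-in generators: the three-level
MAPK signalling cascade (with positive/negative-feedback variants built by
rewiring one module) and the glycolysis pathway with per-enzyme swappable
rate laws, calibrated so all three variants share one reference steady
state.

## Worked example

The classic enzyme motif E + S ⇌ C ⇌ E + P, built as a reaction network,
flattened to ODEs, driven to steady state and audited energetically:

```r
library(bondgraphr)

enzyme <- reaction_network(
  species = c(E = 2, C = 3, S = 1, P = 0.5),        # thermodynamic constants K
  reactions = list(
    bind    = rxn(c(E = 1, S = 1), c(C = 1), mass_action(1.5)),
    release = rxn(c(C = 1), c(E = 1, P = 1), mass_action(0.7))))
model <- bondgraph_model(enzyme, x0 = c(E = 1, C = 0.1, S = 2, P = 0.2))

sys <- assemble_odes(model)
sys$N
#>   bind release
#> E   -1       1
#> C    1      -1
#> S   -1       0
#> P    0       1

ss <- find_steady_state(sys)
ss
#> <steady_state: residual 9.96e-16>
#>         E         C         S         P
#> 0.7655912 0.3344088 0.6551971 1.3103942

reaction_affinities(sys, ss$x, units = "kJ")
#>   reaction          Af          Ar             A
#> 1     bind 0.008305868 0.008305868 -6.181722e-16
#> 2  release 0.008305868 0.008305868  1.634248e-16
```

The closed system settles to detailed balance: both reactions end with zero
affinity (A ≈ 0 to machine precision), i.e. zero driving force and zero
flux — a property guaranteed by construction, not by luck.

An open, driven system shows the opposite: the glycolysis model at steady
state transduces free energy along the pathway.  `energetics_report()`
computes the per-reaction affinities, the pathway weights from the exact
internal null space, the overall reaction, and the pathway total two
independent ways:

```r
energetics_report()
#> Pathway energetics
#>   overall reaction: G6P + 2 NAD + 3 ADP + 2 Pi <=> 2 PYR + 2 NADH + 3 ATP + H + 2 H2O
#>   pgi      A =     43.4 kJ/mol  (x1)
#>   pfk      A =     81.0 kJ/mol  (x1)
#>   fba      A =     14.6 kJ/mol  (x1)
#>   tpi      A =      8.4 kJ/mol  (x1)
#>   gap      A =     51.5 kJ/mol  (x2)
#>   pgk      A =     23.9 kJ/mol  (x2)
#>   gpm      A =     13.5 kJ/mol  (x2)
#>   eno      A =     45.1 kJ/mol  (x2)
#>   pyk      A =     17.0 kJ/mol  (x2)
#>   total: 449.4 kJ/mol (weighted sum), 449.4 kJ/mol (chemostat potentials)
```

Each glucose-6-phosphate consumed yields 2 pyruvate, 3 ATP and 2 NADH while
dissipating 449.4 kJ/mol across the nine reactions (weights 1,1,1,1,2,2,2,2,2
from the stoichiometric null space).

Other entry points: `mapk_cascade()` / `mapk_activation()` (ultrasensitive
signal-response curves, bistability under positive feedback),
`calibrate_mass_action()` / `calibrate_michaelis_menten()` plus
`run_benchmark()` (rate-law comparison under ±30% perturbations),
`kinetic_to_thermo()` (detailed-balance checking and parameter conversion),
`generate_fixture()` (random consistent test networks), and a thin CLI at
`inst/cli/bondgraphr` (`odes`, `simulate`, `steadystate`, `perturb`,
`energetics`, `preset`, `fixture`).

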