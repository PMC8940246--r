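---
title: "Coupled constraint-based and whole-body transport modeling of gut-derived oxidative toxins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coupled constraint-based and whole-body transport modeling of gut-derived oxidative toxins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gutbrainflux)
```

## The modeling problem

Constraint-based models (COBRA) describe metabolism at steady state: given a
stoichiometric matrix $S$, flux bounds $lb \le v \le ub$, and a linear
objective, flux balance analysis (FBA) solves
$\max\, w^\mathsf{T} v$ s.t. $S v = 0$. They say nothing about time or about
where a secreted compound goes. Physiologically based pharmacokinetic (PBPK)
models describe exactly that — transport of a compound between organs through
the blood — but treat each organ as a black box with fixed generation and
elimination rates. This package couples the two so that the gut microbiome's
toxin output, computed mechanistically from diet and community composition,
drives a whole-body distribution model, which in turn bounds what the gut and
brain networks may absorb at the next instant.

Two reactive oxygen species are followed throughout: hydrogen peroxide and
superoxide. The host's superoxide dismutase,
$2\,\mathrm{H}^+ + 2\,\mathrm{O_2^{s-}} \to \mathrm{O_2} + \mathrm{H_2O_2}$,
links the two pools: scavenging superoxide produces peroxide at half the
molar rate, so interventions can lower one toxin while raising the other.

## Community assembly

`build_community()` merges N member models and a host model. Every member id
is suffixed with its tag; every extracellular metabolite gains a reversible
luminal transport reaction into the shared compartment `lu` (positive flux =
secretion into the lumen); every lumen metabolite gains a diet exchange
(uptake side, `lb = -max_uptake` after `apply_diet()`) and a fecal exchange
(secretion side). Member-level boundary exchanges are replaced by the luminal
transports, which is how the common microbiome community-modeling toolchains
assemble such models; the host is linked to the lumen exactly like a member.
Diet fluxes are interpreted per community (mmol/hr) — relative abundance is
encoded in the pareto weights, not by rescaling stoichiometry. Oxygen uptake
is capped per member (`set_oxygen_condition()`, default `lb = -1` mmol/gDW/hr,
the aerobic small-intestine condition).

Exchange identifiers use `_diet`/`_fecal` suffixes (`EX_<met>_lu_diet`)
rather than bracketed compartment tags, because brackets and parentheses are
not valid SBML SIds; the round-trip through `write_sbml()`/`read_sbml()`
stays lossless.

## Multi-objective growth

Every cell in a multicellular model maximizes its own objective, so a single
FBA objective is replaced by a pareto problem over the member biomasses (and
the host's). Two searches are provided:

* **Linear search** (equal weights): starting from the per-objective minima,
  all objective lower bounds advance by equal per-objective increments while
  the LP stays feasible. The increment is (per-objective range)/`max_iterations`
  — the stopping criteria (iteration cap, step norm below tolerance) follow
  the published algorithm, which leaves the step size itself open; dividing
  the range by the iteration cap makes the cap an exact resolution control.
  Once a step fails, the increment is halved until its norm drops below the
  tolerance, so the returned point sits on the front to within `tolerance`.
* **Binary search** (abundance weights): the search ray from the minima has
  direction proportional to the weights (a 20:80 community advances its two
  objectives at a 1:4 ratio); bisection finds the furthest feasible scaling.

Weights follow the fixed scheme of `compute_weights()`: host 1/6, remainder
split `p:(100-p)` between the beneficial and harmful classes, equally within
each class. At $p = 80\%$ a harmful member's weight is $1/18 = 0.0556$ to
four decimals (tabulations that print 0.0555 for one member are rounding of
the same value).

Candidate feasibility is tested by solving the LP with the objective lower
bounds raised to the candidate point — the direct reading of
"advance until infeasible". Because an iterative search stops within its
tolerance of the facet, `fix_pareto_state()` accepts a pinning slack; the
coupling loop pins with a band of ten times the search tolerance, while the
user-facing default remains an exact `lb = ub` pin.

## The whole-body transport model

Each of six tissues (brain, heart, adipose, liver, gut, kidney) is a
permeability-limited, well-stirred tank with a vascular and an extravascular
sub-compartment:

$$\frac{f V_T}{1+f}\frac{dC_T}{dt} = Q_T(C_{ART} - C_T) + P_T S_T\!\left(\frac{C_{EV,T}}{K_T} - C_T\right),$$
$$\frac{V_T}{1+f}\frac{dC_{EV,T}}{dt} = P_T S_T\!\left(C_T - \frac{C_{EV,T}}{K_T}\right) + gen_T - cons_T,
\qquad f = \frac{V_T}{V_{EV,T}}.$$

The left-hand-side volume factors are implemented exactly in this printed
form (conventions for permeability-limited models vary; with these factors
the conserved amount uses effective volumes $fV/(1{+}f)$ vascular and
$V/(1{+}f)$ extravascular, and the equilibrium $C_T = C_{ART}$,
$C_{EV} = K_T C_T$ is stationary — both properties are asserted by tests).
The blood pool closes the system with flow-weighted return and renal
clearance on the arterial side,
$V_B\,\dot C_{ART} = \sum_T Q_T C_T - (\sum_T Q_T) C_{ART} - CL_R C_{ART}$;
clearance can be switched to the kidney vascular compartment
(`clearance_site = "kidney"`). Integration uses `deSolve::lsoda` with
`rtol = 1e-8`, `atol = 1e-12` M; undershoots below zero are clipped with a
warning.

## The coupling loop

`run_integration()` discretizes time (default 15-minute steps over 6 hours,
all compartments starting at $10^{-4}$ M per species). Each step, per organ:

1. The toxin input bound is derived from the organ's current extravascular
   concentration: $\mathrm{bound} = C \cdot V_{EV} \cdot 10^{9} /
   (\mathrm{gram\ weight} \cdot \Delta t)$, in nmol/gDW/hr. The $10^9$
   converts M to nmol and the division by $\Delta t$ implements the static
   assumption that a reaction may consume the whole extravascular pool
   within one step; the organ model's gDW is equated to the organ gram
   weight (rat gut 7.26 g, brain 2 g).
2. Reversible toxin exchanges were split beforehand into irreversible
   input/output pairs, so the bound applies to the input reaction alone.
3. The organ LPs run in the published order: pareto-optimal growth (gut:
   member + host biomasses; brain: the ATP maintenance flux) is pinned; toxin
   outputs are maximized (generation) and pinned; toxin inputs are maximized
   (consumption); for the brain, the GABA and glutamate demand fluxes are
   then optimized under the pinned state.
4. Realized fluxes convert back to mol/hr terms
   ($\mathrm{flux} \times \mathrm{gram\ weight} \times 10^{-9}$) and the
   transport model advances one step (explicit splitting: the LPs always see
   start-of-step concentrations).

An LP may route toxin simultaneously through both halves of a split exchange
pair (uptake plus re-secretion); maximizing outputs before inputs makes such
pass-through the optimal vertex whenever the input bound is generous. The
transport terms therefore use the **net** flux per species — gross realized
fluxes are preserved in the trajectory record. Without netting, the realized
consumption would always equal the bound and the extravascular pool would be
emptied every step regardless of the organ's actual detoxification capacity.

Within each coupling stage the multi-objective maximizations use the binary
search (equal-weight binary and linear search agree within the search
tolerance, which the tests assert); the binary search needs roughly
$\log_2(\mathrm{range}/\mathrm{tolerance})$ LP solves instead of up to
`max_iterations`, which keeps a 24-step, two-organ integration in the
ten-second range.

## Comparison statistics

For a reaction with FVA intervals $(min_1, max_1)$ before and
$(min_2, max_2)$ after a condition change, the mean shift is
$\left|\frac{max_1+min_1}{2} - \frac{max_2+min_2}{2}\right|$ and the range
change is $(max_1-min_1) - (max_2-min_2)$, kept signed. Reactions are ranked
by decreasing mean shift, ties by decreasing range change, residual ties
alphabetically. The pathway score of a subsystem is the fraction of its
reactions whose mean shift exceeds a threshold; "shifted" is not given a
numeric definition in the source description, so the default threshold is
the numerical noise floor `1e-6` (configurable). Scores are reported raw —
no significance test is attached, since none is specified for them.
The toxic vs non-toxic protocol (`compare_toxic_nontoxic()`) raises the lower
bounds of the toxin input/output exchanges to the steady-state fluxes of the
integration (toxic) or to a scaled fraction, default 0 (non-toxic), and
compares FVA under both.

Secretion products are ranked by their fecal-exchange FVA maxima; member
attribution reads the luminal transport fluxes of the flux distribution that
attains each maximum. That vertex is generally not unique, so attribution is
representative; the tests use communities with unique producers.

## What the fixtures emulate — and what they do not

The toy fixtures stand in for genome-scale reconstructions (gut bacterial
collections, a small-intestinal enterocyte, neuronal models), which are
external inputs to this package. They are hand-designed so that every
optimum used in a test is hand-checkable:

* **Members** ferment two dietary carbons. Harmful members gain 2 ATP per
  starch but leak one unit each of H2O2 and superoxide per starch catabolized
  (0.2 per fiber); beneficial members gain 2 ATP per fiber, 1 per starch, and
  cannot produce toxins at all. Toxin output is therefore stoichiometrically
  tied to pinned growth, which makes generation reproducible across
  alternate optima.
* **The host** grows on the members' acetate (cross-feeding) and carries
  capacity-limited catalase and superoxide dismutase.
* **The brain** supplies ATP maintenance, and its glutamate/GABA synthesis
  competes with peroxide/superoxide reduction for NADPH, so forced toxin
  influx lowers the attainable GABA demand flux linearly.
* **Diets**: high-fiber (fiber 500, starch 100) and Western (starch 500,
  fiber 100) plus acetate, oxygen and protons.
* **Transport parameters** are rat-scale: organ volumes of 1-10 mL, blood
  flows of 0.02-0.1 L/hr, $K_T = 1$, renal clearance 0.02 L/hr, and the rat
  organ gram weights (gut 7.26 g, brain 2 g) used by the unit conversion.
  Millilitre-scale volumes are the physically consistent choice for a rat
  and make the microbial source terms visible against the fixed $10^{-4}$ M
  initial condition: the 6-hour plateau sits near
  $C_\infty \approx \mathrm{generation}/CL_R$, above the initial value, so
  the default simulation shows the saturating monotone rise. With
  litre-scale organs the same fluxes would perturb concentrations by parts
  in $10^4$ and every trajectory would be clearance-dominated decay.

Passing tests on these fixtures demonstrate that the algorithms are
implemented correctly (counts, optima, conservation laws, orderings), not
that any real community behaves this way: the fixtures have no transporter
redundancy, no maintenance costs, no realistic secretion spectra, and their
toxin yields are design choices. Quantitative claims about specific organisms
require the external SBML reconstructions and their curated diets.

## Numerical choices

* LP backend: a bounded-variable two-phase primal simplex (RcppArmadillo),
  written for this package and validated against an independent
  interior-point/simplex implementation on random bounded LPs during
  development. Feasibility/optimality tolerance `1e-9`
  (`options(gutbrainflux.lp_tol = ...)`); dense basis inverse with periodic
  refactorization; Bland's rule engages on stalling to preclude cycling.
  FBA flux vectors are vertices and not unique — everything asserted in the
  tests is solver-invariant (objective values, FVA ranges, net exchanges).
* Pareto searches: `max_iterations = 100`, `tolerance = 1e-6` (Euclidean
  norm on the objective vector). FVA after pinning uses 100% of the pinned
  objective value (no optimality fraction), since the fixed state is given
  by the pareto point itself.
* Degenerate inputs: empty diets close all uptakes (growth 0); a member with
  no extracellular metabolites joins the community with a warning and no
  transports; missing SBML bounds default to $(-1000, 1000)$ with a warning.
* Problem sizes: the shipped test suite and acceptance script run the
  five-member community (about 125 reactions merged), 24-96 coupling steps,
  and grid oracles at 50x50 — sizes chosen so every check is exact or
  brute-force verifiable at desk scale.

## Known limitations

* The coupling is a static-optimization dFBA: within a step fluxes are
  constant and growth does not deplete the diet between steps (the diet
  bounds are per-hour rates, reapplied each step).
* Netting removes futile uptake/re-secretion from the transport terms but
  cannot attribute gross pass-through to mechanisms; gross fluxes are
  reported for inspection.
* Member attribution of secretion products inherits LP degeneracy.
* No thermodynamic or loopless constraints; no gap-filling or curation of
  input models.
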