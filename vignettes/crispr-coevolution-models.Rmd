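---
title: "Modelling regulated CRISPR immunity in prokaryote-phage coevolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling regulated CRISPR immunity in prokaryote-phage coevolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crisprcoevo)
```

## The scientific problem

CRISPR cassettes give prokaryotes adaptive immunity: infected cells
acquire short fragments (spacers) from phage protospacers and use them
to restrict subsequent infections.  The same acquisition machinery can,
however, pick up fragments of the host's own genome; such
self-targeting spacers direct the interference machinery against the
host chromosome and kill the cell.  Two mitigating mechanisms are built
into the models implemented here: infection-induced activation (all
CRISPR reactions run in uninfected, "free" cells at a suppressed level
`delta` relative to infected cells, `delta = 0` meaning complete
repression) and spacer deletion (at rate ratio `G_C` relative to
acquisition).  The package asks, with deterministic mass-action ODE
models, when a regulated CRISPR module helps its host, when it behaves
as an abortive-infection (ABI) system, and when autoimmunity drives the
host extinct.

## The two models

**Simple model (3 variables).**  Free cells `P` grow logistically,
phage `V` convert them to infected cells `Q`, and infected cells leave
by restriction (back to `P`, rate group `G_Qp`), autoimmune death
(abortive infection, `G_Qphi`), or lysis (`G_Qv`, releasing `alpha_v`
phage each); free cells die autoimmunely at `delta * G_Pphi`.  All
densities are measured in units of the carrying capacity and time in
units of the adsorption time `1/(alpha_q * Phi_p)`.  `simple_rhs()` is
the field, `fixed_points_simple()` its three steady-state families:
extinction `E*`, the phage-free state `F*` with
`P = 1 - delta * G_Pphi / A_P`, and coexistence `C*`.

The closed form used for `C*` is

```
P_c = (G_V / alpha_v) * (1 + (G_Qphi + G_Qp) / G_Qv)
V_c = G_Q * (A_P (1 - P_c) - delta G_Pphi) / (A_P P_c + G_Qphi + G_Qv)
Q_c = P_c V_c / G_Q,       G_Q = G_Qphi + G_Qp + G_Qv
```

obtained by solving the steady state with the `-P*V` adsorption sink
dropped from the phage equation only.  That neglect is valid when
`alpha_v * G_Qv / G_Q >> 1` (many phage released per infected-cell
removal); `fixed_points_simple()` therefore always reports both this
closed form and a damped-Newton refinement of the exact root seeded
from it, together with their relative discrepancy, and downstream code
uses the refined root.  Across random parameter draws the discrepancy
scales like the inverse of the validity ratio, e.g. about 1% at a ratio
of 100.

The factor `1 + (G_Qphi + G_Qp)/G_Qv` in `P_c` is the immune advantage:
both restriction *and* infected-cell autoimmunity raise the host's
steady-state density above the defenseless phage-limited level
`G_V/alpha_v` — abortive infection is beneficial during coexistence.
Two activation thresholds control feasibility
(`delta_thresholds()`): hosts survive at all only while
`delta < delta1 = A_P/G_Pphi`, and coexistence requires the tighter
`delta < delta2 = A_P (1 - P_c)/G_Pphi`; `delta2 < delta1` always.  In
the `(delta, G_Qphi)` plane the coexistence/phage-evasion boundary is,
in the same large-ratio limit, the straight line
`delta/K1 + G_Qphi/K2 = 1` computed by `coexistence_boundary()`.
Stability is classified twice at every fixed point — Routh-Hurwitz
conditions on the characteristic polynomial and a numerical
eigendecomposition — and any disagreement beyond the marginality
tolerance (1e-9) is downgraded to "marginal" (`assess_stability()`).

**Detailed model (10 variables).**  The spacer content of each
population is tracked as per-cell quotas: active (`Y_*A`), inactive
(PAM-mutated, `Y_*I`) and self-targeting (`Y_*S`) spacers in infected
(`Y_Q*`) and free (`Y_P*`) cells, plus the active phage-protospacer
pool `X_A` available to infected cells.  Quotas are measured in units
of the phage protospacer complement `pi_v`; the host genome carries
`beta * pi_v` self-targeting protospacers, so `beta` is the
host-to-phage protospacer ratio and `beta = 0` represents perfect
self/non-self discrimination during acquisition.  Cell densities are
in carrying-capacity units, phage in burst-size units, and time in
units of the spacer acquisition time `1/alpha_c` (CRISPR evolutionary
time), which makes the population-dynamic groups large (`A_P = 1e6`
at the reference kinetics) and the system very stiff.  Per-cell
immunity and autoimmunity rates are `G_Qp * Y_QA` and
`G_Qphi * Y_QS` (free cells: `delta * G_Qphi * Y_PS`); infections
dilute infected-cell quotas through the per-capita flux `A_V*P*V/Q`,
and restriction returns infected-cell quotas to the free pool through
mixing terms proportional to `G_Qp * Y_QA * Q/P`.

With phage absent the model collapses to the free-cell block: active
and inactive spacers are progressively lost while the self-targeting
quota settles at the acquisition/deletion balance `Y_PS* = beta/G_C`
(`phage_free_fixed_point()`), giving the central survival constraint

```
delta < delta_max = A_P * G_C / (G_Qphi * beta)
```

(`delta_max()`): the tolerable level of free-cell CRISPR activity is
set by growth rate versus the autoimmunity potential of the
equilibrated self-targeting pool.  When spacer quotas have
equilibrated, the population block is *exactly* the simple model with
frozen rate constants; `reduce_to_simple()` performs that mapping
(including the time-unit and phage-unit conversions) and a test
verifies the two fields agree to rounding.

**Variants** (`detailed_rhs(variant = ...)`): `no_abi` removes the
autoimmune loss of infected cells (free-cell autoimmunity retained),
used to quantify how ABI suppresses phage; `deletion_constitutive`
expresses the spacer deletion machinery at full rate in free cells;
`deletion_inverse` additionally represses deletion in infected cells.
Both decoupled-deletion variants cut the phage-free self-targeting
burden from `beta/G_C` to `delta*beta/G_C`, which relaxes the survival
constraint accordingly.

## Parameters, units, defaults

Dimensional containers (`simple_params_dim()`,
`detailed_params_dim()`) use rates per hour, densities per ml.  Two
presets cover the standard conditions:

* `"fig1-simple"`: `alpha_p = 1/hr`, `Phi_p = 1e8 cells/ml`,
  `alpha_q = 5e-9 ml/phage/hr`, `gamma_v = 5/hr`, `alpha_v = 50`
  (giving `A_P = 2`, `G_V = 10`).  The remaining rates are documented
  defaults: `gamma_qp = gamma_qphi = gamma_qv = 1/hr`, and
  `gamma_pphi = 1/hr` so that `G_Pphi = A_P`, which places the
  host-extinction line at exactly `delta = 1`.
* `"table2-detailed"`: additionally `alpha_c = 1e-6/hr`,
  `pi_v = 1000`, `mu_v = 3e-7` per protospacer, `gamma_qv = 1/hr`.
  The per-spacer immunity rate is reported in the literature as a
  range (1e-6 to 1 per spacer per cell per hour); the preset uses 1.
  Parameters that the reference conditions sweep get reproducible
  defaults, flagged in the record: `gamma_c = alpha_c` (`G_C = 1`),
  `gamma_qphi = gamma_qp`, `beta = 1`, `delta = 0.01`.  The burst size
  is not part of the reference kinetics table; 50 is carried over from
  the simple-model preset and documented as an assumption.

Two conventions deserve a note because the sources leave them open.
The inactivation flux `M_V` couples active and inactive free-cell
quotas; dimensional consistency of that equation forces
`M_V = mu_v / alpha_c` (0.3 at the reference values), and
`nondimensionalize_detailed()` uses that definition while allowing an
override.  Second, the regulation scale is biologically meaningful on
`[0, 1]`, and user-facing configuration rejects values above 1; the
parameter containers themselves accept `delta > 1` so that bifurcation
scans can cross the `delta = 1` extinction line.

## Numerical choices

* **Integrator.**  `lsoda` (via deSolve) on compiled C right-hand
  sides, relative tolerance 1e-8, absolute 1e-12.  The stiff (BDF)
  order is capped at 2: the damped predator-prey spiral of the
  population block puts eigenvalue pairs at ~86 degrees from the
  negative real axis, outside the stability wedge of the higher-order
  BDF formulas, which otherwise pins the step size at the oscillation
  period (~1e-6 CRISPR time units) and stalls any horizon-scale run.
  BDF2 is A-stable and steps over the decayed oscillation freely.
* **Singular per-capita terms.**  The ratios `A_V*P*V/Q` and
  `G_Qp*Y_QA*Q/P` are undefined at extinct populations.  Denominators
  are floored at `eps_pop = 1e-12` and each ratio is multiplied by the
  smooth gate `x^2/(x^2 + g^2)` with `g = 1e-10` (the extinction
  threshold).  The smoothness matters: a hard cutoff makes the solver
  chatter whenever a dying population hovers at the threshold.  The
  non-singular quota reactions stay active, so after phage extinction
  the formal infected-cell quotas relax to their acquisition/deletion
  balance — the zero-density limit of the dynamics, and the attractor
  that steady-state maps report.
* **Negative densities** are prevented from feeding back by clamping
  the state at zero inside the right-hand side (which preserves the
  exact zero fixed points) and clipped, with a logged count, in stored
  trajectories.
* **Steady-state detection** (`find_steady_state()`) integrates in
  doubling rounds (default first horizon 50 simple / 100 detailed
  nondimensional units, at most 10 rounds) until (i) the residual
  `max|rhs|`, normalized by the largest rate group of the
  parameterization, falls below 1e-8 — an absolute residual criterion
  would demand ~1e-14 accuracy in `P` when `A_P = 1e6` — and (ii) the
  trailing-window drift of every coordinate, relative to
  `max(|x|, threshold)`, falls below 1e-6.  Coordinates that sit below
  the extinction threshold, and the formal infected-cell quota
  coordinates once the infected pool is extinct, are excluded: a
  population decaying exponentially to zero must not block
  convergence, while one decaying to a small positive level must not
  converge early.  For the detailed model a damped-Newton polish with
  a numerical Jacobian then certifies the root; when the certified
  root lies within 1e-4 of the integrated endpoint, the remaining
  drift is the tail of the slowest relaxation mode (rate `delta*G_C`,
  arbitrarily small) and the state is accepted as converged.
* **Extinction** is reported when a density stays below 1e-10
  (carrying-capacity units) for the rest of the horizon; ODE densities
  never reach exact zero on their own.
* **Default initial condition** for time courses: `P = 0.1`,
  `V = 0.01`, everything else 0 — a small founding population meeting
  a smaller inoculum; overridable everywhere.
* **Boundary tracing** (`trace_boundary_2d()`) classifies each grid
  node by simulation (never by the analytic formulas, which serve as
  independent oracles in the tests) and refines each crossing by
  bisection to a relative tolerance of 1e-3.  Fold/collision points in
  one-parameter continuation are located by a V-fit through the
  branch-distance minimum.
* **Regime classification** (`classify_steady_state()`): regime III if
  the host is extinct; regime I if the immune-advantage score
  `(G_Qp*Y_QA + G_Qphi*Y_QS)/G_Qv` is below `eps_adv = 1e-3` (the
  idealized regime-I condition is an exact zero, unattainable
  numerically); regime II if the restriction share `G_Qp*Y_QA/G_Qv`
  exceeds `eps_restrict = 1e-3`; regime IV otherwise (advantage
  carried by self-targeting spacers alone — a pure ABI system).  Very
  low phage density in regime II is reported but does not affect the
  label.  Regime IV is read as a survival regime: its mechanism
  (hosts exploiting accumulated self-targeting spacers as an
  infection-triggered toxin) requires living hosts.
* **Sweeps** (`sweep_regimes()`) warm-start each cell from its
  neighbour at the next-larger `G_C` in the same `beta` row, flooring
  populations at the default inoculum.  Traversing towards smaller
  `G_C` means inherited self-targeting quotas approach their
  equilibria from below and never transiently overshoot the
  autoimmune-crash threshold; with these choices warm- and
  cold-started maps agree on every cell of the benchmark grids, and
  20x20 maps run in a couple of seconds.

## Study conditions in the tests

The test suite exercises the reference conditions at sizes chosen for
tight feedback: regime maps on 20x20 (beta in 1e-2..1e2, G_C in
1..1e6, log-spaced) at `delta = 0.01` and `delta = 0`; variant
comparisons on shared 10x10 grids at `delta = 0.01` (ABI removal) and
`delta = 1e-4` (decoupled deletion); 50 randomized phage-free draws
for the survival constraint (log-uniform over beta in 1e-1..1e2, G_C
in 1..1e3, G_Qphi in 1e7..1e10, delta in 1e-3..1, draws within 5% of
the boundary excluded — and the lower bounds keep the slowest
relaxation rate `delta*G_C` above ~1e-3 so every draw equilibrates
within the capped horizon); 10 quota-relaxation draws; and
closed-form/root comparisons across 40 random simple-model draws.
Boundary-tracing checks run on coarse grids (at most 9x6 nodes) since
bisection supplies the precision.

## Known limitations

* Spacer *sequences* are not modelled: quotas are population averages,
  so strain structure, spacer diversity and arms-race dynamics are out
  of scope by design.
* The models are deterministic; extinction is a threshold statement
  about densities, not a demographic-stochasticity prediction.
* The regime-II/IV distinction rests on the formal infected-cell
  quotas at steady state; when phage are extinct these are
  zero-density limits rather than measurable cell contents, and near
  the II/IV interface the restriction share crosses its threshold
  non-monotonically in `G_C` (a fold where phage re-establish), so a
  coarse map can show a one-cell-wide regime-IV filament along that
  edge.
* Under `deletion_inverse`, infected-cell quotas have no equilibrium
  after phage extinction (nothing deletes them); such cells report
  convergence of the meaningful coordinates only.
* Hopf bifurcations and limit cycles are not searched for; all mapped
  boundaries are simple crossings between steady-state regimes.
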