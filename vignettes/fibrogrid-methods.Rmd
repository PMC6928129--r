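---
title: "Coupling a logic-based signaling network to an agent-based model of fibrosis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coupling a logic-based signaling network to an agent-based model of fibrosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibrogrid)
```

## The model

`fibrogrid` simulates the progression of cardiac fibrosis by coupling two
models that live on different scales:

* an **intracellular scale**: each fibroblast carries a logic-based
  differential equation (LDE) model of its signaling network, in which the
  activity $y$ of every node evolves as
  $$\frac{dy}{dt} = \frac{F(\mathbf{y})\,y_{max} - y}{\tau},$$
  where $F$ is the inclusive-or combination of the fluxes of all reactions
  targeting the node.  Each reaction multiplies its weight $w$ by the
  logic-gated product of regulator contributions: an activator at
  normalized activity $x$ contributes the normalized Hill activation
  $$f(x) = \frac{B x^n}{K^n + x^n},\qquad
    B = \frac{EC_{50}^n - 1}{2\,EC_{50}^n - 1},\qquad K^n = B - 1,$$
  and an inhibitor contributes $1 - f(x)$.  The rescaling pins
  $f(0)=0$, $f(EC_{50})=\tfrac12$, $f(1)=1$.  Defaults are $w = 0.9$,
  $n = 1.4$, $EC_{50} = 0.6$; time constants derive from the reaction
  class: 0.1 h for signaling, 1 h for transcription, 10 h for
  translation.

* a **tissue scale**: a 10 x 10 grid of 10 um cells, each carrying value
  layers for collagen area fraction and five cytokine concentrations
  (latent and active TGF-$\beta$, IL-1$\beta$, IL-6, TNF-$\alpha$, all
  pg/mL).  Fibroblast agents occupy at most one cell each, migrate
  randomly, and read and write the layers.

The interface between the scales is a set of translator equations.
Concentrations become network input weights by receptor occupancy,
$w_c = C/(C + K_d)$, so a ligand at its dissociation constant produces
half-maximal input.  In the other direction, network output activities
scale secretion: latent TGF-$\beta$ obeys

$$\frac{d[L]}{dt} = k_{gen} + k_{sec}\,a_{latentTGF\beta}
  - (k_{deg} + k_{act})[L],$$

with active TGF-$\beta$ slaved to the latent pool by a rapid-equilibrium
assumption (active TGF-$\beta$ degrades within minutes, far below the 1 h
tick).  IL-1$\beta$ and TNF-$\alpha$ follow generation/degradation
kinetics; IL-6 adds a secretion term scaled by the IL-6 output node.
Collagen obeys

$$\frac{dF}{dt} = \mathrm{occ}\cdot k_{dep}\,(a_{ColI} + a_{ColIII})
  - k_{deg}\,F,$$

deposition only where a fibroblast sits, first-order degradation
everywhere (evenly distributed MMP activity).

### The scheduler

The coupled time step is 1 h.  Each tick executes, in order: translate
local concentrations into input weights; integrate every agent's network
for 1 h with weights frozen; update the cytokine layers with activities
frozen; update the collagen layer; migrate.  This operator splitting
mirrors the sequential method list of the underlying agent-based design.
All agents read their inputs before any layer is updated (simultaneous
update); whether secretion within a tick should be visible to neighbors
in the same tick is genuinely ambiguous, and the simultaneous choice is
flagged here rather than silently assumed.  A six-week run is exactly
1008 ticks.

## Parameters

Receptor dissociation constants (pg/mL): IL-6 462,000; IL-1$\beta$
8,750; TNF-$\alpha$ 323; TGF-$\beta$ 700.  Cytokine kinetics: see
`?coupling_params` for the full table of generation, secretion and
degradation rates.  The generation rates are mass-balance values: the
top-of-gradient generation rate equals the rate whose steady state
sustains a concentration of twice the dissociation constant, e.g.
$k_{gen,TNF\alpha} = 2 K_d k_{deg} = 2 \times 323 \times 1.386 = 895.4$
pg/mL/h.

### The active TGF-$\beta$ volume factor

Taken literally, $[A] = k_{act}[L]$ with the shipped generation rate
would put active TGF-$\beta$ near $4\times10^5$ pg/mL, far above the
prescribed gradient ceiling of twice the dissociation constant
(1,400 pg/mL).  The two compartments have very different volumes: latent
TGF-$\beta$ is matrix-bound in the 1e-9 mL pericellular box, while
active TGF-$\beta$ dissolves into the 3.125e-7 mL media column.
Re-dissolving the activated mass across that 312.5-fold volume ratio,
$$[A] = k_{act}\,[L]\,\frac{V_{peri}}{V_{media}},$$
reproduces the shipped latent generation rate of 530,000 pg/mL/h from
the 2 K_d ceiling to within 0.2%, and keeps the activated fraction of
total TGF-$\beta$ mass at $k_{act}/(1+k_{act}) \approx 4.3\%$, inside
the physiological 4-5% band.  The volume-scaled form is therefore the
default; `coupling_params(volume_scaling = FALSE)` switches to the
literal form for users who absorb the factor into their rates.  The
numerical agreement is evidence for the scaled interpretation, not
proof.

## Numerical choices

* **Network integration** uses `deSolve` with rtol 1e-6 / atol 1e-8.
  Whole-trajectory solves (`simulate_network`) use the stiff-capable
  `lsoda`.  The per-tick agent updates integrate all agents jointly as
  one block-diagonal system with the Adams method: the dynamics are
  non-stiff at these time constants ($\tau \ge 0.1$ h), and avoiding
  Jacobian formation keeps the cost linear in the number of agents.
  Activities are clipped to $[0, y_{max}]$ after each solve.
* **Layer updates** use the exact solution of the frozen-coefficient
  linear ODE over each tick rather than explicit stepping; with
  $k_{deg,TNF\alpha}\,\Delta t = 1.386$ an explicit Euler update would
  be badly damped, while the exponential form is unconditionally stable
  and exact.
* **Migration** uses a Moore (8-neighbor) neighborhood, chosen for
  isotropy on a square grid; the neighborhood is not dictated by the
  model description.  A move goes to a uniformly chosen unoccupied
  in-bounds neighbor; fractional speeds (e.g. 1 grid per 10 h) move with
  the corresponding per-tick probability, preserving the expected
  displacement rate.  Agents are processed in a seeded random order each
  tick, shuffled over position-sorted agents so that relabeling agents
  cannot change the dynamics.
* **OR gating.** Where several reactions target one node, or an OR rule
  lists several regulators, fluxes combine by inclusive-or
  ($g_1 + g_2 - g_1 g_2$).  Whether a user-supplied network expects
  gate-level or reaction-level OR is a convention of its exporting tool;
  users coupling their own networks should confirm this matches.
* **Degenerate inputs.** Gradients on a single-cell axis, agents beyond
  grid capacity, doses for unmapped cytokines, zero baseline mRNA in
  calibration, and out-of-range Hill parameters all fail fast with
  descriptive errors rather than producing silent nonsense.

## Scenarios and calibration

`make_scenario()` builds the canonical conditions: **unstimulated**
(clamped layers pinning all four cytokine weights at the baseline 0.25),
**stimulated** (weights 0.5, i.e. concentrations at $K_d$), **gradient**
(inflammatory cytokines rising left to right, TGF-$\beta$ bottom to top,
each spanning 0.2x to 2x its $K_d$ at steady state, receptor activation
~16.7% to ~66.7%), and **invitro** (clamped dose experiments on a single
fibroblast).  Clamped scenarios freeze the concentration layers only;
collagen always evolves.  Verification scenarios seed one static
fibroblast per cell; collagen in the clamped scenarios starts at the
healthy 4% so the baseline run is a true steady-state check rather than
a 6-week transient.  Agent networks start at $y_{init} = 0$ by default
(the reported endpoints are 6-week steady states, so the initial
transient washes out); `equilibrate = TRUE` pre-equilibrates each agent
to its local steady state instead.

Collagen calibration is two-stage (`fit_collagen_coefficients`): the
ratio $k_{dep}/k_{deg} = 0.04 / (\text{baseline ColI+ColIII mRNA sum})$
is analytic, pinning the healthy 4% baseline; $k_{dep}$ is then swept
over 200 log-spaced candidates in $[10^{-4}, 10^{-1}]$ with $k_{deg}$
constrained to the ratio, minimizing the SSE of the simulated collagen
rise against an infarct time course.  Ties resolve to the smallest
$k_{dep}$.  The shipped defaults $k_{dep} = 0.0056$,
$k_{deg} = 0.0035$ (ratio 1.6) are self-consistent with the bundled
network, whose baseline mRNA sum is tuned to $\approx 0.025$.

## Statistics

Spatial heterogeneity uses the lag-1 semivariance
$r = \frac{1}{2 s_0}\sum_i\sum_j W_{ij}(x_i - x_j)^2$ with rook
(4-neighbor) adjacency.  Rook adjacency is used because the directional
variants presuppose axis-aligned pairs, and it makes the global
statistic decompose exactly: $r_{xy} s_0 = r_x s_{0,x} + r_y s_{0,y}$.
Ordered versus unordered pairs cancels through $s_0$.  By default the
statistic is evaluated at the final tick.

Parameter sensitivity (`sensitivity_coefficients`) perturbs each of the
17 coupling and collagen parameters to 0.1x, reruns with the identical
seed so migration noise cancels, and reports
$S = \frac{y_i - y_o}{p_i - p_o}\cdot\frac{p_o}{y_o}$ for total collagen
and the three semivariances.  The per-cell gradient generation fields
scale with their $k_{gen}$ parameter (so perturbing a generation rate
rescales the whole gradient), while perturbing a $K_d$ leaves the
concentration field untouched and acts purely through receptor
occupancy — this is what makes $K_d$ perturbations consequential.

## The bundled network and synthetic data

The shipped 26-species network (`fixture_network()`) is a synthetic
miniature, not a published topology: it exists so the package builds,
tests and calibrates with no external input.  It encodes the qualitative
circuit motifs that the coupled model exercises — TGF-$\beta$/Smad3
driving collagen, $\alpha$SMA and F-actin; IL-1$\beta$-induced Smad7
antagonizing TGF$\beta$R1; IL-6 through gp130/STAT with NF-$\kappa$B
crosstalk; an AP1/ET-1 autocrine loop; MMP1 integrating AP1 and
NF-$\kappa$B activation against Smad3 inhibition.  Its two collagen
mRNA reaction weights were tuned once (offline, then frozen in the
shipped CSV) so the baseline mRNA sum is ~0.025.  Real fibroblast
networks are far larger and quantitatively different; passing tests on
the fixture demonstrate the engine, the coupling and the statistics,
not biological predictions.  User networks load through
`read_network_tables()` in the same two-table dialect.

`synth_infarct_timecourse()` generates the calibration stand-in: a
saturating-exponential rise from the 4% baseline to a scar plateau
(default 35% over a 10-day time constant — typical of the collagen
accumulation measured in healing rat infarcts), sampled weekly over six
weeks with seeded Gaussian noise.  It emulates the shape and sampling of
such measurements, not any specific animal's values, and carries no
inter-animal variance structure.

## Problem sizes used in the shipped tests

Analytic and single-operation checks run at full scale instantly.  The
two full-scale runs retained in the test suite are the 6-week clamped
verification and the calibrated 6-week baseline (100 static agents, 1008
ticks each).  Stochastic comparisons are run at sizes chosen to give
clear separation at reasonable cost: the migration-speed contrast uses
20 agents for 240 ticks across 10 seeds per speed, and sensitivity sign
checks use a 4 x 4 grid for 120 ticks; both effects are
direction-stable well below full scale.

## Known limitations

* No cytokine diffusion between cells, no proliferation, no apoptosis,
  no chemotaxis, and no collagen fiber orientation: concentrations are
  per-cell well-mixed compartments and migration is unbiased.
* MMP activity is implicit: collagen degradation is uniform first-order.
* The inclusive-or gating convention and the Moore migration
  neighborhood are documented choices, not measured facts.
* Single-cell compartment volumes approximate 96-well culture geometry;
  tissue geometries would need different volumes and likely diffusion.
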