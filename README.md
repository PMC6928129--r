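# fibrogrid

Hybrid multiscale simulation of tissue fibrosis: a logic-based
differential-equation (LDE) model of cardiac-fibroblast intracellular
signaling coupled to a 2-D agent-based model (ABM) of cytokine fields and
collagen remodeling.

After a myocardial infarction, fibroblasts build and remodel scar tissue
under spatially varying inflammatory (IL-1β, IL-6, TNFα) and fibrotic
(TGFβ) cues. `fibrogrid` is for modelers who want to ask how perturbations
at the signaling level — a receptor affinity, a secretion rate, a
migration speed — propagate to tissue-level collagen content and its
spatial heterogeneity.

## The model in brief

Each fibroblast agent carries a signaling network integrated as a
normalized-Hill logic ODE: node activity *y* follows
*dy/dt = (F·y_max − y)/τ*, where *F* combines reaction fluxes by
inclusive-or, each flux being the reaction weight times logic-gated
normalized-Hill activations *f(x) = B·xⁿ/(Kⁿ + xⁿ)* (with *f*(0)=0,
*f*(EC₅₀)=½, *f*(1)=1) of its regulators. The tissue is a 10 × 10 grid of
10 µm cells with value layers for collagen and five cytokines. Every hour
the model (1) converts local concentrations into network input weights by
receptor occupancy *w = C/(C + K_d)*, (2) integrates each agent's network,
(3) updates cytokine layers (generation, fibroblast secretion scaled by
network outputs, first-order degradation; active TGFβ in rapid
equilibrium with the latent pool), (4) deposits collagen where fibroblasts
sit — *dF/dt = k_dep(a_ColI + a_ColIII) − k_deg F* — and degrades it
everywhere, then (5) migrates agents randomly. Six weeks is exactly 1008
ticks.

Network models are read from two CSV tables (species + reaction rules in
the `"[!]A [&|] [!]B => target"` dialect); a self-contained 26-species
synthetic network ships with the package, calibrated so its baseline
collagen mRNA output sustains the healthy 4% collagen area fraction under
the default kinetics.

## Worked example

Twenty fibroblasts migrating for one simulated week across crossed
cytokine gradients (inflammatory cues rising left→right, TGFβ
bottom→top, each spanning 0.2–2 × its dissociation constant):

```r
library(fibrogrid)

net <- fixture_network()
net
#> Logic-based ODE network model
#>   26 species, 37 reactions, 6 input nodes
#>   inputs: TGFb, IL1b, IL6, TNFa, AngII, Mech

world <- make_scenario("gradient", model = net, n_agents = 20,
                       migration_speed = 1, seed = 42)
sim <- run_simulation(world, duration = "1 week")
sim
#> Coupled simulation: 168 ticks, 20 agents, 2 layer snapshots
#>   final collagen: total 1.946, mean per cell 0.01946

unlist(semivariance(sim$world$layers$collagen)[c("r_global", "r_x", "r_y")])
#>     r_global          r_x          r_y
#> 1.679547e-05 1.484989e-05 1.874104e-05
```

Mean collagen is ~1.9% after one week: with only 20 of 100 cells occupied
at any time, deposition is sparse and the field is still far from the 4%
healthy steady state, which is why the lag-1 semivariance (the spatial
heterogeneity statistic, here per ordered rook-neighbor pair) is
non-zero: collagen has accumulated in pockets along the migration paths.

Individual cells can be tracked through their changing environment:

```r
tr <- agent_trace(sim, agent_id = 1, nodes = c("ColImRNA", "MMP1"))
round(tail(tr[, c("tick", "col", "row", "w_tgfb", "w_il6",
                  "ColImRNA", "MMP1")], 3), 4)
#>     tick col row w_tgfb  w_il6 ColImRNA   MMP1
#> 167  166   2   3 0.4442 0.3829   0.0529 0.1179
#> 168  167   2   4 0.4997 0.3767   0.0533 0.1079
#> 169  168   2   5 0.5452 0.3765   0.0621 0.0979
```

This agent is migrating up the TGFβ gradient (rows 3→5): its TGFβ input
weight rises and collagen I mRNA follows, while MMP1 — activated by
inflammatory signaling but repressed by Smad3 — drifts down.

Other entry points: `simulate_network()` for network-only runs,
`verification_sse()` for coupled-vs-network equivalence checks,
`fit_collagen_coefficients()` + `synth_infarct_timecourse()` for
calibrating the collagen kinetics against an infarct time course, and
`sensitivity_coefficients()` for the normalized parameter sweep. The
vignette (`vignettes/fibrogrid-methods.Rmd`) documents the equations,
parameter tables, and numerical choices.

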