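---
title: "Models and methods: oxygen transport and outflow saturation heterogeneity in capillary networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coshnet)
```

## The scientific problem

Cortical capillary beds deliver oxygen through a mesh of short, tortuous
vessels with strongly heterogeneous flow, hematocrit and transit times. Red
blood cells (RBCs) that linger on slow paths unload more oxygen than fast
ones, so the hemoglobin saturation (HS) at the distal ends of capillary
paths is spread out. That spread — the capillary outflow saturation
heterogeneity (COSH), defined as the RBC-flow-weighted standard deviation of
distal HS — measures how close the most desaturated outflows are to causing
local tissue hypoxia even when mean oxygenation is adequate. Passive
diffusive exchange of oxygen through the shared tissue, between RBCs in one
capillary (RBC diffusive interaction) and between neighboring capillaries
(capillary diffusive interaction), damps this heterogeneity. `coshnet`
implements a complete simulation pipeline to quantify that damping on
capillary networks, and a seeded synthetic-network generator so that every
stage is testable without access to reconstructed imaging data.

## The transport model

Along a capillary, hemoglobin saturation obeys

$$Q_{O_2}(S)\,\frac{dS}{dx} = -j_t(x), \qquad
Q_{O_2}(S) = v_{rbc}\left(\mu_{LD}\,\pi r_c^2\,C_0
  + \pi r_p^2\,\alpha_{\mathrm{eff}}\,\frac{dP_{eq}}{dS}\right),$$

where $v_{rbc}$ is the RBC velocity, $\mu_{LD}$ the linear density (fraction
of vessel length occupied by RBCs), $r_c$ and $r_p$ the RBC and lumen radii,
$C_0$ the RBC oxygen binding capacity, and $P_{eq}(S) = P_{50}
(S/(1-S))^{1/n}$ the inverse Hill equilibrium. The local extraction rate of
a concentric tissue sleeve of radius $r_t$ is $j_t = M_0 \pi (r_t^2 -
r_w^2)$ with uniform consumption $M_0$ and outer wall radius $r_w$.
Saturation is floored at zero: a fully desaturated RBC stops supplying
tissue. Axial diffusion inside the capillary is neglected.

At a converging bifurcation, the child's inlet saturation distribution
collects the parents' distal values with RBC-flux weights
$w_i = q_{rbc,i}/\sum_j q_{rbc,j}$, carried recursively as discrete
"atom" sets; diverging daughters inherit the parent distribution unchanged.
Propagating this through the flow-directed (acyclic) network gives a model
*without* diffusive interaction when the geometric (nearest-vessel) tissue
radii are used, and *with* capillary interaction when the functional radii
(below) are used.

Closed-form companions describe the interaction itself: a saturation
difference $\Delta S$ between paired capillaries and the within-capillary
SD $\sigma_S$ both decay as

$$Q_{O_2}(\bar S)\,\frac{dH}{dx} = -\frac{H}{K}\,
 \frac{dP_{eq}}{dS}\Big|_{\bar S},\qquad
 K_{CI} = K_{IV} + \frac{\log(r_{t,\mathrm{mean}}/r_w) - \tfrac12}
 {2\pi D_t \alpha_t},$$

with $K = K_{CI}$ (capillary interaction) or $K = K_{RI}$ (RBC
interaction): exponential damping whose rate is proportional to the
heterogeneity itself. `predict_deltaS_decay()`, `predict_sigmaS_decay()`
and `fit_decay_rate()` expose these predictions; with frozen coefficients
they are exact exponentials, which the tests exploit as analytic oracles.

## The Lagrangian surrogate

The reference for the interaction effects is a particle model
(`simulate_rbc_transport()`): individual RBCs advect at the vessel RBC
speed, are injected at inflow vessels by a gamma renewal process with mean
headway $\ell_{rbc}/(\mu_{LD} v_{rbc})$ and coefficient of variation
`spacing_cv` (default 0.5), and are routed at diverging bifurcations by
Bernoulli draws with the RBC-flux fractions. Each vessel's tissue territory
is cut into axial bins (default 5 um, widened per vessel so that one 1 ms
step never skips a bin). An RBC exchanges oxygen with the bin at its
position with flux $g\,(P_{eq}(S) - P_t)$ and conductance $g =
\ell_{rbc}/K_{IV}$ — the per-length intravascular resistance convention, so
that in the uniformly spaced, steady-tissue limit the particle model
reduces exactly to the transport equation (verified to 2% in the tests).
Bins consume $M_0 V$ continuously, are coupled axially by tissue diffusion,
and laterally to their nearest bins of *other* vessels within 30 um (up to
4 links), with the pair conductance given by the single Krogh spreading
term of $K_{CI}$. Lateral coupling is the pathway for capillary diffusive
interaction; the shared bins within one vessel provide RBC interaction; the
stochastic injection and routing produce the hematocrit fluctuations that
*grow* heterogeneity in vessels that start nearly uniform.

Two numerical safeguards matter. First, the explicit tissue update is
stabilized by flooring the effective bin capacitance at $2\,dt\,g_{max}$,
which only affects nearly volume-free bins. Second, the run starts from the
steady RBC inventory: every vessel is pre-filled at its mean spacing
(pre-filled RBCs never enter the path records). Without pre-filling, slow
vessels keep filling for longer than 10 s and the oxygen budget drifts
through the averaging window; with it, the 10 s run / last-2 s averaging
protocol genuinely samples a statistically steady state, and the window
budget (release = consumption + storage change − shortfall) closes to
round-off.

## Tissue territories

`assign_geometric_territories()` partitions the tissue box (network
bounding box plus a 5 um margin) into 1 um voxels assigned to the vessel
with the nearest centerline (exact nearest-segment sweep with a brute-force
remainder pass; ties go to the lowest vessel id). The equivalent cylinder
radius follows from $V = L\pi(r_t^2 - r_w^2)$. The functional radius of a
vessel is found by bisection so that integrating the transport equation
along the vessel reproduces its observed mean saturation drop; with the
particle run's time-averaged $\mu_{LD}$ (realized RBC flux over the
averaging window, as the drops themselves), the fitted volume equals the
vessel's oxygen release divided by $M_0$. Vessels with a negative drop (net
oxygen uptake from tissue, which occurs in a few slow vessels) keep
$r_{t,\mathrm{fun}} = r_w$ but carry their signed (negative) functional
volume, so the totals remain physically meaningful. Total functional volume
is compared against the total geometric volume over the *whole* partition —
a vessel without RBC coverage supplies nothing, but its territory is still
consumed (fed by neighbors through the tissue), so it stays in the
denominator. Over a finite averaging window, release and consumption
differ by the change in tissue oxygen storage (zero-mean across seeds, SD
about 2% of consumption — RBC flow through the network fluctuates
permanently, and tissue Po2 with it) plus any consumption shortfall in
anoxic bins. Both terms are measured exactly by the particle run, so the
conservation report closes the budget with them (the uncorrected value is
kept alongside); the corrected residual is a few tenths of a percent per
network and stays below one percent pooled over the seeded ensemble.

## The synthetic study conditions

The generator (`generate_network()`) emulates the reported statistics of
reconstructed mouse somatosensory cortex capillary networks: ~92 vessels in
a ~219 x 220 x 168 um box, diameters drawn at 5 +/- 1.5 um and clamped at 3
um, lengths 57 +/- 41 um, ~22 converging bifurcations, inflow tube
hematocrit 0.25 and RBC speeds 0.9 +/- 0.48 mm/s. Topology comes from a
strongly jittered cubic lattice with biased random edge pruning (degree
three dominates; face-adjacent nodes are preferentially stranded as
degree-one boundary stubs, mimicking how an imaged box truncates the mesh).
Tortuous centerlines realize target arc lengths above the chords, with an
iterated clamped affine map matching the length moments (within 5% at n =
500). The ground-truth flow is produced by the package's own
hydraulic-power reconstruction against full-coverage speed targets drawn
from the reported velocity distribution, which gives a hydraulically
consistent field with realistic speed spread; a naive noisy-pressure
boundary condition instead produces a heavy slow-vessel tail (speed CoV >
1) unlike the reported networks. What the generator does *not* emulate:
penetrating arterioles/venules, laminar depth structure, spatially
correlated velocity fields, or the true adjacency statistics of cortical
meshes — so passing tests demonstrate correct mechanics and faithful
statistics of the stated conditions, not morphological realism.

Flow reconstruction (`reconstruct_flow()`) minimizes dissipated hydraulic
power plus a weighted speed-misfit. Because flows are linear in the
boundary pressures at fixed hematocrit, each flow-direction iterate is an
equality-constrained quadratic problem solved exactly (gauge fixed by the
mean boundary pressure); measured speeds are signed by the current
direction estimate and the sign pattern is iterated to a fixed point,
nested in an under-relaxed outer loop with the phase-separation hematocrit
distribution (relaxation 0.5, deepened on stalls, up to 150 iterations —
the discrete switching of the Pries split law precludes the naive
20-iteration schedule). The misfit weight defaults to 1e4 times the initial
power-to-misfit ratio; at a factor of 100 the power term still visibly
shrinks the speeds. Without measurements the quadratic collapses to zero
flow; a mean inflow-outflow pressure-drop constraint is then activated.

## Parameters

| symbol | default | units | meaning |
|---|---|---|---|
| $C_0$ | 0.5 | um^3 O2/um^3 RBC | RBC oxygen capacity |
| $P_{50}$, $n$ | 47.9, 2.64 | mmHg, — | Hill equilibrium |
| $\alpha_{\mathrm{eff}}$ | 0 | um^3 O2/(um^3 mmHg) | capillary solubility (see below) |
| $\alpha_t$, $D_t$ | 3e-5, 2000 | as above, um^2/s | tissue solubility, diffusivity |
| $M_0$ | 2e-4 | um^3 O2/(um^3 s) | tissue consumption |
| $K_{IV}$, $K_{RI}$ | 1.0, 4.0 | mmHg s um/um^3 O2 | intravascular / RBC-interaction resistance |
| $V_{rbc}$ | 49 | um^3 | mouse RBC volume |

All are overridable through `oxygen_params()`; conclusions asserted by the
test suite are parameter-relative (orderings, rate ratios, conservation),
not absolute values. Two defaults deserve justification. `alpha_eff = 0`:
plasma-dissolved oxygen advection contributes under 2.5% of the convective
capacity at capillary saturations, and excluding it keeps the
particle-based and equation-based model variants exactly consistent (the
particle model tracks hemoglobin-bound oxygen); the physical value ~3.3e-5
can be supplied. `m0 = 2e-4` is fixed by the oxygen budget of the study
conditions: with the generator's realized perfusion and inflow hematocrit
0.25, it reproduces an extraction fraction of ~0.17, i.e. mean path
saturation drops of ~0.1 from an inflow saturation of 0.6 — the regime the
reference networks operate in. (A conventional bulk-cortex consumption
value of ~8e-4 would exceed what this capillary-box perfusion can deliver
and drive the tissue anoxic.)

## The analysis design

`run_cosh_study()` chains the full experiment on one seeded network:
generate, sample sparse speed measurements (40% coverage, 50 um/s noise),
reconstruct flow with inflow hematocrit 0.25, voxelize territories, run the
particle model (10 s, 1 ms steps, last 2 s averaged), fit functional radii
from its per-vessel drops, propagate the transport equation along all
inflow-to-outflow paths with geometric and with functional radii, and
assemble:

* the three-way COSH comparison (`compare_models()`): geometric-radius
  equation (no interaction) vs functional-radius equation (capillary
  interaction) vs particle model (full interaction), with the total
  reduction split into capillary and RBC shares;
* the tissue-volume conservation report;
* COSH/CTH statistics and the correlation suite (saturation drop vs
  transit time and path length; functional vs geometric radii, saturation
  and RBC flow; F-test on the radius spreads).

Distal-saturation sets are pooled per path, weighted by RBC flux (each
exiting RBC of the particle run is one sample of that ensemble). On the
default study conditions the no-interaction COSH is ~0.10-0.15 and the
particle-model COSH ~0.03-0.10: diffusive interaction removes 40-80% of
the outflow heterogeneity, and the coefficient of variation of the
saturation drop stays well below that of the transit times — transit-time
heterogeneity overstates outflow heterogeneity.

One pattern needs a caveat: the transport equation makes the saturation
drop an integral over transit *time*, so on the equation's path records the
drop correlates more strongly with transit time than with path length in
every seeded network. The particle model reproduces the magnitudes of both
correlations, but its hematocrit-fluctuation noise can reorder the two on
individual seeds; the suite therefore asserts the property where it is
structural.

## Problem sizes and determinism

The shipped tests and the acceptance script use 5 constant-inflow studies
at full reference size (92 vessels, 1 um voxels, 10 s runs) and 10
uniform-inflow studies at 60 vessels with 2 um voxels for the
heterogeneity-evolution checks; one study completes in about half a minute.
Every stochastic stage draws from a seed derived from the study's master
seed, so studies, pipelines and written artifacts are exactly reproducible.

## Known limitations

* The tissue is a set of lumped axial compartments, not a resolved 3-D
  Po2 field: quantitative agreement with fully resolved moving-RBC
  simulations is not claimed, only the mechanisms (both interactions,
  fluctuation-driven heterogeneity growth) and conservation structure.
* Region-dependent diffusivity/solubility inside the capillary (RBC,
  plasma, endothelium sublayers) is summarized by the resistance
  coefficients $K_{IV}$, $K_{RI}$.
* The generator's topology is a pruned lattice; degree statistics beyond
  the converging-bifurcation count are not matched to real networks.
* Networks of ~100 vessels truncate capillary paths, as in the reference
  study; absolute COSH values depend on that scale.
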