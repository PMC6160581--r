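# coshnet

Oxygen transport and outflow saturation heterogeneity in capillary
networks.

Cortical capillary beds have strongly heterogeneous flow, hematocrit and
red-blood-cell (RBC) transit times, so the hemoglobin saturation (HS) at
the distal ends of capillary paths is spread out. That spread — the
**capillary outflow saturation heterogeneity (COSH)**, the RBC-flow
weighted standard deviation of distal HS — determines how close the least
oxygenated outflows are to causing local tissue hypoxia even when mean
oxygenation is fine. Passive oxygen exchange through the shared tissue
(**diffusive interaction**, between RBCs within a capillary and between
neighboring capillaries) damps this heterogeneity. `coshnet` quantifies
that damping.

The package is aimed at microcirculation modelers. It provides:

* **Hemoglobin saturation transport**: the Hill-equilibrium differential
  equation `Q_O2(S) dS/dx = -j_t`, with
  `Q_O2 = v_rbc (mu_LD pi r_c^2 C0 + pi r_p^2 alpha_eff dP_eq/dS)` and the
  Krogh-sleeve extraction rate `j_t = M0 pi (r_t^2 - r_w^2)`, propagated
  through the flow-directed network with RBC-flux weighted discrete
  saturation distributions at converging bifurcations
  (`propagate_network()`, `path_outflow_ode()`).
* **Network hydraulics**: Poiseuille flow with the Pries in-vivo apparent
  viscosity and phase-separation laws, and reconstruction of unknown
  boundary pressures from sparse RBC velocity measurements by minimizing
  dissipated hydraulic power plus the measurement misfit
  (`reconstruct_flow()`).
* **A Lagrangian moving-RBC surrogate** (`simulate_rbc_transport()`):
  individual RBCs exchanging oxygen with axially-binned, laterally coupled
  tissue compartments — the reference model in which both kinds of
  diffusive interaction and hematocrit-fluctuation effects emerge.
* **Tissue territories**: exact nearest-centerline voxel partition
  (geometric radii) and functional radii fitted so the transport equation
  reproduces each vessel's observed saturation drop, with a conservation
  check of the summed volumes (`assign_geometric_territories()`,
  `fit_functional_radii()`, `conservation_report()`).
* **Closed-form interaction models**: exponential damping of paired-
  capillary differences and within-capillary SD with coefficients
  `K_CI = K_IV + (log(r_t/r_w) - 1/2)/(2 pi D_t alpha_t)` and `K_RI`
  (`predict_deltaS_decay()`, `predict_sigmaS_decay()`).
* **A seeded synthetic-network generator** emulating the topology and flow
  statistics of reconstructed mouse somatosensory cortex networks
  (~90 vessels, diameters 5 +/- 1.5 um, lengths 57 +/- 41 um, speeds
  0.9 +/- 0.5 mm/s, inflow tube hematocrit 0.25), so the whole pipeline is
  testable without imaging data (`generate_network()`).

Results come back as tibbles; fitted objects have `tidy()`/`glance()`
methods and `autoplot()`/`plot_*()` figures.

## Worked example

One complete study on a seeded synthetic network — generate, reconstruct
flow from sparse noisy velocity measurements, run the particle model for
10 s, fit functional territories, and compare the three model variants:

```r
library(coshnet)

st <- run_cosh_study(seed = 1)   # ~30 s
st
#> <cosh_study> seed 1, 92 vessels
#> <cosh_comparison>
#>           model    n  mean_s_v       cosh frac_below_0.2
#>   ode_geometric  111 0.4992940 0.09969479     0.02985458
#>  ode_functional  111 0.4881535 0.04187029     0.00000000
#>      lagrangian 1228 0.4907871 0.02920597     0.00000000
#>   COSH reduction: 70.7% total (capillary 58.0%, RBC 12.7%)
#>   tissue-volume conservation discrepancy: 0.11%
```

Reading the numbers: all three models agree on the mean distal saturation
(~0.49 from an inflow value of 0.6, i.e. a mean drop of ~0.1), but the
flow-weighted SD of distal saturation falls from 0.100 without diffusive
interaction (transport equation with geometric tissue radii) to 0.029 in
the full particle model — interaction removes ~70% of the outflow
heterogeneity on this network, most of it through capillary interaction.
Without interaction, 3% of the RBC flow leaves below S = 0.2; with it,
none does. The conservation line verifies that the summed functional
tissue volumes (from the fitted extraction rates), corrected by the
measured window storage change, match the summed geometric territories to
0.1%.

```r
glance(st$comparison)
#> # A tibble: 1 x 5
#>   reduction_total reduction_capillary reduction_rbc share_capillary share_rbc
#>             <dbl>               <dbl>         <dbl>           <dbl>     <dbl>
#> 1            70.7                58.0          12.7            82.0      18.0

tidy(st$summary)
#> # A tibble: 5 x 5
#>   pair                  n     r   p_value degenerate
#> 1 delta_s_vs_tau     1228 0.714 6.81e-192 FALSE
#> 2 delta_s_vs_length  1228 0.514 8.81e- 84 FALSE
#> 3 r_fun_vs_r_geo       91 0.462 4.05e-  6 FALSE
#> 4 r_fun_vs_s_mean      91 0.673 2.81e- 13 FALSE
#> 5 r_fun_vs_q_rbc       91 0.416 4.08e-  5 FALSE
```

The saturation drop along RBC paths correlates with transit time (r =
0.71) more than with path length (r = 0.51), and the functional tissue
radii track each vessel's saturation (r = 0.67) much better than its
geometric territory (r = 0.46). The drop's coefficient of variation
(0.27) is far below that of the transit times (0.84): transit-time
heterogeneity overstates outflow heterogeneity.

`autoplot(st$comparison)`, `plot_outflow_distributions(st)`,
`plot_sigma_evolution(st)` and `plot_drop_vs_transit(st)` draw the
corresponding figures; `run_pipeline()` drives the same analysis from a
YAML configuration and writes CSV/VTK/JSON artifacts (see
`inst/extdata/demo_config.yaml` for a 30-vessel demonstration).

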