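# plugflow

Simulation of surfactant replacement therapy (SRT) as liquid plug
transport through a 3D branching airway tree.

When a surfactant mixture is instilled into the trachea it forms a liquid
plug that ventilation airflow drives toward the acini. Two mechanisms
decide how much arrives and where: while transiting an airway of radius
*a* at velocity *U*, the plug loses volume to a trailing wall film of
relative thickness

    h/a = 0.36 (1 − exp(−2 Ca^0.523)),   Ca = μU/σ,

and at every bifurcation it splits between the daughters with a factor
α ∈ [0, 1] solving a quadratic balance of inertial, viscous, capillary and
gravitational terms (Reynolds, capillary and Bond numbers, the
dimensionless plug volume V₁/(πa³), the daughter/parent diameter ratios,
and the bifurcation's pitch and roll relative to gravity). The cumulative
film loss is the *coating cost* V_CC; delivery performance is summarised
by the efficiency η = 100 ΣVᵢ/V_D, the homogeneity index
HI = (M ΣVᵢ²/(ΣVᵢ)² − 1)^(−1/2), and an image-based quadrant homogeneity
index computed from a rendered sphere projection of the terminal
distribution.

The package is aimed at researchers in respiratory biofluid mechanics and
drug delivery who want to explore dose volume, flow rate, posture and
aliquoting strategies on realistic — strongly monopodial, rat-like —
airway geometries. It provides:

* airway-tree infrastructure: a morphometry-table reader/writer, a JSON
  round-trip of the fully embedded tree, a Weibel-style symmetric builder,
  a seeded stochastic monopodial generator emulating rat-lung statistics
  (0.34 cm trachea, ≈1457 terminal branches, ≈30-generation trunk), and a
  matched-wall-area symmetric comparator;
* the plug mechanics as pure functions (`film_thickness_ratio`,
  `transit_loss`, `split_coefficients`, `split_plug`,
  `dimensionless_state`);
* an instillation engine (`instill`) with posture sequences (LLD, RLD,
  head-up vertical, divided L+R), multiple aliquots with persistent
  precursor films, and per-breath snapshots, plus parameter sweeps;
* performance metrics (`efficiency`, `homogeneity_index`,
  `render_terminal_spheres`, `sqhi`, `molecular_dose`) and published
  condition presets (`condition_preset`, `toy_tree`).

## Worked example

Dose escalation on a synthetic monopodial rat tree, divided
right-then-left lateral decubitus, clinical surfactant (30 cP, 30 dyn/cm),
6 mL·s⁻¹·kg⁻¹:

```r
library(plugflow)
tr <- generate_monopodial_tree(seed = 1)
tr
#> airway_tree (monopodial_generator)
#>   airways:          3161
#>   terminal branches: 1581
#>   max generation:    27
#>   tracheal diameter: 0.34 cm
#>   wall surface area: 31.91 cm^2
#>   body weight:       0.33 kg

fl <- fluid_properties(viscosity = 0.30, density = 1, surface_tension = 30)
for (d in c(1.125, 2.5, 5.8)) {
  r <- instill(tr, protocol(d, 0.330, 6, postures = posture_sequence_LR()), fl)
  cat(sprintf("dose %5.3f mL/kg: eta %5.1f%%  HI %4.2f  V_CC %5.3f mL\n",
              d, r$eta, r$HI, r$V_CC))
}
#> dose 1.125 mL/kg: eta  22.9%  HI 0.65  V_CC 0.286 mL
#> dose 2.500 mL/kg: eta  65.2%  HI 0.72  V_CC 0.287 mL
#> dose 5.800 mL/kg: eta  85.0%  HI 0.72  V_CC 0.287 mL
```

Reading the numbers: at the lowest dose, 77% of the instilled volume is
spent coating airway walls and only 23% reaches the acini; increasing the
dose raises the efficiency steeply while the coating cost stays on its
plateau (≈0.29 mL — the tree's film capacity at this flow), and the
homogeneity index stays well below 1, the signature of a monopodial tree
whose favoured trunk pathways receive most of the surfactant regardless of
dose.

A command-line front end (`exec/plugflow`) wraps the same functions as
`build-tree`, `instill`, `sweep` and `render` subcommands operating on
tree/result JSON and CSV files; every run echoes its resolved
configuration and seed to stderr.

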