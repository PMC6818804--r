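---
title: "Modelling surfactant delivery as liquid plug transport in an airway tree"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling surfactant delivery as liquid plug transport in an airway tree}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plugflow)
```

## The model

Surfactant replacement therapy instils a liquid surfactant mixture into the
trachea, where it forms a plug that ventilation airflow pushes down the
bronchial tree toward the gas-exchanging acini. `plugflow` reduces the
intricate two-phase dynamics to two alternating steps, repeated recursively
through the tree:

**Step A — transit with trailing-film deposition.** A plug moving at
velocity $U$ through an airway of radius $a$ leaves a film of thickness $h$
on the wall, governed by the capillary number $Ca = \mu U / \sigma$:

$$H = h/a = 0.36\,\bigl(1 - e^{-2\,Ca^{0.523}}\bigr).$$

The film volume per unit length is the annulus
$q = \pi h (2a - h)$ (the unique geometric completion of the thickness
law), charged only over wall that is still dry: a plug riding a precursor
film laid by an earlier plug loses nothing until it reaches virgin wall. A
plug whose volume is exhausted by the dry annulus dies mid-airway and is
counted entirely as coating. Inertia is neglected in the film law; computed
film thicknesses vary by less than about 10% over the Reynolds range the
rat simulations traverse (0–200), which makes the capillary-only law an
acceptable approximation.

**Step B — splitting at a bifurcation.** The surviving volume $V_1$ divides
between the two daughters. With daughter 2 the upper one, the splitting
factor $\alpha = V_2/V_1$ solves the quadratic
$A\alpha^2 + B\alpha + C = 0$ whose coefficients combine the parent-scale
Reynolds ($Re = \rho U a/\mu$), Bond ($Bo = \rho g a^2/\sigma$) and
capillary numbers, the dimensionless plug volume
$\tilde V_1 = V_1/(\pi a^3)$, the daughter/parent diameter ratios
$\lambda_i$, and the gravity-projection factors
$f_i = \sin\theta_i\sin\varphi - \cos\theta_i\sin\gamma$
(`split_coefficients()`). For a symmetric bifurcation the solution
collapses to the closed form

$$\alpha = \frac12\left(1 -
  \frac{X \sin\theta \sin\varphi}{1 - X\cos\theta\sin\gamma}\right),
  \qquad
  X = \frac{2\,Bo\,\tilde V_1 \lambda^4}{(Re\,\lambda^2 + 16 \tilde V_1)\,Ca},$$

which the test suite uses as an independent oracle for the quadratic
solver. Two competing influences emerge: velocity evens the split
($X \to 0$ as $U$ grows), while gravity diverts volume to the lower
daughter; branching asymmetry adds a volume-dependent bias, with small
plugs favouring the *smaller* daughter (capillary dominance) and large
plugs the larger one.

The airways are rigid: tree geometry does not change with posture or lung
inflation, and the model stops at the terminal bronchioles — a plug
reaching the distal end of a terminal airway delivers its remaining volume
to the acinus there.

## Geometry and orientation conventions

The body frame is $\hat x$ anterior, $\hat y$ toward the animal's left,
$\hat z$ caudal→cranial; the trachea points along $-\hat z$. Each airway
stores a signed branching angle $\theta$ to its parent's axis and a
rotation angle $\psi$ of its bifurcation plane relative to the parent's
(siblings share $\psi$); `embed_tree()` turns these into unit axes and 3D
coordinates recursively, starting from an anterior reference plane at the
trachea. Postures are gravity directions in this frame: left lateral
decubitus is $\hat g = +\hat y$, right lateral $-\hat y$, head-up vertical
$-\hat z$; a reverse-Trendelenburg tilt rotates $\hat g$ toward the caudal
axis by a configurable angle (default 0, since the tilt used in bench
experiments is typically unreported). At a bifurcation the pitch is
$\sin\gamma = \hat g\cdot\hat d_\mathrm{parent}$ ($\gamma > 0$ when the
parent points downhill) and the roll $\varphi$ is the elevation angle of
the in-plane transverse axis oriented toward the upper daughter; the upper
daughter (label 2) is the one with the higher distal endpoint, ties broken
deterministically toward the smaller id. This is the one sign convention
under which the quadratic reproduces the symmetric closed form exactly.

## The synthetic monopodial tree

No public morphometric cast accompanies the package, so
`generate_monopodial_tree()` emulates the summary statistics of the rat
(Long-Evans-style) conducting tree: a 0.34 cm trachea, on the order of
1.5 thousand terminal branches, a longest path approaching 30 generations,
and strongly monopodial bifurcations — a dominant trunk daughter with a
large diameter ratio and small branching angle, and a small lateral
daughter at a large angle. Defaults and the reasoning behind them:

* `lambda_major = 0.92`, `lambda_minor = 0.50`, sd 0.12. A trunk ratio
  near 0.9 is what sustains a ~30-generation dominant path from 0.34 cm
  down to the terminal-bronchiole scale; the lateral ratio then follows
  from requiring the terminal count band: with cutoff ratio
  $c = D_\mathrm{min}/D_0$ the count scales as $c^{-\beta}$ where
  $\lambda_M^\beta + \lambda_m^\beta = 1$. Milder, more dichotomous ratios
  (e.g. 0.83/0.72, the values of the package's illustrative single
  bifurcation) produce a 14-generation, nearly symmetric tree whose
  delivery is far more homogeneous than monopodial lungs exhibit — they
  describe one bifurcation, not the whole tree.
* branching angles 19.3° ± 14.6° (trunk) and 60.5° ± 19.4° (lateral),
  truncated normals in degrees; rotation angles uniform on 24–53° with a
  random sign. These are published rat-tree statistics.
* `length_to_diameter = 3` with lognormal scatter 0.4 — airway lengths of
  a few diameters with the wide size dispersion real lateral branches
  show. The scatter matters: it is what spreads terminal depths (and hence
  delivered volumes) over orders of magnitude and keeps the homogeneity
  index of realistic runs below 1.
* `diameter_cutoff = 0.019` cm, i.e. terminal bronchioles around 0.2 mm:
  the one free knob calibrated, once, so the default terminal count lands
  in a band around 1457 (20-seed mean ≈ 1390, range ≈ 850–2600).

The generator is seeded and byte-reproducible. What it does **not**
emulate: lobar anatomy and the fixed left/right volume fractions of a real
rat lung, airway curvature, cartilage-ring irregularity, and any
correlation between sibling dimensions beyond the draw of a common
bifurcation plane. Passing tests on this tree therefore demonstrate the
transport model's behaviour on monopodial *statistics*, not agreement with
any individual animal's cast.

`matched_symmetric_tree()` builds the standard comparator: a regular
dichotomous tree taking each generation's mean diameter and length,
90° openings, alternating bifurcation planes, depth
$\lfloor\log_2 M\rfloor$, with lengths rescaled by one factor so the total
wall area $\sum \pi D L$ — the coating capacity — matches the asymmetric
original exactly.

## Simulation engine

`instill()` drives the protocol: the dose ($V_D$ = dose volume per kg ×
body weight) is divided over posture phases and equal aliquots (breaths);
each aliquot is seeded at the trachea and propagated depth-first.
Ventilation flow partitions at every bifurcation in proportion to the
terminal count each daughter subtends (a uniform-ventilation assumption;
the velocity entering the splitting balance is the parent airway's, since
the balance is nondimensionalised at the parent scale). Propagation is
event-driven and quasi-static — a breath is one full propagation pass of
its aliquot, with no inspired-volume limit on travel; a transit-time
estimate supports this simplification in the rat, where a plug crosses the
whole path in roughly 0.2–0.5 s against inspirations of 0.3–1 s. Wall
coating persists across aliquots and posture phases; posture changes
re-orient gravity only, and plugs never move retrograde.

Numerical choices:

* **Root selection** for the splitting quadratic: both roots are computed
  with the numerically stable form; roots inside $[0,1]$ are preferred;
  if both qualify the one nearer 0.5 is taken (continuity with the
  zero-gravity limit); if neither, the nearest real root is clamped. The
  degenerate case $A = B = 0,\ C \neq 0$ (zero volume and inertia) sends
  the plug entirely with the gravity bias and emits a message.
* **Termination**: a plug below `min_plug_volume` (default $10^{-6}$ mL,
  about $10^{-5}$ of a typical dose) is deposited onto its current
  airway's wall; this bounds recursion without affecting reported indices
  at the tolerances used.
* **Conservation**: every split satisfies $V_2 + V_3 = V_1$ in floating
  point by construction ($V_3 = V_1 - V_2$), and transit loss charges
  exactly what leaves the plug, so $V_D = \sum_i V_i + V_{CC}$ holds to
  $10^{-10}$ relative across the test matrix.
* **Ties** (exactly equal daughter elevations) relabel by id, making runs
  bit-reproducible.

## Performance indices

Efficiency is the delivered percentage,
$\eta = 100 \sum_i V_i / V_D$; its complement is the coating cost
fraction. The homogeneity index is the reciprocal standard deviation of
the normalised terminal distribution,
$HI = (M \sum V_i^2 / (\sum V_i)^2 - 1)^{-1/2}$: infinite for a perfectly
uniform distribution, $1/\sqrt{M-1}$ (its minimum) when one terminal
receives everything, and below 1 for the poorly homogeneous distributions
monopodial trees produce. The exponent $-1/2$ is applied as the index's
defining expression; the flattened minimum is read as $1/\sqrt{M-1}$,
which the concentration case attains exactly.

The quadrant homogeneity index mimics bench image analysis:
`render_terminal_spheres()` draws an acinus-sized sphere at each terminal
(grey level = delivered volume / `full_coat_volume`, default $10^{-3}$ mL,
the saturation volume of one acinus; overlapping spheres add, clipped at
black), `sqhi()` thresholds at 90% grey, splits the projected bounding box
into 2×2 equal rectangles and reports min/max of the per-quadrant covered
area fractions. The sphere radius defaults to 2% of the projected
bounding-box diagonal — an acinar scale derived from tree extent — and the
index is stable to raster refinement (256² vs 1024² agree within 2% on
smooth inputs). Quadrants are axis-aligned on the whole projected image;
any registration to photographs is out of scope.

## Design choices where the design was open

* **Flow partition.** Published descriptions are silent on how air flow
  divides; proportionality to subtended terminals is the choice that
  reduces to exact halving on symmetric trees and keeps velocities defined
  everywhere.
* **Dose per breath in the multiple-aliquot reference condition.** The
  tabulated condition ("1 per breath, 10 breaths") conflicts with the
  accompanying text (0.1 mL/kg per breath, 1 mL/kg total); the presets
  follow the text.
* **Morphometry dialect.** One documented tab-delimited format (0-based
  ids, cm, degrees, root parent −1), with a JSON export that round-trips
  the full embedded state. Diameters are read as circular diameters.
* **Posture sequence L+R.** Half the dose in right lateral decubitus
  first, then left, as the divided protocol is usually described.

## Known limitations

* **Aliquot count and efficiency.** Under quasi-static propagation with
  persistent films, the final efficiency is nearly invariant to how a
  fixed total dose is divided (the film cost per wetted length does not
  depend on plug size, and precursor films are lossless), and a single
  bolus is very slightly favoured because its larger $\tilde V_1$
  strengthens the gravity bias. The suite asserts this measured behaviour:
  at equal total dose, 15 aliquots change $\eta$ by under $10^{-3}$
  relative while *homogeneity* improves. Reports that repeated small
  aliquots raise efficiency itself rest on breath-resolved plug dynamics
  (stalling, coalescence) that the two-step model does not specify; a
  breath-resolved engine is the natural extension.
* The quadrant index of a cumulative delivery can dip by ~0.01 between
  breaths as quadrants fill at different rates; it is not a monotone
  functional of a growing distribution.
* No surfactant physicochemistry: surface tension is constant (Marangoni
  spreading, film rupture and plug re-formation are not modelled), and
  intra-acinar transport is out of scope.
* Problem sizes: the examples and tests run the default synthetic tree
  (~1–1.5 thousand terminals, ~3–5 thousand airways); single instillations
  take well under a second and the full suite a few minutes.

## Reproducing the headline behaviours

```{r example, eval = FALSE}
tr  <- generate_monopodial_tree(seed = 1)
fl  <- fluid_properties(viscosity = 0.30, density = 1, surface_tension = 30)

# dose escalation, divided L+R posture, 6 mL/s/kg
for (d in c(1.125, 2.5, 5.8)) {
  r <- instill(tr, protocol(d, 0.330, 6, postures = posture_sequence_LR()), fl)
  cat(sprintf("dose %5.3f mL/kg: eta %5.1f%%  HI %4.2f  V_CC %5.3f mL\n",
              d, r$eta, r$HI, r$V_CC))
}

# the symmetric comparator at equal wall area
sym <- matched_symmetric_tree(tr)
```
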