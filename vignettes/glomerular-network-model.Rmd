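---
title: "A network model of glomerular filtration and capillary wall mechanics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A network model of glomerular filtration and capillary wall mechanics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(glomsim)
```

## The model

A rat glomerulus is idealised as a network of straight cylindrical
capillaries that filter plasma into Bowman's space. The package solves the
coupled steady-state fields on that network — node pressures, per-segment
pressure/flow/protein profiles, erythrocyte distribution — and derives the
two mechanical loads on the capillary wall: endothelial shear stress and
circumferential (hoop) stress.

### The filtering capillary

On a segment of length $L$ and diameter $D$, with hydraulic resistance
$R = 128\mu L/(\pi D^4)$ and a wall resistance to filtration $R^f$, the
transmural pressure $u(x) = p(x) - p_{BS}$ obeys

$$u''(x) = a^2\, u(x), \qquad a^2 = \frac{R}{R^f L^2},$$

with Dirichlet end conditions at the adjoining nodes. The package solves
this in closed form in the hyperbolic basis: with
$\theta = aL = \sqrt{R/R^f}$ the end flows are

$$Q(0) = \frac{u_i\cosh\theta - u_j}{\sqrt{R R^f}\sinh\theta},\qquad
  Q(L) = \frac{u_i - u_j\cosh\theta}{\sqrt{R R^f}\sinh\theta},$$

and the filtrate produced by the segment (its CSGFR) is
$\int_0^L u\,dx / (R^f L) = Q(0) - Q(L)$ exactly. A finite-difference
boundary-value solver exists in the test suite purely as an oracle; the
closed form is used everywhere because it is exact, fast, and yields
numerically stable two-port coefficients ($\theta/\tanh\theta$ and
$\theta/\sinh\theta$, with series expansions below $\theta = 10^{-4}$).

$R^f$ is not a free parameter: consistency between the pressure-profile
filtration law and the Starling law,
$dQ/dx = -k\pi D\,(u - \Pi(C))$, requires

$$R^f = \frac{\int_0^L u\,dx}
  {k \pi D L \int_0^L \bigl(u - \Pi(C(x))\bigr)\,dx},$$

where $k$ is the hydraulic conductivity of the filtration barrier,
$\Pi(C) = 2.1C + 0.16C^2 + 0.009C^3$ (mmHg, $C$ in g/dl) is the colloid
osmotic pressure, and $C(x) = C_0 (Q_0 - E)/(Q(x) - E)$ follows from protein
mass balance with the erythrocyte flow $E$ constant along a segment. When
the osmotic integral exceeds the hydrostatic one the segment has reached
*filtration equilibrium*: it is flagged non-filtering and behaves as a plain
resistor. Because the filtration conductance $g = 1/R^f$ tends to zero
continuously as the net drive vanishes, the solver works throughout in $g$
and clamps it at zero — no discontinuous switching is needed at the
equilibrium boundary.

### The network

Node pressures solve a sparse symmetric linear system assembled from the
segment two-ports plus the afferent and efferent arterioles, modelled as
fixed resistors to the boundary pressures (mean arterial pressure and
peritubular capillary pressure). Filtration enters the node balance through
the asymmetry of the two-port, so pressures automatically account for the
volume lost to Bowman's space.

Plasma proteins mix at nodes (flow-weighted) and erythrocytes split at
diverging bifurcations by the empirical logit-linear phase-separation law,
with the low-flow cutoffs it prescribes; the blood's apparent viscosity
follows the empirical in-vitro diameter/hematocrit law (Fåhræus–Lindqvist
minimum near 5–10 µm). Both laws are cited, not printed, in the source
material, so they are implemented from the published coefficient sets,
stored in `rheology_params()` and overridable; the tests validate them
against independent scalar evaluations of the same formulas rather than
against any paper value. Because flow always runs down the transmural
potential, ordering nodes by decreasing solved pressure is a topological
order of the flow-oriented graph; the propagation sweep uses exactly that,
so no cycle-breaking heuristics are required.

Anastomosing topologies produce *watershed* segments: fed from both ends at
a vanishing mean flow (below `stagnant_tol`, default $10^{-4}$ of the
afferent blood inflow). No steady convective concentration profile exists on
such a segment — protein mass balance would let it filter without an osmotic
brake — and physically it self-limits to filtration equilibrium. The solver
therefore tapers both its filtration conductance and its erythrocyte supply
smoothly to zero across the stagnancy threshold (a hard switch would flip
state between iterations); the forfeited filtrate is bounded by the
threshold flow itself, i.e. well under 0.1 % of SNGFR.

The whole map — pressures → profiles → protein/erythrocyte propagation →
$R^f$ and viscosity updates — is iterated to a fixed point. Apparent
viscosities start at the plasma value (1.24 cP at the reference 5.94 g/dl);
the initial $R^f$ comes from one no-filtration pressure solve with
$\Pi \equiv \Pi(C_A)$, which is better informed than a depth-interpolated
pressure ramp and costs one sparse solve. Updates are under-relaxed, with a
*per-segment* adaptive factor (initially `relax`, default 0.5): a segment
whose update direction alternates between iterations — low-flow segments
near the equilibrium boundary have a local map slope exceeding one in
magnitude and would otherwise sustain a period-2 oscillation — has its
factor halved until its damped map contracts, and recovers it afterwards.
The iteration is declared converged when every *unrelaxed* discrepancy
(computed update minus current value) falls below the tolerance, default
0.001 %, so small damping factors cannot fake convergence. The filtration
side of the criterion is measured on $\theta^2 = R\,g$ — the quantity the
two-port actually depends on — with a small additive floor, because a
segment at filtration equilibrium has an astronomically large, physically
irrelevant $R^f$ whose relative changes would otherwise stall the
criterion. On the default anatomy the solver converges in 25–70 iterations.

### Wall mechanics

Shear stress is Poiseuille wall shear at the length-averaged flow,
$\tau = 32\mu \bar Q/(\pi D^3)$; no correction is made for the radial
filtration flow (a stated limitation of the approach). Hoop stress is
Young–Laplace at the length-averaged transmural pressure,
$\sigma = D \bar{\Delta p} / (2t)$. The wall thickness model is

$$t = t^e + t^{bm} + t^{pod}_{min} + \tfrac{1}{2}h^{pod} + \langle \text{ridge} \rangle,$$

with an endothelium of 40 nm, a scenario-dependent basement membrane
(149.82 nm in the base case), and interdigitated podocyte foot processes
(height 300 nm, width 170 nm) represented as a pedestal of half the process
height plus a $\cos^2$ ridge of the same amplitude. The printed form of the
ridge integral in the source material is typographically corrupted; the
reconstruction used here tiles the circumference $\pi D$ with an integer
number of ridges of period as close to $w^{pod}$ as possible, making the
quadrature mean exactly $h^{pod}/4$ under full coverage (≈ 0.415 µm total
in the base case) and weakly non-increasing in $D$. The ridge profile is an
injectable function for sensitivity work, and `t_pod_min` (no published
value; default 0) shifts the thickness additively.

## The synthetic anatomy

The original serially-sectioned rat anatomy is not available as data, so the
package generates networks constrained to its published statistics: 320
segments, 193 nodes, mean diameter 8.3 µm (range 2–21.3), mean length
20.9 µm (range 2.5–109), total lateral surface area $1.76\times10^5$ µm².

```{r}
net <- generate_shea_like_network(shea_params(), seed = 1)
summarize_network(net)
```

Design choices, fixed once and stated here:

* **Topology.** A single afferent inlet feeds 5 parallel lobules (the
  anatomical literature describes lobular organisation with cross-cutting
  anastomoses); each lobule is an expand-then-contract layered graph of
  bifurcations and coalescences converging on one efferent outlet, with 10 %
  of all segments added as cross-lobule anastomoses at matching relative
  depth. Interior node degree is capped at 4. A cap of 3 would be
  preferable (every divergence a true bifurcation) but is arithmetically
  impossible at 320 segments over 193 nodes (mean degree 3.32); nodes with
  more than two outgoing segments — in practice only the inlet hub — fall
  back to a flow-proportional erythrocyte split.
* **Dimensions.** Diameters and lengths are truncated log-normals
  (right-skewed, as the printed max/mean ratios of ~2.6 and ~5.2 demand),
  rescaled to match the target means exactly. The surface-area target is
  then met by pairwise re-pairing of lengths to diameters (preserving both
  marginals) plus a final global length rescale of well under 0.5 %.
* **No coordinates.** The network is purely topological plus $(L, D)$;
  spatial layouts are out of scope.

The generator emulates the printed morphometry and lobular organisation; it
does not emulate the true anatomy's spatial correlations (e.g. wider
segments adjacent to the arterioles) or its exact degree sequence.
Consequently, segment-level quantities that depend on the specific anatomy
— mean network shear stress, the low-shear segment fraction, the fitted
hydraulic conductivities of the disease table — are checked as
order-of-magnitude and directional properties, not as point reproductions.

## Calibration and scenarios

Following micropuncture practice, arteriolar resistances are fitted so that
the mean glomerular capillary pressure $P_{GC}$ (mean over segments of the
length-averaged pressure) and the afferent *plasma* flow $Q_A$ hit their
targets (damped quasi-Newton on $(\log R_{AA}, \log R_{EA})$, converged at
0.05 mmHg and 0.1 %); then the hydraulic conductivity $k$ is fitted so SNGFR
hits its target (bracketed root-find on $[10^{-6}, 10^{-3}]$
nl · min⁻¹ · mmHg⁻¹ · µm⁻², tolerance 0.1 %, monotone and saturating in $k$).
The two fits alternate to joint convergence (at most 10 rounds; 2–3 in
practice). The source material does not state the nesting order; resistances
first matches its narrative. Disease presets are fitted independently per
condition, not warm-started from their controls.

```{r, eval = FALSE}
res <- run_scenario(scenario_preset("base"), net)
res
```

The base case (MAP 115 mmHg, Bowman pressure 13 mmHg, afferent protein
5.94 g/dl, targets $P_{GC} = 50$ mmHg, $Q_A = 129$ nl/min, SNGFR 30 nl/min)
yields $k \approx 2\times10^{-5}$ nl · min⁻¹ · mmHg⁻¹ · µm⁻², a filtration
fraction of 0.23, and a mean of afferent and efferent colloid osmotic
pressures of 25 mmHg — the last is a network-independent identity of protein
mass balance at those targets. The filtration coefficient computed as
$k \times S_f$ exceeds the one computed from the filtration equation
$SNGFR/(\Delta P - \bar\Pi)$, because the two-point average $\bar\Pi$
understates the true network mean osmotic pressure under heterogeneous
filtration.

Disease presets bundle the published hemodynamic targets with structural
remodeling: diabetes (diameters ×1.14, basement membrane 162 nm),
5/6-nephrectomy (diameters ×1.23), hypertension (no structural change).
Across any synthetic anatomy tested, hoop stress rises in all three
conditions over their controls, and shear stress rises in 5/6-nephrectomy
and falls in hypertension — the directional pattern the model exists to
probe.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `Ht_sys`, `f_Ht` | 0.45, 0.8 | — | afferent hematocrit $= f_{Ht}\,Ht_{sys}$ |
| `mu_ref`, `C_ref`, `mu_slope` | 1.24, 5.94, 0.035 | cP, g/dl, cP/(g/dl) | plasma viscosity law |
| `osmotic_coef` | 2.1, 0.16, 0.009 | mmHg/(g/dl)$^n$ | osmotic cubic |
| `p_e` | 13 | mmHg | peritubular capillary pressure |
| `tol` | $10^{-5}$ | — | fixed-point tolerance (0.001 %) |
| `relax` | 0.5 | — | under-relaxation (1 = plain iteration) |
| `t_e`, `h_pod`, `w_pod` | 40, 300, 170 | nm | wall layers |

Two of these resolve ambiguities in the source material and are deliberately
exposed rather than hidden. First, the statement that "20 % of the systemic
hematocrit appears in the microvasculature" conflicts with the cited
literature, which reports a roughly 20 % *reduction*; `f_Ht = 0.8`
implements the reduction reading, and `f_Ht = 0.2` restores the literal one.
Second, the plasma-viscosity slope is not printed anywhere; the law is
anchored at the stated 1.24 cP at 5.94 g/dl with a slope of 0.035 cP/(g/dl),
in the range of the cited literature. The systemic hematocrit 0.45 and
peritubular pressure 13 mmHg are standard rat values, also not printed.

## Numerical choices

* Internal unit system is CGS (dyn, cm, s, poise), converted at the API
  boundary (1 mmHg = 1333.22 dyn/cm²; 1 nl/min = $10^{-6}/60$ cm³/s),
  because vascular resistances are conventionally quoted in dyn·s/cm⁵.
* The osmotic integral of the $R^f$ update has no closed form ($C(x)$
  depends on $Q(x)$); inside the network loop it is evaluated by 32-point
  Gauss–Legendre quadrature vectorised over all segments — the integrand is
  a smooth composition of hyperbolic profiles, and the tests verify
  agreement with $10^5$-point trapezoid sums to better than $10^{-8}$
  relative. The exported single-segment `update_filtration_resistance()`
  uses adaptive quadrature with a $10^{-12}$ absolute tolerance.
* Degenerate inputs: a segment that filters away (nearly) all its plasma
  gets its local concentration capped, which drives the next consistency
  update to the non-filtering branch — transient nonphysical states resolve
  themselves rather than erroring mid-iteration.
* Multiple efferent outlets (the original anatomy had two efferent vessels
  joined at a created node, with no junction dimensions given) are merged
  through short wide stubs (1 µm × 40 µm by default, resistance orders of
  magnitude below any capillary) flagged and excluded from summaries.

## Problem sizes used by the tests

The packaged checks run the full 320-segment default preset for generator
fidelity, base-case calibration, conservation laws and the stress envelope;
parameter recovery (10 seeds) and the six disease-condition calibrations run
on a reduced preset of the same construction (110 segments, 69 nodes, 3
lobules, proportionally scaled surface area), where per-segment flows — and
hence shear — are higher than on the full anatomy but every directional and
conservation property is unchanged.

## Known limitations

* Steady state only: no autoregulatory dynamics, no compliant diameters.
* No macromolecule sieving (reflection coefficient 1), no re-absorption —
  segments past filtration equilibrium simply stop filtering.
* Shear ignores the filtration-induced radial velocity component.
* The equilibrium clamp applies to the integral criterion over a segment,
  not pointwise; a segment whose osmotic pressure exceeds the drive on only
  part of its length is still treated as uniformly filtering or not.
* Anatomy-specific point values (mean shear 42.4 dyn/cm², mean hoop
  59.0 kPa, the 23 %→43 % low-shear fractions) are not reproducible on
  synthetic anatomies and are treated as envelopes only.
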