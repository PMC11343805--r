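---
title: "Modeling atherosclerosis initiation from the outside in"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling atherosclerosis initiation from the outside in}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(atherofem)
```

## The model

Medium and large arteries are nourished both from the lumen and, through the
vasa vasorum (VV) — a microvessel network in the adventitia — from the
outside.  The outside-in hypothesis holds that atherosclerosis begins with VV
malfunction: the starved outer wall becomes inflamed, monocytes are
recruited, and the familiar cascade — differentiation into macrophages,
transformation into foam cells, attraction of smooth muscle cells (SMC),
collagen synthesis — builds a plaque from the wall outward-in rather than
from a damaged endothelium inward.  `atherofem` implements a fully coupled
continuum model of that chain of events in an idealized half artery.

### Mechanics: anisotropic hyperelasticity with growth and remodeling

The wall is a two-layer (intima-media and adventitia) mixture of an
elastin-dominated isotropic matrix and `n_F = 4` collagen fiber families
(circumferential, axial, and two diagonal at ±45°).  Per unit reference
volume the stored energy is

$$\Psi = \rho_0^m\,\mu\,(\bar I_1 - 3)
 + \sum_j \rho_0^{cj}\,\frac{k_1}{2k_2}\!\left(e^{k_2\langle I_{4e}^{cj}-1\rangle^2}-1\right)
 + \rho_0\left[\frac{\kappa}{2}\Big(\theta-\frac{\rho_0}{\rho_0(0)}\Big)^2
 + p\,(J-\theta)\right],$$

with stiffness parameters given per unit **mass** and multiplied by the
current reference densities: when cells and collagen accumulate, both the
stored energy and — through the volumetric term — the preferred volume grow.
The Macaulay bracket switches fibers off in compression.  The last term is
the mixed three-field treatment of near-incompressible growth: the
element-constant dilatation $\theta$ is driven toward the relative mass
increase $\rho_0/\rho_0(0)$, so added mass converts into volume, and the
growth *direction* is not prescribed — it emerges from energy minimization,
i.e. growth proceeds into the most compliant directions.

Collagen turns over.  Each family carries an inelastic, isochoric remodeling
stretch $\lambda_r^j$ along its direction $a^j$,

$$F_r^{j} = \lambda_r^j\, a^j\!\otimes a^j + (\lambda_r^j)^{-1/2}(I - a^j\!\otimes a^j),
\qquad
\dot\lambda_r^j = k_r\,\frac{\lambda_e^j - \lambda_{pre}}{\lambda_{pre}-1},$$

which drives the elastic fiber stretch $\lambda_e^j = \lambda^j/\lambda_r^j$
toward the deposition prestretch $\lambda_{pre}$; homeostatic stretch and
prestretch coincide.  The normalization by $(\lambda_{pre}-1)$ degenerates as
$\lambda_{pre}\to 1$, so configuration validation requires
$\lambda_{pre} > 1.001$.

### Chemo-biology

Four cell species and two mass densities are tracked.  Nutrients obey a
*steady* referential diffusion–reaction equation (no storage term — transport
is fast compared to disease progression),
$\nabla_X\cdot(D_N J C^{-1}\nabla_X C_N) - R_N = 0$, with constant
consumption $R_N$ and a diffusivity throttled by the plaque size function
$f_\rho = \langle\tilde\rho_0 - \rho_0/\rho_0(0)\rangle/(\tilde\rho_0-1)$:
healthy tissue diffuses at $D_{N,max}$, tissue densified to the ratio
$\tilde\rho_0$ at $D_{N,min}$.  We clamp $f_\rho \le 1$ because resorption
below the initial mass is not modeled, and we deliberately do **not** clamp
$C_N$ at zero: the constant sink can push it slightly negative far from
sources, and silently flooring it would distort the gradients that drive
chemotaxis (the solver reports negative minima instead).

Monocytes and macrophages diffuse and chemotax *up* the nutrient gradient
(toward the still-nourished lumen), differentiate
(monocyte → macrophage, rate $E_{MoMa}$), transform
(macrophage → foam cell, rate $E_{MaF}$) and die (monocyte apoptosis
$a_{Mo}$).  Foam cells and SMC are non-migratory and live as Gauss-point
internal variables, as does the collagen density with its implicit
Macaulay-capped production
$\dot\rho_0^c = r_c (C_{SMC}-\bar C_{SMC})\langle 1-\rho_0^c/(K_c\bar\rho_0^c)\rangle$;
the matrix density never changes (elastin's half-life is decades).  All
concentrations are solved in scaled form (nutrients per $10^{-5}$ kg/m³,
cells per $10^{13}$ cells/m³).

### Discretization

Trilinear hexahedra interpolate displacement and the three diffusive
concentrations (6 dof/node); $(p, \theta)$ are element-constant and condensed
exactly (the mixed potential is stationary at the mean-dilatation values
$\theta^* = \int\rho_0 J / \int\rho_0$,
$p^* = \kappa(\theta^* - \overline{\rho_0/\rho_0(0)})$).  Backward Euler in
time; at every Gauss point the internal variables are re-solved from their
previous-step values inside each residual evaluation (local Newton per
fiber family for $\lambda_r$, implicit linear solve with branch check for
the capped collagen).  The global system is solved monolithically with
Newton's method and a consistent tangent assembled per element by central
finite differences of the analytic element residual — because the residual
map embeds the internal-variable update, the sensitivity
$dh/dp = -(\partial Q/\partial h)^{-1}\partial Q/\partial p$ is included
automatically.  The analytic first Piola–Kirchhoff stress is verified
against a central-difference gradient of the energy in the test suite.
Lumen pressure is a follower load (normal to the deformed surface, with its
unsymmetric tangent); outer nodes carry radial springs whose stiffness
scales 1×/2×/4× with the node's outer-facet multiplicity.  Dirichlet
conditions are imposed by value substitution and row/column elimination;
the sparse linearized systems use a direct LU factorization.

### The vasa vasorum generator

VV microvessels are stochastic binary fractal trees seeded on the outer
surface.  Each tree lives in its cross-sectional plane, points radially
inward, has 2 or 3 bifurcation generations, parent/child length ratios drawn
uniformly in (0.9, 1.1) and in-plane branch rotations drawn uniformly in
(2π/5, 8π/5); uniform is the natural choice where only ranges are given.
Segments are clipped at a configurable inner radius (default mid-media —
trees "reach into the media" without a stated depth, so the conservative
default stops halfway) and at the outer surface.  Branch lengths stay below
half the smallest element edge so that every traversed element contains a
tree vertex; an element is "supplied" when it contains at least one vertex,
and supplied elements carry the nutrient Dirichlet value during the disease
phase.  A mid-vessel axial band (default 20 % of the length, centered) is
free of trees: this is the modeled VV obstruction, and the monocyte
recruitment patch is the same band restricted to the inner two thirds of the
intima-media layer.

## The two-phase experiment

```{r, eval = FALSE}
cfg <- simulation_config()          # 3 x 8 x 16 mesh, 10 months of disease
home <- run_homeostasis_phase(cfg)  # preload to the homeostatic state
dis <- run_disease_phase(home, cfg) # VV occlusion and plaque growth
dis$summary
```

**Preload.** Blood pressure (13 kPa, follower), 15 mm axial stretch and the
embedding springs (80/160/320 kN/mm by multiplicity) are ramped in a few
quasi-static increments and held with all concentrations frozen at their
initial values while $\lambda_r$ evolves, until
$\max |\lambda_e - \lambda_{pre}| < 10^{-4}$ at every Gauss point.  The
remodeling stretches start at 1 — no prestretch-consistent initialization is
assumed; homeostasis is *found*, not imposed.

**Disease.** The VV network is generated with its occluded band, scaled
nutrient concentration 1 is prescribed on the lumen and in supplied
elements, scaled monocyte concentration 10 on the recruitment patch, and the
coupled system is marched 10 months (months are 30 days of simulated time)
with adaptive steps (initial 0.5 d, growth factor 1.2 after fast
convergence, cap 10 d, halving on a rejected step).  Summary rows are
recorded every step; snapshots at 1, 6 and 10 months.

The published monocyte recruitment value ($10^{-14}$ cells/m³) is
inconsistent with the $10^{13}$ cells/m³ scaling (it would be a scaled
$10^{-27}$, numerically null); the package default is a scaled value of 10,
i.e. $10^{14}$ cells/m³, configurable via `monocyte_dirichlet_scaled`.

## Parameter defaults and their provenance

Geometry (r_i = 25 mm, t_IM = 10 mm, t_A = 5 mm, l = 200 mm), loads,
boundary values, the concentration scales and the collagen cap `K_c = 5`
("increased by factor five … the maximum allowed") are study conditions.
The remaining moduli and rates are package defaults (tagged
`decision-default` in config provenance), fixed once by scale analysis
before any end-to-end run was judged:

* `mu = 30 J/kg`, `k1 = 200 J/kg`, `k2 = 10`: with the default densities
  these give a matrix shear stiffness of a few tens of kPa and fiber
  stresses of a few kPa at the 10 % prestretch — arterial orders of
  magnitude.  `kappa = 5e4 J/kg` puts the volumetric stiffness three
  decades above shear (near-incompressible growth).
* `lambda_pre = 1.1`, `k_r = 1e-6 /s`: the homeostatic gap decays on a
  ~1-day time scale, so the preload phase settles within simulated weeks.
* `alpha = 1e-13 kg/cell` (0.1 ng — immune-cell scale), with the
  `1e13 cells/m³` baseline SMC population contributing ~1 kg/m³.
* `E_MoMa = E_MaF = a_Mo = 5e-7 /s` (≈ 3-week conversion time scales) and
  `r_smc = 1e-7 /s`: with the scaled monocyte recruitment value of 10 these
  accumulate foam cells and SMC to hundreds of kg/m³ over ten months —
  enough, with capped collagen, to roughly double the local mass and
  visibly narrow the lumen, while keeping the deformation solvable on the
  coarse mesh.
* `r_c = 5e-18 kg/(cell s)`: collagen production saturates its cap within
  weeks of SMC accumulation, so the factor-five plateau is established well
  before the 6-month output.
* `D_N ∈ [2e-10, 1e-9] m²/s`, `R_N = 3e-11 kg/(m³ s)`: the consumption and
  the *minimum* diffusivity must be chosen together — the steady dip scales
  as `R_N L² / 2 D_N`, and once the plaque throttles diffusivity the dip
  deepens by the full `D_max/D_min` contrast.  These values keep the scaled
  nutrient O(1) below its boundary value in the occluded band even at
  minimum diffusivity (mild negativity remains possible and is reported,
  not clamped), so the chemotactic velocities stay in the mm-per-week range
  throughout the run instead of running away as the plaque densifies.
  `rho_tilde = 1.5` lets the growing plaque throttle its own supply in the
  second half of the run.
* `D_Mo = D_Ma = 5e-11 m²/s`, `r_Mo = r_Ma = 5e-6 m⁵/(kg s)`: transport
  ranges of a few mm to cm per month, with advection dominating toward the
  lumen (element Péclet numbers stay below ~1 on the default mesh, so plain
  Bubnov–Galerkin needs no stabilization).

The `k_cm` residual-scaling constants (default `1e11`) only equilibrate the
species rows against the mechanical rows in the monolithic system; a test
asserts the converged solution is unchanged when they are scaled tenfold.

## Numerical choices

* Gauss quadrature 2×2×2 (full integration for trilinear elements).
* Newton: absolute residual tolerance 1e-8 (scaled rows), relative 1e-10,
  25 iterations, backtracking line search with a bounded nonmonotone escape
  (the Macaulay branches — tension-only fibers, collagen cap, plaque-size
  clamp — can force a transient residual increase while the branch
  assignment settles); a failed step halves the time step down to a floor
  before aborting.
* Local solver: scalar Newton per fiber family to 1e-14, one-sided
  derivatives on the active Macaulay branch; the capped collagen update is
  an exact implicit solve with a branch-consistency check.
* Element tangents by differencing the analytic element residual with
  relative perturbation 1e-7: central differencing by default (the oracle
  contract used in the tests), one-sided forward differencing inside the
  scenario driver where it halves the assembly cost at a tangent accuracy
  (~1e-6 relative) still far below what Newton needs.  Newton contracts
  quadratically until the differencing floor (~1e-8).
* Determinism: the only randomness is the VV network, driven by a single
  named seed recorded in `metadata.json`; repeated runs are bitwise
  identical.

## What the scaled-down run shows — and what it does not

The default 3×8×16 mesh is deliberately coarse: it runs the full two-phase
experiment in minutes on one CPU, and the test suite asserts the *structure*
of the response on it — homeostasis to 1e-4, the collagen plateau at
exactly the cap, monotone lumen narrowing, deepening nutrient scarcity, and
the monocyte → macrophage → foam cell → SMC event ordering (plateau times
for the saturating species, half-rise times for the accumulating ones).
Field values on this mesh are not converged; resolution is a config choice
and convergence in space/time is the user's responsibility.  The synthetic
scenario also idealizes reality: a straight cylinder, a single SMC
phenotype, no lipoprotein transport (folded into constant rates), no
endothelial mechano-sensing, no necrotic core, isotropic elastin, and no
hemodynamics.  Passing tests therefore demonstrate internal consistency of
the coupled solver under the documented study conditions, not clinical
calibration of the 1/6/10-month timeline.

## Known limitations

* The lumen may eventually self-contact under extreme growth; contact is
  not modeled and such runs stop with a step-size underflow diagnostic.
* Static condensation of `(p, θ)` is exact for the element-constant pair;
  no alternative saddle-point path is provided.
* The steady nutrient equation is re-solved within every Newton iteration;
  for very large meshes an operator-split option would be cheaper but is
  not implemented (the monolithic tangent keeps quadratic convergence).
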