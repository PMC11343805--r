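# atherofem

A finite-element simulator of atherosclerosis **initiation from the outside
in**: obstruction of the vasa vasorum — the microvessel network that nourishes
the outer wall of medium and large arteries — starves a band of the wall,
recruits monocytes, and sets off the cascade (macrophage differentiation,
foam-cell transformation, smooth-muscle-cell attraction, collagen synthesis)
whose accumulated mass grows a plaque and narrows the lumen.  The package is
aimed at computational biomechanics researchers studying arterial growth and
remodeling.

## The model in brief

An idealized half artery (inner radius 25 mm, intima-media 10 mm, adventitia
5 mm, length 200 mm) is discretized with mixed trilinear hexahedra carrying
displacement **u** and scaled nutrient, monocyte and macrophage
concentrations, plus element-constant pressure *p* and dilatation *θ*.  The
stored energy per unit reference volume is

```
Ψ = ρ0_m μ (Ī₁ − 3)
  + Σⱼ ρ0_cj (k₁/2k₂)(exp(k₂⟨I₄ₑ^j − 1⟩²) − 1)
  + ρ0 [ κ/2 (θ − ρ0/ρ0(0))² + p (J − θ) ]
```

— an isotropic elastin matrix, four tension-only collagen fiber families,
and a volumetric term that converts mass increase into volume (growth in the
most compliant direction, not a prescribed direction).  Collagen remodels:
each family's inelastic stretch λ_r evolves as
`λ̇_r = k_r (λ_e − λ_pre)/(λ_pre − 1)` until the elastic fiber stretch
matches the deposition prestretch (homeostasis).  Nutrients obey a steady
referential diffusion–reaction equation whose diffusivity is throttled by
the local mass increase; monocytes/macrophages diffuse, chemotax up the
nutrient gradient, differentiate and transform; foam cells, smooth muscle
cells, collagen and the remodeling stretches are Gauss-point internal
variables condensed out of the monolithic backward-Euler/Newton solve.
The vasa vasorum is a seeded stochastic fractal-tree network (2–3 binary
levels, parent/child length ratios in (0.9, 1.1), branch rotations in
(2π/5, 8π/5)) whose occluded mid-vessel band defines where nutrients go
missing.

See the methods vignette (`vignettes/outside-in-atherosclerosis.Rmd`) for
the full model, parameter table and numerical choices.

## Worked example

The default configuration is the scaled-down study: coarse 3×8×16 mesh,
homeostatic preload, then ten months of disease after vasa-vasorum
occlusion.

```r
library(atherofem)

cfg  <- simulation_config()              # defaults; seed = 1
home <- run_homeostasis_phase(cfg)       # ramp + hold to homeostasis
dis  <- run_disease_phase(home, cfg)     # occlusion, recruitment, growth
dis$summary
```

```
  t_days lumen_radius_mid     int_C_Mo     int_C_Ma      int_C_F    int_C_SMC
1     30       0.02596942 0.0004199791 0.0002730999 0.0002179754 2.481639e-05
2    180       0.01685422 0.0004047766 0.0004057811 0.0027623622 1.944708e-03
3    300       0.01563353 0.0004050910 0.0004050570 0.0048619578 5.938151e-03
  max_collagen_fold_im    min_C_N min_C_N_plaque
1             1.146462  0.6945659      0.7244949
2             4.999889 -1.0440544     -0.9050445
3             5.000000 -1.2601417     -1.1178233
```

Reading the rows: after one month the mid-vessel lumen radius (metres) has
barely moved off its homeostatic 26 mm and collagen is near baseline; by six
months the intima-media collagen has hit the factor-five cap (`K_c = 5`,
4.999889 ≈ 5) and the lumen has narrowed to 16.9 mm; by ten months foam
cells and smooth muscle cells (referential volume integrals, scaled units ×
m³) dominate the added mass, the lumen is down to 15.6 mm, and the minimum
scaled nutrient concentration inside the plaque band has fallen from 0.72 to
−1.12 — the growing plaque throttles its own supply (the steady consumption
model admits negative minima; they are reported, not clamped).  Along the
step-by-step series the species events are ordered as in the underlying
disease narrative: monocytes plateau first (day ~36), then macrophages
(day ~90), then foam cells and smooth muscle cells reach half their final
mass (days ~163 and ~219).  Set
`cfg$out_dir` to also write VTU/PVD snapshots, `summary.csv` and
`metadata.json`.

A thin CLI wraps the same functions:

```sh
Rscript inst/cli/athero.R mesh --out mesh.vtu
Rscript inst/cli/athero.R vv   --seed 3 --out network.vtp
Rscript inst/cli/athero.R run  --config cfg.yaml --out results/
```

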