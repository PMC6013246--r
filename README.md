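# myonuc

Force-balance modelling of nuclear positioning in multinucleated muscle
cells.

Skeletal muscle fibres carry many nuclei that spread out along the cell to
maximise their mutual distances — a single central file in narrow cells, a
zigzagged double file in wide ones, with extra crowding near the cell poles.
`myonuc` is for quantitative cell biologists and biophysical modellers who
want to ask *which* microtubule-mediated forces can produce these patterns.
Instead of assuming a mechanism, the package simulates a whole family of
candidate force laws and screens them against the patterns.

## The model

Nuclei are overdamped particles in a rectangular cell of half-width *b* and
half-length *l*; the velocity of nucleus *i* is the sum of pairwise
internuclear forces *f*, forces *g*<sub>S</sub>/*g*<sub>P</sub> from the
normal projections onto the cell sides/poles, and a divergent short-range
size exclusion (nuclear radius 7 µm). Every interaction is a signed power
law

&nbsp;&nbsp;*f*(*d*) = σ·*M*·(*d*/*d*<sub>ref</sub>)<sup>α</sup>·*H*(*c* − *d*),&nbsp;&nbsp;*d*<sub>ref</sub> = 40 µm,

with sign σ (repulsion/attraction), exponent α ∈ {−1, 0, 1}, relative
magnitude *M* and finite reach *c*. That yields 216 models in 36 classes
(sign/exponent of the internuclear and side laws). A two-stage screen —
pattern validity in reference wide/thin cells, then width-trend and
robustness criteria on fourteen representative cells — reduces the family to
two classes, which are then calibrated and analysed in closed form: the
single-file state of the reduced zigzag strip model loses stability in a
pitchfork, at critical spacing λ\* = *d*<sub>ref</sub>·√(2/*M*<sub>S</sub>)
(attractive-increasing side forces, "M1") or critical width-to-spacing ratio
*r*\* = √(*M*<sub>S</sub>/2) (repulsive-decreasing side forces, "M2"), and an
anisotropic-stress model predicts nuclear aspect ratios from the same
forces.

## A worked example

```r
library(myonuc)

model <- calibrated_model("M2")    # repulsive-decreasing everywhere,
                                   # M_S = 2.2, M_P = 3.2
thin  <- cell_geometry(25, 250, 9)    # a VL4-like cell, 50 x 500 um
wide  <- cell_geometry(40, 250, 15)   # a VL3-like cell, 80 x 500 um

eq <- relax_to_equilibrium(initial_conditions(thin, "random", seed = 3),
                           model, thin)
eq
#> <equilibrium_result> converged, max residual 8.12e-05 after t = 824 (794 steps)
classify_pattern(eq$final, thin)$label
#> [1] "SF"

eqw <- relax_to_equilibrium(initial_conditions(wide, "random", seed = 4),
                            model, wide)
classify_pattern(eqw$final, wide)$label
#> [1] "DF"
mean_abs_x(eqw$final)        # file offset, um
#> [1] 10.63851

# the analytic strip model explains the switch: SF is stable iff b < r* lambda
sf_is_stable(model, lambda = 2 * 250 / 10, b = 25)$stable   # thin cell
#> [1] TRUE
df_equilibrium(m <- calibrated_model("M2", M_S = 2), 40, 60)  # fork offset
#> [1] 20
```

The thin cell relaxes to a centred single file, the wide one to a double
file whose ~11 µm offset matches the pitchfork prediction for its spacing;
`run_filter1()` / `run_filter2()` reproduce the 216 → 12 → 2 screen at desk
scale, `calibrate()` recovers force magnitudes from (synthetic) nuclear
positions, and `fit_kappa()` fits the nuclear stiffness to aspect-ratio
tables.

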