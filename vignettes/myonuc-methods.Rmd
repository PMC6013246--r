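---
title: "Force-balance modelling of myonuclear positioning: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Force-balance modelling of myonuclear positioning: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(myonuc)
```

## The model

Larval body-wall muscles of *Drosophila* are flat, roughly rectangular,
multinucleated cells. Their nuclei spread along the long axis, form a single
central file (SF) in narrow cells and a zigzagged double file (DF) in wide
ones, and crowd slightly toward the cell poles. `myonuc` implements an
interacting-particle account of this patterning: each nucleus is a point
particle in a rectangle of half-width $b$ (short axis, $x$) and half-length
$l$ (long axis, $y$), moving in the overdamped regime, so its velocity equals
the sum of the forces on it (the drag coefficient is normalised to 1):

$$\dot X_i \;=\; \sum_{j \ne i} f(\lVert X_i - X_j\rVert)\,\hat u_{ij}
  \;+\; \sum_{k \in \{L,R\}} g_S(d_{ik})\,\hat u_{ik}
  \;+\; \sum_{k \in \{U,D\}} g_P(d_{ik})\,\hat u_{ik},$$

where the boundary terms act along the normal projections onto the two sides
and two poles, and all unit vectors point from the source toward the nucleus.
Each of the three interactions is a signed power law

$$f(d) = \sigma\, M \left(\frac{d}{d_{\mathrm{ref}}}\right)^{\alpha}
  H(c - d),$$

with sign $\sigma = \pm 1$ (repulsive/attractive), exponent $\alpha$
(decreasing, constant or increasing with distance), relative magnitude $M$
(the internuclear amplitude is the force unit, $M_N \equiv 1$), finite reach
$c$, and the reference distance $d_{\mathrm{ref}} = 40\,\mu m$, the typical
internuclear spacing. Restricting $\alpha \in \{-1, 0, 1\}$ gives
$2^3 \times 3^3 = 216$ models; because the pole law matters little for the
pattern class, models sharing $(\sigma_N, \alpha_N, \sigma_S, \alpha_S)$ form
one of $36$ *model classes*.

A short-range divergent size-exclusion force
$Q_{SE}\,(1/d^2 - 1/D^2)\,H(D - d)$ with $Q_{SE} = 2000$ keeps nuclei (radius
$r = 7\,\mu m$, contact distance $D = 2r$; $D = r$ against the boundary) from
overlapping.

### Numerical treatment of the cutoff

A literal Heaviside reach leaves the force discontinuous at $d = c$, and
several screen configurations then have *no* continuous equilibrium: for
example the strong short-range pole law of the second screening stage jumps
from 0 to over 300 force units at its 25 µm reach, so the outermost nuclei
chatter on the cutoff surface and the velocity residual can never meet the
convergence threshold. The package therefore ends every finite reach with a
linear taper over the final 2 µm below $c$ (forces are unchanged for
$d < c - 2$, exactly zero at and beyond $c$). All screen-relevant distances
sit either well inside or beyond the reach, and equilibria become well
defined.

### Relaxation to equilibrium

`relax_to_equilibrium()` integrates the overdamped system with an adaptive
embedded Euler/Heun pair (per-step position error held at $10^{-3}\,\mu m$ by
default); steps that would carry a nucleus across the boundary are rejected
and retried smaller, never clamped. A configuration counts as converged when
every nucleus's velocity 2-norm is below $10^{-4}$ (model units). Stiff
boundary layers — size-exclusion contact in collapsing clusters, the tapered
strong pole ramp — pin an explicit scheme at its stability limit, where the
residual plateaus; the integrator detects that stall (no residual improvement
between checkpoints) and finishes with a damped Levenberg–Marquardt
root-finder on the force balance, seeded by the relaxation endpoint. If the
root-finder fails the run is mid-transit, and integration resumes with a
backed-off checkpoint interval. Convergence is only ever reported when the
final residual genuinely satisfies the threshold, and the model-time budget
($10^6$ by default) marks runs that never settle.

## The screen

**Stage 1** (`run_filter1()`) scans every class over a parameter grid in a
wide (2b = 80 µm, N = 15) and a thin (2b = 50 µm, N = 9) reference cell of
length 500 µm, from a seeded random start and from nuclei equally spaced on
the long axis. A pattern is *valid* when nuclei keep one radius of boundary
clearance (K1), one diameter of mutual clearance (K2), classify DF in the
wide and SF in the thin cell (K3), span over two thirds of the cell length
(K4), and keep a mean nearest-neighbour distance above 30 µm (wide) / 45 µm
(thin) (K5). A class survives when valid patterns occur in both geometries,
not necessarily at the same parameters. The full protocol comprises
$216 \times 4^3 \times 5^2 \times 2 \times 2 \approx 1.4\times 10^6$
simulations; the package's reduced default (cutoffs $\{25, 50, \infty\}$,
three log-spaced magnitudes in $[0.1, 10]$, the repulsive-decreasing pole
family) reproduces the known twelve-class outcome in a few minutes on one
CPU.

Validity additionally requires *strict linear stability* of the equilibrium
(largest Jacobian eigenvalue real part below $-10^{-6}$). Two artefacts force
this choice. First, the exactly symmetric equally-spaced start converges onto
the *unstable* single file whenever the side forces cancel identically (for
instance attractive constant side laws with infinite reach), which would
admit patterns reachable only on a measure-zero manifold. Second, when the
axial spacing coincides with a grid cutoff the equally-spaced start is
literally force-free — a frozen, marginal configuration, not an observable
pattern. Genuine cutoff-locked equilibria settle on the taper ramp, where the
force gradient is steeply negative, and pass the gate; the slowest physical
modes relax at rates of order $10^{-3}$ per model time unit, far from the
threshold.

**Stage 2** (`run_filter2()`) takes the twelve survivors to fourteen
representative cells — nucleus counts 7–23 zipped with widths 42–117 µm, the
(9, 51) and (15, 83) pairs matching the measured VL4 and VL3 population
means — with the pole law fixed to strong short-range repulsion
$(\sigma_P, \alpha_P, c_P, M_P) = (1, -1, 25, 200)$. The SF/DF criterion is
dropped (cell sizes vary) and the nearest-neighbour gate becomes
population-level: the mean NND over all fourteen cells must lie in
$40 \pm 5\,\mu m$ (K5*). For every $(c_N, c_S)$ the *score* is the
$M_S$-maximised sum of the per-criterion fractions of cells passing K1, K2,
K4 plus the K5* gate — a number in $[0, 4]$.

A converged configuration only counts as a pattern if it is not *frozen*:
when every interaction on some direction sits at or beyond its cutoff the
Jacobian acquires numerically exact zero modes (|Re λ| < 10⁻⁹, typically
10⁻¹⁷ in practice, three-plus orders below the softest genuine
near-pitchfork modes), and such states — spacing no longer held by any
force — fail all criteria. Two rejection criteria follow. The *trend*
criterion asks whether the class can reproduce the observed width dependence
of nuclear decentering. It is evaluated on an ensemble of three random
starts per cell, because a single start leaves the verdict at the mercy of
which multistable equilibrium one seed selects: among parameter combinations
scoring within 0.5 of the class's best (the top eight at most), some
combination must give an ensemble-averaged mean-absolute-$x$ curve that
rises with width (Spearman rank correlation at least 0.5 across the 14
cells — per-step monotonicity is the wrong test, since adjacent widths can
carry different nucleus counts and the fork offset follows the spacing)
*and* show the observed population endpoints: fully valid centred single
files in the three thinnest (VL4-width) cells for a majority of starts, and
a converged double-file pattern in at least one of the two widest cells in
some start (full criterion validity is not demanded there: one defect pair
in a 23-nucleus zigzag does not negate the fork's presence, and the
clearance criteria already enter the score). The endpoint requirement
replaces the original fit against the (undeposited) 200-cell data set;
without it, a repulsive constant side force with short reach and large
magnitude acts as pure wall padding and produces a monotone curve whose
thin-cell "files" sit pinned at $\pm(b - c_S)$ — a pattern the measured
thin cells rule out, and the decentering classes whose curves dip at small
widths fail the same thin-cell test. The *robustness* criterion
perturbs the selected internuclear reach by ±25% and requires the
$M_S$-maximised score to stay within 1 of the selected score: the classes
with constant or increasing internuclear repulsion only work when the reach
matches the nuclear spacing, and their score collapses off that ridge.

**Calibration** (`calibrate()`) fixes the two surviving families — repulsive
decreasing internuclear and pole forces with side forces either attractive
increasing (M1) or repulsive decreasing (M2), all with infinite reach — and
grids $(M_S, M_P)$ over 13 log-spaced values in $[0.1, 10]$. Every cell is
relaxed from its measured (here: synthetic) configuration and the error is
the mean Euclidean displacement of the equilibrium from the start; the full
169-point error surface is returned, never a silent argmin.

## Strip analytics

Viewing the cell as an infinite strip with nuclei evenly spaced at
$\lambda = 2l/(N+1)$ and alternating offsets $\pm x$, the dynamics reduce to
one ODE,

$$\dot x = \frac{4 f(d(x))}{d(x)}\,x + g_S(b + x) - g_S(b - x),
  \qquad d(x) = \sqrt{4x^2 + \lambda^2},$$

whose centred fixed point (the SF) is stable iff
$2 f(\lambda)/\lambda < -g_S'(b)$. For the power-law family this reads
$b^{1-\alpha_S}\lambda^{\alpha_N-1} <
-\sigma_S \alpha_S M_S d_{\mathrm{ref}}^{\alpha_N-\alpha_S}/2$; published
renderings of this inequality are typographically ambiguous, so the package's
closed forms are re-derived from the stability condition and verified against
numeric root-finding on the strip ODE (the root is the source of truth
wherever they might disagree). Specialised to the calibrated families this
gives the critical spacing $\lambda^* = d_{\mathrm{ref}}\sqrt{2/M_S}$ (M1; SF
stable iff $\lambda > \lambda^*$, independent of width) and the critical
width-to-spacing ratio $r^* = \sqrt{M_S/2}$ (M2; SF stable iff
$b < r^*\lambda$). Past the pitchfork the stable offsets are
$\bar x = \tfrac12\sqrt{\lambda^{*2} - \lambda^2}$ (M1) and
$\bar x = \sqrt{(b^2 - (r^*\lambda)^2)/(2 M_S + 1)}$ (M2). Cutoffs are
ignored throughout the strip analytics, matching the calibration-step laws.

The acceptance suite confirms the reduction against the full 2-D model by
relaxing the predicted zigzag in a long strip. Because the infinite-range
laws are effectively logarithmic potentials, a free chain redistributes
toward the poles and never holds uniform spacing; the comparison therefore
limits the internuclear reach to the nearest neighbours of the ansatz (the
interactions the reduction itself keeps), uses the strong short pole law as a
near-hard wall, and compares the interior mean offset against the closed form
evaluated at the realised interior spacing. Agreement is within a few
percent for both families.

### Nuclear shape

Treating a nucleus as an area-preserving deformable disc of stiffness
$\kappa$, pushed by net forces $f_x$ (from the sides and the opposing file)
and $f_y$ (from its axial neighbours), the oriented aspect ratio is
$(\kappa - f_y)^2/(\kappa - f_x)^2$; `shape_forces()` assembles $f_{x,y}$
for the SF and DF patterns (with a short- and a long-range variant that
excludes or includes the second axial neighbours) and `fit_kappa()` recovers
$\kappa$ from per-cell observed ratios by minimising the mean absolute error
over a reported error surface.

## Synthetic data

No measured dataset is distributed, so `sample_population()`,
`place_nuclei()` and `attach_shapes()` generate populations with the
published statistical structure: cell length $499.2 \pm 57.7$ µm (VL3) /
$491.8 \pm 57.1$ µm (VL4), width $80.4 \pm 17.5$ / $51.7 \pm 11.3$ µm,
nucleus counts $15.3 \pm 2.9$ / $9.3 \pm 1.6$ (normals truncated at 3 SD and
positivity; counts rounded, at least 2), nuclear radius 7 µm, and positions
at model equilibria plus Gaussian jitter of 2 µm by default. Count and width
are sampled independently unless the optional coupling flag is set
(correlation ≈ 0.7 through a shared latent factor), mirroring the observed
count–area correlation. What the generator does *not* emulate: imaging and
segmentation noise, non-rectangular outlines and the boundary-preserving
flattening applied to real cells, or correlations between neighbouring
nuclei's shapes. Tests passing on synthetic data therefore demonstrate the
pipeline's internal soundness (parameter recovery, pattern statistics,
analytic consistency), not biological validity of the calibrated values.

## Problem sizes and reproducibility

The package's default study conditions are chosen so the full test suite and
the acceptance script run on a single CPU in well under an hour: the stage-1
screen uses the reduced grid above (about 18,000 simulations), stage 2 uses
cutoffs $\{20, 50, 110, 500\}$ and four log-spaced magnitudes over the
fourteen cells, calibration uses 30 synthetic cells on the full 13×13
magnitude grid, and the Monte-Carlo baselines use a few hundred
realisations. Every stochastic entry point takes an explicit seed (default
0) and restores the caller's RNG state; screens and the pipeline are
deterministic given their seeds. Known limitations: single random start per
screen simulation (multistable configurations contribute whichever
equilibrium their seed selects — visible as occasional "neither"
classifications of defective zigzags), the desk-scale grids are coarser than
the full protocol, and the equally-spaced start converges to symmetric
saddles by construction (handled by the stability gate).
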