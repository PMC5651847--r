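---
title: "Modelling countershading camouflage and its dependence on body orientation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling countershading camouflage and its dependence on body orientation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(countershade)
```

## The problem

Countershading — darker coloration on the surfaces that face the dominant
illumination — can cancel the shading gradient that reveals a body's 3D
shape. But the cancellation is only exact for one body pose under one light
field: tilt the animal and the paint no longer matches the light, so the
shading (and with it the shape cue) reappears. This package models that
chain quantitatively for a Lambertian ellipsoidal body ("caterpillar")
under a sunny daylight field, generates visual-search stimuli in which such
a target hides among flat folded "leaves", simulates observers searching
those displays, and fits the mixed models a psychophysicist would use on
the resulting accuracy and reaction-time data.

## The light field

`sky_model()` assembles three components, all in arbitrary linear
radiometric units (every downstream quantity is a ratio):

* a **direct sun beam**, a delta function with irradiance $E_{sun}$ at
  normal incidence. The default sun position is azimuth 270°, altitude 45°
  — above and behind a viewer who faces azimuth 90°;
* a **diffuse sky dome** following the CIE general-sky two-factor form
  $L(\theta, \chi) \propto \varphi(\theta)\, f(\chi)$, with gradation
  $\varphi(Z) = 1 + a e^{b/\cos Z}$ and scattering indicatrix
  $f(\chi) = 1 + c\,(e^{d\chi} - e^{d\pi/2}) + e \cos^2\chi$, normalized so
  the zenith radiance equals `zenith_radiance`. The default coefficient set
  is the standard clear ("sunny") sky $(a,b,c,d,e) = (-1, -0.32, 10, -3,
  0.45)$; standard overcast and isotropic sets are provided and the vector
  is fully configurable, since the exact sky type behind any particular
  rendering pipeline is rarely recoverable;
* a **constant-radiance ground** below the horizon: a Lambertian ground of
  albedo $\rho$ returns $L_g = \rho E_{hor}/\pi$, where $E_{hor}$ is the
  total (sun + sky) irradiance on an up-facing horizontal patch. Because an
  up-facing patch never sees the ground, one pass closes this coupling
  exactly; higher bounces would be $O(\rho^2)$ of the diffuse term and are
  ignored.

When `sun_irradiance` is not given it is set so that direct horizontal
irradiance is `sun_diffuse_ratio` (default 5) times the diffuse horizontal
irradiance — a typical clear-sky split. The default ground albedo is 0.3,
a mid-range vegetated-ground value. Neither number is critical: they shape
the curves below only through ratios, and both are arguments.

Irradiance on a patch with unit normal $n$ is

$$E(n) = E_{sun} \max(0, n\cdot s) +
\int_{\Omega^+(n)} L_{env}(\omega)\,(n\cdot\omega)\, d\omega .$$

The integral uses a product rule: Gauss–Legendre nodes in elevation around
$n$ (default 64) crossed with uniform azimuth nodes (default 32). Each
elevation ring is clipped analytically at the world horizon so the rule
never straddles the sky/ground radiance discontinuity, and the ground
term's cosine-weighted solid angle has the closed form $\pi(1 - n_z)/2$.
With these choices the isotropic-environment error is about $5\times
10^{-4}$ relative, doubling the resolution moves results by under 0.03%,
and the rule agrees with a $10^6$-sample cosine-weighted Monte-Carlo
estimate to well within 0.5%. The minimum accepted resolution is 16 × 8;
nothing in the scene occludes anything else (the target is convex, and the
stimuli were explicitly arranged so that cast shadows could not act as
cues), so no visibility term appears.

## Geometry and pose

`make_ellipsoid()` builds an icosphere-subdivision mesh scaled to the
(60, 20, 20) mm target — 120 mm long, 40 mm wide, $20\cdot 4^s$ faces at
subdivision $s$. At the reference pose the long axis lies along world
"north" (y), fronto-parallel to the viewer; the depth axis points along the
viewing direction. **Pitch** tilts the long axis vertically (±90°),
**roll** spins the body about the long axis (±180°), **yaw** rotates it
about the vertical (±180°); rotations compose intrinsically in the order
roll → pitch → yaw about the body centroid. Every experimental condition
varies a single angle, so the composition order affects no reported
quantity; it is fixed for reproducibility.

`make_leaf()` derives a distractor from the same ellipsoid: the depth
semi-axis is flattened (default ratio 0.1), the cross-section is then bent
about the long axis, and finally the vertical extent is rescaled so the
projected outline matches the unfolded ellipse — on screen, leaves and
caterpillar share the same 2D shape, leaving the shading gradient as the
only cue to the target's volume. Two bend modes exist because the original
parametrization is not recoverable from a verbal description: the default
smooth mode bends the sheet onto a circular arc whose tangents turn by
half the fold angle at each lateral extreme (so the extremes form the full
fold dihedral), and a `crease` mode rotates each half rigidly by half the
fold angle. Both have the same extreme dihedral; the smooth mode is the
default reading of "curved along the long axis".

## Optimal countershading and apparent shading

With Lambertian reflectance, a patch of albedo $\rho(x)$ returns radiance
$\rho(x) E(x)/\pi$. Choosing

$$\rho(x) = \pi\, L_{leaf} / E(x),$$

where $L_{leaf}$ is the radiance of a horizontal upward-facing leaf patch
(`leaf_reference_radiance()`), makes every face of the body return exactly
$L_{leaf}$: the body is radiometrically flat and matches the backdrop. In
this implementation the identity is exact by construction — the same
quadrature computes $E$ in both the optimization and the rendering, so the
per-face radiance CV at the reference pose is at machine precision, and
remains below 1% under any refinement of the rule.

Faces turned far from the light can demand $\rho > 1$, which no physical
pigment provides. The map is left **unclamped by default** (with a
warning): this preserves the flatness identity and treats the reflectance
as the mathematical optimum. A `clamp = TRUE` mode caps the albedo at 1,
breaking flatness on the darkest faces, for users who want only physically
realisable coatings.

**Apparent shading** is the spread of outgoing radiance over the body —
max minus min across faces (`apparent_shading()`). By default only
viewer-visible faces (back-face test against the viewing direction) enter,
since an observer sees one side of an opaque body; a full-surface mode is
available because either convention is defensible and the choice moves the
curves only modestly. The statistic is computed on face radiances rather
than rasterized pixels, which makes it independent of image resolution.

`shading_curves()` sweeps pitch, roll and yaw through departures
{0, 15, 30, 45, 90}° (the other two angles held at zero), rotating the
painted body under the fixed light field and recording the apparent
shading. One shared factor normalizes all fifteen values so the global
maximum is exactly 1. At the reference pose the shading is zero; it grows
monotonically along each axis, steepest in yaw under the default light
field, because yawing turns the body's long flank toward or away from the
low sun.

One property worth stating because it is easy to assume and false: a
uniformly coloured body does **not** always show more apparent shading
than the countershaded one. Near the reference pose it does, by a factor
of 100 or more. But at large departures the countershaded body's paint
gradient compounds with the rotated illumination gradient — dark dorsal
paint can face the full sun while pale ventral paint sits in shadow — and
its radiance range then exceeds the uniform body's, whose spread is nearly
orientation-invariant. The detectability advantage of countershading at
all orientations reported in search experiments is a behavioural result
(driven largely by overall background match), not a max–min dominance at
the physical level, and the package makes no such claim.

## Stimuli, designs and the synthetic observer

`sample_scene()` places one target and 20 or 40 leaves uniformly on a
square fronto-parallel plane, redrawing the **whole** position set until
all pairwise centre distances are at least 1.3 leaf lengths (per-item
redrawing would bias the spatial distribution). The default plane side is
30 item lengths (3600 mm). This is larger than the nominal on-screen
item-to-field ratio of the modelled display (items of 1.27° of visual
angle in a 10.58° field, about 1:8.3): at that ratio, 41 hard-core discs
of diameter 1.3 item lengths exceed the random-packing jamming density and
no rejection sampler can place them. With the default plane the acceptance probability
per attempt is about 0.8% at 41 items, well within the $10^4$-attempt
budget. Leaf poses are drawn as roll ~ N(0°, 50°), yaw ~ N(0°, 10°),
pitch ~ Uniform(−180°, 180°) (wrapped into the canonical pitch range via
the (p, r, y) ≡ (180° − p, r + 180°, y + 180°) equivalence), and fold
angles ~ N(20°, 20°) truncated to [0°, 90°) since a negative fold is
meaningless.

`render_scene()` rasterizes the scene flat-shaded (one radiance per face,
depth-buffered, orthographic — at item sizes of ~1.3° of visual angle
perspective effects are negligible) with backdrop and ground filled at the
horizontal-leaf radiance. `tone_map()` applies the display mapping:
rescale so the 99th-percentile pixel is 1, clip the rest.

`make_design()` builds the 200-trial session: five departure levels × two
set sizes, 20 trials per cell, order shuffled by seed.

`simulate_trials()` is the synthetic-data generator. For participant $j$
and a trial with normalized shading $s$ and $n$ distractors:

$$P(\text{correct}) = g + (1-g)\,\text{logistic}(\beta_0 + \beta_1 s + u_j),
\qquad u_j \sim N(0, \sigma_u^2),$$

$$\log \mu_{RT} = \alpha_0 + \alpha_1 s +
\alpha_2 e^{-\lambda s}\log n + v_j, \qquad
RT \sim \text{Gamma}(k, \mu_{RT}), \quad v_j \sim N(0, \sigma_v^2).$$

The guess floor $g$ defaults to $1/(n_{items}+1)$, reflecting a
forced-choice identification stage in which a lost observer still selects
some item; recovery studies use $g = 0$ because the analysis models
ignore the floor. The
$e^{-\lambda s}\log n$ term is the simplest form that makes search
inefficient near the reference orientation and efficient (slope ≈ 0) at
90°. The defaults ($\beta_0 = -0.5$, $\beta_1 = 4$, $\sigma_u = 0.8$,
$\alpha_0 = 0.56$, $\alpha_1 = -1$, $\alpha_2 = 0.35$, $\lambda = 3$,
$k = 8$, $\sigma_v = 0.3$) were chosen once to give plausible human
magnitudes — accuracy rising from ~0.4 to ~0.9 across the sweep, mean RTs
falling from ~7 s to ~1.3 s, an ~90 ms/item set-size cost at the reference
pose — and are explicitly **not** fitted to any behavioural dataset. What
the generator emulates is the statistical structure the analysis assumes:
monotone dependence on apparent shading, participant-level intercepts,
Gamma RTs, a decaying set-size effect. What it does not emulate: sequential
and learning effects, lapses, eye movements, RT–accuracy trade-offs, or
any image-computable detection process — so passing tests validate the
pipeline's statistics, not a theory of search.

## Statistical analysis

`fit_glmm()` fits binomial-logit (accuracy) and Gamma (reaction time)
mixed models with a per-participant random intercept, by maximum
likelihood with adaptive Gauss–Hermite quadrature (default 25 nodes; 1 =
Laplace). Accuracy data are aggregated to binomial counts at a fixed
participant-by-cell grain, which leaves all likelihood ratios unchanged
and speeds refits; complete separation triggers a warning and a 0.5-count
data-augmentation penalty. The Gamma link defaults to log — the inverse
link is the classical default but log is numerically safer for RTs and
keeps the set-size term interpretable; both are available and the choice
is recorded in the fit. RT models use correct trials only by default
(whether the original analyses did is not recoverable; the filter is a
switch). `lrt()` compares nested fits: the 5-level departure factor
against the intercept-only null has 4 degrees of freedom. Its type-I error
at the study design size (10 participants × 200 trials) is calibrated by
simulation in the test suite. `tukey_pairwise()` produces all 10 pairwise
level contrasts with single-step adjusted p-values from the joint normal
distribution of the contrast statistics, using a seeded quasi-random
integration so adjusted p-values reproduce to the integration tolerance.
`search_efficiency()` reports the per-level RT cost per added distractor
with seeded bootstrap standard errors.

## Problem sizes and numerical choices

The package's own test and acceptance computations use: the 1280-face
target (subdivision 3) with the 64 × 32 quadrature for all headline
radiometric numbers; 320-face meshes and a 16 × 8 rule where only
structure is being exercised; 100 scenes for placement statistics; 500
replicates for the type-I calibration and one 40 000-trial simulation for
parameter recovery. Degenerate inputs fail loudly: zero-irradiance faces
(unbounded optimal albedo), all-zero rasters, sub-minimum quadrature,
non-unit normals, impossible packings, indivisible designs.

## Known limitations

Single-band radiometry only (no colour, no chromaticity calibration); no
cast shadows or inter-reflections (by design: the modelled scenes are
arranged so shadows cannot act as cues); no perceptual conspicuousness
model beyond the max–min radiance statistic; random intercepts only (no
random slopes or crossed effects). The package ships no behavioural data:
empirical test statistics from a given human experiment require that
experiment's trial tables (see `read_trials()` for ingesting them) — the
simulation-based calibration and power checks play that role here.
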