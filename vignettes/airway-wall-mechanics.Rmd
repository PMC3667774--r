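---
title: "Airway wall mechanics: model, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Airway wall mechanics: model, calibration and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's account of its science: the continuum
model and its assumptions, the calibration machinery, the synthetic data
standing in for measured inputs, the numerical choices, and the places
where the design was genuinely open and a choice had to be made.

## The mechanical model

One airway is an incompressible, homogeneous, isotropic, hyperelastic
thick-walled cylinder in plane strain. A material point at undeformed
radius $r$ (inner radius $r_{in}$, outer $r_{out}$, in mm) moves, under
an axial stretch $\lambda_z$ and deformed inner radius $R_{in}$, to

$$R(r) = \sqrt{R_{in}^2 + (r^2 - r_{in}^2)/\lambda_z},$$

which is volume conservation in closed form. The stretches are
$\lambda_\theta = R/r$, $\lambda_r = 1/(\lambda_\theta\lambda_z)$
(incompressibility), and the first invariant is
$I_1 = \lambda_\theta^2 + \lambda_r^2 + \lambda_z^2$.

The strain-energy density is an $I_1$-only form,

$$W(I_1) = \tfrac{k_1}{2}(I_1-3) +
  \tfrac{k_3}{4k_2}\!\left[e^{k_2 (I_1-3)^2}-1\right],$$

a neo-Hookean term plus a Fung-type quadratic exponential. The form was
selected to satisfy the properties the airway data demand: zero energy
and stress at the reference; a nonzero ground-state stiffness set by
$k_1$ alone ($dW/dI_1 = k_1/2$ at $I_1 = 3$), which governs
distensibility over the compliant 0–1 kPa range; and a highly nonlinear
stiffening regime governed by $k_2$ and $k_3$ that produces the
noncompliant plateau of the pressure–radius curve near total lung
capacity. Structurally, $k_1$ maps onto the elastin-dominated response
and $k_3$ onto collagen recruitment; the tree calibration ties them with
$k_3 = 6k_1$.

Because the Lagrange multiplier enforcing incompressibility cancels in
stress differences, the hoop-minus-radial stress is purely constitutive,
$\sigma_\theta - \sigma_r = 2(\lambda_\theta^2 - \lambda_r^2)\,dW/dI_1$,
and radial equilibrium integrates to the luminal pressure
$P_{in} = \int_{R_{in}}^{R_{out}} (\sigma_\theta - \sigma_r)/R \, dR$
with the sign convention $\sigma_r(R_{in}) = -P_{TM}$,
$\sigma_r(R_{out}) = 0$ (outer pressure zero). Only $P_{TM} \ge 0$ is
modelled: describing the buckling-prone negative branch would require a
different energy function, and the solver rejects it explicitly.

Two derived quantities carry the physiology:

* the **incremental modulus** $Y_{inc}$, the slope of the inner-wall
  $\sigma_\theta$–$\lambda_\theta$ curve along the quasi-static
  inflation path — the tissue's operating-point stiffness; and
* the **specific compliance** $\Delta\lambda_\theta/\Delta P_{TM}$ over
  0–3 kPa, referenced to the undeformed inner radius. The package
  reports it in 1/kPa throughout. (Printed literature values of ~4.4–5.1
  "Pa⁻¹" for this quantity are dimensionally inconsistent with a
  stretch change over 3 kPa; a typeset scale factor was evidently lost,
  so no unit reconciliation is attempted.)

As a benchmark for the compliance predictions we use parenchymal hole
expansion: if lung volume at 0 kPa is 15% of its 3 kPa volume and holes
expand isotropically, the linear expansion is $(1/0.15)^{1/3} = 1.882$,
i.e. a specific compliance of 0.294 /kPa — the accepted ceiling for
airway dilation.

## Numerics

The pressure integral is pulled back to the undeformed radial
coordinate, where the limits are parameter-independent and the integrand
is smooth. The public `luminal_pressure()` uses adaptive Gauss–Kronrod
quadrature (absolute tolerance $10^{-8}$ kPa) with a fixed 64-node
Gauss–Legendre rule as fallback; the hot paths (inverse solver, fitting,
calibration) use the Gauss–Legendre kernel directly together with the
analytic derivative $dP/dR_{in}$, obtained by differentiating under the
integral sign. The two routes agree to ~$10^{-12}$ kPa, and both match a
$10^5$-point composite trapezoid oracle to better than $10^{-6}$ kPa in
the test suite.

The inverse solver exploits an exact solution for its starting bracket:
uniaxial extension of an incompressible isotropic tube is traction-free,
so the zero-pressure state at stretch $\lambda_z$ has
$R_{in} = r_{in}/\sqrt{\lambda_z}$ exactly. From there the bracket is
grown geometrically and a safeguarded Newton iteration converges to a
$10^{-9}$ kPa pressure residual; strain stiffening makes the
pressure–radius map strictly monotone, so the root is unique. The same
exactness is used when inferring a stress-free reference from a measured
curve: the zero-pressure record, acquired at the axial pre-stretch, maps
back through $r = R\sqrt{\lambda_z}$ with no model evaluation at all.

$Y_{inc}$ is computed by central finite difference on $\lambda_\theta$
(relative step $10^{-4}$; halving the step changes the value by well
under 0.1%), switching to a one-sided difference next to the
zero-pressure limit where the lower perturbation would cross into the
negative-pressure branch.

## Parameter estimation

`airway_fit()` reproduces the per-airway analysis: the objective is the
sum of squared differences between measured pressures and the model
pressure evaluated at the measured inner radii (pressure is the
controlled variable, radius the imaged one), over the retained
$P_{TM} \ge 0$ branch. The search is an exhaustive log-spaced grid —
defaults $k_1 \in [0.5, 50]$ kPa, $k_2 \in [0.01, 5]$,
$k_3 \in [0.5, 300]$ kPa, 20 points per axis — with two
shrink-and-refine rounds (5× per round, odd point counts so the
incumbent stays on the grid, windows clipped to the original bounds),
deterministic with a lexicographic tie-break. Log spacing suits
stress-like constants spanning decades. A best point on the original
boundary raises a diagnostic warning.

On noiseless synthetic curves whose generating triplet lies on the
initial grid the fit is exact (the zero of the objective is preserved
through refinement). With 0.5% relative radius noise, $k_1$ is the
weakly identified direction: the squared-pressure objective is dominated
by the stiff plateau where radius noise has maximal pressure leverage,
and the $(k_1,k_2,k_3)$ ridge lets errors-in-variables attenuation pull
individual estimates tens of percent from truth. Averaged over the
20-replicate study (seeds 1–20) the mean $k_1$ recovers to within 10% on
the study's thick-walled distal-airway configuration; the per-replicate
spread is the honest cost of fitting in the pressure direction, which is
kept because it matches how such data are analysed.

## Homeostasis calibration of the tree

Two conditions define mechanical homeostasis across the conducting tree:
at the operating pressure (0.75 kPa; 0.5 kPa available as the
sensitivity alternative) the inner-wall circumferential stress equals
12 kPa for every airway, and every airway's $Y_{inc}$–$P_{TM}$ relation
follows one shared reference curve. Each generation is specified by its
lumen radius and wall area at total lung capacity (taken as 3.0 kPa, the
top of the 0–3 kPa analysis range); the stress-free reference that
reproduces those dimensions is re-solved inside every objective
evaluation by a damped fixed-point iteration, conserving wall volume
through the axial pre-stretch of 1.2.

The calibration itself is nested rather than a joint two-parameter
search, for a reason found the hard way. The inner-wall stress at the
operating pressure is continuous and monotone in $\log k_1$ and spans
the set-point for every admissible geometry, so the stress condition is
enforced exactly by root-solving $k_1$ inside each evaluation; a
log-spaced grid search with two refinement rounds over $k_2$ then
selects the stiffening exponent whose modulus curve best matches the
reference. A joint weighted grid over $(k_1,k_2)$ was tried first and
discarded: with equal weights the modulus residual (tens to hundreds of
kPa) swamps the stress residual entirely (mean stress drifted to
16.5 kPa), and with stress-dominated weights the coarse grid selects
incumbents by accidental stress proximity and refinement locks in poor
$k_2$ values. The nested design is deterministic, faster (the inner
iterations skip the modulus curve), and if the set-point is unattainable
within the $k_1$ bounds it raises an error reporting the closest
achievable stress.

The modulus residual is an RMSE on the **log** scale over an 11-point
grid from 0.25 to 3 kPa. The modulus spans roughly 19 to 3000 kPa over
that range, so an absolute-kPa RMSE is a statement about the top of the
curve only; on the log scale the whole curve counts, and the calibrated
modulus at 0.75 kPa lands within a few percent of the reference for
every generation. The absolute RMSE is still reported in the residuals.
An airway counts as converged when its stress residual is below 0.1 kPa
and its log-RMSE below 0.35; the log-RMSE cannot vanish away from the
nominal geometry because the attainable modulus-curve family varies with
relative wall thickness.

The shipped reference curve (`extdata/yinc_reference_synthetic.csv`) is
synthetic: it is the modulus–pressure curve of a nominal mid-range
airway (generation 7 of the default tree) solved so that its modulus at
0.75 kPa is 245 kPa — the midpoint of the physiological 180–310 kPa
band — while its inner-wall stress is 12 kPa. `make_yinc_reference()`
regenerates it, and a test asserts the fixture matches its constructor.

## The synthetic tree and what it does (not) show

The generator emulates the structure of CT-derived human dimension
tables: an exponential lumen-radius decay with generation
($R_0 = 9$ mm, factor 0.79 per generation, 15 generations) and a single
linear wall-area–radius line shared by newborn, child and adult trees
(slope 7.2 mm, intercept 0.3 mm²), so that an airway's wall area depends
only on its radius, not its age. Radii for younger ages scale by factors
0.3 (newborn) and 0.5 (child). The slope/intercept pair was chosen once,
by an attainability analysis, so that both homeostasis conditions are
simultaneously satisfiable at every generation: it puts the tracheal
wall-thickness-to-radius ratio at TLC near 0.12, rising toward the
periphery as the linear law dictates. Pressure–radius curves add
multiplicative Gaussian noise (default 0.5% relative, a nominal
sub-pixel imaging precision — arbitrary, and documented as such) to both
radii, never to the controlled pressure; all randomness flows through
explicit seeds and global RNG state is restored.

What passing tests on these data show is that the machinery is
self-consistent: exact forward–inverse round trips, exact noiseless
recovery, calibration that truly holds the set-points, and tree-wide
predictions with the expected orderings. What they cannot show is
fidelity to real airways: the synthetic tree has no biological scatter
about the dimension line, no inter-animal variability, no hysteresis or
viscoelasticity, and its wall-area line was chosen for attainability,
not measured. Directional results (compliance rising toward the
periphery while staying below the parenchymal benchmark; tidal strains
of ~4–5% against deep-inspiration strains of ~9–11%, varying less than
2-fold across the tree; compliance falling from newborn to adult) mirror
the physiology qualitatively, and their numerical values are properties
of the synthetic conditions.

## Growth and remodeling

A log-log least-squares fit of $k_1$ (and $k_2$) against wall area
across the calibrated adult generations defines the growth law; $k_3$
follows the fixed ratio. The law extrapolates its log-linear trend
beyond the fitted wall-area range (with a warning) rather than clamping:
newborn peripheral wall areas lie below every adult value and remodeled
walls grow above the tracheal value, so clamping would flatten growth
trajectories and block remodeling; a clamping mode is retained as an
option. Growth trajectories assign each age stage its dimensions, take
material constants from the law, rebuild the reference geometry, and
report specific compliance normalised to the newborn value.

Chronic constriction is modelled as the airway held at a radius reduced
by a given fraction of its operating radius. The held inner wall then
sits at a reduced circumferential stretch, and with the radial boundary
condition $-P_{TM}$ its stress falls below the set-point. Remodeling
walks along the growth law — anchored through the airway's own
calibrated point, so zero constriction means zero change — until the
stiffer material restores the set-point at the held stretch; the
bronchodilator comparison then evaluates the passive compliance of the
thicker, stiffer wall against baseline. An alternative operationalisation
(re-equilibrating the remodeled airway passively at the constricted
radius) was implemented and rejected: under it, thickening always lowers
the inner-wall stress, so no growth can restore homeostasis.

Two quantitative features of the adopted model deserve emphasis. First,
it is hypersensitive by construction: an operating-point stiffness near
245 kPa means a few percent of radius erases a large fraction of the
12 kPa set-point, and with the shallow fitted law
($k_1 \propto A_w^{0.39}$) the restoring wall area grows as the deficit
to the power $1/0.39$. Second, it has a hard feasibility boundary: once
the held stretch falls below $1/\sqrt{\lambda_z} \approx 0.913$ the
inner wall is in circumferential compression and no stiffness restores a
tensile stress — for the synthetic trachea this happens near 12–24%
constriction. The error path reports the achievable stress range, and
remodeling sweeps in the tests run over 2–10% constriction, where wall
area increases and passive compliance decreases strictly monotonically.

## Degenerate inputs and edge behaviour

Negative transmural pressures raise an informative error everywhere.
Curves without a record within 0.05 kPa of zero pressure, or without
outer radii there, cannot yield a reference geometry and say so. Grids
with non-positive bounds, dimension tables with duplicated or
non-contiguous generations, wall-area lines implying walls thinner than
1% of the radius, and modulus references that are not monotone in
pressure are all rejected at construction. Ties in the grid search break
lexicographically toward the smallest parameter vector, making every fit
bit-reproducible.

## Problem sizes

The shipped defaults were chosen as the package's standard working
sizes: 31-point pressure ramps, 20³-point fitting grids with two
refinements, a 15-generation tree whose full calibration takes well
under a minute on one core, a 20-replicate noise study, and 50-instance
quadrature oracle checks. All are configurable through `grid_spec()`,
`homeostasis_spec()` and the generator configs.

## Known limitations

The wall is elastic, homogeneous and isotropic; there is no
viscoelasticity, no layered or fibre-reinforced structure, no smooth
muscle tone, and no negative-pressure buckling. Plane strain fixes the
axial stretch, so dynamic axial lengthening during breathing is outside
the model. The homeostasis reference curve is a synthetic stand-in for a
population mean, and the tree dimensions are generated, not measured —
quantitative outputs are twins of the synthetic study conditions, not of
any real lung.
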