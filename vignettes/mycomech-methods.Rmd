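---
title: "Methods: compression mechanics of mycelium-bound composites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: compression mechanics of mycelium-bound composites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mycomech)
```

Mycelium-bound composites are cylindrical specimens of plant particles
(hemp shives, rapeseed straw, and similar lignocellulosic substrates)
bound by a fungal hyphal network and tested in uniaxial compression as
candidate replacements for petroleum foams. This vignette is the package's
own account of the models and numerical choices behind each stage of the
analysis; it states no result that the test suite or the acceptance script
does not itself compute.

## Reduction of compression records

A testing machine reports force $F$ (N) against crosshead displacement $u$
(mm). With reference cross-section $A_0 = \pi D_0^2/4$ (mm²) and height
$L_0$ (mm), the engineering quantities are $\sigma = F/A_0$ (MPa, since N
and mm² combine to MPa directly) and $\varepsilon = u/L_0$. Strain is
positive in compression; the model layer uses the stretch
$\lambda = 1 - \varepsilon$ and signed stresses, and the conversion
between the curve's stress magnitudes and the model's signed stresses
happens exactly once, at the fit boundary. Samples recorded before the
force first crosses the machine pre-load (1 N by default) are trimmed; the
sample bracketing the crossing is kept so interpolation has no gap.

Summary statistics follow standard foam-testing practice:

* **Compressive strength** $\sigma_{st}$: stress linearly interpolated at
  20 % strain. A curve ending earlier yields an explicit missing value,
  never 0.
* **Elastic modulus** $m$: ordinary least-squares slope of $\sigma$ versus
  $\varepsilon$ inside a window. The lower bound is 10 % strain — below
  it the cross-section is unevenly loaded because specimens grow with
  slightly inclined top faces. The upper bound uses the elastic recovery:
  the post-test height $h_p$ splits the maximum applied strain into a
  plastic part $(L_0 - h_p)/L_0$ and an elastic recovery
  $\varepsilon_{\max} - (L_0 - h_p)/L_0$ (clipped at 0 with a warning if a
  measurement implies the impossible). Whether the recovery acts as a
  *span* on top of the 10 % floor (default, `rule = "span"`, upper bound
  $0.10 + $ recovery) or as an *absolute* bound is configurable, because
  either reading is defensible; the span reading uses exactly the
  post-test measurement and is the default. When the resulting bound
  exceeds the last recorded strain it is clamped to the measured range:
  the slope cannot be observed beyond the data. A consequence worth
  knowing: for a material that yields before 10 % strain (the EPS-like
  benchmark), this window measures the plateau slope, not the initial
  stiffness — which is the honest reading of the definition, and why the
  benchmark's tabulated "modulus" is small.
* **Mean curves**: replicates are linearly interpolated (no smoothing —
  reproducible and order-preserving) onto a uniform strain grid bounded by
  the shortest replicate, so no point is extrapolated; the band is a
  pointwise two-sided Student-t 95 % interval, a choice made here since
  several CI constructions would be consistent with common practice.

## The compressible Neo-Hookean model

The strain-energy density in principal stretches is

$$w(\lambda_i) = c\left(\lambda_1^2+\lambda_2^2+\lambda_3^2-3
 -2\ln(\lambda_1\lambda_2\lambda_3)\right) + d\,(\lambda_1\lambda_2\lambda_3-1)^2,$$

with $c$ (shear-like) and $d$ (volumetric) in MPa, both strictly positive.
Requiring the lateral faces to be stress free under axial stretch
$\lambda$ gives a quadratic for the volume ratio $J$,
$d J^2 + (c/\lambda - d)J - c = 0$, whose unique positive root determines
the lateral stretch $\sqrt{J/\lambda}$ and the closed-form axial second
Piola–Kirchhoff stress

$$S_{33}(\lambda) = 2c\left(1-\frac{1}{\lambda^2}\right)
 + d\,\frac{\psi}{\lambda^3}\left(\frac{\psi}{2\lambda}-1\right),
 \qquad \psi = 2\lambda J .$$

Expanded, $\psi(\lambda) = \lambda - c/d + \sqrt{4(c/d)\lambda^2 +
(\lambda - c/d)^2}$. A widely circulated variant of this expression
carries $(\lambda + c/d)^2$ inside the root; that form does **not**
satisfy the stress-free identity $S_{33}(1) = 0$ (the package exposes it
behind `psi_form = "as-published"` and a test demonstrates the violation),
so the re-derived minus-sign form is the default and the only one used for
fitting. At extreme ratios $c/d$ the $\psi$ formula cancels terms of size
$c/d$, so the attainable accuracy of the identity is
$\varepsilon_{mach}\,(1 + c/d)$ — the tests and the acceptance script
normalise by that scale.

Every closed-form evaluation is verifiable against an independent route:
`uniaxial_stress_oracle()` minimises $w(q, q, \lambda)$ over the lateral
stretch $q$ (robust 1-D search, polished by Newton iterations on
$\partial w/\partial q = 0$ because the search alone only locates the
minimiser to about $\sqrt{\varepsilon_{mach}}$), then differentiates the
energy centrally. Agreement is better than $10^{-8}$ relative over
$\lambda \in [0.5, 0.99]$ and $c/d \in [10^{-2}, 10^{2}]$.

Linearising about the identity gives shear modulus $\mu = 2c$ and Lamé
constant $\Lambda = 2d$, hence

$$E = \frac{2c(2c+3d)}{c+d}, \qquad \nu = \frac{d}{2(c+d)} \in (0, \tfrac12),$$

used to seed the fit and to check the finite-element solver in its linear
limit.

### Parameter identification

`fit_neo_hooke()` runs bounded nonlinear least squares
(Levenberg–Marquardt) on $\log c, \log d$ — positivity without
constrained-solver edge cases — with box bounds $10^{-6}$–$10^{3}$ MPa and
an initial guess that inverts the small-strain formulas against the data's
secant modulus at an assumed $\nu_0 = 0.25$ (which makes $d_0 = c_0$).
Residuals are unweighted; no random restarts, so the fit is deterministic.

Two stress interpretations are offered. The default (`second_piola`) fits
$|S_{33}|$ directly to $\sigma = F/A_0$ — the convention this analysis
chain is built around — even though $F/A_0$ is strictly the nominal stress
$\lambda S_{33}$. The `nominal` interpretation fits $\lambda|S_{33}|$ and
is the self-consistent choice; it is what the synthetic-data recovery
tests and the FEM cross-checks use, since the forward model generates
nominal forces. Fitting noise-free nominal data with the second-Piola
interpretation biases $(c, d)$ noticeably — users comparing fitted
parameters across software should check which convention was applied.

Identifiability is asymmetric: $c$ controls the dominant shear response
and is recovered to within about 1 % from six replicates with 2 %
multiplicative force noise, while $d$ only enters through the lateral
contraction and is recovered to a few percent, degrading as $c/d$ grows
(shear-dominated materials barely constrain the volumetric term). The
acceptance script reports the worst-case recovery error over three
conditions spanning $c/d$ from 0.6 to 2.

## Finite-element simulation of the test

The simulation reproduces the test setup: a cylinder with a slightly
slanted top face compressed by a rigid horizontal stamp.

* **Mesh**: structured 8-node hexahedra. A uniform square grid maps onto
  the disk by the smooth elliptical map
  $x = \xi\sqrt{1-\eta^2/2},\; y = \eta\sqrt{1-\xi^2/2}$ (boundary nodes
  exactly on the circle, Jacobians positive). The slant scales each
  node's height linearly, $z \mapsto z\,(1 + \tan\alpha\, x/L_0)$, keeping
  the bottom flat while the top height varies by $D_0\tan\alpha$. The
  coarse polygonal footprint under-covers the disk (about 10 % at one
  element across the radius, vanishing quadratically on refinement), so
  all homogeneous-solution comparisons use the mesh's own cross-section
  `mesh_cross_section_area()`, for which the coarse solution is exact;
  at the refinement used in tests the *nominal-stress* response changes by
  well under 2 % — the discretisation, not the footprint, is the quantity
  a refinement study probes.
* **Elements**: total-Lagrangian tri-linear hexahedra with full 2×2×2
  Gauss quadrature, $S = 2\,\partial w/\partial C$ evaluated from the
  invariant form of the energy, analytic consistent tangent (verified
  against central differences of the internal force). No locking
  treatment: $\nu < 1/2$ strictly and fitted foams sit at moderate $d/c$;
  a documented limitation for nearly incompressible parameter sets.
* **Contact**: node-wise frictionless penalty against the stamp plane;
  penetration $g$ draws a restoring force $\kappa g$. The default
  $\kappa = 1000\,E A_{node}/L_0$ (dimensionally consistent, $A_{node}$
  the tributary top area per node) keeps the penetration error of the
  reaction near 0.1 %, so a tenfold stiffer penalty moves the reaction by
  well under 0.5 %.
* **Boundary conditions**: the bottom face is fixed vertically and free
  laterally, with three pinned in-plane components to remove rigid-body
  modes. This frictionless set admits the exact homogeneous uniaxial
  solution — the key cross-module oracle: a flat-top frictionless run must
  reproduce $A_{mesh}\lambda|S_{33}(\lambda)|$ (within 2 % up to 30 %
  compression even on a 2×2×2-element mesh, the residual coming from
  penalty penetration). A fully clamped option exists for qualitative
  barreling.
* **Solver**: uniform stamp increments of $L_0/100$ by default, Newton
  iteration to a relative residual of $10^{-9}$ (relative to the contact
  reaction), automatic increment halving on non-convergence or element
  inversion, partial results returned with a warning rather than lost.
* **Output**: stamp travel versus reaction, per-element von Mises
  equivalent of the Cauchy stress $\sigma = J^{-1} F S F^T$ (the
  equivalent-stress measure is this package's choice), nodal
  displacements; legacy-ASCII VTK plus delimited tables.

## Particle statistics

Maximum Feret diameter is the convex-hull diameter; the minimum is the
smallest projection width over hull-edge directions (the rotating-calipers
minimum is always attained flush against a hull edge). Sieve
classification needs a passage criterion for image-derived outlines: the
minimum Feret diameter is used as the passage dimension, the standard
proxy for elongated particles through square meshes; a particle passes a
mesh iff its minimum Feret is strictly smaller. Default meshes 0.63, 2 and
3.15 mm give undersize/small/medium/large fractions; mass defaults to
polygon area × unit thickness when true masses are absent, and fractions
sum to 1 to within $10^{-12}$. Histograms of the min/max Feret ratio use
20 uniform bins on (0, 1] by default, the modal ratio being the fullest
bin's midpoint (ties to the lower bin).

## The synthetic-data generator

The generator emulates the study conditions the analysis is designed for,
with every choice fixed up front:

* Geometry: cylinders with $D_0 \in [69, 71]$ mm, $L_0 \in [60, 70]$ mm,
  top-face slant up to 3°, sampled uniformly.
* Forward model: displacement on a 0.1 mm grid (machine-like sampling, far
  finer than any feature analysed); effective strain
  $\max(0, (u - u_{toe})/L_0)$ with a smooth exponential toe
  $u_{toe}(u) = t\,(1 - e^{-s u/t})$ standing in for the gradual
  compaction of the soft surface mycelium — the simplest smooth monotone
  engagement model, a stand-in rather than an inference of the real
  layer's mechanics; force $A_0 \lambda |S_{33}(\lambda)|$.
* Noise: multiplicative lognormal with unit mean (forces stay positive),
  2 % coefficient of variation in the demo; between-specimen scatter is
  unit-mean lognormal on $(c, d)$, 5 % in the demo. Records stop at 1.8 kN
  or a per-condition displacement limit (32/42/44 and 30/35/40 mm for the
  six demo conditions), whichever comes first, and carry a stop flag.
* The demo's six conditions emulate a two-substrate × three-size design
  with ground-truth $c = d$ chosen so strengths fall in the 0.05–0.12 MPa
  range typical of such composites and decrease from small to large
  particles; the post-test height assigns 30 % of the maximum strain as
  plastic. An EPS-like benchmark (linear rise to a plateau with mild
  hardening, then quadratic densification) is appended for comparative
  report plumbing only — it is a three-segment cartoon, not a fitted
  material, and is excluded from constitutive fitting.
* Particle presets: rotated rectangles, lognormal length and width/length
  aspect, small vertex jitter with hull reconstruction to stay convex. The
  hemp-like preset has a lower modal aspect (0.28) than the rapeseed-like
  one (0.48), encoding "thinner, more elongated" in the modal value; real
  populations differ in ways this deliberately does not capture (the two
  real distributions also differ in breadth and skew, and real modal
  orderings can differ from elongation orderings).

What passing tests on these synthetics do and do not show: they verify the
algebra, the estimators and the solvers against known ground truth; they do
not validate the Neo-Hookean model against real composites (real curves
show plasticity and damage the model omits), nor do they reproduce any
laboratory modulus or strength — raw experimental records for such
composites are generally not deposited, which is exactly why the generator
exists.

## Reproducibility and problem sizes

One master seed fans out to per-stage child seeds (drawn from the parent
stream), so stages rerun independently yet reproducibly; `run_pipeline()`
output is byte-identical under a fixed seed and configuration apart from
one timestamp header field, and serialized reports omit the output path so
location does not perturb bytes. The test and acceptance problem sizes —
coarse FEM meshes of 8–64 elements, six replicates per condition, 1000 to
5000 Monte-Carlo draws — were chosen as the smallest sizes at which every
verified property is comfortably resolved; all checks complete in a few
minutes on a single CPU.

## Known limitations

* No viscoelasticity, damage, or substrate debonding in the constitutive
  model; curves beyond the quasi-elastic range are fitted only in the
  least-squares sense.
* No friction models in contact; no densification-onset or
  energy-absorption metrics in the reduction.
* Tri-linear hexahedra without locking treatment lose accuracy as
  $\nu \to 1/2$.
* The toe model and the EPS benchmark are plumbing for testing pipelines,
  not material science.
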