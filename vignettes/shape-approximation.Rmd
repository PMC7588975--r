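---
title: "Shape approximation of uptake regions: models, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shape approximation of uptake regions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(roifit)
```

## The problem

Dopamine-transporter SPECT imaging shows the striatum as a bright uptake
region. In healthy subjects the region is elongated — comma-shaped in a
2D-combined image, cashew-shaped in 3D — while in Parkinsonian
degeneration it contracts toward an oval or sphere. Volume-based summaries
cannot distinguish two regions of equal volume but different shape, so
`roifit` represents the region *directly* by an implicit shape equation
and uses the fitted coefficients as classification features.

Two families are implemented:

* **2D ellipse** — the conic
  $\Psi_{2D}(x,y) = Ax^2 + 2Bxy + Cy^2 + Dx + Ey + F$ with the ellipse
  condition $B^2 < AC$;
* **3D cashew-shaped quartic** — the base surface
  $\Psi_0(x,y,z) = (1.5x^2 + y^2 + z^2 + a^2 - b^2)^2
   - 4a^2\left((x-c)^2 + (y-d)^2\right)$
  with $a,b,c,d \in [0,1]$, generalised by a rigid transform
  $\Psi(x) = \Psi_0\!\big(s\,M\,(x - t)\big)$, where $M = R_x R_y R_z$ is
  the fixed-order rotation, $t$ the translation and $s > 0$ the scale.

Given boundary points $p_1,\dots,p_n$ of the region, the fitted shape
minimises the **total Euclidean distance**
$\sum_i d(p_i, H)$, $d(p,H) = \min_{x \in H} \lVert p - x \rVert$, over
the parameter vector, where $H$ is the zero set of $\Psi$. This is a
geometric (orthogonal) criterion, not an algebraic residual: the variable
$y$ is not a function of $x$ on a closed curve, so ordinary least squares
does not apply.

## Distance by flashlight searching

$d(p, H)$ has no closed form for the quartic, so it is computed by an
iterative *flashlight search* (FS):

1. **Initialisation.** Inspect the boundary of a ball around $p$ small
   enough that $\Psi$ keeps one sign on it (the radius is halved until it
   does, starting from the first-order distance estimate
   $|\Psi(p)|/\lVert\nabla\Psi(p)\rVert$ when that is smaller than the
   default $0.1\times$ scale). Aim a ray at the boundary point minimising
   $|\Psi|$ and take the surface root nearest $p$ along it. We use
   $|\Psi|$, not the printed signed minimum, because the signed rule
   points away from the surface when $\Psi(p) < 0$; for interior points
   the absolute value moves toward the zero set regardless of sign. When
   the chosen ray misses the surface entirely (possible for the crescent
   lobes of the cashew), the next-best directions are tried, and finally
   the steepest-descent direction of $|\Psi|$.
2. **Tangent probes.** At the current surface point $x_m$, place probe
   points on the tangent plane at distance $\delta$ (the two in-plane
   directions in 2D; $k = 8$ evenly spaced directions in 3D), map each
   back to the surface along the ray from $p$, and move to the candidate
   closest to $p$. If no candidate improves, shrink $\delta$ by one half.
3. **Stopping.** Let $G(x)$ be the cosine of the acute angle between
   $p - x$ and the surface normal at $x$; stop when $1 - G(x) < \tau$
   (default $\tau = 10^{-8}$), i.e. at a foot of the perpendicular.

The per-iteration distances are non-increasing by construction, and the
estimate converges to $d(p,H)$ as $\delta, \tau \to 0$ for smooth,
locally convex families; the suite verifies this numerically (the error
against a dense-sampling oracle is non-increasing in $\delta$) instead of
reproving it analytically.

Defaults (all configurable through `fs_config()`): ball-search grid of
360 directions in 2D and a 1962-point Fibonacci sphere in 3D; ray-root
scan of 512 subdivisions over $\pm 4\times$ the data scale;
$\delta = 0.05\times$ scale; shrink factor 0.5; `max_iter` 200. The two
built-in families run in compiled code; the compiled path refines probe
roots by Newton's method started at the probe point, which lands on the
surface arc adjacent to $x_m$ and agrees with the reference R
implementation to $10^{-5}$ on random instances (tested). Arbitrary
user-supplied implicit surfaces use the plain R path.

The descent is local, and on a strongly non-convex surface a far query
point can have candidate feet on several sheets that the local $|\Psi|$
cue cannot rank. The compiled path therefore multi-starts the descent:
up to two starts come from the ball cue, and for queries whose
first-order distance exceeds a quarter of the search-ball radius, up to
four more from a coarse global scan of rays cast from the surface's
interior reference point (from which every sheet is visible); the
shortest converged distance wins. Near-surface queries — the fitting hot
path, where the local and global foot coincide — skip the global scan,
so the extra robustness costs nothing where speed matters.

`brute_force_distance()` is the package's independent oracle: the minimum
distance to $10^5$ surface points sampled by seeded ray shooting from an
interior point, picking a random root per ray so that all sheets of the
surface are reachable. It over-estimates the true distance by at most the
local sample spacing, which is orders of magnitude below the $10^{-3}$
agreement asserted in the acceptance suite.

## Fitting by particle swarm

The criterion is minimised by a plain bound-constrained particle swarm
(`pso_minimize()`):
$$v_i^{t+1} = \omega v_i^t + c_1 r_1 (P_i^t - x_i^t) + c_2 r_2 (G^t - x_i^t),
  \qquad x_i^{t+1} = x_i^t + v_i^{t+1},$$
with fresh scalar uniforms $r_1, r_2$ per particle per iteration,
positions clamped to bounds (the offending velocity component is zeroed),
infeasible parameter vectors (e.g. $B^2 \ge AC$, $s \le 0$) receiving an
infinite objective rather than repair, and defaults $c_1 = 1$, $c_2 = 2$,
$\omega = 0.5$, 100 particles. The run stops at `max_iter` or when the
best objective's relative change stays below `stop_tol` for 20
consecutive iterations. Seeded runs are bit-reproducible.

**Ellipse.** The swarm is centred on the closed-form direct least-squares
conic fit (Halir–Flusser stabilisation of the Fitzgibbon method), with
particles drawn in a box of half-width 50% per coordinate (floored at 10%
of the largest coefficient so near-zero coordinates still move). The
conic is scale-degenerate, so all reported coefficients are normalised to
the gauge $A + C = 1$ (an ellipse guarantees $A + C > 0$), which makes
them identifiable features.

**Cashew.** The 11-dimensional criterion is highly multimodal, and two
structural degeneracies shape the initialisation design:

* *Scale gauge.* $\Psi_0(\lambda u;\lambda\theta) =
  \lambda^4 \Psi_0(u;\theta)$, so $(a,b,c,d,s) \to \lambda(a,b,c,d,s)$
  describes the same surface. Fitted parameters are reported in the gauge
  $a + b = 1$.
* *Frame branches.* With $c = d = 0$ the base shape is even in every
  coordinate, so sixteen rotation frames describe the same seed shape but
  different branches once $c, d > 0$; because $c, d \ge 0$, only the
  correctly oriented frame can reach an asymmetric optimum.

`fit_cashew()` therefore initialises in three deterministic stages:
(1) a ring-geometry estimate — the principal plane of the cloud, a Kasa
circle fit for the ring centre and radius, and the RMS off-ring deviation
for the tube thickness; (2) a swarm plus Nelder–Mead polish on a cheap
vectorised *projection-distance surrogate* of the FS loss (a few Newton
projection steps along the gradient per point), seeded at the sixteen
frames $\times$ two $a$ levels $\times$ two ring-radius corrections with
a small asymmetric $(c,d)$ to break the frame tie; (3) the final swarm on
the true FS loss, centred tightly on the surrogate optimum. Stage 3 is
the printed update rule on the exact objective; stages 1–2 only choose
where it starts. On the reference recovery problem (200 boundary points,
noise sd 0.02, 30 particles, 100 iterations) the fitted surface is within
Hausdorff $0.14$ of the truth (bound $0.1\times$ cloud extent $\approx
0.30$) and the per-point loss is below the injected noise level.

## From images to boundary points

Grayscale images are min–max normalised to $[0,1]$; the region of
interest is the set of pixels with value above 0.6 (the threshold is a
parameter). Connected components below 10 pixels are discarded as
speckle. Boundary pixels are foreground pixels 4-adjacent to background,
reported as physical coordinates (pixel centres, origin at the lower-left
pixel centre, x rightward, y upward). Left and right striatum are
separated by a deterministic 2-means split on the x coordinate, with a
single-ROI fallback (and warning) when either side would have fewer than
6 points. For 3D fitting, boundaries are extracted per slice and lifted
to 3D using the slice z positions; slice selection is an explicit input,
as in practice the relevant slices are chosen by physicians.

2D-combined images are formed by the pixel-wise mean of the selected
slices (maximum available by flag); the mean preserves relative uptake,
matching summed-projection practice.

## Feature sets

| Set | Content | Length |
|-----|---------|--------|
| 1 | 8 uptake-histogram proportions + ROI/background uptake ratio | 9 |
| 2 | ellipse coefficients, left then right | 12 |
| 3 | cashew parameters, left then right | 22 |
| 4 | Sets 1 + 2 | 21 |
| 5 | Sets 1 + 2 + 3 | 43 |

Set 1's proportions are computed over the supra-threshold pixels
($\ge 0.60$), in the eight bins $[0.60, 0.65), \dots, [0.95, 1.00]$, so
they form a probability vector; the base population could equally have
been the whole image, but conditioning on uptake matches the reading of
the ratios as *relative* area of different uptake magnitudes. The ninth
feature is one ratio — mean uptake near the region (threshold mask
dilated by 2 px) over mean background uptake (complement of the 6 px
dilation); both masks are configurable. Coefficients enter raw (no
derived eccentricities, no circular encoding of angles). A cubic
polynomial grayscale surface (`fit_poly_surface()`, ten OLS coefficients)
is provided for completeness; the 34-feature literature set that builds
on it is defined outside this package and is not reimplemented.

## Evaluation protocol

`repeated_holdout()` implements the full protocol: per round, an 80/20
split stratified over the four reading grades (per-stratum test counts
rounded half away from zero — this reproduces test sizes 35/25/15/51 for
strata of 174/127/77/256); on the training part each of the six candidate
classifiers (SVM, naive Bayes, random forest, gradient boosting, logistic
regression, LDA — wrapped behind a pluggable `classifier()` contract; the
harness owns no learning mathematics) is tuned over a 5-value grid by
stratified 5-fold CV accuracy; the best candidate is refit on the full
training data and scored on the held-out part. The identical split is
reused for every feature set within a round, so per-round accuracies are
paired and `paired_t_test()` applies. Summaries report mean, SD and the
percentile 95% interval over rounds (the percentile interval makes no
normality assumption), plus per-candidate selection counts.

## Synthetic data: what it emulates, and what not

The generator exists because no imaging data are distributed with the
package. `generate_cohort()` emulates the *geometry* of the two-class
problem: class 0 subjects carry elongated bright shapes (ellipse aspect
ratio about 2, ring-like cashews, peak intensity 0.95), class 1 subjects
compact dimmer shapes (aspect near 1, blob-like quartics with $a < b$,
peak 0.80), with per-subject jitter on every parameter. A per-subject
mixing coefficient interpolates between the prototypes and defines the
four strata (clear cases near the prototypes, borderline cases between),
with within-class stratum proportions 174:127 and 256:77 following the
reference cohort. Images are 96×96 (2D) and four 72×72 slices (3D),
background 0.2, Gaussian pixel noise sd 0.02; intensity falls off as
$\exp(-\max(\Psi,0)/\lambda)$ with $\lambda$ calibrated so the 0.6 level
sits within a fraction of a pixel of the true zero set.

The phantoms deliberately do **not** model SPECT physics: no Poisson
counting noise, no projection/reconstruction blur, no partial-volume
effects, no anatomical background structure. Passing tests therefore
demonstrate that the algorithms recover known geometry from pixel data
and that richer shape features help classification *when the generative
geometry matches the model families* — they do not certify clinical
performance.

## Numerical choices and degenerate inputs

* Root finding: scan + bisection to $|\Psi| < 10^{-10}$; sampled surface
  points satisfy $|\Psi| < 10^{-9}$.
* Points within first-order distance $10^{-8}$ of the surface contribute
  zero loss without running FS; an unrecoverable FS failure makes the
  loss $+\infty$, so the swarm treats that parameter vector as
  infeasible.
* Equal nearest points (e.g. the centre of a circle): the returned foot
  depends on the direction grid; the distance itself is deterministic.
* Degenerate inputs error early with specific messages: constant images,
  empty ROIs, collinear point sets, one-class truth vectors,
  zero-variance paired differences.
* Angles are stored in $[0, 2\pi)$; gimbal-locked rotations resolve with
  $\theta_z = 0$.

## Problem sizes used by the test and acceptance runs

Full-budget fitting (100 particles, 200 iterations, $10^5$-sample
oracles) is accurate but slow, so the automated runs use reduced budgets
chosen once: recovery checks run 20–30 particles and 50–100 iterations on
100–200 boundary points; the swarm-constant sensitivity grid runs the
27 settings $c_1 \in \{0.8,1,1.2\}$, $c_2 \in \{1.6,2,2.4\}$,
$\omega \in \{0.4,0.5,0.6\}$ at 10 particles on one synthetic subject;
the cohort study uses 120 subjects, 20 evaluation rounds and the
`cohort_budget()` reduced per-subject budgets (coarser FS grids, at most
50–70 boundary points per side, light surrogate effort). At these sizes
the headline properties hold with comfortable margins (e.g. FS agrees
with the $10^5$-sample oracle to better than $10^{-3}$; the full feature
set does not classify worse than the ellipse-only set on the synthetic
cohort).

## Known limitations

* The FS distance is exact only up to its tolerances and can in principle
  return a local foot on strongly non-convex surfaces; the acceptance
  suite bounds this empirically on the two families used.
* The cashew coefficients are features in a fixed gauge; their absolute
  values are not anatomical measurements.
* Classification results on synthetic cohorts transfer to real data only
  insofar as real uptake regions resemble the model families; the
  package's contribution is the fitting and evaluation machinery, not a
  clinical claim.
* Fitting cost grows linearly in boundary points × particles ×
  iterations; very large studies should lower `cohort_budget()` or
  parallelise across subjects outside the package.
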