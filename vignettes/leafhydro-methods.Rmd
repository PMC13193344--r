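---
title: "Models and estimators behind leafhydro"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and estimators behind leafhydro}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leafhydro)
```

This vignette is the package's account of its science: the models fitted,
the estimator conventions adopted where the field leaves them unstated,
the numerical choices, and what the synthetic generators do and do not
emulate.

## The pressure–volume model

During slow bench drying, a leaf's water potential is the sum of an
osmotic and a turgor component. Writing the symplastic relative water
content as $R_s = (\mathrm{RWC} - \mathrm{AWF})/(1 - \mathrm{AWF})$,
the linear-turgor construction used throughout classical PV analysis is

$$\Psi_\pi = \Psi_{FT}/R_s, \qquad
  \Psi_p = \max\{0,\; -\Psi_{FT} - \varepsilon_s (1 - R_s)\}, \qquad
  \Psi = \Psi_p + \Psi_\pi,$$

with $\Psi_{FT}$ the osmotic potential at full turgor, AWF the apoplastic
water fraction (water outside the osmotically active symplast), and
$\varepsilon_s$ a symplastic-basis elastic modulus. Its two signature
properties drive everything downstream: $\Psi(\mathrm{RWC}{=}1) = 0$, and
past the turgor loss point $-1/\Psi$ is *exactly* linear in RWC (van't
Hoff dilution). The turgor loss point is
$\Psi_{TLP} = \Psi_{FT}\,\varepsilon_s/(\varepsilon_s + \Psi_{FT})$.

### Segmentation: finding the osmotic line

The analysis transforms the drydown to $y = -1/\Psi$ vs RWC and must
split it into a curvilinear turgid region and the linear osmotic region.
Three methods are provided (`pv_fit_config(breakpoint_method = ...)`):

* **`dry_growth` (default).** Start from the `min_points_linear` driest
  points — which the bench protocol guarantees are post-TLP — fit the
  line, and walk towards full turgor, admitting the next point unless it
  deviates *upward* by more than `growth_k` (3) times the residual scale
  (with a small relative floor, `rel_floor`, guarding the zero-residual
  noise-free case). The test is one-sided because turgid points always
  lie above the osmotic line. This rule recovers the exact breakpoint on
  noise-free model curves.
* **`piecewise_rss`.** Two-segment least squares over all admissible
  breakpoints. Kept for sensitivity analysis, with a caveat: because the
  turgid branch of $-1/\Psi$ is strongly convex with a large dynamic
  range, the straight-line two-segment objective systematically leaks
  turgid points into the osmotic line, and because
  $\mathrm{Var}(-1/\Psi) \approx \sigma_\Psi^2/\Psi^4$ the wet-end points
  dominate the unweighted RSS under noise. It is not the default for
  those reasons.
* **`incremental_r2`.** Grow the linear region from the dry end while its
  $r^2$ stays above `r2_min` (0.99). Simple, but the threshold is
  scale-dependent.

Points wetter than $\Psi = -10^{-9}$ MPa cannot be inverse-transformed
and are excluded from transformed-space fits (they still contribute to
turgor and capacitance calculations in raw $\Psi$ space). Points below
the protocol floor `psi_floor` (−3.0 MPa by default, matching the
bench-drying endpoint) are excluded before fitting; simulated
observations carry their actual drydown floor as an attribute so the
analysis window can match the measurement window.

### Parameter conventions

From the fitted osmotic line $y = a + b\,\mathrm{RWC}$:

* $\Psi_{FT} = -1/(a + b)$; $\mathrm{AWF} = -a/b$ (the RWC where the
  line predicts all symplastic water gone). The AWF is taken from the
  RWC-intercept; no other estimator is attempted.
* Turgor over the turgid region is $\Psi_p = \Psi - \Psi_\pi$ with
  $\Psi_\pi = -1/(a + b\,\mathrm{RWC})$. **RWC$_{TLP}$ is the
  zero-turgor intercept of the turgor–RWC regression** (the classical
  graphical intersection), not the first point assigned to the linear
  region: at the protocol's 0.2–0.3 MPa sampling the nearest-point
  convention discretises $\Psi_{TLP}$ by up to a full sampling step
  (~20% relative error for shallow turgor loss points), whereas the
  intercept is exact in the linear-turgor model. The nearest-point
  convention remains the fallback when the turgor regression is
  degenerate.
* $\varepsilon$ follows the printed convention
  $(\Delta\Psi_p/\Delta\mathrm{RWC})\cdot\mathrm{RWC}$, the slope of the
  *initial turgor loss line* times an evaluation RWC. Two choices were
  genuinely open. (1) *Which points form the initial line*: turgid points
  still carrying at least `turgor_frac` (25%) of the maximum turgor —
  near-zero-turgor points around the breakpoint carry no slope
  information and make the regression sensitive to breakpoint placement.
  (2) *Which RWC multiplies the slope*: the mean RWC of those points
  (`epsilon_eval = "mean_turgid"`; `"full_turgor"` evaluates at RWC = 1
  instead). Note that this measured $\varepsilon$ equals
  $\varepsilon_s\,\overline{\mathrm{RWC}}/(1-\mathrm{AWF})$ under the
  model — it is a total-RWC-basis quantity, deliberately distinct from
  the generator's symplastic $\varepsilon_s$.
* $C_{bulk} = (\Delta\mathrm{RWC}/\Delta\Psi)\cdot(DW/LA)\cdot(SW/DW)/M$
  with $M = 18.015$ g mol⁻¹, the formula implemented exactly as printed
  (including the $SW/DW$ ratio rather than the strict water-mass ratio
  $(SW{-}DW)/DW$ — fidelity to the published formula wins). The secant
  $\Delta\mathrm{RWC}/\Delta\Psi$ is taken over the same initial
  turgor-loss region by default; a fixed first-$k$-points window is
  available via `initial_slope_points`.

### Why the default estimator refines with a model fit

The graphical estimator is exact on clean data but information-limited
under realistic noise: the turgid region spans only
$\Delta\mathrm{RWC} \approx 0.08$ over ~6 points, so with 0.03 MPa
pressure-chamber noise and 0.5 mg balance noise the turgor-slope
regression alone carries ~10% median error in $\varepsilon$, with
oracle decompositions showing no headroom in that estimator family.
The default (`estimator = "model"`) therefore refits the three model
parameters $(\Psi_{FT}, \varepsilon_s, \mathrm{AWF})$ by weighted least
squares *in $\Psi$ space*, where measurement noise is homoscedastic,
seeded by the graphical estimates. Weights
$1/(\sigma_\Psi^2 + (\partial\Psi/\partial\mathrm{RWC}\cdot\sigma_{RWC})^2)$
absorb the mass-noise errors-in-variables; $\sigma_\Psi$ and the balance
precision are the `psi_precision` (0.03 MPa) and `mass_precision`
(5×10⁻⁴ g) configuration fields, i.e. instrument specifications, and
enter only these weights. Reported parameters still follow the printed
conventions above. This roughly halves the error of every parameter
(e.g. $\varepsilon$: ~10.6% → ~4% median) and changes nothing on
noise-free curves. `estimator = "graphical"` disables the refinement.

Constraints are enforced by construction: $\Psi_{FT} = -e^{p_1}$,
$\varepsilon_s = -\Psi_{FT} + e^{p_2}$ (so the turgor loss point always
exists), $\mathrm{AWF} = \mathrm{logis}(p_3)$; two Nelder–Mead runs
(reltol 10⁻¹², ≤1500 iterations each) from the graphical seed.

## Light responses

Both gas-exchange responses use the nonrectangular hyperbola, the lower
root of $\theta A^2 - (\phi Q + A_{sat})A + \phi Q A_{sat} = 0$, minus
$R_d$ for assimilation or plus $g_0$ for conductance; the response at
$Q = 0$ is therefore $-R_d$ (or $g_0$) exactly, and the asymptote is
$A_{sat} - R_d$. Fitting choices:

* $\theta$ mapped through a logistic into (0, 1), $\phi$ and the
  saturated response through logs; a fit with $\theta$ within 10⁻⁶ of a
  bound is flagged (`theta_at_bound`).
* Responses are rescaled by their maximum absolute value before
  optimisation so assimilation (tens of µmol m⁻² s⁻¹) and conductance
  (tenths of mol m⁻² s⁻¹) behave identically numerically.
* Eight deterministic starts built from data heuristics ($\phi_0$ from
  the slope over the two lowest nonzero light levels, saturation from the
  maximum response, $\theta_0 \in \{0.5, 0.9\}$, ×{1,2} and ×{1,1.3}
  spreads); short Nelder–Mead runs from each, then two tight polishes of
  the best. The polished objective never exceeds the best start, and the
  whole procedure is bit-reproducible. Residuals are unweighted
  (homoscedastic assumption; no weighting scheme is standard here).
* The default design is the 9-level sequence 2000…0 µmol m⁻² s⁻¹; a
  design lacking a level ≤50 or ≥1200 triggers an identifiability
  warning.

Leaf hydraulic conductance is the plain evaporative-flux ratio
$K_{leaf} = E/(\Psi_{stem}-\Psi_{leaf})$; a non-positive driving gradient
is an error (an equilibrated or mismeasured leaf pair), and $E$ is taken
at face value under the usual assumption that boundary-layer conductance
exceeds stomatal conductance.

## Phylogenetic comparative layer

**Covariance.** `phylo_covariance(tree, lambda)` is the shared
root-to-tip path-length matrix with off-diagonals multiplied by Pagel's
$\lambda$; the diagonal is untouched, so $\lambda = 0$ is a star-like
(independent) model and $\lambda = 1$ plain Brownian motion. Trees must
be ultrametric (checked at ingest within a relative tolerance of 10⁻⁶ of
mean depth); zero-length terminal branches make the matrix singular and
are a hard error rather than being jittered.

**PGLS.** $\hat\beta = (X^\top V^{-1}X)^{-1}X^\top V^{-1}y$ via a
Cholesky rotation. $\lambda$ is estimated by maximising the profile
log-likelihood ($\sigma^2$ profiled out as $r^\top V^{-1} r/n$) with
Brent search on [0, 1] at 10⁻⁶ tolerance plus explicit endpoint
evaluation, ties resolved toward the interior (profiles can be monotone
to a boundary). Coefficient tests are two-sided $t$ on $n - k$ degrees of
freedom, the usual GLS convention. Because several $r^2$ definitions
coexist for GLS, the package states its choice prominently:
$r^2 = 1 - \mathrm{RSS}_V/\mathrm{TSS}_V$ with TSS taken about the GLS
(phylogenetically weighted) mean at the same $\hat\lambda$, and
$\mathrm{adj}\,r^2 = 1-(1-r^2)(n-1)/(n-p-1)$ with $p$ the number of
non-intercept predictors. Published adjusted-$r^2$ values are
package-convention-dependent; comparisons across software should check
this definition first.

**Ancestral states.** ML Brownian-motion reconstruction solves the
linear system given by the branch-length-weighted graph Laplacian
(weights $1/\ell_e$): internal states are the conditional means given the
tips, identical to the re-rooting algorithm used elsewhere in the field
(the test suite checks both a brute-force likelihood optimiser and
`phytools::fastAnc` agreement). Variances are
$\hat\sigma^2 \cdot \mathrm{diag}(L_{II}^{-1})$ — the conditional
variance of each internal node given the tips — and 95% CIs are
state ± 1.96·√variance. $\hat\sigma^2$ comes from the tip likelihood
with the ML divisor $n$ by default (`sigma2_method = "unbiased"` uses
$n-1$); with 50 tips this makes intervals ~1% narrower than the unbiased
choice, visible as root-CI coverage slightly below 95% in the
calibration simulations. A constant trait gives $\hat\sigma^2 = 0$ and
degenerate (zero-width) intervals, flagged rather than hidden.
"Posterior probability" language sometimes attached to such maps is
just the ML estimate + CI mapped onto the tree; no Bayesian machinery is
involved or implied.

## Group comparisons and climate PCA

Kruskal–Wallis uses the tie-corrected midrank statistic (delegated to
`stats::kruskal.test`) with a $\chi^2_{k-1}$ reference; an all-tied input
has $H$ defined as 0 with $p = 1$. The test addresses stochastic
dominance among groups, not strictly differences in means — the package
makes no stronger claim. The post hoc procedure is Dunn's pooled-rank
z-tests with Holm adjustment (the standard nonparametric follow-up when
only letters are reported and no procedure is named); pairwise
Mann–Whitney is available as an alternative. Letters come from the
insert-and-absorb algorithm on the significance graph: groups sharing a
letter are pairwise non-significant and the letter count is minimal.

Climate PCA standardises columns (zero-variance columns dropped with a
warning) and decomposes by singular values. Orientation is made
reproducible by flipping each component so its largest-magnitude loading
is positive; the scientific orientation of PC1 (e.g. "warm-wet
positive") is reported, not asserted, and can be flipped downstream. PC1
is the climate axis passed to PGLS; PC2 is retained in outputs but not
modelled. One subtlety worth recording: under a one-factor model with
loadings $\ell$, *standardised* PCA loadings are not proportional to
$\ell$ (standardisation rescales each column); factor recovery must be
assessed after mapping loadings back to the raw scale by the column
standard deviations, which is what the tests do.

## Synthetic generators: what they emulate, and what they do not

Every pipeline input has a seeded generator whose defaults are the study
conditions the analysis is designed for:

* **PV drydowns** follow the linear-turgor model above on a grid of
  water-potential targets spaced `psi_step` = 0.25 MPa apart (the
  protocol's 0.2–0.3 MPa intervals) from 0 down to −3.0 MPa, with
  Gaussian noise of 0.03 MPa on $\Psi$ (pressure chamber) and
  5×10⁻⁴ g on mass (4-point balance). When the implied turgor loss
  point lies near the −3.0 MPa floor, the drydown is extended by
  `n_min_osmotic` (4) steps past the TLP — a drydown that stops at
  turgor loss cannot identify the osmotic line, and in practice an
  operator dries until the inverse plot straightens; the observation
  records the floor actually used. Default mass ratios (SW 0.12 g,
  DW 0.04 g, LA 10 cm²) give DW/LA = 40 g m⁻² and SW/DW = 3, typical of
  grass leaves.
* **Light curves** evaluate the hyperbola at the standard 9-level design
  with 0.5 µmol m⁻² s⁻¹ noise (assimilation scale).
* **Trees** are pure-birth, rescaled to unit depth; **traits** are drawn
  from $\mathcal{N}(\mu, \sigma^2 C_\lambda)$ so the generator and the
  estimators share only the covariance definition, not code paths.
* **Climate** is a one-factor model over 19 variables with mixed-sign
  loadings (means positive, seasonality/range negative) and idiosyncratic
  noise, emulating the dominant axis structure of the standard
  bioclimatic set.
* **The study generator** assembles 13 populations in five groups
  (3 C3-2x, 3 C3–C4-2x, 3 C4-2x, 3 C4-6x, 1 C4-12x; three replicate
  leaves each), planting C4-associated shifts: higher minor vein density,
  bundle-sheath area, apoplastic fraction, hydraulic conductance, and
  δ13C near −12.5‰ vs −25 to −27‰ for non-C4; thicker leaves at higher
  ploidy. Replicates are aggregated to population means once, in a
  dedicated stage, before any comparative modelling (per-leaf parameters
  are derived first, then averaged — the alternative order is not
  supported because PV parameters are nonlinear in the raw series).

What passing tests on these generators shows is *internal* correctness:
estimators recover the quantities the generative model defines, at the
stated noise. Real leaves violate the generators in known ways — plateau
(oversaturation) effects at the wet end of PV curves, non-Gaussian
pressure-chamber errors, light-response hysteresis, non-Brownian trait
evolution, spatially structured climate — and none of these are
emulated. Results on real data therefore inherit the usual caveats of
the underlying methods, not a guarantee from this test suite. No attempt
is made to mimic any particular species' trait values or geography.

## Numerical choices and degenerate inputs

* Breakpoint ties go to the wettest admissible boundary; a fully linear
  curve (no turgid region) is legal and flagged, with the TLP falling
  back to the first linear point.
* An osmotic line with non-positive slope is a fit failure (unphysical),
  not a warning. AWF at or above the driest linear-region RWC is flagged
  unreliable.
* `pv_parameter_table()` converts per-record failures into `NA` rows
  with the error message in a `flags` column rather than aborting a
  batch.
* The λ profile and the PV model fit are bounded-parameter optimisations
  with smooth reparameterisations instead of box constraints, avoiding
  optimiser boundary failures.
* Pipeline problem sizes (13 populations × 3 replicates; 200-replicate
  recovery simulations; 500-draw coverage checks; 100-tip recovery
  trees) were chosen as the smallest sizes at which the sampling
  distributions of the checked statistics are stable; they keep a full
  test run in the low minutes on a single core.

## Known limitations

* No plateau/rehydration-artifact trimming at the wet end of PV curves.
* No CO₂-response modelling, no energy-balance recomputation of E, no
  boundary-layer correction.
* Comparative models are univariate BM/λ only — no OU or early-burst
  models, no multivariate PGLS, no phylogenetic ANOVA; within-population
  measurement error is not propagated into PGLS — population means are
  fitted, as is conventional when each point is a replicate mean.
* C3 vs C3–C4 sub-classification requires external physiological
  evidence and is accepted as a user-supplied label; only the C4 /
  non-C4 split is computed from δ13C.
* Phylogenies are consumed ultrametric; no inference or dating.
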