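# leafhydro

Leaf water-relations analysis for comparative plant ecophysiology:
pressure–volume (PV) curve parameter extraction, light-response curve
fitting, leaf hydraulic conductance, anatomical trait derivation, and a
phylogenetic comparative layer — with seeded forward generators for every
input, so the whole pipeline runs and is testable without field data.

## Who this is for

Plant ecophysiologists comparing leaf hydraulic traits across populations
or species — for example, testing whether the leaf anatomy of C4 grasses
(dense minor veins, enlarged bundle sheaths) is associated with higher
leaf hydraulic conductance and capacitance, while controlling for shared
evolutionary history with a phylogeny.

## What it computes

**Pressure–volume parameters.** A bench-dried leaf yields paired
(fresh mass, Ψ_leaf) measurements. With relative water content
RWC = (FW − DW)/(SW − DW), the post-turgor-loss points fall on a straight
line in −1/Ψ vs RWC. From the curve the package derives:

* Ψ_FT — osmotic potential at full turgor, −1/(osmotic line at RWC = 1)
* AWF — apoplastic water fraction, the RWC-intercept of the osmotic line
* Ψ_TLP, RWC_TLP — turgor loss point, where the turgor pressure
  Ψ_p = Ψ − Ψ_π extrapolates to zero
* ε — bulk modulus of elasticity, ε = (ΔΨ_p/ΔRWC)·RWC over the initial
  turgor-loss line
* C_bulk — bulk leaf capacitance,
  C_bulk = (ΔRWC/ΔΨ)·(DW/LA)·(SW/DW)·(1/M), in mol m⁻² MPa⁻¹

The default estimator refines the classical graphical (inverse-plot)
estimates with a weighted least-squares fit of the linear-turgor PV model
in Ψ-space; `pv_fit_config(estimator = "graphical")` keeps the pure
graphical path. See the methods vignette for why.

**Light responses.** Net assimilation and stomatal conductance are fitted
with the nonrectangular hyperbola

    A_n = [φQ + A_sat − sqrt((φQ + A_sat)² − 4θφQA_sat)] / (2θ) − R_d

(and the analogous form with g_sat and +g_0 for conductance), with θ
constrained to (0, 1] and eight deterministic multistarts.

**Leaf hydraulic conductance.** Evaporative flux method:
K_leaf = E/(Ψ_stem − Ψ_leaf), with Ψ_stem from an adjacent bagged leaf.

**Anatomy.** Major/minor vein densities per unit leaf width (the minor
density is VLA2), mean bundle-sheath area per leaf width
((IBSA/width + PBSA/width)/2), and δ13C-based classification
(δ13C > −17‰ ⇒ C4).

**Comparative layer.** PGLS with maximum-likelihood Pagel's λ (profile
likelihood over [0, 1], adjusted r², t-based p-values), Brownian-motion
ML ancestral state reconstruction with per-node variances and 95% CIs,
tie-corrected Kruskal–Wallis tests with Dunn/Holm post hocs and compact
letter displays, and standardised PCA of 19 bioclimatic variables with
PC1 extracted as a climate axis for PGLS.

## Worked example

```r
library(leafhydro)

# a drydown with known ground truth (psi noise 0.03 MPa, mass noise 0.5 mg)
truth <- pv_ground_truth(psi_ft = -1.2, epsilon = 10, awf = 0.25, seed = 1)
obs <- simulate_pv_curve(truth)
derive_pv_parameters(obs, pv_fit_config(psi_floor = attr(obs, "psi_floor")))
#> PV parameters (leaf 'synthetic'):
#>   psi_TLP = -1.373 MPa   psi_FT = -1.192 MPa
#>   RWC_TLP = 0.902       AWF    = 0.254
#>   epsilon = 11.81 MPa   C_bulk = 0.4804 mol m^-2 MPa^-1
#>   osmotic line r^2 = 0.9874 (breakpoint index 7)
```

The generating truth was Ψ_FT = −1.2 MPa and AWF = 0.25 with an implied
Ψ_TLP of −1.364 MPa, so each parameter is recovered to within a few
percent at realistic instrument noise.

```r
s <- simulate_light_curve(0.06, 25, 0.7, 1.5, "assimilation",
                          noise_sd = 0.5, seed = 1)
fit_nonrectangular_hyperbola(s)
#> Nonrectangular hyperbola fit (assimilation):
#>   phi = 0.05941  A_sat = 24.1218  theta = 0.8314  R_d = 1.8974
#>   rmse = 0.259  converged = TRUE

compute_kleaf(2.0, -0.3, -0.8)   # E / (psi_stem - psi_leaf)
#> [1] 4
```

A full synthetic study (13 populations in five photosynthetic-type ×
ploidy groups, 3 leaves each, on a pure-birth phylogeny) runs end to end:

```r
res <- run_pipeline(pipeline_config(seed = 1, out_dir = "results/run1"))
res$pgls[1:3, c("model", "lambda", "slope_p", "adj_r2")]
#>             model    lambda      slope_p    adj_r2
#> 1   K_leaf ~ VLA2 1.0000000 5.474745e-10 0.9706749
#> 2 Psi_leaf ~ VLA2 1.0000000 1.200564e-06 0.8820195
#> 3    g_sat ~ VLA2 0.9667435 2.642580e-08 0.9407878
```

The generator plants higher minor vein density and hydraulic conductance
in C4 populations, and the PGLS layer recovers those associations
(positive K_leaf ~ VLA2 slope, strong phylogenetic signal). Every
intermediate (per-leaf PV parameters, light fits, K_leaf, anatomy,
population trait table, letter displays, PCA, PGLS and ancestral-state
tables) is written as tidy CSV with a JSON metadata sidecar, and the run
is byte-identical when repeated with the same seed.

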