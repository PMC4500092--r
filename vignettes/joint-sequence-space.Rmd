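---
title: "Dissecting a joint protein-DNA binding-energy landscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting a joint protein-DNA binding-energy landscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jointscape)
```

## The system and its sequence space

`jointscape` analyzes the joint sequence space defined by an ancient
transition in steroid-receptor DNA specificity: three recognition-helix
sites of the DNA-binding domain that toggle between ancestral and derived
residues (glu/GLY at 25, gly/SER at 26, ala/VAL at 29) crossed with the two
variable nucleotide positions (3 and 4) of the six-base RE half-site. The
space holds 8 proteins x 16 REs = 128 complexes; each genotype's phenotype
is its free energy of dissociation, dG = -RT ln K_d in kcal/mol, so larger
values mean tighter binding and effects of independent factors add.
Additivity of free energies is the reason a *linear* model is the right
decomposition here, and deviations from additivity are, by definition,
epistasis.

```{r space}
enumerate_protein_genotypes()$label
head(enumerate_re_genotypes(), 4)
```

## The regression model

Protein sites are encoded as single +/-1 coordinates (ancestral -1, derived
+1; coefficients a, b, c), nucleotides by the tetrahedral WYK embedding
(A = (1,-1,-1), C = (-1,1,-1), G = (-1,-1,1), T = (1,1,1)). Because the
four WYK vectors sum to zero and the +/-1 protein codes are balanced, the
intercept of every model equals the grand-mean dG and all other
coefficients are mean-centered contrasts. Term groups nest in a fixed
order -- INTERCEPT, P1, P2, R1_3, R1_4, R2, X2, X3 (and an optional P3,
off by default because the third-order structure of interest crosses the
molecular interface) -- and on the complete balanced factorial all design
columns are mutually orthogonal:

```{r ortho}
X <- build_design_matrix(enumerate_joint_genotypes(),
                         model_spec(c("P1", "P2", "R1_3", "R1_4", "R2",
                                      "X2", "X3")))
ncol(X)                                 # 85 columns through third order
max(abs(crossprod(X)[upper.tri(crossprod(X))]))
```

Orthogonality is what makes the decomposition clean: each group's
coefficients are the same whether or not other groups are present, and raw
R-squared increments in `variance_partition()` are order-invariant.

State-level quantities are linear contrasts of the coefficients:

* effect of nucleotide n at a site = (w, y, k) . WYK(n); e.g. C3 is
  -w3 + y3 - k3;
* pairwise RE epistasis of (n3, n4) = the nine R2 coefficients dotted with
  WYK(n3) x WYK(n4);
* effect of a substitution = 2a (the derived-minus-ancestral background
  difference on a balanced factorial);
* marginal protein-pair interaction = 2ab; the double-mutant-cycle
  alternative (4ab) is available via `convention = "cycle"`;
* cross-interface shift = 2 (a . w3, ...) . WYK(n): how a replacement
  changes a nucleotide state's effect, with third-order analogues for RE
  pair contrasts and protein pairs.

A one-hot 0/1 ("binary") encoding of the same groups is provided as a
cross-check. It is rank-deficient by construction (the four indicators of
a site sum to the intercept), so those fits use the minimum-norm
least-squares solution and effects are extracted as mean-relative
contrasts of the fitted cell values, which are unique projections. On any
complete landscape the two encodings agree to numerical precision; the
test suite asserts this over 100 random landscapes.

## Inference: likelihood ratios and variance shares

Model fits are replicate-level, not cell-mean-level: the per-protein RE
model {INTERCEPT, R1_3, R1_4, R2} has 16 parameters for 16 cells and is
saturated at the mean level, so significance only makes sense with
replicates (the generator defaults to triplicates, matching practice for
anisotropy assays). Nested models are compared with the Gaussian
likelihood-ratio statistic, variance profiled at its MLE, referred to a
chi-squared distribution with df equal to the number of added columns;
p-values are Bonferroni-multiplied by the family size (by default the
number of comparisons made in the current analysis, recorded in the
output). The chi-squared reference is asymptotic: with 384 replicate
observations it is accurate (the acceptance suite verifies a type-I error
inside [0.03, 0.08] at alpha = 0.05 over 1000 null simulations), while at
48 observations per protein it is mildly anticonservative -- stars on
per-protein logos should be read accordingly. One subtlety the null
simulation respects: the chi-squared reference assumes the simple model is
true, so the null landscape must contain no structure unmodeled by *both*
fits; fixed structure orthogonal to both models inflates both residual sums
of squares and makes the profiled-variance LRT conservative.

Adjusted-R-squared increments may be legitimately negative (a useless group
costs degrees of freedom); numeric tables keep the signed value and energy
logos floor the displayed width at zero, which is purely display semantics.
For a saturated fit (n == rank) the adjusted R-squared is reported equal to
the raw R-squared and the profiled log-likelihood degenerates to +Inf; logo
construction detects this and omits stars with a warning rather than
manufacturing significance.

```{r logo}
sim <- generate_landscape(preset_ancsr1(noise_sd = 0.15, replicates = 3),
                          seed = 42)
logo <- build_energy_logo(sim$measurements, protein = "glu-gly-ala")
head(as.data.frame(logo), 6)
```

## Binding curves

`fit_single_site()` fits A([P]) = A_free + (A_bound - A_free) [P] / (K_d +
[P]) by Levenberg-Marquardt. Defaults: baseline = minimum anisotropy,
plateau = maximum, K_d initialized at the concentration nearest half-max,
with up to five log-spaced restarts; temperature 298.15 K and R =
1.9872e-3 kcal/(mol K) are configurable and recorded in the estimate. The
hyperbolic (no-depletion) model is the default because the labeled probe
is at 5 nM, far below most K_d values in this system; a quadratic
depletion-corrected variant sits behind `depletion = TRUE` for tight
binders. A fitted K_d outside the titrated concentration range sets
`in_range = FALSE` rather than failing: such estimates are extrapolations
and should be treated as bounds.

## Functional criteria and pathway analysis

The map from biochemistry to function is a deliberate, simple
nonlinearity: a complex is functional iff (1) its mean dG is strictly
greater than the grand mean over all 128 complexes and (2) it is within a
tenfold affinity factor of its protein's best target, implemented in energy
space as dG >= best - RT ln(fold) (1.364 kcal/mol at the defaults). Ties
for best target are all retained; the grand mean is taken over the full
8 x 16 landscape. Both choices are configurable because the thresholding
set and tie handling admit alternatives; thresholds are always recomputed
from the supplied landscape, never cached.

Two scenarios are analyzed on the resulting neutral network (functional
complexes joined by single-molecule moves): the accessibility of the six
protein-replacement orderings under purifying selection (every intermediate
protein must retain at least one functional RE, endpoints included), and
joint TF-RE drift paths by breadth-first search (connectivity is always
exact; shortest-path enumeration is capped, default 10,000, only to bound
output size on permissive landscapes). `gating_analysis()` classifies, for
each functional complex, which admissible moves make a previously
inadmissible move in the partner (or the same) molecule admissible
(permissive) or the converse (restrictive), and every reported event can be
re-verified directly from the two admissibility conditions -- the test
suite does exactly that, and also checks all path outputs against a naive
breadth-first-search oracle on 100 random landscapes.

One consequence of the strict grand-mean criterion worth knowing: no
classified landscape can have all 128 complexes functional (values above
their own mean everywhere is impossible), so the all-functional graph
invariant (576 edges = 128 x 9 / 2) is exercised with directly constructed
calls, and full trajectory accessibility with a landscape in which every
protein has one boosted RE.

## The synthetic generator

`landscape_params()` specifies a landscape in state-effect space -- the
same mean-relative, zero-sum-constrained quantities the fits recover --
and converts internally to coefficient space (an effect of size e
contributes e/2 times the +/-1 coordinate). This resolves the inherent
ambiguity in parameterizing a landscape from logo-style published values:
a noiseless generate-then-fit round trip returns exactly the configured
numbers (asserted to 1e-9 over 500 random parameter sets).

`preset_ancsr1()` encodes the ancestral protein's reported determinants:
G3 = 1.0 and T4 = 0.5 kcal/mol main effects, +0.8 kcal/mol G3xT4
epistasis, a negative G3xA4 contrast, and the 1.3 kcal/mol average-affinity
gain of the site-25 replacement. Magnitudes not printed in the source
study's text are explicit placeholders -- the G3xA4 magnitude (-0.5), the
equal split of each site's complement across non-preferred states, the
grand mean (10 kcal/mol, in the range of measured half-site energies), and
the two affinity-reducing substitution effects (-0.5, -0.4) -- and the
`provenance` field tags every parameter as `"paper"` or `"placeholder"` so
no invented number can masquerade as a measured one. Replicate noise is
Gaussian and homoscedastic with default sd 0.2 kcal/mol at 3 replicates
per cell, a realistic precision for anisotropy-derived energies.

What the generator deliberately does not emulate: heteroscedastic noise
(weak binders are harder to measure), censoring at the titration range,
correlated replicate errors, and the actual supplementary measurement
values of the source study, which are not printed in its text. Passing
recovery tests therefore demonstrates the correctness of the estimators
under the stated error model, not robustness to real-data pathologies.

## Numerical choices and problem sizes

* OLS via QR; abc/WYK designs must be full column rank, and rank
  deficiency names the collinear terms instead of silently dropping them.
* Binary-encoding fits use the SVD pseudoinverse (tolerance
  `max(dim) * eps * d1`).
* Zero-sum parameter constraints are validated at construction to 1e-8.
* Residual sds below ~1e-12 kcal/mol are treated as exact fits when
  deciding whether likelihood statistics are meaningful.
* All randomness flows through explicit seeds; fits are deterministic
  given input bytes, and byte-identical inputs give byte-identical
  reports.
* Test-suite problem sizes (chosen to exercise the asymptotics cleanly):
  1000 null simulations for LRT calibration at n = 384; 500 noiseless
  parameter-recovery seeds; 100 landscapes each for encoding equivalence
  and pathway-oracle equivalence; 500 simulations for CI coverage at the
  per-protein scale (n = 48).

## Limitations

Only this 2^3 x 4^2 space is supported; the machinery would generalize but
is neither exposed nor tested beyond it. No cooperativity or dimeric
binding (the underlying assay isolates half-sites and the replacements do
not affect cooperativity); no population-genetic weighting of paths
(fixation probabilities, mutation biases) -- accessibility here is purely
the topology of the thresholded network; and the biophysical-correlates
module consumes precomputed structural summaries (hydrogen-bond and
contact-pair counts), it does not run or parse simulations.
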