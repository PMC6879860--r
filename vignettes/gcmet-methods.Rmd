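---
title: "gcmet: models, estimators, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{gcmet: models, estimators, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Scope

`gcmet` couples two inferential routes to one question: can a single
regulatory defect — heightened glucocorticoid receptor (GR)
sensitivity — generate the pattern of metabolic dysfunction seen in
stress-related disease? The model route builds an integrated
HPA–inflammation–signaling–metabolism ODE system and asks, via
metabolic control analysis (MCA), which rate and interaction
parameters reproduce the direction-of-change signature of the
dysfunctional state. The data route takes a cohort feature table and
asks, via covariate-balanced causal estimation and natural-effects
mediation, whether a continuous GR-sensitivity proxy (cortisol
suppression after dexamethasone) plausibly acts on metabolites through
an inflammation / insulin-resistance / oxidative-stress / energy-deficit
mediator complex. Everything is exercised end-to-end on synthetic
cohorts with closed-form ground truth.

# The rate-law grammar

Species concentrations obey `dM_i/dt · V = Σ RP_j − Σ RC_k ± T_t`. A
reaction rate is a product of optional blocks:

* substrate saturation `M/(M + Km)` per substrate (or elementary mass
  action, `law = "mass_action"`, which exists so that linear systems
  with exact closed forms can be expressed for oracle testing);
* allosteric factors: activation `A/(A + K_j)`, deactivation
  `K_i/(I + K_i)`, and product inhibition. The printed form of the
  product-inhibition factor in the source material is typographically
  collapsed; it is read here as `A/(A + K_i) · 1/(1 + I/K_p)` because a
  product-inhibition factor must decrease in the inhibiting product and
  this is the minimal hyperbolic form that does so. The reading is
  isolated behind `allosteric_factors()` so an alternate algebra can be
  swapped without touching callers.
* a signaling/transcription multiplier
  `Wf · (1 + Σ_a w_a S^na/(S^na + K^na)) · Π_d K^nd/(I^nd + K^nd)`.
  The grouping — activators additive, deactivators multiplicative — is
  chosen so the factor reduces exactly to `Wf` with no regulation,
  which is what makes basal calibration meaningful. Cooperativity
  exponents are real-valued (GR sensitivity is tuned continuously).

Transport is passive (`ε (C_b − C_cyt)`) or facilitated (difference of
saturation terms). Concentrations are clipped at zero before factor
evaluation: the rate laws are undefined for negative state, and
adaptive integrators can undershoot.

# The reduced reference instance

The shipped model (`reference_model()`, also as JSON under
`inst/extdata/`) has 31 species in two nominal compartments (plasma,
tissue; both unit volume under the homogeneous-plasma assumption — one
well-mixed value per plasma feature shared across modules). It
instantiates the four coupled modules of the full-scale integrated
model at reduced size: the HPA cascade CRH → ACTH → cortisol with GR
central negative feedback; IL-6/TNF production under the GR
anti-inflammatory arm; insulin, cAMP/PKA and HIF1α signaling nodes;
and a metabolic core (glycogenolysis and gluconeogenesis,
insulin-dependent glucose uptake, glycolysis, lactate overflow, TCA
entry via citrate, glutaminolysis, β-oxidation through a carnitine
pool, triglyceride synthesis, proteolysis to alanine/glutamine, a
urea-cycle arm, and conserved ATP/ADP and NADH/NAD pairs). Glycogen
and the two exogenous inputs (stress drive, epinephrine) are clamped;
the glycogen clamp mimics steady substrate supply during MCA. Only
glycogen is clamped among metabolites because that is the only stated
clamp; the inputs are clamped because they are boundary conditions.

The two headline parameters are Hill exponents of GR action:

* `n` — cooperativity of the central negative feedback (and of GR
  nuclear translocation). The cortisol operating point sits slightly
  **above** the central half-effect constants, so raising `n` sharpens
  feedback.
* `nx` — cooperativity of the anti-inflammatory inhibition of
  IL-6/TNF. The operating point sits **below** the immune half-effect
  constant (`K_cx = 1.4` vs cortisol ≈ 1.2), so raising `nx` *weakens*
  cytokine suppression at ambient cortisol: the relative difference in
  GR inhibitory thresholds between the central and immune arms is what
  turns "more sensitive GR" into "more inflammation".

Jointly raising `n` and `nx` 1.5-fold then produces, at the new steady
state: IL-6/TNF up → TNF-mediated insulin resistance (glucose uptake
and pyruvate oxidation inhibited) → plasma glucose and insulin up,
citrate down; cytokine- and lactate-stabilized HIF1α up → lactate up,
β-oxidation down → carnitines up, ATP production down; GR-driven
gluconeogenesis, proteolysis and triglyceride synthesis up → alanine,
glutamine, triglycerides up, fatty acids down; ATP-limited urea-cycle
flux and IL-6-driven arginase → ornithine up, arginine down; ATP/ADP
down. This reproduces the full 12-feature metabolic-dysfunction
signature plus the cytokine directions and the energy-charge drop.

**Known limitation.** In the reduced instance ACTH and cortisol
themselves move slightly *down* (≈ −3%) under joint sensitization: at
this network size the sharpened central feedback outweighs the
cytokine drive on the HPA axis, whereas the full-scale model (whose
parameterization is out of scope here) exhibits the positive
cytokine-driven HPA response. The 16-feature extended signature is
therefore not asserted against the reduced instance; the 12-feature
core plus IL-6/TNF/ATP-to-ADP is.

Calibration was directional, not quantitative: parameters were chosen
so that baseline concentrations are O(1), pools are bounded (every
pool has a saturating or first-order drain that can absorb its maximal
inflow), and the stated qualitative responses hold (stress step →
cortisol rise; glucose load → insulin rise; cytokine challenge →
cortisol rise; GR sensitization → the signature). No quantitative
trajectory claims are made or tested.

# Numerics

Integration is adaptive Cash–Karp RK45 (relative tolerance 1e-8,
absolute 1e-10) with non-negativity clipping after accepted steps.
Steady states are found by integrating in expanding chunks with a
damped-Newton polish (numerical Jacobian on the unclamped coordinates,
step halving, zero clipping) and are accepted only when
`max |dM/dt| < 1e-6`; non-convergence is flagged, never silently
returned, and MCA entries from non-convergent perturbations surface as
`NA` with a report, never as zeros. The residual contract is
re-checkable by evaluating the assembled RHS at the returned state.

MCA uses the finite-perturbation form with the baseline steady state
as the base point and normalizes by the nominal parameter and baseline
concentration, so `MCRC = (C_f/C_0 − 1)/(f − 1)`. The "mean
cumulative" screen is the sum over signature features of the absolute
mean-over-folds coefficient: absolute values per feature, because the
magnitude screen and the direction match are separate stages (the
per-feature threshold 0.001 and cumulative threshold 0.1 are only
mutually consistent under this reading — a signed sum could cancel
below 0.1 while every feature passes 0.001 in magnitude). The
direction trichotomy and the no-change tolerance of
`match_signature()` both default to 1% relative change.

# Cohort statistics

"Median-normalized" is implemented as per-sample centering of
log-scale values by that sample's median over the metabolite panel
(the common metabolomics batch practice); per-feature centering is
available via `method = "per_feature"` since the phrase is ambiguous.
Natural log is used; base changes only rescale. The Mann–Whitney test
uses exact permutation enumeration up to combined n = 20 (valid under
ties, since the permutation distribution conditions on the observed
values) and a tie-corrected normal approximation with continuity
correction beyond. Cohen's d uses the pooled SD. Storey q-values use
the smoother π₀ estimate and fall back to π₀ = 1 — exactly
Benjamini–Hochberg — when the estimate is degenerate or the panel is
small (< 20 p-values). Correlation maps are Spearman with average
ranks, pairwise-complete observations, a minimum of 4 complete pairs,
and a t-approximation p-value; between-group fold changes are capped
at 4 in magnitude, sign-flipped pairs are flagged rather than ratioed,
and near-zero control correlations are reported as capped and flagged.

# Causal pipeline

**Balancing.** Continuous-exposure covariate balance is implemented as
entropy balancing: minimum-KL weights subject to zero weighted means
of the standardized covariates and exposure, and zero weighted
cross-moments between each covariate and the exposure (and its square,
`moments = c(1, 2)`). The dual is a smooth convex log-partition
function solved by damped Newton to machine precision; infeasible
constraint sets (e.g. a covariate collinear with the exposure) are
rejected with a residual report. This reproduces the balancing
*contract* of covariate-balancing generalized propensity scores with a
convex, dependency-light formulation. The balance report is
recomputable from the returned weights.

**ACE.** γ is the weighted least-squares slope of log-outcome on
log-exposure (an elasticity). The sandwich variance includes the
balanced covariates in the regression: because the weights make the
covariates orthogonal to the exposure, the point estimate is
unchanged, but the residuals then exclude covariate-explained
variance, giving a correctly sized rather than conservative error
(verified by simulation: coverage ≈ 94%, type-I ≈ 5–6% at n = 1000).

**Sensitivity.** For each lattice point (ζ_t, ζ_y) a latent
standard-normal confounder is drawn with those marginal correlations
to the standardized exposure and outcome (the joint-normal conditional
construction; 20 draws averaged, noise share floored so the confounder
never exactly duplicates a regressor), and the covariate-adjusted
estimate is re-fit with the confounder added. The confounder's outcome
association is signed with the baseline estimate so confounding
attenuates the effect toward zero. τ₁ is the x = y diagonal crossing
of the estimate through zero (linear interpolation); τ₂ — reported
only when the unperturbed estimate is significant — is where the
*original-sign* effect stops being significant, read from the signed z
statistic falling through the two-sided critical value (the two-sided
p-value dips above α only in a narrow window around the zero crossing,
which a lattice can straddle; the signed-z reading makes τ₂ ≤ τ₁ hold
structurally). Under a null effect τ₁ scales as the square root of the
empirical partial correlation, so null-design checks use large n.

**Mediation.** Natural effect models are fit on an expanded data set:
each sample is replicated over hypothetical exposure levels (default:
the observed level and a +1% log-scale shift, giving 2n rows). Row
weights are the product of (i) a mediator density ratio
`f(M | hypothetical, X)/f(M | actual, X)` from Gaussian linear working
models with working independence across the joint mediator complex,
and (ii) a stabilized inverse-probability factor
`f(T)/f(T | X)` from a Gaussian linear conditional exposure-density
model (population-level estimates, controlling for group). Weights are
truncated at the 1st/99th percentiles and the truncation logged. In
the weighted regression of the outcome on both exposure copies plus
covariates, the coefficient on the **actual** exposure is the natural
direct effect ψ_d (the outcome was observed under it) and the
coefficient on the **hypothetical** exposure is the natural indirect
effect ψ_i (it indexes the mediator distribution through the weights);
ψ_t = ψ_d + ψ_i by construction. This labeling is the mathematically
forced one for the expanded-data weighting estimator — on the linear
SEM (a = 0.5, b = 0.8, c′ = 0.3) the actual-exposure coefficient
recovers c′ and the hypothetical-exposure coefficient recovers a·b —
and is the opposite of a naive reading in which the hypothetical copy
carries the direct path. Confidence intervals are nonparametric
bootstrap over samples (cluster bootstrap on the expansion), default
1000 resamples. Only the joint mediator bundle is supported, because
bidirectional effects among the mediators preclude per-mediator path
decomposition under ignorability.

# The synthetic world

`generate_cohort()` draws a linear-Gaussian system on the log scale:
8 covariates (age, BMI, education, race, ethnicity, a 10-indicator
medication block, smoking, alcohol) → exposure (cortisol suppression,
with a +0.3 log-scale group shift) → 4 mediators (exposure loadings
0.4, 1.4, 0.32, 0.3, echoing the magnitudes of reported
exposure–mediator elasticities) → 35 log-normal metabolites with
direct loadings ±0.15 and mediator loadings ±0.12, signed by the
signature direction so the exposure effect is not common-mode across
the panel (a common-mode effect would be removed by median
normalization — real metabolomics signal is not common-mode, and
neither is this). Group shifts on outcomes default to d = 0.5 on the
log scale (the small-to-moderate range 0.3–0.7 is configurable),
mirroring a mixed significant/trend panel at n = 165. Noise SDs
default to 0.5. Every causal estimand has a closed form (path
products), recorded in the truth report with ψ_t = ψ_d + ψ_i exact.
What the generator does *not* emulate: assay artifacts (batch effects,
limits of detection, drift), heavy-tailed or skewed noise beyond
log-normality, and mediator–mediator feedback — so a green test
establishes estimator correctness under the linear-Gaussian DGP, not
robustness to those features.

# Degenerate inputs and tie-breaks

Constant features flag Cohen's d as undefined rather than dividing by
zero; identical groups give p = 1. Signature matching treats
sub-tolerance changes as "no change", which mismatches any ±
expectation (the conservative reading of a directional claim).
Correlation entries with fewer than 4 complete pairs are missing, not
zero. Clamped species are bit-identical across a trajectory. The
Mann–Whitney exact path breaks ties by average ranks inside the
permutation distribution, so tied data need no special casing.

# Known limitations

* The reference instance is directional; no quantitative trajectory of
  the full-scale system is reproduced, and its ACTH/cortisol response
  to joint GR sensitization is flat-to-negative (see above).
* The ACE sandwich treats the balancing weights as fixed; simulation
  shows mild residual anticonservatism (type-I ≈ 6% at n = 1000).
* Mediator working models are linear with working independence; the
  natural-effects outcome model is linear main-effects (interactions
  are a config-level extension, not implemented).
* Thermodynamic (Haldane) consistency of rate laws, SBML import, and
  parameter fitting are out of scope by design.
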