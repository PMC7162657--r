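---
title: "Control energy of brain state transitions: models, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Control energy of brain state transitions: models, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements: the
dynamical model and its assumptions, the estimation machinery, the tunable
parameters, what the synthetic cohorts do and do not emulate, and the design
decisions taken where the methodology was genuinely open.

## The dynamical model

The brain's regional activity vector `x(t)` (length N, one entry per
parcellated region) is assumed to evolve under noise-free linear
time-invariant dynamics on the structural connectome,
`dx/dt = A x + B u`, where `A` is the subject's symmetric, nonnegative,
zero-diagonal connectivity matrix after stability normalization, `B` is a
0–1 diagonal input matrix naming the control regions (default: all of them),
and `u(t)` is exogenous control input. Linearization is a strong assumption —
real neural dynamics are nonlinear — but it is the standard operating regime
for connectome control analyses: it is informative near an operating point,
local controllability of the linearization implies local controllability of
the nonlinear system, and it admits closed-form optimal control.

The quantity of interest is the cost of a *specific* transition: from a
baseline state (all zeros, the task-versus-rest contrast origin) to a target
state with activity 1 on the fronto-parietal system and 0 elsewhere (or any
user-supplied continuous activation map). The optimal input minimizes the
weighted sum of integrated squared distance from the target (restricted by a
0–1 diagonal matrix `S` to the constrained set, default the fronto-parietal
nodes) and integrated input power weighted by `ρ`, subject to the hard
terminal equality `x(T) = x_T`. Applying the Pontryagin minimum principle
yields `u* = -(1/2ρ) B' p*` and an affine linear system in the stacked state
and costate,

```
d/dt [x; p] = [[A, -BB'/(2ρ)], [-2S, -A']] [x; p] + [0; 2 S x_T]
```

The per-region energy is `E_i = ∫₀ᵀ u_i*(t)² dt` (no `ρ` factor — `ρ` shapes
the optimization, not the reported energy), the system-level energy is the
mean over a system's regions, and the trajectory distance at a time point is
the Euclidean distance to the target over the constrained set.

### Terminal condition

The running state cost is restricted to the constrained set, but the terminal
equality is imposed on the **full** state vector, exactly as the boundary
condition of the two-point boundary value problem is formulated. One could
imagine a variant that pins only the constrained nodes at `T`; the derivation
implemented here does not admit it without changing the shooting structure,
so no partial-terminal option is exposed. In practice the off-target terminal
values are near zero anyway because the baseline is zero and the dynamics are
stable. Similarly, the distance series is computed over the constrained set
by default (configurable to all nodes); whole-brain energies computed with
`S` = fronto-parietal versus `S` = all nodes correlate above 0.8 across
synthetic subjects, so conclusions do not hinge on this choice.

## Numerics

**Shooting via the matrix exponential.** `build_augmented_system()` assembles
the 2N×2N matrix above, computes `e^{ÃT}` once (dense Padé via
`Matrix::expm`), and obtains the particular solution
`c = Ã⁻¹(e^{ÃT} - I) b̃` by a linear solve, never an explicit inverse; the
solve residual is checked against `1e-8·‖b̃‖`. The initial costate follows
from the terminal condition as `p(0) = E12⁻¹ (x_T - E11 x0 - c1)`, where
`E12` is the upper-right block of `e^{ÃT}`. Its condition number is estimated
and the solver refuses to proceed past `1e12`, advising a larger `ρ` or a
shorter horizon — the regimes in which the shooting formulation degrades.

**Exact propagation.** The trajectory is advanced by the one-step propagator
`z_{k+1} = e^{Ã·dt} z_k + c_dt`, the exact discretization of the affine
system: one additional matrix exponential at step size `dt`, then
matrix–vector products. This is numerically equivalent to evaluating the
closed-form solution at every grid time but costs one expensive operation
instead of one thousand.

**Quadrature.** Energies integrate `u_i²` by the trapezoid rule on the stored
grid: exact for constant inputs, and with `dt = 0.001` the error for smooth
inputs is far below every tolerance used here (for `u = t` on `[0, 1]` the
error is about `1.7e-7` against the closed-form 1/3).

**Defaults.** `T = 1` and `dt = 0.001` (1,000 steps per trajectory) are the
conventional horizon and resolution for this analysis; `ρ = 1` is the neutral
choice for the energy weight, which no published value constrains — it is
exposed as a parameter and all package properties are quoted at `ρ = 1`.

**Validation.** An independent direct-transcription solver
(`direct_transcription_energy()`) discretizes the control as piecewise
constant, propagates states with the exact interval propagator, and solves
the resulting equality-constrained quadratic program through its KKT system.
It shares no code path with the shooting solver and converges to the
continuous optimum from above; on random stable systems with N ≤ 8 the two
agree to well under 1% in total energy (typically ~1e-6 relative at 250
intervals). Further analytic anchors: zero transitions cost zero energy, and
with `x0 = 0` the energy is exactly quadratic in the target amplitude.

## Adjacency normalization

Three conventions are used at different stages:

* **control**: `A/(1 + ξ0) - I`, all eigenvalues strictly negative.
* **modal**: `A/(1 + ξ0)`, spectral radius below 1, for modal
  controllability.
* **modularity**: `A/ξ0`, nonnegative (subtracting the identity would make
  `Q` uninterpretable), spectral radius 1.

where `ξ0` is the spectral radius of the raw matrix. For the control mode a
**literal** variant `A/ξ0 - I` is available behind
`scaling = "literal"`: dividing by `ξ0` itself leaves a zero eigenvalue
(marginal stability), which conflicts with the stated purpose of the
subtraction, so the `1 + ξ0` denominator is the default. The two variants
differ slightly in their scale behavior: denominators of the form `1 + ξ0`
do not cancel a global rescaling of the raw weights, while `A/ξ0` forms are
exactly scale invariant; the invariance tests assert exactness only where it
holds mathematically. Modularity `Q` itself is scale invariant regardless,
and is computed with the standard Newman weighted formula against the fixed
a-priori partition — no community detection. Participation coefficients use
`P_i = 1 - Σ_s (k_is/k_i)²` with the convention `P_i = 0` for isolated nodes
(the undefined 0/0 case).

## Null networks

The null model preserves each subject's degree sequence exactly and weight
multiset exactly, and the strength sequence approximately. Binary topology is
randomized by Maslov–Sneppen degree-preserving double-edge swaps
(`igraph::rewire`, budget 10 swap attempts per edge, exposed as a flag);
original weights are then re-assigned to the new edges by iterative rank
matching: repeatedly pick a random unassigned edge, rank its residual
strength product among unassigned edges, and give it the like-ranked
remaining weight. A swap-refinement polish then exchanges weights of random
edge pairs whenever the squared strength error drops (up to 20 sweeps). On
random sparse graphs this reproduces node strengths to r > 0.99 per
surrogate. The inner loops are implemented in C++ because they are O(m²) per
surrogate and run thousands of times across an ensemble; they draw from R's
RNG, so surrogates are seed-deterministic.

Dense tractography-style matrices are a special case: a complete graph admits
no degree-preserving swap, so topology is left unchanged and the null
reduces to strength-preserving weight permutation, with a message. This is
still a meaningful null — it destroys the alignment between strong weights
and the modular block structure — and it is the regime the synthetic cohorts
exercise.

Two tests compare real and null networks: a paired t-test of per-subject
mean null energy against real energy (difference reported as null − real),
and a one-tailed permutation p-value for developmental effect sizes,
`p = (k + 1)/(n + 1)` with `k` the number of null effects at least as
negative as the real one — the add-one form keeps p strictly positive.

## Developmental and cognitive statistics

Age models are GAMs, `feature ~ s(age) + sex + handedness + motion + tbv +
network_strength`, with penalized cubic regression splines (`bs = "cr"`,
basis dimension 10) and REML smoothness selection — basis family and
dimension are this package's choices; penalized splines with REML are the
field standard for developmental trajectories. The smooth-term p-value is
unsigned, so it is converted to a signed Z by
`Z = sign(partial r) · Φ⁻¹(1 - p/2)`, the sign coming from the linear partial
correlation of feature and age given the covariates; this reconstruction is
a convention, documented as such. The partial correlation itself is the
Pearson correlation of OLS residuals, with a Fisher-z 95% CI whose effective
sample size is reduced by the number of covariates (the CI method is also a
package choice; nothing in the analysis depends on its exact form).
Executive-function models add the score as a linear term ahead of the age
spline; its partial correlation removes the spline-adjusted age trend from
both sides. Multiple comparisons use Benjamini–Hochberg FDR at q = 0.05.

Mediation residualizes predictor, mediator and outcome on the covariates,
standardizes each to unit variance (one reading of "normalized residuals";
results are invariant to the alternative scalings up to units), estimates
paths by two OLS fits so that `indirect = a·b` and `c = c' + a·b` hold as
identities, and attaches a percentile bootstrap CI over case resampling
(default 10,000 resamples) plus a two-sided sign-proportion p-value
`2·min(Pr(boot ≤ 0), Pr(boot ≥ 0))` — the CI is the primary inference; the
p-value is a convenience and can degenerate to 0 when no resample crosses
zero.

## Brain-maturity prediction

Nested two-fold cross-validation: subjects are sorted by age (stable sort,
ties keep input order) and odd ranks form subset 1 — a split that matches
the age distributions of the halves. Both outer directions are run, so every
subject is predicted exactly once per scheme. Features are min–max scaled
with parameters fit on the training half only (test values may leave
[0, 1]; a feature constant on training scales to 0). Ridge coefficients are
closed-form on the centered scaled design with an unpenalized intercept. The
penalty grid is the 16 consecutive powers of two from 2⁻¹⁰ to 2⁵; the inner
two-fold procedure scores each λ by the sum of the min–max-normalized mean
correlation and normalized mean reciprocal MAE across the grid. Min–max (not
z-score) normalization was chosen for boundedness and predictable tie
behavior; z-scoring is available behind a flag, and ties break toward the
larger λ (stronger regularization, smaller variance). Significance uses
permutation of the feature-to-subject correspondence with the full nested
procedure re-run per permutation (default 1,000, giving a floor of
p ≈ 0.001); random-split mode repeats the whole procedure on random halves
(default 100) and averages. For interpretation, a final model is trained on
all subjects (λ from the inner procedure on the full sample) and its weight
vector is left-multiplied by the feature covariance — the Haufe transform —
turning decoding weights into an activation pattern whose absolute value
ranks regional importance and correctly silences suppressor features.

## The synthetic cohort generator

The generator produces the study conditions the rest of the package assumes,
so that every stage is testable without access-controlled data. Connectomes
are block-modular: 8 systems (default 8 nodes each, N = 64) with lognormal
multiplicative edge noise (σ = 0.5) around a within-system mean (0.15) and a
smaller between-system mean (0.05) — heavy-tailed positive weights mimicking
tractography connection probabilities, which is a modeling choice: the
empirical weight law of real probability matrices is not documented, and
lognormal is the natural minimal heavy-tailed candidate. Three effects are
planted:

* within-fronto-parietal weights scale by `1 + γ·(age - 8)/15` (default
  γ = 0.3), the developmental strengthening of executive connectivity;
* a standardized latent `L = a·z(age) + e` (a = 0.5) scales edges incident
  to two designated cingulate nodes by `1 + c·L` (c = 0.15);
* the executive score is `b·L + f·z(age) + noise` (b = 0.4, f = 0.3),
  so the mediation chain age → cingulate connectivity → executive score runs
  *through the connectomes*: any mediated signal detected downstream had to
  survive the optimal-control computation, not merely a planted energy
  column.

Covariates are realistic in correlation structure only: in-scanner motion
declines with age (r ≈ −0.3, stressing covariate adjustment), total brain
volume depends weakly on sex, handedness is ~88% right. Ages are uniform on
[8, 23]. Default cohort size is 300 subjects at 64 nodes — desk scale;
the full 232-node, ~950-subject configuration is supported but is not the
test default.

What the generator does **not** emulate: spatial embedding and
distance-dependent connectivity, tractography false positives/negatives,
hub/rich-club architecture beyond what block structure induces, non-uniform
age sampling, and measurement noise in the phenotypes. Passing tests
therefore demonstrate that the pipeline recovers effects of the planted kind
at realistic sizes — not that real developing connectomes behave this way.

## Problem sizes and runtime choices

The test suite and the reproduction script (`scripts/acceptance.R`) use
sizes chosen to exercise every claim in minutes on one CPU: 20 random
systems of N ≤ 8 for solver validation (250 transcription intervals), a
100-subject cohort with 20 surrogates per subject for the null comparison,
the 300-subject default cohort for the developmental, prediction
(1,000 permutations) and mediation analyses, 200 replicate features for the
type-I calibration, 50 seeded runs for Haufe-ranking reliability, and
n = 2000 with 10,000 (point estimate) or 1,000 (replicate sweep) bootstrap
resamples for mediation calibration.

## Known limitations

* Linear dynamics; no stochastic input, no feedback (Riccati) control, no
  nonlinear extensions.
* The shooting solver degrades for long horizons or tiny `ρ` (ill-conditioned
  `E12`); it detects this and refuses rather than returning noise.
* GAM smooth p-values are approximate; the type-I calibration holds at the
  default conditions but has not been explored across extreme smoothness
  regimes.
* The strength sequence of null networks is preserved approximately (to
  r > 0.99), not exactly — exact joint degree+strength+multiset preservation
  is not generally possible.
* The mediation model is the single-mediator a/b/c/c′ scheme; no multiple
  mediators, no longitudinal structure.
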