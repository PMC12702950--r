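---
title: "Structured sparse screening of athlete cardiovascular risk: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structured sparse screening of athlete cardiovascular risk: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardiospectra)
```

## The screening problem

Pre-participation cardiovascular screening of athletes must separate two
populations whose measurements overlap: hearts remodeled benignly by
training, and hearts in the early stages of cardiomyopathy or other
conditions that raise the risk of an adverse event under exertion. A
binary classifier applied directly to the measurements tends either to
miss early disease or to exclude healthy athletes; this package instead
reasons through a small set of *latent clinical states* — canonically
`normal`, `remodeling` (physiological adaptation), `borderline`, and
`pathological` — and derives the screening decision from a posterior over
those states.

An athlete is a numeric feature vector $x \in \mathbb{R}^d$ partitioned
into five blocks: hereditary/family history (`h`), physical examination
(`f`), ECG (`e`), echocardiography (`s`) and metadata such as age, sex
and training intensity (`m`). The state space carries two per-state
quantities on $[0,1]$: the event prior $\pi(z)$ — the probability of a
cardiovascular adverse event conditional on the state — and an
exertion-adjusted risk level $\rho(z)$ used by the embedding layer. Both
are inputs: they may come from guidelines, registry estimates, or (in
synthetic workflows) from the per-state event rate.

## Engine 1: structured sparse inference

The first engine scores each state with a bilinear function
$F(x, z_j) = x^\top U V_{j\cdot}$, a rank-$r$ factorization
$\Theta = UV^\top$ of the joint parameter matrix ($r \le \min(d, |Z|)$).
The posterior is the solution of

$$q = \arg\max_{q \in \Delta_s} \; \sum_j q_j F(x, z_j) - \tfrac12\|q\|_2^2,$$

over the simplex restricted to at most $s$ nonzero entries — i.e. the
*sparsemax* projection of the scores, additionally capped. Sparsemax
yields exactly sparse posteriors, so the handful of states that survive
form an explicit, clinically readable set of diagnostic hypotheses. Two
structural constraints modify the projection:

* **Compatibility.** A rule set of threshold predicates (e.g. "the
  pathological state requires `e_12` > 0.2") zeroes the posterior on
  states whose diagnostic criteria the profile fails. States without
  rules are compatible by default; comparators are taken literally, so a
  tie at a strict threshold fails.
* **Support cap.** If the sparsemax support exceeds `s`, the projection
  is re-solved on the `s` largest masked-in scores. This restriction is
  exact: for this objective the capped optimum is always attained on a
  top-score set. Ties break toward the lower state index so results are
  deterministic.

Risk is the posterior-weighted event prior
$\hat r(x) = \sum_z q(z\mid x)\,\pi(z)$, the flag is the strict
threshold $\phi = \mathbb{1}[\hat r > \tau]$, and the *rationalization
set* — states with mass above $\varepsilon_R$ (default 0.05), in
decreasing order — is reported alongside every positive screen.

When every state of an athlete is masked out, `screen_cohort()` either
raises an error or, with `on_incompatible = "refer"`, returns the
athlete flagged with `NA` risk for expert review; a fully incompatible
profile is a finding, not a number.

**Fitting.** The scoring parameters are fit on labeled (or
pseudo-labeled) cohorts by maximizing the mean log softmax probability
of the labeled state with ridge penalty
$\tfrac{\lambda}{2}\|UV^\top\|_F^2$ ($\lambda = 10^{-3}$), by gradient
ascent with backtracking line search from a seeded random start. The
softmax is a smooth surrogate for the piecewise-linear sparsemax used at
inference. Penalizing the *effective* matrix $UV^\top$ (rather than $U$
and $V$ separately) makes the full-rank factorized problem share its
optimum with the dense concave problem, which `rank = NULL` solves
directly; the test suite verifies the two agree to $10^{-6}$ in loss.
Note the scoring function is strictly linear in $x$ (no intercept), so
class structure that is not separable by hyperplanes through the origin
— e.g. states ordered along a single ray — is better handled by the
embedding engine below.

## Engine 2: risk-stratified exertional embedding

The second engine learns a single affine projection
$h = \sigma(Wx + b)$, $W \in \mathbb{R}^{k\times d}$, into a latent
space where each state owns a Gaussian prototype: centroid $\mu_z$ and
shrunk covariance
$\Sigma_z = (1-\gamma)S_z + \gamma\,\bar\sigma^2_z I$ (empirical class
covariance $S_z$, shrinkage $\gamma = 0.1$ toward its mean diagonal,
with a $10^{-8}$ variance floor so degenerate classes remain
invertible). Alignment is the negated squared Mahalanobis distance
$\alpha(z) = -(h-\mu_z)^\top\Sigma_z^{-1}(h-\mu_z)$, and the posterior
is the softmax of the alignments truncated to the `s` best masked-in
states and renormalized. Exertional risk substitutes $\rho$ for $\pi$:
$\hat r = \sum_z q(z\mid h)\,\rho(z)$.

Three further mechanisms:

* **Fidelity.** The benign centroid $\bar h$ is the mean embedding of
  the designated benign state (by default the first label containing
  "remodel"); an embedding whose Euclidean distance to $\bar h$ reaches
  the margin $\delta$ is flagged for expert review (strict inequality to
  pass).
* **Stability.** `stability_check()` perturbs a profile with seeded
  blockwise Gaussian noise, embeds both versions and reports the
  embedding distance against a tolerance — a post-hoc diagnostic of
  representation stability under physiological fluctuation, not a
  training constraint.
* **Screening surface.** For 1- or 2-dimensional embeddings,
  `screening_surface()` evaluates $\hat r$ on a grid and returns the
  near-level-set $\{h : |\hat r(h) - \tau| \le \text{tol}\}$, a
  geometric picture of the decision boundary. Risk evaluation itself
  works in any $k$; only the surface extraction is limited to $k \le 2$.

**Training.** The hybrid loss is
$L = L_{\text{align}} + \lambda_1 L_{\text{fid}} + \lambda_2 L_{\text{orth}}$
with $L_{\text{align}} = -\sum_i \log q(z^*_i \mid x_i)$ under the capped
posterior, $L_{\text{fid}} = \sum_i \max(0, \|h_i - \bar h\| - \delta)^2$,
and $L_{\text{orth}} = \|WW^\top - I\|_F^2$. Optimization alternates: each
epoch refits the prototypes from the current embeddings, then takes one
full-batch gradient step on $(W, b)$ with prototypes and each sample's
posterior support frozen. Labels that fall off the capped support
contribute through a $10^{-12}$ probability floor and are counted in an
`off_support` diagnostic.

Numerical choices that experience forced, all deterministic:

* *Gradient scale.* The data-dependent terms are averaged over the batch
  for the gradient (learning rate independent of $n$); reported losses
  keep the summed form of the formulas. Gradient steps are norm-clipped
  (default 10) because $\Sigma_z^{-1}$, and with it the alignment
  gradient, grows without bound as classes tighten.
* *Initialization.* Rows of $W$ are drawn Gaussian and rescaled so
  initial pre-activations have standard deviation 0.5 over the cohort,
  with $b$ centering them — this keeps a saturating activation in its
  responsive range at the start.
* *Multi-start.* The alternating scheme can hit local optima in which
  two prototypes merge; `n_starts = 3` seeded restarts are run and the
  fit with the lowest final weighted loss kept (the same defense
  `kmeans` uses with `nstart`).
* *Activation default.* The activation is a free design choice; we
  default to `identity`. Under an affine map the Mahalanobis geometry is
  invariant to any invertible linear distortion of the latent space, so
  the alignment layer can undo whatever the projection does — training
  is then robust to feature scale. A bounded activation such as `tanh`
  interacts badly with the orthogonality penalty on raw-scale features:
  orthonormal rows of $W$ saturate the units, several states collapse
  onto a corner of $[-1,1]^k$, and recovery accuracy plateaus well below
  what the data support. `tanh` and `relu` remain available and are
  sensible when features are standardized first.
* *Fidelity weight.* $\lambda_1$ defaults to 0.01. The fidelity margin
  is primarily a flagging criterion; with a large training weight the
  hinge pulls every state into the benign ball and dominates the loss
  value, which both distorts the geometry and misleads the multi-start
  selection toward collapsed solutions.

## Composition of the two engines

The two engines are deliberately exposed side by side:
`screen_cohort(posterior_source = "cardiospectra")` uses the bilinear
scores with the capped sparsemax, `posterior_source = "rsee"` the
Mahalanobis alignments with the capped softmax, and both feed the same
risk/decision/rationalization layer. Each engine produces a posterior
over the same states, and there is no single canonical way to hand one
engine's posterior to the other, so the package treats the choice of
posterior source as configuration rather than resolving it silently.
The binary decision is in every case the threshold on the
posterior-weighted risk computed from the compatibility-masked
posterior.

## The evaluation layer

Cohort-level evaluation uses exact confusion counts, the screening
utility $U(\phi) = \alpha\,\mathrm{TPR} - \beta\,\mathrm{FPR}$
($\alpha, \beta > 0$ weight missed cases against unjust exclusions;
$U \in [-\beta, \alpha]$), and exact threshold tuning: since flags are
step functions of $\tau$, candidate thresholds are the midpoints between
consecutive sorted unique risks plus the endpoints 0 and 1, and the
search is exhaustive. Utility ties resolve toward the smallest
threshold, encoding the stated clinical preference for sensitivity as a
deterministic rule. Temporal risk is the trapezoidal integral of a
sampled hazard trajectory $\lambda(t) \ge 0$ on a strictly increasing
grid — exact for piecewise-linear hazards, with linear interpolation at
off-grid query times; the grid conventionally starts at 0.

## The synthetic cohort generator

`generate_cohort()` draws each athlete's latent state from configured
proportions, features independently per coordinate from
state-conditional Gaussians, and the event label Bernoulli with
$\pi(z)$. The `overlap` control pulls the remodeling and pathological
means toward their midpoint by a fraction of their separation — the
generator's explicit model of the diagnostic grey zone. Three named
scenarios define the package's study conditions:

* `separable` — four states on a mean ladder 3 standard deviations apart
  on every informative coordinate (the ECG and echo blocks; 12 of 20
  features), for parameter-recovery checks;
* `greyzone` — an adjacent ladder with `overlap = 5/6`, leaving the
  remodeling and pathological means 0.5 sd apart while every other pair
  stays at least 3 sd apart;
* `null` — all states identical, the negative control under which any
  trained model must fall back to chance.

Shared conditions across the scenarios: a 20-feature schema
(h = 3, f = 3, e = 8, s = 4, m = 2), state proportions
(0.55, 0.25, 0.12, 0.08) for (normal, remodeling, borderline,
pathological) — a mostly-healthy screening population with a small
pathological tail — event priors $\pi$ = (0.01, 0.02, 0.10, 0.30) and
exertion risks $\rho$ = (0.05, 0.10, 0.40, 0.90), chosen once as
plausible screening-registry magnitudes: benign states nearly
event-free, a pathological state with a 30% conditional event
probability, and $\rho$ steeper than $\pi$ because exertion
concentrates risk in the diseased states. Default cohort size is
n = 2000 with an 80/20 train/held-out split in the recovery analyses;
property-style checks use 1,000–10,000 random draws. These sizes give
binomial standard errors well inside the margins the checks assert
while keeping the default test run fast.

What the generator does *not* emulate is as important for interpreting
green tests: features are conditionally independent given the state
(no within-block correlation unless configured), class-conditional
distributions are exactly Gaussian, there are no missing values, no
label error unless `label_noise` is set, no covariate shift between
cohorts, and "ECG block" means a block of numbers, not waveforms.
Passing recovery tests therefore show that the estimators recover the
structure they assume, at realistic sizes and noise — not that the
model is adequate for any particular clinical data stream. Raw-modality
encoders (imaging, waveforms, wearables, text) are out of scope by
design; features arrive as precomputed numbers.

## Reproducibility and interfaces

Every stochastic operation takes an explicit seed and restores the
caller's RNG state; identical configs and seeds produce byte-identical
cohorts, serialized models and reports. Models serialize to JSON
(row-major arrays, shapes validated on load), cohorts and reports to
comma-delimited text, rules and schemas to YAML. The command-line entry
point (`inst/cli/cardiospectra`, a thin wrapper over `cardio_cli()`)
exposes `simulate`, `fit`, `screen` and `evaluate` subcommands with exit
codes 0 (success), 2 (config error), 3 (data error), 4 (numerical
failure), and logs the package version, config hash and seed to stderr.
Ablation flags mirror the model's component study:
`--no-sparse-posterior` (dense softmax), `--no-compat` (ignore rules),
`--no-latent` (direct logistic regression on features via `stats::glm`,
bypassing the latent layer entirely). A missing seed in a simulation
config is an error, never a silent default.

## Known limitations

* The bilinear scoring function has no intercept; cohorts whose states
  are not separable by central hyperplanes need the embedding engine.
* The capped-softmax training gradient freezes each sample's support
  per step; labels pushed off-support stop receiving gradient and are
  only surfaced through the `off_support` diagnostic.
* Guideline priors and compatibility rules are generic threshold
  conjunctions; no specific published criteria set is encoded, and
  mapping real guideline cutoffs onto feature columns is left to the
  user.
* Missing feature values are a hard error; no imputation is provided.
* $\pi(z)$ and $\rho(z)$ are taken as inputs. An empirical estimator
  (per-state event rate) is natural on labeled synthetic cohorts, but
  no calibration machinery is included.
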