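---
title: "Modelling Alzheimer's disease progression with a linear velocity field"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling Alzheimer's disease progression with a linear velocity field}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adpm)
```

## The model

`adpm` treats Alzheimer's disease progression as the flow of a
five-dimensional latent state
$x(t) = [x_\tau, x_{A\beta}, x_\mathrm{lang}, x_\mathrm{mem},
x_\mathrm{praxis}]$ — CSF total tau, CSF amyloid-beta 1-42, and three
cognitive traits — under an affine linear velocity field

$$\frac{dx}{dt} = v(x, y) = \Big(V + y_\mathrm{age} W_\mathrm{age} +
y_\mathrm{APOE4} W_\mathrm{APOE4}\Big)\, x + v_0 ,$$

where $y$ are the subject's covariates (standardized baseline age and
APOE $\varepsilon4$ carriership).  Each subject contributes a single
subject-level parameter, the initial state $x_0^s$ at their first visit;
the entire trajectory then follows from the shared velocity field.  This
removes the usual disease-staging assumption: any combination of biomarker
levels is an admissible starting point, and the field itself — not a
canonical trajectory — expresses how tau, amyloid and cognition push each
other along.

The velocity matrices are block-sparse: the CSF rows receive no input from
the cognitive columns, encoding the assumption that biomarker kinetics are
not driven by cognitive status while cognition may be driven by both.
`velocity_sparsity_mask()` exposes the forced-zero pattern; it is enforced
at construction, in every MCMC draw, and verified in the tests.

Because the field is affine with time-constant coefficients, trajectories
are exact matrix exponentials of the augmented system
$\exp\!\big(t \left[\begin{smallmatrix} A & b \\ 0 & 0
\end{smallmatrix}\right]\big)$, which avoids inverting $A$ (estimated
matrices may be singular) and propagates backwards in time just as well as
forwards.  `solve_trajectory()` implements this with a fixed-size
Padé scaling-and-squaring exponential; the test-suite checks it against an
adaptive Runge–Kutta integrator (deSolve) to $10^{-6}$ and against scalar
closed forms to $10^{-10}$.

### Conventions

* State ordering is fixed as `tau, abeta, lang, mem, praxis`; the CSF block
  is components 1–2.
* Time is measured in years with $t = 0$ at each subject's first
  observation.
* Higher latent tau and higher cognitive traits mean *worse*; higher latent
  amyloid means *more* CSF amyloid-beta, i.e. healthier (the assay value
  falls as brain amyloid load rises).
* Baseline age is frozen along the trajectory.  Advancing age continuously
  would make the system matrix time-dependent and forfeit the closed-form
  solution; over typical forecast horizons the induced velocity change is
  second order relative to the state dependence.

## Observation layer

Each channel $k$ is linked to its latent component through a sigmoid

$$\mathrm{link}_k(x) = \ell_k + (u_k - \ell_k)\,
\mathrm{logistic}\big(s_k (x - m_k)\big),$$

which produces plateau effects at the observation scale, with additive
Gaussian noise $\sigma_k$ in observation units.  CSF amyloid-beta is
right-censored at the assay ceiling of 1700 pg/mL: censored rows contribute
the Gaussian tail mass $\log P(X > 1700)$ instead of a density.  The
likelihood primitive also handles lower detection limits
(`censored_gaussian_loglik(side = "lower")`); the cohort pipeline applies
only the upper assay limit.

Cognitive items are handled in two stages by default: polytomous item
responses are scored once into three domain traits by a graded-response IRT
model (`score_traits()`, maximum-a-posteriori under a standard-normal
prior with curvature standard errors), and the dynamic model treats the
trait estimates as Gaussian observations.  A fully joint item-level
likelihood would couple the IRT scale to the dynamic scale; the two-stage
route keeps the cognitive scale fixed and is the common practice for
pre-scored test batteries.  Item-to-domain assignment and category counts
are configuration, not assumptions baked into the code.

### Identification of the latent scale

A sigmoid link with free asymptotes, slope, midpoint, *and* a free latent
scale is not identifiable.  The package fixes the asymptotes per channel
from configuration (defaults chosen to bracket the plausible observation
range) and, by default, also fixes slope and midpoint, anchoring the latent
scale exactly; `estimate_links = TRUE` frees slope and midpoint under
anchoring priors (log-normal around 1 for the slope, normal around the
configured midpoint) for analyses where the default anchoring is too rigid.
Fixing the links is the stricter and more reproducible identification and
is what all shipped defaults and experiments use.

## Clinical layer

Diagnosis labels CN $<$ MCI $<$ AD enter through an ordered logit with
linear predictor $\eta = \beta_x \cdot x(t) + \beta_y \cdot y$ evaluated at
the assessment time and cutpoints $c_1 < c_2$:
$P(\mathrm{CN}) = \mathrm{logistic}(c_1 - \eta)$,
$P(\mathrm{CN} \cup \mathrm{MCI}) = \mathrm{logistic}(c_2 - \eta)$.
Label probabilities along a forecast trajectory give prognosis curves, and
the first crossing of $P(\mathrm{AD})$ over 30/50/70% defines predicted
conversion times (`time_to_conversion()`, linear interpolation on the
forecast grid, 10-year horizon with an explicit beyond-horizon flag).
Multi-arm enrollment categories are collapsed by a documented, configurable
map (SMC to CN; EMCI and LMCI to MCI).

## Priors and inference

Hierarchical prior: $x_0^s \sim \mathcal N(\mu_0, \mathrm{diag}\,\tau_0^2)$
with $\mu_0 \sim \mathcal N(0, 5^2)$ and $\tau_0 \sim$ half-Normal(2.5).
Free velocity entries and $v_0$ get $\mathcal N(0, 0.5^2)$ — on the
standardized latent scale this keeps prior-predictive trajectories changing
order-one per decade, matching the slow dynamics of the disease.  Noise
sds get half-Normal priors scaled to an eighth of each channel's
observation range; ordered-logit coefficients $\mathcal N(0, 5^2)$ with an
induced ordered prior on the cutpoints ($c_1$ normal, log-gap normal).
Age is standardized as $(\mathrm{age} - 75)/10$ throughout.

`adpm()` samples the posterior with a blocked scheme written for this
likelihood:

* **Velocity field and all subject initial states** move jointly by
  Hamiltonian Monte Carlo.  The gradient of the trajectory likelihood is
  exact: for a linear functional $g^\top e^{Mt} z$ of the augmented
  exponential, the derivative with respect to $M$ is the Fréchet derivative
  of the exponential in the rank-one direction $g z^\top$, computed by
  paired Padé recurrences at about three times the cost of one
  exponential; the derivative with respect to $x_0^s$ reuses the cached
  state-transition operators.  Step size (dual-averaging style, target
  acceptance 0.70) and a diagonal mass matrix adapt during warmup only.
* **Noise sds, link shapes, ordered-logit block**: covariance-adapted
  Metropolis on unconstrained transforms.
* **$\mu_0$**: conjugate Gibbs; **$\tau_0$**: log-scale random walk.
* An optional per-subject Metropolis refresh of $x_0^s$ (on by default,
  `x0_refresh`) exploits that states are affine in $x_0$ given cached
  operators; with the initial states already inside the HMC trajectory it
  is a robustness aid, and the shipped experiments disable it for speed
  after verifying identical recovery and interval calibration.

The subject states are parameterized directly (centered): each subject's
likelihood dominates its hierarchical prior here, so there is no funnel
geometry to escape, and centering keeps the $\mu_0$ update conjugate.
Convergence is reported per population parameter as split-half
$\widehat R$ and effective sample size; $\widehat R > 1.05$ raises a
warning on the fit object rather than failing silently.

Initialization matters for short chains: subject states start at the
inverse-link of their earliest observations, and the velocity parameters at
a ridge regression of inverse-link finite differences on midpoint states
(possible whenever some visits observe all channels; zero otherwise).

## Forecasting new subjects

Following the validation design, a new subject is forecast from a
conditioning window (default the first two years): for each posterior draw
of the population parameters, the subject's $x_0$ is sampled conditional on
the windowed observations and diagnoses with the population parameters held
fixed — a short warm-started Metropolis chain per draw — and the
trajectory and label probabilities follow per draw.  Reported curves are
draw averages; per-draw crossing times accompany the point prediction
(the 50% crossing of the mean curve) so that the uncertainty is not lost.
Forecast grids are monthly by default and may extend 10 years backwards and
20 forwards; uniform grids use a single exponential per draw plus
recurrence.

## Synthetic cohorts

`simulate_cohort()` forward-simulates the full generative model so that
every other module is testable without access-controlled data.  The
default configuration emulates the structure of a large multi-site AD
study: exponential follow-up durations (cognitive mean ≈ 4 years, maximum
15; CSF mean ≈ 1.5 years, maximum 10), baseline-plus-thinned visit grids
with jitter calibrated so CSF visit counts average ≈ 1.9 per subject and
cognitive visits ≈ 5.6, annual diagnosis assessments (at most one per
year), amyloid censoring at 1700 pg/mL, and multi-site grouping.  The
default "true" parameters are illustrative, not estimates: their signs
express the canonical cascade (high tau accelerates tau and cognitive
decline; low CSF amyloid accelerates both; APOE4 and age load on the
biomarker rows) with magnitudes that traverse the latent range over one to
two decades.  A `regular` schedule (all channels at equispaced visits) is
provided for parameter-recovery experiments.

What the generator deliberately does **not** reproduce: item-level
cognitive responses (traits are emitted directly; item machinery is
exercised separately), covariate-dependent initial-state distributions,
informative missingness or dropout linked to severity, site effects beyond
grouping, diagnosis label stickiness (labels are drawn independently at
each assessment, so occasional reversions occur — as they do in real
data), and measurement batch effects.  Passing recovery tests on these
cohorts therefore demonstrates correctness of the machinery under the
model's own assumptions, not robustness to the misspecifications real
cohorts add.

## Evaluation machinery

`run_loso_experiment()` reproduces the internal–external validation
design: one fold per site, training on the remaining sites, forecasting
each held-out subject from its first two years, and scoring predicted
label probabilities at every later diagnosis assessment.  The report
contains AD-vs-non-AD AUROC (rank statistic with half ties — checked
against exhaustive pair counting), conversion AUROC at fixed horizons,
confidence- and classwise-reliability diagrams with Beta(1,1)-Binomial
95% intervals at 0.2-wide bins (the confidence diagram restricted to
probabilities above 0.4, since 1/3 is the smallest attainable maximum of
three class probabilities), decision curves
$\mathrm{NB}(p) = TP/N - FP/N\,p/(1-p)$ against treat-all and treat-none,
and time-to-conversion errors (converters against first AD diagnosis,
non-converters against maximum follow-up).  Calibration is pooled at the
assessment level; within-subject clustering is noted in the report as an
acknowledged caveat.  One master seed fans out per-fold seeds.

## Numerical choices and problem sizes

* Padé order 6 with scaling-and-squaring threshold 0.25 for all fixed-size
  exponentials; trajectory overflow (unstable systems at extreme times)
  raises an error naming the offending time.
* Cumulative logits are evaluated through `log1p`-based forms; interior
  ordinal probabilities are floored at $10^{-300}$ before logging.
* Censored rows use the exact Gaussian tail, not a density approximation.
* Threshold crossings interpolate linearly between grid points; grid
  refinement changes the 50% crossing by less than one grid step (tested).
* Shipped experiments use cohorts of 150 subjects (recovery, 20
  replicates), 48 subjects across 12 sites (cross-validation), and reduced
  chain lengths (around 100–300 warmup and 100–300 retained draws, one
  chain) — sizes chosen to exercise every code path at useful statistical
  resolution while keeping the whole suite runnable on a laptop; analyses
  of real cohorts should use the package defaults (2 chains, 1000 + 1000)
  or more.

## Limitations

* Linear velocity fields cannot express saturating or non-monotone
  dynamics in the latent space itself; plateaus arise only through the
  observation links.
* Five channels only; adding modalities grows the velocity matrices
  quadratically and would likely need further structural zeros.
* The model is associational.  Forecasts describe natural progression
  under the observed dynamics; simulating interventions (e.g. forcing the
  amyloid component) is not a supported use, because nothing here
  identifies causal effects.
* Two-stage cognition scoring ignores trait-estimation uncertainty beyond
  the reported standard errors.
* The conditional initial-state sampler is a cut-style approximation: the
  new subject's data do not feed back into the population posterior.
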