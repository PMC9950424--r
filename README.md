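# adpm — multidimensional ODE-based modelling of Alzheimer's disease progression

`adpm` is an R package for clinicians and biostatisticians who want to
model the *joint* evolution of Alzheimer's disease biomarkers and
cognition without assuming a canonical ordering of pathological events.
Instead of fitting one reference trajectory that all patients traverse at
different speeds, the package estimates a **velocity field**: the
instantaneous rate of change of a five-dimensional state

x(t) = [ CSF total tau, CSF amyloid-beta 1-42, language, memory, praxis ]

as an affine linear function of the state itself and two covariates,

dx/dt = ( V + age·W_age + APOE4·W_apoe ) x + v0 ,

with the structural constraint that biomarker velocities are unaffected by
cognitive status (a forced-zero block in the matrices).  Each subject
contributes a single parameter, the initial state x0 at first visit;
trajectories are exact matrix exponentials of the augmented system, so
singular velocity matrices and backward propagation are handled without
numerical integration.

On top of the dynamics sit:

* **an observation layer** — sigmoid links with plateau effects, Gaussian
  noise, right-censoring of amyloid at the 1700 pg/mL assay ceiling, and
  graded-response IRT scoring of cognitive items into domain traits;
* **a clinical layer** — an ordered logit mapping the latent state and
  covariates to the probabilities of CN < MCI < AD at any time, which
  turns forecast trajectories into prognosis curves and
  time-to-conversion predictions (first crossing of P(AD) over 30/50/70%);
* **hierarchical Bayesian inference** — a blocked MCMC sampler written for
  this likelihood, whose velocity-field and initial-state updates are
  Hamiltonian Monte Carlo with exact adjoint gradients through the matrix
  exponential;
* **evaluation machinery** — leave-one-site-out cross-validation,
  AUROC, multi-class reliability diagrams with Beta-Binomial intervals,
  decision-curve analysis, and time-to-conversion error analysis;
* **a synthetic cohort generator** that emulates the structure of
  multi-site AD studies (irregular unsynchronised visits, ~1.9 CSF and
  ~5.6 cognitive visits per subject, follow-ups up to 10–15 years,
  censored amyloid), so the whole pipeline is testable without
  access-controlled data.

## A worked example

```r
library(adpm)

# a synthetic 4-site cohort with known ground truth
cohort <- simulate_cohort(generator_config(n_subjects = 60, n_sites = 4,
                                           seed = 42))
summary(cohort)
#> subjects: 60   sites: 4
#> CSF visits/subject: 1.70 (max 6), follow-up 0.94 (max 5.1) y
#> cognitive visits/subject: 5.15 (max 14), follow-up 3.28 (max 15.1) y
#> censored abeta fraction: 0.059
#> diagnosis labels:
#>  CN MCI  AD
#> 154  66  23

fit <- adpm(cohort, adpm_config(), chains = 2, warmup = 400, iter = 400,
            seed = 1)
print(fit)
#> adpm fit: 60 subjects, 800 draws (2 chains), max split-Rhat 1.944
#> velocity matrix V (posterior mean, 1/year):
#>           tau  abeta   lang    mem praxis
#> tau     0.075 -0.240  0.000  0.000  0.000
#> abeta  -0.106 -0.211  0.000  0.000  0.000
#> lang    0.121 -0.016  0.043  0.015 -0.027
#> mem     0.090 -0.220 -0.005  0.039 -0.034
#> praxis  0.078 -0.039  0.017 -0.016  0.043
```

The printed matrix is the posterior-mean velocity field in latent units
per year: the zero upper-right block is the structural assumption, the
positive tau column of the cognitive rows says higher tau speeds cognitive
decline, and the negative amyloid entries say low CSF amyloid does the
same.  (With only 60 sparsely observed subjects the entries are noisy and
the fit warns about split-Rhat on short chains — `summary(fit)` shows the
per-parameter diagnostics; real analyses should use the default
2 × (1000 + 1000) chains.)

Forecasting a held-out-style subject from its first two years, then
reading off threshold crossings of the predicted dementia probability:

```r
fc <- forecast(fit, cohort, "S0040", grid = seq(0, 10, by = 1/12),
               ndraws = 100)
time_to_conversion(fc)
#> time to conversion for S0040 (years): t30 = 0.23, t50 = 2.47, t70 = 4.41
```

This subject's true (noiseless) crossing time in the generator's ground
truth is 2.16 years; the point prediction (the 50% mark) lands at 2.47.
`plot(fc)` draws the three label-probability curves.  The posterior
velocity distribution in a region of biomarker space — for instance,
subjects with elevated tau — comes with 90% highest-density intervals:

```r
velocity_summary(fit, region = list(tau = c(0.5, Inf)), ndraws = 100)
#>   component        mean   hdi_lower hdi_upper   n
#> 1       tau  0.04484143 -0.22904847 0.2903184 905
#> 2     abeta -0.09451876 -0.33736322 0.1334550 905
#> ...
```

The full validation design is one call:

```r
report <- run_loso_experiment(cohort, adpm_config())
write_eval_report(report, "eval/")
```

A thin command-line driver wraps the same functions
(`system.file("cli", "adpm.R", package = "adpm")`) with subcommands
`simulate`, `fit`, `predict` and `evaluate`, a YAML config, and
deterministic seeding.

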