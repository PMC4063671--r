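---
title: "Suboptimal Bayesian observer models for probabilistic target estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Suboptimal Bayesian observer models for probabilistic target estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(priorcue)
```

## The task and its generative model

On every trial of the estimation task an array of 100 dots is displayed on a
horizontal line: a discretized representation of that trial's "prior"
density over target positions, obtained as a regular sample of the inverse
cdf at levels $(i - \tfrac12)/100$. The true target is one of the dots,
chosen uniformly. A cue is shown at a vertical distance from the line that
signals its reliability; its horizontal position is the target plus Gaussian
noise, with a small sd for near ("short") cues and a large sd for far
("long") cues. The subject moves a cursor to the line and scores a success
when the true target falls within the cursor's diameter.

All positions are expressed in *screen units* (window width 1, with 0.01
screen units = 3 mm). Sessions cross eight priors of one class with the two
cue reliabilities (16 conditions, 36–40 repetitions each); a dataset is a
Gaussian *training* session followed by a *test* session whose prior class
defines the group (Gaussian, unimodal or bimodal), about 1200 trials over 32
conditions. Trials whose cue lands outside the dot range are excluded from
analysis but kept during generation, preserving the joint statistics of the
task. The package's `task_gen` functions (`session_priors()`,
`build_session_plan()`, `sample_trial()`, `edge_filter()`) implement exactly
this generative model.

The three prior classes are:

* **Gaussian** — sds evenly spaced 0.04 to 0.18 screen units;
* **unimodal** — fixed total sd, varying skewness and excess kurtosis;
  realized as the two-Gaussian mixture that matches the first four central
  moments while locally maximizing differential entropy (a constrained
  numerical solve with a floor on component sds prevents degenerate
  spikes); one platykurtic member is an 11-component equally-spaced
  mixture, since strongly negative excess kurtosis is not reachable by a
  unimodal two-Gaussian mixture;
* **bimodal** — fixed total sd, two equal-variance components with varying
  separation and relative weight (closed-form construction; zero
  separation collapses to a single Gaussian).

The published per-prior descriptor values (skew/kurtosis pairs, separations
and weights, the common test-session sd, and the true cue sds) are not
machine-readable from the available text, so the package ships an editable
table of synthetic defaults in `priorcue_config()`: cue sds 0.06/0.14,
unimodal and bimodal total sd 0.11 (the midpoint of the Gaussian sd grid,
so that task difficulty is comparable across classes), and descriptor
tables chosen inside the feasible unimodality region in decreasing order of
structure. The construction operations are exact for any feasible
descriptor, so replacing the table reproduces any published set.

Asymmetric priors are mirrored about their mean with probability 1/2, and
the uniform prior location is drawn so the whole dot span stays inside the
screen. All modelling is translation-equivariant, so analyses work in
coordinates relative to the prior mean (mirrored back for flipped trials).

## Observer models

Every observer builds a posterior by Bayes' rule. For a mixture-of-Gaussians
prior $p(x) = \sum_i \pi_i \,\mathcal N(x;\mu_i,\sigma_i^2)$ and a Gaussian
likelihood centred on the cue $x_c$ with *subjective* sd $\tilde\sigma$
(allowed to mismatch the true cue sd), the posterior is again a mixture with
closed-form weights $Z_i \propto \pi_i\,\mathcal N(x_c;\mu_i,
\sigma_i^2+\tilde\sigma^2)$, means $(\mu_i\tilde\sigma^2 + x_c\sigma_i^2) /
(\sigma_i^2+\tilde\sigma^2)$ and variances $\sigma_i^2\tilde\sigma^2 /
(\sigma_i^2+\tilde\sigma^2)$ (`posterior_update()`). For a single-Gaussian
prior the posterior mean is the familiar reliability-weighted combination
with cue weight $w = \sigma_p^2/(\sigma_p^2+\tilde\sigma^2)$.

The model space is factorial:

* **Decision rule.** *BDT* minimizes the expected loss and responds
  deterministically at the optimum. The task's hit-or-miss loss is
  approximated by an inverted Gaussian of scale $\sigma_\ell$, which makes
  the expected loss a (negative) Gaussian mixture in the action; the
  optimum is its global mode, found by a fixed-point (mean-shift)
  iteration started from every component mean with tolerance $10^{-10}$,
  global pick by expected loss, exact ties broken to the smaller
  coordinate (`optimal_target()`). *SPK* (stochastic posterior) draws the
  target from a density proportional to the posterior raised to a power
  $\kappa \ge 1$ — a tractable stand-in for noise in the inference or in
  action selection that interpolates between posterior matching
  ($\kappa = 1$) and MAP ($\kappa \to \infty$). *PPM* fixes $\kappa = 1$.
  *PSA* responds with the mean of $K$ posterior draws, computed exactly
  for integer $K$ through the multinomial expansion of the mixture, by
  linear interpolation of densities for non-integer $K$, and by the
  central-limit Gaussian beyond $K = 8$ (the exact expansion grows
  combinatorially; fitted values of $K$ are small, so the cap is
  inactive in practice).
* **Gaussian approximation.** *MV* replaces the posterior by the
  moment-matched Gaussian; *LA* by the Laplace Gaussian at the global
  mode with variance $-1/\partial_x^2\log p$ (usually narrower, as it sees
  only the main peak).
* **S — cue-estimation noise.** The internal measurement of the cue is
  $x_m \sim \mathcal N(x_c, \sigma_s^2)$; the observer's effective
  likelihood variance becomes $\tilde\sigma^2 + \sigma_s^2$ and the
  response probability marginalizes over $x_m$. The short-cue value is a
  per-session parameter; the long-cue value is tied by the cue-distance
  ratio (measurement error proportional to distance). The observer is not
  modelled as aware of this internal variability; predictions are
  unchanged by that choice up to a redefinition of $\tilde\sigma$.
* **P — noisy estimation of the prior.** Log-normal (Weber-like) noise of
  shape $\eta$ on the task-relevant parameter of the prior: on the width
  for single-peak priors (and on the overall scale of the many-component
  platykurtic prior), and independently on the two weights for
  two-component priors (equivalent to Gaussian noise on the log-odds of
  the weights).
* **L — lapse.** With probability $\lambda$ the target is drawn from the
  (internal) prior instead of the decision rule.

The response adds Gaussian motor noise of sd $\sigma_m$ to the chosen
target. Expected-loss minimization deliberately ignores motor variance; for
this narrow loss the induced shift is negligible and the approximation is
documented rather than corrected. Latent S/P variables are marginalized by
Gauss–Hermite quadrature, order 20 for one latent dimension and a tensor
grid of order 12 (two) or 8 (three) when S and P co-occur — nested latents
only arise for two-component priors with both factors on.

For single-Gaussian trials the response density is an exact Gaussian
(`gaussian_closed_form_response()`): mean $\mu_p + w(x_c-\mu_p)$ and
variance $w^2\sigma_s^2 + \sigma_{\rm post}^2/\kappa + \sigma_m^2$, with
$\kappa = \infty$ for BDT and 1 for PPM. The generic numeric path and the
closed form agree to $10^{-13}$ in the tests, which is the package's main
guard against quadrature errors.

Parameter sharing across the two sessions follows the task's conventions:
$\sigma_m$ shared; three free likelihood sds (short/long training, short
test) with the long test value tied by the training ratio; one parameter
per session for each of $\kappa$ (or $K$), $\sigma_s$, $\eta$, $\lambda$.
This yields 4 free parameters for BDT and PPM and 6 for SPK and PSA, and
the basic factorial set BDT/SPK/PPM × S × P × L has 24 models.

## Loss model

The success window equals the cursor diameter: radius 1.25 cm =
0.041\overline{6} screen units, window $d \approx 0.0833$. The
inverted-Gaussian scale $\sigma_\ell$ is not printed in the available text;
the default is the least-squares best Gaussian approximation to the square
well of the configured window, computed once at configuration time by a
one-dimensional fit (about 0.032 screen units for the default window), and
overridable in the configuration. An extended variant with free loss width
is expressible by fitting with a modified configuration; it is not part of
the factorial comparison.

## Likelihood, fitting and model scores

The dataset log-likelihood sums, over non-edge trials, the log of the
regularized response density $\tilde p = p + \varepsilon$ with
$\varepsilon = \phi(5) \approx 1.4867\times10^{-6}$ (the standard-normal
density five sds out). The floor bounds any single trial's contribution
from below so isolated outliers cannot dominate the fit.

Parameter posteriors use a factorized prior: Uniform(0, 1) on likelihood
sds and lapse rates (screen units), Uniform(0, 4) on $\eta$ to avoid edge
effects, Uniform(0, 1] on $1/\kappa$ — equivalently $p(\kappa) \propto
\kappa^{-2}$ on $\kappa \ge 1$, integrable and mildly favouring small
powers — and informative log-normal priors on $\sigma_m$ and $\sigma_s$.
The published log-normal hyperparameters came from a separate sensorimotor
calibration experiment and are not available; the package defaults (median
0.01 screen units, log-shape 0.5) are stand-ins of the right magnitude and
are configurable.

Sampling is coordinate-wise slice sampling with stepping-out and shrinkage,
three parallel chains from dispersed starts, convergence summarized by the
Gelman–Rubin statistic. Fits are scored by
$\mathrm{DIC} = 2\overline{D} - D(\hat\theta)$ with deviance
$D = -2\log L$ and $\hat\theta$ a per-parameter 10%-trimmed mean (the
published trimming fraction is not printed; 10% per side is the package
default and configurable). A multi-start MAP search (`map_search()`) is
available as an optional check against stuck chains.

Across subjects, models are compared by random-effects Bayesian model
selection on $\log\text{evidence} = -\mathrm{DIC}/2$ (the deviance-scale
version of a log marginal likelihood; the conversion is configurable):
variational updates of Dirichlet counts with symmetric prior
$\alpha_0 = 0.3$ — a weak belief that few models are present — with
exceedance probabilities by Monte-Carlo Dirichlet sampling, and cumulative
(factor-level) evidence by summing member probabilities. A fixed-effects
group-DIC comparison (`gdic()`) is provided alongside, with the
conservative 10-point significance threshold. Results should be read
together with an $\alpha_0$ sweep; in the package's recovery experiments
rankings are stable over $\alpha_0 \in [0.1, 1]$.

## The extended decision comparison and model equivalences

The second factorial space crosses {BDT, SPK, PPM, PSA} ×
{no approximation, MV, LA} × {no lapse, lapse} = 24 combinations, compared
only on trials whose generative posterior is materially non-Gaussian
(KL divergence of the moment-matched Gaussian from the posterior at least
0.02 nats; Gaussian sessions drop out automatically) because the rules
coincide on Gaussian posteriors.

Several combinations define the same family of response distributions, and
`extended_model_set()` derives the equivalences by density comparison on a
battery of non-Gaussian posteriors over a shared grid of decision powers:

* on an MV- or LA-approximated (hence Gaussian) posterior, SPK and PSA
  both generate $\mathcal N(\text{centre}, \text{var}/k)$ with
  $k \in [1,\infty)$ — identical families, so SPK-MV ≡ PSA-MV and
  SPK-LA ≡ PSA-LA;
* a deterministic BDT observer uses only the location of the expected-loss
  minimum. Under the task's hit-window loss idealization (the
  narrow-loss limit of the inverted-Gaussian surrogate) that location is
  the posterior mode, which the Laplace approximation preserves by
  construction, so BDT ≡ BDT-LA. The comparison applies the narrow-loss
  limit to deterministic rules deliberately: the finite-$\sigma_\ell$
  smoothing is a numerical device, and letting it separate two rules that
  prescribe the same action would promote an implementation detail to a
  model distinction.

With their lapse counterparts these six merges reduce 24 combinations to
18 distinct observer models; PPM-MV and PPM-LA stay distinct from the
SPK/PSA families because they carry no free power parameter, and the
comparison verifies every non-merged pair is separated on the battery.

## Synthetic cohorts and what recovery shows

`simulate_subject()` draws the full generative process — session plans,
trial latents, S/P internal measurements, lapses, decision draws, motor
noise — reproducibly from one integer seed; `simulate_group()` scatters
parameters log-normally around population means (synthetic magnitudes, as
the published group means are not machine-readable), truncated to each
parameter's support.

The generator emulates the experiment's probabilistic structure, not its
phenomenology: no reaction times, no cosmetic dot jitter, no practice
block or feedback-driven learning, and stationary parameters within
session. Recovery results therefore certify the inference machinery —
that the package identifies its own generative models and parameters at
realistic trial counts — not that human data satisfy the models'
assumptions.

Recovery experiments in the acceptance tests use the Gaussian group, where
the exact closed-form likelihood keeps full two-session fits fast; the
decision, P and L factors are all identifiable there (the power $\kappa$
scales the posterior-variance share of response variance, $\eta$ produces
prior-width-dependent overdispersion, lapses produce prior-shaped
outliers). Problem sizes are deliberately desk-scale: 3 recovery
replicates with chains of 3 × (60 + 180) sweeps for parameter coverage,
one 8-subject cohort at 3 × (20 + 55) for model recovery, and
reconstruction budgets of 3 × (25 + 75); at these sizes the DIC margin
between the generating stochastic-posterior model and its BDT/PPM
competitors is two orders of magnitude larger than the 10-point
significance threshold.

## Nonparametric reconstruction of priors

`reconstruct_priors()` represents one condition's prior as a mixture of
`M` Gaussians on an equally spaced grid spanning the discretized prior's
range, component sd equal to the spacing, and samples the mixing weights
(flat prior over log weights within a wide box, softmax map to the
simplex, one reference log-weight pinned for identifiability, mirror-tied
weights when symmetry is enforced) under the pooled stochastic-posterior
with-lapse likelihood with each subject's parameters fixed — following
the published choice of reconstructing under that model without
additional prior noise. Test-session trials are used, since group priors
are session-specific. The default `M = 30` resolves the published-scale
reconstruction; the acceptance run uses `M = 11` with symmetry, which is
sufficient for Gaussian-width recovery. Individual log-weights are only
weakly identified (neighbouring components trade off), so convergence is
diagnosed on the functionals of interest — the per-draw prior mean and
variance — rather than on raw weight chains; displayed mean priors may be
smoothed for plotting but stored draws never are.

## Numerical choices and degenerate inputs

Density grids default to step $5\times10^{-4}$ screen units over the
component range ± 6 total sds; quantiles are bisection roots polished by
Newton steps to $|F(x)-q| \le 10^{-12}$; KL integrals use adaptive
quadrature with absolute tolerance $10^{-10}$ and clamp tiny negative
results; the mode finder errors with its best iterate after $10^3$
fixed-point iterations; Laplace approximation rejects non-negative
curvature at the mode; zero-probability trials raise errors rather than
silently flooring. Mixture weights must sum to 1 within $10^{-8}$ and are
renormalized beyond $10^{-12}$.

## Known limitations

The package does not implement repeated-measures ANOVA conveniences (its
tables are meant for external stats tools), discrete-prior or
uniform-lapse observer variants beyond configuration hooks, nonstationary
or trial-dependent observers, or neural noisy-posterior simulations (the
power-function form of SPK is taken as given). The deposited human
datasets ship as a MATLAB container; no MATLAB reader is bundled, so
external data enter through the documented CSV dialect.
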