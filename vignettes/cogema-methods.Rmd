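---
title: "Modelling high-frequency wearable assessments of cognition, mood, and activity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling high-frequency wearable assessments of cognition, mood, and activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cogema)
```

## The measurement setting

`cogema` analyses ecological momentary assessment (EMA) studies in which
participants carry a smartwatch for several weeks and

* complete a 30-second 2-back working-memory test up to three times a day
  (morning, afternoon, evening prompts);
* answer a three-item mood questionnaire once a day (an afternoon prompt,
  with an evening fallback when the afternoon prompt was missed), each item
  on a 1--4 severity scale, summed to a 3--12 total where higher means more
  severe symptoms;
* contribute passively recorded daily step counts and daily mean heart
  rate.

Each n-back session presents 30 symbols; a trial is a *target* when its
symbol matches the one shown two trials earlier, so the first two trials
are never targets. Performance is summarised as d-prime.

## Session scoring

The scorer uses the log-linear extreme-rate correction: with $h$ hits out
of $n_T$ targets and $f$ false alarms out of $n_N$ non-targets,

$$d' = z\!\left(\frac{h + 0.5}{n_T + 1}\right) -
       z\!\left(\frac{f + 0.5}{n_N + 1}\right),$$

clamped to $[-3.33, 3.33]$. For the standard 9-target/21-non-target
session the uncorrected perfect score would be infinite; the correction
plus clamp makes a perfect session score exactly $+3.33$ and an all-wrong
session exactly $-3.33$, reproducing the task's documented score range
for any session geometry. The exact correction used by the original task
software is unpublished; the clamped log-linear rule is this package's
declared convention, verified in the test-suite against an independent
inverse-error-function computation over all 220 possible outcomes.

```{r score}
dprime_from_counts(hits = 7, false_alarms = 2, n_targets = 9,
                   n_nontargets = 21)
```

## Cleaning rules

Three rules run before any modelling, each flagging rather than deleting
records so that counts are conserved and auditable:

* **Onset harmonization.** Study day 1 is the first calendar day with any
  responded assessment (cognitive or mood); earlier passive-only days are
  flagged `pre_onset`.
* **Non-wear days.** Days with fewer than 100 recorded steps *or* no
  heart-rate record are flagged; exactly 100 steps counts as wearing
  (the rule is strictly "fewer than").
* **Sparse hours.** Observations are pooled across participants and days
  into half-open clock-hour bins $[h{:}00, h{+}1{:}00)$, separately for
  d-prime and mood; bins with fewer than 25 pooled assessments are
  excluded. Clock-hour bins (not rolling windows) are assumed.

## Change-over-time models

Every outcome is modelled with a linear mixed model estimated by maximum
likelihood (`nlme::lme`): polynomial fixed effects of time, a
participant-level random intercept and random slope on time (in all
models, including intercept-only fixed structures), and autoregressive
residual correlation --- continuous-time AR(1), $\mathrm{corr}(e_i,e_j) =
\phi^{|t_i - t_j|}$ with $t$ in days, for the irregularly sampled
cognition and mood streams, and daily AR(1), $\phi^{|\mathrm{lag}|}$ on
the day index, for steps and heart rate. Analysis-scale transforms are
identity for d-prime and mood, square root for steps, and natural log for
heart rate (configurable).

Polynomial degrees 0--3 are all fitted; selection walks forward from the
intercept-only model and replaces the current selection whenever the
nested likelihood-ratio test has $p < .05$, the highest such degree
winning. AIC and BIC are reported but never drive the decision. Internally
the polynomial basis is orthogonalised for numerical stability and
coefficients are mapped back to the raw day scale (an exact linear map via
a Vandermonde solve); the reported intercept is the fixed curve's value at
time zero. Time for the cognition and mood models is continuous days
since onset computed from timestamps; the assessment-count axis is
deliberately reserved for the learning-curve stage. Fitting retries
across a grid of random-effect structures (full covariance, diagonal,
intercept-only) and optimizers (BFGS, then `nlminb`); any simplification
is flagged `singular`, and outright failure yields `converged = FALSE`
rather than a silent answer.

## Diurnal and weekday effects

Time of day (continuous clock hours) and weekday (numeric code 1 =
Monday ... 7 = Sunday) enter as linear-plus-quadratic fixed-effect blocks
appended to the selected trend model; a block is retained only when the
likelihood-ratio test against the base model has $p < .05$. For d-prime
and mood the time-of-day block is tested first and weekday on top of the
survivor; daily streams admit weekday only. Although the source analyses
describe the weekday variable as "dummy coded", they report single linear
and quadratic weekday coefficients, so weekday is treated as a numeric
1--7 axis here. Terms are centred before squaring to limit collinearity
and back-transformed to the raw axis scale for reporting.

## Individual learning curves

The practice trajectory of each participant is characterised in four
steps:

1. **Starting point**: the fixed intercept plus the participant's
   predicted random intercept from the selected cognition trend model
   (the conditional value at time zero).
2. **Baseline adjustment**: $Y_k = d'_k - \text{starting point}$ over the
   participant's completed assessments $k = 1, 2, \dots$
3. **Smoothing**: a trailing 3-assessment moving average (the typical
   number of assessments per day) with partial start windows --- trailing
   rather than centred so no future data enter and the assessment axis
   stays aligned.
4. **Inverse-curve fit**: nonlinear least squares for $Y = a - b/X$
   (bounded Levenberg--Marquardt, $b \ge 0$; initial values $a_0$ = mean
   of the last five smoothed points, $b_0 = a_0 -$ first smoothed point).
   The fit is *adequate* when both parameters are significant two-sided
   at $p < .05$ on $n-2$ degrees of freedom; participants with
   nonsignificant slopes show no clear learning effect and are retained
   in all downstream analyses.

The 90% learning rate solves $a - b/X = 0.9a$, giving $X = 10b/a$
assessments; the corresponding study day is the first whose cumulative
completed-assessment count reaches $\lceil 10b/a \rceil$. The stable
maximum is the asymptote plus the starting point.

Two numerical caveats are documented deliberately. First, smoothing a
hyperbolic series steepens its apparent early decay, biasing $\hat b$ (and
hence the rate) upward; the unsmoothed sensitivity fit is therefore also
emitted (`a_unsmoothed`, `b_unsmoothed`). Second, a polynomial trend
model cannot fully separate a participant's pre-practice baseline from
their learned plateau: the extracted starting point is contaminated by a
participant-specific mixture of asymptote and slope. In simulation this
caps the correlation between generating intercepts and extracted starting
points around 0.7--0.8 at realistic parameter spreads, and inflates the
apparent slope-asymptote correlation among fitted curves. Recovery of
asymptotes is therefore assessed against known starting points (isolating
the curve-fitting machinery), while starting-point extraction is reported
as-is with this identifiability limit in mind.

## Residual covariation

Fluctuations are the conditional residuals of each outcome's final model
(trend plus retained periodic terms): deviations of each observation from
the participant's own fitted trajectory. D-prime residuals are averaged
within day to put all outcomes on a common daily time scale; step and
heart-rate residuals stay on their transformed scales. The analysis
sequence is: a concurrent mixed model of daily mood residuals on d-prime,
step, and heart-rate residuals (random intercepts, daily AR(1) errors);
lagged models (previous day and following day, consecutive-day pairs
only) for predictors significant in the concurrent model; a rerun after
excluding each learner's days strictly before their 90% learning day (the
plateau day itself is kept as the first post-learning day; non-learners
keep all data); and, when d-prime remains significant, a sensitivity
rerun restricted to days with the full three-session quota. Lagged models
do not adjust for the concurrent association (they are separate models).
When the response is an exact linear function of the predictors the mixed
likelihood is unbounded; the degenerate case returns the exact
least-squares solution, flagged.

## The synthetic cohort generator

`generate_cohort()` emulates the study conditions: 30 participants, 42
days, up to three sessions and one mood response per day. Latent
cognition at completed assessment $k$ is
$\text{intercept} + a - b/k$ for learners (intercept alone for
non-learners), plus optional polynomial day trends, quadratic
time-of-day structure, and AR(1) noise, clamped to the scoring bounds.
Mood totals add a baseline, a subtle linear day trend, couplings to
same-day and previous-day step fluctuations and same-day cognitive
fluctuations, and AR(1) noise, then clip and round into 3--12 (items are
any three 1--4 values consistent with the total, since only the total is
analysed). Steps and heart rate carry quadratic weekday structure on
their transformed scales. Non-wear days jointly corrupt the observed
activity record (a sub-100 step count, heart rate removed) while the
latent steps still drive mood, so the cleaning rules have real work to
do. Session and mood nonresponse are Bernoulli per prompt, the evening
mood prompt being suppressed after an afternoon response. Enrolment is
staggered across weekdays so weekday effects are not confounded with
study day. Everything is reproducible bit-for-bit from `(config, seed)`.

Default magnitudes are anchored to the published cohort where printed
values exist: stable maxima near 1.94 (intercepts $\mathcal N(1.0,
0.4^2)$, asymptotes $\mathcal N(0.95, 0.35^2)$), slopes giving 90%
learning rates near 22 assessments with a slope-asymptote correlation of
0.70, 10% non-learners, diurnal terms $-0.02/h$ and $+0.001/h^2$,
weekday terms $3.52/-0.64$ (sqrt-steps) and $0.01/-0.002$ (log bpm),
about 2% non-wear days, and a negative d-prime-to-mood coupling of 0.06
score units per d-prime unit. The step-to-mood couplings are anchored to
the within-person coupling *correlation* implied by published test
statistics ($|\rho| \approx 0.15$, i.e. $-10^{-4}$ score units per step
at the generator's step variance) rather than to a printed per-step
coefficient, which is only interpretable relative to an unknown residual
step variance. Step noise is serially uncorrelated by default
(day-to-day step totals show little residual autocorrelation once weekly
structure is removed); cognition, mood, and heart-rate noise use
$\phi = 0.3$.

Trial-level generation places hit and false-alarm probabilities
symmetrically about the criterion midpoint ($z_h = \delta$,
$z_f = -\delta$) and solves for $\delta$ so that the *expected corrected,
clamped* d-prime of a scored session equals the latent value --- an exact
220-term binomial expectation inverted with `uniroot`. At the scoring
bounds the probabilities degenerate (every target answered, no false
alarms), making boundary sessions deterministic.

What the generator does *not* emulate: realistic compliance-by-hour
profiles, device wear-time patterns beyond whole non-wear days,
reaction times, or item-level mood response styles. Passing tests
therefore validate the statistical machinery under the assumed data
model, not robustness to every artefact of real wearable data.

## Simulation study designs and problem sizes

The package's replicated validation studies (in `tests/testthat/`) use
these designs, chosen to exercise each stage at meaningful power on a
single CPU:

* **Recovery** (100 seeds): default 30x42 cohorts; asymptote recovery via
  learning curves given true starting points; starting-point recovery via
  the cubic trend model fitted to daily mean d-prime (the day-scale
  aggregation preserves the participant-level structure the intercepts
  live on).
* **Trend selection** (60 cubic / 100 null replicates): 30x42 cohorts
  with one session per day; the cubic arm plants the least-squares cubic
  projection of the mean practice trajectory as a day trend; the null arm
  has no trend. With three sequential nested tests at $\alpha = .05$ the
  null intercept-only rate is expected near $1 - 3\alpha$. All day-scale
  simulation arms use the daily AR(1) residual form, which coincides
  with the continuous-time structure at one observation per day and fits
  several times faster.
* **Covariation** (200 null / 60 coupled replicates): one session per
  day and no practice or periodic structure, so a first-degree
  residualization model is correctly specified; with one observation per
  day the continuous-time and daily AR(1) structures coincide, and the
  faster daily form residualizes the cognition and mood streams. The
  null arm runs at the full 42-day length: conditional residuals used as
  data lose roughly two within-participant degrees of freedom per stream
  to the residualization, so shorter series understate standard errors
  and push the type-I rate above nominal. The coupled arm (28-day
  cohorts) switches the serial noise off, because lag direction is
  identifiable only when the fluctuation noise is serially unstructured:
  with autocorrelated noise (or strong couplings) a single-lag GLS model
  provably absorbs part of the same-day coupling into the reverse-lag
  coefficient.
* **End-to-end**: the full default cohort through `run_pipeline()`,
  twice, compared for bit-identical reports.

## A worked example

```{r example, eval = FALSE}
cfg <- simulation_config()          # the default 30 x 42 cohort
run <- run_pipeline(cfg)            # simulate + clean + all model stages
print(run)
```

On the default seed this prints cubic as the selected cognition trend,
around 27/30 adequate learning-curve fits with a mean stable maximum
near 1.8 d-prime units, and a concurrent covariation table in which the
step-residual coefficient is negative (relatively higher activity with
relatively better, i.e. lower, mood totals).

## Known limitations

* Starting-point extraction inherits the baseline/plateau identifiability
  limit described above; treat extracted intercepts as conditional model
  values, not pre-practice ability.
* The smoothed-series inverse fit overstates $b$; rates are comparable
  within a fixed smoothing convention but not across conventions.
* p-values from the mixed models use nlme's default within-group degrees
  of freedom; in the null simulations they run slightly conservative
  (rejection near 3--5% at nominal 5%).
* The mood total is modelled as continuous; its 3--12 discretisation is
  mild but real, and extreme baselines can clip.
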