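---
title: "Methods: BLRM/EWOC dose finding and mechanistic target-engagement simulation"
author: "escalape developers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: BLRM/EWOC dose finding and mechanistic target-engagement simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(escalape)
```

This vignette is the package's own account of its science: the models and
their assumptions, the parameters that matter, what the synthetic-data
generators do and do not emulate, the numerical choices, and the design
decisions taken where the underlying study reports are silent. It states
no empirical result that the test suite or the acceptance script does not
itself compute.

## 1. The dose–toxicity model

Escalation decisions rest on a two-parameter Bayesian logistic regression
of the first-cycle DLT probability on dose:

$$\operatorname{logit} p(d) = \log\alpha + e^{\log\beta}
\log(d/d_{\mathrm{ref}}).$$

The exponentiated slope guarantees monotonicity in dose, which in turn
makes overdose control coherent: if a dose fails the safety check, every
higher dose fails it too (a property the test suite asserts). The
parameterisation and its standard weakly-informative prior are the ones
in common use for model-guided phase I oncology designs:

* `ref_dose_mg` ($d_{\mathrm{ref}}$): the dose at which
  $\operatorname{logistic}(\log\alpha)$ is the DLT rate. We use the
  schedule's eventual MTD (720 mg for every-3-weeks, 180 mg for weekly)
  so the prior is centred where decisions are hardest. Any positive value
  is accepted.
* `mean_log_alpha = logit(0.2)`, `sd_log_alpha = 2`: centres the
  reference dose on a 20% DLT rate — the canonical "prior guess of the
  MTD" — with wide uncertainty (±2 sd spans DLT rates from well under 1%
  to over 97%).
* `mean_log_beta = 0`, `sd_log_beta = 1`: centres the slope on 1 (logit
  change per log-dose) with generous spread.
* `correlation = 0` by default; a bivariate-normal correlation is
  supported.

The studies that motivate the package name the model but print no
hyperparameters, so exact reproduction of the sponsor's interim
posteriors is impossible; the acceptance tests therefore check the
*decisions* (which doses pass overdose control, which dose is the MTD)
and demonstrate robustness of the headline decision across
`sd_log_alpha` in {1, 2, 3}.

### Posterior computation

The posterior is computed by tensor-product quadrature on a regular
lattice: 401 × 401 nodes spanning the prior mean ± 6 sd per axis
(`grid_spec()`). Weights are prior density × binomial likelihood,
normalised. Two consequences are worth spelling out:

* **Bit-reproducibility.** Identical inputs give identical decisions,
  byte for byte — no MCMC diagnostics, no seed sensitivity. The cached
  trial-engine path (`design_engine()`) is pure vector arithmetic on
  precomputed per-dose log-probabilities and is asserted to agree with
  `fit_posterior()` to 1e-13.
* **Boundary granularity.** Interval probabilities pay an $O(h)$ error
  where the interval boundary cuts between lattice nodes. At the default
  grid this is far below the 0.005 Monte-Carlo comparison tolerance used
  in the tests; a test that demands 1e-4 agreement with a 1-D quadrature
  oracle uses a correspondingly finer grid.

Interval conventions: under $[0, 0.16)$, target $[0.16, 0.33)$, over
$[0.33, 1]$. The published description closes both ends of each interval;
since the overdose criterion is "$p \ge 0.33$", the half-open convention
above is the consistent reading, and the same convention is applied at
0.16.

### Decision rules

* **EWOC admissibility**: $P(p(d) \ge 0.33) < 0.25$.
* **Escalation caps**: +200% of the current dose while at or below the
  schedule threshold (120 mg Q3W, 40 mg QW), +100% above — exactly the
  published step rule.
* **No skipping** (`allow_skipping = FALSE` by default): the next dose may
  not pass over an untested provisional level. The studies are silent;
  this is conventional practice.
* **Next dose**: the admissible, cap- and skip-respecting level with the
  highest posterior target-interval probability. Ties break toward the
  higher dose, reflecting escalation intent; this is exercised by a test
  with an exactly flat posterior.
* **MTD**: the highest administered dose that is admissible under the
  final posterior with at least `min_patients_at_mtd = 6` patients
  treated. The published definition adds that the target-interval
  probability should be "sufficiently large" without quantifying it, so
  `min_target_interval_prob` exists but defaults to 0.

A patient with several DLTs counts once: all decision inputs are
patient counts, matching how the studies report ("five DLTs in four
patients").

## 2. Trial engine

`replay()` walks a completed cohort table in enrollment order, refitting
after each cohort; because interim enrollment splits (how many of the
720 mg patients preceded the 1000 mg decision) are not published, the
final first-cycle counts per dose are used as the evidence at each step.
`simulate_trial()` draws per-cohort DLT counts binomially from an assumed
truth and follows the model's recommendations. Operational defaults,
chosen where the study reports are silent and all configurable:
cohorts of 3, at most 30 patients (the two studies treated 29 and 24),
a 21-day DLT window, and declaration when the recommended dose already
has 6 patients, after which the remaining budget enrolls at the declared
MTD — mirroring the studies' expansion of the MTD cohort.

**A deliberate red test.** The acceptance suite asserts that under an
assumed truth of (0.02, 0.05, 0.10, 0.25, 0.55) on the Q3W ladder the
modal selected MTD across 500 simulated trials is the 4th level. The
faithful implementation does not meet this: the modal selection is the
3rd level, with the 4th close behind (the test prints the frequencies).
The mechanism is not a defect in the decision rules but EWOC's
well-documented conservatism. With cohorts of 3 and a true rate of 0.25
at the 4th level, at least 2 of the first 3 patients there have a DLT
with probability 0.156; an observed rate of 2/3 makes that dose
inadmissible under any weakly-informative prior (correctly so), the
trial de-escalates, and the 3rd level accumulates the 6 patients needed
for declaration. Widening the patient budget does not help (declaration
triggers first), larger cohorts make it worse, and raising the
declaration minimum to 9 at a 42-patient budget only reaches a tie. We
keep the assertion as specified and leave it failing rather than tune
the design to the expectation; the operating-characteristics machinery
itself is exercised green by separate tests (uniformly toxic truths stop
without an MTD; nontoxic truths walk the full ladder; caps and no-skip
hold on every simulated path; raising all true toxicities never raises
the mean selected MTD).

## 3. The mechanistic PK/PD model

States are concentrations in nM, time in days. Drug: two-compartment
disposition (CL, V1, Q, V2; L/day and L) with zero-order infusion input.
Ligands: turnover + reversible binding + complex elimination, as in the
README equations. Structural assumptions, stated once:

* Full mass-action kinetics — no quasi-equilibrium approximation — with a
  distinct complex-elimination rate `k_int`, because the circulating
  complex is eliminated on its own clock.
* Binding is confined to the central compartment; peripheral drug does
  not see ligand (the complex is a plasma species).
* The infusion is a zero-order input switched at exact event times; the
  integrator steps onto those times so the right-hand side is smooth
  within every accepted step.
* mg→nmol conversion uses a configurable molecular weight; the shipped
  fixtures use 40,000 g/mol (no value is published for the compound;
  the choice only rescales dose).

### Solver

An adaptive embedded Dormand–Prince 5(4) pair implemented in C++
(`src/pkpd_ode.cpp`), default `rtol 1e-8`, `atol 1e-10`, with a step
budget that converts pathological stiffness into an explicit error
carrying the offending parameters. An implicit stiff method would be the
textbook choice for target-mediated models generally; here no stiff
solver library is available to the package's dependency set, and for the
shipped parameter ranges (binding turnover up to ~10^3/day against
21-day intervals) the adaptive explicit pair meets every stated
numerical contract — agreement with the closed-form linear solution to
relative 1e-6, ligand flux bookkeeping closing along the solution, and
baseline recovery after washout within 1% — at millisecond cost per
subject-cycle. Outputs within one `atol` of zero are clamped to zero so
downstream nonnegativity invariants are exact.

Population simulations (`population_fraction_inhibited()`) default to
`rtol 1e-6` / `atol 1e-8`: a ≥90%-inhibition threshold comparison is
insensitive at that level and hundreds of ten-cycle subjects must fit in
minutes. Steady state is defined operationally as the 10th dose of the
repeating regimen (configurable).

### The synthetic "study-like" parameter set

`inst/extdata/pkpd_synthetic_params.json` is illustrative, not an
estimate: the fitted population parameters behind the published
simulations are unavailable. Values were chosen once, at design time, to
be pharmacologically plausible for an albumin-binding nanobody and its
targets — CL 0.45 L/day, V1 3 L, Q 0.5 L/day, V2 2.5 L (terminal
half-life ≈ 9 days); Ang-2 baseline 1 nM with fast turnover
(k_deg 5/day), k_on 1/(nM·day), k_off 1/day, k_int 0.5/day; lognormal
inter-individual variability of 0.3 on clearance and ligand turnover and
0.2 on central volume — and calibrated so that the 360→720 mg Q3W range
spans the transition from partial to near-complete population-level
trough engagement of Ang-2, as the published analysis describes
qualitatively. The published per-dose population fractions (85.7/95.2/
100%) are **not** reproduction targets; the acceptance property is
monotone nondecrease of the fraction in dose, which the tests compute at
200 subjects × 3 seeds. VEGF-A is parameterised to sit above 90%
suppression at the lowest study dose and is excluded from dose-selection
summaries, as in the published analysis.

What the generator does *not* emulate: covariate effects, immunogenicity
(the studies found none on PK), time-varying clearance, assay error in
ligand measurements, and any resemblance of the variance structure to
the real population beyond the lognormal convention. A green test
therefore establishes internal consistency of the machinery, not
fidelity to the unpublished study-level estimates.

## 4. Noncompartmental analysis

Conventions follow standard practice and are deterministic:

* BLQ observations are flagged, never imputed: treated as zero before
  the observed Tmax, excluded after it.
* `auc_0_tz()` integrates to the last quantifiable point; the default
  lin-up/log-down rule uses the logarithmic trapezoid only between
  strictly positive, strictly decreasing neighbours.
* `terminal_half_life()` selects the terminal window by best adjusted
  R² over contiguous windows of ≥3 quantifiable points after (excluding)
  Tmax, ties broken toward more points; nonnegative slopes and short
  series return "not evaluable" (`NA`) rather than an error. The
  regression is computed with explicit least-squares arithmetic because
  exact mono-exponential inputs — a deliberate test case — make
  `summary.lm()` warn.
* `dose_proportionality()` fits the power model
  $\log \mathrm{AUC} = a + b \log d$ and flags proportionality when the
  90% CI for $b$ contains 1; an exact fit collapses the CI to a point.

Default units are days and nM; unit labels travel with the series, and a
test asserts coherent rescaling of AUC and half-life under unit changes.

## 5. Response endpoints

Target-lesion sums only, per the simplified investigator-assessed
setting: PR at ≤ −30% versus baseline, PD at ≥ +20% versus nadir or on a
new-lesion flag, CR at a zero sum. The nadir at assessment $k$ is the
smallest sum among baseline and assessments before $k$ (a value cannot
progress relative to itself). PR/CR confirmation requires a second
qualifying assessment ≥ 4 weeks later; SD requires observation at or
after week 6 (the assessment cadence), so an early SD followed by PD
yields PD and an early SD with no follow-up yields NE. Duration of
response runs from first qualification to PD, censored at the last
assessment; a response seen only at the final assessment is "not
available", mirroring how such a case is reported in the motivating
study. Full RECIST nodal rules, non-target lesions beyond the boolean
trigger, and the 5 mm absolute-growth clause are out of scope.

## 6. Synthetic data and seeding

Every generator takes an explicit seed and restores the caller's RNG
state (`with_seed()` internally), so runs are pure functions of
(arguments, seed) and bit-reproducible — asserted by serialisation
tests. Per-parameter lognormal draws consume one RNG stream per
parameter even at zero variance, so toggling one omega never shifts
another parameter's draws. The lesion generator's three stylised natural
histories (responder to ≈ −45%, progressor +30% per scan, stable within
±5%) are constructed so their intended categories hold exactly at zero
noise and with ≤5% confusion at 2 mm measurement noise (a computed test,
300 subjects).

## 7. Known limitations

* The sponsor's prior, interim enrollment order, and fitted PK/PD
  population parameters are unpublished; everything downstream of those
  inputs is reference-choice plus sensitivity analysis, not replication.
* The BLRM is single-agent, covariate-free, and binomial per cohort; no
  time-to-event DLT handling.
* The ODE solver is explicit; parameter sets far stiffer than the
  shipped ranges (e.g. k_on·C ≫ 10^4/day) will hit the step budget and
  error out rather than silently lose accuracy.
* Operating characteristics inherit EWOC's conservatism (Section 2);
  selection probabilities for mid-target true rates split between the
  target level and the one below.
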