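# escalape

Model-guided phase I dose finding and early-phase pharmacology in R:
a Bayesian logistic regression model (BLRM) with escalation with overdose
control (EWOC) for dose-limiting toxicity (DLT), a mechanistic
two-compartment PK model with mass-action drug–ligand binding for
target-engagement-based dose selection, noncompartmental exposure
analysis, trial replay / operating-characteristics simulation, and
RECIST 1.1-style response endpoints — plus seeded synthetic-data
generators so the whole pipeline is testable offline.

The package is built around the escalation machinery of two first-in-human
studies of a bispecific anti-VEGF/anti-Ang-2 nanobody given every 3 weeks
(Q3W) or weekly (QW). The per-dose first-cycle cohort tables of both
studies ship as fixtures, so every decision of those escalations can be
replayed end-to-end.

## Who this is for

Trial statisticians and pharmacometricians who want a small, fully
deterministic, dependency-light implementation of the BLRM/EWOC decision
rules to replay an escalation, audit a proposed design's operating
characteristics, or couple toxicity-driven escalation with a
ligand-suppression PK/PD simulator.

## The models

**Dose–toxicity.** The probability of a first-cycle DLT at dose $d$ is

$$\operatorname{logit} p(d) \;=\; \log\alpha + e^{\log\beta}\,
  \log(d / d_{\mathrm{ref}}),$$

with a bivariate normal prior on $(\log\alpha, \log\beta)$. The default
reference prior is weakly informative:
$\log\alpha \sim N(\operatorname{logit}(0.2),\,2^2)$,
$\log\beta \sim N(0,\,1)$, independent, with $d_{\mathrm{ref}}$ the
schedule's reference dose (720 mg Q3W, 180 mg QW). The posterior is
computed by deterministic tensor-product quadrature on a 401×401 lattice,
so decisions are bit-reproducible. DLT rates are summarised over the
intervals under $[0, 0.16)$, target $[0.16, 0.33)$ and over $[0.33, 1]$.
A dose is **EWOC-admissible** when $P(p(d) \ge 0.33 \mid \text{data}) <
0.25$; the recommended next dose maximises the target-interval
probability among admissible levels subject to the escalation cap
(+200% up to a schedule threshold, +100% above) and a no-skipping rule.
The MTD is the highest administered admissible dose with at least 6
patients treated.

**PK/PD.** Drug concentration $C$ (central, nM) follows two-compartment
kinetics with zero-order infusion input; each circulating ligand $L$
(Ang-2, optionally VEGF-A) turns over ($k_{syn}, k_{deg}$), binds drug
reversibly ($k_{on}, k_{off}$) and is eliminated as complex $X$ at
$k_{int}$:

$$\dot L = k_{syn} - k_{deg} L - k_{on} C L + k_{off} X, \qquad
  \dot X = k_{on} C L - (k_{off} + k_{int}) X .$$

Percent inhibition is $1 - L / (k_{syn}/k_{deg})$; the dose-selection
summary is its minimum over a full dosing interval, and
`population_fraction_inhibited()` reports the fraction of a lognormally
varying population holding ≥90% inhibition through the interval.

## Worked example: replaying the weekly-schedule escalation

```r
library(escalape)
fx <- make_study_fixtures()

res <- replay(fx$qw$cohorts, fx$qw$design)
res
#> BLRM-EWOC trial: 5 decision step(s), 24 patients, 4 DLT patient(s)
#> Declared MTD: 180 mg

final <- res$decisions[[length(res$decisions)]]$summary
print(final, digits = 2)
#>   dose_mg p_under p_target  p_over overdose_prob admissible
#> 1      40    0.96    0.039 0.00054       0.00054       TRUE
#> 2     120    0.78    0.213 0.00581       0.00581       TRUE
#> 3     150    0.62    0.367 0.01621       0.01621       TRUE
#> 4     180    0.40    0.544 0.05602       0.05602       TRUE
#> 5     240    0.18    0.502 0.31649       0.31649      FALSE
```

Reading the table: after the full weekly cohort history (0/2 at 40 mg,
1/5 at 120, 0/3 at 150, 1/11 at 180, 2/3 at 240), the posterior
probability that the DLT rate at 240 mg is at least 0.33 is 0.316 —
above the 0.25 feasibility bound, so 240 mg fails overdose control —
while 180 mg passes comfortably (0.056) and carries the largest
target-interval probability (0.544). The declared MTD is therefore
180 mg, matching the study.

On the Q3W table, the top dose stays admissible:

```r
post <- fit_posterior(fx$q3w$design$prior, fx$q3w$cohorts)
ewoc_admissible(post, 1000, fx$q3w$design$rules)
#> $admissible
#> [1] TRUE
#> $overdose_prob
#> [1] 0.02324671
```

but with only 5 patients treated at 1000 mg the MTD declaration (which
requires 6) falls to 720 mg — again as in the study.

## Command line

A thin CLI ships in `inst/cli/escalape` (replay, PK/PD simulation,
population target-engagement fractions, NCA, operating characteristics,
synthetic-data generation); see the header of that file for usage.

## More

The methods vignette (`vignettes/escalape-methods.Rmd`) documents the
model assumptions, every tunable parameter with units and defaults, the
synthetic-data generators and their limits, numerical choices, and known
limitations — including one deliberate red test on the design's
operating characteristics.
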