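---
title: "Signal detection for spontaneous adverse-event reports: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signal detection for spontaneous adverse-event reports: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvsignals)
```

# The problem

Spontaneous adverse-event reporting databases (the Japanese JADER, the FDA's
FAERS, WHO VigiBase) collect case reports rather than exposures, so absolute
risks cannot be estimated from them. What can be estimated is
*disproportionality*: whether a drug-event pair is reported more often than
the rest of the database would predict. `pvsignals` implements a complete
screening pipeline for such data in its common four-table layout — one table
each for demographics, drug exposures, reactions, and medical history,
linked by a case identifier — with a motivating application to hemorrhagic
transformation (HT, bleeding into a cerebral infarct) and intracerebral
hemorrhage (ICH) in patients receiving the thrombolytic alteplase together
with antiplatelets or anticoagulants.

All analyses are case-level: a case counts once for a drug or an event no
matter how many rows mention it, and all three reported drug roles
(suspected, concomitant, interaction) count as exposure.

# Adverse-event signal indices

For one exposure definition and one event term set, every case falls in one
cell of a 2×2 table with counts $N_{11}, N_{10}, N_{01}, N_{00}$ (exposed
with event, exposed without, unexposed with, unexposed without).

**Reporting odds ratio.**
$\mathrm{ROR} = N_{11}N_{00} / (N_{10}N_{01})$, with
$95\%\ \mathrm{CI} = \exp\!\left(\ln \mathrm{ROR} \pm z_{0.975}
\sqrt{\tfrac1{N_{11}}+\tfrac1{N_{10}}+\tfrac1{N_{01}}+\tfrac1{N_{00}}}\right)$.
With any zero cell the odds ratio is undefined; by default no continuity
correction is applied (an optional Haldane 0.5 correction exists but is off)
and the estimate is reported non-evaluable — a non-evaluable estimate never
produces a positive signal. $z_{0.975}$ is fixed at 1.959964 everywhere for
bit-stable results.

**Information component.** The Bayesian confidence propagation neural
network (BCPNN) IC is a shrinkage estimator of
$\log_2 \frac{P(\text{drug},\text{event})}{P(\text{drug})P(\text{event})}$.
With priors $\gamma_{11}=1$, $\alpha_1=\beta_1=1$, $\alpha=\beta=2$ and
$\gamma$ recomputed per table so the IC is centred at zero under
independence,

$$E(IC) = \log_2 \frac{(N_{11}+\gamma_{11})(N_{++}+\alpha)(N_{++}+\beta)}
 {(N_{++}+\gamma)(N_{1+}+\alpha_1)(N_{+1}+\beta_1)},$$

with the standard three-term variance and the interval
$E(IC) \pm 2\sqrt{V(IC)}$. The pseudo-counts keep the IC finite at
$N_{11}=0$ and pull extreme small-count disproportionalities toward zero
(a single report of a unique pair in a million-report database scores about
1 bit, not $\log_2 10^6$). One subtlety worth knowing: the prior scale
$\gamma$ grows like $N_{++}^2/(N_{1+}N_{+1})$, so shrinkage vanishes only
when the margins carry information relative to the total
($N_{1+}N_{+1} \gg N_{++}$) — a large database alone does not eliminate it.

**Signal rule.** A pair is a positive adverse-event signal only as a
conjunction: the ROR is evaluable with 95% CI lower bound above 1 *and* the
IC interval lower bound is above 0.

# Drug-drug interaction statistics

For a drug pair, cases are partitioned into four exposure strata (both,
first only, second only, neither), giving per-stratum event counts
$n_{ij1}$ and totals $n_{ij+}$ with rates $p_{ij}=n_{ij1}/n_{ij+}$. Four
statistics are computed, each with its conventional threshold:

1. **Omega shrinkage measure**:
   $\Omega = \log_2 \frac{n_{111}+0.5}{E_{111}+0.5}$, with lower bound
   $\Omega_{025} = \Omega - z_{0.975}/(\ln 2\,\sqrt{n_{111}})$; signal when
   $\Omega_{025}>0$. The natural logarithm in the denominator is the reading
   that reproduces published values. Pairs with $n_{111}=0$ are
   non-evaluable and excluded.
2. **Additive model**: $AM = p_{11}-p_{10}-p_{01}+p_{00}$; signal when
   $AM>0$. A point estimate without an interval, by construction.
3. **Multiplicative model**: $MM = p_{11}p_{00}/(p_{10}p_{01})$; signal
   when $MM>1$.
4. **Chi-square statistic**:
   $\chi = (n_{111}-E_{111}-0.5)/\sqrt{E_{111}}$; signal when $\chi>2$.

The composite verdict is positive when **at least two of the four** models
flag the pair; non-evaluable models count as not flagged, so a lone
additive-model excess (a common small-count artifact) is never a composite
signal.

**The expected count $E_{111}$.** The source literature for the omega
shrinkage measure derives the no-interaction reference from survival-odds
additivity:
$$\frac{1}{1-g_{111}} = \frac{1}{1-p_{10}} + \frac{1}{1-p_{01}} -
\frac{1}{1-p_{00}}, \qquad E_{111} = g_{111}\,n_{11+},$$
with $g_{111}$ clamped into $[\max(p_{10},p_{01}),\,1)$. This reference is
close to risk additivity at small rates. Published screening tables print
$E_{111}$ directly, and `ddi_statistics()` accepts an externally supplied
expected count so results can be reproduced from printed inputs without
committing to any particular $E_{111}$ derivation.

Note the four models do not share a null except when both single-drug
effects are absent: a pair that is exactly multiplicative-null with strong
single-drug effects has $p_{11}$ far above the additive reference, and the
omega, additive and chi statistics will correctly report that excess. This
matters when interpreting joint calibration claims (see the simulation
section).

# Predictors of the event

Among cases exposed to the target drug, a multivariable logistic regression
models the event indicator on fixed a-priori covariates: male sex, older
age (the decade labels "70s" and above; "under 10s" through "60s" are
younger), and per-comorbidity history flags from term-set matches on the
history table. Cases with unknown sex or age class are dropped
(complete-case; the data provide no basis for imputation). Covariates with
zero variance or no variation within either response class are excluded
before fitting and reported with reasons, mirroring the "N.A." convention
of published predictor tables. Estimation is maximum likelihood via
iteratively reweighted least squares (convergence tolerance $10^{-8}$, at
most 100 iterations); inference is two-sided Wald: OR with
$\exp(\hat\beta \pm 1.959964\,\mathrm{SE})$ intervals and normal p-values.
Separation is flagged, not penalized — no Firth correction is applied, so a
separated fit is reported as unreliable rather than silently corrected.

# Time-to-onset and outcomes

Time-to-onset is the whole-day difference between the earliest onset of a
matching event and the earliest first administration of the drug. Unknown
is a sink state: any missing date, a partial (year-month) date, or a
negative difference gives unknown. Day-level arithmetic is required, which
is why partial dates are not interpolated. The analysis window defaults to
20 days, inclusive — day 20 is within the period; later onsets are excluded
and counted. Summaries report day-binned counts, the median and the mode of
known in-window values. Outcome records use six categories (recovery,
remission, no recovery, after-effect, death, unknown); recovery + remission
aggregate to "recovered", the other three known categories to "not
recovered", with proportions over known-outcome cases and percentages
rounded to integers. When a case has several event records with different
outcomes the most severe is used.

Published onset tables bin days 4–20 together; when reconstructing such a
distribution the bin is placed at day 4, which provably cannot move the
median because the median index falls inside the day-0/1 mass.

# Term sets and drug classes as configuration

Events and comorbidities are matched by flat preferred-term sets (exact
string equality after case-folding and whitespace collapsing) — no
dictionary hierarchy is traversed. Because the standard dictionaries are
licensed, the package ships *synthetic placeholder* term sets (3 PTs for
HT, 9 for ICH, narrow comorbidity sets) in an editable YAML config; every
analysis function takes term sets as parameters, so licensed lists drop in
without code changes. The drug-class map (aspirin, P2Y12 inhibitors,
cilostazol, ozagrel sodium, other antiplatelets, DOACs, warfarin potassium,
heparin group, argatroban, alteplase) ships as YAML as well; names are
matched after normalization but salt suffixes are kept, since distinct
salts are distinct products.

# The simulator

`simulate_reports()` draws independent reports: per-drug Bernoulli
exposures, then the target event with probability
$p = p_0 \prod_{\text{exposed } d} RR_d$, an index administration date, a
geometric time-to-onset, independent missingness on administration and
onset dates, and an outcome category per reaction record. One drug pair may
carry a planted interaction: *additive excess* sets
$p_{11} = p_{00}+(p_{10}-p_{00})+(p_{01}-p_{00})+m$ and *multiplicative
factor* sets $p_{11} = p_{00}(p_{10}/p_{00})(p_{01}/p_{00})\,m$ — exactly
the null structures of the additive and multiplicative statistics, so
$m \neq 0$ (resp. $m \neq 1$) is a true planted interaction and the
generator's `truth` object records the exact stratum probabilities for
recovery tests. Identical configuration and seed give identical datasets.

Default generator conditions, chosen once as realistic for this data type:
baseline event probability 0.001 (the rare-event regime of a single
preferred term in a large database), exposure probabilities in the
0.01–0.05 range, missing-date probability 0.2 (administration dates are
frequently absent in spontaneous reports), geometric onset with mean 2
days, and an outcome distribution with a majority of non-recovered
categories, as observed for serious hemorrhagic events. What the simulator
deliberately does **not** model: reporting biases (Weber, notoriety,
masking), correlated multi-event profiles, duplicate or follow-up reports,
and real dictionary vocabularies. Passing recovery tests therefore
demonstrate statistical correctness of the estimators under the assumed
reporting model, not robustness to reporting bias.

## Simulation problem sizes used by the test suite

The packaged tests exercise: stratum-frequency convergence at $10^5$
reports (within 3 binomial standard errors of the planted truth); recovery
of a planted relative reporting rate 10 by the ROR at $2\times10^5$
reports; null-interaction calibration at 200 replicates of 50,000 reports
under the all-models-shared null (no single-drug effects), where the omega
model's positive rate must not exceed any other model's rate by more than
2 Monte-Carlo standard errors — the omega shrinkage measure is the most
conservative of the four; and recovery of a planted multiplicative factor
of 5 at 100 replicates of 50,000 reports with exposure probabilities 0.3,
where stratum sizes are large enough that the small-sample bias of the
ratio estimator stays inside the Monte-Carlo band. These sizes make the
whole suite run in about a minute and a half on one CPU while leaving
comfortable power for every property checked.

# Numerical and design choices

* $z_{0.975}$ fixed at 1.959964; IC priors fixed at the standard values;
  all internal computation at full precision, presentation rounding to 2
  decimals.
* Zero cells: no continuity correction by default; non-evaluable estimates
  never claim signals.
* The 2×2/4×2 denominator population is whatever report collection the
  caller passes — the statistic is scope-agnostic, the caller chooses the
  scope (all drugs, one indication, ...).
* Duplicate case ids in the demographics table: first row wins with a
  warning; follow-up de-duplication beyond that is out of scope.
* Ties in the time-to-onset mode are broken toward the smaller day.
* The published-table reproduction suite feeds printed $(n_{111}, E_{111})$
  pairs directly into the omega and chi formulas. Sixteen of eighteen rows
  reproduce the printed statistics exactly at 2-decimal rounding; in two
  rows the printed $E_{111}$ (itself rounded to 2 decimals) limits the
  achievable agreement to ±0.015, which the tests assert explicitly.

# Known limitations

Disproportionality is not risk: no denominator of exposed patients exists,
so RORs and ICs rank hypotheses, nothing more. The interaction statistics
are screening tools with different references (additive vs multiplicative),
and the two-of-four composite is a pragmatic, not a principled, rule. No
adjustment for multiple testing is applied at screening. Three-drug
interactions are out of scope — no accepted model exists. Term-set matching
is flat and exact; misspelled or differently coded terms silently fail to
match, which is why term sets are configuration to be curated, not code.
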