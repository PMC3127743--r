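---
title: "Priority-level assignment in acute care: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Priority-level assignment in acute care: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mapleAC)
```

## The problem

Older people admitted to acute hospital care are at high risk of adverse
outcomes — death, institutionalisation, failed discharge home — and the
clinical information needed to anticipate those outcomes is scattered
across functional, cognitive, behavioural and social domains. MAPLe-AC
(Method for Assigning Priority Levels for Acute Care) condenses a
standardized comprehensive geriatric assessment (interRAI-AC v1.1) into a
single ordinal priority level, `low < mild < moderate < high < very_high`,
computed at three points of an episode: pre-morbid status (the 30 days
before admission), admission status (the 24 hours before admission), and
day 7 or the day before discharge, whichever comes first. The algorithm is
a crosswalk of a 44-item home-care tool; 31 items are directly available
on the acute-care instrument, and this package implements exactly that
31-item crosswalk (`maple_item_map()`).

This package provides four things: the embedded subscales, the decision
tree as an overridable data file, a calibrated synthetic episode
generator, and the validation battery (logistic endpoint models with
c-statistics, ROC curves, Cox survival models, cross-tabulations).

## Subscales

**Cognitive Performance Scale (CPS, 0–6).** Built from coma status,
short-term memory, daily decision-making, making self understood, and
eating self-performance. Coma dominates everything (CPS 6); severely
impaired decision-making yields 5, or 6 when the person is also totally
dependent in eating; otherwise the score follows counts of impaired and
severely impaired cognitive items. The implementation ships twice: as
procedural code (`cps_score()`) and as a verbatim per-case transcription
of the scoring grid used only by the tests. Transcription slips are the
dominant failure mode for clinical scales, and the two encodings are
compared exhaustively over all enumerable inputs.

**ADL hierarchy (0–6).** Four "late-loss" activities of daily living —
personal hygiene, toilet use, locomotion, eating — each coded 0
(independent) to 6 (total dependence), with 8 meaning "activity did not
occur". The hierarchy weights later-loss activities more heavily:
extensive assistance in eating or locomotion scores above the same level
of assistance in hygiene or toileting. The same dual encoding and
exhaustive comparison applies, plus an exhaustive check that raising any
single item's dependence code never lowers the score.

The "did not occur" code maps to total dependence by default — the
standard scoring convention — and is overridable through the
`did_not_occur` argument everywhere it matters.

**ADL decline** is TRUE when the ADL hierarchy at a later time point
strictly exceeds the pre-morbid one. Improvement is not decline. At the
pre-morbid point the category is FALSE by definition: a pre-morbid
priority level must be computable, and no earlier baseline exists there.

**Behaviour disturbance** is the disjunction of verbally abusive,
physically abusive, socially inappropriate behaviour, and resisting care.

**Institutional-risk screener.** A count over exactly 8 categories: prior
nursing-home stay; not going out (homebound); bladder incontinence; a
qualifying diagnosis (any dementia, Alzheimer's disease, multiple
sclerosis, head trauma); ADL decline; hygiene or bathing problems;
indicators of delirium; meal-preparation and shopping problems. The flag
activates at **3 or more** categories in the acute-care algorithm (the
home-care original uses 4; `cutoff = 4` restores it). Two mappings were
genuinely open and are resolved as follows, both config-visible:

* *Going out*: the risk fires when the person did **not** go out
  (homebound), consistent with the nursing-home-risk protocol the
  screener derives from; `homebound_is_risk = FALSE` flips the polarity.
* *Indicators of delirium*: the acute-care instrument carries several
  acute-change items; the category is the disjunction of four delirium
  indicator items (easily distracted, episodes of disorganized speech,
  mental function varies over the day, acute change in mental status).

**Geriatric screener.** The home-care screener minus its stamina item,
which has no acute-care counterpart: a count over short-term memory
problems, impaired decision-making, medication-management problems, and
meal-preparation problems. The home-care source does not pin down the
remaining composition precisely, so the set is isolated behind one
function (`geriatric_screener()`) and can be revised without touching the
tree. Stamina-like inputs are ignored by construction.

## The decision tree is data

The published account of the algorithm names the classifiers and the five
output levels but does not print the exact branch structure. The tree is
therefore shipped as a **data file**, not code:
`inst/extdata/tree_default.yaml`, version string
`maple-ac-reference-1.0`, carried into every output for provenance. Rules
are ordered highest severity first and evaluated first-match-wins with
default level `low`, so the rule set is total by construction. Conditions
are restricted expressions over the twelve classifier-vector fields
(comparisons, `&`, `|`, `!`, parentheses only); anything else — unknown
fields, function calls — fails at load time, never at scoring time.

The reference encoding escalates as follows: `very_high` for an active
institutional-risk flag combined with severe impairment (ADL ≥ 4, CPS ≥ 4,
or behaviour disturbance); `high` for ADL ≥ 3, CPS ≥ 3, behaviour
disturbance, pressure ulcers, or an active risk flag alone; `moderate`
for falls, swallowing difficulty, medication-management problems, decline
in decision-making, or mild ADL/CPS impairment; `mild` for isolated
screener or meal-preparation findings; `low` otherwise.

Because every condition is monotone in its fields and rules are ordered
by severity, the assignment is monotone: raising any single classifier
component never lowers the level. This, along with totality and
determinism, is verified exhaustively over the full discrete classifier
grid (≈2.8 × 10⁵ vectors), and the vectorised rule engine is checked
against an independently written one-row-at-a-time interpreter.

## Synthetic cohorts

No episode-level data from the original studies are deposited, so the
generator is the package's test bed. It emulates:

* **Covariate marginals** of the two study cohorts (Nordic, n = 763;
  Canadian, n = 393): sex, age bands (75–79 reference, 80–84, 85–89,
  90+), living alone, prior 90-day hospitalisation, reason for
  hospitalisation (new problem / exacerbation / both).
* **Priority-level marginals** at each of the three time points, from the
  published distributions (e.g. Nordic pre-morbid 39.4 / 10.4 / 24.1 /
  19.8 / 6.3 %).
* **Item patterns by inverse construction**: for each drawn level, an
  item pattern that the active tree maps back to exactly that level.
  Patterns are randomised within level-preserving bounds, and the closed
  loop is verified by re-scoring every generated assessment; any mismatch
  is a hard error, because it means the generator and the tree spec have
  drifted apart.
* **Binary discharge outcomes** from a logistic model whose odds ratios
  are the published coefficient sets (selectable per endpoint and time
  point); the intercept is not published and is solved numerically so the
  marginal endpoint rate matches the published proportion (82.0%
  discharged home, Nordic). ORs are intercept-invariant, so recovery
  checks are unaffected by this choice.
* **Days to death** (Nordic only) as exponential survival with
  covariate-dependent rate — proportional hazards hold exactly — with the
  published hazard ratios as generating values, the baseline daily rate
  solved so the cumulative one-year death probability matches the
  published 26.5%, and censoring at day 365.

Choices the sources do not determine, made once: covariates are drawn
independently (no joint distribution is published); diagnosis-group
prevalences for the survival covariates (neoplasms 15%, mental and
behavioural 10%, respiratory 20%) are realistic for elderly acute medical
admissions; the `other` discharge category is carved from the negative
class of the generating endpoint so that refits of that endpoint are
unaffected by its disposition; an episode recorded dead at discharge is
constrained to be a follow-up death within 28 days, keeping the
discharge/survival records coherent.

What the generator does **not** emulate: within-hospital clustering,
country effects beyond the two profiles, correlation between covariates,
correlation of priority levels across time points, or time-varying
hazards. Passing recovery tests therefore show that the estimation
machinery is correct under the stated generating model — not that the
published effect sizes would replicate on new clinical data.

A single RNG stream (Mersenne-Twister, explicitly pinned) drives each
generation; the seed, profile, generating model and tree version are
recorded in the cohort's provenance attribute and in every CLI sidecar.

## Validation battery

Endpoint models are fitted by maximum likelihood (`stats::glm`), with the
published covariate coding: sex (women = 1), age bands with 75–79 as
reference, reason for hospitalisation with "new problem" as reference,
and the priority level with `very_high` as reference for home endpoints
and `low` for adverse endpoints. Reference rows are reported with
estimate exactly 1.00 and no interval; other estimates carry 95% Wald
intervals on the log scale. Both pseudo-R² variants are reported —
unscaled (Cox–Snell) as the headline, mirroring the SAS "R-Square"
column the source tables came from, and max-rescaled (Nagelkerke) —
because the source does not name its variant. The c-statistic is the area
under the ROC curve of the fitted probabilities.

The ROC curve is built over all distinct score thresholds and integrated
by the trapezoid rule, which equals the Mann–Whitney concordance
probability with ties counted one half; tests verify this identity
against an O(n²) all-pairs oracle to 10⁻¹² and cross-check against an
independent ROC implementation.

Survival models use `survival::coxph` with the Efron tie approximation by
default — day-granularity data guarantee ties, and Efron is the
lower-bias standard — switchable to Breslow. Covariates follow the
published survival models, including the three ICD-10 diagnosis-group
flags (neoplasms; mental and behavioural; respiratory), which live as
episode-level columns in the CSV dialect since they are not derivable
from the 31 crosswalk items.

Endpoint denominators in the source differ across endpoints, implying
endpoint-specific handling of the `other` outcome category that the text
does not spell out. `endpoint_spec()` therefore exposes the disposition
(`positive` / `negative` / `excluded`) rather than hard-coding one
reading; the default counts `other` negative for home endpoints and
excludes it for adverse endpoints. Because the generator assigns `other`
only within an endpoint's negative class, either disposition leaves the
generating odds ratios recoverable.

## Numerical choices and degenerate inputs

* Missing data are two-tier: items feeding the core scales (ADL and
  cognition sets) block their classifier when absent — the episode is
  excluded from models needing it, mirroring varying denominators in
  practice — while boolean clinical/risk flags default to "not present"
  with a warning, matching how such forms are filled in.
* Intercept and baseline-rate solving use `uniroot` on the exact
  covariate mixture (enumerated combinations × marginal probabilities),
  to tolerances of 10⁻¹⁰, so generation is deterministic given the seed.
* Complete separation or monotone likelihood in a fit raises an explicit
  error naming the offending covariates rather than returning absurd
  estimates; single-class endpoints error before fitting.
* Ties in rule evaluation cannot arise: first-match-wins over an ordered
  list is a total order, and all-missing vectors are rejected upstream.
* Cross-tabulations use the Pearson statistic without continuity
  correction; categories unused by both cohorts are dropped, and a
  remaining zero expected count is an error with the table attached.

## Problem sizes

The test suite works at sizes chosen to make stochastic checks sharp but
cheap: exhaustive enumerations for all discrete-grid properties (8⁴ ADL
combinations, 1,024 CPS inputs, 2⁸ risk combinations, ≈2.8 × 10⁵
classifier vectors), n = 5,000–20,000 cohorts for parameter recovery,
n = 100,000 for calibration of the level marginals (±1 percentage point),
and 30 replicate cohorts at n = 5,000 for interval-coverage checks. With
the published effect sizes as generating values, recovery of the most
extreme odds ratio (51.71, against a reference cell holding roughly fifty
events at this design size) is the noisiest quantity: its log-scale
sampling deviation is about 0.15, so single-run estimates scatter
noticeably around the generating value even though the estimator is
unbiased; the replicate-coverage tests are the more informative check for
that corner.

## Known limitations

The shipped tree is a **reference encoding**: the exact published branch
diagram is not available in text form, so the encoding exercises every
published classifier with the published activation constants (five
levels, 8 risk categories, cut-off 3) but its internal thresholds are
this package's own, clearly versioned and fully overridable from the YAML
file. Scored outputs should not be read as clinical reproductions of the
original tool. The generator's independence assumptions make it
conservative for studying confounding; it cannot be used to study joint
covariate structure. One admission per patient; no alternate-level-of-care
fourth assessment; no home-care (44-item) algorithm.
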