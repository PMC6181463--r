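---
title: "A severity-state Markov model for the costs and consequences of chronic musculoskeletal pain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A severity-state Markov model for the costs and consequences of chronic musculoskeletal pain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paincohort)
```

## The model

`paincohort` implements a cost–consequence evaluation of chronic
musculoskeletal pain from a health-system perspective. The core is a
four-state Markov cohort model over pain severity: mild (VAS 1–3),
moderate (VAS 4–6), severe (VAS 7–10) and death from other causes.
Chronic pain is assumed non-fatal — health loss accrues through quality
of life, not mortality — and transitions are assumed independent of the
originating pathology, so a single monthly transition matrix drives all
six modelled conditions (knee and hip osteoarthritis, lower back pain,
chronic shoulder pain, myofascial syndrome, fibromyalgia).

Each pathology's prevalent cohort enters the model distributed over the
three living states according to its severity split, and is propagated
through 12 one-month cycles (the one-year horizon):

$$\mathbf{n}_{t+1} = \mathbf{n}_t P, \qquad t = 0, \dots, 11,$$

with $P$ row-stochastic and the death state absorbing. Total occupancy
(including deaths) is conserved every cycle; the test suite checks this
to $10^{-6}$ over 1000 random row-stochastic matrices.

No incident cases flow in during the year, and there is no half-cycle
correction: with a one-month cycle the correction is negligible relative
to parameter uncertainty, and plain start-of-cycle accounting keeps the
arithmetic exactly reproducible. Costs accrue on the state occupied at
the *start* of each cycle, a convention that had to be fixed explicitly
because either choice is defensible.

## Elicited transition probabilities

No published estimates exist for monthly severity transitions under
usual management, so they are treated as elicited quantities. Each of
the six off-diagonal living transitions (mild→moderate, mild→severe,
moderate→mild, moderate→severe, severe→mild, severe→moderate) is one
elicitation question; each expert distributes weight 1 over a grid of 21
candidate probability values, and a panel of 13 experts yields
$21 \times 13 = 273$ weighted support options per question.

Pooling is a **linear opinion pool**: every (expert, bin) option is kept
as a support point whose pooled weight is the expert's bin weight times
the expert's pooling weight (equal by default, configurable — the
aggregation literature offers no canonical unequal weighting and we do
not attempt performance-based weights). Keeping the full 273-point
support, rather than collapsing to a parametric fit, preserves the
empirical uncertainty the panel revealed; the probabilistic sensitivity
analysis resamples this pooled density directly.

Two conventions deserve flagging:

* The 21 grid options are placed at the midpoints of an even partition
  of $[0,1]$. The number of options is given; their placement is not, so
  the even-midpoint grid is a declared package convention.
* Stay probabilities are the complements of the elicited off-diagonal
  flows. Because the six questions are answered independently, a row's
  destination probabilities need not cohere exactly; rows are
  renormalized to sum to 1 before mortality is applied. When a full
  nine-entry row is supplied instead, it is renormalized the same way.

Background mortality competes multiplicatively: living-to-living entries
are scaled by $1 - d$ and the death column of every living row is $d$,
the simplest composition consistent with death arising only from other
causes.

### Mortality conversion

The published figure — 5.1 deaths per 1000 inhabitants per year — is a
crude death *rate*, so `mortality_parameter()` converts it as a constant
instantaneous rate acting for one month:

$$d = 1 - e^{-r/12}, \qquad r = 5.1/1000,$$

giving 0.42 per 1000 per month at two decimals. For inputs that are
annual *probabilities* the package provides `annual_to_monthly_prob()`,
the standard compounding conversion $1-(1-p)^{1/12}$. The two differ in
the third significant digit here (0.425 vs 0.426 per 1000); the rate
reading is the demographically correct one for a crude death rate and
is what reproduces the published monthly figure.

## Costing

Direct costs are valued through per-state monthly **resource baskets**:
rows of (resource, category, unit price in 2015 CLP, monthly quantity,
user fraction), with the four categories medical visits, pharmacological
treatment, physiotherapy and hospitalization. A basket's per-patient
monthly cost is $\sum \text{price} \times \text{quantity} \times
\text{user fraction}$, and the expected direct cost is that cost
multiplied into the patient-months the trace accumulates in the state.
Hospitalization is modelled *inside* the severe basket as an episode
price times a monthly admission probability rather than as a separate
health state, since only a fraction of severe patients is ever admitted;
the severe basket also carries an emergency-department visit with user
fraction 0.9. No discounting is applied over the one-year horizon.

The package ships `reference_baskets()`, a synthetic line-item
construction calibrated so that per-state monthly totals, converted at
the 2015 purchasing-power parity of 394.35 CLP/USD, equal the published
per-patient management costs of USD 63.5 (mild), 101.82 (moderate) and
734.5 (severe). The totals are validated figures; the line-item
composition underneath them is the package's own and is labelled
synthetic.

All monetary report tables carry both CLP and USD columns, which agree
through the configured rate exactly.

## Consequences

Four consequences are computed per pathology:

* **Years lived with disability (pain domain).**
  $\text{YLD} = \text{cases} \times \text{duration} \times DW \times
  f_{\text{pain}}$, where $DW \in [0,1]$ is the disability weight and
  $f_{\text{pain}}$ restricts it to the share of disability driven by
  pain. The default convention is prevalent-year cases with duration
  1 year (annualized YLD), because the model's one-year expected-cost
  frame has no incidence inflow; an incidence × duration reading uses
  the same arithmetic with different inputs. The pain-domain adjustment
  is a single multiplicative factor per pathology — its published form
  is not specified beyond "adjusted", and a scalar multiplier is the
  simplest faithful reading.
* **Depression attributable to chronic pain.** The population
  attributable fraction uses Levin's formula
  $\text{PAF} = p(RR-1)/(1+p(RR-1))$ from the exposure prevalence and
  relative risk — the standard estimator from cross-sectional survey
  data. Attribution is gated to moderate and severe states: mild pain is
  assumed to carry depression *associated with* but not *attributable
  to* pain. Knee and hip osteoarthritis carry a relative risk of 1
  (PAF 0) in the synthetic defaults, mirroring the published assumption
  of no attributable depression for them. In the PSA, sampling noise can
  push a relative risk below 1; a negative attributable fraction is
  truncated to zero attributable cases.
* **Anxiety.** Implemented as proportion × prevalent population ×
  cost per case — the simplest formalization of a prevalence-correlated
  cost.
* **Productivity loss** under the human-capital approach:
  episodes × days × average daily wage is the societal loss; the health
  system bears only the fraction of leave days it actually pays.
  Myofascial syndrome carries a **structural zero**: it has no ICD-10
  code and cannot be identified in medical-leave records, so its
  productivity loss is reported as `NA` with an explanatory flag —
  deliberately distinguishable from a computed zero.

## Scenarios

The base case assumes every prevalent case is diagnosed and managed. The
reduced-diagnosis scenario sets the diagnosed fractions to 50% of mild
and 75% of moderate cases (severe always fully diagnosed); undiagnosed
patients incur no management cost but still count for prevalence
reporting. Diagnosis gating applies to direct costs and YLDs (both are
defined on the managed/diagnosed cohort); depression and anxiety
attribution are prevalence-based and unchanged.

The myofascial-syndrome severity split is not observable in the health
survey; the specialist consultation fractions (7.5% mild, 35% moderate,
60% severe) are the only stated anchor. Two readings are exposed behind
`mfs_split_mode`: the default normalizes the consultation fractions into
a severity split; the alternative keeps the generated split and treats
the consultation fractions as per-state cost-incurring multipliers. The
mapping is an interpretation either way, and is flagged as such.

## Uncertainty analysis

One-way deterministic sensitivity analysis re-evaluates the full
pipeline at the low/base/high values of one parameter, all else held at
base (`one_way_sa()`, `tornado_table()`).

The PSA (`run_psa()`, default 5000 iterations) jointly redraws every
uncertain parameter and re-runs the model. Distribution families follow
standard health-economic conventions, moment-matched to the bundle's
base values, and are fully configurable:

| parameter type | family | default spread |
|---|---|---|
| elicited transitions | pooled empirical density | as elicited |
| severity splits | Dirichlet | concentration 60 |
| prevalence, proportions, fractions | beta | concentration 100 |
| state-level monthly costs, per-case costs, leave days | gamma | CV 0.2 |
| relative risks | gamma | CV 0.15 |
| mortality | fixed | — |

The PSA samples the *state-level monthly basket totals* rather than
every basket line item: the cost pipeline is linear in the basket total,
so item-level resampling would add parameters without changing the
induced outcome distribution under this gamma parameterization.

Each outcome is summarized by a deterministic point estimate (the model
at parameter means — which, by moment matching, reproduces the base-case
run exactly), the sample mean, and an equal-tailed percentile
**Bayesian credibility interval** using linear interpolation between
order statistics (quantile type 7). Both point-estimate readings are
reported because published tables do not say which was used.
Equal-tailed percentile intervals (not HPD) were chosen for determinism
and comparability. All parameters are sampled independently; no
correlation structure is imposed because none is stated.

## The synthetic-data generator

The real input table is published only as a figure, so its cell values
are unavailable; `generate_parameter_set()` emulates a complete input
set with known ground truth instead. What it emulates:

* six pathologies with prevalence drawn from a Beta(2, 2) stretched over
  1–11% — the range spanning symptomatic hip osteoarthritis (~1%) to
  lower back pain (~10%) in adult populations — over a 13-million adult
  population;
* severity splits Dirichlet-distributed around (0.30, 0.45, 0.25);
* one 13-expert, 21-bin elicitation panel per transition question. Each
  expert's central belief is drawn from a Beta moment-matched to the
  true probability and concentration (so the expert-level expectation
  *is* the truth), and the histogram discretizes a Beta with that mean —
  smooth, bounded, and with controllable spread. With 200 experts at
  concentration 50 the pooled mean recovers the truth within ±0.02
  (a tested property);
* cost baskets gamma-jittered (CV 0.15) around the reference baskets;
* burden and productivity inputs with magnitudes typical of
  musculoskeletal disease (disability weights 0.10–0.21, pain-domain
  fraction ~0.7, depression relative risk ~2, ~4% annual leave rate,
  2015 Chilean daily wage ~USD 30).

What it does **not** emulate: the actual Chilean parameter values. The
generated totals are therefore internally consistent but not comparable
to the published national totals — with ~36% of adults carrying one of
the six conditions under the default prevalence draws, the synthetic
aggregate cost is roughly an order of magnitude above the published
Chilean figure. Passing tests demonstrate that the arithmetic, pooling,
propagation and uncertainty machinery are correct and reproducible, not
that any particular national estimate is recovered.

Ground-truth monthly transition defaults (persistence ~0.78–0.85 on the
diagonal, worsening flows 0.03–0.15) encode the clinical picture of
chronic pain under usual management: largely persistent, with modest
monthly movement between adjacent severities.

## Numerical and engineering choices

* Bundles serialize to CSV tables plus a schema-versioned JSON manifest.
  Doubles are written in shortest round-trip form and re-parsed with the
  correctly rounded base-R converter, so a write/read round trip is
  exact to the last bit.
* Reports contain no timestamps; a rerun with identical inputs and seed
  is byte-identical (tested via file checksums at the full 5000
  iterations).
* Validation (`validate_bundle()`) reports *all* invariant violations
  with the offending pathology, question or basket row named, not just
  the first.
* Degenerate inputs: `concentration = Inf` or a truth of exactly 0 or 1
  collapses an expert histogram to a point mass on the nearest bin;
  empty baskets cost zero; a zero cohort yields a zero trace.
* Test problem sizes (1000 random matrices for conservation, 100 random
  panels for pooling-oracle equivalence, 5000 PSA iterations for the
  closed-form and determinism checks) were chosen to make the checked
  properties statistically sharp while keeping the default suite under a
  minute.

## Known limitations

* No incident inflow, early retirement, presenteeism or adjustment
  disorder — all outside the model's health-system frame or unmeasurable
  in the available data structure.
* Transition probabilities are aetiology-independent and time-constant
  by design; both are strong assumptions the elicitation structure
  cannot relax.
* The "21 × 21 squared matrix" construction behind the published pooled
  densities is not fully described; this package's reading — a weighted
  support of expert × bin options — is an interpretation, recorded as
  such.
* GDP shares are a convenience division by a user-supplied denominator;
  the package ships no GDP series.
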