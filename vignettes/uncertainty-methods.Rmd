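---
title: "Models and methods behind herdfit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind herdfit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(herdfit)
```

herdfit compares two feeding strategies for growing-finishing pigs —
conventional phase feeding (CON) and a daily fit model (DFM) that blends
two diets each day — on the basis of paired life-cycle impact-assessment
(LCIA) values. This vignette documents the models, the assumptions behind
them, and the design choices made where more than one reasonable
implementation existed.

## The blending model

A feeding plan is a sequence of phases; each phase has a duration in days,
a daily feed intake per animal, and (for DFM) a pair of diets. Within a
phase of length $d$, the feed-2 share on day $D$ (1-based) is

$$PD = \frac{100}{d}(D - 1)\ \%,$$

a linear ramp: day 1 is always pure feed 1 and the last day reaches
$100 - 100/d$ percent feed 2. The ramp deliberately never attains 100%
feed 2 inside a phase — that is what the formula gives, and forcing the
endpoint would break the affine structure (slope exactly $100/d$ per day)
that the tests rely on. Feed amounts follow as percentages of the day's
intake, so feed-1 kg + feed-2 kg always equals the intake: blending
redistributes mass between diets, it never changes how much is fed.

Costs: phase feeding costs $CCF = \sum_i D_i F_i I_i$ (duration × feed
price × daily intake); daily blending costs $CDA = \sum_{\text{days}}
CTC \cdot DFI$ with the blended per-kg price $CTC = \frac{AFI_1}{100} FP_1 +
\frac{AFI_2}{100} FP_2$. The feed shares enter $CTC$ as fractions so that
$CTC$ has currency/kg units and $CDA$ is dimensionally consistent; with the
shares taken literally as percentages the cost would be inflated a
hundredfold. Two consequences are useful as sanity checks and are enforced
in the test suite: when both diets have the same price, $CDA = CCF$
exactly, and in general $CDA$ is bracketed by the all-cheap and
all-expensive plans. No published cost figures exist for this model, so the
cost operations are validated purely by such properties and hand-enumerated
micro-examples (e.g. a two-day phase with prices 1 and 0 costs
$1 + 0.5 = 1.5$).

The plan schema allows any diet pairing per phase; the synthetic generator
uses adjacent-diet pairing (phase $i$ blends diet $i$ with diet $i+1$),
which matches a progressive transition across the feeding period. A
low-energy "diluting" sixth diet used against every phase diet is equally
expressible by putting the same feed-2 id in every phase.

## The reduction statistic

For each impact category and scenario the headline number is

$$\text{red} = 100 \cdot \frac{\text{CON} - \text{DFM}}{\text{CON}}
            = 100\left(1 - \frac{\text{DFM}}{\text{CON}}\right),$$

positive when DFM has the lower impact. It is scale-invariant and linear in
the DFM value, two properties exploited by the sensitivity analysis below.

The packaged table `pig_lcia_table()` stores the published (from, to) pairs
verbatim, including the water-use rows, where the source is internally
inconsistent: the pairs are printed with CON larger than DFM (a positive
arithmetic reduction) while the published summary table carries those rows
with a negative sign. The package keeps the pairs and reports their
arithmetic sign; the contradiction is surfaced rather than silently
"fixed". A related choice: the published narrative counts its categories
loosely, but paired values are printed for ten categories in three
scenarios, so the packaged table has 30 records. Acidification appears in
the category registry and the GSD map but has no published pair.

## Uncertainty propagation

Deterministic LCIA values inherit the uncertainty of background inventory
data. Each value is modeled as a lognormal random variable — the standard
choice for inventory data, being positive and right-skewed — parameterized
by its **median** (set to the deterministic value) and a geometric standard
deviation (GSD), so the log-scale SD is $\sigma = \log \text{GSD}$. Median
rather than mean parameterization is deliberate: it keeps the median of the
simulated reduction at the deterministic reduction, which is what the
published summary table shows (P50 tracking the deterministic column).

Because both systems share most background processes, their errors co-move:
a Pearson correlation $\rho = 0.85$ is imposed between the paired log-scale
deviates (a Gaussian copula). The source does not state on which scale the
correlation applies; for GSD ≤ 1.3 the log- and natural-scale correlations
differ negligibly, and the log-scale choice is the one that admits a closed
form. Under it the impact ratio is itself lognormal:

$$\frac{\text{DFM}_i}{\text{CON}_i} \sim \text{Lognormal}\!\left(\mu_\Delta,\,
  s_\Delta^2\right),\quad
  \mu_\Delta = \log\frac{\text{DFM}}{\text{CON}},\quad
  s_\Delta = \sqrt{2(1-\rho)}\,\log \text{GSD},$$

so the reduction quantile at level $q$ is
$100\,(1 - e^{\mu_\Delta + z_{1-q} s_\Delta})$ (upper reduction quantiles
come from lower ratio quantiles) and
$P(\text{DFM} < \text{CON}) = \Phi(-\mu_\Delta / s_\Delta)$.
`analytic_summary()` implements this closed form and serves as the
independent oracle for the simulation path `mc_summary()`; the test suite
checks their agreement within order-statistic standard errors across
randomized configurations, handling the multiplicity of several hundred
3-SE checks by bounding the exceedance rate rather than demanding every
single check clear 3 SE (which a correct implementation would fail with
high probability).

```{r}
analytic_summary(6127.30, 5360.84, gsd = 1.20, rho = 0.85)
```

Tunable parameters, defaults, and rationale:

* `n_iter` (default 10,000): matches the published procedure; Monte Carlo
  noise on P5/P95 is then a few tenths of a percentage point.
* `rho` (default 0.85, dimensionless): shared-background correlation.
  Higher ρ narrows the reduction distribution — shared errors cancel in a
  ratio — and the probability of a positive reduction rises accordingly.
* `gsd_map`: per-category GSDs (dimensionless, ≥ 1) assigned
  Pedigree-style, from 1.05 (climate change, fossil subcategory) to 1.30
  (freshwater ecotoxicity). The published note omits the fossil
  resource-use category; the default assigns 1.10, back-calculated from
  that row's interval width, and any entry can be overridden. The note's
  1.08/1.05 labels for overall climate change and its fossil subcategory
  are followed as printed even though the published intervals hint the two
  may be swapped; validation targets avoid those rows.
* `percentiles` (default 0.05/0.50/0.95): a 90% interval around the median.

Numerical conventions worth stating because they move P5/P95 by $O(1/N)$:
empirical quantiles use linear interpolation on the sorted sample
(`type = 7`, R's default); the beat probability uses the strict inequality
reduction > 0 (ties have probability zero under the continuous model);
`gsd = 1` or `rho = 1` (with equal GSDs) collapse to the degenerate case,
where every quantile equals the deterministic reduction and the probability
is 0, ½ or 1 by its sign. Each (category, scenario) record draws from an
RNG substream derived by hashing the record key with the master seed, so
adding, dropping or reordering records never perturbs another record's
draws.

## One-at-a-time sensitivity

Each LCIA value (DFM and CON separately) is perturbed by ±10%, ±20% and
±30% while everything else is held constant, and the normalized coefficient

$$S_i = \frac{|\Delta\ \text{reduction (pp)}|}{|\Delta\ \text{input (\%)}|}$$

is recorded — twelve coefficients per record, whose mean absolute value
ranks categories. The denominator is the relative change of the perturbed
input in percent (a +10% perturbation has $\Delta = 10$); this is the
convention that reproduces the published coefficients. Two closed forms
fall out of the ratio structure and serve as exact test oracles: the
DFM-side coefficient equals $\text{DFM}/\text{CON}$ at every level, and the
CON-side coefficient equals $(\text{DFM}/\text{CON})/|1+\ell|$. Values near
1 simply restate that the statistic is a ratio; no re-sampling happens
inside the OAT stage — it operates on deterministic values.

```{r}
oat_sensitivity(6127.30, 5360.84)$mean_abs_si
```

## Synthetic data and what passing tests show

`generate_table()` draws one observed (CON, DFM) pair per record from the
same correlated median-parameterized lognormal model the analysis assumes,
around a known truth `(true_con, true_con (1 - r/100))`. One pair per
record mirrors the real data situation — a deterministic LCA yields a
single table per scenario — and replicate tables come from varying the
seed. The sealed truth is returned beside the observed table so recovery
can be measured: with analysis GSD/ρ equal to the generating GSD/ρ, the
median estimated reduction is unbiased for the truth and the [P5, P95]
interval covers it 90% of the time (exactly, by construction — the
pivotal quantity $\log(\text{ratio}_{obs}/\text{ratio}_{true})/s_\Delta$
is standard normal). The test suite verifies both on 200 replicate tables
of five categories each, with N = 2,000 iterations per record — sizes
chosen to keep the recovery check's own Monte Carlo error well below the
1-percentage-point and ±5% acceptance margins.

What the generator does **not** emulate: model-form error (real background
data are not exactly lognormal, and the true pairing of CON and DFM errors
is not exactly a Gaussian copula), inter-category correlation, and any
uncertainty in the blending model's own inputs. Passing recovery tests
therefore demonstrate internal consistency of the pipeline under its own
assumptions, not robustness of real LCA conclusions to violations of
those assumptions; coverage degrades when the analysis GSD understates the
generating GSD.

`generate_phase_plan()` emulates the shape of the study's feeding plans:
five phases totalling 120 days by default, with durations drawn in a
realistic 2–6-week range and rescaled to the exact total by
largest-remainder rounding, and intakes of 1.2–3.2 kg/day spanning a
growing-finishing trajectory.

## Known limitations

* The LCA itself — inventory modeling, characterization, least-cost diet
  formulation — is out of scope; the package starts from LCIA values.
* The GSD map is an assignment, not a full Pedigree scoring from
  data-quality indicators; only the resulting GSDs are modeled.
* P5 values in the published table sit slightly off the closed form for
  some rows (a possible quantile-convention difference at the source);
  validation therefore leans on P95, the median and the probability.
* Sensitivity is strictly one-at-a-time; no variance-based (Sobol-style)
  decomposition is attempted, and GSD/ρ themselves are not perturbed.
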