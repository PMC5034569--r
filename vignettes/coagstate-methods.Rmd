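---
title: "Latent disease states in trauma coagulopathy: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent disease states in trauma coagulopathy: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coagstate)
```

## The problem

Severely injured trauma patients can become coagulopathic: their blood stops
clotting effectively, and mortality rises sharply. Clinically the condition
is tracked with a panel of ten blood measurements — the clotting-time assays
PT and PTT (seconds) and the activity levels of factors II, V, VII, VIII,
IX, X, antithrombin III and protein C (percent of normal). The panel is
drawn on a fixed schedule after admission, but intensive-care reality makes
the series short and full of holes: many analytes are skipped at attended
visits, and series end abruptly at death, discharge or drop-out.

`coagstate` models such a cohort with a hidden Markov model (HMM): each
patient occupies, at each 24 h step, one of `K` unobserved disease states;
the state evolves as a first-order Markov chain with initial distribution
$\pi$ and transition matrix $A$ (row = from, column = to), and the observed
10-vector $x_t$ is drawn from a state-specific multivariate Gaussian
$\mathcal N(\mu_k, \Sigma_k)$. The states are not labelled in advance —
they are whatever discrete structure the blood panel supports — and are read
off the fitted parameters afterwards.

## Preprocessing onto the 24 h grid

Raw visits occur at hours 0, 2, 3, 4, 6, 12, 24, 48, 72, 96 and 120. The
intermediate early hours are individually too sparse to model, so
`aggregate_timepoints()` averages hours 0–6 into the hour-0 slot and hours
12–24 into the hour-24 slot (per analyte, ignoring missing cells), giving at
most six equally spaced slots per patient. Patients with no observed analyte
in the first 24 h are removed by `filter_patients()`: they cannot anchor the
initial state.

Two kinds of absence are distinguished, and the distinction drives the whole
design:

* an analyte missing at an attended visit is **missing at random** (MAR) —
  the model integrates over it;
* a series ending early is **censoring** — the likelihood simply stops at
  the last attended slot `T`, and those slots enter no missingness
  accounting.

An interior slot with no observed analyte (data before and after, nothing at
the slot) is kept as an all-missing row whose emission term contributes a
factor of one; the state there is inferred purely through the transition
structure. This preserves the equal spacing the Markov chain needs.

## EM with missing observation components

The observed-data likelihood of a series sums over state paths and
integrates over missing components. Because emissions are Gaussian, both
operations are exact:

* the emission term of a partially observed row is the marginal Gaussian
  density of its observed sub-vector (`marginal_emission_loglik()`);
* the posterior of the missing sub-vector given the observed one is again
  Gaussian, with the regression mean
  $\mu_m + \Sigma_{mo}\Sigma_{oo}^{-1}(x_o - \mu_o)$ and the Schur
  complement covariance $\Sigma_{mm} - \Sigma_{mo}\Sigma_{oo}^{-1}
  \Sigma_{om}$ (`conditional_moments()`). This closed form is the contract;
  the classical sweep-operator recursion produces the same quantities and
  any implementation agreeing to $10^{-10}$ is conforming. We compute it
  with Cholesky factorizations of the observed block, which are stable for
  the well-conditioned 10-dimensional panels involved.

The E-step (`e_step()`) runs scaled forward–backward per patient to get the
smoothed state probabilities $\gamma$ and pairwise posteriors $\xi$, and
completes each row's first and second moments with the conditional moments
above. The M-step (`m_step()`) is then the standard closed form. On a fully
observed panel every completion is the identity and the algorithm reduces
exactly to complete-data Baum–Welch — a reduction the test suite checks
against an independent implementation, iterate for iterate.

Numerical choices:

* **Scaling.** Per-step normalizers rather than log-space recursions; at
  `T <= 6` both are exact to near machine precision, and scaling keeps the
  pairwise posteriors cheap.
* **Covariance ridge.** Every M-step adds `1e-6` times the mean diagonal to
  each $\Sigma_k$. With ~25 % of entries missing, a 10×10 covariance can
  otherwise drift to singularity late in a run.
* **Initialization.** Seeded k-means on mean-imputed rows gives the initial
  means; every state starts from the pooled covariance; $\pi$ and the rows
  of $A$ start near-uniform with a mild Dirichlet jitter (concentration 50)
  to break symmetry. The seed is recorded in the fit, and the same seed
  reproduces the fit bit for bit.
* **Convergence.** Relative log-likelihood change below `1e-6`, capped at
  500 iterations. A state whose posterior weight collapses raises a
  degenerate-state error rather than limping on; multi-restart selection
  logs and skips such runs.
* **Compiled core.** The per-iteration work is done in C++
  (RcppArmadillo), grouping rows by missingness pattern so each pattern's
  Cholesky factor and regression matrix is computed once per state. A pure-R
  path (`engine = "r"`) implements the identical contract and the tests
  assert agreement to $10^{-10}$.

Decoding uses log-space Viterbi (`viterbi()`), with ties broken toward the
lowest state index.

## Choosing the number of states

`select_model()` sweeps `K = 3..8`, fitting each `K` from `n_restarts`
seeded initializations (restart seeds are `base_seed + 1000 K + i`, recorded
in the output), and keeps the per-K best fit. Model size is scored by
$\mathrm{BIC} = -2\log p(X) + \mathrm{n\_params}\cdot\log(\mathrm{n\_data})$
with $\mathrm{n\_params} = (K-1) + K(K-1) + dK + K\,d(d+1)/2$. `n_data`
counts (patient, time) observation vectors, not patients: the likelihood is
a product over those vectors, and that is the granularity at which
information accrues. Ties go to the smaller `K`. The default of 10 restarts
keeps a desk-scale sweep in minutes; raising it (the reference analysis used
50) only sharpens the per-K minimum.

## State summaries

* `occupancy()` sums $\gamma_t$ over patients per slot — the expected
  number of patients per state per time, the standard occupancy display.
* `attribute_outcomes()` credits each death/discharge to the last decoded
  state when the series has at least two time points and the outcome falls
  within 120 h (5 days) of the last measurement. The 5-day window follows
  the slot spacing: with 24 h slots, a 24 h window would discard almost all
  outcomes. Single-point series are excluded because censoring dominates
  them. States with no contributors report `NA`, never a fabricated zero.
* `trajectory_frequencies()` collapses each decoded path to its distinct
  consecutive states, appends the outcome, and ranks the patterns.
* `forecast_states()` propagates the last smoothed state distribution
  through powers of $A$.
* `align_states()` resolves label switching against a reference
  parameterization by exact optimal assignment on emission-mean distances
  (exhaustive over permutations; `K <= 8`).

### The stage partition

Inspecting the fitted transition matrix of the reference 6-state model shows
a clear direction of flow: an unstable admission state, a block of
moderately persistent states, and highly persistent terminal states.
`stage_partition()` formalizes this. Transitions at or above a threshold
(default 0.04) form a directed graph; strongly connected components are
condensed to a DAG. Topology alone, however, cannot finish the job: a
moderately persistent state that happens to receive no above-threshold
inflow is topologically a source, yet it is not an admission state, and a
highly persistent state that still leaks into an absorbing one is not a
sink, yet it clearly belongs to the terminal block. The partition therefore
combines topology with persistence, which is how the stages are described
clinically in the first place:

* **late** — components grown back from the graph's sinks through
  components whose successors are all already late, requiring every member
  state to be highly persistent (`A[k,k] >= 0.9`);
* **early** — source components (no above-threshold inflow) whose member
  states are all transient (`A[k,k] < 0.5`);
* **intermediate** — everything else.

On the reference transition matrix this yields early = {S0},
intermediate = {S1, S2, S3}, late = {S4, S5}. All three cutoffs are
arguments; a thresholded graph with no edges returns a flagged degenerate
partition with a warning rather than an error, since an identity-like
transition matrix is a legitimate (if uninformative) fit.

## The synthetic cohort generator

No public release of the underlying trauma cohort exists, so validation is
closed-loop: `generator_config()` defaults encode the reference fitted
model — the printed initial distribution, transition matrix and
state-conditional means; sequence-length weights proportional to the
reported counts of patients with 1..6 consecutive slots
(588, 289, 42, 60, 2, 89); entry-level missingness of 25.3 %; and the
reported per-state death/discharge probabilities with outcome delays
uniform on 0–120 h so every simulated outcome falls inside the attribution
window (a wider range is available to exercise window exclusion). One
printed transition row sums to 0.999; the rounding deficit is absorbed into
the row's largest entry.

Two generator choices are declared stand-ins, not reported values:

* **Covariances** were never published. The default ground truth is
  diagonal, with each analyte's standard deviation set to 20 % of that
  analyte's between-state mean range — large enough that states overlap,
  small enough that they remain identifiable.
* **Masking** is independent per entry (MCAR), the simplest mechanism
  consistent with the MAR assumption the model needs; a `pt_dependent` mode
  makes the masking probability of the other analytes increase with the
  patient's PT, exercising genuinely MAR (observed-data-dependent)
  missingness. After masking, any patient left with nothing in the first
  24 h has one early entry unmasked so the generated cohort satisfies the
  inclusion rule by construction.

The reported cohort counts contain a small internal discrepancy: the
consecutive-run counts sum to 1070 patients and 2076 pairs while the totals
are quoted as 1090 and 2176, presumably due to non-consecutive observation
patterns not tabulated. The generator uses the tabulated consecutive-run
counts as printed and the package reports both figures where relevant; no
attempt is made to force agreement.

What the generator does **not** emulate: physiologic dynamics within a
state (observations are conditionally independent given the state),
informative missingness beyond the PT-dependent mode, non-Gaussian tails,
measurement rounding, or outcome-dependent censoring. Passing closed-loop
tests therefore demonstrates that the estimation machinery is correct and
well calibrated under the model's own assumptions — not that the model is
an adequate description of any particular real cohort.

## Problem sizes and what the checks show

The validation suite works at desk scale, chosen so each check is decisively
powered under the generator's conditions:

```{r, eval = FALSE}
cfg <- generator_config(seed = 1L)

# state-count selection: n = 1000 patients, K = 3..8, 10 restarts per K
study <- simulate_study(cfg, 1000)
select_model(study$panel, K_range = 3:8, n_restarts = 10, base_seed = 42)

# parameter recovery: n = 2000; initial/transition entries within 0.05,
# emission means within 5 % of each analyte's between-state range
st <- simulate_study(generator_config(seed = 303L), 2000)
fit <- fit_em(st$panel, K = 6, seed = 7)

# outcome attribution and missingness calibration: n = 5000
```

Smaller `n` leaves the BIC comparison between `K = 5`, `6`, `7`
under-resolved; larger `n` only slows the loop. Oracle checks (path
enumeration, quadrature marginalization, Schur closed forms, the
complete-data reduction) run on instances with `K <= 3`, `T <= 4`,
`d <= 3`, where brute force is exact.

## Known limitations

* A single shared $\pi$ is fit across patients regardless of admission
  acuity, matching the reference analysis.
* Transitions to death/discharge are not modelled as absorbing states; the
  transition matrix describes dynamics among the blood-panel states only,
  and outcome attribution is a separate post-hoc summary.
* No covariates, semi-Markov dwell times, continuous-time transitions or
  non-Gaussian emissions.
* BIC is the only selection criterion offered.
* EM finds local optima; the restart sweep mitigates but cannot guarantee
  global optimality.
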