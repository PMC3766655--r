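---
title: "Care vocabularies: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Care vocabularies: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carelex)
```

# The model

carelex analyzes medical practice as a language. Each paired observation
of a patient state and the contemporaneous practitioner response is
encoded as a word with two halves:

* a **derangement symbol**: each goal variable classified as below (0),
  within (1), or above (2) its goal range. Mechanical ventilation (MV)
  uses 4 variables (SpO2, pH, mean arterial pressure, plateau pressure);
  dialysis anemia management (HD) uses 6 codes (hemoglobin, ferritin, and
  iron-saturation states, ESA dose tertile, hemoglobin trend, and a binned
  distance of hemoglobin from its target range).
* an **intervention symbol**: for MV, the *direction* of change of every
  setting in the active mode (magnitude deliberately discarded), a
  fluid-bolus flag, or a mode switch; for HD, the categorical ESA action
  inferred from the month-over-month dose ratio, plus an iron action.

Words are counted into a vocabulary, ranked by frequency (ties broken
lexicographically so tables are deterministic), and fitted with the
Zipf-like law $f_i = \beta r_i^{-a}$ by ordinary least squares of
$\ln f_i$ on $\ln r_i$ — natural logarithms throughout, slope $-a$,
intercept $\ln\beta$. We report the Pearson correlation $r$ of the
log–log points and $R^2 = r^2$ (identical to the regression $R^2$ for
simple OLS). This is descriptive curve fitting in the tradition of
rank–frequency analysis, not maximum-likelihood tail estimation; no
hypothesis test of "power law vs. not" is attempted.

The null models ask how much of such structure is expected from
randomness punctuated by pauses. A typist strikes one of $N$ non-space
keys uniformly at random, or the space key with probability $q$; the
space ends a word. Then word length is geometric,
$P(L) = q(1-q)^L$; zero-length words are excluded and the law
renormalized, because the clinical analyses only consider patterns and
solutions of length $\ge 1$. All $N^L$ words of length $L$ share
probability $q((1-q)/N)^L$, so the rank–frequency curve is a staircase
whose large-rank log–log slope is $\ln(1-q)/\ln N - 1$; the
*random-text* variant treats the space bar as just another key,
$q = 1/(N+1)$, giving slope $-\ln(N+1)/\ln N$. Block tables store only
rank boundaries (exact integers, refusing to tabulate past $2^{53}$), so
the 1946-key clinical keyboard is handled without materializing $N^L$
words.

# Boundary conventions and numerical choices

* Goal inequalities are honored strictly as clinically written: SpO2 = 90
  with goal "> 90" codes *below*; plateau pressure = 30 with goal "< 30"
  codes *above*; iron saturation = 20 with goal "> 20" codes *below*.
  The hemoglobin band 10–12 g/dL is inclusive at both ends.
* The pH lower bound is disease-specific; the default is 7.30,
  overridable per patient via an optional `ph_lb` column.
* One-sided goals never emit their unbounded side; the ternary coding is
  uniform so a single code path serves both schemes.
* ESA dose-ratio bins follow the stated categories (start, stop,
  ±25–50%, ±>50%); ratios in (0.75, 1.25) are deliberately coded *none*,
  since the categories leave sub-threshold changes unassigned.
* Hemoglobin trend uses |Δ| ≤ 0.5 g/dL/month as *stable* (configurable);
  the distance-to-target bins are in-range, ≤ 1, ≤ 2, > 2 g/dL outside.
  Missing months are allowed; trends compare against the immediately
  preceding *available* month, and a patient's first month codes
  *stable* with a flag.
* Hemoglobin is treated as g/dL throughout (a 10–12 band is
  physiologically meaningless in g/L).
* Incomplete dyads (missing physiologic values or mode-required
  settings) are dropped at encoding time by `validate_dyads()`, which
  conserves row counts (clean + excluded = input); structural schema
  violations (wrong-mode settings present, non-monotone step indices,
  unparseable numbers) are instead rejected at read time with line
  numbers and reasons.
* A mode switch counts as an intervention-pattern length of 1 (one input
  changed — the mode) but is excluded from per-mode length tables, since
  it belongs to neither keyboard.
* The effective space frequency is estimated as
  completions / (interventions + completions), i.e. the frequency of the
  "space" event in the concatenated keystroke stream. The package's log
  schema carries one baseline row per patient, which pipelines exclude
  from intervention counts (`baseline_rows = 1`).
* Degenerate rank tables (all frequencies equal) return slope 0 with an
  explicit `degenerate` flag rather than an error; fits require at least
  two qualifying ranks.
* `fit_power_law(min_count=)` defaults to 1 — the fit uses *all*
  observed ranks. The option exists because the singleton tail of a
  small sample flattens the empirical curve; the per-group machinery
  exposes it unchanged.

# What the generators emulate — and what they do not

`gen_vent_sessions()` emulates multi-subject simulator sessions: 29
subjects by default, 100 virtual patients each (analyses typically keep
the last 25 per subject), one baseline row per patient, adjustment rows,
and a terminal completion/abandonment row. Derangement symbols are drawn
from a severity-weighted mix over the 24 feasible MV symbols (weight
0.5 per deranged variable — uncomplicated states are commoner than
multiply deranged ones); physiologic values are then drawn inside the
corresponding goal-range strata with margins, so encoding reproduces the
intended codes exactly. Emitted settings move multiplicatively in the
commanded direction (FiO2 contracts toward its physical range), so the
direction-only encoding round-trips exactly.

The practitioner policy is **conditional-Zipf over habitual
repertoires**: for each (derangement symbol, mode) a seeded preference
ordering over 12 recurring intervention patterns, shared by all
subjects, used with probability proportional to
$j^{-a}$ ($a$ = `policy_exponent`, default 0.95). Two properties follow:
the stream restricted to one (symbol, mode) is exactly Zipf($a$), and
the population stream is a Zipf mixture concentrated on few recurring
words. A calibration study on generated sessions at the default study
scale (29 subjects × 25 analyzed patients, ≈ 2 900 words) showed the
population OLS slope recovers the generating exponent closely over the
full table (`min_count = 1`), which is why the pipelines use that
default. Per-subject streams (~100 words each) flatten substantially —
an instructive finite-sample effect: a practitioner-level sample sees
only the head of the shared vocabulary, and estimated per-subject slopes
sit well above the generating exponent even though every subject uses
the identical policy. Passing tests on these data therefore demonstrate
estimator correctness and pipeline integrity at population scale, *not*
that per-practitioner slopes from ~100 dyads are unbiased estimates of
individual behavior.

Completion is Bernoulli per step by default (`p_complete_per_step`
= 0.2), making solution lengths geometric with mean 4 and the effective
space frequency ≈ 0.2 — the intermittent-silence model's own generating
process, useful as a self-consistency oracle. The
`solution_model = "powerlaw"` option draws solution lengths from a
discrete power law (a completion hazard decaying with step), emulating
goal-directed problem solving; its solution-length rank tables diverge
sharply from the intermittent-silence prediction fitted with the same
observed space frequency, which the tests assert on fixed seeds.

`gen_dialysis_records()` produces 30 patients × 36 months by default:
hemoglobin mean-reverts toward an equilibrium that rises with log ESA
dose (gain 1.0 g/dL per unit log-dose, monthly noise SD 0.5 g/dL — the
scale of real monthly hemoglobin variability), ferritin and iron
saturation respond to iron administration, and a stochastic prescriber
policy concentrated on a few habitual responses updates doses at exact
ratio midpoints (×1.3, ×1.7, ×0.7, ×0.4) so the realized doses encode
back to the intended action categories.

Neither generator models physiology mechanistically: there is no lung
mechanics, no erythropoiesis pharmacokinetics beyond the one-parameter
response, no inter-practitioner heterogeneity in MV policy, and no
dependence of the next derangement on the intervention just taken. Real
logs will violate all of these idealizations; the generators exist to
give every pipeline stage inputs with known ground truth.

# Observed-versus-null comparisons

`observed_vs_null()` compares an observed length rank table with a null
model's analytic length law on a common rank axis: the model's
probabilities are sorted in decreasing order, the observed shares are
zero beyond their own support, and the total variation distance is
computed exactly with the model's analytic tail included. The largest
absolute log share ratio is reported over the observed ranks. A stream
generated by the null model itself yields a small distance
(≈ sampling noise); a deterministic or strongly concentrated observed
distribution yields a distance approaching 1.

# Problem sizes

The test suite and the acceptance script run at deliberately modest
sizes, chosen so each check is decisive but quick: 10⁵ words for
Monte-Carlo/analytic agreement (binomial noise well below the asserted
bounds), 29 × 25 patients for end-to-end recovery (≈ 2 900 words, the
scale the analysis targets), 29 × 20 000 tokens for the per-group
recovery harness, block tables to 20 length blocks (4 for N = 1946,
the exact-integer capacity limit).

# Known limitations

* OLS on log–log rank–frequency is a biased estimator of tail exponents;
  it is used here because it is the estimator the analysis is defined
  with. A likelihood-based alternative is out of scope.
* The canonical word grammar is stable but scheme-specific; adding a new
  clinical domain means defining its symbol alphabet and grammar
  extension.
* ESA tertiles are population tertiles over the input dataset, so word
  identities are dataset-relative in the HD scheme.
* The typing null models assume equiprobable non-space keys; unequal key
  probabilities (letter-frequency/Mandelbrot refinements) are not
  implemented.
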