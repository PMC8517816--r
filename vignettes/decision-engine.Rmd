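---
title: "An expert-elicited Bayesian network for momentary mental-health advice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An expert-elicited Bayesian network for momentary mental-health advice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emibayes)
```

## Why an expert-elicited network

Clinical data fine-grained enough to answer questions like "how does a
patient three months after a suicide attempt, with a habitually low anxiety
level, answer a question about momentary anxiety?" do not exist. emibayes
therefore implements a decision engine whose every probability is elicited
from clinicians and organised as a discrete Bayesian network `B = [G, Θ]`:
the graph `G` links context → dimension states → questions and severities →
advice, and `Θ` is the set of conditional probability tables attached to
those links. Elicitation is supported by two helpers: per-100-subject count
tables (`counts_to_distribution()`, the form in which answer distributions
are naturally stated) and the roulette / chips-and-bins method
(`roulette_to_distribution()`).

Because the model is built rather than learned, validation is preclinical
and in silico: simulated patients with prescribed answer trajectories are
run through the engine, and the resulting belief and advice trajectories are
reviewed for clinical plausibility. The package treats that simulation
protocol as first-class, tested code.

## The update cycle

Each scoring triggers one pass per dimension, then one over the advice:

1. **Immediate value (IF).** Given IF, the answers to a dimension's
   questions are conditionally independent, so the posterior is a
   naive-Bayes product of the prior and one elicited likelihood column per
   answered question, renormalised (`if_posterior()`). Unanswered questions
   contribute no factor — a deliberate choice for partially filled sessions.
2. **Cumulated value (CF).** `cf_update()` applies
   `CF_new = (1 − α)·IF + α·CF_old` elementwise to the two distributions.
   The recurrence contracts exactly: ‖CF_new − IF‖₁ = α‖CF_old − IF‖₁.
3. **Contextual severity (CS).** `cs_infer()` marginalises the elicited
   `P(CS | IF, CF)` table over the current IF and CF distributions, treated
   as independent within the step; their coupling lives entirely in the CF
   recurrence. The table encodes habituation: the same immediate level is
   far more serious on top of a high cumulated level than on a calm history.
4. **Advice.** `advice_score()` evaluates the exact noisy-OR marginal
   `1 − (1 − leak)·Π_p E[1 − activation_p(CS_p)]`; `normalize_advice()`
   rescales the catalogue to relative scores (uniform, with a degeneracy
   flag, if every absolute score is zero — only reachable with all-zero
   activations).

Two design points were genuinely open and are resolved as follows:

- **The scoring-time prior is the current CF**, not the static context
  prior, which enters only at step 0. A habitually anxious patient and a
  calm one should interpret — and be interpreted through — the same answer
  differently, and the adaptive prior is what produces the progressive
  "mirror" of IF by CS over repeated scorings that the review exports are
  meant to show. The alternative (static prior every step) would make the
  IF posterior memoryless and the CS dynamics much slower.
- **CF is a distribution, not a scalar.** A scalar "mean percentage" reading
  of the cumulated value cannot index the discrete `P(CS | IF, CF)` table;
  applying the forgetting recurrence elementwise to the distribution vector
  preserves normalisation (any convex combination of distributions is a
  distribution) and keeps the severity inference well-defined.

Numeric policy: the naive-Bayes product is accumulated in log space; zero
likelihood cells are kept exactly zero (no smoothing), and evidence that
annihilates every level raises a typed `inconsistent_evidence` error rather
than being silently renormalised — with log-space accumulation, a genuine
all-`-Inf` log-posterior is distinguishable from underflow, which the
max-subtraction normalisation prevents. Advice ties are broken by descending
absolute score, then stable model order. Visual-analog scores are binned at
25/50/75 by default, overridable per question.

## The shipped knowledge base

`default_model()` loads `inst/extdata/default_model.yaml` (format
`ema-bn/1`, explicit level order absent < low < medium < high);
`build_default_model()` constructs the identical object in code, and a test
pins the two together. It contains 9 clinical dimensions, 23 questions and
10 pieces of advice, with forgetting factor α = 0.5.

Only the anxiety dimension is clinically elicited end to end: its three
question wordings and the answer table (per 100 subjects at each true
level), the context priors by age group and gender, the severity table —
including the canonical cells (IF = CF = high → CS high with 0.99; IF low on
CF high → 0.9; IF high on CF absent → 0.05) — and the call-friends
activation column (99/80/50 per 100 patients at high/medium/low severity).

The remaining eight dimensions reconcile the named symptom categories with
the nine-dimension structure by splitting cognitive retardation out of the
depression markers; this assignment is non-canonical and marked as such.
Their tables are **placeholders**: structurally valid, deterministic, and
not clinical ground truth. The recipe is fixed — each placeholder prior is
the equal-weight mix of the anxiety context prior and a per-dimension base
rate chosen once for plausibility; every question reuses the anxiety answer
table; every severity table reuses the shared `P(CS | IF, CF)`. Advice
parent sets and activation columns beyond call-friends are likewise
plausible placeholders, chosen so that emergency-type advice is driven by
suicidal ideation and anxiety while lifestyle advice (sleep hygiene,
physical activity, social rhythm) is not anxiety-dependent; mindfulness and
cardiac coherence share their anxiety activation and differ only through
cognitive retardation. Any clinical deployment must replace all placeholder
tables with elicited ones — `validate_model()` checks the structural
invariants (row normalisation to 1e-9, cross-reference integrity, monotone
activations, VAS threshold ordering) but cannot check clinical content.

**Forgetting factor.** α = 0.5 is the package default, configurable per
model and per run. It is calibrated to the design requirement that a
patient with a stable clinical state reaches a stable advice ranking within
three scorings (`convergence_steps()` measures this as the earliest step
from which the full ranking equals the final one); smaller α reacts faster
but forgets habituation, larger α resists acute worsening.

## The in silico protocol

`extreme_profiles()` produces the three distributions reviewed first: the
context prior, P(++) (all of a dimension's questions at the highest
severity) and P(−−) (all at the lowest). For every dimension of the default
model P(−−) ⪯ prior ⪯ P(++) in stochastic order — the elicited answer
tables have monotone likelihood ratios, so extreme evidence sharpens the
prior in the expected direction.

`scenario_spec()` + `run_scenario()` implement the 15-scoring worsening
protocols: nine scorings at the lowest severity, then either an immediate
jump to the highest answers (onset step 10, default) or a progressive ramp.
Two operationalisations deserve a note:

- **Ramp shape.** The progressive pattern ramps the true level linearly
  from onset to the final scoring, rounding *upward*
  (`ceiling(3·(t − onset)/(n − onset))`, levels 0,1,2,2,3,3 for the default
  geometry). Rounding to nearest holds the highest level for a single
  scoring, which leaves the cumulated value — and hence the terminal
  severity — visibly short of the immediate pattern's endpoint; with the
  upward ramp both patterns end within 0.05 of each other at step 15, as
  the same terminal evidence should.
- **Non-target dimensions** are left unanswered by default. This isolates
  cross-dimension advice effects exactly: a dimension that receives no
  evidence keeps its belief constant, so advice not parented by the target
  dimension keeps a constant absolute score (and a falling normalized score
  as target-driven advice rises) to machine precision. The alternative —
  feeding lowest-severity answers to every other dimension,
  `nontarget = "lowest"` — is available, but it makes non-target beliefs
  drift geometrically toward certainty-at-absent and the "constant absolute
  score" property then holds only approximately.

Deterministic extreme answers are the default (`answer_mode =
"deterministic_extreme"`); `"sampled"` draws answers from
`P(answer | IF = true level)` under the scenario seed, for population-style
replication — averaged over many seeded patients the sampled beliefs
approach the deterministic trajectory when the answer tables are nearly
degenerate. Seeded runs are reproducible end to end; the RNG state of the
calling session is restored after sequence generation.

`export_review_tables()` writes the expert-review artifacts: per-scoring
expected-severity scores with the review sign convention (IF positive, CS
negated), per-scoring absolute and normalized advice scores, and a full
JSON bundle. The accept-or-revise loop itself is a human process; the
package's contract ends at deterministic, re-exportable artifacts.

## Testing strategy

The enumeration oracle (`enumeration_oracle()`, `bn_from_model()`,
`noisy_or_cpt()`) computes posteriors by exhaustively summing the factorised
joint — after removing barren nodes and clamping evidence, both
posterior-preserving — and is used only in tests, as the independent
reference for the engine's closed forms on random small models (1–3
dimensions). `model_dimension()` reports the network's independent-parameter
count Σ(rᵢ−1)·qᵢ, checked against a brute-force enumeration of
parent configurations.

Problem sizes throughout the suite are desk-scale by design: random-model
oracle comparisons use up to three dimensions and two questions each (the
reduced joints stay under 10⁶ configurations), and the sampled-population
check uses a one-dimension model with 500 seeded patients, enough for the
Monte-Carlo error to sit well inside the 0.05 comparison band.

## Limitations

- Eight of nine dimensions, and nine of ten advice parameterisations, are
  structural placeholders; conclusions about clinical behaviour are
  supported only for the anxiety slice and the structure itself.
- The simulator prescribes answer trajectories; it does not model usage
  behaviour (missed sessions, dropout, response styles).
- Parameters are static: there is no learning from accumulated usage data.
- The noisy-OR assumption — parents contribute independently, severities
  independent across dimensions at a step — is an elicitation convenience,
  not a clinical claim.
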