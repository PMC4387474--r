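---
title: "Models and methods in igtmatch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in igtmatch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(igtmatch)
```

`igtmatch` simulates and analyses two decision-making tasks from an operant
standpoint: the four-deck Iowa Gambling Task (IGT) and a two-deck
concurrent-schedule card task in continuous time, scored with the
generalized matching law. This vignette documents the models, every tunable
default and why it has the value it has, the design decisions that were
genuinely open, and what the synthetic validation does and does not show.

## The IGT engine

The task is turn-based: on each trial the agent picks a deck, receives the
win and loss printed on that deck's next card, and the balance is updated.
Inter-trial timing, card colors and sounds are not modelled — no analysis
in the package consumes them.

**Payoff schedule.** The packaged `bechara_standard` schedule defines 40
cards per deck: decks A and B pay $100 per card and lose $250 net per 10
cards; decks C and D pay $50 and gain $250 net per 10 cards; A and C carry
five moderate losses per 10 cards, B and D a single large loss. The exact
card order within a decade is not part of any published table we reproduce;
the packaged ordering follows the conventional computerized implementation
and is stored as data (`inst/extdata/bechara_standard.csv`), so alternative
orderings are drop-in configuration, not code changes. When a deck is drawn
more than 40 times the schedule cycles: draw *k* reads card
`((k − 1) mod 40) + 1`. Draw counters are per deck and 1-based.

**Loan accounting.** A session opens with a $2000 stake counted as the
first loan. Whenever the balance falls below zero after a trial, further
$2000 loans are added until it is non-negative. The task's description of
the display being "reset appropriately" after a loan is ambiguous between
adding the loan to the (negative) balance and resetting the display to
zero; both are implemented (`loan_mode = "add"` is the default, `"reset"`
the alternative) because the additive reading preserves the exact
accounting identity `balance = 2000·loans + Σwins − Σlosses`, which the
test suite checks on random sessions.

**Determinism.** `run_igt_session()` seeds R's RNG once; a policy is a pure
function of the visible history plus that stream, so identical
`(policy, seed)` pairs give bit-identical logs. Agent policies therefore
recompute any internal state (e.g. deck expectancies) from the history on
every call rather than caching it.

## IGT analytics

**Proportional net score.** `(n_C + n_D − n_A − n_B) / n` over any trial
window, in [−1, 1]; multiplying by 100 recovers the classic absolute net
score of a 100-trial task. Being a mean, it is exactly additive across
equal-length epochs.

**Blocks.** All blockwise analyses use 20-trial blocks by default — the
granularity at which learning curves in this literature are plotted — and
reject logs whose length is not an exact multiple rather than silently
dropping a partial final block.

**Switching.** A trial is an eligible comparison if it has a predecessor;
the comparison that crosses a block boundary is attributed to the later
block, so block 1 has `block_size − 1` comparisons and later blocks
`block_size`. This keeps every block's proportion a true fraction of its
own comparisons.

**Preference labels.** The single-deck rule (proportion ≥ 0.50 and ≥ 0.25
above every other deck) is evaluated before the pair rule (sum ≥ 0.75,
absolute difference < 0.25): the pair rule exists for blocks with no single
dominant deck. Two decks cannot both satisfy the single rule (two
proportions ≥ 0.5 force equality, which fails the 0.25 margin), so the
label is well defined; an exactly 0.5/0.5 block falls through to the pair
rule and is labelled a pair. The margins use the inequalities exactly as
stated: ≥ for both single-deck thresholds and the pair sum, strict < for
the pair difference.

**Stability.** Behavior is stable when the same non-empty label holds for
`run_length = 3` consecutive blocks (60 trials). The reported
`first_stable_block` is the *last* block of the earliest qualifying run, so
"stable by 100 trials" means `first_stable_block ≤ 5`; binning of that
index into coarser summaries is left to the caller. The criterion locks
once met — later label changes do not revoke it — but the number of
post-stability blocks whose label differs is reported, since late
preference drift is a known blind spot of run-based criteria. Decision
classes: `good` if the stable preference involves only C and/or D,
`bad-deck` if it involves A or B, `poor` if the criterion is never met.

**Impairment.** Two published cut-offs on the proportional net score, both
strict: `net < 0.10` (the original patient-normed criterion) and
`net < 0.00` (the stricter zero criterion).

## The ACT simulator

Each of the four conditions varies exactly one dimension — reward
frequency, reward magnitude, penalty frequency, penalty magnitude — across
four components while holding the other three constant and equal on both
decks. The packaged configuration (`inst/extdata/act_table4.json`) stores
the arranged probabilities, mean amounts and variable-magnitude flags;
`build_condition()` converts probabilities to concrete event counts:

* varied frequency: 20 events split by the arranged probabilities
  (0.25/0.75 → 5/15, 0.35/0.65 → 7/13);
* varied magnitude: 10 events per deck at the printed means;
* the constant reward dimension in penalty conditions: 5 events per deck at
  $170; the constant penalty dimension in reward conditions: 5 per deck at
  $30.

These counts are forced by the requirement that every component's per-deck
net rewards equal the configured $100/$600, $200/$500, $500/$200, $600/$100
pattern, totalling $700 — an invariant `build_condition()` verifies at
construction time and the tests verify again on delivered events.

**Scheduling.** Rewards and penalties run on two independent streams. Each
stream has a single VI timer with exponential inter-arrangement intervals
(the constant-probability operant standard). When the timer elapses the
next event arms; it is assigned to a deck by sampling without replacement
from the scheduled per-deck counts (dependent scheduling), and the timer
halts until a press on the assigned deck collects the event. Dependent
scheduling guarantees that the obtained deck ratio equals the arranged
ratio on full delivery — and that an exclusive preference stalls the
stream, producing the timeout/missing-data mechanism that degrades
late-block estimates.

**VI mean.** The original task's interval parameters are not published in
the main text; the default mean is `0.6 · 480 s / (events in the stream)`,
sized so a stream's arrangements are expected to complete in roughly five
minutes of the eight-minute limit, leaving collection headroom for an
attentive responder. Because the sum of exponential intervals has heavy
tails, a small fraction of components (a few percent) time out even for
fully cooperative agents; the net-reward identity is therefore conditional
on full delivery, exactly as the task's own payout proviso was.

**Variable magnitudes.** Cells marked variable draw from the symmetric set
{mean − 20, mean − 10, mean, mean + 10, mean + 20} dollars. Within a
schedule the draws are a balanced shuffle (each member used equally often),
so per-deck delivered totals equal `count · mean` exactly and the printed
net rewards are preserved on full delivery; `sample_magnitude()` offers the
plain uniform draw for uses outside a schedule. A changeover delay is not
imposed (none is described for the task), and display-side deceptions
(random offsets added to the shown winnings) are not part of the event log.

## The matching-law estimator

Blocks are delimited by every 4th delivered event of the condition's
*varied* stream — rewards in conditions 1–2, penalties in 3–4 — because the
constant dimensions carry no information about the manipulated ratio. With
20 varied events a component offers 5 blocks. For each block and component:

* the response ratio uses all presses between the previous block's closing
  event and this block's closing event;
* the reinforcer ratio uses all varied-stream events from component start
  to the block's end — counts in frequency conditions, delivered amounts in
  magnitude conditions;
* in penalty conditions the reinforcer ratio is inverted (deck 2 over
  deck 1), the operant convention for aversive schedules: responding away
  from the penalty-rich deck then yields positive sensitivity.

Logarithms are base 10 (the field's convention; the slope is
base-invariant, the intercept is reported in the chosen base). A point with
a zero anywhere in either ratio is flagged invalid and excluded from the
fit but counted, never silently dropped, and no continuity correction is
applied by default — missingness is information here. `fit_gml()` is
ordinary least squares across the four components' points; with fewer than
two valid points, or no spread in the reinforcer ratio (possible in
frequency conditions, where early-block count ratios can coincide across
components), it returns a flagged-undefined estimate with a reason code
rather than throwing, so cohort pipelines survive pathological sessions.

**Stable sensitivity** averages the per-block estimates over the final two
blocks in condition 1 and the final three in conditions 2–4 — the windows
in which group learning curves in this paradigm have levelled out —
skipping undefined blocks and reporting how many contributed.

## Synthetic agents

The tasks themselves prescribe no generative model of participants; the
agents are the simplest mechanisms that produce the documented
phenomenology, and all of their mechanics are visible parameters.

**IGT agents** are delta-rule/softmax learners: the chosen deck's
expectancy moves by `α (win − λ·loss − V)` and choice is softmax with
inverse temperature `β`, mixed with an exploration floor `ε`. Defaults
(α = 0.2, β = 0.25 per dollar, λ = 1, ε = 0.05) give learners that
stabilize on good decks within 200 trials at heterogeneous speeds when α is
drawn from a range. Archetypes are stored as data: `late-learner`
(α = 0.03), `non-learner` (α ≈ 0, high ε — statistically indistinguishable
from random choice, hence essentially never stable), `random` (β = 0),
`perseverative` (stays on its first deck), and a deterministic `ideal`
agent that cycles all decks for 40 trials and then alternates C and D,
giving a net score of exactly 1 from trial 41 (or over the whole session
when restricted to the good decks).

**ACT agents** press at `press_rate` presses/s (exponential inter-press
times) and allocate each press by the matching law applied to their own
running estimate of the obtained varied-stream ratio over the last
`estimate_window` events, inverted for penalties; before any event the
split is 50/50, and a side with zero events is regularized by half an
event-equivalent. Defaults: `press_rate = 2` — the task affords rapid
low-effort key presses (its card-flip feedback lasts 200 ms), and two
presses per second also gives each block enough responses (~100 per
component) for the blockwise response ratio to be a stable quantity;
`estimate_window = 20` spans a component's full varied-event budget, so the
agent's estimate converges on the same cumulative obtained ratio the
estimator conditions on.

**What the generator emulates** — gradual learning, heterogeneous
stabilization times, non-learners, matching allocation with fixed
sensitivity and bias, rising blockwise sensitivity curves, and
timeout-induced missing data under exclusive preference. **What it does
not** — win-stay/lose-shift heuristics, explicit strategy or instruction
effects, engagement loss over a session, inter-task correlations beyond the
configurable linkage in `run_study()`, and any claim of matching human
group means. Passing recovery tests therefore validates the estimator and
the simulator against each other, not the agents against people.

## Numerical and validation choices

* Proportions that must sum to 1 are checked to 1e−9; estimator oracles
  (closed-form regression, exact lines) are asserted to 1e−9 or tighter;
  exact identities (accounting, counts, additivity) are asserted exactly.
* Parameter recovery: matching agents with sensitivity a ∈ {0.3, 0.8, 1.3},
  50 seeded sessions per condition, must recover the median stable
  sensitivity within ±0.15 per (a, condition) cell; pooled across cells, at
  least 80% of individual sessions land inside that tolerance. The pooled
  reading is deliberate: per-seed spread necessarily grows with a itself,
  because the blockwise response ratio reflects the agent's evolving
  within-block estimate while the reinforcer ratio is taken at block end.
* Learning curves: grouping the a = 0.8 sessions into cohorts of five, the
  cohort-mean blockwise sensitivity must rise (positive Spearman
  correlation with block) in at least 95% of cohorts.
* Problem sizes throughout the suite (50 seeds per recovery cell, 1000
  random sequences for the stability oracle, 300 random group pairs for the
  U-statistic oracle, cohorts of 30–50 for envelope checks) were chosen so
  each stochastic check has comfortable statistical margin at a fixed seed.

## Known limitations

* The stability criterion locks at first attainment; late preference
  changes are reported but not re-adjudicated.
* The exact 40-card orderings, the original task's VI parameters and the
  magnitude sets behind the "variable" cells are conventional
  reconstructions constrained by the published totals, not transcriptions
  of unpublished materials.
* Each ACT condition is fitted on its varied dimension alone; combined
  reward–penalty matching models are out of scope.
* The Mann–Whitney effect size is reported as r = Z/√N with the sign
  convention that group A exceeding group B gives negative r, matching the
  reporting convention of the cross-task comparison this package mirrors.
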