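# igtmatch

Operant analysis of Iowa Gambling Task performance and matching-law
sensitivity estimation, with synthetic agents for end-to-end validation.

## The problem

The Iowa Gambling Task (IGT) is the de-facto standard laboratory test of
affective decision making: participants repeatedly choose among four card
decks whose rewards and penalties are arranged so that the decks with large
wins ($100) lose money in the long run while the decks with small wins ($50)
gain. Performance is usually scored by the *net score* — choices from the
good decks (C, D) minus choices from the bad decks (A, B) — yet healthy
participants show striking variability on it, and standard cut-offs classify
many of them as impaired. Two factors confound the interpretation:
individual differences in *learning rate* (a slow learner's score over a
fixed 100 trials looks like a deficit) and the absence of any direct measure
of *sensitivity* to the frequency and magnitude of rewards and punishers.

`igtmatch` implements the computational core of an operant re-analysis of
this problem, for behavioral scientists who want to simulate, score, and
validate such designs without human data:

* a deterministic **IGT engine** (standard 40-card four-deck payoff
  schedule, cycling after 40 draws; 200-trial sessions; $2000 loan
  accounting) driven by pluggable agent policies;
* **operant-style IGT analytics**: proportional net scores per epoch,
  20-trial-block deck-preference and switching profiles, impairment
  classification (net < 0.10 and net < 0.00 criteria), and a *stability
  criterion* — a single deck is preferred when its block proportion is at
  least 0.50 and leads every other deck by at least 0.25; a deck pair when
  the two sum to at least 0.75 and differ by less than 0.25; behavior is
  stable when the same preference holds for three consecutive blocks;
* an **Auckland Card Task (ACT) simulator**: a two-deck concurrent
  variable-interval (VI) schedule task in continuous time, with independent
  reward and penalty streams, dependent (Stubbs–Pliskoff) scheduling, four
  conditions varying one dimension each (reward frequency, reward
  magnitude, penalty frequency, penalty magnitude) over four components
  with arranged ratios from 1:3 to 3:1, an 8-minute component time limit,
  and exact net-reward bookkeeping ($700 per fully delivered component);
* a **generalized-matching-law estimator**. The model, in the field's
  standard notation:

  log10(B1/B2) = a · log10(R1/R2) + log c

  where B1/B2 is the response (key-press) ratio, R1/R2 the obtained
  reinforcer ratio, the slope *a* is **sensitivity** and the intercept
  log c the **bias**. Ratios are formed blockwise (every 4th delivered
  event of the varied stream closes a block), responses counted within the
  block, reinforcers cumulated from component start to block end; the fit
  is ordinary least squares across the four components. Undefined ratios
  (a deck with zero presses or zero events) are flagged missing, never
  silently corrected;
* **synthetic agents**: delta-rule/softmax IGT learners (with archetypes:
  ideal, random, perseverative, late-learner, non-learner) and
  matching-law ACT responders with known sensitivity and bias — the ground
  truth for parameter-recovery validation;
* **cross-task reporting**: good vs. persistent-poor decision-maker
  classification, Mann–Whitney U tests with rank-biserial effect size
  r = Z/√N, and a deterministic CSV/JSON report bundle.

## Worked example

```r
library(igtmatch)

## IGT: simulate a learner and analyze its trajectory
agent <- igt_agent(learning_rate = 0.25, inverse_temperature = 0.3)
log   <- run_igt_session(agent, n_trials = 200, seed = 42)
log
#> IGT trial log: participant sim, 200 trials, final balance $6250
#>   deck counts: A=9 B=9 C=162 D=20
#>   loans taken: 1 ($2000 total)
net_score(log, c(1, 100));  net_score(log, c(101, 200))
#> [1] 0.64
#> [1] 1
stability_analysis(log)
#> Stability: 'C' stable by block 6 (class: good)
```

The agent chose good decks on 82% of the first 100 trials (net 0.64),
reached the stability criterion in block 6 (trials 101–120), and was
exclusively on good decks thereafter (net 1.0).

```r
## ACT: estimate sensitivity to reward magnitude for a matching agent
act  <- act_agent(sensitivity = 0.8)
sess <- run_act_session(act, condition_id = 2, seed = 42)
est  <- session_sensitivity(sess)
attr(est, "block_fits")[[5]]
#> GML fit (block 5): sensitivity 0.572, log bias 0.006 (R^2 0.986, n=4)
est$sensitivity
#> [1] 0.7341796
```

The block-5 fit regresses the four components' log response ratios on their
log obtained-amount ratios; the stable estimate (mean of the last three
blocks in condition 2) recovers the agent's programmed sensitivity of 0.8
to within ordinary sampling error.

```r
## Cross-task: compare good vs poor IGT performers on ACT sensitivity
study <- run_study(n_participants = 10, seed = 42)
study$tests$penalty_magnitude
#> Mann-Whitney U = 0, p = 0.01667 (exact), r = -0.757 (n = 7 vs 3)
```

Seven of the ten synthetic participants mastered the IGT, three never
stabilized; the negative r says the good decision makers had the higher
penalty-magnitude sensitivities (by construction of this demo cohort).

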