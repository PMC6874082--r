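---
title: "Simulating and analysing a social-information estimation task"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analysing a social-information estimation task}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(beastsim)
```

## The task and its measurement model

`beastsim` simulates an incentivised numerosity-estimation experiment in
the BEAST (Berlin Estimate AdjuStment Task) family. In each round a
participant sees an image with a true count of 50–60 animals for six
seconds and types a first estimate $E_1$. They are then shown the estimate
$X$ of another person — in one five-round block an unfamiliar peer
student, in the other an adult; block order is counterbalanced — and type
a second estimate $E_2$. Social information use in a round is the fraction
of the distance toward $X$ the revision covers,

$$ s = \frac{E_2 - E_1}{X - E_1}, $$

and a participant's weight on a source is the mean $S$ of $s$ over the
valid rounds of a condition ($S_{peer}$, $S_{adult}$). The predicted
second estimate under a weight $S$ is the convex combination
$(1-S)E_1 + S X$. Rounds in which the participant moves away from the
information ($s<0$, "contrarian") or beyond it ($s>1$, "overshoot") are
not weighted averages of the two estimates; the default `omit` policy
drops them, with `include` and `clip` (replace $s$ by the nearest value in
$[0,1]$) available as robustness variants.

The experiment controls how far social information sits from the first
estimate. After $E_1$ is entered, a target value is computed as
$X' = E_1(1+\Delta)$ if $E_1$ is below the true count and
$X' = E_1(1-\Delta)$ if above (a fair coin decides the direction when
$E_1$ is exactly correct), with the round-wise schedule
$\Delta = (0.25, 0.15, 0.20, 0.15, 0.25)$. The value actually displayed is
the entry of a pre-recorded estimate bank closest to $X'$. The bank is
built from 24 adults and 14 students who completed the task without social
information, each going through six iterations of the five rounds — 144
adult and 84 student estimates per round. Payoffs are 100 points for an
exact estimate minus 5 points per animal of error, floored at 0; every
completed 20 points converts to one bonus item on top of two
participation items.

Two engine-level choices are not fixed by the task description and are
made here explicitly. First, bank candidates equal to $E_1$ are excluded
before the nearest-value search, so that $s$ is always defined; $X'$
itself is always at least 15% away from $E_1$, but a bank entry could
coincide with it. Second, exact nearest-value ties are broken by a seeded
uniform draw, which is unbiased and reproducible. $X'$ is kept as a real
number throughout; only the bank snap produces an integer, which makes any
rounding convention for $X'$ moot.

## The synthetic cohort and its calibration

No raw data from the original study are available, so the package ships a
generative stand-in whose *observable summaries* are pinned to the
study's reported behaviour. Each agent produces

* **first estimates** $E_1 = \max(1, \mathrm{round}(T e^{z}))$ with
  $z \sim N(\mu, \sigma)$, $\sigma = 0.15$ and
  $\mu = \log 0.9 - \sigma^2/2$, so that $E[E_1/T] = 0.90$ — the typical
  ~10% underestimation of such tasks. The dispersion is a calibration
  choice; only the mean bias is reported for the original sample.
* **second estimates** by drawing an adjustment heuristic per round:
  *stay* ($s^*=0$), *copy* ($s^*=1$), *contrarian* (fixed $s^*=-0.2$),
  *overshoot* (fixed $s^*=1.2$), or *compromise* with $s^*$ from a Beta
  law on $(0,1)$, then $E_2 = \mathrm{round}(E_1 + s^*(X-E_1))$ clamped to
  $\ge 1$. Contrarian and overshoot magnitudes are constants rather than
  draws because those rounds are discarded by the default filter — only
  their rates matter.

The default mixture is calibrated in closed form, not by search. With
per-condition stay/copy probabilities $(0.285, 0.165)$ for peer and
$(0.255, 0.195)$ for adult, contrarian/overshoot rates $0.022/0.056$ in
both conditions, and a compromise Beta with mean $0.504$ and precision 5
(shape $2.52, 2.48$) shifted by $+0.0107$ in the adult condition, the
expected filtered mean is

$$ E[S \mid 0 \le s \le 1] \;=\;
   \frac{p_{copy} + p_{comp}\,\mu_{comp}}{p_{stay}+p_{copy}+p_{comp}}
   \;=\; 0.4370 \ (\text{peer}), \quad 0.4750 \ (\text{adult}), $$

matching the study's reported 43.7% and 47.5% condition means, while the
pooled stay/copy rates are 27%/18% and the invalid rates 2.2%/5.6%.
`expected_adjustment()` exposes this closed form; the recovery harness
uses it as the truth that the pipeline must recover. The condition effect
is deliberately decomposed into a stay→copy probability swap *plus* a
small compromise-mean shift: a single additive shift of the mean could
not reproduce the observed pattern of more stays under peer and more
copies under adult sources, which the round-level logistic models test.
`household_shift` defaults to 0 — the null household effect — and is the
dial the calibration harness exercises for type-I error.

```{r}
p <- agent_params()
p
```

The demographic generator emits exact margins (deterministic counts,
randomised cross-tabulation): 148 extended- and 108 nuclear-household
adolescents, two schools (149/107), genders 125/131, integer ages 11–15
from a discretised normal targeting mean 13.38, sd 0.88. These are the
study's 256 analysable participants; its 264 *recruited* adolescents
included 8 without household information whose school and gender are not
reported, so the default cohort scales the school and gender margins
proportionally onto 256 rather than inventing the dropped participants.
Block order alternates by enrolment index — a deterministic
counterbalance. Ages drive nothing behaviourally; `cohabiting_aunts_uncles`
is recorded only so household coding can be redefined in robustness
analyses.

What the generator does *not* emulate is worth keeping in mind when
reading green tests: there is no between-participant heterogeneity in the
mixture weights (so participant-level random-effect variances are
essentially zero and singular mixed-model fits are expected and
tolerated), no age or gender effects, no learning or fatigue across
rounds, and no response-time structure. Passing recovery tests show the
measurement and inference chain is faithful, not that real adolescents
behave like the mixture.

## A worked run

```{r}
schedule <- make_stimulus_schedule(seed = 11)
bank <- build_bank(schedule, seed = 12)
bank_counts(bank, 1)

trials <- simulate_experiment(cohort_config(), bank, seed = 13)
adjust <- compute_adjustments(trials, policy = "omit")
summaries <- participant_summaries(adjust)
paired_test(summaries)
```

```{r}
heuristic_frequencies(adjust, pooling = "all_rounds")
```

The condition-level linear mixed model regresses the (at most two) $S$
values per participant on source type (peer = 0, adult = 1), household
type (nuclear = 0, extended = 1), their interaction, gender
(male = 0, female = 1) and age, with random intercepts for participant
nested in school:

```{r}
fit_adjustment_lmm(summaries, cohort_profiles(trials))
```

Round-level logistic mixed models with the same structure test stay
($s=0$) and copy ($s=1$) decisions, and an accuracy model regresses
deviations from the true count on estimate period (first vs second) with
period nested in participant nested in school:

```{r, eval = FALSE}
fit_stay_glmm(adjust, cohort_profiles(trials))
fit_copy_glmm(adjust, cohort_profiles(trials))
fit_accuracy_lmm(deviation_table(trials))
```

## Numerical and inferential choices

* **Exact category boundaries.** $s$ is a ratio of integer differences,
  so `s == 0` and `s == 1` are exact in floating point; classification
  uses no epsilon. Integer rounding of $E_2$ can relabel a compromise
  drawn very close to 0 or 1 as a stay or copy when $|X-E_1|$ is small —
  realistic measurement coarseness that leaves the filtered mean
  essentially unchanged (rounding error is symmetric) and cannot push a
  valid round outside $[0,1]$.
* **Wald inference.** Coefficient p-values use the normal approximation
  for both LMMs (on the REML $t$) and GLMMs (on $z$). Exact agreement
  with any particular df correction is not claimed; signs, magnitudes and
  calibration are what the harness checks.
* **Two schools.** The school variance component is weakly identified
  with two levels; the default keeps the nested structure and tolerates a
  singular fit (flagged, and reported as a zero variance), with
  `drop_school = TRUE` available.
* **Stay/copy denominators.** The logistic models default to rounds with
  $0 \le s \le 1$ (the filtered set), with `rounds = "all"` as a switch;
  the heuristic-frequency table likewise exposes both `all_rounds` and
  `valid_rounds` denominators, because published percentage breakdowns of
  this task are ambiguous about the denominator.
* **Degenerate inputs** (constant outcomes, single participants,
  zero-variance differences) return flagged results — `degenerate`,
  `converged = FALSE` — rather than errors, so replicate harness runs
  never abort.
* **Seeds.** Every entry point takes a seed; a master seed spawns
  labelled child seeds (`spawn_seeds()`) for schedule, bank, cohort,
  sessions and harness, so stages can be re-run independently and a
  `(config, seed)` pair reproduces every artifact byte-for-byte.

## Validation by parameter recovery

`recovery_harness()` simulates replicate experiments end to end and
compares what the analysis chain recovers against the analytic mixture
expectations: bias and RMSE of the recovered $S_{peer}$ and $S_{adult}$
cohort means, realised contrarian/overshoot rates, and rejection rates of
the paired test and of the mixed model's source-type and interaction
terms — power where the generator encodes an effect, type-I error where
it encodes none (the interaction, under the default
`household_shift = 0`).

```{r, eval = FALSE}
rec <- recovery_harness(cohort_config(), n_replicates = 50, seed = 101,
                        models = character(0))
rec
```

The shipped test suite runs this at the study's size (50 replicates of
the 256-participant cohort) for the mean-recovery and rate checks, and a
500-replicate null-calibration check of the interaction at a reduced
cohort of 80 participants — sizes chosen so the whole suite stays quick
while the binomial band around the nominal 5% level is tight enough to be
informative. The command-line layer (`beast_cli()`; subcommands `bank`,
`simulate`, `analyze`, `recover`) drives the same functions from a shell
and logs seeds and a config hash with every artifact.

## Limitations

The package analyses data it simulates; nothing here estimates the
heuristic mixture from real data. Reproducing the original study's exact
coefficient table is out of reach by construction (its raw data are not
public) and is not attempted: the package's claim is that, under a
generator calibrated to the study's printed summaries, the full
measurement and inference chain recovers those summaries and is
statistically calibrated.
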