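# beastsim

Simulation and inference for a social-information estimation task in the
BEAST (Berlin Estimate AdjuStment Task) family: participants estimate how
many animals an image shows, see the estimate of another person — a peer
student or an adult — and estimate again. The package is aimed at
behavioural scientists who want a fully reproducible, testable version of
this paradigm: a task engine that serves controlled social information, a
synthetic adolescent cohort that responds through an explicit
heuristic-mixture model, the complete measurement and inference chain,
and a parameter-recovery harness that validates the pipeline against its
own generative truth.

## The measurement model

Social information use in a round is the adjustment

    s = (E2 - E1) / (X - E1)

where `E1` and `E2` are the first and second estimates and `X` the
displayed social information. Per condition, a participant's weight on a
source is `S`, the mean of `s` over valid rounds (`S_peer`, `S_adult`);
rounds with `s < 0` (contrarian) or `s > 1` (overshoot) are omitted by
default, with `include` and `clip` policies as robustness variants.
Displayed information is controlled: a target `X' = E1 * (1 ± Δ)` points
toward the true count with round-wise `Δ = (0.25, 0.15, 0.20, 0.15,
0.25)`, and the value shown is the nearest entry of a pre-recorded
estimate bank (144 adult and 84 student estimates per round, from 24 + 14
members × 6 iterations). Estimates earn `max(0, 100 - 5 |error|)` points.

Inference mirrors the paradigm's standard analysis: a paired t-test of
`S_peer` vs `S_adult`, a linear mixed model of condition-level `S` on
source type × household type + gender + age with participant nested in
school (lme4), logistic mixed models of round-level stay/copy decisions,
and an accuracy mixed model of deviations from the truth on estimate
period.

## Worked example

```r
library(beastsim)

schedule <- make_stimulus_schedule(seed = 11)
bank     <- build_bank(schedule, seed = 12)          # 144 + 84 per round
trials   <- simulate_experiment(cohort_config(), bank, seed = 13)

adjust    <- compute_adjustments(trials, policy = "omit")
summaries <- participant_summaries(adjust)
paired_test(summaries)
#> Paired t-test, S_adult vs S_peer: t = 2.337, d.f. = 255, P = 0.02021
#>   mean S_peer = 0.4347, mean S_adult = 0.4729, Cohen's d = 0.146 (n = 256 pairs)
```

The simulated cohort weights adult-sourced information (mean adjustment
~47%) above peer-sourced information (~43%), and the paired test detects
the difference — the behaviour the default generator is calibrated to
produce. The condition-level mixed model tells the same story in
regression form:

```r
fit_adjustment_lmm(summaries, cohort_profiles(trials))
#> <model fit: adjustment_lmm>  n = 512, N = 256 [singular]
#>                        term  estimate std_error statistic   p_value
#> 1               (Intercept)  0.486569  0.111945   4.34652 1.383e-05
#> 2                model_type  0.039863  0.024023   1.65940 9.704e-02
#> ...
```

(`model_type` is the peer = 0 / adult = 1 contrast; the singular flag is
expected — synthetic agents share one mixture, so the participant-level
variance is genuinely zero.) A command-line layer wraps the same
pipeline:

```sh
Rscript inst/scripts/beast_pipeline.R bank     --config cfg.yaml --out bank.csv
Rscript inst/scripts/beast_pipeline.R simulate --config cfg.yaml --bank bank.csv --out trials.csv
Rscript inst/scripts/beast_pipeline.R analyze  --in trials.csv --participants participants.csv --out results.json
Rscript inst/scripts/beast_pipeline.R recover  --config cfg.yaml --out report.json
```

See `vignettes/beast-pipeline.Rmd` for the generative model, its
closed-form calibration, and the design decisions.

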