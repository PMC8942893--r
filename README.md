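# libetbind

Analysis tools for **temporal (intentional) binding** experiments run with
the rotating **Libet clock** — the paradigm in which participants timestamp
their own key-presses and the tones those key-presses cause by reading a
position off a rotating clock face. Binding is the signature compression of
subjective time around voluntary action: relative to single-event
baselines, actions are reported *later* (positive action binding) and
caused tones *earlier* (negative tone binding). It is the standard implicit
measure of the sense of agency, and it is sensitive to stimulus parameters
such as the clock's rotation speed, which makes a reproducible,
parameter-aware analysis pipeline worth having.

The package is aimed at researchers analysing Libet-clock trial logs (or
planning such experiments via simulation) and covers the full chain:

* **Clock geometry** — reported positions ↔ event times with circular
  wrap-around: error = reported − actual, reduced to (−T/2, T/2] for
  period T; negative = anticipatory.
* **Binding scores** — per participant × condition, action binding
  = mean(operant action error) − mean(baseline action error), tone binding
  likewise; single-pass M ± 2.5 SD trial trimming per cell; deterministic
  group-level participant screening (Tukey fences gated by group
  skewness/kurtosis).
* **Inference** — within-subject ANOVA on participant cell means with
  Mauchly's test and the Greenhouse–Geisser correction, partial
  η²ₚ = F·df₁/(F·df₁ + df₂), Bonferroni pairwise contrasts, Cousineau
  within-subject CIs (optional Morey factor).
* **Directional Bayes factors** — Dienes half-normal BFs,
  BF = ∫₀^∞ N(M; θ, SE)·2N(θ; 0, s) dθ / N(M; 0, SE), with a *prior
  ledger* that derives the half-normal scales s from a donor experiment's
  binding effects (three pairwise omnibus speed effects plus the
  extreme-speed tone effect).
* **Synthetic data** — a generative simulator whose defaults encode
  published block-level summaries of five clock-parameter experiments,
  used for type-I calibration, power, and parameter-recovery checks.

## Worked example

Simulate a clock-speed replication experiment at its published parameters
(40 participants × 3 speeds × 4 blocks × 30 trials), analyse it, and test
the speed effects against priors derived from the original experiment:

```r
library(libetbind)

params <- generative_params(reference_block_summaries(2))
trials <- simulate_trials(params, seed = 42)
report <- run_analysis(
  trials,
  donor_summary = shift_from_block_means(reference_block_summaries(1))
)
print(report)
```

```
<binding_report>
  40 participant(s), 3 condition(s)
  summary table (ms):
  condition  event baseline_mean baseline_sd operant_mean operant_sd shift_mean
 speed_1280 action        -30.26       56.03        -1.50      62.41      28.76
 speed_1280   tone        -31.02       53.92      -106.93     123.41     -75.91
 speed_2560 action        -42.22       76.85       -16.30      68.54      25.92
 speed_2560   tone        -39.48       56.39      -114.79     134.81     -75.31
 speed_5120 action         -0.87       80.20        17.28      98.19      18.15
 speed_5120   tone        -24.96       65.00       -61.71     153.03     -36.75
 ...
Repeated-measures ANOVA (participant-level cell means)
          effect df_effect df_error      F         p partial_eta_sq ...
       condition         2       78  2.209 1.167e-01        0.05359
           event         1       39 42.400 1.011e-07        0.52090
 condition:event         2       78  5.703 4.881e-03        0.12760
  Bayes factors:
                              label      type prior_sd      M    SE      bf     verdict
   omnibus speed_1280 vs speed_2560   omnibus    23.47  3.439 15.96  0.6521 insensitive
   omnibus speed_2560 vs speed_5120   omnibus     8.84 46.330 16.10  4.1940 supports_H1
   omnibus speed_1280 vs speed_5120   omnibus    32.31 49.770 17.29 23.5300 supports_H1
 tone-only speed_1280 vs speed_5120 tone_only    30.90 39.160 14.85 14.4800 supports_H1
```

Reading it: every condition shows the binding signature (positive action
shifts ~20–30 ms, negative tone shifts), tone binding weakens at the slow
5120 ms speed, the condition × event interaction is significant
(F(2, 78) = 5.70, p = .005), and the half-normal Bayes factors — whose
prior scales (23.47, 8.84, 32.31, 30.90 ms) are derived arithmetically
from the donor experiment's shift table — support a speed effect driven by
the extreme-speed tone contrast. `write_report_bundle(report, "out/")`
exports the tables as CSV plus a full-precision `report.json`.

The standalone calculator reproduces a published replication BF from its
printed summary statistics (M = |−79.91 − (−31.80)| = 48.11 ms,
SE = M/√F with F(1, 39) = 10.18, prior SD 30.9 ms):

```r
dienes_bf(48.11, 48.11 / sqrt(10.18), 30.9)
#> BF[0, 30.9] = 53.4 (supports_H1)
#>   M = 48.11 ms, SE = 15.08 ms; prior: explicit
```

A thin command-line front-end with `simulate`, `analyze`, `bf` and
`recover` subcommands ships in `inst/cli/libetbind.R`.

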