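---
title: "Methods: temporal binding from Libet-clock trial logs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: temporal binding from Libet-clock trial logs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(libetbind)
```

# The measurement problem

Temporal (intentional) binding is the subjective compression of the interval
between a voluntary action and its outcome: relative to single-event
baselines, actions are reported later and their outcomes earlier. The
classic measurement instrument is the Libet clock — a rotating marker whose
face position the participant reads off at the moment of the judged event.
A binding experiment crosses four block types (baseline action, operant
action, baseline tone, operant tone; in operant blocks a key-press causes a
tone 250 ms later) with one or more stimulus-parameter conditions, such as
rotation period (1280 / 2560 / 5120 ms per revolution), marking scheme, or
hand length.

`libetbind` implements the complete analysis chain from trial-level clock
reports to inferential summaries, and a generative simulator of such
experiments. This vignette documents the model at each stage, the tunable
parameters and their defaults, the numerical choices, and what the
simulation-based checks do and do not establish.

# From clock reports to judgment errors

A reported position $u \in [0, 60)$ clock units maps linearly to a phase
time $u \cdot T / 60$ ms, where $T$ is the rotation period. The signed
judgment error is the circular difference between reported phase and true
event time, reduced to the symmetric representative interval
$(-T/2, \, T/2]$; a boundary tie goes to the positive side. Negative errors
are anticipatory reports. Two choices deserve note:

* **Fractional positions are accepted.** Participants report whole numbers,
  but the pipeline does not enforce integers: rounding conventions differ
  between labs, and quantization belongs to the *generator*, not the
  analysis. Any convention produces valid input here.
* **The wrap interval is symmetric with a deterministic tie-break.** At the
  error magnitudes binding studies produce (well under 150 ms, i.e. under a
  quarter revolution even at the fastest speed) the representative is never
  ambiguous; the tie-break matters only for adversarial inputs and is fixed
  so results are reproducible.

Marking scheme, hand length, and face diameter are carried as metadata only.
They never enter a computation: parameter-manipulation experiments find no
effect of either on binding, so they are simulator parameters, not model
terms.

# Binding scores, trimming, screening

Per participant and condition, action binding is the mean operant-action
error minus the mean baseline-action error; tone binding likewise for tone
blocks. Positive action binding and negative tone binding are the canonical
signature.

**Trial trimming** is a single pass per participant × condition × block
cell: compute the cell mean and sample SD (denominator $n-1$) once, keep
trials with $|e - \bar e| \le k \cdot SD$, default $k = 2.5$. The rule is
deliberately not iterated, the boundary is kept, and cells with fewer than
two trials are kept whole with a flag. The per-cell scope is a choice the
report records (per-cell means and SDs are exported), since pooling
conventions vary; exclusion percentages are reported pooled across the four
blocks of a condition, the resolution at which such studies print them.

**Participant screening** replaces "visual inspection of boxplots" with the
rule a boxplot draws. Per condition × measure, participants beyond
3 × IQR of the quartiles are excluded outright; those beyond 1.5 × IQR are
excluded only when the measure's group distribution is itself distorted
(|skewness| > 2 or |excess kurtosis| > 2, bias-corrected small-sample
formulas, computed before any exclusion). This makes a historically
subjective step deterministic: the same table always yields the same
exclusions, and every exclusion carries its triggering values.

A bookkeeping caveat the report documents: the group mean of
per-participant shifts equals the difference of block grand means only when
every participant keeps equal trial counts; after trimming, counts can
differ slightly, so the two summaries may diverge in the second decimal.

# Repeated-measures inference

The ANOVA operates on participant-level cell means (trials never enter the
linear model; the dependent variable is the mean baseline-corrected error).
The classical univariate within-subject decomposition tests each effect
against its participant-by-effect interaction stratum. For effects with
three or more levels, Mauchly's $W$ and the Greenhouse–Geisser
$\hat\varepsilon$ are computed from the covariance of orthonormal contrast
scores; the corrected p-value uses $\hat\varepsilon$-scaled degrees of
freedom. Both p-values are always reported; the *reported* p switches to
the corrected one only when Mauchly's test is significant at 0.05,
mirroring the convention of correcting only analyses that need it.

Two numerical notes:

* $\hat\varepsilon$ is clamped to $[1/(\text{levels}-1), 1]$, its
  theoretical range; a zero-variance contrast matrix yields undefined
  diagnostics rather than a spurious test. When a stratum has no variance
  at all (every participant flat across cells), the effect F is reported
  as 0 with an undefined p, not as the 0/0 floating-point artifact.
* The Greenhouse–Geisser correction is conservative *in the upper tail*:
  for F below ~1, shrinking both degrees of freedom can slightly lower an
  already-large p. The property tests therefore assert monotonicity for
  F ≥ 1.5, where rejection is possible.

Pairwise follow-ups are paired t-tests on participant means with Bonferroni
multiplication (capped at 1). Cohen's d is returned in both common flavours
— $d_z$ (mean difference / SD of differences) and the pooled-SD variant —
because published binding reports are inconsistent about which they print;
neither is privileged.

**Cousineau within-subject CIs** normalise each observation by the
participant's own mean (plus the grand mean) before computing per-condition
half-widths $t_{n-1} \cdot SD/\sqrt n$. The plain Cousineau estimator is
biased low by $\sqrt{(J-1)/J}$ ($J$ = number of cells); the Morey factor
$\sqrt{J/(J-1)}$ that undoes this is available but **off by default**,
matching the original procedure that figure captions in this literature
cite.

# Half-normal Bayes factors and the prior ledger

Evidence for a directional effect is summarised by the Dienes Bayes factor:
data enter as a mean difference $M$ with standard error $SE$ (normal
likelihood), the alternative as a half-normal prior on the effect with mean
0 and scale $s$ set to the magnitude of a *donor* experiment's effect:

$$
BF = \frac{\int_0^\infty N(M;\,\theta, SE)\; 2N(\theta;\,0, s)\,d\theta}
          {N(M;\,0, SE)}.
$$

The numerator has a closed form (Gaussian product plus a normal CDF), which
is the implementation; an adaptive-quadrature evaluation over
$[0, 8\max(SE, s)]$ ships alongside as an independent cross-check and the
two agree to $10^{-6}$ relative tolerance across the working grid
($M/SE \in [0,5]$, $s/SE \in [0.1, 10]$). Verdict thresholds are the
conventional 3 (support for the directional alternative) and 0.33 (support
for the null), boundaries inclusive mapping to "insensitive".

**The prior ledger** turns a donor experiment's 2-df speed × event
interaction into three 1-df directional effects, one per speed pair: the
change in action binding plus the change in tone-binding *magnitude*
between the faster and slower clock (tone shifts are negative, so this
equals the action change minus the signed tone change). The sign convention
is not derivable from first principles — four combinations are a priori
plausible — and was fixed by enumeration: exactly one convention reproduces
all three published prior scales from the donor table, and that enumeration
is kept as a test. A fourth ledger entry, the tone-only magnitude
difference between extreme speeds, serves the focused tone contrast. Every
entry records the four shift means it came from, so each prior is
reproducible from a binding table.

Two $(M, SE)$ routes are exposed: from a published 1-df contrast,
$SE = |M|/\sqrt F$ (since $|t| = \sqrt F$); from raw scores,
$SE = SD(\text{differences})/\sqrt n$. $M$ keeps its observed sign: an
effect opposing the predicted direction lowers the BF and is flagged.

# The generative model

The simulator exists so the full pipeline can be exercised, calibrated, and
stress-tested without raw data. Its defaults encode the published
block-level summaries bundled in `inst/extdata/block_summaries.csv` (30
condition × event rows across five experiments, with participant counts).

For participant $i$, block $b$, trial $t$:

$$ e_{ibt} = \mu_b + u_{ib} + \epsilon_{ibt}, \qquad
   \epsilon_{ibt} \sim N(0, \sigma), $$

with the trial timeline: spontaneous key-presses at Uniform(2560, 7680) ms
after onset (a window wider than one revolution at every speed, avoiding
phase bias; the source procedures never state this distribution), operant
tones 250 ms after the action, baseline tones at Uniform(2500, 5000) ms.
Reported positions are the true time plus error, wrapped to the face and by
default rounded to whole units (quantization biases cell means by at most
half a unit, $T/120$ ms, verified by test).

Parameter choices, in order of how much they matter:

* **Cell means $\mu_b$** come straight from the bundled tables.
* **Trial noise $\sigma$ = 100 ms.** Not identifiable from participant-level
  summaries (only SDs of participant block means are printed); 100 ms is a
  realistic clock-timing trial SD and, at 30 trials/block, contributes
  $100/\sqrt{30} \approx 18$ ms to participant-mean SDs — small against the
  printed 40–165 ms. Recorded in the params object.
* **Participant-effect SD $\tau$** is solved per cell as
  $\sqrt{SD_\text{table}^2 - \sigma^2/n_\text{trials}}$ so simulated
  participant-mean SDs match the printed ones exactly; cells where that is
  not solvable (none, at the defaults) fall back to $\tau = SD_\text{table}$,
  $\sigma = 0$, with a flag.
* **Correlation structure.** $u_{ib}$ is not i.i.d. across cells.
  Within a condition × event, baseline and operant effects correlate at
  `rho` = 0.85: independent draws would give binding-shift SDs roughly
  double the printed ones, perfectly shared draws roughly half; 0.85 is the
  value the printed block and shift SDs jointly imply (e.g. the fast-speed
  action cell implies 0.853). Across conditions within an event, effects
  share a trait component at `rho_cond` = 0.6: clock-reading bias and
  binding propensity are stable characteristics, and the printed
  extreme-speed 1-df contrast implies a cross-condition shift correlation
  near 0.55 — independent conditions would overstate the SD of
  between-condition differences by ~40%. Both are single scalars applied to
  all cells; per-cell correlation matrices are not identifiable from the
  published summaries and are not attempted.

What the simulator does **not** model: why binding occurs (no cue
combination or pre-activation machinery — means are inputs, not
predictions); effects of markings or hand length (none were found; the
labels are carried but map to identical parameters unless the user sets
them apart); non-normal trial noise, lapses, or sequential effects. Passing
recovery tests therefore shows the *pipeline* is calibrated for data with
this covariance structure — not that real data satisfy it.

# Calibration and problem sizes

The checks the package runs on itself, at the sizes it runs them:

* **Exactness:** shift arithmetic from printed block means; the prior
  ledger; the closed-form/quadrature BF agreement; partial
  $\eta_p^2 = F \cdot df_1 / (F \cdot df_1 + df_2)$ from printed statistics.
* **Oracle equivalence:** the ANOVA path against an independently coded
  sums-of-squares decomposition on random 5 × 3 × 2 designs (10 seeds,
  $10^{-10}$ tolerance), the $F = t^2$ identity on 2-level factors, and the
  sphericity diagnostics against the multivariate-route reference
  implementation.
* **Type-I calibration:** 200 replicates of the full simulate → trim →
  bind → ANOVA pipeline at the study's own size (40 participants × 3
  conditions × 4 blocks × 30 trials) under null condition effects; the
  condition × event interaction should reject at ~5%.
* **Power / recovery:** at published effect sizes the extreme-speed tone
  contrast should be detected in a clear majority of replicates, and
  programmed shifts recovered within 3 SE from a single seeded dataset.

200 replicates bounds the Monte-Carlo SE of the type-I estimate at ~1.5
points, tight enough to detect gross miscalibration while keeping the whole
suite fast on one CPU.

# Known limitations

* Published omnibus F statistics, pairwise p-values, exclusion counts and
  Cohen's d values are not reproducible from printed summaries alone; they
  require the raw trial data. The property-based calibration above is the
  substitute, and the printed Cohen's d values match neither standard
  formula exactly, which is why both flavours are reported and neither is
  asserted.
* The standard error of the *omnibus* (summed) effects is not derivable
  from published tables; Bayes factors for those effects use
  participant-level differences from the analysed data, so published
  omnibus BF values are reproduced in structure, not asserted numerically.
* Screening is one deterministic operationalisation of a judgment call;
  alternatives (Mahalanobis-distance multivariate screens, KS-test gates)
  are deliberately out of scope beyond the moments the report exposes.
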