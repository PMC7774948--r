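# gazescan

Eye-head coordination and time-based visual-scanning entropy for
driving-simulator gaze recordings.

When a driver has to work a peripheral device (here: a navigation display
on the center console) while keeping a car at speed, two things happen to
their oculomotor behavior as visual demands grow: the **head** takes over a
larger share of horizontal gaze shifts, and the **scanpath** becomes more
stereotyped and less explorative. `gazescan` is an R package plus analysis
workflow that quantifies both from synchronized 120 Hz eye-in-head and
head-in-world yaw/pitch traces:

* **Gaze reconstruction & AOI labeling** — compose eye-in-head with
  head-in-world rotation into gaze-in-space, intersect gaze rays with the
  scene geometry (central screen, navigation device), label each sample's
  area of interest.
* **Eye-head coordination** — within visual-search trials, the OLS slope
  *b* of head rotation on eye rotation per axis, after removing pairs in
  low-density 1°×1° cells (< 20 occurrences). *b* = 0 means eyes-only
  shifts; larger |*b*| means more head recruitment.
* **Time-based transition entropy** — cut each effector's trace into
  120 ms bins, state each bin by its net displacement (shift/stay at 1°),
  build the first-order transition model, and report the normalized
  conditional entropy

  H = −Σᵢ pᵢ Σⱼ p(j|i) log₂ p(j|i) / log₂ n  ∈ [0, 1],

  computed over the whole scenario for eye, head and gaze. Low H =
  predictable, stereotyped scanning.
* **Statistics** — two-sample Kolmogorov-Smirnov comparison of rotation
  distributions, Box-Cox skew gate, condition × group ANOVA with η²
  (replication-style fixed-effects df and conventional mixed-model df, both
  exposed), Tukey HSD.
* **Synthetic scanpath generator** — sessions and whole cohorts with known
  ground truth (semi-Markov AOI dwells, tunable head-contribution gain and
  scan randomness, first-order eye-leads-head dynamics), so every stage is
  validated by parameter recovery. No raw recordings are required anywhere.

The `analysis/` scripts are thin numbered drivers over the package:
`01_simulate_cohort.R` … `05_stats.R` regenerate a 21-participant,
two-condition cohort deterministically and write all report tables under
`results/`.

## Worked example

```r
library(gazescan)

# one degraded-vision session with known generative parameters
p <- default_params("degraded", "higher")
p$seed <- 42L
s <- simulate_session(p)

session_entropy(s, "eye")
#> <entropy_result> eye 0.7706 bits, normalized 0.7706 (2 states, 3249 pairs, mode standard)

session_slopes(s)[, c("axis", "slope", "n_retained", "n_total")]
#>    axis      slope n_retained n_total
#> 1   yaw 0.64974792       3980    5040
#> 2 pitch 0.07762797       4746    5040
```

The yaw slope ≈ 0.65 recovers the session's head strategy: with a head
gain of 0.5 the steady-state head/eye displacement ratio is
0.5/(1−0.5) = 1, diluted by road fixations near the origin; the pitch slope
stays near the much smaller vertical head gain. Running the full cohort
(`analysis/04_entropy.R`) prints the condition contrast the pipeline is
built to detect — eye and gaze entropy drop under degraded vision, the
head barely moves:

```
condition means per effector:
        condition
effector degraded optimal
    eye    0.7604  0.8043
    gaze   0.8588  0.8909
    head   0.2915  0.3185
```

and `analysis/05_stats.R` prints the matching tests, e.g. for eye entropy
`paper_df F(1, 38) = 32.55, p = 1.4e-06` vs `mixed F(1, 19) = 42.50`.

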