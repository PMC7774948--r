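---
title: "Methods: eye-head coordination and time-based scanning entropy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: eye-head coordination and time-based scanning entropy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

When drivers divide attention between the road and an in-vehicle device,
their oculomotor behavior reorganises: the head becomes more involved in
gaze shifts and the visual scanning pattern becomes more stereotyped.
`gazescan` implements a complete pipeline for quantifying both phenomena
from synchronized eye-in-head and head-in-world rotation recordings of a
dual-task driving-simulator scenario (here, 390 s sessions at 120 Hz with
seven 6 s visual-search trials on a navigation device), together with a
synthetic scanpath generator so that every stage can be validated by
parameter recovery rather than by eyeballing.

Two outcome families are computed per session:

* **Eye-head coordination**: the OLS slope of head rotation regressed on
  eye rotation, per axis (yaw, pitch), within the visual-search trials,
  after a density filter. Slope 0 means eyes-only gaze shifts; larger
  magnitudes mean more head recruitment.
* **Time-based transition entropy**: the normalized conditional entropy of
  a first-order Markov model over 120 ms movement bins, computed over the
  whole scenario for the eye, the head and the reconstructed gaze. Low
  entropy indicates predictable, stereotyped scanning.

# Coordinate conventions and gaze reconstruction

Angles are degrees end to end: negative yaw left, positive right; negative
pitch down, positive up. The world frame is right-handed with +x right,
+y up, +z forward from the driver. A direction for yaw $\psi$ and pitch
$\theta$ is $(\cos\theta\sin\psi, \sin\theta, \cos\theta\cos\psi)$.

`reconstruct_gaze()` combines eye-in-head and head-in-world orientation in
two modes. *Compose* applies the head rotation — yaw about the world
vertical, then pitch about the rotated horizontal axis — to the eye-in-head
direction vector and converts back to yaw/pitch. The Euler order is a
declared convention of this package: recording hardware defines angles
operationally and different reasonable orders disagree only through cross
terms of order $\psi\theta$. *Additive* simply sums angles. The two modes
agree exactly when either input is zero or when pitch is identically zero
(rotations about a shared axis commute), and for gaze shifts of amplitude
up to 15° split arbitrarily between eye and head the maximum disagreement
we measure is about 0.25°, i.e. below half a degree. That 15° domain is the
physiologically relevant one — larger gaze shifts are exactly the ones that
recruit the head. Note that letting all four input angles range
independently over ±15° (so combined shifts up to ~30° and beyond) drives
the worst-case disagreement to about 1.6°; this is the intrinsic
non-commutation error of any yaw/pitch convention, not an implementation
artifact.

Head roll is carried through session files but ignored by the analysis,
which concerns yaw and pitch only. The eye origin is treated as coincident
with the head origin; at target distances of 0.7 m and beyond the
translation between the eye and head centers is a second-order effect.

Areas of interest are labelled by casting the gaze ray from the eye origin:
`device` if it hits the navigation-device rectangle (tested first — the
device is nearer and occludes the screen along shared rays), else
`central_screen`, else `other`; invalid samples map to `other`. The default
geometry places a 7 m x 1.7 m screen 2 m ahead and an 8-inch device 0.7 m
away, down-right (direction yaw +22°, pitch −18°).

# Coordination slopes

Within the trial windows (half-open `[start, end)`, as are all intervals in
the package), simultaneous eye/head samples are paired with no lag
compensation. Pairs are counted on a 1° x 1° grid anchored at 0° and pairs
in cells with fewer than 20 occurrences are removed; the filter is applied
per session (participant x condition), because it targets the individual's
artefacts and the regression is fitted per individual. The regression is
unweighted OLS on retained samples with an unconstrained intercept; the
filter prunes outliers, the fit itself stays on raw rotations. Per-cell
summaries average the per-participant slopes.

Design choices left open by convention and resolved here: the grid is
anchored at 0° (reproducible binning, no data-dependent offsets); the
filter is per participant, not pooled; intercepts are unconstrained.

On the sign of the slope: the generator splits every gaze shift of
amplitude $A$ into a head share `head_gain`$\cdot A$ and an eye share
$(1-$`head_gain`$)\cdot A$, which makes the steady-state head/eye
displacement ratio `head_gain / (1 - head_gain)` — a positive quantity.
Field recordings can instead show negative head-on-eye slopes, because
during fixation the vestibulo-ocular reflex counter-rotates the eye against
ongoing head movement. The generator makes no claim about which regime a
given dataset occupies; for validating slope *recovery* under a known
ground truth of either sign, `simulate_coordination_pairs(slope, ...)`
draws (eye, head) pairs directly from `head = slope * eye + noise`.

# Time-based transition entropy

The trace is cut into contiguous 120 ms bins anchored at the session start
(the width approximates the minimum fixation duration; at 120 Hz a bin
holds 14 or 15 samples). A trailing partial bin is dropped. Each bin's net
displacement is the Euclidean distance between the (yaw, pitch) of its
first and last valid samples — a net displacement, deliberately not an arc
length, since $\sqrt{X^2 + Y^2}$ describes a single movement vector. Bins
with more than 50% invalid samples are flagged invalid and enter the chain
as a sentinel that is excluded from transition counts, so blinks and
tracking loss cannot fabricate transitions.

Each bin is mapped to a movement state. The default policy is a
shift/stay dichotomy at a 1° displacement threshold — one encoding
applicable uniformly to eye, head and gaze, which is what makes the three
effectors comparable. Quantile-based states (`displacement_quantiles`) and,
for gaze, majority area-of-interest labels (`aoi_labels`) are provided as
alternatives. From consecutive valid-bin pairs, the transition model
collects counts, joint probabilities $p(i,j)$, stationary probabilities
$p_i$ (the row marginals), and conditionals $p(j|i)$.

The default entropy is the standard Shannon conditional entropy of the
first-order chain,

$$H = -\sum_i p_i \sum_j p(j|i)\, \log_2 p(j|i),$$

normalized by $\log_2 n$ over the realized state set (so the shift/stay
policy normalizes by 1 bit; a single-state chain is 0 by convention). A
second mode, `literal`, evaluates $-\sum_i p_i \sum_j p(i,j) \log_2 p(i,j)$
with the *joint* probability inside the logarithm. The literal form
circulates in the applied literature as a "conditional entropy equation"
but is not the standard conditional entropy; we default to the standard
form because it matches the measure's stated interpretation (complexity and
randomness of scanpaths: exactly 0 for deterministic transitions, exactly 1
for a uniform i.i.d. chain) and keep the literal form as an explicit option
for comparison with analyses that used it. With two states the two modes
are numerically close but not equal.

`bin_ms` is a first-class parameter rather than a constant: the head moves
more slowly than the eyes, and a 120 ms window may be too short to resolve
head transitions — users can lengthen it per effector. The per-bin X,Y
positions entering the displacement are yaw/pitch angles; this is a
documented operationalisation, since nothing in the measure requires
metric screen coordinates.

# The synthetic generator

`simulate_session()` produces ground-truth-tagged sessions with the
statistical structure the analysis assumes:

* a latent fixation-target timeline: road viewing with occasional mirror
  glances outside trials; semi-Markov road/device alternation with
  exponential dwells (means 1.2 s road, 1.5 s device, rescaled to the
  configured in-trial switch rate) during trials; within every dwell,
  refixation events at rate $0.2 + 1.5 \cdot$`state_randomness` per second
  re-draw a Gaussian jitter offset (SD 2°) around the AOI center;
* first-order dynamics: the gaze approaches each new target with
  $\tau = 60$ ms, the head approaches its share `head_gain * target` with
  $\tau = 350$ ms, and the eye-in-head angle is the difference — the
  simplest model that yields realistic eye-leads-head traces; the exact
  response-speed profile is a stand-in, not a claim about any recorded
  kinematics;
* independent Gaussian measurement noise per channel (0.3° eye, 0.2° head).

Exponential dwells are the memoryless default, one parameter per AOI.
Between trials the driver is on the road because entropy is computed over
the whole scenario and therefore needs between-trial structure. Device
fixation targets are clamped inside the device's angular extent so the
latent "device" state always points into the device plane.

`state_randomness` (in [0, 1]) is the single dial for scanning
unpredictability; normalized entropy is monotonically increasing in it.
The degraded-vision condition is encoded as +0.05 (lower group) / +0.20
(higher group) on `head_gain_yaw` and −0.10 / −0.18 on `state_randomness`,
mirroring the direction and relative group ordering of the phenomena the
pipeline is built to detect: more horizontal head recruitment and more
stereotyped eye/gaze scanning under degraded vision, with the weakest
condition effect on the head. Under optimal vision the two groups are
identical by design. Cohorts add per-participant Gaussian trait offsets
(SD 0.04 on gain, 0.05 on randomness) shared by the participant's two
sessions; session seeds derive deterministically from one master seed, so a
cohort is reproducible bit for bit and different master seeds change only
the random realizations, never the metadata.

What the generator does **not** emulate: saccadic main-sequence kinematics,
blinks and tracking dropouts (validity flags exist and are honoured
throughout, but default sessions are fully valid), vergence, scene
content, and vehicle dynamics. Consequently, passing recovery tests shows
the *pipeline* is correct and sensitive under the stated statistical
structure; it does not certify performance on real recordings with
device-specific artefacts. The absolute normalized entropies of simulated
sessions (about 0.76-0.89 for the eye under the default shift/stay
encoding) should not be compared against published absolute values, which
depend strongly on the (usually unstated) state encoding; comparisons
within the pipeline — between conditions, groups and effectors — are the
meaningful quantities.

# Statistical stage

Rotation distributions are compared between conditions with the two-sample
Kolmogorov-Smirnov test (asymptotic p-values; samples here are tens of
thousands of rotation samples, where exact computation is infeasible and
unnecessary). Outcome variables pass a Shapiro-Wilk normality gate at
$\alpha = 0.05$ (the standard small-$n$ choice; subsampled to 5000 values
when longer) and, if rejected, are Box-Cox transformed with $\lambda$
estimated by profile maximum likelihood after shifting to positivity; the
transform record (lambda, shift, skew before/after) is kept in the run
manifest.

The condition x group ANOVA is offered in two modes. `paper_df` is a
fixed-effects two-way ANOVA on the 42 session-level values, giving error df
$N_{sessions} - 4 = 38$ and df (1, 38) for every effect at 21
participants — the structure replication tables in this literature print,
even when the design is described as mixed. `mixed` is the statistically
conventional alternative: the group effect tested against the
between-participant stratum and the condition and interaction effects
against the within-participant stratum, df (1, 19) at 21 participants. Both
are exposed and labelled because the discrepancy cannot be resolved from a
printed table alone; `paper_df` is the default for replication-shaped
output, and effect sizes are $\eta^2 = SS_{effect}/SS_{total}$ in both
modes. Tukey HSD (Tukey-Kramer under unequal cell sizes) handles post-hoc
pairwise comparisons. No multiple-testing correction is applied across
outcome families, matching standard practice in this analysis style.

# Numerical and problem-size choices

* Half-open intervals everywhere (trial windows, bins, grid cells); sample
  indexing is 0-based in time (`t = k / rate`).
* Trial windows are placed by stick-breaking: the free time left after
  reserving windows (6 s), inter-trial gaps (1.5 s) and session margins
  (3 s) is split uniformly — placement is rejection-free and infeasible
  requests fail loudly.
* Session CSVs round-trip at 9 significant decimal digits: reading a file
  and rewriting it reproduces the bytes exactly.
* Quantile states use type-1 (inverse-ECDF) quantiles with ties breaking
  toward the lower state.
* Zero-probability cells contribute $0 \log 0 = 0$; a single-state model
  normalizes to 0 by convention.
* Simulation sizes: statistical calibration uses 1000 null replicates (KS,
  ANOVA) and 2000 (Tukey familywise error); the power analysis uses 200
  replicated 21-participant cohorts with 120 s sessions — long enough for
  ~1000 entropy bins per session, chosen as the package's standing
  configuration for replicated runs, with the degraded-vision entropy
  decrement of `power_cohort_spec()` calibrated once so the condition main
  effect on eye entropy carries $\eta^2 \approx 0.25$ (measured mean
  $\eta^2 \approx 0.25$, detection power ~0.93-0.97 at $\alpha = 0.05$).

# Known limitations

* The compose-mode Euler order is a declared convention; hardware that
  defines angles differently needs a frame adapter before `read_session()`.
* The density filter's behavior on heavily clustered bimodal data removes
  transition-path samples by design; slopes then describe the dense
  fixation clusters.
* Entropy absolute values are encoding-dependent (see above); only
  within-pipeline contrasts are interpretable.
* The mixed-mode ANOVA assumes compound symmetry (trivially satisfied at
  two conditions).
* `resample_and_sync()` interpolates linearly; during saccades this
  underestimates peak velocity, which is irrelevant for displacement bins
  but matters if the traces are reused for kinematic analyses.
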