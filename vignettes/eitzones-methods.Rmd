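---
title: "Pixel classification of EIT PEEP trials: model, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pixel classification of EIT PEEP trials: model, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement and the model

Chest EIT reconstructs *relative* impedance: every pixel value is the
change of impedance against a baseline frame, in arbitrary units, and
regional air content is the dominant driver of that change. Two
consequences shape everything in this package:

* absolute aeration is not available, so all region definitions must be
  relative — here, relative to the maximum of the image being
  thresholded, which also makes every mask invariant under positive
  rescaling of the data;
* the meaning of "air at end-expiration" depends on the baseline. A
  pixel has end-expiratory air only *relative to a moment when it had
  less*, which is why devices reference the whole recording against the
  lowest-impedance frame of the trial (at zero PEEP).

Given per-step frame sequences, the pipeline is: locate breaths on the
global (whole-image sum) waveform; average the frames at the last five
end-inspirations and end-expirations into status images `EI` and `EE`;
form the tidal image `TV = EI − EE`; threshold `EE` at 25 % and `TV` at
20 % of their maxima to get the end-expiratory and tidal lung regions;
and take set differences for the categories (overinflated =
end-expiratory minus tidal; cyclic = tidal minus end-expiratory;
recruited = end-expiratory minus the reference step's end-expiratory
region). Percentages share one denominator, the end-expiratory lung
region at the highest PEEP.

Assumptions worth stating: breathing is quasi-periodic and dominates the
global signal; five breaths of averaging is enough to suppress
uncorrelated noise; the imaged slice stays comparable across PEEP steps
(a high PEEP can push the diaphragm and shift lung tissue through the
electrode plane — the method cannot detect that); and a pixel is treated
as a unit, so partial-volume mixtures are classified by their dominant
behaviour.

## Baseline re-referencing (`rebase_mode`)

`analyze_trial()` accepts `rebase_mode = "none" | "trial" | "step"`, and
the default is `"none"`. The reasoning: device exports are already
referenced against a trial-wide low-impedance baseline, and the phantom
generator emits data in the same convention. The `"trial"` mode
re-references every step against the minimum-sum frame of the lowest
PEEP step, reproducing the device behaviour when raw per-step data are
supplied. A per-step mode (`"step"`) exists but cannot support
end-expiratory analysis: in steady state the minimum-sum frame of a step
*is* its end-expiratory frame, so per-step re-referencing drives `EE`
to zero everywhere and the 25 % threshold has nothing to bite on —
`lung_mask()` then raises "no positive signal" by design. We consider
this a property of the physics, not a parameter choice, and therefore
did not make `"step"` a default despite its apparent symmetry.

## Parameters that matter

| parameter | default | units | rationale |
|---|---|---|---|
| `ee_frac` | 0.25 | fraction of max(EE) | end-expiratory lung cut; dynamic images are noisier, so it sits 5 points above the tidal cut |
| `tidal_frac` | 0.20 | fraction of max(TV) | tidal lung cut; 20–35 % is the usable range reported for relative EIT thresholds |
| `reference_peep_cmH2O` | 6 | cmH2O | recruitment reference; at ≤ 3 cmH2O the end-expiratory signal can be comparable to reconstruction noise |
| `n_breaths` | 5 | breaths | averaging depth for status images |
| `min_breath_s` | 1.0 | s | shortest admissible breath (60/min) |
| `min_prominence_frac` | 0.15 | fraction of dynamic range | rejects cardiac oscillation (~1.5–2 Hz, much smaller than tidal excursion) without an explicit frequency filter |
| smoothing window | 0.25 | s | moving average before extremum search; marks are mapped back to raw-signal extrema so averaging uses recorded frames |

Threshold behaviour is monotone by construction: raising `ee_frac` can
only shrink the end-expiratory lung region, hence the overinflated
region, and — against a *fixed* reference mask — the recruited region.
When the reference mask is recomputed at the same raised threshold the
recruited set is not formally guaranteed to shrink (its complement term
grows), though in practice it does; the test suite asserts the formal
property against a fixed reference and the empirical one on phantom
trials.

## Numerical choices

* **Strict inequality** at the threshold (`value > frac · max`): a pixel
  exactly at the threshold is excluded, so boundary behaviour is
  reproducible.
* **Baseline tie-break**: `rebase()` takes the earliest frame among
  minimal-sum ties.
* **Breath detection**: candidate extrema come from sign changes of the
  smoothed derivative (flat runs inherit the preceding slope, so a
  plateau yields one mark); sub-prominence peak–trough pairs are removed
  innermost-first, which preserves alternation; same-type marks closer
  than `min_breath_s` are resolved by dropping the weaker mark plus one
  intervening opposite mark. Monotone leading/trailing segments produce
  no marks, so incomplete half-breaths at the recording edges are
  ignored.
* **Degenerate inputs** fail loudly rather than silently: constant
  global signal (zero dynamic range), images with no positive values,
  out-of-range mark indices, a missing reference step. A step that fails
  inside a trial is flagged and skipped; the trial continues.
* **Overlap semantics**: a pixel may be simultaneously overinflated and
  recruited; counts are per-category without de-duplication. Rendering
  precedence (overinflated > cyclic > recruited) is a display decision
  only — overinflation wins because it is the safety-critical finding.
  The yellow outline traces the union of the end-expiratory and tidal
  lung regions and never overwrites a category pixel.

## What the phantom emulates — and what it does not

Every pixel follows `a(PEEP) + b(PEEP) · w(t) + ε(t)` with `w` a raised
sinusoid in [0, 1] at 30 breaths/min, sampled at 40 Hz on a 32 × 32
grid, so `a` is the end-expiratory aeration against the trial baseline
and `b` the tidal amplitude. Archetypes move `a` and `b` with PEEP as
hard switches at per-pixel opening / overdistension pressures: normal
(`a, b > 0` throughout), overdistending (`b → 0` above its onset, `a`
stays high), recruitable (`a = b = 0` below its opening pressure),
cyclically collapsing (`b > 0`, `a = 0` below its opening pressure), and
non-lung. Hard switches keep the ground truth unambiguous — the labels
are the classifier definitions applied to the noiseless `a` and `b`.
The default layout grades the switching pressures with depth (ventral
overdistension onsets 6–18 cmH2O, dorsal opening pressures 7–19 and
12–36 cmH2O), which produces gradually monotone region sizes and keeps
every category represented at every analyzed step — a deliberate choice,
because recovery of a structure can only be measured where the structure
exists (Dice against an empty truth mask collapses to 0 on a single
false positive).

Step duration defaults to 30 s: the analysis uses only the final five
breaths, so longer recordings change nothing downstream; 15 breaths per
step leaves detection unambiguous. Amplitudes are all-or-none per pixel
(`b` is 0 or the full tidal amplitude), placing every true lung pixel at
5× the tidal threshold and 4× the end-expiratory threshold — comfortably
outside the noise band at the 5–10 % noise levels used in validation.

What the phantom does **not** emulate: reconstruction artefacts and the
blurry point-spread function of real EIT (real region borders are soft,
not pixel-sharp), electrode-contact drift, posture changes, cardiac
stroke artefacts beyond an optional global sinusoid, spatially
correlated noise, and gravitational gradients *within* an archetype
band. Passing the recovery tests therefore demonstrates that the
pipeline implements its definitions correctly and is robust to sensor
noise — not that those definitions are clinically valid on any
particular patient; that validation requires recorded data.

## Group-level statistics

Per-subject Pearson r between a category's pixel count and a physiology
variable is the primary statistic, summarized as group mean ± SD; counts
(not percentages) are correlated by default, with a flag to switch.
There is no canonical test for "is the group-mean r nonzero" in this
design; `correlate_trials(..., group_test = TRUE)` offers a one-sample
t-test on Fisher-z-transformed per-subject r, clearly labelled as one
plausible reading rather than a default output.

## Problem sizes used in validation

The test suite runs on 16 × 16 phantoms (6–20 s steps) for unit checks
and on the full default 32 × 32, 11-step, 30 s phantom for the
end-to-end recovery, trend and threshold checks; the oracle-equivalence
test enumerates 1000 random 8 × 8 images against per-pixel brute-force
loops; correlation calibration uses 8 steps × 10 subjects against a
5000-replicate Monte-Carlo band. These sizes are the package's own
choices: they are the smallest instances that exercise every code path
while keeping the suite fast to run routinely.

## Known limitations

* No anatomical segmentation: the lung region is defined functionally,
  so a completely non-ventilated, non-aerated area is invisible, and an
  off-lung artefact brighter than the lung would shift both thresholds
  (an optional `roi` argument to `lung_mask()` restricts the maximum if
  needed; by default nothing is masked).
* The end-expiratory maximum may be dominated by an overdistended
  cluster, biasing the 25 % cut; no correction is applied.
* Incremental trials only are modelled by the phantom; decremental
  semantics amount to relabelling but hysteresis is not simulated.
* The package deliberately does not recommend an "optimal PEEP"; it
  reports regional information to be weighed with oxygenation and
  clinical context.
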