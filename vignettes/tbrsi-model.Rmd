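---
title: "A decay-and-interference model of working memory in complex span tasks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A decay-and-interference model of working memory in complex span tasks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tbrsi)
```

## The model

`tbrsi` simulates serial recall in complex span tasks — lists of memoranda
interleaved with bursts of distractors — under the time-based
resource-sharing (TBRS) account, extended so that forgetting has *two*
causes and maintenance has *two* counter-measures:

* **Time-based decay** acts on the *bindings* between items and their serial
  positions. Positions are coded by overlapping sets of position units
  (adjacent positions share a proportion of units, which is what makes
  neighbouring positions confusable); encoding an item strengthens the
  weights between the item and the current position's units following a
  saturating exponential, $w \leftarrow A - (A - w)\,e^{-r\,t}$, with
  asymptote $A = 1$ for memoranda and processing rate $r \sim N(R, s)$.
  Whenever attention is elsewhere every weight decays as $w\,e^{-D\,t}$.
* **Interference** acts on the *representations* of the memoranda, which are
  distributed vectors over 64 feature units. A distractor distorts the
  last-presented memorandum by setting every *shared* feature unit halfway
  between the memorandum's and the distractor's value.
* **Reactivation**, the first half of refreshing, counteracts decay: during
  free time, positions are visited cyclically; the item best bound to the
  visited position is retrieved (with Gaussian noise, so refreshing can pick
  — and then strengthen — the wrong item) and its binding is re-encoded for
  a short step of mean duration $T_r$.
* **Restoration**, the second half, counteracts interference: the retrieved
  memorandum's representation is averaged halfway toward its closest stable
  long-term engram. Interference and restoration are literally the same
  averaging operator pointed at different targets; if distortion has crossed
  the decision boundary, restoration converges on the wrong engram.

Recall cues each position in turn: every item in the lexicon (including
never-presented ones) competes with its summed position-unit weights plus
retrieval noise; a winner whose noiseless activation falls below the
threshold $\theta$ is an omission. A retrieved memorandum representation is
mapped to its closest engram before being output, so a heavily distorted
item can be output as a different memorandum; if a distractor wins the
binding competition the response is an intrusion. Decay continues during
recall, so later output positions retrieve from weaker traces.

## Parameters

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `R`, `s` | 6, 1 | 1/s | mean/sd of the processing rate of encoding, refreshing and recall |
| `theta` | 0.05 | – | retrieval threshold on the noiseless winning activation |
| `sigma` | 0.02 | – | sd of retrieval noise added to each candidate's activation |
| `D` | 0.5 | 1/s | exponential decay rate of bindings |
| `Tr` | 0.08 | s | mean duration of one refreshing step |
| `Te` | 0.5 | s | mean encoding duration per memorandum |
| `Ta` / `dac` | task | s | mean attentional capture per distractor step |
| `distractor_strength` | 0.5 | – | encoding asymptote of distractor-position bindings |
| `repeated_capture` | off / 0.05 | s | reduced capture for repeated distractors after a burst's first |
| `duration_cv` | 0.25 | – | coefficient of variation of all stochastic durations |

The task factors of the benchmark grid are the list length (1–9), the
number of distractors per burst `nd` (0, 1, 4, 8), the capture duration
`dac` (0.3, 0.5, 0.7 s), the free time `ft` (0, 0.1, 0.6, 1.2, 2.0 s), and
three stimulus factors described below. The cognitive load of the
distracting phase is the nominal `dac / (dac + ft)`.

## Synthetic stimuli

`generate_lexicon()` is the model's only source of stimuli; it emulates the
*statistical structure* of a stimulus set, not any particular material:

* Memoranda are a pool of 26 letter-like items, each using the same
  contiguous 16-unit block (the memoranda *domain*) of the 64 feature
  units, with values i.i.d. uniform on $[0, 1]$. 26 and 16 are conventional
  choices (an alphabet-sized response set; a quarter of the feature space);
  the model's behaviour depends on them only through the density of the
  memoranda cloud, which sets the identification error rate.
* Each distractor type also uses 16 units: `round(mdo * 16)` sampled inside
  the domain (interference by confusion operates only there) and the rest
  outside it. On shared units its value is the memoranda-pool mean plus
  $N(0, \mathrm{mdd}^2)$ noise, **truncated to $[0, 1]$** — all item values
  live on the same bounded feature scale, so increasing `mdd` pushes
  distractor features toward the extremes of the scale rather than off it.
  Unbounded noise makes the superposition effect collapse recall at
  moderate `mdd`, which is qualitatively wrong: the superposition channel
  should be the weaker of the two. With truncation, the `mdd` effect is
  real but saturating.
* `hod = "identical"` reuses one distractor type for the whole trial;
  `"distinct"` gives every distractor token its own type, and the shared
  units are re-sampled per type, so distinct distractors hit changing parts
  of the memoranda — one reason repeated distractors are less harmful.

What the generator does *not* emulate: structured similarity between
memoranda (lists are mutually random), semantic or phonological content,
serial-position-dependent item difficulty, and any participant-level
variation. Passing tests therefore show that the *mechanisms* produce the
benchmark effects under clean stimulus statistics, not that the model fits
any particular dataset.

## Design choices where the design was open

* **Identification pool.** Mapping a (possibly distorted) memorandum
  representation to a stable engram — during restoration and at recall
  output — searches the *memoranda* engrams: restoration is repair of a
  memorandum from long-term knowledge, and a recall response is a
  memorandum-shaped output. Distractor intrusions still occur, at the
  binding-competition stage, where the full lexicon (presented or not)
  competes. `identify_ltm(..., candidates = "all")` exposes the wider pool
  for exploration.
* **Distance.** `ltm_distance()` is the mean squared value difference over
  the union of used units, a unit used by one side only contributing its
  squared value; this keeps the distance symmetric and zero exactly on
  identical vectors.
* **Distractor bindings.** Distractors are bound to the current position at
  asymptote 0.5 while they capture attention; their traces decay like any
  other and are neither removed nor repaired. Interference applies once per
  distractor episode, to the last-presented memorandum.
* **Timing.** All operation durations are Gaussian around their means with
  coefficient of variation 0.25, floored at 10 ms; processing rates are
  floored at 0.1/s. Each recall step takes a duration drawn around $1/R$.
  The refreshing pointer restarts at position 1 at every free-time slot,
  and a step that does not fit the remaining budget is skipped (the budget
  is never overdrawn, but decay always spans the full interval).
* **Refreshing a winner that is not a memorandum.** Whatever wins the
  refresh retrieval is reactivated — including a distractor (attention is
  captured by the most active trace). Restoration applies only to
  memoranda, whose representations are the only ones that get distorted.
* **Numerics.** Decay is applied lazily per weight row using the semigroup
  property of the exponential, which makes the event-driven simulation
  exact regardless of how intervals are split. Retrieval noise for the
  many zero-activation candidates is drawn as the maximum of $m$ i.i.d.
  Gaussians through the inverse CDF, which is distributionally identical to
  drawing all of them. Distance ties are broken toward the lowest item
  index.

## Problem sizes

The factorial benchmark grid (4 × 3 × 5 × 6 × 7 × 2 levels by 9 list
lengths = 45,360 cases) is exposed at any number of runs per case. The
package's own verification uses 20 runs per case on the MDO-restricted
grids (7,560 cases each, ~150,000 trials per grid): because span scores are
averaged over 840 factor combinations, the Monte-Carlo standard error of a
grand-mean span at 20 runs/case is below 0.01 span units, so small run
counts already give stable grand means. Property checks use reduced grids
(a few hundred cases at 10–40 runs). Full-scale 5,000-run reproductions
are a cluster-scale exercise via `cmd_grid()`'s checkpointed runner.

## Limitations

* The distracting task itself is not simulated — only its attentional
  capture and its interference with the last memorandum.
* Memoranda do not interfere with each other, neither during maintenance
  nor during recall output; benchmark phenomena that depend on
  within-list similarity are out of scope.
* No individual differences: a single parameter set generates all trials.
* The meta-analytic line `cl_reference_line()` is an overlay for plots,
  not a fit; no parameter was estimated from human data.
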