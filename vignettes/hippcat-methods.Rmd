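---
title: "Modelling hippocampal pathway contributions to category learning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling hippocampal pathway contributions to category learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`hippcat` simulates a rate-coded model of the hippocampal circuit and
asks how its two main pathways divide the labour of rapid category
learning.  Five layers represent the circuit: an external `Input` layer
(clamped to the stimulus), superficial and deep entorhinal cortex
(`EC_in`, `EC_out`, linked one-to-one), and the hidden subfields `DG`
(400 units), `CA3` (80) and `CA1` (100), sized after human subfield
ratios.  The **trisynaptic pathway** (TSP) runs EC_in → DG → CA3 → CA1
with sparse connectivity — each DG and CA3 unit samples 25% of EC_in,
CA3 samples 5% of DG — and a fast learning rate (0.02).  The
**monosynaptic pathway** (MSP) is the dense EC_in → CA1 projection at a
10× slower rate (0.002).  CA3 carries a full off-diagonal recurrent
projection; CA1 connects bidirectionally with EC_out, and EC_out
recirculates one-to-one into EC_in (the "big loop").

Units carry activations in [0, 1].  A unit's drive is the weighted sum
of presynaptic activity, normalized per projection by its expected
active fan-in so sparse and full projections are comparable.
Within-layer inhibition is set-point k-winner-take-all: the inhibition
level sits midway between the k-th and (k+1)-th largest drives, and the
activation is a logistic function of (drive − inhibition).  DG and CA3
are strongly inhibited (k = 4, ~1% and 5%), CA1 more weakly (k = 25).
Layers settle by damped Gauss–Seidel sweeps in the anatomical order
(EC_in, DG, CA3, CA1, EC_out), each cycle moving activations 30% of the
way to their instantaneous target, until the largest change falls below
1e-4 (or 100 cycles; non-convergence is flagged, not fatal).

## Learning

The network trains as an autoencoder: the stimulus is clamped on
`Input` and must be reproduced on `EC_out`.  Weight changes follow
Contrastive Hebbian Learning under a theta-phase schedule.  Each intact
trial has two minus phases — at the simulated theta *trough* CA3 → CA1
is inhibited so CA1 is EC-driven; at the *peak* EC_in → CA1 is
inhibited so CA1 is CA3-driven — contrasted against one *plus* phase in
which the target is clamped on EC_out.  Each pathway learns from the
minus phase in which it drives CA1 (monosynaptic projections contrast
the trough, trisynaptic the peak), which keeps the two pathways'
learning independent; the fully averaged pairing is available
(`run_trial(pairing = "averaged")`) but mixes pathway-specific phase
differences into every update and, at these learning rates, prevents
multi-pattern learning.  Deltas are softly bounded into [0, 1]
(increases scaled by 1 − w, decreases by w).

Three mechanisms standard in this model family carry most of the
explanatory load:

* **Weight-contrast enhancement with an offset.**  Learnable binding
  and monosynaptic weights are stored in [0, 1] but enter the drive
  through a sigmoid `1 / (1 + (1.25 · (1 − w)/w)^gain)` with gain 12.  Initial weights sit in a narrow mid-range band
  (U[0.45, 0.55]), below the sigmoid's expression midpoint.  The
  offset therefore acts as an *expression threshold*: weight changes
  must accumulate across repeated reinforcement before they influence
  activity.  At the slow monosynaptic rate, an item-specific
  association (~9 exposures in the satellite task) stays below
  threshold while category-level structure (~46 exposures) is strongly
  expressed — this, not the learning rate alone, is what makes the
  MSP a structure learner rather than an exemplar memorizer.  At the
  fast trisynaptic rate the threshold is crossed within 2–3 exposures,
  giving near one-shot binding.
* **Hebbian self-organization in CA3.**  The CA3 recurrent projection
  learns by a conditional-PCA Hebbian rule (`dw = lr · post ·
  (pre − w)`) at elevated strength, turning CA3 into an
  auto-associator whose attractors support cued pattern completion.
  The sparse input projections (EC_in → DG/CA3, DG → CA3) keep fixed,
  widely initialized random weights: their job is stable pattern
  separation, and Hebbian tuning of those weights collapses the code
  onto category attractors (we verified this empirically).
* **Inhibition floors.**  EC_in (0.5), EC_out (0.3) and CA1 (0.1)
  carry a lower bound on the inhibition level, i.e. a leak that
  weakly-driven layers do not overcome.  The CA1 floor is what
  dissociates the pathways on single-feature probes: a lone input
  feature delivered through the diffuse MSP leaves CA1 silent, whereas
  concentrated drive from a completed CA3 pattern passes.  MSP-only
  networks therefore cannot emit unique-feature memories (they score
  exactly at chance), while TSP-only networks can.

One open wiring question we resolved against the obvious default:
CA1 → EC_out learns at the fast rate.  At 0.002, item-specific output
associations cannot cross the expression threshold in ~9 exposures, and
no lesion condition could ever output a unique feature; pathway
identity is still preserved because output content is dictated by the
CA1 code (separated via TSP, overlapping via MSP).

The EC_in → EC_out one-to-one shortcut is wired but defaults to
strength 0: any appreciable input→output copy makes recognition probes
trivially self-satisfying and lifts untrained scores far above their
chance levels, contradicting the interpretability of every behavioural
measure.

## The three paradigms

`build_satellite_dataset()` — three categories × five "satellites" over
27 binary units (9 per category: 5 shared, of which the first is the
category-prototypical feature, plus 4 unique-feature units).  Each
non-prototype exemplar swaps one non-prototypical shared feature for a
unique feature.  Training: 140 trials; we use shuffled epochs truncated
at 140 (≈9–10 balanced repetitions per item) — an unbalanced
with-replacement draw leaves some items with too few exposures to learn
at all and makes every score bimodal across seeds.  Probes: unique
features alone (chance 0.25), categorization on the prototypical units
(chance 1/3), and 18 novel satellites (2 shared + 2 unique features).

`build_weather_dataset()` — the probabilistic weather task: 4 cards in
the 14 one-to-three-card combinations, with presentation frequencies
and P(sun) per combination from the classic published contingency (the
YAML in `inst/extdata` is editable; the three anchor probabilities
0.90 / 0.79 / 0.15 are asserted in tests).  Two units per outcome raise
category salience; the two 50/50 combinations are flagged out of
analysis but still trained.  Training is observational autoencoding
(cards + sampled outcome on input and target) for at most 50 trials,
with the stopping rule: after at least 25 trials, five consecutive
trials with sum squared error below 1.2.

`build_typicality_dataset()` — two categories over 10 binary features
(2 units each) plus 5 label units per category.  Prototypes share no
features and are never trained; the 20 training items share 9, 8, 7 or
6 features with their prototype in the fixed distribution
{9:2, 8:3, 7:3, 6:2}.  Five shuffled epochs give 100 trials.  The
42-item test set holds both prototypes and five novel items per
remaining distance level; probes omit the labels.  The monosynaptic
rate is lowered to 5e-4 here: the highly overlapping items otherwise
drive degenerate learning.

All arbitrary identities (which features swap, which novel combinations
appear) are seeded draws; the counts never vary.

## What the generator does and does not emulate

The stimuli are abstract binary feature vectors, as in the modelled
experiments; there is no image structure, no continuous feature
dimensions, and no feedback/reward signal (the weather task is the
observational variant).  Passing tests therefore speak to the circuit's
computational division of labour on discrete structured input, not to
perceptual processing of real stimuli.

## Lesions, scoring, similarity analysis

Lesions silence one pathway for the whole run — `TSP-only` sets the
EC_in → CA1 strength to 0, `MSP-only` zeroes the CA3 → CA1 weights —
and switch to a single-minus-phase schedule (with one pathway there is
only one meaningful minus phase).  CA1 ↔ EC_out is never lesioned
since it carries all output.  Probing clamps the probe on `Input`,
settles with all gates open (minus the lesion) and reads EC_out;
weights are bit-identical before and after (hash-checked in tests).

Scores are activation ratios over defined unit sets: sum-based ratios
for unique-feature/categorization/generalization, the literal
mean-based form for weather recognition (which can exceed 1), and both
sum- (default) and mean-based variants for typicality generalization.
A denominator summing below 1e-3 — a silent output — carries no
evidence and returns the chance level; with logistic activations an
exact zero never occurs, so this is the spec'd fallback made numeric.

Representational similarity uses Pearson correlations between evoked
hidden-layer patterns.  The *initial* response is operationalized
structurally — the EC_out → EC_in gate is held at 0 during settling —
so the subfields are seen before big-loop recurrence lets CA1 influence
DG and CA3; the *settled* response uses the full loop.  Constant
patterns get correlation 0 with a warning.

## Problem sizes and reproduction

The standard design is 100 randomly initialized networks per lesion
condition, which is what `scripts/acceptance.R` and the acceptance
test-suite use for the satellite and weather simulations (50 per
condition for the typicality simulation, whose individual networks are
the slowest; summary statistics are stable at that size).  All
randomness — masks, weights, trial orders, contingency draws — derives
from a single integer seed.

## Known limitations

* Single-feature cue retrieval through the trisynaptic pathway ignites
  the CA3 attractor in only a minority of probes (the cue must reach at
  least one trained CA3 winner through a 25% mask), so trained-item
  categorization from unique-feature cues plateaus near 0.45–0.55
  rather than the ~0.7–1.0 range reported for the original simulation
  environment; the corresponding ordinal dissociations all hold, the
  absolute level does not.
* The generalization advantage of MSP-only over intact networks is
  reproduced in direction but is small relative to seed noise; the
  intact network in this implementation loses less from trisynaptic
  interference than the original.
* MSP-only networks recognize atypical features of full typicality
  items better than the original's, because full-item probes clear the
  CA1 floor through the monosynaptic route; the intact-advantage
  dissociation on that task is correspondingly weaker.
* Exact transfer-function and inhibition constants of the original
  simulation environment are unavailable; every value used here is in
  `inst/extdata/hippocampus.yaml` and overridable per run.
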