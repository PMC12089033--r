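---
title: "The microzone computation: model, calibration and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The microzone computation: model, calibration and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mzn)
```

## The model in one paragraph

`mzn` simulates one cerebellar microzone network as a cascade of linear
unit functions connected by random sampling. Mossy fibre rates enter a
granular-layer region of 41 ranks × 100 fields; terminal branching and
clustering make every field's received rates behave like an independent
random sample, with replacement, of its rank's rates. A calibrated
inhibition chain converts each field's input into a sparse set of active
granule cells; pooled by files, these are the parallel fibre rates
received by the corresponding microzone sector. Stellate cells average a
binomially sized sample of those rates, Purkinje dendritic compartments
average small samples of stellate outputs from two flanking networks,
somata average compartments, and ~50 nuclear cells average random subsets
of the 400 somata. Because every step is an independent
sampling-and-averaging of the previous layer, the central limit theorem
progressively narrows the rate distribution while conserving its mean:
the network distils a collective signal without any learned parameter.
The simulation is a snapshot — one moment of a continuously refreshed
analogue computation; no temporal dynamics are modelled.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `n_ranks` × `fields_per_rank` | 41 × 100 | — | the region supplying parallel fibre input to one microzone; one sector (4 Purkinje, 80 stellate cells) per file |
| `granule_per_field` | 9000 | cells | granule complement of a 200 × 150 µm field |
| `glomeruli_per_field` | 700 | — | sites where inhibition meets granule dendrites |
| `active_fraction_target` | 0.005 | fraction | the sparse code; 0.5% of the ~84 000 parallel fibres crossing an inner stellate territory gives the 420-trial contact law |
| `stellate_law()` | Binomial(420, 0.0119) | — | active inputs per stellate cell; `p = 0.0119` is the rounded contact ratio 1000/84 000 and reproduces the printed probability table to 4 decimals (the unrounded ratio differs in the 4th decimal at x = 0 and x = 2) |
| `compartment_sample_size` | 6 | units | stellate cells innervating one Purkinje compartment, ~20% of a flank network |
| `nuclear_sample_min/max` | 30–50 | cells | convergence onto one nuclear output cell |
| sine drive | A = 100, baseline = 125, SD = 12.5 | Hz | keeps rank means inside the 0–250 Hz operating range; the within-rank spread is narrow so the drive is carried by rank means |

Rates are carried on a single linear "normalised Hz" axis throughout; all
unit functions are means, so any affine rescaling of the axis changes no
result.

## Input synthesis: what the generator emulates

Each rank draws its mossy fibre rates i.i.d. from a configurable
distribution (uniform 0–250 Hz, normal SD 40, a disjoint-band
"discontinuous" distribution spanning 50–300 Hz, or the sinusoidal swim
drive), truncated at zero. Distribution over fields models terminal
branching and clustering: each fibre places 4–12 terminal clusters along
its rank with a minimum centre-to-centre separation of 3 fields, each
cluster holds 2–7 terminals, and a binomially split random overlap
fraction sends part of every cluster into the adjacent field, capped so a
single cluster leaves at most 4 terminals in one field. These values are
the package's own reparameterisation of "several branches, several
terminals each": they were chosen, once, to satisfy three constraints
simultaneously and robustly — (i) ≈700 terminals per field, (ii) no
single fibre contributing ≥1% of any field's terminals even in fields at
the light tail of the terminal-count distribution, and (iii)
replacement-like field statistics. Wider per-cluster ranges meet (i) but
violate (ii) in light fields, because a large kept cluster can exceed 1%
of a below-average terminal complement.

Two boundary conventions are worth stating. First, cluster *positions*
wrap around the rank (the field row is treated as circular). Fields are
nominal subdivisions, not anatomy; an absorbing boundary would give the
two end fields ~25% fewer terminals purely as an artefact of where the
modelled window ends. Second, the minimum centre gap of 3 fields encodes
that clusters are about one field wide and separated by at least 200 µm
edge to edge, so the two-field footprints of one fibre's clusters are
disjoint — equivalently, a fibre never contributes two clusters to the
same field.

What the generator does *not* emulate: real mossy fibre rate
distributions (inputs here are synthetic test distributions), lobule- or
modality-specific termination patterns, 3-D cluster geometry, and any
temporal structure (bursts, refresh). Tests passing on this input show
that the *architecture* regulates density and distils signals for any
input shape in the operating range; they say nothing about what real
mossy fibre codes look like.

## Granular recoding and calibration

Within a field, 10 Golgi units each average 4 sampled terminal rates;
each of the 700 glomeruli averages 4 sampled Golgi rates, yielding the
inhibition level `scale × (sample mean) + offset`, floored at 0. Each of
the 9000 granule cells draws 4 dendritic pairs (random terminal
excitation vs random glomerular inhibition); a dendrite wins on strict
inequality (ties lose — a zero-measure event for continuous rates, and a
deterministic rule for degenerate ones), the cell fires on ≥3 wins of 4,
and an active cell's rate is the mean of all 4 dendritic excitations (the
linear unit function; a winners-only readout is available). The Golgi
chain sizes are plausible round numbers, configurable; the 3-of-4 rule
gives a steep, easily calibrated sparseness curve.

The calibrated constant is the **additive offset**, not the multiplier.
Inhibition then tracks the local mossy mean plus a constant, which has
two consequences that the multiplicative alternative lacks: a uniform
shift of all input rates shifts every layer's mean by exactly that amount
(unit slope — the cascade stays linear in the input), and the active
fraction is invariant across ranks whose means differ, which is what
keeps density regulated under the spatially varying swim drive. The
multiplier is retained (`mode = "scale"`) for experiments that want it.

Calibration is bisection on the offset against the mean active fraction
over a subsample of fields. Every objective evaluation reuses the same
dendritic draws — the very substreams the production run will use under
the same seed — so the objective is an exactly monotone step function,
bisection converges deterministically, and the calibrated run reproduces
the achieved fraction exactly on the evaluated fields. The default
subsample (min(all, 400) fields) trades calibration cost against the
field-heterogeneity error of the subsample mean; runs whose downstream
statistics are sensitive to the achieved mean (e.g. cross-shape
comparisons of file densities) should evaluate most or all fields.
If even the lower inhibition bound cannot reach the target the boundary
value is returned with a warning; an unbracketable target is an error.

## The molecular cascade

Stellate sample sizes are drawn from the Binomial(420, 0.0119) law,
truncated to ≥1 by redrawing: the mean-of-inputs unit function is
undefined on an empty sample, and truncation is the minimal intervention
(it raises the mean sample size from 5.00 to 5.03). Units sample only
their own sector's file pool, without replacement when the pool allows.

Purkinje flank networks are 16 same-sector units plus 0–8 (uniform) from
each sagittally neighbouring sector, drawn only from the inner three
depth layers (the outer two of the five layers have too short a
horizontal axon range to reach a neighbouring sector); edge sectors have
one neighbour and no wrap — the microzone, unlike the nominal field row,
has real ends. Each compartment samples 6 units per flank without
replacement *within* the draw but independently *across* compartments,
since innervating one compartment does not exclude a stellate cell from
innervating others. Compartment values average the two flanks; somata
average the 16 compartments; nuclear cells average 30–50 somata sampled
without replacement.

## The swimming experiment and its oracle

The swim drive gives rank *r* of *R* the mean
`baseline + A sin(phase + 2π·w·(r−1)/R)`, with `w` the fraction of one
body wavelength spanned by the row of ranks. Averaging a sinusoid over a
window of `L = 2πw` radians attenuates its amplitude by
`g(L) = (2/L)|sin(L/2)|`, so a mean-conserving network should show a
phase-swept output range of `2·A·g(2πw)`: exactly 0 at a full wavelength
(`w = 1`), ~0.30·2A at 3/4, ~0.64·2A at 1/2, ~0.90·2A at 1/4 — and the
1/2 : 3/4 ratio is 2.12. The inhibition constant is calibrated once, at
the first phase, and frozen across the sweep: the biological constant
does not track cycle phase. With the 41-rank discrete grid the
full-wavelength phase sum cancels exactly (ranks sample a full circle),
so residual range there is pure sampling noise; tests compare it to a
replicate noise floor measured at a fixed phase. The default comparison
threshold for the oracle is 25% relative, absorbing the granular layer's
mild nonlinearity (the active-cell mean is a thresholded-tail statistic,
not exactly the rank mean) and nuclear sampling noise.

## Numerical and reproducibility choices

* Every stage draws from a substream keyed by `(master seed, stage,
  unit index)` via a congruential hash below 2^31, so stage order cannot
  change results, any stage can be replayed in isolation, and reruns are
  bit-identical. Simulators restore the caller's RNG state on exit.
* Cluster positions use an exact stars-and-bars gap-composition sampler
  (uniform over valid circular arrangements), not rejection.
* Counts derived from continuous arithmetic are rounded to nearest, not
  floored (the anatomy is "~84 000", "around 420").
* Degenerate inputs are defined: constant rates propagate exactly
  (means of constants), empty fields and empty file pools are errors
  naming the location, and a flank network smaller than the compartment
  sample size is an error (unreachable at default geometry).

## Study sizes used by the test suite

Printed-arithmetic checks (the probability table, 84 000 / 420 / 4100 /
8000 / 400) run at the exact default geometry. Stochastic figure-level
checks run on reduced-density geometries that preserve the full 41-rank
topology — `scale` shrinks the per-field granule/glomerulus/terminal
complement (e.g. `scale = 0.08` with 40 files for density regulation,
`scale = 0.4` for the cascade, `scale = 0.06` with 30 files for the
~130 network evaluations of the swim block) — sizes chosen so that each
check's sampling error
is several times smaller than the effect it measures. The compartment-
span check uses the full default molecular layer driven by synthetic
60-unit file pools.

## Known limitations

* The granular transform is a stylised stand-in for the richer upstream
  granular-layer model it summarises: the sparse code's *shape* (a
  thresholded upper tail, span ~120 units under 0–250 uniform input) is
  broader than the focused code the full model produces, which inflates
  absolute molecular-layer spans; cross-layer ratios and all regulation,
  conservation, linearity and phase-sensitivity properties are
  unaffected.
* No temporal dynamics, no basket-cell pathway, no plasticity, no
  nucleo-olivary feedback; the Purkinje soma value is the integrated
  modulation on the shared linear axis, not an absolute firing rate
  (spontaneous rate and the sign convention of inhibition are affine
  choices outside the computation).
* The granule-cell ascending-axon and parallel-fibre feedback loops that
  may tighten physiological density regulation further are absent, so
  simulated field-to-field variation is an upper bound.
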