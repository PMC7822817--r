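---
title: "Neuromorphic tactile encoding: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neuromorphic tactile encoding: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurotact)
```

## The system

`neurotact` simulates a bio-inspired tactile pathway: a 5×5 pressure-sensor
array (taxels, 2.8 mm pitch, 10-bit ADC, 1 ms sampling) is read out by a
population of 23 digital afferents — 6 slowly adapting type-I (SA-I)
mechanoreceptive afferents, 12 rapidly adapting type-I (RA-I) afferents and
5 nociceptors — whose spike trains are decoded to recognise the sharpness of
an indented object. The pipeline has five stages:

1. **Stimulus**: a cone or cube is pressed into the array with a trapezoidal
   depth profile (250 ms onset, 2000 ms hold, 250 ms offset by default).
2. **Innervation**: each afferent innervates a few spatially nearby taxels
   with random weights, forming overlapping receptive fields.
3. **Encoding**: Izhikevich spiking dynamics convert each afferent's drive
   into a spike train; an optional Q13.18 fixed-point mode reproduces
   digital-hardware arithmetic.
4. **Decoding**: windowed spike counts (rate code) or Victor–Purpura
   distances (temporal code) summarise the population response.
5. **Classification**: PCA to three components plus a 5-nearest-neighbour
   classifier under stratified five-fold cross-validation.

## Neuron model

All afferents use the two-variable Izhikevich model in its power-of-two
rescaled form (the classical voltage equation multiplied by 0.78125 so every
coefficient is a power of two, convenient for digital arithmetic):

$$v' = \tfrac{1}{32}v^2 + 4v + 109.375 - u + k_s \tfrac{I}{C_m}, \qquad
  u' = a(bv - u),$$

with reset $v \leftarrow c$, $u \leftarrow u + d$ when $v \ge 30$ mV, Euler
discretised at $dt = 1$ ms. SA-I and RA-I afferents use the regular-spiking
preset ($a = 0.02,\ b = 0.2,\ c = -65,\ d = 8$), nociceptors the
fast-spiking preset ($a = 0.1,\ b = 0.2,\ c = -65,\ d = 2$). Input gains are
$k_1 = 1/32$ (SA-I), $k_2 = 1/8$ (nociceptor) and $k_3 = 128$ with
$\tau = 1$ s applied to the rectified derivative (RA-I); $C_m = 1$ F.

With zero input the regular-spiking neuron settles at the stable root of
$\tfrac{1}{32}v^2 + 3.8v + 109.375 = 0$, about $-74.82$ mV; the test suite
checks the simulated rest state against that root computed independently
with `polyroot`.

**A discretization hazard that shaped the calibration.** At `dt = 1` ms the
Euler map is only faithful at physiological firing rates. If sustained input
drives a neuron fast enough that the recovery variable `u` climbs beyond
roughly 60, a single Euler step overshoots the membrane potential far below
the left branch of the quadratic nullcline, from where the $v^2$ term
catapults it above threshold in one step — the neuron then oscillates
forever, even with zero input. Real hardware running these exact equations
has the same property, so the operating currents must keep rates below
roughly 150 Hz. This is why the interface conversion gains (below) are small.

## Input conditioning per afferent class

* **SA-I**: drive = receptive-field weighted sum of taxel counts, applied
  every step (sustained response).
* **RA-I**: the drive is differenced at 1 ms and full-wave rectified,
  `k3 * |I[n+1] - I[n]|`. Rectification is full-wave so both onset
  (increasing pressure) and offset (decreasing pressure) excite the neuron;
  during the hold phase the derivative is zero and the RA-I afferent is
  silent.
* **Nociceptor**: every channel sees the whole array through the statistic
  `MCV / NoT` — the maximum taxel value divided by the number of taxels
  above threshold. Concentrated force (sharp contact) gives few active
  taxels with a high maximum, hence a large "noxious" input; the same force
  spread over many taxels is innocuous. In fixed-point mode the division is
  a right-shift by `ceil(log2(NoT))`, as a digital divider would implement
  it. The five nociceptor channels receive small, seeded multiplicative gain
  perturbations (±5%) so they are not bit-identical copies.

### Interface conversion gains

The ADC-to-current conversion of the interface circuit is a free calibration
of the model. Defaults: 2 for SA-I, 1 for nociceptors, 1/32 for the RA-I
derivative pathway. The calibration objectives, fixed before any classifier
was evaluated, were: (i) rates in the physiological range (SA-I
≈ 10–40 Hz, graded with contact area; nociceptors up to a few hundred Hz
for sharp contacts), (ii) the SA-I population rate strictly increasing and
the nociceptor rate strictly decreasing across the 1–9 mm object set
(verified over many innervation seeds), and (iii) no Euler catapult
(see above). The RA-I value 1/32 compensates the large derivative gain
`k3 = 128` so that onset/offset inputs land in the same moderate
suprathreshold range as the sustained SA-I inputs.

## Synthetic stimulus generator

No robotic dataset is distributed, so the package generates one. A trial is
a 2501-frame sequence (1 ms steps) of integer ADC counts.

**Contact model.** Per-taxel pressure is

$$p_{ij} = g \cdot d(t) \cdot s^{-1/2} \cdot \mathrm{cov}_{ij},$$

where $d(t)$ is the trapezoidal depth (mm), $s$ the feature size (cone apex
diameter or cube width, mm), and $\mathrm{cov}_{ij}$ the object's contact
cross-section — a disc for cones, a square for cubes, edge-smoothed by a
Gaussian of width 1.4 mm (half the pitch) standing in for the
force-dispersing silicone layer — integrated over each taxel's cell by a
7×7 midpoint rule. The $s^{-1/2}$ factor models Hertz-like contact-stress
concentration: sharp indentors press a small area at high local stress. The
gain $g = 750$ counts/mm puts the sharpest object near the 10-bit full
scale at 1.4 mm depth. Consequences, verified in the test suite: peak
pressure strictly decreases with feature size, the half-peak active-taxel
count strictly increases, and total pressure grows with contact area. The
last property is what lets the SA-I population rate grow with bluntness —
a normalised (size-independent) total force cannot reproduce that ordering
under the model's nearly linear rate-vs-current curve.

**Trial-to-trial variability.** Two seeded sources: a per-trial contact-
centre jitter, uniform in ±1 mm on both axes (repositioning error across
the 10 repeated touches), and additive Gaussian sensor noise per frame and
taxel with sd 0.5 counts. The noise default is deliberately at the
effective-ADC-noise level: at 1 kHz sampling, a white noise floor much above
one count would be amplified by the RA-I derivative gain into sustained
firing through the hold phase, which rapidly adapting afferents do not show;
with realistic sub-LSB noise, the RA-I channels burst at onset and offset
and stay (essentially) silent in between. Variability across repeated
touches is dominated by the jitter.

**What the generator does not emulate**: finite-element skin mechanics,
sensor hysteresis and creep, correlated (drift-like) noise, robot timing
variability, and electrical crosstalk. Passing tests on this synthetic data
therefore demonstrate the internal consistency of the encoding/decoding
machinery and its qualitative agreement with the physiology it mimics — not
performance on any particular physical sensor.

## Innervation

Per afferent: a centre drawn uniformly over the grid; a taxel count drawn as
`1 + Poisson(mean_taxels - 1)` (mean exactly `mean_taxels`, degenerate at
1), capped at — and saturating to — the neighbourhood size; taxels sampled
without replacement from the Chebyshev radius-1 neighbourhood (radius 2 when
`mean_taxels > 9`); weights i.i.d. uniform on (0.25, 1]. Weights are not
normalised per field, so drive and firing rate grow with field size.
Coverage statistics (`coverage_stats`) show the expected unused-taxel count
falling as fields widen.

## Decoding and evaluation

* **Rate code**: spike counts in `(start, end]` windows measured from
  contact onset; the standard analysis window is `(0, 500]` ms.
* **Temporal code**: exact Victor–Purpura distances by dynamic programming
  (insertion/deletion cost 1, shift cost `q|Δt|`), summed over channels
  (labelled lines — afferents are physically distinct, so spikes cannot be
  exchanged across channels). The default `q = 0.05`/ms corresponds to a
  40 ms insert-vs-shift crossover, mid-range temporal precision for 2.5 s
  trials; it is exposed as a parameter and swept in experiments.
* **Classifier**: per training fold, channels are standardised to unit
  training variance, PCA keeps three components, and held-out trials are
  projected with the training fit (no leakage) before a 5-NN majority vote;
  ties go to the label of the nearest neighbour among the tied labels
  (deterministic). Standardisation keeps a few high-variance channels from
  monopolising the leading components. Five-fold stratified cross-validation
  is the headline protocol; a stratified 80/20 split is available
  (`eval_config(protocol = "split")`) since cross-validation is the more
  reproducible summary.

## Fault injection

Taxel faults zero a seeded subset of sensor outputs at the interface —
before innervation and before the nociceptor statistic — and therefore
require re-encoding; channel faults silence a seeded subset of the 23 spike
trains after encoding. Realised counts use round-half-up, the damaged
subsets persist across all trials of one condition, and the sweep grid is
0–50% in steps of 10% with 10 fault seeds per point. A characteristic
interaction: killing taxels while the strongest taxel survives can only
raise the nociceptor input (`NoT` drops, `MCV` does not), so sensor damage
makes innocuous touches read as more noxious.

## Reproducibility and numerical choices

* One master seed fans out to every random stream (trial noise/jitter,
  innervation, nociceptor gains, CV folds, fault subsets) through a
  documented Lehmer-style scheme (`derive_seed`); result tables are written
  with numerics fixed to six decimals so reruns are byte-identical.
* Q13.18 fixed point: round-to-nearest on conversion, truncation after
  multiplication, saturation (flagged) at the 32-bit register bounds. All
  rescaled model constants except $a$ and $b$ are dyadic and exactly
  representable; whole-trial fixed-point encodings match floating point to
  within one spike per channel on the mechanoreceptor pathways.
* The nociceptor taxel threshold defaults to 102 counts (10% of full
  scale), low enough that every object of the default set registers at full
  indentation; blunt touches stay innocuous because the `MCV/NoT` division —
  not the threshold — suppresses spread contacts. A higher threshold would
  silence the blunter half of the object set entirely and flatten the rate
  gradient the contribution analysis measures.
* Degenerate inputs: zero depth gives an all-zero frame; a footprint
  entirely off-grid gives zeros with a warning; empty spike-count windows
  give zero features; `NoT = 0` gives zero nociceptor input; empty
  validation folds and classes missing from a training fold are rejected
  with informative errors.

## Problem sizes used in the tests

Unit tests run on shortened trapezoids (50/200/50 ms) and small datasets;
the study-level checks use the full protocol: 80-trial datasets (8 objects
× 10 touches, 2.5 s at 1 ms), phenomenology averaged over 6 innervation
maps, pipeline accuracy averaged over 10 master seeds, fault sweeps over
10 fault seeds per fraction, and the synergy comparison over 20 master
seeds × 3 innervation maps × 2 fold assignments. These sizes give the
monotonicity and ordering contrasts comfortable statistical margins while
keeping a full run in minutes on one core.

## Known limitations

* The `dt = 1` ms Euler discretization caps usable firing rates; faster
  dynamics would need a smaller step than the hardware convention used here.
* The contact model is a geometric stress heuristic, not contact mechanics;
  absolute rates and accuracies are not predictions for any physical device.
* With sub-millisecond-uncorrelated sensor noise above ~1 ADC count the
  RA-I derivative pathway saturates with noise-driven spikes; modelling
  noisier sensors would require a band-limited front-end filter, which the
  hardware convention modelled here does not include.
* The five nociceptors differ only by small gain perturbations; with exact
  division and no perturbation they would be bit-identical.
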