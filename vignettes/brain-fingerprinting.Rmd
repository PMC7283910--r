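---
title: "Brain-network fingerprinting from EEG: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Brain-network fingerprinting from EEG: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

brainfp implements a pipeline that turns multichannel EEG recordings into
directed functional-connectivity "fingerprints" and identifies participants
from them. This vignette explains the model at each stage, the tunable
parameters and why their defaults are what they are, what the synthetic
cohort generator does and does not emulate, and the numerical and design
choices a maintainer should know about.

## The pipeline at a glance

For each run of each participant:

1. **Filter** the 64-channel signal: zero-phase FIR band-pass 1–70 Hz with
   a 60 Hz notch.
2. **Artifact hook**: an optional user-supplied cleaning function (by
   default the identity).
3. **Segment** the run by its event annotations (rest `e1`, task onsets
   `e2`/`e3`), concatenating repeated occurrences of the same event code.
4. **First-difference** each segment channel-wise.
5. **Symbolize**: pool all 64 channels of the segment, split the pooled
   amplitude distribution into terciles, and map each sample to {1, 2, 3}.
6. **Symbolic transfer entropy (STE)**: the plug-in estimate of first-order
   transfer entropy between every ordered channel pair, giving a 64×64
   non-negative asymmetric coupling matrix per (participant, task, event).
7. **Brain network**: the minimum spanning arborescence (Chu–Liu/Edmonds)
   of the coupling-derived weighted digraph.
8. **Fingerprint**: the complex eigen-spectrum of the coupling matrix,
   z-score normalized and coarse-grained onto a 2-D grid.
9. **Identification (SDSS)**: per-participant reference grids are built
   from the three events of a reference task; a held-out spectrum is
   scored against every reference by histogram intersection and labelled
   with the arg-max.

## Transfer entropy and the symbol alphabet

For symbol processes $X$ (target) and $Y$ (source), first order in both,

$$TE_{Y \to X} = \sum_{x_{n+1}, x_n, y_n} P(x_{n+1}, x_n, y_n)\,
  \log_2 \frac{P(x_{n+1}, x_n, y_n)\,P(x_n)}{P(x_{n+1}, x_n)\,P(x_n, y_n)},$$

estimated by plugging in empirical joint frequencies; zero-probability
terms contribute 0, and the plug-in value is non-negative (tiny negative
round-off is clamped). The unit is bits.

Two state spaces are supported by `ste_matrix()`:

* `states = "symbols"` (default): the raw tercile symbols, a 3-state
  process.
* `states = "words"`: the phase-space embedding of the symbols into
  overlapping length-3 words (`m = 3`, delay `tau = 1`), a 27-state
  process.

The default is the symbol-level estimator because of estimator bias. The
plug-in TE of independent processes concentrates near $d/(2 n \ln 2)$
bits, where $d$ is the number of free parameters of the conditional model.
For the word process $d \approx 1404$ (2 free next-symbol probabilities
per (word, word) conditioning cell), giving a bias of ~0.19 bits at
n = 5375 samples and ~0.51 bits at n = 1968 — the two segment lengths the
event protocol actually produces. Two consequences were measured on
synthetic cohorts: weak couplings drown in the bias floor, and matrices
estimated from segments of different lengths acquire length-dependent
offsets that invert the between/within distance ordering. The 3-state
estimator has $d = 12$ (bias < 0.001 bits at these lengths) and none of
these pathologies; it is the same first-order formula, applied to the
alphabet the tercile map produces. The word-level estimator remains
available and is tested at its analytic expectations.

Terciles are pooled across all 64 channels of one (participant, task,
event) segment — not per channel — so a channel's symbols encode its
amplitude relative to the whole head at that moment. Threshold ranks are
$\lfloor L/3 \rfloor$ and $\lfloor 2L/3 \rfloor$ of the pooled sorted
sequence; values equal to a threshold go to the upper band, and the top
band is closed.

## Filtering

The FIR band-pass is a Hamming windowed sinc, applied forward–backward
(zero phase) after reflect-padding by one filter length. With
`fir_order = "auto"` the tap count follows the common EEG rule
$\lceil 3.3 / (\Delta f / f_s) \rceil$ with transition width
$\Delta f = \min(\max(f_{low}/4,\,2),\,f_{low})$; at 160 samples/s with a
1 Hz lower edge this gives 528 taps. The notch is a 2 Hz-wide FIR
band-stop rather than an IIR biquad, to preserve phase linearity. Because
each forward–backward pass of a symmetric FIR equals one convolution with
the kernel's self-convolution, the whole cascade is collapsed into a
single combined kernel applied by FFT to all channels at once; this is
exact up to floating point and roughly 20× faster than per-channel
filtering.

Filtering is applied to the whole run before segmentation, so event
boundaries do not create filter transients inside segments.

## The directed brain network

The coupling matrix defines a complete weighted digraph (no self-loops).
`from_ste()` offers two weight orientations: `"literal"` uses TE values as
distances, so the minimum arborescence minimizes summed TE; `"negate"`
flips the sign so the tree maximizes total information flow. The default
is `"literal"`; neither orientation can be validated against a printed
reference network, so the mode is always recorded in the artifact
metadata.

`minimum_arborescence()` is a full recursive Chu–Liu/Edmonds
implementation: pick each non-root node's cheapest incoming edge; if the
chosen edges contain a cycle, contract it into a super-node, reducing the
weight of each entering edge by the weight of the cycle edge it would
displace; recurse, then expand each contraction by dropping the displaced
cycle edge. Ties among equal-weight entering edges go to the lowest
source index, so results are deterministic given a root. The root policy
is seeded-random by default (the seed is logged), with an explicit
electrode override. Correctness is tested against exhaustive enumeration
of all spanning arborescences on hundreds of random digraphs.

## Spectra, normalization and coarse-graining

The 64 complex eigenvalues of the coupling matrix are the fingerprint.
Eigen-solvers return them in arbitrary order, so the package imposes a
canonical order (descending modulus, then descending real part, then
non-negative imaginary part first); the canonical vector of 64 real parts
followed by 64 imaginary parts (length 128) is what enters cohort-level
ANOVA layouts.

Z-scoring is per matrix and per component: real and imaginary parts are
standardized independently to mean 0, sample SD 1. A zero-variance
component (e.g. a spectrum that is entirely real) cannot be standardized
and is set to 0 with a warning. Per-matrix scoping keeps a participant's
fingerprint self-contained — no cohort statistics leak into it.

Coarse-graining bins eigenvalues into square cells of side `theta`, lower
edge of the first cell closed. The SDSS default is `theta = 0.5` on the
z-scored scale. The choice matters: a z-scored spectrum spans roughly six
standard deviations, so cells of size 1 collapse the fingerprint into a
~6×6 grid whose central cells are occupied by every participant's bulk
eigenvalues; measured on synthetic cohorts, identification accuracy rises
substantially when moving from `theta = 1` to `theta = 0.5`, and is flat
between 0.5 and 0.25. A cell size of 1 is the natural choice only when
gridding raw, unnormalized spectra whose spread is an order of magnitude
larger; `coarse_grain()` itself is scale-agnostic and supports both.

## SDSS identification

The reference set is the fitted model (`sdss_reference()`): per
participant, the grids of the three reference-task event spectra are
summed cell-wise on ranges pooled over all reference eigenvalues, giving
one 192-point reference fingerprint each. Summation (not union of
support) preserves mass, so intersection scores are comparable across
participants.

The score between a 64-point test grid and a reference grid is the
histogram intersection $\sum_c \min(t_c, r_c)$ — symmetric, bounded by
the smaller total mass, and equal to the total mass only for identical
grids. The winner is the arg-max; ties resolve to the lowest participant
id and are flagged. Test eigenvalues outside the reference ranges are
clipped into boundary cells and counted, never dropped silently.

The cross-test protocol draws, per repetition, a random partition of the
cohort into three groups (as equal as possible; 3×33 for a cohort of 99),
assigns each group to one of three held-out task pools, identifies every
item, and records the fraction correct over the whole cohort.
Identification outcomes are deterministic, so the package computes them
once and lets the draws resample only the partition — 1,000 draws cost
the same as one.

## The synthetic cohort generator

`make_cohort()` and `simulate_run()` exist so the whole pipeline,
including the identification experiment, runs end-to-end without any
external data. Dynamics are first-order vector-autoregressive:
$x_{t+1} = A^\top x_t + \eta\,\varepsilon_t$ over 64 channels at 160
samples/s, with the event protocol reproducing the reference run timing
exactly (eight 672-sample rest spans alternating with seven 656-sample
task onsets; run length 19248).

Each participant's coupling $A_p$ is the fingerprint:

* sparse support, edge probability ~5% (scaled per participant by a
  0.8–1.2 factor);
* gains uniform in magnitude 0.5–1 with random sign — mixed
  excitatory/inhibitory influence keeps the spectral radius of the raw
  draw low, so after rescaling to the participant's target radius
  (0.85–0.95) individual edges remain strong enough for the symbolic
  estimator to detect at event-segment lengths;
* a participant-specific hub structure: 2–8 hub channels whose outgoing
  couplings are boosted ×3 before the rescale.

The hub structure deserves emphasis. The eigen-spectrum is invariant
under channel permutations, so two participants who differ only in
*which* pairs are coupled — at identical density, gain distribution and
radius — have nearly indistinguishable spectra even when their coupling
matrices are far apart in Frobenius distance (matrix-level
nearest-neighbour identification is perfect on such cohorts while
spectrum-level identification hovers near 0.65). Hub-dominated
connectivity, with individual variation in hub number and placement,
gives each participant a characteristic set of large-modulus eigenvalue
outliers that survive z-scoring and estimation noise; it is also the
realistic structure for brain networks, where a few "key nodes" carry
disproportionate out-strength — the same nodes that surface as the
largest out-degree hubs of the spanning-tree networks.

Task runs modulate the gains of two disjoint event-specific edge subsets
by a factor $1 + 0.1\,g$ with per-run gains $g = 1, 1.5, 2, 2.5$
(reference run plus three held-out runs). Modulation is deliberately
mild — 10–25% — because the condition being emulated is a cohort whose
individual networks stay essentially constant across cognitive states; a
stability guard rescales a modulated coupling back to spectral radius
0.97 in the rare case modulation pushes it above.

What the generator does **not** emulate: 1/f spectral slopes, volume
conduction and reference-electrode mixing, oscillatory rhythms,
artifacts (ocular, muscular), or non-stationarity within a run.
Passing the end-to-end recovery experiment therefore shows that the
pipeline's stages compose correctly and that detectable, stable directed
couplings are identified and discriminated — not that real EEG cohorts
will reach the same accuracy.

Cohort draws are rejected until all pairwise Frobenius distances between
couplings reach the `separability` floor (default 1); the floor is
verified exhaustively and a labelled error reports an infeasible
combination after a bounded number of retries.

## Problem sizes used in the shipped experiments

The test-suite and acceptance-script experiments use a cohort of 10
participants with four simulated runs each (one reference, three
held-out), full-length 19248-sample runs, and 200–1,000 cross-test
draws. At these sizes the complete end-to-end experiment — simulation,
filtering, 120 coupling matrices, networks, spectra, reference fit,
identification and cross test — takes on the order of a minute on a
single CPU. Estimator closed-form checks use sequences of length 10⁴;
the arborescence oracle enumerates all spanning arborescences on 200
random digraphs with up to 5 nodes.

## Numerical conventions and degenerate inputs

* Latencies are 1-based inclusive sample indices; an event's last sample
  is `latency + duration - 1`, and the gap convention between
  consecutive events is `next_start − previous_end`.
* $0 \log 0 = 0$ throughout the entropy code; conditional probabilities
  with empty denominators contribute nothing.
* Plug-in TE values are clamped at 0 from below (round-off only).
* All-equal pooled amplitudes give `t_low = t_high`, sending every
  sample to symbol 3; TE is then exactly 0.
* Grids conserve mass for every `theta`; a point exactly on the shared
  lower range edge belongs to the first cell.
* Every source of randomness (cohort draw, run noise, random root,
  cross-test draws) takes an explicit seed.

## Known limitations

* The identification stage is a lossy summary by design: the coupling
  matrices separate participants better than their spectra (the
  permutation invariance discussed above), and histogram intersection is
  mass-sensitive — rescaling reference masses is not score-neutral.
* The plug-in TE estimator is biased upward at short segment lengths;
  the package mitigates this via the 3-state default but does not
  bias-correct.
* The EDF reader covers the common layout of the reference dataset
  (16-bit samples, one annotation channel, EDF+C); it is not a general
  EDF++ implementation.
* The artifact-removal stage is a hook, not an implementation: cleaning
  quality is entirely the responsibility of the supplied function.
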