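---
title: "Quantifying protein footprints on RNA: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying protein footprints on RNA: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(footprintr)
```

This vignette is the package's own account of the models it implements:
the generative model behind the synthetic data, the quantification
conventions, the difference-calling and motif-assignment rules, and the
cooperative binding fit, together with the numerical choices made where
the method leaves them open.

## The measurement model

Hydroxyl radicals cleave the RNA backbone at a rate roughly
proportional to the solvent accessibility of each nucleotide's ribose.
In a high-throughput readout, cleavage positions are detected by primer
extension with fluorescent primers and resolved by capillary
electrophoresis; a parallel reaction omitting the radical-generating
catalyst provides a background channel of reverse-transcription stops
unrelated to cleavage. The quantity of interest at nucleotide $i$ is a
*normalized reactivity* $r_i$ on a scale where 1.0 is the mean
intensity of highly reactive (fully exposed) nucleotides.

The synthetic generator mirrors this chain. Plus-channel intensity is

$$I^{+}_i = s \cdot a_i \cdot \varepsilon_i + b_i, \qquad
  I^{-}_i = b'_i$$

where $a_i \in [0,1]$ is ground-truth accessibility, $s$ the intensity
scale (arbitrary fluorescence units, default 1000),
$\varepsilon_i$ multiplicative lognormal noise with mean 1 and
coefficient of variation `noise_cv`, and $b_i, b'_i$ independent
background draws with mean `background_rate`·$s$. The noise is
multiplicative and lognormal because probing intensities are positive
and right-skewed; the background is drawn independently of
accessibility because the control channel measures primer-extension
stops, not cleavage.

**Noise default.** `noise_cv = 0.05`. Capillary-resolved cleavage data
are quantitative, with replicate agreement at the few-percent level;
0.05 keeps replicate (free-vs-free) smoothed reactivity differences
about six standard deviations below the 0.2 calling threshold, which is
what the fixed-threshold calling rule assumes of well-behaved replicate
background. Property tests that specifically probe behavior at an
elevated background (mean replicate |Δ| = 0.1, i.e. half the threshold)
set that noise level explicitly.

**Footprint depth.** The fractional accessibility loss at
protein-contact sites in the bound state is a free parameter
(`footprint_depth`, default 0.8): footprint depth at protected sites is
not a quantity the measurement conventions fix, so it is exposed and
documented rather than hard-coded. At the default, bound-state
reactivity at a fully exposed contact site drops from ~0.9 to ~0.18,
i.e. a difference of roughly −0.7, far beyond the calling threshold.

## The toy RNA

`build_toy_structure()` lays out, in order: a short 5′ exon, a P2
hairpin closed by a GAAA tetraloop (L2), a buried core helix P4, a P5
receptor hairpin, a second core helix P6, a P8 receptor hairpin, a P9
hairpin with the second GAAA tetraloop (L9), and a 3′ exon, with
junction segments absorbing the remaining length (minimum total
80 nt — below that the two motifs cannot be placed). Two
tetraloop-receptor contacts are annotated: L2 docks on P8 and L9 on P5,
linking distant parts of the molecule the way such contacts tie
together the helical domains of group I introns.

Free-state accessibility is high (uniform 0.75–1.0) everywhere except
the two core helices, which are buried (0.10–0.20) and together cover
~20% of the RNA — matching the observation that a large, not-yet-docked
RNA shows only about a fifth of its nucleotides protected, with the
tertiary-contact elements themselves reactive. In the bound state,
accessibility is reduced by `footprint_depth` at three segments per
motif: the tetraloop, the loop-proximal half of the receptor stem (the
docking face, both strands), and the outer half of the receptor stem
(the exterior-facing extension). This encodes the three-part protection
signature that `signature_check()` later tests for; the "extension
toward the exterior" is operationalized as the receptor-helix half
farther from the docking face, a deliberately simple reading of how
such protections extend along the receptor helix.

What the generator does *not* emulate: electrophoretic mobility shifts
between dye channels, ladder misalignment, sequence-dependent reverse
transcriptase stops, heteroscedastic saturation of strong peaks, or
partial occupancy mixtures. Passing tests therefore demonstrate that
the quantification rules are implemented correctly and behave as
designed under a realistic noise model — not that the pipeline is
robust to every artifact of real capillary data.

## Trace processing

`simulate_trace()` renders a profile as Gaussian peak trains (one peak
per nucleotide and channel) on a shared elution axis, with peak area
equal to intensity times an exponential decay $d^{\,i}$ in the 1-based
position $i$ (default $d = 0.999$, emulating processivity loss of the
primer-extension signal). `integrate_peaks()` recovers areas by
numerical integration within ±3 peak widths of each expected center,
and `correct_signal_decay()` divides by $d^{\,i}$. The grid step is at
most half the peak width, and peak width must be smaller than the peak
spacing (rejected otherwise), so adjacent windows do not overlap and
the ±3-width window captures all but ~0.3% of each peak's mass — the
source of the documented 1% round-trip tolerance. Peak *area*, not
height, is the intensity estimate, making the step robust to width
variation. This module is deliberately a simplified surrogate for
production trace-analysis software: it does no dye mobility correction
and no base calling, and uses a single known decay rate rather than
fitting one.

## Normalization and classification

`normalize_reactivity()` implements the 8%-after-2% rule: with $N$
unmasked positions sorted by descending intensity (ties broken by
position), the top $\lceil 0.02N \rceil$ values are excluded and the
mean of the next $\lceil 0.08N \rceil$ values is the normalization
factor. Ceiling counts guarantee non-empty sets, and a minimum of 25
unmasked positions is required so the reference set exists. By
construction the reference-set mean after division is exactly 1.0; the
transform is scale-invariant and idempotent. Background subtraction
precedes normalization as `max(plus − scale·minus, 0)` with channel
scale defaulting to 1 — the floor at zero reflects that negative
cleavage is meaningless.

Nucleotides with reactivity at or below 0.5 are classified solvent
inaccessible. The "one-half the mean" cutoff is read against the
defined reference mean of 1.0 (hence 0.5), because the classification
rule is stated immediately after that definition; reading it as half
the overall profile mean would make the cutoff depend on the fraction
of buried nucleotides, which the scale was designed to avoid.

Smoothing (`smooth_reactivity()`, default 3-nt centered window) is for
display and difference mapping only; normalization statistics and the
inaccessibility classification always use unsmoothed values. At the
sequence ends the window shrinks to available neighbors, and masked
positions are dropped from each window mean.

## Difference calling

`difference_profile()` subtracts free from bound reactivities
(protections negative, enhancements positive), unioning masks and
refusing mixed smoothing states. Differences are computed on smoothed
profiles by default — the convention for displayed difference plots —
with unsmoothed mode a flag away. `call_changes()` applies a fixed
effect-size threshold, |Δ| ≥ 0.2, *inclusive* ("0.2 or greater"). This
is deliberately not a p-value procedure and no multiple-testing
correction applies; the threshold represents 2× a typical mean
replicate background of 0.1, and `estimate_threshold()` reproduces that
logic from user-supplied replicate comparisons (multiplier × mean |Δ|),
falling back to the default 0.2 when no replicates are available.
`segment_regions()` groups same-direction calls allowing `max_gap`
intervening positions (default 1, so a single masked site cannot split
a footprint).

## Motif assignment

`find_gnra_tetraloops()` matches hairpin loops of exactly four unpaired
nucleotides closed by a pair whose sequence is G, any, purine, A.
Calls are classified per *position*: `within` if inside an element
participating in a tetraloop-receptor contact, `adjacent` if within
`adjacency_k` nucleotides of such an element along the sequence, else
`distal`. "Immediately adjacent" is quantified as `adjacency_k = 2` by
default — the method itself never fixes this distance, so it is an
exposed parameter; position-level classification (rather than
element-level) prevents a long junction that merely abuts a receptor
helix from inheriting `adjacent` status wholesale. `motif_coverage()`
is the fraction of protected positions classed within/adjacent, is
monotone non-decreasing in `adjacency_k`, and is reported as undefined
(not 0) when there are no protections.

## Cooperative binding fits

`fit_hill()` estimates $(A, n, K_{1/2})$ by bounded Levenberg-Marquardt
least squares on fraction bound, with the model written in the ratio
form $A\,(p/K_{1/2})^n / ((p/K_{1/2})^n + 1)$ for numerical range
safety. Loss is unweighted by default (a weighted mode exists).
Initialization needs no user input: $A_0$ = maximum observed fraction,
$K_0$ = concentration nearest half-max, and $n_0 \in \{1, 2, 3\}$
multi-start, keeping the best converged start by residual sum of
squares — this makes fits deterministic given the data. Bounds
($A \in (0, 1.1]$, $n \in (0.2, 6]$, $K_{1/2} \in (0, 10^5]$ nM)
prevent degenerate solutions on flat data; if no start converges the
fit is returned with `converged = FALSE` and `NA` coefficients rather
than a best-effort number. $R^2 = 1 - SS_{res}/SS_{tot}$; zero-variance
data leaves it undefined with a warning. Preconditions: at least 5
points spanning at least a decade; an optional RNA-concentration check
warns when the trace-RNA assumption of the Hill form is violated
(RNA above $K_{1/2}/5$). The Hill form is phenomenological — the
package deliberately does not model sequential versus concerted binding
mechanisms.

Under the simulation conditions used throughout the tests (12
log-spaced concentrations spanning the titration midpoint, Gaussian
noise sd 0.02 on fraction bound), the median recovered $K_{1/2}$ over
100 replicate curves lands within a few percent of truth and the median
recovered $n$ within ±0.1. The per-curve spread of $\hat n$ is wider
(sd ≈ 0.1–0.15, growing with $n$) because only the few concentrations
in the transition region inform the Hill coefficient — an inherent
property of a 12-point design, not of the optimizer, which the test
suite verifies agrees with an exhaustive grid search.

## Problem sizes and determinism

The test suite and the acceptance script run entirely on generated
data at the scale the analyses are designed for: 540-nt profiles
(80–300 nt for focused unit tests), 12-point titrations with 100
replicate curves per scenario, and 100-seed end-to-end pipeline
replicates. Every stochastic step takes an explicit integer seed
(`withr::with_seed`, so the global RNG state is untouched), making all
generators bit-reproducible and pipeline reruns byte-identical.

## Known limitations

- Trace processing is a surrogate: known peak positions (or simple
  local-maxima detection), a single global decay rate, no mobility
  correction.
- Background subtraction supports only a linear per-channel scale
  (default 1); whether real two-dye channels need per-channel scaling
  is instrument-dependent.
- Reactivity differences carry no replicate-variance error model; the
  fixed-threshold rule is faithful to the quantification convention but
  blind to position-specific noise.
- The receptor "extension" segment is a geometric convention (outer
  stem half); real footprints shade into flanking elements in ways a
  secondary-structure model cannot resolve.
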