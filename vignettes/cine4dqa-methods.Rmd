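---
title: "Comparing motion artifacts in cine 4D CT: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing motion artifacts in cine 4D CT: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cine4dqa)
```

## The problem

In cine 4D CT the scanner images one couch position repeatedly over at
least a full breathing cycle, steps to the next position, and the
reconstructed images are retrospectively binned by respiratory phase —
one image per couch position per phase bin, stacked into `B` phase
volumes. Each couch block of a sorted volume therefore comes from a
*different* breathing cycle than its neighbors. When the surrogate phase
is computed correctly, spatially adjacent edge slices across a couch
transition show the anatomy at (nearly) the same respiratory state and
join smoothly. When the respiratory monitor miscalculates phases —
typically by missing or falsely detecting inhalation peaks — the wrong
cine frames are selected and the anatomy jumps at couch transitions:
duplicated, truncated or overlapping structures, most visible around the
dome of the diaphragm.

`cine4dqa` implements an automated, observer-free way to decide which of
two sortings of the *same* acquisition has fewer or smaller such
artifacts, plus everything needed to validate that decision without
patient data.

## The similarity metric

For two axial slices with pixel values $I_A, I_B$ (Hounsfield Units), the
package uses the normalized correlation coefficient

$$C_{A,B} = \frac{\sum_{u,v} I_A(u,v)\, I_B(u,v)}
  {\sqrt{\sum_{i,j} I_A^2(i,j)}\ \sqrt{\sum_{k,l} I_B^2(k,l)}} \in [-1, +1].$$

Two points matter:

* **No mean subtraction.** This is the cosine similarity of the raw HU
  vectors, not the Pearson correlation. Centering would discard the DC
  level that distinguishes, say, a lung-dominated slice from a
  soft-tissue-dominated one, and `ncc()` deliberately does not do it.
* **Numerics.** Accumulation is in double precision regardless of the
  input storage type (integer HU sums overflow 32-bit accumulators at
  512×512), and the final ratio is clamped to $[-1, +1]$ against
  floating-point rounding. Identical nonzero slices give exactly $+1$;
  all-zero slices make the denominator vanish and raise a
  `degenerate_slice` error rather than returning NaN.

## The transition metric

With slices indexed $I(n, s)$ — couch position $n \in [1, N]$, slice
$s \in [1, S]$ within the block — the edge slices at couch transition $n$
are $I(n, S)$ and $I(n+1, 1)$. Their NCC $C_n$ is compared against the
mean of the two intracouch neighbor NCCs, $C_{n,n}$ between $I(n, S-1)$
and $I(n, S)$ and $C_{n,n+1}$ between $I(n+1, 1)$ and $I(n+1, 2)$:

$$D_{b,n} = \tfrac12\left(C_{n,n} + C_{n,n+1}\right) - C_n,
  \qquad n \in [1, N-1].$$

The intracouch pairs were acquired seconds apart within one cycle, so
any similarity loss there is anatomical, not respiratory; the edge pair
spans two cycles and carries the respiratory error on top. $D_{b,n}$
thus isolates (to first order) the respiratory discontinuity. Exactly
one neighbor on each side is used — a wider baseline window is not
offered, because the metric is defined by this local contrast and $S$
can be as small as 2. There is no wrap-around: transitions exist only
between physically adjacent couch blocks.

$D_{b,n}$ is **not** an absolute quality score. A static, abrupt
anatomical boundary (lung apex, liver dome at rest) produces a large
$D_{b,n}$ with no artifact present. The package therefore only ever
scores *differences*:

$$\Delta D_{b,n} = D^{\mathrm{orig}}_{b,n} - D^{\mathrm{recalc}}_{b,n}.$$

Static discontinuities are identical in both sortings of the same cine
acquisition and cancel exactly. Each phase row of $\{\Delta D_{b,n}\}$
is summed and mapped to $+1 / 0 / -1$ by its sign; the overall score is
the mean of the $B$ signs, in $[-1, +1]$, positive when the
"recalculated" (second) set has fewer or smaller artifacts. The scoring
is exactly antisymmetric in its two inputs.

**Zero tolerance.** "The row sum is zero" is exact arithmetic on ideal
data but fragile in floating point. A row sum with magnitude at most
$10^{-12}(N-1)$ is assigned sign 0 (`zero_tol` argument of
`score_residual()`). This preserves the guarantee that comparing a set
against itself scores exactly 0, while being ten orders of magnitude
below any physically meaningful residual.

## Respiratory phase model

Retrospective phase is anchored at inhalation peaks: $0\%$ at every
peak, advancing linearly in time to $100\%$ at the next peak,

$$\phi(t) = 100\,\frac{t - p_i}{p_{i+1} - p_i}, \qquad t \in [p_i, p_{i+1}).$$

Commercial monitoring systems do not publish their phase algorithm;
linear-in-time interpolation between peaks is the canonical
retrospective definition and is used here as a stated convention, not as
a claim about any vendor's implementation. Phase is undefined outside
the peak span — `compute_phase()` either errors or returns `NA` there,
and the sorter never selects a frame with undefined phase.

Peak corruption is the lever that turns correct phases into
miscalculated ones: `edit_peaks()` deletes peaks (merging two cycles
into one double-length cycle, so a true 0% instant becomes 50%) and
inserts spurious ones (splitting a cycle), matching by nearest time
within a 0.2 s default tolerance — a deterministic stand-in for a manual
phase-recalculation review.

## The breathing phantom

The synthetic generator exists so that the whole
miscalculated-vs-recalculated experiment can be recreated with a known
ground truth. It is deliberately minimal: a circular soft-tissue body
(default 150 mm radius, +40 HU) with two elliptical lungs (−750 HU) in
−1000 HU background, and a hemispherical diaphragm dome (+60 HU, 60 mm
radius) rising into the right lung. The dome apex follows

$$z(t) = z_0 - A \sin^{2k}(\pi t / \tau),$$

full exhale at $t = 0$, full inhale ($z_0 - A$) at mid-cycle. Defaults:
amplitude $A = 15$ mm, period $\tau = 4$ s, exponent $2k = 4$ (the
even-power sine gives the long end-exhale dwell of quiet breathing).
The surrogate trace is the apex displacement itself, so its inhalation
peaks coincide with motion extrema by construction; a real external
surrogate (abdominal surface) adds phase lag and drift that are out of
scope here.

Cine acquisition images couch positions sequentially — default
`N = 8` positions × `S = 8` slices of 64×64 px (6 mm pixels, 2.5 mm
slices), 5 s per couch position at 4 frames/s — and `phase_sort()`
assigns each of the 10 bins the frame whose phase is circularly closest
to the bin label, ties to the earlier frame. Gaussian image noise
(default 20 HU, a typical thoracic CT level) flows from one explicit
seed; the entire pair-generation pipeline is bit-reproducible given the
seed. These default sizes keep a full validation pair under a couple of
seconds to generate and score; the test suite runs its Monte-Carlo
properties at this scale (20 seeds for detection/localization, 8 seeds
per corruption level for monotonicity).

Two geometric choices are load-bearing for validation:

* the dome crosses several couch transitions over the breathing cycle,
  so wrong-cycle frame selection produces exactly the edge-slice
  discontinuities the metric targets;
* the lungs end abruptly at `lung_z_max` (default 87.5% of the scan
  span, which falls on a couch transition of the default geometry),
  giving a large *static* $D_{b,n}$ in both sets — the canonical
  confounder that must cancel in $\Delta D$ and does so exactly in the
  noise-free phantom.

What the phantom does **not** emulate: CT physics (no sinogram,
reconstruction, partial-volume or beam-hardening effects), irregular
breathing beyond peak corruption (no amplitude drift, no
cycle-to-cycle variability), in-plane anatomy deformation, and real
surrogate-to-diaphragm coupling. Passing phantom tests therefore shows
that the metric detects and localizes *selection* artifacts under
controlled conditions — not that it handles every artifact morphology of
clinical data.

`make_validation_pair()` deliberately never deletes the first or last
inhalation peak, so the corrupted and true peak sets span the same time
interval and both sortings choose from identical candidate frames; a
zero-corruption pair is then frame-identical and scores exactly 0.

## Observer statistics

Manual scoring mirrors the automated one: per patient, five paired
views are each marked for the set with fewer/smaller artifacts
(+1 recalculated, −1 original, 0 neither) and averaged. Inter-observer
agreement is summarized as complete agreement (same choice), partial
agreement (exactly one observer chose "neither") and complete
disagreement (opposite sets).

The signed-rank tests use Wilcoxon's original convention: zero
differences are discarded before ranking, tied absolute differences get
mid-ranks, and the two-sided p-value is the exact probability
$P(|W^+ - \mu| \ge |w^+ - \mu|)$, $\mu = n(n+1)/4$, over all $2^n$
equally likely sign assignments of the observed rank multiset. The
enumeration is evaluated through its generating function
$\prod_i (1 + x^{2 r_i})$ (ranks doubled so mid-ranks become integers),
which is the same distribution at polynomial cost; the unit tests keep
a literal $2^n$ enumeration and the closed-form no-tie distribution as
independent oracles. The statistical software used for the published
analysis is not documented down to its tie convention; this convention
is adopted because it is the classical exact definition, and the
package reports p at full precision, rounding only for display. Above
$n = 20$ effective observations the test switches to the standard
normal approximation with tie-corrected variance and flags that in its
`method` field.

The per-patient score table and the 50 selection records ship as CSV
fixtures. Only the 3×3 cross-tabulation counts constrain the selection
records; their assignment to patients and views is an arbitrary fixed
expansion, which affects nothing computed from them.

## I/O and interface choices

* Sorted image sets are read from NIfTI (one volume per phase bin) or
  from a text "array-stack" layout (`meta.json` plus one header-less CSV
  per phase, each row one slice flattened row-major) designed to be a
  dependency-free fixture format. DICOM series are recognized but
  rejected with a named error: no DICOM reader is available to this
  package, and guessing vendor-specific couch grouping rules from
  metadata would be worse than refusing.
* All user-facing indices (phase rows, transition columns, `n`, `s`,
  `m`) are 1-based, matching the field's notation; CSV and JSON reports
  use that indexing.
* Numeric CSV output is written with `%.17g`, which round-trips IEEE
  doubles exactly; report read-back is bit-faithful.
* Slices are ordered by ascending scan-axis position; `s = 1` is the
  first slice of a couch block in that ordering. Non-uniform
  slices-per-couch is rejected — the metric's indexing assumes a
  constant `S`.
* The `cine4dqa` command (installed under `exec/`) is a thin wrapper
  over the exported functions; `compare` takes the *original* set first
  and the *recalculated* set second, and a positive printed score
  favors the second argument.

## Known limitations

* The comparison is strictly relative: it ranks two sortings of the
  same acquisition and offers no absolute quality score for a single
  scan (a large $D_{b,n}$ alone cannot distinguish artifact from
  anatomy).
* Full-field NCC: no masking of the couch, table or background is
  applied, matching the metric's definition; an optional mask is not
  implemented.
* The exact-enumeration p-value is conditional on the observed tie
  pattern; different tie-handling conventions (e.g. average of
  attained levels, continuity-corrected approximations) give slightly
  different values for heavily tied data.
* Phantom realism limits are listed above; in particular, sensitivity
  at very low contrast boundaries or high noise has not been
  characterized against human observers.
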