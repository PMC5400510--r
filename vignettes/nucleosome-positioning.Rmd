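---
title: "Dyad-density nucleosome positioning on origin templates: model and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dyad-density nucleosome positioning on origin templates: model and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyadkit)
```

dyadkit measures where nucleosomes sit on a short, defined DNA template —
typically a ~3.8 kb fragment carrying the *S. cerevisiae* replication origin
*ARS1* whose chromatin was assembled in vitro with a chromatin-remodeling
enzyme — from paired-end MNase-seq fragments. This vignette explains the
statistical model, every tunable parameter, what the built-in simulator does
and does not emulate, and the numerical conventions the package commits to.

## The dyad-density model

MNase preferentially digests linker DNA, so a mononucleosome-protected
fragment of ~147 bp is centred near the nucleosome dyad. The pipeline turns a
fragment library into a dyad-density landscape in four steps.

**Size selection.** Only fragments of 125–175 bp (inclusive) are kept. The
closed interval is a deliberate reading of the conventional "125–175 bp"
range; both bounds are arguments to `filter_by_length()`. Shorter fragments
are subnucleosomal (over-digestion, non-histone footprints), longer ones
under-digested dinucleosomal material; either would blur the midpoint-to-dyad
correspondence.

**Midpoint extraction.** Each fragment `[start, end)` (0-based, half-open
throughout the package; SAM's 1-based positions are converted on ingestion)
contributes one midpoint `floor((start + end) / 2)`. Even-length fragments
have no integer centre; flooring is applied uniformly, a deterministic bias
of at most 0.5 bp that is symmetric across a landscape and cannot displace a
peak by more than one base.

**Kernel aggregation.** The track is a kernel density estimate on the
integer grid:

$$d(x) = \sum_{m} \varphi(x;\, m, \sigma), \qquad \sigma = 20\text{ bp},$$

where $\varphi$ is the unit-mass normal density and the sum runs over all
retained midpoints. "20 bp Gaussian kernel" is interpreted as the kernel
*standard deviation* — the most common convention in midpoint-smoothing
analyses — but because FWHM or full-window readings exist, $\sigma$ is the
`bandwidth_bp` argument, not a constant. The kernel is truncated at
`truncation_sd` = 3 standard deviations without renormalization: the mass
loss is below 0.3% (the unnormalized track built from interior midpoints
sums to `n_midpoints` within that margin, which the test suite checks), and
truncation bounds the cost of the discrete convolution used internally. No
reflection or padding is applied at the template edges; kernel mass falling
off the template is simply lost, the simplest contract that never invents
signal. The step size is fixed at 1 bp — on a ~3.8 kb template there is no
reason to coarsen.

**Depth normalization.** "Normalized to read depth" is made concrete as
*signal per million size-selected fragments*: values are multiplied by
$10^6 / n_\text{midpoints}$. The factor is recorded in the track's
`scale_constant`, so any alternative depth convention is a single
multiplicative change away. Normalization is required before peak calling
and refuses to run twice; duplicating every fragment of a library leaves the
normalized track unchanged.

## Consensus peaks and their parameters

A consensus nucleosome position is a local maximum of the normalized track
with height strictly above `threshold` (default 2). Two numerical
conventions make the discrete search deterministic:

* **Plateaus.** A maximal run of equal values flanked by strictly lower
  neighbours counts as one maximum at its central position, taking the
  left-of-centre base when the run has even length. Template edges never
  qualify.
* **Suppression.** Candidate maxima closer together than `min_separation`
  (default 120 bp) are resolved greedily: candidates are visited in
  descending height, ties broken leftmost, and a candidate is dropped when a
  kept peak lies within the separation. 120 bp sits just under the ~147 bp
  of DNA a histone octamer wraps — two genuine dyads cannot be much closer —
  while tolerating modest asymmetry in fuzzy peaks.

The threshold's unit is tied to the per-million normalization above. On a
3.8 kb template at that scale even a flat 10% background sits near
$0.1 \times 10^6 / 3800 \approx 26$ units, so the default threshold of 2
excludes only near-empty regions; it is kept because it is the conventional
default for this analysis, and it is fully configurable. A practical
consequence, visible in simulations: inside a wide nucleosome-free region
(NFR) whose flanks are farther apart than `min_separation`, background noise
can produce a supra-threshold local maximum that is reported as a peak.
Windowed queries around expected positions, or a higher threshold, handle
this; it is a limitation of the threshold convention, not of the caller.

**Cross-condition comparison.** `pair_and_shift()` matches reference and
alternate peak lists one-to-one, closest pairs first (ties toward the
smaller alternate position), within `pairing_window` = 100 bp — half a
nucleosome repeat, so a flank that slides keeps its identity while unrelated
peaks do not pair. Shifts are `alt − ref` in ACS-relative bp: a downstream
flank moving from +222 to +168 is a −54 bp shift toward the origin.
`estimate_spacing()` reports the mean and sample SD of successive inter-peak
distances — a nucleosome-repeat-length estimate and a regularity score.

## Coordinates

`template_coords()` fixes the frame: template length (default 3800 bp), the
absolute 0-based offset of the first ACS nucleotide, and the orientation in
which ACS-relative coordinates increase. Neither the offset nor the ACS
strand is a universal constant of such templates, so both are configuration,
and reverse orientation is supported. The package default (offset 1700,
forward) centres the origin so that both flanks carry full nucleosome
arrays; `to_acs_relative()` / `from_acs_relative()` are exact inverses on
the template.

## What the simulator emulates

`make_landscape_preset()` + `simulate_mnase_library()` generate libraries
with the statistical structure of remodeled origin templates:

* a **landscape** of weighted dyads (ACS-relative), each with Gaussian
  positional fuzz (default sd 10 bp, a typical in-vitro positioning spread);
* **fragment lengths** drawn from Normal(147, 10) rounded and truncated to
  [100, 200] bp: the mean is the canonical nucleosome footprint; the spread
  and bounds are chosen so the 125–175 bp filter is a real filter (it
  retains ~79% of nucleosomal fragments) rather than a no-op;
* a **uniform background** fraction (default 0.1) emulating free-DNA
  digestion products and mis-assembled material, giving thresholding
  something to reject;
* fragments crossing a template edge are **redrawn**, not clipped, so the
  length distribution is preserved near the edges.

The presets encode signature origin-proximal arrangements: `ISW1a` has an
NFR over the origin ([−120, +120] — NFR boundaries are not sharply defined
experimentally, so this is a configurable default spanning the functional
origin elements) with flanks at −200 and +222 and further dyads tiled at
165 bp; `ISW2` has an origin-encroaching dyad at −54 with the downstream
flank pulled in to +168 (its residual NFR is the [+20, +94] linker between
those footprints — the generic NFR would conflict with the −54 dyad);
`irregular` places dyads by seeded random sequential adsorption with a
147 bp exclusion (a remodeler that does not phase arrays); `single_dyad` is
a one-nucleosome fixture with no background, so that "exactly one peak" is a
meaningful end-to-end assertion. The +222 and the −54/+168 positions are the
remodeler signatures the package is anchored to; the −200 upstream ISW1a
flank and the 165 bp tiling have no canonical published value and are
package defaults, exposed as arguments.

Everything is reproducible: one seed drives preset construction (only
`irregular` consumes randomness) and fragment generation, and the caller's
RNG state is restored afterwards.

**What it does not emulate** — and hence what passing tests do not show
about real data: sequence-dependent MNase cut bias (real digests nick
preferentially at AT-rich linkers, skewing midpoints by a few bp), partial
or over-digestion ladders, nucleosome occupancy below 100% with
condition-dependent assembly efficiency, remodeler-specific fuzz differing
between positions, PCR duplicates, and mappability artefacts. Recovery of
planted dyads demonstrates that the estimator is unbiased and precise under
the generative model, not that a 20 bp kernel is optimal for any particular
real library.

## Replicate quantification

`relative_to_reference()` implements percent-of-reference-mean
quantification for densitometry-style replicate tables: the reference
condition's mean intensity is 100% *exactly* (by construction, not by
rounding), every intensity is expressed relative to it, and per-condition
means with sample standard deviations (n − 1, the right choice at n = 3
biological replicates, and the recorded convention where "standard
deviation" alone is ambiguous) are returned. Percentages are invariant
under any common rescaling of the raw units.

## Problem sizes and determinism

The test suite exercises the kernel against a brute-force double-loop KDE
(200 midpoints, agreement within 1e-9), mass conservation at 5000
midpoints, and full-pipeline planted-dyad recovery at 20,000–50,000
fragments; `scripts/acceptance.R` uses 50,000-fragment libraries, a depth
at which the consensus peak recovers each planted origin-proximal dyad
coordinate exactly across seeds. These sizes were chosen as the smallest
that make recovery stable to the base pair; larger libraries change
nothing but runtime. All stochastic steps flow from a single integer seed.

## Known limitations

* The threshold-2 default is near-vacuous under per-million normalization
  on short templates (see above); users comparing against analyses that
  normalized differently should set `threshold` on their own scale.
* Floor-rounding of midpoints and plateau centring can each displace a
  reported position by one base on perfectly symmetric input; sub-base-pair
  positioning is out of scope.
* Edge behaviour (no padding, redraw-on-crossing in the simulator) makes
  the outermost ~100 bp of a template quantitatively untrustworthy.
* The caller is a local-maximum scanner, not a model-based (HMM or
  template-matching) nucleosome caller; overlapping alternative positions
  within one linker are reported as a single consensus.
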