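---
title: "Replication profiling of multi-origin circular chromosomes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Replication profiling: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oriMFA)
```

## The problem

Haloarchaeal chromosomes replicate from several origins of unequal firing
efficiency, and some origins are *dormant*: their sequence architecture (an
inverted pair of origin recognition boxes, ORBs, upstream of a `cdc6`
initiator gene) is intact, yet no replication initiation is detectable
until stronger origins are removed. Marker frequency analysis (MFA)
makes origin activity visible genome-wide: in a replicating population,
loci near active origins are present in more copies than late-replicating
loci, so the ratio of exponential-phase to stationary-phase abundance
forms peaks at origins. `oriMFA` implements the full desk-side version of
this analysis: a population-level forward model and simulators, the MFA
processing chain, an origin peak caller with activation comparison, and a
sequence-based origin predictor.

## The forward model

Consider a circular chromosome of length $L$ carrying origins $o_1, \dots,
o_k$ with firing efficiencies $e_i \in [0,1]$. In each replicating cell a
subset $S$ of origins fires, each origin independently with probability
$e_i$; cells in which no origin fires are not viable replication states,
so the distribution is renormalized over non-empty subsets. Forks move
bidirectionally at constant speed $v$, so the locus at position $x$
replicates at time

$$t_S(x) = \min_{i \in S} \frac{d_{\circ}(x, o_i)}{v},$$

where $d_{\circ}$ is the shortest arc distance. For an exponentially
growing asynchronous culture with doubling time $T$, cell age is
distributed with density $(2\ln 2 / T)\, 2^{-a/T}$ on $[0, T]$, which
gives the classical expected copy number $2^{1 - t_S(x)/T}$ for a locus
replicated at time $t_S(x)$. Mixing replicating cells (fraction $f$, the
*cycling fraction*) with non-replicating cells gives the marker frequency

$$\mathrm{MF}(x) = f \, \mathbb{E}_S\!\left[2^{1 - t_S(x)/T}\right] + (1-f),$$

which lies in $[1, 1+f]$. `expected_marker_frequency()` evaluates the
expectation by exact enumeration over the $\le 2^k - 1$ non-empty subsets
(at most 12 origins); the test suite checks it against an independent
Monte-Carlo population sampler. Multi-round replication is excluded by a
validated precondition: the replication period implied by every reachable
firing configuration (half the largest inter-origin gap of the subset,
divided by $v$) must fit within one doubling time.

### What the model predicts about weak origins

Two structural consequences of this model matter for interpretation.
First, an origin whose efficiency is small relative to the passive copy
number contributed by its neighbours produces only a shallow cusp: the
peak of an origin with $e \approx 0.3$ sitting a megabase from stronger
origins rises merely a few thousandths of a ratio unit above the
passive-replication saddle next to it, even without noise. Second,
passive replication creates saddle points (loci equidistant from two
fired origins) that bound the topographic prominence of weak peaks. Both
follow in closed form from the equation above, and both match the
biological observation that weak-origin peaks are the first to fade when
fewer cells cycle. Under the default noise level, peaks of origins with
efficiency below roughly $M_{\mathrm{passive}} / (2 + M_{\mathrm{passive}})$
(about 0.4 in the default geometry) are at or below the detection limit
of any caller; the package reports prominences so that borderline calls
can be judged against the chosen threshold rather than silently forced.

## Simulators

`simulate_microarray()` emulates a two-channel tiling-array experiment:
the exponential-phase channel measures $\mathrm{MF}(x)$, the
stationary-phase channel a uniform copy number of 1, each multiplied by
log-normal noise $\exp N(0, \sigma)$ per channel. `simulate_reads()`
draws read start positions with density proportional to
$\mathrm{MF}(x)$ (evaluated on a 500-bp grid, effectively exact for a
profile varying on megabase scales). `generate_genome()` builds a random
GC-rich background sequence and plants, at each requested `cdc6` locus, a
gene feature, a delimiter gene bounding a 300-bp upstream intergenic
region, and an inverted ORB pair inside it; the annotation carries the
planted coordinates as ground truth. All simulators are pure functions of
their inputs and seed.

### Default study conditions

The defaults describe the wild-type condition the package is built
around, and are chosen once:

| parameter | default | units | rationale |
|---|---|---|---|
| chromosome length | 2,900,000 | bp | typical haloarchaeal main chromosome |
| origins | 300 kb / 1.3 Mb / 2.2 Mb (+ dormant at 2.7 Mb) | bp | three active origins spread over the circle plus one dormant locus |
| efficiencies | 0.9 / 0.5 / 0.3 (dormant 0) | probability/round | strongly unequal firing, matching the unequal peak heights of real profiles |
| doubling time $T$ | 180 | min | rich-medium growth of a mesophilic haloarchaeon |
| fork speed $v$ | $L / (1.6\,T) \approx 10^4$ | bp/min | the slowest reachable configuration (a lone origin) finishes at $0.8\,T$; ~170 bp/s is a plausible archaeal fork rate |
| cycling fraction $f$ | 0.5 | — | mid-exponential culture; peak amplitude scales with $f$ |
| probe density | 34 | probes/kb | the tiling density of the emulated arrays |
| channel noise $\sigma$ | 0.07 | ln-scale | keeps the outlier-exclusion fraction well below the 0.4% seen on real arrays; a calibration choice, since array noise is not published |

The generator emulates probe-level multiplicative noise, unequal origin
efficiency, passive replication and dormancy. It does **not** emulate
spatial array artifacts, dye bias, GC-coverage bias, replication-fork
stalling or collision, recombination-dependent initiation, or
cell-to-cell fork-speed variation — so green tests here demonstrate
correctness of the analysis chain under the stated model, not robustness
to every artifact of real arrays.

## The MFA processing chain

Processing follows the canonical recipe exactly: per-probe ratios
(exponential over stationary, `compute_ratios()`); exclusion of outlier
probes with ratio strictly above 2 or strictly below 0.5
(`filter_outliers()` — the bounds themselves are retained, the filter is
idempotent, and the excluded fraction is reported); arithmetic averaging
of 30 consecutive retained probes into one point located at the first
probe of the bin (`bin_probes()`); and a centered 5-point moving average
with a 1-point slide (`smooth_profile()`), wrapping across the
coordinate origin on circular chromosomes (linear mode shrinks edge
windows symmetrically instead of padding). Sequencing profiles are
counts of read starts in non-overlapping 1-kb windows
(`window_read_counts()`).

Numerical conventions where the recipe is silent: a final partial bin is
kept when it holds at least half a bin (15 probes) and dropped otherwise,
so no point is ever supported by less than half a bin; the final short
read window is kept with its raw count; averaging operates on plain
ratios (not log ratios), the literal reading of "ratios averaged"; no
normalization is applied beyond the exponential/stationary ratio.
Coordinates are 0-based half-open everywhere internally; GFF3 is
converted at the boundary.

## Peak calling and efficiency estimation

The peaks of a replication profile are megabase-wide, so naive local
maxima on the 5-point track fragment into dozens of noise bumps.
`call_peaks()` therefore:

1. applies an internal detection moving average spanning about half of
   `min_separation` (default 100 kb), capped at a tenth of the profile —
   small test profiles are scanned unsmoothed;
2. finds plateau-aware local maxima on that track and scores each by
   topographic prominence (height minus the higher of the two flanking
   minima, walking each side until a higher point);
3. keeps peaks with prominence at least `min_prominence`. The default
   threshold is 5 times a robust estimate of the detection track's
   amplitude noise, computed from the MAD of the high-pass residual with
   a correction for the input track's autocorrelation length, floored at
   0.1% of the profile range; on profiles scanned without detection
   smoothing it reduces to 5 times the MAD of successive differences.
   With noiseless input the residual vanishes and the threshold drops to
   the floor, so exact profiles are called exactly;
4. greedily enforces `min_separation` (keeping the higher call);
5. refines each position with a broken-stick fit: the profile around the
   apex is regressed on an intercept, a linear (under noise, quadratic)
   background and a kink term $|j - b|$, and the breakpoint $b$ of the
   best peak-shaped fit is reported. A cusp's breakpoint is invariant
   under the symmetric smoothing applied upstream, which makes this
   estimator unbiased where a centroid or parabola vertex is dragged
   toward the shallower flank of an asymmetric peak. The fit bandwidth
   is noise-adaptive: narrow (the detection window) when the measured
   noise is negligible, wide (three times `min_separation`) otherwise —
   the standard bias–variance choice of nonparametric estimation.

Even so, position accuracy is information-limited: for the default
middle origin ($e = 0.5$) the matched-filter bound on the per-simulation
position error is of the order of 5 kb at default noise, and the
$e = 0.3$ origin sits below the detectability threshold discussed above.
The test suite asserts the exact noiseless behaviour and the robust
noisy properties (no more than one spurious call per profile; strong
origins recovered within the 20-kb matching tolerance).

Relative firing efficiency is estimated as peak height above the global
profile minimum, normalized to sum to 1 (`estimate_efficiency()`). A
model-inversion estimator (fitting the forward model to the whole
profile) would be more efficient but is deliberately left out of this
version for testability. `compare_profiles()` matches parent and mutant
peak sets against known origins within `match_tolerance` (default 20 kb,
roughly the positional blur of binning plus smoothing) and labels each
origin `active`, `lost`, `activated` or `unchanged-absent`; swapping
parent and mutant exchanges `lost` and `activated`.
`classify_predicted_origins()` labels sequence-predicted origins
`active` or `dormant` by peak support.

## Sequence-based origin prediction

`predict_origins()` applies, per `cdc6` gene: strand-aware extraction of
the immediately upstream intergenic region (truncated to 2 kb);
an exhaustive mismatch-tolerant repeat search for motifs of 18–35 bp
occurring at least twice on either strand (`find_repeated_motifs()`);
selection of motifs whose consensus carries a G-string; and the
requirement of an inverted pair (at least one instance per strand). The
repeat engine scans every alignment offset of the region against itself
and its reverse complement, extends windows maximally under the mismatch
budget (default 3 mismatches), collapses heavily overlapping windows to
the best one (longest, then fewest mismatches, then leftmost), and
canonicalizes inverted pairs as plus-left/minus-right; the consensus is
the per-column majority with ties to the first instance. For regions up
to ~2 kb this exhaustive search is exact and fast, and the test suite
checks it against a literal all-substring-pairs comparison. An
expectation-maximization motif discoverer would scale better but is
neither needed at these region sizes nor exactly testable.

The "G-string" has no published formal definition; it is implemented as
a run of at least `g_run` (default 4) consecutive G on either strand of
the consensus, exposed in configuration. Conservation of initiator
proteins is assessed with `cdc6_identity()`: global affine-gap alignment
under BLOSUM62 (gap opening 11, extension 1), identity defined as
identical columns over alignment length including gap columns, with
orthology called above a configurable 80% threshold. A local-alignment
identity would use a different denominator, which is why the threshold
is exposed rather than hard-coded.

## Determinism, degenerate inputs, tie-breaks

Every stochastic function takes a seed and restores the caller's RNG
state. Degenerate inputs fail loudly: all-zero efficiencies, positions
off the chromosome, non-positive stationary signals (named by probe),
malformed BED/bedGraph/TSV rows (named by line), empty profiles, even
or too-small smoothing windows, already-smoothed profiles, firing
configurations whose replication period exceeds the doubling time.
Plateau maxima collapse to their middle point; equal-height peak
conflicts within `min_separation` keep the first-sorted call; consensus
ties go to the first instance.

## Problem sizes used by the test suite

Full-scale checks (2.9-Mb chromosome, 98,600 probes) are used where the
study conditions matter: the outlier-exclusion bound (10 replicates),
parameter recovery (20 replicates), the activation comparison, and the
Monte-Carlo oracle (200,000 sampled cells at 20 loci for each of five
origin configurations). Unit tests run on smaller replicons (50–600 kb)
and 300-bp motif regions so that the complete suite finishes in about a
minute.

## Known limitations

* Efficiency estimates are *relative* (normalized peak excess), not
  absolute per-round firing probabilities; inverting the forward model
  would be required for absolute estimates.
* Origins with efficiency below the passive-masking threshold of the
  model (~0.4 in the default geometry) are undetectable at default noise
  by construction; their dormancy calls are reliable, their activity
  calls are not.
* The repeat engine targets intergenic regions (≤ ~2 kb); it is
  quadratic in region length and not meant for whole-genome motif
  discovery.
* Identity is full-length global identity; comparisons with
  local-alignment identities from other tools need the exposed threshold
  adjusted.
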