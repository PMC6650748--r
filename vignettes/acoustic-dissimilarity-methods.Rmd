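---
title: "Methods: acoustic structure and perceived dissimilarity of natural sounds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: acoustic structure and perceived dissimilarity of natural sounds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

How do listeners tell natural sounds apart? Identification and
dissimilarity-rating studies of single sound classes (musical timbres,
speakers, everyday objects) have each implicated spectral envelope,
temporal envelope, spectrotemporal variability and periodicity cues, but a
single-category design cannot say which cues matter *between* classes.
`audissim` implements an analysis pipeline for a cross-category design: a
36-item set spanning vocal sounds (vowels from different speakers),
musical instrument notes, and everyday environmental sounds, all clipped
to their first 250 ms, with instrument pitch yoked to vowel fundamental
frequencies so that F0 is informative only where it naturally varies.

The pipeline has three layers:

1. **Stimuli and features.** A synthetic stimulus generator plus a suite
   of acoustic descriptors; each stimulus is summarized by scalar features
   (median/IQR over analysis frames) and two vector representations (ERB
   cochleagram channel summaries, modulation power spectrum).
2. **Simulated behavior.** Rater and identifier models with known ground
   truth stand in for human data, which are not distributed with the
   package.
3. **Analysis.** Representational similarity analysis (standard and
   semi-partial Kendall tau with permutation nulls and FDR control),
   ordinal MDS by stress majorization, and identification-side analyses
   (chance tests, subcategory recoding, confusion-vs-rating comparison,
   split-half reliability).

## The synthetic stimulus set

The generator reproduces the *conditions* of the design, not the sound of
any particular recording.

* **Vocal sounds** (6 speakers x /a/, /i/): jittered glottal pulse train
  with a one-pole spectral-tilt filter, passed through a two-resonator
  formant cascade (/a/: F1 710, F2 1100 Hz; /i/: F1 280, F2 2250 Hz —
  canonical vowel-space values). Speakers differ by a formant scale
  factor (vocal-tract length), glottal tilt, and a graded aspiration
  level. Each utterance is assigned a target note from the nine-note set
  {G2, A2, Ab2, Bb2, B2, C3, Ab3, Bb3, B3}; its raw F0 is drawn within
  ±0.4 semitone of the target, so the matched note always recovers the
  assignment while raw F0 varies across roughly 97–252 Hz. (Sampling raw
  F0 uniformly over the whole range was considered and rejected: it
  produces matched notes outside the design's note set, which the
  instrument renderings and pairing rule depend on.)
* **Instruments** (12 recipes over five families): additive harmonic
  tones with exponential spectral rolloff (`brightness`), a linear attack
  of 3–110 ms, exponential or sustained decay, and family-graded breath
  noise. Tones are deterministic given their parameters and are rendered
  at all ten pairing notes (the nine vowel notes plus E3, the median of
  the vowel F0 range, used whenever an instrument is paired with
  anything but a vowel).
* **Environmental sounds** (6 excitation media x 2 tokens): Gaver-style
  recipes over a noise excitation — modal-ringing impact bursts, lowpass
  air turbulence, chirping droplets over a liquid bed, gated crackle
  (deformation), amplitude-modulated rattle over a wobbling motor hum
  (mechanical), and band-passed noise under a slow amplitude walk
  (movement). The coherent ring/hum components matter: without them every
  environmental token sits at the aperiodicity ceiling and the set
  becomes categorically separable in a way real recordings are not (see
  *Numerical choices* below).

All clips are synthesized at 44.1 kHz for 300 ms and then standardized
exactly as the design prescribes: onset = first sample whose absolute
amplitude (on a 20 Hz high-passed, zero-phase 4th-order Butterworth copy)
strictly exceeds 10% of that copy's maximum; trim to 250 ms from onset;
5-ms raised-cosine ramps; RMS normalization. The RMS target (0.05 full
scale) is a free constant — every analysis is either level-invariant or
within-set — and ramping precedes normalization so the normalized level
is exact on the output samples.

```{r}
library(audissim)
set <- standardize_set(build_stimulus_set(seed = 1))
features <- feature_table(set)
```

## The descriptor suite

| feature | definition | summary |
|---|---|---|
| log-attack-time | log10 time from 10% to 90% of the RMS envelope maximum (first crossings) | global |
| temporal centroid | center of gravity of the RMS envelope | global |
| spectral centroid | energy-weighted mean of ERB-channel center frequencies, per frame | median, IQR |
| spectral flatness | geometric/arithmetic mean ratio of the channel envelope, per frame | median, IQR |
| spectral variability | 1 − correlation of successive channel spectra | median |
| aperiodicity | depth of the chosen YIN dip | median |
| F0 | YIN fundamental with parabolic interpolation | median, IQR |
| ERB cochleagram | 77 gammatone channels, 30 Hz–16 kHz, envelope framed at 200 Hz | per-channel median + IQR |
| modulation power spectrum | 2-D FFT of a Gaussian-window log spectrogram, top 50 dB | full matrix (dB) |

Implementation notes:

* **Cochleagram.** Center frequencies are ERB-rate spaced
  (Glasberg–Moore, ERB(f) = 24.7(4.37 f/1000 + 1)); each channel is a
  4th-order gammatone magnitude response applied in the frequency domain
  to the analytic spectrum, so the envelope is the magnitude of the
  complex band signal. Channel gains are normalized for equal
  broadband-noise response; this makes the cochleagram flatness of white
  noise behave like FFT spectral flatness (≈0.93 here) instead of being
  depressed by the bandwidth-proportional noise gain of peak-normalized
  filters. A 200 Hz frame rate leaves 50 frames per 250-ms clip.
* **YIN.** 25 ms windows, 5 ms hop, 60–800 Hz search, dip threshold 0.1,
  aggregated over *all* frames (environmental sounds have no voiced
  subset to restrict to). The window spans one full period of the lowest
  search frequency, the mathematical minimum for the difference function.
  Aperiodicity is the cumulative-mean-normalized difference at the chosen
  dip, bounded to [0, 1].
* **Modulation power spectrum.** The spectrogram grid is chosen so the
  modulation Nyquist limits are 47.92 Hz (temporal) and 31.24 cyc/kHz
  (spectral): hop = 1/(2 × 47.92) s and bin spacing = 16.0 Hz, realized
  as nfft = round(sr/16.0) with the axis computed from the realized
  spacing. The Gaussian window's sigma equals the hop (window length
  6 sigma); this resolves 100-Hz harmonic spacing (sigma_f ≈ 15 Hz)
  while keeping frames near-independent. Log magnitudes are clipped to
  the top 50 dB before the 2-D FFT; pairwise distances use the flattened
  power in dB.
* **Degenerate frames.** All-zero frames have no centroid and are
  excluded from summaries; zero-variance frames are skipped in the
  variability sequence; flatness uses a 1e-12 floor per channel.

## Simulated raters and identifiers

The rater model turns weighted, z-scored feature distances into expected
ratings through a logistic squash onto [1, 9]; observed ratings add a
per-participant criterion shift (SD 0.5) and trial noise (SD 2), then
round and clip. Participants alternate between two complementary
630-pair lists (each unordered pair once per list, opposite orders
across lists), rated in random order over three 210-trial blocks.

Default weights put the cochleagram-IQR distance clearly on top (2.0),
with aperiodicity (0.45), spectral variability, cochleagram median,
spectral centroid and the remaining envelope features behind it. Two
design constraints pinned these defaults, and both are worth stating
because they are easy to get wrong:

* *Identifiability.* The spectral-variability family is strongly
  collinear (any aperiodic signal is also spectrally variable), so a
  generating feature can only be recovered as the top standard
  correlation if its weight clearly dominates. The package's recovery
  experiment (20 seeds, 50 raters) verifies the default satisfies this.
* *Non-degeneracy.* If the dominant weight is a near-binary distance
  (e.g., aperiodicity with env tokens all at the ceiling), expected
  ratings become perfectly separable by pair type, and ordinal MDS then
  admits the classic two-cluster zero-stress degenerate solution. A
  continuous dominant distance plus graded environmental aperiodicity
  keeps the rating structure realistically overlapping (3-D stress
  ≈ 0.08 with all axes populated).

The trial-noise SD was set to 2 rating units so the simulated
split-half reliability (~0.98 Spearman–Brown adjusted) sits where human
raters land on this design; raters at that noise still use the full
1–9 scale (both endpoints above 0.5% of responses).

The identifier model scores response j to stimulus i as
−d(i, j)/temperature + self_bias·[i = j] through a softmax, with d the
weighted standardized feature distance scaled to [0, 1]. Small
temperatures give perfect identification; a huge temperature with zero
self-bias gives uniform 1/36 guessing (the chance-calibration check).
Blocks re-sample the instrument note, which is recorded per trial; the
response probabilities themselves are computed from the supplied feature
table (E3 renderings by default) — re-extracting features for all 120
note renderings each run would multiply runtime without changing any
property the analyses test.

What the simulations do *not* emulate: semantic or memory-based
similarity, learning across blocks, response-order effects, and
individual differences beyond a criterion shift. Passing recovery tests
therefore show the *analysis machinery* is sound — they say nothing
about whether human raters weight features this way.

## RSA

For each subset of item pairs (all 630 unordered pairs; within-category
66 each; between-category 144 each) and each applicable feature, the
package computes the standard Kendall tau-b between behavioral
dissimilarities and feature distances, and a semi-partial tau that
residualizes the *predictor's ranks* on the other features' ranks before
correlating — matching the reading "each feature while holding the other
features constant", with rank residualization because the statistic is
rank-ordered. F0 features enter only where F0 was free to vary:
vocal–vocal (median and IQR) and vocal–instrument (IQR).

Inference is one-sided (large positive tau) by permutation of the
behavioral vector: p = (r + 1)/(n + 1) with r the count of null
statistics meeting or exceeding the observed one, n = 10,000 by default.
Each (subset, feature, statistic) cell has its own permutation stream
derived from the master seed. FDR (Benjamini–Hochberg) is applied within
each subset-by-statistic family; applying it across subsets jointly was
the other admissible reading, and within-subset was chosen because each
subset is reported as its own analysis. Ordered-pair mode (1260 cells,
behavioral matrix used asymmetrically) is available; unordered is the
default since acoustic predictors are symmetric and would otherwise be
double-counted.

Kendall tau is computed by an O(n log n) merge-sort implementation in
C++ (with tie corrections); unit tests pin it to an explicit O(n²)
pair-count oracle, and the permutation machinery is calibrated against
its nominal type-I rate (0.04–0.06 at alpha = 0.05 under independence).

## Ordinal MDS

SMACOF stress majorization with monotone (isotonic) regression on the
dissimilarity ranks, primary approach to ties (tie blocks may untie
freely; within blocks, pairs are pre-ordered by current distance).
The diagonal is fixed at the scale minimum (1) before fitting, matching
how identical pairs — never presented — are defined. Initialization is
classical (Torgerson) scaling plus random starts (8 by default, best
final stress kept); the majorized stress sequence is non-increasing by
construction and asserted on every run; tolerance 1e-6 relative change,
at most 1000 iterations. The final configuration is rotated to principal
axes, and axis reflections are resolved by forcing the feature with the
largest |tau| on each axis to correlate positively. Reported stress is
Kruskal's stress-1.

On simulated data the scree shows the familiar elbow and the 3-D axes
recover the expected structure: axis 1 tracks aperiodicity/variability,
axis 2 the spectral envelope, axis 3 the temporal envelope. No numeric
stress value is a target — the matrix depends on simulated raters — so
the scree is checked only for its monotonicity property.

## Identification analyses and reliability

Item accuracy is the per-participant diagonal/row-sum of the confusion
counts; chance comparisons use one-tailed Wilcoxon signed-rank tests
(alternative: greater) against 1/36 (all items) and 1/12
(within-category), FDR over items. `stats::wilcox.test` supplies the
exact distribution for small samples without ties and the
continuity-corrected normal approximation otherwise, which is the
standard convention at these sample sizes. Subcategory recoding marks
any response within the stimulus's vowel / instrument family /
excitation medium as correct, and can only raise accuracy (asserted as
an invariant).

The confusion–rating comparison averages both matrices across their
diagonals (stimulus/response order does not map onto pair order), fixes
the rating diagonal at 1, and reports Kendall tau over the upper
triangle including the diagonal ("full") or excluding the diagonal and
zero-confusion cells ("restricted"). Split-half reliability draws 100
random participant halves, correlates per-half mean ratings per
unordered pair (unordered, so both halves stay covered under the
two-list counterbalancing), adjusts by Spearman–Brown 2r/(1+r), and
averages.

## Numerical choices and limitations

* Problem sizes in the tests and the acceptance script (36 items, 50
  raters, 10,000 permutations for the headline report, 2,000 null
  datasets at 999 permutations for the type-I calibration, 20 recovery
  seeds) were chosen to give stable statistics at desk scale.
* Integer 1–9 ratings cap tau-b against a continuous predictor at about
  0.94 for perfectly noise-free raters (ties claim ~11% of pairs even
  under an ideal uniform 9-level spread); aggregating across raters with
  criterion variability smooths the rounding, which is why the
  recovery check uses multiple raters rather than a single one.
* The stimulus generator is a caricature: two formants, no consonant
  transitions, stylized instruments, six-recipe environmental taxonomy,
  mono only. Its purpose is to realize the category contrasts the
  analyses depend on (periodicity, envelope, variability orderings),
  which it does with margin.
* Nearest-note ties resolve to the lower note; "exceeds" in onset
  detection is a strict inequality — both purely for determinism.
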