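---
title: "Methods: screening TF occupancy on a circular mitochondrial genome"
author: "mitochip"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening TF occupancy on a circular mitochondrial genome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

ChIP-seq libraries for nuclear transcription factors routinely show strong
"enrichment" over the mitochondrial genome (chrM). Most of it is artifact:
the D-loop/control region, with its triple-stranded structure, is
preferentially captured in sequencing libraries and appears enriched in
nearly every dataset, and NUMTs (mitochondrial segments inserted in the
nuclear genome) complicate read mapping. Genuine punctate occupancy has a
specific, testable signature: sonication fragments straddle the bound site,
so plus-strand read 5' ends pile up about half a fragment length upstream
of the site and minus-strand 5' ends the same distance downstream. A
symmetric blob of signal, however strong, is not occupancy.

`mitochip` operationalizes that visual screen as a scored classifier,
computes the supporting tracks (k-mer mappability, strand-specific
coverage, base-resolution 5'-end profiles) on a circular contig, trains a
sequence-to-profile neural model as corroborating evidence, and aggregates
calls across datasets into orthogonal-evidence tiers. Everything is
exercised end to end on synthetic data from the package's own simulator,
so every stage is testable without external downloads.

## Coordinates on a circle

All coordinates are 0-based, half-open, reduced modulo the genome length
`L`. Features spanning the origin are carried canonically as
`(start, width)` with `start < L` (so `end = start + width` may exceed
`L`); on serialization to BED they are split into two lines sharing a
feature name. This convention makes rotation equivariance exactly testable:
rotating reads, masks and the genome by `r` must rotate every track and
every call by `r`, and the test suite asserts this for tracks, mappability
and the full screen.

## The read simulator (what it emulates, and what it does not)

The simulator is the package's stated world:

* **Background**: `background_fraction` of the reads are uniform on the
  circle, on a random strand.
* **Occupancy sites**: a fragment of length `~ Normal(fragment_length_mean,
  fragment_length_sd)` (truncated below at the read length) is centered on
  the site; one end is sequenced, giving a plus-strand read whose 5' end
  sits near `site - f/2` or a minus-strand read with its 5' end near
  `site + f/2`. The plus/minus 5'-end summit separation therefore converges
  to `fragment_length_mean` — the asymmetric signature the screen keys on.
* **Artifact sites**: 5' ends are drawn from one symmetric Gaussian
  (sd = half the mean fragment length) around the site, strand chosen by a
  fair coin — strong but strand-symmetric, like the D-loop.
* **Allocation**: non-background reads are split across sites
  proportionally to their `enrichment` weights. With the default scenario
  (50,000 reads, background 0.5, five 20x occupancy sites and one
  artifact), the realized coverage fold at a site is ~30x over the median
  background, comfortably above the screen's `fold_min = 3`.

Defaults follow the stated data conventions where they exist (36 bp
single-end reads) and field conventions where they do not (fragment length
200 +/- 30 bp; the fragment-length distribution of the real libraries is
never stated). Not modeled, deliberately: sequencing errors, quality
scores, adapters, paired-end fragments, GC bias. A green screen test
therefore establishes that the classifier separates asymmetric from
symmetric enrichment at realistic coverage — not that it is robust to
library-prep pathologies absent from this generator.

All randomness flows from a single integer seed through a save/restore
wrapper around R's RNG, so identical configurations give byte-identical
outputs without disturbing the caller's random stream.

## Mappability

Following the self-mapping construction, the k-mer starting at every
position (k = 36, the read length) is realigned against the contig; a base
is fully mappable iff all k k-mers covering it realign uniquely. Uniqueness
mirrors a `-v 2 -k 2 -m 1 --best --strata` aligner contract: only the best
stratum (minimum mismatches) counts, and exactly one placement may exist
there. Because a k-mer always matches its own origin with zero mismatches,
the best stratum is always the exact stratum, and the rule reduces to "no
second exact occurrence (on either strand)". The mismatch budget is
consequently inert under this semantics — a property worth knowing about
the original construction. A `best_strata = FALSE` switch implements the
stricter reading (any second placement within the mismatch budget discards
the k-mer), under which more allowed mismatches can only shrink the
mappable set; the monotonicity property is tested in that mode, and both
modes are verified base-for-base against a brute-force all-pairs oracle on
small genomes. Reverse-complement placements count toward multiplicity by
default (double-stranded alignment); a switch disables this.

Both circular and linear k-mer enumeration are supported. In linear mode
(the default, matching a linear chrM reference) the first and last k-1
bases can never be covered by k k-mers and are reported unmappable; tests
use circular mode.

## Tracks

`five_prime_track` counts read 5' ends per base and strand (minus-strand
5' end = rightmost aligned base — the convention is not stated anywhere
authoritative, so the standard one is used and documented).
`coverage_track` counts overlapping read bodies with modular wrap. Both
satisfy exact conservation identities (5' totals = read count; coverage
totals = summed read lengths) that the tests assert. Duplicate handling
follows the stated rules: paired-end records are collapsed to one
representative per (position, strand, template length) key, first record
in file order wins; single-end records are all retained, since single-end
duplicate removal cannot be separated from genuine signal at sharp,
high-coverage sites. No MAPQ filtering is applied — unique mapping is an
upstream aligner contract.

## The occupancy screen

1. **Background**: median of total (plus+minus) coverage over mappable,
   unmasked bases — robust to the peaks themselves. Floored at 1 count
   when zero.
2. **Candidates**: maximal circular runs of smoothed total coverage above
   `fold_min x background` (default 3x, 15 bp moving average), runs
   separated by gaps up to `g_max` merged, width >= `w_min` (25 bp) kept.
   `g_max` defaults to 150 bp: a genuine site's plus and minus coverage
   humps are separated by roughly `fragment_length - 2 x read_length`
   (~130 bp for a 200 bp library of 36-mers) of near-background signal, so
   any merge gap smaller than that valley bisects every true site into two
   half-candidates. This is the one place the package deliberately departs
   from a smaller initial default; the threshold remains a reported knob.
3. **Asymmetry**: within each candidate (padded by `max_lag` = 500 bp),
   the smoothed plus 5' profile is correlated with the minus profile
   shifted left by each lag in [0, 500]. `best_lag` is the maximizing lag
   (ties break to the smallest); the score is the correlation gain over
   lag 0. A site with fragment length f gives `best_lag ~ f` and a large
   gain; a symmetric artifact gives `best_lag ~ 0` and no gain.
4. **Classification**: `masked` if the candidate overlaps a configured
   artifact mask (e.g. the D-loop/control region — no authoritative
   coordinates exist, so the mask is a configurable interval list) beyond
   half its width; `occupancy_like` if `best_lag` falls in [50, 400] and
   the score reaches 0.3; `artifact_like` if the profile is
   strand-symmetric (lag below 50 or score below 0.3); otherwise
   `ambiguous` (including candidates with an empty strand, whose
   correlation is undefined). Regions with mappable fraction < 0.5 are
   flagged, not discarded: organellar peaks dwarf nuclear-repeat
   artifacts.

All thresholds are explicit `screen_params()` knobs echoed in every
report; none are inherited from the literature, which screened by eye.

## The sequence-to-profile model

The architecture is the BPNet family: one-hot DNA input (2,114 bp default)
into a trunk of nine zero-padded convolutions with ReLU — a wide first
layer (kernel 21), then kernel-3 layers with dilation doubling per layer
and additive residual skips between successive layers (interpreting
"residual connections between the convolution layers" as per-layer
additive skips). Two heads:

* **Profile head**: a kernel-75 valid convolution to two strands of
  logits. With input 2,114 the head emits 2,040 positions for a 1,000 bp
  output window; the arithmetic implies an unstated crop, resolved here as
  a center crop (standard for this family, and verified by shape tests).
  The cropped logits are stacked with the control profile and passed
  through a size-1 convolution; probabilities come from a single softmax
  over both strands jointly, and the profile loss is the multinomial
  negative log-likelihood `-sum(counts * log p)`.
* **Counts head**: global average pooling, a dense layer, concatenation
  with the control log total, and a final dense layer predicting the log
  of total counts over both strands, trained with squared error. The
  total loss is NLL + `counts_loss_weight` x MSE with weight 1.0 by
  default (the weighting is not stated anywhere; it is a config knob and
  all shipped tests pass at the default). Count targets use `log1p` so
  empty windows stay finite; predicted expected counts are
  `softmax probability x exp(predicted log total)`.

The engine is a self-contained R implementation (im2col convolutions, exact
hand-written backprop, Adam). Analytic gradients are verified against
finite differences in the test suite, and a single-example overfit reaches
the entropy floor of its target — the two checks that matter for a
hand-rolled network.

**Training set**: reproducible peak windows plus GC-matched non-peak
windows at 3:1; outlier peaks above 1.2x the 99th-percentile total count
are removed; fresh jitter up to +/-128 bp per epoch on peak windows;
reverse-complement augmentation (strand-swapped, reversed targets); folds
grouped by contig so no window crosses train/validation/test. The
GC-matching tolerance is unstated; +/-2% is the default knob. Fold models
carry a quality verdict — usable iff held-out profile NLL beats the
analytic uniform baseline `total x log(2 x output_length)` — rather than
silently predicting from an untrainable model.

**Prediction over the circle**: `output_length` tiles around the genome
(the last tile wraps; overlapping bases are averaged), each tile's input
being its centered circular context; every window is predicted as the
average of the forward and reverse-complement passes, which makes the
pipeline exactly RC-equivariant; multiple fold models are averaged.

**Receptive-field arithmetic and the scaled-down world.** The trunk's
receptive field is `21 + sum_l 2 * 2^(l-1)`: 1,041 bp for the 9-layer
default (plus +/-37 from the profile head). The scaled-down test
configuration (4 layers, 16 filters, input 514 / output 250) sees only
about +/-61 bp of sequence per output base. A conventional 200 bp-fragment
library places the strand summits +/-100 bp from the motif — outside that
receptive field, making the sequence-to-profile mapping inexpressible by
construction (a failure mode worth documenting: scaling down the
architecture also scales down the fragment length it can model). The
model-learnability world therefore simulates a short-fragment (80 +/- 10
bp) library, whose summits at +/-40 bp sit inside the receptive field. The
screen tests keep the conventional 200 bp library, which the full-size
configuration handles easily. The scaled-down optimizer settings (batch 4,
learning rate 5e-3, up to 120 epochs, patience 30) reflect the tiny
training set — with ~40 windows, the full-size defaults (batch 64, lr
1e-3) yield too few optimizer steps to move the logits at all.

**Corroboration** is asymmetric by design: an observed occupancy call is
corroborated when its estimated binding position (midpoint of the two
strand summits) lies within `d_max` (100 bp) of a predicted peak (local
maxima of the predicted track strictly above a quantile threshold);
predicted-but-unobserved peaks do not penalize, since these models
routinely predict occupancy at motifs not bound in the assayed context.

## Evidence tiers

Reagent identity is `class + identifier` (antibody catalog id or epitope
tag), optionally lot-sensitive — polyclonal lots can behave as different
reagents, and both behaviors are supported because lot metadata is often
missing. Tiers, computed deterministically and invariant to dataset order:

* `orthogonally_replicated` — concordant occupancy sites (greedy modular
  matching within 100 bp) from >= 2 distinct reagent identities: two
  different antibodies, or an antibody plus endogenous tagging.
* `replicated_same_reagent` — >= 2 concordant peak-bearing datasets, one
  reagent identity.
* `single_dataset` — the only available dataset has peaks.
* `discordant_only` / `no_evidence` — the remaining cases.

A `discordant` flag is set whenever some datasets for a target show peaks
and others show none; it never raises a tier. `model_corroborated` is set
when any peak-bearing dataset's corroboration score reaches 0.5 (a
configurable operationalization of a criterion the source applied
qualitatively). Profile clustering across datasets uses unit-normalized
tracks, correlation distance and average linkage; zero-total tracks are
excluded with a warning, and constant tracks are assigned correlation 0
rather than NA.

## Numerical and degenerate-input choices

* Smoothing is a circular moving average with an odd window.
* Cross-correlation ties break to the smallest lag; an empty strand gives
  an undefined (flagged) asymmetry and an `ambiguous` label.
* An all-zero coverage track yields an empty candidate list with a
  message, not an error; zero background with nonzero peaks floors the
  background at 1 count.
* Softmax is computed with max-subtraction; the NLL gradient is the exact
  `total x p - counts`.
* Predicted-peak thresholds are strict (`>`), so a perfectly flat
  predicted track has no peaks.
* `n_folds = 1` degenerates to train = validate = test on everything (for
  smoke runs only); multi-fold training refuses a single-contig world and
  says so.

## Known limitations

* The screen assumes punctate sites; broad occupancy domains would fail
  the lag window by design.
* The simulator's artifact is a single symmetric Gaussian; real D-loop
  enrichment has structure the classifier never sees in testing.
* The neural engine is pure R: adequate for the scaled-down acceptance
  setting (minutes on one CPU), not for genome-scale training.
* Tier rules are a discrete operationalization of criteria the source
  literature states qualitatively; the thresholds (`d_max`,
  corroboration 0.5) are documented conventions.
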