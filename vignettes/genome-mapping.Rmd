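---
title: "Two-color nanochannel genome mapping: models, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-color nanochannel genome mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanomapr)
```

## The problem

Nanochannel genome mapping images long DNA molecules (BAC clones of roughly
100–220 kb) whose nicking-endonuclease recognition sites have been
fluorescently labeled in two colors: Nt.BspQI (GCTCTTC, green, channel 1)
and Nt.BbvCI (CCTCAGC, red, channel 2). Each imaged molecule yields an
ordered list of label positions; many molecules of the same clone are
clustered and condensed into a consensus map; overlapping consensus maps of
adjacent clones are tiled into a region genome map. Because the map is
sequencing-independent, it can validate a draft sequence assembly: an in
silico motif map of the assembly is aligned to the genome map and
disagreements are classified into extra sequence (wrongly scaffolded
contigs), missing sequence (assembly gaps), interval mismatches (local
misassembly), and high-density label regions (collapsed tandem repeats).

`nanomapr` implements this whole pipeline on simulated data with known
ground truth: in silico digestion, a single-molecule simulator, consensus
construction, ordered-map alignment and tiling, and assembly checking.

## Coordinate and label conventions

All in-memory coordinates are 0-based bp; every on-disk format (BNX-, CMAP-
and XMAP-style text) is 1-based, with the +1/−1 applied exactly once at the
I/O boundary. A label is placed at the first base of a motif occurrence; the
enzyme's actual nick offset within the motif (≤ 7 bp) is far below map
resolution and is ignored. Both strands are scanned — each nickase
recognizes one strand, so occurrences of the motif and of its reverse
complement both produce a visible label. Runs of at least 10 consecutive N
are recorded as scaffold-gap annotations; shorter N runs are treated as
non-matching bases.

Coordinates are *calibrated* bp. Physically a confined molecule stretches to
about 85% of its B-DNA contour length (0.34 nm/bp); that global factor
cancels out of calibrated coordinates and only enters the nm-scale report
(`report_stretch()`). What remains in the data is per-molecule stretch
*variation*, modeled as a multiplicative factor drawn from
Normal(1, `stretch_sd`).

## The generative model

`simulate_molecules()` draws full-length clone molecules (the clones are
Cre-linearized, so fragmentation is not modeled) and applies noise in a
fixed, documented order:

1. each true site is dropped with probability 1 − `label_efficiency`;
2. false labels are added as a Poisson process (`false_label_rate` per
   100 kb per channel), uniform along the molecule;
3. every surviving label is perturbed by Normal(0, `sizing_sd_bp`);
4. a per-molecule scale factor Normal(1, `stretch_sd`) multiplies all
   positions and the length;
5. same-channel labels closer than `optical_resolution_bp` merge; a merged
   group is emitted at the arithmetic mean of its members, and a new group
   opens when a label lies at least one resolution from the current group's
   *first* label. For an isolated close pair this is exactly midpoint
   merging; for a long dense run (a labeled tandem array) it produces spots
   spaced about one resolution apart, which is how an extended run of
   emitters is actually imaged — a single collapsed spot would be wrong;
6. the molecule is reported reverse-oriented with probability
   `flip_probability`.

Defaults: efficiency 0.85, 1 false label per 100 kb, sizing sd 500 bp,
resolution 1000 bp, stretch sd 0.02, flip probability 0.5. The instrument
behind the real data publishes no error rates, so these are declared
assumptions chosen to be typical of nick-label imaging, not fitted values;
the sizing sd and resolution together reproduce the documented ~1.5-kb
same-color resolution limit (see below). Every molecule carries ground
truth (source interval, orientation, per-label provenance), and the whole
simulation is a pure function of its seed.

What the simulator does *not* emulate: chimeric molecules, fragmentation,
sequence-dependent label efficiency, intensity information, and image-level
artifacts. A green test therefore establishes correctness of the analysis
under this idealized noise model, not instrument-level robustness.

## Consensus construction

Molecules are compared pairwise on channel 1 only (the two-color overlay
follows once clusters exist, mirroring how the original analysis clusters
on the green channel and overlays red). Each molecule's channel-1 labels are
rasterized onto a length-normalized axis (bins of `bin_width_bp` = 2 kb on
the pool's median length, Gaussian-smoothed with a one-bin kernel), and the
pair distance is the Euclidean norm of the vector difference, minimized
over the two query orientations. Molecules with no channel-1 labels cannot
be placed and are flagged out rather than erroring.

Average-linkage hierarchical clustering (`stats::hclust`) cuts the tree at
a height chosen by silhouette: candidate cuts between the top merge heights
are scored by mean silhouette width, the finest cut within 0.05 of the best
is kept, and a pool whose best silhouette is under 0.3 stays one cluster.
The originally considered rule (0.6 × median pairwise distance) assumes a
mixed pool where most pairs are between-clone; on a single-clone pool every
distance is within-clone noise and that rule shatters the pool, so it was
replaced. Preferring the finest near-tie cut is deliberate: over-splitting
a clone still yields valid (if redundant) consensus maps, while merging two
clones yields garbage.

Within a cluster, orientations are propagated relative to the cluster's
first molecule, each molecule is mirrored into the common frame if needed
and rescaled to the consensus length (the median molecule length) —
rescaling cancels per-molecule stretch variation exactly, which matters:
without it a 2% stretch sd smears far-end positions by ±3 kb on a 150-kb
clone. Pooled positions are histogrammed (`hist_bin_bp` = 500), candidate
peaks are local maxima whose ±3-bin window is supported by at least
`support_frac` = 0.3 of the molecules, each candidate is fit with a
least-squares Gaussian on its ±3-bin neighborhood (falling back to the raw
moment estimate when the fit is degenerate, e.g. a noiseless spike), and
fitted peaks closer than the optical resolution are merged by
support-weighted averaging.

### Resolving near-resolution doublets

Two same-channel sites ~1.5 kb apart produce a pooled label density that is
*unimodal* under the defaults: molecules that detected both labels
contribute two side modes, but the ~24% of molecules whose labels merged
contribute a narrow midpoint component that fills the valley. No
mode-finding procedure can split that density. The signature that survives
is overdispersion: the single-Gaussian fit has sd well above the instrument
sizing accuracy. Peaks with fitted sd above 1.2 × `label_sd_bp` are
therefore re-fit with the three-component mixture the imaging model itself
implies — sites at μ ± s/2, plus a midpoint component whose weight is the
merge probability given s — by profiling s with a per-molecule likelihood.
The per-molecule form matters twice over: a molecule showing two labels
contributes the *truncated* separation density (pairs survive only when
their apparent separation exceeded the resolution, which skews survivor
separations outward and makes a naive mixture fit overestimate s), and the
one-label/two-label pattern itself is informative. The peak is split only
when the fitted separation reaches the resolution and the doublet model
beats the single-site model by at least 5 log-likelihood units. Measured on
the simulator defaults this resolves 1.25-kb pairs in ≥ 95% of runs and
never splits 0.8-kb pairs, bracketing the documented ~1.5-kb limit.

## Ordered-map alignment

`align_maps()` runs a dynamic program over the position-ordered union of
both channels: matches require equal channels, matches are jointly monotone,
and the score is

    n_match * match_bonus − Σ min(Δ² / (2 (σ² L + σ0²)), outlier_penalty)
                          − miss_penalty · (skipped reference labels)
                          − false_penalty · (skipped query labels)

with Δ the difference of matched flanking interval lengths and L the
reference interval length. The variance-linear-in-length form is the
standard sizing-error model for ordered maps. Two calibration points are
worth recording. First, σ0 reflects *consensus-map* peak accuracy
(2 × 150² bp²), not molecule-level noise; with looser variances a random
monotone chain between two unrelated 30-label maps accumulates positive
score and dovetail alignment becomes unusable. Second, the per-interval
penalty is capped (`outlier_penalty` = 12): a genuine structural
discrepancy — a 3-kb misassembled interval, an 85-kb gap — then costs a
bounded amount and the chain continues through it, leaving a matched flank
pair bracketing the event for the classifier; without the cap the aligner
would break at every structural variant and the two sides would have to be
re-associated heuristically. `fit` mode anchors the whole query inside the
reference (query-end labels penalized, reference ends free); `overlap` mode
is a free-ends dovetail. The `lookback` band (10 labels) bounds the skips
between consecutive matches for speed; setting it to the map size gives the
exact optimum, which the test suite verifies against exhaustive enumeration
of all monotone matchings on small maps.

`merge_consensus()` computes all-pairs dovetails, keeps accepted ones, and
places maps greedily along a maximum-weight spanning tree (best overlap
first), composing offsets and orientations. Redundant edges are checked
against the placement; a disagreeing edge at least as strong as the tree's
edges raises a contradiction error naming the pair, while weaker
disagreements are ignored as the spurious alignments they almost always
are. Clones joined by no accepted overlap start a new segment, and the seam
is recorded as a break — the map-only analogue of adjacent clones sharing
no nick motifs. The global orientation of each segment is arbitrary
(a genome map has no intrinsic left end); consumers compare in the better
of the two frames.

## Assembly checking

`compare_assembly()` fit-aligns each scaffold map to the genome map and
walks consecutive matched pairs. With Δ = query span − reference span and
tol = max(1.5 kb, 3 × pooled peak sd):

* unmatched query labels between flanks and Δ > tol → EXTRA_SEQUENCE;
* unmatched reference labels and −Δ > tol → MISSING_SEQUENCE (the reported
  map-gap distance is the genome-map distance between the flanking matched
  labels, which is how a label-free gap is sized);
* no unmatched labels but |Δ| > tol → INTERVAL_MISMATCH, unless the query
  interval crosses an annotated scaffold gap or contig junction, in which
  case the surplus/deficit is attributed to the junction (EXTRA or MISSING):
  a length-only discrepancy inside one contig is a misassembly, the same
  discrepancy at a junction is a scaffolding error. Junction annotations
  come only from the input (N runs); they are never inferred;
* genome-map segments covered by no accepted alignment and holding at least
  `min_labels` labels → MISSING_SEQUENCE;
* scaffold ends protruding beyond the aligned span → UNALIGNED_END.

A long structural event can be interrupted by a single spurious matched
pair inside it (the outlier cap tolerates such matches), splitting one
event into two adjacent rows; adjacent MISSING rows are re-fused and their
size recomputed over the fused flanks. Completeness is the per-bp aligned
fraction: the union of aligned spans minus discrepant intervals, over the
map length minus user-supplied exclusions. "Aligned" is deliberately per-bp
rather than per-interval; the alternative reading was considered and the
per-bp span is documented as the implemented definition.

`anchor_scaffolds()` fit-aligns each unplaced scaffold against each gap
window (gap ± 20-kb flank); a placement needs an accepted score that beats
the runner-up for that gap by at least 5 score units, two indistinguishable
candidates are both reported ambiguous, and greedy assignment by score
guarantees no gap is filled twice and no scaffold placed twice.

### Tandem-repeat signatures

A tandem array whose unit carries a nick site produces label density beyond
the optical resolution. `detect_label_repeats()` slides a 3-kb window over
the consensus frame with two triggers. The count trigger — mean
per-molecule label count ≥ 1.5 × consensus peak count — catches arrays
whose labels form no discrete peaks. It is, however, defeatable: with exact
repeat units the greedy merge quantizes merged labels onto a half-unit
lattice and the consensus manufactures pseudo-peaks that "explain" the
density. The run trigger therefore also flags windows where ≥ 35% of the
covering molecules carry a run of ≥ 4 labels spaced within twice the
resolution — the per-molecule signature of density at the resolution limit,
visible in the strip diagram of any single molecule regardless of what the
consensus makes of it. Region bounds are refined to the half-plateau
crossings of the dense-run label density, which is unbiased under the
symmetric sizing-noise smear of the edges; a known unit length converts the
region length into an estimated copy number. A genuine cluster of 4+
distinct sites spaced between the resolution and twice the resolution is
indistinguishable from an array by density alone and will flag — that
ambiguity is inherent to the signal, and such calls are reported with their
evidence rather than suppressed.

## The end-to-end scenario

`end2end_demo()` builds a 2.1-Mb region with two planted tandem arrays
(14 and 12 copies of a 670-bp unit with one channel-1 site per unit, the
second array inverted), tiles it with 27 clones (~150 ± 15 kb), simulates
per-clone molecule pools, builds consensus maps, merges the genome map,
digests a corrupted assembly carrying four planted defects (an 8-kb extra
contig, an 85-kb deletion bridged by an N-gap, a 3,063-bp motif-free
interval expansion, and the first array collapsed to a single unit), runs
detection, anchors the deleted segment back from the unplaced pool, applies
the report-driven corrections to the sequence, and recomputes completeness.
Everything is a function of one seed. The synthetic draft aligns better
than a real 454 draft would (before-correction completeness is ~94%, not
~75% — random sequence has no repeat-induced scaffolding noise beyond what
is planted), so the demo asserts the *direction* of improvement, which is
the property that generalizes.

## Numerical choices and degenerate inputs

* Gaussian peak fits fall back to raw-position moments when the ±3-bin
  neighborhood is degenerate (fewer than 3 nonzero bins), so a noiseless
  spike yields its exact position with sd 0.
* Tie-breaking in alignment prefers more matched labels, then smaller
  absolute offset; writers sort stably and format floats fixedly, so equal
  seeds give byte-identical files.
* Empty channels produce empty peak lists, not errors; empty sequences
  produce length-0 maps; molecules with zero channel-1 labels are flagged
  out of clustering with infinite distance.
* The doublet likelihood uses a soft truncation edge (a 100-bp normal CDF
  ramp at the resolution) because consensus-frame rescaling jitters
  apparent separations slightly across the merge threshold; a hard
  indicator makes single molecules veto the correct model.
* All derived seeds stay below 2^31.

## Known limitations

Clustering is quadratic in pool size and the aligner has no seeding index —
both are fine at BAC scale and would need engineering for whole-genome use.
Confidence values on alignments are raw scores, not calibrated
probabilities. The consensus is a single pass (no EM refinement against the
molecules). Repeat copy-number estimates quantize by one unit and inherit
the region-length error. Sequence-level correction in the demo excises
surplus intervals symmetrically around the interval midpoint, which is
adequate at map resolution but would not splice exact junction sequence.
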