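---
title: "Probe design and in situ sequencing decoding for RNA-splinted ligation assays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probe design and in situ sequencing decoding for RNA-splinted ligation assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splintseq)
```

## The assay this package models

Targeted spatial transcriptomics by RNA-splinted ligation works by
hybridizing a barcoded padlock probe directly onto an mRNA so that the
probe's two terminal arms sit adjacent on the target. An RNA-splinted
DNA ligase seals the nick between the arms, circularizing the probe
without any reverse transcription; rolling-circle amplification (RCA)
then turns each circularized probe into a bright clonal DNA punctum
that is read out over multiple rounds of fluorescent in situ
sequencing. Every stage of the computational side of that assay is
implemented here:

1. **Probe design** (`design_probes()` and friends): choosing 25-nt
   target footprints, splitting them into hybridization arms, screening
   specificity and secondary structure, assembling 60-nt oligos.
2. **Barcodes** (`generate_code()`, `decode_barcodes()`): an 8-base
   DNA code with minimum pairwise Hamming distance 3 and the
   corresponding error-correcting decoder.
3. **Image decoding** (`decode_stacks()`): registration, background
   subtraction, spot segmentation and per-round basecalling of
   8-round, 4-channel 3D stacks.
4. **Cells and spatial statistics** (`segment_nuclei()`,
   `assign_amplicons()`, `delaunay_network()`,
   `interaction_enrichment()`, `gene_proximity()`).
5. **Low-plex statistics** (`count_spots()`, `tdr()`, `sensitivity()`,
   `probe_cov()`, `expression_correlation()`).
6. **A seeded synthetic generator** (`make_transcriptome()`,
   `make_field()`, `render_rounds()`, `sim_preset()`) that produces
   every input the other stages consume, with full ground truth.

## Probe architecture and design filters

A multiplexed probe is 60 nt, written 5'→3':

```
[18-nt 5' arm][4-base barcode copy][23-nt anchor][8-base barcode][7-nt 3' arm]
```

The two arms are reverse complements of the two sub-windows of a 25-nt
target footprint; the 18/7 split is the default because it maximizes
amplicon yield at high ligation fidelity in arm-length sweeps from 2 to
22 nt. The 4-base element repeats positions 5–8 of the 8-base barcode
so that short sequencing-by-ligation reads from either direction still
cover those bases. The 23-nt anchor (RCA priming / sequencing anchor)
is a configuration value (`default_anchor()`), not a constant of the
method.

Design proceeds per target transcript:

* **Enumeration.** All 25-mers are candidates except windows containing
  a G or C homotetramer (`GGGG`/`CCCC`), which interfere with synthesis
  and G-quadruplex-prone hybridization. A `legacy_g_filter` restores
  the original G-only behaviour.
* **Junction filter.** The ordered pair of probe bases meeting at the
  ligation nick modulates splint-ligase efficiency. The default table
  (`default_junction_table()`) marks every junction containing G as
  disfavored — TG, CG and GA are the worst performers — and TC, CC, AC
  as favored. We adopt the convention that the junction string is
  (probe 3'-arm terminal base, probe 5'-arm terminal base); because the
  table is an ordinary named vector, the opposite reading costs only a
  user-supplied table.
* **Off-target screen.** `offtarget_screen()` computes the exact
  minimum Hamming distance from the footprint to every 25-nt window of
  every other expressed gene, and requires at least 6 mismatches. The
  expressed reference is built by `filter_reference()`, which removes
  genes with expression baseMean < 10 (strict inequality: a gene at
  exactly 10 is kept). We deliberately use an ungapped all-window scan
  instead of a heuristic gapped aligner: it is exact, conservative, and
  verifiable against an independent alignment oracle, which the test
  suite does on every build. Sense-strand only by default (targets are
  mRNA); `scan_reverse = TRUE` adds the reverse complement.
* **Structure ranking.** `structure_score()` scores intramolecular
  structure of the assembled oligo. The default backend is a
  deterministic Watson–Crick maximum-pairing dynamic program (G:C -3,
  A:T -2 per pair, -1 per stacked pair, minimum hairpin loop 3). We do
  not score G·T wobbles: leaving them out keeps the documented symmetry
  `score(s) == score(revcomp(s))` exact. An external thermodynamic
  folding backend (`backend = "rnafold"`) can be used when the binary
  is on the PATH; scores from different backends are never mixed in one
  ranking. `rank_and_select()` keeps the 10 least-structured probes
  (ties broken by transcript coordinate, which makes the ranking a
  deterministic function of the candidate set).

Short targets (mature miRNAs, 18–23 nt) cannot carry a 25-nt footprint:
the whole target is used, the 3' arm is kept at least 7 nt, and the
split with the best junction class wins over the 18/7 proportion.

Coordinates are 0-based and half-open everywhere.

## Barcodes and error correction

`generate_code(8, 3)` builds a greedy lexicode: all 4^8 = 65,536 words
in lexicographic order (A < C < G < T), keeping a word iff it is at
Hamming distance ≥ 3 from every kept word. The implementation blocks
the radius-2 neighbourhood of each accepted word, which is
algebraically identical to the naive greedy rule but visits far fewer
pairs; the tiny-alphabet tests compare it against the naive rule
directly. The full 8/3 lexicode has 1,024 words — far more than the
173 needed for a 96 mRNA + 77 miRNA panel. Generation is fully
deterministic; a seed only shuffles which gene receives which barcode,
and the gene↔barcode table is always serialized next to results
(`write_barcode_table()`).

The decoder follows the published rule exactly: perfect matches pass;
otherwise the read's Hamming distance to all references is computed,
reads with minimum distance > 2 are discarded, reads whose minimum is
achieved by more than one reference are discarded as ambiguous, and the
rest are corrected to the unique nearest reference (distance 1 or 2).
Because the code's minimum distance is 3, *every* single-substitution
error is corrected to the true reference — the triangle inequality
guarantees it, and the test suite checks all 173 × 24 corruptions
exhaustively.

We re-implemented generation as a plain lexicode rather than porting an
external generator's heuristics: the only stated contract is 8 bases,
distance 3, ≥ 173 codes, and a deterministic dependency-free generator
satisfies it. Our code set is therefore not expected to be identical
to any other generator's, which is why the reference table always
travels with the data. Composition filters (homopolymer exclusion, GC
bounds) exist but are off by default, since the assay specifies none.

## Image decoding

Input is one 4-channel 3D stack per sequencing round, arrays indexed
(z, y, x, channel) with a (z, y, x) voxel size in nm (500-nm z steps
against ~250-nm xy pixels in the emulated acquisition).

* **Registration** (`register_rounds()`): each round's channel-summed
  volume is aligned to the reference round by the integer translation
  maximizing their mean-centred cross-correlation (computed by FFT,
  bounded by `max_shift`). A normalized peak correlation below 0.2
  flags the round as low-confidence. This deliberately replaces
  feature-based non-rigid warping, which is out of scope: for chambered
  cultures and for the rigid synthetic fields the generator produces, a
  global translation is the appropriate model, and planted integer
  shifts are recovered exactly.
* **Background subtraction** (`subtract_background()`): per z-plane
  grey morphological opening with a 5-pixel box, subtracted from the
  image, negatives clamped to zero. Flat regions vanish; puncta
  narrower than the element survive untouched.
* **Composite segmentation** (`segment_amplicons()`): the sum of all
  rounds and channels is upsampled in Z by a shape-preserving
  (Fritsch–Carlson monotone) piecewise cubic — the default factor makes
  voxels isotropic from the voxel-size metadata — then filtered with a
  difference of Gaussians (sigmas 1 and 3 in interpolated voxels),
  thresholded by the global Otsu method, and split by a seeded
  watershed: local maxima of the filtered volume (minimum separation =
  the small sigma) seed the labels and each foreground voxel joins its
  nearest seed. Labels are sampled back onto the original Z grid and
  relabelled contiguously. Seeding from maxima keeps the procedure
  deterministic and matches the punctate character of RCA amplicons.
* **Basecalling** (`basecall_all()`): within each round the four
  channels are quantile-normalized against the mean of their order
  statistics (the standard reference choice), pooling all voxels of the
  volume. Per amplicon and channel, the mean of the top
  `min(30, n_voxels)` normalized intensities is computed and the argmax
  channel called; exact ties keep the first channel in configured order
  and are counted in `n_tied_rounds`. The "top 30" unit is voxels
  (the natural 3D reading). Basecalls are invariant to any monotone
  rescaling of a single channel — a property test squares one channel
  and expects identical barcodes. Concatenated calls are decoded by the
  barcode module.

## Cells and spatial statistics

Nuclei are segmented on the z-projected DAPI image by grey top-hat
filtering, Otsu thresholding and a distance-map watershed; the
structure-tensor energy pre-filter used by some pipelines is available
behind a flag but off by default, because the simpler chain is
deterministic and sufficient for smooth nucleus images. Perinuclear
zones grow from the nuclei by sequential dilation with collisions
resolved to the nearest nucleus, so zones are disjoint and contain
their nuclei by construction.

Amplicons inside a zone are assigned to that cell directly; the rest
are clustered together with the nucleus centroids by affinity
propagation (similarity = negative squared Euclidean distance, damping
0.9, at most 1000 iterations), with the shared preference bisected
until the cluster count equals the nucleus count. Non-convergence
falls back to nearest-zone assignment with a warning. The
cell-by-gene matrix counts only perfectly matched or corrected
amplicons, and `filter_matrix()` applies the detection filters
(expression threshold 1, gene detected in ≥ 5 cells, ≥ 15 detected
genes per cell) genes-first then cells — the order is stated because it
matters at the boundary, and it makes the filter idempotent.

The spatial network is the Delaunay triangulation of cell centroids
(built in-package by Bowyer–Watson with a strict in-circumcircle
predicate, verified against a brute-force empty-circumcircle oracle)
with edges longer than 400 units removed unless that would leave a node
with fewer than 2 neighbours. The 400-unit cutoff is interpreted in
the same units as the centroids (pixels, in this package's outputs).
`interaction_enrichment()` compares observed edge counts per label pair
with their mean over 2000 uniform label permutations and reports
observed/expected ratios, empirical two-sided p-values and the central
95% simulation band. `gene_proximity()` applies the same
permutation-null logic to amplicon pairs within a radius (default 50
px); this is our interpretation of a proximity statistic whose exact
published form lives in supplementary material we do not reproduce, and
it is documented as such.

## Low-plex statistics

`count_spots()` max-projects a stack, removes background with a
rolling-ball-style grey opening (radius 10 for RCA amplicons, 2 for
single-molecule FISH puncta), optionally smooths with a 3×3 box, and
counts local maxima above mean + 3 sd. The detector's threshold rule
is stated explicitly because the original particle-tracker settings are
not published. `tdr()` is M/(M+MM)×100 for a matched probe and its
single-mismatch junction control; `sensitivity()` is the ratio of mean
spots per cell against smFISH in percent; `probe_cov()` uses the
sample (n−1) standard deviation, a convention we state because the
source does not.

## The synthetic generator, and what passing tests mean

`make_transcriptome()` plants 25-nt near-homolog windows at exact
Hamming distances, which is precisely the structure the off-target
screen must resolve (distance 5 fails, distance 6 passes).
`make_field()` and `render_rounds()` emulate the 96-plex experiment at
desk scale: the `96plex-mini` preset is 4 cells × ~60 amplicons in a
32 × 256 × 256 volume over 8 rounds — chosen so the full pipeline runs
in about a minute on one CPU — with log-normal gene abundances over a
96-gene panel, Gaussian point spreads (σ ≈ 1.2 z / 1.5 xy voxels),
per-round global shifts, additive Gaussian noise, and amplicons
separated by ≥ 6 px in XY, reflecting the physical exclusion of
400–800-nm RCA puncta.

The generator is deliberately idealized: no autofluorescence, no
chromatic aberration, no channel bleed-through (available as an
option), no optical sectioning artefacts, rigid motion only. Passing
the end-to-end tests therefore demonstrates that the algorithms are
implemented correctly and are self-consistent — ground truth in, ground
truth out — not that the pipeline meets any particular accuracy on real
microscopy data, whose registration and crowding regimes are harsher.
Headline figures of the real assay that depend on its imaging data
(fractions of perfect versus corrected barcodes, per-gene
sensitivities) are *not* reproduced here for that reason.

## Numerical choices and degenerate inputs

* Ties in ranking and basecalling always break deterministically
  (coordinate order, configured channel order) and are flagged where
  scientifically relevant.
* Empty inputs degrade with warnings, not errors, wherever a
  downstream stage can still proceed (empty foreground, blank nucleus
  image, fewer than 3 centroids); contract violations (zero-voxel
  amplicon, round count ≠ barcode length, undefined TDR) are errors.
* The off-target screen returns `Inf` against an empty non-target
  reference and passes, which is the correct vacuous answer.
* All simulation and permutation functions take explicit seeds and
  save/restore the global RNG state, so library calls never perturb a
  user's session RNG.

## Worked example

A miniature end-to-end run (the README shows the same example with its
printed output):

```{r example, eval = FALSE}
sim <- sim_preset("96plex-mini", seed = 1)
res <- decode_stacks(sim$stacks, sim$code)
decode_table(res$amplicons)$summary

nuc <- segment_nuclei(sim$dapi, tophat_size = 51)
zones <- perinuclear_zones(nuc$labels, n_dilations = 10)
cells <- assign_amplicons(res$amplicons, nuc$cells, zones)
m <- build_count_matrix(cells, res$amplicons, nuc$cells)
```

## Known limitations

* Registration is translational; tissue that deforms between rounds
  needs external non-rigid registration before decoding.
* The segmentation watershed is seeded by local maxima; amplicons
  closer than the DoG scale merge.
* Affinity propagation is O(n²) in memory and time; fields with many
  thousands of unassigned amplicons should rely on larger perinuclear
  zones.
* The structure score is a pairing count with stacking bonus, not a
  thermodynamic free energy; it ranks probes, it does not predict
  melting behaviour.
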