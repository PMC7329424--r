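---
title: "Sketch-based count matrices: model, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sketch-based count matrices: model, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dropsketch)
```

dropsketch computes gene–cell molecule count matrices from droplet
single-cell RNA-seq reads without alignment. This vignette explains the
model behind each stage, the parameters that matter, the numerical
conventions, and the limits of what the synthetic-data tests demonstrate.

## The classification model

The core assumption is that a sequencing read is a contiguous substring of
one transcript (up to substitution errors and strand). Instead of aligning,
we ask: *does the read share enough rare k-mers with some window of a
transcript?*

**Windows and sketches.** A sequence of length $L$ is cut into
$m = \lfloor (L-k)/t \rfloor + 1$ windows of size $w$ placed every $t$
bases, truncated at the sequence end; the union of windows covers the
sequence, and with the default stride $t = w - k + 1$ every k-mer belongs
to exactly one stride bin. Each window is summarized by a minhash sketch:
apply a fixed 64-bit hash $h_1$ to the canonical form of every k-mer in
the window and keep the $s$ smallest distinct values. Sketch overlap is a
locality-sensitive estimate of k-mer-set overlap, so two windows sharing
most of their sequence share most of their sketch.

**Database.** Reference transcripts are sketched once; each feature is
stored in a multi-value table with its (transcript, window) location.
Features occurring at more than `max_locations` locations (repeats,
low-complexity sequence) are deleted outright — deletion rather than
truncation avoids biasing toward whichever locations were inserted first.

**Mapping.** A read is sketched with the *same* windowing parameters —
this symmetry is what makes lookup meaningful. Every feature occurrence in
the read increments a hit counter at every stored location of that
feature. Because the read is assumed contiguous, hits for a true origin
concentrate in a few consecutive reference windows: the mapping score is
the maximum hit sum over any $r$ consecutive windows, so scattered
spurious hits never aggregate. Transcripts scoring at least `threshold`
are candidates; if all candidates belong to one gene the read maps to it
with the maximum candidate score, if they span two or more genes the read
is discarded as ambiguous (no fractional assignment), and with no
candidate it is unmapped.

**Deduplication.** PCR amplifies molecules unevenly, so reads are
collapsed per (cell, gene) by UMI with the directional rule: build an edge
$A \to B$ whenever the UMIs are Hamming distance 1 apart and
$\mathrm{count}(A) \ge f\cdot\mathrm{count}(B) - 1$ (default $f = 2$),
then traverse from the highest-count unvisited UMI outward; each
traversal is one molecule. The asymmetry encodes the error model: a
sequencing-error UMI should be much rarer than the true UMI it derives
from, while two genuinely distinct molecules with similar UMIs and
comparable counts stay separate.

## Parameters

| Parameter | Default | Meaning and rationale |
|---|---|---|
| `k` | 16 | k-mer length (bases). Long enough that random 16-mer collisions are rare (`4^16 ≈ 4·10^9`), short enough to tolerate substitutions. |
| `s` | 16 | sketch size: features kept per window. Larger = more sensitive, bigger database. |
| `w` | `floor((R+k-1)/2)` = 56 for R = 98 | window size (bases). Chosen so a full-length read spans two full windows plus a one-k-mer remainder. |
| `t` | `w-k+1` = 41 | window stride (bases); every k-mer is considered exactly once. |
| `r` | `floor((R-k-1)/t)+2` = 3 | accumulation range (windows): the most reference stride bins the k-mer starts of one contiguously placed read can intersect, so a single alignment's hits are never split. |
| `threshold` | 28 | minimum accumulated score, inclusive. A full-length read offers at most 33 features (16+16+1); 28 is ≈ 85% of that — high enough to suppress spurious assignment, low enough to tolerate a few misses. |
| `max_locations` | 1000 | cap on stored locations per feature; over-cap features are deleted. |
| `whitelist_fraction` | 0.95 | prefix-sum cutoff for barcode whitelisting (see below). |
| `dedup_factor` | 2 | directional occurrence factor $f$. |
| `cb_len`, `umi_len` | 16, 10 | Chromium v2 mate-1 layout. |

### Threshold, inclusivity, and window-aligned guarantees

The candidate rule is inclusive (`score >= threshold`): with a 33-feature
maximum, requiring ≥ 28 keeps the effective stringency at ≈ 85%, in the
region where stringency helps without demanding a near-perfect feature
match.

An exact guarantee exists for *window-aligned* reads: an error-free read
starting on a reference window boundary reproduces two full reference
windows verbatim, so its first two read-window sketches equal the stored
sketches exactly and the score is at least 32 ≥ 28 (at least 30 for the
reverse-complement orientation, where windows shift by one k-mer). Reads
at arbitrary offsets carry no deterministic floor: each read-sketch
feature is only *likely* to also be among the $s$ smallest of its
overlapping reference window, and in clean simulations a small percentage
of reads score just below 28 and go unmapped. This is why the exact
ground-truth recovery tests use the simulator's window-aligned mode, while
the default uniform mode exercises realistic behaviour.

### Whitelist fraction

The prefix rule admits barcodes, sorted by count descending (ties broken
lexicographically so results are order-free), while the inclusive prefix
sum stays strictly below `fraction × total`. Two consequences matter:

* the last-sorted barcode (prefix = total) is never admitted, whatever the
  fraction — in real data the tail is erroneous barcodes, so this is
  harmless, but on error-free synthetic data it always costs one true
  cell, and validation against known cells should pass the true set via
  `whitelist =` / `--use-whitelist`;
* the fraction must sit clearly *below* the fraction of reads carrying an
  error-free barcode. If barcode errors affect a proportion $p$ of reads,
  true barcodes occupy $(1-p)$ of the prefix mass; a fraction above that
  admits low-count erroneous barcodes until the cutoff is reached. At a
  per-base error rate of 0.003 ($p \approx 0.05$) a fraction of 0.90 is
  safe; 0.95 sits on the boundary.

Barcode rescue uses Levenshtein distance ≤ 1 by default (for the
fixed-length 16-mers this coincides with Hamming distance except for
malformed inputs; a substitutions-only `method = "hamming"` is available).
Ambiguous rescue — two whitelist members at distance 1 — is resolved
toward the strictly more frequent member, else the read is discarded.

## Numerical conventions

* $h_1$ is the splitmix64 finalizer applied to the canonical 2-bit k-mer
  code, truncated to the low 53 bits so every feature value is exactly
  representable as an R double; it is fixed, so every sketch, database and
  score in this package is bit-reproducible. The table's bucket hash is
  delegated to the host hash map and never affects results.
* k-mers are canonical (min of forward and reverse-complement encodings):
  cDNA reads can be antisense to their transcript, and canonicalization
  handles both orientations in one pass.
* k-mers containing `N` are skipped, not randomized — determinism.
* Positions and window indices are 0-based half-open throughout; native
  matrix output is 0-based, MatrixMarket 1-based per that standard.
* Degenerate inputs: sequences shorter than $k$ yield one empty window
  and no features; mate-2 reads shorter than $k$ (and mate-1 reads
  shorter than 26 nt) are typed `malformed` discards; empty read sets
  produce an empty matrix over the full gene list.
* Cells are emitted in lexicographic barcode order, a deliberate
  deterministic replacement for thread-dependent output order; batch
  processing (`batches`) is a pure decomposition whose merge is
  associative, and the test suite asserts byte-identical output across
  batch counts.

## What the simulator does and does not show

`simulate_reference()` / `simulate_experiment()` generate a multi-isoform
transcriptome (isoforms share a 60% prefix, exercising same-gene
multi-candidate resolution; optional gene pairs share a verbatim
read-length block, exercising true gene ambiguity), a set of true cell
barcodes with configurable pairwise Hamming separation, per-molecule UMIs,
PCR duplication (`1 + Binomial(pcr_max_dup, pcr_rate)` reads per
molecule), independent substitution error rates for CB, UMI and cDNA, and
strand flips with probability ½. Ground truth (molecule matrix and
per-read provenance) is exact.

Two idealizations are deliberate. Per-(cell, gene) UMIs are drawn with
pairwise Hamming distance ≥ 2, because the directional rule merges two
equal-count UMIs at distance 1 ($1 \ge 2\cdot1-1$) — with truly random
UMIs, occasional collisions make exact truth recovery impossible by
construction, and real data indeed pays a small undercount there. And the
window-aligned start mode exists to make exact recovery provable, as
discussed above. Passing the recovery tests therefore demonstrates
correctness of the machinery — sketching, lookup, scoring, correction,
collapse, output — under the model's assumptions; it does not measure
accuracy on real libraries, which additionally contain empty droplets,
ambient RNA, doublets, indels and quality-dependent errors that the
simulator does not model.

Problem sizes used by the validation suite — 200 random
reference/read instances for the mapping oracle, 1000 random UMI multisets
for the dedup oracle, a 20-gene × 2-isoform, 50-cell, ~20k-read simulation
for recovery — are the package's chosen balance between coverage and a
suite that runs in well under a minute per property.

## Known limitations

* Transcriptome references only; no splice-aware genome indexing.
* Gene-level counts; reads compatible with several genes are discarded
  rather than fractionally assigned, which slightly undercounts genes
  whose sequence is largely shared.
* One whitelisting heuristic (sorted prefix sum) and one UMI scheme
  (directional); no external permit lists, no EM-based cell calling.
* The 53-bit hash truncation doubles the collision probability relative
  to full 64-bit values; at transcriptome scale (~10^7–10^8 stored
  k-mers) collisions remain orders of magnitude below one per sketch.
* In-memory processing: the feature table is a tibble, not an
  out-of-core store; references and read sets are bounded by RAM.
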